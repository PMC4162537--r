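#' One-sided Fisher exact test for a 2x2 table
#'
#' Hypergeometric tail probability of tables at least as extreme as the
#' observed one in the direction of the observed association, computed by
#' full enumeration of the support of the (1,1) cell given the margins.
#' "More extreme" means further from the cell's conditional expectation
#' on the side where it was observed. Probabilities are evaluated from
#' binomial coefficients directly (no distribution shortcut), so the test
#' doubles as an independent reference for the printed confusion table.
#'
#' @param table A 2x2 matrix (or something coercible) of non-negative
#'   integer counts.
#' @return The one-sided p-value; 1 when a margin is zero (the table is
#'   then fully determined by its margins).
#' @examples
#' fisher_exact_one_sided(matrix(c(12, 2, 0, 6), 2))  # 91/125970
#' @export
fisher_exact_one_sided <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stopf("need a 2x2 table")
  if (any(tab < 0)) stopf("negative entries in the table")
  if (any(tab != round(tab))) stopf("table entries must be integers")
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  if (n == 0) stopf("empty table")
  # a zero margin fixes the whole table: the conditional support is a
  # single point, so no association is testable and p = 1 (as fisher.test)
  if (r1 == 0 || r1 == n || c1 == 0 || c1 == n) return(1)
  x_obs <- tab[1L, 1L]
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  # P(X = x) with X the (1,1) cell, margins fixed
  lp <- function(x) {
    lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  }
  probs <- exp(vapply(support, lp, numeric(1L)))
  expected <- r1 * c1 / n
  if (x_obs >= expected) {
    p <- sum(probs[support >= x_obs])
  } else {
    p <- sum(probs[support <= x_obs])
  }
  min(1, p)
}

#' Rank-based AUC of diagnostic scores
#'
#' Probability that a randomly chosen tumor sample scores above a
#' randomly chosen control, ties counted one half — the Mann-Whitney
#' form of the area under the ROC curve.
#'
#' @param scores Numeric vector of continuous scores (higher = more
#'   tumor-like).
#' @param truth Character vector of `"tumor"` / `"control"`.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, truth) {
  pos <- scores[truth == "tumor"]
  neg <- scores[truth == "control"]
  if (length(pos) == 0L || length(neg) == 0L)
    stopf("both classes must be present")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Diagnostic performance metrics from held-out predictions
#'
#' Builds the 2x2 confusion table (prediction x truth) and computes
#' accuracy (percent correct), sensitivity (correctly called tumors /
#' tumors), specificity (correctly called controls / controls), the
#' rank-based AUC of the continuous scores ([auc_rank()]), and the
#' one-sided Fisher exact p of the confusion table
#' ([fisher_exact_one_sided()]). A pre-tabulated confusion matrix may be
#' supplied instead of per-sample vectors (AUC is then unavailable).
#'
#' @param predictions,truth Character vectors of `"tumor"` / `"control"`.
#' @param scores Optional continuous scores aligned with `predictions`.
#' @param confusion Optional 2x2 matrix, rows = prediction
#'   (tumor, control), columns = truth (tumor, control), overriding the
#'   vectors.
#' @param sample_ids Optional ids for the per-sample output table.
#' @return An object of class `DiscriminationResult`: list with
#'   `confusion`, `accuracy` (percent), `n_correct`, `n`, `sensitivity`,
#'   `specificity`, `auc`, `fisher_p`, and `samples` (per-sample table,
#'   when vectors were supplied).
#' @examples
#' # printed confusion table of the 14-tumor / 6-control study
#' classification_metrics(confusion = matrix(c(12, 2, 0, 6), 2))
#' @export
classification_metrics <- function(predictions = NULL, truth = NULL,
                                   scores = NULL, confusion = NULL,
                                   sample_ids = NULL) {
  samples <- NULL
  if (is.null(confusion)) {
    if (is.null(predictions) || is.null(truth))
      stopf("supply either predictions+truth or a confusion table")
    predictions <- as.character(predictions)
    truth <- as.character(truth)
    lv <- c("tumor", "control")
    confusion <- table(factor(predictions, levels = lv),
                       factor(truth, levels = lv))
    confusion <- matrix(as.integer(confusion), 2L, 2L,
                        dimnames = list(prediction = lv, truth = lv))
    samples <- data.frame(sample_id = sample_ids %||% seq_along(truth),
                          truth = truth, prediction = predictions,
                          score = if (is.null(scores)) NA_real_ else scores,
                          stringsAsFactors = FALSE)
  } else {
    confusion <- as.matrix(confusion)
    if (!all(dim(confusion) == c(2L, 2L)))
      stopf("'confusion' must be 2x2")
    if (is.null(dimnames(confusion)))
      dimnames(confusion) <- list(prediction = c("tumor", "control"),
                                  truth = c("tumor", "control"))
  }
  if (any(confusion != round(confusion)) || any(confusion < 0))
    stopf("confusion entries must be non-negative integers")
  storage.mode(confusion) <- "integer"
  n <- sum(confusion)
  if (any(colSums(confusion) == 0)) stopf("a truth class is empty")
  n_correct <- sum(diag(confusion))
  sens <- confusion[1L, 1L] / sum(confusion[, 1L])
  spec <- confusion[2L, 2L] / sum(confusion[, 2L])
  auc <- if (!is.null(scores) && !is.null(truth)) auc_rank(scores, truth)
         else NA_real_
  structure(list(confusion = confusion,
                 accuracy = 100 * n_correct / n,
                 n_correct = n_correct, n = n,
                 sensitivity = sens, specificity = spec,
                 auc = auc,
                 fisher_p = fisher_exact_one_sided(confusion),
                 samples = samples),
            class = "DiscriminationResult")
}

#' @export
print.DiscriminationResult <- function(x, ...) {
  cat("Discrimination result (LOOCV held-out predictions)\n")
  print(x$confusion)
  cat(sprintf("accuracy    %.1f%% (%d/%d)\n", x$accuracy, x$n_correct, x$n))
  cat(sprintf("sensitivity %.3f\nspecificity %.3f\n", x$sensitivity,
              x$specificity))
  if (!is.na(x$auc)) cat(sprintf("AUC         %.3f\n", x$auc))
  cat(sprintf("Fisher p    %.4g (one-sided exact)\n", x$fisher_p))
  invisible(x)
}
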