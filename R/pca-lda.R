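#' Embed miRNAs into two dimensions by PCA
#'
#' Treats each miRNA as an observation in sample space: the rows of the
#' (per-sample z-scored) miRNA x sample matrix are projected onto the
#' first two principal axes of their covariance. Each sample dimension is
#' centered over miRNAs before the decomposition (a near no-op after
#' per-sample standardization, performed anyway for safety). Scores are
#' deterministic up to a per-axis sign; a sign convention (largest
#' absolute loading positive) is applied so repeated runs agree exactly.
#'
#' @param x An `ExpressionMatrix` with `scale = "zscore"`, at least 3
#'   miRNAs and 2 samples, and no missing values.
#' @param n_pc Number of axes (fixed at 2 for the outlier-selection
#'   method; exposed for diagnostics).
#' @return A numeric matrix (miRNA x n_pc) of PC scores, rownames the
#'   miRNA ids, with attribute `sdev` (axis standard deviations). A
#'   rank-1 input (proportional sample columns) yields zero PC2 scores.
#' @export
pca_embed_mirnas <- function(x, n_pc = 2L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "zscore")
    stopf("miRNA embedding expects a per-sample z-scored matrix")
  v <- x$values
  if (anyNA(v)) stopf("missing values not allowed in PCA embedding")
  if (nrow(v) < 3L || ncol(v) < 2L)
    stopf("need at least 3 miRNAs and 2 samples")
  if (ncol(v) < n_pc)
    stopf("need at least %d samples for %d components", n_pc, n_pc)
  centered <- sweep(v, 2L, colMeans(v), "-")
  sv <- svd(centered, nu = 0L)
  # rank-deficient input (e.g. proportional sample columns) is allowed:
  # axes beyond the rank simply carry (numerically) zero scores
  rot <- sv$v[, seq_len(n_pc), drop = FALSE]
  # sign convention: dominant loading of each axis is positive
  for (j in seq_len(n_pc)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- centered %*% rot
  colnames(scores) <- paste0("PC", seq_len(n_pc))
  attr(scores, "sdev") <- sv$d[seq_len(n_pc)] / sqrt(max(1L, nrow(v) - 1L))
  scores
}

#' Select outlier miRNAs far from the PCA origin
#'
#' The unsupervised feature-extraction rule: rank miRNAs by Euclidean
#' distance of their 2-D PC scores from the origin and keep the top `M`.
#' Ties for the last slot are broken by lexicographic miRNA id.
#'
#' @param coords Score matrix from [pca_embed_mirnas()].
#' @param M Number of miRNAs to select.
#' @return A `data.frame` of class `FeatureSelection` with columns
#'   `mirna_id`, `PC1`, `PC2`, `distance`, sorted by decreasing distance.
#' @export
select_outlier_mirnas <- function(coords, M) {
  if (!is_count(M) || M < 1L) stopf("'M' must be a positive integer")
  if (M > nrow(coords))
    stopf("M = %d exceeds the %d available miRNAs", M, nrow(coords))
  d <- sqrt(rowSums(coords^2))
  ord <- order(-d, rownames(coords))
  keep <- ord[seq_len(M)]
  out <- data.frame(mirna_id = rownames(coords)[keep],
                    PC1 = coords[keep, 1L],
                    PC2 = coords[keep, 2L],
                    distance = d[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("FeatureSelection", "data.frame")
  out
}

#' Embed samples on the selected-miRNA submatrix
#'
#' With the matrix restricted to the `M` selected miRNAs, samples become
#' the observations (points in M-dimensional miRNA space); their scores
#' on the first `M_prime` principal axes are the low-dimensional
#' representation handed to the discriminant. The returned object stores
#' the centering vector and rotation so held-out samples can be projected
#' into the same space with [predict()].
#'
#' @param x An `ExpressionMatrix` (z-scored), full miRNA universe.
#' @param selection A `FeatureSelection` (or character vector of miRNA
#'   ids).
#' @param M_prime Number of PC score dimensions to retain.
#' @param samples Optional sample ids to fit on (defaults to all);
#'   held-out samples can be projected later.
#' @return An object of class `sample_embedding` with elements `scores`
#'   (n x M_prime), `rotation`, `center`, `mirna_ids`.
#' @export
pca_embed_samples <- function(x, selection, M_prime = 2L, samples = NULL) {
  ids <- if (inherits(selection, "FeatureSelection")) selection$mirna_id
         else as.character(selection)
  sub <- subset_expression(x, mirnas = ids, samples = samples)
  obs <- t(sub$values)           # samples as observations
  if (anyNA(obs)) stopf("missing values not allowed in sample embedding")
  if (!is_count(M_prime) || M_prime < 1L)
    stopf("'M_prime' must be a positive integer")
  center <- colMeans(obs)
  centered <- sweep(obs, 2L, center, "-")
  sv <- svd(centered, nu = 0L)
  rank <- sum(sv$d > max(dim(centered)) * .Machine$double.eps * max(sv$d[1L], 1e-300))
  if (M_prime > rank)
    stopf("M_prime = %d exceeds the available rank %d", M_prime, rank)
  rot <- sv$v[, seq_len(M_prime), drop = FALSE]
  for (j in seq_len(M_prime)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  scores <- centered %*% rot
  colnames(scores) <- paste0("PC", seq_len(M_prime))
  structure(list(scores = scores, rotation = rot, center = center,
                 mirna_ids = ids),
            class = "sample_embedding")
}

#' @export
predict.sample_embedding <- function(object, x, samples = NULL, ...) {
  sub <- subset_expression(x, mirnas = object$mirna_ids, samples = samples)
  obs <- t(sub$values)
  out <- sweep(obs, 2L, object$center, "-") %*% object$rotation
  colnames(out) <- colnames(object$scores)
  out
}

#' Fisher linear discriminant for two classes
#'
#' Classical LDA: the discriminant direction is
#' `w = S_pooled^{-1} (mean_tumor - mean_control)` with `S_pooled` the
#' pooled within-class covariance; a sample's score is `w . x - c` where
#' the cut-point `c` places the boundary at the midpoint of the projected
#' class means, shifted by the log prior ratio. Positive scores are
#' called tumor. `prior = "proportional"` (default, the convention of
#' standard LDA implementations) weights by training class frequencies;
#' `"equal"` ignores the imbalance. A singular pooled covariance is
#' ridge-regularized (`lambda = 1e-6 * trace/dim`) with a message;
#' identical class means degrade to a majority-class rule with a warning.
#'
#' @param scores Numeric matrix, samples x dimensions. Each class should
#'   have at least 2 samples; a singleton class is tolerated (its
#'   covariance contribution is zero) so that leave-one-out folds of
#'   minimal designs remain fittable.
#' @param labels Character/factor vector of `"tumor"` / `"control"`.
#' @param prior `"proportional"` or `"equal"`.
#' @return An object of class `lda_model`.
#' @export
lda_fit <- function(scores, labels, prior = c("proportional", "equal")) {
  prior <- match.arg(prior)
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stopf("LDA needs exactly 2 classes, got: %s", paste(classes, collapse = ", "))
  if (!setequal(classes, c("tumor", "control")))
    stopf("labels must be 'tumor' and 'control'")
  n1 <- sum(labels == "tumor"); n0 <- sum(labels == "control")
  if (n1 < 1L || n0 < 1L || n1 + n0 < 3L)
    stopf("each class needs samples and at least 3 in total (tumor=%d, control=%d)",
          n1, n0)
  m1 <- colMeans(scores[labels == "tumor", , drop = FALSE])
  m0 <- colMeans(scores[labels == "control", , drop = FALSE])
  d <- ncol(scores)
  # singleton classes contribute no degrees of freedom to the pooled
  # covariance (their weight is zero); LOOCV on a 2-vs-2 design hits this
  class_cov <- function(cls) {
    s <- scores[labels == cls, , drop = FALSE]
    if (nrow(s) < 2L) matrix(0, d, d) else stats::cov(s)
  }
  Sp <- ((n1 - 1) * class_cov("tumor") + (n0 - 1) * class_cov("control")) /
    (n1 + n0 - 2)
  degenerate <- sqrt(sum((m1 - m0)^2)) < 1e-12
  if (degenerate)
    warnf("identical class means: falling back to the majority class")
  w <- tryCatch(solve(Sp, m1 - m0), error = function(e) NULL)
  if (is.null(w)) {
    lambda <- 1e-6 * sum(diag(Sp)) / d
    if (lambda <= 0) lambda <- 1e-6
    message(sprintf("singular pooled covariance: ridge lambda = %.3g", lambda))
    w <- solve(Sp + diag(lambda, d), m1 - m0)
  }
  p1 <- if (prior == "proportional") n1 / (n1 + n0) else 0.5
  cut <- sum(w * (m1 + m0)) / 2 - log(p1 / (1 - p1))
  structure(list(w = w, cut = cut, means = rbind(control = m0, tumor = m1),
                 prior = c(control = 1 - p1, tumor = p1),
                 degenerate = degenerate,
                 majority = if (n1 >= n0) "tumor" else "control"),
            class = "lda_model")
}

#' Score and classify samples with a fitted discriminant
#'
#' @param model An `lda_model` from [lda_fit()].
#' @param scores Numeric matrix (or vector for a single sample) in the
#'   same score space the model was fitted on.
#' @return A `data.frame` with columns `score` (positive favours tumor)
#'   and `label`.
#' @export
lda_score <- function(model, scores) {
  stopifnot(inherits(model, "lda_model"))
  scores <- rbind(as.matrix(scores))
  if (ncol(scores) != length(model$w)) scores <- t(scores)
  s <- as.vector(scores %*% model$w) - model$cut
  if (model$degenerate) {
    lab <- rep(model$majority, length(s))
    s <- rep(0, length(s))
  } else {
    lab <- ifelse(s > 0, "tumor", "control")
  }
  data.frame(score = s, label = lab, row.names = rownames(scores),
             stringsAsFactors = FALSE)
}

#' PCA-based feature extraction + LDA with leave-one-out cross-validation
#'
#' The full diagnostic procedure: (1) miRNAs are embedded in 2-D by PCA
#' of the z-scored expression matrix and the `M` farthest from the origin
#' are selected — an unsupervised step that never sees the labels, so it
#' is computed once on all samples without label leakage; (2) for each
#' held-out sample, the sample embedding (PCA on the M-row submatrix) and
#' the linear discriminant are refit on the remaining n-1 samples, the
#' held-out sample is projected and scored, and its predicted label
#' recorded; (3) held-out predictions are aggregated into a confusion
#' table and diagnostic metrics ([classification_metrics()]).
#'
#' @param x An `ExpressionMatrix`; `scale = "zscore"` required.
#' @param labels A `SampleTable` covering the samples of `x` with labels
#'   `tumor`/`control` (samples labelled `unknown` are refused).
#' @param M Number of outlier miRNAs to select (the study used 11).
#' @param M_prime Number of sample-PC scores fed to the discriminant.
#' @param prior Passed to [lda_fit()].
#' @return A `DiscriminationResult` (see [classification_metrics()]) with
#'   an extra element `selection`, the `FeatureSelection` used.
#' @export
loocv_classify <- function(x, labels, M = 11L, M_prime = 2L,
                           prior = c("proportional", "equal")) {
  prior <- match.arg(prior)
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "zscore")
    stopf("classification expects a per-sample z-scored matrix; see zscore_by_sample()")
  lab <- labels$label[match(colnames(x$values), labels$sample_id)]
  if (anyNA(lab))
    stopf("samples missing from the SampleTable: %s",
          paste(setdiff(colnames(x$values), labels$sample_id), collapse = ", "))
  if (any(lab == "unknown"))
    stopf("samples with label 'unknown' cannot be cross-validated")
  n <- ncol(x$values)
  if (n < 4L) stopf("need at least 4 samples for LOOCV")
  if (length(unique(lab)) != 2L) stopf("both classes must be present")
  coords <- pca_embed_mirnas(x)
  selection <- select_outlier_mirnas(coords, M)
  sams <- colnames(x$values)
  pred <- character(n); sc <- numeric(n)
  for (i in seq_len(n)) {
    train <- sams[-i]
    if (length(unique(lab[-i])) != 2L)
      stopf("fold holding out '%s' loses an entire class", sams[i])
    emb <- pca_embed_samples(x, selection, M_prime = M_prime, samples = train)
    fit <- lda_fit(emb$scores, lab[-i], prior = prior)
    proj <- predict(emb, x, samples = sams[i])
    res <- lda_score(fit, proj)
    pred[i] <- res$label; sc[i] <- res$score
  }
  out <- classification_metrics(predictions = pred, truth = lab, scores = sc,
                                sample_ids = sams)
  out$selection <- selection
  out
}
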