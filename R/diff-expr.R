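#' Wilcoxon rank-sum test with exact enumeration for small samples
#'
#' The statistic is the rank sum of the first group (midranks for ties).
#' For combined sizes up to `exact_limit` with no ties, the exact null
#' distribution is obtained by enumerating all `choose(n, n1)` equally
#' likely rank assignments; otherwise the normal approximation with tie
#' correction and a 0.5 continuity correction toward the null is used.
#' The two-sided p is `min(1, 2 * min(lower tail, upper tail))`.
#'
#' @param x,y Numeric vectors (each non-empty, combined length >= 3).
#' @param alternative `"two_sided"` (default), `"greater"` (x tends
#'   larger), or `"less"`.
#' @param exact_limit Largest combined n for which enumeration is used
#'   (default 14, so any 7-vs-7 or smaller comparison is exact).
#' @return A list with `statistic` (rank sum of `x`), `p`, and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("two_sided", "greater", "less"),
                              exact_limit = 14L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) stopf("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n < 3L) stopf("combined sample size must be >= 3")
  pooled <- c(x, y)
  if (anyNA(pooled)) stopf("missing values in the data")
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  ties <- anyDuplicated(pooled) > 0L
  if (!ties && n <= exact_limit) {
    # enumerate every assignment of n1 ranks out of 1..n
    combos <- utils::combn(n, n1)
    sums <- colSums(matrix(seq_len(n)[combos], nrow = n1))
    total <- ncol(combos)
    p_greater <- sum(sums >= w) / total
    p_less <- sum(sums <= w) / total
    method <- "exact"
  } else {
    mu <- n1 * (n + 1) / 2
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    sigma <- sqrt(sigma2)
    if (sigma == 0) {                       # all values identical
      p_greater <- p_less <- 1
    } else {
      p_greater <- stats::pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
      p_less <- stats::pnorm((w - mu + 0.5) / sigma)
    }
    method <- "normal"
  }
  p <- switch(alternative,
              two_sided = min(1, 2 * min(p_greater, p_less)),
              greater = p_greater,
              less = p_less)
  list(statistic = w, p = p, method = method)
}

#' Per-miRNA two-sided Wilcoxon rank-sum tests, tumor vs control
#'
#' Tests each requested miRNA for a tumor/control expression difference.
#' Raw (unadjusted) p-values are reported by default — the study design
#' this mirrors tested a pre-selected handful of miRNAs — with an
#' optional Benjamini-Hochberg column.
#'
#' @param x An `ExpressionMatrix` (any scale; the rank statistic is
#'   invariant to monotone per-sample transforms such as the log).
#' @param labels A `SampleTable`; samples labelled `unknown` are ignored.
#' @param ids miRNA ids to test (default: all), output preserves this
#'   order.
#' @param alpha Significance level for the flag column.
#' @param adjust If `TRUE`, append a `p_bh` Benjamini-Hochberg column.
#' @param exact_limit Passed to [wilcoxon_rank_sum()].
#' @return A `data.frame`: `mirna_id`, `n_tumor`, `n_control`,
#'   `statistic`, `p_two_sided`, `significant` (+ optional `p_bh`).
#' @export
per_mirna_tests <- function(x, labels, ids = NULL, alpha = 0.05,
                            adjust = FALSE, exact_limit = 14L) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  ids <- ids %||% rownames(x$values)
  missing <- setdiff(ids, rownames(x$values))
  if (length(missing))
    stopf("unknown miRNA id(s): %s", paste(missing, collapse = ", "))
  lab <- labels$label[match(colnames(x$values), labels$sample_id)]
  tum <- which(lab == "tumor"); ctl <- which(lab == "control")
  if (length(tum) == 0L || length(ctl) == 0L)
    stopf("both tumor and control samples are required")
  res <- lapply(ids, function(id) {
    wilcoxon_rank_sum(x$values[id, tum], x$values[id, ctl],
                      exact_limit = exact_limit)
  })
  out <- data.frame(mirna_id = ids,
                    n_tumor = length(tum), n_control = length(ctl),
                    statistic = vapply(res, `[[`, numeric(1L), "statistic"),
                    p_two_sided = vapply(res, `[[`, numeric(1L), "p"),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_two_sided < alpha
  if (adjust) out$p_bh <- stats::p.adjust(out$p_two_sided, method = "BH")
  out
}

#' Boxplot-style group summaries per miRNA
#'
#' Median, quartiles (type-7 quantiles), Tukey whisker bounds (most
#' extreme data point within 1.5 IQR of the nearer quartile) and group
#' size, for each miRNA in each labelled group.
#'
#' @inheritParams per_mirna_tests
#' @return A `data.frame` with one row per miRNA x group.
#' @export
group_summary <- function(x, labels, ids = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  ids <- ids %||% rownames(x$values)
  lab <- labels$label[match(colnames(x$values), labels$sample_id)]
  groups <- list(tumor = which(lab == "tumor"),
                 control = which(lab == "control"))
  rows <- list()
  for (id in ids) {
    for (g in names(groups)) {
      v <- x$values[id, groups[[g]]]
      v <- v[!is.na(v)]
      if (length(v) == 0L) next
      q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
      iqr <- q[3L] - q[1L]
      lo <- min(v[v >= q[1L] - 1.5 * iqr])
      hi <- max(v[v <= q[3L] + 1.5 * iqr])
      rows[[length(rows) + 1L]] <-
        data.frame(mirna_id = id, group = g, n = length(v),
                   median = q[2L], q1 = q[1L], q3 = q[3L],
                   whisker_low = lo, whisker_high = hi,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
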