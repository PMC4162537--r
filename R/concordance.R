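#' Pearson correlation with pairwise missing-value handling
#'
#' Plain Pearson product-moment correlation after dropping pairs with a
#' missing member. Errors (rather than returning `NA`) when fewer than 3
#' complete pairs remain or either vector is constant, so degenerate
#' comparisons surface loudly.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Pearson r in `[-1, 1]`, with attribute `n_used` giving the
#'   number of complete pairs.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y lengths differ")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stopf("fewer than 3 complete pairs (%d)", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("constant vector: correlation undefined")
  r <- stats::cor(x, y)
  attr(r, "n_used") <- length(x)
  r
}

#' Single-sample cross-platform correlation of log expression
#'
#' Pearson correlation between log NGS read counts and log probe-averaged
#' microarray signal for one sample, computed over the positive common
#' miRNA subset of that sample (see [positive_common_subset()]).
#'
#' @param ngs Raw NGS `ExpressionMatrix` (mature-miRNA level).
#' @param array Raw microarray `ExpressionMatrix`, already probe-averaged
#'   to mature-miRNA level.
#' @param sample Sample id present in both matrices.
#' @param cfg A [log_config()].
#' @return Pearson r with attribute `n_used`.
#' @export
platform_correlation <- function(ngs, array, sample, cfg = log_config()) {
  n1 <- subset_expression(ngs, samples = sample)
  a1 <- subset_expression(array, samples = sample)
  sub <- positive_common_subset(n1, a1,
                                rule = if (cfg$pseudocount > 0) "nonnegative" else "positive")
  ln <- log_transform(sub$ngs, cfg)
  la <- log_transform(sub$array, cfg)
  pearson_cor(ln$values[, 1L], la$values[, 1L])
}

#' Cross-platform correlation of differential log expression
#'
#' For a pair of samples, the per-miRNA log difference
#' (`sample_i - sample_j`) is formed on each platform and the two
#' difference vectors are correlated. The subset used is the positive
#' common subset over all four expression vectors, so the same miRNAs
#' enter both differences. The result is invariant to swapping the pair
#' (both axes flip sign) and to per-miRNA offsets shared by both samples.
#'
#' @inheritParams platform_correlation
#' @param pair Character vector of two distinct sample ids.
#' @return Pearson r with attribute `n_used`.
#' @export
differential_correlation <- function(ngs, array, pair, cfg = log_config()) {
  if (length(pair) != 2L || pair[1L] == pair[2L])
    stopf("'pair' must be two distinct sample ids")
  n2 <- subset_expression(ngs, samples = pair)
  a2 <- subset_expression(array, samples = pair)
  sub <- positive_common_subset(n2, a2,
                                rule = if (cfg$pseudocount > 0) "nonnegative" else "positive")
  ln <- log_transform(sub$ngs, cfg)$values
  la <- log_transform(sub$array, cfg)$values
  pearson_cor(ln[, 1L] - ln[, 2L], la[, 1L] - la[, 2L])
}

#' Mean cross-platform differential correlation over all sample pairs
#'
#' Arithmetic mean of [differential_correlation()] over all unordered
#' pairs of the given samples. Pairs whose comparison fails a
#' precondition (e.g. too few usable miRNAs) are skipped and counted.
#'
#' @inheritParams platform_correlation
#' @param samples Character vector of at least 2 sample ids.
#' @return Mean r with attributes `n_pairs` (used) and `n_skipped`.
#' @export
mean_pairwise_differential_correlation <- function(ngs, array, samples,
                                                   cfg = log_config()) {
  samples <- unique(as.character(samples))
  if (length(samples) < 2L) stopf("need at least 2 samples")
  pairs <- utils::combn(sort(samples), 2L, simplify = FALSE)
  rs <- numeric(0)
  skipped <- 0L
  for (p in pairs) {
    r <- tryCatch(differential_correlation(ngs, array, p, cfg),
                  error = function(e) NULL)
    if (is.null(r)) skipped <- skipped + 1L else rs <- c(rs, as.numeric(r))
  }
  if (length(rs) == 0L) stopf("all %d pairs failed preconditions", skipped)
  out <- mean(rs)
  attr(out, "n_pairs") <- length(rs)
  attr(out, "n_skipped") <- skipped
  out
}

#' Pairwise correlation matrix of technical replicates
#'
#' Pearson correlations of log expression between every pair of replicate
#' matrices sharing a miRNA universe. Values that are non-positive in a
#' member of a pair are dropped pairwise. For multi-sample replicate
#' matrices the correlation is computed on the stacked (vectorized) log
#' matrix.
#'
#' @param replicates List of >= 2 raw `ExpressionMatrix` objects over the
#'   same miRNAs and samples.
#' @param cfg A [log_config()].
#' @return A symmetric k x k correlation matrix with unit diagonal.
#' @export
replicate_correlation_matrix <- function(replicates, cfg = log_config()) {
  k <- length(replicates)
  if (k < 2L) stopf("need at least 2 replicates")
  ids <- rownames(replicates[[1L]]$values)
  for (r in replicates[-1L]) {
    if (!identical(rownames(r$values), ids))
      stopf("replicates disagree on the miRNA universe")
  }
  logs <- lapply(replicates, function(r) as.vector(log_transform(r, cfg)$values))
  out <- diag(1, k)
  rownames(out) <- colnames(out) <- names(replicates) %||%
    paste0("rep", seq_len(k))
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      out[i, j] <- out[j, i] <- as.numeric(pearson_cor(logs[[i]], logs[[j]]))
    }
  }
  out
}
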