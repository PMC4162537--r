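#' Log-transform configuration
#'
#' Log base and pseudocount used wherever "logarithmic expression" is
#' computed. Defaults: base 10 (read-count dynamic range spans close to
#' five decades, so decades are the natural unit) and pseudocount 0,
#' meaning non-positive values are excluded (marked `NA`) rather than
#' shifted.
#'
#' @param base Logarithm base, > 1.
#' @param pseudocount Non-negative value added before taking logs.
#' @return A list of class `LogConfig`.
#' @export
log_config <- function(base = 10, pseudocount = 0) {
  if (!is.numeric(base) || base <= 1) stopf("'base' must be > 1")
  if (!is.numeric(pseudocount) || pseudocount < 0)
    stopf("'pseudocount' must be >= 0")
  structure(list(base = base, pseudocount = pseudocount),
            class = "LogConfig")
}

#' Log-transform a raw ExpressionMatrix
#'
#' Entries with `value + pseudocount > 0` become
#' `log_base(value + pseudocount)`; other entries are marked missing
#' (`NA`) and are dropped pairwise by the correlation routines.
#'
#' @param x A raw-scale `ExpressionMatrix`.
#' @param cfg A [log_config()].
#' @return An `ExpressionMatrix` with `scale = "log"`.
#' @export
log_transform <- function(x, cfg = log_config()) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (x$scale != "raw")
    stopf("log_transform expects a raw-scale matrix, got scale=%s", x$scale)
  v <- x$values + cfg$pseudocount
  out <- ifelse(v > 0, log(v, base = cfg$base), NA_real_)
  dimnames(out) <- dimnames(x$values)
  expression_matrix(out, platform = x$platform, scale = "log")
}

#' Standardize each sample column to zero mean and unit sample variance
#'
#' Every sample's expression vector (over miRNAs) is centered and scaled
#' so it has mean 0 and sample variance 1 (n-1 denominator). Missing
#' entries are ignored in the moments and stay missing. The operation is
#' idempotent and invariant to per-sample affine rescaling.
#'
#' @param x An `ExpressionMatrix` with at least two miRNAs.
#' @return An `ExpressionMatrix` with `scale = "zscore"`.
#' @export
zscore_by_sample <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (nrow(x$values) < 2L)
    stopf("need at least 2 miRNAs per sample to standardize")
  mu <- colMeans(x$values, na.rm = TRUE)
  sd <- apply(x$values, 2L, stats::sd, na.rm = TRUE)
  zero <- which(!is.finite(sd) | sd == 0)
  if (length(zero))
    stopf("constant expression in sample(s): %s",
          paste(colnames(x$values)[zero], collapse = ", "))
  out <- sweep(sweep(x$values, 2L, mu, "-"), 2L, sd, "/")
  expression_matrix(out, platform = x$platform, scale = "zscore")
}

#' Average probe-level signals into mature-miRNA rows
#'
#' Implements the microarray summarization step: the value of a mature
#' miRNA in a sample is the arithmetic mean of the signals of all probes
#' assigned to it. Probes absent from the map are dropped with a warning
#' reporting how many were lost.
#'
#' @param x A probe-level microarray `ExpressionMatrix`.
#' @param map A [probe_map()] assigning probes to mature miRNAs.
#' @return A mature-miRNA-level `ExpressionMatrix` (same platform and
#'   scale tags); miRNAs appear in order of first probe occurrence.
#' @export
average_probes_to_mirna <- function(x, map) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(map, "ProbeMap"))
  probes <- rownames(x$values)
  known <- probes %in% map$probe_id
  if (!all(known)) {
    warnf("dropping %d probe(s) absent from the probe map", sum(!known))
  }
  v <- x$values[known, , drop = FALSE]
  if (nrow(v) == 0L) {
    out <- matrix(numeric(0), nrow = 0L, ncol = ncol(x$values),
                  dimnames = list(character(0), colnames(x$values)))
    return(expression_matrix(out, platform = x$platform, scale = x$scale))
  }
  mir <- map$mirna_id[match(rownames(v), map$probe_id)]
  lev <- mir[!duplicated(mir)]
  f <- factor(mir, levels = lev)
  sums <- rowsum(v, f)
  counts <- as.vector(table(f))
  out <- sums / counts
  rownames(out) <- lev
  expression_matrix(out, platform = x$platform, scale = x$scale)
}

#' Restrict two platforms to their usable common miRNAs
#'
#' Returns both matrices restricted to the miRNAs present on both
#' platforms whose values are usable for log correlation in every column
#' passed. The default `rule = "positive"` keeps miRNAs strictly positive
#' on both platforms (a value of 0 has no logarithm); `rule =
#' "nonnegative"` reproduces a literal non-negative reading and is meant
#' to be combined with a positive pseudocount downstream. Rows of both
#' outputs are aligned in lexicographic miRNA order so the result does
#' not depend on input row order.
#'
#' @param ngs,array `ExpressionMatrix` objects (any scale; typically raw).
#' @param rule `"positive"` (default) or `"nonnegative"`.
#' @return A list with elements `ngs` and `array`, row-aligned.
#' @export
positive_common_subset <- function(ngs, array,
                                   rule = c("positive", "nonnegative")) {
  rule <- match.arg(rule)
  stopifnot(inherits(ngs, "ExpressionMatrix"),
            inherits(array, "ExpressionMatrix"))
  common <- intersect(rownames(ngs$values), rownames(array$values))
  if (length(common) == 0L)
    stopf("no miRNAs shared between the two matrices")
  ok <- function(v) {
    if (rule == "positive") all(!is.na(v) & v > 0) else all(!is.na(v) & v >= 0)
  }
  keep <- vapply(common, function(id) {
    ok(ngs$values[id, ]) && ok(array$values[id, ])
  }, logical(1L))
  ids <- sort(common[keep])
  if (length(ids) == 0L)
    stopf("no miRNAs satisfy the %s rule on both platforms", rule)
  list(ngs = subset_expression(ngs, mirnas = ids),
       array = subset_expression(array, mirnas = ids))
}
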