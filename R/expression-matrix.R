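#' ExpressionMatrix: a tagged miRNA-by-sample expression matrix
#'
#' The central container of the package: a numeric matrix with miRNAs as
#' rows and samples as columns, tagged with the measurement platform
#' (`"ngs"` read counts or `"microarray"` processed signals) and the scale
#' the values live on (`"raw"`, `"log"`, or `"zscore"`). Raw NGS matrices
#' must hold non-negative integer counts; log-scale matrices may contain
#' `NA` where the raw value was not positive.
#'
#' @param values Numeric matrix, miRNAs in rows, samples in columns.
#' @param mirna_ids Character vector of unique row identifiers; defaults
#'   to `rownames(values)`.
#' @param sample_ids Character vector of unique column identifiers;
#'   defaults to `colnames(values)`.
#' @param platform `"ngs"` or `"microarray"`.
#' @param scale One of `"raw"`, `"log"`, `"zscore"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `platform`, `scale`.
#' @examples
#' m <- matrix(c(10, 0, 5, 3, 0, 7), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("miR-a", "miR-b", "miR-c"), c("s1", "s2")))
#' expression_matrix(m, platform = "ngs", scale = "raw")
#' @export
expression_matrix <- function(values, mirna_ids = rownames(values),
                              sample_ids = colnames(values),
                              platform = c("ngs", "microarray"),
                              scale = c("raw", "log", "zscore")) {
  platform <- match.arg(platform)
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stopf("'values' must be a numeric matrix")
  # R normalizes character(0) dimnames to NULL, so empty axes are legal
  if (is.null(mirna_ids) && nrow(values) == 0L) mirna_ids <- character(0)
  if (is.null(sample_ids) && ncol(values) == 0L) sample_ids <- character(0)
  if (is.null(mirna_ids) || is.null(sample_ids))
    stopf("miRNA and sample identifiers are required")
  mirna_ids <- as.character(mirna_ids)
  sample_ids <- as.character(sample_ids)
  if (length(mirna_ids) != nrow(values))
    stopf("%d miRNA ids for %d rows", length(mirna_ids), nrow(values))
  if (length(sample_ids) != ncol(values))
    stopf("%d sample ids for %d columns", length(sample_ids), ncol(values))
  if (anyDuplicated(mirna_ids))
    stopf("duplicate miRNA ids: %s",
          paste(unique(mirna_ids[duplicated(mirna_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids))
    stopf("duplicate sample ids: %s",
          paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (scale == "raw") {
    if (anyNA(values))
      stopf("raw-scale matrices must not contain missing values")
    if (platform == "ngs") {
      if (any(values < 0))
        stopf("raw NGS counts must be non-negative")
      if (any(values != round(values)))
        stopf("raw NGS counts must be integers")
    }
  }
  dimnames(values) <- list(mirna_ids, sample_ids)
  structure(list(values = values, platform = platform, scale = scale),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Row (miRNA) and column (sample) identifiers of an ExpressionMatrix
#' @param x An `ExpressionMatrix`.
#' @return Character vector of identifiers, in matrix order.
#' @export
mirna_ids <- function(x) rownames(x$values)

#' @rdname mirna_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d miRNAs x %d samples [platform=%s, scale=%s]\n",
              nrow(x$values), ncol(x$values), x$platform, x$scale))
  n <- min(5L, nrow(x$values))
  k <- min(5L, ncol(x$values))
  print(x$values[seq_len(n), seq_len(k), drop = FALSE])
  if (nrow(x$values) > n) cat(sprintf("... %d more miRNAs\n", nrow(x$values) - n))
  invisible(x)
}

#' Subset an ExpressionMatrix by miRNA and/or sample identifiers
#'
#' @param x An `ExpressionMatrix`.
#' @param mirnas,samples Character vectors of identifiers to keep (in the
#'   requested order); `NULL` keeps everything.
#' @return An `ExpressionMatrix` with the same platform/scale tags.
#' @export
subset_expression <- function(x, mirnas = NULL, samples = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  v <- x$values
  if (!is.null(mirnas)) {
    missing <- setdiff(mirnas, rownames(v))
    if (length(missing))
      stopf("unknown miRNA ids: %s", paste(missing, collapse = ", "))
    v <- v[mirnas, , drop = FALSE]
  }
  if (!is.null(samples)) {
    missing <- setdiff(samples, colnames(v))
    if (length(missing))
      stopf("unknown sample ids: %s", paste(missing, collapse = ", "))
    v <- v[, samples, drop = FALSE]
  }
  expression_matrix(v, platform = x$platform, scale = x$scale)
}

#' SampleTable: per-sample phenotype and platform metadata
#'
#' Holds one row per sequencing/array sample: the diagnostic label
#' (`tumor` for HCC tissue, `control` for matched non-tumorous tissue,
#' `unknown`), a replicate-group identifier shared by technical replicates
#' of the same specimen, and the platforms on which the sample was
#' measured.
#'
#' @param sample_id Character vector of unique sample identifiers.
#' @param label Diagnostic labels; case-insensitive, must fold to
#'   `tumor`, `control`, or `unknown`.
#' @param replicate_group Specimen identifiers shared by technical
#'   replicates. Defaults to `sample_id` (every sample its own specimen).
#' @param platforms Character vector; each entry a `";"`-separated subset
#'   of `ngs`/`microarray` (the words `both` and `neither` are accepted).
#' @return A `data.frame` of class `SampleTable`.
#' @export
sample_table <- function(sample_id, label,
                         replicate_group = sample_id,
                         platforms = "ngs") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stopf("duplicate sample ids: %s",
          paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  label <- tolower(trimws(as.character(label)))
  bad <- setdiff(unique(label), c("tumor", "control", "unknown"))
  if (length(bad))
    stopf("unknown label(s): %s (expected tumor/control/unknown)",
          paste(bad, collapse = ", "))
  replicate_group <- as.character(replicate_group)
  if (any(!nzchar(replicate_group)) || anyNA(replicate_group))
    stopf("every replicate_group must be non-empty")
  platforms <- tolower(trimws(as.character(platforms)))
  platforms[platforms == "both"] <- "ngs;microarray"
  platforms[platforms == "neither"] <- ""
  canon <- function(p) {
    parts <- setdiff(trimws(strsplit(p, "[;,+]")[[1L]]), "")
    bad <- setdiff(parts, c("ngs", "microarray"))
    if (length(bad)) stopf("unknown platform(s): %s", paste(bad, collapse = ", "))
    paste(sort(unique(parts)), collapse = ";")
  }
  platforms <- vapply(platforms, canon, character(1L), USE.NAMES = FALSE)
  out <- data.frame(sample_id = sample_id, label = label,
                    replicate_group = rep_len(replicate_group, length(sample_id)),
                    platforms = rep_len(platforms, length(sample_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("SampleTable", "data.frame")
  out
}

#' ProbeMap: many-to-one microarray probe to mature miRNA assignment
#'
#' @param probe_id Character vector of unique probe identifiers.
#' @param mirna_id Mature miRNA identifier each probe is assigned to.
#' @return A `data.frame` of class `ProbeMap` with columns `probe_id`,
#'   `mirna_id`.
#' @export
probe_map <- function(probe_id, mirna_id) {
  probe_id <- as.character(probe_id)
  mirna_id <- as.character(mirna_id)
  if (length(probe_id) != length(mirna_id))
    stopf("probe_id and mirna_id lengths differ")
  if (anyDuplicated(probe_id))
    stopf("probe(s) mapped more than once: %s",
          paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  out <- data.frame(probe_id = probe_id, mirna_id = mirna_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("ProbeMap", "data.frame")
  out
}
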