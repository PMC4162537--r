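#' Read a miRDeep2-style expression table into an ExpressionMatrix
#'
#' Parses the quantifier output dialect in which each row is one mature
#' miRNA (possibly repeated once per precursor) and read counts live in a
#' `read_count` column. Two layouts are accepted: a single `read_count`
#' column (one sample per file; the sample id defaults to the file name)
#' or several columns named `read_count_<sample>` / `read_count.<sample>`
#' for multi-sample exports. Columns named `precursor`, `total`, or
#' containing `(norm)` are ignored.
#'
#' Because a mature miRNA processed from several precursors appears on
#' several rows, rows sharing a miRNA id are combined: `aggregate = "sum"`
#' (default) adds their counts — read counts are additive evidence for the
#' same mature sequence — while `"first"` keeps the first row only.
#'
#' @param path Path to the delimited table (comma or tab; auto-detected).
#' @param aggregate How to combine duplicate mature-miRNA rows.
#' @param sample_id Sample identifier used for single-column tables;
#'   defaults to the file name without extension.
#' @param delim Optional explicit delimiter overriding auto-detection.
#' @return An `ExpressionMatrix` with `platform = "ngs"`, `scale = "raw"`.
#' @export
read_mirdeep2_counts <- function(path, aggregate = c("sum", "first"),
                                 sample_id = NULL, delim = NULL) {
  aggregate <- match.arg(aggregate)
  df <- read_delim_table(path, delim)
  if (nrow(df) == 0L) stopf("'%s': empty data section", path)
  id_col <- intersect(c("miRNA", "mirna", "mirna_id"), names(df))[1L]
  if (is.na(id_col)) id_col <- names(df)[1L]
  count_cols <- grep("^read_count([._]|$)", names(df), value = TRUE)
  count_cols <- count_cols[!grepl("\\(norm\\)", count_cols)]
  if (length(count_cols) == 0L)
    stopf("'%s': format error, no read_count column", path)
  samples <- sub("^read_count[._]?", "", count_cols)
  if (length(count_cols) == 1L && !nzchar(samples))
    samples <- sample_id %||% tools::file_path_sans_ext(basename(path))
  raw <- as.matrix(df[count_cols])
  if (!is.numeric(raw) || anyNA(raw))
    stopf("'%s': non-numeric read counts", path)
  if (any(raw < 0))
    stopf("'%s': negative read counts", path)
  ids <- as.character(df[[id_col]])
  if (aggregate == "first") {
    keep <- !duplicated(ids)
    raw <- raw[keep, , drop = FALSE]
    ids <- ids[keep]
  } else if (anyDuplicated(ids)) {
    # order-preserving sum over precursors of the same mature id
    first <- !duplicated(ids)
    agg <- rowsum(raw, group = factor(ids, levels = ids[first]))
    raw <- agg
    ids <- ids[first]
  }
  expression_matrix(raw, mirna_ids = ids, sample_ids = samples,
                    platform = "ngs", scale = "raw")
}

#' Read an Agilent-style processed-signal table
#'
#' Accepts a simplified single-table dialect of a feature-extraction
#' export: a header row naming a probe-id column (`ProbeName`, `probe_id`,
#' or the first column) and one `gProcessedSignal` column per sample
#' (either a lone `gProcessedSignal` column, or
#' `gProcessedSignal_<sample>` columns). Full multi-section vendor files
#' are out of scope; extract the data section upstream.
#'
#' @inheritParams read_mirdeep2_counts
#' @return A probe-level `ExpressionMatrix` with `platform = "microarray"`,
#'   `scale = "raw"`.
#' @export
read_agilent_signals <- function(path, sample_id = NULL, delim = NULL) {
  df <- read_delim_table(path, delim)
  if (nrow(df) == 0L) stopf("'%s': format error, empty data section", path)
  id_col <- intersect(c("ProbeName", "probe_id", "probe"), names(df))[1L]
  if (is.na(id_col)) id_col <- names(df)[1L]
  sig_cols <- grep("^gProcessedSignal([._]|$)", names(df), value = TRUE)
  if (length(sig_cols) == 0L)
    stopf("'%s': format error, no gProcessedSignal column", path)
  samples <- sub("^gProcessedSignal[._]?", "", sig_cols)
  if (length(sig_cols) == 1L && !nzchar(samples))
    samples <- sample_id %||% tools::file_path_sans_ext(basename(path))
  probes <- as.character(df[[id_col]])
  if (anyDuplicated(probes))
    stopf("duplicate probe id(s): %s",
          paste(unique(probes[duplicated(probes)]), collapse = ", "))
  sig <- as.matrix(df[sig_cols])
  if (!is.numeric(sig) || anyNA(sig))
    stopf("'%s': non-numeric gProcessedSignal values", path)
  expression_matrix(sig, mirna_ids = probes, sample_ids = samples,
                    platform = "microarray", scale = "raw")
}

#' Read a sample metadata table
#'
#' Expects columns `sample_id`, `label`, `replicate_group`, `platforms`
#' (see [sample_table()] for the accepted values; labels are
#' case-folded).
#'
#' @inheritParams read_mirdeep2_counts
#' @return A validated `SampleTable`.
#' @export
read_sample_table <- function(path, delim = NULL) {
  df <- read_delim_table(path, delim)
  need <- c("sample_id", "label")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stopf("'%s': missing column(s) %s", path, paste(missing, collapse = ", "))
  sample_table(df$sample_id, df$label,
               replicate_group = df$replicate_group %||% df$sample_id,
               platforms = df$platforms %||% "ngs")
}

#' Read a probe-to-miRNA map
#'
#' @inheritParams read_mirdeep2_counts
#' @return A `ProbeMap`.
#' @export
read_probe_map <- function(path, delim = NULL) {
  df <- read_delim_table(path, delim)
  missing <- setdiff(c("probe_id", "mirna_id"), names(df))
  if (length(missing))
    stopf("'%s': missing column(s) %s", path, paste(missing, collapse = ", "))
  probe_map(df$probe_id, df$mirna_id)
}

#' Write / read the canonical expression TSV
#'
#' The canonical on-disk form is a tab-separated table preceded by a
#' two-line comment header recording the platform and scale tags:
#' \preformatted{# platform: ngs
#' # scale: raw
#' mirna_id<TAB>s1<TAB>s2...}
#' Values are written with 15 significant digits so a write/read
#' round-trip is the identity to floating-point text precision.
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output (or input) file path.
#' @return `write_expression_matrix()` returns `path` invisibly;
#'   `read_expression_matrix()` returns an `ExpressionMatrix`.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(sprintf("# platform: %s", x$platform),
               sprintf("# scale: %s", x$scale)), con)
  df <- data.frame(mirna_id = rownames(x$values),
                   format(x$values, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  header <- readLines(path, n = 2L, warn = FALSE)
  get_tag <- function(tag) {
    line <- grep(sprintf("^# %s:", tag), header, value = TRUE)
    if (length(line) != 1L)
      stopf("'%s': missing '# %s:' header line", path, tag)
    trimws(sub(sprintf("^# %s:", tag), "", line))
  }
  platform <- get_tag("platform")
  scale <- get_tag("scale")
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 2L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[-1L])
  expression_matrix(m, mirna_ids = df[[1L]], sample_ids = colnames(m),
                    platform = platform, scale = scale)
}

#' Write a SampleTable or ProbeMap as TSV
#' @param x The table to write.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
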