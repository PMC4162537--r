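`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x == round(x)
}

#' Detect the field delimiter of a delimited text file
#'
#' Chooses between tab and comma by inspecting the first non-empty,
#' non-comment line. A tab anywhere in that line wins (Agilent and
#' miRDeep2 exports are tab-delimited even when named `.csv`).
#'
#' @param path Path to a delimited text file.
#' @return A single character, `"\t"` or `","`.
#' @keywords internal
detect_delim <- function(path) {
  lines <- readLines(path, n = 25L, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stopf("'%s': no data lines found", path)
  if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
}

read_delim_table <- function(path, delim = NULL) {
  delim <- delim %||% detect_delim(path)
  df <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df) <- sub("^#", "", names(df))
  df
}

# seeds derived for sub-generators stay below 2^31
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 101 + as.numeric(offset)) %% 2147483647
}
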