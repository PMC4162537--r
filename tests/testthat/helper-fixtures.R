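# fixtures are built in code at test time; nothing is read from disk
# except temp files written here.

make_expr <- function(values, mirnas = NULL, samples = NULL,
                      platform = "ngs", scale = "raw") {
  if (!is.matrix(values)) values <- as.matrix(values)
  mirnas <- mirnas %||% sprintf("miR-%02d", seq_len(nrow(values)))
  samples <- samples %||% sprintf("s%d", seq_len(ncol(values)))
  expression_matrix(values, mirnas, samples, platform = platform,
                    scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_mirdeep2_fixture <- function(path = tempfile(fileext = ".csv"),
                                   dup_mature = FALSE) {
  lines <- c("#miRNA\tread_count_s1\tread_count_s2\tprecursor",
             "miR-a\t10\t0\tpre-a",
             "miR-b\t5\t3\tpre-b",
             "miR-c\t0\t7\tpre-c")
  if (dup_mature)
    lines <- c(lines, "miR-b\t4\t6\tpre-b2")
  writeLines(lines, path)
  path
}

write_agilent_fixture <- function(path = tempfile(fileext = ".txt"),
                                  duplicate_probe = FALSE, empty = FALSE) {
  header <- "ProbeName\tgProcessedSignal"
  rows <- c("p1\t2.0", "p2\t4.0", "p3\t1.5", "p4\t8.25")
  if (duplicate_probe) rows <- c(rows, "p2\t9.0")
  if (empty) rows <- character(0)
  writeLines(c(header, rows), path)
  path
}

write_sample_fixture <- function(path = tempfile(fileext = ".tsv"),
                                 n_tumor = 14, n_control = 6,
                                 dup = FALSE) {
  ids <- c(sprintf("T%02d", seq_len(n_tumor)),
           sprintf("N%02d", seq_len(n_control)))
  if (dup) ids[2] <- ids[1]
  df <- data.frame(sample_id = ids,
                   label = rep(c("Tumor", "control"), c(n_tumor, n_control)),
                   replicate_group = ids,
                   platforms = "ngs")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# small, fully deterministic z-scored matrix with planted features
# (alternating-sign shift) separating two sample clusters; used by the
# classifier unit tests
make_separable_zscore <- function(n_mirna = 60, n_tumor = 8, n_control = 4,
                                  shift = 4, n_planted = 4, seed = 99) {
  set.seed(seed)
  n <- n_tumor + n_control
  v <- matrix(rnorm(n_mirna * n), n_mirna, n)
  for (j in seq_len(n_planted))
    v[j, seq_len(n_tumor)] <- v[j, seq_len(n_tumor)] + shift * (-1)^j
  dimnames(v) <- list(sprintf("miR-%02d", seq_len(n_mirna)),
                      c(sprintf("T%02d", seq_len(n_tumor)),
                        sprintf("N%02d", seq_len(n_control))))
  z <- zscore_by_sample(make_expr(v, mirnas = rownames(v),
                                  samples = colnames(v),
                                  platform = "microarray", scale = "raw"))
  st <- sample_table(colnames(v),
                     rep(c("tumor", "control"), c(n_tumor, n_control)))
  list(z = z, samples = st)
}
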