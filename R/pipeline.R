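#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> normalize -> concordance ->
#' classify -> difftest (-> filter-novel when calls are supplied) and
#' writes every stage's table plus a run manifest (configuration hash,
#' seed, package version) under `outdir`. Driven either by a flat
#' key-value config file (`key: value` lines, `#` comments) or by an R
#' list with the same keys.
#'
#' Recognized keys: `counts`, `signals`, `probe_map`, `samples`,
#' `candidate_calls` (paths; all optional — missing inputs are
#' simulated), `seed`, `M`, `M_prime`, `log_base`, `pseudocount`,
#' `min_probability`, `min_samples`, and any `sim_*`-prefixed
#' [generator_config()] field (e.g. `sim_n_mirna: 500`).
#'
#' @param config Path to a key-value config file, or a named list.
#' @param outdir Output directory (created if needed).
#' @param seed Integer seed overriding the config's.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = list(), outdir = "mirnadx-out",
                         seed = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) read_keyvalue_config(config) else config
  stopifnot(is.list(cfg))
  stage <- cfg$stage %||% "run"
  done <- function(res) { invisible(res) }
  seed <- as.integer(seed %||% cfg$seed %||% 1L)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  for (key in c("samples", "counts")) {
    # classification needs labels: fail before any compute if half-specified
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stopf("config names a missing %s file: %s", key, cfg[[key]])
  }
  if (!is.null(cfg$counts) && is.null(cfg$samples))
    stopf("a counts file without a sample table cannot be classified")

  sim_keys <- grep("^sim_", names(cfg), value = TRUE)
  sim_args <- stats::setNames(lapply(cfg[sim_keys], type_convert_scalar),
                              sub("^sim_", "", sim_keys))
  sim_args$seed <- seed
  gen <- do.call(generator_config, sim_args)

  if (is.null(cfg$counts)) {
    say("simulate: drawing synthetic experiment (seed %d)", seed)
    exp <- simulate_experiment(gen)
    counts <- exp$counts; signals <- exp$signals
    pmap <- exp$probe_map; samples <- exp$samples
    write_expression_matrix(counts, file.path(outdir, "counts.tsv"))
    write_expression_matrix(signals, file.path(outdir, "signals.tsv"))
    write_tsv_table(pmap, file.path(outdir, "probe_map.tsv"))
    write_tsv_table(samples, file.path(outdir, "samples.tsv"))
  } else {
    say("load: reading supplied expression tables")
    counts <- read_mirdeep2_counts(cfg$counts)
    samples <- read_sample_table(cfg$samples)
    signals <- if (!is.null(cfg$signals)) read_agilent_signals(cfg$signals)
    pmap <- if (!is.null(cfg$probe_map)) read_probe_map(cfg$probe_map)
  }
  if (stage == "simulate")
    return(done(list(counts = counts, signals = signals, samples = samples)))

  lcfg <- log_config(base = as.numeric(cfg$log_base %||% 10),
                     pseudocount = as.numeric(cfg$pseudocount %||% 0))

  say("normalize: log + per-sample z-score")
  # classification matrix: log10(count + 1) then z-score (complete matrix)
  logc <- log_transform(counts, log_config(lcfg$base, pseudocount = 1))
  z <- zscore_by_sample(logc)
  write_expression_matrix(z, file.path(outdir, "zscore.tsv"))
  if (stage == "normalize") return(done(list(zscore = z)))

  conc <- NULL
  if (!is.null(signals) && !is.null(pmap)) {
    say("concordance: cross-platform correlations")
    avg <- average_probes_to_mirna(signals, pmap)
    shared <- intersect(sample_ids(counts), sample_ids(avg))
    per_sample <- vapply(shared, function(s)
      as.numeric(platform_correlation(counts, avg, s, lcfg)), numeric(1L))
    mean_diff <- if (length(shared) >= 2L)
      as.numeric(mean_pairwise_differential_correlation(counts, avg, shared,
                                                        lcfg))
      else NA_real_
    conc <- list(per_sample = per_sample, mean_differential = mean_diff)
    utils::write.table(
      data.frame(sample_id = shared, pearson_r = per_sample),
      file.path(outdir, "concordance.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (stage == "concordance") return(done(list(concordance = conc)))

  say("classify: PCA-based feature extraction + LOOCV LDA")
  M <- as.integer(cfg$M %||% 11L)
  M_prime <- as.integer(cfg$M_prime %||% 2L)
  disc <- loocv_classify(z, samples, M = M, M_prime = M_prime)
  utils::write.table(disc$samples, file.path(outdir, "predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  metrics <- data.frame(
    metric = c("accuracy_percent", "sensitivity", "specificity", "auc",
               "fisher_p"),
    value = c(disc$accuracy, disc$sensitivity, disc$specificity, disc$auc,
              disc$fisher_p))
  utils::write.table(metrics, file.path(outdir, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (stage == "classify") return(done(list(discrimination = disc)))

  say("difftest: per-miRNA Wilcoxon on the selected features")
  tests <- per_mirna_tests(z, samples, ids = disc$selection$mirna_id)
  utils::write.table(tests, file.path(outdir, "difftest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (stage == "difftest") return(done(list(tests = tests)))

  report <- NULL
  calls <- if (!is.null(cfg$candidate_calls)) {
    say("filter-novel: applying candidate retention criteria")
    utils::read.table(cfg$candidate_calls, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  }
  if (!is.null(calls)) {
    retained <- filter_novel_candidates(
      calls,
      min_probability = as.numeric(cfg$min_probability %||% 80),
      min_samples = as.integer(cfg$min_samples %||% 4L))
    report <- candidate_report(retained, calls)
    utils::write.table(report, file.path(outdir, "novel_candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "mirnadx",
    version = as.character(utils::packageVersion("mirnadx")),
    seed = seed,
    config = cfg[setdiff(names(cfg), "seed")],
    config_hash = config_hash(cfg),
    outputs = list.files(outdir, pattern = "\\.tsv$"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: %d tables in %s", length(manifest$outputs), outdir)
  invisible(list(counts = counts, zscore = z, concordance = conc,
                 discrimination = disc, tests = tests, novel = report,
                 manifest = manifest))
}

type_convert_scalar <- function(x) {
  if (!is.character(x)) return(x)
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) num else x
}

read_keyvalue_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+)\\s*:\\s*(.*)$", lines))
  bad <- lines[vapply(kv, length, integer(1L)) != 3L]
  if (length(bad)) stopf("malformed config line(s): %s", paste(bad, collapse = "; "))
  stats::setNames(lapply(kv, function(m) type_convert_scalar(trimws(m[3L]))),
                  vapply(kv, `[[`, character(1L), 2L))
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(cfg),
                   vapply(cfg, function(v) paste(format(v), collapse = ","),
                          character(1L)),
                   sep = "="), tmp)
  unname(tools::md5sum(tmp))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `normalize`, `concordance`,
#' `classify`, `difftest`, `filter-novel`, and `run` (the full
#' pipeline). Invoke from a shell via the installed launcher
#' (`system.file("cli", "mirnadx", package = "mirnadx")`) or from R as
#' `mirnadx_main(c("run", "--seed", "7", "--outdir", "out"))`.
#' Global flags: `--config FILE`, `--outdir DIR`, `--seed INT`,
#' `--quiet`. Stage-specific inputs come from the config file.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status, invisibly (0 on success).
#' @export
mirnadx_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: mirnadx <simulate|normalize|concordance|classify|difftest|",
    "               filter-novel|run> [--config FILE] [--outdir DIR]",
    "               [--seed INT] [--quiet]", sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(2L)) }
  cmd <- args[[1L]]
  opts <- parse_cli_flags(args[-1L])
  subcommands <- c("simulate", "normalize", "concordance", "classify",
                   "difftest", "filter-novel", "run")
  if (!cmd %in% subcommands) {
    message(sprintf("unknown subcommand '%s'\n%s", cmd, usage))
    return(invisible(2L))
  }
  cfg <- if (!is.null(opts$config)) read_keyvalue_config(opts$config) else list()
  cfg$stage <- cmd
  status <- tryCatch({
    run_pipeline(cfg, outdir = opts$outdir %||% "mirnadx-out",
                 seed = opts$seed, quiet = isTRUE(opts$quiet))
    0L
  }, error = function(e) {
    message(sprintf("mirnadx %s failed: %s", cmd, conditionMessage(e)))
    1L
  })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (a == "--quiet") { opts$quiet <- TRUE; i <- i + 1L; next }
    if (!startsWith(a, "--") || i == length(args))
      stopf("unexpected argument '%s'", a)
    key <- sub("^--", "", a)
    val <- args[[i + 1L]]
    opts[[key]] <- if (key == "seed") as.integer(val) else val
    i <- i + 2L
  }
  opts
}
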