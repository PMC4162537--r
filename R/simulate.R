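#' Configuration of the paired NGS/microarray simulator
#'
#' Describes the synthetic world the generator draws from: a hepatic-style
#' small-RNA profiling study of `n_tumor` tumors and `n_control` matched
#' non-tumorous tissues, profiled by sequencing (all samples) and by
#' microarray (the first `n_array_tumor` tumor samples, mirroring a
#' design in which only part of the tumors were arrayed).
#'
#' The generative model, bottom up:
#' \itemize{
#' \item Baseline log abundance of miRNA i:
#'   `a_i ~ Exponential(mean = baseline_log_sd)` (natural log): a
#'   right-skewed, heavy-tailed abundance distribution — a dense bulk of
#'   rare miRNAs plus a handful of dominant ones — spanning roughly five
#'   decades at the default mean of 1.8, the shape and dynamic range
#'   hepatic small-RNA libraries exhibit (a single miRNA can absorb a
#'   large share of all assigned reads).
#' \item Specimen effects `b_ij ~ N(0, sample_effect_sd)`: biological
#'   variation of each miRNA in each specimen, shared by every platform
#'   and replicate measuring that specimen.
#' \item Planted disease signal: the `n_diff` most abundant miRNAs carry
#'   a `log2_fold_changes` shift in tumor columns only. Coupling the
#'   signal to abundance mirrors hepatic biology, where the dominant
#'   liver miRNAs are precisely the diagnostic ones, and the default
#'   effect vector down-regulates the most abundant of them.
#' \item Sequencing: per-sample assigned-read budgets are
#'   `mean_library_size * mapped_fraction` on average (log-normal across
#'   samples, CV `library_size_cv`); counts are negative binomial with
#'   dispersion `nb_dispersion` around the multinomial-style expected
#'   share of each miRNA.
#' \item Microarray: each of `probes_per_mirna` probes has a fixed
#'   affinity offset (`N(0, probe_affinity_sd)`, constant across
#'   samples) plus per-measurement noise (`N(0, array_noise_sd)`), both
#'   on the natural-log scale. Affinity offsets depress single-sample
#'   cross-platform correlation but cancel from sample differences —
#'   which is why the defaults reproduce a regime where both sit near
#'   0.6. `array_noise_sd`/`probe_affinity_sd` are calibrated so the
#'   per-sample cross-platform log correlation lands near 0.61.
#' \item Technical replicates: Poisson re-draws around an observed count
#'   matrix with log-normal jitter `replicate_noise_sd`, calibrated so
#'   replicate log correlations exceed 0.98.
#' }
#'
#' @param n_mirna Number of mature miRNAs (default 300).
#' @param n_tumor,n_control Group sizes (defaults 14 and 6, the study
#'   design whose confusion tables these simulations emulate).
#' @param n_diff Number of planted differential miRNAs (default 11).
#' @param log2_fold_changes Planted tumor/control log2 fold changes,
#'   recycled to length `n_diff`; assigned to the planted miRNAs in
#'   decreasing order of baseline abundance. Default magnitudes lie in
#'   [1.5, 2.5] with mixed signs, the negative entries on the most
#'   abundant miRNAs.
#' @param mean_library_size Mean total reads per sample (default 2.2e6).
#' @param mapped_fraction Fraction of reads assigned to miRNAs (default
#'   0.57); unmapped reads are only emulated as budget scaling.
#' @param nb_dispersion Negative-binomial dispersion of counts (default
#'   0.2; 0 gives Poisson).
#' @param baseline_log_sd Mean (= sd) of the exponential baseline
#'   log-abundance distribution (default 1.8).
#' @param sample_effect_sd Biological specimen-to-specimen sd (default
#'   0.6; jointly constrained by the differential-correlation regime and
#'   the stated rank-test power at |log2FC| = 2, see the methods vignette).
#' @param array_noise_sd Per-measurement microarray log noise (default
#'   0.5, calibrated; see above).
#' @param probe_affinity_sd Fixed per-probe affinity spread (default
#'   3.0, calibrated).
#' @param probes_per_mirna Probes per mature miRNA on the array
#'   (default 2).
#' @param replicate_noise_sd Technical-replicate log jitter (default
#'   0.05, calibrated).
#' @param library_size_cv Log-normal CV of per-sample budgets (default
#'   0.1).
#' @param n_array_tumor Number of tumor samples also measured on the
#'   array (default 11).
#' @param seed Integer seed; every draw of every stage derives its
#'   stream from it.
#' @return A list of class `GeneratorConfig`.
#' @export
generator_config <- function(n_mirna = 300L, n_tumor = 14L, n_control = 6L,
                             n_diff = 11L,
                             log2_fold_changes = c(-2, 1.5, -1.5, 2, 2.5,
                                                   1.5, 2, -1.5, 2.5, 1.5, 2),
                             mean_library_size = 2.2e6,
                             mapped_fraction = 0.57,
                             nb_dispersion = 0.2,
                             baseline_log_sd = 1.8,
                             sample_effect_sd = 0.6,
                             array_noise_sd = 0.5,
                             probe_affinity_sd = 3.0,
                             probes_per_mirna = 2L,
                             replicate_noise_sd = 0.05,
                             library_size_cv = 0.1,
                             n_array_tumor = 11L,
                             seed = 1L) {
  cfg <- list(n_mirna = as.integer(n_mirna), n_tumor = as.integer(n_tumor),
              n_control = as.integer(n_control), n_diff = as.integer(n_diff),
              log2_fold_changes = as.numeric(log2_fold_changes),
              mean_library_size = mean_library_size,
              mapped_fraction = mapped_fraction,
              nb_dispersion = nb_dispersion,
              baseline_log_sd = baseline_log_sd,
              sample_effect_sd = sample_effect_sd,
              array_noise_sd = array_noise_sd,
              probe_affinity_sd = probe_affinity_sd,
              probes_per_mirna = as.integer(probes_per_mirna),
              replicate_noise_sd = replicate_noise_sd,
              library_size_cv = library_size_cv,
              n_array_tumor = as.integer(n_array_tumor),
              seed = as.integer(seed))
  with(cfg, {
    if (n_mirna < 1L || n_tumor < 1L || n_control < 1L)
      stopf("all counts must be positive")
    if (n_diff < 0L || n_diff > n_mirna)
      stopf("n_diff must lie in [0, n_mirna]")
    if (mean_library_size <= 0 || mapped_fraction <= 0 || mapped_fraction > 1)
      stopf("invalid library size or mapped fraction")
    if (nb_dispersion < 0 || baseline_log_sd <= 0 || sample_effect_sd < 0 ||
        array_noise_sd < 0 || probe_affinity_sd < 0 ||
        replicate_noise_sd < 0 || library_size_cv < 0)
      stopf("dispersions and noise sds must be non-negative")
    if (probes_per_mirna < 1L) stopf("probes_per_mirna must be >= 1")
    if (n_array_tumor < 0L) stopf("n_array_tumor must be >= 0")
  })
  if (cfg$n_diff > 0L)
    cfg$log2_fold_changes <- rep_len(cfg$log2_fold_changes, cfg$n_diff)
  cfg$n_array_tumor <- min(cfg$n_array_tumor, cfg$n_tumor)
  class(cfg) <- "GeneratorConfig"
  cfg
}

sim_sample_ids <- function(cfg) {
  c(sprintf("T%02d", seq_len(cfg$n_tumor)),
    sprintf("N%02d", seq_len(cfg$n_control)))
}

sim_labels <- function(cfg) {
  rep(c("tumor", "control"), c(cfg$n_tumor, cfg$n_control))
}

#' Draw the latent (true) log-abundance matrix
#'
#' Baseline abundances plus specimen effects plus the planted tumor
#' shifts, on the natural-log scale. The planted miRNAs are the `n_diff`
#' with the largest baselines (see [generator_config()]); their fold
#' changes apply to tumor columns only.
#'
#' @param cfg A [generator_config()].
#' @return A list of class `LatentMatrix`: `values` (miRNA x sample),
#'   `planted_ids`, `log2_fold_changes` (named by planted id).
#' @export
simulate_latent_expression <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  set.seed(derive_seed(cfg$seed, 11))
  n <- cfg$n_mirna
  ns <- cfg$n_tumor + cfg$n_control
  mir <- sprintf("mir-%03d", seq_len(n))
  baseline <- stats::rexp(n, rate = 1 / cfg$baseline_log_sd)
  b <- matrix(stats::rnorm(n * ns, 0, cfg$sample_effect_sd), n, ns)
  values <- baseline + b
  dimnames(values) <- list(mir, sim_sample_ids(cfg))
  planted <- character(0)
  lfc <- numeric(0)
  if (cfg$n_diff > 0L) {
    planted <- mir[order(-baseline)][seq_len(cfg$n_diff)]
    lfc <- cfg$log2_fold_changes
    names(lfc) <- planted
    tumor_cols <- seq_len(cfg$n_tumor)
    values[planted, tumor_cols] <-
      values[planted, tumor_cols] + lfc * log(2)
  }
  structure(list(values = values, planted_ids = planted,
                 log2_fold_changes = lfc),
            class = "LatentMatrix")
}

#' Draw negative-binomial sequencing counts from a latent matrix
#'
#' Per-sample assigned-read budgets are log-normal around
#' `mean_library_size * mapped_fraction`; miRNA i's expected count in
#' sample j is the budget times its softmax share of the latent column;
#' observed counts are NB with the configured dispersion (Poisson at 0).
#'
#' @param latent A [simulate_latent_expression()] result.
#' @param cfg The same [generator_config()].
#' @return An `ExpressionMatrix`, `platform = "ngs"`, `scale = "raw"`.
#' @export
simulate_ngs_counts <- function(latent, cfg) {
  stopifnot(inherits(latent, "LatentMatrix"),
            inherits(cfg, "GeneratorConfig"))
  set.seed(derive_seed(cfg$seed, 23))
  v <- latent$values
  ns <- ncol(v)
  budget <- cfg$mean_library_size * cfg$mapped_fraction
  sdlog <- sqrt(log(1 + cfg$library_size_cv^2))
  lib <- stats::rlnorm(ns, log(budget) - sdlog^2 / 2, sdlog)
  shares <- vapply(seq_len(ns), function(j) {
    e <- exp(v[, j] - max(v[, j]))
    e / sum(e)
  }, numeric(nrow(v)))
  shares <- matrix(shares, nrow(v), ns)
  mu <- sweep(shares, 2L, lib, "*")
  counts <- matrix(0, nrow(v), ns, dimnames = dimnames(v))
  if (cfg$nb_dispersion > 0) {
    counts[] <- stats::rnbinom(length(mu), mu = mu,
                               size = 1 / cfg$nb_dispersion)
  } else {
    counts[] <- stats::rpois(length(mu), mu)
  }
  expression_matrix(counts, platform = "ngs", scale = "raw")
}

#' Draw probe-level microarray signals from a latent matrix
#'
#' Only the arrayed samples (first `n_array_tumor` tumor columns) are
#' measured. Each mature miRNA gets `probes_per_mirna` probes; probe p's
#' signal is `exp(latent + affinity_p + noise)` with a fixed per-probe
#' affinity offset and i.i.d. measurement noise (see
#' [generator_config()]). The probe-to-miRNA assignment is attached as
#' attribute `probe_map` and also returned by [attr()].
#'
#' @inheritParams simulate_ngs_counts
#' @return A probe-level `ExpressionMatrix`, `platform = "microarray"`,
#'   `scale = "raw"`, with attribute `probe_map` (a [probe_map()]).
#' @export
simulate_microarray_signals <- function(latent, cfg) {
  stopifnot(inherits(latent, "LatentMatrix"),
            inherits(cfg, "GeneratorConfig"))
  set.seed(derive_seed(cfg$seed, 37))
  arrayed <- colnames(latent$values)[seq_len(cfg$n_array_tumor)]
  v <- latent$values[, arrayed, drop = FALSE]
  n <- nrow(v); k <- cfg$probes_per_mirna
  probes <- sprintf("probe_%s_%d", rep(rownames(v), each = k),
                    rep(seq_len(k), n))
  pmap <- probe_map(probes, rep(rownames(v), each = k))
  affinity <- stats::rnorm(n * k, 0, cfg$probe_affinity_sd)
  lat <- v[rep(seq_len(n), each = k), , drop = FALSE]
  noise <- matrix(stats::rnorm(length(lat), 0, cfg$array_noise_sd),
                  nrow(lat), ncol(lat))
  sig <- exp(lat + affinity + noise)
  dimnames(sig) <- list(probes, arrayed)
  out <- expression_matrix(sig, platform = "microarray", scale = "raw")
  attr(out, "probe_map") <- pmap
  out
}

#' Re-sequence a count matrix as technical replicates
#'
#' Emulates repeated sequencing of the same libraries: each replicate
#' draws Poisson counts around the observed counts perturbed by
#' log-normal jitter of sd `replicate_noise_sd` (no biological
#' redraw — technical replicates share the specimen).
#'
#' @param counts A raw NGS `ExpressionMatrix` (the means to re-draw
#'   around).
#' @param cfg A [generator_config()].
#' @param k Number of replicates, >= 2.
#' @return A named list of `k` `ExpressionMatrix` replicates.
#' @export
simulate_technical_replicates <- function(counts, cfg, k = 2L) {
  stopifnot(inherits(counts, "ExpressionMatrix"),
            inherits(cfg, "GeneratorConfig"))
  if (!is_count(k) || k < 2L) stopf("need k >= 2 replicates")
  if (counts$scale != "raw" || counts$platform != "ngs")
    stopf("replicates are drawn from a raw NGS count matrix")
  set.seed(derive_seed(cfg$seed, 53))
  out <- lapply(seq_len(k), function(r) {
    jitter <- matrix(stats::rnorm(length(counts$values), 0,
                                  cfg$replicate_noise_sd),
                     nrow(counts$values), ncol(counts$values))
    m <- matrix(stats::rpois(length(counts$values),
                             counts$values * exp(jitter)),
                nrow(counts$values), ncol(counts$values),
                dimnames = dimnames(counts$values))
    expression_matrix(m, platform = "ngs", scale = "raw")
  })
  names(out) <- paste0("rep", seq_len(k))
  out
}

#' Simulate discovery-tool candidate calls
#'
#' Emits a call table exercising the novel-candidate filter: the first
#' four candidates are constructed to satisfy both retention criteria
#' (probability > 80 in at least 4 distinct samples — the number of
#' surviving precursors the emulated study reported), the remainder draw
#' probabilities spanning [0, 100] and sample support from 1 up, so some
#' fail on probability, some on reproducibility.
#'
#' @param cfg A [generator_config()].
#' @param n_candidates Total number of candidates, >= 1.
#' @return A `CandidateCalls` table.
#' @export
simulate_candidate_calls <- function(cfg, n_candidates = 10L) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  if (!is_count(n_candidates) || n_candidates < 1L)
    stopf("n_candidates must be >= 1")
  set.seed(derive_seed(cfg$seed, 71))
  samples <- sim_sample_ids(cfg)
  n_pass <- min(4L, n_candidates)
  rows <- list()
  for (i in seq_len(n_candidates)) {
    id <- sprintf("cand-%03d", i)
    chrom <- sprintf("chr%d", sample(22L, 1L))
    start <- sample(1e6:2e8, 1L)
    coord <- sprintf("%s:%d-%d:%s", chrom, start, start + 80L,
                     sample(c("+", "-"), 1L))
    if (i <= n_pass) {
      n_det <- sample(4:min(8L, length(samples)), 1L)
      prob <- stats::runif(n_det, 85, 99.9)
    } else {
      n_det <- sample(seq_len(min(6L, length(samples))), 1L)
      prob <- stats::runif(n_det, 0, 100)
    }
    det <- sample(samples, n_det)
    rows[[i]] <- candidate_calls(
      candidate_id = rep(id, n_det), coordinate = rep(coord, n_det),
      probability = prob, sample_id = det,
      read_support = stats::rnbinom(n_det, mu = 30, size = 1),
      mature_sequence = paste(sample(c("A", "C", "G", "U"), 22L,
                                     replace = TRUE), collapse = ""))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("CandidateCalls", "data.frame")
  out
}

#' Simulate a full paired profiling experiment
#'
#' Convenience wrapper drawing the latent truth, the NGS count matrix for
#' all samples, the probe-level array matrix for the arrayed samples
#' (plus probe map), and the sample metadata table.
#'
#' @param cfg A [generator_config()].
#' @return A list: `latent`, `counts`, `signals`, `probe_map`,
#'   `samples` (a `SampleTable`), `config`.
#' @export
simulate_experiment <- function(cfg = generator_config()) {
  latent <- simulate_latent_expression(cfg)
  counts <- simulate_ngs_counts(latent, cfg)
  signals <- simulate_microarray_signals(latent, cfg)
  arrayed <- colnames(signals$values)
  ids <- sim_sample_ids(cfg)
  samples <- sample_table(
    ids, sim_labels(cfg),
    platforms = ifelse(ids %in% arrayed, "ngs;microarray", "ngs"))
  list(latent = latent, counts = counts, signals = signals,
       probe_map = attr(signals, "probe_map"), samples = samples,
       config = cfg)
}
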