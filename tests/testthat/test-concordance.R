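test_that("pearson_cor matches the covariance/SD definition and contracts", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 6)
  # oracle: direct formula
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(as.numeric(pearson_cor(x, y)), oracle, tolerance = 1e-12)
  expect_equal(round(oracle, 4), 0.9562)   # 8 / sqrt(5 * 14)
  expect_equal(as.numeric(pearson_cor(x, x)), 1)
  expect_equal(as.numeric(pearson_cor(x, -x)), -1)
  expect_error(pearson_cor(c(1, 2), c(3, 4)), "3 complete")
  expect_error(pearson_cor(c(1, 1, 1), x[1:3]), "constant")
  # pairwise NA dropping is reported
  r <- pearson_cor(c(x, NA), c(y, 1))
  expect_identical(attr(r, "n_used"), 4L)
})

test_that("platform_correlation is near 1 in the noiseless large-count limit", {
  cfg <- generator_config(n_mirna = 200, array_noise_sd = 0,
                          probe_affinity_sd = 0, sample_effect_sd = 0.5,
                          nb_dispersion = 0, mean_library_size = 2e7,
                          probes_per_mirna = 1, seed = 4)
  exp <- simulate_experiment(cfg)
  avg <- average_probes_to_mirna(exp$signals, exp$probe_map)
  r <- platform_correlation(exp$counts, avg, "T01")
  expect_gte(as.numeric(r), 0.99)
})

test_that("random id shuffling destroys the cross-platform correlation", {
  cfg <- generator_config(seed = 11)
  exp <- simulate_experiment(cfg)
  avg <- average_probes_to_mirna(exp$signals, exp$probe_map)
  set.seed(2)
  hits <- vapply(seq_len(100), function(i) {
    shuf <- avg
    rownames(shuf$values) <- sample(rownames(shuf$values))
    abs(as.numeric(platform_correlation(exp$counts, shuf, "T01"))) < 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("differential correlation is swap-invariant, shift-invariant, exact on identical input", {
  cfg <- generator_config(seed = 3)
  exp <- simulate_experiment(cfg)
  avg <- average_probes_to_mirna(exp$signals, exp$probe_map)
  r_ij <- differential_correlation(exp$counts, avg, c("T01", "T02"))
  r_ji <- differential_correlation(exp$counts, avg, c("T02", "T01"))
  expect_equal(as.numeric(r_ij), as.numeric(r_ji), tolerance = 1e-12)
  expect_error(differential_correlation(exp$counts, avg, c("T01", "T01")),
               "distinct")

  # identical matrices on both platforms -> r = 1
  fake <- exp$counts
  fake$platform <- "microarray"
  r1 <- differential_correlation(exp$counts, fake, c("T01", "T02"))
  expect_equal(as.numeric(r1), 1, tolerance = 1e-12)

  # per-miRNA constant shared by both samples and platforms cancels
  shift <- exp(rnorm(nrow(avg$values)))
  shifted_counts <- exp$counts
  shifted_arr <- avg
  shifted_arr$values <- avg$values * shift
  r_base <- differential_correlation(exp$counts, avg, c("T01", "T02"))
  r_shift <- differential_correlation(shifted_counts, shifted_arr,
                                      c("T01", "T02"))
  expect_equal(as.numeric(r_base), as.numeric(r_shift), tolerance = 1e-10)
})

test_that("mean pairwise differential correlation averages unordered pairs", {
  cfg <- generator_config(seed = 5)
  exp <- simulate_experiment(cfg)
  avg <- average_probes_to_mirna(exp$signals, exp$probe_map)
  two <- mean_pairwise_differential_correlation(exp$counts, avg,
                                                c("T01", "T02"))
  expect_equal(as.numeric(two),
               as.numeric(differential_correlation(exp$counts, avg,
                                                   c("T01", "T02"))))
  s3 <- c("T01", "T02", "T03")
  a <- mean_pairwise_differential_correlation(exp$counts, avg, s3)
  b <- mean_pairwise_differential_correlation(exp$counts, avg, rev(s3))
  expect_equal(as.numeric(a), as.numeric(b))
  expect_identical(attr(a, "n_pairs") + attr(a, "n_skipped"), 3L)

  fake <- exp$counts; fake$platform <- "microarray"
  r <- mean_pairwise_differential_correlation(exp$counts, fake, s3)
  expect_equal(as.numeric(r), 1, tolerance = 1e-12)
})

test_that("replicate correlation matrix is symmetric with unit diagonal", {
  cfg <- generator_config(seed = 6)
  counts <- simulate_ngs_counts(simulate_latent_expression(cfg), cfg)
  m <- replicate_correlation_matrix(list(counts, counts))
  expect_equal(m[1, 2], 1)
  reps <- simulate_technical_replicates(counts, cfg, k = 3)
  mm <- replicate_correlation_matrix(reps)
  expect_equal(mm, t(mm), tolerance = 1e-12)
  expect_equal(diag(mm), c(rep1 = 1, rep2 = 1, rep3 = 1))
  expect_true(all(mm >= -1 & mm <= 1))

  other <- subset_expression(counts, mirnas = rev(mirna_ids(counts)))
  expect_error(replicate_correlation_matrix(list(counts, other)), "universe")
})
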