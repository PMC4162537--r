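test_that("generator config validates its invariants", {
  expect_error(generator_config(n_diff = 400), "n_diff")
  expect_error(generator_config(mapped_fraction = 1.5), "mapped")
  expect_error(generator_config(nb_dispersion = -1), "non-negative")
  cfg <- generator_config(n_diff = 3)
  expect_length(cfg$log2_fold_changes, 3)
})

test_that("latent matrix: determinism, planted structure, null case", {
  cfg <- generator_config(seed = 7)
  a <- simulate_latent_expression(cfg)
  b <- simulate_latent_expression(cfg)
  expect_identical(a, b)
  expect_length(a$planted_ids, 11)

  # planted shift is exactly lfc * log(2) on tumor columns (no specimen noise)
  cfg0 <- generator_config(seed = 7, sample_effect_sd = 0, n_diff = 2,
                           log2_fold_changes = c(2, -1.5))
  lat <- simulate_latent_expression(cfg0)
  tum <- seq_len(cfg0$n_tumor); ctl <- cfg0$n_tumor + seq_len(cfg0$n_control)
  for (i in seq_along(lat$planted_ids)) {
    id <- lat$planted_ids[i]
    expect_equal(mean(lat$values[id, tum]) - mean(lat$values[id, ctl]),
                 unname(lat$log2_fold_changes[i]) * log(2),
                 tolerance = 1e-12)
  }
  # non-planted miRNAs share group means
  np <- setdiff(rownames(lat$values), lat$planted_ids)[1]
  expect_equal(mean(lat$values[np, tum]), mean(lat$values[np, ctl]),
               tolerance = 1e-12)

  # n_diff = 0: no planted set
  latn <- simulate_latent_expression(generator_config(seed = 7, n_diff = 0))
  expect_length(latn$planted_ids, 0)
})

test_that("NGS counts: support, Poisson limit, library budget", {
  cfg <- generator_config(seed = 8)
  lat <- simulate_latent_expression(cfg)
  counts <- simulate_ngs_counts(lat, cfg)
  v <- counts$values
  expect_true(all(v >= 0) && all(v == round(v)))
  expect_identical(counts$platform, "ngs")

  # dispersion -> 0 limit at fixed mean 50: sample variance of 10 000
  # generator draws sits within 3 SE of the Poisson value (var = mean)
  cfg1 <- generator_config(n_mirna = 1, n_diff = 0, sample_effect_sd = 0,
                           n_tumor = 5000, n_control = 5000,
                           library_size_cv = 0,
                           mean_library_size = 50 / 0.57, nb_dispersion = 0,
                           seed = 10)
  c1 <- simulate_ngs_counts(simulate_latent_expression(cfg1), cfg1)
  x <- as.vector(c1$values)
  expect_lt(abs(mean(x) - 50), 3 * sqrt(50 / length(x)))
  se_var <- 50 * sqrt(2 / length(x))   # large-sample SE of a Poisson variance
  expect_lt(abs(var(x) - 50), 3 * se_var)

  # column sums track the assigned-read budget over seeds
  budget <- cfg$mean_library_size * cfg$mapped_fraction
  mean_sum <- mean(vapply(1:20, function(s) {
    cc <- generator_config(seed = s)
    mean(colSums(simulate_ngs_counts(simulate_latent_expression(cc), cc)$values))
  }, numeric(1)))
  expect_lt(abs(mean_sum - budget) / budget, 0.05)
})

test_that("microarray signals: positivity, noiseless limit, probe map", {
  cfg <- generator_config(seed = 12)
  lat <- simulate_latent_expression(cfg)
  sig <- simulate_microarray_signals(lat, cfg)
  expect_true(all(sig$values > 0))
  pm <- attr(sig, "probe_map")
  expect_s3_class(pm, "ProbeMap")
  expect_identical(nrow(pm), nrow(sig$values))
  expect_identical(ncol(sig$values), cfg$n_array_tumor)

  # noiseless single-probe limit: probe-averaged log signal == latent
  cfg0 <- generator_config(array_noise_sd = 0, probe_affinity_sd = 0,
                           probes_per_mirna = 1, seed = 12)
  sig0 <- simulate_microarray_signals(simulate_latent_expression(cfg0), cfg0)
  avg0 <- average_probes_to_mirna(sig0, attr(sig0, "probe_map"))
  lat0 <- simulate_latent_expression(cfg0)
  r <- cor(log(avg0$values[, 1]), lat0$values[rownames(avg0$values), 1])
  expect_equal(r, 1, tolerance = 1e-12)
})

test_that("technical replicates: determinism, monotone noise, k contract", {
  cfg <- generator_config(seed = 13)
  counts <- simulate_ngs_counts(simulate_latent_expression(cfg), cfg)
  r1 <- simulate_technical_replicates(counts, cfg, k = 2)
  r2 <- simulate_technical_replicates(counts, cfg, k = 2)
  expect_identical(r1, r2)
  expect_error(simulate_technical_replicates(counts, cfg, k = 1), "k >= 2")

  # larger replicate noise strictly lowers the correlation
  lo <- replicate_correlation_matrix(simulate_technical_replicates(counts, cfg, 2))
  cfg_hi <- generator_config(seed = 13, replicate_noise_sd = 2)
  hi <- replicate_correlation_matrix(
    simulate_technical_replicates(counts, cfg_hi, 2))
  expect_lt(hi[1, 2], lo[1, 2])
})

test_that("candidate calls: determinism, support, guaranteed survivor", {
  cfg <- generator_config(seed = 14)
  a <- simulate_candidate_calls(cfg, 10)
  b <- simulate_candidate_calls(cfg, 10)
  expect_identical(a, b)
  expect_true(all(a$probability >= 0 & a$probability <= 100))
  retained <- filter_novel_candidates(a)
  expect_gte(nrow(retained), 1)
})

test_that("full experiment is reproducible bit-for-bit from (config, seed)", {
  cfg <- generator_config(seed = 21)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$counts$values, e2$counts$values)
  expect_identical(e1$signals$values, e2$signals$values)
  expect_identical(e1$samples, e2$samples)
  e3 <- simulate_experiment(generator_config(seed = 22))
  expect_false(identical(e1$counts$values, e3$counts$values))
})
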