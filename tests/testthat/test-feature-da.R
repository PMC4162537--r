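test_that("miRNA embedding: rank-1 input, dominant row, equivariance", {
  # rank-1 matrix (proportional sample columns): all PC2 scores vanish
  base <- c(-2, -1, 0, 1, 2)
  v <- cbind(base, 2 * base)
  em <- make_expr(v, platform = "microarray", scale = "zscore")
  co <- pca_embed_mirnas(em)
  expect_lt(max(abs(co[, 2])), 1e-10)

  fx <- make_separable_zscore()
  coords <- pca_embed_mirnas(fx$z)
  expect_identical(rownames(coords), mirna_ids(fx$z))

  # a miRNA with 10x the centered magnitude attains the max distance;
  # oracle: direct eigendecomposition of the crossproduct
  set.seed(3)
  w <- matrix(rnorm(40), 10, 4)
  w <- sweep(w, 2, colMeans(w))
  w[4, ] <- w[4, ] * 10 / sqrt(mean(w[4, ]^2) / mean(w[-4, ]^2))
  emw <- make_expr(w, platform = "microarray", scale = "zscore")
  cow <- pca_embed_mirnas(emw)
  d <- sqrt(rowSums(cow^2))
  expect_identical(unname(which.max(d)), 4L)
  ev <- eigen(crossprod(sweep(w, 2, colMeans(w))))$values
  expect_equal(sum(d^2), sum(ev[1:2]), tolerance = 1e-8)  # scores carry top-2 energy

  # row-permutation equivariance (up to the deterministic sign convention)
  perm <- sample(nrow(w))
  emp <- make_expr(w[perm, ], mirnas = mirna_ids(emw)[perm],
                   platform = "microarray", scale = "zscore")
  cop <- pca_embed_mirnas(emp)
  expect_equal(abs(cop[mirna_ids(emw), ]), abs(cow), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("outlier selection ranks by distance with lexicographic ties", {
  coords <- rbind(A = c(3, 4), B = c(1, 0), C = c(0, 2))
  sel <- select_outlier_mirnas(coords, 2)
  expect_s3_class(sel, "FeatureSelection")
  expect_identical(sel$mirna_id, c("A", "C"))
  expect_equal(sel$distance, c(5, 2))
  expect_identical(select_outlier_mirnas(coords, 3)$mirna_id, c("A", "C", "B"))
  expect_error(select_outlier_mirnas(coords, 4), "exceeds")

  # tie for the last slot: lexicographically smaller id kept
  tie <- rbind(A = c(5, 0), Z = c(0, 3), B = c(3, 0))
  sel2 <- select_outlier_mirnas(tie, 2)
  expect_identical(sel2$mirna_id, c("A", "B"))
})

test_that("sample embedding separates planted clusters and projects held-out", {
  fx <- make_separable_zscore()
  coords <- pca_embed_mirnas(fx$z)
  sel <- select_outlier_mirnas(coords, 5)
  expect_true(all(c("miR-01", "miR-02") %in% sel$mirna_id))
  emb <- pca_embed_samples(fx$z, sel, M_prime = 2)
  lab <- fx$samples$label
  pc1 <- emb$scores[, 1]
  expect_true(max(pc1[lab == "control"]) < min(pc1[lab == "tumor"]) ||
              min(pc1[lab == "control"]) > max(pc1[lab == "tumor"]))

  # duplicated sample columns embed identically
  v <- fx$z$values[, c(1, 1, 2, 3)]
  colnames(v) <- c("a", "b", "c", "d")
  dup <- make_expr(v, mirnas = mirna_ids(fx$z), samples = colnames(v),
                   platform = "microarray", scale = "zscore")
  eq <- pca_embed_samples(dup, sel, M_prime = 2)
  expect_equal(eq$scores["a", ], eq$scores["b", ], tolerance = 1e-10)

  # full-rank scores reproduce pairwise sample distances of the submatrix
  M <- nrow(sel)
  full <- pca_embed_samples(fx$z, sel, M_prime = min(M, ncol(fx$z$values) - 1))
  sub <- t(fx$z$values[sel$mirna_id, ])
  expect_equal(as.matrix(dist(full$scores)), as.matrix(dist(sub)),
               tolerance = 1e-8)

  # projection of a training sample equals its fitted score
  proj <- predict(emb, fx$z, samples = sample_ids(fx$z)[1])
  expect_equal(proj[1, ], emb$scores[1, ], tolerance = 1e-10)
})

test_that("lda_fit recovers closed-form discriminants", {
  # 1-D symmetric case: threshold at 0, sign classifier (equal priors)
  s <- matrix(c(-1.1, -0.9, -1.0, 0.9, 1.1, 1.0), ncol = 1)
  lab <- rep(c("control", "tumor"), each = 3)
  fit <- lda_fit(s, lab, prior = "equal")
  res <- lda_score(fit, matrix(c(-0.5, 0.5), ncol = 1))
  expect_identical(res$label, c("control", "tumor"))
  expect_equal(res$score[1], -res$score[2], tolerance = 1e-9)

  # identical class means: majority fallback with warning
  same <- matrix(c(1, 3, 2, 2, 1, 3), ncol = 1)   # both class means = 2
  expect_warning(
    dfit <- lda_fit(same, c(rep("tumor", 4), rep("control", 2))),
    "majority")
  expect_identical(lda_score(dfit, matrix(0))$label, "tumor")

  # 2-D Gaussian toy, means (0,0)/(3,0), isotropic: the learned direction
  # concentrates on the x-axis (sampling error at n = 200 is a few degrees)
  angles <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rbind(matrix(rnorm(200), 100, 2),
               sweep(matrix(rnorm(200), 100, 2), 2, c(3, 0), "+"))
    lab <- rep(c("control", "tumor"), each = 100)
    fit <- lda_fit(x, lab)
    w <- fit$w / sqrt(sum(fit$w^2))
    acos(abs(w[1])) * 180 / pi
  }, numeric(1))
  expect_lt(mean(angles), 5)
  expect_lt(median(angles), 5)

  expect_error(lda_fit(s, rep("tumor", 6)), "2 classes")
  expect_error(lda_fit(s[1:2, , drop = FALSE], c("tumor", "control")),
               "at least 3")
})

test_that("LOOCV classifies separable data and completes the minimal design", {
  fx <- make_separable_zscore()
  res <- loocv_classify(fx$z, fx$samples, M = 4, M_prime = 2)
  expect_s3_class(res, "DiscriminationResult")
  expect_identical(sum(res$confusion), 12L)
  expect_gte(res$accuracy, 90)
  expect_gte(res$auc, 0.9)

  # minimal 2v2 run yields a 2x2 table summing to 4
  fx4 <- make_separable_zscore(n_mirna = 10, n_tumor = 2, n_control = 2,
                               shift = 4, seed = 5)
  res4 <- loocv_classify(fx4$z, fx4$samples, M = 3, M_prime = 1)
  expect_identical(sum(res4$confusion), 4L)
})

test_that("axis sign flips change nothing downstream", {
  fx <- make_separable_zscore()
  coords <- pca_embed_mirnas(fx$z)
  sel_a <- select_outlier_mirnas(coords, 5)
  flipped <- coords %*% diag(c(-1, 1))
  rownames(flipped) <- rownames(coords)
  sel_b <- select_outlier_mirnas(flipped, 5)
  expect_identical(sel_a$mirna_id, sel_b$mirna_id)
  expect_equal(sel_a$distance, sel_b$distance)
})

test_that("classification metrics reproduce the printed worked example", {
  tab <- matrix(c(12, 2, 0, 6), 2)   # rows prediction, cols truth
  m <- classification_metrics(confusion = tab)
  expect_equal(m$accuracy, 90)
  expect_identical(m$n_correct, 18L)
  expect_equal(m$fisher_p, 91 / 125970, tolerance = 1e-12)
  expect_equal(m$sensitivity, 12 / 14)
  expect_equal(m$specificity, 6 / 6)

  # perfect classifier
  perfect <- classification_metrics(
    predictions = rep(c("tumor", "control"), c(14, 6)),
    truth = rep(c("tumor", "control"), c(14, 6)),
    scores = c(seq(1, 2, length.out = 14), seq(-2, -1, length.out = 6)))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$auc, 1)

  # accuracy invariant under relabeling both predictions and truth
  pred <- c("tumor", "control", "tumor", "control", "tumor")
  tru <- c("tumor", "tumor", "tumor", "control", "control")
  swap <- function(x) ifelse(x == "tumor", "control", "tumor")
  expect_equal(classification_metrics(pred, tru)$accuracy,
               classification_metrics(swap(pred), swap(tru))$accuracy)
})

test_that("AUC is the rank statistic with ties at one half", {
  sc <- c(3, 2, 1, 2)
  tr <- c("tumor", "tumor", "control", "control")
  # pairs: (3>1),(3>2),(2>1),(2==2 -> 1/2) => 3.5/4
  expect_equal(auc_rank(sc, tr), 3.5 / 4)
  expect_equal(auc_rank(-sc, tr), 1 - 3.5 / 4)
})

test_that("one-sided Fisher exact agrees with brute force on all margins <= 30", {
  brute <- function(tab) {
    r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
    support <- max(0, r1 + c1 - n):min(r1, c1)
    p <- dhyper(support, c1, n - c1, r1)   # independent oracle
    x <- tab[1, 1]
    if (x >= r1 * c1 / n) sum(p[support >= x]) else sum(p[support <= x])
  }
  expect_equal(fisher_exact_one_sided(matrix(c(12, 2, 0, 6), 2)),
               91 / 125970, tolerance = 1e-12)
  expect_equal(fisher_exact_one_sided(matrix(c(14, 0, 0, 6), 2)),
               1 / choose(20, 14), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    a <- sample(0:n, 1); b <- sample(0:(n - a), 1)
    c <- sample(0:(n - a - b), 1); d <- n - a - b - c
    tab <- matrix(c(a, c, b, d), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_one_sided(tab), brute(tab), tolerance = 1e-12)
  }

  # the (1,1) cell at its support minimum covers the whole tail -> p = 1
  tab_min <- matrix(c(0, 5, 5, 0), 2)
  expect_equal(fisher_exact_one_sided(tab_min),
               brute(tab_min), tolerance = 1e-12)
  expect_error(fisher_exact_one_sided(matrix(c(-1, 2, 3, 4), 2)), "negative")
})
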