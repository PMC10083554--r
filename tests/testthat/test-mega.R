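test_that("Rao's transformation of Wilks' lambda reproduces reported
           headline values", {
  res <- wilks_to_f(0.932, p = 76, n = 2029, rank_design = 4)
  expect_equal(res$df2, 1950)
  expect_equal(round(res$F, 2), 1.87)
  expect_equal(round(100 * res$variance_explained), 7)
  expect_error(wilks_to_f(0.5, 100, 50, 4), "degrees of freedom")
})

test_that("MANCOVA matches the reference multivariate fit", {
  set.seed(30)
  n <- 80
  p <- 4
  dx <- rbinom(n, 1, 0.5)
  age <- rnorm(n, 33, 8)
  sex <- rbinom(n, 1, 0.5)
  Y <- matrix(rnorm(n * p), n, p) + 0.4 * dx
  colnames(Y) <- paste0("r", 1:p)
  ours <- mancova_wilks(Y, dx, age, sex)
  ref <- summary(stats::manova(Y ~ age + sex + dx), test = "Wilks")
  ref_row <- ref$stats["dx", ]
  expect_equal(ours$lambda, unname(ref_row["Wilks"]), tolerance = 1e-10)
  expect_equal(ours$F, unname(ref_row["approx F"]), tolerance = 1e-10)
  expect_equal(ours$df1, unname(ref_row["num Df"]))
  expect_equal(ours$df2, unname(ref_row["den Df"]))
  expect_equal(ours$p_nominal, unname(ref_row["Pr(>F)"]), tolerance = 1e-10)

  # det-ratio equals 1/(1 + lambda_1) for the single eigenvalue of E^-1 H
  X <- cbind(1, age, sex, dx)
  X0 <- cbind(1, age, sex)
  E <- crossprod(qr.resid(qr(X), Y))
  E0 <- crossprod(qr.resid(qr(X0), Y))
  H <- E0 - E
  ev <- Re(eigen(solve(E) %*% H, only.values = TRUE)$values)
  expect_equal(ours$lambda, 1 / (1 + max(ev)), tolerance = 1e-8)
  expect_equal(ours$variance_explained, 1 - ours$lambda)
})

test_that("single-response MANCOVA reduces to the univariate ANCOVA F", {
  set.seed(31)
  n <- 120
  dx <- rbinom(n, 1, 0.4)
  age <- rnorm(n, 30, 10)
  sex <- rbinom(n, 1, 0.5)
  y <- 0.2 * dx + 0.01 * age + rnorm(n)
  ours <- mancova_wilks(matrix(y, ncol = 1, dimnames = list(NULL, "y")),
                        dx, age, sex)
  aov_tab <- summary(stats::aov(y ~ age + sex + dx))[[1]]
  expect_equal(ours$F, aov_tab["dx", "F value"], tolerance = 1e-10)
  expect_equal(ours$p_nominal, aov_tab["dx", "Pr(>F)"], tolerance = 1e-10)
  uni <- univariate_followup(matrix(y, ncol = 1,
                                    dimnames = list(NULL, "y")),
                             dx, age, sex)
  expect_equal(uni$F, ours$F, tolerance = 1e-10)
})

test_that("stratified permutations preserve counts and are reproducible", {
  set.seed(32)
  n <- 200
  strata <- rep(paste0("s", 1:5), each = 40)
  dx <- unlist(lapply(1:5, function(i) rbinom(40, 1, 0.3 + 0.08 * i)))
  strata_idx <- split(seq_len(n), strata)
  tab0 <- table(strata, dx, dnn = NULL)
  for (b in 1:40) {
    perm <- asymmeta:::permute_within_strata(dx, strata_idx, seed = 5, b = b)
    expect_identical(table(strata, perm, dnn = NULL), tab0)
  }
  # same (seed, index) gives the same draw independent of order
  expect_identical(
    asymmeta:::permute_within_strata(dx, strata_idx, seed = 5, b = 17),
    asymmeta:::permute_within_strata(dx, strata_idx, seed = 5, b = 17))

  Y <- matrix(rnorm(n * 6), n, 6)
  colnames(Y) <- paste0("r", 1:6)
  age <- rnorm(n, 33, 9)
  sex <- rbinom(n, 1, 0.5)
  r1 <- stratified_permutation_test(Y, dx, age, sex, strata,
                                    n_perm = 300, seed = 9)
  r2 <- stratified_permutation_test(Y, dx, age, sex, strata,
                                    n_perm = 300, seed = 9, chunk = 37)
  expect_equal(r1$p_perm, r2$p_perm)
  expect_equal(r1$n_exceed, r2$n_exceed)
  expect_equal(r1$p_perm, r1$n_exceed / r1$n_perm)
  expect_lte(r1$p_perm, 1)
  # observed statistic agrees with the direct MANCOVA computation
  direct <- mancova_wilks(Y, dx, age, sex)
  expect_equal(r1$F, direct$F, tolerance = 1e-10)
  expect_equal(r1$lambda, direct$lambda, tolerance = 1e-10)
  # a stratum with a single diagnosis class is reported as fixed
  dx1 <- dx
  dx1[strata == "s1"] <- 1L
  r3 <- stratified_permutation_test(Y, dx1, age, sex, strata,
                                    n_perm = 50, seed = 9)
  expect_true("s1" %in% r3$single_class_strata)
})

test_that("harmonization removes injected batch shifts and preserves
           diagnosis effects", {
  set.seed(33)
  n <- 400
  p <- 30
  batch <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[batch == "b", 5] <- X[batch == "b", 5] + 10
  adj <- combat_harmonize(X, batch)
  shift0 <- mean(X[batch == "b", 5]) - mean(X[batch == "a", 5])
  shift1 <- mean(adj[batch == "b", 5]) - mean(adj[batch == "a", 5])
  expect_lt(abs(shift1 / shift0), 0.02)

  dx <- rep(rep(0:1, each = n / 4), 2)
  Y <- matrix(rnorm(n * p), n, p)
  Y[batch == "b", ] <- Y[batch == "b", ] * 1.3 + 1
  Y[, 3] <- Y[, 3] + 0.5 * dx
  adj2 <- combat_harmonize(Y, batch, mod = stats::model.matrix(~dx))
  d0 <- mean(Y[dx == 1, 3]) - mean(Y[dx == 0, 3])
  d1 <- mean(adj2[dx == 1, 3]) - mean(adj2[dx == 0, 3])
  expect_lt(abs(d1 - d0) / abs(d0), 0.05)

  # near-identity on data without batch structure
  Z <- matrix(rnorm(n * p), n, p)
  adjz <- combat_harmonize(Z, batch)
  expect_lt(sqrt(mean((adjz - Z)^2)), 0.2 * sd(Z))

  expect_error(combat_harmonize(X, c("solo", batch[-1])), "singleton")
  Xz <- X
  Xz[batch == "a", 2] <- 1
  expect_error(combat_harmonize(Xz, batch), "zero-variance")
  expect_error(combat_harmonize(X, rep("a", n)), "2 batches")
})

test_that("post-harmonization QC drops negative volumes and incomplete
           rows", {
  cat78 <- dk_region_catalog()
  m_ids <- cat78$measure_id[cat78$multivariate_eligible]
  n <- 25
  set.seed(34)
  L <- matrix(abs(rnorm(n * length(m_ids), 5, 1)), n,
              dimnames = list(NULL, m_ids))
  R <- L + rnorm(length(L), 0, 0.1)
  qc0 <- post_harmonization_qc(L, R, cat78)
  expect_true(all(qc0$keep))
  L2 <- L
  L2[3, "vol_lateralventricle"] <- -10   # one injected negative volume
  L2[8, "thick_cuneus"] <- NA            # one incomplete individual
  qc <- post_harmonization_qc(L2, R, cat78)
  expect_equal(qc$n_dropped_negative, 1)
  expect_equal(qc$n_dropped_incomplete, 1)
  expect_false(qc$keep[3])
  expect_false(qc$keep[8])
  expect_equal(sum(!qc$keep), 2)
})

test_that("correlation screen reports extremes and warns appropriately", {
  set.seed(35)
  n <- 2000
  ind <- matrix(rnorm(n * 10), n, 10)
  sc0 <- correlation_screen(ind)
  expect_lt(sc0$max_abs_r, 0.1)
  # shared latent factor inducing r close to 0.4
  f <- rnorm(n)
  a <- sqrt(0.4) * f + sqrt(1 - 0.4) * rnorm(n)
  b <- sqrt(0.4) * f + sqrt(1 - 0.4) * rnorm(n)
  sc1 <- correlation_screen(cbind(a, b, rnorm(n)))
  expect_lt(abs(sc1$max_abs_r - 0.4), 0.05)
  dup <- cbind(x = ind[, 1], y = ind[, 1])
  expect_warning(sc2 <- correlation_screen(dup), "exceeds")
  expect_equal(sc2$max_abs_r, 1)
  expect_warning(correlation_screen(cbind(ind[, 1], rep(1, n))), "constant")
})

test_that("univariate follow-up ranks an injected effect first", {
  set.seed(36)
  n <- 1200
  p <- 12
  dx <- rbinom(n, 1, 0.5)
  age <- rnorm(n, 33, 9)
  sex <- rbinom(n, 1, 0.5)
  Y <- matrix(rnorm(n * p), n, p)
  colnames(Y) <- paste0("r", 1:p)
  Y[, 4] <- Y[, 4] + 0.35 * dx
  uni <- univariate_followup(Y, dx, age, sex)
  expect_equal(uni$measure_id[1], "r4")
  expect_lt(uni$p[1], 1e-6)
  # cross-check one follow-up F against summary.aov
  ref <- summary(stats::aov(Y[, 4] ~ age + sex + dx))[[1]]["dx", "F value"]
  expect_equal(uni$F[uni$measure_id == "r4"], ref, tolerance = 1e-10)
})

test_that("the pooled multivariate arm runs end-to-end on synthetic data", {
  co <- small_cohort(seed = 37, n_sites = 4, mean_n = 90)
  mega <- run_mega(co$data, n_perm = 200, seed = 3)
  expect_s3_class(mega$mancova, "mancova_result")
  expect_equal(mega$mancova$df1, 76)
  expect_true(mega$mancova$lambda > 0 && mega$mancova$lambda <= 1)
  expect_equal(mega$mancova$p_perm, mega$mancova$n_exceed / 200)
  expect_equal(nrow(mega$univariate), 76)
  expect_equal(mega$n_analyzed, mega$n_cases + mega$n_controls)
})
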