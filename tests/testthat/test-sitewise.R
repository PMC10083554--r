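test_that("eligibility rule matches the distributed-analysis protocol", {
  expect_false(check_eligibility(4, 100, 0)$pass)   # group below 5
  expect_true(check_eligibility(5, 5, 0)$pass)      # boundary: 10 >= 10
  expect_false(check_eligibility(6, 6, 3)$pass)     # 12 < 10 + 3
  expect_true(check_eligibility(7, 6, 3)$pass)      # 13 >= 13
  expect_match(check_eligibility(4, 100, 0)$reason, "group")
})

test_that("VIF computation matches the closed form and reference oracles", {
  set.seed(3)
  n <- 500
  # centred orthogonal predictors: all VIFs 1
  X <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  expect_equal(as.vector(compute_vif(X)), rep(1, 3), tolerance = 1e-8)
  # duplicated predictor: infinite, flagged
  Xd <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  Xd <- cbind(Xd, x3 = Xd[, "x1"])
  v <- compute_vif(Xd)
  expect_equal(unname(v[c("x1", "x3")]), c(Inf, Inf))
  expect_true(all(attr(v, "flagged")[c("x1", "x3")]))
  # two predictors correlated at r: VIF = 1/(1 - r^2); r = 0.9 flags (5.263)
  r <- 0.9
  x1 <- rnorm(n)
  x2 <- r * x1 + sqrt(1 - r^2) * rnorm(n)
  v2 <- compute_vif(cbind(x1 = x1, x2 = x2))
  r_emp <- cor(x1, x2)
  expect_equal(as.vector(v2), rep(1 / (1 - r_emp^2), 2), tolerance = 1e-8)
  expect_gt(1 / (1 - 0.9^2), 5)     # 5.263: the construction is flagged
  # cross-check against the regression-based reference implementation
  skip_if_not_installed("car")
  df <- data.frame(y = rnorm(n), x1 = x1, x2 = x2)
  ref <- car::vif(lm(y ~ x1 + x2, df))
  expect_equal(as.vector(v2), unname(ref), tolerance = 1e-8)
})

test_that("t to Cohen's d conversion reproduces the stated equations", {
  expect_equal(t_to_cohens_d(0, 40, 60, 96), 0)
  expect_equal(t_to_cohens_d(2, 50, 50, 96), 2 * 100 / (50 * sqrt(96)))
  expect_equal(round(t_to_cohens_d(2, 50, 50, 96), 4), 0.4082)
  expect_equal(d_standard_error(0, 50, 50), sqrt((99 / 97) * (4 / 100)))
  expect_equal(d_standard_error(0, 50, 50), 0.20205, tolerance = 1e-4)
  # se strictly increasing in |d| at fixed n
  ds <- seq(0, 2, by = 0.1)
  expect_true(all(diff(d_standard_error(ds, 50, 50)) > 0))
  # CI width is exactly 2 * 1.96 * se
  ci <- ci95(0.3, 0.1)
  expect_equal(unname(ci["high"] - ci["low"]), 2 * 1.96 * 0.1)
  expect_error(d_standard_error(0, 1, 2), "exceed 3")
})

test_that("diagnosis-only model t and d match classical two-group oracles", {
  for (seed in 1:10) {
    n1 <- sample(20:60, 1)
    n2 <- sample(20:60, 1)
    df <- two_group_frame(n1, n2, delta = 0.3, seed = seed)
    X <- cbind(1, df$diagnosis)
    colnames(X) <- c("(Intercept)", "diagnosis")
    fit <- asymmeta:::ols_term_t(X, df$ai_test, "diagnosis")
    tt <- t.test(ai_test ~ diagnosis, df, var.equal = TRUE)
    expect_equal(unname(fit$t), -unname(tt$statistic), tolerance = 1e-10)
    # the conversion equals classical pooled-SD Cohen's d up to the exact
    # finite-sample factor sqrt(N / (N - 2)) implied by the stated formula
    d_conv <- t_to_cohens_d(fit$t, n1, n2, fit$df)
    g0 <- df$ai_test[df$diagnosis == 0]
    g1 <- df$ai_test[df$diagnosis == 1]
    sp <- sqrt(((n1 - 1) * var(g0) + (n2 - 1) * var(g1)) / (n1 + n2 - 2))
    d_classic <- (mean(g1) - mean(g0)) / sp
    N <- n1 + n2
    expect_equal(unname(d_conv), d_classic * sqrt(N / (N - 2)),
                 tolerance = 1e-10)
    # and is asymptotically the classical value
    expect_equal(unname(d_conv), d_classic, tolerance = 2 / (N - 2) + 1e-3)
  }
})

test_that("site model is scale-free, coding-symmetric and dummy-invariant", {
  ai <- small_ai_table(seed = 10, n_sites = 5, mean_n = 120)
  rows <- as.data.frame(ai)[ai$dataset_id == "site05", ]   # two scanners
  expect_gt(length(unique(rows$scanner_id)), 1)
  base <- fit_site_model(rows, "thick_precuneus", "m1")
  expect_false(base$skipped)

  # multiplying the response by a constant leaves t, d, se unchanged
  sc <- rows
  sc$ai_thick_precuneus <- sc$ai_thick_precuneus * 37
  scaled <- fit_site_model(sc, "thick_precuneus", "m1")
  expect_equal(scaled[c("t", "d", "se_d")], base[c("t", "d", "se_d")],
               tolerance = 1e-10)

  # swapping the diagnosis coding flips t and d and mirrors the CI
  fl <- rows
  fl$diagnosis <- 1L - fl$diagnosis
  flipped <- fit_site_model(fl, "thick_precuneus", "m1")
  expect_equal(flipped$t, -base$t, tolerance = 1e-10)
  expect_equal(flipped$d, -base$d, tolerance = 1e-10)
  expect_equal(flipped$ci_low, -base$ci_high, tolerance = 1e-10)

  # a constant shift on one scanner's responses is absorbed by its dummy
  sh <- rows
  idx <- sh$scanner_id == sort(unique(sh$scanner_id))[2]
  sh$ai_thick_precuneus[idx] <- sh$ai_thick_precuneus[idx] + 0.5
  shifted <- fit_site_model(sh, "thick_precuneus", "m1")
  expect_equal(shifted$t, base$t, tolerance = 1e-8)
})

test_that("batch fitting equals the single-fit API and records skips", {
  ai <- small_ai_table(seed = 11, n_sites = 3, mean_n = 50)
  eff <- fit_sitewise(ai, "m1", measures = c("vol_pallidum", "area_cuneus"))
  for (k in seq_len(nrow(eff))) {
    rows <- as.data.frame(ai)[ai$dataset_id == eff$dataset_id[k], ]
    single <- fit_site_model(rows, eff$measure_id[k], "m1")
    expect_equal(eff$t[k], single$t, tolerance = 1e-12)
    expect_equal(eff$d[k], single$d, tolerance = 1e-12)
  }
  # a tiny dataset is skipped with its reason recorded
  tiny <- as.data.frame(ai)[ai$dataset_id == "site01", ][1:8, ]
  tiny$diagnosis <- rep(c(0L, 1L), 4)
  rec <- fit_site_model(tiny, "vol_pallidum", "m1")
  expect_true(rec$skipped)
  expect_match(rec$skip_reason, "group|total")
})

test_that("unilateral post hoc models analyse each hemisphere separately", {
  ai <- small_ai_table(seed = 12, n_sites = 2, mean_n = 80)
  effL <- fit_sitewise(ai, "unilateral_posthoc",
                       measures = "thick_middletemporal", response = "L")
  effR <- fit_sitewise(ai, "unilateral_posthoc",
                       measures = "thick_middletemporal", response = "R")
  expect_true(all(!effL$skipped) && all(!effR$skipped))
  expect_identical(effL$response, rep("L", nrow(effL)))
  expect_false(isTRUE(all.equal(effL$t, effR$t)))
})
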