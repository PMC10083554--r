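# Shared fixtures: small synthetic cohorts built in code at test time.

small_cohort <- function(seed = 1, n_sites = 3, mean_n = 60,
                         effects = effect_spec()) {
  generate_cohort(sites = default_site_specs(n_sites, mean_n),
                  effects = effects, seed = seed)
}

small_ai_table <- function(seed = 1, n_sites = 3, mean_n = 60,
                           effects = effect_spec()) {
  build_ai_table(small_cohort(seed, n_sites, mean_n, effects)$data)
}

# one-dataset two-group frame with a single synthetic AI column, used for
# oracle comparisons against classical two-sample statistics
two_group_frame <- function(n1, n2, delta = 0, sd = 1, seed = 1) {
  set.seed(seed)
  data.frame(
    dataset_id = "dsA",
    scanner_id = "dsA_s1",
    individual_id = sprintf("i%03d", seq_len(n1 + n2)),
    diagnosis = rep(c(0L, 1L), c(n1, n2)),
    sex = rbinom(n1 + n2, 1, 0.5),
    age = round(rnorm(n1 + n2, 33, 10), 1),
    ai_test = rnorm(n1 + n2, 0, sd) + rep(c(0, delta), c(n1, n2)),
    stringsAsFactors = FALSE)
}

# brute-force Benjamini-Hochberg: q_(i) = min_{j >= i} m * p_(j) / j
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- pmin(1, m * ps / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

# profiled restricted log-likelihood of the intercept-only random-effects
# model, evaluated on a grid of tau^2 values (independent grid-search oracle)
reml_loglik_grid <- function(y, v, tau2_grid) {
  vapply(tau2_grid, function(t2) {
    w <- 1 / (v + t2)
    mu <- sum(w * y) / sum(w)
    -0.5 * (sum(log(v + t2)) + log(sum(w)) + sum(w * (y - mu)^2))
  }, numeric(1))
}
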