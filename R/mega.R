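#' Empirical-Bayes batch harmonization of a measure matrix
#'
#' Removes batch (dataset x scanner) location and scale effects from a
#' matrix of individuals x measures using the parametric empirical-Bayes
#' location/scale model (ComBat): features are standardized against the
#' covariate fit, per-batch location and scale parameters are estimated and
#' shrunk toward batch-level priors, batch effects are removed and the
#' covariate structure restored. Left-hemisphere and right-hemisphere
#' matrices are harmonized in separate calls; the biological covariates
#' (diagnosis, age, sex) are preserved while harmonization parameters are
#' estimated.
#'
#' @param mat Numeric matrix, individuals in rows, measures in columns,
#'   no missing values.
#' @param batch Batch label per individual (dataset x scanner); every batch
#'   must contain at least 2 individuals.
#' @param mod Covariate model matrix to preserve (e.g.
#'   `model.matrix(~ diagnosis + age + sex)`), full rank.
#' @param verbose Print progress messages from the harmonization fit.
#' @return The adjusted matrix (same dimensions and dimnames).
#' @export
combat_harmonize <- function(mat, batch, mod = NULL, verbose = FALSE) {
  mat <- as.matrix(mat)
  if (anyNA(mat)) stop("harmonization input must be complete (no NA)")
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop("at least 2 batches are required")
  sizes <- table(batch)
  if (any(sizes < 2))
    stop("singleton batch(es): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  for (b in levels(batch)) {
    vars <- apply(mat[batch == b, , drop = FALSE], 2, stats::var)
    if (any(vars <= 0))
      stop("zero-variance feature within batch ", b, ": ",
           paste(colnames(mat)[vars <= 0], collapse = ", "))
  }
  if (!is.null(mod)) {
    mod <- as.matrix(mod)
    if (qr(mod)$rank < ncol(mod)) stop("covariate design is rank deficient")
  }
  fun <- function() sva::ComBat(dat = t(mat), batch = batch, mod = mod,
                                par.prior = TRUE, prior.plots = FALSE)
  adj <- if (verbose) fun() else suppressMessages(fun())
  t(adj)
}

#' Post-harmonization quality control
#'
#' Drops individuals left with a non-positive adjusted value on any
#' volume-family (subcortical) measure after harmonization (such values are
#' artefacts of the location/scale adjustment and make the asymmetry index
#' undefined), and enforces complete data on all supplied measures.
#'
#' @param left,right Adjusted matrices (individuals x measures, same
#'   column order), columns named by `measure_id`.
#' @param catalog Region catalog used to identify the volume family.
#' @return List with `keep` (logical per individual), `n_dropped_negative`,
#'   `n_dropped_incomplete`.
#' @export
post_harmonization_qc <- function(left, right, catalog = dk_region_catalog()) {
  stopifnot(identical(dim(left), dim(right)))
  vol_cols <- intersect(colnames(left),
                        catalog$measure_id[catalog$family == "subcortical"])
  complete <- stats::complete.cases(left) & stats::complete.cases(right)
  nonpos <- rep(FALSE, nrow(left))
  if (length(vol_cols)) {
    lv <- left[, vol_cols, drop = FALSE]
    rv <- right[, vol_cols, drop = FALSE]
    nonpos <- rowSums(lv <= 0, na.rm = TRUE) > 0 |
      rowSums(rv <= 0, na.rm = TRUE) > 0
  }
  keep <- complete & !nonpos
  list(keep = keep,
       n_dropped_negative = sum(complete & nonpos),
       n_dropped_incomplete = sum(!complete))
}

#' Pairwise correlation screen of asymmetry indices
#'
#' Computes the Pearson correlation matrix of the asymmetry indices
#' entering the multivariate model and reports the maximum absolute
#' off-diagonal correlation; a warning (not a failure) is raised when it
#' exceeds the threshold (default 0.5). Constant columns yield undefined
#' correlations, reported as `NA` with a warning.
#'
#' @param ai_mat Numeric matrix of asymmetry indices.
#' @param threshold Warning threshold on |r|.
#' @return List with `max_abs_r` and `cor_matrix`.
#' @export
correlation_screen <- function(ai_mat, threshold = 0.5) {
  ai_mat <- as.matrix(ai_mat)
  if (ncol(ai_mat) < 2) stop("at least 2 columns are required")
  sds <- apply(ai_mat, 2, stats::sd, na.rm = TRUE)
  if (any(sds == 0))
    warning("constant column(s); correlations undefined: ",
            paste(colnames(ai_mat)[sds == 0], collapse = ", "))
  cm <- suppressWarnings(stats::cor(ai_mat, use = "pairwise.complete.obs"))
  off <- abs(cm[upper.tri(cm)])
  max_abs_r <- if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE)
  if (!is.na(max_abs_r) && max_abs_r > threshold)
    warning(sprintf("maximum pairwise |r| = %.3f exceeds %.2f",
                    max_abs_r, threshold))
  list(max_abs_r = max_abs_r, cor_matrix = cm)
}

#' Rao's F approximation for Wilks' lambda (single-df hypothesis)
#'
#' For a one-degree-of-freedom hypothesis on `p` responses with a design of
#' rank `r` in `n` individuals, `df1 = p`, `df2 = n - r - p + 1` and
#' `F = ((1 - Lambda) / Lambda) * (df2 / df1)`; the transformation is exact
#' in form for single-df hypotheses. The share of multivariate variance
#' associated with the hypothesis is `1 - Lambda`.
#'
#' @param lambda Wilks' lambda in (0, 1].
#' @param p Number of response variables.
#' @param n Number of individuals.
#' @param rank_design Rank of the full design matrix (including intercept).
#' @return List with `F`, `df1`, `df2`, `p_value`, `variance_explained`.
#' @examples
#' wilks_to_f(0.932, p = 76, n = 2029, rank_design = 4)
#' @export
wilks_to_f <- function(lambda, p, n, rank_design) {
  stopifnot(lambda > 0, lambda <= 1)
  df1 <- p
  df2 <- n - rank_design - p + 1
  if (df2 <= 0) stop("insufficient residual degrees of freedom")
  Fstat <- ((1 - lambda) / lambda) * (df2 / df1)
  list(F = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       variance_explained = 1 - lambda)
}

#' MANCOVA of all asymmetry indices on diagnosis
#'
#' Tests all asymmetry indices simultaneously against case-control status
#' with age and sex as covariates. Wilks' lambda is `det(E) / det(E + H)`
#' where `E` is the residual SSCP matrix of the full model and `H` the
#' hypothesis SSCP for diagnosis; Rao's approximation converts it to an F
#' statistic ([wilks_to_f()]).
#'
#' @param Y Numeric matrix of responses (individuals x measures), complete.
#' @param diagnosis 0/1 vector (control = 0, case = 1).
#' @param age,sex Covariates.
#' @return A list of class `mancova_result`: `lambda`, `F`, `df1`, `df2`,
#'   `p_nominal`, `variance_explained`, `n`.
#' @export
mancova_wilks <- function(Y, diagnosis, age, sex) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  p <- ncol(Y)
  X0 <- cbind(1, age, sex)
  X <- cbind(X0, diagnosis)
  r <- qr(X)$rank
  if (n <= p + r) stop("sample too small: need N > p + rank(design)")
  q0 <- qr(X0)
  Yr <- qr.resid(q0, Y)
  dr <- qr.resid(q0, diagnosis)
  s <- sum(dr^2)
  if (s == 0) stop("diagnosis is collinear with the covariates")
  Tm <- crossprod(Yr)                      # E + H
  cT <- tryCatch(chol(Tm), error = function(e) NULL)
  if (is.null(cT)) {
    qy <- qr(Yr)
    bad <- colnames(Y)[qy$pivot[-seq_len(qy$rank)]]
    stop("response set is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  h <- crossprod(Yr, dr)                   # p x 1
  u <- backsolve(cT, h, transpose = TRUE)
  lambda <- 1 - sum(u^2) / s               # det(E)/det(E+H), rank-one H
  rao <- wilks_to_f(lambda, p, n, r)
  structure(list(lambda = lambda, F = rao$F, df1 = rao$df1, df2 = rao$df2,
                 p_nominal = rao$p_value,
                 variance_explained = 1 - lambda, n = n),
            class = "mancova_result")
}

# derive a per-permutation RNG seed from (seed, index); counter-based so the
# stream for permutation b is independent of execution order
perm_seed <- function(seed, b) {
  as.integer((as.double(seed) * 1000003 + b * 7919) %% 2147483647)
}

# permute labels within each stratum, preserving per-stratum counts
permute_within_strata <- function(diagnosis, strata_idx, seed, b) {
  set.seed(perm_seed(seed, b))
  out <- diagnosis
  for (idx in strata_idx) out[idx] <- diagnosis[idx][sample.int(length(idx))]
  out
}

#' Stratified label-swapping permutation test for the MANCOVA
#'
#' Builds the permutation null of the MANCOVA F statistic by randomly
#' permuting case-control labels within each stratum (dataset, and scanner
#' within multiscanner datasets), preserving every stratum's case/control
#' counts on each draw, and recomputing the full MANCOVA F per permutation.
#' The permutation p-value is the number of permuted F statistics greater
#' than or equal to the observed F, divided by the number of permutations
#' (a zero count therefore reports p = 0; the resolution limit `1/n_perm`
#' is returned alongside). Strata containing a single diagnosis class are
#' left unchanged by construction and are reported.
#'
#' Permutation streams are derived from `(seed, permutation index)`, so the
#' result is reproducible and independent of chunking or execution order.
#'
#' @param Y Response matrix (individuals x measures), complete.
#' @param diagnosis 0/1 labels.
#' @param age,sex Covariates.
#' @param strata Stratum label per individual.
#' @param n_perm Number of permutations (>= 1).
#' @param seed Integer seed.
#' @param chunk Internal batch size for vectorised evaluation.
#' @return A list of class `mancova_result` extended with `p_perm`,
#'   `n_exceed`, `n_perm`, `seed`, `resolution`, `single_class_strata`.
#' @export
stratified_permutation_test <- function(Y, diagnosis, age, sex, strata,
                                        n_perm = 10000, seed = 1,
                                        chunk = 500) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  Y <- as.matrix(Y)
  n <- nrow(Y)
  stopifnot(length(diagnosis) == n, length(strata) == n)
  obs <- mancova_wilks(Y, diagnosis, age, sex)
  strata <- factor(strata)
  strata_idx <- split(seq_len(n), strata)
  single_class <- names(strata_idx)[vapply(strata_idx, function(i)
    length(unique(diagnosis[i])) < 2, logical(1))]

  X0 <- cbind(1, age, sex)
  q0 <- qr(X0)
  Yr <- qr.resid(q0, Y)
  cT <- chol(crossprod(Yr))
  df1 <- ncol(Y)
  df2 <- obs$df2
  n_exceed <- 0L
  b0 <- 0L
  while (b0 < n_perm) {
    nb <- min(chunk, n_perm - b0)
    D <- vapply(seq_len(nb) + b0, function(b)
      permute_within_strata(diagnosis, strata_idx, seed, b), numeric(n))
    Dr <- qr.resid(q0, D)
    s <- colSums(Dr^2)
    H <- crossprod(Yr, Dr)
    U <- backsolve(cT, H, transpose = TRUE)
    lam <- 1 - colSums(U^2) / s
    Fperm <- ((1 - lam) / lam) * (df2 / df1)
    n_exceed <- n_exceed + sum(Fperm >= obs$F - 1e-12)
    b0 <- b0 + nb
  }
  out <- unclass(obs)
  out$p_perm <- n_exceed / n_perm
  out$n_exceed <- as.integer(n_exceed)
  out$n_perm <- as.integer(n_perm)
  out$seed <- as.integer(seed)
  out$resolution <- 1 / n_perm
  out$single_class_strata <- single_class
  class(out) <- "mancova_result"
  out
}

#' Univariate ANCOVA follow-up of the multivariate model
#'
#' Per-response analysis of covariance for diagnosis adjusting for age and
#' sex, on the same individuals and responses as the MANCOVA; returns the
#' per-measure F statistics and nominal p-values ranked by significance
#' (no FDR adjustment here, matching the follow-up presentation of the
#' multivariate arm).
#'
#' @inheritParams mancova_wilks
#' @return data.frame with `measure_id`, `F`, `df1`, `df2`, `p`, sorted by
#'   `p`.
#' @export
univariate_followup <- function(Y, diagnosis, age, sex) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  X0 <- cbind(1, age, sex)
  X <- cbind(X0, diagnosis)
  r <- qr(X)$rank
  q0 <- qr(X0)
  qf <- qr(X)
  E0 <- colSums(qr.resid(q0, Y)^2)
  E1 <- colSums(qr.resid(qf, Y)^2)
  df2 <- n - r
  Fs <- (E0 - E1) / (E1 / df2)
  ps <- stats::pf(Fs, 1, df2, lower.tail = FALSE)
  out <- data.frame(measure_id = colnames(Y), F = Fs, df1 = 1L, df2 = df2,
                    p = ps, stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the pooled individual-level multivariate arm
#'
#' Orchestrates the mega-analysis on a pooled bilateral table: cleans
#' bilateral pairs, restricts to individuals with complete data on all 76
#' regional measures, harmonizes the left and right matrices separately
#' with [combat_harmonize()] (batch = dataset x scanner, preserving
#' diagnosis, age and sex), applies [post_harmonization_qc()], recomputes
#' asymmetry indices from the harmonized hemispheres, screens pairwise
#' correlations, and runs the MANCOVA with its stratified permutation test
#' and univariate follow-ups.
#'
#' @param bilateral Wide bilateral table (see [generate_cohort()]).
#' @param catalog Region catalog.
#' @param n_perm Number of label-swapping permutations.
#' @param seed Integer seed for the permutation streams.
#' @param harmonize Set `FALSE` to skip batch harmonization (e.g. for
#'   calibration studies of the permutation test itself).
#' @return List with `mancova` (the permutation [mancova_result]),
#'   `univariate` (follow-up table), `screen` (correlation screen),
#'   `qc` (drop counts), `n_analyzed`, `n_cases`, `n_controls`.
#' @export
run_mega <- function(bilateral, catalog = dk_region_catalog(),
                     n_perm = 10000, seed = 1, harmonize = TRUE) {
  validate_catalog(catalog)
  eligible <- catalog[catalog$multivariate_eligible, , drop = FALSE]
  m_ids <- eligible$measure_id
  L <- as.matrix(bilateral[paste0(m_ids, "_L")])
  R <- as.matrix(bilateral[paste0(m_ids, "_R")])
  colnames(L) <- colnames(R) <- m_ids
  cp <- clean_pair(as.vector(L), as.vector(R))
  L[] <- cp$L
  R[] <- cp$R
  complete <- stats::complete.cases(L) & stats::complete.cases(R)
  L <- L[complete, , drop = FALSE]
  R <- R[complete, , drop = FALSE]
  covs <- bilateral[complete, c("dataset_id", "scanner_id", "diagnosis",
                                "age", "sex"), drop = FALSE]
  batch <- interaction(covs$dataset_id, covs$scanner_id, drop = TRUE)
  if (harmonize) {
    mod <- stats::model.matrix(~diagnosis + age + sex, covs)
    L <- combat_harmonize(L, batch, mod)
    R <- combat_harmonize(R, batch, mod)
  }
  qc <- post_harmonization_qc(L, R, catalog)
  L <- L[qc$keep, , drop = FALSE]
  R <- R[qc$keep, , drop = FALSE]
  covs <- covs[qc$keep, , drop = FALSE]
  batch <- droplevels(batch[qc$keep])
  AI <- compute_ai(L, R)
  screen <- correlation_screen(AI)
  res <- stratified_permutation_test(AI, covs$diagnosis, covs$age, covs$sex,
                                     strata = batch, n_perm = n_perm,
                                     seed = seed)
  uni <- univariate_followup(AI, covs$diagnosis, covs$age, covs$sex)
  list(mancova = res, univariate = uni, screen = screen,
       qc = qc[c("n_dropped_negative", "n_dropped_incomplete")],
       n_analyzed = nrow(AI),
       n_cases = sum(covs$diagnosis == 1L),
       n_controls = sum(covs$diagnosis == 0L))
}

#' @export
print.mancova_result <- function(x, ...) {
  cat(sprintf("MANCOVA: Wilks' lambda = %.4f, F(%d, %d) = %.3f, p = %.3g\n",
              x$lambda, x$df1, x$df2, x$F, x$p_nominal))
  cat(sprintf("variance explained = %.1f%%\n",
              100 * x$variance_explained))
  if (!is.null(x$p_perm))
    cat(sprintf("permutation p = %.3g (%d / %d exceedances, seed %d)\n",
                x$p_perm, x$n_exceed, x$n_perm, x$seed))
  invisible(x)
}
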