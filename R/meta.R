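# Restricted maximum-likelihood estimation of the between-dataset variance
# tau^2 in the normal-normal model y_i ~ N(x_i' beta, v_i + tau^2).
# Fisher scoring on tau^2 (score / expected information), floored at zero,
# with a DerSimonian-Laird fallback on non-convergence. X defaults to an
# intercept column (ordinary random-effects pooling); a general X gives
# mixed-effects meta-regression.
reml_tau2 <- function(y, v, X = NULL, tol = 1e-8, maxit = 100) {
  k <- length(y)
  if (is.null(X)) X <- matrix(1, k, 1)
  X <- as.matrix(X)
  p <- ncol(X)
  if (k <= p) return(list(tau2 = 0, converged = TRUE, fallback = FALSE))

  # restricted log-likelihood (up to a constant), profiled over beta
  llfun <- function(t2) {
    w <- 1 / (v + t2)
    Xw <- X * w
    A <- crossprod(X, Xw)
    b <- solve(A, crossprod(Xw, y))
    r <- y - drop(X %*% b)
    -0.5 * (sum(log(v + t2)) +
              as.numeric(determinant(A, logarithm = TRUE)$modulus) +
              sum(w * r^2))
  }

  # DerSimonian-Laird style start
  w0 <- 1 / v
  A0 <- solve(crossprod(X, X * w0))
  b0 <- A0 %*% crossprod(X * w0, y)
  Q <- sum(w0 * (y - drop(X %*% b0))^2)
  denom <- sum(w0) - sum(diag(A0 %*% crossprod(X * w0, X * w0)))
  dl <- max(0, (Q - (k - p)) / max(denom, .Machine$double.eps))

  tau2 <- dl
  ll_cur <- llfun(tau2)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- 1 / (v + tau2)
    Xw <- X * w
    A <- solve(crossprod(X, Xw))
    b <- A %*% crossprod(Xw, y)
    r <- y - drop(X %*% b)
    Py <- w * r
    M2 <- crossprod(Xw, Xw)            # X' W^2 X
    M3 <- crossprod(Xw, Xw * w)        # X' W^3 X
    trP <- sum(w) - sum(diag(A %*% M2))
    AM <- A %*% M2
    trP2 <- sum(w^2) - 2 * sum(diag(A %*% M3)) + sum(AM * t(AM))
    score <- -0.5 * trP + 0.5 * sum(Py^2)
    info <- 0.5 * trP2
    if (info <= 0) break
    step <- score / info
    # step-halving: only accept steps that do not decrease the restricted
    # likelihood, so the iteration cannot stall off the optimum
    new <- max(0, tau2 + step)
    ll_new <- llfun(new)
    halvings <- 0L
    while (ll_new < ll_cur - 1e-12 && halvings < 30L) {
      step <- step / 2
      new <- max(0, tau2 + step)
      ll_new <- llfun(new)
      halvings <- halvings + 1L
    }
    if (halvings == 30L) new <- tau2
    if (abs(new - tau2) < tol * (1 + tau2)) {
      tau2 <- new
      converged <- TRUE
      break
    }
    tau2 <- new
    ll_cur <- llfun(tau2)
  }
  # the boundary is always a candidate when the likelihood is decreasing
  if (llfun(0) >= llfun(tau2)) tau2 <- 0
  if (!converged) {
    warning("REML Fisher scoring did not converge; ",
            "falling back to DerSimonian-Laird tau^2")
    return(list(tau2 = dl, converged = FALSE, fallback = TRUE))
  }
  list(tau2 = tau2, converged = converged, fallback = FALSE)
}

#' Random-effects pooling of per-dataset effect sizes (REML)
#'
#' Pools per-dataset Cohen's d estimates under the random-effects model
#' `d_i ~ N(mu, se_i^2 + tau^2)`, estimating the between-dataset variance
#' `tau^2` by restricted maximum likelihood (Fisher scoring, floored at
#' zero, DerSimonian-Laird fallback on non-convergence). The pooled effect
#' is the inverse-variance weighted mean with weights
#' `1 / (se_i^2 + tau^2)`; inference is by the Wald z statistic. Cochran's
#' Q and I^2 are reported at fixed-effect weights.
#'
#' @param d Numeric vector of per-dataset effects.
#' @param se Their standard errors (all positive).
#' @return A list of class `meta_result`: `k`, `d_pooled`, `se_pooled`,
#'   `z`, `p`, `tau2`, `Q`, `I2`, `converged`.
#' @examples
#' reml_pool(c(-0.1, -0.05, -0.12), c(0.04, 0.05, 0.06))
#' @export
reml_pool <- function(d, se) {
  if (length(d) == 0) stop("at least one effect is required")
  if (length(d) != length(se)) stop("d and se must have equal length")
  if (!all(is.finite(d)) || !all(is.finite(se)) || any(se <= 0))
    stop("non-finite effects or non-positive standard errors")
  k <- length(d)
  v <- se^2
  if (k == 1) {
    z <- d / se
    return(structure(list(k = 1L, d_pooled = d, se_pooled = se, z = z,
                          p = z_to_p_two_sided(z), tau2 = 0, Q = 0, I2 = 0,
                          converged = TRUE), class = "meta_result"))
  }
  est <- reml_tau2(d, v)
  w <- 1 / (v + est$tau2)
  d_pooled <- sum(w * d) / sum(w)
  se_pooled <- sqrt(1 / sum(w))
  z <- d_pooled / se_pooled
  wf <- 1 / v
  mu_f <- sum(wf * d) / sum(wf)
  Q <- sum(wf * (d - mu_f)^2)
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  structure(list(k = as.integer(k), d_pooled = d_pooled,
                 se_pooled = se_pooled, z = z, p = z_to_p_two_sided(z),
                 tau2 = est$tau2, Q = Q, I2 = I2,
                 converged = est$converged),
            class = "meta_result")
}

#' Two-sided p-value from a z statistic
#'
#' `p = 2 Phi(-|z|)`.
#'
#' @param z Finite z statistic (vectorised).
#' @return Two-sided normal p-value.
#' @examples
#' z_to_p_two_sided(-1.96)
#' @export
z_to_p_two_sided <- function(z) {
  if (any(!is.finite(z))) stop("z must be finite")
  2 * stats::pnorm(-abs(z))
}

#' Benjamini-Hochberg adjusted p-values within one family
#'
#' Step-up false-discovery-rate adjustment of a family of p-values. In the
#' primary analysis families are the 35 cortical thickness, 35 cortical
#' surface area, and 8 subcortical volume asymmetry indices, adjusted
#' separately; effects with q < 0.05 are declared significant.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values (same length/order as `p`).
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Meta-analyse a per-site summary table
#'
#' Groups a [fit_sitewise()] summary table by measure, pools the
#' non-skipped per-dataset effects with [reml_pool()], and adjusts the
#' pooled p-values by Benjamini-Hochberg within measure families
#' (thickness / area / subcortical by default; set
#' `family_mode = "all"` to treat every measure tested in the scan as one
#' family, as used for the interaction scans).
#'
#' @param site_effects data.frame from [fit_sitewise()].
#' @param catalog Region catalog supplying family labels.
#' @param family_mode `"measure_family"` or `"all"`.
#' @return data.frame with one row per measure: `measure_id`, `model_id`,
#'   `family`, `k`, `d_pooled`, `se_pooled`, `z`, `p`, `q`, `tau2`, `Q`,
#'   `I2`.
#' @export
meta_analyze <- function(site_effects, catalog = dk_region_catalog(),
                         family_mode = c("measure_family", "all")) {
  family_mode <- match.arg(family_mode)
  fams <- measure_families(catalog)
  used <- site_effects[!site_effects$skipped, , drop = FALSE]
  if (!nrow(used)) return(data.frame())
  out <- do.call(rbind, lapply(split(used, used$measure_id), function(g) {
    mr <- reml_pool(g$d, g$se_d)
    data.frame(measure_id = g$measure_id[1], model_id = g$model_id[1],
               family = unname(fams[g$measure_id[1]]),
               k = mr$k, d_pooled = mr$d_pooled, se_pooled = mr$se_pooled,
               z = mr$z, p = mr$p, q = NA_real_, tau2 = mr$tau2,
               Q = mr$Q, I2 = mr$I2, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  fam_key <- if (family_mode == "all") rep("all", nrow(out)) else out$family
  for (f in unique(fam_key)) {
    idx <- fam_key == f
    out$q[idx] <- bh_fdr(out$p[idx])
  }
  out
}

#' Mixed-effects meta-regression with a single moderator
#'
#' Regresses per-dataset effects on a dataset-level moderator (categorical
#' or numeric) under a random-effects model with REML `tau^2`, and tests
#' the moderator with a Wald omnibus chi-square on all non-intercept
#' coefficients (Cochran's Q_M test). A moderator that is constant across
#' datasets is skipped with a reason.
#'
#' @param d,se Per-dataset effects and standard errors.
#' @param moderator Vector of dataset-level moderator values.
#' @return List with `QM`, `df`, `p`, `coef`, `tau2`, `skipped`,
#'   `skip_reason`.
#' @export
meta_regress <- function(d, se, moderator) {
  if (length(unique(moderator[!is.na(moderator)])) < 2)
    return(list(QM = NA_real_, df = NA_integer_, p = NA_real_,
                coef = NULL, tau2 = NA_real_, skipped = TRUE,
                skip_reason = "moderator constant across datasets"))
  ok <- !is.na(moderator) & is.finite(d) & is.finite(se)
  d <- d[ok]; se <- se[ok]; moderator <- moderator[ok]
  X <- stats::model.matrix(~mod, data.frame(mod = moderator))
  if (length(d) <= ncol(X))
    return(list(QM = NA_real_, df = NA_integer_, p = NA_real_, coef = NULL,
                tau2 = NA_real_, skipped = TRUE,
                skip_reason = "fewer datasets than moderator levels"))
  v <- se^2
  est <- reml_tau2(d, v, X)
  w <- 1 / (v + est$tau2)
  A <- solve(crossprod(X, X * w))
  b <- drop(A %*% crossprod(X * w, d))
  j <- seq_len(ncol(X))[-1]
  QM <- drop(t(b[j]) %*% solve(A[j, j, drop = FALSE]) %*% b[j])
  list(QM = QM, df = length(j),
       p = stats::pchisq(QM, length(j), lower.tail = FALSE),
       coef = stats::setNames(b, colnames(X)), tau2 = est$tau2,
       skipped = FALSE, skip_reason = NA_character_)
}

#' Outlier-dataset sensitivity analysis
#'
#' Flags datasets whose externally studentized deleted residual from the
#' random-effects model exceeds a threshold (default 2.5 in absolute
#' value): for each dataset the model is re-pooled without it, and the
#' residual `(d_i - mu_{-i}) / sqrt(se_i^2 + tau2_{-i} + se(mu_{-i})^2)` is
#' computed. The meta-analysis is then re-run with the flagged datasets
#' excluded, and both results are reported.
#'
#' @param d,se Per-dataset effects and standard errors (k >= 3).
#' @param dataset_id Optional dataset labels.
#' @param threshold Absolute studentized-residual threshold.
#' @return List with `flagged` (dataset labels), `residuals`, `full`
#'   (the all-dataset [reml_pool()] result) and `repooled` (without the
#'   flagged datasets; identical to `full` if none flagged).
#' @export
outlier_sensitivity <- function(d, se, dataset_id = NULL, threshold = 2.5) {
  k <- length(d)
  if (k < 3) stop("outlier sensitivity requires at least 3 datasets")
  if (is.null(dataset_id)) dataset_id <- paste0("ds", seq_len(k))
  resid <- numeric(k)
  for (i in seq_len(k)) {
    mi <- reml_pool(d[-i], se[-i])
    resid[i] <- (d[i] - mi$d_pooled) /
      sqrt(se[i]^2 + mi$tau2 + mi$se_pooled^2)
  }
  names(resid) <- dataset_id
  flagged <- dataset_id[abs(resid) > threshold]
  full <- reml_pool(d, se)
  keep <- !(dataset_id %in% flagged)
  repooled <- if (all(keep)) full else reml_pool(d[keep], se[keep])
  list(flagged = flagged, residuals = resid, full = full,
       repooled = repooled)
}

#' Pool correlation coefficients across datasets
#'
#' Transforms per-dataset correlations to the Fisher z scale
#' (`atanh(r)`, standard error `1 / sqrt(n - 3 - n_adjust)` where
#' `n_adjust` counts partialled-out covariates), pools them with
#' [reml_pool()], and back-transforms the pooled value with `tanh`.
#'
#' @param r Per-dataset correlations (|r| < 1).
#' @param n Per-dataset sample sizes.
#' @param n_adjust Number of covariates partialled out of each correlation.
#' @return List with `k`, `r_pooled`, `z`, `p`, `tau2` (on the Fisher
#'   scale), `ci_low`, `ci_high` (back-transformed 95% CI).
#' @export
pool_correlations <- function(r, n, n_adjust = 0) {
  if (any(abs(r) >= 1)) stop("correlations must lie strictly within (-1, 1)")
  if (any(n - 3 - n_adjust <= 0)) stop("sample sizes too small to pool")
  fz <- atanh(r)
  se <- 1 / sqrt(n - 3 - n_adjust)
  mr <- reml_pool(fz, se)
  list(k = mr$k, r_pooled = tanh(mr$d_pooled), z = mr$z, p = mr$p,
       tau2 = mr$tau2,
       ci_low = tanh(mr$d_pooled - 1.96 * mr$se_pooled),
       ci_high = tanh(mr$d_pooled + 1.96 * mr$se_pooled))
}
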