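#' Per-dataset eligibility rule
#'
#' A dataset is skipped for a given model when its total analysed sample is
#' smaller than ten plus the number of scanner dummy covariates, or when
#' either diagnostic group has fewer than five individuals. Skipping is a
#' recorded outcome, not an error.
#'
#' @param n_controls,n_cases Group sizes among the analysed (complete-case)
#'   rows.
#' @param n_scanner_dummies Number of scanner dummy covariates in the model.
#' @param min_total,min_group The rule's constants (defaults 10 and 5).
#' @return A list with `pass` (logical) and `reason` (`NA` when passing).
#' @examples
#' check_eligibility(4, 100, 0)   # skip: group < 5
#' check_eligibility(5, 5, 0)     # pass: 10 >= 10
#' @export
check_eligibility <- function(n_controls, n_cases, n_scanner_dummies = 0,
                              min_total = 10, min_group = 5) {
  if (min(n_controls, n_cases) < min_group)
    return(list(pass = FALSE,
                reason = sprintf("diagnostic group smaller than %d",
                                 min_group)))
  if (n_controls + n_cases < min_total + n_scanner_dummies)
    return(list(pass = FALSE,
                reason = sprintf("total N %d below %d + %d scanner dummies",
                                 n_controls + n_cases, min_total,
                                 n_scanner_dummies)))
  list(pass = TRUE, reason = NA_character_)
}

#' Variance inflation factors of a design matrix
#'
#' For each non-intercept predictor column, the VIF is `1 / (1 - R^2)` from
#' regressing that column on all the others (with an intercept). Perfect
#' collinearity yields `Inf`. Values above the threshold (default 5) are
#' flagged.
#'
#' @param X Numeric design matrix of predictors, excluding the intercept.
#' @param threshold Flagging threshold.
#' @return Named numeric vector of VIFs with attribute `flagged` (logical
#'   vector of the same length).
#' @export
compute_vif <- function(X, threshold = 5) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  vifs <- stats::setNames(numeric(p), colnames(X))
  for (j in seq_len(p)) {
    y <- X[, j]
    tss <- sum((y - mean(y))^2)
    if (tss == 0) { vifs[j] <- Inf; next }
    Z <- cbind(1, X[, -j, drop = FALSE])
    rss <- sum(stats::lm.fit(Z, y)$residuals^2)
    r2 <- 1 - rss / tss
    vifs[j] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  attr(vifs, "flagged") <- vifs > threshold
  vifs
}

#' Convert a regression t-statistic to Cohen's d
#'
#' `d = t (n1 + n2) / (sqrt(n1 n2) sqrt(df))`, where `n1` is the number of
#' controls, `n2` the number of cases, and `df` the residual degrees of
#' freedom of the linear model. With diagnosis coded control = 0 / case = 1,
#' a negative `d` means a lower asymmetry index (less leftward / more
#' rightward) in cases.
#'
#' @param t Diagnosis (or interaction) t-statistic.
#' @param n1,n2 Group sizes (controls, cases).
#' @param df Residual degrees of freedom.
#' @return Cohen's d.
#' @export
t_to_cohens_d <- function(t, n1, n2, df) {
  stopifnot(df > 0, n1 > 0, n2 > 0)
  t * (n1 + n2) / (sqrt(n1 * n2) * sqrt(df))
}

#' Standard error of Cohen's d
#'
#' `se(d) = sqrt( ((n1 + n2 - 1) / (n1 + n2 - 3)) * (4 / (n1 + n2)) *
#' (1 + d^2 / 8) )`.
#'
#' @param d Cohen's d.
#' @param n1,n2 Group sizes; `n1 + n2` must exceed 3.
#' @return Standard error of d.
#' @export
d_standard_error <- function(d, n1, n2) {
  n <- n1 + n2
  if (any(n <= 3)) stop("n1 + n2 must exceed 3")
  sqrt(((n - 1) / (n - 3)) * (4 / n) * (1 + d^2 / 8))
}

#' 95% confidence interval for Cohen's d
#'
#' `d -/+ 1.96 se(d)`.
#'
#' @param d Cohen's d.
#' @param se_d Its standard error.
#' @return Numeric vector `c(low, high)` (or a 2-column matrix for vector
#'   input).
#' @export
ci95 <- function(d, se_d) {
  lo <- d - 1.96 * se_d
  hi <- d + 1.96 * se_d
  if (length(d) == 1L) c(low = lo, high = hi) else cbind(low = lo, high = hi)
}

# model registry: extracted term and model-specific behaviour per model id
model_registry <- function(model_id) {
  switch(model_id,
    m1 = list(term = "diagnosis"),
    m2_hand = list(term = "diagnosis"),
    m3_icv = list(term = "diagnosis"),
    m4_hand_icv = list(term = "diagnosis"),
    m5_age2 = list(term = "diagnosis"),
    m6_medication = list(term = "med_first", cases_only = TRUE),
    m8_dx_by_age = list(term = "dx_age"),
    m9_dx_by_sex = list(term = "dx_sex"),
    unilateral_posthoc = list(term = "diagnosis"),
    stop("unknown model_id: ", model_id))
}

# Prepare everything about one dataset x model that does not depend on the
# response: the covariate design (with NA rows kept), the extracted term,
# scanner dummy count, and the grouping vectors for eligibility counts.
# Age is centred on the dataset's observed mean for squared/interaction
# terms (numerical conditioning).
prepare_site_design <- function(rows, model_id) {
  reg <- model_registry(model_id)
  if (isTRUE(reg$cases_only)) rows <- rows[rows$diagnosis == 1L, , drop = FALSE]
  n <- nrow(rows)
  age <- rows$age
  age_c <- age - mean(age, na.rm = TRUE)
  cols <- list(`(Intercept)` = rep(1, n))
  if (model_id == "m6_medication") {
    mc <- rows$medication_class
    keep <- !is.na(mc) & mc %in% c("first_gen", "second_gen", "both", "none")
    med_first <- ifelse(mc == "first_gen", 1, 0)
    med_first[!keep] <- NA
    cols$med_first <- med_first
    cols$med_both <- ifelse(mc == "both", 1, 0)
    cols$med_none <- ifelse(mc == "none", 1, 0)
  } else {
    cols$diagnosis <- rows$diagnosis
  }
  cols$sex <- rows$sex
  cols$age <- age
  if (model_id == "m5_age2") cols$age_c2 <- age_c^2
  if (model_id == "m8_dx_by_age") cols$dx_age <- rows$diagnosis * age_c
  if (model_id == "m9_dx_by_sex") cols$dx_sex <- rows$diagnosis * rows$sex
  if (model_id %in% c("m2_hand", "m4_hand_icv"))
    cols$handedness <- rows$handedness
  if (model_id %in% c("m3_icv", "m4_hand_icv")) cols$icv <- rows$icv
  scanners <- sort(unique(rows$scanner_id))
  n_dummies <- 0L
  if (length(scanners) > 1) {
    for (s in scanners[-1])           # lexicographically first = reference
      cols[[paste0("scanner_", s)]] <- as.numeric(rows$scanner_id == s)
    n_dummies <- length(scanners) - 1L
  }
  X <- do.call(cbind, cols)
  cov_complete <- stats::complete.cases(X)
  group <- if (model_id == "m6_medication") {
    g <- rep(NA_integer_, n)
    g[!is.na(rows$medication_class) &
        rows$medication_class == "second_gen"] <- 0L
    g[!is.na(rows$medication_class) &
        rows$medication_class == "first_gen"] <- 1L
    g
  } else rows$diagnosis
  list(X = X, cov_complete = cov_complete, term = reg$term,
       n_dummies = n_dummies, group = group, rows = rows,
       dataset_id = rows$dataset_id[1], model_id = model_id)
}

# OLS t-statistic of a single term; NULL for rank-deficient designs
ols_term_t <- function(X, y, term) {
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R) || qr(X)$rank < ncol(X)) return(NULL)
  XtXinv <- chol2inv(R)
  beta <- drop(XtXinv %*% crossprod(X, y))
  names(beta) <- colnames(X)
  res <- y - drop(X %*% beta)
  df <- length(y) - ncol(X)
  if (df <= 0) return(NULL)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(XtXinv))
  j <- match(term, colnames(X))
  if (is.na(j)) return(NULL)
  list(t = beta[j] / se[j], beta = beta[j], se_beta = se[j], df = df)
}

skip_record <- function(dataset_id, measure_id, model_id, reason,
                        response = NA_character_) {
  data.frame(dataset_id = dataset_id, measure_id = measure_id,
             model_id = model_id, response = response,
             t = NA_real_, df = NA_real_, n1 = NA_integer_, n2 = NA_integer_,
             d = NA_real_, se_d = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, max_vif = NA_real_, vif_flag = FALSE,
             skipped = TRUE, skip_reason = reason, stringsAsFactors = FALSE)
}

# the single computational path: fit one prepared design against one
# response vector, with eligibility, t extraction and d conversion
fit_prepared <- function(prep, y, measure_id, response, vifs = NULL) {
  cc <- prep$cov_complete & !is.na(y)
  group <- prep$group[cc]
  n1 <- sum(group == 0L, na.rm = TRUE)
  n2 <- sum(group == 1L, na.rm = TRUE)
  elig <- check_eligibility(n1, n2, prep$n_dummies)
  if (!elig$pass)
    return(skip_record(prep$dataset_id, measure_id, prep$model_id,
                       elig$reason, response))
  fit <- ols_term_t(prep$X[cc, , drop = FALSE], y[cc], prep$term)
  if (is.null(fit))
    return(skip_record(prep$dataset_id, measure_id, prep$model_id,
                       "rank-deficient design", response))
  if (is.null(vifs))
    vifs <- compute_vif(prep$X[cc, -1, drop = FALSE])
  d <- t_to_cohens_d(fit$t, n1, n2, fit$df)
  se_d <- d_standard_error(d, n1, n2)
  ci <- ci95(d, se_d)
  data.frame(dataset_id = prep$dataset_id, measure_id = measure_id,
             model_id = prep$model_id, response = response,
             t = unname(fit$t), df = fit$df,
             n1 = as.integer(n1), n2 = as.integer(n2),
             d = unname(d), se_d = unname(se_d),
             ci_low = unname(ci[1]), ci_high = unname(ci[2]),
             max_vif = max(vifs), vif_flag = any(attr(vifs, "flagged")),
             skipped = FALSE, skip_reason = NA_character_,
             stringsAsFactors = FALSE)
}

response_column <- function(measure_id, response) {
  switch(response,
         ai = paste0("ai_", measure_id),
         L = paste0(measure_id, "_L"),
         R = paste0(measure_id, "_R"))
}

#' Fit one per-dataset univariate model
#'
#' Ordinary least-squares fit of one asymmetry index (or unilateral
#' measure) within one dataset, following the distributed-analysis
#' protocol: the primary model (`m1`) regresses the response on diagnosis,
#' sex and age, adding n-1 scanner dummy covariates for multi-scanner
#' datasets; covariate variants add handedness, intracranial volume, or a
#' centred squared-age term (`m2_hand`, `m3_icv`, `m4_hand_icv`,
#' `m5_age2`); interaction models add diagnosis-by-age or diagnosis-by-sex
#' products and extract the interaction t (`m8_dx_by_age`,
#' `m9_dx_by_sex`); the medication model (`m6_medication`) is fitted among
#' cases only with medication class, extracting the first- versus
#' second-generation contrast. The extracted t-statistic is converted to
#' Cohen's d with its standard error and 95% CI via [t_to_cohens_d()] and
#' [d_standard_error()]. Eligibility ([check_eligibility()]) is evaluated
#' on the complete-case rows of the model; collinearity is screened with
#' [compute_vif()] (VIF > 5 flags but never drops). Rows with missing
#' covariates are dropped for this model only.
#'
#' @param rows Rows of an [build_ai_table()] result for one dataset.
#' @param measure_id Catalog measure to analyse.
#' @param model_id One of `"m1"`, `"m2_hand"`, `"m3_icv"`, `"m4_hand_icv"`,
#'   `"m5_age2"`, `"m6_medication"`, `"m8_dx_by_age"`, `"m9_dx_by_sex"`,
#'   `"unilateral_posthoc"`.
#' @param response `"ai"` (default), or `"L"` / `"R"` for the unilateral
#'   post hoc models.
#' @param vifs Optional precomputed [compute_vif()] result (collinearity is
#'   a property of the predictors, so [fit_sitewise()] screens once per
#'   dataset and model); when `NULL` it is computed from this fit's design.
#' @return One-row data.frame (a site-effect record) with `t`, `df`, `n1`,
#'   `n2`, `d`, `se_d`, `ci_low`, `ci_high`, VIF diagnostics and skip
#'   status.
#' @export
fit_site_model <- function(rows, measure_id, model_id = "m1",
                           response = c("ai", "L", "R"), vifs = NULL) {
  response <- match.arg(response)
  col <- response_column(measure_id, response)
  if (is.null(rows[[col]])) stop("unknown response column: ", col)
  prep <- prepare_site_design(rows, model_id)
  fit_prepared(prep, prep$rows[[col]], measure_id, response, vifs)
}

#' Fit a model across all datasets and measures
#'
#' Runs the per-dataset model of [fit_site_model()] for every case-control
#' dataset and every requested measure, producing the per-site
#' summary-statistics table that the central meta-analysis consumes (one
#' row per dataset x measure x model, with t, df, group sizes, Cohen's d,
#' SE, CI and flags). Case-only datasets are skipped with a recorded
#' reason; the design is prepared once per dataset and the collinearity
#' screen run once per dataset and model.
#'
#' @param ai_table An [build_ai_table()] result (all datasets pooled).
#' @param model_id Model identifier, see [fit_site_model()].
#' @param measures Character vector of `measure_id`s; default all catalog
#'   measures.
#' @param catalog Region catalog (defaults to the one attached to
#'   `ai_table`).
#' @param response Response type passed to [fit_site_model()].
#' @return data.frame of site-effect records.
#' @export
fit_sitewise <- function(ai_table, model_id = "m1", measures = NULL,
                         catalog = NULL, response = "ai") {
  if (is.null(catalog)) catalog <- attr(ai_table, "catalog")
  if (is.null(catalog)) stop("catalog must be supplied")
  if (is.null(measures)) measures <- catalog$measure_id
  reg <- model_registry(model_id)
  resp_cols <- vapply(measures, response_column, "", response = response)
  df <- as.data.frame(ai_table)
  out <- vector("list", 0L)
  for (ds in unique(df$dataset_id)) {
    rows <- df[df$dataset_id == ds, , drop = FALSE]
    case_only <- all(rows$diagnosis == 1L)
    if (case_only && !isTRUE(reg$cases_only)) {
      out[[length(out) + 1L]] <- do.call(rbind, lapply(measures, function(m)
        skip_record(ds, m, model_id, "case-only dataset", response)))
      next
    }
    prep <- prepare_site_design(rows, model_id)
    Y <- as.matrix(prep$rows[resp_cols])
    vifs <- tryCatch(
      compute_vif(prep$X[prep$cov_complete, -1, drop = FALSE]),
      error = function(e) NULL)
    out[[length(out) + 1L]] <- do.call(rbind, lapply(seq_along(measures),
      function(j) fit_prepared(prep, Y[, j], measures[j], response, vifs)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
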