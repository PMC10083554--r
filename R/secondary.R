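# partial correlation of x and y adjusting for covariate matrix Z
partial_cor <- function(x, y, Z) {
  cc <- stats::complete.cases(x, y, Z)
  x <- x[cc]; y <- y[cc]
  Z <- as.matrix(Z)[cc, , drop = FALSE]
  n <- length(x)
  if (n < 4 + ncol(Z)) return(list(r = NA_real_, n = n))
  q <- qr(cbind(1, Z))
  rx <- qr.resid(q, x)
  ry <- qr.resid(q, y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    return(list(r = NA_real_, n = n))
  list(r = stats::cor(rx, ry), n = n)
}

#' Interaction scans across all asymmetry indices
#'
#' Fits the diagnosis-by-age or diagnosis-by-sex interaction model in every
#' case-control dataset (both main effects always included), converts the
#' interaction t-statistic to Cohen's d with the same conversion chain as
#' the primary analysis, pools across datasets by REML, and adjusts the
#' pooled p-values by Benjamini-Hochberg over all asymmetry indices tested
#' in the scan (a single FDR family).
#'
#' @param ai_table An [build_ai_table()] result.
#' @param which `"dx_by_age"` or `"dx_by_sex"`.
#' @param measures Measures to scan (default: all catalog measures).
#' @param catalog Region catalog.
#' @return List with `site_effects` (per-dataset records) and `meta`
#'   (pooled results, one row per measure, q over the whole scan).
#' @export
run_interaction_scan <- function(ai_table,
                                 which = c("dx_by_age", "dx_by_sex"),
                                 measures = NULL, catalog = NULL) {
  which <- match.arg(which)
  model_id <- if (which == "dx_by_age") "m8_dx_by_age" else "m9_dx_by_sex"
  if (is.null(catalog)) catalog <- attr(ai_table, "catalog")
  eff <- fit_sitewise(ai_table, model_id, measures = measures,
                      catalog = catalog)
  meta <- meta_analyze(eff, catalog, family_mode = "all")
  list(site_effects = eff, meta = meta)
}

#' Within-group age trends of asymmetry and unilateral measures
#'
#' For one measure, computes the per-dataset partial correlation (adjusting
#' sex) of age with the asymmetry index and with the left and right
#' measurements separately, within cases and within controls, and pools
#' each correlation across datasets on the Fisher z scale with REML.
#' Dataset-group cells with fewer than `min_n` usable individuals are
#' skipped.
#'
#' @param ai_table An [build_ai_table()] result.
#' @param measure_id Measure to analyse.
#' @param min_n Minimum individuals per dataset per group.
#' @return data.frame with one row per group x response
#'   (`ai`, `L`, `R`): pooled `r`, `z`, `p`, `k` datasets.
#' @export
within_group_age_trends <- function(ai_table, measure_id, min_n = 10) {
  responses <- c(ai = paste0("ai_", measure_id),
                 L = paste0(measure_id, "_L"),
                 R = paste0(measure_id, "_R"))
  out <- list()
  for (grp in c(0L, 1L)) {
    rows <- ai_table[ai_table$diagnosis == grp, , drop = FALSE]
    for (resp in names(responses)) {
      col <- responses[[resp]]
      if (is.null(rows[[col]])) stop("unknown column: ", col)
      rs <- lapply(split(rows, rows$dataset_id), function(g)
        partial_cor(g$age, g[[col]], g["sex"]))
      r <- vapply(rs, `[[`, numeric(1), "r")
      n <- vapply(rs, `[[`, numeric(1), "n")
      ok <- !is.na(r) & n >= min_n & abs(r) < 1
      rec <- data.frame(group = if (grp == 1L) "cases" else "controls",
                        response = resp, measure_id = measure_id,
                        k = sum(ok), r_pooled = NA_real_, z = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE)
      if (sum(ok) >= 1) {
        pc <- pool_correlations(r[ok], n[ok], n_adjust = 1)
        rec$r_pooled <- pc$r_pooled
        rec$z <- pc$z
        rec$p <- pc$p
      }
      out[[length(out) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Medication-class contrast among cases
#'
#' Case-only per-dataset models of asymmetry on medication class (with sex,
#' age and scanner dummies), extracting the first- versus
#' second-generation antipsychotic contrast, converting it to Cohen's d,
#' pooling by REML, and adjusting over all tested asymmetry indices.
#' Datasets lacking at least five users of each generation are skipped.
#'
#' @param ai_table An [build_ai_table()] result.
#' @param measures Measures to test (default: all catalog measures).
#' @param catalog Region catalog.
#' @return List with `site_effects` and `meta` (as in
#'   [run_interaction_scan()]).
#' @export
medication_contrast <- function(ai_table, measures = NULL, catalog = NULL) {
  if (is.null(catalog)) catalog <- attr(ai_table, "catalog")
  eff <- fit_sitewise(ai_table, "m6_medication", measures = measures,
                      catalog = catalog)
  meta <- meta_analyze(eff, catalog, family_mode = "all")
  list(site_effects = eff, meta = meta)
}

#' Clinical correlation scan among cases
#'
#' For each (asymmetry index, clinical variable) pair, computes the
#' per-dataset partial correlation among cases (adjusting age and sex),
#' pools across datasets on the Fisher z scale with REML, and adjusts by
#' Benjamini-Hochberg over the whole tested grid. Dataset cells with fewer
#' than `min_n` non-missing cases, and zero-variance variables, are
#' skipped; pairs with no usable dataset produce no row.
#'
#' @param ai_table An [build_ai_table()] result.
#' @param measures Character vector of `measure_id`s.
#' @param variables Clinical column names (e.g. `"sans_total"`,
#'   `"duration_of_illness"`).
#' @param min_n Minimum non-missing cases per dataset.
#' @return data.frame with one row per tested pair: `measure_id`,
#'   `variable`, `k`, `r_pooled`, `z`, `p`, `q`.
#' @export
clinical_correlation_scan <- function(ai_table, measures, variables,
                                      min_n = 10) {
  cases <- ai_table[ai_table$diagnosis == 1L, , drop = FALSE]
  out <- list()
  for (m in measures) {
    col <- paste0("ai_", m)
    if (is.null(cases[[col]])) stop("unknown measure: ", m)
    for (v in variables) {
      if (is.null(cases[[v]])) stop("unknown clinical variable: ", v)
      rs <- lapply(split(cases, cases$dataset_id), function(g) {
        if (sum(stats::complete.cases(g[[col]], g[[v]], g$age, g$sex)) <
            min_n)
          return(list(r = NA_real_, n = 0L))
        if (stats::sd(g[[v]], na.rm = TRUE) %in% c(0, NA))
          return(list(r = NA_real_, n = 0L))
        partial_cor(g[[col]], g[[v]], g[c("age", "sex")])
      })
      r <- vapply(rs, `[[`, numeric(1), "r")
      n <- vapply(rs, `[[`, numeric(1), "n")
      ok <- !is.na(r) & n >= min_n & abs(r) < 1
      if (!sum(ok)) next
      pc <- pool_correlations(r[ok], n[ok], n_adjust = 2)
      out[[length(out) + 1L]] <- data.frame(
        measure_id = m, variable = v, k = sum(ok),
        r_pooled = pc$r_pooled, z = pc$z, p = pc$p, q = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(measure_id = character(), variable = character(),
                      k = integer(), r_pooled = numeric(), z = numeric(),
                      p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res$q <- bh_fdr(res$p)
  rownames(res) <- NULL
  res
}
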