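#' Clean a bilateral measurement pair
#'
#' Applies the pre-processing rules for bilateral measures: values equal to
#' zero are set to missing (they almost always reflect data-entry errors in
#' segmentation output), and whenever one hemisphere is missing the opposite
#' hemisphere is set missing too, so that asymmetry indices are only ever
#' computed from complete pairs. Negative inputs are physically impossible
#' for thickness, area or volume and are rejected with an error rather than
#' silently converted.
#'
#' Both arguments are vectorised and must have equal length. The operation
#' is idempotent.
#'
#' @param L,R Numeric vectors of left/right measurements (may contain `NA`).
#' @return A list with cleaned components `L` and `R`.
#' @examples
#' clean_pair(c(2.5, 2.5, NA), c(0, 2.4, 2.4))
#' @export
clean_pair <- function(L, R) {
  if (length(L) != length(R)) stop("L and R must have equal length")
  if (any(L < 0, na.rm = TRUE) || any(R < 0, na.rm = TRUE))
    stop("negative bilateral measurement encountered; ",
         "physically impossible input rejected")
  L[!is.na(L) & L == 0] <- NA_real_
  R[!is.na(R) & R == 0] <- NA_real_
  bad <- is.na(L) | is.na(R)
  L[bad] <- NA_real_
  R[bad] <- NA_real_
  list(L = L, R = R)
}

#' Compute the asymmetry index
#'
#' `AI = (L - R) / ((L + R) / 2)`. The denominator removes the automatic
#' scaling of a raw `L - R` difference with the overall magnitude of the
#' measure, so indices are comparable across regions and individuals.
#' Positive values indicate leftward asymmetry (`L > R`), negative values
#' rightward. For positive measures the index is bounded in (-2, 2), is
#' antisymmetric under swapping hemispheres, and is invariant under common
#' rescaling of both sides.
#'
#' @param L,R Positive numeric vectors (use [clean_pair()] first; `NA`
#'   propagates to `NA`).
#' @return Numeric vector of asymmetry indices.
#' @examples
#' compute_ai(2, 1)  # 2/3
#' @export
compute_ai <- function(L, R) {
  if (any(L <= 0, na.rm = TRUE) || any(R <= 0, na.rm = TRUE))
    stop("compute_ai requires strictly positive measurements; ",
         "clean the pair first")
  (L - R) / ((L + R) / 2)
}

#' Build the per-individual asymmetry-index table
#'
#' Converts a wide bilateral table (`<measure_id>_L` / `<measure_id>_R`
#' column pairs plus covariates) into an asymmetry-index table: one
#' `ai_<measure_id>` column per catalog measure, computed after applying
#' the [clean_pair()] rules. Cleaned left/right columns are retained so
#' that unilateral post hoc models can be fitted from the same object.
#' Family labels (35 thickness, 35 area, 8 subcortical) and the
#' 76-measure multivariate-eligibility mask travel with the catalog.
#'
#' @param table Bilateral data.frame (e.g. `generate_cohort()$data` or
#'   [read_bilateral_table()]).
#' @param catalog Region catalog; every `measure_id` must have both `_L`
#'   and `_R` columns in `table`.
#' @return A data.frame of class `ai_table` carrying the covariate columns,
#'   cleaned `_L`/`_R` columns and the `ai_*` columns, with attributes
#'   `catalog` and `missing_counts` (per-measure count of missing AIs).
#' @export
build_ai_table <- function(table, catalog = dk_region_catalog()) {
  validate_catalog(catalog)
  need <- c(paste0(catalog$measure_id, "_L"), paste0(catalog$measure_id, "_R"))
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("bilateral table is missing measure columns: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...")
  if (!"individual_id" %in% names(table))
    stop("bilateral table must contain an individual_id column")
  if (anyDuplicated(table$individual_id))
    stop("duplicated individual_id in bilateral table")

  covar_cols <- setdiff(names(table), need)
  out <- table[covar_cols]
  miss_counts <- integer(nrow(catalog))
  for (j in seq_len(nrow(catalog))) {
    m <- catalog$measure_id[j]
    cp <- clean_pair(table[[paste0(m, "_L")]], table[[paste0(m, "_R")]])
    out[[paste0(m, "_L")]] <- cp$L
    out[[paste0(m, "_R")]] <- cp$R
    ai <- rep(NA_real_, nrow(table))
    ok <- !is.na(cp$L)
    ai[ok] <- compute_ai(cp$L[ok], cp$R[ok])
    out[[paste0("ai_", m)]] <- ai
    miss_counts[j] <- sum(!ok)
  }
  names(miss_counts) <- catalog$measure_id
  structure(out, catalog = catalog, missing_counts = miss_counts,
            class = c("ai_table", "data.frame"))
}

#' Flag datasets with suspicious image orientation
#'
#' Heuristic quality-control flag for possible left/right image flips: for
#' a strongly lateralised reference measure, a dataset whose mean asymmetry
#' index has the opposite sign to the cohort-wide consensus (and is
#' non-trivially large) is flagged with a warning. Flagging is advisory
#' only; no data are altered.
#'
#' @param ai_table An [build_ai_table()] result.
#' @param measure Reference `measure_id`; default is the catalog entry with
#'   the largest absolute baseline mean AI.
#' @param min_abs Minimum |dataset mean AI| required to flag.
#' @return Character vector of flagged `dataset_id`s (possibly empty).
#' @export
flag_orientation <- function(ai_table, measure = NULL, min_abs = 0.01) {
  catalog <- attr(ai_table, "catalog")
  if (is.null(measure))
    measure <- catalog$measure_id[which.max(abs(catalog$baseline_mean_ai))]
  ai <- ai_table[[paste0("ai_", measure)]]
  if (is.null(ai)) stop("unknown measure: ", measure)
  consensus <- sign(mean(ai, na.rm = TRUE))
  ds_means <- tapply(ai, ai_table$dataset_id, mean, na.rm = TRUE)
  flagged <- names(ds_means)[!is.na(ds_means) &
                             sign(ds_means) == -consensus &
                             abs(ds_means) >= min_abs]
  if (length(flagged))
    warning("possible left/right orientation issue (", measure, ") in: ",
            paste(flagged, collapse = ", "))
  flagged
}
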