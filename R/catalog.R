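#' Desikan-Killiany region catalog for bilateral asymmetry analysis
#'
#' Builds the catalog of the 78 bilaterally paired brain structural measures
#' analysed by the pipeline: 34 Desikan-Killiany cortical regions measured for
#' thickness and for surface area, one hemisphere-level average per cortical
#' modality (mean thickness, total surface area), and 8 subcortical volumes.
#' Each entry carries a measurement family, a flag for hemisphere-level
#' averages, and the baseline parameters used by the synthetic cohort
#' generator: the bilateral mean and SD of the raw measure (mm, mm^2 or mm^3),
#' the population mean asymmetry index, and the between-individual SD of the
#' asymmetry index.
#'
#' Baselines are plausible adult values on the FreeSurfer scale; asymmetry
#' index means are small (|AI| <= 0.05 for thickness, <= 0.1 for area and
#' volume). The two hemisphere-average entries are excluded from the
#' multivariate arm, leaving 76 regional measures
#' (`multivariate_eligible`).
#'
#' @return A data.frame with one row per measure and columns `measure_id`,
#'   `family` (one of `"thickness"`, `"area"`, `"subcortical"`),
#'   `is_hemisphere_average`, `multivariate_eligible`,
#'   `baseline_bilateral_mean`, `baseline_bilateral_sd`, `baseline_mean_ai`,
#'   `ai_sd`.
#' @examples
#' cat34 <- dk_region_catalog()
#' table(cat34$family)
#' sum(cat34$multivariate_eligible)
#' @export
dk_region_catalog <- function() {
  regions <- c(
    "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
    "entorhinal", "frontalpole", "fusiform", "inferiorparietal",
    "inferiortemporal", "insula", "isthmuscingulate", "lateraloccipital",
    "lateralorbitofrontal", "lingual", "medialorbitofrontal",
    "middletemporal", "paracentral", "parahippocampal", "parsopercularis",
    "parsorbitalis", "parstriangularis", "pericalcarine", "postcentral",
    "posteriorcingulate", "precentral", "precuneus",
    "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
    "superiorparietal", "superiortemporal", "supramarginal", "temporalpole",
    "transversetemporal")

  thick_mean <- c(2.45, 2.65, 2.55, 1.85, 3.30, 2.70, 2.70, 2.45, 2.75, 3.05,
                  2.45, 2.15, 2.65, 2.00, 2.50, 2.85, 2.40, 2.75, 2.60, 2.65,
                  2.45, 1.65, 2.05, 2.50, 2.55, 2.35, 2.85, 2.40, 2.70, 2.15,
                  2.80, 2.55, 3.60, 2.35)
  thick_ai <- c(0.010, -0.015, 0.005, 0.008, -0.020, 0.000, 0.004, 0.012,
                -0.006, 0.015, -0.010, 0.003, 0.006, -0.004, 0.008, -0.008,
                0.002, 0.010, 0.012, -0.005, 0.006, 0.004, -0.006, 0.008,
                0.005, -0.003, 0.012, 0.004, -0.002, 0.006, 0.020, -0.004,
                -0.015, 0.025)
  thick_ai_sd <- c(0.060, 0.075, 0.055, 0.065, 0.090, 0.085, 0.050, 0.045,
                   0.050, 0.055, 0.070, 0.050, 0.055, 0.055, 0.065, 0.048,
                   0.060, 0.070, 0.060, 0.075, 0.060, 0.080, 0.050, 0.065,
                   0.045, 0.045, 0.088, 0.050, 0.040, 0.045, 0.050, 0.050,
                   0.090, 0.090)

  area_mean <- c(980, 700, 2250, 1500, 400, 250, 3400, 4900, 3600, 2250,
                 1000, 5100, 2600, 3300, 1900, 3500, 1600, 750, 1650, 700,
                 1500, 1450, 4400, 1200, 5200, 3900, 800, 6000, 7300, 5500,
                 3700, 3800, 450, 500)
  area_ai <- c(0.060, -0.030, 0.010, -0.040, 0.020, 0.010, 0.015, -0.050,
               0.020, -0.020, -0.030, 0.010, 0.015, 0.020, -0.015, 0.030,
               -0.010, 0.040, 0.050, -0.060, -0.040, 0.030, 0.010, -0.020,
               0.020, 0.010, 0.070, -0.010, 0.015, 0.020, 0.060, -0.030,
               0.040, 0.100)
  area_ai_sd <- c(0.110, 0.120, 0.090, 0.100, 0.130, 0.140, 0.080, 0.080,
                  0.090, 0.090, 0.110, 0.080, 0.080, 0.085, 0.095, 0.085,
                  0.100, 0.110, 0.105, 0.130, 0.110, 0.110, 0.080, 0.100,
                  0.075, 0.080, 0.120, 0.080, 0.070, 0.080, 0.085, 0.090,
                  0.130, 0.150)

  sub_id <- c("thalamus", "caudate", "putamen", "pallidum", "hippocampus",
              "amygdala", "accumbens", "lateralventricle")
  sub_mean <- c(7500, 3600, 5100, 1500, 4100, 1600, 550, 7600)
  sub_sd <- c(650, 420, 600, 220, 420, 220, 110, 3300)
  sub_ai <- c(0.005, -0.015, 0.020, 0.040, -0.020, 0.010, -0.030, -0.080)
  sub_ai_sd <- c(0.050, 0.060, 0.050, 0.090, 0.060, 0.090, 0.140, 0.300)

  out <- rbind(
    data.frame(measure_id = paste0("thick_", regions),
               family = "thickness", is_hemisphere_average = FALSE,
               baseline_bilateral_mean = thick_mean,
               baseline_bilateral_sd = 0.15,
               baseline_mean_ai = thick_ai, ai_sd = thick_ai_sd,
               stringsAsFactors = FALSE),
    data.frame(measure_id = "thick_hemi_mean",
               family = "thickness", is_hemisphere_average = TRUE,
               baseline_bilateral_mean = 2.50, baseline_bilateral_sd = 0.10,
               baseline_mean_ai = 0.002, ai_sd = 0.020,
               stringsAsFactors = FALSE),
    data.frame(measure_id = paste0("area_", regions),
               family = "area", is_hemisphere_average = FALSE,
               baseline_bilateral_mean = area_mean,
               baseline_bilateral_sd = 0.12 * area_mean,
               baseline_mean_ai = area_ai, ai_sd = area_ai_sd,
               stringsAsFactors = FALSE),
    data.frame(measure_id = "area_hemi_total",
               family = "area", is_hemisphere_average = TRUE,
               baseline_bilateral_mean = 89000, baseline_bilateral_sd = 8000,
               baseline_mean_ai = 0.010, ai_sd = 0.025,
               stringsAsFactors = FALSE),
    data.frame(measure_id = paste0("vol_", sub_id),
               family = "subcortical", is_hemisphere_average = FALSE,
               baseline_bilateral_mean = sub_mean, baseline_bilateral_sd = sub_sd,
               baseline_mean_ai = sub_ai, ai_sd = sub_ai_sd,
               stringsAsFactors = FALSE))
  out$multivariate_eligible <- !out$is_hemisphere_average
  rownames(out) <- NULL
  validate_catalog(out)
  out
}

#' Validate a region catalog
#'
#' Checks the structural invariants of a region catalog: 35 thickness + 35
#' area + 8 subcortical entries (78 total), exactly one hemisphere-average
#' entry per cortical family (76 multivariate-eligible measures), strictly
#' positive baseline means, and |mean AI| < 2.
#'
#' @param catalog A catalog data.frame as returned by [dk_region_catalog()].
#' @return The catalog, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_catalog <- function(catalog) {
  req <- c("measure_id", "family", "is_hemisphere_average",
           "baseline_bilateral_mean", "baseline_bilateral_sd",
           "baseline_mean_ai", "ai_sd")
  miss <- setdiff(req, names(catalog))
  if (length(miss))
    stop("catalog is missing columns: ", paste(miss, collapse = ", "))
  fam <- table(factor(catalog$family,
                      levels = c("thickness", "area", "subcortical")))
  if (!identical(as.integer(fam), c(35L, 35L, 8L)))
    stop("catalog must contain exactly 35 thickness, 35 area and 8 ",
         "subcortical entries; got ", paste(fam, collapse = "/"))
  hemi <- catalog[catalog$is_hemisphere_average, ]
  if (nrow(hemi) != 2L || !setequal(hemi$family, c("thickness", "area")))
    stop("catalog must contain exactly one hemisphere-average entry for ",
         "thickness and one for area")
  if (anyDuplicated(catalog$measure_id))
    stop("duplicated measure_id in catalog")
  if (any(catalog$baseline_bilateral_mean <= 0))
    stop("non-positive baseline bilateral mean in catalog")
  if (any(catalog$baseline_bilateral_sd <= 0) || any(catalog$ai_sd <= 0))
    stop("non-positive baseline SD in catalog")
  if (any(abs(catalog$baseline_mean_ai) >= 2))
    stop("baseline mean AI must lie strictly within (-2, 2)")
  invisible(catalog)
}

# family labels of all measures, named by measure_id
measure_families <- function(catalog) {
  stats::setNames(catalog$family, catalog$measure_id)
}
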