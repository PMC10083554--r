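#' Specification of one simulated acquisition site
#'
#' Describes a single case-control dataset in a simulated multi-site study:
#' group sizes, scanner mixture, demographics, and the site-level technical
#' offsets applied to the bilateral measures and asymmetry indices.
#'
#' @param dataset_id Character token identifying the dataset.
#' @param n_cases,n_controls Non-negative group sizes. A site with
#'   `n_controls = 0` is a case-only dataset and is skipped by all
#'   case-control stages downstream.
#' @param scanners data.frame with columns `scanner_id` and `proportion`
#'   (proportions must sum to 1). Default: a single scanner.
#' @param age_mean,age_sd Age distribution in years (truncated to 16-80).
#' @param male_fraction_cases,male_fraction_controls Proportions of males
#'   (sex is coded female = 0, male = 1).
#' @param site_offset_mean_scale Multiplicative offset applied to the
#'   baseline bilateral means of all measures at this site (scanner or
#'   protocol scaling).
#' @param site_offset_ai_shift Additive shift on all asymmetry indices at
#'   this site (e.g. a protocol-induced lateral bias).
#' @param noise_inflation Factor >= 1 inflating the measurement SD.
#' @return A list of class `site_spec`.
#' @export
site_spec <- function(dataset_id, n_cases, n_controls,
                      scanners = NULL,
                      age_mean = 33, age_sd = 10,
                      male_fraction_cases = 0.67,
                      male_fraction_controls = 0.52,
                      site_offset_mean_scale = 1,
                      site_offset_ai_shift = 0,
                      noise_inflation = 1) {
  if (is.null(scanners))
    scanners <- data.frame(scanner_id = paste0(dataset_id, "_s1"),
                           proportion = 1, stringsAsFactors = FALSE)
  stopifnot(is.data.frame(scanners),
            all(c("scanner_id", "proportion") %in% names(scanners)))
  if (n_cases < 0 || n_controls < 0)
    stop("group sizes must be non-negative")
  if (abs(sum(scanners$proportion) - 1) > 1e-8)
    stop("scanner proportions must sum to 1")
  if (noise_inflation < 1)
    stop("noise_inflation must be >= 1")
  structure(list(dataset_id = as.character(dataset_id),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 scanners = scanners,
                 age_mean = age_mean, age_sd = age_sd,
                 male_fraction_cases = male_fraction_cases,
                 male_fraction_controls = male_fraction_controls,
                 site_offset_mean_scale = site_offset_mean_scale,
                 site_offset_ai_shift = site_offset_ai_shift,
                 noise_inflation = noise_inflation),
            class = "site_spec")
}

#' Default multi-site study layouts
#'
#' Deterministic (seed-free) site specifications emulating a multi-site
#' consortium study. Sites vary in size, age structure, scanner count
#' (every fifth site uses two scanners), technical scaling, additive AI
#' offsets and noise level. The default layout (14 sites of about 145
#' individuals, ~46% cases) mirrors the scale of a pooled individual-level
#' subsample; `n_sites = 45` with `mean_n = 244` gives a consortium-scale
#' layout of roughly 5,000 cases and 6,000 controls.
#'
#' @param n_sites Number of case-control sites.
#' @param mean_n Average individuals per site.
#' @param case_fraction Average fraction of cases per site.
#' @param include_case_only If `TRUE`, append one case-only site (no
#'   controls), as can occur in real consortia; downstream case-control
#'   stages must skip it.
#' @return A list of [site_spec()] objects.
#' @export
default_site_specs <- function(n_sites = 14, mean_n = 145,
                               case_fraction = 0.46,
                               include_case_only = FALSE) {
  stopifnot(n_sites >= 1)
  i <- seq_len(n_sites)
  n_tot <- round(mean_n * seq(0.6, 1.4, length.out = n_sites))
  n_cases <- round(n_tot * (case_fraction + 0.04 * sin(2.3 * i)))
  n_controls <- n_tot - n_cases
  sites <- lapply(i, function(k) {
    two_scanners <- (k %% 5L) == 0L
    id <- sprintf("site%02d", k)
    scanners <- if (two_scanners)
      data.frame(scanner_id = paste0(id, c("_s1", "_s2")),
                 proportion = c(0.6, 0.4), stringsAsFactors = FALSE)
    else NULL
    site_spec(dataset_id = id,
              n_cases = n_cases[k], n_controls = n_controls[k],
              scanners = scanners,
              age_mean = 25 + 16 * (k - 1) / max(1, n_sites - 1),
              age_sd = 8 + 3 * ((k - 1) %% 3L) / 2,
              site_offset_mean_scale = 1 + 0.06 * sin(1.7 * k),
              site_offset_ai_shift = 0.008 * cos(2.1 * k),
              noise_inflation = 1 + 0.15 * ((k - 1) %% 3L))
  })
  if (include_case_only)
    sites <- c(sites, list(site_spec(
      dataset_id = sprintf("site%02d_caseonly", n_sites + 1L),
      n_cases = round(mean_n * 0.5), n_controls = 0)))
  sites
}

#' Ground-truth effect specification for the synthetic cohort
#'
#' Defines the true signal structure of a simulated study. Diagnosis effects
#' are given on the Cohen's d scale and are converted to asymmetry-index
#' units through each region's AI noise SD, so that the injected `d_true`
#' is recoverable by the downstream estimation chain. Any per-region
#' argument may be a single number (recycled to all regions) or a named
#' vector overriding specific `measure_id`s (unnamed regions get 0, or the
#' scalar default).
#'
#' @param d_true Diagnosis effect on AI per region, Cohen's d units.
#' @param dx_age_interaction Diagnosis-by-age interaction slope on AI per
#'   region, in Cohen's d units per year of (centred) age.
#' @param age_slope Age slope on AI per region, AI units per year.
#' @param sex_effect Sex (male - female) effect on AI per region, AI units.
#' @param missing_rate Proportion of left/right cells set missing.
#' @param zero_artifact_rate Proportion of left/right cells set to an exact
#'   zero, mimicking data-entry errors.
#' @param medication_effect Named vector: first- vs second-generation
#'   antipsychotic contrast on AI per region (cases only), Cohen's d units.
#' @param clinical_effects Optional data.frame with columns `measure_id`,
#'   `variable`, `r` injecting a within-case correlation of approximately
#'   `r` between a clinical variable and a region's AI.
#' @return A list of class `effect_spec`.
#' @export
effect_spec <- function(d_true = 0, dx_age_interaction = 0,
                        age_slope = -2e-4, sex_effect = 0.005,
                        missing_rate = 0.001, zero_artifact_rate = 5e-4,
                        medication_effect = 0,
                        clinical_effects = NULL) {
  for (r in c(missing_rate, zero_artifact_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  structure(list(d_true = d_true,
                 dx_age_interaction = dx_age_interaction,
                 age_slope = age_slope, sex_effect = sex_effect,
                 missing_rate = missing_rate,
                 zero_artifact_rate = zero_artifact_rate,
                 medication_effect = medication_effect,
                 clinical_effects = clinical_effects),
            class = "effect_spec")
}

#' All-null effect specification
#'
#' Convenience wrapper for a global-null study: no diagnosis, age, sex,
#' interaction, medication or clinical effects, and (by default) no
#' missingness or zero artifacts. Used for calibration checks.
#'
#' @param missing_rate,zero_artifact_rate Optional perturbation rates.
#' @return An [effect_spec()].
#' @export
null_effect_spec <- function(missing_rate = 0, zero_artifact_rate = 0) {
  effect_spec(d_true = 0, dx_age_interaction = 0, age_slope = 0,
              sex_effect = 0, missing_rate = missing_rate,
              zero_artifact_rate = zero_artifact_rate)
}

# expand a scalar-or-named-vector effect field to the full per-region vector
expand_effect <- function(x, measure_ids, default = 0) {
  out <- rep(if (length(x) == 1L && is.null(names(x))) x else default,
             length(measure_ids))
  names(out) <- measure_ids
  if (!is.null(names(x))) {
    unknown <- setdiff(names(x), measure_ids)
    if (length(unknown))
      stop("unknown measure_id in effect spec: ",
           paste(unknown, collapse = ", "))
    out[names(x)] <- x
  }
  out
}

# standard normal truncated to be positive, location mu scale sd (vectorised)
rnorm_pos <- function(n, mu, sd) {
  lo <- stats::pnorm(0, mu, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mu, sd)
}

rnorm_trunc <- function(n, mu, sd, lower, upper) {
  lo <- stats::pnorm(lower, mu, sd)
  hi <- stats::pnorm(upper, mu, sd)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mu, sd)
}

#' Generate a synthetic multi-site case-control bilateral cohort
#'
#' Simulates per-individual bilateral regional brain measures with known
#' ground truth. For each individual and region a latent bilateral size
#' `M ~ Normal(baseline mean x site scale, baseline SD x noise inflation)`
#' (truncated positive) and a latent asymmetry
#' `A = baseline AI + site shift + age and sex terms + diagnosis terms +
#' noise` are drawn, and the hemispheres are constructed as
#' `L = M (1 + A/2)`, `R = M (1 - A/2)`, so that the asymmetry index
#' `(L - R) / ((L + R)/2)` recovers `A` exactly. Missing values and exact
#' zeros (data-entry artifacts) are then injected at the specified rates.
#' Cases additionally receive clinical columns (medication class,
#' chlorpromazine-equivalent dose, age at onset, illness duration,
#' SANS/SAPS/PANSS scores).
#'
#' Age is centred at 33 years for all age-dependent terms, and diagnosis is
#' coded control = 0 / case = 1, sex female = 0 / male = 1.
#'
#' @param catalog Region catalog, see [dk_region_catalog()].
#' @param sites List of [site_spec()] objects (at least one).
#' @param effects An [effect_spec()] with the ground truth.
#' @param seed Integer seed; identical `(catalog, sites, effects, seed)`
#'   give byte-identical output.
#' @return A list of class `synthetic_cohort` with elements `data` (the
#'   wide bilateral table: `individual_id`, `dataset_id`, `scanner_id`,
#'   `diagnosis`, `age`, `sex`, `handedness`, `icv`, clinical columns, and
#'   one `<measure_id>_L` / `<measure_id>_R` pair per catalog entry) and
#'   `truth` (the effect specification echoed back, with the expanded
#'   per-region effect vectors attached).
#' @examples
#' cohort <- generate_cohort(sites = default_site_specs(2, 40), seed = 1)
#' dim(cohort$data)
#' @export
generate_cohort <- function(catalog = dk_region_catalog(),
                            sites = default_site_specs(),
                            effects = effect_spec(), seed) {
  if (missing(seed)) stop("seed must be supplied")
  validate_catalog(catalog)
  if (!length(sites)) stop("at least one site is required")
  if (!all(vapply(sites, inherits, logical(1), "site_spec")))
    stop("sites must be a list of site_spec objects")
  if (!inherits(effects, "effect_spec"))
    stop("effects must be an effect_spec object")
  set.seed(as.integer(seed))

  m_ids <- catalog$measure_id
  d_true <- expand_effect(effects$d_true, m_ids)
  dx_age <- expand_effect(effects$dx_age_interaction, m_ids)
  age_slope <- expand_effect(effects$age_slope, m_ids)
  sex_eff <- expand_effect(effects$sex_effect, m_ids)
  med_eff <- expand_effect(effects$medication_effect, m_ids)

  # per-individual demographic frame across all sites
  demo <- do.call(rbind, lapply(sites, function(s) {
    n <- s$n_cases + s$n_controls
    if (n == 0L) return(NULL)
    dx <- rep(c(1L, 0L), c(s$n_cases, s$n_controls))
    male_frac <- ifelse(dx == 1L, s$male_fraction_cases,
                        s$male_fraction_controls)
    scanner <- s$scanners$scanner_id[
      sample.int(nrow(s$scanners), n, replace = TRUE,
                 prob = s$scanners$proportion)]
    data.frame(dataset_id = s$dataset_id, scanner_id = scanner,
               diagnosis = dx,
               age = round(rnorm_trunc(n, s$age_mean, s$age_sd, 16, 80), 1),
               sex = as.integer(stats::runif(n) < male_frac),
               site_scale = s$site_offset_mean_scale,
               ai_shift = s$site_offset_ai_shift,
               noise_inflation = s$noise_inflation,
               stringsAsFactors = FALSE)
  }))
  n_tot <- nrow(demo)
  demo$individual_id <- sprintf("%s_i%04d", demo$dataset_id,
                                as.integer(stats::ave(seq_len(n_tot),
                                                      demo$dataset_id,
                                                      FUN = seq_along)))
  demo$handedness <- as.integer(stats::runif(n_tot) < 0.90) # right = 1
  demo$icv <- round(stats::rnorm(n_tot, 1.5e6, 1.5e5))

  clin <- simulate_clinical(demo)
  med_first <- !is.na(clin$medication_class) &
    clin$medication_class == "first_gen"
  age_c <- demo$age - 33

  # per-case clinical z-scores used for injected clinical correlations
  clin_z <- NULL
  if (!is.null(effects$clinical_effects)) {
    ce <- effects$clinical_effects
    stopifnot(all(c("measure_id", "variable", "r") %in% names(ce)))
    clin_z <- lapply(unique(ce$variable), function(v) {
      x <- clin[[v]]
      z <- (x - mean(x, na.rm = TRUE)) / stats::sd(x, na.rm = TRUE)
      z[is.na(z)] <- 0
      z
    })
    names(clin_z) <- unique(ce$variable)
  }

  lr <- vector("list", 2L * nrow(catalog))
  lr_names <- character(2L * nrow(catalog))
  for (j in seq_len(nrow(catalog))) {
    m <- catalog$measure_id[j]
    M <- rnorm_pos(n_tot,
                   catalog$baseline_bilateral_mean[j] * demo$site_scale,
                   catalog$baseline_bilateral_sd[j] * demo$noise_inflation)
    # the site's simulated AI noise SD; d-scale effects convert through it
    # so that d_true is recoverable as a Cohen's d at every site
    sd_ai <- catalog$ai_sd[j] * demo$noise_inflation
    A <- catalog$baseline_mean_ai[j] + demo$ai_shift +
      age_c * age_slope[m] + demo$sex * sex_eff[m] +
      demo$diagnosis * (d_true[m] * sd_ai) +
      demo$diagnosis * age_c * (dx_age[m] * sd_ai) +
      demo$diagnosis * (med_eff[m] * sd_ai) * med_first +
      stats::rnorm(n_tot, 0, sd_ai)
    if (!is.null(clin_z)) {
      ce_m <- effects$clinical_effects[
        effects$clinical_effects$measure_id == m, , drop = FALSE]
      for (q in seq_len(nrow(ce_m)))
        A <- A + demo$diagnosis * ce_m$r[q] * clin_z[[ce_m$variable[q]]] *
          sd_ai
    }
    A <- pmax(pmin(A, 1.95), -1.95)
    lr[[2L * j - 1L]] <- M * (1 + A / 2)
    lr[[2L * j]] <- M * (1 - A / 2)
    lr_names[2L * j - 1L] <- paste0(m, "_L")
    lr_names[2L * j] <- paste0(m, "_R")
  }
  names(lr) <- lr_names
  meas <- as.data.frame(lr)

  # inject artifacts cell-wise, after construction
  n_cells <- n_tot * ncol(meas)
  u <- stats::runif(n_cells)
  miss_idx <- which(u < effects$missing_rate)
  zero_idx <- which(u >= effects$missing_rate &
                    u < effects$missing_rate + effects$zero_artifact_rate)
  mm <- as.matrix(meas)
  mm[miss_idx] <- NA_real_
  mm[zero_idx] <- 0
  meas <- as.data.frame(mm)

  data <- cbind(
    demo[c("individual_id", "dataset_id", "scanner_id", "diagnosis",
           "age", "sex", "handedness", "icv")],
    clin, meas)
  rownames(data) <- NULL

  truth <- effects
  truth$expanded <- list(d_true = d_true, dx_age_interaction = dx_age,
                         age_slope = age_slope, sex_effect = sex_eff,
                         medication_effect = med_eff)
  structure(list(data = data, truth = truth, seed = as.integer(seed)),
            class = "synthetic_cohort")
}

# case-only clinical profile columns; controls get NA everywhere
simulate_clinical <- function(demo) {
  n <- nrow(demo)
  case <- demo$diagnosis == 1L
  med <- rep(NA_character_, n)
  med[case] <- sample(c("first_gen", "second_gen", "both", "none", "unknown"),
                      sum(case), replace = TRUE,
                      prob = c(0.15, 0.55, 0.10, 0.10, 0.10))
  cpz <- rep(NA_real_, n)
  on_med <- case & med %in% c("first_gen", "second_gen", "both")
  cpz[on_med] <- round(exp(stats::rnorm(sum(on_med), log(400), 0.6)))
  onset <- rep(NA_real_, n)
  onset[case] <- round(rnorm_trunc(sum(case), 23, 5, 12, demo$age[case]), 1)
  duration <- rep(NA_real_, n)
  duration[case] <- round(demo$age[case] - onset[case], 1)
  sans <- rep(NA_real_, n)
  sans[case] <- round(rnorm_trunc(sum(case), 25, 12, 0, 125))
  saps <- rep(NA_real_, n)
  saps[case] <- round(rnorm_trunc(sum(case), 20, 12, 0, 170))
  panss_pos <- rep(NA_real_, n)
  panss_pos[case] <- round(rnorm_trunc(sum(case), 15, 5, 7, 49))
  panss_neg <- rep(NA_real_, n)
  panss_neg[case] <- round(rnorm_trunc(sum(case), 15, 5, 7, 49))
  panss_tot <- rep(NA_real_, n)
  panss_tot[case] <- panss_pos[case] + panss_neg[case] +
    round(rnorm_trunc(sum(case), 30, 8, 16, 112))
  data.frame(medication_class = med, cpz_equivalent_dose = cpz,
             age_at_onset = onset, duration_of_illness = duration,
             sans_total = sans, saps_total = saps,
             panss_total = panss_tot, panss_positive = panss_pos,
             panss_negative = panss_neg, stringsAsFactors = FALSE)
}

#' Write a synthetic cohort to disk
#'
#' Writes the wide bilateral table as CSV and the ground-truth effect
#' specification as a sidecar JSON file.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "bilateral_table.csv")
  js <- file.path(dir, "ground_truth.json")
  utils::write.csv(cohort$data, csv, row.names = FALSE)
  truth <- cohort$truth
  class(truth) <- NULL
  jsonlite::write_json(truth, js, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(table = csv, truth = js))
}

#' Read a bilateral table written by [write_cohort()]
#'
#' @param path CSV path.
#' @return A data.frame in the wide bilateral-table layout.
#' @export
read_bilateral_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
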