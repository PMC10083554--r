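#' Pipeline run configuration
#'
#' Validated configuration object for [run_pipeline()]. All stages are pure
#' functions of (inputs, config, seed), so a run is fully reproduced by its
#' manifest.
#'
#' @param input Optional path to an existing bilateral-table CSV; when
#'   `NULL` a synthetic cohort is generated.
#' @param stages Character subset of
#'   `c("simulate", "ai", "sitewise", "meta", "mega")` (in pipeline order);
#'   `"all"` expands to all of them.
#' @param models Model identifiers run in the sitewise stage.
#' @param fdr_alpha Family-wise FDR significance level.
#' @param vif_threshold Collinearity flag threshold.
#' @param eligibility_min_total,eligibility_min_group Eligibility constants
#'   (total N below `min_total` + scanner dummies, or any group below
#'   `min_group`, skips a dataset).
#' @param outlier_threshold Studentized-residual threshold for the
#'   outlier sensitivity analysis.
#' @param n_perm Permutations for the multivariate arm.
#' @param seed Integer seed for all randomness.
#' @param n_sites,mean_n Synthetic layout (when simulating).
#' @param effects [effect_spec()] ground truth (when simulating).
#' @param out_dir Output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(input = NULL, stages = "all", models = "m1",
                       fdr_alpha = 0.05, vif_threshold = 5,
                       eligibility_min_total = 10, eligibility_min_group = 5,
                       outlier_threshold = 2.5, n_perm = 10000, seed = 1,
                       n_sites = 14, mean_n = 145, effects = effect_spec(),
                       out_dir = tempfile("asymmeta_run_")) {
  all_stages <- c("simulate", "ai", "sitewise", "meta", "mega")
  if (identical(stages, "all")) stages <- all_stages
  unknown <- setdiff(stages, all_stages)
  if (length(unknown)) stop("unknown stages: ", paste(unknown, collapse = ", "))
  if (fdr_alpha <= 0 || fdr_alpha >= 1) stop("fdr_alpha must lie in (0, 1)")
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (vif_threshold <= 0 || outlier_threshold <= 0)
    stop("thresholds must be positive")
  if (!is.null(input) && !file.exists(input))
    stop("input file not found: ", input)
  structure(list(input = input, stages = stages, models = models,
                 fdr_alpha = fdr_alpha, vif_threshold = vif_threshold,
                 eligibility_min_total = eligibility_min_total,
                 eligibility_min_group = eligibility_min_group,
                 outlier_threshold = outlier_threshold,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 n_sites = n_sites, mean_n = mean_n, effects = effects,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys match the arguments of [run_config()]
#' (the `effects` key, if present, is passed to [effect_spec()]).
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$effects)) {
    ef <- raw$effects
    for (fld in c("d_true", "dx_age_interaction", "age_slope", "sex_effect",
                  "medication_effect"))
      if (!is.null(ef[[fld]]) && is.list(ef[[fld]]))
        ef[[fld]] <- unlist(ef[[fld]])
    raw$effects <- do.call(effect_spec, ef)
  }
  do.call(run_config, raw)
}

# small polynomial rolling hash of a JSON rendering, for the manifest
# (arithmetic kept in doubles below 2^53 so it is exact on every platform)
config_hash <- function(config) {
  bytes <- utf8ToInt(as.character(
    jsonlite::toJSON(unclass(config)[setdiff(names(config), "out_dir")],
                     auto_unbox = TRUE, force = TRUE)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full asymmetry analysis pipeline
#'
#' Executes the configured stages in order: simulate (or load) the
#' bilateral table, build the asymmetry-index table, fit the per-dataset
#' models, meta-analyse (with outlier sensitivity for FDR-significant
#' measures), and run the pooled multivariate arm. Writes all stage
#' outputs as CSV/JSON under `config$out_dir` plus a machine-readable
#' `manifest.json` (package version, seed, config hash, per-stage row
#' counts). Any stage rejection surfaces as an error.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  catalog <- dk_region_catalog()
  manifest <- list(package = "asymmeta",
                   version = as.character(utils::packageVersion("asymmeta")),
                   seed = config$seed, config_hash = config_hash(config),
                   stages = config$stages, counts = list())
  results <- list()

  if (!is.null(config$input)) {
    bilateral <- read_bilateral_table(config$input)
  } else {
    if (!"simulate" %in% config$stages)
      stop("no input file given and simulate stage not requested")
    cohort <- generate_cohort(catalog,
                              default_site_specs(config$n_sites,
                                                 config$mean_n),
                              config$effects, seed = config$seed)
    write_cohort(cohort, config$out_dir)
    bilateral <- cohort$data
    results$cohort <- cohort
  }
  manifest$counts$individuals <- nrow(bilateral)

  if (any(c("ai", "sitewise", "meta", "mega") %in% config$stages)) {
    ai <- build_ai_table(bilateral, catalog)
    utils::write.csv(as.data.frame(ai), file.path(config$out_dir,
                                                  "ai_table.csv"),
                     row.names = FALSE)
    results$ai_table <- ai
    manifest$counts$ai_columns <- sum(startsWith(names(ai), "ai_"))
  }

  if (any(c("sitewise", "meta") %in% config$stages)) {
    eff <- do.call(rbind, lapply(config$models, function(m)
      fit_sitewise(ai, m, catalog = catalog)))
    utils::write.csv(eff, file.path(config$out_dir, "site_effects.csv"),
                     row.names = FALSE)
    results$site_effects <- eff
    manifest$counts$site_effect_rows <- nrow(eff)
  }

  if ("meta" %in% config$stages) {
    meta <- do.call(rbind, lapply(config$models, function(m)
      meta_analyze(eff[eff$model_id == m, ], catalog)))
    utils::write.csv(meta, file.path(config$out_dir, "meta_results.csv"),
                     row.names = FALSE)
    results$meta <- meta
    manifest$counts$meta_rows <- nrow(meta)
    # outlier sensitivity for measures significant at the configured FDR
    sig <- meta$measure_id[!is.na(meta$q) & meta$q < config$fdr_alpha]
    sens <- lapply(sig, function(m) {
      g <- eff[eff$measure_id == m & !eff$skipped, ]
      if (nrow(g) < 3) return(NULL)
      o <- outlier_sensitivity(g$d, g$se_d, g$dataset_id,
                               config$outlier_threshold)
      data.frame(measure_id = m,
                 flagged = paste(o$flagged, collapse = ";"),
                 d_repooled = o$repooled$d_pooled,
                 z_repooled = o$repooled$z, p_repooled = o$repooled$p,
                 stringsAsFactors = FALSE)
    })
    sens <- do.call(rbind, sens)
    if (!is.null(sens))
      utils::write.csv(sens, file.path(config$out_dir,
                                       "outlier_sensitivity.csv"),
                       row.names = FALSE)
    results$outlier_sensitivity <- sens
  }

  if ("mega" %in% config$stages) {
    mega <- run_mega(bilateral, catalog, n_perm = config$n_perm,
                     seed = config$seed)
    report <- c(unclass(mega$mancova)[c("lambda", "F", "df1", "df2",
                                        "p_nominal", "p_perm", "n_perm",
                                        "n_exceed", "seed",
                                        "variance_explained")],
                list(n_analyzed = mega$n_analyzed,
                     n_cases = mega$n_cases, n_controls = mega$n_controls,
                     max_abs_r = mega$screen$max_abs_r))
    jsonlite::write_json(report, file.path(config$out_dir,
                                           "mega_report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(mega$univariate,
                     file.path(config$out_dir, "univariate_followup.csv"),
                     row.names = FALSE)
    results$mega <- mega
    manifest$counts$mega_n <- mega$n_analyzed
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
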