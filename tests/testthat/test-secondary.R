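test_that("interaction scan shares the sitewise/meta code path exactly", {
  ai <- small_ai_table(seed = 40, n_sites = 4, mean_n = 80)
  measures <- c("vol_pallidum", "thick_insula", "area_fusiform")
  scan <- run_interaction_scan(ai, "dx_by_age", measures = measures)
  direct_eff <- fit_sitewise(ai, "m8_dx_by_age", measures = measures)
  direct_meta <- meta_analyze(direct_eff, attr(ai, "catalog"),
                              family_mode = "all")
  expect_equal(scan$site_effects, direct_eff)
  expect_equal(scan$meta, direct_meta)
  # one FDR family across the whole scan
  expect_equal(scan$meta$q, bh_fdr(scan$meta$p), tolerance = 1e-12)
})

test_that("a constructed diagnosis-by-age interaction is recovered", {
  cat78 <- dk_region_catalog()
  sd_pall <- cat78$ai_sd[cat78$measure_id == "vol_pallidum"]
  eff <- effect_spec(dx_age_interaction = c(vol_pallidum = 0.02),
                     missing_rate = 0, zero_artifact_rate = 0)
  co <- generate_cohort(sites = default_site_specs(8, 250), effects = eff,
                        seed = 41)
  ai <- build_ai_table(co$data)
  scan <- run_interaction_scan(ai, "dx_by_age",
                               measures = c("vol_pallidum", "vol_caudate",
                                            "thick_cuneus", "area_lingual"))
  m <- scan$meta
  expect_equal(m$measure_id[which.min(m$p)], "vol_pallidum")
  expect_gt(m$d_pooled[m$measure_id == "vol_pallidum"], 0)
  # sex-interaction scan on the same (sex-balanced) data stays null
  scan9 <- run_interaction_scan(ai, "dx_by_sex",
                                measures = c("vol_pallidum", "vol_caudate"))
  expect_true(all(scan9$meta$q > 0.05))
})

test_that("within-group age trends separate group-specific slopes", {
  # age slope in controls only: cancel it in cases via the interaction
  cat78 <- dk_region_catalog()
  sdx <- cat78$ai_sd[cat78$measure_id == "vol_pallidum"]
  eff <- effect_spec(age_slope = c(vol_pallidum = -0.004),
                     dx_age_interaction =
                       stats::setNames(0.004 / sdx, "vol_pallidum"),
                     sex_effect = 0, missing_rate = 0,
                     zero_artifact_rate = 0)
  co <- generate_cohort(sites = default_site_specs(6, 300), effects = eff,
                        seed = 42)
  ai <- build_ai_table(co$data)
  tr <- within_group_age_trends(ai, "vol_pallidum")
  r_ctrl <- tr$r_pooled[tr$group == "controls" & tr$response == "ai"]
  r_case <- tr$r_pooled[tr$group == "cases" & tr$response == "ai"]
  expect_lt(r_ctrl, -0.15)
  expect_lt(abs(r_case), 0.1)

  # identical multiplicative age trends on both hemispheres cancel in the
  # asymmetry index but show up unilaterally
  co2 <- small_cohort(seed = 43, n_sites = 4, mean_n = 250,
                      effects = null_effect_spec())
  tab <- co2$data
  fac <- 1 - 0.006 * (tab$age - 33)
  tab$vol_hippocampus_L <- tab$vol_hippocampus_L * fac
  tab$vol_hippocampus_R <- tab$vol_hippocampus_R * fac
  tr2 <- within_group_age_trends(build_ai_table(tab), "vol_hippocampus")
  ctrl <- tr2[tr2$group == "controls", ]
  r_L <- ctrl$r_pooled[ctrl$response == "L"]
  r_ai <- ctrl$r_pooled[ctrl$response == "ai"]
  expect_lt(r_L, -0.3)
  expect_lt(ctrl$r_pooled[ctrl$response == "R"], -0.3)
  # the shared trend cancels in the index: |r_ai| is sampling noise,
  # an order of magnitude below the unilateral trend
  expect_lt(abs(r_ai), 0.25 * abs(r_L))
})

test_that("medication contrast recovers an injected effect and skips
           unusable datasets", {
  eff <- effect_spec(medication_effect = c(thick_middletemporal = -0.6),
                     missing_rate = 0, zero_artifact_rate = 0)
  co <- generate_cohort(sites = default_site_specs(8, 300), effects = eff,
                        seed = 44)
  ai <- build_ai_table(co$data)
  res <- medication_contrast(ai, measures = c("thick_middletemporal",
                                              "thick_cuneus"))
  row <- res$meta[res$meta$measure_id == "thick_middletemporal", ]
  expect_lt(row$d_pooled, 0)
  expect_gt(-0.6, row$d_pooled - 1.96 * row$se_pooled)
  expect_lt(-0.6, row$d_pooled + 1.96 * row$se_pooled)

  # a dataset whose cases all use second-generation drugs is skipped
  tab <- co$data
  only2 <- tab$dataset_id == "site03" & tab$diagnosis == 1L
  tab$medication_class[only2] <- "second_gen"
  eff3 <- medication_contrast(build_ai_table(tab),
                              measures = "thick_cuneus")
  rec <- eff3$site_effects[eff3$site_effects$dataset_id == "site03", ]
  expect_true(all(rec$skipped))
})

test_that("clinical correlation scan pools injected structure and
           tolerates empty input", {
  ce <- data.frame(measure_id = "thick_superiortemporal",
                   variable = "sans_total", r = -0.3,
                   stringsAsFactors = FALSE)
  eff <- effect_spec(clinical_effects = ce, missing_rate = 0,
                     zero_artifact_rate = 0)
  co <- generate_cohort(sites = default_site_specs(6, 250), effects = eff,
                        seed = 45)
  ai <- build_ai_table(co$data)
  res <- clinical_correlation_scan(
    ai, measures = c("thick_superiortemporal", "thick_cuneus"),
    variables = c("sans_total", "duration_of_illness"))
  hit <- res[res$measure_id == "thick_superiortemporal" &
             res$variable == "sans_total", ]
  expect_lt(hit$r_pooled, -0.15)
  expect_lt(hit$q, 0.05)
  null_rows <- res[res$measure_id == "thick_cuneus", ]
  expect_true(all(abs(null_rows$r_pooled) < 0.12))
  expect_true(all(res$q >= res$p - 1e-15))

  # variable unavailable everywhere: empty result, no crash
  tab <- co$data
  tab$sans_total <- NA_real_
  empty <- clinical_correlation_scan(build_ai_table(tab),
                                     measures = "thick_cuneus",
                                     variables = "sans_total")
  expect_equal(nrow(empty), 0)
})
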