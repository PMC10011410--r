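make_tc <- function(values, role = "treatment", metric = "caspase_count",
                    plate = "T1", well = "A01", compound = "C1", conc = 10) {
  data.frame(plate_id = plate, well = well, compound_id = compound,
             concentration_um = conc, replicate = 1, role = role,
             metric = metric, time_h = seq(0, by = 4, length.out = length(values)),
             value = values, stringsAsFactors = FALSE)
}

test_that("background correction subtracts reagent-free means and clips at zero", {
  tc <- rbind(make_tc(rep(25, 4)),
              make_tc(rep(10, 4), role = "reagent_free", well = "B01",
                      compound = "VEHICLE", conc = 0))
  out <- background_correct(tc)
  expect_equal(out$value, rep(15, 4))
  expect_equal(attr(out, "n_clipped"), 0L)
  expect_false(any(out$role == "reagent_free"))

  # sample below background: clipped to 0 and logged
  tc2 <- rbind(make_tc(c(5, 5, 25, 25)),
               make_tc(rep(10, 4), role = "reagent_free", well = "B01",
                       compound = "VEHICLE", conc = 0))
  out2 <- background_correct(tc2)
  expect_equal(out2$value, c(0, 0, 15, 15))
  expect_equal(attr(out2, "n_clipped"), 2L)

  # zero background: identity
  tc3 <- rbind(make_tc(c(1, 2, 3, 4)),
               make_tc(rep(0, 4), role = "reagent_free", well = "B01",
                       compound = "VEHICLE", conc = 0))
  expect_equal(background_correct(tc3)$value, c(1, 2, 3, 4))

  expect_error(background_correct(make_tc(rep(1, 4))), "reagent-free")
})

test_that("trapezoid AUC matches analytic values and is additive/linear", {
  t60 <- seq(0, 60, by = 4)
  expect_equal(trapezoid_auc(t60, rep(5, 16)), 300)           # rectangle
  expect_equal(trapezoid_auc(t60, 6 * t60 / 60), 180)         # triangle
  expect_equal(trapezoid_auc(c(0, 4, 8, 12), c(0, 4, 4, 0)), 32)

  # additive over contiguous intervals, linear in the trace
  set.seed(83)
  v <- rnorm(16)
  expect_equal(trapezoid_auc(t60[1:9], v[1:9]) + trapezoid_auc(t60[9:16], v[9:16]),
               trapezoid_auc(t60, v))
  w <- rnorm(16)
  expect_equal(trapezoid_auc(t60, 2 * v + 3 * w),
               2 * trapezoid_auc(t60, v) + 3 * trapezoid_auc(t60, w))

  expect_error(trapezoid_auc(c(0, 4, 4), c(1, 2, 3)), "strictly increasing")
  expect_error(trapezoid_auc(1, 1), ">= 2")
})

test_that("health summaries flag exclusions and keep them out of aggregates", {
  tc <- rbind(make_tc(rep(2, 16), compound = "good"),
              make_tc(rep(9, 16), compound = "glowy", well = "A02"),
              make_tc(rep(1, 16), role = "vehicle", compound = "VEHICLE",
                      conc = 0, well = "B01"))
  hs <- summarize_health(tc, exclusions = c(glowy = "autofluorescent"))
  expect_setequal(hs$compound_id, c("good", "glowy", "VEHICLE"))
  ex <- hs[hs$compound_id == "glowy", ]
  expect_true(all(ex$excluded))
  expect_identical(unique(ex$exclude_reason), "autofluorescent")
  expect_false(any(hs$excluded[hs$compound_id != "glowy"]))
  expect_equal(hs$auc[hs$compound_id == "good"], 2 * 60)
})

test_that("end-to-end synthetic health summary ranks injured above vehicle", {
  cfg <- small_config(seed = 31, n_compounds_per_cluster = 1,
                      n_inert_compounds = 1, tc_noise_sd = 0)
  scr <- generate_screen(cfg)
  tc <- generate_timecourses(cfg, scr$truth)
  hs <- summarize_health(background_correct(tc))
  strong <- scr$truth$compound_id[scr$truth$effect >= 1.5 &
                                    scr$truth$concentration_um == 20][1]
  casp <- hs[hs$metric == "caspase_count", ]
  auc_strong <- casp$auc[casp$compound_id == strong & casp$concentration_um == 20]
  auc_veh <- casp$auc[casp$compound_id == "VEHICLE"]
  expect_gt(auc_strong, auc_veh)
})

test_that("per-compound aggregates omit excluded compounds", {
  tc <- rbind(make_tc(rep(2, 16), compound = "good"),
              make_tc(rep(4, 16), compound = "good", conc = 20, well = "A03"),
              make_tc(rep(9, 16), compound = "glowy", well = "A02"))
  hs <- summarize_health(tc, exclusions = "glowy")
  agg <- aggregate_health_by_compound(hs)
  expect_identical(unique(agg$compound_id), "good")   # excluded is absent
  expect_equal(agg$mean_auc, mean(c(2, 4)) * 60)      # mean of time-AUCs
  expect_equal(agg$n_concentrations, 2L)
})

test_that("uniformity plates correct multiplicative row/column gains", {
  wells <- expand.grid(row = LETTERS[1:4], col = sprintf("%02d", 1:4),
                       stringsAsFactors = FALSE)
  wells$well <- paste0(wells$row, wells$col)
  row_gain <- c(A = 1.2, B = 1.0, C = 0.9, D = 1.1)
  col_gain <- setNames(c(0.8, 1.0, 1.1, 1.05), sprintf("%02d", 1:4))
  truth <- 500
  uni <- data.frame(well = wells$well,
                    lum = truth * row_gain[wells$row] * col_gain[wells$col])
  # the uniformity factors are normalized by the grand mean, so correction
  # recovers a flat plate up to one global constant
  samples <- data.frame(well = wells$well,
                        lum = 1000 * row_gain[wells$row] * col_gain[wells$col])
  corr <- uniformity_correct(samples, uni)
  expect_lt(diff(range(corr$lum)) / mean(corr$lum), 1e-10)

  bad <- data.frame(well = "P24", lum = 1)
  expect_error(uniformity_correct(bad, uni), "does not cover")
})

test_that("standard curves fit, recover and reject degenerate input", {
  conc <- 6.4 / 2^(0:9)
  lum <- 2 * conc
  curve <- fit_standard_curve(conc, lum)
  expect_equal(curve$slope, 2, tolerance = 1e-12)
  expect_equal(curve$intercept, 0, tolerance = 1e-12)

  # 1% noise: recovered concentrations within 3% down to the mid-range
  set.seed(89)
  noisy <- rep(1e5 * conc, 3) * (1 + rnorm(30, 0, 0.01))
  curve2 <- fit_standard_curve(rep(conc, 3), noisy)
  rec <- invert_standard_curve(curve2, 1e5 * conc)
  expect_lt(max(abs(rec[1:6] / conc[1:6] - 1)), 0.03)

  expect_error(fit_standard_curve(conc[1:3], lum[1:3]), "5 standard")
  expect_error(fit_standard_curve(conc, -2 * conc), "not positive")
})

test_that("glutathione quantification applies stoichiometry and outlier flags", {
  curve <- fit_standard_curve(6.4 / 2^(0:9), 10 * 6.4 / 2^(0:9))  # slope 10
  veh_total <- 10 * 4; veh_gssg <- 10 * 1
  # total 10 uM, GSSG 2 uM -> GSH = 10 - 2*2 = 6, ratio 3
  r1 <- quantify_glutathione(100, 20, curve, curve, veh_total, veh_gssg)
  expect_equal(r1$gsh_um, 6)
  expect_equal(r1$ratio, 3)
  expect_identical(r1$flag, "ok")

  # total 3, GSSG 2 -> GSH = -1: flagged, ratio withheld
  r2 <- quantify_glutathione(30, 20, curve, curve, veh_total, veh_gssg)
  expect_identical(r2$flag, "gsh_negative")
  expect_true(is.na(r2$ratio))

  # GSSG at 250% of vehicle: outlier flag, ratio withheld
  r3 <- quantify_glutathione(100, 25, curve, curve, veh_total, veh_gssg)
  expect_equal(r3$gssg_pct_vehicle, 250)
  expect_identical(r3$flag, "outlier_gssg")
  expect_true(is.na(r3$ratio))

  # GSSG ~ 0 with GSH > 0: undefined-high, not a division
  r4 <- quantify_glutathione(100, 0, curve, curve, veh_total, veh_gssg)
  expect_identical(r4$flag, "undefined_high")
  expect_true(is.na(r4$ratio))

  # flags are mutually exclusive with a reported ratio
  all_r <- rbind(r1, r2, r3, r4)
  expect_true(all(is.na(all_r$ratio) == (all_r$flag != "ok")))
})

test_that("forward-simulated glutathione plates recover planted values", {
  cfg <- small_config(seed = 37, n_compounds_per_cluster = 1,
                      n_inert_compounds = 1, gsh_noise = 0.01)
  scr <- generate_screen(cfg)
  gsh <- generate_glutathione_plate(cfg, scr$truth)
  out <- glutathione_from_plate(gsh$plate)
  merged <- merge(out$results, gsh$truth_gsh,
                  by = c("compound_id", "concentration_um"))
  expect_gt(nrow(merged), 10)
  expect_lt(max(abs(merged$total_um / merged$true_total_um - 1)), 0.03)
  # GSSG sits at the bottom of the calibration range where the OLS
  # intercept uncertainty dominates; accuracy is checked in aggregate
  expect_lt(mean(abs(merged$gssg_um / merged$true_gssg_um - 1)), 0.03)
  expect_lt(max(abs(merged$gssg_um / merged$true_gssg_um - 1)), 0.05)
})
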