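# Band lookups, boundary conventions and score invariants.

test_that("RAPS matches hand lookups, including rounding and extremes", {
  expect_equal(raps_score(106, 94, 20, 15)$total, 0L)
  # 120.5 rounds up into the 110-139 band (+2); 72.5 -> 73 stays zero band
  expect_equal(raps_score(120.5, 72.5, 22, 15)$total, 2L)
  b <- raps_score(120.5, 72.5, 22, 15)
  expect_equal(unname(b$components["pulse_rate"]), 2L)
  expect_equal(raps_score(30, 40, 4, 3)$total, 16L)
})

test_that("REMS matches hand lookups", {
  expect_equal(rems_score(80, 90, 16, 15, spo2 = 99, age = 30)$total, 0L)
  b <- rems_score(120, 72, 22, 15, spo2 = 95, age = 78)
  expect_equal(b$total, 8L)
  expect_equal(unname(b$components["age"]), 6L)
  expect_equal(unname(b$components["pulse_rate"]), 2L)
  expect_equal(rems_score(30, 40, 3, 3, spo2 = 60, age = 80)$total, 26L)
})

test_that("MEWS matches hand lookups with gap and rounding conventions", {
  expect_equal(mews_score(110, 95, 12, 37.0, avpu = "Alert")$total, 0L)
  expect_equal(mews_score(65, 135, 32, 34.5, avpu = "Unresponsive")$total, 14L)
  # SBP 70 and HR 40 fall in one-unit table gaps -> higher-acuity band;
  # 38.45 degC rounds half-up to 38.5 -> +2
  b <- mews_score(70, 40, 21, 38.45, avpu = "Voice")
  expect_equal(unname(b$components), c(3L, 2L, 2L, 2L, 1L))
  expect_equal(b$total, 10L)
  # one unit past the gap lands in the lower-acuity band
  expect_equal(unname(mews_score(71, 41, 21, 37, "Alert")$components[1:2]),
               c(2L, 1L))
})

test_that("MEDS awards the published weights row by row", {
  expect_equal(meds_score(40, FALSE, FALSE, 300, 2, FALSE, FALSE, FALSE,
                          FALSE, 16, 98)$total, 0L)
  all_true <- meds_score(70, TRUE, TRUE, 120, 8, TRUE, TRUE, TRUE, TRUE,
                         30, 85)
  expect_equal(all_true$total, 27L)
  expect_equal(sum(unname(all_true$components)), 6 + 3 + 3 + 3 + 3 + 3 +
                 2 + 2 + 2)
  expect_equal(meds_score(70, FALSE, TRUE, 120, 2, FALSE, FALSE, FALSE,
                          FALSE, 18, 95)$total, 9L)
  # age boundary is strict (> 65)
  expect_equal(meds_score(65, FALSE, FALSE, 300, 2, FALSE, FALSE, FALSE,
                          FALSE, 16, 98)$total, 0L)
  # altered mental status falls back to gcs <= 13 when flag absent
  expect_equal(meds_score(40, FALSE, FALSE, 300, 2, FALSE, FALSE,
                          altered_mental_status = NULL, FALSE, 16, 98,
                          gcs = 12)$total, 2L)
})

test_that("tachypnea/hypoxia uses strict boundaries and the mask clause", {
  expect_false(tachypnea_or_hypoxia(20, 90, FALSE))
  expect_true(tachypnea_or_hypoxia(22, 98, FALSE))
  expect_true(tachypnea_or_hypoxia(12, 99, TRUE))
  expect_true(tachypnea_or_hypoxia(12, NA, TRUE))
  expect_error(tachypnea_or_hypoxia(12, NA, FALSE),
               "missing required input: spo2")
})

test_that("AVPU derivation from GCS follows the stated mapping", {
  expect_equal(avpu_from_gcs(c(15, 14)), c("Alert", "Alert"))
  expect_equal(avpu_from_gcs(c(13, 10, 9)), rep("Voice", 3))
  expect_equal(avpu_from_gcs(c(8, 4)), rep("Pain", 2))
  expect_equal(avpu_from_gcs(3), "Unresponsive")
  expect_error(avpu_from_gcs(16), "gcs")
  expect_error(avpu_from_gcs(2), "gcs")
})

test_that("missing inputs raise errors naming the field; impute mode logs", {
  expect_error(raps_score(NULL, 94, 20, 15),
               "missing required input: pulse_rate")
  expect_error(rems_score(80, 90, 16, 15, spo2 = NA, age = 30),
               "missing required input: spo2")
  expect_error(mews_score(110, 95, 12, 37.0),
               "missing required input: avpu")
  expect_error(meds_score(70, FALSE, TRUE, NA, 2, FALSE, FALSE, FALSE,
                          FALSE, 18, 95),
               "missing required input: platelet_count")
  expect_message(b <- raps_score(NULL, 94, 20, 15, impute = TRUE),
                 "imputing normal value for missing pulse_rate")
  expect_equal(b$total, 0L)
  expect_equal(b$imputed, "pulse_rate")
})

test_that("band lookups are exhaustive over the physiological sweep", {
  fine <- seq(0, 300, by = 0.1)
  for (f in list(raps_points_pulse = edscores:::raps_points_pulse,
                 raps_points_map = edscores:::raps_points_map,
                 mews_points_sbp = edscores:::mews_points_sbp,
                 mews_points_hr = edscores:::mews_points_hr)) {
    pts <- f(round_half_up(fine))
    expect_false(anyNA(pts))
    expect_true(all(pts %in% 0:4))
  }
  rr <- seq(0, 80, by = 0.1)
  expect_true(all(edscores:::raps_points_rr(round_half_up(rr)) %in% 0:4))
  expect_true(all(edscores:::mews_points_rr(round_half_up(rr)) %in% 0:3))
  temp <- seq(25, 45, by = 0.1)
  expect_true(all(edscores:::mews_points_temp(temp) %in% c(0L, 2L)))
  expect_true(all(edscores:::raps_points_gcs(3:15) %in% 0:4))
  expect_true(all(edscores:::rems_points_spo2(0:100) %in% 0:4))
  expect_true(all(edscores:::rems_points_age(18:110) %in% c(0L, 2L, 3L, 5L, 6L)))
})

test_that("every banded variable is a unimodal valley around its zero band", {
  is_valley <- function(pts) {
    d <- diff(pts)
    d <- d[d != 0]
    # once points start rising with acuity they never fall back
    !is.unsorted(sign(d))
  }
  grid <- seq(0, 300, by = 1)
  expect_true(is_valley(edscores:::raps_points_pulse(grid)))
  expect_true(is_valley(edscores:::raps_points_map(grid)))
  expect_true(is_valley(edscores:::raps_points_rr(0:80)))
  expect_true(is_valley(edscores:::raps_points_gcs(15:3)))
  expect_true(is_valley(edscores:::rems_points_age(0:110)))
  expect_true(is_valley(edscores:::rems_points_spo2(100:0)))
  expect_true(is_valley(edscores:::mews_points_sbp(grid)))
  expect_true(is_valley(edscores:::mews_points_hr(grid)))
  expect_true(is_valley(edscores:::mews_points_rr(0:80)))
  expect_true(is_valley(edscores:::mews_points_temp(seq(25, 45, 0.1))))
})

test_that("component attribution sums to total on random inputs", {
  v <- random_vitals(200, seed = 42)
  for (i in seq_len(nrow(v))) {
    b <- raps_score(v$pr[i], v$map[i], v$rr[i], v$gcs[i])
    expect_identical(b$total, sum(b$components))
    b <- rems_score(v$pr[i], v$map[i], v$rr[i], v$gcs[i], v$spo2[i], v$age[i])
    expect_identical(b$total, sum(b$components))
    b <- mews_score(v$sbp[i], v$hr[i], v$rr[i], v$temp[i], gcs = v$gcs[i])
    expect_identical(b$total, sum(b$components))
  }
})

test_that("score ranges are respected and maxima attained", {
  v <- random_vitals(500, seed = 7)
  raps <- vapply(seq_len(nrow(v)), function(i)
    raps_score(v$pr[i], v$map[i], v$rr[i], v$gcs[i])$total, integer(1))
  rems <- vapply(seq_len(nrow(v)), function(i)
    rems_score(v$pr[i], v$map[i], v$rr[i], v$gcs[i], v$spo2[i],
               v$age[i])$total, integer(1))
  mews <- vapply(seq_len(nrow(v)), function(i)
    mews_score(v$sbp[i], v$hr[i], v$rr[i], v$temp[i], gcs = v$gcs[i])$total,
    integer(1))
  expect_true(all(raps >= 0 & raps <= 16))
  expect_true(all(rems >= 0 & rems <= 26))
  expect_true(all(mews >= 0 & mews <= 14))
})

test_that("vectorised cohort scoring agrees with per-patient calculators", {
  coh <- generate_cohort(seed = 11)
  scored <- score_cohort(coh)
  df <- as.data.frame(coh)
  idx <- seq(1, nrow(df), by = 7)
  for (i in idx) {
    expect_equal(scored$raps[i],
                 raps_score(df$pulse_rate[i], df$mean_arterial_pressure[i],
                            df$respiratory_rate[i], df$gcs[i])$total)
    expect_equal(scored$rems[i],
                 rems_score(df$pulse_rate[i], df$mean_arterial_pressure[i],
                            df$respiratory_rate[i], df$gcs[i], df$spo2[i],
                            df$age[i])$total)
    expect_equal(scored$mews[i],
                 mews_score(df$systolic_bp[i], df$pulse_rate[i],
                            df$respiratory_rate[i], df$temperature[i],
                            avpu = df$avpu[i])$total)
    expect_equal(scored$meds[i],
                 meds_score(df$age[i], df$terminal_illness[i],
                            df$septic_shock[i], df$platelet_count[i],
                            df$band_percent[i],
                            df$lower_respiratory_infection[i],
                            df$nursing_home_resident[i],
                            df$altered_mental_status[i],
                            df$oxygen_by_mask[i], df$respiratory_rate[i],
                            df$spo2[i])$total)
  }
})
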