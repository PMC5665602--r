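# Vectorised band-lookup primitives for the four severity scores.
#
# Each function maps an already-rounded integer-valued vital to the points
# its band carries. The lookups are written as exhaustive threshold chains:
# every finite input falls into exactly one band, so no NA can escape.
#
# Published band tables occasionally leave one-unit gaps between adjacent
# rows (MEWS systolic BP 70, MEWS heart rate 40). The package convention is
# to assign the adjacent higher-acuity band: conservative triage never
# under-scores a boundary value.

# --- RAPS / REMS share the PR, MAP, RR bands -------------------------------

raps_points_pulse <- function(pr) {
  ifelse(pr <= 39, 4L,
  ifelse(pr <= 54, 3L,
  ifelse(pr <= 69, 2L,
  ifelse(pr <= 109, 0L,
  ifelse(pr <= 139, 2L,
  ifelse(pr <= 179, 3L, 4L))))))
}

raps_points_map <- function(map) {
  ifelse(map <= 49, 4L,
  ifelse(map <= 69, 2L,
  ifelse(map <= 109, 0L,
  ifelse(map <= 129, 2L,
  ifelse(map <= 159, 3L, 4L)))))
}

raps_points_rr <- function(rr) {
  ifelse(rr <= 5, 4L,
  ifelse(rr <= 9, 2L,
  ifelse(rr <= 11, 1L,
  ifelse(rr <= 24, 0L,
  ifelse(rr <= 34, 1L,
  ifelse(rr <= 49, 3L, 4L))))))
}

raps_points_gcs <- function(gcs) {
  ifelse(gcs >= 14, 0L,
  ifelse(gcs >= 11, 1L,
  ifelse(gcs >= 8, 2L,
  ifelse(gcs >= 5, 3L, 4L))))
}

# --- REMS-only bands -------------------------------------------------------

rems_points_age <- function(age) {
  ifelse(age < 45, 0L,
  ifelse(age <= 54, 2L,
  ifelse(age <= 64, 3L,
  ifelse(age <= 74, 5L, 6L))))
}

rems_points_spo2 <- function(spo2) {
  ifelse(spo2 > 89, 0L,
  ifelse(spo2 >= 86, 1L,
  ifelse(spo2 >= 75, 3L, 4L)))
}

# --- MEWS bands ------------------------------------------------------------

mews_points_sbp <- function(sbp) {
  # table rows: <70 -> +3, 71-80 -> +2; exactly 70 takes the higher-acuity +3
  ifelse(sbp <= 70, 3L,
  ifelse(sbp <= 80, 2L,
  ifelse(sbp <= 100, 1L,
  ifelse(sbp <= 199, 0L, 2L))))
}

mews_points_hr <- function(hr) {
  # table rows: <40 -> +2, 41-50 -> +1; exactly 40 takes the higher-acuity +2
  ifelse(hr <= 40, 2L,
  ifelse(hr <= 50, 1L,
  ifelse(hr <= 100, 0L,
  ifelse(hr <= 110, 1L,
  ifelse(hr <= 129, 2L, 3L)))))
}

mews_points_rr <- function(rr) {
  ifelse(rr < 9, 2L,
  ifelse(rr <= 14, 0L,
  ifelse(rr <= 20, 1L,
  ifelse(rr <= 29, 2L, 3L))))
}

mews_points_temp <- function(temp) {
  # bands are defined at 0.1 degC resolution; inputs arrive rounded to 0.1.
  # compare on a x10 integer grid to dodge binary representation error.
  t10 <- round_half_up(temp * 10)
  ifelse(t10 < 350, 2L, ifelse(t10 <= 384, 0L, 2L))
}

mews_points_avpu <- function(avpu) {
  pts <- c(Alert = 0L, Voice = 1L, Pain = 2L, Unresponsive = 3L)
  out <- unname(pts[as.character(avpu)])
  if (anyNA(out)) {
    validation_error(sprintf(
      "avpu must be one of Alert/Voice/Pain/Unresponsive, got: %s",
      paste(unique(setdiff(as.character(avpu), names(pts))), collapse = ", ")))
  }
  out
}

# --- MEDS fixed weights ----------------------------------------------------

MEDS_POINTS <- c(
  terminal_illness            = 6L,
  age_over_65                 = 3L,
  tachypnea_or_hypoxia        = 3L,
  septic_shock                = 3L,
  platelets_below_150         = 3L,
  bands_over_5pct             = 3L,
  lower_respiratory_infection = 2L,
  nursing_home_resident       = 2L,
  altered_mental_status       = 2L
)
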