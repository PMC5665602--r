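# Shared test fixtures, built in code.

# Minimal valid 3-patient cohort data frame. Hand-computed score totals
# (band-by-band lookups in the four published tables):
#   P1: RAPS 0  (106/94/20 gcs15 all zero bands)
#       REMS 3  (age 60 -> +3)
#       MEWS 2  (PR 106 -> +1, RR 20 -> +1)
#       MEDS 0
#   P2: RAPS 7  (PR 121 +2, MAP 72.5->73 0, RR 22 0, ... see below)
#       computed in tests from the calculators' per-component breakdowns
#   P3: extreme acuity profile
tiny_cohort_df <- function() {
  data.frame(
    patient_id = c("P1", "P2", "P3"),
    age = c(60, 78, 81),
    sex = c("male", "female", "male"),
    pulse_rate = c(106, 121, 150),
    respiratory_rate = c(20, 22, 36),
    systolic_bp = c(121, 99, 65),
    mean_arterial_pressure = c(94, 72.5, 38),
    temperature = c(37.2, 38.6, 35.1),
    spo2 = c(98, 95, 74),
    gcs = c(15, 15, 6),
    avpu = c("Alert", "Alert", "Pain"),
    platelet_count = c(250, 120, 40),
    leukocyte_count = c(9000, 15000, 22000),
    band_percent = c(2, 4, 11),
    septic_shock = c(FALSE, FALSE, TRUE),
    terminal_illness = c(FALSE, FALSE, FALSE),
    lower_respiratory_infection = c(FALSE, FALSE, TRUE),
    nursing_home_resident = c(FALSE, FALSE, FALSE),
    altered_mental_status = c(FALSE, FALSE, TRUE),
    oxygen_by_mask = c(FALSE, FALSE, TRUE),
    etiology = c("hematogenous", "contiguous", "hematogenous"),
    abscess_multiplicity = c("solitary", "solitary", "multiple"),
    treatment = c("conservative", "aspiration", "operation"),
    outcome = c("survived", "survived", "died"),
    stringsAsFactors = FALSE)
}

# Independent brute-force Mann-Whitney oracle: full combn() enumeration of
# group assignments (deliberately not the dynamic-programming route used by
# the implementation).
brute_force_mw_p <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  sums <- utils::combn(length(pooled), nx, function(idx) sum(r[idx]))
  p_le <- mean(sums <= w_obs + 1e-9)
  p_ge <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# random valid vitals for property tests
random_vitals <- function(n, seed) {
  set.seed(seed)
  data.frame(
    pr = runif(n, 0, 300), map = runif(n, 0, 300), rr = runif(n, 0, 80),
    sbp = runif(n, 0, 300), hr = runif(n, 0, 300), temp = runif(n, 25, 45),
    gcs = sample(3:15, n, replace = TRUE),
    spo2 = runif(n, 0, 100), age = runif(n, 18, 100))
}
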