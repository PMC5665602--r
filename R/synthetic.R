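# Seeded synthetic cohort generator.
#
# Published cohort tables report continuous variables as median (IQR) and
# categorical ones as counts. Each continuous variable is modelled as a
# log-normal (positive support, right skew typical of vitals and labs)
# fitted to the reported median and quartiles, sampled truncated to its
# 1st-99th percentile and clamped to hard physiological bounds; categorical
# variables are drawn from the reported arm frequencies. Variables are
# independent within an arm - the published tables carry no correlation
# structure, and that independence is a documented limitation.

CONTINUOUS_VARS <- c("age", "pulse_rate", "respiratory_rate",
                     "mean_arterial_pressure", "temperature",
                     "platelet_count", "leukocyte_count")

# hard physiological clamps applied after truncated log-normal sampling
PHYS_BOUNDS <- list(
  age = c(18, 100), pulse_rate = c(20, 250), respiratory_rate = c(4, 60),
  mean_arterial_pressure = c(30, 200), temperature = c(30, 43),
  platelet_count = c(5, 1500), leukocyte_count = c(300, 2e5)
)

#' Fit a log-normal to a reported median and interquartile range
#'
#' The median pins the log-scale location exactly (`mu = log(median)`); the
#' log-scale spread is the least-squares fit of the 25th and 75th
#' log-percentiles to the reported quartiles, `sigma = log(q3/q1) / (2
#' z_0.75)`. When the IQR is log-symmetric about the median the fit is
#' exact and the residual is zero.
#'
#' @param median reported median (> 0).
#' @param q1,q3 reported 25th and 75th percentiles, `0 < q1 < median < q3`.
#' @return list with `mu`, `sigma`, and `residual` (root-sum-of-squares of
#'   the log-scale quartile misfit).
#' @examples
#' fit_lognormal_to_median_iqr(100, 80, 125)  # log-symmetric: residual ~ 0
#' @export
fit_lognormal_to_median_iqr <- function(median, q1, q3) {
  if (!is.numeric(median) || !is.numeric(q1) || !is.numeric(q3) ||
      any(!is.finite(c(median, q1, q3)))) {
    parameter_error("median, q1, q3 must be finite numbers")
  }
  if (!(q1 > 0 && q1 < median && median < q3)) {
    parameter_error(sprintf(
      "quantiles must satisfy 0 < q1 < median < q3, got q1=%s median=%s q3=%s",
      format(q1), format(median), format(q3)))
  }
  z <- stats::qnorm(0.75)
  mu <- log(median)
  sigma <- (log(q3) - log(q1)) / (2 * z)
  resid <- sqrt((mu - z * sigma - log(q1))^2 + (mu + z * sigma - log(q3))^2)
  list(mu = mu, sigma = sigma, residual = resid)
}

#' Specify one outcome arm of a synthetic cohort
#'
#' Distributional targets for one arm (survivors or non-survivors):
#' median/IQR targets for the continuous variables, category probabilities
#' for the categorical ones, and the auxiliary knobs (SpO2 mean/sd, pulse
#' pressure for deriving systolic BP from MAP, probabilities for the
#' infection-history flags) that published cohort tables typically omit but
#' the score calculators need.
#'
#' @param n arm size.
#' @param continuous named list over `age`, `pulse_rate`,
#'   `respiratory_rate`, `mean_arterial_pressure`, `temperature`,
#'   `platelet_count` (1e9/L), `leukocyte_count` (/uL); each element
#'   `c(median, q1, q3)`.
#' @param gcs_band probabilities for GCS bands `c(le8, b9to11, ge12)`.
#' @param p_male,p_septic_shock,p_terminal_illness Bernoulli probabilities.
#' @param etiology probabilities over
#'   hematogenous/sickle_cell_related/traumatic/contiguous.
#' @param multiplicity probabilities over solitary/multiple.
#' @param treatment probabilities over conservative/aspiration/operation.
#' @param spo2 `c(mean, sd)` of a clipped normal on \[40, 100\].
#' @param pulse_pressure mmHg; systolic BP is derived as
#'   `MAP + 2/3 * pulse_pressure`.
#' @param p_nursing_home,p_lower_respiratory_infection,p_band_gt5,p_oxygen_by_mask
#'   probabilities of the remaining MEDS flags (explicitly synthetic
#'   defaults, not published quantities).
#' @return object of class `arm_spec`.
#' @export
arm_spec <- function(n, continuous, gcs_band, p_male, p_septic_shock,
                     p_terminal_illness, etiology, multiplicity, treatment,
                     spo2 = c(97, 2), pulse_pressure = 40,
                     p_nursing_home = 0.05,
                     p_lower_respiratory_infection = 0.10,
                     p_band_gt5 = 0.15, p_oxygen_by_mask = 0.05) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    parameter_error("n must be a positive integer")
  }
  missing_vars <- setdiff(CONTINUOUS_VARS, names(continuous))
  if (length(missing_vars)) {
    parameter_error(sprintf("continuous targets missing for: %s",
                            paste(missing_vars, collapse = ", ")))
  }
  for (v in CONTINUOUS_VARS) {
    tgt <- continuous[[v]]
    if (length(tgt) != 3L) {
      parameter_error(sprintf("%s target must be c(median, q1, q3)", v))
    }
    fit_lognormal_to_median_iqr(tgt[[1]], tgt[[2]], tgt[[3]])  # validates
  }
  check_probs <- function(p, what, len, lev) {
    if (length(p) != len || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      parameter_error(sprintf("%s must be %d probabilities summing to 1",
                              what, len))
    }
    p <- p / sum(p)
    if (is.null(names(p))) names(p) <- lev
    p
  }
  gcs_band <- check_probs(gcs_band, "gcs_band", 3L,
                          c("le8", "b9to11", "ge12"))
  etiology <- check_probs(etiology, "etiology", 4L, ETIOLOGY_LEVELS)
  multiplicity <- check_probs(multiplicity, "multiplicity", 2L,
                              MULTIPLICITY_LEVELS)
  treatment <- check_probs(treatment, "treatment", 3L, TREATMENT_LEVELS)
  for (p in c(p_male, p_septic_shock, p_terminal_illness, p_nursing_home,
              p_lower_respiratory_infection, p_band_gt5, p_oxygen_by_mask)) {
    if (p < 0 || p > 1) parameter_error("flag probabilities must be in [0,1]")
  }
  structure(list(
    n = as.integer(n), continuous = continuous[CONTINUOUS_VARS],
    gcs_band = gcs_band, p_male = p_male, p_septic_shock = p_septic_shock,
    p_terminal_illness = p_terminal_illness, etiology = etiology,
    multiplicity = multiplicity, treatment = treatment, spo2 = spo2,
    pulse_pressure = pulse_pressure, p_nursing_home = p_nursing_home,
    p_lower_respiratory_infection = p_lower_respiratory_infection,
    p_band_gt5 = p_band_gt5, p_oxygen_by_mask = p_oxygen_by_mask),
    class = "arm_spec")
}

#' Specify a two-arm synthetic cohort
#'
#' @param survivor_arm,nonsurvivor_arm [arm_spec()] objects.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(survivor_arm, nonsurvivor_arm) {
  stopifnot(inherits(survivor_arm, "arm_spec"),
            inherits(nonsurvivor_arm, "arm_spec"))
  structure(list(survivor_arm = survivor_arm,
                 nonsurvivor_arm = nonsurvivor_arm),
            class = "cohort_spec")
}

#' Default synthetic cohort specification
#'
#' The packaged reference specification: a 114-patient splenic-abscess ED
#' cohort with 100 survivors and 14 non-survivors, each arm calibrated to
#' the published survivor/non-survivor medians, IQRs and group frequencies
#' (age, vitals, platelets, leukocytes, GCS bands, sex, septic shock,
#' terminal illness, etiology, abscess multiplicity, treatment). The
#' non-survivor septic-shock probability is the count-based 6/14 (the
#' printed percentage, 42.84, rounds the same count slightly differently).
#' SpO2, systolic BP and the remaining MEDS flags are not published for this
#' cohort; their defaults are synthetic choices documented in
#' [arm_spec()].
#'
#' @param n_survivors,n_nonsurvivors arm sizes (defaults 100 and 14); scale
#'   these up for distribution-level checks.
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(n_survivors = 100, n_nonsurvivors = 14) {
  survivor <- arm_spec(
    n = n_survivors,
    continuous = list(
      age = c(55.5, 42, 71),
      pulse_rate = c(106, 88, 117.5),
      respiratory_rate = c(20, 19, 20.5),
      mean_arterial_pressure = c(94, 75.5, 112),
      temperature = c(38, 36.9, 39),
      platelet_count = c(221, 152, 303.5),
      leukocyte_count = c(13000, 8950, 18550)),
    gcs_band = c(le8 = 1, b9to11 = 1, ge12 = 98) / 100,
    p_male = 0.70, p_septic_shock = 0.04, p_terminal_illness = 0.01,
    etiology = c(hematogenous = 62, sickle_cell_related = 8,
                 traumatic = 11, contiguous = 19) / 100,
    multiplicity = c(solitary = 74, multiple = 26) / 100,
    treatment = c(conservative = 49, aspiration = 24, operation = 27) / 100,
    spo2 = c(97, 2),
    p_nursing_home = 0.05, p_lower_respiratory_infection = 0.10,
    p_band_gt5 = 0.15, p_oxygen_by_mask = 0.05)
  nonsurvivor <- arm_spec(
    n = n_nonsurvivors,
    continuous = list(
      age = c(55, 52, 78),
      pulse_rate = c(120.5, 108, 142),
      respiratory_rate = c(22, 20, 27),
      mean_arterial_pressure = c(72.5, 59, 98),
      temperature = c(38, 37, 39),
      platelet_count = c(162.5, 41, 224),
      leukocyte_count = c(13500, 6900, 20500)),
    gcs_band = c(le8 = 2, b9to11 = 2, ge12 = 10) / 14,
    p_male = 0.50, p_septic_shock = 6 / 14, p_terminal_illness = 1 / 14,
    etiology = c(hematogenous = 10, sickle_cell_related = 4,
                 traumatic = 0, contiguous = 0) / 14,
    multiplicity = c(solitary = 6, multiple = 8) / 14,
    treatment = c(conservative = 9, aspiration = 2, operation = 3) / 14,
    spo2 = c(93, 4),
    p_nursing_home = 0.10, p_lower_respiratory_infection = 0.20,
    p_band_gt5 = 0.30, p_oxygen_by_mask = 0.10)
  cohort_spec(survivor, nonsurvivor)
}

sample_lognormal <- function(n, target, bounds) {
  fit <- fit_lognormal_to_median_iqr(target[[1]], target[[2]], target[[3]])
  # inverse-CDF draw truncated to the fitted 1st-99th percentile; the
  # truncation is symmetric in probability so the median is untouched
  x <- stats::qlnorm(stats::runif(n, 0.01, 0.99), fit$mu, fit$sigma)
  pmin(pmax(x, bounds[1]), bounds[2])
}

generate_arm <- function(spec, outcome, id_prefix) {
  n <- spec$n
  cont <- lapply(CONTINUOUS_VARS, function(v) {
    sample_lognormal(n, spec$continuous[[v]], PHYS_BOUNDS[[v]])
  })
  names(cont) <- CONTINUOUS_VARS
  band <- sample(c("le8", "b9to11", "ge12"), n, replace = TRUE,
                 prob = spec$gcs_band)
  gcs <- integer(n)
  gcs[band == "le8"] <- sample(3:8, sum(band == "le8"), replace = TRUE)
  gcs[band == "b9to11"] <- sample(9:11, sum(band == "b9to11"), replace = TRUE)
  gcs[band == "ge12"] <- sample(12:15, sum(band == "ge12"), replace = TRUE)
  spo2 <- round_half_up(pmin(pmax(
    stats::rnorm(n, spec$spo2[1], spec$spo2[2]), 40), 100))
  map <- round_half_up(cont$mean_arterial_pressure, 1)
  data.frame(
    patient_id = sprintf("%s%04d", id_prefix, seq_len(n)),
    age = round_half_up(pmax(cont$age, 18)),
    sex = ifelse(stats::runif(n) < spec$p_male, "male", "female"),
    pulse_rate = round_half_up(cont$pulse_rate, 1),
    respiratory_rate = round_half_up(cont$respiratory_rate, 1),
    systolic_bp = round_half_up(map + 2 / 3 * spec$pulse_pressure, 1),
    mean_arterial_pressure = map,
    temperature = round_half_up(cont$temperature, 1),
    spo2 = spo2,
    gcs = gcs,
    avpu = avpu_from_gcs(gcs),
    platelet_count = round_half_up(cont$platelet_count, 1),
    leukocyte_count = round_half_up(cont$leukocyte_count),
    band_percent = round_half_up(ifelse(
      stats::runif(n) < spec$p_band_gt5,
      stats::runif(n, 6, 15), stats::runif(n, 0, 5)), 1),
    septic_shock = stats::runif(n) < spec$p_septic_shock,
    terminal_illness = stats::runif(n) < spec$p_terminal_illness,
    lower_respiratory_infection =
      stats::runif(n) < spec$p_lower_respiratory_infection,
    nursing_home_resident = stats::runif(n) < spec$p_nursing_home,
    altered_mental_status = gcs <= 13,
    oxygen_by_mask = stats::runif(n) < spec$p_oxygen_by_mask,
    etiology = sample(ETIOLOGY_LEVELS, n, replace = TRUE,
                      prob = spec$etiology),
    abscess_multiplicity = sample(MULTIPLICITY_LEVELS, n, replace = TRUE,
                                  prob = spec$multiplicity),
    treatment = sample(TREATMENT_LEVELS, n, replace = TRUE,
                       prob = spec$treatment),
    outcome = outcome,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic patient cohort
#'
#' Deterministic given `seed`: arm sizes are exact, continuous variables are
#' drawn from log-normals fitted to the arm's median/IQR targets (truncated
#' to the 1st--99th percentile and clamped to physiological bounds),
#' categorical variables from the arm's probabilities, and the outcome label
#' is set by arm. AVPU is derived from the sampled GCS and the
#' altered-mental-status flag is `gcs <= 13`.
#'
#' @param spec a [cohort_spec()]; default [default_cohort_spec()].
#' @param seed integer RNG seed.
#' @return a [cohort()] with `provenance = "synthetic"`.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' outcome_counts(coh)   # 100 survived, 14 died
#' @export
generate_cohort <- function(spec = default_cohort_spec(), seed) {
  if (!inherits(spec, "cohort_spec")) {
    parameter_error("spec must be a cohort_spec")
  }
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    parameter_error("a single integer seed is required")
  }
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  surv <- generate_arm(spec$survivor_arm, "survived", "S")
  nons <- generate_arm(spec$nonsurvivor_arm, "died", "N")
  cohort(rbind(surv, nons), provenance = "synthetic",
         seed = as.integer(seed))
}
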