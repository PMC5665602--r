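#' Score breakdown objects
#'
#' Every calculator returns a `score_breakdown`: the score total together
#' with the per-variable point attribution, so a clinician (or a test) can
#' audit exactly which band each vital landed in.
#'
#' @param system one of `"RAPS"`, `"REMS"`, `"MEWS"`, `"MEDS"`.
#' @param components named integer vector of points per variable.
#' @param imputed character vector of field names that were filled with
#'   zero-band normal values (empty unless `impute = TRUE` was used).
#' @return an object of class `score_breakdown` with elements `system`,
#'   `total`, `components`, `imputed`.
#' @export
score_breakdown <- function(system, components, imputed = character()) {
  system <- match.arg(system, c("RAPS", "REMS", "MEWS", "MEDS"))
  components <- vapply(components, as.integer, integer(1))
  structure(
    list(system = system,
         total = sum(components),
         components = components,
         imputed = imputed),
    class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("%s = %d\n", x$system, x$total))
  for (nm in names(x$components)) {
    cat(sprintf("  %-28s +%d%s\n", nm, x$components[[nm]],
                if (nm %in% x$imputed) " (imputed normal)" else ""))
  }
  invisible(x)
}

# Zero-band "normal" substitutes used by the optional impute mode (d7-style
# explicit imputation: every substitution is recorded on the breakdown and
# announced with a message, never silent).
NORMAL_VALUES <- list(
  pulse_rate = 90, mean_arterial_pressure = 90, respiratory_rate = 18,
  gcs = 15, spo2 = 98, systolic_bp = 150, heart_rate = 75,
  temperature = 37, avpu = "Alert", age = 40,
  platelet_count = 300, band_percent = 2
)

resolve_input <- function(value, field, impute, imputed_acc) {
  if (is_missing_value(value)) {
    if (!impute) missing_input_error(field)
    message(sprintf("imputing normal value for missing %s = %s",
                    field, format(NORMAL_VALUES[[field]])))
    imputed_acc$fields <- c(imputed_acc$fields, field)
    return(NORMAL_VALUES[[field]])
  }
  value
}

#' Rapid Acute Physiology Score (RAPS)
#'
#' Four-variable physiologic severity score over pulse rate, mean arterial
#' pressure, respiratory rate and Glasgow Coma Scale; range 0--16. Real
#' valued vitals are rounded half-up to the integer grid of the band table
#' before lookup.
#'
#' @param pulse_rate beats/min.
#' @param mean_arterial_pressure mmHg.
#' @param respiratory_rate breaths/min.
#' @param gcs Glasgow Coma Scale, integer in 3--15.
#' @param impute if `TRUE`, missing inputs are replaced by zero-band normal
#'   values (each substitution is messaged and recorded); if `FALSE`
#'   (default) a missing input is an error.
#' @return a [score_breakdown()].
#' @examples
#' raps_score(106, 94, 20, 15)$total   # 0
#' raps_score(30, 40, 4, 3)$total      # 16 (maximal bands)
#' @export
raps_score <- function(pulse_rate, mean_arterial_pressure, respiratory_rate,
                       gcs, impute = FALSE) {
  acc <- new.env()
  acc$fields <- character()
  pr <- resolve_input(pulse_rate, "pulse_rate", impute, acc)
  map <- resolve_input(mean_arterial_pressure, "mean_arterial_pressure",
                       impute, acc)
  rr <- resolve_input(respiratory_rate, "respiratory_rate", impute, acc)
  g <- resolve_input(gcs, "gcs", impute, acc)
  check_scalar_number(pr, "pulse_rate", 0)
  check_scalar_number(map, "mean_arterial_pressure", 0)
  check_scalar_number(rr, "respiratory_rate", 0)
  check_scalar_number(g, "gcs", 3, 15)
  score_breakdown("RAPS", c(
    pulse_rate = raps_points_pulse(round_half_up(pr)),
    mean_arterial_pressure = raps_points_map(round_half_up(map)),
    respiratory_rate = raps_points_rr(round_half_up(rr)),
    gcs = raps_points_gcs(round_half_up(g))
  ), imputed = acc$fields)
}

#' Rapid Emergency Medicine Score (REMS)
#'
#' RAPS extended with age and peripheral oxygen saturation; range 0--26.
#'
#' @inheritParams raps_score
#' @param spo2 peripheral oxygen saturation, percent in 0--100.
#' @param age years.
#' @return a [score_breakdown()].
#' @examples
#' rems_score(120, 72, 22, 15, spo2 = 95, age = 78)$total  # 8
#' @export
rems_score <- function(pulse_rate, mean_arterial_pressure, respiratory_rate,
                       gcs, spo2, age, impute = FALSE) {
  acc <- new.env()
  acc$fields <- character()
  pr <- resolve_input(pulse_rate, "pulse_rate", impute, acc)
  map <- resolve_input(mean_arterial_pressure, "mean_arterial_pressure",
                       impute, acc)
  rr <- resolve_input(respiratory_rate, "respiratory_rate", impute, acc)
  g <- resolve_input(gcs, "gcs", impute, acc)
  s <- resolve_input(spo2, "spo2", impute, acc)
  a <- resolve_input(age, "age", impute, acc)
  check_scalar_number(pr, "pulse_rate", 0)
  check_scalar_number(map, "mean_arterial_pressure", 0)
  check_scalar_number(rr, "respiratory_rate", 0)
  check_scalar_number(g, "gcs", 3, 15)
  check_scalar_number(s, "spo2", 0, 100)
  check_scalar_number(a, "age", 0)
  score_breakdown("REMS", c(
    age = rems_points_age(round_half_up(a)),
    pulse_rate = raps_points_pulse(round_half_up(pr)),
    mean_arterial_pressure = raps_points_map(round_half_up(map)),
    respiratory_rate = raps_points_rr(round_half_up(rr)),
    gcs = raps_points_gcs(round_half_up(g)),
    spo2 = rems_points_spo2(round_half_up(s))
  ), imputed = acc$fields)
}

#' Modified Early Warning Score (MEWS)
#'
#' Five-variable track-and-trigger score over systolic blood pressure, heart
#' rate, respiratory rate, temperature and AVPU consciousness level; range
#' 0--14. Temperature is rounded half-up to 0.1 degC before lookup (so
#' 38.45 degC scores as 38.5, +2); the +1 temperature band does not exist.
#' An explicit `avpu` always takes precedence; when absent it is derived
#' from `gcs` via [avpu_from_gcs()].
#'
#' @param systolic_bp mmHg.
#' @param heart_rate beats/min.
#' @param respiratory_rate breaths/min.
#' @param temperature degrees Celsius.
#' @param avpu one of `"Alert"`, `"Voice"`, `"Pain"`, `"Unresponsive"`, or
#'   `NULL` to derive from `gcs`.
#' @param gcs Glasgow Coma Scale, used only when `avpu` is absent.
#' @inheritParams raps_score
#' @return a [score_breakdown()].
#' @examples
#' mews_score(110, 95, 12, 37.0, avpu = "Alert")$total              # 0
#' mews_score(65, 135, 32, 34.5, avpu = "Unresponsive")$total       # 14
#' @export
mews_score <- function(systolic_bp, heart_rate, respiratory_rate, temperature,
                       avpu = NULL, gcs = NULL, impute = FALSE) {
  acc <- new.env()
  acc$fields <- character()
  sbp <- resolve_input(systolic_bp, "systolic_bp", impute, acc)
  hr <- resolve_input(heart_rate, "heart_rate", impute, acc)
  rr <- resolve_input(respiratory_rate, "respiratory_rate", impute, acc)
  temp <- resolve_input(temperature, "temperature", impute, acc)
  if (is_missing_value(avpu)) {
    if (!is_missing_value(gcs)) {
      check_scalar_number(gcs, "gcs", 3, 15)
      avpu <- avpu_from_gcs(round_half_up(gcs))
    } else {
      avpu <- resolve_input(NULL, "avpu", impute, acc)
    }
  }
  check_scalar_number(sbp, "systolic_bp", 0)
  check_scalar_number(hr, "heart_rate", 0)
  check_scalar_number(rr, "respiratory_rate", 0)
  check_scalar_number(temp, "temperature", 20, 45)
  score_breakdown("MEWS", c(
    systolic_bp = mews_points_sbp(round_half_up(sbp)),
    heart_rate = mews_points_hr(round_half_up(hr)),
    respiratory_rate = mews_points_rr(round_half_up(rr)),
    temperature = mews_points_temp(round_half_up(temp, 1)),
    avpu = mews_points_avpu(avpu)
  ), imputed = acc$fields)
}

#' Tachypnea-or-hypoxia criterion
#'
#' The respiratory criterion of the MEDS score: respiratory rate strictly
#' above 20 breaths/min, or oxygen delivered by mask, or peripheral oxygen
#' saturation strictly below 90 percent. Boundary values (RR exactly 20,
#' SpO2 exactly 90) do not qualify. Vectorised.
#'
#' @param respiratory_rate breaths/min.
#' @param spo2 percent; may be `NA` when `oxygen_by_mask` is `TRUE`.
#' @param oxygen_by_mask logical.
#' @return logical vector.
#' @examples
#' tachypnea_or_hypoxia(20, 90, FALSE)  # FALSE (boundaries excluded)
#' tachypnea_or_hypoxia(12, 99, TRUE)   # TRUE  (mask clause)
#' @export
tachypnea_or_hypoxia <- function(respiratory_rate, spo2, oxygen_by_mask) {
  if (is_missing_value(respiratory_rate)) missing_input_error("respiratory_rate")
  if (is_missing_value(oxygen_by_mask)) missing_input_error("oxygen_by_mask")
  if (anyNA(spo2) && !all(oxygen_by_mask[is.na(spo2)])) {
    missing_input_error("spo2")
  }
  respiratory_rate > 20 | oxygen_by_mask |
    (!is.na(spo2) & spo2 < 90)
}

#' Mortality in Emergency Department Sepsis (MEDS) score
#'
#' Nine weighted criteria for ED patients with suspected infection; range
#' 0--27. The respiratory criterion is computed internally via
#' [tachypnea_or_hypoxia()]. Septic shock and altered mental status are
#' consumed as chart-abstracted boolean flags; when the altered-mental-status
#' flag is absent it defaults to `gcs <= 13`.
#'
#' @param age years, >= 18.
#' @param terminal_illness rapidly fatal comorbid disease with perceived
#'   30-day mortality (logical).
#' @param septic_shock logical flag; not re-derived from hemodynamics.
#' @param platelet_count in 1e9 cells/L.
#' @param band_percent band neutrophils, percent of WBC differential.
#' @param lower_respiratory_infection logical.
#' @param nursing_home_resident logical.
#' @param altered_mental_status logical, or `NULL`/`NA` to fall back to
#'   `gcs <= 13`.
#' @param oxygen_by_mask logical, feeds the respiratory criterion.
#' @param respiratory_rate breaths/min, feeds the respiratory criterion.
#' @param spo2 percent, feeds the respiratory criterion.
#' @param gcs Glasgow Coma Scale; only used when `altered_mental_status` is
#'   absent.
#' @return a [score_breakdown()].
#' @examples
#' meds_score(age = 70, terminal_illness = FALSE, septic_shock = TRUE,
#'            platelet_count = 120, band_percent = 2,
#'            lower_respiratory_infection = FALSE,
#'            nursing_home_resident = FALSE, altered_mental_status = FALSE,
#'            oxygen_by_mask = FALSE, respiratory_rate = 18,
#'            spo2 = 95)$total    # 9
#' @export
meds_score <- function(age, terminal_illness, septic_shock, platelet_count,
                       band_percent, lower_respiratory_infection,
                       nursing_home_resident, altered_mental_status,
                       oxygen_by_mask, respiratory_rate, spo2 = NA,
                       gcs = NULL, impute = FALSE) {
  acc <- new.env()
  acc$fields <- character()
  a <- resolve_input(age, "age", impute, acc)
  plt <- resolve_input(platelet_count, "platelet_count", impute, acc)
  bp <- resolve_input(band_percent, "band_percent", impute, acc)
  check_scalar_number(a, "age", 18)
  check_scalar_number(plt, "platelet_count", 0)
  check_scalar_number(bp, "band_percent", 0, 100)
  check_flag(terminal_illness, "terminal_illness")
  check_flag(septic_shock, "septic_shock")
  check_flag(lower_respiratory_infection, "lower_respiratory_infection")
  check_flag(nursing_home_resident, "nursing_home_resident")
  check_flag(oxygen_by_mask, "oxygen_by_mask")
  if (is_missing_value(altered_mental_status)) {
    if (is_missing_value(gcs)) missing_input_error("altered_mental_status")
    check_scalar_number(gcs, "gcs", 3, 15)
    altered_mental_status <- gcs <= 13
  }
  check_flag(altered_mental_status, "altered_mental_status")
  resp <- tachypnea_or_hypoxia(respiratory_rate, spo2, oxygen_by_mask)

  met <- c(
    terminal_illness            = terminal_illness,
    age_over_65                 = a > 65,
    tachypnea_or_hypoxia        = resp,
    septic_shock                = septic_shock,
    platelets_below_150         = plt < 150,
    bands_over_5pct             = bp > 5,
    lower_respiratory_infection = lower_respiratory_infection,
    nursing_home_resident       = nursing_home_resident,
    altered_mental_status       = altered_mental_status
  )
  score_breakdown("MEDS", MEDS_POINTS * met, imputed = acc$fields)
}

#' Derive AVPU level from the Glasgow Coma Scale
#'
#' Conventional correspondence used when a chart records GCS but not AVPU
#' (always overridden by an explicit AVPU): GCS 14--15 Alert, 9--13 reacts
#' to Voice, 4--8 reacts to Pain, 3 Unresponsive. Vectorised.
#'
#' @param gcs integer vector in 3--15.
#' @return character vector of AVPU levels.
#' @examples
#' avpu_from_gcs(c(15, 10, 3))
#' @export
avpu_from_gcs <- function(gcs) {
  if (is_missing_value(gcs)) missing_input_error("gcs")
  if (any(!is.finite(gcs) | gcs < 3 | gcs > 15)) {
    validation_error("gcs must be in [3, 15]")
  }
  ifelse(gcs >= 14, "Alert",
  ifelse(gcs >= 9, "Voice",
  ifelse(gcs >= 4, "Pain", "Unresponsive")))
}

#' Score every patient in a cohort
#'
#' Vectorised application of the four calculators over a cohort data frame,
#' appending one integer total column per requested system (`raps`, `rems`,
#' `mews`, `meds`). AVPU is taken from the `avpu` column where present and
#' derived from `gcs` otherwise; the altered-mental-status flag falls back
#' to `gcs <= 13` where missing.
#'
#' @param cohort a [cohort()] or data frame with the cohort schema columns.
#' @param systems subset of `c("raps", "rems", "mews", "meds")`.
#' @return the input with appended score columns (class preserved).
#' @export
score_cohort <- function(cohort, systems = c("raps", "rems", "mews", "meds")) {
  systems <- match.arg(systems, several.ok = TRUE)
  df <- as.data.frame(cohort)
  pr <- round_half_up(df$pulse_rate)
  map <- round_half_up(df$mean_arterial_pressure)
  rr <- round_half_up(df$respiratory_rate)
  gcs <- round_half_up(df$gcs)
  out <- cohort
  if ("raps" %in% systems) {
    out$raps <- raps_points_pulse(pr) + raps_points_map(map) +
      raps_points_rr(rr) + raps_points_gcs(gcs)
  }
  if ("rems" %in% systems) {
    out$rems <- rems_points_age(round_half_up(df$age)) +
      raps_points_pulse(pr) + raps_points_map(map) + raps_points_rr(rr) +
      raps_points_gcs(gcs) + rems_points_spo2(round_half_up(df$spo2))
  }
  if ("mews" %in% systems) {
    avpu <- if ("avpu" %in% names(df)) as.character(df$avpu) else
      rep(NA_character_, nrow(df))
    derive <- is.na(avpu) | avpu == ""
    if (any(derive)) avpu[derive] <- avpu_from_gcs(gcs[derive])
    out$mews <- mews_points_sbp(round_half_up(df$systolic_bp)) +
      mews_points_hr(round_half_up(df$pulse_rate)) +
      mews_points_rr(rr) +
      mews_points_temp(round_half_up(df$temperature, 1)) +
      mews_points_avpu(avpu)
  }
  if ("meds" %in% systems) {
    ams <- df$altered_mental_status
    if (is.null(ams)) ams <- rep(NA, nrow(df))
    ams[is.na(ams)] <- gcs[is.na(ams)] <= 13
    resp <- tachypnea_or_hypoxia(df$respiratory_rate, df$spo2,
                                 df$oxygen_by_mask)
    out$meds <- as.integer(
      6L * df$terminal_illness +
      3L * (df$age > 65) +
      3L * resp +
      3L * df$septic_shock +
      3L * (df$platelet_count < 150) +
      3L * (df$band_percent > 5) +
      2L * df$lower_respiratory_infection +
      2L * df$nursing_home_resident +
      2L * ams)
  }
  out
}
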