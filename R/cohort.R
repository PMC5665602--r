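# Cohort data model: one row per ED patient, plain data.frame underneath.
#
# CSV dialect is deliberately boring: comma separated, UTF-8, "." decimal,
# lowercase true/false booleans, empty cell = missing. Lines starting with
# "#" are provenance headers and are skipped on read.

ETIOLOGY_LEVELS <- c("hematogenous", "sickle_cell_related", "traumatic",
                     "contiguous")
MULTIPLICITY_LEVELS <- c("solitary", "multiple")
TREATMENT_LEVELS <- c("conservative", "aspiration", "operation")
OUTCOME_LEVELS <- c("survived", "died")
SEX_LEVELS <- c("male", "female")
AVPU_LEVELS <- c("Alert", "Voice", "Pain", "Unresponsive")

COHORT_NUMERIC <- c("age", "pulse_rate", "respiratory_rate", "systolic_bp",
                    "mean_arterial_pressure", "temperature", "spo2", "gcs",
                    "platelet_count", "leukocyte_count", "band_percent")
COHORT_LOGICAL <- c("septic_shock", "terminal_illness",
                    "lower_respiratory_infection", "nursing_home_resident",
                    "altered_mental_status", "oxygen_by_mask")
COHORT_ENUM <- list(sex = SEX_LEVELS, avpu = AVPU_LEVELS,
                    etiology = ETIOLOGY_LEVELS,
                    abscess_multiplicity = MULTIPLICITY_LEVELS,
                    treatment = TREATMENT_LEVELS, outcome = OUTCOME_LEVELS)

COHORT_COLUMNS <- c("patient_id", "age", "sex", "pulse_rate",
                    "respiratory_rate", "systolic_bp",
                    "mean_arterial_pressure", "temperature", "spo2", "gcs",
                    "avpu", "platelet_count", "leukocyte_count",
                    "band_percent", COHORT_LOGICAL, "etiology",
                    "abscess_multiplicity", "treatment", "outcome")

#' Construct a patient cohort
#'
#' Wraps a validated per-patient data frame (see the README for the column
#' schema) together with its provenance (`"observed"` or `"synthetic"`) and,
#' for synthetic cohorts, the generator seed.
#'
#' @param records data frame, one row per patient.
#' @param provenance `"observed"` or `"synthetic"`.
#' @param seed integer seed used to generate the cohort, or `NULL`.
#' @param validate run [validate_cohort()] (default `TRUE`).
#' @return object of class `cohort` (a data frame with provenance
#'   attributes).
#' @export
cohort <- function(records, provenance = c("observed", "synthetic"),
                   seed = NULL, validate = TRUE) {
  provenance <- match.arg(provenance)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (validate) validate_cohort(records)
  structure(records,
            provenance = provenance,
            seed = if (is.null(seed)) NULL else as.integer(seed),
            class = c("cohort", "data.frame"))
}

#' @export
print.cohort <- function(x, ...) {
  oc <- outcome_counts(x)
  cat(sprintf("<cohort> %d patients (%s%s): %d survived, %d died\n",
              nrow(x), attr(x, "provenance") %||% "observed",
              if (!is.null(attr(x, "seed")))
                sprintf(", seed %d", attr(x, "seed")) else "",
              oc[["survived"]], oc[["died"]]))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... and %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Outcome composition of a cohort
#'
#' @param cohort a [cohort()] or compatible data frame.
#' @return named integer vector with elements `survived` and `died`.
#' @export
outcome_counts <- function(cohort) {
  c(survived = sum(cohort$outcome == "survived", na.rm = TRUE),
    died = sum(cohort$outcome == "died", na.rm = TRUE))
}

#' Validate a cohort data frame
#'
#' Checks ids, ranges and enum labels cell by cell and reports every
#' offending row/field pair in one error, so a bad CSV can be repaired in a
#' single pass. Missing values (empty cells) are allowed everywhere except
#' `patient_id`; score calculators decide later how to handle them.
#'
#' @param records data frame with cohort schema columns.
#' @return the records, invisibly, if valid; otherwise a validation error
#'   listing each offending row and field.
#' @export
validate_cohort <- function(records) {
  problems <- character()
  note <- function(rows, field, what) {
    if (length(rows)) {
      problems <<- c(problems, sprintf("row %d, %s: %s", rows, field, what))
    }
  }
  missing_cols <- setdiff(c("patient_id", COHORT_NUMERIC, COHORT_LOGICAL,
                            "outcome"), names(records))
  if (length(missing_cols)) {
    validation_error(sprintf("cohort is missing columns: %s",
                             paste(missing_cols, collapse = ", ")))
  }
  id <- records$patient_id
  note(which(is.na(id) | id == ""), "patient_id", "missing")
  dup <- which(duplicated(id) & !is.na(id))
  note(dup, "patient_id", sprintf("duplicate id '%s'", id[dup]))

  range_check <- function(field, lower, upper) {
    v <- records[[field]]
    bad <- which(!is.na(v) & (v < lower | v > upper))
    note(bad, field, sprintf("value %s outside [%s, %s]",
                             format(v[bad]), format(lower), format(upper)))
  }
  range_check("gcs", 3, 15)
  range_check("spo2", 0, 100)
  range_check("band_percent", 0, 100)
  range_check("age", 18, 130)
  range_check("temperature", 20, 45)
  for (f in c("pulse_rate", "respiratory_rate", "systolic_bp",
              "mean_arterial_pressure", "platelet_count",
              "leukocyte_count")) {
    range_check(f, 0, Inf)
  }
  for (f in COHORT_LOGICAL) {
    v <- records[[f]]
    if (!is.logical(v)) {
      validation_error(sprintf("column %s must be logical (true/false)", f))
    }
  }
  for (f in intersect(names(COHORT_ENUM), names(records))) {
    v <- as.character(records[[f]])
    bad <- which(!is.na(v) & v != "" & !(v %in% COHORT_ENUM[[f]]))
    note(bad, f, sprintf("unknown label '%s' (allowed: %s)", v[bad],
                         paste(COHORT_ENUM[[f]], collapse = "/")))
  }
  if (length(problems)) {
    validation_error(paste0("cohort validation failed:\n  ",
                            paste(problems, collapse = "\n  ")))
  }
  invisible(records)
}

#' Read a patient cohort from CSV
#'
#' @param path CSV file path; lines beginning with `#` are treated as
#'   provenance comments. A `# seed=N` / `# provenance=...` header written
#'   by [write_cohort()] is restored onto the returned object.
#' @param schema optional named character vector mapping file column names
#'   to schema names, e.g. `c(hr = "pulse_rate")`.
#' @return a [cohort()].
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    eds_error(sprintf("cohort file not found: %s", path), "edscores_io_error")
  }
  head_lines <- readLines(path, n = 10L, encoding = "UTF-8")
  meta <- grep("^#", head_lines, value = TRUE)
  prov <- if (any(grepl("provenance=synthetic", meta))) "synthetic"
          else "observed"
  seed <- NULL
  seed_line <- grep("seed=([0-9]+)", meta, value = TRUE)
  if (length(seed_line)) {
    seed <- as.integer(sub(".*seed=([0-9]+).*", "\\1", seed_line[[1]]))
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        na.strings = "", encoding = "UTF-8")
  if (!is.null(schema)) {
    hit <- names(df) %in% names(schema)
    names(df)[hit] <- schema[names(df)[hit]]
  }
  df$patient_id <- as.character(df$patient_id)
  for (f in intersect(COHORT_LOGICAL, names(df))) {
    v <- df[[f]]
    if (is.character(v)) {
      bad <- which(!is.na(v) & !(v %in% c("true", "false")))
      if (length(bad)) {
        validation_error(sprintf(
          "row %d, %s: boolean cells must be true/false, got '%s'",
          bad[1], f, v[bad[1]]))
      }
      df[[f]] <- v == "true"
    } else {
      df[[f]] <- as.logical(v)
    }
  }
  cohort(df, provenance = prov, seed = seed)
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort()]: the produced file reads back with identical
#' records. A provenance comment header records the package version and,
#' for synthetic cohorts, the generator seed.
#'
#' @param cohort a [cohort()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (f in intersect(COHORT_LOGICAL, names(df))) {
    df[[f]] <- ifelse(is.na(df[[f]]), NA_character_,
                      ifelse(df[[f]], "true", "false"))
  }
  con <- tryCatch(file(path, open = "wb", encoding = "UTF-8"),
                  error = function(e) eds_error(
                    sprintf("cannot open '%s' for writing: %s", path,
                            conditionMessage(e)), "edscores_io_error"))
  on.exit(close(con))
  seed <- attr(cohort, "seed")
  header <- sprintf("# edscores %s cohort | provenance=%s%s",
                    as.character(utils::packageVersion("edscores")),
                    attr(cohort, "provenance") %||% "observed",
                    if (!is.null(seed)) sprintf(" | seed=%d", seed) else "")
  writeLines(header, con)
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "", fileEncoding = "")
  invisible(path)
}
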