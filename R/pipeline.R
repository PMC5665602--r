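# End-to-end study pipeline: univariate group comparisons, per-score
# logistic calibration of death probabilities, and ROC-based mortality
# prediction evaluation.

SCORE_SYSTEMS <- c("raps", "rems", "mews", "meds")

fmt_median_iqr <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
  sprintf("%.1f (%.1f-%.1f)", q[[2]], q[[1]], q[[3]])
}

fmt_mean_sd <- function(x) {
  sprintf("%.2f (%.2f)", mean(x, na.rm = TRUE), stats::sd(x, na.rm = TRUE))
}

#' Run the full mortality-prediction study pipeline
#'
#' Executes, on one cohort, the analysis sequence of a severity-score
#' validation study: (1) univariate survivor versus non-survivor
#' comparisons (Mann-Whitney U for continuous variables, Fisher's exact
#' test for categorical ones); (2) per-score univariate logistic
#' calibration, per-patient probabilities of death, arm summaries of those
#' probabilities (both mean/SD and median/IQR) and a Mann-Whitney
#' comparison between arms; (3) per-score ROC curve, AUROC, Youden-optimal
#' cutoff and the confusion-matrix test characteristics at that cutoff.
#'
#' @param cohort a [cohort()] (scored columns are added if absent).
#' @param systems score systems to evaluate, subset of
#'   `c("raps", "rems", "mews", "meds")`.
#' @return object of class `study_report` with elements `composition`,
#'   `univariate` (data frame), `calibration` (data frame plus `fits`),
#'   `performance` (data frame plus `rocs`), and `scored` (the scored
#'   cohort).
#' @examples
#' rep <- run_study_pipeline(generate_cohort(seed = 7))
#' rep$performance[, c("system", "auc", "cutoff")]
#' @export
run_study_pipeline <- function(cohort, systems = SCORE_SYSTEMS) {
  systems <- match.arg(systems, several.ok = TRUE)
  df <- as.data.frame(cohort)
  if (!("outcome" %in% names(df)) || anyNA(df$outcome)) {
    validation_error("pipeline requires an outcome for every patient")
  }
  died <- df$outcome == "died"
  if (!any(died) || all(died)) {
    validation_error("both outcome classes must be present")
  }
  missing_scores <- setdiff(systems, names(df))
  if (length(missing_scores)) {
    df <- as.data.frame(score_cohort(df, systems))
  }

  ## --- stage 1: univariate comparisons ------------------------------------
  cont_vars <- c("age", "temperature", "pulse_rate", "respiratory_rate",
                 "mean_arterial_pressure", "leukocyte_count",
                 "platelet_count")
  uni <- lapply(cont_vars, function(v) {
    cmp <- mann_whitney_u(df[[v]][!died], df[[v]][died])
    data.frame(variable = v,
               survivors = fmt_median_iqr(df[[v]][!died]),
               nonsurvivors = fmt_median_iqr(df[[v]][died]),
               p_value = cmp$p_value, method = cmp$method,
               stringsAsFactors = FALSE)
  })
  cat_tables <- list(
    male = table(factor(df$sex == "male", c(TRUE, FALSE)), died),
    gcs_band = table(cut(df$gcs, c(2, 8, 11, 15),
                         labels = c("le8", "b9to11", "ge12")), died),
    platelet_below_150 = table(factor(df$platelet_count < 150,
                                      c(TRUE, FALSE)), died),
    septic_shock = table(factor(df$septic_shock, c(TRUE, FALSE)), died),
    terminal_illness = table(factor(df$terminal_illness, c(TRUE, FALSE)),
                             died),
    treatment = table(factor(df$treatment, TREATMENT_LEVELS), died),
    etiology = table(factor(df$etiology, ETIOLOGY_LEVELS), died),
    abscess_multiplicity = table(factor(df$abscess_multiplicity,
                                        MULTIPLICITY_LEVELS), died)
  )
  uni_cat <- lapply(names(cat_tables), function(v) {
    tab <- cat_tables[[v]]
    m <- matrix(as.integer(tab), ncol = 2,
                dimnames = list(rownames(tab), c("survived", "died")))
    m <- m[, c("survived", "died"), drop = FALSE]
    cmp <- fisher_exact(m)
    pct <- function(col, n) paste(sprintf("%d (%.1f%%)", col,
                                          100 * col / n), collapse = "; ")
    data.frame(variable = v,
               survivors = pct(m[, "survived"], sum(m[, "survived"])),
               nonsurvivors = pct(m[, "died"], sum(m[, "died"])),
               p_value = cmp$p_value, method = cmp$method,
               stringsAsFactors = FALSE)
  })
  univariate <- do.call(rbind, c(uni, uni_cat))

  ## --- stage 2: logistic calibration of death probabilities ---------------
  fits <- list()
  calib_rows <- lapply(systems, function(s) {
    fit <- fit_univariate_logistic(df[[s]], died)
    fits[[s]] <<- fit
    p <- predict_probability(fit, df[[s]])
    cmp <- mann_whitney_u(p[!died], p[died])
    data.frame(system = toupper(s),
               beta0 = fit$beta0, beta1 = fit$beta1,
               surv_mean_sd = fmt_mean_sd(p[!died]),
               nonsurv_mean_sd = fmt_mean_sd(p[died]),
               surv_median_iqr = fmt_median_iqr(p[!died]),
               nonsurv_median_iqr = fmt_median_iqr(p[died]),
               surv_mean = mean(p[!died]), nonsurv_mean = mean(p[died]),
               p_value = cmp$p_value,
               stringsAsFactors = FALSE)
  })
  calibration <- do.call(rbind, calib_rows)

  ## --- stage 3: ROC / cutoff / test characteristics -----------------------
  rocs <- list()
  perf_rows <- lapply(systems, function(s) {
    roc <- roc_curve(df[[s]], died)
    rocs[[s]] <<- roc
    cut <- optimal_cutoff(roc)
    m <- confusion_metrics(df[[s]], died, cut)
    data.frame(system = toupper(s), auc = roc$auc, cutoff = cut,
               sensitivity = m$sensitivity, specificity = m$specificity,
               ppv = m$ppv, npv = m$npv, accuracy = m$accuracy,
               tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn,
               stringsAsFactors = FALSE)
  })
  performance <- do.call(rbind, perf_rows)

  structure(list(
    composition = outcome_counts(df),
    univariate = univariate,
    calibration = calibration,
    fits = fits,
    performance = performance,
    rocs = rocs,
    scored = df,
    systems = systems,
    provenance = attr(cohort, "provenance") %||% "observed",
    seed = attr(cohort, "seed")),
    class = "study_report")
}

#' @export
print.study_report <- function(x, digits = 3, ...) {
  cat(sprintf("Study report: %d patients (%d survived, %d died)\n\n",
              sum(x$composition), x$composition[["survived"]],
              x$composition[["died"]]))
  cat("Univariate survivor vs non-survivor comparisons:\n")
  u <- x$univariate
  u$p_value <- signif(u$p_value, digits)
  print(u, row.names = FALSE)
  cat("\nLogistic probability of death per score (survivors vs non-survivors):\n")
  cal <- x$calibration[, c("system", "beta0", "beta1", "surv_mean_sd",
                           "nonsurv_mean_sd", "surv_median_iqr",
                           "nonsurv_median_iqr", "p_value")]
  cal$beta0 <- round(cal$beta0, 4); cal$beta1 <- round(cal$beta1, 4)
  cal$p_value <- signif(cal$p_value, digits)
  print(cal, row.names = FALSE)
  cat("\nMortality prediction performance:\n")
  p <- x$performance
  for (col in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    p[[col]] <- sprintf("%.2f%%", 100 * p[[col]])
  }
  p$auc <- round(p$auc, 4)
  print(p[, c("system", "auc", "cutoff", "sensitivity", "specificity",
              "ppv", "npv", "accuracy")], row.names = FALSE)
  invisible(x)
}

#' Write study report artifacts to a directory
#'
#' Writes `metrics.csv` (performance table), `calibration.csv`,
#' `univariate.csv`, `roc_points.csv` (all ROC coordinates, one block per
#' system) and `report.txt` (the printed report). Every file carries a
#' provenance header with package version, seed and configuration.
#'
#' @param report a [run_study_pipeline()] result.
#' @param dir output directory (created if needed).
#' @param config optional named character vector echoed into headers.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir, config = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  header <- sprintf(
    "# edscores %s | provenance=%s%s%s",
    as.character(utils::packageVersion("edscores")),
    report$provenance,
    if (!is.null(report$seed)) sprintf(" | seed=%d", report$seed) else "",
    if (length(config)) paste0(" | ", paste(names(config), config,
                                            sep = "=", collapse = " ")) else "")
  write_with_header <- function(df, path) {
    con <- file(path, "wb", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE,
                       na = "")
  }
  write_with_header(report$performance, file.path(dir, "metrics.csv"))
  write_with_header(report$calibration, file.path(dir, "calibration.csv"))
  write_with_header(report$univariate, file.path(dir, "univariate.csv"))
  roc_df <- do.call(rbind, lapply(names(report$rocs), function(s) {
    r <- report$rocs[[s]]
    data.frame(system = toupper(s), threshold = r$thresholds,
               tpr = r$tpr, fpr = r$fpr, stringsAsFactors = FALSE)
  }))
  write_with_header(roc_df, file.path(dir, "roc_points.csv"))
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "wb", encoding = "UTF-8")
  writeLines(header, con)
  sink(con)
  print(report)
  sink()
  close(con)
  invisible(dir)
}
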