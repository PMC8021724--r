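# File I/O with schema validation, plus the end-to-end pipeline
# (simulate -> score -> label -> evaluate -> compare).
#
# CSV dialect: comma-separated, UTF-8, "." decimal separator, blank cell =
# missing, header row required.

.require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    .stop_invalid("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  }
}

.collect <- function(errors, cond, msg) {
  if (any(cond, na.rm = TRUE)) {
    rows <- which(cond)
    c(errors, sprintf("%s (rows %s)", msg, paste(rows, collapse = ", ")))
  } else errors
}

#' Read and validate the infant-record table
#'
#' @param path Path to `infants.csv`.
#' @return Validated data frame; a schema error lists every offending row.
#' @export
read_infants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("infant_id", "gestational_age_weeks", "birth_weight_g",
                         "chorioamnionitis", "antenatal_steroid_complete",
                         "cord_base_deficit_mmol_l", "fio2_admission_pct"), path)
  e <- character(0)
  e <- .collect(e, duplicated(df$infant_id), "duplicate infant_id")
  e <- .collect(e, !is.finite(df$birth_weight_g) | df$birth_weight_g <= 0,
                "birth_weight_g must be positive")
  e <- .collect(e, !df$chorioamnionitis %in% c(0, 1), "chorioamnionitis must be 0/1")
  e <- .collect(e, !df$antenatal_steroid_complete %in% c(0, 1),
                "antenatal_steroid_complete must be 0/1")
  e <- .collect(e, !is.finite(df$cord_base_deficit_mmol_l) | df$cord_base_deficit_mmol_l < 0,
                "cord_base_deficit_mmol_l must be a non-negative deficit magnitude")
  e <- .collect(e, !is.finite(df$fio2_admission_pct) | df$fio2_admission_pct < 21 |
                  df$fio2_admission_pct > 100, "fio2_admission_pct must lie in [21, 100]")
  if (length(e)) .stop_invalid("schema errors in %s:\n  %s", path, paste(e, collapse = "\n  "))
  df
}

#' Read and validate the long-format observation table
#'
#' @param path Path to `observations.csv`.
#' @return Validated data frame; a schema error lists every offending row.
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("infant_id", "hour", "heart_rate_bpm", "hypotension_inotropes",
                         "vent_mode", "pip_cmh2o", "fio2_pct", "ph",
                         "base_deficit_mmol_l", "pco2_mmhg", "surfactant_doses_cum"), path)
  e <- character(0)
  e <- .collect(e, !df$hour %in% simple_schedule(), "hour not in {6,12,18,24,48,72}")
  e <- .collect(e, duplicated(df[, c("infant_id", "hour")]), "duplicate (infant_id, hour)")
  e <- .collect(e, !is.na(df$heart_rate_bpm) & df$heart_rate_bpm <= 0,
                "heart_rate_bpm must be positive")
  e <- .collect(e, !is.na(df$hypotension_inotropes) & !df$hypotension_inotropes %in% c(0, 1),
                "hypotension_inotropes must be 0/1")
  e <- .collect(e, !is.na(df$vent_mode) &
                  !tolower(df$vent_mode) %in% c("none", "conventional", "hfov"),
                "unknown vent_mode")
  e <- .collect(e, !is.na(df$vent_mode) & tolower(df$vent_mode) == "none" & !is.na(df$pip_cmh2o),
                "pip_cmh2o must be blank when vent_mode is none")
  e <- .collect(e, !is.na(df$fio2_pct) & (df$fio2_pct < 21 | df$fio2_pct > 100),
                "fio2_pct must lie in [21, 100]")
  e <- .collect(e, !is.na(df$ph) & (df$ph <= 6.5 | df$ph >= 8.0), "ph out of range (6.5, 8.0)")
  e <- .collect(e, !is.na(df$base_deficit_mmol_l) & df$base_deficit_mmol_l < 0,
                "base_deficit_mmol_l must be non-negative")
  e <- .collect(e, !is.na(df$pco2_mmhg) & df$pco2_mmhg <= 0, "pco2_mmhg must be positive")
  e <- .collect(e, !is.na(df$surfactant_doses_cum) &
                  (df$surfactant_doses_cum < 0 |
                     df$surfactant_doses_cum != round(df$surfactant_doses_cum)),
                "surfactant_doses_cum must be a non-negative integer")
  if (length(e)) .stop_invalid("schema errors in %s:\n  %s", path, paste(e, collapse = "\n  "))
  df
}

#' Read and validate the echo table
#'
#' @param path Path to `echo.csv`.
#' @return Validated data frame.
#' @export
read_echo <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("infant_id", "hour", "la_ao", "duct_diameter_mm", "weight_kg"), path)
  e <- character(0)
  e <- .collect(e, !df$hour %in% echo_schedule(), "hour not in {24,48,72}")
  e <- .collect(e, duplicated(df[, c("infant_id", "hour")]), "duplicate (infant_id, hour)")
  for (v in c("la_ao", "duct_diameter_mm", "weight_kg")) {
    e <- .collect(e, !is.finite(df[[v]]) | df[[v]] <= 0, sprintf("%s must be positive", v))
  }
  if (length(e)) .stop_invalid("schema errors in %s:\n  %s", path, paste(e, collapse = "\n  "))
  df
}

#' Read a full cohort from a directory of CSVs
#'
#' Expects `infants.csv`, `observations.csv`, `echo.csv` and optionally
#' `labels.csv` in `dir`, validates each, and checks referential
#' consistency across tables.
#'
#' @param dir Directory containing the CSVs.
#' @return List with `infants`, `observations`, `echo` and (if present)
#'   `labels`.
#' @export
read_cohort <- function(dir) {
  infants <- read_infants(file.path(dir, "infants.csv"))
  observations <- read_observations(file.path(dir, "observations.csv"))
  echo <- read_echo(file.path(dir, "echo.csv"))
  stray <- setdiff(unique(observations$infant_id), infants$infant_id)
  if (length(stray)) {
    .stop_invalid("observations reference unknown infant(s): %s", paste(stray, collapse = ", "))
  }
  out <- list(infants = infants, observations = observations, echo = echo)
  lab_path <- file.path(dir, "labels.csv")
  if (file.exists(lab_path)) {
    out$labels <- utils::read.csv(lab_path, stringsAsFactors = FALSE)
  }
  out
}

#' Write a synthetic cohort to a directory of CSVs
#'
#' Emits `infants.csv`, `observations.csv`, `echo.csv` and `labels.csv`.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$infants, file.path(dir, "infants.csv"), row.names = FALSE)
  utils::write.csv(cohort$observations, file.path(dir, "observations.csv"), row.names = FALSE)
  utils::write.csv(cohort$echo, file.path(dir, "echo.csv"), row.names = FALSE)
  utils::write.csv(cohort$labels, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Run the full pipeline: simulate, score, label, evaluate, compare
#'
#' Generates (or loads) a cohort, computes per-hour SIMPLE scores with the
#' scoring engine, labels infants from the echo criterion plus the
#' symptomatic flag, evaluates the score per assessment hour (empirical
#' ROC, AUC with DeLong significance, Youden-optimal cut-off, sensitivity
#' and specificity with exact CIs), and produces the group-comparison
#' table. Deterministic given the configured seed.
#'
#' @param config A [cohort_config()]; its seed drives all randomness.
#' @param out_dir Optional output directory; when given, writes
#'   `scores.csv`, `roc.csv`, `summary.json`, `group_summary.csv` and
#'   `report.txt`.
#' @return List with `cohort`, `scores`, `evaluations` (per-hour
#'   `roc_eval` objects), `summary` (per-hour data frame), and
#'   `group_summary`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL) {
  cohort <- generate_cohort(config)
  scores <- score_cohort(cohort$infants, cohort$observations)
  lab <- cohort$labels[match(unique(scores$infant_id), cohort$labels$infant_id), ]
  is_case <- stats::setNames(lab$group == "case", lab$infant_id)

  evaluations <- list(); summary_rows <- list(); roc_rows <- list()
  for (h in simple_schedule()) {
    sh <- scores[scores$hour == h, ]
    y <- is_case[sh$infant_id]
    roc <- empirical_roc(sh$total, y, hour = h)
    sig <- auc_significance(roc)
    ss <- sens_spec_at(sh$total, y, roc$optimal_cutoff)
    evaluations[[as.character(h)]] <- roc
    summary_rows[[as.character(h)]] <- data.frame(
      hour = h, n_cases = roc$n_cases, n_controls = roc$n_controls,
      auc = roc$auc, auc_p_value = sig$p_value,
      optimal_cutoff = roc$optimal_cutoff,
      sensitivity = ss$estimate[1], sens_lower = ss$lower[1], sens_upper = ss$upper[1],
      specificity = ss$estimate[2], spec_lower = ss$lower[2], spec_upper = ss$upper[2])
    roc_rows[[as.character(h)]] <- data.frame(
      hour = h, threshold = roc$thresholds,
      sensitivity = roc$sensitivity, specificity = roc$specificity)
  }
  summary <- do.call(rbind, summary_rows)
  rownames(summary) <- NULL

  demo <- merge(cohort$infants, cohort$outcomes, by = "infant_id")
  demo <- demo[match(lab$infant_id, demo$infant_id), ]
  group_summary <- summarize_groups(
    demo[, c("gestational_age_weeks", "birth_weight_g", "chorioamnionitis",
             "antenatal_steroid_complete", "mortality", "ivh_grade3")],
    lab$group == "case")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out_dir, "scores.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, roc_rows), file.path(out_dir, "roc.csv"), row.names = FALSE)
    utils::write.csv(group_summary, file.path(out_dir, "group_summary.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, n_total = config$n_total, n_cases = config$n_cases,
           max_attainable_score = sum(simple_item_maxima()),
           per_hour = summary),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = 10, pretty = TRUE)
    .write_report(file.path(out_dir, "report.txt"), config, cohort, scores, summary, is_case)
  }

  list(cohort = cohort, scores = scores, evaluations = evaluations,
       summary = summary, group_summary = group_summary)
}

.write_report <- function(path, config, cohort, scores, summary, is_case) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("SIMPLE score evaluation on a synthetic ELBW cohort (seed %d)", config$seed)
  w("Infants: %d (%d hsPDA cases, %d controls); maximum attainable score: %d",
    config$n_total, config$n_cases, config$n_total - config$n_cases,
    sum(simple_item_maxima()))
  w("Rejection-sampling acceptance rate: %.2f", cohort$acceptance_rate)
  w("")
  w("Per-hour score distributions, median (min-max):")
  for (h in simple_schedule()) {
    sh <- scores[scores$hour == h, ]
    y <- is_case[sh$infant_id]
    f <- function(v) sprintf("%g (%g-%g)", stats::median(v), min(v), max(v))
    w("  %2d h  cases %s | controls %s", h, f(sh$total[y]), f(sh$total[!y]))
  }
  w("")
  w("Per-hour ROC statistics (rule: score > cut-off predicts hsPDA):")
  for (i in seq_len(nrow(summary))) {
    s <- summary[i, ]
    w(paste0("  %2d h  AUC %.3f (p %s)  cut-off >%g  ",
             "sens %.2f%% (%.1f-%.1f)  spec %.2f%% (%.1f-%.1f)"),
      s$hour, s$auc, format.pval(s$auc_p_value, digits = 3), s$optimal_cutoff,
      100 * s$sensitivity, 100 * s$sens_lower, 100 * s$sens_upper,
      100 * s$specificity, 100 * s$spec_lower, 100 * s$spec_upper)
  }
  invisible(path)
}
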