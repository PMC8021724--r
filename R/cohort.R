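# Synthetic ELBW cohort generator.
#
# The generator emulates the study design: 48 infants (30 hsPDA cases /
# 18 controls), observed at 6, 12, 18, 24, 48 and 72 h, with echo at
# 24/48/72 h. Item-level clinical values are drawn from group-conditional
# distributions; SIMPLE totals are never sampled directly — every total is
# recomputed by the scoring engine, and an infant's trajectory is accepted
# only if its per-hour totals fall inside the configured per-group ranges.

.hours <- c(6L, 12L, 18L, 24L, 48L, 72L)

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(hi, pmax(lo, stats::qnorm(p, mean, sd)))
}

# 31-bit deterministic per-infant substream seed
.substream_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 2654435761 + idx * 40503) %% 2147483647)
}

.default_hour_matrix <- function(case, control) {
  m <- rbind(case = case, control = control)
  colnames(m) <- as.character(.hours)
  m
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the study conditions: cohort composition (48 infants,
#' 30 cases), group-conditional item prevalences (chorioamnionitis 21/30
#' vs 5/18, missing antenatal steroids 19/30 vs 4/18, hypotension on
#' inotropes 22/30 vs 2/18, tachycardia 16/30 vs 3/18, HFOV 9/30 vs 1/18,
#' surfactant 16/30 vs 6/18 with repeat dosing 9/30 vs 0/18, cord-gas
#' deficit >= 12 mmol/L in 7/30 vs 4/18), per-group per-hour total-score
#' targets (median and min-max), per-group per-day echo-index targets, and
#' demographic medians/ranges. Continuous covariates are drawn from
#' truncated normal distributions whose bin-occupancy probabilities are
#' the calibrated per-item parameters.
#'
#' @param n_total Number of infants (default 48).
#' @param n_cases Number of hsPDA cases (default 30).
#' @param seed Integer seed; the cohort is a deterministic function of it.
#' @param score_targets Named list (`case`, `control`) of 6x3 matrices
#'   (rows = hours; columns `median`, `min`, `max`) of total-score targets.
#' @param echo_targets Named list (`case`, `control`) of per-day `la_ao`
#'   and `duct_per_kg` triplets `(median, min, max)`.
#' @param prevalence Named list of per-group item probabilities (see
#'   defaults in the function body).
#' @param max_attempts Per-infant cap on rejection-sampling attempts.
#' @param acceptance_floor Minimum tolerated overall acceptance rate.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_total = 48L, n_cases = 30L, seed = 1L,
                          score_targets = NULL, echo_targets = NULL,
                          prevalence = NULL,
                          max_attempts = 400L, acceptance_floor = 1e-3) {
  if (is.null(score_targets)) {
    score_targets <- list(
      case = cbind(median = c(12, 13, 13, 14, 15, 14),
                   min    = c(5, 5, 5, 5, 10, 9),
                   max    = c(19, 20, 22, 19, 23, 21)),
      control = cbind(median = c(4, 4, 4, 4, 4, 4),
                      min    = c(2, 2, 2, 2, 2, 2),
                      max    = c(18, 13, 14, 14, 13, 12))
    )
    rownames(score_targets$case) <- rownames(score_targets$control) <- as.character(.hours)
  }
  if (is.null(echo_targets)) {
    echo_targets <- list(
      case = list(
        la_ao = rbind(`24` = c(1.7, 1.2, 2.8), `48` = c(1.6, 1.3, 3.4), `72` = c(1.6, 1.2, 2.9)),
        duct_per_kg = rbind(`24` = c(2.1, 1.1, 3.7), `48` = c(2.1, 1.1, 3.8), `72` = c(2.3, 0.9, 3.5))),
      control = list(
        la_ao = rbind(`24` = c(1.3, 1.0, 2.3), `48` = c(1.2, 0.9, 1.8), `72` = c(1.2, 0.9, 1.5)),
        duct_per_kg = rbind(`24` = c(1.9, 1.2, 2.7), `48` = c(1.6, 1.3, 2.3), `72` = c(1.3, 1.1, 2.1)))
    )
  }
  if (is.null(prevalence)) {
    prevalence <- list(
      chorioamnionitis = c(case = 21 / 30, control = 5 / 18),
      steroid_missing  = c(case = 19 / 30, control = 4 / 18),
      hypotension      = c(case = 22 / 30, control = 2 / 18),
      tachycardia      = c(case = 16 / 30, control = 3 / 18),
      cord_gas_high    = c(case = 7 / 30, control = 4 / 18),
      vent_class = list(case = c(none = 0.13, conventional = 0.57, hfov = 0.30),
                        control = c(none = 0.50, conventional = 0.444, hfov = 1 / 18)),
      surfactant = list(case = c(14, 7, 9) / 30, control = c(12, 6, 0) / 18),
      fio2_admission = list(case = c(0.30, 0.45, 0.25), control = c(0.88, 0.11, 0.01))
    )
  }
  cfg <- list(n_total = as.integer(n_total), n_cases = as.integer(n_cases),
              seed = as.integer(seed), score_targets = score_targets,
              echo_targets = echo_targets, prevalence = prevalence,
              demographics = list(
                gest_age = list(case = c(25, 1.8, 21, 29), control = c(26, 1.3, 24, 29)),
                birth_weight = list(case = c(700, 155, 340, 990), control = c(820, 95, 620, 995))),
              outcome_rates = list(mortality = c(case = 16 / 30, control = 0),
                                   ivh_grade3 = c(case = 17 / 30, control = 1 / 18)),
              max_attempts = as.integer(max_attempts),
              acceptance_floor = acceptance_floor)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Validate a cohort configuration
#'
#' Checks feasibility before any sampling: group sizes, probabilities in
#' \[0, 1\], and target ranges that contain their medians.
#'
#' @param config A [cohort_config()] object.
#' @return The config, invisibly; errors on infeasible settings.
#' @export
validate_cohort_config <- function(config) {
  if (config$n_cases > config$n_total || config$n_cases < 1 ||
      config$n_total < 2) {
    .stop_invalid("configuration error: need 1 <= n_cases < n_total")
  }
  probs <- unlist(config$prevalence)
  if (any(probs < 0 | probs > 1)) {
    .stop_invalid("configuration error: prevalences must lie in [0, 1]")
  }
  for (g in c("case", "control")) {
    st <- config$score_targets[[g]]
    if (any(st[, "min"] > st[, "median"] | st[, "median"] > st[, "max"])) {
      .stop_invalid("configuration error: %s score range excludes its median", g)
    }
    for (idx in c("la_ao", "duct_per_kg")) {
      et <- config$echo_targets[[g]][[idx]]
      if (any(et[, 2] > et[, 1] | et[, 1] > et[, 3])) {
        .stop_invalid("configuration error: %s echo %s range excludes its median", g, idx)
      }
    }
  }
  invisible(config)
}

# Hour-resolved severity dials (bin-occupancy probabilities for the
# dynamic items), calibrated once against the per-hour score targets.
.severity_defaults <- function() {
  list(
    # P(ventilated at hour | conventional-vent class)
    vent_occ = .default_hour_matrix(c(0.78, 0.78, 0.78, 0.82, 0.88, 0.80),
                                    c(0.25, 0.15, 0.10, 0.06, 0.03, 0.01)),
    # P(still on inotropes at hour | ever-hypotensive)
    hypo_occ = .default_hour_matrix(c(0.95, 0.95, 0.95, 0.95, 0.95, 0.90),
                                    c(1.00, 0.90, 0.80, 0.70, 0.55, 0.50)),
    # P(on HFOV at hour | HFOV class); otherwise conventional w.p. 0.7
    hfov_occ = .default_hour_matrix(c(0.50, 0.50, 0.50, 0.60, 0.72, 0.58),
                                    c(0.30, 0.20, 0.10, 0.05, 0.03, 0.03)),
    # P(heart rate elevated at hour | ever-tachycardic)
    tachy_occ = .default_hour_matrix(c(0.45, 0.40, 0.40, 0.55, 0.65, 0.45),
                                     c(0.35, 0.30, 0.25, 0.25, 0.20, 0.18)),
    tachy_severe = c(case = 0.25, control = 0.20),
    metab = list(
      case = rbind(`6` = c(0.45, 0.32, 0.15, 0.08), `12` = c(0.58, 0.26, 0.11, 0.05),
                   `18` = c(0.58, 0.26, 0.11, 0.05), `24` = c(0.42, 0.31, 0.18, 0.09),
                   `48` = c(0.30, 0.34, 0.23, 0.13), `72` = c(0.50, 0.29, 0.14, 0.07)),
      control = rbind(`6` = c(0.90, 0.08, 0.02, 0), `12` = c(0.90, 0.08, 0.02, 0),
                      `18` = c(0.90, 0.08, 0.02, 0), `24` = c(0.90, 0.08, 0.02, 0),
                      `48` = c(0.92, 0.06, 0.02, 0), `72` = c(0.92, 0.07, 0.01, 0))),
    resp = list(
      case = rbind(`6` = c(0.30, 0.35, 0.25, 0.10), `12` = c(0.48, 0.32, 0.15, 0.05),
                   `18` = c(0.48, 0.32, 0.15, 0.05), `24` = c(0.32, 0.35, 0.24, 0.09),
                   `48` = c(0.22, 0.35, 0.29, 0.14), `72` = c(0.40, 0.34, 0.19, 0.07)),
      control = rbind(`6` = c(0.85, 0.12, 0.03, 0), `12` = c(0.88, 0.10, 0.02, 0),
                      `18` = c(0.90, 0.08, 0.02, 0), `24` = c(0.92, 0.07, 0.01, 0),
                      `48` = c(0.94, 0.05, 0.01, 0), `72` = c(0.90, 0.08, 0.02, 0))),
    pip_start = list(case = c(20.5, 2, 15, 27), control = c(18.5, 2, 14, 24)),
    pip_drift = c(case = 0.15, control = -1.5),
    fio2_drift = c(case = 0.8, control = NA),        # cases: slow creep upward
    fio2_wean = c(lo = 0.08, hi = 0.15)  # controls: fractional FiO2 cut per 6 h review
  )
}

.draw_level <- function(probs) sample.int(length(probs), 1, prob = probs) - 1L

.ph_from_level <- function(lv) switch(lv + 1L,
  stats::runif(1, 7.36, 7.44), stats::runif(1, 7.25, 7.35),
  stats::runif(1, 7.10, 7.249), stats::runif(1, 6.95, 7.09))

.bd_from_level <- function(lv) switch(lv + 1L,
  stats::runif(1, 0.5, 3.9), stats::runif(1, 4, 10),
  stats::runif(1, 10.1, 16), stats::runif(1, 16.1, 22))

.pco2_from_level <- function(lv) switch(lv + 1L,
  stats::runif(1, 32, 45), stats::runif(1, 45.1, 55),
  stats::runif(1, 55.1, 65), stats::runif(1, 65.1, 80))

.fio2_adm_from_level <- function(lv, group) switch(lv + 1L,
  # controls are admitted on modest supplemental oxygen that is then weaned
  if (group == "case") stats::runif(1, 21, 39) else stats::runif(1, 33, 39.5),
  stats::runif(1, 40, 60), stats::runif(1, 61, 95))

# Draw one candidate infant (record + 6-hour observation trajectory).
.draw_candidate <- function(id, group, cfg, sev) {
  pv <- cfg$prevalence
  dm <- cfg$demographics
  g <- group

  ga <- .rtruncnorm(1, dm$gest_age[[g]][1], dm$gest_age[[g]][2],
                    dm$gest_age[[g]][3], dm$gest_age[[g]][4])
  bw <- .rtruncnorm(1, dm$birth_weight[[g]][1], dm$birth_weight[[g]][2],
                    dm$birth_weight[[g]][3], dm$birth_weight[[g]][4])
  cord <- if (stats::runif(1) < pv$cord_gas_high[[g]]) {
    if (g == "case") stats::runif(1, 12, 18) else stats::runif(1, 12, 15.5)
  } else stats::runif(1, 1, 11.5)
  fio2_adm <- .fio2_adm_from_level(.draw_level(pv$fio2_admission[[g]]), g)

  record <- data.frame(
    infant_id = id,
    gestational_age_weeks = round(ga, 1),
    birth_weight_g = round(bw),
    chorioamnionitis = as.integer(stats::runif(1) < pv$chorioamnionitis[[g]]),
    antenatal_steroid_complete = as.integer(stats::runif(1) >= pv$steroid_missing[[g]]),
    cord_base_deficit_mmol_l = round(cord, 1),
    fio2_admission_pct = round(fio2_adm, 1),
    stringsAsFactors = FALSE)

  vent_class <- sample(names(pv$vent_class[[g]]), 1, prob = pv$vent_class[[g]])
  hypo_ever <- stats::runif(1) < pv$hypotension[[g]]
  tachy_ever <- stats::runif(1) < pv$tachycardia[[g]]
  surf_total <- .draw_level(pv$surfactant[[g]])

  n_h <- length(.hours)
  vent <- character(n_h); pip <- rep(NA_real_, n_h)
  fio2 <- numeric(n_h); hr <- numeric(n_h); hypo <- integer(n_h)
  ph <- numeric(n_h); bd <- numeric(n_h); pco2 <- numeric(n_h)

  pip_prev <- NA_real_
  for (k in seq_len(n_h)) {
    h <- as.character(.hours[k])
    vent[k] <- if (vent_class == "none") "none"
      else if (vent_class == "conventional") {
        if (stats::runif(1) < sev$vent_occ[g, h]) "conventional" else "none"
      } else {
        u <- stats::runif(1)
        if (u < sev$hfov_occ[g, h]) "hfov"
        else if (u < sev$hfov_occ[g, h] + 0.7 * (1 - sev$hfov_occ[g, h])) "conventional"
        else "none"
      }
    if (vent[k] != "none") {
      if (is.na(pip_prev)) {
        ps <- sev$pip_start[[g]]
        pip[k] <- .rtruncnorm(1, ps[1], ps[2], ps[3], ps[4])
      } else {
        pip[k] <- min(30, max(12, pip_prev + sev$pip_drift[[g]] + stats::rnorm(1, 0, 1.2)))
      }
      pip_prev <- pip[k]
    } else pip_prev <- NA_real_

    if (g == "case") {
      base <- if (k == 1) record$fio2_admission_pct * (1 + stats::rnorm(1, 0, 0.12)) else
        fio2[k - 1] + sev$fio2_drift[["case"]] + stats::rnorm(1, 0, 2)
      fio2[k] <- min(100, max(21, base))
    } else {
      # stepwise weaning: fractional FiO2 reduction per 6 h review
      prev_f <- if (k == 1) record$fio2_admission_pct else fio2[k - 1]
      gap <- if (k == 1) 6 else .hours[k] - .hours[k - 1]
      w <- stats::runif(1, sev$fio2_wean["lo"], sev$fio2_wean["hi"])
      fio2[k] <- max(21, prev_f * (1 - w)^(gap / 6) + stats::rnorm(1, 0, 0.4))
    }

    hypo[k] <- as.integer(hypo_ever && stats::runif(1) < sev$hypo_occ[g, h])

    hr[k] <- if (tachy_ever && stats::runif(1) < sev$tachy_occ[g, h]) {
      if (stats::runif(1) < sev$tachy_severe[[g]]) stats::runif(1, 181, 205)
      else stats::runif(1, 160, 180)
    } else stats::runif(1, 125, 158)

    mlev <- .draw_level(sev$metab[[g]][h, ])
    ph[k] <- .ph_from_level(mlev)
    bd_lev <- if (mlev > 0 && stats::runif(1) < 0.45) mlev - 1L else mlev
    bd[k] <- .bd_from_level(bd_lev)
    pco2[k] <- .pco2_from_level(.draw_level(sev$resp[[g]][h, ]))
  }

  surf_cum <- if (surf_total == 0) rep(0L, n_h)
    else if (surf_total == 1) rep(1L, n_h)
    else c(1L, rep(2L, n_h - 1))

  obs <- data.frame(
    infant_id = id, hour = .hours,
    heart_rate_bpm = round(hr),
    hypotension_inotropes = hypo,
    vent_mode = vent,
    pip_cmh2o = round(pip, 1),
    fio2_pct = round(fio2, 1),
    ph = round(ph, 2),
    base_deficit_mmol_l = round(bd, 1),
    pco2_mmhg = round(pco2, 1),
    surfactant_doses_cum = surf_cum,
    stringsAsFactors = FALSE)
  list(record = record, obs = obs)
}

#' Build the rejection-sampling envelope for item-level generation
#'
#' Turns the configured score targets and prevalences into per-item
#' sampling parameters, runs an analytic feasibility pre-check (the
#' minimum attainable total given items forced by probability-one
#' prevalences must not exceed the target maximum), and probes the
#' envelope empirically to estimate the per-group acceptance rate.
#'
#' @param config A [cohort_config()] object.
#' @param n_probe Number of probe draws per group for the acceptance-rate
#'   estimate.
#' @return List with `severity` (the per-item sampling parameters) and
#'   `acceptance_rate` (named per-group estimate). Errors with an
#'   infeasibility diagnosis when the pre-check fails or the probed
#'   acceptance rate falls below the configured floor.
#' @export
calibrate_items <- function(config, n_probe = 60L) {
  validate_cohort_config(config)
  sev <- .severity_defaults()
  pv <- config$prevalence

  for (g in c("case", "control")) {
    # minimum attainable total: items forced by prevalence-one settings
    # plus the smallest attainable birth-weight score for the group
    bw_hi <- config$demographics$birth_weight[[g]][4]
    hfov_forced <- isTRUE(pv$vent_class[[g]][["hfov"]] >= 1)
    forced <- score_birth_weight(bw_hi) +
      (pv$chorioamnionitis[[g]] >= 1) + (pv$steroid_missing[[g]] >= 1) +
      (pv$hypotension[[g]] >= 1) + (if (hfov_forced) 3L else 0L)
    if (forced > max(config$score_targets[[g]][, "max"])) {
      .stop_invalid(paste0("infeasible targets for %s group: forced items alone ",
                           "give %d points, above the configured maximum %d"),
                    g, forced, max(config$score_targets[[g]][, "max"]))
    }
  }

  rate <- c(case = NA_real_, control = NA_real_)
  if (n_probe > 0) for (g in c("case", "control")) {
    acc <- 0L
    rng <- config$score_targets[[g]]
    for (i in seq_len(n_probe)) {
      set.seed(.substream_seed(config$seed + 7L, i + ifelse(g == "case", 0L, n_probe)))
      cand <- .draw_candidate("probe", g, config, sev)
      sc <- score_trajectory(cand$record, cand$obs)
      ok <- all(sc$total >= rng[as.character(sc$hour), "min"] &
                  sc$total <= rng[as.character(sc$hour), "max"])
      acc <- acc + ok
    }
    rate[g] <- acc / n_probe
    if (rate[g] < config$acceptance_floor) {
      .stop_invalid(paste0("infeasible targets for %s group: envelope acceptance ",
                           "rate %.4f below floor %.4f"), g, rate[g], config$acceptance_floor)
    }
  }
  list(severity = sev, acceptance_rate = rate)
}

#' Generate echo assessments calibrated to the study's echo indices
#'
#' Group-conditional truncated-normal draws of the LA/Ao ratio and the
#' weight-indexed duct diameter, truncated to the printed per-day ranges.
#' Cases are forced to satisfy the hsPDA criterion at at least one hour
#' (redrawn, then forced at 24 h as a last resort); controls are left as
#' drawn, so they may exceed 1.5 on day 1 but carry no symptomatic flag.
#'
#' @param config A [cohort_config()] object.
#' @param labels Data frame with `infant_id`, `group` (`"case"`/
#'   `"control"`) and `birth_weight_g`.
#' @return Data frame: `infant_id`, `hour`, `la_ao`, `duct_diameter_mm`,
#'   `weight_kg`.
#' @export
generate_echo <- function(config, labels) {
  et <- config$echo_targets
  rows <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    g <- labels$group[i]
    set.seed(.substream_seed(config$seed + 13L, i))
    wt <- labels$birth_weight_g[i] / 1000 * (1 - 0.01 * (1:3))  # mild postnatal loss
    la <- duct <- numeric(3)
    for (d in 1:3) {
      t_la <- et[[g]]$la_ao[d, ]; t_du <- et[[g]]$duct_per_kg[d, ]
      la[d] <- .rtruncnorm(1, t_la[1], (t_la[3] - t_la[2]) / 4, t_la[2], t_la[3])
      duct[d] <- .rtruncnorm(1, t_du[1], (t_du[3] - t_du[2]) / 4, t_du[2], t_du[3]) * wt[d]
    }
    if (g == "case") {
      for (try in 1:20) {
        if (any(classify_hspda(la, duct, wt))) break
        for (d in 1:3) {
          t_la <- et[[g]]$la_ao[d, ]
          la[d] <- .rtruncnorm(1, t_la[1], (t_la[3] - t_la[2]) / 4, t_la[2], t_la[3])
        }
      }
      if (!any(classify_hspda(la, duct, wt))) {
        la[1] <- stats::runif(1, 1.55, et[[g]]$la_ao[1, 3])  # force the deciding hour
      }
    }
    rows[[i]] <- data.frame(infant_id = labels$infant_id[i], hour = echo_schedule(),
                            la_ao = round(la, 2), duct_diameter_mm = round(duct, 2),
                            weight_kg = round(wt, 3), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Generate a complete synthetic cohort
#'
#' Draws infant records, observation trajectories and echo assessments
#' for `n_total` infants (`n_cases` of them symptomatic hsPDA cases),
#' deterministic in the configured seed. Per-infant rejection sampling
#' guarantees that every accepted infant's recomputed per-hour totals lie
#' inside the configured per-group ranges, and every case satisfies the
#' echo criterion at at least one hour.
#'
#' @param config A [cohort_config()] object (default configuration if
#'   omitted).
#' @return List of class `synthetic_cohort`: `infants`, `observations`,
#'   `echo`, `labels` (with `group`, `symptomatic`, echo label and
#'   deciding hour), `outcomes` (demonstration mortality/IVH flags),
#'   `acceptance_rate`, and the `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  cal <- calibrate_items(config, n_probe = 0L)
  sev <- cal$severity

  n <- config$n_total
  ids <- sprintf("inf%03d", seq_len(n))
  set.seed(.substream_seed(config$seed, 0L))
  case_idx <- sort(sample.int(n, config$n_cases))
  group <- ifelse(seq_len(n) %in% case_idx, "case", "control")

  infants <- vector("list", n); observations <- vector("list", n)
  attempts_total <- 0L
  for (i in seq_len(n)) {
    rng <- config$score_targets[[group[i]]]
    accepted <- NULL
    for (a in seq_len(config$max_attempts)) {
      set.seed(.substream_seed(config$seed, i * 1000L + a))
      cand <- .draw_candidate(ids[i], group[i], config, sev)
      sc <- score_trajectory(cand$record, cand$obs)
      attempts_total <- attempts_total + 1L
      if (all(sc$total >= rng[as.character(sc$hour), "min"] &
                sc$total <= rng[as.character(sc$hour), "max"])) {
        accepted <- cand
        break
      }
    }
    if (is.null(accepted)) {
      .stop_invalid("rejection sampling failed for infant %s (%s) after %d attempts",
                    ids[i], group[i], config$max_attempts)
    }
    infants[[i]] <- accepted$record
    observations[[i]] <- accepted$obs
  }
  infants <- do.call(rbind, infants)
  observations <- do.call(rbind, observations)
  acceptance_rate <- n / attempts_total

  labels <- data.frame(infant_id = ids, group = group,
                       symptomatic = group == "case",
                       birth_weight_g = infants$birth_weight_g,
                       stringsAsFactors = FALSE)
  echo <- generate_echo(config, labels)
  lab <- label_cohort(echo, stats::setNames(labels$symptomatic, labels$infant_id))
  labels <- merge(labels, lab$infants, by = "infant_id", sort = FALSE)
  labels$birth_weight_g <- NULL

  set.seed(.substream_seed(config$seed, 999999L))
  outcomes <- data.frame(
    infant_id = ids,
    mortality = as.integer(stats::runif(n) < config$outcome_rates$mortality[group]),
    ivh_grade3 = as.integer(stats::runif(n) < config$outcome_rates$ivh_grade3[group]),
    stringsAsFactors = FALSE)

  structure(list(infants = infants, observations = observations,
                 echo = lab$assessments, labels = labels, outcomes = outcomes,
                 acceptance_rate = acceptance_rate, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ELBW cohort: %d infants (%d cases, %d controls), seed %d\n",
              nrow(x$infants), sum(x$labels$group == "case"),
              sum(x$labels$group == "control"), x$config$seed))
  cat(sprintf("  rejection-sampling acceptance rate: %.2f\n", x$acceptance_rate))
  invisible(x)
}
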