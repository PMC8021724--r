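# SIMPLE scoring engine: 14 items, each 0-3 points, summed to a 0-29 total.
#
# Bin-boundary convention used throughout: a value landing on a shared bin
# endpoint is assigned to the lower-severity bin (equivalently, the bin in
# which the endpoint is printed as the start/end of a closed range). All
# base-deficit inputs are magnitudes of the deficit (non-negative); a base
# excess of -14 mmol/L is entered as deficit 14.

#' Names of the 14 SIMPLE items, in canonical order
#'
#' @return Character vector of the 14 item names, in the fixed column order
#'   used by [compute_simple()] and `scores.csv`.
#' @export
simple_items <- function() {
  c("chorioamnionitis", "antenatal_steroid", "birth_weight", "cord_gas",
    "hypotension", "tachycardia", "invasive_mv", "metabolic_acidosis",
    "respiratory_acidosis", "max_pip", "pip_reduction", "fio2_admission",
    "fio2_reduction", "surfactant")
}

#' Per-item maximum attainable points
#'
#' @return Named integer vector of per-item maxima; the sum is the maximum
#'   attainable SIMPLE total (29).
#' @export
simple_item_maxima <- function() {
  stats::setNames(
    c(1L, 1L, 3L, 2L, 1L, 2L, 3L, 3L, 3L, 2L, 2L, 2L, 2L, 2L),
    simple_items()
  )
}

#' Scheduled assessment hours
#'
#' @return Integer vector of the postnatal assessment hours.
#' @export
simple_schedule <- function() c(6L, 12L, 18L, 24L, 48L, 72L)

#' Echo assessment hours
#'
#' @return Integer vector of the echocardiography hours.
#' @export
echo_schedule <- function() c(24L, 48L, 72L)

.stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Score birth weight
#'
#' Bins: > 1250 g scores 0; 1000-1250 g scores 1; 750-1000 g scores 2;
#' < 750 g scores 3. Shared endpoints (750, 1000, 1250) take the
#' lower-severity bin.
#'
#' @param bw Birth weight in grams (vectorised).
#' @return Integer points 0-3.
#' @export
score_birth_weight <- function(bw) {
  if (any(!is.finite(bw) | bw <= 0)) .stop_invalid("birth weight must be positive")
  ifelse(bw > 1250, 0L, ifelse(bw >= 1000, 1L, ifelse(bw >= 750, 2L, 3L)))
}

#' Score cord blood gas base deficit
#'
#' Deficit magnitude < 12 scores 0; 12-16 scores 1; > 16 scores 2.
#'
#' @param bd Cord base deficit magnitude, mmol/L (non-negative, vectorised).
#' @return Integer points 0-2.
#' @export
score_cord_gas <- function(bd) {
  if (any(!is.finite(bd) | bd < 0)) .stop_invalid("base deficit magnitude must be non-negative")
  ifelse(bd < 12, 0L, ifelse(bd <= 16, 1L, 2L))
}

.score_ph <- function(ph) {
  ifelse(ph > 7.35, 0L, ifelse(ph >= 7.25, 1L, ifelse(ph >= 7.10, 2L, 3L)))
}

.score_bd_ladder <- function(bd) {
  ifelse(bd < 4, 0L, ifelse(bd <= 10, 1L, ifelse(bd <= 16, 2L, 3L)))
}

#' Score metabolic acidosis from pH and base deficit
#'
#' Each input is binned on its own ladder (pH: > 7.35 / 7.25-7.35 /
#' 7.10-7.25 / < 7.10; deficit magnitude: < 4 / 4-10 / 10-16 / > 16) and
#' the item takes the higher of the two ladder scores.
#'
#' @param ph Arterial/capillary pH, must lie in (6.5, 8.0) (vectorised).
#' @param bd Base deficit magnitude at the assessment, mmol/L.
#' @return Integer points 0-3.
#' @export
score_metabolic_acidosis <- function(ph, bd) {
  if (any(!is.finite(ph) | ph <= 6.5 | ph >= 8.0)) .stop_invalid("pH out of physiologic range (6.5, 8.0)")
  if (any(!is.finite(bd) | bd < 0)) .stop_invalid("base deficit magnitude must be non-negative")
  pmax(.score_ph(ph), .score_bd_ladder(bd))
}

#' Score respiratory acidosis from PCO2
#'
#' PCO2 at or below 45 mmHg (including hypocapnia below 35) scores 0;
#' (45, 55] scores 1; (55, 65] scores 2; above 65 scores 3.
#'
#' @param pco2 Partial pressure of CO2, mmHg (vectorised).
#' @return Integer points 0-3.
#' @export
score_respiratory_acidosis <- function(pco2) {
  if (any(!is.finite(pco2) | pco2 <= 0)) .stop_invalid("PCO2 must be positive")
  ifelse(pco2 <= 45, 0L, ifelse(pco2 <= 55, 1L, ifelse(pco2 <= 65, 2L, 3L)))
}

#' Score need of invasive mechanical ventilation
#'
#' No ventilation scores 0, conventional invasive ventilation 1, HFOV 3.
#' A score of 2 is unattainable for this item.
#'
#' @param mode Character vector with values `"none"`, `"conventional"` or
#'   `"hfov"` (case-insensitive).
#' @return Integer points in \{0, 1, 3\}.
#' @export
score_ventilation <- function(mode) {
  m <- tolower(as.character(mode))
  bad <- !m %in% c("none", "conventional", "hfov")
  if (any(bad)) .stop_invalid("unknown ventilation mode: %s", paste(unique(m[bad]), collapse = ", "))
  unname(c(none = 0L, conventional = 1L, hfov = 3L)[m])
}

#' Score tachycardia
#'
#' Heart rate < 160 bpm scores 0; 160-180 scores 1; > 180 scores 2.
#'
#' @param hr Heart rate, beats/min (vectorised).
#' @return Integer points 0-2.
#' @export
score_tachycardia <- function(hr) {
  if (any(!is.finite(hr) | hr <= 0)) .stop_invalid("heart rate must be positive")
  ifelse(hr < 160, 0L, ifelse(hr <= 180, 1L, 2L))
}

#' Score maximum peak inspiratory pressure
#'
#' PIP < 18 cmH2O scores 0; 18-23 scores 1; > 23 scores 2. `NA` (infant not
#' invasively ventilated) scores 0: the item is inapplicable and defaults
#' to least severity.
#'
#' @param pip Maximum PIP, cmH2O, or `NA` when not ventilated (vectorised).
#' @return Integer points 0-2.
#' @export
score_max_pip <- function(pip) {
  if (any(!is.na(pip) & (!is.finite(pip) | pip < 0))) .stop_invalid("PIP must be non-negative")
  ifelse(is.na(pip) | pip < 18, 0L, ifelse(pip <= 23, 1L, 2L))
}

#' Score a percent reduction relative to the prior assessment
#'
#' Used for both the PIP-reduction and FiO2-reduction items. The reduction
#' is `100 * (prior - current) / prior`; a reduction above 20% scores 0,
#' 10-20% scores 1 and below 10% (including any increase) scores 2.
#'
#' @param prior Value at the preceding assessment (positive).
#' @param current Value at the present assessment (positive).
#' @return Integer points 0-2.
#' @export
score_reduction <- function(prior, current) {
  if (any(!is.finite(prior) | prior <= 0)) .stop_invalid("prior value must be positive")
  if (any(!is.finite(current) | current <= 0)) .stop_invalid("current value must be positive")
  red <- 100 * (prior - current) / prior
  ifelse(red > 20, 0L, ifelse(red >= 10, 1L, 2L))
}

#' Score FiO2 at NICU admission
#'
#' FiO2 < 40% scores 0; 40-60% scores 1; > 60% scores 2.
#'
#' @param fio2 Fraction of inspired oxygen, percent, in \[21, 100\].
#' @return Integer points 0-2.
#' @export
score_fio2_admission <- function(fio2) {
  if (any(!is.finite(fio2) | fio2 < 21 | fio2 > 100)) .stop_invalid("FiO2 must lie in [21, 100] percent")
  ifelse(fio2 < 40, 0L, ifelse(fio2 <= 60, 1L, 2L))
}

#' Score cumulative surfactant doses
#'
#' No dose scores 0, a single dose 1, repeated dosing (2 or more) 2.
#'
#' @param doses Cumulative count of surfactant doses given up to the
#'   assessment hour (non-negative integer, vectorised).
#' @return Integer points 0-2.
#' @export
score_surfactant <- function(doses) {
  if (any(!is.finite(doses) | doses < 0 | doses != round(doses))) {
    .stop_invalid("surfactant doses must be a non-negative integer count")
  }
  ifelse(doses == 0, 0L, ifelse(doses == 1, 1L, 2L))
}

.as_row <- function(x) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1) .stop_invalid("expected a single row, got %d", nrow(x))
    as.list(x)
  } else {
    as.list(x)
  }
}

#' Compute the SIMPLE score breakdown for one infant at one hour
#'
#' Applies all 14 item scorers to a static perinatal record plus one
#' time-point observation and sums them. The two reduction items compare
#' against the chronologically preceding observation; at the 6 h assessment
#' the admission state is the baseline (admission FiO2 from the record; no
#' admission PIP exists, so the PIP-reduction item is inapplicable at 6 h
#' and scores 0 with a flag). Items that cannot apply score 0 with a flag:
#' the PIP items when the infant is not invasively ventilated, and the
#' FiO2-reduction item when the infant is on room air (21%) at the
#' assessment, where no further weaning is possible. Dynamic fields that
#' are `NA` score 0 and are flagged as missing.
#'
#' @param record One-row data frame (or list) with fields `infant_id`,
#'   `birth_weight_g`, `chorioamnionitis`, `antenatal_steroid_complete`,
#'   `cord_base_deficit_mmol_l`, `fio2_admission_pct`.
#' @param obs One-row data frame (or list) with fields `infant_id`, `hour`,
#'   `heart_rate_bpm`, `hypotension_inotropes`, `vent_mode`, `pip_cmh2o`,
#'   `fio2_pct`, `ph`, `base_deficit_mmol_l`, `pco2_mmhg`,
#'   `surfactant_doses_cum`.
#' @param prior The preceding observation in the same form, or `NULL` to use
#'   the admission baseline (for the 6 h assessment).
#' @return One-row data frame: `infant_id`, `hour`, the 14 item-point
#'   columns in [simple_items()] order, `total`, and `flags` (semicolon-
#'   separated data-quality notes, `""` if none).
#' @export
compute_simple <- function(record, obs, prior = NULL) {
  rec <- .as_row(record)
  ob <- .as_row(obs)
  if (!identical(as.character(rec$infant_id), as.character(ob$infant_id))) {
    .stop_invalid("record and observation belong to different infants (%s vs %s)",
                  rec$infant_id, ob$infant_id)
  }
  if (!ob$hour %in% simple_schedule()) {
    .stop_invalid("hour %s is not in the assessment schedule (6,12,18,24,48,72)", ob$hour)
  }
  flags <- character(0)

  pts <- stats::setNames(integer(14), simple_items())
  pts["chorioamnionitis"] <- as.integer(isTRUE(as.logical(rec$chorioamnionitis)))
  pts["antenatal_steroid"] <- as.integer(!isTRUE(as.logical(rec$antenatal_steroid_complete)))
  pts["birth_weight"] <- score_birth_weight(rec$birth_weight_g)
  pts["cord_gas"] <- score_cord_gas(rec$cord_base_deficit_mmol_l)
  pts["fio2_admission"] <- score_fio2_admission(rec$fio2_admission_pct)

  dyn <- function(name, value, scorer) {
    if (is.null(value) || (length(value) == 1 && is.na(value))) {
      flags <<- c(flags, paste0(name, ":missing"))
      0L
    } else {
      scorer(value)
    }
  }
  pts["hypotension"] <- dyn("hypotension", ob$hypotension_inotropes,
                            function(v) as.integer(isTRUE(as.logical(v))))
  pts["tachycardia"] <- dyn("tachycardia", ob$heart_rate_bpm, score_tachycardia)
  pts["metabolic_acidosis"] <- if (is.na(ob$ph) || is.na(ob$base_deficit_mmol_l)) {
    flags <- c(flags, "metabolic_acidosis:missing")
    0L
  } else {
    score_metabolic_acidosis(ob$ph, ob$base_deficit_mmol_l)
  }
  pts["respiratory_acidosis"] <- dyn("respiratory_acidosis", ob$pco2_mmhg,
                                     score_respiratory_acidosis)
  pts["surfactant"] <- dyn("surfactant", ob$surfactant_doses_cum, score_surfactant)

  mode <- ob$vent_mode
  if (is.null(mode) || is.na(mode)) {
    flags <- c(flags, "invasive_mv:missing")
    mode <- "none"
  }
  pts["invasive_mv"] <- score_ventilation(mode)
  ventilated <- tolower(as.character(mode)) != "none"
  if (ventilated) {
    pts["max_pip"] <- score_max_pip(ob$pip_cmh2o)
    if (is.na(ob$pip_cmh2o)) flags <- c(flags, "max_pip:missing")
  } else {
    pts["max_pip"] <- 0L
    flags <- c(flags, "max_pip:inapplicable")
  }

  prior_row <- if (is.null(prior)) NULL else .as_row(prior)
  prior_fio2 <- if (is.null(prior_row)) rec$fio2_admission_pct else prior_row$fio2_pct
  prior_pip <- if (is.null(prior_row)) NA_real_ else prior_row$pip_cmh2o
  if (is.null(prior_row)) flags <- c(flags, "reductions:baseline=admission")

  if (is.na(ob$fio2_pct) || is.na(prior_fio2)) {
    flags <- c(flags, "fio2_reduction:missing")
    pts["fio2_reduction"] <- 0L
  } else if (ob$fio2_pct <= 21) {
    # on room air: no further weaning is possible, so failure-to-reduce
    # cannot be scored as severity; least-severity default, flagged
    pts["fio2_reduction"] <- 0L
    flags <- c(flags, "fio2_reduction:room-air")
  } else {
    pts["fio2_reduction"] <- score_reduction(prior_fio2, ob$fio2_pct)
  }
  if (ventilated && !is.na(ob$pip_cmh2o) && !is.na(prior_pip)) {
    pts["pip_reduction"] <- score_reduction(prior_pip, ob$pip_cmh2o)
  } else {
    pts["pip_reduction"] <- 0L
    flags <- c(flags, "pip_reduction:inapplicable")
  }

  out <- data.frame(infant_id = as.character(rec$infant_id),
                    hour = as.integer(ob$hour),
                    stringsAsFactors = FALSE)
  for (nm in simple_items()) out[[nm]] <- as.integer(pts[[nm]])
  out$total <- as.integer(sum(pts))
  out$flags <- paste(flags, collapse = ";")
  out
}

#' Score an infant's full assessment trajectory
#'
#' Scores each scheduled observation in chronological order. The reduction
#' items at each hour compare against the preceding observation; the first
#' observation uses the admission baseline. Dynamic values that are missing
#' at an hour are carried forward from the most recent earlier observation
#' (and flagged); values never observed score 0 with a missing flag.
#'
#' @param record One-row infant record (see [compute_simple()]).
#' @param observations Data frame of that infant's observations, one row
#'   per scheduled hour.
#' @return Data frame with one [compute_simple()] row per hour, ordered by
#'   hour.
#' @export
score_trajectory <- function(record, observations) {
  rec <- .as_row(record)
  obs <- observations[observations$infant_id == rec$infant_id, , drop = FALSE]
  if (nrow(obs) != nrow(observations)) {
    .stop_invalid("observations contain infant ids other than %s", rec$infant_id)
  }
  if (nrow(obs) == 0) .stop_invalid("no observations for infant %s", rec$infant_id)
  if (anyDuplicated(obs$hour)) .stop_invalid("duplicate assessment hours for infant %s", rec$infant_id)
  if (!all(obs$hour %in% simple_schedule())) {
    .stop_invalid("hours outside the 6-72 h schedule for infant %s", rec$infant_id)
  }
  obs <- obs[order(obs$hour), , drop = FALSE]
  if (is.unsorted(obs$surfactant_doses_cum, na.rm = TRUE)) {
    .stop_invalid("cumulative surfactant doses decrease over time for infant %s", rec$infant_id)
  }

  # carry forward missing dynamic values within the schedule
  carry_cols <- c("heart_rate_bpm", "hypotension_inotropes", "vent_mode",
                  "pip_cmh2o", "fio2_pct", "ph", "base_deficit_mmol_l",
                  "pco2_mmhg", "surfactant_doses_cum")
  carried <- matrix(FALSE, nrow(obs), length(carry_cols),
                    dimnames = list(NULL, carry_cols))
  for (cc in carry_cols) {
    v <- obs[[cc]]
    for (i in seq_along(v)[-1]) {
      # pip may be legitimately NA when not ventilated; only carry within
      # ventilated stretches
      if (is.na(v[i]) && !is.na(v[i - 1]) &&
          (cc != "pip_cmh2o" || !is.na(obs$vent_mode[i]) &&
             tolower(obs$vent_mode[i]) != "none")) {
        v[i] <- v[i - 1]
        carried[i, cc] <- TRUE
      }
    }
    obs[[cc]] <- v
  }

  rows <- vector("list", nrow(obs))
  for (i in seq_len(nrow(obs))) {
    prior <- if (i == 1) NULL else obs[i - 1, , drop = FALSE]
    row <- compute_simple(rec, obs[i, , drop = FALSE], prior)
    cf <- carry_cols[carried[i, ]]
    if (length(cf)) {
      extra <- paste0(cf, ":carried-forward", collapse = ";")
      row$flags <- if (nzchar(row$flags)) paste(row$flags, extra, sep = ";") else extra
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Score every infant in a cohort
#'
#' @param infants Infant-record data frame, one row per infant.
#' @param observations Long-format observation data frame for all infants.
#' @return Data frame of per-infant per-hour score breakdowns
#'   (the `scores.csv` layout).
#' @export
score_cohort <- function(infants, observations) {
  missing_obs <- setdiff(infants$infant_id, observations$infant_id)
  if (length(missing_obs)) {
    .stop_invalid("no observations for infant(s): %s", paste(missing_obs, collapse = ", "))
  }
  res <- lapply(seq_len(nrow(infants)), function(i) {
    id <- infants$infant_id[i]
    score_trajectory(infants[i, , drop = FALSE],
                     observations[observations$infant_id == id, , drop = FALSE])
  })
  do.call(rbind, res)
}
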