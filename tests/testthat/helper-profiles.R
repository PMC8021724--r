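# Builders for infant records and observations used across tests.

benign_record <- function(id = "a") {
  data.frame(infant_id = id, gestational_age_weeks = 27, birth_weight_g = 1300,
             chorioamnionitis = 0, antenatal_steroid_complete = 1,
             cord_base_deficit_mmol_l = 2, fio2_admission_pct = 25,
             stringsAsFactors = FALSE)
}

worst_record <- function(id = "a") {
  data.frame(infant_id = id, gestational_age_weeks = 24, birth_weight_g = 600,
             chorioamnionitis = 1, antenatal_steroid_complete = 0,
             cord_base_deficit_mmol_l = 20, fio2_admission_pct = 80,
             stringsAsFactors = FALSE)
}

make_obs <- function(id = "a", hour = 6, hr = 150, hypo = 0, vent = "none",
                     pip = NA, fio2 = 22, ph = 7.40, bd = 2, pco2 = 40, surf = 0) {
  data.frame(infant_id = id, hour = hour, heart_rate_bpm = hr,
             hypotension_inotropes = hypo, vent_mode = vent, pip_cmh2o = pip,
             fio2_pct = fio2, ph = ph, base_deficit_mmol_l = bd,
             pco2_mmhg = pco2, surfactant_doses_cum = surf,
             stringsAsFactors = FALSE)
}

# a deliberately mixed mid-severity profile
mid_record <- function(id = "m") {
  data.frame(infant_id = id, gestational_age_weeks = 25, birth_weight_g = 880,
             chorioamnionitis = 1, antenatal_steroid_complete = 1,
             cord_base_deficit_mmol_l = 13, fio2_admission_pct = 45,
             stringsAsFactors = FALSE)
}

# random raw inputs for property tests (always valid)
random_profile <- function() {
  list(bw = runif(1, 400, 1400),
       cord = runif(1, 0, 20),
       hr = runif(1, 120, 200),
       vent = sample(c("none", "conventional", "hfov"), 1),
       pip = runif(1, 14, 28),
       ph = runif(1, 7.0, 7.45),
       bd = runif(1, 0, 20),
       pco2 = runif(1, 30, 75),
       fio2_adm = runif(1, 21, 95),
       prior = runif(1, 20, 60),
       current = runif(1, 20, 60),
       surf = sample(0:3, 1))
}

# independent hand ledger: sum the 14 standalone item scorers
hand_total <- function(rec, obs, prior_fio2, prior_pip = NA) {
  ventilated <- obs$vent_mode != "none"
  sum(as.integer(rec$chorioamnionitis == 1),
      as.integer(rec$antenatal_steroid_complete == 0),
      score_birth_weight(rec$birth_weight_g),
      score_cord_gas(rec$cord_base_deficit_mmol_l),
      as.integer(obs$hypotension_inotropes == 1),
      score_tachycardia(obs$heart_rate_bpm),
      score_ventilation(obs$vent_mode),
      score_metabolic_acidosis(obs$ph, obs$base_deficit_mmol_l),
      score_respiratory_acidosis(obs$pco2_mmhg),
      if (ventilated) score_max_pip(obs$pip_cmh2o) else 0L,
      if (ventilated && !is.na(prior_pip)) score_reduction(prior_pip, obs$pip_cmh2o) else 0L,
      score_fio2_admission(rec$fio2_admission_pct),
      if (obs$fio2_pct <= 21) 0L else score_reduction(prior_fio2, obs$fio2_pct),
      score_surfactant(obs$surfactant_doses_cum))
}
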