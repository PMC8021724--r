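test_that("item scorers reproduce the rubric bins, boundaries to the lower-severity bin", {
  cases <- list(
    list(score_birth_weight, list(720), 3),
    list(score_birth_weight, list(750), 2),
    list(score_birth_weight, list(1000), 1),
    list(score_birth_weight, list(1250), 1),
    list(score_birth_weight, list(1300), 0),
    list(score_cord_gas, list(5), 0),
    list(score_cord_gas, list(12), 1),
    list(score_cord_gas, list(14), 1),
    list(score_cord_gas, list(16), 1),
    list(score_cord_gas, list(20), 2),
    list(score_respiratory_acidosis, list(30), 0),
    list(score_respiratory_acidosis, list(40), 0),
    list(score_respiratory_acidosis, list(45), 0),
    list(score_respiratory_acidosis, list(55), 1),
    list(score_respiratory_acidosis, list(65), 2),
    list(score_respiratory_acidosis, list(70), 3),
    list(score_tachycardia, list(150), 0),
    list(score_tachycardia, list(160), 1),
    list(score_tachycardia, list(170), 1),
    list(score_tachycardia, list(180), 1),
    list(score_tachycardia, list(190), 2),
    list(score_max_pip, list(17), 0),
    list(score_max_pip, list(18), 1),
    list(score_max_pip, list(22), 1),
    list(score_max_pip, list(23), 1),
    list(score_max_pip, list(25), 2),
    list(score_max_pip, list(NA), 0),
    list(score_fio2_admission, list(30), 0),
    list(score_fio2_admission, list(40), 1),
    list(score_fio2_admission, list(50), 1),
    list(score_fio2_admission, list(60), 1),
    list(score_fio2_admission, list(80), 2),
    list(score_surfactant, list(0), 0),
    list(score_surfactant, list(1), 1),
    list(score_surfactant, list(3), 2)
  )
  for (cs in cases) {
    expect_equal(do.call(cs[[1]], cs[[2]]), cs[[3]],
                 info = paste(deparse(cs[[2]]), "->", cs[[3]]))
  }
})

test_that("ventilation item scores {0, 1, 3} with no attainable 2", {
  expect_equal(score_ventilation("none"), 0L)
  expect_equal(score_ventilation("conventional"), 1L)
  expect_equal(score_ventilation("hfov"), 3L)
  expect_false(2L %in% score_ventilation(c("none", "conventional", "hfov")))
  expect_error(score_ventilation("cpap"), "unknown ventilation mode")
})

test_that("metabolic acidosis takes the worse of the pH and deficit ladders", {
  expect_equal(score_metabolic_acidosis(7.20, 8), 2L)   # pH 2 vs BD 1
  expect_equal(score_metabolic_acidosis(7.40, 2), 0L)
  expect_equal(score_metabolic_acidosis(7.30, 17), 3L)  # BD 3 dominates pH 1
  # boundaries land in the lower-severity bin on each ladder
  expect_equal(score_metabolic_acidosis(7.35, 0.5), 1L)
  expect_equal(score_metabolic_acidosis(7.25, 0.5), 1L)
  expect_equal(score_metabolic_acidosis(7.10, 0.5), 2L)
  expect_equal(score_metabolic_acidosis(7.40, 4), 1L)
  expect_equal(score_metabolic_acidosis(7.40, 10), 1L)
  expect_equal(score_metabolic_acidosis(7.40, 16), 2L)
})

test_that("reduction item bins the percent change with inclusive 10-20 band", {
  expect_equal(score_reduction(20, 15), 0L)  # 25% reduction
  expect_equal(score_reduction(20, 16), 1L)  # exactly 20%
  expect_equal(score_reduction(20, 18), 1L)  # exactly 10%
  expect_equal(score_reduction(20, 19), 2L)  # 5%
  expect_equal(score_reduction(20, 20), 2L)  # no change
  expect_equal(score_reduction(20, 22), 2L)  # increase
})

test_that("item scorers reject invalid input", {
  expect_error(score_birth_weight(0), "positive")
  expect_error(score_cord_gas(-1), "non-negative")
  expect_error(score_metabolic_acidosis(8.5, 2), "pH")
  expect_error(score_respiratory_acidosis(-5), "positive")
  expect_error(score_tachycardia(0), "positive")
  expect_error(score_max_pip(-2), "non-negative")
  expect_error(score_reduction(0, 10), "positive")
  expect_error(score_fio2_admission(150), "\\[21, 100\\]")
  expect_error(score_surfactant(1.5), "integer")
  expect_error(score_surfactant(-1), "integer")
})

test_that("all-best profile scores 0 and all-worst scores the 29-point maximum", {
  best <- compute_simple(benign_record(), make_obs(hour = 12, fio2 = 21),
                         prior = make_obs(hour = 6, fio2 = 30))
  expect_equal(best$total, 0L)

  worst_prior <- make_obs(hour = 24, hr = 190, hypo = 1, vent = "hfov",
                          pip = 24, fio2 = 70, ph = 7.05, bd = 20, pco2 = 70, surf = 2)
  worst_obs <- make_obs(hour = 48, hr = 190, hypo = 1, vent = "hfov",
                        pip = 26, fio2 = 80, ph = 7.05, bd = 20, pco2 = 70, surf = 2)
  worst <- compute_simple(worst_record(), worst_obs, prior = worst_prior)
  expect_equal(worst$total, 29L)
  expect_equal(sum(simple_item_maxima()), 29L)
})

test_that("per-item points never exceed the per-item maxima", {
  set.seed(42)
  maxima <- simple_item_maxima()
  for (i in 1:25) {
    p <- random_profile()
    rec <- benign_record()
    rec$birth_weight_g <- p$bw; rec$cord_base_deficit_mmol_l <- p$cord
    rec$fio2_admission_pct <- p$fio2_adm
    rec$chorioamnionitis <- rbinom(1, 1, 0.5)
    rec$antenatal_steroid_complete <- rbinom(1, 1, 0.5)
    obs <- make_obs(hour = 12, hr = p$hr, hypo = rbinom(1, 1, 0.5), vent = p$vent,
                    pip = if (p$vent == "none") NA else p$pip, fio2 = p$current,
                    ph = p$ph, bd = p$bd, pco2 = p$pco2, surf = p$surf)
    prior <- make_obs(hour = 6, vent = p$vent,
                      pip = if (p$vent == "none") NA else p$pip + runif(1, -4, 4),
                      fio2 = p$prior, surf = 0)
    br <- compute_simple(rec, obs, prior)
    pts <- unlist(br[simple_items()])
    expect_true(all(pts <= maxima) && all(pts >= 0))
    expect_true(br$total >= 0 && br$total <= 29)
  }
})

test_that("compute_simple total equals the hand-summed ledger of the 14 item scorers", {
  set.seed(7)
  for (i in 1:40) {
    p <- random_profile()
    rec <- mid_record()
    rec$birth_weight_g <- p$bw; rec$cord_base_deficit_mmol_l <- p$cord
    rec$fio2_admission_pct <- p$fio2_adm
    obs <- make_obs(id = "m", hour = 24, hr = p$hr, hypo = rbinom(1, 1, 0.5),
                    vent = p$vent, pip = if (p$vent == "none") NA else p$pip,
                    fio2 = p$current, ph = p$ph, bd = p$bd, pco2 = p$pco2, surf = p$surf)
    prior <- make_obs(id = "m", hour = 18, vent = p$vent,
                      pip = if (p$vent == "none") NA else max(12, p$pip - 2),
                      fio2 = p$prior)
    br <- compute_simple(rec, obs, prior)
    expect_equal(br$total,
                 hand_total(rec, obs, prior_fio2 = prior$fio2_pct,
                            prior_pip = prior$pip_cmh2o))
  }
})

test_that("worsening any single input never decreases the total", {
  set.seed(11)
  base_rec <- mid_record()
  base_obs <- make_obs(id = "m", hour = 24, hr = 155, vent = "conventional",
                       pip = 19, fio2 = 35, ph = 7.30, bd = 6, pco2 = 50, surf = 1)
  prior <- make_obs(id = "m", hour = 18, vent = "conventional", pip = 20, fio2 = 40)
  base <- compute_simple(base_rec, base_obs, prior)$total

  worsen <- list(
    function(r, o) { r$birth_weight_g <- 700; list(r, o) },
    function(r, o) { r$cord_base_deficit_mmol_l <- 17; list(r, o) },
    function(r, o) { r$chorioamnionitis <- 1; list(r, o) },
    function(r, o) { r$antenatal_steroid_complete <- 0; list(r, o) },
    function(r, o) { r$fio2_admission_pct <- 70; list(r, o) },
    function(r, o) { o$heart_rate_bpm <- 190; list(r, o) },
    function(r, o) { o$hypotension_inotropes <- 1; list(r, o) },
    function(r, o) { o$vent_mode <- "hfov"; list(r, o) },
    function(r, o) { o$pip_cmh2o <- 26; list(r, o) },
    function(r, o) { o$fio2_pct <- 45; list(r, o) },   # smaller reduction
    function(r, o) { o$ph <- 7.05; list(r, o) },
    function(r, o) { o$base_deficit_mmol_l <- 18; list(r, o) },
    function(r, o) { o$pco2_mmhg <- 70; list(r, o) },
    function(r, o) { o$surfactant_doses_cum <- 3; list(r, o) }
  )
  for (w in worsen) {
    mod <- w(base_rec, base_obs)
    expect_gte(compute_simple(mod[[1]], mod[[2]], prior)$total, base)
  }
})

test_that("identical inputs give identical breakdowns", {
  rec <- mid_record()
  obs <- make_obs(id = "m", hour = 48, vent = "conventional", pip = 20, fio2 = 40)
  prior <- make_obs(id = "m", hour = 24, vent = "conventional", pip = 21, fio2 = 42)
  expect_identical(compute_simple(rec, obs, prior), compute_simple(rec, obs, prior))
})

test_that("classification by score > 8.5 and score > 8 agree on attainable totals", {
  set.seed(3)
  totals <- integer(0)
  for (i in 1:60) {
    p <- random_profile()
    rec <- benign_record()
    rec$birth_weight_g <- p$bw; rec$cord_base_deficit_mmol_l <- p$cord
    rec$fio2_admission_pct <- p$fio2_adm
    rec$chorioamnionitis <- rbinom(1, 1, 0.5)
    obs <- make_obs(hour = 12, hr = p$hr, vent = p$vent,
                    pip = if (p$vent == "none") NA else p$pip, fio2 = p$current,
                    ph = p$ph, bd = p$bd, pco2 = p$pco2, surf = p$surf)
    prior <- make_obs(hour = 6, vent = p$vent,
                      pip = if (p$vent == "none") NA else p$pip, fio2 = p$prior)
    totals <- c(totals, compute_simple(rec, obs, prior)$total)
  }
  expect_true(all(totals == round(totals)))
  expect_identical(totals > 8.5, totals > 8)
})

test_that("compute_simple validates hours and infant identity", {
  expect_error(compute_simple(benign_record(), make_obs(hour = 10)), "schedule")
  expect_error(compute_simple(benign_record("a"), make_obs(id = "b")), "different infants")
})

test_that("missing dynamic values score 0 and are flagged", {
  obs <- make_obs(hour = 6, hr = NA, pco2 = NA)
  br <- compute_simple(benign_record(), obs)
  expect_equal(br$tachycardia, 0L)
  expect_equal(br$respiratory_acidosis, 0L)
  expect_match(br$flags, "tachycardia:missing")
  expect_match(br$flags, "respiratory_acidosis:missing")
})

test_that("trajectory scoring uses the admission baseline first, then the prior hour", {
  rec <- benign_record()
  rec$fio2_admission_pct <- 40
  obs <- rbind(make_obs(hour = 6, fio2 = 30),   # 25% reduction vs admission -> 0
               make_obs(hour = 12, fio2 = 27),  # 10% vs 6 h -> 1
               make_obs(hour = 18, fio2 = 27))  # 0% -> 2
  tr <- score_trajectory(rec, obs)
  expect_equal(tr$fio2_reduction, c(0L, 1L, 2L))
  expect_match(tr$flags[1], "baseline=admission")
  # PIP reduction has no admission baseline: inapplicable at 6 h
  expect_equal(tr$pip_reduction[1], 0L)
  expect_match(tr$flags[1], "pip_reduction:inapplicable")
})

test_that("constant settings score 2 on both reduction items at later hours", {
  rec <- benign_record()
  rec$fio2_admission_pct <- 40
  obs <- rbind(make_obs(hour = 6, vent = "conventional", pip = 20, fio2 = 40),
               make_obs(hour = 12, vent = "conventional", pip = 20, fio2 = 40),
               make_obs(hour = 24, vent = "conventional", pip = 20, fio2 = 40))
  tr <- score_trajectory(rec, obs)
  expect_equal(tr$fio2_reduction, c(2L, 2L, 2L))   # 0% vs admission too
  expect_equal(tr$pip_reduction[-1], c(2L, 2L))
})

test_that("trajectory totals match element-wise compute_simple calls", {
  set.seed(19)
  rec <- mid_record()
  hours <- simple_schedule()
  obs <- do.call(rbind, lapply(seq_along(hours), function(i) {
    make_obs(id = "m", hour = hours[i], hr = runif(1, 130, 195),
             vent = "conventional", pip = runif(1, 16, 26), fio2 = runif(1, 25, 60),
             ph = runif(1, 7.05, 7.44), bd = runif(1, 1, 18),
             pco2 = runif(1, 35, 75), surf = min(i, 2))
  }))
  tr <- score_trajectory(rec, obs)
  for (i in seq_along(hours)) {
    prior <- if (i == 1) NULL else obs[i - 1, ]
    expect_equal(tr$total[i], compute_simple(rec, obs[i, ], prior)$total)
  }
})

test_that("trajectory rejects duplicate hours and decreasing surfactant counts", {
  rec <- benign_record()
  expect_error(score_trajectory(rec, rbind(make_obs(hour = 6), make_obs(hour = 6))),
               "duplicate")
  expect_error(score_trajectory(rec, rbind(make_obs(hour = 6, surf = 2),
                                           make_obs(hour = 12, surf = 1))),
               "surfactant")
})

test_that("missing values are carried forward within a trajectory and flagged", {
  rec <- benign_record()
  obs <- rbind(make_obs(hour = 6, pco2 = 70),
               make_obs(hour = 12, pco2 = NA))
  tr <- score_trajectory(rec, obs)
  expect_equal(tr$respiratory_acidosis, c(3L, 3L))
  expect_match(tr$flags[2], "pco2_mmhg:carried-forward")
})
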