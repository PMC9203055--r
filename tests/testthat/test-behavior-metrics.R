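test_that("trial selection applies each inclusion rule", {
  # block at 59% control correct: whole block removed
  base <- lapply(1:100, function(i) {
    make_trial(trial_index = i, block_id = 1L,
               towers_right = c(30, 60), towers_left = c(40),
               choice = if (i <= 59) "R" else "L")
  })
  tr <- dplyr::bind_rows(base)
  out <- suppressWarnings(select_trials(tr))
  expect_equal(nrow(out), 0)
  expect_warning(select_trials(tr), "no trials")

  # 61% block survives
  tr2 <- tr
  tr2$choice <- c(rep("R", 61), rep("L", 39))
  expect_equal(nrow(select_trials(tr2)), 100)

  # distance and end-of-maze rules
  tr3 <- make_trials(
    make_trial(trial_index = 1),
    make_trial(trial_index = 2, traveled_distance = 370),   # > 1.1 * 330
    make_trial(trial_index = 3, traveled_distance = 362.9), # just under
    make_trial(trial_index = 4, reached_end = FALSE),
    make_trial(trial_index = 5, is_warmup = TRUE),
    make_trial(trial_index = 6, is_easy_block = TRUE),
    make_trial(trial_index = 7), make_trial(trial_index = 8),
    make_trial(trial_index = 9), make_trial(trial_index = 10)
  )
  out3 <- select_trials(tr3)
  expect_equal(nrow(out3), 6)
  counts <- attr(out3, "selection_counts")
  expect_equal(unname(counts["warmup_or_easy"]), 2)
  expect_equal(unname(counts["distance_or_end"]), 2)
})

test_that("percent_correct judges against realized tower counts", {
  tr <- make_trials(
    make_trial(towers_right = c(30, 60), towers_left = c(40), choice = "R"),
    make_trial(towers_right = c(30, 60), towers_left = c(40), choice = "R"),
    make_trial(towers_right = c(30), towers_left = c(40, 80), choice = "L",
               rewarded_side = "L"),
    make_trial(towers_right = c(30), towers_left = c(40, 80), choice = "R",
               rewarded_side = "L")
  )
  expect_equal(percent_correct(tr), 0.75)
  # invariant to trial order
  expect_equal(percent_correct(tr[sample(4), ]), 0.75)
  # relabeling left/right with choices relabeled leaves it unchanged
  fl <- tr
  fl$towers_right <- tr$towers_left; fl$towers_left <- tr$towers_right
  fl$choice <- ifelse(tr$choice == "R", "L", "R")
  fl$rewarded_side <- ifelse(tr$rewarded_side == "R", "L", "R")
  expect_equal(percent_correct(fl), percent_correct(tr))
  expect_error(percent_correct(tr[0, ]), "no trials")
})

test_that("performance delta has null symmetry and detects real effects", {
  # identical arms: delta ~ 0, p ~ 0.5
  tr <- dplyr::bind_rows(lapply(1:200, function(i) {
    make_trial(trial_index = i, laser_on = i %% 2 == 0,
               towers_right = c(30, 60), towers_left = c(40),
               choice = if ((i * 7) %% 10 < 8) "R" else "L")
  }))
  pd <- performance_delta(tr, n_boot = 2000, seed = 1)
  expect_equal(pd$delta, 0, tolerance = 1e-9)
  expect_gt(pd$p_value, 0.2); expect_lt(pd$p_value, 0.8)

  # generator with during-laser modulation 0: performance drops, p < 0.05
  cfg <- validation_config()
  coh <- suppressWarnings(generate_cohort(
    n_mice = 4, trials_per_mouse = 300, laser_frac = 0.35, epochs = "tile",
    config = cfg, n_warmup = 0, seed = 17,
    gcm = choice_model(base_weight = 1, lapse = 0,
                       laser_modulation = c(during = 0, pre1 = 0, pre2 = 0,
                                            pre3 = 0, post1 = 0, post2 = 0))
  ))
  pd2 <- performance_delta(coh, n_boot = 2000, seed = 2)
  expect_lt(pd2$delta, 0)
  expect_lt(pd2$p_value, 0.05)
  expect_gt(pd2$n_laser, 300)
  expect_error(performance_delta(tr[!tr$laser_on, ]), "both")
})

test_that("psychometric points use the stated bins and weighting", {
  set.seed(5)
  tr <- dplyr::bind_rows(lapply(1:500, function(i) {
    nr <- rpois(1, 6); nl <- rpois(1, 4)
    make_trial(trial_index = i,
               towers_right = if (nr) seq(12, 198, length.out = nr) else numeric(0),
               towers_left = if (nl) seq(13, 197, length.out = nl) else numeric(0),
               choice = if (runif(1) < plogis(0.4 * (nr - nl))) "R" else "L")
  }))
  pts <- psychometric_curve(tr)
  expect_lte(nrow(pts), 6)  # six bins covering [-15, 15) in steps of 5
  expect_true(all(pts$ci_lo <= pts$p_right & pts$p_right <= pts$ci_hi))
  # weighted mean delta lies inside each bin
  delta <- vapply(tr$towers_right, length, integer(1)) -
    vapply(tr$towers_left, length, integer(1))
  expect_true(all(pts$delta_mean >= -15 & pts$delta_mean < 15))
  # normal CIs also available
  pts2 <- psychometric_curve(tr, ci = "normal")
  mid <- pts2$p_right > 0 & pts2$p_right < 1
  expect_true(all(pts2$ci_hi[mid] - pts2$ci_lo[mid] > 0))
})

test_that("four-parameter sigmoid is recovered from known generative values", {
  a <- 0.8; b <- 0.1; d0 <- 0; lam <- 3
  set.seed(21)
  deltas <- round(rnorm(50000, 0, 6))
  p <- b + a / (1 + exp(-(deltas - d0) / lam))
  choice <- ifelse(runif(length(p)) < p, "R", "L")
  tr <- tibble::tibble(
    mouse_id = "m1", session_id = "s1", block_id = 1L,
    trial_index = seq_along(deltas), rewarded_side = "R",
    towers_right = lapply(pmax(deltas, 0), function(k) seq_len(k) * 13),
    towers_left = lapply(pmax(-deltas, 0), function(k) seq_len(k) * 13),
    tower_times_right = list(numeric(0)), tower_times_left = list(numeric(0)),
    speed = 50, choice = choice, laser_on = FALSE,
    area_set = NA_character_, epoch = NA_character_,
    laser_onset_y = NA_real_, laser_offset_y = NA_real_,
    laser_onset_time = NA_real_, laser_offset_time = NA_real_,
    traveled_distance = 330, reached_end = TRUE,
    is_warmup = FALSE, is_easy_block = FALSE
  )
  fit <- fit_psychometric(psychometric_curve(tr))
  expect_equal(fit$a, a, tolerance = 0.05 * a / 0.8)
  expect_lt(abs(fit$b - b), 0.05)
  expect_equal(fit$delta0, d0, tolerance = 0.3)
  expect_equal(fit$lambda, lam, tolerance = 0.05 * lam)
  # trial-wise MLE agrees
  fit2 <- fit_psychometric(tr, method = "mle")
  expect_equal(fit2$lambda, lam, tolerance = 0.1 * lam)
  # symmetric data -> delta0 ~ 0 (already covered by d0 = 0 recovery above)
  expect_true(fit$identifiable)
})

test_that("spatial evidence weights recover flat and localized profiles", {
  cfg <- task_config(speed_cv = 0)
  # flat: all towers weighted equally by the generator
  coh <- generate_cohort(n_mice = 3, trials_per_mouse = 400, laser_frac = 0,
                         config = cfg, n_warmup = 0, seed = 31,
                         gcm = choice_model(base_weight = 0.4, lapse = 0,
                                            bias_sd = 0, weight_sd = 0))
  sw <- spatial_evidence_weights(coh, n_boot = 200, seed = 1)
  expect_length(sw$beta, 4)
  expect_lt(max(sw$beta) - min(sw$beta), 2 * max(sw$boot_sd[-1]))
  expect_true(all(sw$p_values < 0.05))  # every bin informative

  # only bin 1 informative: weight towers by position in the generator
  set.seed(32)
  tr <- dplyr::bind_rows(lapply(1:2000, function(i) {
    tw <- draw_tower_positions(cfg, sample(c("R", "L"), 1))
    d1 <- sum(tw$towers_right < 57.5) - sum(tw$towers_left < 57.5)
    make_trial(trial_index = i, towers_right = tw$towers_right,
               towers_left = tw$towers_left,
               choice = if (runif(1) < plogis(0.8 * d1)) "R" else "L")
  }))
  sw2 <- spatial_evidence_weights(tr, n_boot = 100, seed = 2)
  # the logistic fit agrees with a brute-force Newton solver
  d_oracle <- optotower:::spatial_bin_deltas(tr)
  oracle <- newton_logistic(d_oracle, as.numeric(tr$choice == "R"))
  expect_lt(max(abs(c(sw2$beta0, sw2$beta) - oracle)), 1e-6)
  expect_gt(sw2$beta[1], 0.5)
  expect_lt(sw2$p_values[1], 0.05)
  expect_true(all(abs(sw2$beta[2:4]) < 0.15))

  # no towers at all -> error
  none <- make_trials(make_trial(towers_right = numeric(0),
                                 towers_left = numeric(0)),
                      make_trial(trial_index = 2,
                                 towers_right = numeric(0),
                                 towers_left = numeric(0)))
  expect_error(spatial_evidence_weights(none), "no towers")
})

test_that("weight-curve delta uses the printed sign convention", {
  cfg <- validation_config()
  coh <- suppressWarnings(generate_cohort(
    n_mice = 3, trials_per_mouse = 400, laser_frac = 0.35, epochs = "cue2q",
    config = cfg, n_warmup = 0, seed = 41,
    gcm = choice_model(base_weight = 0.8, lapse = 0,
                       laser_modulation = c(during = 0.2))
  ))
  tr <- coh$trials
  wd <- weight_curve_delta(tr[tr$laser_on, ], tr[!tr$laser_on, ],
                           n_boot = 200, seed = 3)
  expect_equal(nrow(wd), 4)
  # cue2q spans 50-100 cm: reduced on-weights -> negative delta in bin 2
  expect_lt(wd$delta[2], 0)
  expect_lt(wd$p_value[2], 0.05)
  # identical arms -> deltas ~ 0
  wd0 <- weight_curve_delta(tr[!tr$laser_on, ], tr[!tr$laser_on, ],
                            n_boot = 100, seed = 4)
  expect_true(all(abs(wd0$delta) < 1e-9))
})

test_that("speed change recovers the laser speed gain", {
  coh <- suppressWarnings(generate_cohort(
    n_mice = 3, trials_per_mouse = 400, laser_frac = 0.35, epochs = "cue2h",
    n_warmup = 0, seed = 51, config = validation_config()
  ))
  sc <- speed_change(coh, segment = c(100, 200), n_boot = 2000, seed = 5)
  expect_lt(abs(sc$pct_change - 8), 2.5)  # ~8% speedup
  expect_lt(sc$p_value, 0.05)
  # a segment the laser never covers shows ~ no change
  sc0 <- speed_change(coh, segment = c(200, 300), n_boot = 500, seed = 6)
  expect_lt(abs(sc0$pct_change), 2)
  expect_error(speed_change(coh, segment = c(250, 400)), "outside")
})
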