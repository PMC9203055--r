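test_that("dummy laser windows follow the control trial's own kinematics", {
  # nearest laser trial's window at y = 100-150; control runs at 50 cm/s
  # from y = -30, so it crosses y = 100 at t = 130/50 = 2.6 s
  tr <- make_trials(
    make_trial(trial_index = 1, laser_on = TRUE, epoch = "cue3q",
               area_set = "V1", laser_onset_y = 100, laser_offset_y = 150,
               laser_onset_time = 2.6, laser_offset_time = 3.6),
    make_trial(trial_index = 2, speed = 50),
    make_trial(trial_index = 5, laser_on = TRUE, epoch = "cue1q",
               area_set = "V1", laser_onset_y = 0, laser_offset_y = 50,
               laser_onset_time = 0.6, laser_offset_time = 1.6),
    make_trial(trial_index = 8, speed = 50)
  )
  out <- assign_dummy_laser_windows(tr)
  expect_equal(out$laser_onset_time[2], (100 + 30) / 50)
  expect_equal(out$laser_offset_time[2], (150 + 30) / 50)
  expect_equal(out$epoch[2], "cue3q")
  # trial 8 is equidistant from laser trials 5 and ... 5 only (|8-5|=3 vs
  # |8-1|=7): uses trial 5's window
  expect_equal(out$laser_onset_y[4], 0)
  # equidistant tie goes to the earlier laser trial
  tr2 <- make_trials(
    make_trial(trial_index = 1, laser_on = TRUE, epoch = "cue1q",
               area_set = "V1", laser_onset_y = 0, laser_offset_y = 50,
               laser_onset_time = 0.6, laser_offset_time = 1.6),
    make_trial(trial_index = 2, speed = 50),
    make_trial(trial_index = 3, laser_on = TRUE, epoch = "cue3q",
               area_set = "V1", laser_onset_y = 100, laser_offset_y = 150,
               laser_onset_time = 2.6, laser_offset_time = 3.6)
  )
  out2 <- assign_dummy_laser_windows(tr2)
  expect_equal(out2$epoch[2], "cue1q")
  # all-control session errors
  expect_error(assign_dummy_laser_windows(make_trials(make_trial())),
               "no laser")
})

test_that("time-binned design reproduces the worked example", {
  tr <- make_trial(
    laser_on = TRUE, epoch = "cue1h", area_set = "V1",
    towers_right = c(30, 95, 125), towers_left = c(70, 180),
    tower_times_right = c(0.4, 1.7, 2.3), tower_times_left = c(1.2, 3.4),
    laser_onset_y = 0, laser_offset_y = 100,
    laser_onset_time = 2.0, laser_offset_time = 3.0
  )
  d <- build_time_binned_design(tr)
  # chronological bins pre3 pre2 pre1 during post1 post2:
  # Pre (nearest-first) = (+1, -1, 0), During = +1, Post = (-1, 0);
  # the tower at t = 0.4 is outside all windows and excluded
  expect_equal(unname(d$raw[1, ]), c(0, -1, 1, 1, -1, 0))
  expect_equal(d$bins, c("pre3", "pre2", "pre1", "during", "post1", "post2"))
})

test_that("design columns are partitioned, z-scored, and structurally zero", {
  coh <- test_cohort()
  des <- build_time_binned_design(coh)
  dat <- des$data
  las <- dat$int_L == 1
  for (cl in des$cols_laser) expect_true(all(dat[[cl]][!las] == 0))
  for (cl in des$cols_control) {
    expect_true(all(dat[[cl]][las] == 0))
    expect_equal(mean(dat[[cl]][!las]), 0, tolerance = 1e-10)
    expect_equal(sd(dat[[cl]][!las]), 1, tolerance = 1e-10)
  }
  # towerless trial contributes all-zero evidence (pre z-scoring)
  t0 <- make_trial(towers_right = numeric(0), towers_left = numeric(0),
                   tower_times_right = numeric(0),
                   tower_times_left = numeric(0),
                   laser_onset_time = 2, laser_offset_time = 3,
                   laser_onset_y = 70, laser_offset_y = 120)
  d0 <- build_time_binned_design(t0)
  expect_true(all(d0$raw == 0))
  # overlapping window errors
  bad <- make_trial(laser_onset_time = 3, laser_offset_time = 2,
                    laser_onset_y = 70, laser_offset_y = 120)
  expect_error(build_time_binned_design(bad), "after onset")
})

test_that("design is equivariant to a constant time shift", {
  coh <- test_cohort()
  tr <- coh$trials[1:120, ]
  shift <- function(x, c) lapply(x, function(v) v + c)
  tr2 <- tr
  tr2$tower_times_right <- shift(tr$tower_times_right, 2.5)
  tr2$tower_times_left <- shift(tr$tower_times_left, 2.5)
  tr2$laser_onset_time <- tr$laser_onset_time + 2.5
  tr2$laser_offset_time <- tr$laser_offset_time + 2.5
  d1 <- build_time_binned_design(tr)
  d2 <- build_time_binned_design(tr2)
  expect_equal(d1$raw, d2$raw)
})

test_that("mixed fit with homogeneous mice matches the plain logistic MLE", {
  cfg <- validation_config()
  coh <- suppressWarnings(generate_cohort(
    n_mice = 4, trials_per_mouse = 250, laser_frac = 0.3, epochs = "tile",
    config = cfg, n_warmup = 0, seed = 61,
    gcm = choice_model(base_weight = 0.8, bias_sd = 0, weight_sd = 0,
                       lapse = 0, laser_modulation = c(during = 0.5))
  ))
  coh <- assign_dummy_laser_windows(coh)
  des <- build_time_binned_design(coh)
  fit_glm <- fit_mixed_logistic(des, random = "none")
  # the zero-variance model is the ordinary logistic MLE: check against an
  # independent Newton-Raphson oracle
  dat <- des$data
  ev <- c(des$cols_control, des$cols_laser)
  X <- as.matrix(dat[c("int_L", ev)])  # int_C absorbed into the intercept
  oracle <- newton_logistic(X, dat$choice)
  est <- setNames(fit_glm$coefficients$estimate, fit_glm$coefficients$term)
  expect_equal(unname(est["int_C"]), oracle[1], tolerance = 1e-6)
  expect_equal(unname(est["int_L"] - est["int_C"]), oracle[2],
               tolerance = 1e-5)
  expect_equal(unname(est[ev]), oracle[-(1:2)], tolerance = 1e-6)
  # with no true heterogeneity the mixed fit's fixed effects stay close to
  # the unpooled MLE (variance components shrink toward zero)
  fit_mix <- fit_mixed_logistic(des, random = "full")
  expect_lt(max(abs(fit_mix$coefficients$estimate -
                      fit_glm$coefficients$estimate)), 0.2)
  expect_true(fit_mix$converged)
  # bias ~ logit(mean choice) when evidence columns carry no signal:
  # check on label-shuffled choices
  des0 <- des
  set.seed(1)
  des0$data$choice <- sample(des0$data$choice)
  f0 <- fit_mixed_logistic(des0, random = "none")
  b0 <- f0$coefficients$estimate[f0$coefficients$term == "int_C"]
  expect_equal(b0, qlogis(mean(des0$data$choice[des0$data$int_C == 1])),
               tolerance = 0.1)
})

test_that("mixed fit recovers generative weights within 2 SE for most terms", {
  coh <- test_cohort()  # during modulation 0.3, base weight 1
  des <- build_time_binned_design(coh)
  fit <- fit_mixed_logistic(des)
  cf <- fit$coefficients[fit$coefficients$partition == "control", ]
  zs <- des$zstats[cf$term]
  truth <- 1 * vapply(zs, function(z) z[["sd"]], numeric(1))
  cover <- abs(cf$estimate - truth) <= 2 * cf$se
  expect_gte(mean(cover), 0.5)
  expect_error(fit_mixed_logistic(
    build_time_binned_design(coh$trials[coh$trials$mouse_id == "m01", ])),
    "2 mice")
})

test_that("normalized weights implement the printed anchors and guards", {
  f <- glmm_fit_manual(
    control = c(pre1 = 0.8, during = 0.8, post1 = 0.8, zero = 1e-5),
    laser = c(pre1 = 0.8, during = 0, post1 = 1.6, zero = 0.3),
    se_control = c(pre1 = 0.1, during = 0.1, post1 = 0.1, zero = 0.1),
    se_laser = c(pre1 = 0.1, during = 0.1, post1 = 0.1, zero = 0.1)
  )
  nw <- normalized_weights(f)
  expect_equal(nw$value[nw$bin == "pre1"], 0)       # E^L = E^C -> 0
  expect_equal(nw$value[nw$bin == "during"], -1)    # E^L = 0 -> -1
  expect_equal(nw$value[nw$bin == "post1"], 1)      # doubling -> +1
  expect_false(nw$defined[nw$bin == "zero"])        # |E^C| < eps guard
  expect_true(is.na(nw$value[nw$bin == "zero"]))
  # delta-method SE for independent errors: sqrt(vL/C^2 + L^2 vC / C^4)
  expect_equal(nw$se[nw$bin == "during"],
               sqrt(0.1^2 / 0.8^2 + 0 * 0.1^2), tolerance = 1e-9)
})

test_that("cross-validated fits predict held-out choices", {
  cfg <- validation_config()
  # near-deterministic generator: held-out accuracy ~ 1
  coh <- suppressWarnings(generate_cohort(
    n_mice = 3, trials_per_mouse = 150, laser_frac = 0.2, epochs = "tile",
    config = cfg, n_warmup = 0, seed = 71,
    gcm = choice_model(base_weight = 3, bias_sd = 0, weight_sd = 0, lapse = 0)
  ))
  coh <- assign_dummy_laser_windows(coh)
  des <- build_time_binned_design(coh)
  cv <- suppressWarnings(crossval_glmm(des, k = 5, seed = 1,
                                       random = "intercepts"))
  expect_gt(max(cv$accuracy), 0.9)
  expect_equal(cv$best_fit$accuracy, max(cv$accuracy))
  # pure-noise choices: accuracy ~ 0.5
  des0 <- des
  set.seed(2)
  des0$data$choice <- rbinom(nrow(des0$data), 1, 0.5)
  cv0 <- crossval_glmm(des0, k = 5, seed = 1, random = "intercepts")
  expect_lt(abs(mean(cv0$accuracy) - 0.5), 0.1)
})

test_that("control-only data reproduce the control-only logistic fit", {
  coh <- test_cohort()
  tr <- coh$trials[!coh$trials$laser_on, ]
  des <- build_time_binned_design(tr)
  expect_length(des$cols_laser, 0)  # laser partition entirely dropped
  fit <- fit_mixed_logistic(des, random = "none")
  # same as fitting glm directly on the control columns
  dat <- des$data
  X <- as.matrix(dat[des$cols_control])
  ref <- glm(dat$choice ~ X, family = binomial())
  expect_equal(
    unname(fit$coefficients$estimate[match(des$cols_control,
                                           fit$coefficients$term)]),
    unname(coef(ref)[-1]), tolerance = 1e-8)
})

test_that("shuffle null preserves stratum counts and centers on zero", {
  coh <- test_cohort()
  tr <- coh$trials
  strata <- paste(tr$mouse_id, tr$epoch)
  before <- tapply(tr$laser_on, strata, sum)
  # capture one shuffle's labels via a 1-shuffle run with fixed seed
  null <- shuffle_null(coh, n_shuffle = 3, seed = 5, random = "none")
  expect_s3_class(null, "shuffle_null")
  expect_true(all(is.finite(null$null_mean)))
  vals <- attr(null, "values")
  expect_equal(dim(vals), c(3, 6))
  expect_error(shuffle_null(coh, n_shuffle = 0), "at least 1")
})

test_that("the two-condition significance rule combines FDR and null band", {
  w <- tibble::tibble(
    bin = c("a", "b", "c"),
    value = c(-0.5, -0.05, -0.5), se = c(0.05, 0.05, 0.05),
    defined = TRUE
  )
  null <- tibble::tibble(bin = c("a", "b", "c"),
                         null_mean = 0, null_sd = 0.1)
  out <- coefficient_significance(w, null)
  # a: tiny p and outside the band -> significant
  expect_true(out$significant[1])
  # b: inside the band -> not significant regardless of p
  expect_false(out$outside_null_band[2])
  expect_false(out$significant[2])
  # estimate inside band never significant even with p = 1e-5
  w2 <- w; w2$value[2] <- -0.08
  out2 <- coefficient_significance(w2, null)
  expect_false(out2$significant[2])
  # all p = 1 -> nothing significant
  w3 <- w; w3$value <- 0
  out3 <- coefficient_significance(w3, null)
  expect_false(any(out3$significant))
  # missing null -> t-test only, flagged
  expect_warning(out4 <- coefficient_significance(w), "t-test-only")
  expect_true(attr(out4, "ttest_only"))
})

test_that("model-comparison z follows the printed formula", {
  w1 <- tibble::tibble(bin = c("a", "b", "c"), value = c(1.0, 0.5, 0),
                       se = c(0.2, 0.1, 0.1))
  w2 <- tibble::tibble(bin = c("a", "b", "c"), value = c(0.5, 0.5, 0),
                       se = c(0.1, 0.1, 0.1))
  z <- compare_models_z(w1, w2)
  expect_equal(z$z[1], 0.5 / sqrt((1 * 0.2)^2 + (0.5 * 0.1)^2),
               tolerance = 1e-9)
  expect_equal(z$z[1], 2.4254, tolerance = 1e-4)
  expect_equal(z$z[2], 0)                 # equal coefficients
  expect_false(z$defined[3])              # 0/0 flagged undefined
  expect_error(compare_models_z(w1, w2[c(2, 1, 3), ]), "mismatch")
})

test_that("even-combination test compares combined to the average", {
  w <- function(v, se = 0.05) tibble::tibble(bin = c("a", "b"),
                                             value = v, se = se)
  singles <- list(w(c(-0.4, -0.2)), w(c(-0.6, -0.4)))
  avg <- c(-0.5, -0.3)
  # combined equals the average -> z ~ 0
  ec <- even_combination_test(singles, w(avg))
  expect_equal(ec$prediction$value, avg)
  expect_equal(ec$prediction$se, rep(sqrt(2 * 0.05^2) / 2, 2))
  expect_true(all(ec$comparison$z < 1e-9))
  # combined = 2 x average with small SEs -> significant
  ec2 <- even_combination_test(singles, w(2 * avg, se = 0.01))
  expect_true(all(ec2$comparison$p_value < 0.05))
  # single list of length 1: prediction equals that fit
  ec3 <- even_combination_test(singles[1], w(c(-0.4, -0.2)))
  expect_equal(ec3$prediction$value, c(-0.4, -0.2))
})

test_that("area-group comparison runs a mixed repeated-measures ANOVA", {
  set.seed(9)
  tab <- expand.grid(area = c("V1", "PPC", "mM2", "aM2"),
                     bin = c("pre1", "during", "post1"),
                     stringsAsFactors = FALSE)
  tab$group <- ifelse(tab$area %in% c("V1", "PPC"), "posterior", "frontal")
  tab$value <- rnorm(nrow(tab), 0, 0.01)
  out <- area_group_comparison(tab)
  expect_true(all(c("group", "bin", "group:bin") %in% out$effect))
  # identical groups -> tiny group F
  expect_lt(out$F[out$effect == "group"], 10)
  # a real group difference is detected
  tab2 <- tab
  tab2$value <- tab2$value + ifelse(tab2$group == "frontal", -1, 0)
  out2 <- area_group_comparison(tab2)
  expect_lt(out2$p_value[out2$effect == "group"], 0.01)
  # single area per group -> error
  expect_error(area_group_comparison(tab[tab$area %in% c("V1", "mM2"), ]),
               "2 areas")
})
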