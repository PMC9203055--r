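#' @importFrom stats rpois runif rnorm rbinom plogis rlnorm sd quantile
#'   median var setNames
#' @importFrom tibble tibble as_tibble
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All generators go through this so that
# cohorts are reproducible and do not disturb the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Draw tower positions for one trial
#'
#' Tower counts on each side are Poisson with mean `tower_rate_major` on the
#' rewarded side and `tower_rate_minor` on the other; positions are uniform
#' on `[tower_min_y, cue_length]` conditional on a minimum within-side
#' spacing of `refractory` cm. The conditional-uniform draw is performed by
#' sorting uniforms on the interval shrunk by `refractory * (n - 1)` and
#' re-inflating, which is exactly the distribution obtained by re-sampling
#' until the spacing constraint holds. Counts are clipped to the maximum
#' feasible under the refractory constraint.
#'
#' @param config A [task_config()].
#' @param rewarded_side `"R"` or `"L"`.
#' @param seed Optional integer seed (restores RNG state afterwards).
#' @return A list with sorted numeric vectors `towers_right`, `towers_left`.
#' @examples
#' tw <- draw_tower_positions(task_config(), "R", seed = 1)
#' min(diff(tw$towers_right))
#' @export
draw_tower_positions <- function(config, rewarded_side = c("R", "L"),
                                 seed = NULL) {
  rewarded_side <- match.arg(rewarded_side)
  with_seed(seed, {
    rate_r <- if (rewarded_side == "R") config$tower_rate_major else config$tower_rate_minor
    rate_l <- if (rewarded_side == "L") config$tower_rate_major else config$tower_rate_minor
    list(
      towers_right = draw_spaced_positions(rpois(1, rate_r), config),
      towers_left  = draw_spaced_positions(rpois(1, rate_l), config)
    )
  })
}

# n uniform points on [min_y, cue_length] conditioned on spacing >= refractory.
draw_spaced_positions <- function(n, config) {
  span <- config$cue_length - config$tower_min_y
  n_max <- floor(span / config$refractory) + 1
  if (n_max < 1) {
    stop("configuration error: refractory too large for the cue region",
         call. = FALSE)
  }
  n <- min(n, n_max)
  if (n == 0) return(numeric(0))
  shrunk <- span - config$refractory * (n - 1)
  u <- sort(runif(n, 0, shrunk))
  config$tower_min_y + u + config$refractory * (seq_len(n) - 1)
}

#' Simulate a trial trajectory through the maze
#'
#' Running is modeled as a single per-trial speed drawn from a log-normal
#' with mean `mean_speed` and coefficient of variation `speed_cv`, constant
#' within the trial except inside the laser interval, where it is multiplied
#' by `1 + laser_speed_gain` (inactivations mildly speed mice up). The
#' trajectory is piecewise linear in y, which makes tower times and laser
#' onset/offset times available in closed form via [time_at_y()].
#'
#' @param config A [task_config()].
#' @param laser_interval_y Length-2 y interval (cm) where the laser is on,
#'   or `NULL` for a control trial.
#' @param seed Optional integer seed.
#' @param max_retries Retries for a non-positive speed draw (log-normal draws
#'   are positive; retries only guard pathological configs).
#' @return An object of class `trajectory`: list with `speed`, `gain`,
#'   `laser_interval`, `y_start`, `y_end`.
#' @examples
#' tr <- simulate_trajectory(task_config(), c(0, 100), seed = 2)
#' time_at_y(200, tr) - time_at_y(0, tr)  # cue-region traversal time
#' @export
simulate_trajectory <- function(config, laser_interval_y = NULL, seed = NULL,
                                max_retries = 10) {
  maze_end <- config$cue_length + config$delay_length
  if (!is.null(laser_interval_y)) {
    stopifnot(length(laser_interval_y) == 2)
    if (laser_interval_y[1] < 0 || laser_interval_y[2] > maze_end ||
        laser_interval_y[1] >= laser_interval_y[2]) {
      stop("laser_interval_y outside the maze or empty", call. = FALSE)
    }
  }
  with_seed(seed, {
    cv <- config$speed_cv
    sdlog <- sqrt(log(1 + cv^2))
    meanlog <- log(config$mean_speed) - sdlog^2 / 2
    speed <- rlnorm(1, meanlog, sdlog)
    tries <- 0
    while (speed <= 0 && tries < max_retries) {
      speed <- rlnorm(1, meanlog, sdlog)
      tries <- tries + 1
    }
    if (speed <= 0) stop("could not draw a positive speed", call. = FALSE)
    structure(
      list(speed = speed,
           gain = if (is.null(laser_interval_y)) 0 else config$laser_speed_gain,
           laser_interval = laser_interval_y,
           y_start = -config$start_length,
           y_end = maze_end),
      class = "trajectory"
    )
  })
}

#' Time at which a trajectory reaches a maze position
#'
#' Inverts the piecewise-linear kinematics of a [simulate_trajectory()]
#' object: time 0 is the trial start at `y_start`, and speed inside the
#' laser interval is scaled by `1 + gain`.
#'
#' @param y Numeric vector of maze positions (cm).
#' @param traj A `trajectory` object.
#' @return Numeric vector of times (s); `NA` for positions before the start.
#' @export
time_at_y <- function(y, traj) {
  v0 <- traj$speed
  v1 <- v0 * (1 + traj$gain)
  li <- traj$laser_interval
  t <- rep(NA_real_, length(y))
  ok <- y >= traj$y_start
  yy <- y[ok]
  if (is.null(li) || traj$gain == 0) {
    t[ok] <- (yy - traj$y_start) / v0
  } else {
    lo <- li[1]; hi <- li[2]
    d_pre  <- pmax(0, pmin(yy, lo) - traj$y_start)
    d_in   <- pmax(0, pmin(yy, hi) - lo)
    d_post <- pmax(0, yy - hi)
    t[ok] <- d_pre / v0 + d_in / v1 + d_post / v0
  }
  t
}

#' Sample a trajectory on a regular time grid
#'
#' @param traj A `trajectory` object.
#' @param dt Sample spacing (s).
#' @return A tibble with `time`, `y`, `speed` from trial start until the
#'   maze end is reached.
#' @export
trajectory_samples <- function(traj, dt = 0.1) {
  t_end <- time_at_y(traj$y_end, traj)
  times <- seq(0, t_end, by = dt)
  y <- y_at_time(times, traj)
  v <- rep(traj$speed, length(times))
  if (!is.null(traj$laser_interval) && traj$gain != 0) {
    inside <- y >= traj$laser_interval[1] & y < traj$laser_interval[2]
    v[inside] <- v[inside] * (1 + traj$gain)
  }
  tibble(time = times, y = y, speed = v)
}

# Inverse of time_at_y on the same piecewise-linear kinematics.
y_at_time <- function(t, traj) {
  v0 <- traj$speed
  li <- traj$laser_interval
  if (is.null(li) || traj$gain == 0) {
    return(pmin(traj$y_start + v0 * t, traj$y_end))
  }
  v1 <- v0 * (1 + traj$gain)
  t_lo <- time_at_y(li[1], traj)
  t_hi <- time_at_y(li[2], traj)
  y <- ifelse(t <= t_lo, traj$y_start + v0 * t,
         ifelse(t <= t_hi, li[1] + v1 * (t - t_lo),
                li[2] + v0 * (t - t_hi)))
  pmin(y, traj$y_end)
}

# Label the laser-aligned window containing each tower time, or NA if the
# tower falls outside all windows. Bins are half-open, closed toward the
# alignment point: pre_i = (onset - i*bin, onset - (i-1)*bin], during =
# (onset, offset], post_i = (offset + (i-1)*bin, offset + i*bin].
# The during window is assigned last so that a tower exactly at laser onset
# belongs to it.
window_of_time <- function(t, onset, offset, bin_s = 0.5,
                           n_pre = 3, n_post = 2) {
  out <- rep(NA_character_, length(t))
  for (i in seq_len(n_pre)) {
    sel <- t > onset - i * bin_s & t <= onset - (i - 1) * bin_s
    out[sel] <- paste0("pre", i)
  }
  for (i in seq_len(n_post)) {
    sel <- t > offset + (i - 1) * bin_s & t <= offset + i * bin_s
    out[sel] <- paste0("post", i)
  }
  out[t >= onset & t <= offset] <- "during"
  out
}

#' Simulate a choice from the generative decision rule
#'
#' Evaluates the ground-truth logistic rule of [choice_model()]: each
#' tower contributes its side sign times the mouse's evidence weight,
#' multiplied by the modulation factor of the laser-aligned window it falls
#' in (1 on control trials and outside all windows), plus the mouse's bias;
#' a lapse mixes in coin flips.
#'
#' @param tower_times_right,tower_times_left Tower trigger times (s).
#' @param gcm A [choice_model()].
#' @param bias Mouse-specific bias (log-odds).
#' @param weight Mouse-specific evidence weight (log-odds per tower).
#' @param laser_on Logical; whether the laser modulations apply.
#' @param laser_onset,laser_offset Laser window times (s); required if
#'   `laser_on`.
#' @param seed Optional integer seed.
#' @param return_prob If `TRUE`, return `P(right)` instead of sampling.
#' @return `"R"` or `"L"` (or the probability of right if `return_prob`).
#' @examples
#' gcm <- choice_model(lapse = 0)
#' simulate_choice(c(1, 2), numeric(0), gcm, bias = 0, weight = 0.5,
#'                 laser_on = FALSE, return_prob = TRUE)
#' @export
simulate_choice <- function(tower_times_right, tower_times_left, gcm,
                            bias, weight, laser_on = FALSE,
                            laser_onset = NA_real_, laser_offset = NA_real_,
                            seed = NULL, return_prob = FALSE) {
  if (anyNA(tower_times_right) || anyNA(tower_times_left)) {
    stop("tower with undefined time", call. = FALSE)
  }
  tt <- c(tower_times_right, tower_times_left)
  ss <- c(rep(1, length(tower_times_right)), rep(-1, length(tower_times_left)))
  mod <- rep(1, length(tt))
  if (laser_on) {
    if (is.na(laser_onset) || is.na(laser_offset)) {
      stop("laser trial without laser window times", call. = FALSE)
    }
    win <- window_of_time(tt, laser_onset, laser_offset)
    has <- !is.na(win)
    mod[has] <- gcm$laser_modulation[win[has]]
  }
  lp <- bias + sum(ss * weight * mod)
  p_right <- gcm$lapse / 2 + (1 - gcm$lapse) * plogis(lp)
  if (return_prob) return(p_right)
  with_seed(seed, if (runif(1) < p_right) "R" else "L")
}

#' Generate a synthetic behavioral cohort
#'
#' Builds a full cohort of accumulating-towers sessions with known ground
#' truth: per-mouse biases and evidence weights are drawn from the
#' [choice_model()] population, towers are placed per [draw_tower_positions()],
#' running follows [simulate_trajectory()], and choices follow
#' [simulate_choice()]. Laser trials receive an inactivation epoch (y
#' interval) and area-set label; the laser window times follow from the
#' trajectory. Control trials have no laser window until
#' [assign_dummy_laser_windows()] is applied.
#'
#' @param n_mice Number of mice.
#' @param trials_per_mouse Trials per mouse (split into sessions of
#'   `trials_per_session`).
#' @param laser_frac Total fraction of laser trials (the task caps this at
#'   ~0.35 across conditions; 0.02–0.15 per condition).
#' @param area_set Area-set label applied to laser trials.
#' @param epochs Character vector of epoch names (subset of
#'   `names(config$epochs)`) sampled uniformly for laser trials.
#' @param config A [task_config()].
#' @param gcm A [choice_model()].
#' @param trials_per_session Session length in trials.
#' @param n_warmup Visually guided warm-up trials at the start of each
#'   session (flagged, never laser).
#' @param seed Integer seed; the cohort is reproducible given the seed.
#' @return An object of class `tower_cohort`: list with `trials` (a tibble,
#'   one row per trial with list-columns for tower positions/times),
#'   `config`, `gcm`, `mouse_effects` (ground-truth per-mouse parameters),
#'   and `seed`.
#' @examples
#' coh <- generate_cohort(n_mice = 2, trials_per_mouse = 20, seed = 1)
#' nrow(coh$trials)
#' @export
generate_cohort <- function(n_mice = 15, trials_per_mouse = 500,
                            laser_frac = 0.15, area_set = "Post",
                            epochs = names(config$epochs),
                            config = task_config(), gcm = choice_model(),
                            trials_per_session = 250, n_warmup = 10,
                            seed = NULL) {
  stopifnot(all(epochs %in% names(config$epochs)))
  per_cond <- laser_frac / length(epochs)
  if (laser_frac > 0 && (per_cond < 0.02 || per_cond > 0.15)) {
    warning(sprintf(
      "per-condition laser fraction %.3f outside the documented 0.02-0.15 range",
      per_cond), call. = FALSE)
  }
  if (laser_frac > 0.35) {
    warning("total laser fraction above the documented 0.35 cap", call. = FALSE)
  }
  with_seed(seed, {
    mouse_ids <- sprintf("m%02d", seq_len(n_mice))
    mouse_effects <- tibble(
      mouse_id = mouse_ids,
      bias = rnorm(n_mice, gcm$bias_mean, gcm$bias_sd),
      weight = rnorm(n_mice, gcm$base_weight, gcm$weight_sd)
    )
    rows <- vector("list", n_mice)
    for (m in seq_len(n_mice)) {
      n_sessions <- max(1, ceiling(trials_per_mouse / trials_per_session))
      sess_sizes <- rep(trials_per_session, n_sessions)
      sess_sizes[n_sessions] <-
        trials_per_mouse - trials_per_session * (n_sessions - 1)
      srows <- vector("list", n_sessions)
      for (s in seq_len(n_sessions)) {
        srows[[s]] <- simulate_session(
          mouse_id = mouse_ids[m], session_id = sprintf("s%02d", s),
          n_trials = sess_sizes[s], n_warmup = n_warmup,
          laser_frac = laser_frac, area_set = area_set, epochs = epochs,
          config = config, gcm = gcm,
          bias = mouse_effects$bias[m], weight = mouse_effects$weight[m]
        )
      }
      rows[[m]] <- dplyr::bind_rows(srows)
    }
    structure(
      list(trials = dplyr::bind_rows(rows), config = config, gcm = gcm,
           mouse_effects = mouse_effects, seed = seed),
      class = "tower_cohort"
    )
  })
}

simulate_session <- function(mouse_id, session_id, n_trials, n_warmup,
                             laser_frac, area_set, epochs, config, gcm,
                             bias, weight) {
  n_tot <- n_trials + n_warmup
  maze_len <- config$start_length + config$cue_length + config$delay_length
  warmup <- seq_len(n_tot) <= n_warmup
  rewarded <- sample(c("R", "L"), n_tot, replace = TRUE)
  laser_on <- !warmup & runif(n_tot) < laser_frac
  epoch <- rep(NA_character_, n_tot)
  epoch[laser_on] <- sample(epochs, sum(laser_on), replace = TRUE)
  tw_r <- vector("list", n_tot); tw_l <- vector("list", n_tot)
  tt_r <- vector("list", n_tot); tt_l <- vector("list", n_tot)
  speed <- numeric(n_tot); choice <- character(n_tot)
  on_y <- off_y <- on_t <- off_t <- rep(NA_real_, n_tot)
  for (i in seq_len(n_tot)) {
    interval <- if (laser_on[i]) config$epochs[[epoch[i]]] else NULL
    tw <- if (warmup[i]) {
      # visually guided: towers only on the rewarded side
      pos <- draw_spaced_positions(rpois(1, config$tower_rate_major), config)
      if (rewarded[i] == "R") list(towers_right = pos, towers_left = numeric(0))
      else list(towers_right = numeric(0), towers_left = pos)
    } else {
      draw_tower_positions(config, rewarded[i])
    }
    traj <- simulate_trajectory(config, interval)
    tw_r[[i]] <- tw$towers_right; tw_l[[i]] <- tw$towers_left
    tt_r[[i]] <- time_at_y(tw$towers_right - config$tower_trigger_distance, traj)
    tt_l[[i]] <- time_at_y(tw$towers_left - config$tower_trigger_distance, traj)
    speed[i] <- traj$speed
    if (laser_on[i]) {
      on_y[i] <- interval[1]; off_y[i] <- interval[2]
      on_t[i] <- time_at_y(interval[1], traj)
      off_t[i] <- time_at_y(interval[2], traj)
    }
    choice[i] <- if (warmup[i]) {
      rewarded[i]  # guided trials are essentially always correct
    } else {
      simulate_choice(tt_r[[i]], tt_l[[i]], gcm, bias, weight,
                      laser_on[i], on_t[i], off_t[i])
    }
  }
  tibble(
    mouse_id = mouse_id, session_id = session_id,
    block_id = ifelse(warmup, 0L, 1L), trial_index = seq_len(n_tot),
    rewarded_side = rewarded,
    towers_right = tw_r, towers_left = tw_l,
    tower_times_right = tt_r, tower_times_left = tt_l,
    speed = speed, choice = choice, laser_on = laser_on,
    area_set = ifelse(laser_on, area_set, NA_character_),
    epoch = epoch,
    laser_onset_y = on_y, laser_offset_y = off_y,
    laser_onset_time = on_t, laser_offset_time = off_t,
    traveled_distance = maze_len, reached_end = TRUE,
    is_warmup = warmup, is_easy_block = FALSE
  )
}

#' @export
print.tower_cohort <- function(x, ...) {
  cat("<tower_cohort>\n")
  cat(sprintf("  %d trials, %d mice, %.1f%% laser\n",
              nrow(x$trials), length(unique(x$trials$mouse_id)),
              100 * mean(x$trials$laser_on)))
  invisible(x)
}

# Accept a cohort or a bare trial tibble.
as_trials <- function(x) {
  if (inherits(x, "tower_cohort")) x$trials
  else if (is.data.frame(x)) x
  else stop("expected a tower_cohort or a trials data frame", call. = FALSE)
}

# Rebuild the trajectory object for one trial row (list-column friendly).
trial_trajectory <- function(trial, config) {
  interval <- if (isTRUE(trial$laser_on)) {
    c(trial$laser_onset_y, trial$laser_offset_y)
  } else NULL
  structure(
    list(speed = trial$speed,
         gain = if (is.null(interval)) 0 else config$laser_speed_gain,
         laser_interval = interval,
         y_start = -config$start_length,
         y_end = config$cue_length + config$delay_length),
    class = "trajectory"
  )
}
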