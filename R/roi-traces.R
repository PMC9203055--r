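#' Default intrinsic timescales per cortical area (s)
#'
#' Posterior areas have shorter timescales than frontal areas, in line with
#' the cortical hierarchy of intrinsic timescales.
#' @return Named numeric vector over the 8 per-hemisphere ROI labels.
#' @export
default_tau <- function() {
  c(V1 = 0.20, mV2 = 0.27, PPC = 0.36, RSC = 0.49,
    M1 = 0.66, mM2 = 0.89, aM2 = 1.20, AUX = 0.40)
}

#' ROI dynamics model for synthetic widefield traces
#'
#' Describes 16 ROIs (7 named dorsal-cortex areas plus one unnamed filler
#' per hemisphere, honoring the 16-ROI count used by the coupling
#' predictors). Each ROI's activity evolves with an autoregressive kernel
#' over the past `ar_order` samples whose weights decay exponentially with
#' the ROI's intrinsic timescale tau:
#' \deqn{a_i \propto e^{-i \, dt / \tau}, \qquad \sum_i a_i = g < 1,}
#' plus lag-1 coupling from the other ROIs, task-event drive, and Gaussian
#' noise. With `ar_order = 1` this reduces to an AR(1) process with lag-1
#' coefficient `ar_gain` (and lag-1 autocorrelation ~= `ar_gain`); the
#' multi-lag kernel is the default because the timescale analysis reads tau
#' from the decay of the lag profile, which a single-lag kernel cannot
#' carry. Stationarity (spectral radius of the companion form < 1) is
#' verified at construction.
#'
#' @param tau Named per-area timescales (s), recycled over hemispheres.
#' @param ar_order Number of autoregressive lags in the generative kernel.
#' @param ar_gain Sum of the AR kernel weights (< 1 for stationarity). For
#'   `ar_order = 1` this is the lag-1 coefficient itself, so use
#'   `exp(-dt/tau)` to realize a target AR(1) timescale.
#' @param coupling_strength Lag-1 coupling weight between homotopic
#'   (cross-hemisphere) ROI pairs; all other couplings are zero.
#' @param task_amp Amplitude of the tower-evoked response (z units).
#' @param noise_sd Innovation SD.
#' @param dt Sample spacing (s; 10 Hz native).
#' @return An object of class `roi_model`.
#' @export
roi_model <- function(tau = default_tau(), ar_order = 20, ar_gain = 0.7,
                      coupling_strength = 0.05, task_amp = 0.4,
                      noise_sd = 1, dt = 0.1) {
  areas <- names(tau)
  labels <- c(paste0(areas, "_L"), paste0(areas, "_R"))
  tau16 <- rep(unname(tau), 2)
  if (any(tau16 <= 0)) stop("tau must be positive", call. = FALSE)
  n <- length(labels)
  coupling <- matrix(0, n, n, dimnames = list(labels, labels))
  half <- length(areas)
  for (i in seq_len(half)) {
    coupling[i, i + half] <- coupling_strength
    coupling[i + half, i] <- coupling_strength
  }
  kernels <- matrix(vapply(tau16, function(tt) {
    w <- exp(-seq_len(ar_order) * dt / tt)
    ar_gain * w / sum(w)
  }, numeric(ar_order)), nrow = ar_order)  # ar_order x n (works at order 1)
  model <- structure(
    list(roi_labels = labels, tau_true = setNames(tau16, labels),
         ar_order = ar_order, ar_gain = ar_gain,
         kernels = t(kernels),  # n x ar_order
         coupling = coupling, task_amp = task_amp,
         noise_sd = noise_sd, dt = dt),
    class = "roi_model"
  )
  rho <- companion_spectral_radius(model)
  if (rho >= 1) {
    stop(sprintf("unstable ROI dynamics (spectral radius %.3f >= 1)", rho),
         call. = FALSE)
  }
  model$spectral_radius <- rho
  model
}

companion_spectral_radius <- function(model) {
  n <- length(model$roi_labels); p <- model$ar_order
  A <- matrix(0, n * p, n * p)
  for (lag in seq_len(p)) {
    blk <- diag(model$kernels[, lag], n)
    if (lag == 1) blk <- blk + model$coupling
    A[seq_len(n), (lag - 1) * n + seq_len(n)] <- blk
  }
  if (p > 1) {
    A[n + seq_len(n * (p - 1)), seq_len(n * (p - 1))] <-
      diag(n * (p - 1))
  }
  max(Mod(eigen(A, only.values = TRUE)$values))
}

#' @export
print.roi_model <- function(x, ...) {
  cat(sprintf("<roi_model> %d ROIs, AR order %d, spectral radius %.3f\n",
              length(x$roi_labels), x$ar_order, x$spectral_radius))
  invisible(x)
}

#' Generate synthetic ROI traces for a set of trials
#'
#' Simulates the coupled autoregressive dynamics of a [roi_model()] while
#' the animal traverses the maze (samples restricted to 0 <= y <= 300 cm,
#' 10 Hz), attaching per-sample behavior channels: position y, a smooth
#' bounded random-walk view angle theta and its derivative, running speed,
#' tower-event indicators (1 at the sample containing each tower trigger),
#' the cumulative net evidence, and per-trial upcoming-choice /
#' previous-choice / previous-reward flags (+1/-1 coded). Tower events
#' drive the contralateral hemisphere with an exponentially decaying kernel.
#' A burn-in is simulated and discarded; activity is finally z-scored per
#' ROI across all samples.
#'
#' @param model A [roi_model()].
#' @param x A `tower_cohort` or trial table (one session's worth, or more).
#' @param config Task configuration (taken from the cohort when available).
#' @param n_burn Burn-in samples discarded before the first trial.
#' @param seed Optional integer seed.
#' @return An object of class `trace_set`: `dff` (ROI x sample matrix,
#'   z-scored), `time` (s), `trial_bounds` (tibble `trial`, `start`,
#'   `end`), `behavior` (per-sample tibble), `model`, `z_scored = TRUE`.
#' @export
generate_roi_traces <- function(model, x, config = NULL, n_burn = 200,
                                seed = NULL) {
  trials <- as_trials(x)
  if (is.null(config)) {
    config <- if (inherits(x, "tower_cohort")) x$config else task_config()
  }
  n_roi <- length(model$roi_labels)
  p <- model$ar_order
  dt <- model$dt
  half <- n_roi / 2

  # per-trial behavior channels on the 10 Hz grid, 0 <= y <= 300
  beh_list <- vector("list", nrow(trials))
  ev_list <- vector("list", nrow(trials))
  n_samp <- integer(nrow(trials))
  prev_choice <- 0; prev_rew <- 0
  with_seed(seed, {
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      traj <- trial_trajectory(tr, config)
      t0 <- time_at_y(0, traj)
      t_end <- time_at_y(config$cue_length + config$delay_length, traj)
      times <- seq(t0, t_end, by = dt)
      n_i <- length(times)
      y <- pmin(pmax(y_at_time(times, traj), 0), traj$y_end)
      sp <- rep(traj$speed, n_i)
      if (!is.null(traj$laser_interval) && traj$gain != 0) {
        ins <- y >= traj$laser_interval[1] & y < traj$laser_interval[2]
        sp[ins] <- sp[ins] * (1 + traj$gain)
      }
      theta <- numeric(n_i)
      for (k in 2:max(2, n_i)) {
        if (k > n_i) break
        theta[k] <- max(-1, min(1, 0.9 * theta[k - 1] + rnorm(1, 0, 0.05)))
      }
      dtheta <- c(0, diff(theta)) / dt
      ev_r <- numeric(n_i); ev_l <- numeric(n_i)
      idx_r <- floor((tr$tower_times_right[[1]] - t0) / dt) + 1
      idx_l <- floor((tr$tower_times_left[[1]] - t0) / dt) + 1
      idx_r <- idx_r[idx_r >= 1 & idx_r <= n_i]
      idx_l <- idx_l[idx_l >= 1 & idx_l <= n_i]
      for (j in idx_r) ev_r[j] <- ev_r[j] + 1
      for (j in idx_l) ev_l[j] <- ev_l[j] + 1
      cum_delta <- cumsum(ev_r) - cumsum(ev_l)
      ch <- if (tr$choice == "R") 1 else -1
      correct <- trial_correct(tr)
      beh_list[[i]] <- tibble(
        y = y, theta = theta, dtheta = dtheta, speed = sp,
        tower_R = ev_r, tower_L = ev_l, cum_delta = cum_delta,
        ch = rep(ch, n_i), pch = rep(prev_choice, n_i),
        prw = rep(prev_rew, n_i)
      )
      ev_list[[i]] <- cbind(ev_r, ev_l)
      n_samp[i] <- n_i
      prev_choice <- ch
      prev_rew <- if (correct == 1) 1 else -1
    }

    n_tot <- sum(n_samp)
    ends <- cumsum(n_samp)
    starts <- ends - n_samp + 1
    beh <- dplyr::bind_rows(beh_list)

    # tower drive: contralateral hemisphere, exponential kernel (0.3 s)
    kern <- exp(-(0:5) * dt / 0.3)
    drive_R_events <- beh$tower_R  # right towers -> left hemisphere
    drive_L_events <- beh$tower_L
    conv_trial <- function(v) {
      out <- numeric(length(v))
      for (ti in seq_along(n_samp)) {
        seg <- v[starts[ti]:ends[ti]]
        out[starts[ti]:ends[ti]] <-
          stats::filter(c(seg, numeric(0)), kern, sides = 1,
                        method = "convolution")[seq_along(seg)]
      }
      out[is.na(out)] <- 0
      # leading samples where the kernel is truncated: use partial sums
      for (ti in seq_along(n_samp)) {
        seg <- v[starts[ti]:ends[ti]]
        nk <- length(kern)
        for (k in seq_len(min(nk - 1, length(seg)))) {
          out[starts[ti] + k - 1] <- sum(kern[seq_len(k)] * seg[k:1])
        }
      }
      out
    }
    dr_left_hemi <- conv_trial(drive_R_events)
    dr_right_hemi <- conv_trial(drive_L_events)
    drive <- matrix(0, n_roi, n_tot)
    drive[seq_len(half), ] <- model$task_amp *
      matrix(dr_left_hemi, half, n_tot, byrow = TRUE)
    drive[half + seq_len(half), ] <- model$task_amp *
      matrix(dr_right_hemi, half, n_tot, byrow = TRUE)

    # simulate the coupled AR(p) dynamics with burn-in
    T_all <- n_burn + n_tot
    X <- matrix(0, n_roi, T_all)
    K <- model$kernels  # n_roi x p
    C <- model$coupling
    eps <- matrix(rnorm(n_roi * T_all, 0, model$noise_sd), n_roi, T_all)
    for (t in 2:T_all) {
      lags <- min(p, t - 1)
      past <- X[, t - seq_len(lags), drop = FALSE]   # n_roi x lags
      ar <- rowSums(K[, seq_len(lags), drop = FALSE] * past)
      cp <- C %*% X[, t - 1]
      dr <- if (t > n_burn) drive[, t - n_burn] else 0
      X[, t] <- ar + as.numeric(cp) + dr + eps[, t]
    }
    X <- X[, n_burn + seq_len(n_tot), drop = FALSE]
    X <- t(scale(t(X)))  # z-score each ROI across all samples
    rownames(X) <- model$roi_labels

    structure(
      list(dff = X, time = (seq_len(n_tot) - 1) * dt,
           trial_bounds = tibble(trial = seq_along(n_samp),
                                 start = starts, end = ends),
           behavior = beh, model = model, z_scored = TRUE),
      class = "trace_set"
    )
  })
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set> %d ROIs x %d samples (%d trials, dt = %g s)\n",
              nrow(x$dff), ncol(x$dff), nrow(x$trial_bounds),
              diff(x$time[1:2])))
  invisible(x)
}

#' Emulate dual-wavelength fluorescence acquisition
#'
#' Composes a calcium-signal channel and an isosbestic channel sharing a
#' multiplicative hemodynamic artifact, as produced by alternating 470 nm
#' (signal + hemodynamics) and 410 nm (hemodynamics only) illumination:
#' `F_blue = F0 * (1 + signal) * (1 + artifact)` and
#' `F_violet = F0 * (1 + artifact)`. The default artifact is a slow
#' sinusoid with random phase; with `artifact_gain = 0` the violet channel
#' is constant.
#'
#' @param signal Numeric vector of fractional signal (e.g. a scaled ROI
#'   trace); must satisfy `signal > -1` so fluorescence stays positive.
#' @param artifact_gain Peak fractional amplitude of the shared artifact.
#' @param f0 Baseline fluorescence (arbitrary units).
#' @param dt Sample spacing (s).
#' @param artifact_freq Artifact frequency (Hz).
#' @param seed Optional integer seed (random artifact phase).
#' @return List with `F_blue`, `F_violet`, `artifact`, `dt`.
#' @export
emulate_dual_channel <- function(signal, artifact_gain = 0.05, f0 = 100,
                                 dt = 0.1, artifact_freq = 0.1, seed = NULL) {
  if (any(signal <= -1)) {
    stop("signal must stay above -1 (non-negative fluorescence)", call. = FALSE)
  }
  with_seed(seed, {
    tt <- (seq_along(signal) - 1) * dt
    phase <- runif(1, 0, 2 * pi)
    artifact <- artifact_gain * sin(2 * pi * artifact_freq * tt + phase)
    F_blue <- f0 * (1 + signal) * (1 + artifact)
    F_violet <- f0 * (1 + artifact)
    if (any(F_blue <= 0) || any(F_violet <= 0)) {
      stop("negative fluorescence after composition", call. = FALSE)
    }
    list(F_blue = F_blue, F_violet = F_violet, artifact = artifact, dt = dt)
  })
}
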