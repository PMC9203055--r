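#' Trial selection for analysis
#'
#' Applies the behavioral inclusion rules: drops warm-up and easy-block
#' trials, drops whole session blocks whose control (laser-off) performance
#' is below 60% correct, and drops trials that did not reach the end of the
#' maze or whose traveled distance exceeds the nominal maze length by more
#' than 10%.
#'
#' @param x A `tower_cohort` or trial table.
#' @param min_block_perf Minimum control fraction correct for a block.
#' @param max_distance_factor Maximum traveled distance as a multiple of the
#'   nominal maze length.
#' @param maze_length Nominal maze length (cm).
#' @return The filtered object (same type as the input), with a
#'   `selection_counts` attribute recording removals per rule. An empty
#'   result is allowed and flagged with a warning.
#' @export
select_trials <- function(x, min_block_perf = 0.6,
                          max_distance_factor = 1.1, maze_length = 330) {
  trials <- as_trials(x)
  n0 <- nrow(trials)

  keep_task <- !trials$is_warmup & !trials$is_easy_block
  n_warm <- sum(!keep_task)
  trials <- trials[keep_task, , drop = FALSE]

  # block-level control performance
  key <- paste(trials$mouse_id, trials$session_id, trials$block_id)
  correct <- trial_correct(trials)
  block_ok <- vapply(split(seq_len(nrow(trials)), key), function(idx) {
    ctrl <- idx[!trials$laser_on[idx]]
    length(ctrl) > 0 && mean(correct[ctrl]) >= min_block_perf
  }, logical(1))
  keep_block <- block_ok[key]
  n_block <- sum(!keep_block)
  trials <- trials[keep_block, , drop = FALSE]

  keep_dist <- trials$reached_end &
    trials$traveled_distance <= max_distance_factor * maze_length
  n_dist <- sum(!keep_dist)
  trials <- trials[keep_dist, , drop = FALSE]

  if (nrow(trials) == 0) warning("no trials survive selection", call. = FALSE)
  counts <- c(warmup_or_easy = n_warm, low_perf_block = n_block,
              distance_or_end = n_dist, kept = nrow(trials), input = n0)
  if (inherits(x, "tower_cohort")) {
    x$trials <- trials
    attr(x, "selection_counts") <- counts
    x
  } else {
    attr(trials, "selection_counts") <- counts
    trials
  }
}

# Correctness against the realized tower counts: the correct side is the one
# with more towers; on exact ties the rewarded-side label governs.
trial_correct <- function(trials) {
  nr <- vapply(trials$towers_right, length, integer(1))
  nl <- vapply(trials$towers_left, length, integer(1))
  majority <- ifelse(nr > nl, "R", ifelse(nl > nr, "L", trials$rewarded_side))
  as.numeric(trials$choice == majority)
}

#' Overall performance
#'
#' Fraction of trials in which the animal turned to the side with the
#' higher tower count (judged against realized counts, not the rewarded
#' label; ties fall back to the rewarded side).
#'
#' @param x A cohort or trial table.
#' @return A single fraction in `[0, 1]`.
#' @export
percent_correct <- function(x) {
  trials <- as_trials(x)
  if (nrow(trials) == 0) stop("no trials", call. = FALSE)
  mean(trial_correct(trials))
}

#' Laser-induced change in overall performance
#'
#' Computes `delta = %correct(laser) - %correct(control)` with a bootstrap
#' SD and a one-sided p-value (fraction of bootstrap iterations with
#' delta > 0, i.e. testing that inactivation decreases performance).
#' Trials are resampled with replacement within each arm.
#'
#' @param x Cohort or trial table containing both arms.
#' @param n_boot Bootstrap iterations (default 10,000).
#' @param seed Optional integer seed.
#' @return A list with `delta`, `sd`, `p_value`, `n_laser`, `n_control`.
#' @export
performance_delta <- function(x, n_boot = 10000, seed = NULL) {
  trials <- as_trials(x)
  if (!any(trials$laser_on) || !any(!trials$laser_on)) {
    stop("need both laser and control trials", call. = FALSE)
  }
  if (n_boot < 100) warning("n_boot < 100: poor p resolution", call. = FALSE)
  correct <- trial_correct(trials)
  cl <- correct[trials$laser_on]
  cc <- correct[!trials$laser_on]
  delta <- mean(cl) - mean(cc)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      mean(cl[sample.int(length(cl), replace = TRUE)]) -
        mean(cc[sample.int(length(cc), replace = TRUE)])
    }, numeric(1))
    p <- mean(reps > 0)
    list(delta = delta, sd = stats::sd(reps),
         p_value = if (p == 0) 1 / n_boot else p,
         n_laser = length(cl), n_control = length(cc))
  })
}

trial_delta <- function(trials) {
  vapply(trials$towers_right, length, integer(1)) -
    vapply(trials$towers_left, length, integer(1))
}

#' Binned psychometric data
#'
#' Bins the net evidence Delta = #R - #L towers in increments of five
#' between -15 and 15 (six bins, half-open `[lo, hi)`; values outside the
#' range are dropped) and reports, per bin, the trial-weighted mean Delta,
#' the fraction of rightward choices, and a binomial confidence interval.
#'
#' @param x Cohort or trial table.
#' @param edges Bin edges (default `seq(-15, 15, 5)`).
#' @param ci `"clopper-pearson"` (exact, default) or `"normal"`.
#' @param level Confidence level.
#' @return A tibble with `delta_mean`, `p_right`, `ci_lo`, `ci_hi`, `n`.
#' @export
psychometric_curve <- function(x, edges = seq(-15, 15, 5),
                               ci = c("clopper-pearson", "normal"),
                               level = 0.95) {
  ci <- match.arg(ci)
  trials <- as_trials(x)
  delta <- trial_delta(trials)
  right <- trials$choice == "R"
  bin <- cut(delta, edges, right = FALSE, include.lowest = FALSE)
  ok <- !is.na(bin)
  rows <- lapply(levels(bin), function(b) {
    sel <- ok & bin == b
    n <- sum(sel)
    if (n == 0) return(NULL)
    k <- sum(right[sel])
    ci_b <- binom_ci(k, n, ci, level)
    tibble(delta_mean = mean(delta[sel]), p_right = k / n,
           ci_lo = ci_b[1], ci_hi = ci_b[2], n = n)
  })
  dplyr::bind_rows(rows)
}

binom_ci <- function(k, n, method, level) {
  if (method == "clopper-pearson") {
    as.numeric(stats::binom.test(k, n, conf.level = level)$conf.int)
  } else {
    p <- k / n
    z <- stats::qnorm(1 - (1 - level) / 2)
    se <- sqrt(p * (1 - p) / n)
    c(max(0, p - z * se), min(1, p + z * se))
  }
}

#' Fit a four-parameter psychometric sigmoid
#'
#' Least-squares fit of \eqn{p_R(\Delta) = b + a / (1 + e^{-(\Delta -
#' \Delta_0)/\lambda})} to binned psychometric points, weighted by the
#' number of trials per bin. An alternative trial-wise maximum-likelihood
#' fit is available via `method = "mle"`.
#'
#' @param points Output of [psychometric_curve()] (for `method = "ls"`), or
#'   a cohort/trial table (for `method = "mle"`).
#' @param method `"ls"` (default, fit to binned proportions) or `"mle"`.
#' @return A list of class `psychometric_fit` with `b`, `a`, `delta0`,
#'   `lambda`, `residuals` (ls only), `identifiable`, `converged`.
#' @export
fit_psychometric <- function(points, method = c("ls", "mle")) {
  method <- match.arg(method)
  if (method == "mle") {
    trials <- as_trials(points)
    delta <- trial_delta(trials)
    right <- as.numeric(trials$choice == "R")
    nll <- function(par) {
      p <- par[1] + par[2] / (1 + exp(-(delta - par[3]) / par[4]))
      p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
      -sum(right * log(p) + (1 - right) * log(1 - p))
    }
    opt <- stats::optim(c(b = 0.05, a = 0.9, delta0 = 0, lambda = 3), nll,
                        method = "L-BFGS-B",
                        lower = c(0, 0, -30, 1e-3), upper = c(1, 1, 30, 100))
    return(structure(
      list(b = opt$par[["b"]], a = opt$par[["a"]],
           delta0 = opt$par[["delta0"]], lambda = opt$par[["lambda"]],
           residuals = NULL, identifiable = stats::sd(right) > 0,
           converged = opt$convergence == 0),
      class = "psychometric_fit"
    ))
  }
  if (nrow(points) < 4) stop("need at least 4 non-empty bins", call. = FALSE)
  identifiable <- stats::sd(points$p_right) > 0
  if (!identifiable) {
    warning("degenerate bins (single choice throughout): fit not identifiable",
            call. = FALSE)
  }
  start <- list(b = max(1e-3, min(points$p_right)),
                a = max(0.1, diff(range(points$p_right))),
                delta0 = 0, lambda = 3)
  fit <- minpack.lm::nlsLM(
    p_right ~ b + a / (1 + exp(-(delta_mean - delta0) / lambda)),
    data = points, start = start, weights = points$n,
    lower = c(b = 0, a = 0, delta0 = -30, lambda = 1e-3),
    upper = c(b = 1, a = 1, delta0 = 30, lambda = 100),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- as.list(stats::coef(fit))
  structure(
    list(b = cf$b, a = cf$a, delta0 = cf$delta0, lambda = cf$lambda,
         residuals = stats::resid(fit), identifiable = identifiable,
         converged = fit$convInfo$isConv),
    class = "psychometric_fit"
  )
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf(
    "<psychometric_fit> b=%.3f a=%.3f delta0=%.3f lambda=%.3f%s\n",
    x$b, x$a, x$delta0, x$lambda,
    if (!x$identifiable) " (non-identifiable)" else ""))
  invisible(x)
}

# Per-trial net evidence (#R - #L) within each of four equal spatial
# segments spanning [min_y, cue_length].
spatial_bin_deltas <- function(trials, min_y = 10, cue_length = 200,
                               n_bins = 4) {
  edges <- seq(min_y, cue_length, length.out = n_bins + 1)
  count_bins <- function(pos) {
    # half-open [lo, hi): a value on an edge goes to the higher bin;
    # the final edge is included in the last bin
    idx <- findInterval(pos, edges, rightmost.closed = TRUE)
    tabulate(idx[idx >= 1 & idx <= n_bins], nbins = n_bins)
  }
  nr <- t(vapply(trials$towers_right, count_bins, numeric(n_bins)))
  nl <- t(vapply(trials$towers_left, count_bins, numeric(n_bins)))
  d <- nr - nl
  colnames(d) <- paste0("bin", seq_len(n_bins))
  d
}

#' Spatial evidence-weighting curve
#'
#' Logistic regression of choice on the net evidence from each of four
#' equally spaced cue-region segments (10-200 cm; towers cannot occur
#' before y = 10). Coefficient SDs come from bootstrap resampling of
#' trials; two-sided bootstrap p-values are reported per bin. If the fit
#' is completely separated, a lightly ridge-regularized fallback is used
#' and flagged.
#'
#' @param x Cohort or trial table.
#' @param n_boot Bootstrap iterations for the coefficient SD (default 200).
#' @param seed Optional integer seed.
#' @param min_y,cue_length Segment span (cm).
#' @return A list of class `spatial_weights`: `beta0`, `beta` (length 4),
#'   `boot_sd` (length 5, intercept first), `p_values` (length 4),
#'   `separation`.
#' @export
spatial_evidence_weights <- function(x, n_boot = 200, seed = NULL,
                                     min_y = 10, cue_length = 200) {
  trials <- as_trials(x)
  d <- spatial_bin_deltas(trials, min_y, cue_length)
  if (all(d == 0)) stop("no towers in any trial: evidence columns are zero",
                        call. = FALSE)
  y <- as.numeric(trials$choice == "R")
  fit <- fit_logistic_safe(d, y)
  with_seed(seed, {
    boots <- matrix(NA_real_, n_boot, ncol(d) + 1)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(d), replace = TRUE)
      boots[b, ] <- fit_logistic_safe(d[idx, , drop = FALSE], y[idx])$coef
    }
    pv <- vapply(seq_len(ncol(d)), function(j) {
      col <- boots[, j + 1]
      2 * min(mean(col > 0), mean(col < 0), 0.5)
    }, numeric(1))
    structure(
      list(beta0 = fit$coef[1], beta = fit$coef[-1],
           boot_sd = apply(boots, 2, stats::sd), p_values = pv,
           separation = fit$separation),
      class = "spatial_weights"
    )
  })
}

# Plain logistic MLE with a detected-separation ridge fallback.
fit_logistic_safe <- function(X, y) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  coefs <- fit$coefficients
  if (sep || any(abs(coefs[-1]) > 25)) {
    sep <- TRUE
    g <- glmnet::glmnet(cbind(X, 0), y, family = "binomial", alpha = 0,
                        lambda = 1e-3, standardize = FALSE)
    coefs <- c(as.numeric(g$a0),
               as.numeric(g$beta)[seq_len(ncol(X))])
  }
  list(coef = unname(coefs), separation = sep)
}

#' Laser-induced change in the spatial evidence-weighting curve
#'
#' Fits [spatial_evidence_weights()] separately to laser-on and laser-off
#' trials and subtracts on minus off per bin, so that negative values mean
#' smaller evidence weights under inactivation. Bootstrap SD and one-sided
#' p-values (fraction of iterations with delta > 0) per bin.
#'
#' @param trials_on,trials_off Trial tables for the two arms.
#' @param n_boot Bootstrap iterations (default 10,000).
#' @param seed Optional integer seed.
#' @return A tibble with `bin`, `delta`, `sd`, `p_value`.
#' @export
weight_curve_delta <- function(trials_on, trials_off, n_boot = 10000,
                               seed = NULL) {
  trials_on <- as_trials(trials_on); trials_off <- as_trials(trials_off)
  d_on <- spatial_bin_deltas(trials_on)
  d_off <- spatial_bin_deltas(trials_off)
  y_on <- as.numeric(trials_on$choice == "R")
  y_off <- as.numeric(trials_off$choice == "R")
  est <- fit_logistic_safe(d_on, y_on)$coef[-1] -
    fit_logistic_safe(d_off, y_off)$coef[-1]
  with_seed(seed, {
    reps <- matrix(NA_real_, n_boot, length(est))
    for (b in seq_len(n_boot)) {
      i_on <- sample.int(nrow(d_on), replace = TRUE)
      i_off <- sample.int(nrow(d_off), replace = TRUE)
      reps[b, ] <- fit_logistic_safe(d_on[i_on, , drop = FALSE], y_on[i_on])$coef[-1] -
        fit_logistic_safe(d_off[i_off, , drop = FALSE], y_off[i_off])$coef[-1]
    }
    p <- colMeans(reps > 0)
    tibble(bin = paste0("bin", seq_along(est)), delta = est,
           sd = apply(reps, 2, stats::sd),
           p_value = ifelse(p == 0, 1 / n_boot, p))
  })
}

#' Laser-induced change in running speed within a maze segment
#'
#' Speed per trial is displacement over duration within the segment
#' (computed from the trial's piecewise-linear kinematics). Reports the
#' percent change of laser versus control trials and a two-sided bootstrap
#' p-value (fraction of iterations whose sign differs from the empirical
#' mean change).
#'
#' @param x Cohort (needed for the task geometry) with both arms.
#' @param segment Length-2 y interval (cm).
#' @param n_boot Bootstrap iterations (default 10,000).
#' @param seed Optional integer seed.
#' @return A list with `pct_change`, `p_value`, `mean_on`, `mean_off`.
#' @export
speed_change <- function(x, segment, n_boot = 10000, seed = NULL) {
  if (!inherits(x, "tower_cohort")) {
    stop("speed_change needs a tower_cohort (for the task geometry)",
         call. = FALSE)
  }
  cfg <- x$config
  maze_end <- cfg$cue_length + cfg$delay_length
  if (segment[1] < -cfg$start_length || segment[2] > maze_end ||
      segment[1] >= segment[2]) {
    stop("segment outside the maze", call. = FALSE)
  }
  trials <- x$trials
  seg_speed <- vapply(seq_len(nrow(trials)), function(i) {
    traj <- trial_trajectory(trials[i, ], cfg)
    dt <- time_at_y(segment[2], traj) - time_at_y(segment[1], traj)
    (segment[2] - segment[1]) / dt
  }, numeric(1))
  on <- seg_speed[trials$laser_on]
  off <- seg_speed[!trials$laser_on]
  if (!length(on) || !length(off)) {
    stop("need both laser and control trials", call. = FALSE)
  }
  est <- 100 * (mean(on) / mean(off) - 1)
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      100 * (mean(on[sample.int(length(on), replace = TRUE)]) /
               mean(off[sample.int(length(off), replace = TRUE)]) - 1)
    }, numeric(1))
    p <- if (est == 0) 1 else mean(sign(reps) != sign(est))
    list(pct_change = est, p_value = if (p == 0) 1 / n_boot else p,
         mean_on = mean(on), mean_off = mean(off))
  })
}
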