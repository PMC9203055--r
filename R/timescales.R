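#' Exponential-decay fit to autoregressive coefficients
#'
#' Fits \eqn{B + A e^{-x/\tau}} by nonlinear least squares to the
#' autoregressive coefficients at lags 0.1-2 s, after normalizing them to
#' the coefficient at 0.1 s (the first lag). The decay constant tau is the
#' ROI's intrinsic timescale.
#'
#' @param ar_coeffs Autoregressive coefficients, ordered by lag.
#' @param lags Lag values in seconds (default `seq(0.1, 2, 0.1)`).
#' @param tau_init,tau_bounds Initializations (the best of several starts
#'   by residual sum of squares is kept) and box bounds for tau (s).
#' @return An object of class `exp_decay_fit`: `B`, `A`, `tau`,
#'   `r_squared`, `converged`, `identifiable`.
#' @examples
#' lags <- seq(0.1, 2, 0.1)
#' fit_exp_decay(exp(-lags / 0.5), lags)$tau
#' @export
fit_exp_decay <- function(ar_coeffs, lags = seq(0.1, 2, 0.1),
                          tau_init = c(0.1, 0.3, 1, 3),
                          tau_bounds = c(1e-3, 20)) {
  stopifnot(length(ar_coeffs) == length(lags))
  if (length(lags) < 5) stop("need at least 5 lags", call. = FALSE)
  if (abs(ar_coeffs[1]) < 1e-8) {
    stop("first-lag coefficient is ~0: cannot normalize", call. = FALSE)
  }
  yn <- ar_coeffs / ar_coeffs[1]
  if (stats::sd(yn) < 1e-10) {
    return(structure(
      list(B = mean(yn), A = 0, tau = NA_real_, r_squared = NA_real_,
           converged = FALSE, identifiable = FALSE),
      class = "exp_decay_fit"
    ))
  }
  resid_fn <- function(p) yn - (p[1] + p[2] * exp(-lags / p[3]))
  fits <- lapply(tau_init, function(t0) {
    minpack.lm::nls.lm(
      par = c(B = yn[length(yn)], A = yn[1] - yn[length(yn)], tau = t0),
      fn = resid_fn,
      lower = c(-Inf, -Inf, tau_bounds[1]),
      upper = c(Inf, Inf, tau_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                           ptol = 1e-15)
    )
  })
  sse <- vapply(fits, function(f) sum(resid_fn(f$par)^2), numeric(1))
  fit <- fits[[which.min(sse)]]
  p <- fit$par
  r2 <- 1 - sum(resid_fn(p)^2) / sum((yn - mean(yn))^2)
  structure(
    list(B = unname(p[1]), A = unname(p[2]), tau = unname(p[3]),
         r_squared = r2, converged = fit$info %in% 1:4,
         identifiable = TRUE),
    class = "exp_decay_fit"
  )
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  if (x$identifiable) {
    cat(sprintf("<exp_decay_fit> tau = %.3f s (B = %.3f, A = %.3f, R2 = %.3f)\n",
                x$tau, x$B, x$A, x$r_squared))
  } else {
    cat("<exp_decay_fit> non-identifiable (flat coefficients)\n")
  }
  invisible(x)
}

#' Estimate intrinsic timescales for a trace set
#'
#' Runs the full timescale pipeline per ROI: builds the encoding design,
#' fits the cross-validated ridge encoding model, extracts the
#' autoregressive coefficient profile over lags 0.1-2 s, and fits the
#' exponential decay.
#'
#' @param traces A trace set.
#' @param rois ROI labels (default: all).
#' @param lambda_grid,k,n_repeats,seed,lambda_rule Passed to
#'   [crossval_ridge()]; the penalty defaults to the one-SE rule toward the
#'   smallest penalty because shrinkage biases the lag-profile shape that
#'   the exponential fit reads out.
#' @return A tibble with `roi`, `area`, `hemisphere`, `tau`, `r_squared`,
#'   `accuracy`, `lambda`.
#' @export
estimate_timescales <- function(traces, rois = rownames(traces$dff),
                                lambda_grid = default_lambda_grid(),
                                k = 3, n_repeats = 10, seed = NULL,
                                lambda_rule = "min_1se") {
  rows <- lapply(rois, function(roi) {
    des <- build_encoding_design(traces, roi)
    fit <- crossval_ridge(des, lambda_grid, k, n_repeats, seed = seed,
                          lambda_rule = lambda_rule)
    ar <- fit$coefficients[des$groups$A]
    ed <- fit_exp_decay(unname(ar), lags = des$ar_lags)
    tibble(roi = roi, area = sub("_[LR]$", "", roi),
           hemisphere = sub("^.*_", "", roi),
           tau = ed$tau, r_squared = ed$r_squared,
           accuracy = fit$accuracy, lambda = fit$lambda)
  })
  dplyr::bind_rows(rows)
}

#' Summarize timescales across sessions, hemispheres, and mice
#'
#' Averages tau over hemispheres within each mouse-session-area cell, then
#' over sessions within each mouse, reports per-area medians and IQRs of
#' the mouse-level values, and (with at least 2 mice and a complete
#' design) a one-way repeated-measures ANOVA with area as the factor.
#' Mice missing an area are dropped from the ANOVA with a warning; with a
#' single mouse the ANOVA is skipped.
#'
#' @param fits Tibble with columns `mouse`, `session`, `hemisphere`,
#'   `area`, `tau` (e.g. stacked [estimate_timescales()] outputs with
#'   `mouse`/`session` added).
#' @return A list with `per_mouse` (mouse x area tau), `summary`
#'   (per-area median and IQR), `anova` (or `NULL`).
#' @export
timescale_summary <- function(fits) {
  stopifnot(all(c("mouse", "session", "hemisphere", "area", "tau") %in%
                  names(fits)))
  per_ms <- dplyr::summarise(
    dplyr::group_by(fits, .data$mouse, .data$session, .data$area),
    tau = mean(.data$tau, na.rm = TRUE), .groups = "drop"
  )
  per_mouse <- dplyr::summarise(
    dplyr::group_by(per_ms, .data$mouse, .data$area),
    tau = mean(.data$tau, na.rm = TRUE), .groups = "drop"
  )
  smry <- dplyr::summarise(
    dplyr::group_by(per_mouse, .data$area),
    tau_median = stats::median(.data$tau),
    tau_iqr = stats::IQR(.data$tau),
    n_mice = dplyr::n(), .groups = "drop"
  )
  anova <- NULL
  mice <- unique(per_mouse$mouse)
  if (length(mice) >= 2 && length(unique(per_mouse$area)) >= 2) {
    n_area <- length(unique(per_mouse$area))
    counts <- table(per_mouse$mouse)
    complete <- names(counts)[counts == n_area]
    dropped <- setdiff(mice, complete)
    if (length(dropped)) {
      warning("dropped from ANOVA (missing areas): ",
              paste(dropped, collapse = ", "), call. = FALSE)
    }
    if (length(complete) >= 2) {
      anova <- rm_anova(per_mouse[per_mouse$mouse %in% complete, ],
                        dv = "tau", subject = "mouse", within = "area")
    }
  }
  list(per_mouse = per_mouse, summary = smry, anova = anova)
}
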