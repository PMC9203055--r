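#' Assign dummy laser windows to control trials
#'
#' Control trials get laser onset/offset times defined as the times at
#' which their own trajectory crossed the y positions where the laser was
#' on in the nearest inactivation trial of the same session (nearest by
#' trial-index distance; ties go to the earlier trial). The nearest laser
#' trial's epoch and area-set labels are copied so control trials carry the
#' grouping labels the mixed model needs. Control trials that never cross
#' the dummy offset position are flagged (`dummy_ok = FALSE`) and excluded
#' by the design builder.
#'
#' @param x A `tower_cohort` or trial table with at least one laser trial
#'   per session.
#' @return The input with `laser_onset_time`, `laser_offset_time`,
#'   `laser_onset_y`, `laser_offset_y`, `epoch`, `area_set` filled on
#'   control trials, plus a `dummy_ok` column.
#' @export
assign_dummy_laser_windows <- function(x) {
  cohort <- inherits(x, "tower_cohort")
  trials <- as_trials(x)
  cfg <- if (cohort) x$config else task_config()
  if (!any(trials$laser_on)) stop("no laser trials in the data", call. = FALSE)
  trials$dummy_ok <- TRUE

  key <- paste(trials$mouse_id, trials$session_id)
  for (k in unique(key)) {
    idx <- which(key == k)
    las <- idx[trials$laser_on[idx]]
    if (!length(las)) {
      stop(sprintf("session '%s' has no laser trials", k), call. = FALSE)
    }
    ctrl <- idx[!trials$laser_on[idx]]
    for (i in ctrl) {
      d <- abs(trials$trial_index[las] - trials$trial_index[i])
      cand <- las[d == min(d)]
      src <- cand[which.min(trials$trial_index[cand])]
      on_y <- trials$laser_onset_y[src]
      off_y <- trials$laser_offset_y[src]
      traj <- trial_trajectory(trials[i, ], cfg)
      max_y <- trials$traveled_distance[i] - cfg$start_length
      if (!trials$reached_end[i] && off_y > max_y) {
        trials$dummy_ok[i] <- FALSE
        next
      }
      trials$laser_onset_y[i] <- on_y
      trials$laser_offset_y[i] <- off_y
      trials$laser_onset_time[i] <- time_at_y(on_y, traj)
      trials$laser_offset_time[i] <- time_at_y(off_y, traj)
      trials$epoch[i] <- trials$epoch[src]
      trials$area_set[i] <- trials$area_set[src]
    }
  }
  n_bad <- sum(!trials$dummy_ok)
  if (n_bad) {
    warning(sprintf("%d control trial(s) never cross the dummy laser window; flagged",
                    n_bad), call. = FALSE)
  }
  if (cohort) { x$trials <- trials; x } else trials
}

#' Build the laser-aligned, time-binned evidence design
#'
#' For every trial, towers are assigned to laser-aligned windows: three
#' 0.5 s bins before laser onset (`pre1` nearest the onset), the whole
#' laser interval (`during`), and two 0.5 s bins after offset. The net
#' evidence Delta = #R - #L towers per window is then partitioned into
#' control columns (nonzero only on control trials) and laser columns
#' (nonzero only on laser trials), each z-scored over the trials of its own
#' arm; structural zeros are untouched, so laser-partition columns are
#' exactly 0 on control trials. All-zero (degenerate) columns are dropped
#' and recorded. Towers outside all windows contribute to no column.
#'
#' @param x Cohort or trial table with laser windows on every trial (run
#'   [assign_dummy_laser_windows()] first).
#' @param bin_s Bin width (s).
#' @param n_pre,n_post Number of pre/post bins.
#' @return An object of class `evidence_design`: list with `data` (tibble:
#'   `choice` 0/1 with 1 = right, `mouse_id`, `epoch`, `int_C`, `int_L`,
#'   evidence columns `dC_*`/`dL_*`), `bins` (chronological labels),
#'   `cols_control`, `cols_laser`, `dropped`, `zstats`, and the binning
#'   parameters.
#' @export
build_time_binned_design <- function(x, bin_s = 0.5, n_pre = 3, n_post = 2) {
  trials <- as_trials(x)
  if ("dummy_ok" %in% names(trials)) {
    trials <- trials[trials$dummy_ok, , drop = FALSE]
  }
  if (anyNA(trials$laser_onset_time) || anyNA(trials$laser_offset_time)) {
    stop("all trials need (dummy) laser windows; run assign_dummy_laser_windows()",
         call. = FALSE)
  }
  if (any(trials$laser_offset_time <= trials$laser_onset_time)) {
    stop("laser offset must be after onset", call. = FALSE)
  }
  wins <- c(paste0("pre", rev(seq_len(n_pre))), "during",
            paste0("post", seq_len(n_post)))  # chronological
  raw <- matrix(0, nrow(trials), length(wins), dimnames = list(NULL, wins))
  for (i in seq_len(nrow(trials))) {
    on <- trials$laser_onset_time[i]; off <- trials$laser_offset_time[i]
    for (side in c(1, -1)) {
      tt <- if (side == 1) trials$tower_times_right[[i]] else trials$tower_times_left[[i]]
      if (!length(tt)) next
      w <- window_of_time(tt, on, off, bin_s, n_pre, n_post)
      for (lab in unique(w[!is.na(w)])) {
        raw[i, lab] <- raw[i, lab] + side * sum(w == lab, na.rm = TRUE)
      }
    }
  }
  laser <- trials$laser_on
  zstats <- list(); dropped <- character(0)
  cols <- list()
  for (part in c("C", "L")) {
    arm <- if (part == "C") !laser else laser
    for (win in wins) {
      nm <- paste0("d", part, "_", win)
      v <- numeric(nrow(trials))
      mu <- mean(raw[arm, win]); s <- stats::sd(raw[arm, win])
      if (!sum(arm) || is.na(s) || s == 0) {
        dropped <- c(dropped, nm)
        next
      }
      v[arm] <- (raw[arm, win] - mu) / s
      zstats[[nm]] <- c(mean = mu, sd = s)
      cols[[nm]] <- v
    }
  }
  dat <- tibble(
    choice = as.numeric(trials$choice == "R"),
    mouse_id = factor(trials$mouse_id),
    epoch = factor(trials$epoch),
    int_C = as.numeric(!laser),
    int_L = as.numeric(laser)
  )
  for (nm in names(cols)) dat[[nm]] <- cols[[nm]]
  structure(
    list(data = dat, bins = wins,
         cols_control = grep("^dC_", names(cols), value = TRUE),
         cols_laser = grep("^dL_", names(cols), value = TRUE),
         dropped = dropped, zstats = zstats,
         bin_s = bin_s, n_pre = n_pre, n_post = n_post,
         raw = raw, laser = laser),
    class = "evidence_design"
  )
}

#' @export
print.evidence_design <- function(x, ...) {
  cat(sprintf("<evidence_design> %d trials (%d laser), bins: %s\n",
              nrow(x$data), sum(x$laser), paste(x$bins, collapse = " ")))
  if (length(x$dropped)) {
    cat("  dropped (degenerate):", paste(x$dropped, collapse = " "), "\n")
  }
  invisible(x)
}

#' Fit the mixed-effects logistic model of choice
#'
#' Maximum-likelihood logistic regression of choice on the partitioned,
#' laser-aligned evidence columns, with fixed-effect bias terms for control
#' and laser trials and random effects: a random intercept per inactivation
#' epoch, random control and laser intercepts per mouse, and (with
#' `random = "full"`) a random slope per mouse for every evidence column.
#' Random-effect variances are independent (diagonal covariance). Fitting
#' uses [lme4::glmer()]; `nAGQ = 0` (the default) estimates via the fast
#' penalized-likelihood step only, which is robust with many variance
#' components, while `nAGQ = 1` uses the full Laplace approximation.
#'
#' @param design An [build_time_binned_design()] object.
#' @param random `"full"` (intercepts + per-mouse slopes), `"intercepts"`,
#'   or `"none"` (plain logistic MLE via [stats::glm()]).
#' @param nAGQ Passed to [lme4::glmer()].
#' @return An object of class `glmm_fit`: `coefficients` (tibble with
#'   `term`, `partition`, `bin`, `estimate`, `se`), `vcov` (fixed effects),
#'   `varcorr`, `logLik`, `converged`, `model`, `design_meta`, `accuracy`.
#' @export
fit_mixed_logistic <- function(design, random = c("full", "intercepts", "none"),
                               nAGQ = 0) {
  random <- match.arg(random)
  dat <- design$data
  if (nlevels(droplevels(dat$mouse_id)) < 2 && random != "none") {
    stop("need at least 2 mice for a mixed model", call. = FALSE)
  }
  ev <- c(design$cols_control, design$cols_laser)
  if (!length(ev)) stop("design is degenerate: no evidence columns", call. = FALSE)
  fixed <- paste(c("0", "int_C", "int_L", ev), collapse = " + ")

  if (random == "none") {
    fml <- stats::as.formula(paste("choice ~", fixed))
    m <- stats::glm(fml, data = dat, family = stats::binomial())
    check_separation(stats::fitted(m), ev, stats::coef(m))
    V <- stats::vcov(m)
    est <- stats::coef(m)
    conv <- m$converged
    vc <- NULL
    ll <- as.numeric(stats::logLik(m))
  } else {
    re <- c(if (nlevels(droplevels(dat$epoch)) > 1) "(1 | epoch)",
            "(0 + int_C | mouse_id)", "(0 + int_L | mouse_id)")
    if (random == "full") {
      re <- c(re, sprintf("(0 + %s | mouse_id)", ev))
    }
    fml <- stats::as.formula(paste("choice ~", fixed, "+",
                                   paste(re, collapse = " + ")))
    m <- lme4::glmer(
      fml, data = dat, family = stats::binomial(), nAGQ = nAGQ,
      control = lme4::glmerControl(optimizer = "bobyqa",
                                   calc.derivs = FALSE,
                                   check.conv.singular = "ignore")
    )
    check_separation(stats::fitted(m), ev, lme4::fixef(m))
    V <- as.matrix(stats::vcov(m))
    est <- lme4::fixef(m)
    msgs <- m@optinfo$conv$lme4$messages
    conv <- is.null(msgs) || !any(grepl("failed to converge", msgs))
    if (!conv) warning("mixed model did not converge; result flagged",
                       call. = FALSE)
    vc <- lme4::VarCorr(m)
    ll <- as.numeric(stats::logLik(m))
  }
  se <- sqrt(diag(V))
  terms <- names(est)
  part <- ifelse(terms %in% c("int_C", "int_L"), "intercept",
                 ifelse(grepl("^dC_", terms), "control", "laser"))
  bin <- ifelse(part == "intercept", NA_character_,
                sub("^d[CL]_", "", terms))
  structure(
    list(coefficients = tibble(term = terms, partition = part, bin = bin,
                               estimate = unname(est), se = unname(se)),
         vcov = V, varcorr = vc, logLik = ll, converged = conv, model = m,
         design_meta = list(bins = design$bins, dropped = design$dropped,
                            random = random),
         accuracy = NA_real_),
    class = "glmm_fit"
  )
}

check_separation <- function(fitted_p, ev_cols, coefs) {
  eps <- 1e-8
  if (all(fitted_p < eps | fitted_p > 1 - eps)) {
    big <- names(coefs)[abs(coefs) > 15]
    stop("complete separation detected; offending columns: ",
         paste(intersect(big, ev_cols), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> %s random effects, logLik %.1f%s\n",
              x$design_meta$random, x$logLik,
              if (!x$converged) " (NOT converged)" else ""))
  print(x$coefficients, n = nrow(x$coefficients))
  invisible(x)
}

#' Cross-validated mixed-model fitting
#'
#' Fits the mixed logistic model on k train/test splits stratified by
#' mouse and laser condition, predicts held-out choices using the fixed
#' effects plus the training-estimated random effects of each trial's
#' mouse and epoch, and returns the fit with the highest held-out choice
#' prediction accuracy along with the full accuracy distribution.
#' Predicted choice is right when P(right) >= 0.5 (ties to right).
#'
#' @param design An `evidence_design`.
#' @param k Number of folds (default 10).
#' @param seed Optional integer seed for the fold assignment.
#' @param ... Passed to [fit_mixed_logistic()].
#' @return A list with `best_fit` (a `glmm_fit`, `accuracy` filled in),
#'   `accuracy` (per-fold vector), and `folds`.
#' @export
crossval_glmm <- function(design, k = 10, seed = NULL, ...) {
  dat <- design$data
  n <- nrow(dat)
  strata <- interaction(dat$mouse_id, dat$int_L, drop = TRUE)
  folds <- with_seed(seed, {
    f <- integer(n)
    for (s in levels(strata)) {
      idx <- sample(which(strata == s))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  accs <- numeric(k)
  fits <- vector("list", k)
  for (fold in seq_len(k)) {
    train <- design; test_rows <- folds == fold
    train$data <- dat[!test_rows, , drop = FALSE]
    miss <- setdiff(unique(as.character(dat$mouse_id[test_rows])),
                    unique(as.character(train$data$mouse_id)))
    if (length(miss)) {
      stop("stratification error: mouse ", paste(miss, collapse = ", "),
           " missing from a training fold", call. = FALSE)
    }
    fit <- fit_mixed_logistic(train, ...)
    p <- predict_choice_prob(fit, dat[test_rows, , drop = FALSE])
    pred <- as.numeric(p >= 0.5)
    accs[fold] <- mean(pred == dat$choice[test_rows])
    fits[[fold]] <- fit
  }
  best <- which.max(accs)
  out <- fits[[best]]
  out$accuracy <- accs[best]
  list(best_fit = out, accuracy = accs, folds = folds)
}

predict_choice_prob <- function(fit, newdata) {
  if (inherits(fit$model, "glm")) {
    stats::predict(fit$model, newdata = newdata, type = "response")
  } else {
    stats::predict(fit$model, newdata = newdata, type = "response",
                   allow.new.levels = TRUE)
  }
}

#' Normalized laser-induced change in evidence weights
#'
#' For each time bin retained in both partitions, computes
#' \eqn{(E^L - E^C) / E^C}: 0 means no difference from control, and -1
#' means complete loss of that bin's evidence weight on the decision.
#' Standard errors come from the delta method using the fixed-effect
#' covariance. Bins whose control coefficient is within `eps` of zero are
#' flagged undefined rather than reported as numbers.
#'
#' @param fit A `glmm_fit` (or [glmm_fit_manual()] object).
#' @param eps Guard for near-zero control coefficients (z-scored units).
#' @return A tibble of class `normalized_weights` with `bin`, `value`,
#'   `se`, `control`, `laser`, `defined`, ordered chronologically.
#' @export
normalized_weights <- function(fit, eps = 1e-3) {
  cf <- fit$coefficients
  bins <- fit$design_meta$bins
  rows <- lapply(bins, function(b) {
    tc <- paste0("dC_", b); tl <- paste0("dL_", b)
    if (!(tc %in% cf$term) || !(tl %in% cf$term)) return(NULL)
    C <- cf$estimate[cf$term == tc]; L <- cf$estimate[cf$term == tl]
    vC <- fit$vcov[tc, tc]; vL <- fit$vcov[tl, tl]
    cLC <- fit$vcov[tl, tc]
    if (abs(C) < eps) {
      return(tibble(bin = b, value = NA_real_, se = NA_real_,
                    control = C, laser = L, defined = FALSE))
    }
    val <- (L - C) / C
    v <- vL / C^2 + (L^2 / C^4) * vC - 2 * (L / C^3) * cLC
    tibble(bin = b, value = val, se = sqrt(max(v, 0)),
           control = C, laser = L, defined = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("normalized_weights", class(out))
  out
}

#' Construct a minimal model-fit object from known coefficients
#'
#' Builds a `glmm_fit`-compatible object directly from per-bin control and
#' laser evidence coefficients and their standard errors (independent
#' errors assumed). Useful for composing results computed elsewhere and
#' for worked examples.
#'
#' @param control,laser Named numeric vectors of per-bin coefficients
#'   (names are bin labels, e.g. `"during"`).
#' @param se_control,se_laser Standard errors (same names).
#' @return A `glmm_fit` object (no model component).
#' @examples
#' f <- glmm_fit_manual(control = c(during = 0.8), laser = c(during = 0.8))
#' normalized_weights(f)$value
#' @export
glmm_fit_manual <- function(control, laser,
                            se_control = setNames(rep(0.1, length(control)),
                                                  names(control)),
                            se_laser = setNames(rep(0.1, length(laser)),
                                                names(laser))) {
  stopifnot(!is.null(names(control)), identical(names(control), names(laser)))
  bins <- names(control)
  terms <- c(paste0("dC_", bins), paste0("dL_", bins))
  est <- c(control, laser)
  se <- c(se_control, se_laser)
  V <- diag(se^2, nrow = length(se))
  dimnames(V) <- list(terms, terms)
  structure(
    list(coefficients = tibble(
           term = terms,
           partition = rep(c("control", "laser"), each = length(bins)),
           bin = rep(bins, 2), estimate = unname(est), se = unname(se)),
         vcov = V, varcorr = NULL, logLik = NA_real_, converged = TRUE,
         model = NULL,
         design_meta = list(bins = bins, dropped = character(0),
                            random = "manual"),
         accuracy = NA_real_),
    class = "glmm_fit"
  )
}

#' Shuffle null distribution of normalized weights
#'
#' Permutes the laser-on labels within mouse-by-epoch strata (keeping
#' per-stratum laser-trial counts exact), re-runs the design construction
#' and model fit for each shuffle, and summarizes the per-bin normalized
#' weights of the shuffled models by their mean and SD. This is the
#' empirical null band used by [coefficient_significance()].
#'
#' @param x Cohort or trial table with laser windows assigned on all trials.
#' @param n_shuffle Number of label shuffles (default 30).
#' @param seed Optional integer seed.
#' @param bin_s,n_pre,n_post Passed to [build_time_binned_design()].
#' @param ... Passed to [fit_mixed_logistic()].
#' @return A tibble of class `shuffle_null` with `bin`, `null_mean`,
#'   `null_sd`, plus attribute `values` (shuffle x bin matrix).
#' @export
shuffle_null <- function(x, n_shuffle = 30, seed = NULL,
                         bin_s = 0.5, n_pre = 3, n_post = 2, ...) {
  if (n_shuffle < 1) stop("need at least 1 shuffle", call. = FALSE)
  trials <- as_trials(x)
  if ("dummy_ok" %in% names(trials)) trials <- trials[trials$dummy_ok, ]
  strata <- paste(trials$mouse_id, trials$epoch)
  vals <- NULL
  with_seed(seed, {
    for (s in seq_len(n_shuffle)) {
      sh <- trials
      for (st in unique(strata)) {
        idx <- which(strata == st)
        if (length(idx) < 2) {
          warning(sprintf("stratum '%s' has < 2 trials; left unshuffled", st),
                  call. = FALSE)
          next
        }
        sh$laser_on[idx] <- sample(sh$laser_on[idx])
      }
      des <- build_time_binned_design(sh, bin_s, n_pre, n_post)
      fit <- fit_mixed_logistic(des, ...)
      nw <- normalized_weights(fit)
      v <- setNames(nw$value, nw$bin)
      vals <- dplyr::bind_rows(vals, as_tibble(as.list(v)))
    }
  })
  out <- tibble(
    bin = names(vals),
    null_mean = vapply(vals, mean, numeric(1), na.rm = TRUE),
    null_sd = vapply(vals, stats::sd, numeric(1), na.rm = TRUE)
  )
  attr(out, "values") <- as.matrix(vals)
  attr(out, "n_shuffle") <- n_shuffle
  class(out) <- c("shuffle_null", class(out))
  out
}

#' Two-condition significance rule for normalized weights
#'
#' A bin is significant only if (i) its FDR-corrected two-sided t-test
#' p-value (coefficient estimate against zero, using its SE) is below
#' `alpha`, and (ii) the interval estimate +/- SE is disjoint from the
#' shuffle-null band mean +/- SD. Without a null band only the t-test rule
#' applies and the result is flagged `ttest_only`.
#'
#' @param weights A [normalized_weights()] tibble.
#' @param null Optional [shuffle_null()] tibble for the same bins.
#' @param alpha Significance level for the FDR-corrected t-test.
#' @param fdr_method Passed to [fdr_correct()].
#' @return The weights tibble with `p_value`, `fdr_significant`,
#'   `outside_null_band`, `significant` columns; attribute `ttest_only`.
#' @export
coefficient_significance <- function(weights, null = NULL, alpha = 0.05,
                                     fdr_method = "literal") {
  w <- weights
  w$p_value <- ifelse(w$defined, 2 * stats::pnorm(-abs(w$value / w$se)), NA)
  ok <- !is.na(w$p_value)
  w$fdr_significant <- FALSE
  w$fdr_significant[ok] <- fdr_correct(w$p_value[ok], alpha, fdr_method)
  ttest_only <- is.null(null)
  if (ttest_only) {
    warning("no shuffle-null band supplied; t-test-only result", call. = FALSE)
    w$outside_null_band <- NA
    w$significant <- w$fdr_significant
  } else {
    nb <- null[match(w$bin, null$bin), ]
    lo_w <- w$value - w$se; hi_w <- w$value + w$se
    lo_n <- nb$null_mean - nb$null_sd; hi_n <- nb$null_mean + nb$null_sd
    w$outside_null_band <- w$defined & (hi_w < lo_n | lo_w > hi_n)
    w$outside_null_band[is.na(nb$null_mean)] <- NA
    w$significant <- w$fdr_significant & w$outside_null_band %in% TRUE
  }
  attr(w, "ttest_only") <- ttest_only
  w
}

#' z-test comparison of per-bin coefficients from two models
#'
#' Computes, per bin, \eqn{z = |\beta_1 - \beta_2| /
#' \sqrt{(\beta_1 SEM_1)^2 + (\beta_2 SEM_2)^2}} with a two-sided normal
#' p-value, FDR-corrected across bins. Bins where both coefficients are
#' zero have an undefined z and are flagged.
#'
#' @param w1,w2 [normalized_weights()] tibbles (or any tibbles with `bin`,
#'   `value`, `se`) sharing the same bins.
#' @param alpha FDR significance level (default 0.025, two-sided).
#' @param fdr_method Passed to [fdr_correct()].
#' @return A tibble with `bin`, `z`, `p_value`, `significant`, `defined`.
#' @export
compare_models_z <- function(w1, w2, alpha = 0.025, fdr_method = "literal") {
  if (!identical(w1$bin, w2$bin)) stop("mismatched bins", call. = FALSE)
  denom <- sqrt((w1$value * w1$se)^2 + (w2$value * w2$se)^2)
  defined <- denom > 0 & !is.na(denom)
  z <- ifelse(defined, abs(w1$value - w2$value) / denom, NA_real_)
  p <- 2 * stats::pnorm(-z)
  sig <- rep(NA, length(z))
  sig[defined] <- fdr_correct(p[defined], alpha, fdr_method)
  tibble(bin = w1$bin, z = z, p_value = p, significant = sig,
         defined = defined)
}

#' Even-combination test for multi-area inactivations
#'
#' Tests whether the effect of inactivating several areas together equals
#' an even combination (the average) of the single-area effects: the
#' prediction per bin is the mean of the single-area normalized weights,
#' with SE \eqn{\sqrt{\sum SE_i^2} / k}, compared to the combined-area fit
#' via [compare_models_z()].
#'
#' @param single_fits List of [normalized_weights()] tibbles (single areas).
#' @param combined_fit [normalized_weights()] tibble for the combined set.
#' @param ... Passed to [compare_models_z()].
#' @return A list with `prediction` (tibble) and `comparison` (z-test).
#' @export
even_combination_test <- function(single_fits, combined_fit, ...) {
  bins <- combined_fit$bin
  for (f in single_fits) {
    if (!identical(f$bin, bins)) stop("mismatched bins", call. = FALSE)
  }
  k <- length(single_fits)
  vals <- sapply(single_fits, function(f) f$value)
  ses <- sapply(single_fits, function(f) f$se)
  if (k == 1) { vals <- cbind(vals); ses <- cbind(ses) }
  pred <- tibble(
    bin = bins,
    value = rowMeans(vals),
    se = sqrt(rowSums(ses^2)) / k
  )
  list(prediction = pred,
       comparison = compare_models_z(pred, combined_fit, ...))
}

#' Area-group comparison of normalized weights
#'
#' Two-way repeated-measures comparison of normalized weights between area
#' groups (e.g. posterior vs frontal), with time bins as the within-subject
#' factor and area group as the between-subject factor; areas are the
#' subjects.
#'
#' @param table Tibble with columns `area`, `group`, `bin`, `value`; one
#'   row per area x bin, balanced over bins.
#' @return The [rm_anova()] effect table.
#' @export
area_group_comparison <- function(table) {
  per_group <- table(unique(table[c("area", "group")])$group)
  if (any(per_group < 2)) {
    stop("need at least 2 areas per group (no within-group df otherwise)",
         call. = FALSE)
  }
  rm_anova(table, dv = "value", subject = "area", within = "bin",
           between = "group")
}
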