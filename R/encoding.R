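#' Divisively corrected fractional fluorescence
#'
#' Computes \eqn{\Delta F/F = R_b / R_v - 1} with \eqn{R_x = F_x / F_0},
#' where each channel's baseline F0 is the histogram mode of F over a
#' centered sliding window (default 30 s, single-frame steps, 100 bins).
#' Any artifact multiplicative in both channels cancels exactly when the
#' baseline tracking is exact.
#'
#' @param F_blue,F_violet Fluorescence vectors (same length).
#' @param window_s Sliding-window length (s); must be shorter than the
#'   recording.
#' @param dt Sample spacing (s).
#' @param n_bins Histogram bins for the mode estimator.
#' @return Numeric vector of corrected dF/F.
#' @export
compute_dff <- function(F_blue, F_violet, window_s = 30, dt = 0.1,
                        n_bins = 100) {
  stopifnot(length(F_blue) == length(F_violet))
  n <- length(F_blue)
  w <- round(window_s / dt)
  if (w >= n) stop("window longer than the recording", call. = FALSE)
  f0_b <- sliding_mode(F_blue, w, n_bins)
  f0_v <- sliding_mode(F_violet, w, n_bins)
  if (any(f0_b <= 0) || any(f0_v <= 0)) {
    stop("zero or negative baseline F0", call. = FALSE)
  }
  (F_blue / f0_b) / (F_violet / f0_v) - 1
}

# Centered sliding-window histogram mode, single-frame steps.
sliding_mode <- function(v, w, n_bins) {
  n <- length(v)
  half <- w %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    window <- v[lo:hi]
    rng <- range(window)
    if (rng[1] == rng[2]) return(rng[1])
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    counts <- tabulate(findInterval(window, edges, rightmost.closed = TRUE),
                       nbins = n_bins)
    k <- which.max(counts)
    (edges[k] + edges[k + 1]) / 2
  }, numeric(1))
}

# Shift a vector by `lag` samples into the past (positive lag) or future
# (negative lag), padding with NA.
shift_lag <- function(v, lag) {
  n <- length(v)
  if (lag == 0) return(v)
  out <- rep(NA_real_, n)
  if (lag > 0) out[(lag + 1):n] <- v[seq_len(n - lag)]
  else out[seq_len(n + lag)] <- v[(1 - lag):n]
  out
}

#' Build the encoding-model design matrix for one ROI
#'
#' Predictor groups: `A`, the ROI's own activity at lags 0.1-2.0 s in the
#' past (20 columns); `C`, the zero-lag activity of the 15 other ROIs; and
#' `T`, the task terms: right/left tower events and cumulative net evidence
#' at lags 0-2 s (21 columns each), view angle, its derivative, and running
#' speed at lags -0.3 to +0.3 s (7 columns each), position y (no lag), and
#' the per-trial constants ch/pch/prw. Rows whose lag window crosses a
#' trial boundary are masked (the first 2 s and last 0.3 s of every trial).
#'
#' @param traces A [generate_roi_traces()] trace set (or compatible list).
#' @param roi_index Index (or label) of the modeled ROI.
#' @return An object of class `encoding_design`: `X` (matrix), `y`
#'   (z-scored response), `groups` (column names per group), `trial`
#'   (trial id per row), `roi_index`, `ar_lags` (s).
#' @export
build_encoding_design <- function(traces, roi_index) {
  dff <- traces$dff
  if (is.character(roi_index)) roi_index <- match(roi_index, rownames(dff))
  if (is.na(roi_index) || roi_index < 1 || roi_index > nrow(dff)) {
    stop("ROI index out of range", call. = FALSE)
  }
  dt <- diff(traces$time[1:2])
  n <- ncol(dff)
  beh <- traces$behavior
  if (nrow(beh) != n) stop("behavior channels misaligned with traces",
                           call. = FALSE)
  y <- as.numeric(dff[roi_index, ])
  ar_lags <- 1:20
  beh_lags <- -3:3
  ev_lags <- 0:20

  cols <- list(); grp <- list(A = character(0), C = character(0),
                              T = character(0))
  for (l in ar_lags) {
    nm <- sprintf("ar_%02d", l)
    cols[[nm]] <- shift_lag(y, l); grp$A <- c(grp$A, nm)
  }
  others <- setdiff(seq_len(nrow(dff)), roi_index)
  for (j in others) {
    nm <- paste0("coup_", rownames(dff)[j])
    cols[[nm]] <- as.numeric(dff[j, ]); grp$C <- c(grp$C, nm)
  }
  for (ch in c("tower_R", "tower_L", "cum_delta")) {
    for (l in ev_lags) {
      nm <- sprintf("%s_%02d", ch, l)
      cols[[nm]] <- shift_lag(beh[[ch]], l); grp$T <- c(grp$T, nm)
    }
  }
  for (ch in c("theta", "dtheta", "speed")) {
    for (l in beh_lags) {
      nm <- sprintf("%s_%+d", ch, l)
      cols[[nm]] <- shift_lag(beh[[ch]], l); grp$T <- c(grp$T, nm)
    }
  }
  for (ch in c("y", "ch", "pch", "prw")) {
    cols[[ch]] <- beh[[ch]]; grp$T <- c(grp$T, ch)
  }
  X <- do.call(cbind, cols)

  tb <- traces$trial_bounds
  trial_of <- integer(n)
  for (i in seq_len(nrow(tb))) trial_of[tb$start[i]:tb$end[i]] <- tb$trial[i]
  idx <- seq_len(n)
  start_of <- tb$start[match(trial_of, tb$trial)]
  end_of <- tb$end[match(trial_of, tb$trial)]
  valid <- trial_of > 0 &
    (idx - max(ar_lags, ev_lags)) >= start_of &
    (idx + max(beh_lags)) <= end_of
  X <- X[valid, , drop = FALSE]
  structure(
    list(X = X, y = y[valid], groups = grp, trial = trial_of[valid],
         roi_index = roi_index, ar_lags = ar_lags * dt, dt = dt),
    class = "encoding_design"
  )
}

#' Ridge regression (closed form)
#'
#' Penalized least squares \eqn{\hat\beta = (X'X + \lambda I)^{-1} X'y}.
#' With `standardize = TRUE` predictors are standardized internally and
#' coefficients returned on the input scale; the intercept is never
#' penalized. At `lambda = 0` this is ordinary least squares and a
#' singular system is an error.
#'
#' @param X Predictor matrix.
#' @param y Response.
#' @param lambda Ridge penalty (>= 0).
#' @param intercept Include an (unpenalized) intercept?
#' @param standardize Standardize predictors before penalization?
#' @return Named coefficient vector (with `"(Intercept)"` first if
#'   requested).
#' @examples
#' fit_ridge(matrix(c(1, 2)), c(1, 2), lambda = 1,
#'           intercept = FALSE, standardize = FALSE)  # 5/6
#' @export
fit_ridge <- function(X, y, lambda, intercept = TRUE, standardize = TRUE) {
  X <- as.matrix(X)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (standardize) {
    mu <- colMeans(X); s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, s, "/")
  } else {
    mu <- rep(0, ncol(X)); s <- rep(1, ncol(X)); Xs <- X
  }
  if (intercept) {
    ybar <- mean(y); yc <- y - ybar
    xbar <- colMeans(Xs); Xc <- sweep(Xs, 2, xbar)
  } else {
    ybar <- 0; yc <- y; xbar <- rep(0, ncol(Xs)); Xc <- Xs
  }
  G <- crossprod(Xc) + diag(lambda, ncol(Xc))
  b_std <- tryCatch(solve(G, crossprod(Xc, yc)),
                    error = function(e) {
                      stop("singular system at lambda = ", lambda, call. = FALSE)
                    })
  b <- as.numeric(b_std) / s
  names(b) <- colnames(X)
  if (intercept) {
    b0 <- ybar - sum((mu + xbar * s) * b)
    c("(Intercept)" = b0, b)
  } else b
}

default_lambda_grid <- function() 10^seq(-3, 3, length.out = 20)

#' Cross-validated ridge encoding fit
#'
#' Threefold cross-validation over trials, repeated `n_repeats` times with
#' re-randomized folds. For each of the 20 penalty values the model is
#' trained on two-thirds of the trials and tested on the remaining third;
#' accuracy is the Pearson correlation between held-out prediction and
#' data over the concatenated test set. The penalty maximizing the median
#' accuracy across all runs is selected, and the median accuracy and
#' median coefficients across the `n_repeats x k` runs at that penalty are
#' reported.
#'
#' @param design An [build_encoding_design()] object, or any list with
#'   `X`, `y`, `trial`.
#' @param lambda_grid Penalty grid (default 20 log-spaced values,
#'   1e-3 to 1e3); the penalty is applied per training observation
#'   (effective ridge penalty `lambda * n_train`), so grid values are
#'   comparable across recording lengths.
#' @param k Folds (default 3).
#' @param n_repeats Fold re-randomizations (default 10).
#' @param seed Optional integer seed (fixes the partitioning, so nested
#'   model versions can share folds exactly).
#' @param columns Optional subset of predictor columns (for nested model
#'   versions).
#' @param lambda_rule `"best"` picks the penalty with the highest median
#'   held-out accuracy; `"min_1se"` picks the smallest penalty whose median
#'   accuracy is within one standard error (of the best penalty's accuracy
#'   across runs) of the maximum. The accuracy curve is typically flat over
#'   decades of penalty, and shrinkage biases coefficient profiles, so
#'   analyses that interpret coefficient shapes (e.g. timescale extraction)
#'   use `"min_1se"`.
#' @return An object of class `encoding_fit`: `coefficients` (median,
#'   named), `lambda`, `accuracy` (median at the chosen penalty),
#'   `accuracy_by_lambda`, `runs` (accuracy matrix run x lambda),
#'   `lambda_grid`, `groups`.
#' @export
crossval_ridge <- function(design, lambda_grid = default_lambda_grid(),
                           k = 3, n_repeats = 10, seed = NULL,
                           columns = NULL,
                           lambda_rule = c("best", "min_1se")) {
  lambda_rule <- match.arg(lambda_rule)
  X <- design$X; y <- design$y; trial <- design$trial
  if (!is.null(columns)) X <- X[, columns, drop = FALSE]
  trials <- unique(trial)
  if (length(trials) < k) stop("fewer trials than folds", call. = FALSE)
  n_lam <- length(lambda_grid)
  n_runs <- k * n_repeats
  acc <- matrix(NA_real_, n_runs, n_lam)
  coefs <- array(NA_real_, c(n_runs, n_lam, ncol(X) + 1))
  run <- 0
  with_seed(seed, {
    for (r in seq_len(n_repeats)) {
      fold_of <- setNames(rep_len(seq_len(k), length(trials)),
                          sample(trials))
      for (f in seq_len(k)) {
        run <- run + 1
        te <- trial %in% as.integer(names(fold_of)[fold_of == f])
        Xtr <- X[!te, , drop = FALSE]; ytr <- y[!te]
        Xte <- X[te, , drop = FALSE]; yte <- y[te]
        # standardize on the training set; eigendecompose once per fold
        mu <- colMeans(Xtr); s <- apply(Xtr, 2, stats::sd); s[s == 0] <- 1
        Xs <- sweep(sweep(Xtr, 2, mu), 2, s, "/")
        ybar <- mean(ytr); yc <- ytr - ybar
        eg <- eigen(crossprod(Xs), symmetric = TRUE)
        Xty <- crossprod(Xs, yc)
        Ut_Xty <- crossprod(eg$vectors, Xty)
        Xse <- sweep(sweep(Xte, 2, mu), 2, s, "/")
        n_tr <- nrow(Xtr)
        for (li in seq_len(n_lam)) {
          # penalty scales with the training-set size so the grid has the
          # same meaning regardless of recording length
          b_std <- eg$vectors %*% (Ut_Xty / (eg$values + lambda_grid[li] * n_tr))
          pred <- as.numeric(Xse %*% b_std) + ybar
          acc[run, li] <- if (stats::sd(pred) == 0 || stats::sd(yte) == 0) {
            0
          } else stats::cor(pred, yte)
          b <- as.numeric(b_std) / s
          b0 <- ybar - sum(mu * b)
          coefs[run, li, ] <- c(b0, b)
        }
      }
    }
  })
  med_acc <- apply(acc, 2, stats::median)
  best <- which.max(med_acc)
  if (lambda_rule == "min_1se") {
    se <- stats::sd(acc[, best]) / sqrt(nrow(acc))
    best <- min(which(med_acc >= med_acc[which.max(med_acc)] - se))
  }
  cf <- apply(coefs[, best, , drop = FALSE], 3, stats::median)
  names(cf) <- c("(Intercept)", colnames(X))
  structure(
    list(coefficients = cf, lambda = lambda_grid[best],
         accuracy = med_acc[best], accuracy_by_lambda = med_acc,
         runs = acc, lambda_grid = lambda_grid,
         groups = design$groups, roi_index = design$roi_index,
         ar_lags = design$ar_lags),
    class = "encoding_fit"
  )
}

#' @export
print.encoding_fit <- function(x, ...) {
  cat(sprintf("<encoding_fit> lambda = %.3g, held-out r = %.3f\n",
              x$lambda, x$accuracy))
  invisible(x)
}

#' Nested encoding-model comparison
#'
#' Fits three versions of the encoding model per ROI — task terms only
#' (`T`), task + autoregressive (`T+A`), and the full model (`T+A+C`) —
#' using exactly the same cross-validation partitioning for all versions,
#' and returns held-out accuracies. With data from several mice, a
#' two-way repeated-measures ANOVA (ROI x model version) and pairwise
#' paired comparisons on mouse-level averages are included.
#'
#' @param trace_sets A single trace set or a named list of trace sets (one
#'   per mouse).
#' @param rois ROI labels to model (default: the 7 named areas of the left
#'   hemisphere; hemispheres are averaged if both are given).
#' @param lambda_grid,k,n_repeats,seed Passed to [crossval_ridge()].
#' @return A list with `accuracies` (tibble `mouse`, `roi`, `model`,
#'   `accuracy`), `anova` (or `NULL` for a single mouse), `posthoc`.
#' @export
model_comparison <- function(trace_sets, rois = NULL,
                             lambda_grid = default_lambda_grid(), k = 3,
                             n_repeats = 10, seed = NULL) {
  if (inherits(trace_sets, "trace_set")) {
    trace_sets <- list(mouse1 = trace_sets)
  }
  rows <- list()
  for (mi in seq_along(trace_sets)) {
    ts <- trace_sets[[mi]]
    mouse <- names(trace_sets)[mi]
    use_rois <- if (is.null(rois)) {
      grep("^(V1|mV2|PPC|RSC|mM2|aM2|M1)_", rownames(ts$dff), value = TRUE)
    } else rois
    for (roi in use_rois) {
      des <- build_encoding_design(ts, roi)
      versions <- list(
        "T" = des$groups$T,
        "T+A" = c(des$groups$T, des$groups$A),
        "T+A+C" = c(des$groups$T, des$groups$A, des$groups$C)
      )
      for (v in names(versions)) {
        fit <- crossval_ridge(des, lambda_grid, k, n_repeats,
                              seed = seed, columns = versions[[v]])
        rows[[length(rows) + 1]] <- tibble(
          mouse = mouse, roi = roi, area = sub("_[LR]$", "", roi),
          model = v, accuracy = fit$accuracy
        )
      }
    }
  }
  acc <- dplyr::bind_rows(rows)
  acc_mouse <- dplyr::summarise(
    dplyr::group_by(acc, .data$mouse, .data$area, .data$model),
    accuracy = mean(.data$accuracy), .groups = "drop"
  )
  anova <- NULL; posthoc <- NULL
  if (length(unique(acc_mouse$mouse)) >= 2) {
    anova <- rm_anova(acc_mouse, dv = "accuracy", subject = "mouse",
                      within = c("area", "model"))
    posthoc <- rm_pairwise(
      dplyr::summarise(dplyr::group_by(acc_mouse, .data$mouse, .data$model),
                       accuracy = mean(.data$accuracy), .groups = "drop"),
      dv = "accuracy", subject = "mouse", factor_name = "model")
  }
  list(accuracies = acc, mouse_level = acc_mouse, anova = anova,
       posthoc = posthoc)
}
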