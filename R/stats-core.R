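#' Bootstrap estimate, SD, and p-value of a statistic
#'
#' Resamples rows (trials) with replacement `n_boot` times and evaluates
#' `statistic` on each resample. The one-sided p-value is the fraction of
#' iterations in which the statistic exceeds zero (testing the hypothesis
#' that the true statistic is negative, e.g. that inactivation decreases
#' performance); the two-sided p-value is the fraction of iterations whose
#' sign differs from that of the point estimate (as used for running-speed
#' changes). A p-value of exactly zero is reported at the resolution floor
#' `1 / n_boot` with `at_floor = TRUE`.
#'
#' @param data A data frame (resampled by row) or vector (by element).
#' @param statistic Function mapping a resample to a scalar.
#' @param n_boot Number of bootstrap iterations (default 10,000).
#' @param sidedness `"one"` or `"two"`.
#' @param seed Optional integer seed.
#' @return A list with `estimate` (on the full data), `sd`, `p_value`,
#'   `at_floor`, `n_boot`, and the vector of bootstrap `replicates`.
#' @examples
#' x <- rnorm(100, 0.2)
#' bootstrap_pvalue(x, mean, n_boot = 500, sidedness = "two", seed = 1)$p_value
#' @export
bootstrap_pvalue <- function(data, statistic, n_boot = 10000,
                             sidedness = c("one", "two"), seed = NULL) {
  sidedness <- match.arg(sidedness)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100: p-value resolution is poor",
                            call. = FALSE)
  est <- statistic(data)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      resample <- if (is.data.frame(data)) data[idx, , drop = FALSE] else data[idx]
      statistic(resample)
    }, numeric(1))
  })
  if (stats::sd(reps) == 0) {
    warning("degenerate bootstrap: statistic constant across resamples",
            call. = FALSE)
  }
  p_raw <- if (sidedness == "one") {
    mean(reps > 0)
  } else {
    if (est == 0) 1 else mean(sign(reps) != sign(est))
  }
  at_floor <- p_raw == 0
  list(estimate = est, sd = stats::sd(reps),
       p_value = if (at_floor) 1 / n_boot else p_raw,
       at_floor = at_floor, n_boot = n_boot, replicates = reps)
}

#' Rank-based false discovery rate correction
#'
#' Ranks p-values in ascending order and deems the i-th ranked value
#' \eqn{P_i} significant if \eqn{P_i \le \alpha i / n}, where n is the
#' number of comparisons. `method = "literal"` applies that per-rank rule
#' exactly as stated; `method = "step_up"` is the conventional
#' Benjamini-Hochberg step-up (all ranks up to the largest passing rank are
#' significant). The two differ only when a low rank fails while a higher
#' rank passes.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param alpha Significance level (0.050 one-sided, 0.025 two-sided by
#'   the convention used here).
#' @param method `"literal"` or `"step_up"`.
#' @return Logical vector of significance flags in input order.
#' @examples
#' fdr_correct(c(0.001, 0.02, 0.03, 0.2), alpha = 0.05)
#' @export
fdr_correct <- function(p_values, alpha = 0.05,
                        method = c("literal", "step_up")) {
  method <- match.arg(method)
  if (length(p_values) == 0) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  n <- length(p_values)
  ord <- order(p_values)
  p_sorted <- p_values[ord]
  pass <- p_sorted <= alpha * seq_len(n) / n
  flags_sorted <- if (method == "literal") {
    pass
  } else {
    if (any(pass)) seq_len(n) <= max(which(pass)) else rep(FALSE, n)
  }
  flags <- logical(n)
  flags[ord] <- flags_sorted
  flags
}

#' Repeated-measures ANOVA
#'
#' Standard univariate repeated-measures decomposition via [stats::aov()]
#' with an `Error(subject/...)` stratum. Supports one or two within-subject
#' factors, or one within- and one between-subject factor (mixed design).
#' The design must be balanced and complete (one observation per subject
#' per within-cell); unbalanced input is an error.
#'
#' @param table Data frame in long format.
#' @param dv Name of the response column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector (length 1 or 2) of within-subject factors.
#' @param between Optional name of a between-subject factor.
#' @return A tibble with one row per effect: `effect`, `df1`, `df2`, `F`,
#'   `p_value`.
#' @examples
#' d <- expand.grid(subj = 1:4, cond = c("a", "b"))
#' d$y <- rnorm(nrow(d)) + (d$cond == "b")
#' rm_anova(d, "y", "subj", "cond")
#' @export
rm_anova <- function(table, dv, subject, within, between = NULL) {
  stopifnot(length(within) %in% 1:2)
  df <- as.data.frame(table)
  df[[subject]] <- factor(df[[subject]])
  for (w in within) df[[w]] <- factor(df[[w]])
  if (!is.null(between)) df[[between]] <- factor(df[[between]])

  cells <- interaction(df[c(subject, within)], drop = FALSE)
  counts <- table(cells)
  if (any(counts != 1)) {
    stop("unbalanced or incomplete design: need exactly one observation per ",
         "subject per within-factor cell", call. = FALSE)
  }

  w_term <- paste(within, collapse = "*")
  rhs <- if (is.null(between)) w_term else paste(between, "*", w_term)
  err <- sprintf("Error(%s/(%s))", subject, w_term)
  fml <- stats::as.formula(paste(dv, "~", rhs, "+", err))
  fit <- stats::aov(fml, data = df)
  smry <- summary(fit)

  out <- list()
  for (stratum in smry) {
    tab <- if (is.list(stratum)) stratum[[1]] else stratum
    tab <- as.data.frame(tab)
    terms <- trimws(rownames(tab))
    keep <- terms != "Residuals"
    resid_df <- tab$Df[!keep]
    for (i in which(keep)) {
      out[[length(out) + 1]] <- tibble(
        effect = terms[i], df1 = tab$Df[i],
        df2 = if (length(resid_df)) resid_df[1] else NA_real_,
        F = tab$`F value`[i], p_value = tab$`Pr(>F)`[i]
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Pairwise paired comparisons after a repeated-measures ANOVA
#'
#' Paired t-tests between all levels of a within-subject factor, with
#' multiplicity adjustment (Holm by default; suited to repeated-measures
#' designs where classical Tukey HSD's independence assumption fails).
#'
#' @inheritParams rm_anova
#' @param factor_name Within-subject factor whose levels are compared.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return A tibble with `level_1`, `level_2`, `t`, `df`, `p_value`,
#'   `p_adjusted`.
#' @export
rm_pairwise <- function(table, dv, subject, factor_name, p_adjust = "holm") {
  df <- as.data.frame(table)
  lv <- unique(as.character(df[[factor_name]]))
  combos <- utils::combn(lv, 2, simplify = FALSE)
  rows <- lapply(combos, function(pair) {
    a <- df[df[[factor_name]] == pair[1], c(subject, dv)]
    b <- df[df[[factor_name]] == pair[2], c(subject, dv)]
    m <- merge(a, b, by = subject)
    tt <- stats::t.test(m[[paste0(dv, ".x")]], m[[paste0(dv, ".y")]],
                        paired = TRUE)
    tibble(level_1 = pair[1], level_2 = pair[2],
           t = unname(tt$statistic), df = unname(tt$parameter),
           p_value = tt$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Bootstrapped power analysis for the inactivation performance effect
#'
#' Subsamples the cohort at a grid of inactivation-trial counts n
#' (preserving the control:laser ratio), computes the bootstrap p-value for
#' the laser-induced change in overall performance at each n, and repeats
#' the whole procedure `repeats` times. Power is defined as the first n at
#' which twice the SEM of the p-value across repeats falls below 0.05;
#' as a sanity check the mean p-value at that n is also reported.
#'
#' @param trials Cohort or trial table with `laser_on`, `choice`, and tower
#'   list-columns (see [percent_correct()]).
#' @param grid Candidate numbers of inactivation trials (default 50 to
#'   1000 in steps of 25; 39 values).
#' @param repeats Number of repeats of the subsample + bootstrap procedure.
#' @param n_boot Bootstrap iterations per subsample.
#' @param seed Optional integer seed.
#' @return A list of class `power_result`: `table` (tibble n, p_mean,
#'   p_sem), `power_n` (`NA` with `reached = FALSE` if never reached),
#'   `p_at_power_n`, `reached`.
#' @export
power_analysis <- function(trials, grid = seq(50, 1000, by = 25),
                           repeats = 10, n_boot = 10000, seed = NULL) {
  trials <- as_trials(trials)
  n_laser <- sum(trials$laser_on)
  n_ctrl <- sum(!trials$laser_on)
  if (max(grid) > n_laser) {
    stop("grid exceeds the number of inactivation trials in the cohort",
         call. = FALSE)
  }
  ratio <- n_ctrl / n_laser
  laser_rows <- which(trials$laser_on)
  ctrl_rows <- which(!trials$laser_on)
  correct <- trial_correct(trials)

  with_seed(seed, {
    p_mat <- matrix(NA_real_, length(grid), repeats)
    for (r in seq_len(repeats)) {
      for (gi in seq_along(grid)) {
        n <- grid[gi]
        n_c <- min(n_ctrl, round(n * ratio))
        sub_l <- sample(laser_rows, n)
        sub_c <- sample(ctrl_rows, n_c)
        p_mat[gi, r] <- boot_delta_p(correct[sub_l], correct[sub_c], n_boot)
      }
    }
    p_mean <- rowMeans(p_mat)
    p_sem <- apply(p_mat, 1, stats::sd) / sqrt(repeats)
    hit <- which(2 * p_sem < 0.05)
    reached <- length(hit) > 0
    structure(
      list(table = tibble(n = grid, p_mean = p_mean, p_sem = p_sem),
           power_n = if (reached) grid[min(hit)] else NA_integer_,
           p_at_power_n = if (reached) p_mean[min(hit)] else NA_real_,
           reached = reached),
      class = "power_result"
    )
  })
}

#' @export
print.power_result <- function(x, ...) {
  cat("<power_result>\n")
  if (x$reached) {
    cat(sprintf("  power n = %d (mean p there = %.4f)\n",
                x$power_n, x$p_at_power_n))
  } else {
    cat("  criterion not reached on the grid\n")
  }
  invisible(x)
}

# Fast one-sided bootstrap p for delta = %correct(laser) - %correct(control),
# resampling each arm with replacement. Vectorized over iterations.
boot_delta_p <- function(correct_laser, correct_ctrl, n_boot) {
  nl <- length(correct_laser); nc <- length(correct_ctrl)
  dl <- matrix(correct_laser[sample.int(nl, nl * n_boot, replace = TRUE)],
               nl, n_boot)
  dc <- matrix(correct_ctrl[sample.int(nc, nc * n_boot, replace = TRUE)],
               nc, n_boot)
  delta <- colMeans(dl) - colMeans(dc)
  p <- mean(delta > 0)
  if (p == 0) 1 / n_boot else p
}
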