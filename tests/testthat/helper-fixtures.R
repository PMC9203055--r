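# Shared fixtures, built in code at test time.

# One hand-specified trial row with sensible defaults; override any field.
make_trial <- function(...) {
  defaults <- list(
    mouse_id = "m1", session_id = "s1", block_id = 1L, trial_index = 1L,
    rewarded_side = "R",
    towers_right = list(c(30, 60, 90)), towers_left = list(c(40, 80)),
    tower_times_right = list(c(0.8, 1.4, 2.0)),
    tower_times_left = list(c(1.0, 1.8)),
    speed = 50, choice = "R", laser_on = FALSE, area_set = NA_character_,
    epoch = NA_character_, laser_onset_y = NA_real_, laser_offset_y = NA_real_,
    laser_onset_time = NA_real_, laser_offset_time = NA_real_,
    traveled_distance = 330, reached_end = TRUE,
    is_warmup = FALSE, is_easy_block = FALSE
  )
  args <- list(...)
  for (nm in names(args)) {
    defaults[[nm]] <- if (nm %in% c("towers_right", "towers_left",
                                    "tower_times_right", "tower_times_left") &&
                          !is.list(args[[nm]])) list(args[[nm]]) else args[[nm]]
  }
  tibble::as_tibble(defaults)
}

make_trials <- function(...) dplyr::bind_rows(...)

# Small cached cohort with a laser effect, shared across tests.
local({
  cache <- new.env(parent = emptyenv())
  test_cohort <<- function() {
    if (is.null(cache$coh)) {
      cfg <- task_config(epochs = c(default_epochs(), list(tile = c(75, 140))))
      coh <- suppressWarnings(generate_cohort(
        n_mice = 4, trials_per_mouse = 120, laser_frac = 0.25,
        epochs = "tile", config = cfg, n_warmup = 0,
        gcm = choice_model(base_weight = 1, lapse = 0,
                           laser_modulation = c(during = 0.3)),
        seed = 321
      ))
      cache$coh <- suppressWarnings(assign_dummy_laser_windows(coh))
    }
    cache$coh
  }
})

# The task configuration with the window-tiling validation epoch included:
# with laser onset at y = 75 and offset at y = 140 cm, the three 0.5 s pre
# bins, the during window, and the two 0.5 s post bins jointly cover every
# tower trigger position in the cue region, so no evidence falls outside
# the model.
validation_config <- function() {
  task_config(epochs = c(default_epochs(), list(tile = c(75, 140))))
}

# Independent brute-force logistic MLE via Newton-Raphson (IRLS), used as
# the oracle for the package's logistic fits.
newton_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  X <- cbind(1, X)
  b <- numeric(ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% b)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    g <- crossprod(X, y - p)
    H <- crossprod(X * W, X)
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  as.numeric(b)
}
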