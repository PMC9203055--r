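SESSION_SCHEMA_VERSION <- "1.0"

#' Write a cohort's session logs to disk
#'
#' Serializes the trial table as CSV (ragged tower arrays JSON-encoded in
#' their cells) plus a JSON manifest recording the schema version, task
#' configuration, generative model, ground-truth mouse effects, and seed.
#' The round trip through [read_sessions()] is lossless.
#'
#' @param cohort A `tower_cohort`.
#' @param path Directory to write into (created if missing).
#' @return The path, invisibly.
#' @export
write_sessions <- function(cohort, path) {
  stopifnot(inherits(cohort, "tower_cohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  trials <- cohort$trials
  flat <- trials
  for (col in c("towers_right", "towers_left",
                "tower_times_right", "tower_times_left")) {
    flat[[col]] <- vapply(trials[[col]], function(v) {
      as.character(jsonlite::toJSON(as.numeric(v), digits = NA))
    }, character(1))
  }
  utils::write.csv(flat, file.path(path, "trials.csv"), row.names = FALSE)
  gcm_out <- unclass(cohort$gcm)
  gcm_out$laser_modulation <- as.list(gcm_out$laser_modulation)
  manifest <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    config = unclass(cohort$config),
    gcm = gcm_out,
    mouse_effects = cohort$mouse_effects,
    seed = cohort$seed,
    n_trials = nrow(trials)
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort's session logs from disk
#'
#' @param path Directory written by [write_sessions()].
#' @return A `tower_cohort`.
#' @export
read_sessions <- function(path) {
  mf <- jsonlite::read_json(file.path(path, "manifest.json"),
                            simplifyVector = TRUE)
  if (!identical(mf$schema_version, SESSION_SCHEMA_VERSION)) {
    stop(sprintf("unrecognized session schema version '%s' (expected '%s')",
                 mf$schema_version, SESSION_SCHEMA_VERSION), call. = FALSE)
  }
  raw <- utils::read.csv(file.path(path, "trials.csv"),
                         stringsAsFactors = FALSE)
  trials <- as_tibble(raw)
  if (nrow(trials)) {
    for (col in c("towers_right", "towers_left",
                  "tower_times_right", "tower_times_left")) {
      trials[[col]] <- lapply(trials[[col]], function(s) {
        as.numeric(jsonlite::fromJSON(s))
      })
    }
  } else {
    for (col in c("towers_right", "towers_left",
                  "tower_times_right", "tower_times_left")) {
      trials[[col]] <- list()
    }
  }
  cfg <- mf$config
  cfg$epochs <- lapply(cfg$epochs, as.numeric)
  cfg$area_sets <- as.character(cfg$area_sets)
  class(cfg) <- "task_config"
  gcm <- mf$gcm
  gcm$laser_modulation <- unlist(gcm$laser_modulation)
  class(gcm) <- "choice_model"
  structure(
    list(trials = trials, config = cfg, gcm = gcm,
         mouse_effects = as_tibble(mf$mouse_effects), seed = mf$seed),
    class = "tower_cohort"
  )
}

#' Analysis run configuration
#'
#' Bundles generator and analysis parameters with the seed so every
#' analysis records the exact configuration used. Round-trips losslessly
#' through JSON.
#'
#' @param n_mice,trials_per_mouse,laser_frac,area_set,epochs Generator
#'   settings (see [generate_cohort()]).
#' @param bin_s,n_pre,n_post Evidence-design binning.
#' @param n_boot Bootstrap iterations for behavior metrics.
#' @param n_shuffle Shuffle-null iterations.
#' @param cv_folds Mixed-model cross-validation folds (0 disables CV).
#' @param random Random-effects structure for [fit_mixed_logistic()].
#' @param seed Integer seed.
#' @param out Optional output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_mice = 15, trials_per_mouse = 500,
                       laser_frac = 0.15, area_set = "Post",
                       epochs = NULL, bin_s = 0.5, n_pre = 3, n_post = 2,
                       n_boot = 10000, n_shuffle = 30, cv_folds = 10,
                       random = "full", seed = 1, out = NULL) {
  structure(
    list(n_mice = n_mice, trials_per_mouse = trials_per_mouse,
         laser_frac = laser_frac, area_set = area_set, epochs = epochs,
         bin_s = bin_s, n_pre = n_pre, n_post = n_post, n_boot = n_boot,
         n_shuffle = n_shuffle, cv_folds = cv_folds, random = random,
         seed = seed, out = out),
    class = "run_config"
  )
}

#' Run the behavioral analysis pipeline
#'
#' Simulate (or accept) a cohort, apply trial selection and dummy-window
#' assignment, compute behavior metrics (overall performance, performance
#' delta, psychometric fit, spatial evidence weights), fit the
#' laser-aligned mixed model (optionally cross-validated), compute
#' normalized weights, the shuffle null, and the two-condition
#' significance flags. Results are returned as a bundle and, when
#' `config$out` is set, written as CSV/JSON with a manifest containing the
#' configuration hash and seed; re-running with the same configuration
#' reproduces the bundle.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-built cohort (skips simulation).
#' @return A list of class `result_bundle`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$out) && !dir.exists(dirname(config$out))) {
    stop("missing output parent directory: ", dirname(config$out),
         call. = FALSE)
  }
  if (is.null(cohort)) {
    cfg <- task_config()
    epochs <- if (is.null(config$epochs)) names(cfg$epochs) else config$epochs
    cohort <- generate_cohort(
      n_mice = config$n_mice, trials_per_mouse = config$trials_per_mouse,
      laser_frac = config$laser_frac, area_set = config$area_set,
      epochs = epochs, config = cfg, seed = config$seed
    )
  }
  cohort <- select_trials(cohort)
  cohort <- assign_dummy_laser_windows(cohort)

  perf <- list(
    control = percent_correct(cohort$trials[!cohort$trials$laser_on, ]),
    laser = percent_correct(cohort$trials[cohort$trials$laser_on, ])
  )
  pdelta <- performance_delta(cohort, n_boot = config$n_boot,
                              seed = config$seed + 1)
  psy <- fit_psychometric(psychometric_curve(cohort))
  spatial <- spatial_evidence_weights(cohort, seed = config$seed + 2)

  design <- build_time_binned_design(cohort, config$bin_s, config$n_pre,
                                     config$n_post)
  if (config$cv_folds >= 2) {
    cv <- crossval_glmm(design, k = config$cv_folds,
                        seed = config$seed + 3, random = config$random)
    fit <- cv$best_fit
    cv_acc <- cv$accuracy
  } else {
    fit <- fit_mixed_logistic(design, random = config$random)
    cv_acc <- NULL
  }
  nw <- normalized_weights(fit)
  null <- shuffle_null(cohort, n_shuffle = config$n_shuffle,
                       seed = config$seed + 4, random = config$random)
  sig <- coefficient_significance(nw, null)

  bundle <- structure(
    list(config = config,
         config_hash = rlang::hash(unclass(config)[setdiff(names(config),
                                                           "out")]),
         seed = config$seed, selection = attr(cohort, "selection_counts"),
         performance = perf, performance_delta = pdelta,
         psychometric = psy, spatial_weights = spatial,
         glmm = fit, cv_accuracy = cv_acc, normalized_weights = nw,
         shuffle_null = null, significance = sig),
    class = "result_bundle"
  )
  if (!is.null(config$out)) write_bundle(bundle, config$out)
  bundle
}

write_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$glmm$coefficients,
                   file.path(path, "coefficients.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$significance),
                   file.path(path, "normalized_weights.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$shuffle_null),
                   file.path(path, "shuffle_null.csv"), row.names = FALSE)
  manifest <- list(
    config = unclass(bundle$config), config_hash = bundle$config_hash,
    seed = bundle$seed,
    performance = bundle$performance,
    performance_delta = bundle$performance_delta[c("delta", "sd", "p_value")],
    psychometric = bundle$psychometric[c("b", "a", "delta0", "lambda")],
    cv_accuracy = bundle$cv_accuracy
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("<result_bundle>\n")
  cat(sprintf("  control %.1f%% correct, laser %.1f%% (delta %.2f pp, p = %.4g)\n",
              100 * x$performance$control, 100 * x$performance$laser,
              100 * x$performance_delta$delta, x$performance_delta$p_value))
  if (!is.null(x$cv_accuracy)) {
    cat(sprintf("  held-out choice prediction accuracy: %.3f (best fold)\n",
                max(x$cv_accuracy)))
  }
  print(as.data.frame(x$significance[, c("bin", "value", "se", "significant")]))
  invisible(x)
}
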