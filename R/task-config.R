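#' Task configuration for the accumulating-towers maze
#'
#' Describes the geometry and stimulus statistics of the virtual T-maze:
#' a 30 cm start region, a 200 cm cue region in which transient towers
#' appear on either side, and a 100 cm delay region. Towers are placed at
#' Poisson-distributed counts per trial (mean `tower_rate_major` on the
#' rewarded side and `tower_rate_minor` on the other side) with a within-side
#' refractory spacing, yielding an overall density of
#' `(tower_rate_major + tower_rate_minor) / (cue_length / 100)` towers per
#' meter (5/m at defaults). Inactivation epochs are y-position intervals.
#'
#' The maze coordinate convention puts `y = 0` at the start of the cue
#' region; the start region occupies `[-30, 0)` and the delay region
#' `[cue_length, cue_length + delay_length]`.
#'
#' @param cue_length Length of the cue region (cm).
#' @param delay_length Length of the delay region (cm).
#' @param start_length Length of the start region (cm).
#' @param tower_rate_major Mean tower count per trial on the rewarded side.
#' @param tower_rate_minor Mean tower count per trial on the non-rewarded side.
#' @param refractory Minimum spacing between consecutive towers on one side (cm).
#' @param overall_density Nominal overall tower density (towers/m), used for
#'   the configuration consistency check.
#' @param tower_min_y Minimum tower position (cm); no towers before this point.
#' @param tower_visibility How long a tower stays visible (s).
#' @param tower_trigger_distance Distance before a tower's position at which it
#'   appears (cm); tower times are defined at this trigger.
#' @param mean_speed Mean running speed (cm/s).
#' @param speed_cv Coefficient of variation of the per-trial speed draw.
#' @param laser_speed_gain Fractional speed increase while the laser is on.
#' @param epochs Named list of inactivation epochs, each a length-2 numeric
#'   y interval (cm).
#' @param area_sets Character vector of targeted area-set labels.
#'
#' @return An object of class `task_config` (a list of the above fields).
#' @examples
#' cfg <- task_config()
#' cfg$cue_length
#' @export
task_config <- function(cue_length = 200,
                        delay_length = 100,
                        start_length = 30,
                        tower_rate_major = 7.7,
                        tower_rate_minor = 2.3,
                        refractory = 12,
                        overall_density = 5,
                        tower_min_y = 10,
                        tower_visibility = 0.2,
                        tower_trigger_distance = 10,
                        mean_speed = 50,
                        speed_cv = 0.15,
                        laser_speed_gain = 0.08,
                        epochs = default_epochs(),
                        area_sets = default_area_sets()) {
  cfg <- list(
    cue_length = cue_length, delay_length = delay_length,
    start_length = start_length,
    tower_rate_major = tower_rate_major, tower_rate_minor = tower_rate_minor,
    refractory = refractory, overall_density = overall_density,
    tower_min_y = tower_min_y, tower_visibility = tower_visibility,
    tower_trigger_distance = tower_trigger_distance,
    mean_speed = mean_speed, speed_cv = speed_cv,
    laser_speed_gain = laser_speed_gain,
    epochs = epochs, area_sets = area_sets
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config>\n")
  cat(sprintf("  maze: start %g + cue %g + delay %g cm\n",
              x$start_length, x$cue_length, x$delay_length))
  cat(sprintf("  towers: %g / %g per trial (major/minor), refractory %g cm\n",
              x$tower_rate_major, x$tower_rate_minor, x$refractory))
  cat(sprintf("  speed: %g cm/s (cv %g), laser gain %g\n",
              x$mean_speed, x$speed_cv, x$laser_speed_gain))
  cat(sprintf("  %d epochs, %d area sets\n",
              length(x$epochs), length(x$area_sets)))
  invisible(x)
}

#' Default inactivation epochs and area sets
#'
#' The six spatially defined inactivation epochs (y intervals in cm) and the
#' nine targeted area sets.
#' @return `default_epochs()`: named list of length-2 numeric intervals;
#'   `default_area_sets()`: character vector.
#' @export
default_epochs <- function() {
  list(
    "cue1q"  = c(0, 50),
    "cue2q"  = c(50, 100),
    "cue3q"  = c(100, 150),
    "cue1h"  = c(0, 100),
    "cue2h"  = c(100, 200),
    "delay"  = c(200, 300)
  )
}

#' @rdname default_epochs
#' @export
default_area_sets <- function() {
  c("V1", "mV2", "PPC", "RSC", "mM2", "aM2", "M1", "Post", "Front")
}

validate_task_config <- function(cfg) {
  stopifnot(cfg$cue_length > 0, cfg$delay_length >= 0, cfg$start_length >= 0)
  if (cfg$refractory <= 0 || cfg$refractory >= cfg$cue_length) {
    stop("configuration error: refractory must lie in (0, cue_length)",
         call. = FALSE)
  }
  if (cfg$tower_min_y >= cfg$cue_length) {
    stop("configuration error: tower_min_y must be below cue_length",
         call. = FALSE)
  }
  dens <- (cfg$tower_rate_major + cfg$tower_rate_minor) /
    (cfg$cue_length / 100)
  if (abs(dens - cfg$overall_density) > 0.1 * cfg$overall_density) {
    warning(sprintf(
      "tower rates imply %.2f towers/m, nominal overall_density is %g",
      dens, cfg$overall_density), call. = FALSE)
  }
  maze_end <- cfg$cue_length + cfg$delay_length
  for (nm in names(cfg$epochs)) {
    ep <- cfg$epochs[[nm]]
    if (length(ep) != 2 || ep[1] >= ep[2] || ep[1] < 0 || ep[2] > maze_end) {
      stop(sprintf("configuration error: epoch '%s' outside [0, %g]",
                   nm, maze_end), call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Generative choice model for synthetic cohorts
#'
#' Parameters of the ground-truth decision rule used by the synthetic
#' cohort generator. A mouse's probability of a rightward choice is
#' \deqn{p_R = lapse/2 + (1 - lapse) \,
#'   \sigma\!\left(b_m + \sum_k s_k \, w_m \, mod(k)\right)}
#' where the sum runs over towers, \eqn{s_k = +1} for right and \eqn{-1}
#' for left towers, \eqn{b_m} and \eqn{w_m} are the mouse's bias and
#' evidence weight, and \eqn{mod(k)} is the laser modulation factor for
#' the laser-aligned window containing tower k (1 on control trials and
#' for towers outside all windows).
#'
#' `laser_modulation` names the six laser-aligned windows chronologically:
#' `pre3`, `pre2`, `pre1` (0.5 s bins before laser onset, `pre1` nearest),
#' `during` (the whole laser interval), `post1`, `post2` (0.5 s bins after
#' offset). All factors equal to 1 makes laser trials distributionally
#' identical to control trials.
#'
#' @param base_weight Population-mean evidence weight (log-odds per tower).
#' @param bias_mean,bias_sd Mean and SD of the per-mouse side bias (log-odds).
#' @param weight_sd SD of the per-mouse evidence weight.
#' @param laser_modulation Named numeric vector of multiplicative factors
#'   (>= 0) for towers in the six laser-aligned windows.
#' @param lapse Probability of a random (coin-flip) choice, in `[0, 0.5]`.
#'
#' @return An object of class `choice_model`.
#' @examples
#' gcm <- choice_model(laser_modulation = c(pre1 = 0.5, during = 0.3))
#' gcm$laser_modulation
#' @export
choice_model <- function(base_weight = 0.6,
                         bias_mean = 0,
                         bias_sd = 0.3,
                         weight_sd = 0.1,
                         laser_modulation = NULL,
                         lapse = 0.02) {
  mods <- c(pre3 = 1, pre2 = 1, pre1 = 1, during = 1, post1 = 1, post2 = 1)
  if (!is.null(laser_modulation)) {
    bad <- setdiff(names(laser_modulation), names(mods))
    if (length(bad)) {
      stop("unknown laser_modulation window(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    mods[names(laser_modulation)] <- laser_modulation
  }
  if (any(mods < 0)) stop("modulation factors must be >= 0", call. = FALSE)
  if (lapse < 0 || lapse > 0.5) stop("lapse must be in [0, 0.5]", call. = FALSE)
  structure(
    list(base_weight = base_weight, bias_mean = bias_mean, bias_sd = bias_sd,
         weight_sd = weight_sd, laser_modulation = mods, lapse = lapse),
    class = "choice_model"
  )
}

# Chronological labels of the laser-aligned evidence windows.
window_labels <- function() c("pre3", "pre2", "pre1", "during", "post1", "post2")
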