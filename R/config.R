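#' Study configuration for the synthetic-study generator
#'
#' Collects the design constants of an encoding/recognition panorama study and
#' the behavioural parameters of the generator. Defaults reproduce the study
#' design the package targets: 80 encoding trials, 40 old + 40 new recognition
#' trials of 10 s each, eye samples at 250 Hz and head pose at 70 Hz.
#'
#' @param n_participants number of simulated participants (default 21).
#' @param n_scenes_encoding scenes shown at encoding (default 80).
#' @param n_old,n_new old / new recognition trial counts (defaults 40 / 40).
#' @param trial_duration_ms trial length in ms (default 10000).
#' @param eye_rate_hz,head_rate_hz sampling rates (defaults 250, 70).
#' @param fixation_shape,fixation_mean_ms gamma shape and mean (ms) of plateau
#'   durations (defaults 4, 200; right-skewed, truncated below at
#'   `min_plateau_ms`).
#' @param recognition_roi_fraction fraction of a scene's regions of interest
#'   revisited during recognition, in (0, 1\]; values below 1 shrink
#'   recognition-phase exploration relative to encoding.
#' @param noise_kappa von Mises–Fisher concentration of within-fixation gaze
#'   jitter (default 12000, about 0.5 degrees SD); `Inf` = noise-free.
#' @param n_rois,horizon_kappa,roi_kappa scene model: number of regions of
#'   interest, concentration of their latitudes toward the horizon, and the
#'   concentration of fixation targets around an ROI center.
#' @param rho idiosyncrasy weight in \[0, 1\]: probability that a fixation
#'   target is drawn from the participant's private ROI set rather than the
#'   scene's.
#' @param n_private_rois private ROIs per participant (default 4).
#' @param head_gain head pitch gain in \[0, 1\]: the latitude of the head's
#'   aim point is this fraction of the gaze target's latitude (default 0.85;
#'   heads pitch less than gaze, concentrating head points on the horizon).
#' @param head_lag_ms pure delay of the head behind the eye target, ms
#'   (default 50).
#' @param head_tau_ms time constant of the head's first-order pursuit of its
#'   aim point, ms (default 30); 0 gives instant tracking.
#' @param head_coarseness in \[0, 1\]: how far the head's aim point is pulled
#'   from the exact fixation target toward the target's region-of-interest
#'   center (default 0.7) -- the head indexes the coarse region while the
#'   eyes inspect detail points.
#' @param mover_sd SD of the log-normal per-participant multiplier on
#'   `head_gain` ("movers" vs "nonmovers"; default 0.15).
#' @param min_target_sep_deg minimum great-circle separation between
#'   successive fixation targets (default 6, i.e. twice the I-DT dispersion
#'   threshold, so distinct plateaus can never merge).
#' @param min_plateau_ms lower truncation of plateau durations (default 100).
#' @param saccade_base_ms,saccade_ms_per_deg saccade duration model:
#'   `base + slope * amplitude` (defaults 20 ms, 2 ms/deg).
#' @param seed integer seed for the whole study.
#' @return a list of class `pg_config`.
#' @export
study_config <- function(n_participants = 21,
                         n_scenes_encoding = 80,
                         n_old = 40,
                         n_new = 40,
                         trial_duration_ms = 10000,
                         eye_rate_hz = 250,
                         head_rate_hz = 70,
                         fixation_shape = 4,
                         fixation_mean_ms = 200,
                         recognition_roi_fraction = 0.5,
                         noise_kappa = 12000,
                         n_rois = 12,
                         horizon_kappa = 8,
                         roi_kappa = 40,
                         rho = 0.2,
                         n_private_rois = 4,
                         head_gain = 0.85,
                         head_lag_ms = 50,
                         head_tau_ms = 30,
                         head_coarseness = 0.7,
                         mover_sd = 0.15,
                         min_target_sep_deg = 6,
                         min_plateau_ms = 100,
                         saccade_base_ms = 20,
                         saccade_ms_per_deg = 2,
                         seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$eye_rate_hz <= 0 || cfg$head_rate_hz <= 0) stop("sampling rates must be positive")
  if (cfg$recognition_roi_fraction <= 0 || cfg$recognition_roi_fraction > 1)
    stop("recognition_roi_fraction must be in (0, 1]")
  if (cfg$n_old > cfg$n_scenes_encoding)
    stop("n_old cannot exceed the number of encoded scenes")
  if (cfg$rho < 0 || cfg$rho > 1) stop("rho must be in [0, 1]")
  if (cfg$head_gain < 0 || cfg$head_gain > 1) stop("head_gain must be in [0, 1]")
  if (cfg$head_lag_ms < 0) stop("head_lag_ms must be non-negative")
  if (cfg$trial_duration_ms < cfg$min_plateau_ms)
    stop("trial shorter than one minimum fixation")
  structure(cfg, class = "pg_config")
}

#' Read / write a study configuration as YAML
#'
#' @param path file path.
#' @return `read_study_config()` returns a `pg_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
read_study_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$seed <- as.integer(vals$seed)
  do.call(study_config, vals)
}

#' @rdname read_study_config
#' @param config a `pg_config`.
#' @export
write_study_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.pg_config <- function(x, ...) {
  cat("<pg_config> ", x$n_participants, " participants, ",
      x$n_scenes_encoding, " encoding + ", x$n_old, " old / ", x$n_new,
      " new recognition trials, ", x$trial_duration_ms / 1000, " s each\n",
      sep = "")
  invisible(x)
}
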