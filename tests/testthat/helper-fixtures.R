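# Shared fixtures: small synthetic studies built once per test run.

# tiny study with default behavioural parameters (used by several suites)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- study_config(n_participants = 3, n_scenes_encoding = 8,
                          n_old = 4, n_new = 4, seed = 420L)
      cache <<- simulate_study(cfg)
    }
    cache
  }
})

# fixation table for a study (the pipeline's detection stage, trimmed)
study_fixation_table <- function(study, max_dispersion = 3, min_duration = 80) {
  dplyr::bind_rows(lapply(study$trials, function(tr) {
    gz <- build_gaze_series(tr)
    fx <- detect_fixations(gz, max_dispersion, min_duration)
    hf <- head_fixations(fx, gz)
    tibble::tibble(participant = tr$participant_id, scene = tr$scene_id,
                   phase = tr$phase, fix_index = fx$fix_index,
                   start = fx$start, end = fx$end, duration = fx$duration,
                   eye_lon = fx$lon, eye_lat = fx$lat,
                   head_lon = hf$lon, head_lat = hf$lat)
  }))
}

small_fixations <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- study_fixation_table(small_study())
    cache
  }
})

# random unit quaternion
random_quat <- function() {
  q <- stats::rnorm(4)
  quat(q[1], q[2], q[3], q[4])
}

# random points on the sphere (uniform)
random_points <- function(n) {
  z <- stats::runif(n, -1, 1)
  th <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(1 - z^2)
  vec_to_sph(cbind(s * cos(th), s * sin(th), z))
}
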