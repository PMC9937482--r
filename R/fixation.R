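# Spherical I-DT fixation detection and per-trial movement measures.

#' Detect fixations with a spherical dispersion-threshold (I-DT) algorithm
#'
#' Sliding-window I-DT operating entirely in angular terms: a candidate window
#' spans at least `min_duration` ms; if its dispersion — the maximum pairwise
#' great-circle distance among the window's samples — is at most
#' `max_dispersion`, the window is extended sample by sample while the
#' dispersion stays within the threshold, a fixation is emitted with the
#' spherical mean of the window as centroid, and the scan restarts after the
#' window; otherwise the window start advances by one sample. No threshold
#' ever touches projected (longitude/latitude) coordinates, so detection is
#' invariant under global rotations and safe at the poles.
#'
#' Fixation intervals are half-open: `end` is the time of the sample after the
#' last window sample (the last sample plus one sample period at the series
#' end), and `duration = end - start`.
#'
#' @param gaze a gaze series tibble (see [build_gaze_series()]) or any tibble
#'   with a time column and the two coordinate columns named by `lon`/`lat`.
#' @param max_dispersion dispersion threshold in degrees (default 3).
#' @param min_duration minimum fixation duration in ms (default 80); a window
#'   qualifies once its timestamps span at least this long.
#' @param lon,lat names of the coordinate columns (default the world-frame eye
#'   point).
#' @return tibble of class `pg_fixations` with columns `fix_index`, `start`,
#'   `end`, `duration`, `lon`, `lat` (centroid); gaze-series metadata
#'   attributes are carried over.
#' @export
detect_fixations <- function(gaze, max_dispersion = 3, min_duration = 80,
                             lon = "eye_lon", lat = "eye_lat") {
  if (nrow(gaze) == 0L) stop("empty sample series")
  t <- gaze$t
  if (is.unsorted(t, strictly = TRUE)) stop("timestamps must be strictly increasing")
  if (max_dispersion <= 0 || min_duration <= 0) stop("thresholds must be positive")
  V <- sph_to_vec(gaze[[lon]], gaze[[lat]])
  n <- nrow(V)
  dt <- if (n > 1L) stats::median(diff(t)) else 0
  cosmax <- cos(max_dispersion * pi / 180)

  m <- idt_scan(t, V, cosmax, min_duration, dt)
  if (nrow(m) > 0L) {
    nrm <- sqrt(rowSums(m[, 3:5, drop = FALSE]^2))
    if (any(nrm < 1e-9)) stop("degenerate spherical mean inside a fixation window")
    ctr <- .vec_to_sph_list(m[, 3:5, drop = FALSE])
  } else {
    ctr <- list(lon = numeric(), lat = numeric())
  }
  fx <- tibble::tibble(fix_index = seq_len(nrow(m)),
                       start = m[, 1], end = m[, 2],
                       duration = m[, 2] - m[, 1],
                       lon = ctr$lon, lat = ctr$lat)
  for (a in c("participant", "scene", "phase")) attr(fx, a) <- attr(gaze, a)
  class(fx) <- c("pg_fixations", class(fx))
  fx
}

#' Head fixations paired with eye fixations
#'
#' The head counterpart of each eye fixation: the spherical mean of the head
#' points over the fixation's half-open time window.
#'
#' @param fixations a `pg_fixations` tibble.
#' @param gaze the gaze series the fixations were detected in.
#' @return tibble with `fix_index`, `lon`, `lat` (head centroid).
#' @export
head_fixations <- function(fixations, gaze) {
  Vh <- sph_to_vec(gaze$head_lon, gaze$head_lat)
  n <- nrow(fixations)
  lon <- lat <- numeric(n)
  for (k in seq_len(n)) {
    rows <- gaze$t >= fixations$start[k] & gaze$t < fixations$end[k]
    if (!any(rows)) stop("fixation window contains no samples")
    ctr <- .sph_mean_c(Vh[rows, , drop = FALSE])
    if (is.null(ctr)) stop("degenerate spherical mean of head points")
    lon[k] <- ctr[1]; lat[k] <- ctr[2]
  }
  tibble::new_tibble(list(fix_index = fixations$fix_index, lon = lon, lat = lat),
                     nrow = n)
}

#' Saccade amplitudes and head shifts
#'
#' Great-circle distances between successive (head) fixation centroids.
#'
#' @param centroids tibble with `lon`, `lat` in fixation order.
#' @return numeric vector of length `nrow(centroids) - 1` (empty for a single
#'   fixation).
#' @export
saccade_amplitudes <- function(centroids) {
  n <- nrow(centroids)
  if (n < 2L) return(numeric())
  angular_distance(centroids$lon[-n], centroids$lat[-n],
                   centroids$lon[-1], centroids$lat[-1])
}

#' @rdname saccade_amplitudes
#' @export
head_shifts <- saccade_amplitudes

#' Exploration tendency
#'
#' Mean great-circle distance of each fixation (after the first) from the
#' trial's first fixation; 0 when there is at most one fixation.
#'
#' @param centroids tibble with `lon`, `lat` in fixation order.
#' @return degrees (scalar).
#' @export
exploration_tendency <- function(centroids) {
  n <- nrow(centroids)
  if (n < 2L) return(0)
  mean(angular_distance(centroids$lon[-1], centroids$lat[-1],
                        centroids$lon[1], centroids$lat[1]))
}

#' Per-trial movement measures
#'
#' Number of fixations, mean fixation duration, exploration tendency of eyes
#' and head, and the saccade-amplitude / head-shift lists, for one trial.
#' With zero fixations the counts are 0 and the means are `NA`.
#'
#' @param fixations a `pg_fixations` tibble.
#' @param head_fix the matching [head_fixations()] tibble (optional; head
#'   measures are `NA` when omitted).
#' @return one-row tibble with list-columns `saccade_amplitudes` and
#'   `head_shifts`.
#' @export
trial_measures <- function(fixations, head_fix = NULL) {
  n <- nrow(fixations)
  tibble::tibble(
    n_fixations = n,
    mean_fixation_duration = if (n > 0) mean(fixations$duration) else NA_real_,
    exploration_eye = if (n > 0) exploration_tendency(fixations) else NA_real_,
    exploration_head = if (!is.null(head_fix) && nrow(head_fix) > 0)
      exploration_tendency(head_fix) else NA_real_,
    saccade_amplitudes = list(saccade_amplitudes(fixations)),
    head_shifts = list(if (is.null(head_fix)) numeric() else head_shifts(head_fix))
  )
}
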