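# Raw eye+head streams -> synchronized world-frame gaze series.

# rowwise shorter-arc slerp between matched quaternion rows
.slerp_rows <- function(q0, q1, f) {
  d <- rowSums(q0 * q1)
  neg <- d < 0
  q1[neg, ] <- -q1[neg, , drop = FALSE]
  d <- pmin(1, abs(d))
  th <- acos(d)
  s <- sin(th)
  lin <- s < 1e-7 # nearly identical: normalized linear interpolation
  w0 <- ifelse(lin, 1 - f, sin((1 - f) * th) / s)
  w1 <- ifelse(lin, f, sin(f * th) / s)
  quat_normalize(q0 * w0 + q1 * w1)
}

#' Interpolate head pose to eye timestamps
#'
#' Spherical linear interpolation of the head quaternion stream at the
#' (higher-rate) eye timestamps. Outside the recorded head span the nearest
#' head frame is held constant.
#'
#' @param head_samples tibble with columns `t`, `qw`, `qx`, `qy`, `qz`
#'   (timestamps in ms, strictly increasing).
#' @param eye_timestamps numeric vector of target timestamps (ms).
#' @return matrix of unit quaternions, one row per eye timestamp.
#' @export
interpolate_head <- function(head_samples, eye_timestamps) {
  if (nrow(head_samples) == 0L) stop("empty head stream")
  th <- head_samples$t
  if (is.unsorted(th, strictly = TRUE)) stop("head timestamps must be strictly increasing")
  Q <- quat_normalize(cbind(head_samples$qw, head_samples$qx,
                            head_samples$qy, head_samples$qz))
  m <- nrow(Q)
  if (m == 1L) return(Q[rep(1L, length(eye_timestamps)), , drop = FALSE])
  i <- findInterval(eye_timestamps, th)
  i <- pmin(pmax(i, 1L), m - 1L)
  f <- (eye_timestamps - th[i]) / (th[i + 1L] - th[i])
  f <- pmin(1, pmax(0, f)) # hold the terminal frames beyond the span
  .slerp_rows(Q[i, , drop = FALSE], Q[i + 1L, , drop = FALSE], f)
}

#' Project eye-in-head directions into world coordinates
#'
#' Composes the head rotation with the eye-in-head direction: the eye point is
#' the world direction of the rotated eye vector, the head point the world
#' direction of the head's forward axis.
#'
#' @param eye_in_head n x 3 matrix of unit eye direction vectors in the head
#'   frame.
#' @param head_q n x 4 matrix of head quaternions (matched rows).
#' @return tibble with `eye_lon`, `eye_lat`, `head_lon`, `head_lat`.
#' @export
project_to_world <- function(eye_in_head, head_q) {
  eye <- vec_to_sph(quat_rotate(head_q, eye_in_head))
  head <- vec_to_sph(quat_rotate(head_q, c(1, 0, 0)))
  tibble::tibble(eye_lon = eye$lon, eye_lat = eye$lat,
                 head_lon = head$lon, head_lat = head$lat)
}

#' Build a synchronized gaze series from a raw trial
#'
#' Interpolates the head stream to the eye timestamps and projects eye and
#' head directions onto the stimulus sphere, keeping the eye-in-head
#' coordinates alongside (needed for head-centered analyses).
#'
#' @param raw a `pg_trial` (from [simulate_trial()] or [read_raw_trial()]).
#' @return tibble of class `pg_gaze` with columns `t`, `eye_lon`, `eye_lat`,
#'   `eih_lon`, `eih_lat`, `head_lon`, `head_lat`; trial metadata is attached
#'   as attributes `participant`, `scene`, `phase`.
#' @export
build_gaze_series <- function(raw) {
  stopifnot(inherits(raw, "pg_trial"))
  t <- raw$eye$t
  if (is.unsorted(t, strictly = TRUE)) stop("eye timestamps must be strictly increasing")
  eih <- cbind(raw$eye$ex, raw$eye$ey, raw$eye$ez)
  q <- interpolate_head(raw$head, t)
  world <- project_to_world(eih, q)
  eihs <- vec_to_sph(eih)
  out <- tibble::new_tibble(list(
    t = t, eye_lon = world$eye_lon, eye_lat = world$eye_lat,
    eih_lon = eihs$lon, eih_lat = eihs$lat,
    head_lon = world$head_lon, head_lat = world$head_lat), nrow = length(t))
  attr(out, "participant") <- raw$participant_id
  attr(out, "scene") <- raw$scene_id
  attr(out, "phase") <- raw$phase
  class(out) <- c("pg_gaze", class(out))
  out
}
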