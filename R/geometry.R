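#' Spherical coordinate conventions
#'
#' All locations on the stimulus sphere are expressed as longitude/latitude in
#' degrees: longitude in \[-180, 180) increasing eastward, latitude in
#' \[-90, 90\] increasing toward the north pole. The world "forward" direction
#' (the trial-start fixation cross) is (0, 0). In Cartesian terms forward is
#' the +x axis, east is +y and up is +z, so a unit vector is
#' (cos(lat)cos(lon), cos(lat)sin(lon), sin(lat)). At the poles the longitude
#' is defined as 0.
#'
#' @name sphere-conventions
NULL

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

# clamp cosines into [-1, 1]; matrix-first pmin/pmax keeps dim attributes
.clamp1 <- function(x) pmax(pmin(x, 1), -1)

#' Wrap longitudes into \[-180, 180)
#'
#' @param lon numeric vector of longitudes in degrees.
#' @return numeric vector wrapped modulo 360 into \[-180, 180).
#' @export
#' @examples
#' wrap_longitude(c(190, -185, 180))
wrap_longitude <- function(lon) {
  ((lon + 180) %% 360) - 180
}

#' Convert longitude/latitude to unit vectors
#'
#' @param lon,lat numeric vectors in degrees (recycled to common length).
#' @return numeric matrix with one row per point and columns `x`, `y`, `z`.
#' @export
#' @examples
#' sph_to_vec(0, 0)   # forward axis
#' sph_to_vec(0, 90)  # up axis
sph_to_vec <- function(lon, lat) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n) * .deg2rad
  lat <- rep_len(lat, n) * .deg2rad
  cl <- cos(lat)
  cbind(x = cl * cos(lon), y = cl * sin(lon), z = sin(lat))
}

#' Convert unit vectors to longitude/latitude
#'
#' The inverse of [sph_to_vec()]; vectors are normalized first so any nonzero
#' vector maps to its ray's intersection with the sphere. At the poles the
#' longitude is reported as 0.
#'
#' @param v numeric matrix (n x 3) or length-3 vector.
#' @return tibble with columns `lon`, `lat` in degrees.
#' @export
vec_to_sph <- function(v) {
  out <- .vec_to_sph_list(v)
  tibble::new_tibble(out, nrow = length(out$lon))
}

# plain-list variant of vec_to_sph for hot paths
.vec_to_sph_list <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-12)) stop("cannot project a zero vector to the sphere")
  v <- v / nrm
  lat <- asin(pmin(1, pmax(-1, v[, 3]))) * .rad2deg
  lon <- atan2(v[, 2], v[, 1]) * .rad2deg
  lon[abs(lat) >= 90 - 1e-12] <- 0
  list(lon = wrap_longitude(lon), lat = lat)
}

# spherical mean of unit-vector rows -> c(lon, lat); NULL if degenerate
.sph_mean_c <- function(V) {
  m <- colSums(V)
  if (sqrt(sum(m^2)) <= 1e-9 * nrow(V)) return(NULL)
  p <- .vec_to_sph_list(m)
  c(p$lon, p$lat)
}

#' Great-circle angular distance
#'
#' Central angle between points on the sphere, in degrees. Vectorized over its
#' arguments (recycled to a common length).
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return numeric vector of angles in \[0, 180\].
#' @export
#' @examples
#' angular_distance(0, 0, 90, 0)   # 90
#' angular_distance(0, 90, 0, -90) # 180
angular_distance <- function(lon1, lat1, lon2, lat2) {
  n <- max(length(lon1), length(lat1), length(lon2), length(lat2))
  la1 <- rep_len(lat1, n) * .deg2rad
  la2 <- rep_len(lat2, n) * .deg2rad
  dlo <- (rep_len(lon2, n) - rep_len(lon1, n)) * .deg2rad
  # Vincenty form: numerically stable for both tiny and near-antipodal angles
  y <- sqrt((cos(la2) * sin(dlo))^2 +
            (cos(la1) * sin(la2) - sin(la1) * cos(la2) * cos(dlo))^2)
  x <- sin(la1) * sin(la2) + cos(la1) * cos(la2) * cos(dlo)
  atan2(y, x) * .rad2deg
}

# angles (deg) between one unit vector u and the rows of matrix V
.angles_to <- function(V, u) {
  acos(pmin(1, pmax(-1, drop(V %*% u)))) * .rad2deg
}

# max pairwise great-circle angle among rows of unit-vector matrix V (degrees)
.max_pairwise_angle <- function(V) {
  if (nrow(V) < 2L) return(0)
  G <- tcrossprod(V)
  acos(pmin(1, pmax(-1, min(G)))) * .rad2deg
}

#' Spherical (resultant-vector) mean of points
#'
#' The normalized, optionally weighted, vector mean projected back to the
#' sphere. Fails explicitly for degenerate sets whose resultant vector is
#' (numerically) zero, e.g. two antipodal points.
#'
#' @param lon,lat coordinates in degrees.
#' @param weights optional non-negative weights, recycled.
#' @return one-row tibble with columns `lon`, `lat`.
#' @export
#' @examples
#' spherical_mean(c(10, -10), c(0, 0)) # (0, 0)
spherical_mean <- function(lon, lat, weights = NULL) {
  if (length(lon) == 0L) stop("spherical_mean needs at least one point")
  V <- sph_to_vec(lon, lat)
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("weights must be non-negative")
    V <- V * rep_len(weights, nrow(V))
  }
  p <- .sph_mean_c(V)
  if (is.null(p)) stop("degenerate spherical mean: resultant vector is zero")
  tibble::new_tibble(list(lon = p[1], lat = p[2]), nrow = 1L)
}

# ---- quaternions ------------------------------------------------------------
# Stored as plain numeric matrices with columns w, x, y, z (one row per
# quaternion); scalar helpers accept length-4 vectors.

.as_quat <- function(q) {
  if (is.null(dim(q))) q <- matrix(q, nrow = 1)
  stopifnot(ncol(q) == 4)
  q
}

#' Construct unit quaternions
#'
#' @param w,x,y,z components (recycled to common length). The result is
#'   normalized and canonicalized to `w >= 0` (q and -q encode the same
#'   rotation).
#' @return n x 4 matrix with columns `w`, `x`, `y`, `z`.
#' @export
quat <- function(w, x, y, z) {
  n <- max(length(w), length(x), length(y), length(z))
  q <- cbind(w = rep_len(w, n), x = rep_len(x, n),
             y = rep_len(y, n), z = rep_len(z, n))
  quat_normalize(q)
}

#' @rdname quat
#' @param q quaternion matrix.
#' @export
quat_normalize <- function(q) {
  q <- .as_quat(q)
  nrm <- sqrt(rowSums(q^2))
  if (any(nrm < 1e-12)) stop("cannot normalize a zero quaternion")
  q <- q / nrm
  flip <- q[, 1] < 0
  q[flip, ] <- -q[flip, ]
  colnames(q) <- c("w", "x", "y", "z")
  q
}

#' Axis-angle quaternion
#'
#' @param axis length-3 vector (normalized internally).
#' @param angle_deg rotation angle in degrees (right-hand rule).
#' @return 1 x 4 quaternion matrix.
#' @export
quat_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  h <- angle_deg * .deg2rad / 2
  quat(cos(h), sin(h) * axis[1], sin(h) * axis[2], sin(h) * axis[3])
}

#' Quaternion product (rowwise)
#'
#' Composes rotations: `quat_multiply(a, b)` applies `b` first, then `a`.
#'
#' @param a,b quaternion matrices (rows recycled to common length).
#' @return quaternion matrix of products.
#' @export
quat_multiply <- function(a, b) {
  a <- .as_quat(a); b <- .as_quat(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) != n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  cbind(
    w = a[, 1] * b[, 1] - a[, 2] * b[, 2] - a[, 3] * b[, 3] - a[, 4] * b[, 4],
    x = a[, 1] * b[, 2] + a[, 2] * b[, 1] + a[, 3] * b[, 4] - a[, 4] * b[, 3],
    y = a[, 1] * b[, 3] - a[, 2] * b[, 4] + a[, 3] * b[, 1] + a[, 4] * b[, 2],
    z = a[, 1] * b[, 4] + a[, 2] * b[, 3] - a[, 3] * b[, 2] + a[, 4] * b[, 1]
  )
}

#' @rdname quat_multiply
#' @param q quaternion matrix.
#' @export
quat_conjugate <- function(q) {
  q <- .as_quat(q)
  cbind(w = q[, 1], x = -q[, 2], y = -q[, 3], z = -q[, 4])
}

#' Rotate vectors by quaternions (rowwise)
#'
#' @param q n x 4 quaternion matrix (or one quaternion applied to all rows).
#' @param v n x 3 matrix of vectors (or one vector).
#' @return n x 3 matrix of rotated vectors.
#' @export
quat_rotate <- function(q, v) {
  q <- .as_quat(q)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  n <- max(nrow(q), nrow(v))
  if (nrow(q) != n) q <- q[rep_len(seq_len(nrow(q)), n), , drop = FALSE]
  if (nrow(v) != n) v <- v[rep_len(seq_len(nrow(v)), n), , drop = FALSE]
  u <- q[, 2:4, drop = FALSE]
  w <- q[, 1]
  # v' = v + 2 u x (u x v + w v)
  cr <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                             a[, 3] * b[, 1] - a[, 1] * b[, 3],
                             a[, 1] * b[, 2] - a[, 2] * b[, 1])
  t1 <- cr(u, v) + w * v
  out <- v + 2 * cr(u, t1)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Rotation angle between quaternions
#'
#' @param a,b quaternion matrices (rowwise).
#' @return angle in degrees in \[0, 180\].
#' @export
quat_angle <- function(a, b) {
  a <- .as_quat(a); b <- .as_quat(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) != n) a <- a[rep_len(seq_len(nrow(a)), n), , drop = FALSE]
  if (nrow(b) != n) b <- b[rep_len(seq_len(nrow(b)), n), , drop = FALSE]
  d <- abs(rowSums(a * b))
  2 * acos(pmin(1, d)) * .rad2deg
}

#' Spherical linear interpolation between unit quaternions
#'
#' Interpolates along the shorter arc (`q1` is negated when `dot(q0, q1) < 0`),
#' falling back to normalized linear interpolation when the endpoints are
#' nearly identical. The rotation angle from `q0` grows linearly in `t`.
#'
#' @param q0,q1 single quaternions (1 x 4 matrices or length-4 vectors).
#' @param t interpolation parameter(s) in \[0, 1\]; vectorized.
#' @return length(t) x 4 quaternion matrix.
#' @export
slerp <- function(q0, q1, t) {
  q0 <- quat_normalize(q0); q1 <- quat_normalize(q1)
  d <- sum(q0 * q1)
  if (d < 0) { q1 <- -q1; d <- -d }
  d <- min(1, d)
  if (d > 1 - 1e-12) {
    out <- outer(1 - t, drop(q0)) + outer(t, drop(q1))
    return(quat_normalize(out))
  }
  th <- acos(d)
  s <- sin(th)
  out <- outer(sin((1 - t) * th) / s, drop(q0)) + outer(sin(t * th) / s, drop(q1))
  quat_normalize(out)
}

#' Zero-roll head quaternion pointing at a sphere location
#'
#' Builds the yaw-then-pitch rotation that takes the world forward axis to the
#' direction (`lon`, `lat`) without introducing roll.
#'
#' @param lon,lat direction in degrees (vectorized).
#' @return n x 4 quaternion matrix.
#' @export
quat_look_at <- function(lon, lat) {
  n <- max(length(lon), length(lat))
  lon <- rep_len(lon, n); lat <- rep_len(lat, n)
  hy <- lon * .deg2rad / 2
  hp <- -lat * .deg2rad / 2 # pitch about +y by -lat raises forward toward +z
  yaw <- cbind(cos(hy), 0, 0, sin(hy))
  pit <- cbind(cos(hp), 0, sin(hp), 0)
  quat_normalize(quat_multiply(yaw, pit))
}
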