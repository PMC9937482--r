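# Directional random samplers used by the synthetic-study generator.

#' Sample from a von Mises distribution (degrees)
#'
#' Best–Fisher rejection sampler on the circle. Used for horizon-concentrated
#' latitudes of region-of-interest centers.
#'
#' @param n number of draws.
#' @param mu_deg mean direction in degrees.
#' @param kappa concentration (> 0); `Inf` returns `mu_deg` exactly.
#' @return numeric vector of angles in degrees in \[-180, 180).
#' @export
rvonmises_deg <- function(n, mu_deg = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be non-negative")
  if (is.infinite(kappa)) return(rep(wrap_longitude(mu_deg), n))
  if (kappa == 0) return(stats::runif(n, -180, 180))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    ok <- (c_ * (2 - c_) - u2 > 0) | (log(c_ / u2) + 1 - c_ >= 0)
    th <- sign(u3 - 0.5)[ok] * acos(pmin(1, pmax(-1, f[ok])))
    take <- min(length(th), n - got)
    if (take > 0) out[(got + 1):(got + take)] <- th[seq_len(take)]
    got <- got + take
  }
  wrap_longitude(mu_deg + out * 180 / pi)
}

#' Sample from a von Mises–Fisher distribution on the sphere
#'
#' Inverse-CDF sampling of the cosine of the colatitude about the mean
#' direction, uniform azimuth, then rotation of the pole to the mean. The
#' spherical analogue of an isotropic Gaussian with concentration `kappa`.
#'
#' @param n number of draws.
#' @param mu_lon,mu_lat mean direction in degrees.
#' @param kappa concentration (> 0); `Inf` returns the mean exactly.
#' @return tibble with columns `lon`, `lat`.
#' @export
rvmf <- function(n, mu_lon = 0, mu_lat = 0, kappa = 1) {
  if (kappa <= 0) stop("kappa must be positive")
  if (is.infinite(kappa)) {
    return(tibble::tibble(lon = rep(wrap_longitude(mu_lon), n),
                          lat = rep(mu_lat, n)))
  }
  local <- .rvmf_offsets(n, kappa)
  out <- .vec_to_sph_list(local %*% t(.rotmat_pole_to(mu_lon, mu_lat)))
  tibble::new_tibble(out, nrow = n)
}

# n x 3 vMF draws about the +z pole (unrotated)
.rvmf_offsets <- function(n, kappa) {
  u <- stats::runif(n)
  # stable closed form for W = cos(angle from the mean direction)
  w <- 1 + (log(u + (1 - u) * exp(-2 * kappa))) / kappa
  w <- pmin(1, pmax(-1, w))
  th <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  cbind(s * cos(th), s * sin(th), w)
}

# rotation matrix taking the +z pole onto direction (lon, lat)
.rotmat_pole_to <- function(lon, lat) {
  d <- drop(sph_to_vec(lon, lat))
  ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- c(ref[2] * d[3] - ref[3] * d[2],
          ref[3] * d[1] - ref[1] * d[3],
          ref[1] * d[2] - ref[2] * d[1])
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(d[2] * t1[3] - d[3] * t1[2],
          d[3] * t1[1] - d[1] * t1[3],
          d[1] * t1[2] - d[2] * t1[1])
  cbind(t1, t2, d, deparse.level = 0)
}
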