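# Spatial statistics: spreads, angular-Gaussian equirectangular heatmaps,
# latitude-weighted heatmap correlations and same/different-scene contrasts.

#' Per-trial spread of points and phase medians
#'
#' For each trial the longitudes are rotated so that their circular mean sits
#' at 0 degrees and wrapped to \[-180, 180), then the ordinary standard
#' deviations of longitudes and latitudes are taken. `spread_statistics()`
#' returns the per-trial SDs; [spread_medians()] the across-trial median per
#' phase (the "spread" summary).
#'
#' @param points tibble with columns `participant`, `scene`, `phase`, `lon`,
#'   `lat` (one row per fixation or sample).
#' @return tibble with one row per trial: `participant`, `scene`, `phase`,
#'   `n`, `sd_lon`, `sd_lat`. Trials with fewer than 2 points are skipped
#'   with a message.
#' @export
spread_statistics <- function(points) {
  grp <- dplyr::group_by(points, .data$participant, .data$scene, .data$phase)
  out <- dplyr::summarise(grp, n = dplyr::n(), sd_lon = {
    mu <- atan2(mean(sin(.data$lon * pi / 180)), mean(cos(.data$lon * pi / 180))) * 180 / pi
    stats::sd(wrap_longitude(.data$lon - mu))
  }, sd_lat = stats::sd(.data$lat), .groups = "drop")
  dropped <- sum(out$n < 2)
  if (dropped > 0) message(dropped, " trial(s) with < 2 points skipped")
  out[out$n >= 2, ]
}

#' @rdname spread_statistics
#' @param spreads output of `spread_statistics()`. Recognition sub-phases
#'   (old/new) are pooled into a single recognition phase, as in the
#'   encoding-versus-recognition spread comparison.
#' @export
spread_medians <- function(spreads) {
  spreads <- dplyr::mutate(spreads, phase = ifelse(.data$phase == "encoding",
                                                   "encoding", "recognition"))
  dplyr::summarise(dplyr::group_by(spreads, .data$phase),
                   n_trials = dplyr::n(),
                   median_sd_lon = stats::median(.data$sd_lon),
                   median_sd_lat = stats::median(.data$sd_lat),
                   .groups = "drop")
}

#' Equirectangular heatmap with an angular Gaussian kernel
#'
#' Each point deposits `exp(-d^2 / (2 sigma^2))` over grid-cell centers, where
#' `d` is the great-circle distance from the point to the cell center,
#' truncated at `3 * sigma`; each point's kernel is normalized to unit mass
#' before accumulation (cells pack denser in longitude near the poles, so an
#' unnormalized kernel would overweight high-latitude points), and the grid is
#' normalized to unit total mass. Because the kernel is defined in angular
#' distance it remains isotropic on the sphere: near the poles the mass
#' spreads over many longitude columns instead of pinching into a few, unlike
#' a planar Gaussian on the projected grid.
#'
#' @param lon,lat point coordinates in degrees.
#' @param sigma kernel width in degrees of angular distance (default 4).
#' @param resolution grid resolution in degrees per cell (default 1).
#' @param weights optional per-point non-negative weights.
#' @return matrix of class `pg_heatmap` with rows = latitudes (90 down to
#'   -90) and columns = longitudes (-180 to 180); attributes `lat_centers`,
#'   `lon_centers`, `resolution`, `empty`.
#' @export
make_heatmap <- function(lon, lat, sigma = 4, resolution = 1, weights = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  nr <- round(180 / resolution); nc <- round(360 / resolution)
  lat_c <- 90 - (seq_len(nr) - 0.5) * resolution
  lon_c <- -180 + (seq_len(nc) - 0.5) * resolution
  grid <- matrix(0, nr, nc)
  empty <- length(lon) == 0L
  if (empty) {
    grid[] <- 1 / (nr * nc) # flagged uniform map
  } else {
    if (is.null(weights)) weights <- rep(1, length(lon))
    cut <- 3 * sigma
    slat <- sin(lat_c * pi / 180); clat <- cos(lat_c * pi / 180)
    for (p in seq_along(lon)) {
      rows <- which(abs(lat_c - lat[p]) <= cut)
      if (!length(rows)) next
      sp <- sin(lat[p] * pi / 180); cp <- cos(lat[p] * pi / 180)
      dlon <- (lon[p] - lon_c) * pi / 180
      d <- acos(.clamp1(outer(slat[rows] * sp, rep(1, nc)) +
                        outer(clat[rows] * cp, cos(dlon)))) * 180 / pi
      kern <- exp(-d^2 / (2 * sigma^2))
      kern[d > cut] <- 0
      ks <- sum(kern)
      if (ks > 0) grid[rows, ] <- grid[rows, ] + weights[p] * kern / ks
    }
    s <- sum(grid)
    if (s > 0) grid <- grid / s else { grid[] <- 1 / (nr * nc); empty <- TRUE }
  }
  structure(grid, lat_centers = lat_c, lon_centers = lon_c,
            resolution = resolution, empty = empty,
            class = c("pg_heatmap", "matrix", "array"))
}

#' Latitude-weighted Pearson correlation of two heatmaps
#'
#' Weighted Pearson correlation over cells with weight `cos(latitude of the
#' cell center)`, the exact inverse of the equirectangular area stretching
#' (the projection stretches area by `1 / cos(latitude)`), so every region of
#' the sphere contributes in proportion to its true area.
#'
#' @param h1,h2 heatmaps from [make_heatmap()] on the same grid.
#' @return correlation in \[-1, 1\]; `NA` (with a warning) if either map has
#'   zero weighted variance.
#' @export
weighted_correlation <- function(h1, h2) {
  if (!identical(dim(h1), dim(h2))) stop("heatmaps must share the same grid")
  w <- rep(cos(attr(h1, "lat_centers") * pi / 180), times = ncol(h1))
  x <- as.vector(h1); y <- as.vector(h2)
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  vx <- sum(w * (x - mx)^2); vy <- sum(w * (y - my)^2)
  if (vx <= 0 || vy <= 0) {
    warning("zero-variance heatmap: correlation undefined")
    return(NA_real_)
  }
  sum(w * (x - mx) * (y - my)) / sqrt(vx * vy)
}

#' Build per-scene heatmaps from a fixation table
#'
#' Pools fixation centroids across participants within scene x phase and
#' builds one heatmap per combination, for the requested target
#' (`eye` = world-frame eye point, `head` = head point).
#'
#' @param fixations tibble with `scene`, `phase`, and coordinate columns
#'   `eye_lon`/`eye_lat` and `head_lon`/`head_lat`.
#' @param target `"eye"` or `"head"`.
#' @param sigma,resolution passed to [make_heatmap()].
#' @return tibble with `scene`, `phase`, `n_points` and a list-column
#'   `heatmap`. Recognition sub-phases are collapsed to `"recognition"`.
#' @export
scene_heatmaps <- function(fixations, target = c("eye", "head"),
                           sigma = 4, resolution = 1) {
  target <- match.arg(target)
  loncol <- paste0(target, "_lon"); latcol <- paste0(target, "_lat")
  fx <- dplyr::mutate(fixations,
                      phase = ifelse(.data$phase == "encoding", "encoding", "recognition"))
  grp <- dplyr::group_by(fx, .data$scene, .data$phase)
  dplyr::summarise(grp, n_points = dplyr::n(),
                   heatmap = list(make_heatmap(.data[[loncol]], .data[[latcol]],
                                               sigma = sigma, resolution = resolution)),
                   .groups = "drop")
}

#' Same-scene versus different-scene heatmap correlations
#'
#' The heatmap-similarity contrast: for every scene, the correlation between
#' two matched maps of the *same* scene is compared with the correlation
#' between maps of *different* scenes (a seeded random derangement), by a
#' paired t test across scenes. Two variants are supported:
#' `mode = "enc_rec"` correlates encoding with recognition maps of one target
#' (eye or head); `mode = "eye_head"` correlates eye with head maps within
#' one phase.
#'
#' @param maps1,maps2 tibbles from [scene_heatmaps()]: the two map sets to
#'   pair (e.g. encoding eye maps and recognition eye maps). Only scenes
#'   present in both are used.
#' @param seed integer seed for the different-scene pairing.
#' @return list of class `pg_contrast`: per-scene tibble (`scene`,
#'   `scene_other`, `r_same`, `r_diff`), means, and the paired t test.
#' @export
heatmap_contrast <- function(maps1, maps2, seed = 1L) {
  scn <- intersect(maps1$scene, maps2$scene)
  if (length(scn) < 2L) stop("need at least 2 scenes")
  m1 <- maps1$heatmap[match(scn, maps1$scene)]
  m2 <- maps2$heatmap[match(scn, maps2$scene)]
  n <- length(scn)
  perm <- withr::with_seed(seed, {
    p <- sample(n)
    while (any(p == seq_len(n))) p <- sample(n) # derangement: never pair a scene with itself
    p
  })
  r_same <- purrr::map_dbl(seq_len(n), ~ weighted_correlation(m1[[.x]], m2[[.x]]))
  r_diff <- purrr::map_dbl(seq_len(n), ~ weighted_correlation(m1[[.x]], m2[[perm[.x]]]))
  tt <- stats::t.test(r_same, r_diff, paired = TRUE)
  structure(list(
    scenes = tibble::tibble(scene = scn, scene_other = scn[perm],
                            r_same = r_same, r_diff = r_diff),
    mean_r_same = mean(r_same), mean_r_diff = mean(r_diff),
    t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    seed = seed
  ), class = "pg_contrast")
}

#' @export
print.pg_contrast <- function(x, ...) {
  cat(sprintf("<pg_contrast> mean r(same) = %.3f, mean r(diff) = %.3f, t(%d) = %.2f, p = %.3g\n",
              x$mean_r_same, x$mean_r_diff, x$df, x$t, x$p))
  invisible(x)
}

#' Convenience wrapper: encoding-vs-recognition or eye-vs-head contrast
#'
#' @param fixations fixation table (see [scene_heatmaps()]).
#' @param mode `"enc_rec"` (same target across phases) or `"eye_head"`
#'   (both targets within one phase).
#' @param target target for `"enc_rec"` mode.
#' @param phase phase for `"eye_head"` mode.
#' @param seed pairing seed.
#' @param sigma,resolution heatmap parameters.
#' @return a `pg_contrast` (see [heatmap_contrast()]).
#' @export
same_vs_different_contrast <- function(fixations, mode = c("enc_rec", "eye_head"),
                                       target = c("eye", "head"),
                                       phase = c("encoding", "recognition"),
                                       seed = 1L, sigma = 4, resolution = 1) {
  mode <- match.arg(mode)
  if (mode == "enc_rec") {
    target <- match.arg(target)
    maps <- scene_heatmaps(fixations, target, sigma, resolution)
    heatmap_contrast(maps[maps$phase == "encoding", ],
                     maps[maps$phase == "recognition", ], seed = seed)
  } else {
    phase <- match.arg(phase)
    eye <- scene_heatmaps(fixations, "eye", sigma, resolution)
    head <- scene_heatmaps(fixations, "head", sigma, resolution)
    heatmap_contrast(eye[eye$phase == phase, ],
                     head[head$phase == phase, ], seed = seed)
  }
}
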