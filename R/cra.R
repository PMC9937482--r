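# Cross-recurrence quantification of equal-length spherical fixation
# sequences: recurrence matrix, the nine measures, and radius calibration.

#' Adjust two fixation sequences to equal length
#'
#' Truncates both sequences to the length of the shorter by dropping trailing
#' fixations, preserving temporal alignment from trial onset.
#'
#' @param seq_e,seq_r tibbles with columns `lon`, `lat` in fixation order.
#' @return list with elements `e`, `r` (equal row counts) and `n`.
#' @export
adjust_lengths <- function(seq_e, seq_r) {
  if (nrow(seq_e) == 0L || nrow(seq_r) == 0L) stop("empty fixation sequence")
  n <- min(nrow(seq_e), nrow(seq_r))
  if (n < 2L) warning("very short adjusted sequence (N = ", n, ")")
  list(e = seq_e[seq_len(n), ], r = seq_r[seq_len(n), ], n = n)
}

#' Cross-recurrence matrix
#'
#' Binary N x N matrix with rows indexing encoding fixations and columns
#' recognition fixations; cell (i, j) is 1 iff the great-circle distance
#' between encoding fixation i and recognition fixation j is at most
#' `radius` (ties at exactly the radius count as recurrent).
#'
#' @param seq_e,seq_r equal-length tibbles with `lon`, `lat`.
#' @param radius recurrence radius in degrees (>= 0). Ties at exactly the
#'   radius count as recurrent (a 1e-9 degree guard absorbs floating-point
#'   noise in the distances).
#' @return integer matrix of class `pg_recurrence` with attribute `radius`.
#' @export
recurrence_matrix <- function(seq_e, seq_r, radius) {
  stopifnot(nrow(seq_e) == nrow(seq_r), radius >= 0)
  D <- cross_distances(seq_e, seq_r)
  structure((D <= radius + 1e-9) + 0L, radius = radius,
            class = c("pg_recurrence", "matrix", "array"))
}

#' @rdname recurrence_matrix
#' @export
cross_distances <- function(seq_e, seq_r) {
  Ve <- sph_to_vec(seq_e$lon, seq_e$lat)
  Vr <- sph_to_vec(seq_r$lon, seq_r$lat)
  # half-chord form on explicit coordinate differences: exact zeros for
  # identical points and accurate small angles
  ch2 <- outer(Ve[, 1], Vr[, 1], "-")^2 + outer(Ve[, 2], Vr[, 2], "-")^2 +
    outer(Ve[, 3], Vr[, 3], "-")^2
  2 * asin(pmin(sqrt(ch2) / 2, 1)) * 180 / pi
}

# run lengths of 1s along every diagonal parallel to the main diagonal
.diag_runs <- function(R) {
  n <- nrow(R)
  runs <- integer(0)
  for (off in (-(n - 1L)):(n - 1L)) {
    i <- if (off >= 0) seq_len(n - off) else seq(1 - off, n)
    j <- i + off
    line <- R[cbind(i, j)]
    r <- rle(line)
    runs <- c(runs, r$lengths[r$values == 1L])
  }
  runs
}

# run lengths of 1s down each column (consecutive i at fixed j)
.col_runs <- function(R) {
  unlist(apply(R, 2L, function(col) { r <- rle(col); r$lengths[r$values == 1L] },
               simplify = FALSE), use.names = FALSE)
}

#' Recurrence measures
#'
#' The nine cross-recurrence statistics. `rec()` is the percentage of
#' recurrent points out of N^2; `det_()` the percentage of recurrent points on
#' diagonal runs (length >= `min_line`, any diagonal parallel to the main
#' one); `laminarity_vertical()` / `laminarity_horizontal()` the percentage on
#' vertical (consecutive encoding indices at one recognition fixation) /
#' horizontal runs together with the mean qualifying run length (the trapping
#' times); `corm()` the center of recurrence mass, positive when recurrences
#' concentrate where the recognition index exceeds the encoding index
#' (primacy); `clust()` the percentage in 8-connected components of at least
#' `min_cluster` recurrences; `ent()` the Shannon entropy (nats) of the
#' distribution of diagonal run lengths >= `min_line`. Measures whose
#' denominator is empty (no recurrences, no qualifying runs) are `NA`.
#'
#' @param R a recurrence matrix.
#' @param min_line minimum run length (default 2).
#' @param min_cluster minimum cluster size (default 8).
#' @return `rec`, `det_`, `corm`, `clust`, `ent` return a scalar; the
#'   laminarity functions a named vector `c(lam, tt)`.
#' @export
rec <- function(R) 100 * sum(R) / length(R)

#' @rdname rec
#' @export
det_ <- function(R, min_line = 2) {
  tot <- sum(R)
  if (tot == 0) return(NA_real_)
  runs <- .diag_runs(R)
  100 * sum(runs[runs >= min_line]) / tot
}

#' @rdname rec
#' @export
laminarity_vertical <- function(R, min_line = 2) {
  tot <- sum(R)
  if (tot == 0) return(c(lam = NA_real_, tt = NA_real_))
  runs <- .col_runs(R)
  q <- runs[runs >= min_line]
  c(lam = 100 * sum(q) / tot, tt = if (length(q)) mean(q) else NA_real_)
}

#' @rdname rec
#' @export
laminarity_horizontal <- function(R, min_line = 2) {
  laminarity_vertical(t(R), min_line)
}

#' @rdname rec
#' @export
corm <- function(R) {
  tot <- sum(R)
  if (tot == 0) return(NA_real_)
  n <- nrow(R)
  ij <- which(R == 1L, arr.ind = TRUE)
  100 * sum(ij[, 2] - ij[, 1]) / ((n - 1) * tot)
}

#' @rdname rec
#' @export
clust <- function(R, min_cluster = 8) {
  tot <- sum(R)
  if (tot == 0) return(NA_real_)
  pts <- which(R == 1L, arr.ind = TRUE)
  np <- nrow(pts)
  if (np == 1L) return(if (min_cluster <= 1) 100 else 0)
  # 8-neighbour adjacency graph over recurrent cells
  key <- pts[, 1] * (ncol(R) + 2L) + pts[, 2]
  idx <- seq_len(np)
  edges <- list()
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    nb <- match((pts[, 1] + di) * (ncol(R) + 2L) + (pts[, 2] + dj), key)
    ok <- !is.na(nb)
    if (any(ok)) edges[[length(edges) + 1L]] <- cbind(idx[ok], nb[ok])
  }
  if (!length(edges)) return(if (min_cluster <= 1) 100 else 0)
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, np - igraph::vcount(g)))
  comp <- igraph::components(g)
  100 * sum(comp$csize[comp$csize >= min_cluster]) / np
}

#' @rdname rec
#' @export
ent <- function(R, min_line = 2) {
  runs <- .diag_runs(R)
  q <- runs[runs >= min_line]
  if (!length(q)) return(NA_real_)
  p <- table(q) / length(q)
  -sum(p * log(p))
}

#' All nine cross-recurrence measures for a sequence pair
#'
#' Adjusts the two sequences to equal length, thresholds the cross-distance
#' matrix at `radius`, and computes REC, DET, hLAM, hTT, vLAM, vTT, CORM,
#' CLUST and ENT.
#'
#' @param seq_e,seq_r tibbles with `lon`, `lat` (encoding and recognition
#'   fixation sequences).
#' @param radius recurrence radius in degrees.
#' @param min_line,min_cluster see [rec()].
#' @return one-row tibble: `rec`, `det`, `hlam`, `htt`, `vlam`, `vtt`,
#'   `corm`, `clust`, `ent`, `n_adjusted`, `radius`.
#' @export
compute_all <- function(seq_e, seq_r, radius, min_line = 2, min_cluster = 8) {
  adj <- adjust_lengths(seq_e, seq_r)
  R <- recurrence_matrix(adj$e, adj$r, radius)
  v <- laminarity_vertical(R, min_line)
  h <- laminarity_horizontal(R, min_line)
  tibble::tibble(rec = rec(R), det = det_(R, min_line),
                 hlam = h[["lam"]], htt = h[["tt"]],
                 vlam = v[["lam"]], vtt = v[["tt"]],
                 corm = corm(R), clust = clust(R, min_cluster),
                 ent = ent(R, min_line),
                 n_adjusted = adj$n, radius = radius)
}

#' Calibrate the recurrence radius to a target mean recurrence
#'
#' Mean cross-recurrence over a set of sequence pairs is a nondecreasing step
#' function of the radius; bisection on \[0, 180\] degrees returns the
#' smallest radius whose mean REC reaches the target. The achieved mean REC
#' should sit within `tol` of the target; an unreachable target (e.g. below
#' the minimum positive recurrence of degenerate pairs) is reported.
#'
#' @param pairs list of sequence pairs, each a list with elements `e` and `r`
#'   (tibbles with `lon`, `lat`).
#' @param target_rec target mean recurrence, percent (default 7).
#' @param tol acceptable overshoot of the achieved mean REC, percentage
#'   points (default 0.01).
#' @param max_iter bisection iterations (default 64).
#' @return one-row tibble: `radius` (degrees), `achieved_rec`, `n_pairs`.
#' @export
calibrate_radius <- function(pairs, target_rec = 7, tol = 0.01, max_iter = 64L) {
  if (!length(pairs)) stop("need at least one sequence pair")
  if (target_rec <= 0 || target_rec > 100) stop("target_rec must be in (0, 100]")
  dists <- purrr::map(pairs, function(p) {
    adj <- adjust_lengths(p$e, p$r)
    cross_distances(adj$e, adj$r)
  })
  mean_rec <- function(rad) mean(purrr::map_dbl(dists, ~ 100 * mean(.x <= rad)))
  if (mean_rec(0) >= target_rec) {
    achieved <- mean_rec(0)
    if (achieved - target_rec > tol)
      warning(sprintf("target %.3g%% unreachable: mean REC is already %.3g%% at radius 0",
                      target_rec, achieved))
    return(tibble::tibble(radius = 0, achieved_rec = achieved, n_pairs = length(pairs)))
  }
  lo <- 0; hi <- 180
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (mean_rec(mid) >= target_rec) hi <- mid else lo <- mid
  }
  achieved <- mean_rec(hi)
  if (achieved - target_rec > tol)
    warning(sprintf("achieved mean REC %.4g%% overshoots the %.4g%% target by more than %g",
                    achieved, target_rec, tol))
  tibble::tibble(radius = hi, achieved_rec = achieved, n_pairs = length(pairs))
}
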