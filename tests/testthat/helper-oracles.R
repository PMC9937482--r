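# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# great-circle angle via explicit unit vectors and acos of the dot product
oracle_angle <- function(lon1, lat1, lon2, lat2) {
  v <- function(lon, lat) {
    lon <- lon * pi / 180; lat <- lat * pi / 180
    c(cos(lat) * cos(lon), cos(lat) * sin(lon), sin(lat))
  }
  a <- v(lon1, lat1); b <- v(lon2, lat2)
  acos(min(1, max(-1, sum(a * b)))) * 180 / pi
}

# 3x3 rotation matrix of a quaternion (w, x, y, z)
oracle_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# ---- cross-recurrence measures by exhaustive enumeration --------------------

oracle_rec <- function(R) 100 * sum(R) / length(R)

# collect run lengths of 1s along all diagonals (parallel to the main one)
oracle_diag_runs <- function(R) {
  n <- nrow(R)
  runs <- integer(0)
  for (off in -(n - 1):(n - 1)) {
    len <- 0L
    for (i in 1:n) {
      j <- i + off
      v <- if (j >= 1 && j <= n) R[i, j] else 0L
      if (v == 1L) len <- len + 1L
      else { if (len > 0L) runs <- c(runs, len); len <- 0L }
    }
    if (len > 0L) runs <- c(runs, len)
  }
  runs
}

oracle_det <- function(R, min_line = 2) {
  tot <- sum(R)
  if (tot == 0) return(NA_real_)
  runs <- oracle_diag_runs(R)
  100 * sum(runs[runs >= min_line]) / tot
}

oracle_col_runs <- function(R) {
  runs <- integer(0)
  for (j in seq_len(ncol(R))) {
    len <- 0L
    for (i in seq_len(nrow(R))) {
      if (R[i, j] == 1L) len <- len + 1L
      else { if (len > 0L) runs <- c(runs, len); len <- 0L }
    }
    if (len > 0L) runs <- c(runs, len)
  }
  runs
}

oracle_vlam <- function(R, min_line = 2) {
  tot <- sum(R)
  if (tot == 0) return(c(NA_real_, NA_real_))
  runs <- oracle_col_runs(R)
  q <- runs[runs >= min_line]
  c(100 * sum(q) / tot, if (length(q)) mean(q) else NA_real_)
}

oracle_hlam <- function(R, min_line = 2) oracle_vlam(t(R), min_line)

oracle_corm <- function(R) {
  tot <- sum(R)
  if (tot == 0) return(NA_real_)
  s <- 0
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R)))
    if (R[i, j] == 1L) s <- s + (j - i)
  100 * s / ((nrow(R) - 1) * tot)
}

# connected components under 8-adjacency by flood fill
oracle_clust <- function(R, min_cluster = 8) {
  tot <- sum(R)
  if (tot == 0) return(NA_real_)
  n <- nrow(R); m <- ncol(R)
  lab <- matrix(0L, n, m)
  cur <- 0L
  sizes <- integer(0)
  for (i0 in 1:n) for (j0 in 1:m) {
    if (R[i0, j0] == 1L && lab[i0, j0] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i0, j0)); lab[i0, j0] <- cur; size <- 0L
      while (length(stack)) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        size <- size + 1L
        for (di in -1:1) for (dj in -1:1) {
          i <- p[1] + di; j <- p[2] + dj
          if (i >= 1 && i <= n && j >= 1 && j <= m &&
              R[i, j] == 1L && lab[i, j] == 0L) {
            lab[i, j] <- cur
            stack[[length(stack) + 1L]] <- c(i, j)
          }
        }
      }
      sizes <- c(sizes, size)
    }
  }
  100 * sum(sizes[sizes >= min_cluster]) / tot
}

oracle_ent <- function(R, min_line = 2) {
  runs <- oracle_diag_runs(R)
  q <- runs[runs >= min_line]
  if (!length(q)) return(NA_real_)
  p <- as.vector(table(q)) / length(q)
  -sum(p * log(p))
}

# planar I-DT with the classic projected-coordinate dispersion
# (max lon - min lon) + (max lat - min lat); used as a contrast case to show
# pole robustness of the spherical detector
planar_idt_count <- function(t, lon, lat, max_dispersion = 3, min_duration = 80) {
  n <- length(t)
  count <- 0L
  i <- 1L
  repeat {
    j <- i
    while (j <= n && t[j] - t[i] < min_duration) j <- j + 1L
    if (j > n) break
    disp <- function(a, b) (max(lon[a:b]) - min(lon[a:b])) +
      (max(lat[a:b]) - min(lat[a:b]))
    if (disp(i, j) <= max_dispersion) {
      k <- j
      while (k < n && disp(i, k + 1L) <= max_dispersion) k <- k + 1L
      count <- count + 1L
      i <- k + 1L
    } else i <- i + 1L
  }
  count
}

# exact Mann-Whitney p by enumeration of all choose(n1+n2, n1) assignments
oracle_u_p <- function(x, y, alternative = "two.sided") {
  n1 <- length(x)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(length(r), n1)
  Us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  eps <- 1e-9
  switch(alternative,
    less = mean(Us <= U + eps),
    greater = mean(Us >= U - eps),
    two.sided = min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps))))
}

# random binary matrix with tunable density
random_R <- function(n, p = 0.3) {
  matrix(as.integer(stats::runif(n * n) < p), n, n)
}
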