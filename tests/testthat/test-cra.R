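# Cross-recurrence quantification: matrix, measures, calibration.

test_that("length adjustment truncates trailing fixations", {
  e <- random_points(30); r <- random_points(25)
  withr::with_seed(71, { e <- random_points(30); r <- random_points(25) })
  adj <- adjust_lengths(e, r)
  expect_equal(adj$n, 25)
  expect_equal(adj$e, e[1:25, ])
  expect_equal(adj$r, r)
  adj2 <- adjust_lengths(r, r)
  expect_equal(adj2$e, r)
  expect_warning(adjust_lengths(e[1, ], r), "short")
  expect_error(adjust_lengths(e[0, ], r), "empty")
})

test_that("recurrence matrix thresholds distances inclusively", {
  e <- tibble::tibble(lon = c(0, 10, 20), lat = c(0, 0, 0))
  R <- recurrence_matrix(e, e, radius = 10) # ties at exactly 10 count
  expect_equal(unclass(R), matrix(c(1, 1, 0, 1, 1, 1, 0, 1, 1), 3),
               ignore_attr = TRUE)
  expect_equal(unclass(recurrence_matrix(e, e, 180)),
               matrix(1L, 3, 3), ignore_attr = TRUE)
  expect_equal(unclass(recurrence_matrix(e, e, 0)), diag(3),
               ignore_attr = TRUE)
  withr::with_seed(72, {
    a <- random_points(15); b <- random_points(15)
    R <- recurrence_matrix(a, b, 40)
    for (i in 1:15) for (j in 1:15) {
      expect_equal(R[i, j],
                   as.integer(oracle_angle(a$lon[i], a$lat[i],
                                           b$lon[j], b$lat[j]) <= 40))
    }
  })
})

test_that("all nine measures equal the brute-force oracle on random matrices", {
  withr::with_seed(73, {
    for (rep in 1:220) {
      n <- sample(2:12, 1)
      R <- random_R(n, stats::runif(1, 0.1, 0.6))
      v <- laminarity_vertical(R); h <- laminarity_horizontal(R)
      ov <- oracle_vlam(R); oh <- oracle_hlam(R)
      expect_identical(rec(R), oracle_rec(R))
      expect_identical(det_(R), oracle_det(R))
      expect_identical(unname(v["lam"]), ov[1])
      expect_identical(unname(v["tt"]), ov[2])
      expect_identical(unname(h["lam"]), oh[1])
      expect_identical(unname(h["tt"]), oh[2])
      expect_identical(corm(R), oracle_corm(R))
      expect_identical(clust(R), oracle_clust(R))
      expect_equal(ent(R), oracle_ent(R), tolerance = 1e-12)
    }
  })
})

test_that("analytic recurrence cases", {
  # all ones
  R1 <- structure(matrix(1L, 6, 6), class = c("pg_recurrence", "matrix", "array"))
  expect_equal(rec(R1), 100)
  # identity matrix: one full diagonal, no vertical/horizontal runs
  I5 <- structure(diag(5L), class = c("pg_recurrence", "matrix", "array"))
  expect_equal(rec(I5), 100 / 5)
  expect_equal(det_(I5), 100)
  expect_equal(corm(I5), 0)
  expect_equal(ent(I5), 0)
  expect_equal(unname(laminarity_vertical(I5)["lam"]), 0)
  expect_equal(unname(laminarity_horizontal(I5)["lam"]), 0)
  # isolated-dot lattice: no diagonal runs of length >= 2
  cb <- matrix(0L, 6, 6); cb[row(cb) %% 2 == 1 & col(cb) %% 2 == 1] <- 1L
  expect_equal(det_(cb), 0)
  # single full column: vertical laminarity 100, horizontal 0
  cc <- matrix(0L, 5, 5); cc[, 3] <- 1L
  expect_equal(unname(laminarity_vertical(cc)), c(100, 5))
  expect_equal(unname(laminarity_horizontal(cc)["lam"]), 0)
  # transpose duality
  withr::with_seed(74, R <- random_R(9, 0.4))
  expect_identical(laminarity_vertical(R), laminarity_horizontal(t(R)))
  # corm extremes
  Rp <- matrix(0L, 4, 4); Rp[1, 4] <- 1L
  expect_equal(corm(Rp), 100)
  Rn <- matrix(0L, 4, 4); Rn[4, 1] <- 1L
  expect_equal(corm(Rn), -100)
  # symmetric matrix -> corm 0
  withr::with_seed(75, S <- random_R(8, 0.3))
  S <- (S | t(S)) + 0L
  expect_equal(corm(S), 0)
  # one 3x3 block of ones: a single cluster of 9 >= 8
  B <- matrix(0L, 8, 8); B[3:5, 4:6] <- 1L
  expect_equal(clust(B), 100)
  # scattered isolated points only
  Sc <- matrix(0L, 8, 8); Sc[cbind(c(1, 4, 7), c(3, 6, 1))] <- 1L
  expect_equal(clust(Sc), 0)
  # run lengths {2, 3} equally frequent -> ln 2
  E <- matrix(0L, 7, 7)
  E[cbind(1:2, 1:2)] <- 1L       # run of 2 on the main diagonal
  E[cbind(4:6, 5:7)] <- 1L       # run of 3 on an upper diagonal
  expect_equal(ent(E), log(2), tolerance = 1e-12)
  # zero recurrences -> missing
  Z <- matrix(0L, 4, 4)
  expect_true(is.na(det_(Z)))
  expect_true(is.na(corm(Z)))
  expect_true(is.na(clust(Z)))
  expect_true(is.na(ent(Z)))
  expect_equal(rec(Z), 0)
})

test_that("measure bounds hold on random matrices", {
  withr::with_seed(76, {
    for (rep in 1:50) {
      R <- random_R(sample(2:10, 1), stats::runif(1))
      m <- c(rec(R), det_(R), laminarity_vertical(R)["lam"],
             laminarity_horizontal(R)["lam"], clust(R))
      m <- m[!is.na(m)]
      expect_true(all(m >= 0 & m <= 100))
      cm <- corm(R)
      if (!is.na(cm)) expect_true(cm >= -100 && cm <= 100)
      en <- ent(R)
      if (!is.na(en)) expect_gte(en, 0)
    }
  })
})

test_that("compute_all bundles the measures after length adjustment", {
  withr::with_seed(77, {
    e <- random_points(12); r <- random_points(10)
    out <- compute_all(e, r, radius = 45)
    expect_equal(out$n_adjusted, 10)
    R <- recurrence_matrix(e[1:10, ], r, 45)
    expect_identical(out$rec, rec(R))
    expect_identical(out$det, det_(R))
    expect_identical(out$corm, corm(R))
    expect_identical(out$clust, clust(R))
    # identity pair below separation radius
    p <- random_points(8)
    idp <- compute_all(p, p, radius = 1e-6)
    expect_equal(idp$rec, 100 / 8)
    expect_equal(idp$det, 100)
    expect_equal(idp$corm, 0)
    expect_equal(idp$ent, 0)
    expect_equal(idp$vlam, 0)
    expect_equal(idp$hlam, 0)
  })
})

test_that("rec is nondecreasing in the radius", {
  withr::with_seed(78, {
    e <- random_points(20); r <- random_points(20)
    radii <- seq(0, 180, length.out = 50)
    recs <- vapply(radii, function(rad) compute_all(e, r, rad)$rec, numeric(1))
    expect_true(all(diff(recs) >= 0))
    expect_equal(recs[50], 100)
  })
})

test_that("radius calibration hits the target mean recurrence", {
  withr::with_seed(79, {
    pairs <- lapply(1:50, function(i) list(e = random_points(20),
                                           r = random_points(20)))
    cal <- calibrate_radius(pairs, target_rec = 7)
    mean_rec <- mean(vapply(pairs, function(p)
      compute_all(p$e, p$r, cal$radius)$rec, numeric(1)))
    expect_gte(mean_rec, 7)
    expect_lt(mean_rec - 7, 0.01)
    expect_equal(cal$achieved_rec, mean_rec, tolerance = 1e-9)
    # smallest such radius: slightly below, the target is missed
    mean_below <- mean(vapply(pairs, function(p)
      compute_all(p$e, p$r, cal$radius * 0.995)$rec, numeric(1)))
    expect_lt(mean_below, 7)
  })
  # identical single-point sequences: any radius works, returns 0
  one <- list(e = tibble::tibble(lon = 5, lat = 5),
              r = tibble::tibble(lon = 5, lat = 5))
  w <- testthat::capture_warnings(
    cal0 <- calibrate_radius(list(one), target_rec = 7))
  expect_true(any(grepl("unreachable", w))) # single-point pairs also warn short
  expect_equal(cal0$radius, 0)
  expect_error(calibrate_radius(list(), 7), "at least one")
  expect_error(calibrate_radius(list(one), 0), "target_rec")
})

test_that("recurrence diagram exports as a coordinate list", {
  e <- tibble::tibble(lon = c(0, 50), lat = c(0, 0))
  R <- recurrence_matrix(e, e, 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_recurrence_points(R, path)
  pts <- utils::read.delim(path)
  expect_equal(nrow(pts), 2)
  expect_equal(pts$i, pts$j)
})
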