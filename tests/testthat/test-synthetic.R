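# Synthetic-study generator: scenes, participants, trials, studies.

test_that("make_scene is reproducible and horizon-concentrated", {
  s1 <- make_scene(99, n_rois = 6, horizon_kappa = 8)
  s2 <- make_scene(99, n_rois = 6, horizon_kappa = 8)
  expect_identical(s1, s2)
  expect_equal(sum(s1$rois$weight), 1, tolerance = 1e-12)
  expect_true(all(s1$rois$weight >= 0))
  # infinite concentration puts every ROI on the horizon
  s <- make_scene(7, n_rois = 20, horizon_kappa = Inf)
  expect_equal(s$rois$lat, rep(0, 20))
  # large-sample latitude SD matches the circular-normal width within 10%
  big <- make_scene(5, n_rois = 1000, horizon_kappa = 8)
  expect_equal(stats::sd(big$rois$lat), (180 / pi) / sqrt(8), tolerance = 0.1)
  expect_error(make_scene(1, n_rois = 0), "n_rois")
})

test_that("trial schedule tiles the trial and starts at the fixation cross", {
  cfg <- study_config(seed = 1)
  sc <- make_scene(3)
  pp <- make_participant(4)
  tr <- simulate_trial(sc, pp, "encoding", cfg, seed = 10)
  gt <- tr$ground_truth
  expect_equal(gt$lon[1], 0)
  expect_equal(gt$lat[1], 0)
  expect_equal(gt$onset[1], 0)
  expect_equal(gt$offset[nrow(gt)], cfg$trial_duration_ms)
  expect_true(all(diff(gt$onset) > 0))
  expect_true(all(gt$offset > gt$onset))
  # plateaus are separated by saccade gaps, never overlap
  expect_true(all(gt$onset[-1] >= gt$offset[-nrow(gt)]))
  # successive targets respect the minimum separation
  sep <- angular_distance(gt$lon[-nrow(gt)], gt$lat[-nrow(gt)],
                          gt$lon[-1], gt$lat[-1])
  expect_true(all(sep >= cfg$min_target_sep_deg - 1e-9))
  # sample streams at the configured rates
  expect_equal(nrow(tr$eye), cfg$trial_duration_ms / 1000 * cfg$eye_rate_hz)
  expect_true(all(diff(tr$eye$t) > 0))
  expect_true(all(diff(tr$head$t) > 0))
  expect_lt(abs(nrow(tr$head) - cfg$trial_duration_ms / 1000 * cfg$head_rate_hz), 2)
  # eye-in-head vectors are unit length
  expect_lt(max(abs(sqrt(tr$eye$ex^2 + tr$eye$ey^2 + tr$eye$ez^2) - 1)), 1e-9)
})

test_that("perfect-coupling limit: head point equals eye point at plateau
           midpoints", {
  cfg <- study_config(noise_kappa = Inf, rho = 0, recognition_roi_fraction = 1,
                      head_gain = 1, head_lag_ms = 0, head_tau_ms = 0,
                      head_coarseness = 0, mover_sd = 0, seed = 2)
  sc <- make_scene(11)
  pp <- make_participant(12, rho = 0, head_gain = 1, head_lag_ms = 0,
                         head_tau_ms = 0, head_coarseness = 0, mover_sd = 0)
  tr <- simulate_trial(sc, pp, "encoding", cfg, seed = 30)
  gz <- build_gaze_series(tr)
  gt <- tr$ground_truth
  mid <- (gt$onset + gt$offset) / 2
  i <- vapply(mid, function(m) which.min(abs(gz$t - m)), integer(1))
  d <- angular_distance(gz$eye_lon[i], gz$eye_lat[i],
                        gz$head_lon[i], gz$head_lat[i])
  expect_lt(max(d), 1e-6)
  # and the eye sits on the ground-truth target
  d2 <- angular_distance(gz$eye_lon[i], gz$eye_lat[i], gt$lon, gt$lat)
  expect_lt(max(d2), 1e-6)
})

test_that("idiosyncrasy weight routes targets to private regions", {
  cfg <- study_config(noise_kappa = Inf, seed = 3)
  sc <- make_scene(21)
  mindist <- function(gt, rois) {
    vapply(seq_len(nrow(gt)), function(i)
      min(angular_distance(gt$lon[i], gt$lat[i], rois$lon, rois$lat)),
      numeric(1))
  }
  pp1 <- make_participant(22, rho = 1)
  tr1 <- simulate_trial(sc, pp1, "encoding", cfg, seed = 40)
  gt1 <- tr1$ground_truth[-1, ] # drop the fixation cross
  expect_lt(mean(mindist(gt1, pp1$private_rois)),
            mean(mindist(gt1, sc$rois)))
  # targets sit within the private ROI scatter (kappa = 40 ~ 9 deg)
  expect_gt(mean(mindist(gt1, pp1$private_rois) < 25), 0.9)
  pp0 <- make_participant(22, rho = 0)
  tr0 <- simulate_trial(sc, pp0, "encoding", cfg, seed = 40)
  gt0 <- tr0$ground_truth[-1, ]
  expect_lt(mean(mindist(gt0, sc$rois)), mean(mindist(gt0, pp0$private_rois)))
})

test_that("restricting the recognition ROI fraction shrinks longitude spread", {
  cfg1 <- study_config(recognition_roi_fraction = 1, seed = 4)
  cfg4 <- study_config(recognition_roi_fraction = 0.25, seed = 4)
  sdlon <- function(gt) {
    l <- gt$lon * pi / 180
    mu <- atan2(mean(sin(l)), mean(cos(l))) * 180 / pi
    stats::sd(wrap_longitude(gt$lon - mu))
  }
  withr::with_seed(41, {
    diffs <- replicate(40, {
      seed <- sample.int(1e6, 1)
      sc <- make_scene(sample.int(1e6, 1))
      pp <- make_participant(sample.int(1e6, 1), rho = 0)
      full <- simulate_trial(sc, pp, "recognition_old", cfg1, seed = seed)
      narrow <- simulate_trial(sc, pp, "recognition_old", cfg4, seed = seed)
      sdlon(full$ground_truth) - sdlon(narrow$ground_truth)
    })
  })
  expect_gt(mean(diffs > 0), 0.7) # narrower in most paired trials
  expect_gt(mean(diffs), 0)      # and clearly narrower on average
  expect_lt(stats::t.test(diffs, alternative = "greater")$p.value, 0.01)
})

test_that("simulate_study reproduces the design arithmetic deterministically", {
  cfg <- study_config(n_participants = 1, seed = 77) # full per-participant design
  st <- simulate_study(cfg)
  tt <- st$trial_table
  expect_equal(sum(tt$phase == "encoding"), 80)
  expect_equal(sum(tt$phase != "encoding"), 80)
  expect_equal(sum(tt$old_new == "old", na.rm = TRUE), 40)
  expect_equal(sum(tt$old_new == "new", na.rm = TRUE), 40)
  # exactly the old trials share a scene with encoding
  enc_scenes <- tt$scene[tt$phase == "encoding"]
  rec <- tt[tt$phase != "encoding", ]
  expect_equal(sum(rec$scene %in% enc_scenes), 40)
  expect_setequal(rec$old_new[rec$scene %in% enc_scenes], "old")
  # responses recorded for every recognition trial
  expect_true(all(!is.na(rec$correct)))
})

test_that("same seed gives identical datasets, different seeds differ", {
  cfg <- study_config(n_participants = 2, n_scenes_encoding = 3, n_old = 2,
                      n_new = 1, seed = 55)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$trial_table, b$trial_table)
  expect_identical(a$trials[[1]]$eye, b$trials[[1]]$eye)
  expect_identical(a$trials[[5]]$head, b$trials[[5]]$head)
  cfg2 <- study_config(n_participants = 2, n_scenes_encoding = 3, n_old = 2,
                       n_new = 1, seed = 56)
  c <- simulate_study(cfg2)
  expect_false(identical(a$trials[[1]]$eye, c$trials[[1]]$eye))
})

test_that("raising idiosyncrasy lowers cross-participant scanpath similarity", {
  sim_rec <- function(rho) {
    cfg <- study_config(noise_kappa = Inf, rho = rho, seed = 6)
    recs <- numeric(0)
    for (s in 1:6) {
      sc <- make_scene(1000 + s)
      p1 <- make_participant(2000 + s, rho = rho)
      p2 <- make_participant(3000 + s, rho = rho)
      t1 <- simulate_trial(sc, p1, "encoding", cfg, seed = 100 + s)
      t2 <- simulate_trial(sc, p2, "encoding", cfg, seed = 200 + s)
      cr <- compute_all(t1$ground_truth[, c("lon", "lat")],
                        t2$ground_truth[, c("lon", "lat")], radius = 10)
      recs <- c(recs, cr$rec)
    }
    mean(recs)
  }
  r0 <- sim_rec(0); r5 <- sim_rec(0.5); r1 <- sim_rec(1)
  expect_gt(r0, r5)
  expect_gt(r5, r1)
})

test_that("config validation rejects inconsistent designs", {
  expect_error(study_config(recognition_roi_fraction = 0), "fraction")
  expect_error(study_config(n_old = 50, n_scenes_encoding = 40), "n_old")
  expect_error(study_config(rho = 1.5), "rho")
  expect_error(study_config(trial_duration_ms = 50), "shorter")
  expect_error(simulate_trial(make_scene(1), make_participant(2), "encoding",
                              study_config(trial_duration_ms = 120, seed = 1),
                              seed = 1),
               NA) # one-fixation trial is legal
})

test_that("study configuration round-trips through YAML", {
  cfg <- study_config(n_participants = 5, rho = 0.35, seed = 9L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, path)
  cfg2 <- read_study_config(path)
  expect_equal(cfg, cfg2, tolerance = 1e-12)
})
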