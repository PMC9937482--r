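# Synthetic-study generator: scene / participant models and trial simulation.
# Fixation targets are drawn from a mixture of scene-defined and
# participant-private von Mises-Fisher regions of interest; the head pursues a
# region-oriented, pitch-reduced aim point with lag and undershoot; the
# eye-in-head stream is derived so that preprocessing reconstructs world gaze
# exactly.

#' Generate a scene model
#'
#' A scene is a weighted set of von Mises-Fisher regions of interest (ROIs)
#' standing in for image content. ROI longitudes are uniform; latitudes are
#' von Mises-concentrated on the horizon (latitude 0), reproducing the
#' horizontal bias of panorama viewing.
#'
#' @param seed integer seed (scene is fully reproducible from it).
#' @param n_rois number of ROIs (>= 1).
#' @param horizon_kappa concentration of ROI latitudes toward 0 degrees.
#' @param roi_kappa concentration of fixation targets around an ROI center.
#' @param scene_id optional identifier (defaults to the seed).
#' @return a list of class `pg_scene` with a `rois` tibble
#'   (`lon`, `lat`, `kappa`, `weight`).
#' @export
make_scene <- function(seed, n_rois = 12, horizon_kappa = 8, roi_kappa = 40,
                       scene_id = paste0("scene", seed)) {
  if (n_rois < 1) stop("n_rois must be at least 1")
  if (!is.infinite(horizon_kappa) && horizon_kappa < 0) stop("invalid horizon_kappa")
  withr::with_seed(seed, {
    lon <- stats::runif(n_rois, -180, 180)
    lat <- rvonmises_deg(n_rois, 0, horizon_kappa)
    while (any(bad <- abs(lat) > 90)) { # vM lives on the full circle; keep latitudes valid
      lat[bad] <- rvonmises_deg(sum(bad), 0, horizon_kappa)
    }
    w <- stats::rexp(n_rois)
  })
  structure(list(
    scene_id = scene_id,
    seed = seed,
    horizon_kappa = horizon_kappa,
    rois = tibble::tibble(lon = wrap_longitude(lon), lat = lat,
                          kappa = roi_kappa, weight = w / sum(w))
  ), class = "pg_scene")
}

#' Generate a participant model
#'
#' Holds a participant's idiosyncrasy weight (probability of fixating a
#' private ROI instead of a scene ROI), a private ROI set, and head-movement
#' propensity (gain times a log-normal "mover" multiplier, plus a lag).
#'
#' @param seed integer seed.
#' @param participant_id identifier (defaults to the seed).
#' @param rho idiosyncrasy weight in \[0, 1\].
#' @param head_gain,head_lag_ms,head_tau_ms,head_coarseness,mover_sd see
#'   [study_config()].
#' @param n_private_rois,horizon_kappa,roi_kappa private ROI set parameters.
#' @return a list of class `pg_participant`.
#' @export
make_participant <- function(seed, participant_id = paste0("p", seed),
                             rho = 0.2, head_gain = 0.85, head_lag_ms = 50,
                             head_tau_ms = 30, head_coarseness = 0.7,
                             mover_sd = 0.15, n_private_rois = 4,
                             horizon_kappa = 8, roi_kappa = 40) {
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (head_gain < 0 || head_gain > 1) stop("head_gain must be in [0, 1]")
  if (head_lag_ms < 0) stop("head_lag_ms must be non-negative")
  priv <- make_scene(seed, n_rois = n_private_rois,
                     horizon_kappa = horizon_kappa, roi_kappa = roi_kappa,
                     scene_id = paste0(participant_id, "_private"))
  mover <- withr::with_seed(seed + 1L, exp(stats::rnorm(1, 0, mover_sd)))
  structure(list(
    participant_id = participant_id,
    seed = seed,
    rho = rho,
    private_rois = priv$rois,
    head_gain = head_gain,
    head_lag_ms = head_lag_ms,
    head_tau_ms = head_tau_ms,
    head_coarseness = head_coarseness,
    mover_scale = mover,
    head_gain_effective = min(1, max(0, head_gain * mover))
  ), class = "pg_participant")
}

# deterministic recognition ROI subset: the ceil(f * n) highest-weight ROIs.
# Recognition narrows both the scene-driven and the private (idiosyncratic)
# target sets: checking a scene against memory concentrates on a few regions.
.eligible_rois <- function(rois, phase, fraction) {
  if (phase == "encoding" || fraction >= 1) return(rois)
  k <- max(1L, ceiling(fraction * nrow(rois)))
  keep <- order(rois$weight, decreasing = TRUE)[seq_len(k)]
  rois[keep, ]
}

# Build the plateau/saccade schedule tiling [0, duration].
# Returns a tibble of segments (type, t0, t1, lon0, lat0, lon1, lat1).
.build_schedule <- function(scene_rois, private_rois, rho, config) {
  T_ <- config$trial_duration_ms
  # truncated-gamma plateau durations, drawn in batches
  pool <- numeric(0)
  rgap <- function() {
    while (!length(pool)) {
      d <- stats::rgamma(64, shape = config$fixation_shape,
                         scale = config$fixation_mean_ms / config$fixation_shape)
      pool <<- d[d >= config$min_plateau_ms]
    }
    out <- pool[1]
    pool <<- pool[-1]
    out
  }
  # one pole-centered rotation frame per ROI so each target jitter is a
  # single 3-vector rotation instead of a full sampler call
  n_sc <- nrow(scene_rois)
  frames <- c(lapply(seq_len(n_sc), function(k)
                .rotmat_pole_to(scene_rois$lon[k], scene_rois$lat[k])),
              lapply(seq_len(nrow(private_rois)), function(k)
                .rotmat_pole_to(private_rois$lon[k], private_rois$lat[k])))
  draw_target <- function(prev_lon, prev_lat) {
    for (i in 1:50) {
      use_priv <- stats::runif(1) < rho
      rois <- if (use_priv) private_rois else scene_rois
      k <- sample.int(nrow(rois), 1, prob = rois$weight)
      off <- .rvmf_offsets(1, rois$kappa[k])
      p <- .vec_to_sph_list(off %*% t(frames[[if (use_priv) n_sc + k else k]]))
      if (angular_distance(prev_lon, prev_lat, p$lon, p$lat) >=
          config$min_target_sep_deg)
        return(c(p$lon, p$lat, rois$lon[k], rois$lat[k]))
    }
    stop("could not draw a fixation target separated from the previous one")
  }
  seg <- list()
  t <- 0
  cur <- c(0, 0, 0, 0) # trial starts at the fixation cross (its own "region")
  d <- min(rgap(), T_)
  seg[[1]] <- c(0, t, t + d, cur, cur)
  t <- t + d
  while (t < T_) {
    nxt <- draw_target(cur[1], cur[2])
    amp <- angular_distance(cur[1], cur[2], nxt[1], nxt[2])
    sd_ <- config$saccade_base_ms + config$saccade_ms_per_deg * amp
    pd <- rgap()
    if (t + sd_ >= T_ || t + sd_ + min(pd, config$min_plateau_ms) > T_) {
      # not enough room for a full saccade plus a detectable plateau:
      # absorb the remainder into the current plateau
      break
    }
    seg[[length(seg) + 1]] <- c(1, t, t + sd_, cur, nxt)
    t <- t + sd_
    pd <- min(pd, T_ - t)
    seg[[length(seg) + 1]] <- c(0, t, t + pd, nxt, nxt)
    t <- t + pd
    cur <- nxt
  }
  m <- do.call(rbind, seg)
  m[nrow(m), 3] <- T_ # extend the final plateau to the trial end
  tibble::new_tibble(list(
    type = ifelse(m[, 1] == 1, "saccade", "plateau"),
    t0 = m[, 2], t1 = m[, 3],
    lon0 = m[, 4], lat0 = m[, 5], roi_lon0 = m[, 6], roi_lat0 = m[, 7],
    lon1 = m[, 8], lat1 = m[, 9], roi_lon1 = m[, 10], roi_lat1 = m[, 11]),
    nrow = nrow(m))
}

# head aim schedule: the head orients toward a point pulled `coarseness` of
# the way from the fixation target to its ROI center (the head indexes the
# coarse region while the eyes inspect detail points), with its latitude
# scaled by the head gain (reduced head pitch). Returns a schedule tibble
# usable with .schedule_path().
.head_aim_schedule <- function(sched, coarseness, gain) {
  aim_pt <- function(lon, lat, clon, clat) {
    vt <- sph_to_vec(lon, lat)
    vc <- sph_to_vec(clon, clat)
    om <- acos(.clamp1(rowSums(vt * vc)))
    s <- sin(om)
    small <- s < 1e-9
    w0 <- ifelse(small, 1 - coarseness, sin((1 - coarseness) * om) / s)
    w1 <- ifelse(small, coarseness, sin(coarseness * om) / s)
    v <- vt * w0 + vc * w1
    p <- vec_to_sph(v / sqrt(rowSums(v^2)))
    p$lat <- gain * p$lat
    p
  }
  a0 <- aim_pt(sched$lon0, sched$lat0, sched$roi_lon0, sched$roi_lat0)
  a1 <- aim_pt(sched$lon1, sched$lat1, sched$roi_lon1, sched$roi_lat1)
  tibble::new_tibble(list(type = sched$type, t0 = sched$t0, t1 = sched$t1,
                          lon0 = a0$lon, lat0 = a0$lat,
                          lon1 = a1$lon, lat1 = a1$lat),
                     nrow = nrow(sched))
}

# Evaluate the noise-free world gaze path at arbitrary times (vectorized):
# plateau segments sit at their target; saccades move along the great circle
# at constant angular speed.
.schedule_path <- function(schedule, t) {
  idx <- findInterval(t, schedule$t0, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  v0 <- sph_to_vec(schedule$lon0[idx], schedule$lat0[idx])
  out <- v0
  sac <- schedule$type[idx] == "saccade"
  if (any(sac)) {
    i <- idx[sac]
    f <- (t[sac] - schedule$t0[i]) / (schedule$t1[i] - schedule$t0[i])
    f <- pmin(1, pmax(0, f))
    a <- v0[sac, , drop = FALSE]
    b <- sph_to_vec(schedule$lon1[i], schedule$lat1[i])
    om <- acos(pmin(1, pmax(-1, rowSums(a * b))))
    s <- sin(om)
    small <- s < 1e-9
    w0 <- ifelse(small, 1 - f, sin((1 - f) * om) / s)
    w1 <- ifelse(small, f, sin(f * om) / s)
    ab <- a * w0 + b * w1
    out[sac, ] <- ab / sqrt(rowSums(ab^2))
  }
  out
}

#' Simulate one raw trial
#'
#' Produces an eye-in-head sample stream at the eye rate, a head quaternion
#' stream at the head rate, and the ground-truth fixation plateaus. Fixation
#' targets come from the (1 - rho) scene / rho private ROI mixture; during
#' recognition only the `recognition_roi_fraction` highest-weight ROIs (scene
#' and private) are eligible. The head pursues an aim point pulled
#' `head_coarseness` of the way from the target to its ROI center, with
#' latitude scaled by `head_gain`, delayed by `head_lag_ms` and smoothed with
#' time constant `head_tau_ms`. Eye-in-head vectors are computed against the
#' same slerp-interpolated head pose used at preprocessing, so world gaze is
#' reconstructed exactly for noise-free trials.
#'
#' @param scene a `pg_scene`.
#' @param participant a `pg_participant`.
#' @param phase one of `"encoding"`, `"recognition_old"`, `"recognition_new"`.
#' @param config a [study_config()].
#' @param seed integer seed for this trial.
#' @param enc_exploration ground-truth exploration tendency (degrees) of the
#'   matching encoding trial; used by the response model for old scenes.
#' @return a list of class `pg_trial` with tibbles `eye` (`t`, `ex`, `ey`,
#'   `ez`: eye-in-head unit vectors), `head` (`t`, `qw`, `qx`, `qy`, `qz`),
#'   `ground_truth` (`lon`, `lat`, `onset`, `offset`), plus metadata, the
#'   realized ground-truth exploration tendency, and (for recognition) the
#'   old/new response and its correctness.
#' @export
simulate_trial <- function(scene, participant, phase, config, seed,
                           enc_exploration = NULL) {
  phase <- match.arg(phase, c("encoding", "recognition_old", "recognition_new"))
  f <- config$recognition_roi_fraction
  rois <- .eligible_rois(scene$rois, phase, f)
  priv <- .eligible_rois(participant$private_rois, phase, f)
  withr::local_seed(seed)

  sched <- .build_schedule(rois, priv, participant$rho, config)
  T_ <- config$trial_duration_ms
  dt_e <- 1000 / config$eye_rate_hz
  t_eye <- seq(0, T_ - dt_e / 2, by = dt_e)
  t_head <- seq(0, T_, by = 1000 / config$head_rate_hz)

  # world gaze: noise-free path plus within-plateau vMF jitter
  w_clean <- .schedule_path(sched, t_eye)
  w_vec <- w_clean
  if (!is.infinite(config$noise_kappa)) {
    idx <- findInterval(t_eye, sched$t0)
    for (k in which(sched$type == "plateau")) {
      rows <- which(idx == k)
      if (!length(rows)) next
      off <- .rvmf_offsets(length(rows), config$noise_kappa)
      w_vec[rows, ] <- off %*% t(.rotmat_pole_to(sched$lon0[k], sched$lat0[k]))
    }
  }

  # head: smooth pursuit of its aim path (region-oriented, pitch-reduced;
  # see .head_aim_schedule), delayed by the lag and approached as a
  # first-order system with time constant tau, so the head lags and
  # under-shoots the eye; tau = 0 reduces to instant tracking.
  aim_sched <- .head_aim_schedule(sched, participant$head_coarseness,
                                  participant$head_gain_effective)
  aim <- .schedule_path(aim_sched, pmax(0, t_head - participant$head_lag_ms))
  tau <- participant$head_tau_ms
  if (tau > 0) {
    alpha <- 1 - exp(-diff(t_head) / tau)
    hdir <- aim
    for (k in seq_len(nrow(aim) - 1L)) {
      h <- hdir[k, ]; a <- aim[k + 1L, ]
      ang <- acos(min(1, max(-1, sum(h * a))))
      if (ang < 1e-9) { hdir[k + 1L, ] <- h; next }
      f <- alpha[k]
      v <- (sin((1 - f) * ang) * h + sin(f * ang) * a) / sin(ang)
      hdir[k + 1L, ] <- v / sqrt(sum(v^2))
    }
  } else {
    hdir <- aim
  }
  hs <- vec_to_sph(hdir)
  q_head <- quat_look_at(hs$lon, hs$lat)

  # eye-in-head against the interpolated head pose (exact round trip)
  head_tbl <- tibble::new_tibble(list(t = t_head, qw = q_head[, 1],
                                      qx = q_head[, 2], qy = q_head[, 3],
                                      qz = q_head[, 4]),
                                 nrow = length(t_head))
  q_at_eye <- interpolate_head(head_tbl, t_eye)
  e_ih <- quat_rotate(quat_conjugate(q_at_eye), w_vec)

  plateaus <- sched[sched$type == "plateau", ]
  gt <- tibble::new_tibble(list(lon = plateaus$lon0, lat = plateaus$lat0,
                                onset = plateaus$t0, offset = plateaus$t1),
                           nrow = nrow(plateaus))
  expl <- if (nrow(gt) > 1) {
    mean(angular_distance(gt$lon[-1], gt$lat[-1], gt$lon[1], gt$lat[1]))
  } else 0

  response <- NA; correct <- NA
  if (phase != "encoding") {
    # logistic response model in realized exploration tendency, anchored at
    # the generator's expected scale (targets roughly uniform in longitude
    # put the mean distance from the start direction near 90 degrees)
    z_rec <- (expl - 90) / 20
    z_enc <- if (!is.null(enc_exploration)) (enc_exploration - 90) / 20 else 0
    p_correct <- if (phase == "recognition_old") {
      stats::plogis(stats::qlogis(0.92) + z_enc - z_rec)
    } else {
      stats::plogis(stats::qlogis(0.92) - z_rec)
    }
    correct <- stats::runif(1) < p_correct
    response <- if (phase == "recognition_old") {
      if (correct) "old" else "new"
    } else {
      if (correct) "new" else "old"
    }
  }

  structure(list(
    participant_id = participant$participant_id,
    scene_id = scene$scene_id,
    phase = phase,
    eye = tibble::new_tibble(list(t = t_eye, ex = e_ih[, 1], ey = e_ih[, 2],
                                  ez = e_ih[, 3]), nrow = length(t_eye)),
    head = head_tbl,
    ground_truth = gt,
    exploration_gt = expl,
    response = response,
    correct = correct
  ), class = "pg_trial")
}

#' @export
print.pg_trial <- function(x, ...) {
  cat("<pg_trial> ", x$participant_id, " / ", x$scene_id, " (", x$phase, "): ",
      nrow(x$eye), " eye samples, ", nrow(x$head), " head samples, ",
      nrow(x$ground_truth), " ground-truth fixations\n", sep = "")
  invisible(x)
}

#' Simulate a full study
#'
#' Encoding block over all scenes, then a recognition block of the `n_old`
#' repeated plus `n_new` novel scenes in randomized order, for each
#' participant. All per-scene, per-participant and per-trial seeds derive
#' deterministically from `config$seed`.
#'
#' @param config a [study_config()].
#' @return a list of class `pg_study` with elements `trials` (list of
#'   `pg_trial`), `trial_table` (tibble: `participant`, `trial`, `phase`,
#'   `scene`, `old_new`, `response`, `correct`), `scenes`, `participants`,
#'   `config`.
#' @export
simulate_study <- function(config = study_config()) {
  n_scenes <- config$n_scenes_encoding + config$n_new
  base <- withr::with_seed(config$seed, {
    list(
      scene_seeds = sample.int(.Machine$integer.max - 1L, n_scenes),
      ppt_seeds = sample.int(.Machine$integer.max - 1L, config$n_participants),
      old_idx = sort(sample.int(config$n_scenes_encoding, config$n_old)),
      order_seeds = sample.int(.Machine$integer.max - 1L, config$n_participants),
      trial_seed0 = sample.int(2^20, 1)
    )
  })
  scenes <- purrr::imap(base$scene_seeds, function(s, i) {
    make_scene(s, n_rois = config$n_rois, horizon_kappa = config$horizon_kappa,
               roi_kappa = config$roi_kappa, scene_id = sprintf("scene%03d", i))
  })
  names(scenes) <- purrr::map_chr(scenes, "scene_id")
  participants <- purrr::imap(base$ppt_seeds, function(s, i) {
    make_participant(s, participant_id = sprintf("p%02d", i), rho = config$rho,
                     head_gain = config$head_gain, head_lag_ms = config$head_lag_ms,
                     head_tau_ms = config$head_tau_ms,
                     head_coarseness = config$head_coarseness,
                     mover_sd = config$mover_sd,
                     n_private_rois = config$n_private_rois,
                     horizon_kappa = config$horizon_kappa,
                     roi_kappa = config$roi_kappa)
  })
  names(participants) <- purrr::map_chr(participants, "participant_id")

  enc_ids <- seq_len(config$n_scenes_encoding)
  new_ids <- config$n_scenes_encoding + seq_len(config$n_new)
  trials <- list()
  rows <- list()
  trial_no <- 0L
  for (pi in seq_along(participants)) {
    ppt <- participants[[pi]]
    ord <- withr::with_seed(base$order_seeds[pi], list(
      enc = sample(enc_ids),
      rec = sample(c(base$old_idx, new_ids))
    ))
    enc_expl <- numeric(length(scenes)) # ground-truth exploration by scene index
    k <- 0L
    for (si in ord$enc) {
      k <- k + 1L; trial_no <- trial_no + 1L
      tr <- simulate_trial(scenes[[si]], ppt, "encoding", config,
                           seed = base$trial_seed0 + 1000L * pi + si)
      enc_expl[si] <- tr$exploration_gt
      trials[[trial_no]] <- tr
      rows[[trial_no]] <- tibble::tibble(
        participant = ppt$participant_id, trial = k, phase = "encoding",
        scene = tr$scene_id, old_new = NA_character_,
        response = NA_character_, correct = NA)
    }
    for (si in ord$rec) {
      k <- k + 1L; trial_no <- trial_no + 1L
      is_old <- si <= config$n_scenes_encoding
      ph <- if (is_old) "recognition_old" else "recognition_new"
      tr <- simulate_trial(scenes[[si]], ppt, ph, config,
                           seed = base$trial_seed0 + 1000L * pi + si + 500000L,
                           enc_exploration = if (is_old) enc_expl[si] else NULL)
      trials[[trial_no]] <- tr
      rows[[trial_no]] <- tibble::tibble(
        participant = ppt$participant_id, trial = k, phase = ph,
        scene = tr$scene_id, old_new = if (is_old) "old" else "new",
        response = tr$response, correct = tr$correct)
    }
  }
  structure(list(
    trials = trials,
    trial_table = dplyr::bind_rows(rows),
    scenes = scenes,
    participants = participants,
    config = config
  ), class = "pg_study")
}

#' @export
print.pg_study <- function(x, ...) {
  cat("<pg_study> ", length(x$participants), " participants, ",
      length(x$trials), " trials\n", sep = "")
  invisible(x)
}
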