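# Study orchestration: encoding/recognition condition pairings, per-condition
# CRA aggregation, memory-performance tables, and the full pipeline.

#' Build the four encoding/recognition pairing conditions
#'
#' Crosses same/different participant with same/different image:
#' * `Sp-Si`: each old recognition trial paired with the same participant's
#'   encoding of the same scene;
#' * `Sp-Di`: each new recognition trial paired with the same participant's
#'   encoding of a seeded-random scene from the D-set (scenes encoded but not
#'   re-shown), drawn without replacement;
#' * `Dp-Si` / `Dp-Di`: as above with the encoding side taken from a
#'   seeded-random *other* participant.
#'
#' @param trial_table tibble with `participant`, `phase`, `scene`, `old_new`
#'   (see [simulate_study()]).
#' @param seed integer pairing seed.
#' @return tibble with `condition`, `participant_rec`, `scene_rec`,
#'   `participant_enc`, `scene_enc`.
#' @export
build_pairings <- function(trial_table, seed = 1L) {
  enc <- trial_table[trial_table$phase == "encoding", ]
  old <- trial_table[trial_table$phase == "recognition_old", ]
  new <- trial_table[trial_table$phase == "recognition_new", ]
  ppts <- unique(trial_table$participant)
  old_scenes <- unique(old$scene)
  d_set <- setdiff(unique(enc$scene), old_scenes)
  if (length(ppts) < 2L) stop("different-participant conditions need at least 2 participants")
  if (!length(d_set)) stop("no D-set: every encoded scene was re-shown")
  withr::with_seed(seed, {
    out <- purrr::map_dfr(ppts, function(p) {
      others <- setdiff(ppts, p)
      po <- old[old$participant == p, ]
      pn <- new[new$participant == p, ]
      d_sp <- sample(rep(d_set, length.out = nrow(pn)))
      d_dp <- sample(rep(d_set, length.out = nrow(pn)))
      dplyr::bind_rows(
        tibble::tibble(condition = "Sp-Si", participant_rec = p,
                       scene_rec = po$scene, participant_enc = p,
                       scene_enc = po$scene),
        tibble::tibble(condition = "Sp-Di", participant_rec = p,
                       scene_rec = pn$scene, participant_enc = p,
                       scene_enc = d_sp),
        tibble::tibble(condition = "Dp-Si", participant_rec = p,
                       scene_rec = po$scene,
                       participant_enc = sample(others, nrow(po), replace = TRUE),
                       scene_enc = po$scene),
        tibble::tibble(condition = "Dp-Di", participant_rec = p,
                       scene_rec = pn$scene,
                       participant_enc = sample(others, nrow(pn), replace = TRUE),
                       scene_enc = d_dp)
      )
    })
  })
  out
}

#' Per-condition cross-recurrence summary
#'
#' Runs [compute_all()] for every pair in every condition, for eye and head
#' fixation sequences, then aggregates: per-pair values, per-participant
#' condition means (listwise by measure over non-missing pairs), and the
#' condition-level mean/SD/n across participants.
#'
#' @param fixations fixation table with `participant`, `scene`, `phase`,
#'   `fix_index`, `eye_lon`, `eye_lat`, `head_lon`, `head_lat`.
#' @param pairings output of [build_pairings()].
#' @param radius_eye,radius_head calibrated recurrence radii (degrees).
#' @param min_line,min_cluster see [rec()].
#' @return list of class `pg_cra_summary` with tibbles `per_pair`,
#'   `per_participant`, `summary`.
#' @export
run_condition_cra <- function(fixations, pairings, radius_eye, radius_head,
                              min_line = 2, min_cluster = 8) {
  fx <- dplyr::arrange(fixations, .data$participant, .data$scene, .data$phase,
                       .data$fix_index)
  key <- paste(fx$participant, fx$scene, fx$phase != "encoding")
  seqs <- split(fx, key)
  get_seq <- function(p, s, rec_side) seqs[[paste(p, s, rec_side)]]
  per_pair <- purrr::pmap_dfr(pairings, function(condition, participant_rec,
                                                 scene_rec, participant_enc,
                                                 scene_enc) {
    e <- get_seq(participant_enc, scene_enc, FALSE)
    r <- get_seq(participant_rec, scene_rec, TRUE)
    if (is.null(e) || is.null(r) || nrow(e) == 0L || nrow(r) == 0L) return(NULL)
    eye <- compute_all(tibble::tibble(lon = e$eye_lon, lat = e$eye_lat),
                       tibble::tibble(lon = r$eye_lon, lat = r$eye_lat),
                       radius_eye, min_line, min_cluster)
    head <- compute_all(tibble::tibble(lon = e$head_lon, lat = e$head_lat),
                        tibble::tibble(lon = r$head_lon, lat = r$head_lat),
                        radius_head, min_line, min_cluster)
    dplyr::bind_cols(
      tibble::tibble(condition = condition, participant = participant_rec,
                     scene_rec = scene_rec, scene_enc = scene_enc,
                     target = c("eye", "head")),
      dplyr::bind_rows(eye, head))
  })
  long <- tidyr::pivot_longer(per_pair,
                              cols = c("rec", "det", "hlam", "htt", "vlam",
                                       "vtt", "corm", "clust", "ent"),
                              names_to = "measure", values_to = "value")
  per_ppt <- dplyr::summarise(
    dplyr::group_by(long, .data$condition, .data$target, .data$participant,
                    .data$measure),
    value = mean(.data$value, na.rm = TRUE), n_pairs = sum(!is.na(.data$value)),
    .groups = "drop")
  summ <- dplyr::summarise(
    dplyr::group_by(per_ppt, .data$condition, .data$target, .data$measure),
    mean = mean(.data$value), sd = stats::sd(.data$value),
    n = dplyr::n(), .groups = "drop")
  structure(list(per_pair = per_pair, per_participant = per_ppt,
                 summary = summ),
            class = "pg_cra_summary")
}

#' @export
print.pg_cra_summary <- function(x, ...) {
  cat("<pg_cra_summary> ", nrow(x$per_pair), " pair evaluations, ",
      length(unique(x$per_participant$participant)), " participants\n", sep = "")
  print(tidyr::pivot_wider(
    x$summary[x$summary$measure == "rec", c("condition", "target", "mean")],
    names_from = "target", values_from = "mean"))
  invisible(x)
}

#' Two-by-two repeated-measures ANOVA (plumbing)
#'
#' Standard within-subject two-factor analysis of variance of per-participant
#' condition means, with factors Image (same/different scene) and Person
#' (same/different participant) derived from the condition labels.
#'
#' @param data tibble with `participant`, `condition` (Sp-Si, Sp-Di, Dp-Si,
#'   Dp-Di) and `value`; one row per participant x condition.
#' @return tibble with `effect` (`image`, `person`, `image:person`), `df1`,
#'   `df2`, `statistic` (F), `p.value`. Participants with missing cells are
#'   dropped with a message.
#' @export
rm_anova_2x2 <- function(data) {
  d <- dplyr::mutate(data,
    image = factor(ifelse(grepl("Si$", .data$condition), "same", "different")),
    person = factor(ifelse(grepl("^Sp", .data$condition), "same", "different")))
  complete <- dplyr::filter(
    dplyr::add_count(dplyr::distinct(d, .data$participant, .data$image, .data$person),
                     .data$participant), .data$n == 4L)
  keep <- unique(complete$participant)
  if (length(setdiff(unique(d$participant), keep)))
    message(length(setdiff(unique(d$participant), keep)),
            " participant(s) dropped for missing cells")
  d <- d[d$participant %in% keep, ]
  if (length(keep) < 2L) stop("repeated-measures ANOVA needs at least 2 complete participants")
  d$participant <- factor(d$participant)
  fit <- stats::aov(value ~ image * person + Error(participant / (image * person)),
                    data = d)
  s <- summary(fit)
  pull <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    i <- trimws(rownames(tab)) == term
    tibble::tibble(effect = sub(":", ":", tolower(term)),
                   df1 = tab[i, "Df"], df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"],
                   statistic = tab[i, "F value"], p.value = tab[i, "Pr(>F)"])
  }
  out <- dplyr::bind_rows(pull("Error: participant:image", "image"),
                          pull("Error: participant:person", "person"),
                          pull("Error: participant:image:person", "image:person"))
  out$effect <- c("image", "person", "image:person")
  out
}

#' Exact Mann-Whitney U test
#'
#' Rank-sum test with an exact null distribution: full permutation
#' enumeration (tie-safe) when the number of group assignments is small
#' enough, the exact no-tie distribution for moderate samples (both n <= 25),
#' and the normal approximation with continuity correction otherwise.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (`"less"` tests whether `x` tends to be smaller than `y`).
#' @param enumerate_max largest number of assignments enumerated exactly.
#' @return list of class `pg_utest`: `statistic` (U for `x`), `p.value`,
#'   `method`.
#' @export
u_test_exact <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         enumerate_max = 2e5) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (choose(n1 + n2, n1) <= enumerate_max) {
    # exhaustive enumeration of group assignments (handles ties exactly)
    combos <- utils::combn(n1 + n2, n1)
    Us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- switch(alternative,
      less = mean(Us <= U + eps),
      greater = mean(Us >= U - eps),
      two.sided = min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps))))
    method <- "exact enumeration"
  } else if (!anyDuplicated(pooled) && n1 <= 25 && n2 <= 25) {
    p <- stats::wilcox.test(x, y, alternative = alternative,
                            exact = TRUE)$p.value
    method <- "exact distribution"
  } else {
    p <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative,
                                             exact = FALSE, correct = TRUE)$p.value)
    if (is.nan(p)) p <- 1 # all observations identical
    method <- "normal approximation"
  }
  structure(list(statistic = U, p.value = p, method = method,
                 alternative = alternative, n1 = n1, n2 = n2),
            class = "pg_utest")
}

#' @export
print.pg_utest <- function(x, ...) {
  cat(sprintf("<pg_utest> U = %g (n1 = %d, n2 = %d), p = %.4g [%s, %s]\n",
              x$statistic, x$n1, x$n2, x$p.value, x$alternative, x$method))
  invisible(x)
}

#' Memory-performance measure table
#'
#' Means and SDs of the per-trial movement measures by phase and correctness
#' category: encoding trials are labelled Hit/Miss by the later recognition
#' response to the same scene (encoding-only scenes are excluded), old
#' recognition trials are Hits/Misses, new recognition trials Correct
#' Rejections / False Alarms. Each measure is contrasted between correct and
#' incorrect trials within phase by an exact Mann-Whitney U test.
#'
#' @param trial_table tibble from [simulate_study()] (needs `participant`,
#'   `phase`, `scene`, `old_new`, `correct`).
#' @param measures tibble with `participant`, `scene`, `phase` and numeric
#'   measure columns (e.g. from [trial_measures()] rows bound together).
#' @return list of class `pg_memory_table`: `cells` (phase x category x
#'   measure mean/SD/n) and `contrasts` (U and p per phase x measure; skipped
#'   with a message when a category is empty).
#' @export
memory_table <- function(trial_table, measures) {
  rec <- trial_table[trial_table$phase != "encoding", ]
  enc_lab <- dplyr::transmute(
    rec[rec$old_new == "old", ],
    participant = .data$participant, scene = .data$scene,
    enc_correct = .data$correct)
  mm <- dplyr::left_join(measures,
                         trial_table[, c("participant", "scene", "phase", "old_new", "correct")],
                         by = c("participant", "scene", "phase"))
  enc <- dplyr::inner_join(mm[mm$phase == "encoding", ], enc_lab,
                           by = c("participant", "scene"))
  enc$group <- ifelse(enc$enc_correct, "Hit", "Miss")
  enc$block <- "encoding"
  old <- mm[mm$phase == "recognition_old", ]
  old$group <- ifelse(old$correct, "Hit", "Miss")
  old$block <- "old"
  new <- mm[mm$phase == "recognition_new", ]
  new$group <- ifelse(new$correct, "CR", "FA")
  new$block <- "new"
  meas_cols <- setdiff(names(measures), c("participant", "scene", "phase"))
  meas_cols <- meas_cols[purrr::map_lgl(measures[meas_cols], is.numeric)]
  all <- dplyr::bind_rows(enc[, c("block", "group", meas_cols)],
                          old[, c("block", "group", meas_cols)],
                          new[, c("block", "group", meas_cols)])
  long <- tidyr::pivot_longer(all, dplyr::all_of(meas_cols),
                              names_to = "measure", values_to = "value")
  cells <- dplyr::summarise(
    dplyr::group_by(long, .data$block, .data$group, .data$measure),
    mean = mean(.data$value, na.rm = TRUE), sd = stats::sd(.data$value, na.rm = TRUE),
    n = sum(!is.na(.data$value)), .groups = "drop")
  contrasts <- purrr::map_dfr(split(long, list(long$block, long$measure)),
    function(d) {
      g <- unique(d$group)
      correct_lab <- intersect(c("Hit", "CR"), g)
      incorrect_lab <- intersect(c("Miss", "FA"), g)
      if (!length(correct_lab) || !length(incorrect_lab)) {
        message("contrast skipped for ", d$block[1], "/", d$measure[1],
                ": empty category")
        return(NULL)
      }
      a <- d$value[d$group %in% correct_lab & !is.na(d$value)]
      b <- d$value[d$group %in% incorrect_lab & !is.na(d$value)]
      if (!length(a) || !length(b)) return(NULL)
      ut <- u_test_exact(a, b)
      tibble::tibble(block = d$block[1], measure = d$measure[1],
                     mean_correct = mean(a), mean_incorrect = mean(b),
                     U = ut$statistic, p.value = ut$p.value, method = ut$method)
    })
  structure(list(cells = cells, contrasts = contrasts), class = "pg_memory_table")
}

#' @export
print.pg_memory_table <- function(x, ...) {
  cat("<pg_memory_table>\n")
  print(tidyr::pivot_wider(x$cells[, c("block", "group", "measure", "mean")],
                           names_from = "block", values_from = "mean"))
  invisible(x)
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a study, builds gaze series, detects eye and head
#' fixations, computes per-trial measures, spread statistics, heatmap
#' contrasts, calibrates eye and head recurrence radii, evaluates the four
#' pairing conditions with cross-recurrence analysis, and assembles the
#' memory table. Deterministic given the configuration (all stage seeds
#' derive from `config$seed`).
#'
#' @param config a [study_config()].
#' @param study optionally, an existing `pg_study` (skips simulation).
#' @param target_rec target mean recurrence for radius calibration (percent).
#' @param max_dispersion,min_duration fixation-detection thresholds.
#' @param sigma,resolution heatmap parameters.
#' @return list of class `pg_report`: `fixation_table`, `measure_table`,
#'   `spreads`, `spread_medians`, `contrast_enc_rec_eye`,
#'   `contrast_enc_rec_head`, `contrast_eye_head_enc`, `radii`,
#'   `cra` (a `pg_cra_summary`), `memory`, `anova_rec`, `trial_table`,
#'   `config`.
#' @export
run_pipeline <- function(config = study_config(), study = NULL,
                         target_rec = 7, max_dispersion = 3, min_duration = 80,
                         sigma = 4, resolution = 1) {
  if (is.null(study)) study <- simulate_study(config)
  fixrows <- list()
  measrows <- list()
  for (tr in study$trials) {
    gz <- build_gaze_series(tr)
    fx <- detect_fixations(gz, max_dispersion, min_duration)
    hf <- head_fixations(fx, gz)
    fixrows[[length(fixrows) + 1L]] <- tibble::tibble(
      participant = tr$participant_id, scene = tr$scene_id, phase = tr$phase,
      fix_index = fx$fix_index, start = fx$start, end = fx$end,
      duration = fx$duration, eye_lon = fx$lon, eye_lat = fx$lat,
      head_lon = hf$lon, head_lat = hf$lat)
    tm <- trial_measures(fx, hf)
    measrows[[length(measrows) + 1L]] <- dplyr::bind_cols(
      tibble::tibble(participant = tr$participant_id, scene = tr$scene_id,
                     phase = tr$phase),
      tm[, c("n_fixations", "mean_fixation_duration", "exploration_eye",
             "exploration_head")])
  }
  fixation_table <- dplyr::bind_rows(fixrows)
  measure_table <- dplyr::bind_rows(measrows)

  eye_pts <- dplyr::transmute(fixation_table, participant = .data$participant,
                              scene = .data$scene, phase = .data$phase,
                              lon = .data$eye_lon, lat = .data$eye_lat)
  spreads <- spread_statistics(eye_pts)

  contrast_er_eye <- same_vs_different_contrast(fixation_table, "enc_rec", "eye",
                                                seed = config$seed + 11L,
                                                sigma = sigma, resolution = resolution)
  contrast_er_head <- same_vs_different_contrast(fixation_table, "enc_rec", "head",
                                                 seed = config$seed + 12L,
                                                 sigma = sigma, resolution = resolution)
  contrast_eh_enc <- same_vs_different_contrast(fixation_table, "eye_head",
                                                phase = "encoding",
                                                seed = config$seed + 13L,
                                                sigma = sigma, resolution = resolution)

  pairings <- build_pairings(study$trial_table, seed = config$seed + 21L)
  sp_si <- pairings[pairings$condition == "Sp-Si", ]
  seq_pairs <- function(target) {
    loncol <- paste0(target, "_lon"); latcol <- paste0(target, "_lat")
    purrr::pmap(sp_si, function(condition, participant_rec, scene_rec,
                                participant_enc, scene_enc) {
      e <- fixation_table[fixation_table$participant == participant_enc &
                          fixation_table$scene == scene_enc &
                          fixation_table$phase == "encoding", ]
      r <- fixation_table[fixation_table$participant == participant_rec &
                          fixation_table$scene == scene_rec &
                          fixation_table$phase != "encoding", ]
      if (!nrow(e) || !nrow(r)) return(NULL)
      list(e = tibble::tibble(lon = e[[loncol]], lat = e[[latcol]]),
           r = tibble::tibble(lon = r[[loncol]], lat = r[[latcol]]))
    })
  }
  eye_pairs <- purrr::compact(seq_pairs("eye"))
  head_pairs <- purrr::compact(seq_pairs("head"))
  rad_eye <- calibrate_radius(eye_pairs, target_rec)
  rad_head <- calibrate_radius(head_pairs, target_rec)
  radii <- dplyr::bind_rows(dplyr::mutate(rad_eye, target = "eye"),
                            dplyr::mutate(rad_head, target = "head"))

  cra <- run_condition_cra(fixation_table, pairings,
                           radius_eye = rad_eye$radius,
                           radius_head = rad_head$radius)

  rec_eye <- cra$per_participant[cra$per_participant$measure == "rec" &
                                 cra$per_participant$target == "eye", ]
  anova_rec <- tryCatch(
    rm_anova_2x2(rec_eye[, c("participant", "condition", "value")]),
    error = function(e) NULL)

  memory <- memory_table(study$trial_table, measure_table)

  structure(list(
    fixation_table = fixation_table, measure_table = measure_table,
    spreads = spreads, spread_medians = spread_medians(spreads),
    contrast_enc_rec_eye = contrast_er_eye,
    contrast_enc_rec_head = contrast_er_head,
    contrast_eye_head_enc = contrast_eh_enc,
    radii = radii, cra = cra, memory = memory, anova_rec = anova_rec,
    trial_table = study$trial_table, config = config
  ), class = "pg_report")
}

#' @export
print.pg_report <- function(x, ...) {
  cat("<pg_report> ", nrow(x$trial_table), " trials, ",
      nrow(x$fixation_table), " fixations\n", sep = "")
  print(x$spread_medians)
  print(x$radii)
  invisible(x)
}
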