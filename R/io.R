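# Plain-text import/export of the tabular interchange formats.

#' Write / read a raw trial
#'
#' One tab-separated file per trial. Comment lines (`#key value`) carry the
#' metadata; data rows are `EYE t ex ey ez` (eye-in-head unit vector at the
#' eye rate) and `HEAD t qw qx qy qz` (head quaternion at the head rate),
#' timestamps in ms from trial onset.
#'
#' @param trial a `pg_trial`.
#' @param path output file.
#' @return `write_raw_trial()` returns `path` invisibly; `read_raw_trial()` a
#'   `pg_trial` (without generator ground truth).
#' @export
write_raw_trial <- function(trial, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(participant = trial$participant_id, scene = trial$scene_id,
            phase = trial$phase, response = as.character(trial$response),
            correct = as.character(trial$correct))
  writeLines(paste0("#", names(meta), "\t", meta), con)
  e <- sprintf("EYE\t%.6f\t%.9f\t%.9f\t%.9f",
               trial$eye$t, trial$eye$ex, trial$eye$ey, trial$eye$ez)
  h <- sprintf("HEAD\t%.6f\t%.9f\t%.9f\t%.9f\t%.9f",
               trial$head$t, trial$head$qw, trial$head$qx, trial$head$qy,
               trial$head$qz)
  writeLines(c(e, h), con)
  invisible(path)
}

#' @rdname write_raw_trial
#' @export
read_raw_trial <- function(path) {
  lines <- readLines(path)
  metal <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^#", "", metal), "\t"))
  meta <- stats::setNames(kv[, 2], kv[, 1])
  datal <- lines[!startsWith(lines, "#")]
  parts <- strsplit(datal, "\t", fixed = TRUE)
  tag <- vapply(parts, `[[`, "", 1L)
  num <- function(rows, k) as.numeric(vapply(parts[rows], `[[`, "", k))
  ei <- which(tag == "EYE"); hi <- which(tag == "HEAD")
  eye <- tibble::tibble(t = num(ei, 2), ex = num(ei, 3), ey = num(ei, 4),
                        ez = num(ei, 5))
  head <- tibble::tibble(t = num(hi, 2), qw = num(hi, 3), qx = num(hi, 4),
                         qy = num(hi, 5), qz = num(hi, 6))
  structure(list(
    participant_id = unname(meta["participant"]),
    scene_id = unname(meta["scene"]),
    phase = unname(meta["phase"]),
    eye = eye[order(eye$t), ], head = head[order(head$t), ],
    ground_truth = tibble::tibble(lon = numeric(), lat = numeric(),
                                  onset = numeric(), offset = numeric()),
    exploration_gt = NA_real_,
    response = if (meta[["response"]] == "NA") NA else meta[["response"]],
    correct = if (meta[["correct"]] == "NA") NA else as.logical(meta[["correct"]])
  ), class = "pg_trial")
}

#' Export tabular results
#'
#' Tab-separated exports of the gaze series, the fixation table and the trial
#' metadata table, round-tripping with `utils::read.delim(path)`.
#'
#' @param x the tibble to write.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a heatmap as a plain-text matrix
#'
#' Three comment header lines record the resolution, the normalization and
#' the row order; the body is the tab-separated grid.
#'
#' @param h a `pg_heatmap`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_heatmap <- function(h, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# resolution_deg\t", attr(h, "resolution")),
    "# normalization\tunit_mass",
    "# rows\tlatitude 90 to -90, cols longitude -180 to 180"), con)
  utils::write.table(unclass(h), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_heatmap
#' @export
read_heatmap <- function(path) {
  hdr <- readLines(path, n = 3L)
  res <- as.numeric(strsplit(hdr[1], "\t")[[1]][2])
  g <- as.matrix(utils::read.table(path, skip = 3L, sep = "\t"))
  dimnames(g) <- NULL
  nr <- nrow(g); nc <- ncol(g)
  structure(g, lat_centers = 90 - (seq_len(nr) - 0.5) * res,
            lon_centers = -180 + (seq_len(nc) - 0.5) * res,
            resolution = res, empty = FALSE,
            class = c("pg_heatmap", "matrix", "array"))
}

#' Export a recurrence diagram as a coordinate list
#'
#' Writes one `i, j` row per recurrent point (encoding index, recognition
#' index) for plotting.
#'
#' @param R a `pg_recurrence` matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recurrence_points <- function(R, path) {
  ij <- which(unclass(R) == 1L, arr.ind = TRUE)
  write_tsv_table(tibble::tibble(i = ij[, 1], j = ij[, 2]), path)
}
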