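# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a heatmap contrast
#'
#' @param x a `pg_contrast`.
#' @param ... unused.
#' @return per-scene tibble with `scene`, `scene_other`, `r_same`, `r_diff`.
#' @export
tidy.pg_contrast <- function(x, ...) x$scenes

#' @rdname tidy.pg_contrast
#' @return `glance()`: one-row tibble with the means, paired t statistic,
#'   degrees of freedom and p value.
#' @export
glance.pg_contrast <- function(x, ...) {
  tibble::tibble(mean_r_same = x$mean_r_same, mean_r_diff = x$mean_r_diff,
                 statistic = x$t, df = x$df, p.value = x$p)
}

#' Tidy an exact U test
#'
#' @param x a `pg_utest`.
#' @param ... unused.
#' @return one-row tibble with `statistic`, `p.value`, `method`,
#'   `alternative`, `n1`, `n2`.
#' @export
tidy.pg_utest <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 method = x$method, alternative = x$alternative,
                 n1 = x$n1, n2 = x$n2)
}

#' Tidy a condition-level CRA summary
#'
#' @param x a `pg_cra_summary`.
#' @param ... unused.
#' @return the condition x target x measure summary tibble.
#' @export
tidy.pg_cra_summary <- function(x, ...) x$summary

#' Tidy / glance a pipeline report
#'
#' @param x a `pg_report`.
#' @param ... unused.
#' @return `tidy()`: the CRA condition summary; `glance()`: one row with the
#'   headline quantities (trial and fixation counts, recognition accuracy,
#'   calibrated radii, spread medians, heatmap contrast means).
#' @export
tidy.pg_report <- function(x, ...) x$cra$summary

#' @rdname tidy.pg_report
#' @export
glance.pg_report <- function(x, ...) {
  rec_trials <- x$trial_table[x$trial_table$phase != "encoding", ]
  sm <- x$spread_medians
  enc <- sm[sm$phase == "encoding", ]
  rcg <- sm[sm$phase != "encoding", ]
  tibble::tibble(
    n_trials = nrow(x$trial_table),
    n_fixations = nrow(x$fixation_table),
    recognition_accuracy = mean(rec_trials$correct),
    radius_eye = x$radii$radius[x$radii$target == "eye"],
    radius_head = x$radii$radius[x$radii$target == "head"],
    spread_lon_encoding = enc$median_sd_lon[1],
    spread_lon_recognition = stats::median(rcg$median_sd_lon),
    r_same_enc_rec_eye = x$contrast_enc_rec_eye$mean_r_same,
    r_diff_enc_rec_eye = x$contrast_enc_rec_eye$mean_r_diff)
}
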