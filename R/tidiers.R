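#' Tidy a trained segmenter into its per-epoch history
#'
#' @param x An `mdr_segmenter`.
#' @param ... Unused.
#' @return A tibble with one row per epoch in long-friendly wide form:
#'   `epoch`, `loss`, `macro_dice`, `dice_fat`, `dice_gland`,
#'   `dice_pectoral`.
#' @export
tidy.mdr_segmenter <- function(x, ...) {
  x$history
}

#' One-row summary of a trained segmenter
#'
#' @param x An `mdr_segmenter`.
#' @param ... Unused.
#' @return A one-row tibble: `depth`, `base_channels`, `epochs`,
#'   `n_parameters`, `final_loss`, `final_macro_dice`.
#' @export
glance.mdr_segmenter <- function(x, ...) {
  n_par <- sum(vapply(x$weights, length, numeric(1)))
  h <- x$history
  tibble::tibble(
    depth = x$config$depth,
    base_channels = x$config$base_channels,
    epochs = nrow(h),
    n_parameters = n_par,
    final_loss = if (nrow(h)) h$loss[nrow(h)] else NA_real_,
    final_macro_dice = if (nrow(h)) h$macro_dice[nrow(h)] else NA_real_
  )
}

#' Tidy a synthetic cohort into its exam records
#'
#' @param x An `mdr_cohort`.
#' @param ... Unused.
#' @return The exam-record tibble (`subject_id`, `age`, `laterality`,
#'   `mdr_percent`); the hidden-truth group labels stay in `x$truth`.
#' @export
tidy.mdr_cohort <- function(x, ...) {
  x$records
}

#' One-row summary of a synthetic cohort
#'
#' @param x An `mdr_cohort`.
#' @param ... Unused.
#' @return A one-row tibble: subject and exam counts, age span, mean and
#'   median MDR.
#' @export
glance.mdr_cohort <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$truth),
    n_exams = nrow(x$records),
    age_min = min(x$records$age),
    age_max = max(x$records$age),
    mean_mdr = mean(x$records$mdr_percent),
    median_mdr = stats::median(x$records$mdr_percent)
  )
}
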