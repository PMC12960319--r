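#' Per-age summary statistics of MDR
#'
#' One row per distinct age present in the exam records, summarizing
#' `mdr_percent` over all images at that age: count, mean, SD, median and the
#' 25th/75th percentiles (linear interpolation between order statistics). A
#' single observation yields SD 0.
#'
#' @param records A data frame of exam records with at least `age` and
#'   `mdr_percent` columns (e.g. `generate_cohort()$records`).
#'
#' @return A tibble with columns `age`, `n_images`, `mean`, `sd`, `median`,
#'   `iqr1`, `iqr3`, ordered by age.
#' @export
age_stratified_stats <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no exam records supplied", call. = FALSE)
  }
  records |>
    dplyr::group_by(.data$age) |>
    dplyr::summarise(
      n_images = dplyr::n(),
      mean = mean(.data$mdr_percent),
      sd = if (dplyr::n() > 1L) stats::sd(.data$mdr_percent) else 0,
      median = stats::median(.data$mdr_percent),
      iqr1 = stats::quantile(.data$mdr_percent, 0.25, names = FALSE),
      iqr3 = stats::quantile(.data$mdr_percent, 0.75, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$age)
}

#' Age-wise divergence between mean and median MDR
#'
#' The mean minus median MDR per age. Positive divergence at post-menopausal
#' ages is the signature of a right-skewed mixture: a majority with low
#' density plus a persistently dense minority pulling the mean up.
#'
#' @param stats_table Output of [age_stratified_stats()].
#' @return A tibble with `age` and `divergence` (mean − median, percent
#'   MDR), preserving age order.
#' @export
mean_median_divergence <- function(stats_table) {
  if (is.null(stats_table) || nrow(stats_table) == 0L) {
    stop("empty statistics table", call. = FALSE)
  }
  tibble::tibble(
    age = stats_table$age,
    divergence = stats_table$mean - stats_table$median
  )
}

#' Moving-average temporal differentiation of an MDR series
#'
#' First difference of a per-age series (`d(a) = x(a+1) - x(a)`, indexed at
#' the earlier age) followed by a centred moving average of odd width
#' `window`; at the edges the window shrinks symmetrically. Applied to the
#' per-age median MDR this shows where the age-related decline flattens into
#' its plateau.
#'
#' @param series Numeric vector indexed by consecutive integer ages
#'   (optionally named by age).
#' @param window Odd integer `>= 1` smoothing width in years (default 5).
#'
#' @return A tibble with `age` (the earlier age of each first difference, if
#'   ages were supplied as names; otherwise the 1-based index), `diff` (raw
#'   first difference) and `smoothed`.
#' @export
temporal_differentiation <- function(series, window = 5L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L) {
    stop("window must be an odd integer >= 1", call. = FALSE)
  }
  if (length(series) < 2L) {
    stop("series must contain at least two consecutive ages", call. = FALSE)
  }
  d <- diff(series)
  half <- (window - 1L) %/% 2L
  n <- length(d)
  smoothed <- vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half)
    hi <- min(n, i + half)
    mean(d[lo:hi])
  }, numeric(1))
  ages <- if (!is.null(names(series))) {
    as.numeric(names(series))[-length(series)]
  } else {
    seq_len(n)
  }
  tibble::tibble(age = ages, diff = unname(d), smoothed = smoothed)
}

#' Annualized MDR decline between two ages
#'
#' `(mdr_start - mdr_end) / (age_end - age_start)`, in percent MDR per year;
#' positive values are declines.
#'
#' @param mdr_start,mdr_end MDR in percent at the two ages.
#' @param age_start,age_end Ages in years, `age_end > age_start`.
#' @return Percent MDR per year.
#' @export
#' @examples
#' annualized_decline(20.5, 60, 16.0, 79) # ~0.24 %/yr
annualized_decline <- function(mdr_start, age_start, mdr_end, age_end) {
  if (age_end <= age_start) {
    stop("age_end must be greater than age_start", call. = FALSE)
  }
  (mdr_start - mdr_end) / (age_end - age_start)
}

#' MDR histogram at one age
#'
#' Bins `mdr_percent` of all records at `age` into `[0, bw), [bw, 2bw), ...`
#' with the final bin closed at 100. Fractions sum to one.
#'
#' @param records Exam records (see [age_stratified_stats()]).
#' @param age Age (years) to select.
#' @param bin_width Bin width in percent MDR (default 10).
#'
#' @return A tibble with `bin_lo`, `bin_hi`, `count`, `fraction`.
#' @export
mdr_histogram <- function(records, age, bin_width = 10) {
  x <- records$mdr_percent[records$age == age]
  if (length(x) == 0L) {
    stop("no exam records at age ", age, call. = FALSE)
  }
  breaks <- seq(0, 100, by = bin_width)
  if (breaks[length(breaks)] < 100) breaks <- c(breaks, 100)
  # left-closed bins, last bin closed on the right so 100% is counted
  idx <- findInterval(x, breaks, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1L)
  tibble::tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    count = counts,
    fraction = counts / length(x)
  )
}

#' Rule for classifying individual MDR trajectories
#'
#' Thresholds for [classify_trajectory()]: a subject whose least-squares MDR
#' slope is at most `slope_rapid` %/yr is "rapidly_decreasing"; otherwise a
#' subject with mean MDR at least `level_persistent`% and slope above
#' `slope_persistent` is "persistently_dense"; everything else (including
#' series of fewer than two exams) is "indeterminate". These defaults are
#' this package's operationalization of the two observed subpopulations, not
#' a published criterion.
#'
#' @param slope_rapid Slope threshold (%/yr) for rapid decline (default -1).
#' @param level_persistent Mean-MDR threshold (%) for persistence (default 50).
#' @param slope_persistent Slope floor (%/yr) for persistence (default -0.5).
#' @return A list of class `"trajectory_rule"`.
#' @export
trajectory_rule <- function(slope_rapid = -1.0,
                            level_persistent = 50,
                            slope_persistent = -0.5) {
  structure(
    list(slope_rapid = slope_rapid,
         level_persistent = level_persistent,
         slope_persistent = slope_persistent),
    class = "trajectory_rule"
  )
}

#' Classify one subject's MDR trajectory
#'
#' @param ages Integer ages of the exams (sorted or not; sorted internally).
#' @param mdr_percent MDR values (percent) at those exams.
#' @param rule A [trajectory_rule()].
#' @return One of `"rapidly_decreasing"`, `"persistently_dense"`,
#'   `"indeterminate"`.
#' @export
classify_trajectory <- function(ages, mdr_percent, rule = trajectory_rule()) {
  if (length(ages) == 0L || length(mdr_percent) == 0L) {
    stop("empty trajectory series", call. = FALSE)
  }
  if (length(ages) != length(mdr_percent)) {
    stop("ages and mdr_percent must have equal length", call. = FALSE)
  }
  if (length(ages) < 2L) return("indeterminate")
  o <- order(ages)
  a <- ages[o]; y <- mdr_percent[o]
  if (stats::var(a) == 0) return("indeterminate") # no age spread, no slope
  slope <- stats::cov(a, y) / stats::var(a) # least-squares slope
  if (slope <= rule$slope_rapid) return("rapidly_decreasing")
  if (mean(y) >= rule$level_persistent && slope > rule$slope_persistent) {
    return("persistently_dense")
  }
  "indeterminate"
}

#' Classify every subject's trajectory in a cohort
#'
#' @param records Exam records with `subject_id`, `age`, `mdr_percent`.
#' @param rule A [trajectory_rule()].
#' @return A tibble with `subject_id`, `n_exams`, `slope` (%/yr, `NA` for
#'   single-exam subjects), `mean_mdr`, `group`.
#' @export
classify_trajectories <- function(records, rule = trajectory_rule()) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no exam records supplied", call. = FALSE)
  }
  records |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_exams = dplyr::n(),
      slope = if (dplyr::n() > 1L) {
        stats::cov(.data$age, .data$mdr_percent) / stats::var(.data$age)
      } else {
        NA_real_
      },
      mean_mdr = mean(.data$mdr_percent),
      group = classify_trajectory(.data$age, .data$mdr_percent, rule),
      .groups = "drop"
    )
}
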