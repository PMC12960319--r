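#' Plot the training history of a segmenter
#'
#' Loss and per-epoch test macro DICE side by side.
#'
#' @param object An `mdr_segmenter`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mdr_segmenter <- function(object, ...) {
  h <- object$history
  if (nrow(h) == 0) stop("segmenter has no training history", call. = FALSE)
  long <- tidyr::pivot_longer(
    h[, c("epoch", "loss", "macro_dice")],
    cols = c("loss", "macro_dice"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Segmenter training history")
}

#' @rdname autoplot.mdr_segmenter
#' @param segmenter An `mdr_segmenter`.
#' @export
plot_training_history <- function(segmenter) {
  autoplot.mdr_segmenter(segmenter)
}

#' Plot per-age mean and median MDR with spread bands
#'
#' Mean with +/- SD band and median with interquartile band, per age, on one
#' panel each; the widening gap between the two curves reflects the
#' right-skewed mixture of declining and persistently dense subjects.
#'
#' @param stats_table Output of [age_stratified_stats()].
#' @return A ggplot object.
#' @export
plot_age_trend <- function(stats_table) {
  long <- dplyr::bind_rows(
    tibble::tibble(age = stats_table$age, stat = "mean",
                   value = stats_table$mean,
                   lo = stats_table$mean - stats_table$sd,
                   hi = stats_table$mean + stats_table$sd),
    tibble::tibble(age = stats_table$age, stat = "median",
                   value = stats_table$median,
                   lo = stats_table$iqr1, hi = stats_table$iqr3)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stat) +
    ggplot2::labs(x = "age (years)", y = "MDR (%)",
                  title = "Age-stratified MDR")
}

#' Plot an MDR histogram at one age
#'
#' @param histogram Output of [mdr_histogram()].
#' @param age Optional age used for the title.
#' @return A ggplot object.
#' @export
plot_mdr_histogram <- function(histogram, age = NULL) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$fraction)) +
    ggplot2::geom_col(width = (histogram$bin_hi - histogram$bin_lo)[1] * 0.95) +
    ggplot2::labs(
      x = "MDR (%)", y = "fraction of images",
      title = if (is.null(age)) "MDR distribution"
              else sprintf("MDR distribution at age %s", age)
    )
}

#' Plot individual MDR trajectories
#'
#' One line per subject, optionally coloured by a trajectory classification.
#'
#' @param records Exam records (`subject_id`, `age`, `mdr_percent`).
#' @param groups Optional tibble with `subject_id` and `group` (e.g. from
#'   [classify_trajectories()]).
#' @return A ggplot object.
#' @export
plot_trajectories <- function(records, groups = NULL) {
  df <- records
  if (!is.null(groups)) {
    df <- dplyr::left_join(df, groups[, c("subject_id", "group")],
                           by = "subject_id")
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age,
                                          y = .data$mdr_percent,
                                          group = .data$subject_id,
                                          colour = .data$group))
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$age,
                                          y = .data$mdr_percent,
                                          group = .data$subject_id))
  }
  p + ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "age (years)", y = "MDR (%)",
                  title = "Individual MDR trajectories")
}

#' Display a phantom image and its mask
#'
#' @param x An `mdr_phantom`.
#' @param ... Unused.
#' @return A ggplot object showing intensity and tissue labels side by side.
#' @export
autoplot.mdr_phantom <- function(x, ...) {
  H <- nrow(x$image); W <- ncol(x$image)
  grid <- tidyr::expand_grid(y = seq_len(H), x_ = seq_len(W))
  df <- dplyr::bind_rows(
    tibble::tibble(grid, panel = "image", value = as.vector(x$image)),
    tibble::tibble(grid, panel = "mask",
                   value = as.vector(x$mask) / max(1, max(x$mask)))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}
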