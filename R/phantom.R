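#' Parameters for a synthetic MLO phantom
#'
#' Builds the parameter set for [generate_phantom()]. The phantom emulates the
#' layout of a mediolateral-oblique (MLO) mammogram: a bright triangular
#' pectoral wedge touching the upper image corner on the chest-wall side, a
#' half-elliptical breast of radiolucent fat against the chest-wall edge, and
#' an elliptical glandular region embedded in the breast. Gland texture is a
#' binary mixture of two intensity modes straddling the pectoral mean, with
#' mixing weight `dense_fraction`, so that the ground-truth mammographic dense
#' rate (MDR) of the emitted image/mask pair equals `dense_fraction` up to
#' pixel-count rounding.
#'
#' @param width,height Image size in pixels. Each must be divisible by 16 so
#'   that the segmenter's pooling pyramid divides evenly.
#' @param pectoral_intensity_mean Mean normalized intensity of the pectoral
#'   muscle wedge, in `[0, 1]`. Must leave headroom (`<= 0.9`) for the bright
#'   glandular mode that sits above it.
#' @param pectoral_fraction Fraction of the image area covered by the
#'   pectoral wedge.
#' @param gland_fraction Fraction of the breast area occupied by the gland.
#' @param dense_fraction Target fraction `p` of gland pixels strictly brighter
#'   than the pectoral mean; this is the phantom's ground-truth MDR.
#' @param fat_intensity_mean Mean normalized intensity of fat. Must be below
#'   `pectoral_intensity_mean` (fat is radiolucent).
#' @param noise_sd Standard deviation of additive Gaussian intensity noise.
#' @param laterality `"left"` or `"right"`; right-sided phantoms are the
#'   horizontal mirror of left-sided ones.
#'
#' @return A list of class `"phantom_params"`.
#' @export
#' @examples
#' p <- phantom_params(width = 160, height = 192, dense_fraction = 0.4)
#' ph <- generate_phantom(p, seed = 7)
#' table(ph$mask)
phantom_params <- function(width = 320L,
                           height = 384L,
                           pectoral_intensity_mean = 0.75,
                           pectoral_fraction = 0.08,
                           gland_fraction = 0.35,
                           dense_fraction = 0.5,
                           fat_intensity_mean = 0.35,
                           noise_sd = 0.02,
                           laterality = c("left", "right")) {
  laterality <- match.arg(laterality)
  p <- list(
    width = as.integer(width), height = as.integer(height),
    pectoral_intensity_mean = pectoral_intensity_mean,
    pectoral_fraction = pectoral_fraction,
    gland_fraction = gland_fraction,
    dense_fraction = dense_fraction,
    fat_intensity_mean = fat_intensity_mean,
    noise_sd = noise_sd,
    laterality = laterality
  )
  class(p) <- "phantom_params"
  validate_phantom_params(p)
  p
}

validate_phantom_params <- function(p) {
  if (p$width <= 0L || p$height <= 0L) {
    stop("phantom dimensions must be positive", call. = FALSE)
  }
  if (p$width %% 16L != 0L || p$height %% 16L != 0L) {
    stop("phantom width and height must each be divisible by 16 ",
         "(segmenter downsampling depth)", call. = FALSE)
  }
  fracs <- c(p$pectoral_fraction, p$gland_fraction, p$dense_fraction)
  if (any(fracs < 0) || any(fracs > 1)) {
    stop("pectoral_fraction, gland_fraction and dense_fraction must lie in [0, 1]",
         call. = FALSE)
  }
  if (p$pectoral_intensity_mean < 0 || p$pectoral_intensity_mean > 0.9) {
    stop("pectoral_intensity_mean must lie in [0, 0.9] so that a dense ",
         "glandular mode can sit above it", call. = FALSE)
  }
  if (p$fat_intensity_mean < 0 || p$fat_intensity_mean > 1) {
    stop("fat_intensity_mean must lie in [0, 1]", call. = FALSE)
  }
  if (p$fat_intensity_mean >= p$pectoral_intensity_mean) {
    stop("fat_intensity_mean must be below pectoral_intensity_mean ",
         "(fat is radiolucent)", call. = FALSE)
  }
  if (p$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  invisible(p)
}

#' Tissue label codes
#'
#' Label masks use the fixed coding 0 = background, 1 = fat, 2 = gland,
#' 3 = pectoral muscle.
#'
#' @format A named integer vector.
#' @export
MDR_LABELS <- c(background = 0L, fat = 1L, gland = 2L, pectoral = 3L)

# Analytic phantom geometry on the canonical (left) orientation.
# Returns the label matrix plus the analytic region areas.
phantom_geometry <- function(p) {
  W <- p$width
  H <- p$height
  x <- matrix(rep(seq_len(W), each = H), nrow = H) # column index
  y <- matrix(rep(seq_len(H), times = W), nrow = H) # row index

  # breast: half-ellipse against the chest wall (left edge)
  a <- 0.85 * W
  b <- 0.42 * H
  cy <- 0.55 * H
  breast <- ((x - 1) / a)^2 + ((y - cy) / b)^2 <= 1

  # pectoral wedge: triangle with legs x0 (top edge) and y0 (left edge),
  # area x0 * y0 / 2 = pectoral_fraction * W * H
  x0 <- W * sqrt(p$pectoral_fraction)
  y0 <- 2 * H * sqrt(p$pectoral_fraction)
  wedge <- (x - 1) / x0 + (y - 1) / y0 <= 1

  # gland: ellipse inside the breast, below the wedge
  breast_area <- pi * a * b / 2
  gland_area <- p$gland_fraction * breast_area
  ratio <- 1.4 * H / W # v / u
  u <- sqrt(gland_area / (pi * ratio))
  v <- u * ratio
  gx <- 0.30 * W
  gy <- 0.58 * H
  gland <- (((x - gx) / u)^2 + ((y - gy) / v)^2 <= 1) & breast & !wedge

  labels <- matrix(MDR_LABELS[["background"]], nrow = H, ncol = W)
  labels[breast] <- MDR_LABELS[["fat"]]
  labels[gland] <- MDR_LABELS[["gland"]]
  labels[wedge] <- MDR_LABELS[["pectoral"]]
  storage.mode(labels) <- "integer"

  list(
    labels = labels,
    area_pectoral = x0 * y0 / 2,
    area_gland = gland_area,
    area_fat = breast_area - gland_area - sum(wedge & breast)
  )
}

#' Generate one synthetic MLO phantom with its ground-truth mask
#'
#' Emits a normalized intensity image and an aligned label mask
#' (0 background, 1 fat, 2 gland, 3 pectoral). Gland pixels are an
#' exact-count two-mode mixture: `round(p * n_gland)` pixels are drawn from a
#' bright mode clamped strictly above the pectoral mean, the rest from a dark
#' mode clamped strictly below it, so the realized dense fraction equals
#' `dense_fraction` to within one pixel and the edge cases `p = 0` / `p = 1`
#' give MDR exactly 0 / 1. Output is bit-identical for a fixed
#' `(params, seed)` pair.
#'
#' @param params A [phantom_params()] object.
#' @param seed Integer seed controlling all randomness in this phantom.
#'
#' @return A list of class `"mdr_phantom"` with elements `image` (numeric
#'   matrix in `[0, 1]`, rows = height), `mask` (integer matrix of labels),
#'   `params` and `seed`.
#' @export
generate_phantom <- function(params, seed) {
  validate_phantom_params(params)
  geom <- phantom_geometry(params)
  labels <- geom$labels
  n_gland <- sum(labels == MDR_LABELS[["gland"]])
  if (n_gland < 16L) {
    stop("degenerate phantom: glandular region has fewer than 16 pixels",
         call. = FALSE)
  }

  img <- withr::with_seed(as.integer(seed), {
    H <- params$height
    W <- params$width
    pect <- params$pectoral_intensity_mean
    base <- matrix(0.05, nrow = H, ncol = W)
    base[labels == MDR_LABELS[["fat"]]] <- params$fat_intensity_mean
    base[labels == MDR_LABELS[["pectoral"]]] <- pect

    # binary texture inside the gland: exact count of bright-mode pixels
    gland_idx <- which(labels == MDR_LABELS[["gland"]])
    n_hi <- round(params$dense_fraction * n_gland)
    hi_idx <- if (n_hi > 0L) gland_idx[sample.int(n_gland, n_hi)] else integer(0)
    lo_idx <- setdiff(gland_idx, hi_idx)
    tex_sd <- 0.03
    base[hi_idx] <- stats::rnorm(length(hi_idx), pect + 0.10, tex_sd)
    base[lo_idx] <- stats::rnorm(length(lo_idx), pect - 0.15, tex_sd)

    img <- base + stats::rnorm(H * W, 0, params$noise_sd)
    # keep the two gland modes strictly on their side of the pectoral mean
    img[hi_idx] <- pmax(img[hi_idx], pect + 0.01)
    img[lo_idx] <- pmin(img[lo_idx], pect - 0.01)
    pmin(pmax(img, 0), 1)
  })

  if (params$laterality == "right") {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    labels <- labels[, rev(seq_len(ncol(labels))), drop = FALSE]
  }

  structure(
    list(image = img, mask = labels, params = params, seed = as.integer(seed)),
    class = "mdr_phantom"
  )
}

#' @export
print.mdr_phantom <- function(x, ...) {
  cat(sprintf(
    "<mdr_phantom %dx%d (%s), p = %.3f, seed = %d>\n",
    x$params$width, x$params$height, x$params$laterality,
    x$params$dense_fraction, x$seed
  ))
  invisible(x)
}

#' Default per-item parameter sampler for phantom sets
#'
#' Draws a fresh [phantom_params()] for each item: dense fraction uniform on
#' `[0, 1]`, gland fraction uniform on `[0.25, 0.45]`, random laterality.
#' Geometry and intensity means are held at their defaults.
#'
#' @param width,height Image size passed through to [phantom_params()].
#' @return A function `f(i)` suitable as the `params_sampler` argument of
#'   [generate_phantom_set()].
#' @export
default_phantom_sampler <- function(width = 320L, height = 384L) {
  force(width)
  force(height)
  function(i) {
    phantom_params(
      width = width, height = height,
      dense_fraction = stats::runif(1),
      gland_fraction = stats::runif(1, 0.25, 0.45),
      laterality = sample(c("left", "right"), 1)
    )
  }
}

#' Generate an annotated set of phantoms with a manifest
#'
#' Draws `n` independent phantoms. Per-item seeds are derived deterministically
#' from the master `seed`, so the whole set (manifest and pixel data) is
#' reproducible bit-for-bit. An optional `split` assigns items to named
#' subsets (e.g. `c(train = 240, test = 60)`).
#'
#' @param n Number of phantoms (`>= 1`).
#' @param params_sampler Function `f(i)` returning the [phantom_params()] for
#'   item `i`; called under the item's derived seed. Defaults to
#'   [default_phantom_sampler()].
#' @param seed Master integer seed.
#' @param split Optional named integer vector summing to `n`; items are
#'   assigned to the named subsets in order.
#'
#' @return A list of class `"mdr_phantom_set"` with `items` (list of
#'   [generate_phantom()] results) and `manifest` (a tibble with one row per
#'   item: id, seed, every parameter field, and `split` if requested).
#' @export
generate_phantom_set <- function(n, params_sampler = NULL, seed = 1L,
                                 split = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be at least 1", call. = FALSE)
  if (is.null(params_sampler)) params_sampler <- default_phantom_sampler()
  if (!is.null(split)) {
    if (is.null(names(split)) || any(!nzchar(names(split)))) {
      stop("split must be a named integer vector", call. = FALSE)
    }
    if (sum(split) != n) stop("split sizes must sum to n", call. = FALSE)
  }

  item_seeds <- withr::with_seed(as.integer(seed),
                                 sample.int(.Machine$integer.max, n))

  items <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    prm <- withr::with_seed(item_seeds[i], params_sampler(i))
    items[[i]] <- generate_phantom(prm, seed = item_seeds[i])
    rows[[i]] <- tibble::tibble(
      item = i, seed = item_seeds[i],
      width = prm$width, height = prm$height,
      pectoral_intensity_mean = prm$pectoral_intensity_mean,
      pectoral_fraction = prm$pectoral_fraction,
      gland_fraction = prm$gland_fraction,
      dense_fraction = prm$dense_fraction,
      fat_intensity_mean = prm$fat_intensity_mean,
      noise_sd = prm$noise_sd,
      laterality = prm$laterality
    )
  }
  manifest <- dplyr::bind_rows(rows)
  if (!is.null(split)) {
    manifest$split <- rep(names(split), times = split)
  }
  structure(list(items = items, manifest = manifest),
            class = "mdr_phantom_set")
}

#' @export
print.mdr_phantom_set <- function(x, ...) {
  cat(sprintf("<mdr_phantom_set of %d items>\n", length(x$items)))
  if (!is.null(x$manifest$split)) print(table(x$manifest$split))
  invisible(x)
}

#' Parameters for a synthetic longitudinal MDR cohort
#'
#' Describes a two-subpopulation screening cohort: a majority whose MDR
#' declines rapidly through the perimenopausal years and a persistently dense
#' minority. Each subject receives `exams_per_subject` exams at distinct
#' integer ages spaced `exam_spacing` years apart, enrolled within
#' `enroll_window` years of the lower age bound, so series span the
#' perimenopausal transition. Subject trajectories are linear in age from a
#' group-specific start level at the lower age bound, plus exam-level noise,
#' clamped to `[0, 100]` percent.
#'
#' @param n_subjects Number of subjects.
#' @param age_range Integer `c(min, max)` age in years (default 40-79).
#' @param exams_per_subject Exams per subject.
#' @param frac_persistent Fraction of subjects in the persistently dense group.
#' @param decline_rate_fast Decline of the rapidly decreasing group, in
#'   percent MDR per year (positive = decline).
#' @param decline_rate_slow Decline of the persistently dense group, percent
#'   MDR per year.
#' @param start_mdr_declining,start_mdr_persistent Numeric `c(mean, sd)` of
#'   the group's MDR (percent) at the lower age bound.
#' @param noise_sd Exam-level noise SD in percent MDR.
#' @param exam_spacing Years between consecutive exams.
#' @param enroll_window Width (years) of the uniform window for the first
#'   exam age, starting at the lower age bound.
#'
#' @return A list of class `"cohort_params"`.
#' @export
cohort_params <- function(n_subjects = 200L,
                          age_range = c(40L, 79L),
                          exams_per_subject = 5L,
                          frac_persistent = 0.2,
                          decline_rate_fast = 1.33,
                          decline_rate_slow = 0.1,
                          start_mdr_declining = c(mean = 50, sd = 8),
                          start_mdr_persistent = c(mean = 70, sd = 8),
                          noise_sd = 2,
                          exam_spacing = 4L,
                          enroll_window = 5L) {
  p <- list(
    n_subjects = as.integer(n_subjects),
    age_range = as.integer(age_range),
    exams_per_subject = as.integer(exams_per_subject),
    frac_persistent = frac_persistent,
    decline_rate_fast = decline_rate_fast,
    decline_rate_slow = decline_rate_slow,
    start_mdr_declining = start_mdr_declining,
    start_mdr_persistent = start_mdr_persistent,
    noise_sd = noise_sd,
    exam_spacing = as.integer(exam_spacing),
    enroll_window = as.integer(enroll_window)
  )
  class(p) <- "cohort_params"
  validate_cohort_params(p)
  p
}

validate_cohort_params <- function(p) {
  if (p$n_subjects < 1L) stop("n_subjects must be at least 1", call. = FALSE)
  if (length(p$age_range) != 2L || p$age_range[1] > p$age_range[2]) {
    stop("age_range must be c(min, max) with min <= max", call. = FALSE)
  }
  if (p$frac_persistent < 0 || p$frac_persistent > 1) {
    stop("frac_persistent must lie in [0, 1]", call. = FALSE)
  }
  if (p$decline_rate_fast < 0 || p$decline_rate_slow < 0) {
    stop("decline rates must be non-negative (positive = decline)", call. = FALSE)
  }
  if (p$exams_per_subject < 1L) stop("exams_per_subject must be >= 1", call. = FALSE)
  if (p$exam_spacing < 1L) stop("exam_spacing must be >= 1 year", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  span <- p$exam_spacing * (p$exams_per_subject - 1L)
  if (p$age_range[1] + span > p$age_range[2]) {
    stop("exam schedule (", span, " years) does not fit inside age_range",
         call. = FALSE)
  }
  invisible(p)
}

#' Generate a synthetic longitudinal MDR cohort
#'
#' Simulates per-subject MDR series with two subpopulations (rapidly
#' decreasing vs persistently dense). Group sizes are exact:
#' `round(frac_persistent * n_subjects)` subjects are persistent. True group
#' membership is returned in a separate truth table so that recovery by
#' [classify_trajectory()] can be tested without leaking labels into the
#' exam records.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed.
#'
#' @return A list of class `"mdr_cohort"` with `records` (tibble:
#'   `subject_id`, `age`, `laterality`, `mdr_percent`) and `truth` (tibble:
#'   `subject_id`, `group` in `{"rapidly_decreasing", "persistently_dense"}`).
#' @export
generate_cohort <- function(params, seed) {
  validate_cohort_params(params)
  p <- params
  withr::with_seed(as.integer(seed), {
    n <- p$n_subjects
    n_pers <- round(p$frac_persistent * n)
    persistent <- rep(FALSE, n)
    if (n_pers > 0L) persistent[sample.int(n, n_pers)] <- TRUE

    span <- p$exam_spacing * (p$exams_per_subject - 1L)
    max_start <- p$age_range[2] - span
    window <- min(p$enroll_window, max_start - p$age_range[1] + 1L)
    first_age <- p$age_range[1] + sample.int(window, n, replace = TRUE) - 1L

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      ages <- first_age[i] + p$exam_spacing * (0:(p$exams_per_subject - 1L))
      if (persistent[i]) {
        start <- stats::rnorm(1, p$start_mdr_persistent[["mean"]],
                              p$start_mdr_persistent[["sd"]])
        rate <- p$decline_rate_slow
      } else {
        start <- stats::rnorm(1, p$start_mdr_declining[["mean"]],
                              p$start_mdr_declining[["sd"]])
        rate <- p$decline_rate_fast
      }
      mdr <- start - rate * (ages - p$age_range[1]) +
        stats::rnorm(length(ages), 0, p$noise_sd)
      rows[[i]] <- tibble::tibble(
        subject_id = sprintf("S%04d", i),
        age = as.integer(ages),
        laterality = sample(c("left", "right"), length(ages), replace = TRUE),
        mdr_percent = pmin(pmax(mdr, 0), 100)
      )
    }
    structure(
      list(
        records = dplyr::bind_rows(rows),
        truth = tibble::tibble(
          subject_id = sprintf("S%04d", seq_len(n)),
          group = ifelse(persistent, "persistently_dense", "rapidly_decreasing")
        ),
        params = p,
        seed = as.integer(seed)
      ),
      class = "mdr_cohort"
    )
  })
}

#' @export
print.mdr_cohort <- function(x, ...) {
  cat(sprintf("<mdr_cohort: %d subjects, %d exam records>\n",
              nrow(x$truth), nrow(x$records)))
  invisible(x)
}
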