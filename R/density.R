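#' Mean pectoral-muscle intensity (the dense-tissue threshold)
#'
#' Arithmetic mean of the normalized image intensities over pectoral-labelled
#' pixels. This value is the per-image reference threshold against which
#' glandular pixels are judged dense.
#'
#' @param image Numeric intensity matrix in `[0, 1]`.
#' @param mask Integer label mask of identical shape (3 = pectoral).
#'
#' @return The mean pectoral intensity, a number in `[0, 1]`.
#' @export
pectoral_mean_intensity <- function(image, mask) {
  if (!all(dim(image) == dim(mask))) {
    stop("image and mask must have identical shapes", call. = FALSE)
  }
  sel <- mask == MDR_LABELS[["pectoral"]]
  if (!any(sel)) {
    stop("empty region: mask contains no pectoral pixels", call. = FALSE)
  }
  mean(image[sel])
}

#' Compute the mammographic dense rate (MDR) for one image
#'
#' The core statistic of the pipeline. The pectoral muscle's mean intensity
#' is taken as the dense-tissue threshold; glandular pixels brighter than it
#' count as dense, and MDR is the dense fraction of the glandular area:
#' `MDR = A_d / A_gl`. The comparison is strict (`>`) by default, matching
#' the statistic's definition; `inequality = "ge"` (`>=`) emulates the visual
#' atlas phrasing in which pixels at the pectoral level already count as
#' dense.
#'
#' @inheritParams pectoral_mean_intensity
#' @param inequality `"gt"` (strict, default) or `"ge"`.
#'
#' @return A one-row tibble of class `"mdr_density_result"` with columns
#'   `d_mj` (pectoral mean intensity), `a_gl` (glandular pixel count), `a_d`
#'   (dense glandular pixel count), `mdr` (in `[0, 1]`), `mdr_percent`, and
#'   `category` (see [classify_composition()]).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_params(width = 160, height = 192,
#'                                       dense_fraction = 0.4), seed = 7)
#' compute_mdr(ph$image, ph$mask)
compute_mdr <- function(image, mask, inequality = c("gt", "ge")) {
  inequality <- match.arg(inequality)
  if (!all(dim(image) == dim(mask))) {
    stop("image and mask must have identical shapes", call. = FALSE)
  }
  gl <- mask == MDR_LABELS[["gland"]]
  a_gl <- sum(gl)
  if (a_gl == 0L) {
    stop("empty region: mask contains no glandular pixels", call. = FALSE)
  }
  d_mj <- pectoral_mean_intensity(image, mask)
  g <- image[gl]
  a_d <- if (inequality == "gt") sum(g > d_mj) else sum(g >= d_mj)
  mdr <- a_d / a_gl
  out <- tibble::tibble(
    d_mj = d_mj,
    a_gl = a_gl,
    a_d = a_d,
    mdr = mdr,
    mdr_percent = 100 * mdr,
    category = classify_composition(mdr)
  )
  class(out) <- c("mdr_density_result", class(out))
  out
}

#' Breast composition category from an MDR value
#'
#' Quantitative analogue of the four-category composition atlas:
#' MDR below 10% is "fatty", 10% to below 50% "scattered", 50% to below 80%
#' "heterogeneous", and 80% or more "extreme_dense".
#'
#' @param mdr MDR value(s) as proportions in `[0, 1]`.
#'
#' @return A factor with levels `fatty`, `scattered`, `heterogeneous`,
#'   `extreme_dense`.
#' @export
#' @examples
#' classify_composition(c(0.05, 0.10, 0.50, 0.80))
classify_composition <- function(mdr) {
  if (any(is.na(mdr)) || any(mdr < 0) || any(mdr > 1)) {
    stop("mdr must lie in [0, 1]", call. = FALSE)
  }
  cut(mdr,
      breaks = c(-Inf, 0.10, 0.50, 0.80, Inf),
      labels = c("fatty", "scattered", "heterogeneous", "extreme_dense"),
      right = FALSE)
}

#' Is a composition category a dense breast?
#'
#' Heterogeneous and extreme-dense compositions are collectively termed dense
#' breasts (elevated masking and cancer risk).
#'
#' @param category A category from [classify_composition()] (factor or
#'   character).
#' @return Logical vector.
#' @export
is_dense_breast <- function(category) {
  category <- as.character(category)
  valid <- c("fatty", "scattered", "heterogeneous", "extreme_dense")
  if (any(!category %in% valid)) {
    stop("unknown composition category", call. = FALSE)
  }
  category %in% c("heterogeneous", "extreme_dense")
}
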