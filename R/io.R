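#' Pipeline configuration
#'
#' Collects the knobs of the end-to-end pipeline. All randomness downstream
#' flows from the single `seed`; output files written by the pipeline embed a
#' hash of this configuration in a header comment so results can be traced to
#' the settings that produced them.
#'
#' @param target_size Integer `c(width, height)` the segmenter operates at.
#' @param dense_inequality `"gt"` (strict, the statistic's definition) or
#'   `"ge"` (atlas emulation); see [compute_mdr()].
#' @param moving_average_window Odd window (years) for
#'   [temporal_differentiation()].
#' @param histogram_bin_width Percent-MDR bin width for [mdr_histogram()].
#' @param trajectory A [trajectory_rule()].
#' @param seed Integer master seed.
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(target_size = c(320L, 384L),
                            dense_inequality = c("gt", "ge"),
                            moving_average_window = 5L,
                            histogram_bin_width = 10,
                            trajectory = trajectory_rule(),
                            seed = 1L) {
  dense_inequality <- match.arg(dense_inequality)
  cfg <- list(
    target_size = as.integer(target_size),
    dense_inequality = dense_inequality,
    moving_average_window = as.integer(moving_average_window),
    histogram_bin_width = histogram_bin_width,
    trajectory = trajectory,
    seed = as.integer(seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

#' Read a grayscale mammogram image
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF and returns intensities
#' normalized to `[0, 1]` by the source bit depth's maximum, oriented so that
#' higher values mean denser tissue. Colour (RGB/RGBA) input is refused
#' rather than silently converted; DICOM is not supported by this build.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return A numeric matrix in `[0, 1]` with attribute `source_path`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    dcm = ,
    dicom = stop("DICOM input is not supported by this build; ",
                 "convert to 16-bit grayscale PNG/TIFF first", call. = FALSE),
    stop("unsupported image format: .", ext, " (expected PNG or TIFF)",
         call. = FALSE)
  )
  if (length(dim(img)) == 3L) {
    stop("colour (multi-channel) input is not supported; supply a grayscale ",
         "image: ", path, call. = FALSE)
  }
  attr(img, "source_path") <- path
  img
}

#' Write a normalized intensity image as 16-bit grayscale TIFF
#'
#' Values are quantized to 16 bits; a written-then-reread image round-trips
#' losslessly thereafter.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output path (`.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(is.matrix(image))
  img <- pmin(pmax(image, 0), 1)
  tiff::writeTIFF(round(img * 65535) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read / write tissue label masks
#'
#' Masks are stored as 8-bit grayscale PNG whose raw code values are the
#' labels `{0, 1, 2, 3}`. Reading validates the label set and fails on any
#' out-of-palette value; the round trip is lossless.
#'
#' @param path Path to the mask PNG.
#' @return `read_mask()`: an integer label matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) {
    stop("mask-format error: mask must be single-channel: ", path,
         call. = FALSE)
  }
  m <- round(raw * 255)
  if (!all(m %in% MDR_LABELS)) {
    stop("mask-format error: values outside the label set {0,1,2,3} in ",
         path, call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_mask
#' @param mask Integer label matrix with values in `{0, 1, 2, 3}`.
#' @return `write_mask()`: `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  if (!all(mask %in% MDR_LABELS)) {
    stop("mask-format error: values outside the label set {0,1,2,3}",
         call. = FALSE)
  }
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Write a CSV with a configuration-hash header
#'
#' Standard comma-separated UTF-8 CSV with a header row, preceded by a
#' `# mdrquant config_hash=` comment line when a configuration is supplied.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param config Optional [pipeline_config()] whose hash is embedded.
#' @return `path`, invisibly.
#' @export
write_mdr_csv <- function(df, path, config = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(config)) {
    writeLines(sprintf("# mdrquant config_hash=%s", config_hash(config)), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mdr_csv
#' @export
read_mdr_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, comment.char = "#"))
}

#' Write a phantom set to disk
#'
#' Images go to `images/item_%04d.tif` (16-bit grayscale TIFF), masks to
#' `masks/item_%04d.png`, and the per-item parameter manifest to
#' `manifest.csv`.
#'
#' @param set An [generate_phantom_set()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom_set <- function(set, dir) {
  stopifnot(inherits(set, "mdr_phantom_set"))
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(set$items)) {
    write_image(set$items[[i]]$image,
                file.path(dir, "images", sprintf("item_%04d.tif", i)))
    write_mask(set$items[[i]]$mask,
               file.path(dir, "masks", sprintf("item_%04d.png", i)))
  }
  write_mdr_csv(set$manifest, file.path(dir, "manifest.csv"))
  invisible(dir)
}

#' Read a phantom set written by [write_phantom_set()]
#'
#' @param dir Directory containing `images/`, `masks/` and `manifest.csv`.
#' @param split Optional split name to select (requires a `split` manifest
#'   column).
#' @return A list with `images`, `masks` and `manifest`, usable directly as a
#'   training or test set for [train_segmenter()].
#' @export
read_phantom_set <- function(dir, split = NULL) {
  manifest <- read_mdr_csv(file.path(dir, "manifest.csv"))
  items <- manifest$item
  if (!is.null(split)) {
    if (is.null(manifest$split)) {
      stop("manifest has no split column", call. = FALSE)
    }
    items <- manifest$item[manifest$split == split]
    manifest <- manifest[manifest$split == split, ]
  }
  list(
    images = lapply(items, function(i) {
      read_image(file.path(dir, "images", sprintf("item_%04d.tif", i)))
    }),
    masks = lapply(items, function(i) {
      read_mask(file.path(dir, "masks", sprintf("item_%04d.png", i)))
    }),
    manifest = manifest
  )
}

#' Write / read a synthetic cohort
#'
#' Exam records go to `exams.csv` (`subject_id`, `age`, `laterality`,
#' `mdr_percent`); hidden-truth group labels go to the sidecar
#' `truth.csv` so that recovery tests never read them by accident.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mdr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mdr_csv(cohort$records, file.path(dir, "exams.csv"))
  write_mdr_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  structure(
    list(
      records = read_mdr_csv(file.path(dir, "exams.csv")),
      truth = read_mdr_csv(file.path(dir, "truth.csv"))
    ),
    class = "mdr_cohort"
  )
}

#' Run the MDR pipeline over a directory of images
#'
#' Reads every PNG/TIFF in `image_dir`, segments it with the supplied
#' segmenter, computes the density result, and returns one row per readable
#' image. Unreadable or degenerate images (colour files, masks without
#' pectoral or gland pixels) are never silently dropped: they appear in the
#' `skips` table with the failure reason, and
#' `nrow(results) + nrow(skips)` always equals the number of input files.
#'
#' @param image_dir Directory of input images.
#' @param segmenter A trained [train_segmenter()] model.
#' @param config A [pipeline_config()]; its `target_size` must match the
#'   segmenter's.
#' @param out_csv Optional path; when given, results are written as CSV with
#'   the configuration hash in a header comment.
#'
#' @return A list of class `"mdr_pipeline_result"` with `results` (tibble:
#'   `image`, `d_mj`, `a_gl`, `a_d`, `mdr`, `mdr_percent`, `category`) and
#'   `skips` (tibble: `image`, `reason`).
#' @export
run_pipeline <- function(image_dir, segmenter, config = pipeline_config(),
                         out_csv = NULL) {
  stopifnot(inherits(segmenter, "mdr_segmenter"))
  if (!all(config$target_size == segmenter$config$target_size)) {
    stop("config target_size does not match the segmenter's input size",
         call. = FALSE)
  }
  files <- sort(list.files(image_dir, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0L) {
    stop("no readable images found in ", image_dir, call. = FALSE)
  }
  results <- list()
  skips <- list()
  for (f in files) {
    row <- tryCatch({
      img <- read_image(f)
      img <- resize_bilinear(img, config$target_size[1], config$target_size[2])
      mask <- predict_mask(segmenter, img)
      res <- compute_mdr(img, mask, inequality = config$dense_inequality)
      dplyr::bind_cols(tibble::tibble(image = basename(f)), res)
    }, error = function(e) {
      structure(conditionMessage(e), class = "pipeline_skip")
    })
    if (inherits(row, "pipeline_skip")) {
      skips[[f]] <- tibble::tibble(image = basename(f),
                                   reason = unclass(row))
    } else {
      results[[f]] <- row
    }
  }
  out <- structure(
    list(
      results = dplyr::bind_rows(results),
      skips = dplyr::bind_rows(skips),
      config = config
    ),
    class = "mdr_pipeline_result"
  )
  if (!is.null(out_csv)) write_mdr_csv(out$results, out_csv, config = config)
  out
}

#' @export
print.mdr_pipeline_result <- function(x, ...) {
  cat(sprintf("<mdr_pipeline_result: %d images, %d skipped>\n",
              nrow(x$results), nrow(x$skips)))
  invisible(x)
}

#' Age-stats CSV mirroring the per-age summary table
#'
#' Writes the [age_stratified_stats()] table with percentages rounded to one
#' decimal place.
#'
#' @param stats_table Output of [age_stratified_stats()].
#' @param path Output path.
#' @param config Optional [pipeline_config()].
#' @return `path`, invisibly.
#' @export
write_age_stats_csv <- function(stats_table, path, config = NULL) {
  tbl <- dplyr::mutate(stats_table,
                       dplyr::across(c("mean", "sd", "median", "iqr1", "iqr3"),
                                     ~ round(.x, 1)))
  write_mdr_csv(tbl, path, config = config)
}
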