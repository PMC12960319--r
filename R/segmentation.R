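#' Training configuration for the U-Net segmenter
#'
#' The segmenter is a classic U-Net style encoder-decoder: `depth` levels of
#' two 3x3 ReLU convolutions with 2x2 max-pooling, a two-convolution
#' bottleneck, and a decoder of nearest-neighbour upsampling, a reducing
#' convolution, skip concatenation and a fusing convolution per level, closed
#' by a 1x1 convolution onto the four tissue classes. Training minimizes
#' per-pixel softmax cross-entropy (optionally plus a soft-DICE term) with
#' Adam.
#'
#' @param epochs Number of training epochs (`>= 0`). The reference protocol
#'   plateaus around 100 epochs; small separable phantom sets converge far
#'   faster.
#' @param batch_size Images per Adam step (gradient accumulation).
#' @param learning_rate Adam step size.
#' @param depth Number of encoder pooling levels (default 4).
#' @param base_channels Channels of the first encoder level; doubled per
#'   level. Use small values (4-8) for CPU-speed test runs.
#' @param loss `"ce"` (cross-entropy) or `"ce_dice"` (cross-entropy plus
#'   soft-DICE over the three tissue classes).
#' @param grad_clip Global gradient-norm ceiling per Adam step (on the
#'   mean-over-batch scale); stabilizes training against occasional loss
#'   spikes. Set to 0 to disable.
#' @param seed Integer seed controlling weight initialization and epoch
#'   shuffling; a fixed seed reproduces the whole training history on one
#'   device.
#' @param target_size Integer `c(width, height)` all images and masks are
#'   resampled to before training/prediction; each dimension must be
#'   divisible by `2^depth`. Default `c(320, 384)` (portrait MLO).
#'
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs = 100L,
                         batch_size = 4L,
                         learning_rate = 1e-3,
                         depth = 4L,
                         base_channels = 16L,
                         loss = c("ce", "ce_dice"),
                         grad_clip = 5,
                         seed = 1L,
                         target_size = c(320L, 384L)) {
  loss <- match.arg(loss)
  cfg <- list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, depth = as.integer(depth),
    base_channels = as.integer(base_channels), loss = loss,
    grad_clip = grad_clip,
    seed = as.integer(seed), target_size = as.integer(target_size)
  )
  if (cfg$grad_clip < 0) stop("grad_clip must be >= 0", call. = FALSE)
  if (cfg$epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  if (cfg$batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (cfg$depth < 1L) stop("depth must be >= 1", call. = FALSE)
  if (cfg$base_channels < 1L) stop("base_channels must be >= 1", call. = FALSE)
  if (length(cfg$target_size) != 2L || any(cfg$target_size < 2L)) {
    stop("target_size must be c(width, height)", call. = FALSE)
  }
  if (any(cfg$target_size %% 2L^cfg$depth != 0L)) {
    stop("target_size dimensions must be divisible by 2^depth", call. = FALSE)
  }
  class(cfg) <- "train_config"
  cfg
}

# Coerce a phantom set / list of phantoms / list(images=, masks=) to paired
# lists of image and mask matrices.
as_segmentation_set <- function(x) {
  if (inherits(x, "mdr_phantom_set")) x <- x$items
  if (is.list(x) && !is.null(x$images)) {
    imgs <- x$images
    msks <- if (is.null(x$masks)) vector("list", length(imgs)) else x$masks
  } else if (is.list(x) && length(x) > 0 && inherits(x[[1]], "mdr_phantom")) {
    imgs <- lapply(x, `[[`, "image")
    msks <- lapply(x, `[[`, "mask")
  } else {
    stop("expected an mdr_phantom_set, a list of mdr_phantom objects, ",
         "or list(images = , masks = )", call. = FALSE)
  }
  if (length(imgs) != length(msks)) {
    stop("images and masks differ in length", call. = FALSE)
  }
  list(images = imgs, masks = msks)
}

# Bilinear resampling of an intensity image to width w, height h.
resize_bilinear <- function(img, w, h) {
  H <- nrow(img); W <- ncol(img)
  if (H == h && W == w) return(img)
  # map output pixel centres to input coordinates
  xs <- (seq_len(w) - 0.5) * W / w + 0.5
  ys <- (seq_len(h) - 0.5) * H / h + 0.5
  x0 <- pmin(pmax(floor(xs), 1), W); x1 <- pmin(x0 + 1, W)
  y0 <- pmin(pmax(floor(ys), 1), H); y1 <- pmin(y0 + 1, H)
  fx <- pmin(pmax(xs - x0, 0), 1)
  fy <- pmin(pmax(ys - y0, 0), 1)
  a <- img[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    img[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    img[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
    img[y1, x1, drop = FALSE] * outer(fy, fx)
  a
}

# Nearest-neighbour resampling (label-preserving) for masks.
resize_nearest <- function(mask, w, h) {
  H <- nrow(mask); W <- ncol(mask)
  if (H == h && W == w) return(mask)
  xs <- pmin(pmax(ceiling((seq_len(w) - 0.5) * W / w), 1), W)
  ys <- pmin(pmax(ceiling((seq_len(h) - 0.5) * H / h), 1), H)
  mask[ys, xs, drop = FALSE]
}

prepare_set <- function(set, target_size, need_masks = TRUE, what = "set") {
  w <- target_size[1]; h <- target_size[2]
  n <- length(set$images)
  imgs <- vector("list", n)
  msks <- vector("list", n)
  for (i in seq_len(n)) {
    img <- set$images[[i]]
    msk <- set$masks[[i]]
    if (need_masks) {
      if (is.null(msk)) stop(what, " item ", i, " has no mask", call. = FALSE)
      if (!all(dim(img) == dim(msk))) {
        stop(what, " item ", i, ": image and mask shapes differ", call. = FALSE)
      }
    }
    imgs[[i]] <- resize_bilinear(img, w, h)
    if (!is.null(msk)) {
      m <- resize_nearest(msk, w, h)
      storage.mode(m) <- "integer"
      msks[[i]] <- m
    }
  }
  list(images = imgs, masks = msks)
}

#' Train the U-Net segmenter
#'
#' Trains the encoder-decoder on paired image/mask data, evaluating macro
#' DICE (unweighted mean over fat, gland and pectoral) on the test set after
#' every epoch. With `epochs = 0` an untrained (randomly initialized)
#' segmenter is returned with an empty history.
#'
#' @param train,test Paired data: an [generate_phantom_set()] result, a list
#'   of [generate_phantom()] objects, or `list(images = , masks = )` of
#'   matrices. All items are resampled to `config$target_size`.
#' @param config A [train_config()].
#'
#' @return An object of class `"mdr_segmenter"` carrying the learned weights,
#'   the `config`, and `history`: a tibble with one row per epoch
#'   (`epoch`, `loss`, `macro_dice`, `dice_fat`, `dice_gland`,
#'   `dice_pectoral`).
#' @export
#' @seealso [predict_mask()], [dice_coefficient()], [macro_dice()]
train_segmenter <- function(train, test, config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  train <- as_segmentation_set(train)
  if (length(train$images) == 0L) stop("empty training set", call. = FALSE)
  test <- as_segmentation_set(test)
  train <- prepare_set(train, config$target_size, what = "training")
  test <- prepare_set(test, config$target_size, what = "test")

  fit <- withr::with_seed(config$seed, {
    cpp_unet_train(
      train$images, train$masks, test$images, test$masks,
      depth = config$depth, base = config$base_channels,
      epochs = config$epochs, lr = config$learning_rate,
      batch = config$batch_size, dice_loss = identical(config$loss, "ce_dice"),
      grad_clip = config$grad_clip, weights_in = NULL
    )
  })

  hist <- fit$history
  colnames(hist) <- c("epoch", "loss", "macro_dice",
                      "dice_fat", "dice_gland", "dice_pectoral")
  structure(
    list(
      weights = fit$weights,
      config = config,
      history = tibble::as_tibble(hist)
    ),
    class = "mdr_segmenter"
  )
}

#' @export
print.mdr_segmenter <- function(x, ...) {
  cat(sprintf(
    "<mdr_segmenter: depth %d, base channels %d, input %dx%d, %d epochs>\n",
    x$config$depth, x$config$base_channels,
    x$config$target_size[1], x$config$target_size[2], nrow(x$history)
  ))
  if (nrow(x$history) > 0) {
    cat(sprintf("  final test macro DICE: %.4f\n",
                x$history$macro_dice[nrow(x$history)]))
  }
  invisible(x)
}

#' Predict a tissue label mask for one image
#'
#' Runs the segmenter forward and takes the per-pixel argmax over the four
#' class scores (ties broken toward the lowest class index). Inference is
#' deterministic.
#'
#' @param segmenter An [train_segmenter()] result.
#' @param image Numeric intensity matrix in `[0, 1]`. Must already have the
#'   segmenter's input size (`config$target_size`); use [resize_bilinear()]
#'   upstream otherwise.
#'
#' @return Integer label matrix (0 background, 1 fat, 2 gland, 3 pectoral) of
#'   the same size as `image`.
#' @export
predict_mask <- function(segmenter, image) {
  stopifnot(inherits(segmenter, "mdr_segmenter"))
  ts <- segmenter$config$target_size
  if (!is.matrix(image) || nrow(image) != ts[2] || ncol(image) != ts[1]) {
    stop("image must be a ", ts[2], "x", ts[1], " (height x width) matrix ",
         "matching the segmenter's input size", call. = FALSE)
  }
  cpp_unet_predict(segmenter$weights, segmenter$config$depth,
                   segmenter$config$base_channels, image)
}

#' DICE overlap coefficient for one tissue class
#'
#' `2 |X ∩ Y| / (|X| + |Y|)` between the binary masks of `class_id` in the
#' predicted and ground-truth label masks. When both masks are empty for the
#' class the coefficient is defined as 1; when exactly one is empty, 0.
#'
#' @param pred,truth Integer label matrices of identical shape.
#' @param class_id Tissue class, one of 1 (fat), 2 (gland), 3 (pectoral).
#'
#' @return A number in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth, class_id) {
  if (!all(dim(pred) == dim(truth))) {
    stop("pred and truth must have identical shapes", call. = FALSE)
  }
  if (length(class_id) != 1L || !class_id %in% 1:3) {
    stop("class_id must be one of 1 (fat), 2 (gland), 3 (pectoral)",
         call. = FALSE)
  }
  x <- pred == class_id
  y <- truth == class_id
  nx <- sum(x); ny <- sum(y)
  if (nx + ny == 0L) return(1.0)
  2 * sum(x & y) / (nx + ny)
}

#' Macro-averaged DICE over the three tissue classes
#'
#' Unweighted mean of [dice_coefficient()] over fat, gland and pectoral
#' (background excluded).
#'
#' @inheritParams dice_coefficient
#' @return A number in `[0, 1]`.
#' @export
macro_dice <- function(pred, truth) {
  mean(vapply(1:3, function(k) dice_coefficient(pred, truth, k), numeric(1)))
}

#' Evaluate a segmenter on a held-out set
#'
#' @param segmenter An [train_segmenter()] result.
#' @param test Paired data accepted by [train_segmenter()].
#' @return A tibble with one row per item: `item`, `macro_dice`, `dice_fat`,
#'   `dice_gland`, `dice_pectoral`.
#' @export
evaluate_segmenter <- function(segmenter, test) {
  test <- as_segmentation_set(test)
  test <- prepare_set(test, segmenter$config$target_size, what = "test")
  purrr::map_dfr(seq_along(test$images), function(i) {
    pred <- predict_mask(segmenter, test$images[[i]])
    d <- vapply(1:3, function(k) dice_coefficient(pred, test$masks[[i]], k),
                numeric(1))
    tibble::tibble(
      item = i, macro_dice = mean(d),
      dice_fat = d[1], dice_gland = d[2], dice_pectoral = d[3]
    )
  })
}
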