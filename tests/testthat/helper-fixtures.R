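# Shared small fixtures. Phantoms used in unit tests are 64x64 or 96x112 so
# the whole non-acceptance suite stays fast; the acceptance tests build their
# own full-size sets.

small_params <- function(...) {
  phantom_params(width = 96L, height = 112L, ...)
}

tiny_params <- function(...) {
  phantom_params(width = 64L, height = 64L, ...)
}

# brute-force per-pixel DICE oracle (independent of the vectorized path)
dice_oracle <- function(pred, truth, class_id) {
  nx <- 0L; ny <- 0L; ni <- 0L
  for (i in seq_along(pred)) {
    px <- pred[i] == class_id
    py <- truth[i] == class_id
    nx <- nx + px
    ny <- ny + py
    ni <- ni + (px && py)
  }
  if (nx + ny == 0L) return(1.0)
  2 * ni / (nx + ny)
}

# brute-force MDR oracle: explicit loops over labelled pixels
mdr_oracle <- function(image, mask, strict = TRUE) {
  psum <- 0; pn <- 0L; a_gl <- 0L; a_d <- 0L
  for (i in seq_along(mask)) {
    if (mask[i] == 3L) { psum <- psum + image[i]; pn <- pn + 1L }
  }
  dmj <- psum / pn
  for (i in seq_along(mask)) {
    if (mask[i] == 2L) {
      a_gl <- a_gl + 1L
      above <- if (strict) image[i] > dmj else image[i] >= dmj
      if (above) a_d <- a_d + 1L
    }
  }
  list(d_mj = dmj, a_gl = a_gl, a_d = a_d, mdr = a_d / a_gl)
}

# a small trained segmenter, trained once per test run and memoized
.seg_cache <- new.env(parent = emptyenv())

small_trained_segmenter <- function() {
  if (is.null(.seg_cache$seg)) {
    sampler <- default_phantom_sampler(width = 96L, height = 112L)
    train <- generate_phantom_set(28, sampler, seed = 501)
    test <- generate_phantom_set(8, sampler, seed = 502)
    cfg <- train_config(
      epochs = 18, batch_size = 4, learning_rate = 2e-3,
      depth = 2, base_channels = 8, seed = 77,
      target_size = c(96L, 112L)
    )
    .seg_cache$seg <- train_segmenter(train, test, cfg)
    .seg_cache$test <- test
  }
  list(seg = .seg_cache$seg, test = .seg_cache$test)
}
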