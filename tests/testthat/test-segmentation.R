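test_that("dice_coefficient matches its definition and conventions", {
  a <- matrix(c(2L, 2L, 2L, 2L, 0L, 0L), nrow = 2)
  expect_identical(dice_coefficient(a, a, 2), 1.0)

  # disjoint nonempty regions
  p <- matrix(c(1L, 0L, 0L, 0L), 2)
  t <- matrix(c(0L, 0L, 1L, 0L), 2)
  expect_identical(dice_coefficient(p, t, 1), 0.0)

  # |X| = 4, |Y| = 4, |X intersect Y| = 2 -> 0.5
  p2 <- matrix(0L, 2, 4); p2[1, ] <- 3L
  t2 <- matrix(0L, 2, 4); t2[1, 3:4] <- 3L; t2[2, 1:2] <- 3L
  expect_identical(dice_coefficient(p2, t2, 3), 0.5)

  # empty-class conventions
  z <- matrix(0L, 2, 2)
  expect_identical(dice_coefficient(z, z, 1), 1.0)
  expect_identical(dice_coefficient(p, z, 1), 0.0)

  expect_error(dice_coefficient(p, matrix(0L, 3, 3), 1), "identical shapes")
  expect_error(dice_coefficient(p, t, 0), "class_id")
  expect_error(dice_coefficient(p, t, 4), "class_id")
})

test_that("dice is symmetric and macro_dice averages the tissue classes", {
  set.seed(7)
  for (i in 1:20) {
    p <- matrix(sample(0:3, 64 * 64, replace = TRUE), 64)
    t <- matrix(sample(0:3, 64 * 64, replace = TRUE), 64)
    oracle <- vapply(1:3, function(k) dice_oracle(p, t, k), numeric(1))
    for (k in 1:3) {
      d <- dice_coefficient(p, t, k)
      expect_identical(d, dice_coefficient(t, p, k))
      expect_equal(d, oracle[k], tolerance = 1e-12)
    }
    expect_equal(macro_dice(p, t), mean(oracle), tolerance = 1e-12)
  }
  # per-class DICEs 1, 0.5, 0 average to 0.5
  p <- matrix(0L, 2, 6); t <- p
  p[1, 1:2] <- 1L; t[1, 1:2] <- 1L            # fat: 1.0
  p[1, 3:4] <- 2L; t[1, 4:5] <- 2L            # gland: 0.5
  p[2, 1] <- 3L; t[2, 3] <- 3L                # pectoral: 0.0
  expect_identical(macro_dice(p, t), 0.5)
})

test_that("train_config validates its invariants", {
  expect_error(train_config(epochs = -1), "epochs")
  expect_error(train_config(target_size = c(100L, 384L)), "divisible")
  cfg <- train_config(depth = 2, target_size = c(64L, 64L))
  expect_s3_class(cfg, "train_config")
})

test_that("epochs = 0 returns an untrained segmenter with an empty history", {
  s <- generate_phantom_set(2, function(i) tiny_params(), seed = 1)
  cfg <- train_config(epochs = 0, depth = 2, base_channels = 4,
                      target_size = c(64L, 64L), seed = 1)
  seg <- train_segmenter(s, s, cfg)
  expect_identical(nrow(seg$history), 0L)
  # prediction still yields a valid label mask, deterministically
  img <- matrix(0, 64, 64)
  m1 <- predict_mask(seg, img)
  expect_true(all(m1 %in% 0:3))
  expect_identical(m1, predict_mask(seg, img))
  expect_error(predict_mask(seg, matrix(0, 32, 32)), "input size")
})

test_that("training is reproducible under a fixed seed and rejects bad input", {
  s <- generate_phantom_set(4, function(i) tiny_params(), seed = 5)
  cfg <- train_config(epochs = 2, batch_size = 2, depth = 2,
                      base_channels = 4, target_size = c(64L, 64L), seed = 9)
  a <- train_segmenter(s, s, cfg)
  b <- train_segmenter(s, s, cfg)
  expect_identical(a$history$loss, b$history$loss)
  expect_identical(a$weights, b$weights)

  expect_error(train_segmenter(list(images = list(), masks = list()), s, cfg),
               "empty training set")
  bad <- list(images = list(matrix(0, 64, 64)),
              masks = list(matrix(0L, 32, 32)))
  expect_error(train_segmenter(bad, s, cfg), "shapes differ")
})

test_that("a small net learns separable phantoms to high DICE", {
  fit <- small_trained_segmenter()
  hist <- fit$seg$history
  expect_gte(hist$macro_dice[nrow(hist)], 0.85)
  # best-so-far test DICE is non-decreasing by construction
  expect_true(all(diff(cummax(hist$macro_dice)) >= 0))

  # held-out phantoms segment well enough for density work
  ev <- evaluate_segmenter(fit$seg, fit$test)
  expect_gte(mean(ev$macro_dice), 0.8)
})

test_that("prediction is approximately equivariant to mirroring", {
  fit <- small_trained_segmenter()
  # the training sampler draws both lateralities, so mirrored test phantoms
  # should segment about as well as the originals
  mirrored <- list(
    images = lapply(fit$test$items, function(it) {
      it$image[, rev(seq_len(ncol(it$image)))]
    }),
    masks = lapply(fit$test$items, function(it) {
      it$mask[, rev(seq_len(ncol(it$mask)))]
    })
  )
  d_orig <- mean(evaluate_segmenter(fit$seg, fit$test)$macro_dice)
  d_mirr <- mean(evaluate_segmenter(fit$seg, mirrored)$macro_dice)
  expect_lte(abs(d_orig - d_mirr), 0.05)
})

test_that("tidy and glance summarize a segmenter", {
  fit <- small_trained_segmenter()
  td <- tidy(fit$seg)
  expect_identical(nrow(td), nrow(fit$seg$history))
  gl <- glance(fit$seg)
  expect_identical(nrow(gl), 1L)
  expect_gt(gl$n_parameters, 0)
  expect_identical(gl$final_macro_dice, td$macro_dice[nrow(td)])
})
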