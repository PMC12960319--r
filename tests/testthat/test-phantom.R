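test_that("phantom generation is bit-reproducible and respects the label set", {
  p <- small_params(dense_fraction = 0.4)
  a <- generate_phantom(p, seed = 7)
  b <- generate_phantom(p, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$mask %in% 0:3))
  expect_identical(dim(a$image), dim(a$mask))
  expect_true(all(a$image >= 0 & a$image <= 1))
  # different seed changes the pixels
  expect_false(identical(a$image, generate_phantom(p, seed = 8)$image))
})

test_that("the pectoral wedge touches the upper corner on the laterality side", {
  left <- generate_phantom(small_params(laterality = "left"), seed = 1)
  right <- generate_phantom(small_params(laterality = "right"), seed = 1)
  expect_identical(left$mask[1, 1], MDR_LABELS[["pectoral"]])
  expect_identical(right$mask[1, ncol(right$mask)], MDR_LABELS[["pectoral"]])
  # mirroring: the right phantom is the column-reversed left phantom
  expect_identical(right$mask, left$mask[, rev(seq_len(ncol(left$mask)))])
})

test_that("every pixel has exactly one label and regions have sane areas", {
  p <- small_params()
  ph <- generate_phantom(p, seed = 3)
  counts <- table(factor(ph$mask, levels = 0:3))
  expect_identical(sum(counts), length(ph$mask))
  geom <- mdrquant:::phantom_geometry(p)
  # rasterized region areas match the analytic geometry within 1% of image area
  area <- prod(dim(ph$mask))
  expect_lt(abs(sum(ph$mask == 3) - geom$area_pectoral), 0.01 * area)
  expect_lt(abs(sum(ph$mask == 2) - geom$area_gland), 0.01 * area)
})

test_that("ground-truth MDR equals the requested dense fraction", {
  # edge cases are exact by construction
  ph0 <- generate_phantom(small_params(dense_fraction = 0), seed = 5)
  expect_identical(compute_mdr(ph0$image, ph0$mask)$mdr, 0)
  ph1 <- generate_phantom(small_params(dense_fraction = 1), seed = 5)
  expect_identical(compute_mdr(ph1$image, ph1$mask)$mdr, 1)

  # derived example: p = 0.40 recovered within +/- 0.03 from the emitted pair
  ph <- generate_phantom(small_params(dense_fraction = 0.40), seed = 7)
  expect_gt(sum(ph$mask == 2), 2000)
  got <- sum(ph$image[ph$mask == 2] > mean(ph$image[ph$mask == 3])) /
    sum(ph$mask == 2)
  expect_true(got >= 0.37 && got <= 0.43)

  # property: recovery within +/- 0.03 across random parameter draws
  set.seed(42)
  for (i in 1:25) {
    p <- stats::runif(1)
    ph <- generate_phantom(small_params(dense_fraction = p), seed = 1000 + i)
    mdr <- compute_mdr(ph$image, ph$mask)$mdr
    expect_lt(abs(mdr - p), 0.03)
  }
})

test_that("invalid phantom parameters are rejected", {
  expect_error(phantom_params(width = 100), "divisible by 16")
  expect_error(phantom_params(dense_fraction = 1.2), "\\[0, 1\\]")
  expect_error(phantom_params(fat_intensity_mean = 0.8,
                              pectoral_intensity_mean = 0.75), "radiolucent")
  expect_error(
    generate_phantom(small_params(gland_fraction = 0.0001), seed = 1),
    "degenerate"
  )
})

test_that("phantom sets are reproducible with a faithful manifest", {
  s1 <- generate_phantom_set(3, default_phantom_sampler(64L, 64L), seed = 1)
  s2 <- generate_phantom_set(3, default_phantom_sampler(64L, 64L), seed = 1)
  expect_identical(s1$manifest, s2$manifest)
  expect_identical(s1$items, s2$items)
  expect_error(generate_phantom_set(0), "at least 1")

  # a fixed sampler is recorded verbatim in the manifest
  fixed <- function(i) tiny_params(dense_fraction = 0.5)
  s3 <- generate_phantom_set(1, fixed, seed = 9)
  expect_identical(s3$manifest$dense_fraction, 0.5)

  # named split assigns subsets of the requested sizes
  s4 <- generate_phantom_set(10, function(i) tiny_params(), seed = 2,
                             split = c(train = 8, test = 2))
  expect_identical(sum(s4$manifest$split == "train"), 8L)
  expect_identical(sum(s4$manifest$split == "test"), 2L)
})

test_that("cohort generation honours its closed-form trajectory", {
  # frac_persistent = 0, zero rates and noise: constant series
  p0 <- cohort_params(n_subjects = 5, frac_persistent = 0,
                      decline_rate_fast = 0, noise_sd = 0)
  flat <- generate_cohort(p0, seed = 1)
  spread <- flat$records |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(r = diff(range(mdr_percent)))
  expect_true(all(spread$r == 0))

  # linear decline 1.33 %/yr from 36.2% at 40 reaches ~10.9% at 59
  p1 <- cohort_params(
    n_subjects = 1, age_range = c(40L, 59L), exams_per_subject = 20L,
    exam_spacing = 1L, enroll_window = 1L, frac_persistent = 0,
    decline_rate_fast = 1.33, start_mdr_declining = c(mean = 36.2, sd = 0),
    noise_sd = 0
  )
  traj <- generate_cohort(p1, seed = 1)$records
  expect_identical(sort(traj$age), 40:59)
  expect_equal(traj$mdr_percent[traj$age == 59], 36.2 - 19 * 1.33,
               tolerance = 1e-12)

  # deterministic group sizes
  co <- generate_cohort(cohort_params(n_subjects = 100, frac_persistent = 0.2),
                        seed = 3)
  expect_identical(sum(co$truth$group == "persistently_dense"), 20L)
  expect_true(all(co$records$mdr_percent >= 0 & co$records$mdr_percent <= 100))
  # distinct integer ages per subject
  dup <- co$records |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(d = anyDuplicated(age))
  expect_true(all(dup$d == 0))
})

test_that("cohort parameter validation catches inverted ranges", {
  expect_error(cohort_params(age_range = c(79, 40)), "min <= max")
  expect_error(cohort_params(exams_per_subject = 15, exam_spacing = 4),
               "does not fit")
})
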