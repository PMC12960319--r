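# independent order-statistic percentile oracle (linear interpolation,
# matching the documented convention)
percentile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  if (n == 1L) return(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

test_that("age-stratified statistics match brute-force oracles", {
  # single record
  one <- tibble::tibble(subject_id = "a", age = 50L, laterality = "left",
                        mdr_percent = 30)
  r <- age_stratified_stats(one)
  expect_identical(
    as.list(r),
    list(age = 50L, n_images = 1L, mean = 30, sd = 0, median = 30,
         iqr1 = 30, iqr3 = 30)
  )

  # symmetric values
  sym <- tibble::tibble(age = 45L, mdr_percent = c(10, 20, 30, 40))
  rs <- age_stratified_stats(sym)
  expect_identical(rs$mean, 25)
  expect_identical(rs$median, 25)

  # random cohort vs loop/sort oracles
  co <- generate_cohort(cohort_params(n_subjects = 120), seed = 11)
  tab <- age_stratified_stats(co$records)
  expect_identical(sum(tab$n_images), nrow(co$records))
  expect_true(all(tab$iqr1 <= tab$median & tab$median <= tab$iqr3))
  for (i in seq_len(nrow(tab))) {
    x <- co$records$mdr_percent[co$records$age == tab$age[i]]
    m <- sum(x) / length(x)
    expect_equal(tab$mean[i], m, tolerance = 1e-9)
    if (length(x) > 1) {
      expect_equal(tab$sd[i], sqrt(sum((x - m)^2) / (length(x) - 1)),
                   tolerance = 1e-9)
    }
    expect_equal(tab$median[i], percentile_oracle(x, 0.5), tolerance = 1e-9)
    expect_equal(tab$iqr1[i], percentile_oracle(x, 0.25), tolerance = 1e-9)
    expect_equal(tab$iqr3[i], percentile_oracle(x, 0.75), tolerance = 1e-9)
  }
  expect_error(age_stratified_stats(one[0, ]), "no exam records")
})

test_that("mean-median divergence is zero for symmetric data, positive for skew", {
  sym <- tibble::tibble(age = rep(50L, 5), mdr_percent = c(10, 20, 30, 40, 50))
  d <- mean_median_divergence(age_stratified_stats(sym))
  expect_equal(d$divergence, 0, tolerance = 1e-12)

  # persistent-dense subgroup skews late ages to the right: mean > median
  co <- generate_cohort(cohort_params(n_subjects = 400, frac_persistent = 0.2),
                        seed = 21)
  tab <- age_stratified_stats(co$records)
  div <- mean_median_divergence(tab)
  late <- div$divergence[div$age >= 52]
  expect_true(mean(late > 0) > 0.9)
  expect_identical(div$age, tab$age)
})

test_that("temporal differentiation smooths the first difference correctly", {
  const <- stats::setNames(rep(25, 10), 40:49)
  td <- temporal_differentiation(const, window = 5)
  expect_true(all(td$smoothed == 0))
  expect_identical(td$age, as.numeric(40:48))

  lin <- stats::setNames(100 - 1.33 * (0:19), 40:59)
  tl <- temporal_differentiation(lin, window = 5)
  expect_equal(tl$smoothed, rep(-1.33, 19), tolerance = 1e-9)

  # noisy series vs brute-force windowed mean, shrinking at the edges
  set.seed(3)
  noisy <- stats::setNames(stats::rnorm(15), 40:54)
  for (w in c(1, 3, 5, 7)) {
    tn <- temporal_differentiation(noisy, window = w)
    d <- diff(noisy)
    half <- (w - 1) / 2
    want <- sapply(seq_along(d), function(i) {
      mean(d[max(1, i - half):min(length(d), i + half)])
    })
    expect_equal(tn$smoothed, want, tolerance = 1e-9)
  }
  expect_error(temporal_differentiation(lin, window = 4), "odd")
  expect_error(temporal_differentiation(lin, window = -1), "odd")
})

test_that("annualized decline reproduces the late-cohort rate", {
  late <- annualized_decline(20.5, 60, 16.0, 79)
  expect_equal(round(late, 2), 0.24)
  expect_equal(late * (79 - 60), 4.5, tolerance = 1e-12)
  expect_identical(annualized_decline(30, 40, 30, 50), 0)
  expect_identical(annualized_decline(30, 40, 20, 50), 1)
  expect_error(annualized_decline(30, 50, 20, 50), "greater than")
})

test_that("MDR histograms bin correctly and conserve mass", {
  rec <- tibble::tibble(age = rep(40L, 4), mdr_percent = rep(5, 4))
  h <- mdr_histogram(rec, 40)
  expect_identical(h$fraction[1], 1)
  expect_identical(sum(h$count), 4L)

  # boundary values land in left-closed bins; 100 stays in the last bin
  rec2 <- tibble::tibble(age = 40L, mdr_percent = c(0, 10, 99.9, 100))
  h2 <- mdr_histogram(rec2, 40)
  expect_identical(h2$count[h2$bin_lo == 0], 1L)
  expect_identical(h2$count[h2$bin_lo == 10], 1L)
  expect_identical(h2$count[h2$bin_lo == 90], 2L)

  set.seed(8)
  for (i in 1:20) {
    co <- generate_cohort(cohort_params(n_subjects = 30), seed = i)
    ages <- unique(co$records$age)
    a <- sample(ages, 1)
    h <- mdr_histogram(co$records, a)
    expect_equal(sum(h$fraction), 1, tolerance = 1e-12)
  }
  expect_error(mdr_histogram(rec, 99), "no exam records")
})

test_that("trajectory classification applies the slope/level rule", {
  expect_identical(classify_trajectory(40:44, rep(60, 5)), "persistently_dense")
  # dropping 2 %/yr from 40%: least-squares slope is exactly -2
  expect_identical(classify_trajectory(40:44, 40 - 2 * (0:4)),
                   "rapidly_decreasing")
  expect_identical(classify_trajectory(50L, 30), "indeterminate")
  expect_identical(classify_trajectory(c(45, 46), c(30, 29.9)),
                   "indeterminate")
  expect_error(classify_trajectory(integer(0), numeric(0)), "empty")
  expect_error(classify_trajectory(1:3, 1:2), "equal length")
})

test_that("trajectory classification recovers the generator's hidden groups", {
  # per-subject misclassification is a ~1% tail event, so the >= 95% recovery
  # property is statistical; test the accuracy averaged over several cohorts
  accs <- vapply(1:5, function(s) {
    co <- generate_cohort(
      cohort_params(n_subjects = 150, frac_persistent = 0.2,
                    noise_sd = 2, exams_per_subject = 5),
      seed = 30 + s
    )
    got <- classify_trajectories(co$records)
    joined <- dplyr::inner_join(got, co$truth, by = "subject_id")
    mean(joined$group.x == joined$group.y)
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})
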