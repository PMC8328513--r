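test_that("closed-form time shift matches its defining equation", {
  expect_equal(relative_time_shift(0, 1.5, 0, 4), 0)
  expect_equal(relative_time_shift(1.5, 1.5, 0, 4), -1 / 16)
  # brute-force root check on a fine grid: -osc(shift) equals the top-down
  # value, with the oscillation in sine convention
  set.seed(7)
  for (k in 1:50) {
    am <- runif(1, 0.6, 3); phi <- runif(1, -pi / 2, pi / 2)
    om <- runif(1, 2, 10); p <- runif(1, 0, am)
    sh <- relative_time_shift(p, am, phi, om)
    expect_equal(-am * sin(2 * pi * om * sh + phi), p, tolerance = 1e-6)
  }
  # grid-search oracle for one worked case: the root nearest the closed form
  p <- 0.5; am <- 1.5; phi <- -0.15 * pi; om <- 4
  tt <- seq(-0.125, 0.125, by = 1e-5)
  res <- abs(-am * sin(2 * pi * om * tt + phi) - p)
  roots <- tt[which(res < 1e-3)]
  sh <- relative_time_shift(p, am, phi, om)
  expect_lt(min(abs(roots - sh)), 2e-5)
})

test_that("time shift decreases monotonically in prediction and clamps", {
  sh <- relative_time_shift(seq(0, 1.5, by = 0.05), 1.5, -0.15 * pi, 4)
  expect_true(all(diff(sh) < 0))
  expect_warning(out <- relative_time_shift(2, 1.5, 0, 4), "clamp")
  expect_equal(out, relative_time_shift(1.5, 1.5, 0, 4))
  expect_error(relative_time_shift(0.5, 0), "positive")
})

test_that("duration converts to rate by unit count", {
  expect_equal(rate_from_duration(0.25, 1), 4)
  expect_equal(rate_from_duration(0.25, 2), 8)
  expect_equal(rate_from_duration(1, 1), 1)
  expect_error(rate_from_duration(0), "positive")
})

test_that("the transform reshapes a skewed prediction distribution", {
  # predictions are strongly right-skewed; expected time shifts computed
  # with each sentence's own rate (3-8 Hz) are distributed more normally
  set.seed(11)
  p <- stats::rbeta(5000, 1.1, 6)
  om <- runif(5000, 3, 8)
  sh <- relative_time_shift(p, 1.5, -0.15 * pi, om)
  skew <- function(x) mean((x - mean(x))^3) / sd(x)^3
  expect_lt(abs(skew(sh)), abs(skew(p)))
})

test_that("onset spectra detect isochrony and its degradation", {
  iso <- onset_spectrum(seq(0, 2.25, by = 0.25), duration_s = 2.5)
  expect_equal(iso$peak_freq_hz, 4)
  # uniform shifts preserve spacing, hence the spectrum peak
  shifted <- onset_spectrum(seq(0, 2.25, by = 0.25) + 0.1, duration_s = 2.5)
  expect_equal(shifted$peak_z, iso$peak_z, tolerance = 1e-9)
  # growing onset jitter degrades the theta-band peak on average
  # (Monte-Carlo; at near-zero jitter the z-score is not monotone because a
  # perfectly periodic train spreads its power over equal harmonics)
  set.seed(13)
  mean_z <- function(s) mean(replicate(150, {
    on <- sort(seq(0, 2.25, by = 0.25) + rnorm(10, 0, s))
    onset_spectrum(on - min(on), duration_s = 2.5)$peak_z
  }))
  expect_gt(mean_z(0.02), mean_z(0.07))
  expect_error(onset_spectrum(0.5), "at least 2")
})

test_that("onset-difference regression recovers planted oscillation parameters", {
  tr <- generate_onset_trains(n_sentences = 120, seed = 21, noise_sd = 0)
  am_grid <- c(1, 1.5, 2)
  phi_grid <- c(-0.3, -0.15, 0) * pi
  f <- fit_expected_onsets(tr, am_grid, phi_grid, n_splits = 30)
  expect_equal(unname(coef(f)), c(1.5, -0.15 * pi))
  expect_gt(f$r2, 0.999)
  # identity-transform baseline cannot beat the generating transform
  expect_lte(f$r2_identity, f$r2 + 1e-6)
})

test_that("shuffling predictions destroys the transform's contribution", {
  tr <- generate_onset_trains(n_sentences = 80, seed = 22, noise_sd = 0.01)
  set.seed(23)
  tr$prediction <- sample(tr$prediction)
  f <- fit_expected_onsets(tr, am_grid = c(1, 1.5),
                           phi_grid = c(-0.15, 0) * pi, n_splits = 20)
  # covariates still explain duration/rate structure, but the transform's
  # gain over the identity baseline vanishes
  expect_equal(f$r2, f$r2_identity, tolerance = 0.02)
})
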