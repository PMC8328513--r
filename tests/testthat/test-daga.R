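test_that("unambiguous and symmetric stimuli decode as expected", {
  # pure /da/: the /da/ node always wins where anything fires
  for (d in c(0, 80, 160)) {
    tr <- run_daga_trial(p_da = 1, delay_ms = d)
    if (!is.na(tr$t_da)) expect_equal(tr$first_active, 1)
  }
  # exactly symmetric feedback and mixture: full ambiguity at any delay
  lm_eq <- lm_daga(0.15, 0.15)
  for (d in c(0, 40, 120))
    expect_equal(run_daga_trial(0.5, d, lm = lm_eq)$first_active, 0.5)
})

test_that("delay modulates the percept of ambiguous stimuli", {
  oc <- outcome_curve(p_da = 0.4, rate_hz = 6.25)
  expect_equal(oc$delay_ms, (0:11) * 320 / 12)
  expect_gt(length(unique(oc$first_active)), 1)   # phase-dependent percept
  expect_true(all(oc$first_active %in% c(0, 0.5, 1)))
  expect_true(all(oc$mean_activity_index >= 0 & oc$mean_activity_index <= 1))
  oc10 <- outcome_curve(p_da = 0.4, rate_hz = 10)
  expect_equal(max(oc10$delay_ms), 200 - 200 / 12)
  expect_error(outcome_curve(0.4, n_delays = 1), "at least 2")
})

test_that("the /da/ bias wins ambiguous trials early in the cycle", {
  for (p in c(0.4, 0.5)) {
    oc <- outcome_curve(p_da = p, rate_hz = 6.25)
    expect_gte(mean(oc$first_active), 0.5)
  }
  # decoders agree in direction where a clear winner exists
  oc <- outcome_curve(p_da = 0.4, rate_hz = 6.25)
  dec <- oc[oc$first_active %in% c(0, 1) &
              oc$mean_activity_index != 0.5, ]
  expect_true(all(sign(dec$mean_activity_index - 0.5) ==
                    sign(dec$first_active - 0.5)))
})

test_that("without the oscillation the outcome curve is delay-flat", {
  oc <- outcome_curve(p_da = 0.4, rate_hz = 6.25,
                      params = stimcon_params(am = 0))
  expect_equal(length(unique(oc$first_active)), 1L)
  # mean activity varies only by onset discretization, not by phase
  expect_lt(diff(range(oc$activity_index)), 0.01)
})

test_that("grid search recovers model-generated curves exactly", {
  # truth parameters chosen so the curve spans the full 0..1 range, making
  # the behavioral min-max normalization the identity
  truth <- list(p_da = 0.4, fb = 0.9, decay = 0.01, off = 0.01)
  p <- stimcon_params()
  p$fb_delay_cycles <- truth$fb; p$fb_decay <- truth$decay
  oc <- outcome_curve(truth$p_da, 6.25, params = p, offset_s = truth$off)
  behavioral <- data.frame(delay_ms = oc$delay_ms,
                           response = oc$first_active)
  expect_equal(range(behavioral$response), c(0, 1))
  g <- daga_grid(p_da = c(0.3, 0.4, 0.5),
                 fb_onset_cycles = c(0.7, 0.9),
                 fb_decay = c(0.01, 0.02), offset_s = c(0, 0.01))
  fit <- fit_daga(behavioral, 6.25, g)
  expect_equal(fit$r2, 1)
  expect_equal(predict(fit), behavioral$response)
  expect_equal(sum(residuals(fit)^2), 0)
  # the generating combination itself scores a perfect fit (the binary
  # decoder can map several combinations onto the same curve)
  s <- fit$surface
  truth_row <- s$p_da == truth$p_da & s$fb_onset_cycles == truth$fb &
    s$fb_decay == truth$decay & s$offset_s == truth$off
  expect_equal(s$r2[truth_row], 1)
})

test_that("ablations degrade the fit on a synthetic behavioral curve", {
  bc <- generate_behavioral_curve(rate_hz = 6.25, seed = 31, n_trials = 40)
  g <- daga_grid(p_da = c(0.3, 0.4, 0.5),
                 fb_onset_cycles = c(0.5, 0.7, 0.9),
                 fb_decay = c(0, 0.02), offset_s = c(-0.01, 0, 0.01))
  full <- fit_daga(bc, 6.25, g, decoder = "mean_activity")
  no_osc <- fit_daga(bc, 6.25, g, decoder = "mean_activity",
                     params = stimcon_params(am = 0))
  no_fb <- fit_daga(bc, 6.25, g, decoder = "mean_activity",
                    lm = lm_daga(0.15, 0.15))
  expect_gt(full$r2, no_osc$r2)
  expect_lt(no_osc$r2, 0)          # flat curve cannot beat the mean
  expect_gte(full$r2, no_fb$r2)
})

test_that("rectified sinusoid baseline behaves across curve types", {
  t_ms <- (0:11) * 320 / 12
  # exact model class, no snapping
  pure <- data.frame(delay_ms = t_ms,
                     response = 0.5 + 0.3 * sin(2 * pi * 6.25 * t_ms / 1000 +
                                                  pi / 2))
  fit <- rectified_sinus_fit(pure, 6.25, snap = FALSE,
                             amp_grid = c(0.1, 0.3, 0.5),
                             phase_grid = c(0, pi / 2, pi),
                             mean_grid = c(0.4, 0.5, 0.6))
  expect_equal(fit$r2, 1)
  expect_equal(fit$amplitude, 0.3)
  # binary-like curve: snapping to {0, 0.5, 1} can only help
  bin <- data.frame(delay_ms = t_ms, response = rep(c(1, 0), each = 6))
  expect_gte(rectified_sinus_fit(bin, 6.25, snap = TRUE)$r2,
             rectified_sinus_fit(bin, 6.25, snap = FALSE)$r2)
  # constant curve: amplitude 0 and R^2 = 0
  flat <- data.frame(delay_ms = t_ms, response = rep(0.5, 12))
  ffit <- rectified_sinus_fit(flat, 6.25)
  expect_equal(ffit$amplitude, 0)
  expect_equal(ffit$r2, 0)
})

test_that("Gaussian AIC penalizes parameters and flags zero residuals", {
  expect_equal(aic_gauss(12, 12, 0), 0)
  expect_lt(aic_gauss(10, 20, 2), aic_gauss(10, 20, 4))
  # halving the RSS wins when the parameter difference is small enough
  expect_lt(aic_gauss(5, 20, 4), aic_gauss(10, 20, 3))
  expect_warning(v <- aic_gauss(0, 10, 2), "-Inf")
  expect_equal(v, -Inf)
  expect_error(aic_gauss(1, 3, 3), "observations")
})
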