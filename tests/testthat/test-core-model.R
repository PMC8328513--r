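p0 <- stimcon_params()

test_that("inhibition gate has exactly three regimes", {
  expect_equal(inhibition_gate(10), 0.6)
  expect_equal(inhibition_gate(50), -0.6)
  expect_equal(inhibition_gate(150), -0.2)
  expect_equal(inhibition_gate(Inf), -0.2)
  # boundaries are half-open; ta = recov_ms belongs to the base regime
  expect_equal(inhibition_gate(c(0, 19.99, 20, 99.99, 100)),
               c(0.6, 0.6, -0.6, -0.6, -0.2))
  # dense sampling never leaves {-3b, 3b, b}
  vals <- inhibition_gate(seq(0, 300, by = 0.25))
  expect_equal(sort(unique(vals)), c(-0.6, -0.2, 0.6))
  expect_error(inhibition_gate(-5), "non-negative")
})

test_that("oscillation is a cosine with the stated period", {
  p <- stimcon_params(am = 1, omega = 4, phi = 0)
  expect_equal(oscillation(0, p), 1)
  expect_equal(oscillation(62.5, p), 0)
  expect_equal(oscillation(125, p), -1)
  t <- seq(0, 500, by = 7)
  for (k in 1:3)
    expect_equal(oscillation(t, p), oscillation(t + k * 250, p))
})

test_that("feedback drive scales prediction rows, holds, then decays", {
  lm <- lm_sentences()
  expect_equal(feedback_drive(lm, "I", 0),
               c(I = 0, eat = 1.5, very = 0, nice = 0, cake = 0))
  expect_equal(unname(feedback_drive(lm, "eat", 0)[c("cake", "nice", "very")]),
               c(0.75, 0.45, 0.30))
  expect_equal(sum(feedback_drive(lm, "eat", -1)), 0)   # before arrival
  hold <- p0$fb_hold_cycles / p0$omega * 1000
  expect_equal(feedback_drive(lm, "eat", hold)[["cake"]], 0.75)
  expect_equal(feedback_drive(lm, "eat", hold + 30)[["cake"]], 0.45)
  # floored at zero after gain * p / decay ms past the hold
  expect_equal(sum(feedback_drive(lm, "eat", hold + 1.5 / 0.01)), 0)
  expect_error(feedback_drive(lm, "pie", 0), "unknown")
})

test_that("oscillation plus base inhibition alone never fires a node", {
  lm <- lm_sentences()
  st <- stimulus_train(lm, data.frame(word = character(0),
                                      onset_ms = numeric(0),
                                      intensity = numeric(0)),
                       duration_ms = 1000)
  sim <- stimcon(lm, st, stimcon_params(phi = 0))
  expect_equal(sum(lengths(sim$events)), 0)
  expect_true(all(sim$activation <= 0.8 + 1e-12))
})

test_that("predicted words reach threshold earlier relative to their onset", {
  lm <- lm_sentences()
  sup <- vapply(c("cake", "nice", "very", "I"), function(w) {
    sim <- stimcon(lm, build_sentence(lm, c("I", "eat", w),
                                      duration_ms = 1100), p0)
    first_event_time(sim, w, 500)
  }, numeric(1))
  # supra-time non-increasing in prediction probability: 0.5, 0.3, 0.2, 0
  expect_true(all(diff(sup[c("I", "very", "nice", "cake")]) <= 0))
  expect_lt(sup[["cake"]], sup[["I"]])
  expect_lt(sup[["cake"]], sup[["very"]])
})

test_that("simulation result traces are internally consistent", {
  lm <- lm_sentences()
  sim <- stimcon(lm, build_sentence(lm, c("I", "eat", "cake"),
                                    duration_ms = 1100), p0)
  for (w in lm$vocabulary) {
    for (ev in sim$events[[w]]) {
      i <- which.min(abs(sim$time_ms - ev))
      expect_gte(sim$activation[w, i], p0$threshold)
      expect_equal(unname(sim$ta[w, i]), 0)  # ta resets exactly at the event
    }
  }
  ta <- sim$ta[is.finite(sim$ta)]
  expect_true(all(ta >= 0))
  # events only at threshold crossings from below
  expect_equal(length(sim$events$cake), 2L)
})

test_that("first_event_time subtracts the reference and handles absence", {
  sim <- list(events = list(a = c(100, 400), b = numeric(0)))
  expect_equal(first_event_time(sim, "a", 200), 200)
  expect_equal(first_event_time(sim, "a", 50), 50)
  expect_true(is.na(first_event_time(sim, "b", 0)))
})

test_that("without feedback the intensity threshold is symmetric in phase", {
  # symmetric (Gaussian) inputs displaced either side of the oscillation
  # peak (at 425 ms) need the same minimal intensity, within one grid step
  lm0 <- stimcon_lm("x", matrix(0, 1, 1))
  pp <- stimcon_params(phi = -2 * pi * 4 * 425 / 1000)
  min_int <- function(delay) {
    for (i in seq(0.1, 3, by = 0.02)) {
      words <- data.frame(word = "x", onset_ms = 425 + delay, intensity = i,
                          shape = "gaussian")
      st <- stimulus_train(lm0, words, duration_ms = 900)
      if (length(stimcon(lm0, st, pp)$events$x)) return(i)
    }
    NA_real_
  }
  for (d in c(20, 40, 60))
    expect_equal(min_int(-d), min_int(d), tolerance = 0.021)
})

test_that("compiled core reproduces a brute-force reference loop exactly", {
  for (seed in 1:10) {
    cs <- random_case(seed)
    par <- stimcon_params(phi = runif(1, -pi, pi))
    sim <- stimcon(cs$lm, cs$stim, par)
    expect_identical(sim$events, oracle_simulate(cs$lm, cs$stim, par),
                     label = paste("case", seed))
  }
})

test_that("simulator rejects inconsistent inputs", {
  lm <- lm_sentences()
  st <- build_sentence(lm, c("I", "eat"))
  expect_error(stimcon(lm, st, stimcon_params(dt = 2)), "step")
  expect_error(stimcon_params(dt = 0), "positive")
  st2 <- build_sentence(lm_daga(), c("N1", "N2"))
  expect_error(stimcon(lm, st2), "vocabulary")
})
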