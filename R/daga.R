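#' Single /da/-/ga/ categorization trial
#'
#' Presents two entrainer stimuli S1 and S2 at the entrainment rate, then an
#' ambiguous /da/-/ga/ mixture at a delay after S2's onset plus one SOA, and
#' decodes the percept two ways: which node reaches threshold first
#' (`first_active`: 1 = /da/, 0 = /ga/, 0.5 = tie or neither; ties in time
#' are broken by the larger mean activity in the decision window), and the
#' relative mean activity `(da - ga) / (da + ga)` of the two nodes over
#' 500 ms after stimulus onset.
#'
#' The entrainment rate sets the oscillation frequency for the trial, and
#' every input is a linear ramp lasting half a cycle, like the main model's
#' word inputs.
#'
#' @param p_da proportion of the ambiguous stimulus that is /da/ (see
#'   [ambiguous_mixture()]).
#' @param delay_ms onset delay of the ambiguous stimulus relative to
#'   isochronous continuation (one SOA after S2's onset).
#' @param rate_hz entrainment rate (Hz); sets `omega`.
#' @param params a [stimcon_params()]; `omega` and `phi` are overridden by
#'   the trial protocol.
#' @param lm the four-node language model; by default [lm_daga()].
#' @param offset_s temporal offset of the final sound (s), accounting for
#'   the time it takes to interpret the ambiguous syllable.
#' @param intensity total intensity of the ambiguous mixture.
#' @param window_ms decision window after stimulus onset (ms).
#' @return List with `first_active`, `activity_index` (raw, un-normalized),
#'   `delay_ms`, and the event times of the two nodes.
#' @examples
#' run_daga_trial(p_da = 0.4, delay_ms = 50)$first_active
#' @export
run_daga_trial <- function(p_da, delay_ms, rate_hz = 6.25,
                           params = stimcon_params(), lm = lm_daga(),
                           offset_s = 0, intensity = 1, window_ms = 500) {
  soa <- 1000 / rate_hz
  ramp <- soa / 2
  params$omega <- rate_hz
  params$phi <- phi_for_peak(rate_hz, ramp)   # peak at S1's ramp end
  onset <- 2 * soa + delay_ms + offset_s * 1000
  if (onset < soa) stop("ambiguous stimulus would precede S2")
  mix <- ambiguous_mixture(p_da, intensity)
  words <- data.frame(word = c("N1", "N2", "da", "ga"),
                      onset_ms = c(0, soa, onset, onset),
                      intensity = c(1, 1, mix["da"], mix["ga"]))
  st <- stimulus_train(lm, words, duration_ms = onset + window_ms + soa,
                       dt = params$dt, ramp_ms = ramp)
  sim <- stimcon(lm, st, params)

  win <- sim$time_ms >= onset & sim$time_ms <= onset + window_ms
  act_da <- mean(pmax(sim$activation["da", win], 0))
  act_ga <- mean(pmax(sim$activation["ga", win], 0))
  t_da <- first_event_time(sim, "da", onset)
  t_ga <- first_event_time(sim, "ga", onset)

  first_active <-
    if (is.na(t_da) && is.na(t_ga)) 0.5
    else if (is.na(t_ga) || (!is.na(t_da) && t_da < t_ga)) 1
    else if (is.na(t_da) || t_ga < t_da) 0
    else if (act_da > act_ga) 1
    else if (act_ga > act_da) 0
    else 0.5
  tot <- act_da + act_ga
  list(first_active = first_active,
       activity_index = if (tot > 0) (act_da - act_ga) / tot else 0,
       delay_ms = delay_ms, t_da = t_da, t_ga = t_ga)
}

#' Delay sweep of /da/-/ga/ outcomes
#'
#' Runs [run_daga_trial()] at evenly spaced delays covering a number of
#' cycles of the presentation rate, and min-max normalizes the
#' mean-activity index over the sweep to `[0, 1]`.
#'
#' @inheritParams run_daga_trial
#' @param n_delays number of delay steps (>= 2).
#' @param n_cycles number of cycles of the presentation rate the sweep
#'   covers.
#' @param delays_ms explicit delays (ms), overriding the regular sweep.
#' @return Data frame with `delay_ms`, `first_active`, `mean_activity_index`
#'   (normalized to `[0, 1]`), and `activity_index` (raw).
#' @examples
#' \donttest{
#' outcome_curve(p_da = 0.4, rate_hz = 6.25)
#' }
#' @export
outcome_curve <- function(p_da, rate_hz = 6.25, n_delays = 12, n_cycles = 2,
                          params = stimcon_params(), lm = lm_daga(),
                          offset_s = 0, intensity = 1,
                          delays_ms = NULL) {
  if (is.null(delays_ms)) {
    if (n_delays < 2) stop("n_delays must be at least 2")
    delays_ms <- (seq_len(n_delays) - 1) * n_cycles * 1000 / rate_hz / n_delays
  }
  rows <- lapply(delays_ms, function(d)
    run_daga_trial(p_da, d, rate_hz, params, lm, offset_s, intensity))
  out <- data.frame(delay_ms = delays_ms,
                    first_active = vapply(rows, `[[`, numeric(1),
                                          "first_active"),
                    activity_index = vapply(rows, `[[`, numeric(1),
                                            "activity_index"))
  rng <- range(out$activity_index)
  out$mean_activity_index <- if (diff(rng) > 0)
    (out$activity_index - rng[1]) / diff(rng) else rep(0.5, nrow(out))
  out[, c("delay_ms", "first_active", "mean_activity_index",
          "activity_index")]
}

#' Grid-search specification for the /da/-/ga/ fit
#'
#' The swept parameters and their default grids: /da/ proportion 10 to 80%
#' in steps of 5%, feedback onset 0.1 to 1.0 cycle in steps of 0.1, feedback
#' decay 0 to 0.1 in steps of 0.01 units/ms, and a temporal offset of the
#' final sound from -0.05 to 0.05 s in steps of 0.01.
#'
#' @param p_da,fb_onset_cycles,fb_decay,offset_s numeric grids.
#' @return A list of class `"daga_grid"`.
#' @export
daga_grid <- function(p_da = seq(0.10, 0.80, by = 0.05),
                      fb_onset_cycles = seq(0.1, 1.0, by = 0.1),
                      fb_decay = seq(0, 0.1, by = 0.01),
                      offset_s = seq(-0.05, 0.05, by = 0.01)) {
  if (!all(lengths(list(p_da, fb_onset_cycles, fb_decay, offset_s)) > 0))
    stop("empty grid")
  structure(list(p_da = p_da, fb_onset_cycles = fb_onset_cycles,
                 fb_decay = fb_decay, offset_s = offset_s),
            class = "daga_grid")
}

#' Fit the model to a behavioral categorization curve
#'
#' Exhaustive grid search over the /da/ proportion, feedback onset, feedback
#' decay, and a temporal offset of the final sound: for every combination an
#' [outcome_curve()] is simulated at the behavioral delays and scored
#' against the (min-max normalized) behavioral responses by
#' `R^2 = 1 - RSS/TSS`. Ablated variants (no oscillation, equal feedback, no
#' inhibition) can be fitted through `params` / `lm`.
#'
#' @param behavioral data frame with columns `delay_ms` and `response`;
#'   responses are min-max normalized to `[0, 1]` before fitting.
#' @param rate_hz entrainment rate of the curve (Hz).
#' @param grid a [daga_grid()].
#' @param decoder `"first_active"` or `"mean_activity"`.
#' @param params base [stimcon_params()] (ablations may modify, e.g.
#'   `am = 0`).
#' @param lm four-node model; equal-feedback ablation passes
#'   `lm_daga(0.15, 0.15)`.
#' @return An object of class `"daga_fit"` with the best parameters, `r2`,
#'   the full R-squared `surface` (one row per combination), the fitted
#'   curve, and the data.
#' @seealso [rectified_sinus_fit()], [aic_gauss()]
#' @export
fit_daga <- function(behavioral, rate_hz = 6.25, grid = daga_grid(),
                     decoder = c("first_active", "mean_activity"),
                     params = stimcon_params(), lm = lm_daga()) {
  decoder <- match.arg(decoder)
  if (!all(c("delay_ms", "response") %in% names(behavioral)))
    stop("behavioral must have columns delay_ms and response")
  y <- behavioral$response
  rng <- range(y)
  y <- if (diff(rng) > 0) (y - rng[1]) / diff(rng) else rep(0.5, length(y))
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("behavioral curve is constant")

  combos <- expand.grid(p_da = grid$p_da,
                        fb_onset_cycles = grid$fb_onset_cycles,
                        fb_decay = grid$fb_decay,
                        offset_s = grid$offset_s,
                        KEEP.OUT.ATTRS = FALSE)
  col <- if (decoder == "first_active") "first_active" else
    "mean_activity_index"
  combos$r2 <- NA_real_
  best <- list(r2 = -Inf)
  for (i in seq_len(nrow(combos))) {
    p <- params
    p$fb_delay_cycles <- combos$fb_onset_cycles[i]
    p$fb_decay <- combos$fb_decay[i]
    oc <- outcome_curve(combos$p_da[i], rate_hz, params = p, lm = lm,
                        offset_s = combos$offset_s[i],
                        delays_ms = behavioral$delay_ms)
    r2 <- 1 - sum((y - oc[[col]])^2) / tss
    combos$r2[i] <- r2
    if (r2 > best$r2) best <- list(r2 = r2, i = i, curve = oc)
  }
  structure(list(best = combos[best$i, 1:4], r2 = best$r2,
                 surface = combos, fitted_curve = best$curve,
                 decoder = decoder, rate_hz = rate_hz,
                 behavioral = data.frame(delay_ms = behavioral$delay_ms,
                                         response = y),
                 k = 4L),
            class = "daga_fit")
}

#' @export
print.daga_fit <- function(x, ...) {
  cat(sprintf("/da/-/ga/ grid-search fit (%s decoder, %g Hz)\n",
              x$decoder, x$rate_hz))
  cat(sprintf("  best: p_da = %.2f, feedback onset = %.1f cycle, decay = %.2f, offset = %+.2f s\n",
              x$best$p_da, x$best$fb_onset_cycles, x$best$fb_decay,
              x$best$offset_s))
  cat(sprintf("  R^2 = %.3f over %d delays (%d combinations searched)\n",
              x$r2, nrow(x$behavioral), nrow(x$surface)))
  invisible(x)
}

#' @export
summary.daga_fit <- function(object, ...) {
  rss <- sum(residuals(object)^2)
  n <- nrow(object$behavioral)
  list(best = object$best, r2 = object$r2, rss = rss, n = n,
       aic = aic_gauss(rss, n, object$k))
}

#' @export
coef.daga_fit <- function(object, ...) {
  unlist(object$best)
}

#' @export
predict.daga_fit <- function(object, ...) {
  col <- if (object$decoder == "first_active") "first_active" else
    "mean_activity_index"
  object$fitted_curve[[col]]
}

#' @export
residuals.daga_fit <- function(object, ...) {
  object$behavioral$response - predict(object)
}

#' @export
plot.daga_fit <- function(x, ...) {
  plot(x$behavioral$delay_ms, x$behavioral$response, pch = 4,
       xlab = "delay (ms)", ylab = "proportion /da/ (normalized)",
       ylim = c(0, 1), ...)
  lines(x$behavioral$delay_ms, predict(x), col = 2)
  legend("topright", c("behavioral", "model"), pch = c(4, NA),
         lty = c(NA, 1), col = c(1, 2), bty = "n")
  invisible(x)
}

#' Rectified sinusoid fit
#'
#' Fits a fixed-frequency sinusoid (amplitude, phase offset, and mean) to a
#' behavioral curve by grid search, optionally snapping its predictions to
#' the nearest allowed response level (0, 0.5, 1) before scoring — the
#' baseline model the network fit is compared against.
#'
#' @param behavioral data frame with `delay_ms` and `response` in `[0, 1]`.
#' @param rate_hz sinusoid frequency (Hz).
#' @param snap snap predictions to `levels` before scoring?
#' @param levels allowed response levels when snapping.
#' @param amp_grid,phase_grid,mean_grid search grids.
#' @return List with `r2`, `amplitude`, `phase`, `mean`, `fitted`, and `k`
#'   (3 swept parameters).
#' @export
rectified_sinus_fit <- function(behavioral, rate_hz = 6.25, snap = FALSE,
                                levels = c(0, 0.5, 1),
                                amp_grid = seq(0, 1, by = 0.05),
                                phase_grid = seq(0, 2 * pi, by = pi / 20),
                                mean_grid = seq(0, 1, by = 0.05)) {
  y <- behavioral$response
  t_ms <- behavioral$delay_ms
  tss <- sum((y - mean(y))^2)
  best <- list(rss = Inf)
  for (a in amp_grid) for (ph in phase_grid) for (m in mean_grid) {
    pred <- m + a * sin(2 * pi * rate_hz * t_ms / 1000 + ph)
    if (snap)
      pred <- levels[max.col(-abs(outer(pred, levels, "-")))]
    rss <- sum((y - pred)^2)
    if (rss < best$rss)
      best <- list(rss = rss, amplitude = a, phase = ph, mean = m,
                   fitted = pred)
  }
  # a constant curve is fitted exactly by its mean: R^2 = 0 by convention
  best$r2 <- if (tss > 0) 1 - best$rss / tss else if (best$rss == 0) 0 else
    -Inf
  best$k <- 3L
  best
}

#' Gaussian-likelihood AIC
#'
#' `n * log(rss / n) + 2k`, the Akaike information criterion for a
#' least-squares fit with Gaussian residuals; lower is better.
#'
#' @param rss residual sum of squares (> 0).
#' @param n number of observations (> k).
#' @param k number of fitted parameters.
#' @return AIC value; `rss = 0` returns `-Inf` with a warning.
#' @examples
#' aic_gauss(12, 12, 0)  # 0
#' @export
aic_gauss <- function(rss, n, k) {
  if (n <= k) stop("need more observations than parameters")
  if (rss < 0) stop("rss must be non-negative")
  if (rss == 0) {
    warning("zero residual sum of squares; AIC is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + 2 * k
}
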