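#' Synthetic onset trains
#'
#' Generates sentence onset trains with planted structure for validating
#' [fit_expected_onsets()]: per sentence a syllable/word rate is drawn, word
#' predictabilities follow a right-skewed distribution (as next-word
#' probabilities from a language model do), and word-to-word onset
#' differences are built from a previous-word-duration term, a rate term,
#' the expected time shift of [relative_time_shift()] at the generating
#' `(Am, phi)`, and Gaussian noise.
#'
#' This generator stands in for corpus onset data, which is
#' access-restricted; it emulates the statistical shape of such data
#' (skewed predictabilities, 3-8 Hz rates, ~0.4 s word durations), not any
#' particular corpus.
#'
#' @param n_sentences number of sentences.
#' @param n_words words per sentence.
#' @param am,phi generating oscillation amplitude and phase offset (sine
#'   convention, radians).
#' @param noise_sd onset noise (s).
#' @param rate_range_hz per-sentence rate range.
#' @param seed integer seed.
#' @return Data frame with `sentence_id`, `word`, `onset_s`, `prediction`,
#'   `rate_hz`, `prev_duration_s`.
#' @export
generate_onset_trains <- function(n_sentences = 200, n_words = 10,
                                  am = 1.5, phi = -0.15 * pi,
                                  noise_sd = 0.02,
                                  rate_range_hz = c(3, 8), seed = 1) {
  set.seed(seed)
  out <- vector("list", n_sentences)
  for (s in seq_len(n_sentences)) {
    rate <- runif(1, rate_range_hz[1], rate_range_hz[2])
    pred <- stats::rbeta(n_words, 1.2, 4)
    dur <- stats::rlnorm(n_words, meanlog = log(0.35), sdlog = 0.25)
    prev_dur <- c(NA, dur[-n_words])
    shift <- suppressWarnings(relative_time_shift(pred, am, phi, rate))
    dt <- 0.05 + 0.7 * prev_dur[-1] - 0.01 * rate + shift[-1] +
      rnorm(n_words - 1, 0, noise_sd)
    dt <- pmax(dt, 0.02)
    out[[s]] <- data.frame(sentence_id = s, word = seq_len(n_words),
                           onset_s = cumsum(c(0, dt)),
                           prediction = pred, rate_hz = rate,
                           prev_duration_s = prev_dur)
  }
  do.call(rbind, out)
}

#' Synthetic behavioral categorization curve
#'
#' Generates a delay-to-proportion-/da/ curve shaped like the empirical
#' phase-dependent categorization effect — a damped sinusoid at the
#' presentation rate (the bias is stronger at short than long delays) with
#' binomial trial noise. Stands in for the access-restricted behavioral
#' dataset; the fitting machinery is validated on such synthetic curves and
#' on model-generated ones.
#'
#' @param rate_hz presentation rate (Hz).
#' @param n_delays,n_cycles delay sweep, as in [outcome_curve()].
#' @param amplitude,mean,phase sinusoid parameters on the proportion scale.
#' @param damping_ms exponential damping constant of the amplitude (ms).
#' @param n_trials binomial trials per delay (0 for a noise-free curve).
#' @param seed integer seed.
#' @return Data frame with `delay_ms`, `response` (proportion /da/), and
#'   `n_trials`.
#' @export
generate_behavioral_curve <- function(rate_hz = 6.25, n_delays = 12,
                                      n_cycles = 2, amplitude = 0.35,
                                      mean = 0.5, phase = 0,
                                      damping_ms = 150, n_trials = 20,
                                      seed = 1) {
  set.seed(seed)
  delays <- (seq_len(n_delays) - 1) * n_cycles * 1000 / rate_hz / n_delays
  p <- mean + amplitude * exp(-delays / damping_ms) *
    sin(2 * pi * rate_hz * delays / 1000 + phase)
  p <- pmin(1, pmax(0, p))
  resp <- if (n_trials > 0) rbinom(length(p), n_trials, p) / n_trials else p
  data.frame(delay_ms = delays, response = resp,
             n_trials = rep(n_trials, length(p)))
}

#' Write fixture datasets to CSV
#'
#' Reproducible synthetic datasets with documented planted structure:
#' `"onset_trains"` writes [generate_onset_trains()] output,
#' `"behavioral_curves"` writes one [generate_behavioral_curve()] per
#' requested rate.
#'
#' @param kind `"onset_trains"` or `"behavioral_curves"`.
#' @param path output CSV path.
#' @param seed integer seed.
#' @param ... passed to the underlying generator (`rates_hz` selects the
#'   behavioral rates, default 6.25 and 10 Hz).
#' @return The written path, invisibly.
#' @export
generate_fixtures <- function(kind = c("onset_trains", "behavioral_curves"),
                              path, seed = 1, ...) {
  kind <- match.arg(kind)
  if (kind == "onset_trains") {
    write.csv(generate_onset_trains(seed = seed, ...), path,
              row.names = FALSE)
  } else {
    args <- list(...)
    rates <- if (is.null(args$rates_hz)) c(6.25, 10) else args$rates_hz
    args$rates_hz <- NULL
    curves <- do.call(rbind, lapply(rates, function(r) {
      cv <- do.call(generate_behavioral_curve,
                    c(list(rate_hz = r, seed = seed), args))
      cbind(rate_hz = r, cv)
    }))
    write.csv(curves, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a behavioral curve CSV
#'
#' Expects columns `delay_ms` and `response` (proportion /da/ in `[0, 1]`),
#' optionally `n_trials` and `rate_hz`.
#'
#' @param path CSV path.
#' @param rate_hz if the file holds several rates, select one.
#' @return Data frame suitable for [fit_daga()].
#' @export
read_behavioral <- function(path, rate_hz = NULL) {
  x <- read.csv(path)
  if (!all(c("delay_ms", "response") %in% names(x)))
    stop("behavioral CSV must have columns delay_ms and response")
  if (!is.null(rate_hz) && "rate_hz" %in% names(x))
    x <- x[abs(x$rate_hz - rate_hz) < 1e-9, ]
  x
}
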