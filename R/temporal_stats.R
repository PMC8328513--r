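#' Predictability-to-time-shift transform
#'
#' Closed-form expected shift in processing time caused by top-down
#' prediction: setting the bottom-up and inhibition terms aside, a node
#' reaches a given activation when the oscillation balances the top-down
#' drive, which yields
#' `shift = (asin(prediction / (-Am)) - phi) / (2 * pi * omega)`
#' (seconds). The shift is 0 for an unpredicted word (with `phi = 0`) and
#' decreases monotonically as the prediction grows: strongly predicted words
#' are expected earlier on the cycle.
#'
#' The oscillation is taken in sine convention here (phase measured from the
#' ascending zero-crossing), so `phi` in this transform is offset by `-pi/2`
#' from the cosine convention used by [oscillation()].
#'
#' @param prediction top-down drive (prediction probability, possibly scaled
#'   by a feedback gain); values beyond `Am` in magnitude are clamped to the
#'   branch limit with a warning.
#' @param am oscillation amplitude (> 0).
#' @param phi phase offset (radians, sine convention).
#' @param omega oscillation frequency (Hz).
#' @return Relative time shift in seconds (vectorized over `prediction`).
#' @examples
#' relative_time_shift(0, am = 1.5, phi = 0, omega = 4)       # 0
#' relative_time_shift(1.5, am = 1.5, phi = 0, omega = 4)     # -1/16 s
#' @export
relative_time_shift <- function(prediction, am, phi = 0, omega = 4) {
  if (any(am <= 0)) stop("am must be positive")
  if (any(omega <= 0)) stop("omega must be positive")
  x <- prediction / (-am)
  if (any(abs(x) > 1)) {
    warning("|prediction| exceeds the oscillation amplitude; clamping")
    x <- pmin(1, pmax(-1, x))
  }
  (asin(x) - phi) / (2 * pi * omega)
}

#' Duration to rate conversion
#'
#' Speech rate implied by a unit (word/syllable/character) count and a
#' duration: a 250 ms mono-syllabic word has a syllable rate of 4 Hz, a
#' 250 ms bi-syllabic word 8 Hz.
#'
#' @param duration_s duration (s, > 0).
#' @param n_units number of units (>= 1).
#' @return Rate in Hz.
#' @examples
#' rate_from_duration(0.25, 2)  # 8
#' @export
rate_from_duration <- function(duration_s, n_units = 1) {
  if (any(duration_s <= 0)) stop("duration must be positive")
  if (any(n_units < 1)) stop("n_units must be at least 1")
  n_units / duration_s
}

#' Spectral statistic of an onset train
#'
#' Builds a binary impulse time course from word onsets (1 at each onset
#' sample), Fourier-transforms it, z-scores the power values across the
#' 0 to `fmax_hz` bins, and returns the maximal z within a frequency band
#' (by default theta, 3-8 Hz) — a measure of how isochronous the train is.
#'
#' @param onsets_s strictly increasing onset times (s); at least 2.
#' @param fs_hz sampling rate of the impulse time course.
#' @param band_hz length-2 band in which the peak is taken.
#' @param fmax_hz upper edge of the z-scoring interval.
#' @param duration_s time course length (s); defaults to the last onset plus
#'   one sample.
#' @return List with `peak_z` (max z in band), `peak_freq_hz`, and the
#'   data frame `spectrum` (`freq_hz`, `z`).
#' @examples
#' onset_spectrum(seq(0, 2.25, by = 0.25))$peak_freq_hz  # 4 Hz
#' @export
onset_spectrum <- function(onsets_s, fs_hz = 100, band_hz = c(3, 8),
                           fmax_hz = 15, duration_s = NULL) {
  if (length(onsets_s) < 2) stop("need at least 2 onsets")
  if (is.unsorted(onsets_s, strictly = TRUE))
    stop("onsets must be strictly increasing")
  if (onsets_s[1] < 0) stop("onsets must be non-negative")
  if (is.null(duration_s)) duration_s <- max(onsets_s) + 1 / fs_hz
  n <- ceiling(duration_s * fs_hz)
  x <- numeric(n)
  idx <- pmin(n, floor(onsets_s * fs_hz) + 1)
  x[idx] <- 1
  pw <- abs(fft(x))^2
  freq <- (seq_len(n) - 1) * fs_hz / n
  keep <- freq > 0 & freq <= fmax_hz
  z <- (pw[keep] - mean(pw[keep])) / sd(pw[keep])
  freq <- freq[keep]
  inb <- freq >= band_hz[1] & freq <= band_hz[2]
  i <- which(inb)[which.max(z[inb])]
  list(peak_z = z[i], peak_freq_hz = freq[i],
       spectrum = data.frame(freq_hz = freq, z = z))
}

#' Fit expected onset shifts to observed onset differences
#'
#' Grid search over oscillation amplitude and phase offset: for each
#' candidate `(Am, phi)`, word predictabilities are transformed to expected
#' time shifts via [relative_time_shift()] (with each sentence's own rate as
#' `omega`), and observed word-to-word onset differences are regressed on
#' the transform plus rate and previous-word duration covariates. Model
#' performance is the out-of-sample R-squared averaged over repeated 90/10
#' train/test splits.
#'
#' @param trains data frame of onset trains with columns `sentence_id`,
#'   `onset_s`, `prediction`, `rate_hz`, and `prev_duration_s` (see
#'   [generate_onset_trains()]).
#' @param am_grid,phi_grid candidate amplitudes and phase offsets (radians).
#' @param n_splits number of random 90/10 splits.
#' @param test_frac held-out fraction.
#' @return An object of class `"onset_shift_fit"`: list with the R-squared
#'   `surface` (amplitudes x phases), the best `am` and `phi`, `r2` at the
#'   optimum, and `r2_identity` for the untransformed-prediction baseline.
#' @examples
#' tr <- generate_onset_trains(n_sentences = 50, seed = 1, noise_sd = 0)
#' f <- fit_expected_onsets(tr, am_grid = c(1, 1.5, 2),
#'                          phi_grid = c(-0.3, -0.15, 0) * pi, n_splits = 20)
#' coef(f)
#' @export
fit_expected_onsets <- function(trains, am_grid = seq(0.5, 2.5, by = 0.25),
                                phi_grid = seq(-0.45, 0.15, by = 0.05) * pi,
                                n_splits = 100, test_frac = 0.1) {
  need <- c("sentence_id", "onset_s", "prediction", "rate_hz",
            "prev_duration_s")
  if (!all(need %in% names(trains)))
    stop("trains must have columns ", paste(need, collapse = ", "))
  # word-to-word onset differences within sentences
  d <- do.call(rbind, lapply(split(trains, trains$sentence_id), function(s) {
    s <- s[order(s$onset_s), ]
    if (nrow(s) < 2) return(NULL)
    data.frame(dt_s = diff(s$onset_s),
               prediction = s$prediction[-1],
               rate_hz = s$rate_hz[-1],
               prev_duration_s = s$prev_duration_s[-1])
  }))
  d <- d[complete.cases(d), ]
  if (nrow(d) < 20) stop("too few onset differences to fit")

  split_r2 <- function(x) {
    df <- data.frame(y = d$dt_s, x = x, rate = d$rate_hz,
                     prev = d$prev_duration_s)
    r2 <- numeric(n_splits)
    n <- nrow(df)
    for (k in seq_len(n_splits)) {
      test <- sample.int(n, max(1, round(test_frac * n)))
      fit <- lm(y ~ x + rate + prev, data = df[-test, ])
      pred <- predict(fit, newdata = df[test, ])
      r2[k] <- 1 - sum((df$y[test] - pred)^2) /
        sum((df$y[test] - mean(df$y[-test]))^2)
    }
    mean(r2)
  }

  surface <- matrix(NA_real_, length(am_grid), length(phi_grid),
                    dimnames = list(am = am_grid, phi = phi_grid))
  for (a in seq_along(am_grid))
    for (p in seq_along(phi_grid)) {
      x <- suppressWarnings(
        relative_time_shift(d$prediction, am_grid[a], phi_grid[p], d$rate_hz))
      surface[a, p] <- split_r2(x)
    }
  r2_identity <- split_r2(d$prediction)
  best <- arrayInd(which.max(surface), dim(surface))
  structure(list(surface = surface,
                 am = am_grid[best[1]], phi = phi_grid[best[2]],
                 r2 = surface[best], r2_identity = r2_identity,
                 am_grid = am_grid, phi_grid = phi_grid,
                 n = nrow(d)),
            class = "onset_shift_fit")
}

#' @export
print.onset_shift_fit <- function(x, ...) {
  cat(sprintf("Onset-shift fit over %d onset differences\n", x$n))
  cat(sprintf("  best Am = %g, phi = %.3f rad (%.2f pi): out-of-sample R^2 = %.3f\n",
              x$am, x$phi, x$phi / pi, x$r2))
  cat(sprintf("  untransformed-prediction baseline R^2 = %.3f\n",
              x$r2_identity))
  invisible(x)
}

#' @export
coef.onset_shift_fit <- function(object, ...) {
  c(am = object$am, phi = object$phi)
}

#' @export
plot.onset_shift_fit <- function(x, ...) {
  image(x$am_grid, x$phi_grid / pi, x$surface,
        xlab = "oscillation amplitude", ylab = "phase offset (pi rad)",
        main = "out-of-sample R^2", ...)
  points(x$am, x$phi / pi, pch = 4, lwd = 2)
  invisible(x)
}
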