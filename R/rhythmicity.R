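#' Overall model activity
#'
#' The summed, zero-rectified activation of all word nodes on the integration
#' grid — a single non-negative mass time course used for spectral analysis
#' of the network response.
#'
#' @param sim a [stimcon()] result.
#' @return Numeric vector on `sim$time_ms`.
#' @export
overall_activity <- function(sim) {
  colSums(pmax(sim$activation, 0))
}

#' Magnitude spectrum of a simulation's activity
#'
#' Applies a Hanning taper to the mean-removed overall-activity time course
#' on a time segment (by default 0.5 to 2.5 s, excluding onset responses) and
#' returns the magnitude of its discrete Fourier transform.
#'
#' @param sim a [stimcon()] result.
#' @param tmin_s,tmax_s segment bounds (s).
#' @return Data frame with `freq_hz` and `magnitude` up to the Nyquist
#'   frequency.
#' @export
activity_spectrum <- function(sim, tmin_s = 0.5, tmax_s = 2.5) {
  if (tmax_s * 1000 > max(sim$time_ms))
    stop("analysis segment exceeds the simulation length")
  # half-open segment so a 2 s window at 1 kHz gives exact 0.5 Hz bins
  sel <- sim$time_ms >= tmin_s * 1000 & sim$time_ms < tmax_s * 1000
  x <- overall_activity(sim)[sel]
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
  sp <- abs(fft((x - mean(x)) * w))
  fs <- 1000 / sim$params$dt
  freq <- (seq_len(n) - 1) * fs / n
  keep <- freq <= fs / 2
  data.frame(freq_hz = freq[keep], magnitude = sp[keep])
}

power_at <- function(spec, f_hz) {
  spec$magnitude[which.min(abs(spec$freq_hz - f_hz))]
}

pattern_probs <- function(pattern, n_words, p_high = 0.8) {
  switch(pattern,
         "low" = rep(0, n_words),
         "high" = rep(p_high, n_words),
         "low-high" = rep_len(c(0, p_high), n_words),
         "high-low" = rep_len(c(p_high, 0), n_words),
         stop("unknown pattern: ", pattern))
}

#' Rhythmicity of responses to pseudo-rhythmic input
#'
#' Presents a train of sequential words at a fixed base rate with Gaussian
#' sensory inputs, shifts the onsets of the odd words (every second word) by
#' a range of offsets, sweeps stimulus intensity, and records the magnitude
#' of the overall-activity spectrum at the stimulation rate. Word-to-word
#' predictability follows one of four schedules: constant low (0), constant
#' high (0.8), alternating low-high (the shifted odd words are the predicted
#' ones), or alternating high-low.
#'
#' @param pattern one or more of `"low"`, `"high"`, `"low-high"`,
#'   `"high-low"`.
#' @param odd_offsets_ms onset shifts applied to every second word (ms).
#' @param intensities stimulus peak intensities.
#' @param params a [stimcon_params()]; the oscillation frequency sets the
#'   base rate.
#' @param n_words number of words in the train.
#' @param p_high the high predictability level.
#' @param gauss_sd Gaussian input standard deviation (ms).
#' @param tmin_s,tmax_s spectral analysis segment (s).
#' @return An object of class `"rhythmicity_grid"`: long data frame with
#'   columns `pattern`, `odd_offset_ms`, `intensity`, `power_at_rate`.
#' @examples
#' \donttest{
#' rg <- rhythmicity_experiment(c("low-high", "high-low"),
#'                              odd_offsets_ms = seq(-100, 100, by = 50),
#'                              intensities = 0.8)
#' }
#' @export
rhythmicity_experiment <- function(pattern = c("low", "high", "low-high",
                                               "high-low"),
                                   odd_offsets_ms = seq(-100, 100, by = 10),
                                   intensities = seq(0.2, 1.5, by = 0.1),
                                   params = stimcon_params(),
                                   n_words = 10, p_high = 0.8,
                                   gauss_sd = 42,
                                   tmin_s = 0.5, tmax_s = 2.5) {
  pattern <- match.arg(pattern, several.ok = TRUE)
  rate <- params$omega
  soa <- 1000 / rate
  onset0 <- 3 * gauss_sd
  dur <- onset0 + (n_words - 1) * soa + 3 * gauss_sd + 2 * soa
  if (dur < tmax_s * 1000) dur <- tmax_s * 1000 + soa
  odd <- seq(2, n_words, by = 2)   # shifted words (0-based odd positions)

  out <- expand.grid(pattern = pattern, odd_offset_ms = odd_offsets_ms,
                     intensity = intensities,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$power_at_rate <- NA_real_
  lms <- lapply(setNames(pattern, pattern), function(p)
    lm_chain(pattern_probs(p, n_words, p_high)))
  for (r in seq_len(nrow(out))) {
    shifts <- numeric(n_words)
    shifts[odd] <- out$odd_offset_ms[r]
    lmr <- lms[[out$pattern[r]]]
    st <- build_sentence(lmr, lmr$vocabulary, soa_ms = soa,
                         intensities = out$intensity[r], shifts_ms = shifts,
                         shape = "gaussian", onset0_ms = onset0,
                         duration_ms = dur, dt = params$dt,
                         gauss_sd = gauss_sd)
    sim <- stimcon(lmr, st, params)
    out$power_at_rate[r] <- power_at(activity_spectrum(sim, tmin_s, tmax_s),
                                     rate)
  }
  structure(out, class = c("rhythmicity_grid", "data.frame"),
            rate_hz = rate)
}

#' @export
print.rhythmicity_grid <- function(x, ...) {
  cat(sprintf("Rhythmicity grid at %g Hz: %d pattern(s) x %d offsets x %d intensities\n",
              attr(x, "rate_hz"), length(unique(x$pattern)),
              length(unique(x$odd_offset_ms)),
              length(unique(x$intensity))))
  invisible(x)
}

#' Offset of maximal rhythmic power
#'
#' For one predictability pattern and intensity, the odd-word offset at which
#' power at the stimulation rate peaks.
#'
#' @param grid a [rhythmicity_experiment()] result.
#' @param pattern,intensity the cell to inspect.
#' @return The odd-word offset (ms) of maximal power.
#' @export
peak_offset <- function(grid, pattern, intensity) {
  g <- grid[grid$pattern == pattern &
              abs(grid$intensity - intensity) < 1e-9, ]
  if (nrow(g) == 0) stop("no such pattern/intensity cell")
  g$odd_offset_ms[which.max(g$power_at_rate)]
}
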