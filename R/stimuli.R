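#' Single-word input traces
#'
#' Bottom-up input to a word node is an abstract evidence trace, not the
#' acoustic waveform: a linear ramp models linearly increasing confidence in
#' the word's identity over (by default) half a 4 Hz cycle, a Gaussian models
#' a symmetric evidence bump. `linear_ramp()` rises from 0 at `onset_ms` to
#' `intensity` at `onset_ms + duration_ms` (peak sample included, zero
#' immediately after); `gaussian_input()` peaks at `intensity` at its mean
#' `center_ms` and is truncated to +/- 3 standard deviations.
#'
#' @param t_ms times (ms) at which to sample the trace; vectorized.
#' @param onset_ms ramp onset (ms).
#' @param duration_ms ramp duration (ms, > 0); default 125, half a 4 Hz cycle.
#' @param intensity peak input (arbitrary units, >= 0).
#' @param center_ms Gaussian mean (ms): the word's nominal onset time.
#' @param sd_ms Gaussian standard deviation (ms, > 0).
#' @return Numeric vector of input values at `t_ms`.
#' @examples
#' linear_ramp(c(0, 62.5, 125, 126), onset_ms = 0)
#' gaussian_input(c(-42, 0, 42, 130), center_ms = 0)
#' @export
linear_ramp <- function(t_ms, onset_ms, duration_ms = 125, intensity = 1) {
  if (duration_ms <= 0) stop("duration_ms must be positive")
  if (intensity < 0) stop("intensity must be non-negative")
  x <- (t_ms - onset_ms) / duration_ms
  ifelse(x >= 0 & x <= 1, intensity * x, 0)
}

#' @rdname linear_ramp
#' @export
gaussian_input <- function(t_ms, center_ms, sd_ms = 42, intensity = 1) {
  if (sd_ms <= 0) stop("sd_ms must be positive")
  if (intensity < 0) stop("intensity must be non-negative")
  z <- (t_ms - center_ms) / sd_ms
  ifelse(abs(z) <= 3, intensity * exp(-z^2 / 2), 0)
}

word_support_ms <- function(shape, ramp_ms, gauss_sd) {
  # (start, end) of a word's nonzero support relative to its onset, and the
  # offset of its peak
  if (shape == "ramp") c(start = 0, end = ramp_ms, peak = ramp_ms)
  else c(start = -3 * gauss_sd, end = 3 * gauss_sd, peak = 0)
}

#' Stimulus train
#'
#' Per-node bottom-up input time series built by placing word traces at
#' stated onsets. Overlapping inputs on the same node sum. The onset of a
#' ramp word is the ramp start; the onset of a Gaussian word is its mean.
#'
#' @param vocabulary character vector of node labels, or a [stimcon_lm()]
#'   whose vocabulary is used.
#' @param words data frame with columns `word`, `onset_ms`, `intensity`, and
#'   optionally `shape` (`"ramp"` or `"gaussian"`, default `"ramp"`).
#' @param duration_ms total train duration (ms); default covers the last
#'   word's support plus `pad_ms`.
#' @param dt sampling step (ms).
#' @param ramp_ms,gauss_sd shape parameters passed to [linear_ramp()] /
#'   [gaussian_input()].
#' @param pad_ms padding appended after the last word's support when
#'   `duration_ms` is not given; default one 4 Hz cycle.
#' @return An object of class `"stimulus_train"`: list with `time_ms`,
#'   `input` (nodes x samples matrix), `words`, and `dt`.
#' @seealso [build_sentence()] for isochronous word sequences.
#' @export
stimulus_train <- function(vocabulary, words, duration_ms = NULL, dt = 1,
                           ramp_ms = 125, gauss_sd = 42, pad_ms = 250) {
  if (inherits(vocabulary, "stimcon_lm")) vocabulary <- vocabulary$vocabulary
  if (is.null(words$shape)) words$shape <- rep("ramp", nrow(words))
  if (nrow(words) > 0 && !all(words$word %in% vocabulary))
    stop("unknown word(s): ",
         paste(setdiff(words$word, vocabulary), collapse = ", "))
  if (nrow(words) > 0 && any(words$intensity < 0))
    stop("intensity must be non-negative")

  if (is.null(duration_ms)) {
    duration_ms <- if (nrow(words) == 0) 0 else {
      ends <- mapply(function(on, sh)
        on + word_support_ms(sh, ramp_ms, gauss_sd)["end"],
        words$onset_ms, words$shape)
      max(ends) + pad_ms
    }
  }
  time_ms <- if (duration_ms <= 0) numeric(0) else seq(0, duration_ms, by = dt)
  input <- matrix(0, length(vocabulary), length(time_ms),
                  dimnames = list(vocabulary, NULL))
  peaks <- numeric(nrow(words))
  for (k in seq_len(nrow(words))) {
    j <- match(words$word[k], vocabulary)
    tr <- if (words$shape[k] == "ramp")
      linear_ramp(time_ms, words$onset_ms[k], ramp_ms, words$intensity[k])
    else
      gaussian_input(time_ms, words$onset_ms[k], gauss_sd, words$intensity[k])
    input[j, ] <- input[j, ] + tr
    peaks[k] <- words$onset_ms[k] +
      word_support_ms(words$shape[k], ramp_ms, gauss_sd)["peak"]
  }
  words$peak_ms <- peaks
  structure(list(time_ms = time_ms, input = input, words = words, dt = dt),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("Stimulus train: %d node(s), %d word input(s), %.0f ms at dt = %g ms\n",
              nrow(x$input), nrow(x$words),
              if (length(x$time_ms)) max(x$time_ms) else 0, x$dt))
  if (nrow(x$words)) print(x$words, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.stimulus_train <- function(x, ...) {
  data.frame(time_ms = rep(x$time_ms, each = nrow(x$input)),
             node = rep(rownames(x$input), length(x$time_ms)),
             input = as.vector(x$input))
}

#' Isochronous (or shifted) word sequence
#'
#' Places a sequence of words at a base stimulus onset asynchrony, with
#' optional per-word onset shifts and intensities. Word `k` (1-based) is
#' placed at `(k - 1) * soa_ms + shifts_ms[k]`.
#'
#' @param lm a [stimcon_lm()] (or character vocabulary) naming the nodes.
#' @param sentence character vector of words, in order.
#' @param soa_ms base stimulus onset asynchrony (ms); default 250 (4 Hz).
#' @param intensities per-word peak intensities (recycled).
#' @param shifts_ms per-word onset shifts (ms, recycled).
#' @param shape `"ramp"` or `"gaussian"` for every word.
#' @param onset0_ms onset of the first word (ms); defaults to 0 for ramps and
#'   `3 * gauss_sd` for Gaussians so the first bump is fully sampled.
#' @inheritParams stimulus_train
#' @return A [stimulus_train()].
#' @examples
#' st <- build_sentence(lm_sentences(), c("I", "eat", "cake"))
#' st$words$onset_ms
#' @export
build_sentence <- function(lm, sentence, soa_ms = 250, intensities = 1,
                           shifts_ms = 0, shape = c("ramp", "gaussian"),
                           onset0_ms = NULL, duration_ms = NULL, dt = 1,
                           ramp_ms = 125, gauss_sd = 42, pad_ms = soa_ms) {
  shape <- match.arg(shape)
  if (soa_ms <= 0) stop("soa_ms must be positive")
  n <- length(sentence)
  if (is.null(onset0_ms)) onset0_ms <- if (shape == "ramp") 0 else 3 * gauss_sd
  words <- data.frame(word = as.character(sentence),
                      onset_ms = onset0_ms + (seq_len(n) - 1) * soa_ms +
                        rep_len(shifts_ms, n),
                      intensity = rep_len(intensities, n),
                      shape = rep(shape, n),
                      stringsAsFactors = FALSE)
  stimulus_train(lm, words, duration_ms = duration_ms, dt = dt,
                 ramp_ms = ramp_ms, gauss_sd = gauss_sd, pad_ms = pad_ms)
}

#' Ambiguous two-node mixture
#'
#' Splits a fixed total intensity between the /da/ and /ga/ nodes: the two
#' inputs share onset and shape, and their peaks are relative proportions
#' summing to `intensity` (at 30% /da/ the /da/ peak is 0.3 and the /ga/ peak
#' 0.7 of a unit-intensity stimulus).
#'
#' @param p_da proportion of the stimulus that is /da/, in `[0, 1]`.
#' @param intensity total peak intensity (>= 0).
#' @return Named numeric vector with components `da` and `ga`.
#' @examples
#' ambiguous_mixture(0.3)
#' @export
ambiguous_mixture <- function(p_da, intensity = 1) {
  if (p_da < 0 || p_da > 1) stop("p_da must lie in [0, 1]")
  if (intensity < 0) stop("intensity must be non-negative")
  c(da = p_da * intensity, ga = (1 - p_da) * intensity)
}

#' The two fixture language models
#'
#' Convenience accessor returning the five-word sentence model and the
#' four-node /da/-/ga/ model in one list.
#'
#' @return `list(sentences = lm_sentences(), daga = lm_daga())`.
#' @export
fixture_language_models <- function() {
  list(sentences = lm_sentences(), daga = lm_daga())
}
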