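#' Processing-efficiency map
#'
#' Presents a primed sentence (by default /I eat .../) whose final word is
#' varied in content, peak intensity and onset delay relative to isochronous
#' presentation, and records when the node matching the final word first
#' reaches threshold: relative to the word's actual onset (supra-time) and
#' relative to the isochronous grid (iso-time, the oscillation clock). Cells
#' where the node never reaches threshold at or after the word's onset are
#' `NA`.
#'
#' @param lm a [stimcon_lm()].
#' @param context character vector of priming words presented at full
#'   intensity on the isochronous grid.
#' @param target the final word.
#' @param delays_ms onset delays of the final word relative to its
#'   isochronous position (ms).
#' @param intensities peak intensities of the final word's ramp.
#' @param params a [stimcon_params()].
#' @param soa_ms base stimulus onset asynchrony (ms).
#' @param ramp_ms ramp duration (ms).
#' @return An object of class `"efficiency_map"`: list with `supra` and `iso`
#'   matrices (delays x intensities, ms), the grids, `target`, and `params`.
#' @seealso [compression_ratio()], [saturation_intensity()]
#' @examples
#' \donttest{
#' em <- efficiency_map(lm_sentences(), target = "cake",
#'                      delays_ms = seq(-125, 125, by = 25),
#'                      intensities = c(0.25, 0.53, 1))
#' image(em)
#' }
#' @export
efficiency_map <- function(lm, context = c("I", "eat"), target,
                           delays_ms = -125:125,
                           intensities = seq(0, 1, by = 0.01),
                           params = stimcon_params(),
                           soa_ms = 250, ramp_ms = 125) {
  stopifnot(inherits(lm, "stimcon_lm"))
  word_index(lm, c(context, target))
  if (is.unsorted(delays_ms, strictly = TRUE) ||
      is.unsorted(intensities, strictly = TRUE))
    stop("delay and intensity grids must be strictly increasing")

  dt <- params$dt
  iso_pos <- length(context) * soa_ms          # isochronous slot of the target
  dur <- iso_pos + max(delays_ms) + ramp_ms + 2 / params$omega * 1000
  time_ms <- seq(0, dur, by = dt)
  nv <- length(lm$vocabulary)
  tgt <- word_index(lm, target)
  phi <- if (is.null(params$phi)) phi_for_peak(params$omega, ramp_ms)
         else params$phi
  hold_ms <- params$fb_hold_cycles / params$omega * 1000

  base <- matrix(0, nv, length(time_ms))
  for (k in seq_along(context)) {
    j <- word_index(lm, context[k])
    base[j, ] <- base[j, ] + linear_ramp(time_ms, (k - 1) * soa_ms, ramp_ms, 1)
  }

  supra <- iso <- matrix(NA_real_, length(delays_ms), length(intensities),
                         dimnames = list(delays_ms, intensities))
  for (di in seq_along(delays_ms)) {
    onset <- iso_pos + delays_ms[di]
    ramp <- linear_ramp(time_ms, onset, ramp_ms, 1)
    for (ii in seq_along(intensities)) {
      input <- base
      input[tgt, ] <- input[tgt, ] + intensities[ii] * ramp
      res <- .simulate_core(input, lm$prediction, dt,
                            params$am, params$omega, phi,
                            params$base_inhib, params$excit_ms,
                            params$recov_ms, params$threshold,
                            params$fb_delay_cycles, params$fb_decay,
                            params$fb_gain, hold_ms)
      ev <- res$events[[tgt]]
      ev <- ev[ev >= onset]
      if (length(ev)) {
        supra[di, ii] <- ev[1] - onset
        iso[di, ii] <- ev[1] - iso_pos
      }
    }
  }
  structure(list(delays_ms = delays_ms, intensities = intensities,
                 supra = supra, iso = iso, target = target,
                 context = context, soa_ms = soa_ms, params = params),
            class = "efficiency_map")
}

#' @export
print.efficiency_map <- function(x, ...) {
  cat(sprintf("Efficiency map for /%s/ after /%s/: %d delays x %d intensities, %d cells defined\n",
              x$target, paste(x$context, collapse = " "),
              length(x$delays_ms), length(x$intensities),
              sum(!is.na(x$supra))))
  invisible(x)
}

#' @export
image.efficiency_map <- function(x, what = c("supra", "iso"), ...) {
  what <- match.arg(what)
  image(x$delays_ms, x$intensities, x[[what]],
        xlab = "onset delay (ms)", ylab = "intensity",
        main = sprintf("/%s/ %s-time (ms)", x$target, what), ...)
  invisible(x)
}

#' @export
as.data.frame.efficiency_map <- function(x, ...) {
  data.frame(delay_ms = rep(x$delays_ms, length(x$intensities)),
             intensity = rep(x$intensities, each = length(x$delays_ms)),
             supra_time_ms = as.vector(x$supra),
             iso_time_ms = as.vector(x$iso))
}

# contour of iso- (or supra-) times across delays at a fixed intensity
map_contour <- function(map, intensity = 0.53, clock = "iso") {
  ii <- which.min(abs(map$intensities - intensity))
  setNames(map[[clock]][, ii], map$delays_ms)
}

# longest contiguous run over which v is defined, monotone, and free of jump
# discontinuities (|step| > jump_ms per grid cell counts as a line break)
monotone_section <- function(delays, v, jump_ms = 2) {
  best <- NULL
  for (dir in c(1, -1)) {
    i <- 1; n <- length(v)
    while (i <= n) {
      if (is.na(v[i])) { i <- i + 1; next }
      j <- i
      while (j < n && !is.na(v[j + 1]) &&
             dir * (v[j + 1] - v[j]) >= 0 &&
             abs(v[j + 1] - v[j]) <= jump_ms * (delays[j + 1] - delays[j]))
        j <- j + 1
      if (is.null(best) || delays[j] - delays[i] > best[2] - best[1])
        best <- c(delays[i], delays[j])
      i <- j + 1
    }
  }
  best
}

#' Timing-compression ratio
#'
#' How much a window of stimulus-onset variation is compressed into
#' model-response variation on the oscillation clock: the width of a delay
#' window divided by the range of first-event iso-times across that window,
#' along the contour of the efficiency map at a fixed stimulus intensity.
#' By default the window is the longest monotone, discontinuity-free section
#' of the contour; an explicit window (e.g. a published analysis window) can
#' be supplied instead.
#'
#' @param map an [efficiency_map()].
#' @param window_ms length-2 numeric delay window, or `NULL` to use the
#'   detected monotone section.
#' @param intensity contour intensity (nearest grid value is used).
#' @param jump_ms largest iso-time step (ms per ms of delay) still treated as
#'   continuous when detecting the monotone section.
#' @return List with `ratio`, `stim_range_ms`, `model_range_ms`, `window_ms`,
#'   and both ranges as a percentage of the oscillation cycle. A zero model
#'   range yields an infinite ratio (perfect compression).
#' @examples
#' \donttest{
#' em <- efficiency_map(lm_sentences(), target = "cake")
#' compression_ratio(em)                      # detected monotone section
#' compression_ratio(em, window_ms = c(-59, 72))
#' }
#' @export
compression_ratio <- function(map, window_ms = NULL, intensity = 0.53,
                              jump_ms = 2) {
  v <- map_contour(map, intensity)
  delays <- map$delays_ms
  if (is.null(window_ms)) {
    window_ms <- monotone_section(delays, v, jump_ms)
    if (is.null(window_ms)) stop("contour has no defined cells")
  }
  if (window_ms[1] < min(delays) || window_ms[2] > max(delays))
    stop("window lies outside the map's delay grid")
  sel <- delays >= window_ms[1] & delays <= window_ms[2]
  if (anyNA(v[sel]))
    stop("contour has undefined cells inside the window (gap)")
  stim_range <- diff(range(window_ms))
  model_range <- diff(range(v[sel]))
  cycle <- 1000 / map$params$omega
  ratio <- if (model_range == 0) Inf else stim_range / model_range
  list(ratio = ratio,
       stim_range_ms = stim_range, model_range_ms = model_range,
       stim_pct_cycle = 100 * stim_range / cycle,
       model_pct_cycle = 100 * model_range / cycle,
       window_ms = window_ms,
       perfect_compression = model_range == 0)
}

#' Saturation intensity
#'
#' The smallest peak intensity of a linear-ramp input at which a
#' feedback-free node reaches threshold even at the least excitable onset
#' phase of the oscillation — above it, nodes always activate regardless of
#' presentation phase.
#'
#' @param params a [stimcon_params()].
#' @param ramp_ms ramp duration (ms).
#' @param phase_step_ms onset-phase grid step across one cycle (ms).
#' @param tol intensity bisection tolerance.
#' @return List with `intensity` (the saturation level) and `worst_delay_ms`
#'   (the least excitable onset delay relative to the excitability peak).
#' @examples
#' saturation_intensity()$intensity
#' @export
saturation_intensity <- function(params = stimcon_params(), ramp_ms = 125,
                                 phase_step_ms = 1, tol = 0.005) {
  cycle <- 1000 / params$omega
  lm0 <- stimcon_lm("x", matrix(0, 1, 1))
  peak <- 2 * cycle                       # oscillation peak inside the train
  phi <- phi_for_peak(params$omega, peak)
  params$phi <- phi
  dur <- peak + 2 * cycle + ramp_ms
  time_ms <- seq(0, dur, by = params$dt)
  delays <- seq(0, cycle - phase_step_ms, by = phase_step_ms)
  min_int <- vapply(delays, function(d) {
    ramp <- linear_ramp(time_ms, peak + d, ramp_ms, 1)
    crosses <- function(i) {
      res <- .simulate_core(matrix(i * ramp, 1), lm0$prediction, params$dt,
                            params$am, params$omega, phi,
                            params$base_inhib, params$excit_ms,
                            params$recov_ms, params$threshold,
                            params$fb_delay_cycles, params$fb_decay,
                            params$fb_gain, 0)
      length(res$events[[1]]) > 0
    }
    lo <- 0; hi <- 4
    if (!crosses(hi)) return(NA_real_)
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (crosses(mid)) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
  worst <- which.max(min_int)
  list(intensity = max(min_int, na.rm = TRUE),
       worst_delay_ms = delays[worst],
       by_delay = setNames(min_int, delays))
}
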