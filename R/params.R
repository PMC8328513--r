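#' Model parameters
#'
#' Bundle of the simulator's tunable parameters: the constant oscillator, the
#' three-regime inhibition gate, the top-down feedback dynamics, and the
#' integration step. Defaults reproduce the standard parameterization of the
#' model: a 4 Hz oscillator of unit amplitude, base inhibition -0.2 with a
#' 20 ms suprathreshold excitation window and 100 ms recovery, activation
#' threshold 1, and feedback arriving 0.9 cycles after a word's activation,
#' weighted 1.5 times the prediction probability and decaying at 0.01 units
#' per millisecond.
#'
#' @param am oscillation amplitude (activation units, >= 0).
#' @param omega oscillation frequency (Hz, > 0).
#' @param phi oscillation phase offset (radians), or `NULL` to align the
#'   oscillation peak with the peak of the first word's input at simulation
#'   time (see [build_sentence()]).
#' @param base_inhib base inhibition level (activation units, negative).
#' @param excit_ms duration of the post-activation suprathreshold excitation
#'   regime (ms).
#' @param recov_ms time since activation after which inhibition returns to
#'   its base level (ms); must exceed `excit_ms`.
#' @param threshold activation threshold (> 0).
#' @param fb_delay_cycles delay between a word's suprathreshold activation and
#'   the arrival of its feedback at predicted nodes, as a fraction of one
#'   oscillatory cycle.
#' @param fb_hold_cycles duration (in cycles) for which arrived feedback holds
#'   at full strength before the linear decay starts; together with the decay
#'   this makes the feedback signal persist around one full cycle.
#' @param fb_decay linear decay of the feedback signal (units/ms, >= 0).
#' @param fb_gain multiplicative weight on prediction probabilities (> 0).
#' @param dt integration step (ms, > 0).
#' @return An object of class `"stimcon_params"`.
#' @examples
#' p <- stimcon_params()
#' p$omega
#' stimcon_params(am = 1.5, phi = -0.15 * pi)
#' @export
stimcon_params <- function(am = 1, omega = 4, phi = NULL,
                           base_inhib = -0.2, excit_ms = 20, recov_ms = 100,
                           threshold = 1,
                           fb_delay_cycles = 0.9, fb_hold_cycles = 0.5,
                           fb_decay = 0.01, fb_gain = 1.5, dt = 1) {
  stopifnot(is.numeric(am), length(am) == 1, am >= 0)
  if (omega <= 0) stop("omega must be positive")
  if (base_inhib > 0) stop("base_inhib must be negative (0 only for the no-inhibition ablation)")
  if (!(excit_ms > 0 && excit_ms < recov_ms))
    stop("need 0 < excit_ms < recov_ms")
  if (threshold <= 0) stop("threshold must be positive")
  if (fb_delay_cycles <= 0) stop("fb_delay_cycles must be positive")
  if (fb_decay < 0) stop("fb_decay must be non-negative")
  if (fb_hold_cycles < 0) stop("fb_hold_cycles must be non-negative")
  if (fb_gain <= 0) stop("fb_gain must be positive")
  if (dt <= 0) stop("dt must be positive")
  structure(list(am = am, omega = omega, phi = phi,
                 base_inhib = base_inhib, excit_ms = excit_ms,
                 recov_ms = recov_ms, threshold = threshold,
                 fb_delay_cycles = fb_delay_cycles,
                 fb_hold_cycles = fb_hold_cycles, fb_decay = fb_decay,
                 fb_gain = fb_gain, dt = dt),
            class = "stimcon_params")
}

#' @export
print.stimcon_params <- function(x, ...) {
  cat("STiMCON parameters\n")
  cat(sprintf("  oscillator : Am = %g, omega = %g Hz, phi = %s\n",
              x$am, x$omega,
              if (is.null(x$phi)) "auto (peak at first input peak)"
              else format(x$phi)))
  cat(sprintf("  inhibition : base %g, excitation < %g ms, recovery %g ms, threshold %g\n",
              x$base_inhib, x$excit_ms, x$recov_ms, x$threshold))
  cat(sprintf("  feedback   : delay %g cycle, hold %g cycle, decay %g /ms, gain %g\n",
              x$fb_delay_cycles, x$fb_hold_cycles, x$fb_decay, x$fb_gain))
  cat(sprintf("  integration: dt = %g ms\n", x$dt))
  invisible(x)
}

#' Inhibition gate
#'
#' Piecewise-constant inhibition as a function of the time since a node's last
#' suprathreshold activation. Freshly activated nodes are transiently excited
#' (-3 x base inhibition, a positive contribution), then more strongly
#' inhibited (3 x base), and finally return to the base level. Nodes that have
#' never been active sit at base inhibition.
#'
#' @param ta_ms time since last activation (ms); `Inf` (or `NA`) encodes a
#'   node that has never been active. Vectorized.
#' @param params a [stimcon_params()] object.
#' @return Inhibition in activation units: `-3 * base_inhib` on
#'   `[0, excit_ms)`, `3 * base_inhib` on `[excit_ms, recov_ms)`, and
#'   `base_inhib` from `recov_ms` on and for never-active nodes.
#' @examples
#' inhibition_gate(c(10, 50, 150, Inf))  # 0.6 -0.6 -0.2 -0.2
#' @export
inhibition_gate <- function(ta_ms, params = stimcon_params()) {
  ta <- ifelse(is.na(ta_ms), Inf, ta_ms)
  if (any(is.finite(ta) & ta < 0)) stop("ta_ms must be non-negative")
  b <- params$base_inhib
  out <- rep(b, length(ta))
  out[ta < params$recov_ms] <- 3 * b
  out[ta < params$excit_ms] <- -3 * b
  out
}

#' Sinusoidal excitability drive
#'
#' The constant oscillator added to every node's activation:
#' `Am * cos(2 * pi * omega * t + phi)` with `t` in seconds. Phase offset 0
#' puts the excitability peak at time 0.
#'
#' @param t_ms time (ms); vectorized.
#' @inheritParams inhibition_gate
#' @return Oscillation value in activation units.
#' @examples
#' oscillation(c(0, 62.5, 125), stimcon_params(am = 1, omega = 4, phi = 0))
#' @export
oscillation <- function(t_ms, params = stimcon_params()) {
  phi <- if (is.null(params$phi)) 0 else params$phi
  params$am * cos(2 * pi * params$omega * t_ms / 1000 + phi)
}

# phase offset putting the oscillation peak at peak_ms
phi_for_peak <- function(omega, peak_ms) {
  phi <- -2 * pi * omega * peak_ms / 1000
  # wrap to (-pi, pi]
  phi <- phi %% (2 * pi)
  if (phi > pi) phi <- phi - 2 * pi
  phi
}
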