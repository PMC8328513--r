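#' Top-down feedback drive
#'
#' The per-node feedback a context word contributes once its feedback has
#' arrived: `fb_gain * prediction[context, ]`, held at full strength for
#' `fb_hold_cycles` of the oscillation and then decaying linearly at
#' `fb_decay` units/ms, floored at zero. Before arrival the contribution is
#' zero. (Within a simulation, arrival happens `fb_delay_cycles / omega`
#' seconds after the context word's suprathreshold activation on bottom-up
#' input, so the feedback signal persists around one full cycle in total.)
#'
#' @param lm a [stimcon_lm()].
#' @param context_word word label or index of the context (activated) word.
#' @param t_since_arrival_ms time since feedback arrival (ms); negative means
#'   not yet arrived. Scalar.
#' @param params a [stimcon_params()].
#' @return Named numeric vector of per-node feedback (activation units).
#' @examples
#' feedback_drive(lm_sentences(), "eat", 0)    # 1.5 * (0.2, 0.3, 0.5)
#' feedback_drive(lm_sentences(), "eat", 50)
#' @export
feedback_drive <- function(lm, context_word, t_since_arrival_ms,
                           params = stimcon_params()) {
  i <- if (is.character(context_word)) word_index(lm, context_word)
       else as.integer(context_word)
  row <- lm$prediction[i, ]
  if (t_since_arrival_ms < 0) return(setNames(numeric(length(row)),
                                              lm$vocabulary))
  hold_ms <- params$fb_hold_cycles / params$omega * 1000
  pmax(params$fb_gain * row -
         params$fb_decay * max(0, t_since_arrival_ms - hold_ms), 0)
}

#' Simulate the oscillating word-node network
#'
#' Time-stepped integration of the network. At every step each node's
#' activation is the sum of its bottom-up input, the current top-down
#' feedback drive, the inhibition gate at its time-since-activation, and the
#' sinusoidal excitability drive. When a node crosses the activation
#' threshold from below an event is recorded and its time-since-activation
#' resets; if the crossing involved nonzero bottom-up input, the node's
#' prediction row is scheduled as feedback arriving `fb_delay_cycles / omega`
#' seconds later (once per node). Feedback-only activations do not trigger
#' new feedback, and the oscillator's phase is never reset.
#'
#' If `params$phi` is `NULL`, the phase offset is chosen so that the
#' oscillation peak coincides with the peak of the first word's input (ramp
#' endpoint, or Gaussian mean).
#'
#' @param lm a [stimcon_lm()].
#' @param stim a [stimulus_train()] whose nodes match the vocabulary.
#' @param params a [stimcon_params()].
#' @return An object of class `"stimcon_sim"`: list with `time_ms`,
#'   `activation` and `ta` (nodes x samples matrices; `ta` is `Inf` before a
#'   node's first event), `feedback`, `events` (named list of event times,
#'   ms), and the resolved `params`.
#' @examples
#' sim <- stimcon(lm_sentences(), build_sentence(lm_sentences(), c("I", "eat", "cake")))
#' sim$events
#' @export
stimcon <- function(lm, stim, params = stimcon_params()) {
  stopifnot(inherits(lm, "stimcon_lm"), inherits(stim, "stimulus_train"))
  if (!identical(rownames(stim$input), lm$vocabulary))
    stop("stimulus nodes do not match the language model vocabulary")
  if (length(stim$time_ms) < 2) stop("stimulus train is empty")
  if (!isTRUE(all.equal(stim$dt, params$dt)))
    stop("stimulus sampling step does not match params$dt")

  phi <- params$phi
  if (is.null(phi)) {
    phi <- if (nrow(stim$words) == 0) 0 else
      phi_for_peak(params$omega,
                   stim$words$peak_ms[which.min(stim$words$onset_ms)])
  }
  res <- .simulate_core(stim$input, lm$prediction, params$dt,
                        params$am, params$omega, phi,
                        params$base_inhib, params$excit_ms, params$recov_ms,
                        params$threshold,
                        params$fb_delay_cycles, params$fb_decay,
                        params$fb_gain,
                        params$fb_hold_cycles / params$omega * 1000)
  dimnames(res$activation) <- dimnames(stim$input)
  dimnames(res$ta) <- dimnames(stim$input)
  dimnames(res$feedback) <- dimnames(stim$input)
  names(res$events) <- lm$vocabulary
  params$phi <- phi
  structure(list(time_ms = stim$time_ms,
                 activation = res$activation,
                 ta = res$ta,
                 feedback = res$feedback,
                 events = res$events,
                 params = params, lm = lm, stim = stim),
            class = "stimcon_sim")
}

#' First suprathreshold event after a reference time
#'
#' @param sim a [stimcon()] result.
#' @param node word label or index.
#' @param reference_ms reference time (ms), e.g. the word's stimulus onset.
#' @return Time (ms) from `reference_ms` to the first event at or after it,
#'   or `NA` if there is none.
#' @export
first_event_time <- function(sim, node, reference_ms = 0) {
  ev <- sim$events[[node]]
  ev <- ev[ev >= reference_ms]
  if (length(ev) == 0) NA_real_ else ev[1] - reference_ms
}

#' @export
print.stimcon_sim <- function(x, ...) {
  cat(sprintf("STiMCON simulation: %d nodes, %.0f ms (dt = %g ms), omega = %g Hz, phi = %.3f\n",
              nrow(x$activation), max(x$time_ms), x$params$dt,
              x$params$omega, x$params$phi))
  n_ev <- vapply(x$events, length, integer(1))
  for (w in names(x$events))
    cat(sprintf("  %-8s %d event(s)%s\n", w, n_ev[w],
                if (n_ev[w]) paste0(" at ",
                  paste(format(x$events[[w]]), collapse = ", "), " ms")
                else ""))
  invisible(x)
}

#' @export
summary.stimcon_sim <- function(object, ...) {
  data.frame(node = rownames(object$activation),
             n_events = vapply(object$events, length, integer(1)),
             first_event_ms = vapply(object$events, function(e)
               if (length(e)) e[1] else NA_real_, numeric(1)),
             peak_activation = apply(object$activation, 1, max),
             row.names = NULL)
}

#' @export
as.data.frame.stimcon_sim <- function(x, ...) {
  nd <- rownames(x$activation)
  data.frame(time_ms = rep(x$time_ms, each = length(nd)),
             node = rep(nd, length(x$time_ms)),
             activation = as.vector(x$activation),
             ta = as.vector(x$ta))
}

#' @export
plot.stimcon_sim <- function(x, nodes = rownames(x$activation), ...) {
  a <- t(x$activation[nodes, , drop = FALSE])
  matplot(x$time_ms, a, type = "l", lty = 1,
          xlab = "time (ms)", ylab = "activation", ...)
  abline(h = x$params$threshold, lty = 3)
  for (k in seq_along(nodes)) {
    ev <- x$events[[nodes[k]]]
    if (length(ev)) points(ev, rep(x$params$threshold, length(ev)),
                           col = k, pch = 16)
  }
  legend("topleft", legend = nodes, col = seq_along(nodes), lty = 1,
         bty = "n", cex = 0.8)
  invisible(x)
}

#' Export simulation traces and events as CSV
#'
#' Traces are written in long format (`time_ms, node, activation, ta`) and
#' events as (`node, event_time_ms`).
#'
#' @param sim a [stimcon()] result.
#' @param trace_path,events_path output file paths (either may be `NULL`).
#' @return Invisibly, the written paths.
#' @export
write_sim_csv <- function(sim, trace_path = NULL, events_path = NULL) {
  if (!is.null(trace_path))
    write.csv(as.data.frame(sim), trace_path, row.names = FALSE)
  if (!is.null(events_path)) {
    ev <- data.frame(
      node = rep(names(sim$events), vapply(sim$events, length, integer(1))),
      event_time_ms = unlist(sim$events, use.names = FALSE))
    write.csv(ev, events_path, row.names = FALSE)
  }
  invisible(c(trace_path, events_path))
}
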