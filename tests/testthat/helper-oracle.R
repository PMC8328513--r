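# Brute-force plain-R re-implementation of the network update loop, kept
# deliberately naive and independent of the package's compiled core. Used as
# the oracle for event-time equivalence.
oracle_simulate <- function(lm, stim, params) {
  input <- stim$input
  pred <- lm$prediction
  n <- nrow(input)
  nt <- ncol(input)
  dt <- params$dt
  phi <- params$phi
  stopifnot(!is.null(phi))
  hold <- params$fb_hold_cycles / params$omega * 1000
  fb_delay <- params$fb_delay_cycles / params$omega * 1000

  last_ev <- rep(Inf, n)        # Inf == never activated
  prevA <- rep(-Inf, n)
  fb_used <- rep(FALSE, n)
  sources <- list()             # list of (context, arrival)
  events <- rep(list(numeric(0)), n)

  gate <- function(ta) {
    if (!is.finite(ta)) return(params$base_inhib)
    if (ta < params$excit_ms) return(-3 * params$base_inhib)
    if (ta < params$recov_ms) return(3 * params$base_inhib)
    params$base_inhib
  }

  for (ti in seq_len(nt)) {
    t_ms <- (ti - 1) * dt
    osc <- params$am * cos(2 * pi * params$omega * t_ms / 1000 + phi)
    fb <- rep(0, n)
    for (s in sources) {
      since <- t_ms - s$arrival
      if (since < 0) next
      v <- params$fb_gain * pred[s$context, ] -
        params$fb_decay * max(0, since - hold)
      fb <- fb + pmax(0, v)
    }
    for (j in seq_len(n)) {
      ta <- if (is.finite(last_ev[j])) t_ms - last_ev[j] else Inf
      A <- input[j, ti] + fb[j] + gate(ta) + osc
      if (A >= params$threshold && prevA[j] < params$threshold) {
        events[[j]] <- c(events[[j]], t_ms)
        last_ev[j] <- t_ms
        if (!fb_used[j] && input[j, ti] > 0) {
          fb_used[j] <- TRUE
          sources[[length(sources) + 1]] <-
            list(context = j, arrival = t_ms + fb_delay)
        }
      }
      prevA[j] <- A
    }
  }
  names(events) <- lm$vocabulary
  events
}

# small random language model + stimulus train for property tests
random_case <- function(seed) {
  set.seed(seed)
  n <- sample(2:4, 1)
  p <- matrix(runif(n * n), n)
  p[sample(n * n, n)] <- 0
  lmr <- stimcon_lm(paste0("w", seq_len(n)), p / max(rowSums(p)))
  k <- sample(2:4, 1)
  words <- data.frame(word = sample(lmr$vocabulary, k, replace = TRUE),
                      onset_ms = sort(sample(0:600, k)),
                      intensity = round(runif(k, 0.3, 2), 2))
  st <- stimulus_train(lmr, words, duration_ms = 1000)
  list(lm = lmr, stim = st)
}
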