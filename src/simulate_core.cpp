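#include <Rcpp.h>
using namespace Rcpp;

// Time-stepped update of the oscillating word-node network.
//
// Per step, each node's activation is
//   A[n,t] = input[n,t] + feedback[n,t] + inhib(Ta[n]) + osc(t)
// with the three-regime inhibition gate, a cosine excitability drive, and
// top-down feedback scheduled delay_cycles/omega seconds after a node
// crosses threshold on bottom-up input; arrived feedback holds at full
// strength for hold_ms and then decays linearly, floored at zero.
//
// Conventions (documented in the package vignette):
//  - threshold events are crossings from below only; the first sample can fire;
//  - Ta is +Inf before a node's first event (base inhibition);
//  - inhibition at the event sample still uses the pre-event Ta; the returned
//    ta trace shows 0 at the event sample;
//  - a node schedules feedback at most once, at its first suprathreshold
//    crossing with nonzero bottom-up input; concurrent feedback sources sum.

static inline double gate(double ta, double base, double excit, double recov) {
  if (!R_FINITE(ta)) return base;       // never activated
  if (ta < excit) return -3.0 * base;
  if (ta < recov) return 3.0 * base;
  return base;
}

// [[Rcpp::export(name = ".simulate_core")]]
List simulate_core(NumericMatrix input,   // n_nodes x n_steps bottom-up drive
                   NumericMatrix pred,    // n_nodes x n_nodes transition probs
                   double dt,             // integration step, ms
                   double am, double omega, double phi,
                   double base_inhib, double excit_ms, double recov_ms,
                   double threshold,
                   double delay_cycles, double decay_per_ms, double gain,
                   double hold_ms) {
  const int n = input.nrow();
  const int nt = input.ncol();
  if (pred.nrow() != n || pred.ncol() != n)
    stop("prediction matrix does not match the number of nodes");
  if (dt <= 0) stop("step size must be positive");
  if (omega <= 0) stop("oscillation frequency must be positive");

  NumericMatrix act(n, nt), ta_trace(n, nt), fb_trace(n, nt);
  std::vector<double> last_event(n, R_PosInf); // +Inf == never
  std::vector<double> prevA(n, R_NegInf);
  std::vector<bool> fb_done(n, false);
  std::vector<int> src_node;                   // active feedback sources
  std::vector<double> src_arrival;
  std::vector< std::vector<double> > events(n);

  const double fb_delay_ms = delay_cycles / omega * 1000.0;
  const double two_pi = 2.0 * M_PI;

  for (int t = 0; t < nt; ++t) {
    const double t_ms = t * dt;
    const double osc = am * std::cos(two_pi * omega * t_ms / 1000.0 + phi);

    // summed feedback drive at this step
    std::vector<double> fb(n, 0.0);
    for (size_t s = 0; s < src_node.size(); ++s) {
      const double since = t_ms - src_arrival[s];
      if (since < 0) continue;
      const double dec = decay_per_ms * std::max(0.0, since - hold_ms);
      const int c = src_node[s];
      for (int j = 0; j < n; ++j) {
        const double v = gain * pred(c, j) - dec;
        if (v > 0) fb[j] += v;
      }
    }

    for (int j = 0; j < n; ++j) {
      const double ta = R_FINITE(last_event[j]) ? (t_ms - last_event[j])
                                                : R_PosInf;
      const double A = input(j, t) + fb[j] +
        gate(ta, base_inhib, excit_ms, recov_ms) + osc;
      act(j, t) = A;
      fb_trace(j, t) = fb[j];

      const bool crossing = (A >= threshold) && (prevA[j] < threshold);
      if (crossing) {
        events[j].push_back(t_ms);
        last_event[j] = t_ms;
        if (!fb_done[j] && input(j, t) > 0) {
          fb_done[j] = true;
          src_node.push_back(j);
          src_arrival.push_back(t_ms + fb_delay_ms);
        }
      }
      ta_trace(j, t) = R_FINITE(last_event[j]) ? (t_ms - last_event[j])
                                               : R_PosInf;
      prevA[j] = A;
    }
  }

  List ev(n);
  for (int j = 0; j < n; ++j) ev[j] = wrap(events[j]);
  return List::create(_["activation"] = act,
                      _["ta"] = ta_trace,
                      _["feedback"] = fb_trace,
                      _["events"] = ev);
}
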