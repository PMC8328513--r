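---
title: "STiMCON: model, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{STiMCON: model, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimcon)
```

## The model

STiMCON is a rate model of word-level speech tracking. Each word in a small
vocabulary is a node; the activation of node $l$ at time $T$ is

$$A_{l,T} = C_{l-1\rightarrow l}\,A_{l-1,T} \;+\; C_{l+1\rightarrow l}\,A_{l+1,T}
\;+\; \mathrm{inhib}(T_a) \;+\; \mathrm{osc}(T),$$

the sum of bottom-up sensory evidence, top-down feedback weighted by an
internal language model, an inhibition gate driven by the time since the
node's last suprathreshold activation ($T_a$), and a fixed sinusoidal
excitability drive. A node "fires" when its activation crosses the
threshold (1.0) from below. The oscillator never resets: the model asks how
much a *fixed* oscillation, helped only by linguistic predictions, can cope
with pseudo-rhythmic timing.

The three mechanisms interact as follows. The oscillation confines
processing to the excitable part of each cycle (the duty cycle). The
feedback, proportional to the language model's transition probabilities,
pre-activates predicted nodes so they fire earlier on the cycle — the phase
of first activation becomes a code for how expected a word was. The
inhibition gate makes a freshly fired node transiently excited
($-3 \times$ base inhibition for 20 ms), then strongly inhibited
($3 \times$ base) until 100 ms, then returns it to base inhibition
($-0.2$); this frees the late part of the duty cycle for less predictable
words.

## Parameters and defaults

| parameter | default | units | meaning |
|---|---|---|---|
| `am` | 1 | activation | oscillation amplitude |
| `omega` | 4 | Hz | oscillation frequency = base stimulus rate |
| `phi` | auto | rad | phase; aligned so the peak coincides with the first word's input peak |
| `base_inhib` | -0.2 | activation | base inhibition (negative) |
| `excit_ms` / `recov_ms` | 20 / 100 | ms | post-activation excitation window / recovery |
| `threshold` | 1 | activation | suprathreshold crossing level |
| `fb_delay_cycles` | 0.9 | cycles | trigger-to-arrival delay of feedback |
| `fb_hold_cycles` | 0.5 | cycles | hold at full strength before decay |
| `fb_decay` | 0.01 | units/ms | linear decay after the hold |
| `fb_gain` | 1.5 | — | weight on prediction probabilities |
| `dt` | 1 | ms | integration step |

Bottom-up word input is an abstract evidence trace, not acoustics: a linear
ramp from 0 to the word's intensity over 125 ms (half a 4 Hz cycle), or a
Gaussian bump (sd 42 ms, truncated at $\pm 3$ sd) whose mean is the word's
onset. Words are presented at a base stimulus onset asynchrony of 250 ms.

## Conventions the equations leave open

These choices are deliberate and documented here because alternative
readings change the numbers:

* **Real-valued oscillator.** The oscillator is written as a complex
  exponential; activation must be real, so we use the cosine projection
  with $\phi$ chosen so that $\phi = 0$ puts the excitability peak at
  $t = 0$. Automatic phase alignment puts the peak at the *peak* of the
  first word's input (ramp endpoint, Gaussian mean).
* **Feedback time-course.** Feedback triggered by a word's bottom-up
  suprathreshold activation arrives 0.9 cycles later at the strength
  `fb_gain * p`, *holds for half a cycle*, then decays linearly at
  0.01 units/ms (floored at zero); concurrent sources sum, and each node
  triggers feedback only once, at its first bottom-up-driven crossing.
  The hold is the package's resolution of an ambiguity: were the decay to
  start at the moment of arrival, a prediction of 0.5 would be extinguished
  75 ms after arrival, before the excitability peak, and none of the
  model's signature behaviors would occur — no feedback-only activations,
  no ordering of words along the duty cycle by predictability, and almost
  no timing compression. With the hold, the feedback signal persists around
  one full theta cycle from trigger to extinction, which is what the
  mechanism requires; the compression results are insensitive to holds
  between roughly 0.2 and 0.6 cycles.
* **Inhibition regimes** are half-open intervals $[0,20)$, $[20,100)$,
  $[100,\infty)$ ms; before a node's first activation $T_a$ is treated as
  infinite (base inhibition). At the sample where a node crosses threshold
  the gate still uses the pre-crossing $T_a$; the reset takes effect from
  the next sample, and the returned `ta` trace shows 0 at the event.
* **Events** are crossings from below only; while activation stays above
  threshold no further events fire.
* **Integration** is a fixed 1 ms step (all temporal defaults are stated
  in ms); the update loop is implemented in C++ because the grid
  experiments run on the order of $10^5$ short simulations, and an
  independent plain-R reference loop is kept in the test suite and must
  reproduce the compiled event times exactly.

## The experiments

**Efficiency maps.** `/I eat X/` with the final word varied in content,
intensity (0–1, step 0.01) and onset delay (−125..+125 ms, step 1 ms).
For each cell we record the target node's first event at or after its
onset, relative to the onset (supra-time) and to the isochronous grid
(iso-time, the oscillation clock). `compression_ratio()` measures how a
window of onset variation compresses into iso-time variation along the
intensity-0.53 contour; with these defaults about 131 ms of stimulus
variation maps onto about 19 ms of response variation (≈1:6.9) for the
well-predicted /cake/, and about 1:3.1 for the feedback-free /I/. The
"monotone section" is detected as the longest contiguous run of the
contour that is defined, monotone, and free of jump discontinuities
(a step of more than 2 ms of iso-time per 1 ms of delay counts as a line
break); the published analysis window for the /cake/ contour can be passed
explicitly. Over the *entire* defined contour the ratio is dominated by a
discontinuous late-crossing branch whose extent flips with
millisecond-level convention changes; the full-line number is therefore
reported but should not be over-interpreted. `saturation_intensity()`
bisects, per onset phase, the minimal ramp intensity that reaches
threshold and reports the maximum across one full cycle (≈2.2 with the
defaults).

**Rhythmicity.** Ten-word trains at 4 Hz with Gaussian inputs; every
second word is shifted by a common offset, and word-to-word predictability
is constant (0 or 0.8) or alternates. The overall activity — the summed,
zero-rectified node activations — is tapered with a Hann window on the
0.5–2.5 s segment (half-open, so a 2 s window at 1 kHz yields exact
0.5 Hz bins), mean-removed, and the spectral magnitude at the 4 Hz bin is
recorded. When the predictable words are the shifted ones, the response is
most rhythmic when they are shifted *earlier*; the effect appears at
intermediate intensities (around 0.4 in this implementation) where the
stimulus neither dominates nor fails to reach threshold.

**Time-shift transform.** Setting the bottom-up and inhibition terms
aside, the phase at which the oscillation balances a top-down drive $p$
gives the expected shift in processing time,
$\mathrm{shift} = \left(\arcsin(p / (-A_m)) - \phi\right) / (2\pi\omega)$,
using the principal branch — the earlier of the two within-cycle
solutions, matching the idea that predictions prepare a node slightly
early. The transform is written in the sine convention (phase from the
ascending zero-crossing), offset by $-\pi/2$ from the simulator's cosine.
Predictions exceeding $A_m$ are clamped to the branch limit with a warning
so grid searches can cross the boundary. `fit_expected_onsets()` regresses
observed word-to-word onset differences on the transform (with each
sentence's own rate as $\omega$) plus rate and previous-word-duration
covariates, scoring by out-of-sample $R^2$ over repeated 90/10 splits.

**/da/–/ga/ categorization.** A four-node model (two entrainers, then
/da/ and /ga/ predicted at 0.2 and 0.1) is driven at 6.25 or 10 Hz; the
ambiguous mixture splits one unit of intensity between the two percept
nodes. Ramps last half a cycle of the entrainment rate so the protocol
scales with rate. Two decoders: the first node to fire (ties broken by the
larger mean rectified activity in a 500 ms window; 0.5 if neither fires),
and the normalized activity index $(da-ga)/(da+ga)$, min-max scaled over
the delay sweep. `fit_daga()` grid-searches the /da/ proportion, feedback
onset, feedback decay and a final-sound temporal offset against a
behavioral curve min-max normalized to $[0,1]$; ablations (zero-amplitude
oscillation, equal feedback, zero inhibition) reuse the same machinery.
The sinusoid baseline fixes its frequency at the presentation rate and
fits amplitude, phase and mean, optionally snapping predictions to
$\{0, 0.5, 1\}$; models are compared with the Gaussian-residual AIC
$n\log(\mathrm{RSS}/n) + 2k$, with $k = 4$ for the network fit and
$k = 3$ for the sinusoid.

## What the synthetic data emulate — and what they do not

The empirical datasets this model was originally validated against
(corpus word onsets with language-model predictabilities; behavioral
/da/–/ga/ curves) are access-restricted, so the package ships generators
instead:

* `generate_onset_trains()` plants the time-shift structure directly:
  right-skewed predictabilities (Beta(1.2, 4)), per-sentence rates uniform
  on 3–8 Hz, log-normal word durations (median 0.35 s), and onset
  differences built from a duration term, a rate term, the transform at a
  known $(A_m, \phi)$, and Gaussian noise. Parameter recovery on these
  trains demonstrates that the fitting machinery works, *not* that natural
  speech follows the transform.
* `generate_behavioral_curve()` produces a damped sinusoid at the
  presentation rate (damping constant 150 ms, reflecting that the phase
  effect fades at longer delays) with binomial trial noise. Fits to these
  curves validate the grid-search code path; the published empirical
  variance-explained figures cannot be reproduced without the original
  data and are not claimed.

Self-consistency fits (model-generated curves refitted with the grid
search) reach $R^2 = 1$, but with the binary first-active decoder several
grid combinations can produce the same curve, so recovery is of the curve,
not necessarily of every parameter.

## Degenerate inputs and tie-breaks

Empty stimulus trains are valid and produce no events (with the default
amplitude the oscillation plus base inhibition peaks at 0.8, below
threshold). A constant behavioral curve is rejected by `fit_daga()`
(its $R^2$ is undefined) and fitted by the sinusoid baseline with
amplitude 0 and $R^2 = 0$ by convention. Zero residual sums of squares
yield an AIC of $-\infty$ with a warning. Grid-search ties keep the first
combination in grid order.

## Problem sizes

The shipped tests and the acceptance script run the full-resolution
efficiency experiment (251 delays × 101 intensities), the saturation sweep
(250 phases with intensity bisection to 0.005), rhythmicity sweeps at a
reduced offset grid, and grid-search fits on reduced grids containing the
generating parameters; the full printed /da/–/ga/ grid (15 × 10 × 11 × 11
combinations) is available through `daga_grid()` defaults and takes a few
minutes of CPU.

## Known limitations

No phase resetting, frequency adaptation, or acoustic coupling; a single
oscillation frequency (no syllabic/phrasal hierarchy); the prediction
matrix is fixed, not learned. The feedback hold is a modeling convention
(see above), and quantities that depend on the discontinuous parts of
threshold contours are sensitive to it; the monotone-section compression
statistics are the robust ones.
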