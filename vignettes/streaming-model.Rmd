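---
title: "A two-stage model of auditory streaming: pattern discovery and bistable competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage model of auditory streaming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamchains)
```

## The problem and the model in one page

A repeating ABA− tone pattern (low tone A, high tone B, A, silence;
onset interval Δt, separation Δf semitones) is heard either as one
integrated gallop or as two segregated streams, and perception
alternates between these organisations indefinitely.  `streamchains`
simulates this with two coupled stages:

1. **Discovery.**  Repeating patterns ("chains") are found in the event
   stream by probabilistic link formation.  Each incoming tone starts a
   new open chain and offers every existing open chain two independent
   branches: include the tone, or skip it.  A chain whose first and
   last events match in frequency closes into a periodic loop that
   predicts future tones.  A closed loop must survive one clean cycle —
   every predicted tone must arrive, every unpredicted tone must be
   skippable — before a Bernoulli(`p_compete`) draw admits it to the
   competition.  A chain whose prediction goes unmatched is deleted.
   Re-derivations of a pattern already competing are discarded but
   counted as *rediscoveries*.

2. **Competition.**  Each admitted chain is a pair of excitatory and
   inhibitory populations whose only interaction channel is the
   *collision*: two chains colliding when their predictions coincide on
   the same tone.  Prediction successes excite a chain, collisions with
   excited rivals inhibit it, rediscovery supports it, adapting
   self-excitation stabilises the current winner, and slow
   Ornstein-Uhlenbeck noise makes the attractor states metastable.  A
   readout compares low-pass-filtered excitations: the percept is
   *integrated* when the chain spanning both frequency classes beats
   every single-class chain, *segregated* otherwise, *none* before any
   chain competes.

The stimulus generator (`aba_train()`) reproduces the laboratory
paradigm exactly: isochronous pure-tone triplets, A fixed at 400 Hz, B
at Δf ∈ {4, 10, 16, 22} ST above A, Δt ∈ {100, 150, 200, 250} ms,
4-minute trains, 75-ms tones.  Arbitrary repetitive sequences can be
supplied as CSV (`read_events()`); tone duration is carried but unused
because the model is onset-based.

## Stage 1: link probabilities

With d the frequency jump in semitones, Δt the gap in ms between the
chain's last event and the incoming one, n the number of competing
chains that predict the incoming event, and Δn the excess of the
incoming event's prediction count over that of the chain's last event:

$$p_{\mathrm{inc}} = \exp\!\big(-\beta_1 d^2 - \beta_2 n - \Delta t/\tau_{\mathrm{link}}\big),
\qquad
p_{\mathrm{skip}} = 1 - \exp\!\big(-\beta_3\, d^2/\Delta t - \beta_4 \max(0, \Delta n)\big),$$

with $p_{\mathrm{skip}} = 0$ whenever the incoming event matches, in
frequency, an event the chain already contains (a pattern cannot both
contain and skip the same tone — this is what forces the classic
integrated/segregated dichotomy).  The defaults are
β₁ = 0.00015, β₂ = 1, β₃ = 0.0055 (d²/Δt in ST² per second), β₄ = 8,
`p_compete` = 0.2, with matching half-widths of 30 ms and 0.5 ST
defining a strict ellipse in time-feature space.

Three design choices deserve comment, because they decide the model's
signature behaviour over the Δf × Δt grid:

* **Similarity versus rate of change.**  The inclusion cost grows with
  the squared jump d² alone, while the skipping probability grows with
  the jump *per unit time*.  Combined with the temporal-proximity
  factor `exp(−Δt/τ_link)` (default τ_link = 500 ms), this gives the
  two classic effects: large Δf makes the integrated chain hard to
  build and the segregated chains easy to isolate, while long Δt makes
  *every* link hard — in particular the one-per-cycle B−B link spanning
  4Δt — so the segregated pair is discovered very slowly at slow
  presentation rates.  We found that making both probabilities depend
  on the same cost cannot produce this pattern: the B-stream chain then
  either always or never forms across the grid.
* **Signed imbalance.**  Only a *positive* prediction excess of the
  skipped event facilitates skipping.  Once the A-stream chain
  competes, A tones are claimed by two chains and B tones by one, which
  makes A easy to exclude from a B-seeded chain — the discovery of the
  A stream actively recruits its B partner.  An unsigned version also
  fires in the opposite, unwanted direction.
* **First entry only.**  The Bernoulli(`p_compete`) gate applies to a
  chain *first* entering the competition.  A verified duplicate of a
  chain already competing is discarded as a rediscovery without the
  draw; the rediscovery rate is therefore about five times larger than
  it would be with the draw, and it is this rate that couples stimulus
  parameters to the ongoing competition.

Combinatorial control: open chains are capped at 6 nodes and at an age
of twice the longest expected period (8Δt for ABA− input; 2 s for
arbitrary input), which keeps the open population in the low hundreds
for arbitrarily long stimuli.

## Stage 2: dynamics

Per competing chain j, with σ the standard logistic function:

$$\tau_{ei}\dot E_j = -E_j + \sigma\!\Big(w_s \tfrac{S_j}{R_j + c} + w_x \tfrac{X_j}{R_j + c}
 + w_{se} E_j (1 - A_j) - w_{ie} I_j + w_n U_j - \theta_E\Big)$$

$$\tau_{ei}\dot I_j = -I_j + \sigma\!\Big(w_{ei} E_j + \tfrac{w_c}{R_j + c}\textstyle\sum_{k \ne j} C_{jk} E_k - \theta_I\Big)$$

$$\tau_a \dot A_j = -A_j + w_a E_j, \qquad
 dU_j = -\tfrac{U_j}{\tau_n}\,dt + \sigma_U \sqrt{2/\tau_n}\; dW_j$$

S, R, X and C are leaky integrators with time constants 1 s, 5 s, 5 s
and 1 s; each occurrence adds 1/τ so that every variable is a running
average in events per second — on a 500-ms cycle the A-stream, B-stream
and integrated chains settle at exactly 4, 2 and 6 successes/s, and the
time-averaged estimate is independent of the time constant.  The
divisive (R + c) factor (c = 0.1) normalises success, rediscovery and
collision drives across presentation rates, which makes the dominance
statistics of pre-installed chains rate-invariant.  Weights:
`w_inh_to_exc` = 8.1, `w_exc_to_inh` = 1, `w_self_exc` = 3.2,
`w_success` = 3.8, `w_collision` = 3, `w_noise` = 3.4, `w_adapt` = 0.1,
`w_rediscovery` = 7; τ_ei = 50 ms, τ_noise = 500 ms, τ_adapt = 5 s.

Two conventions matter and were fixed by explicit analysis:

* **Adaptation scale.**  `w_adapt` is the saturation level of A at full
  excitation (A tracks `w_adapt * E`).  If A instead tracks E itself,
  self-excitation is eventually destroyed for any dominant chain and
  the three-chain system loses both attractors — the model would
  oscillate deterministically instead of switching stochastically.
* **A chain's event-rate estimate is the stimulus's.**  R integrates
  the overall input rate, which is the same for every chain, so a chain
  admitted mid-run starts from the current estimate rather than zero.
  (Its private success rate S does start at zero, which is what gives
  newly admitted chains their charge-up inertia.)  With R starting at
  zero the ratio S/(R+c) transiently overshoots three-fold and every
  admission would instantly capture the percept.

The three constants not fixed by the published parameter set are the
population thresholds and the noise amplitude.  They were calibrated
once, against the model's documented operating regime, and frozen:
θ_E = 0.8, θ_I = 2.5 make the three-chain system genuinely bistable
(both organisations stable fixed points; every noise-free trajectory
ends in one of exactly two configurations, and noise-free runs stop
switching once the inventory settles), and σ_U = 0.048 sets the
switching rate so that neutral-condition runs (Δf = 16, Δt = 200 ms)
spend close to three quarters of the classified time segregated with
pooled mean phase durations in the low twenties of seconds.  After this
one calibration no parameter was revisited.

## Readout and analysis

Excitations are low-pass filtered (first-order, 500 ms — long enough to
suppress the per-cycle ripple inherited from the event-driven rates,
short against multi-second phases) and compared at every 10-ms sample;
exact ties keep the previous label.  Phases shorter than 300 ms are
absorbed into their neighbours, mirroring the treatment of human button
presses; "none" stretches (before the first admission) are excluded
from phase statistics.  `first_phase_stats()`,
`subsequent_phase_stats()` (time-weighted, with the run-set imputation
rule for runs lacking subsequent phases), `segregation_time_course()`
(2-s centred moving average of the pointwise segregation probability)
and `lognormality_test()` (Shapiro–Wilk on log durations) compute the
standard summaries; heavier comparisons (ANOVA and the like) are left
to the exported tidy phase tables (`condition_phase_table()`), which
any statistics environment can consume.

## What the simulations do and do not show

The generator emulates the laboratory stimulus exactly, so passing
tests show that the *model* reproduces the reported perceptual
statistics under the published parameter values.  They do not show
anything about real listeners beyond that correspondence: there is no
audio front end (events are symbolic onsets), no motor or response
latency, no attention, and no carry-over between trials.  Run-to-run
heterogeneity is substantial and real: because discovery is
self-reinforcing (an admitted chain suppresses the building of rivals
through the n-term), some runs lock into segregation with one or two
phases while others switch dozens of times.  Pooled statistics over 15
runs therefore carry Monte-Carlo standard errors of several seconds
(mean phase duration) and several percentage points (dominance), and
any single re-run of the acceptance protocol should be read with those
error bars in mind.

Known limitations, inherited from the modelled mechanism: only strictly
periodic patterns can be represented; failed chains are deleted rather
than weakened; the include-or-skip exclusivity forbids organisations
that share tones between streams; and the adaptation influence at the
calibrated operating point is modest, so the shape difference between
adapting and non-adapting phase distributions, while present (short
phases are suppressed relative to an exponential when adaptation is
on), is smaller than the difference in their means.

## Numerical choices and problem sizes

Forward Euler at 1 ms (a fiftieth of τ_ei) integrates the dynamics
between events; rate decays use exact exponential factors; the OU
increment uses the square-root-of-step scaling with stationary sd σ_U.
The compiled integrator consumes R's RNG, and each run derives two
independent substreams (discovery draws, dynamics noise) from its seed,
so either stage can be replayed or ablated without disturbing the
other; every run is bit-reproducible from its seed.  A 240-s trial
simulates in about 1.5 s on one CPU.  The test-suite simulations use
15-run batches of 240-s trials for distributional checks and shorter
(30–120 s) runs for structural ones; the acceptance script uses 30
neutral runs plus the 15-run corner protocols, completing in about a
minute.
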