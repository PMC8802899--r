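---
title: "Methods: a spinal circuit account of position-dependent muscle synergies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a spinal circuit account of position-dependent muscle synergies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spinalsynergy)
```

## The scientific question

During an isometric knee extension the limb does not move, yet surface EMG
(sEMG) of the thigh muscles changes systematically with the internal knee
angle and with the position of the hip. Muscle synergy analysis — nonnegative
matrix factorization (NMF) of the smoothed, rectified sEMG — summarises those
changes as a small set of activation patterns shared across muscles. This
package implements, as tested code, the computational argument that the
observed synergy trends can be produced by a small spinal circuit of
exponential integrate-and-fire (EIF) neuron populations whose proprioceptive
afferent inputs change with limb configuration. Because no raw recordings are
distributed with the original study, the package also ships a seeded
synthetic sEMG cohort generator with exported ground truth, so the entire
analysis chain is testable end to end without any data download.

The five muscles are the knee extensors rectus femoris (RF), vastus
lateralis (VL) and vastus medialis (VM), and the knee flexors semitendinosus
(ST) and biceps femoris (BF). The experiment's structure is 17 subjects, two
hip positions (recorded in separate sessions), four internal knee angles
(0°, 20°, 60°, 90°) and six ~5 s maximal-effort bursts per condition,
sampled at 2 kHz.

## The circuit model

Every population consists of EIF neurons,

$$\tau \frac{dv}{dt} = -(v - v_{rest}) + \Delta_T\, e^{(v - v_{thres})/\Delta_T},$$

with $v_{rest} = -70$ mV, $\Delta_T = 1.48$ mV, $v_{thres} = -56$ mV and
$\tau = 3.3$ ms. A note on the leak term: written with $+(v - v_{rest})$ the
equation has no stable resting state (any perturbation above rest diverges),
so the package uses the standard EIF sign convention with $-(v - v_{rest})$,
which reproduces the described behaviour: a stable rest at $-70$ mV, a soft
exponential threshold near $-56$ mV, and runaway spike initiation above the
unstable fixed point around $-52.5$ mV. Crossing the spike-detection cutoff
$v_{spike} = -51$ mV (the value visible as the threshold in published
density plots) emits a spike. The reset rule is not specified by the
original description; the package resets to $v_{rest}$ with no refractory
time, and both choices are exposed in `neuron_params()`.

The network (`build_default_network()`) has eight populations: five motor
pools (MN-RF, MN-VL, MN-VM, MN-ST, MN-BF), mutually inhibiting Extensor and
Flexor interneuron pools, and the RF-specific inhibitory pool InhibRF. Each
interneuron pool inhibits its namesake motor pools (−0.052 mV, 20
connections, 2 ms delay) and excites the opposing pools (+0.052 mV, 70, 2
ms) — an autogenic-inhibition motif with heteronymous facilitation.
Background drive (0.1 mV × 100 connections) runs at 300 Hz into the
interneuron-level pools and 320 Hz into the motor pools; a cortical drive,
the trapezoid 0 → 20 Hz over 1 s, 5 s hold, 1 s down, produces the
contraction. Three external afferent inputs steer the circuit: `senFlInt`
(to the flexor interneurons; net extensor facilitation), `senExtInt` (to the
extensor interneurons) and `senInhRF` (to InhibRF, i.e. RF-specific
inhibition).

Condition presets (`default_afferent_plateaus()`): in position 1 `senFlInt`
falls nonlinearly with angle, 150 → 75 → 38 → 0 Hz; in position 2 it drops
immediately from 150 to 38 Hz, and `senInhRF` rises to 50 Hz at the flexed
angles. Two values are not fixed by the original description and are
configurable: the position-2 value at 60° (19 Hz, continuing the halving
pattern) and the exact "slightly greater" senInhRF level (50 Hz, the value
used for the published position-2 examples). Afferent inputs follow the same
trapezoidal time course as the cortical drive, scaled to their plateaus; the
original description states only that they transition from 0 Hz during the
task, so the trapezoid (shared envelope, no shape free parameters) is the
minimal choice.

### Monte-Carlo ensemble instead of a population-density solver

The reference implementation of this circuit used a population-density
technique (PDT), which evolves the probability density of membrane
potentials per population. This package deliberately does not reimplement a
PDT solver. It simulates each population as a seeded Monte-Carlo ensemble
(default 500 neurons) honouring the same coupling contract: populations
interact only through their average firing rates, delivered as independent
Poisson event streams at rate (number of connections) × (delayed source
rate), each event stepping the membrane by the connection efficacy. The
density view is recovered as a histogram over the ensemble
(`density_snapshot()`). Two numerical choices matter:

* **Rate smoothing.** The per-step binned rate of a finite ensemble is a
  noisy estimate; delivered raw it injects artificial feedback noise. The
  rate signal sent to target populations is exponentially smoothed with a
  1 ms time constant (`smooth_tau`); reported output rates are spike counts
  per 2 ms sampling bin, matching the 0.1 ms integration step and 2 ms
  output sampling of the reference setup.
* **Resolution.** A Monte-Carlo ensemble resolves rate differences down to
  roughly $\sqrt{r / (nT)}$ Hz. Deterministic density methods resolve
  arbitrarily small modulations; this matters for the mechanism checks
  below.

A step-size refinement oracle (part of the test suite) checks that a single
population's stationary rate under constant Poisson drive changes by less
than 5% between dt = 0.1 ms and dt = 0.01 ms.

### Where the ensemble differs from the density method

With the published parameters the motor pools sit deep in the
fluctuation-driven regime (mean membrane potential several millivolts below
the unstable point), so their rates are steeply sensitive to the afferent
level: under the position-1 0° preset the extensor pools fire ~23 Hz while
the flexor pools are almost silent, and at the 90° preset (no afferent
drive) all pools fall to fractions of a hertz. A density method renders
those small rates as smooth deterministic traces; the ensemble renders them
as sparse spikes. Consequences, stated openly because they shape the tests:

* Normalized near-silent channels are shot-noise traces, so the second
  synergy loads the **low-activity muscle group** through its unexplained
  structure — which is also the mechanism by which the experimental
  synergy 2 loads weakly engaged muscles, so the qualitative behaviour is
  preserved.
* Mechanism checks are run at afferent levels the ensemble can resolve. The
  bias-flip and equal-input runs use 150 Hz on `senExtInt` (mirroring the
  0° `senFlInt` level) rather than the 0–15 Hz listed for `senExtInt` in
  the connection table: at 15 Hz the induced rate shift (~10⁻³ mV/ms) is
  orders of magnitude below ensemble shot noise at any affordable size,
  while the claim being tested — the synergy-2 bias direction follows
  sign(senFlInt − senExtInt) — is symmetric in the two inputs.
* The synergy-1 "all muscles loaded" property is checked on equal-drive
  runs, where all five pools have resolvable rates. In strongly biased
  conditions the suppressed pools' synergy-1 weights go to zero in the
  ensemble (their traces are noise), whereas the density method keeps the
  same normalized shape at any amplitude.
* The bias metric is $\beta = \max(W_2[\text{flexors}]) -
  \max(W_2[\text{extensors}])$ on max-normalized weights, averaged over
  three seeds. The group **maximum** is used because the noise-driven
  synergy-2 concentrates its loading on one channel of the low-activity
  group; group means are unstable in exactly the runs where the effect is
  real. Margins: bias/flip claims use $|\beta| > 0.5$, cancellation
  $|\bar\beta| < 0.45$ (measured separations: ~+0.9 under senFlInt
  dominance, ~−0.8 under senExtInt dominance, ~0.0 under equal drive).
* The RF-specific senInhRF effect is small (InhibRF receives no cortical
  drive and fires ~1 Hz at senInhRF = 50 Hz, lowering MN-RF by ~0.6 Hz at
  the 0°-drive level). It is tested with paired same-seed on/off runs and a
  t-statistic over seeds — reliably detectable at 300 neurons — and shown
  to vanish when senInhRF is forced to zero, while MN-VL/VM are unaffected
  (InhibRF projects only to MN-RF).

## The synergy pipeline

`rectify()` → `segment_bursts()` → `lowpass()` (4 Hz, second-order
Butterworth, single-pass causal by default; a zero-phase flag exists) →
`normalize_burst()` → `nmf()` with `select_rank()`.

* **Segmentation** automates what was done by visual inspection in the
  original workflow: a dual-threshold (hysteresis) detector on the
  reference channel's envelope — detection at baseline + 40% of the
  envelope range, onset refined by walking back to the baseline-mean + 3 SD
  crossing, runs merged across gaps below 1.5 s, equal windows of the
  median inter-burst interval centred on each burst. The generator's
  ground-truth onsets are recovered within 250 ms.
* **NMF** is Frobenius-norm multiplicative updates with a deterministic
  nonnegative-double-SVD initialization (zeros filled with the matrix mean,
  since exact zeros are absorbing under multiplicative updates), stopping
  at a relative objective change below 10⁻⁶ or 10,000 iterations. The same
  input always yields the same factors; component order is normalized by
  energy (`sort_synergies()`), with synergy 1 the coordinated-contraction
  component.
* **VAF** is uncentered, $1 - \sum(D - WC)^2 / \sum D^2$, globally and per
  muscle. The centered $R^2$ was rejected because baseline levels are part
  of what the factorization models. Rank selection takes the smallest rank
  in 1..5 whose global VAF reaches 0.90 (first hit wins, scanning
  ascending); a per-muscle VAF below the same threshold flags the
  decomposition as discarded. The discard threshold equals the global one;
  the source text gives only "below 90%".
* Envelopes are decimated to 50 Hz before factorization: the 4 Hz filter
  leaves no content above 4 Hz, so this is lossless in practice and keeps
  the per-burst matrices at 5 × ~450.
* Weight/pattern normalization to unit maximum (`normalize_synergies()`) is
  applied for cross-subject comparison; it intentionally breaks the product
  $WC$, and stored VAF values always refer to the unnormalized fit.
* Synergy pairing across subjects or against ground truth uses greedy
  matching by cosine similarity (`match_components()`).

## The synthetic cohort generator

The generator (`generate_cohort()`, `default_trend()`) emulates the
experiment's structure and amplitude trends; it defines the study
conditions for every downstream test, so its assumptions are spelled out:

* **Signal model.** Raw sEMG is surrogate-modelled as a nonnegative
  envelope multiplying zero-mean white Gaussian noise. The envelope of each
  muscle is a mix of two latent templates,
  $env(t) = a\,s(t) + b\,(1 - \kappa s(t))$: the trapezoidal contraction
  $s(t)$ (0.5 s ramps, 5 s plateau) and a baseline template partially
  suppressed (depth $\kappa = 0.6$) during the contraction — weakly engaged
  antagonists are reciprocally inhibited while the agonists work, which is
  also what the circuit's interneurons do to the flexor pools. This is the
  rank-2 latent structure the pipeline is expected to recover, and the
  suppression is what makes the second component genuinely distinct from
  the first: with a purely additive baseline the normalized bursts are so
  strongly collinear that rank 1 already exceeds 90% VAF.
* **Amplitude table.** Plateau amplitudes $a$ and baselines $b$ are in
  arbitrary units (cross-muscle sEMG amplitudes are not comparable) and
  encode only the ordinal trends: quadriceps fall with angle (two distinct
  drops in position 1, one larger drop at 20° in position 2), RF weaker in
  position 2 at flexed angles, ST rising from 0° to 20° with a raised
  position-1 baseline. Effect sizes were chosen so that the marked
  contrasts are recovered with high power at n = 17 — verified by test, not
  assumed.
* **Variability.** Three multiplicative lognormal layers: a
  per-(subject, muscle, session) gain (SD 0.2; electrode placement and
  anatomy differ per session — note position is a session), a per-burst
  jitter (SD 0.05), and a slow per-channel envelope fluctuation (SD 0.3,
  ~1 Hz bandwidth), representing effort and motor-unit-pool variation
  during a maximal contraction; smoothed MVC-level sEMG amplitude
  commonly fluctuates with a CV of 20–30%. The slow fluctuation is also
  what keeps the per-burst rank-1 VAF below the 90% threshold at the
  flexed angles, as in real recordings, where no two channels are exact
  scalar multiples.
* Optional `MG`/`TA` channels contain unmodulated noise, emulating the two
  recordings discarded for low signal-to-noise ratio; `channel_qc()`
  (burst-to-baseline ratio ≥ 2 in at least one recording of a session)
  removes exactly them. The QC aggregates over recordings because a real
  muscle may be quiescent in one condition yet clearly active in another.
* **What the generator does not emulate:** volume conduction and electrode
  cross-talk, motor-unit discharge structure (the carrier is white), ECG
  and movement artifacts, fatigue within a session, and any force or
  biomechanical output. Passing tests therefore show that the analysis
  chain recovers the encoded structure under realistic amplitude
  statistics — not that it would be robust to every artifact of real sEMG.

## Statistics

Condition comparisons are two-sided Welch t tests at α = 0.05 (the source
reports only "two-sided t test"; the unequal-variance form is the safer
default and the pooled form is a flag) on the mean of the central 4 s of
each burst, anchored at the burst midpoint (the anchor is unstated in the
source). The subject is the unit of observation: the six bursts of a
condition are averaged per subject (configurable). No multiple-testing
correction is applied, matching the original reporting; the output records
this. Null calibration is property-tested: under label permutations the
rejection rate is 0.05 ± 0.02.

One subtlety found while validating the significance-pattern recovery: the
per-subject session gains are shared across the angle conditions of a
session, so unpaired tests between angles are conservative on near-null
contrasts (the shared gain inflates both group variances but cancels in the
difference). This is realistic — real subjects are their own controls — and
it is why the full marked/unmarked significance pattern is recovered in
essentially every seed.

## Problem sizes

Defaults were chosen so that a laptop-class machine runs everything
comfortably: one 7.5 s contraction at 500 neurons/population (~12 s of CPU)
for the headline decomposition; 100–300 neurons/population for multi-run
property checks; the full default cohort (17 × 2 × 4 × 6 bursts at 2 kHz,
~3 minutes including factorization of all 816 bursts); and a 250 Hz cohort
variant for repeated statistical-recovery runs (the 4 Hz envelope is
unaffected by the lower carrier rate).

## Known limitations

* The ensemble cannot resolve sub-hertz rate modulations at practical
  sizes; mechanism checks are therefore run at resolvable afferent levels
  (documented above) rather than at the minimal levels a density method
  could use.
* With the published constants the circuit's operating point is strongly
  fluctuation-driven, making absolute rates steeply dependent on the
  afferent level; only trends and ordering, not rate magnitudes, should be
  compared against recordings.
* The trend checklist's flattening item is evaluated on the data-side
  synergies (quadriceps weights rise with angle while ST falls); in the
  circuit the extensor synergy-2 weights stay near zero instead — a known,
  documented difference between model and data.
* `validate_config()` checks structure and invariants, not scientific
  plausibility of user-supplied amplitude tables beyond the encoded trend
  constraints.
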