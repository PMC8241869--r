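---
title: "Methods: detecting wake slow waves and mapping their behavioural consequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting wake slow waves and mapping their behavioural consequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`wakewave` implements an analysis chain for studying *local sleep* during
wakefulness: sleep-like delta-band slow waves that appear in a subset of
scalp electrodes while a person performs a sustained-attention (Go/NoGo)
task, and that are thought to accompany attentional lapses — mind wandering
(MW, impulsive errors) and mind blanking (MB, sluggish errors) — reported at
random experience-sampling probes. The chain is:

1. a synthetic-session generator (stimuli, probes, latent vigilance,
   ground-truth slow waves, drift-diffusion responses, pupil, EEG);
2. a per-electrode slow-wave detector;
3. behavioural scoring and pre-probe summaries;
4. cluster-based permutation statistics over the electrode montage;
5. a Go/NoGo drift-diffusion model (DDM), simulated and fitted by maximum
   likelihood, conditioned on slow-wave presence per electrode.

Every stage consumes and returns ordinary tibbles (EEG itself lives in a
small `eeg_recording` container), so the pipeline composes with dplyr verbs.

# Slow-wave detection

The detector follows the classical sleep slow-wave algorithm, applied to
waking EEG:

* **Reference and rate.** The signal is re-referenced to the mean of the
  mastoids (TP9, TP10) and down-sampled to 128 Hz. Down-sampling is an
  anti-alias Butterworth low-pass (cut-off at 80% of the target Nyquist,
  order 8, applied forward-backward) followed by cubic-spline interpolation
  onto the 128 Hz grid; this composition is exact to below 1e-5 relative
  amplitude across 0–15 Hz, which a packaged polyphase resampler we tried
  could not guarantee.
* **Band-pass.** A Chebyshev type-II band-pass with stopband edges
  [0.1, 15] Hz and passband [1, 10] Hz. The design targets a 26 dB stopband
  floor and a 2.5 dB passband ceiling so that the nominal contract (at
  least 25 dB, below 3 dB) holds strictly after coefficient discretization;
  the order is the smallest for which the realized magnitude response meets
  both targets with all poles inside the unit circle (order 4 per band edge,
  i.e. an 8th-order filter, at 128 Hz). Filtering is zero-phase
  (forward-backward) so wave timing is preserved for event-locking; note
  this squares the magnitude response, which only sharpens both contracts.
* **Delimitation.** Candidate waves are negative half-waves with a positive
  rebound: start at the last non-negative sample before the negative
  excursion, trough at the most negative sample (earliest on exact ties),
  positive peak at the maximum of the following positive excursion, end at
  the first non-positive sample after it. Crossing times are sample times;
  no sub-sample interpolation. Downward slope is `|trough| / (trough time -
  start)`; upward slope is `peak-to-peak / (peak time - trough time)`.
* **Exclusions.** Waves with a positive peak above 75 uV (blink guard),
  waves within 1 s of any sample exceeding 150 uV absolute, and waves
  shorter than 143 ms are discarded. The amplitude criteria are evaluated on
  the filtered, mastoid-referenced signal — the detection substrate — since
  the choice of signal is otherwise open; the artifact margin is measured
  from the wave's [start, end] span to the nearest offending sample.
* **Selection.** Per electrode, the top 10% of remaining waves by
  peak-to-peak amplitude are kept (count rounded up, so a non-empty
  candidate set keeps at least one wave), and the per-electrode threshold
  voltage is reported. On 1/f background noise at 10 uV RMS the thresholds
  come out near 26 uV, which is in the right range for waking scalp EEG;
  they scale linearly with the noise RMS.

All delimitation quantities are cross-checked in the test suite against an
independent brute-force sample-scan oracle, with exact agreement required.

# Behavioural scoring

A response belongs to the latest stimulus whose onset precedes it; the
response window closes at the next stimulus onset (not offset), so a Go
trial is a miss only if no response lands anywhere in that window.
Reaction times are measured from stimulus onset; trials with RT below
300 ms are excluded from all tallies (neither correct nor error). Pre-probe
summaries use trials whose onset falls in `[probe - 20 s, probe)`, with
optional 10 s windows or a 4 x 5 s split that exactly partitions the 20 s
window. Pupil traces are blink-corrected by linear interpolation across
each blink extended by a 100 ms margin per side (the margin is a parameter;
published blink-correction recipes vary and rarely state one), averaged
over each stimulus presentation window, then over the pre-probe window, and
discretized into five quantile bins per participant and task (ties to the
lower bin) to normalize pupil size across participants.

# Cluster-based permutation statistics

Per-probe, per-electrode features (wave density, amplitude, slopes) are
averaged within subject and condition; the per-electrode statistic is the
paired t across subjects of the within-subject condition difference
(a pluggable `stat_fn` accepts richer models, e.g. mixed-effects t values).
Electrodes with one-tailed p below the cluster-forming alpha 0.025 (i.e.
0.025 per tail, two-sided testing with sign-consistent clusters) are
clustered by montage adjacency; the cluster statistic is the sum of member
t values. The null distribution is the maximum absolute cluster mass over
within-subject sign flips of the difference maps (equivalent to condition
label exchange); when `2^subjects` does not exceed the requested
permutation count the enumeration is exhaustive. The Monte Carlo p value is
`(1 + #{null >= observed}) / (1 + n_perm)`, and significance is declared at
`0.05 / n_comparisons`, Bonferroni-corrected across the map families tested
together (12 by default: three state contrasts by four wave properties).

Electrode neighbourhoods are not standardized in the literature, so they
are explicit here: positions come from the two-arc spherical construction
of the 10-10 system (18 degrees per 10% step), and two electrodes are
neighbours when their chord distance on the unit sphere is at most 0.45,
giving interior electrodes roughly eight neighbours and one connected
component overall. Both the threshold and the positions table are user
inputs to `build_adjacency()`.

The empirical family-wise error of the whole procedure is measured by a
global-null simulation (i.i.d. normal features, random labels); the
acceptance script runs 500 datasets of 26 subjects by 63 electrodes with
1000 permutations each and reports the fraction of datasets with any
significant cluster, which should not exceed 0.05.

# Drift-diffusion model

Go/NoGo decisions are modelled as a two-boundary diffusion with unit noise:
evidence starts at `z * a` and drifts at `v_go > 0` (Go) or `v_nogo < 0`
(NoGo); the upper boundary is a button press after non-decision time
`t_nd`, the lower boundary and the trial deadline are withholds. The drift
bias `v_bias = |v_go| - |v_nogo|` is always derived. Conventions that the
literature leaves to the fitting package are explicit here: withheld trials
contribute the probability of not having crossed the response boundary by
the deadline (lower-boundary absorption plus deadline censoring, obtained
by integrating the response-boundary first-passage density tail on a
1200-point grid); misses and correct withholds are treated identically.

* The simulator is Euler–Maruyama at `dt = 0.5 ms` with a Brownian-bridge
  crossing correction between steps, which removes the `O(sqrt(dt))`
  first-passage bias of the plain scheme; simulated choice fractions match
  the closed-form absorption probability
  `(exp(-2 v a z) - 1) / (exp(-2 v a) - 1)` across a parameter grid within
  Monte Carlo error.
* The likelihood uses the standard small-time/large-time series for the
  Wiener first-passage density with an automatic switching rule and
  truncation bounds for absolute error below 1e-10.
* Fitting is bounded L-BFGS-B from five seeded random starts (best
  log-likelihood wins), non-hierarchical, per condition cell. Hierarchical
  Bayesian estimation is deliberately out of scope; the accuracy criterion
  is parameter recovery — at 5000 trials per condition all five parameters
  are recovered within 10% relative error (0.05 absolute for `z`, `t_nd`).

# The synthetic-session generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream claim is validated. Defaults mirror the task
design: two task variants, three blocks each, probes every 30–70 s
(uniform), ten probes per block (60 per participant), stimulus durations
uniform on 0.75–1.25 s, stimulus identities permuted in blocks of nine with
exactly one NoGo per block and no immediate repeats, 63-channel 10-10
montage sampled at 500 Hz.

The latent layer is a validation device, not a mechanistic claim: vigilance
follows a clamped Ornstein–Uhlenbeck walk (1 Hz grid); two largely
independent "local sleep" intensities (frontal and posterior) each combine
a pull from low vigilance with a dominant slow fluctuation (time constant
about 50 s), so sustained frontal and posterior episodes occur separately.
Slow waves arise as Poisson events: a per-channel baseline (0.5 waves/min
per channel) plus localized multi-channel events — frontal events at up to
30 events/min covering the Fp/AF rows (weight 1), F (0.7) and FC (0.4),
and posterior events likewise over O/PO, P, CP/TP. Wave templates are
half-sine negative lobes followed by half-sine positive rebounds with a
2:1 negative-to-positive amplitude ratio, 0.8–1.2 s duration, 35–75 uV
peak-to-peak, added to `1/f` Gaussian background noise (RMS 10 uV);
the template survives the detection band-pass with under 5% amplitude loss,
so the ±20% recovery check has margin.

Probe reports are drawn from a softmax over the 20-s pre-probe means of the
latent variables: the ON logit rises with vigilance, the MW logit with the
frontal intensity, the MB logit with the posterior intensity. The base
logits (1.501, 0.125, -2.057) were calibrated once, by simulation of the
latent layer alone, so the marginal report mix is approximately 48/39/13%
ON/MW/MB — the prevalence the task literature reports — and were not
revisited afterwards. Responses come from the DDM with baseline parameters
`v_go = 2.5, v_nogo = -1.3, a = 1.4, z = 0.55, t_nd = 0.3 s`; a frontal
wave during the stimulus multiplies `v_nogo` by 0.25 (impulsivity: more
false alarms), a posterior wave multiplies `v_go` by 0.5 (sluggishness:
more misses, slower responses). These couplings are intentionally strong so
that planted effects are recoverable at test scale; the baselines yield
miss and false-alarm rates (roughly 10% and 17–22% pooled) in a plausible
range for this kind of task, with false alarms somewhat below the rates
real participants show. A 1% rate of anticipatory presses (RT 0.15–0.30 s)
exercises the short-RT exclusion.

What the generator does **not** emulate: ocular/cardiac artifacts beyond
blinks and amplitude outliers, bad channels, volume conduction (waves are
added independently per channel), stimulus rendering, the full 8-question
probe battery, or any mechanistic link from waves to reports — the coupling
exists so that recovery of the planted topographic dissociation is a
meaningful end-to-end test, nothing more. Passing these tests therefore
shows the *machinery* is correct, not that real data will show the effects.

All randomness derives from one session seed through fixed per-component
offsets (`stream_seed()`), so identical configurations and seeds reproduce
bit-identical tables; the pipeline writes every table as TSV plus a JSON
manifest carrying the configuration hash and seed.

# Problem sizes and numerical choices

Test and acceptance runs use sizes chosen to make the checks sharp but
cheap: the family-wise error simulation uses 300 null datasets with 500
permutations in the test suite (with a binomial allowance on the estimate)
and 500 datasets with 1000 permutations in the acceptance script; planted
map recovery uses 16 subjects per run and ten seeded runs, requiring the
frontal/posterior dissociation in at least 80% of them; DDM recovery uses
5000 trials per condition; the behavioural dissociation pools 25 simulated
participants. The multi-subject pipeline defaults to using the generator's
ground-truth wave table for the map stages (`detect_from_eeg = FALSE`),
since detector correctness is established separately against injected
recordings and the oracle; flipping the flag runs full EEG synthesis and
detection through the identical downstream path.

Degenerate inputs are defined rather than left to chance: empty candidate
sets propagate as empty tibbles (not errors); zero-length summary windows,
missing mastoids, waves outside a recording, all-missing pupil traces and
DDM data with no responses raise informative errors; summary means over
zero waves are `NA`; quantile-bin ties go to the lower bin.

# Known limitations

* The detector's wave start/end inherit the zero-crossing convention's
  sensitivity to slow noise; under realistic background noise the trough
  time is the stable anchor (the tests match on it), while start times can
  jitter by a few hundred milliseconds.
* The per-electrode statistic is a paired t on subject aggregates, a
  deliberate simplification of mixed-effects modelling; the `stat_fn` hook
  accepts heavier machinery but the permutation null always uses the
  sign-flip scheme, which assumes within-subject exchangeability.
* DDM fits pool trials within a condition cell (optionally per subject via
  the `by` argument); there is no partial pooling, no inter-trial
  variability parameters, and censoring assumes the recorded deadline is
  exact.
* EDF support covers the continuous, equal-rate layout this package writes;
  it is not a general EDF(+) implementation.
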