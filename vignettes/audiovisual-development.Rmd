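---
title: "Modeling the development of audiovisual interactions and the modality switch cost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the development of audiovisual interactions and the modality switch cost}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msidev)
```

## The scientific problem

In a bisensory reaction-time task, observers respond to auditory (A), visual
(V) or combined audiovisual (AV) stimuli presented in a random sequence with
inter-stimulus intervals between 1 and 3 s.  Two robust behavioral
phenomena develop with age.  First, *multisensory gain*: adults respond
faster to AV stimuli than to the best unisensory stimulus, while young
children show no such advantage — early in life the senses appear to
compete rather than cooperate.  Second, the *modality switch effect*:
responses are slower when the current stimulus's modality differs from the
previous one, and this switch cost grows slowly through development while
being absent for AV stimuli.  In autism spectrum disorder (ASD) the
transition from competition to facilitation is delayed through adolescence
and normalizes only in adulthood.

`msidev` implements a mechanistic account of these trajectories: a
five-unit firing-rate network whose cross-modal synapses start inhibitory
and become excitatory under Hebbian training, embedded in a task harness
that turns network activity into reaction times, plus the cohort
experiments (typical development, two ASD perturbations, and early/late
multisensory interventions).

## The network

Five units, each a single neural element: auditory and visual input units
(A, V), a multisensory output unit (M) whose threshold crossing defines the
simulated reaction time, and two modality-specific inhibitory interneurons
(Ia, Iv).  Every unit is a leaky integrator with a logistic activation,

$$\tau\,\dot u_i = -u_i + \mathrm{net}_i, \qquad
  z_i = \frac{z_{\max}}{1 + e^{-a (u_i - \theta)}},$$

with a shared fast time constant $\tau_{\mathrm{fast}}$ (15 ms), slope $a =
0.3$ and center $\theta = 11.5$.  The net inputs implement the wiring:

* A receives the external drive $i_{0a}\,\mathrm{ext}_a$, the cross-modal
  input $W_{av} z_v$ (signed: negative in the immature network, positive
  after development) and slow feedback inhibition $-L_v q_v$; V is
  symmetric.
* M receives the feedforward drive $W_{ma} z_a + W_{mv} z_v$.
* Ia receives $W_{Ia} z_a - L_{va} z_{Iv}$; Iv symmetric.  The strong
  reciprocal inhibition between interneurons implements a winner-takes-all:
  for an AV stimulus only one interneuron stays active.
* The slow traces $q_a, q_v$ low-pass filter the interneuron rates with
  $\tau_{\mathrm{slow}} = 1200$ ms, so the inhibition a stimulus recruits
  is still present 1–3 s later and acts on the *next* stimulus.  This is
  the mechanism behind the switch cost: a visual stimulus charges $q_v$,
  which suppresses the auditory unit when the following stimulus switches
  to A.

External stimuli are 60 ms rectangular pulses of equal efficacy on each
active channel.  The simulated reaction time is the interpolated instant at
which $z_m$ first exceeds 10 percent of $z_{\max}$, minus the stimulus
onset; crossings later than 1 s after onset count as timeouts.

Integration is explicit Euler at $dt = 1$ ms.  The time scales of the model
(15 ms and 1200 ms) are far above the step, and the test suite verifies
that halving $dt$ moves no battery reaction time by as much as 2 ms.

### Winner-takes-all symmetry breaking

An AV stimulus drives both interneurons identically, so the symmetric state
is an unstable fixed point of the mutual-inhibition dynamics.  To select a
winner deterministically we add a seeded, infinitesimal jitter (at most
$10^{-6}$, equal magnitude and opposite sign on the two interneurons) to
the interneuron membrane inputs at each stimulus onset.  The mutual
inhibition is strong enough that this perturbation is amplified to a full
winner/loser split within the stimulus-driven interval; the jitter is far
below every other scale in the model and has no measurable effect on
reaction times.

## Hebbian development

One training *epoch* is one stimulus exposure.  The whole stream is
simulated as a single continuous session (the slow traces carry across
exposures — necessary, because the switch phenomenon lives in the
between-stimulus interaction).  After each exposure the network weights are
updated once:

* feedforward ($W_{ma}, W_{mv}$) and cross-modal ($W_{av}, W_{va}$)
  weights by Hebbian LTP, $w \leftarrow \mathrm{clip}(w + \gamma\,
  \mathrm{pre}\cdot\mathrm{post})$;
* feedback inhibition magnitudes ($L_a, L_v$) by an anti-Hebbian rule,
  $l \leftarrow \mathrm{clip}(l + \gamma\,\mathrm{pre}\,(z_{\max} -
  \mathrm{post}))$, which strengthens the synapse when the presynaptic
  interneuron is active while its target input unit is suppressed
  (classical Hebbian logic is contradictory for inhibitory synapses).

The cross-modal weights live in a signed range, so repeated AV
co-activation drives them across zero from inhibitory to excitatory — the
core developmental transition.  Because potentiation is non-negative the
lower bound of that range only has to contain the immature starting
values; the upper bounds of all classes act as saturation caps in place of
a decay term.

**The pre/post statistic.**  The statistics entering the updates are the
time-averaged *suprathreshold* rates over the 500 ms following the
exposure onset: each rate is reduced by the detection threshold
($0.1\,z_{\max}$, the same threshold the readout uses) and rectified
before averaging.  We first implemented plain mean rates and found they
make cross-modal learning almost independent of the stimulus mix: the
silent unit's baseline firing contributes pre/post products on unisensory
trials comparable to the (strongly suppressed) co-activation on AV trials
in the immature network, and typical and reduced-exposure schedules then
produce the same sign-flip epoch — which would erase the very manipulation
the reduced-exposure experiment is about.  Thresholding the statistic
(in the spirit of activation thresholds in BCM-style rules) makes
learning specific to genuine stimulus-driven co-activation, at the price
of one additional parameter that we tie to the existing detection
threshold rather than tune separately.

**Exposure streams.**  Training mixes are expressed as phase schedules of
(AV, A, V) probabilities.  By default streams are *stratified*: each phase
contains the exact mix proportions (largest-remainder apportionment) in
randomized order.  The cohort comparisons below are differences of a few
hundred microseconds to a few milliseconds between deterministic networks
trained on different mixes; with independent multinomial draws the
binomial noise in the realized composition of a 3000-exposure stream is of
the same order and can mask the systematic effect at unlucky seeds.
Stratification removes composition noise while preserving randomized
order; `stratified = FALSE` restores independent draws (and is what the
distributional tests of the stream generator exercise).

## Parameters

The three shipped presets are calibrated — they are this package's
realization of the published architecture, not published values:

```{r}
network_params("td_child")
learning_rates("td")
```

The immature configurations pair weak feedforward drive and nearly absent
feedback inhibition ($L = 1$) with strongly inhibitory cross-modal
synapses ($W_{av} = -18$; $-21$ in the ASD preset, which differs *only* in
the cross-modal weights).  The calibration targets were the qualitative
orderings of the behavioral phenomena, evaluated over many exposure-stream
seeds: no multisensory gain in the immature network (within 5 ms) but
clear adult gain; a positive, slowly growing unisensory switch cost with a
negligible AV switch cost at every age; reaction times non-increasing with
age in every condition; a cross-modal sign flip between epochs 1000 and
1500 (i.e., between the 13–17-year and adult checkpoints) for typical
development; delayed-but-catching-up ASD trajectories under both
hypotheses; and the early-versus-late intervention ordering.
`scripts/calibrate.R` re-evaluates this battery and reports each
ordering's worst-case margin across seeds.

Age mapping follows the 500-epochs-per-three-years convention: checkpoint
0 is the 6–9-year group, 500 is 10–12, 1000 is 13–17, and the adult row is
the mean over checkpoints 1500–3000 (the adult group spans a much wider
age range than the child groups).

## The cohort experiments

```{r, eval = FALSE}
td <- run_cohort("TD", seed = 1)
asd <- run_cohort("ASD_plasticity", seed = 1)
compare_to_reference(asd, td)
```

* `TD`: typical mix (30% AV / 20% A / 50% V), typical learning rates.
* `ASD_plasticity`: ASD preset, all learning rates at 80 percent.
* `ASD_exposure`: ASD preset, AV share starting at 20 percent (A and V
  splitting the remainder equally) and rising by 10 percentage points
  every 500 epochs.  The literal increments continue to 70 percent;
  `cap_at_td = TRUE` instead stops them at the typical 30 percent, for
  the reading under which exposure merely becomes typical-like.
* `ASD_*_intervention_early` / `_late`: the multisensory intervention
  (60% AV / 10% A / 30% V) applied from epoch 0 or from epoch 500.

Each cohort's 24-cell trajectory (4 age groups × 6 conditions) supports
RMS distances (`trajectory_distance`), the one-way data-source ANOVA
(`anova_oneway`, a wrapper over `stats::oneway.test` with equal
variances), and the qualitative-ordering validator (`check_trajectory`).

## The synthetic reference generator

Empirical median-RT tables for this task are plotted in the literature but
not published as numbers, so `make_fixture_reference()` generates
synthetic stand-ins on the empirical scale (hundreds of ms) that obey the
qualitative orderings (TD-like) or add a middle-age-group delay that
resolves by adulthood (ASD-like).  These tables exist so that the
comparison machinery (`read_reference_table`, `compare_to_reference`) can
be exercised and demonstrated end to end; passing tests against them shows
the pipeline works, not that the model fits any real cohort.  A user with
access to real median RTs supplies them as a CSV with columns `cohort,
age_group, condition, median_rt_ms`.

Model reaction times are reported in model milliseconds without a
non-decision offset; they are a few tens of ms and should be compared to
data via orderings, differences and the ANOVA on cell sets, not by
absolute value.

## Numerical and design notes

* Simulations are deterministic given (events, parameters, initial state,
  dt, jitter seed); same-seed cohort runs are byte-identical.
* Every trial and training session starts from the zero-input resting
  fixed point (damped fixed-point iteration) followed by a 500 ms settling
  period; resting activity stays below the detection threshold.
* Reaction times use linear interpolation between grid samples, so they
  are not quantized at $dt$.
* The AV-switch battery condition averages both variants (V then AV, A
  then AV).
* Timeouts are flagged and propagated, never imputed.
* The full experiment suite (seven cohorts of 3000 exposures plus
  checkpoint batteries) runs in well under a minute on one core thanks to
  the compiled integrator; a pure-R reference step (`step_state`) is kept
  and the test suite verifies the two paths agree to machine precision.

## Limitations

* Single neural element per region: no spatial receptive fields, no
  stimulus features, no incongruent (conflicting) AV stimuli.
* LTP only, with saturation caps standing in for homeostasis; no LTD and
  no critical-period modulation of plasticity.
* The model produces one deterministic RT per condition and checkpoint;
  trial-to-trial RT variability, race-model analyses and RT distributions
  are out of scope ("median" columns keep schema compatibility with
  empirical tables).
* The interneuron-drive and winner-takes-all weights are fixed
  (untrained), as are all biophysical constants; only the six bold
  synapse classes develop.
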