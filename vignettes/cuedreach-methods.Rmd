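---
title: "Models and methods behind cuedreach"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cuedreach}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuedreach)
```

## The experimental setting

`cuedreach` analyses head-fixed cued-reaching experiments: a mouse rests
its paw on a perch, a brief (250-ms) cue signals that a food pellet may
be available in front of it, and the animal can reach, grasp and consume
the pellet. Learning the cue--reach association is quantified by
signal-detection statistics on reach timing; its trial-to-trial dynamics
by a resampling analysis of consecutive-trial sequences; and its neural
correlates by event-kernel regression, clustering and population
decoding of striatal spike trains, plus demodulation of an
amplitude-modulated dopamine-sensor photometry signal. Every stage can
be driven by a synthetic-data module that plants known structure, so the
full pipeline is testable end to end without experimental data.

## Behavioral statistics

**Discriminability.** Performance is summarised by
$d' = \Phi^{-1}(\mathrm{hit}) - \Phi^{-1}(\mathrm{FA})$, where the hit
rate is the fraction of cue trials with at least one reach in the 400-ms
window after cue onset and the false-alarm rate is the analogous
fraction for a pre-cue window. Two false-alarm windows are supported
(0--0.4 s and 0.6--1 s before the cue); under the default
`dual_fa_min` variant the lower of the two candidate $d'$ values is
reported, so preemptive reaching anywhere shortly before the cue lowers
the score. Saturated rates are clipped to $1/(2n)$ and $1 - 1/(2n)$
before the quantile transform; this is the only place the package
invents a rule the analysis description leaves open, and it makes $d'$
finite while preserving ordering. A practical consequence, exercised in
the tests, is that segments of different length have different clipping
floors, so contrasts between segments are only meaningful when neither
rate is saturated.

**Stages and within-session learning.** Sessions are labelled beginner
($d' < 0.25$), intermediate ($0.25 \le d' < 0.75$) or expert
($d' \ge 0.75$). A session counts as *learned* when any of the three
split contrasts (last 75% vs first 25%, halves, last 25% vs first 75%)
exceeds 0.1. *New learning days* are pre-expert days whose $d'$ strictly
exceeds every previous day, computed after discarding the final 10% of
trials (animals disengage late in a session).

**Trial classes.** Each cue trial is classified as cued success, cued
failure, uncued success, uncued failure, or other, keyed on windows
relative to cue onset (outcome within 1 s for cued classes; a
3.5--7-s closed window for uncued outcomes; a 1.5-s post-cue exclusion;
a chewing-at-trial-start exclusion for pre-cue failures). Window
membership uses half-open `[start, end)` intervals except where a rule
is stated as "between a and b", which is closed. The "did not reach
before the cue" criterion spans the whole pre-cue segment of the trial
by default; a variant restricted to the uncued window is provided.

## The trial-to-trial reinforcement bootstrap

Behavior is a 2-vector per trial: reach rate in the cued window
([0, 0.4) s) and in the uncued window ([-3, -0.25) s). For triplets of
consecutive trials $(n-1, n, n+1)$ in which trial $n$ matches a chosen
class, the shift is

$$\Delta = \overline{b}_{n+1} - \overline{b}_{n-1},$$

the difference of plain means, with uncertainty from resampling
triplets with replacement (100 iterations for scatter displays, 1,000
for the smoothed 2-D histogram, which is filtered with an axis-aligned
Gaussian of SD 0.0096 Hz along the uncued axis and 0.024 Hz along the
cued axis and normalised to integrate to 1; the bin grid itself --
101x101 over the draw range plus 10% -- is a package choice). Resampling
operates on triplets, never on single trials. Interleaving filters
select inhibition-off trials followed by an inhibition trial at
positions $n+2 \ldots n+5$ (or the converse), so optogenetic comparisons
are made between temporally interleaved trials. The backwards-time
control conditions the same $(n-1, n+1)$ contrast on the class of trial
$n+2$: a causal update acts forwards only, so planted effects collapse
under this control while correlational structure would not. The
timing-resolved variant bins trial-$n$ successful reaches by their time
relative to the cue (reproducing the variable window widths used at low
reach rates: 1.2 s before the cue, 0.2--1 s after) and reports mean
$\pm$ SE per bin for control versus inhibition trials, indexed by the
lag between the inhibition midpoint and the bin midpoint.

## The synthetic behavioral generator

`generate_session()` draws an inhomogeneous-Poisson reaching process on
the documented trial skeleton: inter-trial interval uniform on 0--3.5 s,
extended by uniform 9.5--13 s with probability 0.7; 1.5 s from trial
start to cue onset (pellet advance plus delay); pellet withdrawn 8 s
after the cue; 10% catch trials (cue on, pellet deliberately omitted);
30% pellet occupancy on the remaining cue trials; spontaneous reach rate
0.25 Hz. Occupancy and catch are independent draws: a catch flag
overrides pellet loading, so the fraction of *non-catch* trials with a
pellet equals the occupancy setting. The cued window multiplies the rate
by `cue_gain`, and a reinforcement state adds `reinforcement_delta` Hz
to the next trial's cued (resp. uncued) rate after a cued (resp.
uncued) success, decaying geometrically with a half-life of one trial
by default -- the one-trial-ahead effect is the modelled phenomenon; its
persistence is deliberately a configuration knob, not an assertion.
Reaches during pellet availability succeed with probability 0.85
(dropping the pellet otherwise, either way dislodging it); reaches
without a pellet are `pellet_missing` failures, which is also how
reaches on catch trials are recorded.

Two modelling consequences matter for interpreting tests. First, a
0.25-Hz Poisson baseline over the roughly 10-s pre-cue span means most
naive trials contain a pre-cue reach, so strict cued successes are rare
at default settings -- as for naive mice. Recovery experiments therefore
use a documented "trained-stage" configuration (baseline 0.1 Hz, cue
gain 30) in which cued successes are frequent, while the calibration
targets (catch fraction, occupancy, beginner baseline rate) always use
the defaults. Second, the generator does not emulate reach kinematics,
satiety drift, chewing bouts, session-level nonstationarity or
non-Poisson bursting; passing tests certify the estimators under the
stated stochastic model, not robustness to those phenomena.

The spike generator draws each unit's rate as
`baseline + sum of event kernels` (the linear-link generative model of
the GLM below), floored at zero with a warning counter, piecewise
constant on 0.1-s bins. Planted group-1 units carry a post-success
kernel peaking at 6 Hz and decaying with a 0.8-s time constant; group-2
units a post-failure ramp sustaining 4 Hz -- within the few-to-ten-Hz
post-outcome modulations typical of striatal projection neurons --
with log-normal per-unit amplitude jitter, baselines uniform on 1--3 Hz
and waveform widths on 0.25--0.45 ms, so every unit classifies as a
putative SPN. The photometry generator emits a 2,000-Hz trace whose
167-Hz carrier is amplitude-modulated by a baseline plus Gaussian
transients: a positive peak 0.83 s after each successful reach and a
negative dip 1.6 s after each failure, with white sample noise
(signal-to-noise = transient amplitude / noise SD).

## Unit typing, PSTHs and data splitting

Units are classified from waveform width at half-maximum and mean rate:
SPN (width >= 0.22 ms, rate < 4 Hz), tonically active neuron (>= 0.22
ms, >= 4 Hz), fast spiking (< 0.22 ms, >= 1.25 Hz), low-firing thin
otherwise. PSTHs are mean count/binwidth across events and exactly
conserve spikes. For physiology, reaches within 3 s of the cue are
cued, 3--5 s ambiguous (excluded), 5--16 s uncued; intervals are
lower-inclusive. The train/test split is a stratified 50/50 draw per
behavioral condition (train receives floor(n/2) on odd counts), made
once per session and shared by all simultaneously recorded units; every
model-fitting step (GLM, clustering, boundary, tensor regression) sees
training trials only, and decoding sees test trials only.

## The event-kernel GLM

Nine behavioral event channels (cue; distractor; reach; success; the
two failure types; and their cued interactions, with outcomes stamped
at the moment the arm is outstretched) are each shifted across 71 lags
from -2 to +5 s at 0.1 s, giving a 639-column indicator design against
binned spike counts with an identity link. The sweep fits ordinary
least squares plus every (alpha, l1_ratio) elastic-net combination
(alpha in {0.01, 0.1, 1}, l1_ratio in {0, 0.1, 0.5, 0.9, 1}, glmnet
parameterisation matching penalty = alpha (l1_ratio |b|_1 +
(1-l1_ratio)/2 |b|_2^2)); regressors are not standardised and the
intercept is unpenalised. The final 10% of time bins is a contiguous
holdout; selection maximises holdout $R^2$ with ties broken toward
larger alpha then larger l1_ratio, and a blocked five-fold CV $R^2$ of
the winner is reported as a diagnostic. Because the reach channel fires
on every outcome event, the design is exactly rank-deficient; OLS
returns the minimum-norm solution, and `effective_event_kernels()`
exposes the identifiable per-event-type responses (the sum of all
channels an event triggers), which is what recovery experiments check.

## Two-group structure in the post-outcome period

The four post-outcome-period kernels (success, failure = mean of the
two failure channels, cued success, cued failure; lags 0--5 s) are
boxcar-smoothed (0.08 s -- a no-op on the 0.1-s grid, effective on finer
grids), concatenated, and max-normalised by the largest absolute value
of the concatenation, preserving relative kernel amplitudes
(per-kernel normalisation is an option). Units with no positive POP
coefficient are excluded. Two-means clustering (best of 20 restarts)
splits the vectors; labels are canonicalised by the modulation index.
The summary metrics are
$m = (c_{2\text{--}5} - c_{0\text{--}2}) / (|c_{2\text{--}5}| +
|c_{0\text{--}2}|)$ averaged over the success and cued-success kernels,
and $s = |c_{1\text{--}5}|$ averaged over the failure kernels. The
separating line in the $(m, s)$ plane is the pooled-covariance
two-class discriminant fitted to the training-set k-means labels (the
original boundary was drawn by hand; the discriminant is the line a
linear classifier would draw), frozen, and applied to any unit; points
on the line go to group 1.

## Kruskal-tensor multinomial regression

Training trials are averaged into an $N \times T \times 4$ tensor
(conditions: success, failure, cued success, cued failure; 0.1-s bins
over the 5-s post-outcome period), with the failure slices advanced by
round(0.77 / 0.1) = 8 bins so the characteristic post-failure dip
(~1.6 s) aligns with the post-success peak (~0.83 s); unmatched edge
bins are dropped from all conditions. The regression predicts each
slice's condition from logits
$z_{mk} = \langle X_m, \sum_r a_r \otimes b_r \otimes c_{k r} \rangle$
with neuron factors $a_r \ge 0$ (projection after each step), optimised
by full-batch ADAM (learning rate 0.007, uniform init on
[0, 0.625]) on cross-entropy plus an L2 penalty (default 1e-3; the
strength is not documented in the source analysis and is exposed in the
configuration). The tensor is divided by its maximum absolute entry
before optimisation -- a pure conditioning choice, undone at prediction
time, without which the logits start deep in softmax saturation at
realistic firing rates. Convergence is declared when the cross-entropy
changes by less than 1e-6 (relative) across 50-epoch checkpoints, or at
20,000 epochs; the check deliberately watches the fit term, because the
penalty keeps drifting long after the classification has stabilised.

Restarts matter: solutions differ in how the two neuron factors divide
the population. The joint loading penalty
$$J = \frac{\sum_n \sum_{i \ne j} |w_{n i} + w_{n j}|}
           {\sum_n \sum_{i \ne j} |w_{n i} - w_{n j}|}$$
is lowest when factors load disjoint neuron groups; among the restarts
of the chosen rank the minimum-J solution is returned. Rank choice is a
judgment on the emitted loss-versus-rank table (rank 2 by default). A
caution from the package's own experiments: on artificial tensors in
which every neuron of a group responds identically, factor mixing is
norm-efficient and every converged restart partially shares loadings;
with realistic per-neuron heterogeneity and baselines (the spike
generator's output), disjoint solutions dominate the restarts and
min-J selects them. Interpret loading structure only on data with
plausible heterogeneity. Shuffle validation predicts success versus
failure on bootstrap-averaged test slices after permuting neurons, time
bins, both, or nothing; each repetition contributes four scored
predictions, giving accuracy at useful granularity.

## Population decoding

Per-unit firing rates are taken 1--5 s after the outstretched arm on
test trials (the first second is excluded so the cue offset precedes
the window). Each bootstrap iteration resamples $n$ units per group
with replacement (one random trial per unit per condition in
single-trial mode) and yields one (group-2 mean, group-1 mean) point
per condition; 100 iterations per display. A linear discriminant with
equal priors and pooled covariance scores the three-way separation
(cued success / uncued success / failures combined) by resubstitution
accuracy, mirroring the original usage; chance is reported empirically
via the condition-label shuffle rather than as 1/3, because the merged
failure class doubles its point count. The group-identity shuffle
permutes unit group labels; both shuffles preserve marginal rate
distributions.

## Photometry demodulation

The raw trace is band-passed to 120--200 Hz (4th-order Butterworth,
zero-phase `filtfilt`), then a multitaper spectrogram (0.1-s windows
stepped by 0.01 s, time-bandwidth 3, 2 Slepian tapers computed from the
standard tridiagonal eigenproblem) yields mean in-band power at 100 Hz,
which tracks the squared carrier envelope. The z-score uses a trailing
(causal) 30-s rolling baseline -- the early part of a recording uses
the expanding window available so far -- followed by a 5-sample running
median (both the trailing convention and the median width are package
choices where the source description says only "rolling" and
"median-filtered"). Event-aligned averages subtract a pre-event
baseline (mean over [-0.5, 0) s for cue alignment, [-2, -1.5) s for
reach alignment) and report mean $\pm$ SE per class, dropping and
counting events too close to the trace edges.

## Numerical choices and degenerate inputs

Zero-count rate windows are valid (rate 0); empty triplet sets error on
estimation but not on extraction; all-zero design columns are retained
with a warning (their coefficients are 0 under any penalty);
rank-deficient normal equations fall back to the minimum-norm
pseudo-inverse solution; identical k-means inputs error; an all-equal
factor pair makes $J$ infinite by convention; zero rolling SD yields
z = 0 with a warning; near-singular LDA covariances are ridge-regularised
with a warning. All stochastic steps take explicit integer seeds, and
generator outputs are bit-reproducible given the seed.

## Problem sizes used by the test-suite

The suite validates estimator behavior at deliberately desk-scale sizes
chosen by the package: sessions of 40--400 trials; triplet pools of
1,500--5,000 sequences for reinforcement recovery (where the planted
0.5-Hz update is recovered with about 3% bias); populations of 3--30
units for GLM, grouping, tensor and decoding experiments; 100
null sessions for bootstrap-coverage calibration; and 20 simulated
photometry sessions at signal-to-noise 2 for the transient round trip.
These sizes make the checks sharp without being expensive; none of the
published effect sizes from real animals are reproduced or asserted.

## Known limitations

The behavioral generator's Poisson reaching has no refractoriness or
bout structure; the update rule is linear-additive with geometric decay
rather than a learned policy; spike generation is conditionally Poisson
(no bursting, no correlations beyond shared events); the photometry
model has a single noise floor and no bleaching or motion artefacts;
and the tensor regression trains on only four trial-averaged slices, so
its generalisation claims rest entirely on the train/test trial split
upstream of averaging.
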