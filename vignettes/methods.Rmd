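---
title: "Models, statistics and design choices in gustate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, statistics and design choices in gustate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gustate` quantifies how an illness state reshapes gustatory cortical
(GC) activity: a state switch in 7–12 Hz ("μ") LFP power, a drop in
rearing behavior, shrinking and de-differentiating single-neuron taste
responses, and a collapse of ensemble coding toward a good-vs-bad
palatability axis. This vignette documents the models behind each stage,
the parameters that matter, the synthetic-data generator that stands in
for animal recordings in all tests, and the design decisions taken where
the analysis was genuinely open.

## The single change-point model

Per-minute μ-band power over the 20-min post-injection window is
z-scored and modeled as two Gaussian states with a single switch:

\[
\mu_1, \mu_2 \sim N(0,1), \quad \sigma \sim \text{HalfCauchy}(1), \quad
\tau \sim \text{Uniform}(0, T),
\]
\[
y_t \sim N(\mu_1, \sigma)\ \text{for } t < \tau, \qquad
y_t \sim N(\mu_2, \sigma)\ \text{for } t \ge \tau .
\]

Because the likelihood is piecewise constant in \(\tau\) between bin
boundaries, the sampler (in compiled code) can update the change
*interval* exactly from its categorical full conditional, draw \(\tau\)
uniformly inside it, update \(\mu_1,\mu_2\) conjugately, and move
\(\sigma\) by Metropolis on \(\log\sigma\). Mixing is essentially
perfect; the default 4 chains × 2000 post-warmup draws (500 warmup) give
split-chain \(\hat R\) ≈ 1.00, and a fit flags itself unreliable at
\(\hat R \ge 1.1\). The test suite checks the sampler against an
exhaustive oracle — the discrete-\(\tau\) marginal with the state means
integrated in closed form and \(\sigma\) integrated numerically — at a
total-variation tolerance of 0.1.

### Detection against the shuffle null

The posterior of \(\tau\) is histogrammed on a 0.5-min grid and compared
with refits of 50 temporally shuffled copies of the series (random
permutations of the minute bins, which by construction contain no change
point). We take each shuffle's **peak** histogram height and set the
detection threshold at the 99th percentile of those 50 peaks; bins of
the actual posterior above it are marked, and the estimate is the mean
of the marked bin centers. Comparing each actual bin against the
percentile of *pooled* per-bin shuffle heights is tempting but wrong for
a detector: for a stationary series the actual data are statistically
one more shuffle, so some bin of its (lumpy) posterior exceeds the
pooled 99th percentile far too often — we measured ≈ 18 % false
detections on pure noise, and ≈ 45 % for bin-wise thresholds. The
peak-height rule keeps false detections at ≤ 2–3 % while still detecting
≈ 85 % of 3-SD shifts with a mean localization error of ≈ 0.4 min.

## Behavior, coupling

Rearing durations (events with both forepaws off the floor > 0.5 s) are
binned per minute with boundary-spanning events split proportionally, so
totals are conserved exactly. Each animal's trace is min-max normalized,
condition means are differenced (LiCl − saline), and a 4-parameter
logistic fit (Levenberg–Marquardt, multi-start over midpoints 4/8/12/16
min with both slope signs, to avoid local minima) reads out onset as the
approach to the lower asymptote. Flat traces short-circuit to a flagged
degenerate fit rather than a spurious convergence error. Quartile
comparisons use two-sample Wilcoxon rank tests by default because the
cohorts are separate animals; a paired mode exists for matched designs.

The coupling test treats the behavioral and LFP change latencies (from
separate cohorts) as two lists and asks whether their summed all-pairs
absolute distance is smaller than for lists drawn i.i.d. uniform over
the window (10,000 simulations; mean-vs-mean distance available as a
mode). The p-value is the fraction of null statistics at or below the
observed one.

## The quartile power comparison

"Normalized per animal" is implemented as **one** min-max scale per
animal covering both of its sessions. Scaling each session separately
destroys the between-session shift the analysis is after: with
per-session scaling the planted 3-noise-SD LiCl shift is detected with
power ≈ 0.2; with the joint scale, power ≈ 0.99 at 7 vs 5 animals and
the null rejection rate stays ≈ 0.03. The absolute normalized
saline−LiCl difference is averaged within 5-min quartiles and tested
with a two-way mixed ANOVA (group × quartile, animal as subject) plus
per-quartile one-way follow-ups.

## Spiking analyses

**Responsiveness.** Trial-wise firing in [−1000, 0) ms vs [200, 1200) ms
(the first 200 ms post-delivery is somatosensory and always excluded)
enters a Mann–Whitney U per neuron, pooling tastes; direction is the
sign of the mean baseline-subtracted evoked rate — a statement about
firing, not synaptic inhibition. The evoked window spans a full second
while skipping the first 200 ms; [200, 1000) is available via arguments.

**Magnitude ANOVA.** The condition × direction ANOVA runs by default on
per-neuron mean |magnitude| (one observation per neuron). The pooled
layout with four per-taste entries per neuron — which reproduces
residual degrees of freedom near 4·(neurons) − 4 — is kept as
`unit = "taste"`, but a neuron's four magnitudes share its response
gain, and that correlation makes the pooled F reject a true null ≈ 4×
too often (measured 0.20 at α = 0.05). Neuron-level units restore the
nominal level (measured 0.03).

**Decoding.** The classifier is a linear discriminant with pooled
covariance and equal priors, shrunk toward the spherical diagonal
average whenever ill-conditioned (always logged). Leave-one-out accuracy
is computed per 250-ms bin; epochs (early 200–400, middle 400–700, late
800–1100 ms) summarize bins by their centers. The early epoch is our
choice of the gap between the exclusion window and the stated middle
epoch. Condition comparisons use session-level epoch accuracies whenever
two or more sessions per condition are available: all trials of a
session share one fitted classifier, so per-trial correctness values are
not independent — pooling them across a single session pair rejected a
true null at ≈ 0.13 in our measurements, while session-level units are
calibrated. With one session per side the function falls back to the
trial-level comparison and documents its within-ensemble meaning. The
within-session variant trains once on the first 5 trials per taste,
never tests on them, averages correctness over post-stimulus bins and
tie-breaking iterations, and groups tested trials into 5-per-taste
blocks; block traces from several sessions are min-max normalized and
tested with a repeated-measures ANOVA plus paired, Bonferroni-corrected
follow-ups versus block 1.

**Palatability.** The moving-window Spearman correlation (250 ms window,
25 ms step) relates trial firing to the canonical ranks
sucrose > NaCl > citric acid > quinine; the group trace reports mean
|ρ| with ρ² alongside, since single-neuron palatability coding has
arbitrary sign. Windows with zero rate variance are excluded with a
count. The pure palatability index uses trial-averaged,
baseline-normalized (−500 ms) response vectors over the **central
150 ms** of each epoch (our reading of "the middle of the epochs"),
distances divided by √(bins) so the index is per-bin scaled:
\( \text{PPI} = \bar D_\text{dissimilar} - \bar D_\text{similar} \)
with the 4 different-palatability and 2 same-palatability pairs averaged
separately so class imbalance cannot bias it. A normalized mode,
\((D_d - D_s)/(D_d + D_s)\), is scale-invariant and equals 1 for a pure
good/bad code; both are reported because the difference form matches the
index's defining formula while the ratio phrasing also appears in the
field. Under exchangeable tastes both forms have expectation 0.

## Held units and clusters

Stability screening compares mean waveforms between sessions with a
pooled-per-sample-SD-normalized Euclidean distance — a deliberately
simple, distribution-free statistic, pluggable behind `stat_fn`, since
the field's "nonparametric clustering statistic" has no single canonical
formula. The null is built from first-third vs last-third within-session
comparisons, bootstrapped and pooled across the population; a unit is
held below the null's 95th percentile.

RD (response-difference) vectors take, per held unit and taste, the
post-delivery (250→750 ms) minus pre-delivery (−750→−250 ms) mean of the
unit's min-max-normalized rates, per condition, as a percent of its
maximum responsiveness; the pre window mirrors the post window's length
(a printed "−750→250 ms" overlaps delivery and is treated as a typo).
Min-max normalization is per unit **across** both sessions so condition
differences stay meaningful. The (saline, LiCl) points are clustered
with full-covariance Gaussian mixtures, k chosen by BIC over 1–6;
membership requires falling inside the cluster's 95 % Mahalanobis
ellipse, and the count of circular angle-histogram peaks is reported as
a model-free cross-check.

Cluster-specific palatability is tested on each neuron's saline−LiCl
difference in epoch-mean ρ² — differencing is what makes the reported
interaction have (k−1)(e−1) numerator degrees of freedom, and it removes
the neuron-specific palatability strength common to both sessions. The
aligned-rank-transform ANOVA (cluster × epoch, neuron as subject)
supplies the F statistic, but the p-value comes from permuting cluster
labels across neurons (199 permutations by default): cluster is a
between-neuron label, so label permutation is exact whatever the
within-neuron covariance, whereas the raw repeated-measures F rejected a
true null at ≈ 0.09–0.13 in our measurements. `n_perm = 0` recovers the
parametric ART p-value.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions all calibration and recovery tests run under.

* **LFP power**: 7 experimental + 5 control animals; 20 one-minute bins;
  noise SD 0.5 a.u.; shift 1.5 a.u. (3× noise) at 15 min, sign
  alternating across animals because both directions occur in vivo. Both
  of an animal's sessions share a slow sinusoidal drift (amplitude 2×
  noise SD, random phase, ~20-min period) emulating within-animal state
  fluctuations; this is what makes two same-day recordings comparable
  after joint normalization.
* **Ensembles**: 30 neurons, 30 trials per taste, 25-ms bins covering
  −1000…+1500 ms. Baseline rates are Gamma with mean 6 Hz; spike counts
  are Poisson per bin (the analyses consume binned rates only, so a
  refractory point process would add nothing they can see). The first
  200 ms post-delivery carries no taste information; identity separation
  (3 Hz per unit tuning weight) lives in 400–700 ms; late-epoch firing
  (800–1100 ms) is monotone in palatability rank (2 Hz per centered rank
  unit). 30 % of neurons respond below baseline. LiCl multiplies the
  epoch-specific components — magnitude × 0.7, identity × 0.5,
  palatability × 1.5 — leaving baseline untouched, which is exactly what
  the baseline-equivalence stage verifies. The first 12 neurons are
  "held" with planted cluster motifs (excitatory→inhibitory,
  inhibitory→excitatory, excitatory→weaker-excitatory); rates are
  floored at 0.05 Hz, so strongly inhibited motifs can clip — a realism
  feature worth remembering when constructing nulls, because clipping
  interacts with the late-epoch palatability term.
* **Behavior**: rearing events as a Poisson process (1.5/min), durations
  0.5 s + Exponential(2 s); after the 12-min sickness onset LiCl
  durations scale by 0.2. The scaling applies to the whole duration, so
  post-onset events may fall below the 0.5-s scoring floor — the floor
  is the upstream scoring rule for healthy rears, not a constraint on a
  sick animal's aborted rears.
* **Waveforms**: difference-of-Gaussians templates with per-sample
  noise; a configurable fraction of units doubles its amplitude in
  session 2 as planted not-held cases.

Each generator seeds its own RNG stream from the master seed via a fixed
offset table, so stages can be regenerated independently. The generator
emulates the *structure* the analyses assume — epochal rate profiles,
Poisson count noise, planted effect directions — not real GC dynamics:
no trial-to-trial state fluctuations, no correlated noise across
neurons, no adaptation across trials (except the explicit within-session
drift fixture). Passing tests therefore demonstrate that the analysis
machinery recovers planted structure at realistic sizes and rejects at
nominal rates when structure is absent; they do not certify performance
on real recordings.

## Calibration and problem sizes

The acceptance suite re-derives, per run: chance-level (25 %) decoding
under label shuffling (15 neurons × 120 trials, 8 shuffle replicates);
a null PPI over 500 exchangeable-taste neurons (±2 Monte-Carlo SE);
change-point recovery over 100 planted series plus 100 stationary series
and the 3-case oracle-equivalence check; 3-cluster recovery over 50
seeds (BIC picks k = 3, adjusted Rand > 0.9); and the rejection rate of
every test stage over 200 null replicates within ±2 binomial SE of
α = 0.05. Null calibration draws the two condition populations from
independent simulated animals, mirroring the pooling of distinct neuron
samples per condition in the experimental design; paired-neuron
fixtures would make the unpaired population tests grossly conservative.
Problem sizes (12–24 neurons, 12 trials per taste, 5 sessions per side
for the decoding comparison) are chosen so each stage's sampling
distribution is exercised with hundreds of replicates while a full run
of the suite stays in the minutes range on a laptop core.

## Known limitations

* The shuffle-null detector is conservative by construction; shifts much
  smaller than 2× the bin noise SD, or within ~2 bins of the window
  edges, are often missed.
* Trial-level decoding comparisons (single session per condition) are
  within-ensemble statements; only multi-session comparisons support
  population claims.
* The waveform-stability statistic is a documented stand-in for a family
  of spike-shape criteria in the literature; decisions near the 95th
  percentile should not be over-interpreted.
* The ART + permutation inference treats neurons as exchangeable units;
  it does not model animal-level clustering of neurons.
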