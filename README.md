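# gustate

Analysis toolkit for rodent gustatory cortex (GC) recordings around
illness induction. When a rat is made ill (e.g., by a LiCl injection),
GC network activity and single-neuron taste coding change together:
7–12 Hz ("μ") LFP power switches state roughly when sickness behaviors
appear, taste responses shrink and lose identity information, and coding
collapses toward a simple good-vs-bad palatability judgment. `gustate`
implements the full analysis battery needed to quantify these effects —
and a synthetic-data generator with planted ground truth, so every stage
is testable without animal data.

The package is tidyverse-native: analysis functions take plain data
frames (long trial tables, event tables, per-minute power tables) and
return tibbles; fitted objects have `tidy()`/`glance()` methods and
`autoplot()`/`plot_*()` figures.

## What it computes

* **Bayesian single change point on μ-band power** — per-minute power is
  z-scored and modeled with two Gaussian states sharing one SD:

  ```
  mu1, mu2 ~ Normal(0, 1)        sigma ~ HalfCauchy(1)
  tau      ~ Uniform(0, T)
  y(t)     ~ Normal(mu1, sigma)  for t <  tau
             Normal(mu2, sigma)  for t >= tau
  ```

  A Gibbs sampler (compiled, exact categorical update of the change
  interval) draws the posterior of `tau`; 50 temporally shuffled series
  give a null for the posterior's histogram peaks, and bins exceeding
  the 99th-percentile peak height are marked. The change-point estimate
  is the mean of the marked bins, or absent if none is marked.
* **Sickness-onset behavior** — rearing-duration traces, normalized
  LiCl−saline difference, per-quartile Wilcoxon tests, and a 4-parameter
  logistic fit whose midpoint reads out onset time.
* **Change-point coupling** — a Monte-Carlo test of whether behavioral
  and LFP change latencies (separate cohorts) are closer than
  independent uniform draws.
* **Taste responsiveness** — per-neuron Mann–Whitney U of evoked
  (200–1200 ms; the first 200 ms is somatosensory) vs pre-stimulus
  firing, excitatory/inhibitory direction, and a condition × direction
  ANOVA on response magnitudes with Tukey follow-ups.
* **Ensemble taste decoding** — leave-one-out linear discriminant
  classification of the four tastes from simultaneous ensemble firing in
  250-ms bins (pooled covariance with shrinkage when ill-conditioned),
  epoch-wise condition comparisons, and a within-session variant trained
  on the first 5 trials per taste to track discriminability as sickness
  sets in.
* **Palatability coding** — moving-window (250 ms / 25 ms) Spearman
  correlation of firing with the canonical hedonic ranks
  sucrose > NaCl > citric acid > quinine, and the pure palatability
  index `PPI = D_dissimilar − D_similar`: the mean Euclidean distance
  between responses to different-palatability taste pairs minus that
  between same-palatability pairs (0 with no palatability structure;
  positive under good/bad polarization).
* **Held units and response-difference clustering** — spike-shape
  stability screening against a within-session 95th-percentile null,
  per-unit × taste response-difference (RD) vectors across conditions,
  Gaussian-mixture clustering with BIC model selection and 95 %
  Mahalanobis membership ellipses, cluster-specific palatability tests
  (aligned-rank ANOVA with label-permutation inference), and
  baseline-equivalence checks.

`run_pipeline()` chains all stages from one seeded configuration and
writes per-stage CSV/JSON plus a summary.

## Worked example

```r
library(gustate)

cfg <- sim_config(seed = 42)          # 7 LiCl + 5 control animals,
                                      # mu-power shift planted at 15 min
lfp <- sim_lfp_power(cfg)

s <- dplyr::filter(lfp$power, animal_id == "exp01", condition == "licl")
detect_changepoint(s, seed = 1)
#> Change point detected at 15.00 min (4 marked bins, threshold 0.158)

quartile_power_anova(lfp$power)
#> Group x quartile interaction: F(3, 30) = 12.00, p = 2.477e-05
#> # A tibble: 4 × 5
#>   quartile    df df_resid statistic  p.value
#> 1 1            1       10   0.0812  0.782
#> 2 2            1       10   0.00386 0.952
#> 3 3            1       10   8.09    0.0174
#> 4 4            1       10  35.0     0.000148
```

The detector recovers the planted 15-min switch, and the group ANOVA
localizes the LiCl–saline power difference to the late quartiles, as it
should when illness effects emerge in the second half of the window.

```r
ens <- sim_ensemble_pair(sim_config(n_neurons = 15,
                                    n_trials_per_taste = 15, seed = 42))
lda_loo_accuracy(ens$saline, t_range = c(200, 1200), seed = 1)
#> LOO-LDA decoding: 15 neurons, 60 trials, 4 bins
#>   epoch  accuracy n_bins
#> 1 early     0.383      1
#> 2 middle    0.65       1
#> 3 late      0.433      2
```

Middle-epoch accuracy (0.65) is far above the 25 % four-taste chance
level — the middle epoch is where the generator plants taste-identity
separation, mirroring where identity coding lives in GC.

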