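---
title: "From RR tachograms to autonomic indicators: the methods behind mefahrv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RR tachograms to autonomic indicators: the methods behind mefahrv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
set.seed(1)
```

```{r setup}
library(mefahrv)
```

# Overview

`mefahrv` condenses beat-to-beat heart-period (RR interval) recordings taken
over the consecutive epochs of a dynamic exercise protocol into a small number
of interpretable *autonomic indicators* on a common 0–100 scale, and supplies
the inference machinery needed to compare athletes, epochs, and groups. The
workflow is:

1. **Proxies** — each tachogram (one subject, one epoch) is reduced to twelve
   heart-rate-variability proxies.
2. **Two-level factor model** — the subject × epoch proxy panel is split into
   a between-subject part (stable individual differences) and a
   within-subject part (epoch-to-epoch autonomic adjustment), and each part is
   factor-analysed separately.
3. **Indicators** — factor scores are mapped to [0, 100] through the
   cumulative distribution of a kernel density estimate, giving
   percentile-like indicators.
4. **Inference** — a battery of rank-based, permutation, and bootstrap
   procedures, with step-up false-discovery-rate control and stratified
   balanced bootstrap confidence intervals.

Every quantity is computable from a synthetic study whose latent structure is
known, so the whole chain is testable end to end.

# The twelve proxies

`compute_proxies()` evaluates, per tachogram:

* **Time domain** — mean heart rate `HR`; the root-mean-square of the
  linearly detrended RR series `RR_RMS` (an overall variability magnitude
  around the local trend, not a difference-based statistic); and `RMSSD`, the
  root-mean-square of successive differences.
* **Spectral** — an autoregressive (Burg) spectrum with the model order
  chosen by AIC over orders 8–16 is decomposed by pole–residue partial
  fractions into spectral components. Components are assigned to a
  low-frequency band (0.03–0.15 Hz, exclusive) and a high-frequency band
  (0.15–0.40 Hz, inclusive at both ends), giving the absolute powers
  `RR_LFa`, `RR_HFa` and total power `RR_TP`. Normalized powers use the
  classical convention `LFnu = 100·LF/(TP − VLF)` (and analogously `HFnu`),
  where VLF collects components at or below 0.03 Hz. Dividing by `TP − VLF`
  rather than `LF + HF` keeps the pair *sub-complementary*
  (`LFnu + HFnu ≤ 100`) instead of making it an exact linear identity, which
  would render every correlation matrix containing both columns singular.
  A residual-whiteness flag (Anderson's test on the AR residual
  autocorrelations) is carried as a per-epoch diagnostic.
* **Phase-rectified signal averaging** — anchor points where RR decreases
  (acceleration capacity `AC`) or increases (deceleration capacity `DC`) are
  averaged over full surrounding windows and contrasted with a Haar wavelet.
  Epochs without a single usable anchor yield `NA` with an explanatory
  attribute; study-level assembly can impute the study median.
* **Symbolic dynamics** — `P0v`, the percentage of length-3 symbol patterns
  with zero variation after uniform quantization of the RR range.
* **Regularity** — `RR_Ro`, one minus the minimum of the corrected
  conditional entropy relative to the Shannon entropy of the one-symbol
  distribution; 0 for an unpredictable series, 1 for a perfectly regular one.

# The two-level factor model

`decompose_panel()` splits the standardized panel into subject means (the
*between-subject* correlation matrix `R_B`, one row per subject) and
subject-centred values (the *within-subject* matrix `R_W`, pooled over all
epochs after removing each subject's own mean). Sampling adequacy is reported
by the Kaiser–Meyer–Olkin measure at both levels, with 0.6 used as the
adequacy threshold.

Each level is factored by iterated principal-axis extraction started from
squared multiple correlations. Communality iterates that overshoot 1 by at
most `heywood_tol = 0.05` are projected back onto the boundary and iteration
continues; a larger overshoot is declared a Heywood case and stops the fit —
small overshoots are a routine artifact of near-collinear proxies, large ones
signal a genuinely inadmissible solution. Factors are varimax-rotated
(Kaiser-normalized, convergence tightened to `eps = 1e-10` so that rotated
loadings are reproducible to many digits), ordered by explained variance, and
sign-fixed so the largest loading in each column is positive.

`choose_n_factors()` retains the factors with eigenvalue above 1 and then
requires every retained, rotated factor to be *interpretable* — at least one
absolute loading at or above 0.6. The returned count carries a human-readable
rationale.

Factors are labelled by the typology of their marker proxies: amplitude
proxies (powers, RMS measures, capacities) yield an *Amplitude* factor,
frequency-balance proxies (normalized powers) a *Frequency* factor, the
regularity index a *Signal Self-Similarity* factor, and the symbolic pattern
measure an *Oscillatory* factor; mixed marker sets fall back to a generic
label with a warning rather than an invented name. Labels become indicator
codes such as `AMP-BS-Ind` (between-subject) or `OSC-WS-Ind`
(within-subject).

Regression factor scores `Z R⁻¹ Λ` are transformed to indicators by
`pkde_transform()`: `100 · F̂(x)` where `F̂` is the cumulative distribution
of a Gaussian kernel density estimate with the Sheather–Jones bandwidth
(falling back to the normal reference rule when the SJ equation has no
solution). The result is bounded, rank-preserving, and directly readable as
"percent of the study distribution below this score".

```{r factor-demo}
panel <- generate_proxy_panel(latent_panel_spec(seed = 11))
fit <- mefa_fit(panel)
fit$bs$labels
round(fit$bs$summary$variance_pct, 1)
```

# Inference battery

Because indicator distributions are bounded and non-Gaussian by construction,
all procedures are rank-, permutation-, or resampling-based:

* `ats_longitudinal()` — rank-based ANOVA-type statistics for the
  group × epoch design with Box-type approximation degrees of freedom: the
  whole-plot group effect is referred to an F distribution with two estimated
  degrees of freedom, the epoch and interaction effects to `F(f, Inf)`.
* `ba_density_test()` — a permutation test on the integrated squared
  difference between the two groups' kernel density estimates over a common
  grid.
* `jt_test()` — ordered-alternative trend test; exhaustively enumerated when
  the assignment count is small, Monte-Carlo with an add-one correction
  otherwise.
* `ks_bootstrap_test()` — Kolmogorov–Smirnov distance calibrated by pooled
  bootstrap resampling.
* `stwrs_test()` — studentized two-sample rank statistic with permutation
  calibration (exact up to 5000 assignments).
* `wsr_test()` — Wilcoxon signed-rank for paired epochs, exact sign
  enumeration up to 14 informative pairs.
* `fdr_adjust()` — Benjamini–Hochberg step-up adjustment, applied *per
  procedure family* so that different tests are not pooled into one ranking.
* `sexage_screen()` — L1 (median) regression with Freedman–Lane residual
  permutation, screening indicators for sex and age effects before group
  comparisons are interpreted.

`epoch_pair_trends()` applies the ATS and signed-rank procedures to every
consecutive epoch pair, adjusts within each procedure family, and reports the
median direction of change. `sensitivity_scores()` condenses the battery into
ordinal levels (`none` / `weak` / `medium` / `strong`) per contrast: `strong`
requires unanimous agreement, `medium` a majority (at least half, rounded
up), `weak` any support at all.

# Resampling

`make_plan()` draws a balanced bootstrap within each stratum (group): across
the `B` replicates, every subject appears exactly `B` times, which removes
the between-replicate Monte-Carlo variation attributable to unequal subject
use. `bootstrap_mefa()` refits the factor model on every replicate at the
factor counts of the original fit, aligns each replicate to the original
solution by Tucker congruence (replicates with congruence below 0.7 are
discarded as unaligned, Heywood replicates as inadmissible), and forms BCa
intervals using leave-one-subject-out jackknife acceleration. Degenerate
replicate distributions collapse to a point interval; one-sided distributions
fall back to percentile intervals with a warning.

# The synthetic study generator

`study_config()` describes a 30-athlete study (two specialties, 15 each)
across nine epochs: supine rest, standing, four incremental exercise stages,
peak effort, and two recovery stages. Defaults encode the physiology the
package targets, not any test outcome:

* epoch profiles of mean RR, LF/HF band power and beat counts follow the
  classical U-shape — high variability at rest, near-total withdrawal at peak
  exercise, partial recovery afterwards;
* a very-low-frequency wander component (AR(2) oscillator near 0.015 Hz)
  keeps total power above the sum of the two analysed bands, as in real
  recordings;
* per-subject lognormal amplitude, sympathovagal-balance tilt, and RR-level
  multipliers create stable individual differences (the between-subject
  factors);
* per-epoch state noise (band-power and RR multipliers) prevents a subject's
  epochs from being deterministic copies of the group profile.

All randomness flows through a single integer seed via a splittable
`child_seed()` scheme, so any subject × epoch tachogram is reproducible in
isolation. `latent_panel_spec()` bypasses the tachogram layer entirely and
simulates a proxy panel from *known* two-level loading matrices — the
ground-truth harness used to validate recovery of the factor structure.

# Limitations

* The tachogram generator produces stationary-by-epoch series; real
  recordings show within-epoch drift and ectopy that the proxies here only
  meet through the artifact guard of the phase-rectified averaging.
* The factor model assumes the same within-subject structure for all
  subjects; subject-specific loadings are out of scope.
* PKDE indicators are relative to the analysed cohort: 50 means "median of
  this study", not a population norm.
* The ANOVA-type approximations are accurate for small samples but the
  whole-plot test is mildly conservative at `n = 15` per group.

# Reproducing a full analysis

```{r pipeline, eval = FALSE}
res <- run_study_pipeline(out_dir = "results/analysis", seed = 42,
                          n_boot = 200, n_permutations = 1000)
```

This writes the proxy panel, loading tables, indicator tables, tidy inference
results, the sensitivity report, and the profile/heatmap figures to
`out_dir`, all reproducible from the single seed.
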