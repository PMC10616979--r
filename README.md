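# mefahrv

Multilevel factor analysis of heart-rate-variability indices over exercise
protocols.

## The problem

A dynamic exercise test records beat-to-beat RR intervals over a sequence of
epochs — rest, standing, incremental work stages, peak effort, recovery. Each
tachogram can be summarized by many partially redundant heart-rate-variability
measures, but practitioners need a handful of interpretable numbers per
athlete and per epoch, plus honest uncertainty statements at small sample
sizes.

`mefahrv` reduces every tachogram to twelve proxies
(time-domain statistics, autoregressive spectral band powers,
phase-rectified acceleration/deceleration capacities, symbolic dynamics, and
a conditional-entropy regularity index), then splits the subject × epoch
panel into its between-subject and within-subject parts,

> x_ij = x̄_i (between) + (x_ij − x̄_i) (within),

factor-analyses each part separately (iterated principal axes, varimax
rotation, eigenvalue-plus-interpretability factor count), and re-expresses
factor scores as indicators on [0, 100] via the cumulative distribution of a
kernel density estimate. Group, epoch, and pairwise contrasts are tested with
a non-parametric battery (rank-based ANOVA-type statistics, permutation and
bootstrap two-sample tests, exact small-sample enumerations, BH false
discovery control) and a stratified balanced bootstrap with BCa intervals.

A synthetic-study generator with known two-level latent structure makes the
whole chain verifiable: simulated cohorts have ground-truth loadings that the
fitted model must recover.

## Worked example

```r
library(mefahrv)

# Simulate a 30-athlete, 9-epoch study and compute the proxy panel
panel <- compute_proxy_panel(generate_study(study_config(seed = 42)),
                             missing_policy = "impute_median")

# Two-level factor model with automatic factor counts
fit <- mefa_fit(panel)
fit$bs$q                       # 2
fit$ws$q                       # 3
fit$ws$labels
#> [1] "Amplitude"              "Oscillatory"            "Signal Self-Similarity"
round(fit$ws$summary$variance_pct, 2)
#>    F1    F2    F3
#> 56.80 13.83 10.73

head(fit$bs_indicators, 3)
#>   subject_id   group AMP-BS-Ind F2-BS-Ind
#> 1       1001 cyclist  34.205911 29.334354
#> 2       1002 cyclist   6.359122 28.791763
#> 3       1003 cyclist  90.640862  5.094572

# Does the amplitude indicator differ between specialties?
jt_test(split(fit$bs_indicators[["AMP-BS-Ind"]], fit$bs_indicators$group),
        n_permutations = 2000, seed = 7)
#> Jonckheere-Terpstra permutation test: statistic = 77, p = 0.1364

# Full pipeline: indicators, inference battery, bootstrap, figures
res <- run_study_pipeline(out_dir = "results/analysis", seed = 42,
                          n_boot = 200, n_permutations = 1000)
```

## Analysis workflow

The `analysis/` directory holds the numbered drivers of the accompanying
study; each reads the previous step's output from `results/`:

1. `01_simulate_study.R` — simulate the cohort and store raw tachograms.
2. `02_compute_proxies.R` — proxy panel and spectral diagnostics.
3. `03_full_analysis.R` — factor model, indicators, inference, bootstrap,
   figures.
4. `04_reference_comparison.R` — congruence of the fitted loadings with the
   bundled reference solutions (`inst/extdata/`).

Run them from the repository root with `Rscript analysis/01_simulate_study.R`
and so on.

## Documentation

The methods vignette (`vignettes/autonomic-indicators.Rmd`) documents each
proxy, the two-level factor model and its numerical safeguards, the inference
battery, the resampling scheme, the synthetic generator's design choices, and
the package's limitations.
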