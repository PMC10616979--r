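# Reference loading matrices

Varimax-rotated loading matrices from a published exercise-physiology study
of two groups of athletes (endurance vs. technical specialty) measured over
the nine epochs of a graded cycling protocol. They serve as the reference
solution for congruence checks and as a worked example of the factor-summary
arithmetic (explained variance, communality shares).

- `reference_bs_loadings.csv` — between-subject solution, 12 proxies x 2
  factors (amplitude, frequency).
- `reference_ws_loadings.csv` — within-subject solution, 12 proxies x 3
  factors (amplitude, signal self-similarity, oscillatory).

Load with `load_reference_loadings()`.
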