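#!/usr/bin/env Rscript

# Step 1: simulate the two-group, nine-epoch exercise study and store the raw
# RR tachograms. Downstream steps read only the CSV written here.

library(mefahrv)

seed <- 42L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

config <- study_config(seed = seed)
series <- generate_study(config)
write_tachogram_csv(series, file.path(out_dir, "tachograms.csv"))

cat(sprintf("wrote %d tachogram epochs for %d subjects to %s\n",
            length(series), 2L * config$n_per_group,
            file.path(out_dir, "tachograms.csv")))
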