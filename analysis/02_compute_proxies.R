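#!/usr/bin/env Rscript

# Step 2: reduce every RR tachogram to the 12 autonomic proxies and store the
# subject x epoch proxy panel plus the spectral-model diagnostics.

library(mefahrv)

out_dir <- "results"
series <- read_tachogram_csv(file.path(out_dir, "tachograms.csv"))

panel <- compute_proxy_panel(series, missing_policy = "impute_median")

diag_cols <- setdiff(names(panel),
                     c("subject_id", "group", "epoch_index",
                       mefahrv:::PROXY_NAMES))
write.csv(panel[, c("subject_id", "group", "epoch_index", diag_cols)],
          file.path(out_dir, "spectral_diagnostics.csv"), row.names = FALSE)
panel <- panel[, c("subject_id", "group", "epoch_index",
                   mefahrv:::PROXY_NAMES)]
write_panel_csv(panel, file.path(out_dir, "proxy_panel.csv"))

cat(sprintf("wrote %d-row proxy panel to %s\n", nrow(panel),
            file.path(out_dir, "proxy_panel.csv")))
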