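# Shared fixtures, computed lazily and cached for the whole test run.

.panel_cache <- new.env(parent = emptyenv())

# Proxy panel from a full simulated tachogram study (30 subjects x 9 epochs).
cached_study_panel <- function(seed = 3) {
  key <- paste0("study", seed)
  if (is.null(.panel_cache[[key]])) {
    .panel_cache[[key]] <- compute_proxy_panel(
      generate_study(study_config(seed = seed)),
      missing_policy = "impute_median")
  }
  .panel_cache[[key]]
}

# Latent-structure panel with strong, known two-level loadings.
cached_latent_panel <- function(seed = 11) {
  key <- paste0("latent", seed)
  if (is.null(.panel_cache[[key]])) {
    .panel_cache[[key]] <- generate_proxy_panel(latent_panel_spec(seed = seed))
  }
  .panel_cache[[key]]
}

# Rescale loading rows so every communality lies in [floor, cap]: rows below
# the floor are inflated, preserving the within-row pattern.
strengthen_loadings <- function(L, floor = 0.65, cap = 0.95) {
  h <- rowSums(L^2)
  scale <- sqrt(pmin(pmax(h, floor), cap) / h)
  L * scale
}

# A small longitudinal null data set for rank-test checks.
null_long_data <- function(n_per_group = 15, n_epochs = 9) {
  n <- 2 * n_per_group
  data.frame(subject_id = rep(sprintf("s%02d", seq_len(n)), each = n_epochs),
             group = rep(rep(c("a", "b"), each = n_per_group), each = n_epochs),
             epoch_index = rep(seq_len(n_epochs), n),
             value = stats::rnorm(n * n_epochs))
}
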