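# End-to-end driver: simulate (or accept) a study, compute proxies, fit the
# two-level factor model, run the inference battery and bootstrap, and write
# every numeric artifact (CSV/JSON) and figure under an output directory.

#' Run the complete analysis pipeline on a (simulated) study
#'
#' Stages: (1) simulate RR tachograms from a [study_config()] unless a proxy
#' panel is supplied; (2) compute the 12-proxy panel; (3) fit the two-level
#' factor model and derive the [0, 100] indicators; (4) run the
#' non-parametric battery (longitudinal rank tests per indicator, per-epoch
#' two-sample battery with FDR, consecutive-epoch trends, sensitivity
#' levels); (5) stratified balanced bootstrap of the factor solution and of
#' the per-epoch indicator medians; (6) write summary tables, profile plots
#' and autonomic heatmaps.
#'
#' @param out_dir output directory (created if needed); `NULL` skips all file
#'   output.
#' @param seed integer master seed.
#' @param config a [study_config()]; ignored when `panel` is given.
#' @param panel optional precomputed proxy panel.
#' @param q_b,q_w factor counts (`NULL` = data-driven choice).
#' @param n_boot bootstrap samples for the factor solution and medians.
#' @param n_permutations resamples for the permutation tests.
#' @param alpha significance level.
#' @param write_figures write png figures and html heatmaps (requires a
#'   working graphics device; tables are always written).
#' @return invisible list with `panel`, `fit`, `inference` (per-indicator
#'   results), `sensitivity`, `bootstrap`, `hr_table`, `summaries`.
#' @export
run_study_pipeline <- function(out_dir = NULL, seed = 1L, config = NULL,
                               panel = NULL, q_b = NULL, q_w = NULL,
                               n_boot = 200L, n_permutations = 1000L,
                               alpha = 0.05, write_figures = !is.null(out_dir)) {
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  emit <- function(df, name) {
    if (!is.null(out_dir)) utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  }

  # 1-2: study simulation and proxy panel
  if (is.null(panel)) {
    config <- config %||% study_config(seed = seed)
    series <- generate_study(config)
    panel <- compute_proxy_panel(series, missing_policy = "impute_median")
    if (!is.null(out_dir)) {
      emit(attr(panel, "diagnostics"), "spectral_diagnostics.csv")
    }
  }
  emit(panel, "proxy_panel.csv")

  # 3: two-level factor model and indicators
  fit <- mefa_fit(panel, q_b = q_b, q_w = q_w)
  loading_table <- function(sol) {
    s <- sol$summary
    df <- as.data.frame(sol$loadings)
    names(df) <- sprintf("%s (%s)", colnames(sol$loadings), sol$labels)
    df <- cbind(proxy = rownames(sol$loadings), df,
                communality = sol$communalities)
    foot <- data.frame(proxy = c("% of total variance",
                                 "cumulative % of total variance",
                                 "% of total communality"),
                       rbind(s$variance_pct, s$cumulative_pct,
                             s$communality_share_pct),
                       communality = NA)
    names(foot) <- names(df)
    rbind(df, foot)
  }
  emit(loading_table(fit$bs), "bs_loadings.csv")
  emit(loading_table(fit$ws), "ws_loadings.csv")
  emit(fit$bs_indicators, "bs_indicators.csv")
  emit(fit$ws_indicators, "ws_indicators.csv")

  bs_cols <- setdiff(names(fit$bs_indicators), c("subject_id", "group"))
  ws_cols <- setdiff(names(fit$ws_indicators), c("subject_id", "group", "epoch_index"))

  # 5 (before inference so trend/CI tables can use the plan): bootstrap
  dec <- fit$decomposition
  plan <- make_plan(dec$groups, B = n_boot, seed = child_seed(seed, 900001))
  boot <- bootstrap_mefa(panel, plan, fit)
  med_cis <- lapply(ws_cols, function(v)
    bootstrap_epoch_medians(fit$ws_indicators, plan, v))
  names(med_cis) <- ws_cols

  # 4: inference battery
  glab <- unique(unname(dec$groups))
  inference <- list()
  tidy_rows <- list()
  sens <- list()
  for (v in ws_cols) {
    ws <- fit$ws_indicators
    ats <- ats_longitudinal(ws, response = v)
    trends <- epoch_pair_trends(ws, v, n_permutations = n_permutations,
                                seed = child_seed(seed, match(v, ws_cols)))
    # per-epoch two-sample battery, FDR-adjusted across epochs per method
    epochs <- sort(unique(ws$epoch_index))
    per_epoch <- lapply(epochs, function(t) {
      x <- ws[[v]][ws$epoch_index == t & ws$group == glab[1]]
      y <- ws[[v]][ws$epoch_index == t & ws$group == glab[2]]
      sd2 <- child_seed(seed, 1000 + 10 * t + match(v, ws_cols))
      list(epoch = t,
           BA = ba_density_test(x, y, n_permutations, sd2),
           JT = jt_test(list(x, y), n_permutations = n_permutations, seed = sd2),
           KS = ks_bootstrap_test(x, y, n_boot = n_permutations, seed = sd2),
           StWRS = stwrs_test(x, y, n_permutations, sd2))
    })
    battery <- do.call(rbind, lapply(per_epoch, function(e)
      data.frame(indicator = v, epoch = e$epoch,
                 method = c("BA", "JT", "KS", "StWRS"),
                 statistic = c(e$BA$statistic, e$JT$statistic,
                               e$KS$statistic, e$StWRS$statistic),
                 p_value = c(e$BA$p_value, e$JT$p_value,
                             e$KS$p_value, e$StWRS$p_value))))
    battery$p_adjusted <- NA_real_
    for (m in unique(battery$method)) {
      selm <- battery$method == m
      battery$p_adjusted[selm] <- fdr_adjust(battery$p_value[selm])
    }
    battery$significant <- battery$p_adjusted <= alpha

    ci_tab <- med_cis[[v]]
    # group-difference CI per epoch from the plan: median difference
    ci_sig_epoch <- vapply(epochs, function(t) {
      val <- ws[ws$epoch_index == t, c("subject_id", "group", v)]
      diffs <- apply(plan$index_matrix, 1, function(s) {
        d <- val[match(s, val$subject_id), ]
        stats::median(d[[v]][d$group == glab[1]]) -
          stats::median(d[[v]][d$group == glab[2]])
      })
      est <- stats::median(val[[v]][val$group == glab[1]]) -
        stats::median(val[[v]][val$group == glab[2]])
      ci <- bca_interval(est, diffs, level = 1 - alpha)
      ci["low"] > 0 || ci["high"] < 0
    }, logical(1))

    # sensitivity aspects
    rs_trend <- trends[trends$pair == sprintf("Ep%d.%d", epochs[1], epochs[2]), ]
    rs_ci <- {
      c1 <- ci_tab[ci_tab$epoch == epochs[1], ]
      c2 <- ci_tab[ci_tab$epoch == epochs[2], ]
      c1$high < c2$low || c2$high < c1$low   # non-overlapping epoch CIs
    }
    rest_stand <- c(ci = rs_ci,
                    ats = rs_trend$significant[rs_trend$method == "ATS"],
                    wsr = rs_trend$significant[rs_trend$method == "WSR"])
    ex_pairs <- trends[trends$from >= epochs[2], ]
    ex_ci <- vapply(unique(ex_pairs$pair), function(pp) {
      fr <- ex_pairs$from[ex_pairs$pair == pp][1]
      to <- ex_pairs$to[ex_pairs$pair == pp][1]
      c1 <- ci_tab[ci_tab$epoch == fr, ]; c2 <- ci_tab[ci_tab$epoch == to, ]
      c1$high < c2$low || c2$high < c1$low
    }, logical(1))
    exercise_pairs <- data.frame(
      pair = unique(ex_pairs$pair),
      ats = vapply(unique(ex_pairs$pair), function(pp)
        ex_pairs$significant[ex_pairs$pair == pp & ex_pairs$method == "ATS"], logical(1)),
      wsr = vapply(unique(ex_pairs$pair), function(pp)
        ex_pairs$significant[ex_pairs$pair == pp & ex_pairs$method == "WSR"], logical(1)),
      ci = unname(ex_ci))
    group_epochs <- data.frame(
      epoch = epochs,
      ci = ci_sig_epoch,
      ba = battery$significant[battery$method == "BA"],
      jt = battery$significant[battery$method == "JT"],
      ks = battery$significant[battery$method == "KS"],
      stwrs = battery$significant[battery$method == "StWRS"])
    sens[[v]] <- sensitivity_scores(
      rest_stand, exercise_pairs, group_epochs,
      c(ats_group = ats$group$p_value <= alpha,
        ats_interaction = ats$interaction$p_value <= alpha))

    inference[[v]] <- list(ats = ats, trends = trends, battery = battery,
                           median_ci = ci_tab)
    tidy_rows[[v]] <- rbind(
      data.frame(indicator = v, aspect = "longitudinal", epoch_pair = NA,
                 method = c("ATS group", "ATS epoch", "ATS interaction"),
                 statistic = c(ats$group$statistic, ats$epoch$statistic,
                               ats$interaction$statistic),
                 p = c(ats$group$p_value, ats$epoch$p_value,
                       ats$interaction$p_value),
                 p_adj = NA, significant = c(ats$group$p_value,
                                             ats$epoch$p_value,
                                             ats$interaction$p_value) <= alpha),
      data.frame(indicator = v, aspect = "consecutive epochs",
                 epoch_pair = trends$pair, method = trends$method,
                 statistic = trends$statistic, p = trends$p_value,
                 p_adj = trends$p_adjusted, significant = trends$significant),
      data.frame(indicator = v, aspect = "group at epoch",
                 epoch_pair = as.character(battery$epoch),
                 method = battery$method, statistic = battery$statistic,
                 p = battery$p_value, p_adj = battery$p_adjusted,
                 significant = battery$significant))
  }
  # BS indicators: two-sample battery on subject scores
  bs_battery <- do.call(rbind, lapply(bs_cols, function(v) {
    x <- fit$bs_indicators[[v]][fit$bs_indicators$group == glab[1]]
    y <- fit$bs_indicators[[v]][fit$bs_indicators$group == glab[2]]
    sd2 <- child_seed(seed, 5000 + match(v, bs_cols))
    data.frame(indicator = v, aspect = "group overall", epoch_pair = NA,
               method = c("BA", "JT", "KS", "StWRS"),
               statistic = c(ba_density_test(x, y, n_permutations, sd2)$statistic,
                             jt_test(list(x, y), n_permutations = n_permutations,
                                     seed = sd2)$statistic,
                             ks_bootstrap_test(x, y, n_permutations, sd2)$statistic,
                             stwrs_test(x, y, n_permutations, sd2)$statistic),
               p = c(ba_density_test(x, y, n_permutations, sd2)$p_value,
                     jt_test(list(x, y), n_permutations = n_permutations,
                             seed = sd2)$p_value,
                     ks_bootstrap_test(x, y, n_permutations, sd2)$p_value,
                     stwrs_test(x, y, n_permutations, sd2)$p_value),
               p_adj = NA, significant = NA)
  }))
  bs_battery$significant <- bs_battery$p <= alpha
  tidy <- rbind(do.call(rbind, tidy_rows), bs_battery)
  emit(tidy, "inference_results.csv")

  sens_json <- lapply(sens, function(s)
    list(levels = s$levels,
         exercise_support = s$exercise_support,
         group_support = s$group_support))
  if (!is.null(out_dir)) {
    jsonlite::write_json(sens_json, file.path(out_dir, "sensitivity_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(
      list(seed = seed, kmo_bs = as.numeric(dec$kmo_b),
           kmo_ws = as.numeric(dec$kmo_w), q_b = fit$bs$q, q_w = fit$ws$q,
           bs_labels = fit$bs$labels, ws_labels = fit$ws$labels,
           bootstrap = list(B = boot$B, n_retained = boot$n_retained,
                            n_heywood = boot$n_heywood,
                            n_unaligned = boot$n_unaligned)),
      file.path(out_dir, "fit_report.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  # 6: summaries and figures
  hr <- hr_percent_of_max(panel)
  emit(hr$by_group, "hr_percent_by_group.csv")
  summaries <- list(
    bs = lapply(bs_cols, function(v) group_summaries(fit$bs_indicators, v)),
    ws_ranges = lapply(ws_cols, function(v)
      group_summaries(fit$ws_indicators, v, per_subject_range = TRUE)))
  names(summaries$bs) <- bs_cols; names(summaries$ws_ranges) <- ws_cols
  for (v in bs_cols) emit(summaries$bs[[v]], sprintf("summary_%s.csv", v))
  for (v in ws_cols) emit(summaries$ws_ranges[[v]], sprintf("summary_ranges_%s.csv", v))

  if (write_figures && !is.null(out_dir)) {
    for (v in ws_cols) {
      p <- median_profile_plot(fit$ws_indicators, v, ci = med_cis[[v]],
                               trends = inference[[v]]$trends)
      ggplot2::ggsave(file.path(out_dir, sprintf("profile_%s.png", v)), p,
                      width = 7, height = 4, dpi = 120)
      pg <- median_profile_plot(fit$ws_indicators, v, by_group = TRUE,
                                trends = inference[[v]]$trends)
      ggplot2::ggsave(file.path(out_dir, sprintf("profile_%s_by_group.png", v)),
                      pg, width = 7, height = 4, dpi = 120)
    }
    pairs <- heatmap_pairings(bs_cols, ws_cols)
    for (i in seq_len(nrow(pairs))) {
      hm <- autonomic_heatmap(fit$bs_indicators, fit$ws_indicators,
                              pairs$bs[i], pairs$ws[i],
                              html_path = file.path(out_dir,
                                sprintf("heatmap_%s_%s.html", pairs$bs[i], pairs$ws[i])))
      ggplot2::ggsave(file.path(out_dir,
                                sprintf("heatmap_%s_%s.png", pairs$bs[i], pairs$ws[i])),
                      hm, width = 8, height = 6, dpi = 120)
    }
  }

  invisible(list(panel = panel, fit = fit, inference = inference,
                 sensitivity = sens, bootstrap = boot, median_cis = med_cis,
                 hr_table = hr, summaries = summaries, plan = plan))
}

# Pair each BS indicator with related-meaning WS indicators: amplitude with
# amplitude; frequency with signal self-similarity and oscillatory; anything
# unmatched falls back to the first WS indicator.
heatmap_pairings <- function(bs_cols, ws_cols) {
  rows <- list()
  for (b in bs_cols) {
    partners <- if (grepl("^AMP", b)) ws_cols[grepl("^AMP", ws_cols)]
                else if (grepl("^FRE", b)) ws_cols[grepl("^SSS|^OSC", ws_cols)]
                else character(0)
    if (length(partners) == 0) partners <- ws_cols[1]
    for (w in partners) rows[[length(rows) + 1]] <- data.frame(bs = b, ws = w)
  }
  do.call(rbind, rows)
}
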