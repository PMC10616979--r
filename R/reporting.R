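# Summary statistics, HR %-of-maximum utilities, median profile plots and
# autonomic heatmap plots (static figure plus a standalone HTML export with
# unencoded scores).

#' Per-subject percentages of maximal heart rate over the epochs
#'
#' `HR.t% = 100 * HR.t / HRmax`, with `HRmax` the subject's maximum over the
#' epochs. Group summaries (mean +/- sd and median +/- MAD per epoch) mirror
#' the usual exercise-intensity tables.
#'
#' @param panel proxy panel data.frame with an `HR` column.
#' @return list with `individual` (subject x epoch data.frame of percentages,
#'   plus `hr_max` and `epoch_of_max`) and `by_group` (group x epoch summary
#'   table).
#' @export
hr_percent_of_max <- function(panel) {
  assert_that(all(c("subject_id", "group", "epoch_index", "HR") %in% names(panel)),
              "panel needs subject_id, group, epoch_index, HR")
  assert_that(!anyNA(panel$HR), "missing HR values")
  ids <- unique(as.character(panel$subject_id))
  rows <- lapply(ids, function(id) {
    sel <- panel$subject_id == id
    hr <- panel$HR[sel][order(panel$epoch_index[sel])]
    ep <- sort(panel$epoch_index[sel])
    hrmax <- max(hr)
    data.frame(subject_id = id, group = panel$group[sel][1],
               epoch = ep, hr_pct = 100 * hr / hrmax,
               hr_max = hrmax, epoch_of_max = ep[which.max(hr)])
  })
  ind <- do.call(rbind, rows)
  by_group <- do.call(rbind, lapply(split(ind, ind[, c("group", "epoch")]),
    function(d) data.frame(group = d$group[1], epoch = d$epoch[1],
                           mean = mean(d$hr_pct), sd = stats::sd(d$hr_pct),
                           median = stats::median(d$hr_pct),
                           mad = stats::mad(d$hr_pct, constant = 1))))
  rownames(by_group) <- NULL
  list(individual = ind, by_group = by_group[order(by_group$group, by_group$epoch), ])
}

#' Group summary statistics of indicator scores
#'
#' Median, unscaled MAD (median absolute deviation from the median, no
#' 1.4826 consistency factor), min, max and range per group; for
#' within-subject indicators, the per-subject range over the epochs first,
#' then its min / median / max within each group.
#'
#' @param scores data.frame with `subject_id`, `group`, the indicator column
#'   `response`, and (for the within-subject variant) `epoch_index`.
#' @param response indicator column name.
#' @param per_subject_range summarize per-subject epoch ranges instead of raw
#'   scores (within-subject indicators).
#' @return data.frame, one row per group.
#' @export
group_summaries <- function(scores, response, per_subject_range = FALSE) {
  assert_that(response %in% names(scores), "missing indicator column %s", response)
  groups <- unique(as.character(scores$group))
  assert_that(length(groups) >= 1 && all(table(scores$group) >= 1), "empty group")
  if (per_subject_range) {
    rng <- do.call(rbind, lapply(split(scores, scores$subject_id), function(d)
      data.frame(group = d$group[1],
                 range = max(d[[response]]) - min(d[[response]]))))
    out <- do.call(rbind, lapply(split(rng, rng$group), function(d)
      data.frame(group = d$group[1], min_range = min(d$range),
                 median_range = stats::median(d$range),
                 max_range = max(d$range))))
  } else {
    out <- do.call(rbind, lapply(split(scores, scores$group), function(d) {
      v <- d[[response]]
      data.frame(group = d$group[1], median = stats::median(v),
                 mad = stats::median(abs(v - stats::median(v))),
                 min = min(v), max = max(v), range = max(v) - min(v))
    }))
  }
  rownames(out) <- NULL
  out
}

#' Median profile plot of a within-subject indicator over the epochs
#'
#' Per-epoch medians with error bars: bootstrap confidence intervals when a
#' CI table is supplied, otherwise +/- unscaled MAD. Drawn for the whole set
#' or per group. Consecutive-epoch significance annotations are added from a
#' trend table when given; a missing table just omits them with a warning.
#'
#' @param ws_table data.frame with `subject_id`, `group`, `epoch_index` and
#'   the indicator column `response`.
#' @param response indicator column name.
#' @param ci optional data.frame `epoch`, `low`, `high` (whole-set plots).
#' @param by_group draw one profile per group.
#' @param trends optional output of [epoch_pair_trends()].
#' @return a ggplot object; the numeric twin is attached as attribute `data`.
#' @export
median_profile_plot <- function(ws_table, response, ci = NULL,
                                by_group = FALSE, trends = NULL) {
  grp_var <- if (by_group) "group" else NULL
  splitter <- if (by_group) ws_table$group else rep("all", nrow(ws_table))
  med <- do.call(rbind, lapply(split(ws_table, list(splitter, ws_table$epoch_index)),
    function(d) {
      v <- d[[response]]
      data.frame(group = if (by_group) d$group[1] else "all",
                 epoch = d$epoch_index[1], median = stats::median(v),
                 mad = stats::median(abs(v - stats::median(v))))
    }))
  rownames(med) <- NULL
  if (!is.null(ci) && !by_group) {
    med <- merge(med, ci[, c("epoch", "low", "high")], by = "epoch")
  } else {
    if (is.null(ci) && !by_group) {
      # MAD bars are the fallback error representation
    }
    med$low <- med$median - med$mad
    med$high <- med$median + med$mad
  }
  p <- ggplot2::ggplot(med, ggplot2::aes(x = epoch, y = median,
                                         colour = group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = low, ymax = high),
                           width = 0.2) +
    ggplot2::scale_x_continuous(breaks = sort(unique(med$epoch))) +
    ggplot2::labs(x = "Epoch", y = response, colour = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(trends)) {
    sig <- trends[trends$method == "ATS" & trends$significant, , drop = FALSE]
    if (nrow(sig) > 0) {
      ypos <- max(med$high) + 0.05 * diff(range(med$median))
      ann <- data.frame(epoch = (sig$from + sig$to) / 2, y = ypos,
                        label = "*", group = med$group[1])
      p <- p + ggplot2::geom_text(data = ann,
        ggplot2::aes(x = epoch, y = y, label = label),
        inherit.aes = FALSE)
    }
  } else {
    warning("no trend table supplied: profile drawn without significance annotations")
  }
  attr(p, "data") <- med
  p
}

# Subject ordering for the heatmap: ascending BS score within group, ties
# broken by subject id.
heatmap_order <- function(bs_scores, bs_col) {
  bs_scores[order(bs_scores$group, bs_scores[[bs_col]],
                  as.character(bs_scores$subject_id)), "subject_id"]
}

#' Autonomic heatmap plot of paired BS and WS indicators
#'
#' One row per subject: the first column holds the between-subject indicator
#' and the following columns the within-subject indicator per epoch. Rows are
#' ordered by ascending BS score within group and the two groups form
#' separate blocks; the colour tonality is monotone in the [0, 100] score. A
#' right-margin summary (median +/- MAD, min, max, range for the BS scores;
#' min / median / max per-subject WS ranges) matches [group_summaries()]
#' exactly. `html_path` additionally writes a standalone HTML version with
#' the unencoded scores in the cells (and on hover).
#'
#' @param bs_scores data.frame `subject_id`, `group`, plus the BS indicator.
#' @param ws_scores data.frame `subject_id`, `group`, `epoch_index`, plus the
#'   WS indicator.
#' @param bs_col,ws_col indicator column names.
#' @param html_path optional path for the HTML export.
#' @return a ggplot object with attributes `data` (the long cell table) and
#'   `margin` (the group summary tables).
#' @export
autonomic_heatmap <- function(bs_scores, ws_scores, bs_col, ws_col,
                              html_path = NULL) {
  ids_b <- unique(as.character(bs_scores$subject_id))
  ids_w <- unique(as.character(ws_scores$subject_id))
  if (!setequal(ids_b, ids_w)) {
    stop_mefahrv("subject(s) present in only one score table: %s",
                 paste(c(setdiff(ids_b, ids_w), setdiff(ids_w, ids_b)), collapse = ", "))
  }
  ord <- as.character(heatmap_order(bs_scores, bs_col))
  cells_bs <- data.frame(subject_id = as.character(bs_scores$subject_id),
                         group = bs_scores$group,
                         column = "BS", score = bs_scores[[bs_col]])
  cells_ws <- data.frame(subject_id = as.character(ws_scores$subject_id),
                         group = ws_scores$group,
                         column = sprintf("Ep%d", ws_scores$epoch_index),
                         score = ws_scores[[ws_col]])
  cells <- rbind(cells_bs, cells_ws)
  col_levels <- c("BS", sprintf("Ep%d", sort(unique(ws_scores$epoch_index))))
  cells$column <- factor(cells$column, levels = col_levels)
  cells$subject_id <- factor(cells$subject_id, levels = ord)

  margin <- list(bs = group_summaries(bs_scores, bs_col),
                 ws_ranges = group_summaries(ws_scores, ws_col,
                                             per_subject_range = TRUE))
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = column,
                                           y = subject_id,
                                           fill = score)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "#fff7e6", high = "#08306b",
                                 limits = c(0, 100)) +
    ggplot2::facet_grid(rows = ggplot2::vars(group), scales = "free_y",
                        space = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s (column 1) with %s per epoch", bs_col, ws_col),
                  fill = "score") +
    ggplot2::theme_minimal()
  attr(p, "data") <- cells
  attr(p, "margin") <- margin
  if (!is.null(html_path)) {
    heatmap_html(cells, col_levels, margin, bs_col, ws_col, html_path)
  }
  p
}

# Standalone HTML heatmap: colored table cells with the raw score printed and
# repeated in the title attribute (shown on hover).
heatmap_html <- function(cells, col_levels, margin, bs_col, ws_col, path) {
  shade <- function(s) {
    # linear ramp from light (#fff7e6) to dark (#08306b), monotone in score
    f <- pmin(pmax(s / 100, 0), 1)
    lo <- c(255, 247, 230); hi <- c(8, 48, 107)
    v <- round(lo + f * (hi - lo))
    sprintf("#%02x%02x%02x", v[1], v[2], v[3])
  }
  rows <- character(0)
  for (g in unique(cells$group)) {
    rows <- c(rows, sprintf("<tr><th colspan='%d' style='text-align:left'>%s</th></tr>",
                            length(col_levels) + 1, g))
    sub <- cells[cells$group == g, ]
    for (id in levels(droplevels(sub$subject_id))) {
      tds <- vapply(col_levels, function(cl) {
        s <- sub$score[sub$subject_id == id & sub$column == cl]
        if (length(s) == 0) return("<td></td>")
        txt <- ifelse(s > 55, "white", "black")
        sprintf("<td title='%s %s: %.2f' style='background:%s;color:%s;text-align:center'>%.1f</td>",
                id, cl, s, shade(s), txt, s)
      }, character(1))
      rows <- c(rows, sprintf("<tr><th>%s</th>%s</tr>", id, paste(tds, collapse = "")))
    }
  }
  head_cells <- paste(sprintf("<th>%s</th>", c("subject", col_levels)), collapse = "")
  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
            sprintf("<title>%s / %s autonomic heatmap</title>", bs_col, ws_col),
            "<style>table{border-collapse:collapse;font:12px sans-serif}td,th{padding:3px 6px}</style>",
            "</head><body>",
            sprintf("<h2>%s (column 1) with %s per epoch</h2>", bs_col, ws_col),
            "<table>", sprintf("<tr>%s</tr>", head_cells), rows, "</table>",
            "<h3>Group summaries</h3><pre>",
            utils::capture.output(print(margin$bs)),
            utils::capture.output(print(margin$ws_ranges)),
            "</pre></body></html>")
  writeLines(html, path)
  invisible(path)
}
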