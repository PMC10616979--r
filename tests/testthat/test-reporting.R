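make_hr_panel <- function() {
  hr <- c(60, 80, 100, 120, 150, 170, 180, 140, 110)
  data.frame(subject_id = rep(c("a", "b"), each = 9),
             group = rep(c("g1", "g2"), each = 9),
             epoch_index = rep(1:9, 2),
             HR = c(hr, rep(90, 9)))
}

test_that("heart-rate percentages are anchored at the per-subject maximum", {
  res <- hr_percent_of_max(make_hr_panel())
  a <- res$individual[res$individual$subject_id == "a", ]
  expect_equal(a$hr_pct[a$epoch == 7], 100)
  expect_equal(a$epoch_of_max[1], 7)
  expect_equal(a$hr_pct[a$epoch == 1], 100 * 60 / 180)
  # a constant trajectory is 100% everywhere
  b <- res$individual[res$individual$subject_id == "b", ]
  expect_true(all(b$hr_pct == 100))
  expect_true(all(res$individual$hr_pct > 0 & res$individual$hr_pct <= 100))
})

test_that("a 90-over-180 heart rate is 50 percent of maximum", {
  panel <- data.frame(subject_id = "s", group = "g", epoch_index = 1:2,
                      HR = c(90, 180))
  res <- hr_percent_of_max(panel)
  expect_equal(res$individual$hr_pct, c(50, 100))
})

test_that("group summaries use the unscaled median absolute deviation", {
  scores <- data.frame(subject_id = c("a", "b", "c"), group = "g",
                       x = c(1, 2, 3))
  s <- group_summaries(scores, "x")
  expect_equal(s$median, 2)
  expect_equal(s$mad, 1)
  expect_equal(s$range, 2)
  one <- group_summaries(data.frame(subject_id = "a", group = "g", x = 5), "x")
  expect_equal(one$mad, 0)
  expect_equal(one$range, 0)
})

test_that("per-subject epoch ranges of a constant trajectory vanish", {
  ws <- data.frame(subject_id = rep(c("a", "b"), each = 3), group = "g",
                   epoch_index = rep(1:3, 2),
                   x = c(5, 5, 5, 1, 4, 9))
  s <- group_summaries(ws, "x", per_subject_range = TRUE)
  expect_equal(s$min_range, 0)   # subject a
  expect_equal(s$max_range, 8)   # subject b
})

test_that("the profile plot mirrors its numeric twin exactly", {
  set.seed(3)
  ws <- data.frame(subject_id = rep(sprintf("s%02d", 1:10), each = 9),
                   group = rep(rep(c("g1", "g2"), each = 5), each = 9),
                   epoch_index = rep(1:9, 10),
                   x = rnorm(90, 50, 10))
  expect_warning(p <- median_profile_plot(ws, "x"), "annotation")
  twin <- attr(p, "data")
  med <- tapply(ws$x, ws$epoch_index, median)
  expect_equal(twin$median[order(twin$epoch)], as.numeric(med))
  # constant data give a flat profile with zero-width bars
  ws0 <- ws; ws0$x <- 42
  expect_warning(p0 <- median_profile_plot(ws0, "x"))
  twin0 <- attr(p0, "data")
  expect_true(all(twin0$median == 42 & twin0$low == 42 & twin0$high == 42))
})

test_that("heatmap rows are ordered by ascending BS score within group", {
  bs <- data.frame(subject_id = c("s1", "s2", "s3", "s4"),
                   group = c("g1", "g1", "g2", "g2"),
                   A = c(80, 20, 50, 50))
  ord <- as.character(mefahrv:::heatmap_order(bs, "A"))
  expect_equal(ord, c("s2", "s1", "s3", "s4"))  # ties broken by subject id
})

test_that("the heatmap encodes scores monotonically and carries its margins", {
  set.seed(8)
  bs <- data.frame(subject_id = sprintf("s%02d", 1:10),
                   group = rep(c("g1", "g2"), each = 5),
                   A = runif(10, 0, 100))
  ws <- data.frame(subject_id = rep(bs$subject_id, each = 9),
                   group = rep(bs$group, each = 9),
                   epoch_index = rep(1:9, 10),
                   W = runif(90, 0, 100))
  p <- autonomic_heatmap(bs, ws, "A", "W")
  cells <- attr(p, "data")
  expect_equal(nrow(cells), 10 + 90)
  expect_equal(levels(cells$column)[1], "BS")
  # margins agree with group_summaries exactly
  marg <- attr(p, "margin")
  expect_equal(marg$bs, group_summaries(bs, "A"))
  expect_equal(marg$ws_ranges, group_summaries(ws, "W", per_subject_range = TRUE))
  # the subject with the minimal BS score sits first in its group block
  first_g1 <- levels(cells$subject_id)[1]
  expect_equal(first_g1, bs$subject_id[which.min(ifelse(bs$group == "g1",
                                                        bs$A, Inf))])
  # mismatched subject sets are refused with the offender named
  expect_error(autonomic_heatmap(bs[-1, ], ws, "A", "W"), "s01")
})

test_that("the HTML heatmap embeds the unencoded scores", {
  bs <- data.frame(subject_id = c("sA", "sB"), group = "g1", A = c(12.34, 99))
  ws <- data.frame(subject_id = rep(c("sA", "sB"), each = 2), group = "g1",
                   epoch_index = rep(1:2, 2), W = c(10, 20, 30, 40))
  path <- withr::local_tempfile(fileext = ".html")
  autonomic_heatmap(bs, ws, "A", "W", html_path = path)
  html <- paste(readLines(path), collapse = "\n")
  expect_match(html, "12.3", fixed = TRUE)
  expect_match(html, "title=")       # hover scores
  expect_match(html, "background:#") # colored cells
})

test_that("the pipeline emits every numeric artifact from one seed", {
  out <- file.path(withr::local_tempdir(), "run")
  res <- suppressWarnings(
    run_study_pipeline(out_dir = out, seed = 5,
                       panel = cached_latent_panel(),
                       n_boot = 120, n_permutations = 200,
                       write_figures = FALSE))
  for (f in c("proxy_panel.csv", "bs_loadings.csv", "ws_loadings.csv",
              "bs_indicators.csv", "ws_indicators.csv",
              "inference_results.csv", "sensitivity_report.json",
              "fit_report.json")) {
    expect_true(file.exists(file.path(out, f)), info = f)
  }
  inf <- read.csv(file.path(out, "inference_results.csv"))
  expect_true(all(c("indicator", "aspect", "method", "p") %in% names(inf)))
  expect_true(all(inf$p >= 0 & inf$p <= 1))
  sens <- jsonlite::read_json(file.path(out, "sensitivity_report.json"))
  expect_true(all(vapply(sens, function(s)
    all(unlist(s$levels) %in% c("none", "weak", "medium", "strong")),
    logical(1))))
})
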