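test_that("rank-based longitudinal tests detect the effect they target", {
  set.seed(41)
  df <- null_long_data()
  shift <- df
  shift$value <- shift$value + 3 * (shift$group == "b")
  a <- ats_longitudinal(shift)
  expect_lt(a$group$p_value, 0.001)
  expect_gt(a$epoch$p_value, 0.05)

  trend <- null_long_data()
  trend$value <- trend$value + 0.8 * trend$epoch_index
  a2 <- ats_longitudinal(trend)
  expect_lt(a2$epoch$p_value, 0.001)
  expect_gt(a2$interaction$p_value, 0.05)
})

test_that("longitudinal tests validate panel completeness and group sizes", {
  df <- null_long_data(n_per_group = 5)
  expect_error(ats_longitudinal(df[-1, ]), "epoch")
  one <- df[df$group == "a", ]
  a <- ats_longitudinal(one)
  expect_null(a$group)
  expect_true(is.finite(a$epoch$p_value))
})

test_that("density-distance permutation test is null on identical multisets", {
  x <- c(1.2, 3.4, 0.8, 2.2, 5.0, 1.9)
  r <- ba_density_test(x, sample(x), n_permutations = 200, seed = 7)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1)
})

test_that("density-distance test detects a three-sigma location shift", {
  set.seed(13)
  x <- rnorm(15)
  y <- rnorm(15) + 3
  r <- ba_density_test(x, y, n_permutations = 500, seed = 3)
  expect_lte(r$p_value, 0.01)
})

test_that("the two-group ordered-alternative statistic is the Mann-Whitney count", {
  set.seed(17)
  x <- rnorm(8); y <- rnorm(9)
  r <- jt_test(list(x, y), n_permutations = 100, seed = 1)
  expect_equal(unname(r$statistic), sum(outer(x, y, "<")) + 0.5 * sum(outer(x, y, "==")))
})

test_that("exhaustive enumeration gives the exact ordered-alternative p-value", {
  r <- jt_test(list(c(1, 2), c(3, 4)), alternative = "increasing")
  expect_equal(r$p_value, 1 / 6)
  expect_true(r$exact)
})

test_that("the distribution-distance statistic hits its boundary cases", {
  x <- c(1, 2, 3, 4, 5)
  r <- ks_bootstrap_test(x, x, n_boot = 100, seed = 2)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)
  r2 <- ks_bootstrap_test(1:8, 101:108, n_boot = 100, seed = 2)
  expect_equal(unname(r2$statistic), 1)
  expect_lt(r2$p_value, 0.05)
})

test_that("studentized rank-sum enumeration is exact for tiny samples", {
  x <- c(1, 2, 3)
  y <- c(2, 3, 1)  # the same multiset under swapped labels
  r <- stwrs_test(x, y)
  expect_gte(r$p_value, 0.99)
  set.seed(5)
  r2 <- stwrs_test(rnorm(15), rnorm(15) + 4, n_permutations = 500, seed = 5)
  expect_lte(r2$p_value, 0.01)
})

test_that("signed-rank enumeration reproduces the one-sided 1/8 oracle", {
  before <- c(10, 10, 10)
  after <- c(11, 12, 13)
  r <- wsr_test(before, after, alternative = "greater")
  expect_equal(r$p_value, 1 / 8)
  expect_error(wsr_test(before, before), "nonzero")
})

test_that("step-up FDR adjustment matches the hand-computed oracle", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  set.seed(3)
  p <- runif(20)
  expect_true(all(fdr_adjust(p) >= p))
  expect_equal(fdr_adjust(p), p.adjust(p, "BH"))
})

test_that("median-regression screening finds a sex effect and only that", {
  set.seed(19)
  n <- 60
  sex <- rep(0:1, each = n / 2)
  age <- runif(n, 20, 40)
  y <- 10 * sex + rnorm(n)
  res <- sexage_screen(y, sex, age, n_permutations = 200, seed = 11)
  expect_lt(res$p_value[res$term == "sex"], 0.05)
  expect_gt(res$p_value[res$term == "age"], 0.05)
  y0 <- rnorm(n)
  res0 <- sexage_screen(y0, sex, age, n_permutations = 400, seed = 14)
  expect_gt(res0$p_value[res0$term == "sex"], 0.05)
})

test_that("a single-sex sample drops the sex terms with a warning", {
  set.seed(20)
  expect_warning(
    res <- sexage_screen(rnorm(20), rep(0, 20), runif(20, 20, 40),
                         n_permutations = 100, seed = 2),
    "sex")
  expect_equal(res$term, "age")
  expect_true(is.finite(res$p_value))
})

test_that("consecutive-epoch trends recover a strong U-shaped profile", {
  set.seed(25)
  n <- 30
  prof <- c(80, 70, 55, 40, 25, 15, 5, 30, 50)
  ws <- data.frame(subject_id = rep(sprintf("s%02d", 1:n), each = 9),
                   group = "g", epoch_index = rep(1:9, n),
                   value = rep(prof, n) + rnorm(9 * n, 0, 3))
  tr <- epoch_pair_trends(ws, "value", n_permutations = 400, seed = 6)
  expect_equal(nrow(tr), 16)  # 8 pairs x 2 procedures
  wsr_rows <- tr[tr$method == "WSR", ]
  expect_true(all(wsr_rows$significant))
  expect_equal(wsr_rows$direction[wsr_rows$pair == "Ep6.7"], "decrease")
  expect_equal(wsr_rows$direction[wsr_rows$pair == "Ep7.8"], "increase")
  expect_error(epoch_pair_trends(ws[ws$epoch_index != 4, ], "value"),
               "epoch")
})

test_that("a flat profile rarely flags consecutive-epoch changes", {
  set.seed(26)
  n <- 30
  ws <- data.frame(subject_id = rep(sprintf("s%02d", 1:n), each = 9),
                   group = "g", epoch_index = rep(1:9, n),
                   value = rnorm(9 * n))
  tr <- epoch_pair_trends(ws, "value", n_permutations = 400, seed = 8)
  expect_lte(sum(tr$significant[tr$method == "WSR"]), 1)
})

test_that("sensitivity levels follow the agreement-count thresholds", {
  expect_equal(sensitivity_level(0, 4), "none")
  expect_equal(sensitivity_level(4, 4), "strong")
  expect_equal(sensitivity_level(2, 4), "medium")
  expect_equal(sensitivity_level(1, 4), "weak")
  expect_equal(sensitivity_level(1, 3), "weak")
  expect_equal(sensitivity_level(2, 3), "medium")
})

test_that("the sensitivity report aggregates the battery as documented", {
  rest <- c(ci = TRUE, ats = TRUE, wsr = TRUE)
  pairs <- data.frame(pair = sprintf("Ep%d.%d", 2:6, 3:7),
                      ats = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                      wsr = c(TRUE, TRUE, TRUE, FALSE, FALSE),
                      ci = c(TRUE, FALSE, TRUE, TRUE, FALSE))
  eps <- data.frame(epoch = 1:9,
                    ba = c(rep(TRUE, 4), rep(FALSE, 5)),
                    jt = c(rep(TRUE, 4), rep(FALSE, 5)),
                    ks = c(rep(TRUE, 3), rep(FALSE, 6)),
                    stwrs = c(rep(TRUE, 4), rep(FALSE, 5)))
  rep1 <- sensitivity_scores(rest, pairs, eps,
                             c(ats_group = TRUE, ats_interaction = FALSE))
  expect_equal(rep1$levels$rest_stand, "strong")
  expect_equal(rep1$levels$exercise_fraction, "medium")  # 4 of 5 supported
  expect_equal(rep1$levels$sports_specialties, "strong") # overall + full epochs
  rep2 <- sensitivity_scores(c(ci = FALSE, ats = FALSE, wsr = FALSE),
                             pairs,
                             within(eps, {ba <- jt <- ks <- stwrs <- FALSE}),
                             c(ats_group = FALSE, ats_interaction = FALSE))
  expect_equal(rep2$levels$rest_stand, "none")
  expect_equal(rep2$levels$sports_specialties, "none")
})
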