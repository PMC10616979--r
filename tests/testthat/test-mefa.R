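test_that("panel decomposition separates between and within variation exactly", {
  # 3 subjects x 2 epochs x 2 proxies toy panel with hand-computed correlations
  panel <- data.frame(subject_id = rep(c("a", "b", "c"), each = 2),
                      group = "g1", epoch_index = rep(1:2, 3),
                      p1 = c(1, 3, 10, 14, 5, 9),
                      p2 = c(2, 6, 4, 8, 6, 10))
  dec <- decompose_panel(panel, proxies = c("p1", "p2"))
  # subject means: p1 = (2, 12, 7) with deviations (-5, 5, 0);
  # p2 = (4, 6, 8) with deviations (-2, 0, 2) -> r = 10 / sqrt(50 * 8) = 0.5
  expect_equal(unname(dec$R_B["p1", "p2"]), 0.5)
  # centred p1 = (-1, 1, -2, 2, -2, 2), p2 = (-2, 2, -2, 2, -2, 2)
  # -> r = 20 / sqrt(18 * 24) = 5 / (3 * sqrt(3))
  expect_equal(unname(dec$R_W["p1", "p2"]), 5 / (3 * sqrt(3)))
  # centering identity: per-subject means of the within matrix vanish
  xt <- dec$xtilde
  per_subj <- rowsum(xt, attr(xt, "subject_id")) / 2
  expect_lt(max(abs(per_subj)), 1e-10)
})

test_that("within-subject correlations match the pooled-covariance oracle", {
  panel <- cached_latent_panel()
  dec <- decompose_panel(panel)
  X <- as.matrix(panel[, mefahrv:::PROXY_NAMES])
  centred <- X - apply(X, 2, function(v) ave(v, panel$subject_id))
  expect_equal(unname(dec$R_W), unname(cor(centred)), tolerance = 1e-10)
})

test_that("subjects constant over epochs leave no within-subject variation", {
  panel <- data.frame(subject_id = rep(c("a", "b", "c"), each = 2),
                      group = "g1", epoch_index = rep(1:2, 3),
                      p1 = rep(c(1, 2, 3), each = 2),
                      p2 = rep(c(5, 1, 4), each = 2))
  expect_error(decompose_panel(panel, proxies = c("p1", "p2")),
               "within")
})

test_that("KMO matches the closed-form equicorrelated oracle", {
  R <- matrix(0.5, 3, 3); diag(R) <- 1
  # all partial correlations are 1/3, so KMO = (3 * .25)/(3 * .25 + 3 * 1/9)
  expect_equal(as.numeric(kmo(R)), 0.75 / (0.75 + 1 / 3), tolerance = 1e-10)
  expect_equal(as.numeric(kmo(R)), 0.6923, tolerance = 5e-4)
  expect_error(kmo(diag(3)), "no correlation structure")
  panel <- cached_latent_panel()
  dec <- decompose_panel(panel)
  expect_true(dec$kmo_b >= 0 && dec$kmo_b <= 1)
  expect_true(dec$kmo_w >= 0 && dec$kmo_w <= 1)
})

test_that("principal-axis extraction recovers an exact one-factor structure", {
  lam <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  R <- tcrossprod(lam); diag(R) <- 1
  pf <- principal_factor(R, 1)
  expect_equal(abs(as.numeric(pf$loadings)), lam, tolerance = 1e-5)
  expect_false(pf$heywood)
  expect_error(principal_factor(R, 0), "q must")
})

test_that("a gross communality violation raises the Heywood flag", {
  # r12 * r13 / r23 > 1 forces the implied communality far above 1
  R <- matrix(c(1, 0.9, 0.9,
                0.9, 1, 0.5,
                0.9, 0.5, 1), 3, 3)
  pf <- principal_factor(R, 1)
  expect_true(pf$heywood)
})

test_that("varimax keeps communalities and restores simple structure", {
  L <- matrix(c(0.9, 0.8, 0.7, 0.15, 0.1, 0.05,
                0.05, 0.15, 0.1, 0.8, 0.7, 0.6), 6, 2)
  theta <- pi / 6
  G <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
  rot <- varimax_rotate(L %*% G)
  # the optimum is invariant to the starting orientation ...
  expect_equal(rot, varimax_rotate(L), tolerance = 1e-6)
  # ... close to the near-simple generating pattern ...
  expect_lt(max(abs(rot - L)), 0.01)
  # ... and communalities are untouched by the orthogonal rotation
  expect_equal(rowSums(rot^2), rowSums(L^2), tolerance = 1e-10)
  # single-factor input is returned unrotated
  L1 <- matrix(c(0.9, -0.5, 0.3), 3, 1)
  expect_equal(unname(varimax_rotate(L1)), unname(L1) * sign(0.9))
})

test_that("factor-count selection follows eigenstructure and interpretability", {
  lam <- cbind(c(rep(0.8, 6), rep(0, 6)), c(rep(0, 6), rep(0.75, 6)))
  R <- tcrossprod(lam); diag(R) <- 1
  expect_equal(choose_n_factors(R), 2, ignore_attr = TRUE)
  set.seed(2)
  J <- diag(12) + matrix(rnorm(144, 0, 0.01), 12, 12)
  J <- cov2cor((J + t(J)) / 2 + diag(12))
  expect_error(choose_n_factors(J), "no factor qualifies")
  panel <- cached_latent_panel()
  dec <- decompose_panel(panel)
  expect_equal(choose_n_factors(dec$R_B), 2, ignore_attr = TRUE)
  expect_equal(choose_n_factors(dec$R_W), 3, ignore_attr = TRUE)
})

test_that("regression factor scores recover a near-noiseless generating factor", {
  set.seed(6)
  f <- rnorm(200)
  lam <- c(0.9, 0.8, 0.85, 0.7)
  X <- outer(f, lam) + matrix(rnorm(800, 0, 0.05), 200, 4)
  Z <- scale(X)
  R <- cor(X)
  pf <- principal_factor(R, 1)
  sc <- factor_scores(X, pf$loadings, R)
  expect_gt(abs(cor(sc[, 1], f)), 0.99)
  # an all-zero standardized row scores zero by linearity
  Z0 <- Z; Z0[1, ] <- 0
  sc0 <- factor_scores(Z0, pf$loadings, R,
                       center = rep(0, 4), scale = rep(1, 4))
  expect_equal(unname(sc0[1, ]), 0)
})

test_that("PKDE scores are percentile-like, bounded, and monotone", {
  set.seed(9)
  x <- rnorm(200)
  scores <- pkde_transform(x)
  expect_true(all(scores >= 0 & scores <= 100))
  at_median <- pkde_transform(x, eval = median(x))
  expect_lt(abs(at_median - 50), 2)
  low <- pkde_transform(x, eval = min(x) - 10 * bw.SJ(x))
  expect_lt(low, 1)
  xs <- sort(x)
  expect_true(all(diff(pkde_transform(x, eval = xs)) > 0))
  # rank preservation
  expect_equal(cor(scores, x, method = "spearman"), 1)
})

test_that("solution summaries follow the variance bookkeeping identities", {
  L <- matrix(0, 12, 1); L[1, 1] <- 1
  s <- summarize_solution(L)
  expect_equal(s$variance_pct, 100 / 12)
  expect_equal(s$communality_share_pct, 100)
  # total communality is invariant under rotation
  L2 <- cbind(c(rep(0.8, 6), rep(0.1, 6)), c(rep(0.1, 6), rep(0.7, 6)))
  rot <- varimax_rotate(L2)
  expect_equal(summarize_solution(rot)$total_communality,
               summarize_solution(L2)$total_communality, tolerance = 1e-10)
})

test_that("reference loading matrices get their interpretive labels", {
  labs_b <- label_factors(load_reference_loadings("between"))
  expect_equal(unname(labs_b), c("Amplitude", "Frequency"))
  labs_w <- label_factors(load_reference_loadings("within"))
  expect_equal(unname(labs_w),
               c("Amplitude", "Signal Self-Similarity", "Oscillatory"))
  # one "generic label" warning is raised per unlabelable factor
  expect_warning(expect_warning(
    labs0 <- label_factors(matrix(0, 12, 2,
      dimnames = list(mefahrv:::PROXY_NAMES, NULL))), "generic"), "generic")
  expect_match(labs0, "Factor", all = TRUE)
})

test_that("indicator codes combine the label and the level", {
  expect_equal(indicator_code(c("Amplitude", "Frequency"), "BS"),
               c("AMP-BS-Ind", "FRE-BS-Ind"))
  expect_equal(indicator_code("Signal Self-Similarity", "WS"), "SSS-WS-Ind")
  expect_equal(indicator_code("Oscillatory", "WS"), "OSC-WS-Ind")
})

test_that("congruence matching undoes permutations and sign flips exactly", {
  L <- default_ws_loadings()
  scrambled <- L[, c(3, 1, 2)] %*% diag(c(-1, 1, -1))
  m <- tucker_congruence(scrambled, L)
  expect_equal(m$perm, c(2, 3, 1))
  expect_equal(m$signs, c(1, -1, -1))
  expect_true(all(m$congruence > 0.9999))
  restored <- scrambled[, m$perm] %*% diag(m$signs)
  expect_equal(unname(restored), unname(L), tolerance = 1e-12)
})

test_that("the full two-level fit produces bounded indicators with labels", {
  panel <- cached_latent_panel()
  fit <- mefa_fit(panel)
  expect_s3_class(fit, "mefa_fit")
  expect_equal(fit$bs$q, 2)
  expect_equal(fit$ws$q, 3)
  bs_cols <- setdiff(names(fit$bs_indicators), c("subject_id", "group"))
  ws_cols <- setdiff(names(fit$ws_indicators),
                     c("subject_id", "group", "epoch_index"))
  expect_true(all(grepl("-BS-Ind$", bs_cols)))
  expect_true(all(grepl("-WS-Ind$", ws_cols)))
  for (v in c(bs_cols)) {
    expect_true(all(fit$bs_indicators[[v]] >= 0 & fit$bs_indicators[[v]] <= 100))
  }
  for (v in c(ws_cols)) {
    expect_true(all(fit$ws_indicators[[v]] >= 0 & fit$ws_indicators[[v]] <= 100))
  }
  expect_equal(nrow(fit$ws_indicators), 270)
  expect_equal(nrow(fit$bs_indicators), 30)
})
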