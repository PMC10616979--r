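test_that("detrending removes an exact linear trend completely", {
  rr <- 900 + 0.5 * (1:200)
  expect_equal(max(abs(detrend_rr(rr))), 0, tolerance = 1e-9)
  expect_equal(detrend_rr(rep(750, 50)), rep(0, 50),
               ignore_attr = TRUE)
})

test_that("detrending agrees with the least-squares regression oracle", {
  set.seed(4)
  rr <- 1000 + rnorm(300, 0, 20)
  fit <- lm(rr ~ seq_along(rr))
  expect_equal(as.numeric(detrend_rr(rr)), unname(residuals(fit)),
               tolerance = 1e-10)
  expect_equal(attr(detrend_rr(rr), "original_mean"), mean(rr))
})

test_that("time-domain statistics match their closed forms", {
  td <- time_domain(rr_series(rep(1000, 20)))
  expect_equal(td$HR, 60)
  expect_equal(td$RMSSD, 0)
  expect_equal(td$RR_RMS, 0)
  expect_equal(time_domain(rr_series(c(800, 810, 800, 810)))$RMSSD, 10)
  expect_equal(time_domain(rr_series(c(900, 1100)))$HR, 60)
})

test_that("AR total power approximates the variance of white noise", {
  set.seed(8)
  rr <- rnorm(2048, 0, 30)
  spec <- fit_ar_spectrum(rr)
  expect_lt(abs(spec$total_power - var(rr)) / var(rr), 0.10)
})

test_that("a narrowband oscillation is located at its generating frequency", {
  set.seed(15)
  osc <- mefahrv:::ar2_oscillator(2048, f_cpb = 0.25, power = 400, r = 0.95)
  rr <- 1000 + osc + rnorm(2048, 0, 3)
  spec <- fit_ar_spectrum(detrend_rr(rr_series(rr)))
  dom <- spec$components[which.max(spec$components$power), ]
  # mean RR 1000 ms makes cycles/beat and Hz numerically identical
  expect_lt(abs(dom$frequency_hz - 0.25), 0.03)
})

test_that("a constant series has no spectrum", {
  expect_error(fit_ar_spectrum(rep(1000, 256)), "variance")
})

test_that("component powers are conserved into the total power", {
  set.seed(23)
  pr <- epoch_profile(1, 900, 400, 300, n_beats = 512)
  s <- generate_rr_epoch(pr, seed = 77)
  spec <- fit_ar_spectrum(detrend_rr(s))
  expect_equal(sum(pmax(spec$components$power, 0)), spec$total_power,
               tolerance = 0.01)
  expect_lt(abs(spec$total_power - var(s$rr)) / var(s$rr), 0.15)
})

fake_spectrum <- function(freq, power) {
  structure(list(components = data.frame(frequency_cpb = freq,
                                         frequency_hz = freq,
                                         power = power),
                 total_power = sum(power)),
            class = "ar_spectrum")
}

test_that("band powers follow band membership and normalized-unit definitions", {
  bp <- band_powers(fake_spectrum(0.25, 400))
  expect_equal(bp$RR_LFa, 0)
  expect_equal(bp$RR_HFa, 400)
  expect_equal(bp$RR_HFnu, 100)

  bp <- band_powers(fake_spectrum(c(0.10, 0.25), c(300, 100)))
  expect_equal(bp$RR_LFnu, 75)
  expect_equal(bp$RR_HFnu, 25)

  bp <- band_powers(fake_spectrum(c(0.01, 0.10), c(500, 500)))
  expect_equal(bp$RR_LFa, 500)
  expect_equal(bp$RR_LFnu, 100)
  expect_equal(bp$RR_TP, 1000)
})

test_that("normalized units are sub-complementary in the presence of high-frequency noise", {
  panel <- cached_study_panel()
  expect_true(all(panel$RR_LFnu + panel$RR_HFnu <= 100 + 1e-9))
  expect_true(any(panel$RR_LFnu + panel$RR_HFnu < 100 - 1e-6))
})

test_that("PRSA is undefined without usable anchors", {
  out <- prsa(rep(1000, 50), "acceleration", window_L = 5)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "anchor")
  out2 <- prsa(seq(900, 1100, length.out = 60), "acceleration", window_L = 5)
  expect_true(is.na(out2))
})

test_that("PRSA capacity matches a hand enumeration of anchor windows", {
  rr <- c(1000, 990, 1000, 990, 1000, 990, 1000, 990, 1000)
  # acceleration anchors with a full +/-2 window are positions 4, 6, 8; the
  # averaged window is X(-2..1) = (990, 1000, 990, 1000), so the Haar
  # contrast at s = 2 is ((990 + 1000) - (1000 + 990)) / 4 = 0
  expect_equal(prsa(rr, "acceleration", window_L = 2), 0, ignore_attr = TRUE)
  # an asymmetric sawtooth gives a nonzero hand-computable value
  rr2 <- c(1000, 980, 1005, 985, 1010, 990, 1015, 995, 1020)
  anchors <- which(diff(rr2) < 0) + 1
  anchors <- anchors[anchors - 2 >= 1 & anchors + 1 <= length(rr2)]
  X <- sapply(-2:1, function(k) mean(rr2[anchors + k]))
  oracle <- (X[3] + X[4] - X[1] - X[2]) / 4
  expect_equal(prsa(rr2, "acceleration", window_L = 2), oracle,
               ignore_attr = TRUE)
})

test_that("anchors with artifact-sized jumps are excluded", {
  rr <- rep(c(1000, 990), 20)
  rr[21] <- 700  # a 30% drop, far beyond the 5% artifact guard
  with_guard <- prsa(rr, "acceleration", window_L = 3)
  no_guard <- prsa(rr, "acceleration", window_L = 3, change_limit = 1)
  expect_false(isTRUE(all.equal(with_guard, no_guard)))
})

test_that("symbolic zero-variation percentages match enumeration oracles", {
  expect_equal(symbolic_p0v(rep(1000, 30)), 100)
  expect_equal(symbolic_p0v(c(700, 760, 820, 880, 940, 1000), n_levels = 6), 0)
  expect_equal(symbolic_p0v(c(800, 800, 800, 900, 900, 900), n_levels = 2), 50)
})

test_that("the regularity index brackets ordered and disordered dynamics", {
  expect_equal(regularity_ro(rep(900, 200)), 1)
  set.seed(12)
  ro_noise <- vapply(1:50, function(s) {
    set.seed(s)
    regularity_ro(runif(1000, 800, 1200))
  }, numeric(1))
  expect_lt(mean(ro_noise), 0.2)
  expect_gt(regularity_ro(rep(c(800, 1000), 100)), 0.8)
})

test_that("every subject must contribute the full set of epochs", {
  st <- generate_study(study_config(n_per_group = 2, seed = 5))
  st_broken <- st[-3]  # drop one epoch of subject 1001
  expect_error(compute_proxy_panel(st_broken), "1001")
})

test_that("the study panel has one row per subject-epoch and all proxies", {
  panel <- cached_study_panel()
  expect_equal(nrow(panel), 270)
  expect_true(all(mefahrv:::PROXY_NAMES %in% names(panel)))
  expect_false(anyNA(panel[, mefahrv:::PROXY_NAMES]))
})

test_that("an HF-dominant epoch yields HF-dominant normalized units", {
  pr <- epoch_profile(1, 900, lf_power = 30, hf_power = 900, vlf_power = 50,
                      n_beats = 512)
  s <- generate_rr_epoch(pr, seed = 31)
  px <- compute_proxies(s)
  expect_gt(px$RR_HFnu, px$RR_LFnu)
})
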