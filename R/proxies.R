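# The 12 autonomic proxies computed per subject-epoch RR series: heart rate,
# tachogram RMS, AR spectral band powers (absolute and normalized), RMSSD,
# PRSA acceleration/deceleration capacity, symbolic 0V percentage and the
# conditional-entropy regularity index.

#' Remove a least-squares linear trend from an RR series
#'
#' Linear detrending over the beat index limits the impact of slow
#' non-stationarities before spectral analysis. The original series mean is
#' kept as an attribute so heart rate can still be computed from it.
#'
#' @param series an [rr_series()] or numeric vector.
#' @return numeric residual series (mean approximately zero) with attribute
#'   `original_mean`.
#' @export
detrend_rr <- function(series) {
  rr <- if (inherits(series, "rr_series")) series$rr else as.numeric(series)
  assert_that(length(rr) >= 3, "series too short to detrend (need >= 3 beats)")
  idx <- seq_along(rr)
  res <- stats::lm.fit(cbind(1, idx), rr)$residuals
  attr(res, "original_mean") <- mean(rr)
  res
}

#' Time-domain proxies: heart rate, tachogram RMS and RMSSD
#'
#' `HR = 60000 / mean(rr)` (beat/min); `RMSSD` is the root mean square of
#' successive RR differences; `RR_RMS` is the root mean square of the
#' mean-centred RR intervals, i.e. the population standard deviation of the
#' tachogram.
#'
#' @param series an [rr_series()] or numeric vector of RR intervals (ms).
#' @return named list with `HR`, `RR_RMS`, `RMSSD`.
#' @export
time_domain <- function(series) {
  rr <- if (inherits(series, "rr_series")) series$rr else as.numeric(series)
  assert_that(length(rr) >= 2, "need >= 2 beats for difference statistics")
  list(HR = 60000 / mean(rr),
       RR_RMS = sqrt(mean((rr - mean(rr))^2)),
       RMSSD = sqrt(mean(diff(rr)^2)))
}

#' Fit an autoregressive spectrum to a detrended RR series
#'
#' AR models are fitted by Burg's method over a range of orders and the order
#' is chosen by the Akaike information criterion. Residual whiteness is
#' checked with Anderson's test on the residual autocorrelations (the share of
#' lags outside the 95% band); failure sets a flag, it is not an error. The
#' spectrum is decomposed into oscillatory components via the poles of the AR
#' transfer function: the power attached to a pole pair is the residue of the
#' spectral density at that pole (plus its conjugate), so the component powers
#' sum exactly to the process variance. Beat-axis frequencies (cycles/beat)
#' are converted to Hz by dividing by the mean RR interval in seconds.
#'
#' @param series an [rr_series()] or a detrended numeric series.
#' @param min_order,max_order AR order search range.
#' @param mean_rr_ms mean RR used for the frequency-axis conversion; taken
#'   from the series when omitted.
#' @return an object of class `ar_spectrum` with elements `order`,
#'   `coefficients`, `innovation_variance`, `components` (data.frame with
#'   `frequency_hz`, `frequency_cpb`, `power`), `total_power`,
#'   `whiteness_ok`, `aic`.
#' @export
fit_ar_spectrum <- function(series, min_order = 8L, max_order = 16L,
                            mean_rr_ms = NULL) {
  if (inherits(series, "rr_series")) {
    mean_rr_ms <- mean_rr_ms %||% mean(series$rr)
    x <- detrend_rr(series)
  } else {
    x <- as.numeric(series)
    mean_rr_ms <- mean_rr_ms %||% (attr(series, "original_mean") %||% mean(x))
    x <- x - mean(x)
  }
  n <- length(x)
  assert_that(n >= 4 * max_order, "series too short for AR order %d", max_order)
  assert_that(stats::var(x) > 0, "zero-variance series: spectrum undefined")

  orders <- min_order:max_order
  fits <- lapply(orders, function(p)
    stats::ar.burg(x, aic = FALSE, order.max = p, demean = FALSE))
  aics <- vapply(seq_along(orders), function(i)
    n * log(fits[[i]]$var.pred) + 2 * orders[i], numeric(1))
  best <- which.min(aics)
  fit <- fits[[best]]
  p <- orders[best]
  a <- fit$ar
  s2 <- fit$var.pred

  # poles: roots of z^p - a1 z^(p-1) - ... - ap
  poles <- polyroot(c(-rev(a), 1))
  if (any(Mod(poles) >= 1 - 1e-10)) {
    stop_mefahrv("non-stationary AR fit: pole on or outside the unit circle")
  }

  # residue decomposition of S(z)/z = s2 * z^(p-1) / (C(z) * Chat(z)),
  # C(z) = prod(z - p_k), Chat(z) = prod(1 - p_k z)
  comp_freq <- comp_pow <- numeric(0)
  used <- rep(FALSE, p)
  for (j in seq_len(p)) {
    if (used[j]) next
    pj <- poles[j]
    Cp <- prod(pj - poles[-j])
    Ch <- prod(1 - poles * pj)
    res_j <- s2 * pj^(p - 1) / (Cp * Ch)
    if (abs(Im(pj)) < 1e-9) {           # real pole: a non-oscillatory component
      comp_freq <- c(comp_freq, if (Re(pj) >= 0) 0 else 0.5)
      comp_pow <- c(comp_pow, Re(res_j))
      used[j] <- TRUE
    } else {                            # conjugate pair
      k <- which(!used & abs(poles - Conj(pj)) < 1e-8 & seq_len(p) != j)[1]
      comp_freq <- c(comp_freq, abs(Arg(pj)) / (2 * pi))
      comp_pow <- c(comp_pow, 2 * Re(res_j))
      used[j] <- TRUE
      if (!is.na(k)) used[k] <- TRUE
    }
  }
  # numerically tiny negative residues can occur; clip and renormalize later
  total <- sum(comp_pow)
  comps <- data.frame(frequency_cpb = comp_freq,
                      frequency_hz = comp_freq / (mean_rr_ms / 1000),
                      power = comp_pow)
  comps <- comps[order(comps$frequency_hz), , drop = FALSE]

  # Anderson's whiteness check on residual autocorrelations
  resid <- stats::na.omit(fit$resid)
  lag_max <- min(25L, length(resid) - 1L)
  acfv <- stats::acf(resid, lag.max = lag_max, plot = FALSE)$acf[-1]
  outside <- mean(abs(acfv) > 1.96 / sqrt(length(resid)))

  structure(list(order = p, coefficients = a, innovation_variance = s2,
                 components = comps, total_power = total,
                 mean_rr_ms = mean_rr_ms,
                 whiteness_ok = outside <= 0.05, aic = aics[best]),
            class = "ar_spectrum")
}

#' Band powers from an AR spectrum
#'
#' Components with centre frequency strictly inside (0.03, 0.15) Hz are summed
#' into the LF band and components in [0.15, 0.40] Hz into the HF band.
#' Components outside both bands contribute nothing to LF/HF but remain in the
#' total power. Normalized units are `100 * LFa / (TP - VLF)` and the same
#' with HFa in the numerator, where VLF is the power at or below the LF lower
#' edge; the two units sum to 100 only when no component lies above the HF
#' band, so the pair carries two (nearly, not exactly, complementary) pieces
#' of information. When both bands are empty the normalized units are
#' undefined and returned as `NA` with a flag.
#'
#' @param spectrum an `ar_spectrum`.
#' @param lf_band,hf_band band limits in Hz.
#' @return named list `RR_TP`, `RR_LFa`, `RR_HFa`, `RR_LFnu`, `RR_HFnu`,
#'   `nu_defined`.
#' @export
band_powers <- function(spectrum, lf_band = c(0.03, 0.15),
                        hf_band = c(0.15, 0.40)) {
  comps <- spectrum$components
  pw <- pmax(comps$power, 0)
  f <- comps$frequency_hz
  lf <- sum(pw[f > lf_band[1] & f < lf_band[2]])
  hf <- sum(pw[f >= hf_band[1] & f <= hf_band[2]])
  tp <- sum(pw)
  vlf <- sum(pw[f <= lf_band[1]])
  # normalized units relative to the power above the very-low-frequency
  # region (TP - VLF); the two units sum to 100 only when no component lies
  # above the HF band, so the pair is not an exact linear identity
  denom <- tp - vlf
  if (denom > 0 && lf + hf > 0) {
    lfnu <- 100 * lf / denom; hfnu <- 100 * hf / denom
    ok <- TRUE
  } else {
    lfnu <- hfnu <- NA_real_; ok <- FALSE
  }
  list(RR_TP = tp, RR_LFa = lf, RR_HFa = hf,
       RR_LFnu = lfnu, RR_HFnu = hfnu, nu_defined = ok)
}

#' Phase-rectified signal averaging capacity
#'
#' Anchors are beats where the RR interval decreases (acceleration) or
#' increases (deceleration) relative to the previous beat; anchors with a
#' relative change larger than `change_limit` of the previous RR are excluded
#' as artifacts, as are anchors without a full window. Windows of
#' `2 * window_L` beats centred on the anchors are averaged into X(k) and the
#' capacity is the Haar-wavelet summary
#' `(sum_{k=0}^{s-1} X(k) - sum_{k=-s}^{-1} X(k)) / (2 s)`
#' (the familiar 4-term formula at `smoothing_s = 2`).
#'
#' @param series an [rr_series()] or numeric vector.
#' @param anchor `"acceleration"` or `"deceleration"`.
#' @param window_L half-window in beats.
#' @param smoothing_s Haar scale in beats.
#' @param change_limit artifact guard on the relative RR change at anchors.
#' @return capacity in ms, or `NA` with attribute `reason` when no usable
#'   anchor exists.
#' @export
prsa <- function(series, anchor = c("acceleration", "deceleration"),
                 window_L = 10L, smoothing_s = 2L, change_limit = 0.05) {
  anchor <- match.arg(anchor)
  rr <- if (inherits(series, "rr_series")) series$rr else as.numeric(series)
  n <- length(rr)
  assert_that(n > 2 * window_L, "series too short for PRSA window %d", window_L)
  d <- diff(rr)
  idx <- which(if (anchor == "acceleration") d < 0 else d > 0) + 1L
  idx <- idx[abs(rr[idx] - rr[idx - 1L]) <= change_limit * rr[idx - 1L]]
  idx <- idx[idx - window_L >= 1L & idx + window_L - 1L <= n]
  if (length(idx) == 0) {
    return(structure(NA_real_, reason = "no usable anchors"))
  }
  # X(k), k = -window_L .. window_L - 1, averaged over anchors
  offs <- seq(-window_L, window_L - 1L)
  X <- vapply(offs, function(k) mean(rr[idx + k]), numeric(1))
  names(X) <- offs
  pos <- sum(X[as.character(0:(smoothing_s - 1L))])
  neg <- sum(X[as.character((-smoothing_s):(-1L))])
  structure((pos - neg) / (2 * smoothing_s), anchors = length(idx))
}

# Uniform quantization over the series' own min-max range; ties at internal
# bin edges fall to the lower bin; a zero-range series maps to a single symbol.
quantize_uniform <- function(rr, n_levels = 6L) {
  rng <- range(rr)
  if (diff(rng) == 0) return(rep(1L, length(rr)))
  width <- diff(rng) / n_levels
  sym <- ceiling((rr - rng[1]) / width)
  sym[sym < 1L] <- 1L
  sym[sym > n_levels] <- n_levels
  as.integer(sym)
}

#' Percentage of zero-variation symbolic patterns (0V)
#'
#' The series is uniformly quantized over its own min-max range into
#' `n_levels` symbols; overlapping patterns of `pattern_length` consecutive
#' symbols are classified by their number of symbol changes, and the 0V
#' percentage is the share of patterns with no change. A zero-range series is
#' a single symbol everywhere, hence 100.
#'
#' @param series an [rr_series()] or numeric vector.
#' @param n_levels quantization levels (default 6).
#' @param pattern_length symbols per pattern (default 3).
#' @return percentage in [0, 100].
#' @export
symbolic_p0v <- function(series, n_levels = 6L, pattern_length = 3L) {
  rr <- if (inherits(series, "rr_series")) series$rr else as.numeric(series)
  assert_that(length(rr) >= pattern_length + 1,
              "series too short for patterns of length %d", pattern_length)
  sym <- quantize_uniform(rr, n_levels)
  n_pat <- length(sym) - pattern_length + 1L
  changes <- vapply(seq_len(n_pat), function(i) {
    w <- sym[i:(i + pattern_length - 1L)]
    sum(diff(w) != 0)
  }, numeric(1))
  100 * mean(changes == 0)
}

# Shannon entropy (nats) of a vector of pattern counts
shannon_entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Regularity index from corrected conditional entropy
#'
#' After uniform quantization into `n_levels` symbols, the conditional entropy
#' of pattern length L is `E(L) - E(L-1)`; the corrected conditional entropy
#' adds back `perc(L) * E(1)` where `perc(L)` is the fraction of length-L
#' patterns observed exactly once (a bias guard for short series). The index is
#' `1 - min_L CCE(L) / E(1)`: 1 for a perfectly predictable series, near 0 for
#' white noise. A zero-range series has `E(1) = 0` and returns 1 by convention.
#'
#' @param series an [rr_series()] or numeric vector.
#' @param n_levels quantization levels (default 6).
#' @param max_pattern_length largest conditioning pattern length searched.
#' @return regularity in [0, 1].
#' @export
regularity_ro <- function(series, n_levels = 6L, max_pattern_length = 10L) {
  rr <- if (inherits(series, "rr_series")) series$rr else as.numeric(series)
  sym <- quantize_uniform(rr, n_levels)
  n <- length(sym)
  e1 <- shannon_entropy(table(sym))
  if (e1 == 0) return(1)
  ent <- function(L) {
    if (L > n) return(NA_real_)
    pat <- vapply(seq_len(n - L + 1L), function(i)
      paste(sym[i:(i + L - 1L)], collapse = "."), character(1))
    tab <- table(pat)
    c(H = shannon_entropy(tab), perc = mean(tab == 1))
  }
  prevH <- 0
  cce <- numeric(0)
  for (L in seq_len(min(max_pattern_length, n - 1L))) {
    v <- ent(L)
    if (anyNA(v)) break
    ce <- v["H"] - prevH
    cce <- c(cce, ce + v["perc"] * e1)
    prevH <- v["H"]
  }
  max(0, min(1, 1 - min(cce) / e1))
}

#' Compute the full proxy vector for one RR series
#'
#' @param series an [rr_series()].
#' @param ar_min_order,ar_max_order AR order search range.
#' @param prsa_window,prsa_smoothing PRSA parameters.
#' @param n_levels quantization levels for the symbolic proxies.
#' @return named list of the 12 proxies plus a `diagnostics` list (AR order,
#'   whiteness flag, count of out-of-band spectral components).
#' @export
compute_proxies <- function(series, ar_min_order = 8L, ar_max_order = 16L,
                            prsa_window = 10L, prsa_smoothing = 2L,
                            n_levels = 6L) {
  td <- time_domain(series)
  spec <- fit_ar_spectrum(series, min_order = ar_min_order,
                          max_order = ar_max_order)
  bp <- band_powers(spec)
  f <- spec$components$frequency_hz
  n_outside <- sum(f <= 0.03 | f > 0.40)
  out <- list(
    HR = td$HR, RR_RMS = td$RR_RMS, RR_TP = bp$RR_TP,
    RR_LFa = bp$RR_LFa, RR_HFa = bp$RR_HFa,
    RR_LFnu = bp$RR_LFnu, RR_HFnu = bp$RR_HFnu,
    RMSSD = td$RMSSD,
    AC = as.numeric(prsa(series, "acceleration", prsa_window, prsa_smoothing)),
    DC = as.numeric(prsa(series, "deceleration", prsa_window, prsa_smoothing)),
    RR_Ro = regularity_ro(series, n_levels = n_levels),
    P0v = symbolic_p0v(series, n_levels = n_levels))
  out$diagnostics <- list(ar_order = spec$order,
                          whiteness_ok = spec$whiteness_ok,
                          n_components_outside_bands = n_outside)
  out
}

#' Compute a proxy panel for a collection of RR series
#'
#' Every subject must contribute all epochs. Proxies that are undefined for a
#' given series (no PRSA anchors, empty LF+HF bands) are stored as missing;
#' the `missing_policy` then decides whether to fail (default), drop the
#' affected subject entirely, or impute the per-epoch median.
#'
#' @param series_collection list of [rr_series()].
#' @param n_epochs expected epochs per subject.
#' @param missing_policy one of `"error"`, `"drop_subject"`, `"impute_median"`.
#' @param ... passed to [compute_proxies()].
#' @return proxy panel data.frame (`subject_id`, `group`, `epoch_index`, 12
#'   proxy columns) with a `diagnostics` attribute.
#' @export
compute_proxy_panel <- function(series_collection, n_epochs = 9L,
                                missing_policy = c("error", "drop_subject",
                                                   "impute_median"), ...) {
  missing_policy <- match.arg(missing_policy)
  rows <- lapply(series_collection, function(s) {
    px <- compute_proxies(s, ...)
    diag <- px$diagnostics
    px$diagnostics <- NULL
    cbind(data.frame(subject_id = s$subject_id, group = s$group,
                     epoch_index = s$epoch_index),
          as.data.frame(px[PROXY_NAMES]),
          data.frame(ar_order = diag$ar_order,
                     whiteness_ok = diag$whiteness_ok,
                     n_outside = diag$n_components_outside_bands))
  })
  panel <- do.call(rbind, rows)
  diagnostics <- panel[, c("subject_id", "epoch_index", "ar_order",
                           "whiteness_ok", "n_outside")]
  panel <- panel[, c("subject_id", "group", "epoch_index", PROXY_NAMES)]

  counts <- table(panel$subject_id)
  bad <- names(counts)[counts != n_epochs]
  if (length(bad) > 0) {
    stop_mefahrv("incomplete subjects (expected %d epochs): %s",
                 n_epochs, paste(bad, collapse = ", "))
  }
  miss <- !stats::complete.cases(panel[, PROXY_NAMES])
  if (any(miss)) {
    who <- unique(panel$subject_id[miss])
    if (missing_policy == "error") {
      stop_mefahrv("missing proxies for subject(s) %s; set missing_policy to drop_subject or impute_median",
                   paste(who, collapse = ", "))
    } else if (missing_policy == "drop_subject") {
      panel <- panel[!(panel$subject_id %in% who), , drop = FALSE]
    } else {
      for (v in PROXY_NAMES) {
        for (t in unique(panel$epoch_index)) {
          sel <- panel$epoch_index == t
          nas <- sel & is.na(panel[[v]])
          if (any(nas)) panel[[v]][nas] <- stats::median(panel[[v]][sel], na.rm = TRUE)
        }
      }
    }
  }
  attr(panel, "diagnostics") <- diagnostics
  panel
}
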