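# Synthetic-study generators: RR tachograms with controlled LF/HF oscillatory
# content, and proxy panels with a known two-level latent factor structure.

#' Describe one protocol epoch of a simulated tachogram
#'
#' An epoch profile fixes the mean RR interval, the absolute LF and HF band
#' powers, the very-low-frequency wander power, the band-centre frequencies,
#' the white-noise floor, and the number of beats for one protocol segment.
#'
#' @param epoch_index integer in 1..9.
#' @param mean_rr mean RR interval (ms), > 0.
#' @param lf_power,hf_power requested band powers (ms^2), >= 0.
#' @param lf_center,hf_center band-centre frequencies (Hz); the LF centre must
#'   lie in (0.03, 0.15) and the HF centre in [0.15, 0.40].
#' @param vlf_power power of the slow wander component (ms^2), >= 0; real
#'   tachograms always carry broadband power below the LF band, and without
#'   it total power degenerates into an exact sum of the band powers.
#' @param vlf_center wander centre frequency (Hz), in (0, 0.03).
#' @param noise_sd white-noise standard deviation (ms), >= 0.
#' @param n_beats number of beats, >= 64.
#' @return an object of class `epoch_profile`.
#' @export
epoch_profile <- function(epoch_index, mean_rr, lf_power, hf_power,
                          lf_center = 0.1, hf_center = 0.25,
                          vlf_power = 0.4 * (lf_power + hf_power),
                          vlf_center = 0.015,
                          noise_sd = 5, n_beats = 300) {
  assert_that(epoch_index %in% 1:9, "epoch_index must be in 1..9")
  assert_that(mean_rr > 0, "mean_rr must be positive")
  assert_that(lf_power >= 0 && hf_power >= 0, "band powers must be >= 0")
  assert_that(lf_center > 0.03 && lf_center < 0.15,
              "lf_center must lie in (0.03, 0.15) Hz")
  assert_that(hf_center >= 0.15 && hf_center <= 0.40,
              "hf_center must lie in [0.15, 0.40] Hz")
  assert_that(vlf_power >= 0, "vlf_power must be >= 0")
  assert_that(vlf_center > 0 && vlf_center < 0.03,
              "vlf_center must lie in (0, 0.03) Hz")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(n_beats >= 64, "n_beats must be >= 64")
  structure(list(epoch_index = as.integer(epoch_index), mean_rr = mean_rr,
                 lf_power = lf_power, hf_power = hf_power,
                 lf_center = lf_center, hf_center = hf_center,
                 vlf_power = vlf_power, vlf_center = vlf_center,
                 noise_sd = noise_sd, n_beats = as.integer(n_beats)),
            class = "epoch_profile")
}

#' A single subject-epoch RR series
#'
#' @param subject_id,group,epoch_index labels identifying the series.
#' @param rr ordered RR intervals (ms), all positive.
#' @return an object of class `rr_series`.
#' @export
rr_series <- function(rr, subject_id = "s1", group = "g1", epoch_index = 1L) {
  assert_that(is.numeric(rr) && length(rr) >= 1, "rr must be numeric")
  assert_that(all(rr > 0), "all RR intervals must be positive")
  structure(list(subject_id = subject_id, group = group,
                 epoch_index = as.integer(epoch_index), rr = as.numeric(rr)),
            class = "rr_series")
}

#' @export
print.rr_series <- function(x, ...) {
  cat(sprintf("<rr_series> subject %s, group %s, epoch %d: %d beats, mean RR %.1f ms\n",
              x$subject_id, x$group, x$epoch_index, length(x$rr), mean(x$rr)))
  invisible(x)
}

# Simulate a beat-domain AR(2) narrow-band oscillator with spectral peak at
# `f_cpb` cycles/beat and pole radius `r`, scaled to theoretical variance
# `power`. Returns a zero-mean series of length n.
ar2_oscillator <- function(n, f_cpb, power, r = 0.95) {
  if (power <= 0) return(rep(0, n))
  theta <- 2 * pi * f_cpb
  a1 <- 2 * r * cos(theta)
  a2 <- -r^2
  # stationary variance of AR(2) with unit innovation variance
  v <- (1 - a2) / ((1 + a2) * ((1 - a2)^2 - a1^2))
  x <- as.numeric(stats::arima.sim(list(ar = c(a1, a2)), n = n,
                                   n.start = 200))
  x * sqrt(power / v)
}

#' Generate one RR-interval epoch from an epoch profile
#'
#' The series is the profile mean plus two narrow-band stochastic oscillators
#' (second-order autoregressive processes with spectral peaks at the LF and HF
#' centre frequencies, scaled to the requested band powers) plus white noise.
#' Frequencies are interpreted on the beat axis via the mean RR interval.
#' Non-positive beats are handled by re-drawing the whole series (rejection,
#' not truncation, so the spectral content is not distorted).
#'
#' @param profile an [epoch_profile()].
#' @param seed integer seed; the same profile and seed give an identical series.
#' @param subject_id,group labels attached to the output.
#' @param pole_radius AR(2) pole radius in (0, 1); controls oscillator bandwidth.
#' @param max_attempts rejection attempts before giving up.
#' @return an [rr_series()].
#' @export
generate_rr_epoch <- function(profile, seed, subject_id = "s1", group = "g1",
                              pole_radius = 0.95, max_attempts = 100L) {
  assert_that(inherits(profile, "epoch_profile"), "profile must be an epoch_profile")
  f_lf <- profile$lf_center * profile$mean_rr / 1000   # Hz -> cycles/beat
  f_hf <- profile$hf_center * profile$mean_rr / 1000
  f_vlf <- profile$vlf_center * profile$mean_rr / 1000
  assert_that(f_hf < 0.5, "HF centre exceeds the beat-axis Nyquist frequency")
  set.seed(seed)
  for (attempt in seq_len(max_attempts)) {
    n <- profile$n_beats
    rr <- profile$mean_rr +
      ar2_oscillator(n, f_lf, profile$lf_power, pole_radius) +
      ar2_oscillator(n, f_hf, profile$hf_power, pole_radius) +
      ar2_oscillator(n, f_vlf, profile$vlf_power, pole_radius) +
      stats::rnorm(n, 0, profile$noise_sd)
    if (all(rr > 0)) {
      return(rr_series(rr, subject_id = subject_id, group = group,
                       epoch_index = profile$epoch_index))
    }
  }
  stop_mefahrv("could not generate a positive RR series for epoch %d (mean %.0f ms): oscillator parameters too extreme",
               profile$epoch_index, profile$mean_rr)
}

#' Default epoch profiles for an exercise-like protocol
#'
#' Encodes the ordinal epoch trends of a rest / stand / incremental-exercise /
#' peak / recovery protocol: mean RR falls monotonically to its minimum at the
#' peak epoch (epoch 7) and partially recovers; total and band powers collapse
#' towards zero at peak and rebound slightly in recovery; the LF:HF power
#' ratio rises from rest to the early exercise steps and inverts near peak.
#' Beat counts sum to roughly 1800 across the nine epochs.
#'
#' @param group `"endurance"` or `"technical"`; the endurance profile has a
#'   lower resting heart rate and larger vagally-mediated (HF) power at rest.
#' @return list of nine [epoch_profile()] objects.
#' @export
default_epoch_profiles <- function(group = c("endurance", "technical")) {
  group <- match.arg(group)
  if (group == "endurance") {
    mean_rr <- c(1050, 850, 700, 560, 460, 400, 355, 470, 610)
    lf <- c(900, 1400, 700, 250, 60, 18, 6, 40, 130)
    hf <- c(1300, 500, 250, 90, 25, 8, 3, 20, 80)
    vlf <- c(1000, 800, 420, 160, 45, 16, 7, 35, 110)
  } else {
    mean_rr <- c(930, 760, 640, 530, 445, 395, 350, 455, 580)
    lf <- c(1100, 1500, 650, 220, 55, 16, 6, 35, 110)
    hf <- c(700, 300, 170, 65, 20, 7, 3, 15, 55)
    vlf <- c(850, 750, 380, 140, 40, 14, 6, 30, 95)
  }
  n_beats <- c(300, 300, 170, 160, 150, 140, 170, 230, 230)
  noise <- c(8, 7, 6, 5, 4, 3, 2.5, 4, 5)
  lapply(1:9, function(t) {
    epoch_profile(t, mean_rr[t], lf[t], hf[t],
                  lf_center = 0.1, hf_center = 0.25,
                  vlf_power = vlf[t], noise_sd = noise[t],
                  n_beats = n_beats[t])
  })
}

#' Configuration for a two-group, nine-epoch simulated study
#'
#' @param n_per_group subjects per group (the emulated study had 15 + 15).
#' @param group_labels two group labels.
#' @param profiles named list of two lists of nine [epoch_profile()] each;
#'   defaults to [default_epoch_profiles()] per group.
#' @param sd_log_amp standard deviation of the per-subject log-normal
#'   multiplier applied to all oscillatory powers (a subject's overall
#'   variability "amplitude"). Zero removes between-subject amplitude
#'   heterogeneity, leaving only realization noise.
#' @param sd_balance standard deviation of the per-subject sympathovagal
#'   tilt: LF powers are multiplied by `exp(b)` and HF powers by `exp(-b)`.
#' @param sd_log_rr standard deviation of the per-subject log-normal
#'   multiplier on the mean RR interval.
#' @param sd_log_state standard deviation of the epoch-level log-normal
#'   fluctuation applied independently to each band power — the visit-to-visit
#'   physiological state noise that keeps the proxies from tracking the epoch
#'   profile deterministically.
#' @param sd_rr_state standard deviation of the epoch-level log-normal
#'   fluctuation of the mean RR interval.
#' @param seed integer base seed.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_per_group = 15, group_labels = c("cyclist", "shooter"),
                         profiles = NULL, sd_log_amp = 0.45,
                         sd_balance = 0.35, sd_log_rr = 0.08,
                         sd_log_state = 0.30, sd_rr_state = 0.03, seed = 1L) {
  assert_that(length(group_labels) == 2, "exactly two groups are supported")
  if (is.null(profiles)) {
    profiles <- list(default_epoch_profiles("endurance"),
                     default_epoch_profiles("technical"))
    names(profiles) <- group_labels
  }
  assert_that(length(profiles) == 2 && all(lengths(profiles) == 9),
              "profiles must hold 9 epoch profiles for each of 2 groups")
  assert_that(sd_log_amp >= 0 && sd_balance >= 0 && sd_log_rr >= 0 &&
                sd_log_state >= 0 && sd_rr_state >= 0,
              "random-effect standard deviations must be >= 0")
  structure(list(n_per_group = as.integer(n_per_group),
                 group_labels = group_labels, profiles = profiles,
                 sd_log_amp = sd_log_amp, sd_balance = sd_balance,
                 sd_log_rr = sd_log_rr, sd_log_state = sd_log_state,
                 sd_rr_state = sd_rr_state, seed = as.integer(seed)),
            class = "study_config")
}

#' Generate a full simulated study of RR series
#'
#' Subjects within a group share the group's epoch profiles but differ by
#' three stable random effects drawn once per subject: a log-normal amplitude
#' multiplier on all oscillatory powers, a sympathovagal balance tilt that
#' scales LF power up and HF power down (or vice versa), and a log-normal
#' multiplier on the mean RR interval. A subject with a large amplitude also
#' tends to have a longer resting RR (the multiplier includes a weak
#' `amp^0.15` coupling), mirroring the usual vagal-tone association.
#'
#' @param config a [study_config()].
#' @return list of [rr_series()], one per subject-epoch
#'   (`2 * n_per_group * 9` in all), with group and epoch labels attached.
#' @export
generate_study <- function(config) {
  assert_that(inherits(config, "study_config"), "config must be a study_config")
  out <- vector("list", 2L * config$n_per_group * 9L)
  k <- 0L
  counter <- 0L
  for (g in 1:2) {
    glab <- config$group_labels[g]
    for (i in seq_len(config$n_per_group)) {
      sid <- sprintf("%d%03d", g, i)
      set.seed(child_seed(config$seed, 500000L + (g - 1L) * config$n_per_group + i))
      amp <- exp(stats::rnorm(1, 0, config$sd_log_amp))
      bal <- stats::rnorm(1, 0, config$sd_balance)
      rr_mult <- exp(stats::rnorm(1, 0, config$sd_log_rr)) * amp^0.15
      for (t in 1:9) {
        counter <- counter + 1L
        k <- k + 1L
        pr <- config$profiles[[g]][[t]]
        set.seed(child_seed(config$seed, 600000L + counter))
        state <- exp(stats::rnorm(3, 0, config$sd_log_state))
        rr_state <- exp(stats::rnorm(1, 0, config$sd_rr_state))
        pr_i <- epoch_profile(pr$epoch_index, pr$mean_rr * rr_mult * rr_state,
                              pr$lf_power * amp * exp(bal) * state[1],
                              pr$hf_power * amp * exp(-bal) * state[2],
                              lf_center = pr$lf_center,
                              hf_center = pr$hf_center,
                              vlf_power = pr$vlf_power * amp * state[3],
                              vlf_center = pr$vlf_center,
                              noise_sd = pr$noise_sd,
                              n_beats = pr$n_beats)
        out[[k]] <- generate_rr_epoch(pr_i,
                                      seed = child_seed(config$seed, counter),
                                      subject_id = sid, group = glab)
      }
    }
  }
  out
}

#' Flatten a list of RR series to a long tachogram table
#'
#' @param series list of [rr_series()].
#' @return data.frame with columns `subject`, `group`, `epoch`, `rr_ms`.
#' @export
tachogram_table <- function(series) {
  do.call(rbind, lapply(series, function(s) {
    data.frame(subject = s$subject_id, group = s$group,
               epoch = s$epoch_index, rr_ms = s$rr)
  }))
}

#' Write / read a tachogram CSV
#'
#' @param series list of [rr_series()] (for writing) .
#' @param path file path.
#' @export
write_tachogram_csv <- function(series, path) {
  utils::write.csv(tachogram_table(series), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tachogram_csv
#' @export
read_tachogram_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("subject", "group", "epoch", "rr_ms") %in% names(df)),
              "tachogram CSV must have columns subject, group, epoch, rr_ms")
  keys <- unique(df[, c("subject", "group", "epoch")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$subject == keys$subject[i] & df$epoch == keys$epoch[i]
    rr_series(df$rr_ms[sel], subject_id = as.character(keys$subject[i]),
              group = as.character(keys$group[i]),
              epoch_index = keys$epoch[i])
  })
}

# ---------------------------------------------------------------------------
# Latent two-level panel generator

#' Specification of a two-level latent factor structure for a proxy panel
#'
#' The generated panel follows an orthogonal two-level factor model: each
#' subject draws between-subject (BS) factor scores that shift all of that
#' subject's rows, and each subject-epoch draws within-subject (WS) factor
#' scores. Uniquenesses are the complements of the row communalities at each
#' level, so every proxy has unit variance at both levels.
#'
#' @param bs_loadings p x qB loading matrix (p = 12).
#' @param ws_loadings p x qW loading matrix.
#' @param n_subjects,n_epochs panel dimensions.
#' @param group_shift length-qB vector added to the BS factor means of the
#'   second group (set to zeros for exchangeable groups).
#' @param group_labels two group labels; subjects are split evenly.
#' @param seed integer seed.
#' @return an object of class `latent_panel_spec`.
#' @export
latent_panel_spec <- function(bs_loadings = default_bs_loadings(),
                              ws_loadings = default_ws_loadings(),
                              n_subjects = 30, n_epochs = 9,
                              group_shift = c(0, 0),
                              group_labels = c("cyclist", "shooter"),
                              seed = 1L) {
  bs_loadings <- as.matrix(bs_loadings)
  ws_loadings <- as.matrix(ws_loadings)
  assert_that(nrow(bs_loadings) == 12 && nrow(ws_loadings) == 12,
              "loading matrices must have p = 12 rows")
  assert_that(ncol(bs_loadings) >= 1 && ncol(ws_loadings) >= 1,
              "at least one factor per level")
  hb <- rowSums(bs_loadings^2); hw <- rowSums(ws_loadings^2)
  assert_that(all(hb <= 1 + 1e-12) && all(hw <= 1 + 1e-12),
              "row communalities must not exceed 1 at either level")
  assert_that(length(group_shift) == ncol(bs_loadings),
              "group_shift must have one entry per BS factor")
  structure(list(bs_loadings = bs_loadings, ws_loadings = ws_loadings,
                 uniquenesses_bs = pmax(1 - hb, 0),
                 uniquenesses_ws = pmax(1 - hw, 0),
                 n_subjects = as.integer(n_subjects),
                 n_epochs = as.integer(n_epochs),
                 group_shift = group_shift, group_labels = group_labels,
                 seed = as.integer(seed)),
            class = "latent_panel_spec")
}

#' Default between-subject loading structure (two factors)
#'
#' A simple-structure pattern mirroring the amplitude / frequency split of the
#' proxy set: factor 1 loads on the time-based proxies (negatively for HR and
#' the acceleration capacity), factor 2 on the ratio-based proxies (with
#' opposite signs for the LF and HF normalized units).
#' @return 12 x 2 matrix with proxy row names.
#' @export
default_bs_loadings <- function() {
  m <- cbind(
    amp = c(HR = -0.50, RR_RMS = 0.85, RR_TP = 0.85, RR_LFa = 0.70,
            RR_HFa = 0.65, RR_LFnu = -0.15, RR_HFnu = 0.30, RMSSD = 0.85,
            AC = -0.75, DC = 0.75, RR_Ro = -0.20, P0v = 0.05),
    fre = c(HR = 0.45, RR_RMS = -0.30, RR_TP = -0.25, RR_LFa = 0.05,
            RR_HFa = -0.25, RR_LFnu = 0.70, RR_HFnu = -0.70, RMSSD = -0.30,
            AC = 0.20, DC = -0.10, RR_Ro = 0.85, P0v = 0.85))
  rownames(m) <- PROXY_NAMES[match(rownames(m), PROXY_NAMES)]
  m[PROXY_NAMES, ]
}

#' Default within-subject loading structure (three factors)
#'
#' Amplitude (time-based proxies), signal self-similarity (regularity and 0V
#' symbolic pattern proxies) and oscillatory (opposite-signed LF/HF normalized
#' units) factors.
#' @return 12 x 3 matrix with proxy row names.
#' @export
default_ws_loadings <- function() {
  m <- cbind(
    amp = c(HR = -0.80, RR_RMS = 0.85, RR_TP = 0.85, RR_LFa = 0.70,
            RR_HFa = 0.60, RR_LFnu = 0.30, RR_HFnu = 0.20, RMSSD = 0.90,
            AC = -0.85, DC = 0.80, RR_Ro = -0.15, P0v = -0.15),
    sss = c(HR = 0.15, RR_RMS = 0.15, RR_TP = -0.10, RR_LFa = 0.00,
            RR_HFa = -0.15, RR_LFnu = 0.10, RR_HFnu = 0.00, RMSSD = -0.25,
            AC = 0.25, DC = -0.20, RR_Ro = 0.90, P0v = 0.90),
    osc = c(HR = -0.10, RR_RMS = 0.00, RR_TP = -0.25, RR_LFa = 0.15,
            RR_HFa = -0.45, RR_LFnu = 0.75, RR_HFnu = -0.75, RMSSD = -0.10,
            AC = 0.00, DC = 0.00, RR_Ro = 0.05, P0v = 0.10))
  rownames(m) <- PROXY_NAMES[match(rownames(m), PROXY_NAMES)]
  m[PROXY_NAMES, ]
}

#' Generate a proxy panel from a two-level latent factor specification
#'
#' @param spec a [latent_panel_spec()].
#' @return data.frame with `subject_id`, `group`, `epoch_index` keys and the
#'   12 proxy columns (`n_subjects * n_epochs` rows), plus attributes
#'   `bs_factors` and `ws_factors` holding the generating factor scores.
#' @export
generate_proxy_panel <- function(spec) {
  assert_that(inherits(spec, "latent_panel_spec"), "spec must be a latent_panel_spec")
  set.seed(spec$seed)
  n <- spec$n_subjects; T <- spec$n_epochs
  qB <- ncol(spec$bs_loadings); qW <- ncol(spec$ws_loadings)
  grp <- rep(spec$group_labels, length.out = 2)
  group_of <- rep(grp, c(ceiling(n / 2), floor(n / 2)))[1:n]
  FB <- matrix(stats::rnorm(n * qB), n, qB)
  FB <- FB + outer(as.numeric(group_of == grp[2]), spec$group_shift)
  EB <- matrix(stats::rnorm(n * 12), n, 12) %*% diag(sqrt(spec$uniquenesses_bs))
  between <- FB %*% t(spec$bs_loadings) + EB          # n x p subject effects
  FW <- matrix(stats::rnorm(n * T * qW), n * T, qW)
  EW <- matrix(stats::rnorm(n * T * 12), n * T, 12) %*%
    diag(sqrt(spec$uniquenesses_ws))
  within <- FW %*% t(spec$ws_loadings) + EW           # nT x p epoch effects
  subj <- rep(sprintf("s%03d", 1:n), each = T)
  X <- between[rep(1:n, each = T), , drop = FALSE] + within
  colnames(X) <- PROXY_NAMES
  panel <- data.frame(subject_id = subj,
                      group = rep(group_of, each = T),
                      epoch_index = rep(1:T, times = n),
                      X, check.names = FALSE)
  attr(panel, "bs_factors") <- FB
  attr(panel, "ws_factors") <- FW
  panel
}

#' Write a proxy panel CSV
#' @param panel proxy panel data.frame.
#' @param path file path.
#' @export
write_panel_csv <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  assert_that(all(c("subject_id", "group", "epoch_index", PROXY_NAMES) %in% names(df)),
              "panel CSV is missing required columns")
  df
}
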