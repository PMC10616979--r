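# Non-parametric test battery: rank-based ANOVA-type statistics for the
# group x epoch longitudinal design, permutation / bootstrap two-sample tests
# (kernel-density, Jonckheere-Terpstra, Kolmogorov-Smirnov, studentized
# rank-sum), the paired signed-rank permutation test, FDR adjustment, the
# median-regression sex/age screen, and the sensitivity-level scoring.

# Moore-Penrose pseudo-inverse via SVD (small matrices only).
pinv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(M), nrow(M)))
  s$v[, keep, drop = FALSE] %*% diag(1 / s$d[keep], sum(keep)) %*%
    t(s$u[, keep, drop = FALSE])
}

new_test_result <- function(method, statistic, p_value, n_resamples = NA_integer_,
                            seed = NA_integer_, ...) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 n_resamples = n_resamples, seed = seed, ...),
            class = "mefahrv_test")
}

#' @export
print.mefahrv_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$method, x$statistic, x$p_value))
  invisible(x)
}

#' Rank-based ANOVA-type tests for a (group x epoch) longitudinal design
#'
#' Mid-ranks over all observations estimate the relative treatment effects;
#' ANOVA-type statistics with Box-type approximation degrees of freedom test
#' "no group effect" (whole-plot, F with two estimated dfs), "no epoch
#' effect" and "no group-by-epoch interaction" (both F(f, Inf)). With a single
#' group only the epoch effect is tested.
#'
#' @param values data.frame with columns `subject_id`, `epoch_index`, and the
#'   response named by `response`; optionally `group`.
#' @param response name of the response column.
#' @param groups optional per-subject group labels (otherwise taken from the
#'   `group` column).
#' @return list of class `ats_result` with elements `group`, `epoch`,
#'   `interaction`, each `(statistic, df1, df2, p_value)` (group-related
#'   entries are `NULL` in the one-group design).
#' @export
ats_longitudinal <- function(values, response = "value", groups = NULL) {
  assert_that(all(c("subject_id", "epoch_index", response) %in% names(values)),
              "values needs subject_id, epoch_index and the response column")
  subj <- as.character(values$subject_id)
  ids <- unique(subj)
  epochs <- sort(unique(values$epoch_index))
  T <- length(epochs)
  assert_that(T >= 2, "need at least 2 epochs")
  if (is.null(groups)) {
    assert_that("group" %in% names(values), "no group labels available")
    groups <- stats::setNames(as.character(values$group[match(ids, subj)]), ids)
  }
  glev <- unique(unname(groups[ids]))
  a <- length(glev)

  # rank matrix: rows = subjects (ordered by group), cols = epochs
  Rk <- matrix(NA_real_, length(ids), T, dimnames = list(ids, epochs))
  r_all <- rank(values[[response]], ties.method = "average")
  for (k in seq_len(nrow(values))) {
    Rk[subj[k], as.character(values$epoch_index[k])] <- r_all[k]
  }
  assert_that(!anyNA(Rk), "panel is incomplete: every subject needs every epoch")
  N <- length(ids) * T
  ord <- order(match(groups[ids], glev))
  Rk <- Rk[ord, , drop = FALSE]
  gvec <- groups[rownames(Rk)]
  n_i <- as.integer(table(factor(gvec, levels = glev)))
  assert_that(all(n_i >= 2), "every group needs at least 2 subjects")

  # one column per group, epochs within columns -> flattened (group, epoch)
  phat <- as.numeric(vapply(glev, function(g)
    (colMeans(Rk[gvec == g, , drop = FALSE]) - 0.5) / N, numeric(T)))
  # block-diagonal covariance estimate of phat
  Vblocks <- lapply(seq_len(a), function(i) {
    Yi <- Rk[gvec == glev[i], , drop = FALSE] / N
    N * stats::cov(Yi) / n_i[i]
  })
  V <- matrix(0, a * T, a * T)
  for (i in seq_len(a)) {
    idx <- ((i - 1) * T + 1):(i * T)
    V[idx, idx] <- Vblocks[[i]]
  }

  Pa <- diag(a) - matrix(1 / a, a, a)
  PT <- diag(T) - matrix(1 / T, T, T)
  one_t <- matrix(1 / T, 1, T)
  one_a <- matrix(1 / a, 1, a)

  ats_one <- function(C, whole_plot = FALSE) {
    Tc <- t(C) %*% pinv(C %*% t(C)) %*% C
    TV <- Tc %*% V
    tr1 <- sum(diag(TV))
    stat <- N * as.numeric(t(phat) %*% Tc %*% phat) / tr1
    f1 <- tr1^2 / sum(diag(TV %*% TV))
    if (whole_plot) {
      tr_blocks <- vapply(seq_len(a), function(i) {
        idx <- ((i - 1) * T + 1):(i * T)
        sum(diag(Tc[idx, idx, drop = FALSE] %*% Vblocks[[i]]))
      }, numeric(1))
      f2 <- tr1^2 / sum(tr_blocks^2 / (n_i - 1))
    } else {
      f2 <- Inf
    }
    list(statistic = stat, df1 = f1, df2 = f2,
         p_value = stats::pf(stat, f1, f2, lower.tail = FALSE))
  }

  if (a == 1) {
    res <- list(group = NULL, epoch = ats_one(PT), interaction = NULL)
  } else {
    res <- list(group = ats_one(kronecker(Pa, one_t), whole_plot = TRUE),
                epoch = ats_one(kronecker(one_a, PT)),
                interaction = ats_one(kronecker(Pa, PT)))
  }
  structure(res, class = "ats_result", groups = glev, n = n_i, T = T)
}

# (1 + b) / (B + 1) Monte-Carlo p-value; exact enumerations use plain b / B.
add_one_p <- function(b, B) (1 + b) / (B + 1)

# All two-group label assignments (columns = indices of group 1) if the count
# is manageable, else NULL.
two_group_assignments <- function(n, n1, limit = 20000) {
  if (choose(n, n1) > limit) return(NULL)
  utils::combn(n, n1)
}

#' Permutation test for equality of two densities (kernel-based)
#'
#' The statistic is the integrated squared difference between Gaussian-kernel
#' density estimates of the two samples at a common bandwidth (geometric mean
#' of the two samples' plug-in bandwidths). The null distribution comes from
#' permuting the group labels.
#'
#' @param x,y numeric samples (each >= 5 values).
#' @param n_permutations Monte-Carlo permutations.
#' @param seed integer seed.
#' @param n_grid integration grid size.
#' @return a `mefahrv_test`.
#' @export
ba_density_test <- function(x, y, n_permutations = 2000L, seed = 1L,
                            n_grid = 101L) {
  x <- as.numeric(x); y <- as.numeric(y)
  assert_that(length(x) >= 5 && length(y) >= 5, "each sample needs >= 5 values")
  assert_that(stats::sd(c(x, y)) > 0, "degenerate samples")
  bw_of <- function(v) if (stats::sd(v) > 0)
    tryCatch(stats::bw.SJ(v), error = function(e) stats::bw.nrd0(v))
  else NA_real_
  h <- exp(mean(log(stats::na.omit(c(bw_of(x), bw_of(y))))))
  pool <- c(x, y)
  n1 <- length(x); n <- length(pool)
  grid <- seq(min(pool) - 3 * h, max(pool) + 3 * h, length.out = n_grid)
  dg <- grid[2] - grid[1]
  K <- outer(pool, grid, function(v, g) stats::dnorm(g, v, h))  # n x grid
  stat_of <- function(idx1) {
    in1 <- seq_len(n) %in% idx1
    d <- colMeans(K[in1, , drop = FALSE]) - colMeans(K[!in1, , drop = FALSE])
    sum(d^2) * dg
  }
  obs <- stat_of(seq_len(n1))
  set.seed(seed)
  perm <- vapply(seq_len(n_permutations),
                 function(b) stat_of(sample.int(n, n1)), numeric(1))
  new_test_result("BA permutation density test", obs,
                  add_one_p(sum(perm >= obs - 1e-12), n_permutations),
                  n_permutations, seed, bandwidth = h)
}

# Jonckheere-Terpstra statistic: sum of pairwise Mann-Whitney counts over
# ordered group pairs (ties counted 1/2).
jt_statistic <- function(samples) {
  s <- 0
  for (i in seq_along(samples)[-length(samples)]) {
    for (j in (i + 1):length(samples)) {
      cmp <- outer(samples[[i]], samples[[j]], "<")
      tie <- outer(samples[[i]], samples[[j]], "==")
      s <- s + sum(cmp) + 0.5 * sum(tie)
    }
  }
  s
}

#' Jonckheere-Terpstra permutation test for ordered alternatives
#'
#' With two groups the statistic reduces exactly to the Mann-Whitney U count.
#' For two groups and small samples the permutation distribution is
#' enumerated exhaustively; otherwise Monte-Carlo permutations are used.
#'
#' @param samples list of numeric vectors ordered by group.
#' @param alternative `"increasing"`, `"decreasing"`, or `"two.sided"`.
#' @param n_permutations Monte-Carlo permutations (ignored when exhaustive
#'   enumeration applies).
#' @param seed integer seed.
#' @return a `mefahrv_test` with an `exact` field.
#' @export
jt_test <- function(samples, alternative = c("two.sided", "increasing",
                                             "decreasing"),
                    n_permutations = 2000L, seed = 1L) {
  alternative <- match.arg(alternative)
  assert_that(length(samples) >= 2, "need at least two groups")
  assert_that(all(lengths(samples) >= 1), "empty group")
  sizes <- lengths(samples)
  pool <- unlist(samples, use.names = FALSE)
  n <- length(pool)
  split_by_sizes <- function(v) {
    ends <- cumsum(sizes)
    starts <- c(1, utils::head(ends, -1) + 1)
    lapply(seq_along(sizes), function(i) v[starts[i]:ends[i]])
  }
  obs <- jt_statistic(samples)

  combs <- if (length(samples) == 2) two_group_assignments(n, sizes[1]) else NULL
  if (!is.null(combs)) {
    stats_perm <- apply(combs, 2, function(idx1)
      jt_statistic(list(pool[idx1], pool[-idx1])))
    exact <- TRUE
    B <- ncol(combs)
  } else {
    set.seed(seed)
    stats_perm <- vapply(seq_len(n_permutations), function(b)
      jt_statistic(split_by_sizes(sample(pool))), numeric(1))
    exact <- FALSE
    B <- n_permutations
  }
  tail_count <- switch(alternative,
    increasing = sum(stats_perm >= obs - 1e-12),
    decreasing = sum(stats_perm <= obs + 1e-12),
    two.sided = {
      mu <- mean(stats_perm)
      sum(abs(stats_perm - mu) >= abs(obs - mu) - 1e-12)
    })
  p <- if (exact) tail_count / B else add_one_p(tail_count, B)
  new_test_result("Jonckheere-Terpstra permutation test", obs, min(p, 1),
                  B, seed, exact = exact, alternative = alternative)
}

# Kolmogorov-Smirnov sup-distance between the ECDFs of two samples.
ks_statistic <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  w <- c(x, y)
  z <- cumsum(ifelse(order(w) <= n1, 1 / n1, -1 / n2))
  if (anyDuplicated(w)) z <- z[c(diff(sort(w)) != 0, TRUE)]
  max(abs(z))
}

#' Bootstrap Kolmogorov-Smirnov two-sample test
#'
#' The null distribution of the sup-distance statistic is obtained by drawing
#' both samples with replacement from the pooled sample, which keeps the test
#' valid in the presence of ties (the reason for bootstrapping rather than
#' using the asymptotic distribution).
#'
#' @param x,y numeric samples (each >= 5 values).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @return a `mefahrv_test`.
#' @export
ks_bootstrap_test <- function(x, y, n_boot = 1000L, seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  assert_that(length(x) >= 5 && length(y) >= 5, "each sample needs >= 5 values")
  obs <- ks_statistic(x, y)
  pool <- c(x, y)
  n1 <- length(x); n2 <- length(y)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    ks_statistic(sample(pool, n1, replace = TRUE),
                 sample(pool, n2, replace = TRUE))
  }, numeric(1))
  new_test_result("KS bootstrap test", obs,
                  add_one_p(sum(boots >= obs - 1e-12), n_boot), n_boot, seed)
}

# Studentized rank-sum statistic: difference of mean pooled ranks scaled by a
# variance estimate that allows unequal spread across groups.
stwrs_statistic <- function(r1, r2) {
  v1 <- stats::var(r1); v2 <- stats::var(r2)
  den <- sqrt(v1 / length(r1) + v2 / length(r2))
  if (den == 0) return(0)
  (mean(r1) - mean(r2)) / den
}

#' Studentized Wilcoxon rank-sum permutation test
#'
#' The rank-sum statistic is centred and scaled by a variance estimate built
#' from the within-group rank variances, which keeps the permutation test
#' close to its nominal level when the two groups have unequal spread. Exact
#' enumeration is used for small two-group designs.
#'
#' @param x,y numeric samples (each >= 5 values; smaller samples are allowed
#'   when exhaustive enumeration applies).
#' @param n_permutations Monte-Carlo permutations.
#' @param seed integer seed.
#' @param alternative `"two.sided"`, `"greater"` (x shifted up), `"less"`.
#' @return a `mefahrv_test` with an `exact` field.
#' @export
stwrs_test <- function(x, y, n_permutations = 2000L, seed = 1L,
                       alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n <- n1 + length(y)
  assert_that(stats::sd(c(x, y)) > 0, "degenerate samples")
  r <- rank(c(x, y), ties.method = "average")
  obs <- stwrs_statistic(r[seq_len(n1)], r[-seq_len(n1)])
  combs <- two_group_assignments(n, n1, limit = 5000)
  if (!is.null(combs)) {
    stats_perm <- apply(combs, 2, function(idx1)
      stwrs_statistic(r[idx1], r[-idx1]))
    exact <- TRUE; B <- ncol(combs)
  } else {
    assert_that(n1 >= 5 && n - n1 >= 5, "each sample needs >= 5 values")
    set.seed(seed)
    stats_perm <- vapply(seq_len(n_permutations), function(b) {
      idx1 <- sample.int(n, n1)
      stwrs_statistic(r[idx1], r[-idx1])
    }, numeric(1))
    exact <- FALSE; B <- n_permutations
  }
  tail_count <- switch(alternative,
    greater = sum(stats_perm >= obs - 1e-12),
    less = sum(stats_perm <= obs + 1e-12),
    two.sided = sum(abs(stats_perm) >= abs(obs) - 1e-12))
  p <- if (exact) tail_count / B else add_one_p(tail_count, B)
  new_test_result("Studentized Wilcoxon rank-sum permutation test", obs,
                  min(p, 1), B, seed, exact = exact, alternative = alternative)
}

#' Permutation Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped; the statistic is the sum of the ranks of the
#' absolute differences carrying a positive sign. The null distribution comes
#' from sign flips: exhaustive over all `2^m` patterns when `m <= max_exact`,
#' Monte-Carlo otherwise.
#'
#' @param before,after paired numeric vectors.
#' @param n_permutations Monte-Carlo sign flips.
#' @param seed integer seed.
#' @param alternative `"two.sided"`, `"greater"` (after > before), `"less"`.
#' @param max_exact largest m for exhaustive enumeration.
#' @return a `mefahrv_test` with an `exact` field.
#' @export
wsr_test <- function(before, after, n_permutations = 2000L, seed = 1L,
                     alternative = c("two.sided", "greater", "less"),
                     max_exact = 14L) {
  alternative <- match.arg(alternative)
  d <- as.numeric(after) - as.numeric(before)
  assert_that(length(after) == length(before), "paired vectors must have equal length")
  d <- d[d != 0]
  if (length(d) == 0) stop_mefahrv("no nonzero differences")
  m <- length(d)
  rk <- rank(abs(d), ties.method = "average")
  obs <- sum(rk[d > 0])
  mu <- sum(rk) / 2
  if (m <= max_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    stats_perm <- as.numeric(signs %*% rk)
    exact <- TRUE; B <- nrow(signs)
  } else {
    set.seed(seed)
    stats_perm <- vapply(seq_len(n_permutations), function(b)
      sum(rk[stats::runif(m) > 0.5]), numeric(1))
    exact <- FALSE; B <- n_permutations
  }
  tail_count <- switch(alternative,
    greater = sum(stats_perm >= obs - 1e-12),
    less = sum(stats_perm <= obs + 1e-12),
    two.sided = sum(abs(stats_perm - mu) >= abs(obs - mu) - 1e-12))
  p <- if (exact) tail_count / B else add_one_p(tail_count, B)
  new_test_result("Wilcoxon signed-rank permutation test", obs, min(p, 1),
                  B, seed, exact = exact, alternative = alternative,
                  n_pairs = m)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted p-values (same order as the input).
#' @export
fdr_adjust <- function(p_values) {
  assert_that(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
              "p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# L1 (median) regression by iteratively reweighted least squares.
l1_fit <- function(X, y, max_iter = 100L, tol = 1e-8, eps = 1e-6) {
  b <- stats::lm.fit(X, y)$coefficients
  for (it in seq_len(max_iter)) {
    r <- y - X %*% b
    w <- 1 / pmax(abs(r), eps)
    b_new <- stats::lm.wfit(X, y, as.numeric(w))$coefficients
    if (max(abs(b_new - b), na.rm = TRUE) < tol) return(b_new)
    b <- b_new
  }
  b
}

#' Median-regression screen for sex and age effects on an indicator
#'
#' Fits a median (least-absolute-deviation) regression of the indicator on
#' sex (0 = female, 1 = male), age, and their interaction, and tests each
#' coefficient by a residual-permutation scheme: residuals of the reduced
#' model (without the term) are permuted, added back to the reduced fit, and
#' the full model refitted. With a single sex present the sex and interaction
#' terms are dropped with a warning. The screen only reports; indicators are
#' never adjusted.
#'
#' @param indicator numeric indicator scores.
#' @param sex 0/1 vector.
#' @param age numeric vector (years).
#' @param n_permutations permutations per term.
#' @param seed integer seed.
#' @return data.frame with `term`, `estimate`, `p_value`.
#' @export
sexage_screen <- function(indicator, sex, age, n_permutations = 200L, seed = 1L) {
  y <- as.numeric(indicator)
  assert_that(length(y) >= 10, "need n >= 10")
  assert_that(all(sex %in% c(0, 1)), "sex must be coded 0/1")
  if (length(unique(sex)) < 2) {
    warning("only one sex present: sex and interaction terms dropped")
    X <- cbind(`(Intercept)` = 1, age = age)
    terms <- "age"
  } else {
    X <- cbind(`(Intercept)` = 1, sex = sex, age = age, `sex:age` = sex * age)
    terms <- c("sex", "age", "sex:age")
  }
  b_full <- l1_fit(X, y)
  set.seed(seed)
  res <- lapply(terms, function(tm) {
    keep <- colnames(X) != tm
    Xr <- X[, keep, drop = FALSE]
    br <- l1_fit(Xr, y)
    fit_r <- as.numeric(Xr %*% br)
    r <- y - fit_r
    perm <- vapply(seq_len(n_permutations), function(bb) {
      y_star <- fit_r + sample(r)
      abs(l1_fit(X, y_star)[tm])
    }, numeric(1))
    data.frame(term = tm, estimate = unname(b_full[tm]),
               p_value = add_one_p(sum(perm >= abs(b_full[tm]) - 1e-12),
                                   n_permutations))
  })
  do.call(rbind, res)
}

#' Consecutive-epoch trend tests for a within-subject indicator
#'
#' For every pair of consecutive epochs, the rank-based ANOVA-type test (one
#' group, two occasions) and the permutation signed-rank test are run on the
#' paired subject values; p-values are FDR-adjusted across the pairs within
#' each test family.
#'
#' @param ws_table data.frame with `subject_id`, `epoch_index` and the
#'   indicator column named by `response`.
#' @param response indicator column name.
#' @param n_permutations passed to [wsr_test()].
#' @param seed integer seed.
#' @param alpha significance level applied after adjustment.
#' @return data.frame with one row per (pair, method): `pair`, `from`, `to`,
#'   `method`, `statistic`, `p_value`, `p_adjusted`, `significant`,
#'   `direction` (`"increase"`, `"decrease"` or `"none"` by the sign of the
#'   median paired change).
#' @export
epoch_pair_trends <- function(ws_table, response, n_permutations = 2000L,
                              seed = 1L, alpha = 0.05) {
  epochs <- sort(unique(ws_table$epoch_index))
  assert_that(length(epochs) >= 2, "need >= 2 epochs")
  assert_that(all(diff(epochs) == 1),
              "epoch indices must be consecutive without gaps")
  ids <- unique(as.character(ws_table$subject_id))
  get_epoch <- function(t) {
    sel <- ws_table$epoch_index == t
    v <- ws_table[[response]][sel]
    names(v) <- as.character(ws_table$subject_id[sel])
    assert_that(setequal(names(v), ids), "missing epoch data for some subject")
    v[ids]
  }
  rows <- list()
  for (k in seq_len(length(epochs) - 1)) {
    t0 <- epochs[k]; t1 <- epochs[k + 1]
    b <- get_epoch(t0); a <- get_epoch(t1)
    pair_df <- data.frame(subject_id = rep(ids, 2),
                          epoch_index = rep(c(t0, t1), each = length(ids)),
                          value = c(b, a))
    ats <- ats_longitudinal(pair_df, response = "value",
                            groups = stats::setNames(rep("all", length(ids)), ids))
    wsr <- wsr_test(b, a, n_permutations = n_permutations,
                    seed = child_seed(seed, k))
    dir <- c("decrease", "none", "increase")[sign(stats::median(a - b)) + 2]
    rows[[length(rows) + 1]] <- data.frame(
      pair = sprintf("Ep%d.%d", t0, t1), from = t0, to = t1,
      method = c("ATS", "WSR"),
      statistic = c(ats$epoch$statistic, wsr$statistic),
      p_value = c(ats$epoch$p_value, wsr$p_value),
      direction = dir)
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  for (m in unique(out$method)) {
    sel <- out$method == m
    out$p_adjusted[sel] <- fdr_adjust(out$p_value[sel])
  }
  out$significant <- out$p_adjusted <= alpha
  out
}

#' Map a count of concordant significant procedures to a sensitivity level
#'
#' Defaults: zero significant procedures give `"none"`; all of them give
#' `"strong"`; at least half (rounded up) give `"medium"`; anything else is
#' `"weak"`.
#'
#' @param count significant procedures.
#' @param n_procedures procedures evaluated.
#' @return one of `"none"`, `"weak"`, `"medium"`, `"strong"`.
#' @export
sensitivity_level <- function(count, n_procedures) {
  assert_that(count >= 0 && count <= n_procedures, "count out of range")
  if (count == 0) return("none")
  if (count == n_procedures) return("strong")
  if (count >= ceiling(n_procedures / 2)) return("medium")
  "weak"
}

#' Sensitivity report for the within-subject indicators
#'
#' Aggregates the battery outcomes per indicator into levels for three
#' aspects: the rest-to-stand postural change (bootstrap CI, ATS and
#' signed-rank outcomes on the first epoch pair), the exercise fraction
#' (per consecutive-pair outcomes from the stand epoch onward; a pair is
#' supported when at least two procedures agree, and flagged `all_significant`
#' when every procedure does), and the group contrast (per-epoch two-sample
#' battery plus the overall longitudinal tests).
#'
#' @param rest_stand named logical vector of procedure outcomes for the
#'   rest-stand pair (e.g. `c(ci = TRUE, ats = TRUE, wsr = FALSE)`).
#' @param exercise_pairs data.frame with a `pair` column and one logical
#'   column per procedure, one row per consecutive pair in the exercise
#'   fraction.
#' @param group_epochs data.frame with an `epoch` column and one logical
#'   column per two-sample procedure.
#' @param group_overall named logical vector of overall longitudinal outcomes
#'   (e.g. `c(ats_group = ..., ats_interaction = ...)`).
#' @return list of class `sensitivity_report` with `levels` and supporting
#'   pair/epoch annotations.
#' @export
sensitivity_scores <- function(rest_stand, exercise_pairs, group_epochs,
                               group_overall) {
  lvl <- list()

  lvl$rest_stand <- sensitivity_level(sum(rest_stand), length(rest_stand))

  proc_cols <- setdiff(names(exercise_pairs), "pair")
  supp <- rowSums(exercise_pairs[, proc_cols, drop = FALSE]) >= 2
  full <- rowSums(exercise_pairs[, proc_cols, drop = FALSE]) == length(proc_cols)
  lvl$exercise_fraction <- sensitivity_level(sum(supp), nrow(exercise_pairs))
  exercise_support <- data.frame(pair = exercise_pairs$pair,
                                 supported = supp, all_significant = full)

  ep_cols <- setdiff(names(group_epochs), "epoch")
  gsupp <- rowSums(group_epochs[, ep_cols, drop = FALSE]) >= 2
  gfull <- rowSums(group_epochs[, ep_cols, drop = FALSE]) == length(ep_cols)
  overall_sig <- any(group_overall)
  lvl$sports_specialties <-
    if (!overall_sig && sum(gsupp) == 0) "none"
    else if (overall_sig && sum(gfull) >= 1) "strong"
    else if (overall_sig && sum(gsupp) >= 1) "medium"
    else "weak"
  group_support <- data.frame(epoch = group_epochs$epoch,
                              supported = gsupp, all_significant = gfull)

  structure(list(levels = lvl, exercise_support = exercise_support,
                 group_support = group_support,
                 group_overall = group_overall),
            class = "sensitivity_report")
}
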