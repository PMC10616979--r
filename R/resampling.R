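# Stratified balanced bootstrap over subjects, BCa confidence intervals, and
# the MEFA-specific bootstrap with Heywood discards and factor alignment.

#' Build a stratified balanced bootstrap plan over subjects
#'
#' Balanced within stratum: `B` copies of each stratum's subject list are
#' concatenated, shuffled within the stratum, and partitioned into the `B`
#' samples, so every subject appears exactly `B` times across the whole plan
#' and every sample preserves the stratum sizes.
#'
#' @param strata named character vector: subject id -> stratum label.
#' @param B number of bootstrap samples.
#' @param seed integer seed.
#' @return object of class `bootstrap_plan` with `index_matrix` (B x n matrix
#'   of subject ids), `strata`, `B`, `seed`.
#' @export
make_plan <- function(strata, B, seed = 1L) {
  assert_that(!is.null(names(strata)), "strata must be a named vector (subject -> stratum)")
  labs <- unique(unname(strata))
  counts <- table(unname(strata))
  assert_that(all(counts >= 1), "empty stratum")
  if (any(counts < 2)) {
    warning("stratum with a single subject: every bootstrap sample repeats it")
  }
  set.seed(seed)
  cols <- lapply(labs, function(s) {
    ids <- names(strata)[strata == s]
    pool <- sample(rep(ids, times = B))
    matrix(pool, nrow = B)               # B x n_s, each id exactly B times
  })
  idx <- do.call(cbind, cols)
  structure(list(index_matrix = idx, strata = strata, B = as.integer(B),
                 seed = as.integer(seed)),
            class = "bootstrap_plan")
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' The bias correction `z0` comes from the share of replicates below the
#' point estimate; the acceleration from the jackknife influence values (or
#' user-supplied influence values, the infinitesimal-jackknife variant). When
#' all replicates fall on one side of the estimate the bias correction is
#' undefined and the plain percentile interval is returned with a warning;
#' a constant replicate distribution gives the degenerate interval.
#'
#' @param estimate point estimate.
#' @param replicates bootstrap replicate values (>= 100 retained).
#' @param jackknife leave-one-out estimates (or influence values with
#'   `influence = TRUE`).
#' @param level confidence level.
#' @param influence interpret `jackknife` as influence values directly.
#' @return named numeric `c(low, high)` with attribute `method`.
#' @export
bca_interval <- function(estimate, replicates, jackknife = NULL, level = 0.95,
                         influence = FALSE) {
  reps <- as.numeric(replicates)
  assert_that(length(reps) >= 100, "need >= 100 retained replicates")
  alpha <- (1 - level) / 2
  if (stats::sd(reps) == 0) {
    return(structure(c(low = reps[1], high = reps[1]), method = "degenerate"))
  }
  prop <- mean(reps < estimate) + 0.5 * mean(reps == estimate)
  if (prop <= 0 || prop >= 1) {
    warning("all replicates on one side of the estimate: falling back to percentile interval")
    qs <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE, type = 6)
    return(structure(c(low = qs[1], high = qs[2]), method = "percentile"))
  }
  z0 <- stats::qnorm(prop)
  if (is.null(jackknife)) {
    a <- 0
  } else {
    u <- if (influence) as.numeric(jackknife)
         else mean(jackknife) - as.numeric(jackknife)   # influence approximation
    denom <- sum(u^2)^1.5
    a <- if (denom == 0) 0 else sum(u^3) / (6 * denom)
  }
  zq <- stats::qnorm(c(alpha, 1 - alpha))
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
  qs <- stats::quantile(reps, adj, names = FALSE, type = 6)
  structure(c(low = qs[1], high = qs[2]), method = "bca", z0 = z0, accel = a)
}

# Rebuild a panel from a vector of (possibly repeated) subject ids; repeated
# subjects get distinct replicate ids so the two-level structure is intact.
resample_panel <- function(panel, subject_ids) {
  pieces <- lapply(seq_along(subject_ids), function(k) {
    block <- panel[panel$subject_id == subject_ids[k], , drop = FALSE]
    block$subject_id <- sprintf("b%03d_%s", k, subject_ids[k])
    block
  })
  do.call(rbind, pieces)
}

#' Bootstrap the two-level factor solution over subjects
#'
#' Each replicate rebuilds the panel from the plan's sampled subjects (a
#' subject always contributes all of its epochs), reruns the decomposition,
#' principal-axis extraction and varimax rotation at the reference factor
#' counts, and aligns the replicate loadings to the reference solution by
#' greedy congruence matching with sign flips. Replicates with a Heywood
#' communality or an alignment congruence below `align_threshold` are
#' discarded and counted.
#'
#' @param panel proxy panel data.frame.
#' @param plan a [make_plan()] plan over the panel's subjects.
#' @param fit reference [mefa_fit()] (fixes `q_b`, `q_w` and the alignment
#'   targets).
#' @param level confidence level for the intervals.
#' @param align_threshold minimum matched congruence per factor.
#' @param proxies proxy column names.
#' @return object of class `mefa_bootstrap`: per-level lists with loading
#'   CI arrays (`low`/`high`, p x q), `variance_pct` summaries, `kmo`
#'   summaries, and bookkeeping `n_retained`, `n_heywood`, `n_unaligned`.
#' @export
bootstrap_mefa <- function(panel, plan, fit, level = 0.95,
                           align_threshold = 0.7, proxies = PROXY_NAMES) {
  assert_that(inherits(plan, "bootstrap_plan"), "plan must be a bootstrap_plan")
  assert_that(inherits(fit, "mefa_fit"), "fit must be a mefa_fit")
  B <- plan$B
  q_b <- fit$bs$q; q_w <- fit$ws$q

  one_rep <- function(subject_ids) {
    rp <- resample_panel(panel, subject_ids)
    dec <- tryCatch(decompose_panel(rp, proxies), error = function(e) NULL)
    if (is.null(dec)) return(list(status = "heywood"))
    level_fit <- function(R, q, ref) {
      pf <- tryCatch(principal_factor(R, q), error = function(e) NULL)
      if (is.null(pf) || pf$heywood) return(NULL)
      L <- varimax_rotate(pf$loadings)
      al <- tucker_congruence(L, ref)
      if (any(al$congruence < align_threshold)) return("unaligned")
      sweep(L[, al$perm, drop = FALSE], 2, al$signs, "*")
    }
    Lb <- level_fit(dec$R_B, q_b, fit$bs$loadings)
    Lw <- level_fit(dec$R_W, q_w, fit$ws$loadings)
    if (is.null(Lb) || is.null(Lw)) return(list(status = "heywood"))
    if (identical(Lb, "unaligned") || identical(Lw, "unaligned")) {
      return(list(status = "unaligned"))
    }
    list(status = "ok", Lb = Lb, Lw = Lw,
         var_b = summarize_solution(Lb)$variance_pct,
         var_w = summarize_solution(Lw)$variance_pct,
         kmo_b = as.numeric(dec$kmo_b), kmo_w = as.numeric(dec$kmo_w))
  }

  reps <- lapply(seq_len(B), function(b) one_rep(plan$index_matrix[b, ]))
  status <- vapply(reps, function(r) r$status, character(1))
  ok <- reps[status == "ok"]
  n_retained <- length(ok)
  if (n_retained < B / 2) {
    stop_mefahrv("more than half of the bootstrap replicates were discarded (%d heywood, %d unaligned of %d)",
                 sum(status == "heywood"), sum(status == "unaligned"), B)
  }

  # jackknife (leave-one-subject-out) for the acceleration
  ids <- unique(as.character(panel$subject_id))
  jack <- lapply(ids, function(id) {
    sub <- panel[panel$subject_id != id, , drop = FALSE]
    tryCatch({
      dec <- decompose_panel(sub, proxies)
      lf <- function(R, q, ref) {
        pf <- principal_factor(R, q)
        L <- varimax_rotate(pf$loadings)
        al <- tucker_congruence(L, ref)
        sweep(L[, al$perm, drop = FALSE], 2, al$signs, "*")
      }
      list(Lb = lf(dec$R_B, q_b, fit$bs$loadings),
           Lw = lf(dec$R_W, q_w, fit$ws$loadings))
    }, error = function(e) NULL)
  })
  n_jack_failed <- sum(vapply(jack, is.null, logical(1)))
  if (n_jack_failed > 0) {
    warning(sprintf("%d leave-one-out refit(s) failed; acceleration estimated from the remaining subjects",
                    n_jack_failed))
    jack <- Filter(Negate(is.null), jack)
  }

  ci_matrix <- function(get_rep, get_jack, ref) {
    p <- nrow(ref); q <- ncol(ref)
    low <- high <- matrix(NA_real_, p, q, dimnames = dimnames(ref))
    for (j in seq_len(p)) for (k in seq_len(q)) {
      reps_jk <- vapply(ok, function(r) get_rep(r)[j, k], numeric(1))
      jk <- vapply(jack, function(r) get_jack(r)[j, k], numeric(1))
      ci <- bca_interval(ref[j, k], reps_jk, jk, level = level)
      low[j, k] <- ci["low"]; high[j, k] <- ci["high"]
    }
    list(low = low, high = high)
  }
  ci_vector <- function(values, ref) {
    vapply(seq_along(ref), function(k) {
      bca_interval(ref[k], vapply(ok, values, numeric(1), k), level = level)
    }, numeric(2))
  }

  load_b <- ci_matrix(function(r) r$Lb, function(r) r$Lb, fit$bs$loadings)
  load_w <- ci_matrix(function(r) r$Lw, function(r) r$Lw, fit$ws$loadings)
  var_b <- ci_vector(function(r, k) r$var_b[k], fit$bs$summary$variance_pct)
  var_w <- ci_vector(function(r, k) r$var_w[k], fit$ws$summary$variance_pct)
  kmo_b <- bca_interval(as.numeric(fit$decomposition$kmo_b),
                        vapply(ok, function(r) r$kmo_b, numeric(1)), level = level)
  kmo_w <- bca_interval(as.numeric(fit$decomposition$kmo_w),
                        vapply(ok, function(r) r$kmo_w, numeric(1)), level = level)

  structure(list(loadings_bs = load_b, loadings_ws = load_w,
                 variance_pct_bs = var_b, variance_pct_ws = var_w,
                 kmo_bs = kmo_b, kmo_ws = kmo_w,
                 B = B, level = level, n_retained = n_retained,
                 n_heywood = sum(status == "heywood"),
                 n_unaligned = sum(status == "unaligned"),
                 seed = plan$seed),
            class = "mefa_bootstrap")
}

#' @export
print.mefa_bootstrap <- function(x, ...) {
  cat(sprintf("<mefa_bootstrap> %d/%d replicates retained (%d Heywood, %d unaligned), level %.2f\n",
              x$n_retained, x$B, x$n_heywood, x$n_unaligned, x$level))
  invisible(x)
}

#' Bootstrap confidence intervals for per-epoch indicator medians
#'
#' Reuses the subject-level plan: per replicate the per-epoch median of the
#' indicator over the sampled subjects is recomputed, and percentile-based
#' BCa intervals are formed per epoch.
#'
#' @param ws_table data.frame with `subject_id`, `epoch_index` and the
#'   indicator column `response`.
#' @param plan a [make_plan()] plan.
#' @param response indicator column name.
#' @param level confidence level.
#' @return data.frame `epoch`, `median`, `low`, `high`.
#' @export
bootstrap_epoch_medians <- function(ws_table, plan, response, level = 0.95) {
  epochs <- sort(unique(ws_table$epoch_index))
  ids <- unique(as.character(ws_table$subject_id))
  val <- matrix(NA_real_, length(ids), length(epochs),
                dimnames = list(ids, epochs))
  for (k in seq_len(nrow(ws_table))) {
    val[as.character(ws_table$subject_id[k]),
        as.character(ws_table$epoch_index[k])] <- ws_table[[response]][k]
  }
  est <- apply(val, 2, stats::median)
  reps <- apply(plan$index_matrix, 1, function(s)
    apply(val[s, , drop = FALSE], 2, stats::median))   # epochs x B
  jack <- vapply(seq_along(ids), function(i)
    apply(val[-i, , drop = FALSE], 2, stats::median), numeric(length(epochs)))
  out <- lapply(seq_along(epochs), function(t) {
    ci <- bca_interval(est[t], reps[t, ], jack[t, ], level = level)
    data.frame(epoch = epochs[t], median = est[t],
               low = ci["low"], high = ci["high"])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
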