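# Two-level exploratory factor analysis of a proxy panel: between-subject /
# within-subject decomposition, KMO adequacy, iterated principal-axis
# extraction, varimax rotation, factor retention, regression factor scores,
# and the kernel-CDF (PKDE) transform to [0, 100] indicators.

#' Decompose a proxy panel into between- and within-subject parts
#'
#' The subject-averaged matrix `Xbar` (one row per subject, the mean over
#' epochs) carries the between-subject (BS) information; the within-centred
#' matrix `Xtilde` (each row minus its subject's mean) carries the
#' within-subject (WS) information. `R_B` is the Pearson correlation matrix of
#' the `Xbar` columns and `R_W` the pooled within correlation computed over
#' all subject-epoch rows of `Xtilde`.
#'
#' @param panel proxy panel data.frame (keys `subject_id`, `group`,
#'   `epoch_index` plus proxy columns).
#' @param proxies character vector of proxy column names.
#' @return list with `xbar` (n x p, rownames = subject ids), `xtilde`
#'   (nT x p with `subject_id`/`epoch_index` attributes), `R_B`, `R_W`,
#'   `kmo_b`, `kmo_w`, `groups` (per-subject group labels), `n`, `T`.
#' @export
decompose_panel <- function(panel, proxies = PROXY_NAMES) {
  assert_that(all(proxies %in% names(panel)), "panel lacks proxy columns")
  assert_that(!anyNA(panel[, proxies]), "panel contains missing proxies")
  subj <- as.character(panel$subject_id)
  ids <- unique(subj)
  n <- length(ids)
  T <- nrow(panel) / n
  assert_that(n >= 3, "need at least 3 subjects")
  assert_that(T >= 2 && all(table(subj) == T), "every subject needs the same number (>= 2) of epochs")

  X <- as.matrix(panel[, proxies])
  xbar <- rowsum(X, subj)[ids, , drop = FALSE] / T
  xtilde <- X - xbar[subj, , drop = FALSE]

  sd_b <- apply(xbar, 2, stats::sd)
  sd_w <- apply(xtilde, 2, stats::sd)
  if (any(sd_b == 0)) stop_mefahrv("zero between-subject variance for proxy %s",
                                   paste(proxies[sd_b == 0], collapse = ", "))
  if (any(sd_w == 0)) stop_mefahrv("zero within-subject variance for proxy %s",
                                   paste(proxies[sd_w == 0], collapse = ", "))
  R_B <- stats::cor(xbar)
  R_W <- stats::cor(xtilde)
  groups <- panel$group[match(ids, subj)]
  attr(xtilde, "subject_id") <- subj
  attr(xtilde, "epoch_index") <- panel$epoch_index
  list(xbar = xbar, xtilde = xtilde, R_B = R_B, R_W = R_W,
       kmo_b = kmo(R_B), kmo_w = kmo(R_W),
       groups = stats::setNames(as.character(groups), ids), n = n, T = T)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' `KMO = sum(r^2) / (sum(r^2) + sum(q^2))` over off-diagonal pairs, where `q`
#' are the anti-image partial correlations obtained from the inverse
#' correlation matrix. Values below 0.6 conventionally indicate a poor basis
#' for factor analysis.
#'
#' @param R correlation matrix.
#' @return KMO value in [0, 1] with attribute `adequate` (KMO >= 0.6).
#' @export
kmo <- function(R) {
  R <- as.matrix(R)
  inv <- tryCatch(solve(R), error = function(e)
    stop_mefahrv("singular correlation matrix: KMO undefined"))
  d <- 1 / sqrt(diag(inv))
  partial <- -inv * outer(d, d)
  off <- upper.tri(R)
  ssr <- sum(R[off]^2)
  ssq <- sum(partial[off]^2)
  if (ssr + ssq == 0) stop_mefahrv("no correlation structure: KMO is 0/0")
  structure(ssr / (ssr + ssq), adequate = ssr / (ssr + ssq) >= 0.6)
}

#' Iterated principal-axis factor extraction
#'
#' Starts from squared multiple correlations as initial communalities,
#' eigen-decomposes the reduced correlation matrix, takes the top-q
#' eigenvectors scaled by the root eigenvalues as loadings, and iterates the
#' communalities to convergence. Communality updates that barely overshoot 1
#' (by at most `heywood_tol`) are projected back onto the boundary and the
#' iteration continues — a standard boundary treatment for highly correlated
#' indicator pairs; a larger overshoot is a genuine Heywood case, which stops
#' the iteration and flags the solution so the caller can abort (primary
#' fits) or discard (bootstrap replicates).
#'
#' @param R correlation matrix.
#' @param q number of factors (1 <= q < p).
#' @param max_iter,tol iteration controls.
#' @param heywood_tol largest tolerated communality overshoot above 1 before
#'   the solution is flagged as a Heywood case.
#' @return list with `loadings` (p x q), `communalities`, `heywood`,
#'   `iterations`, `converged`.
#' @export
principal_factor <- function(R, q, max_iter = 200L, tol = 1e-7,
                             heywood_tol = 0.05) {
  R <- as.matrix(R)
  p <- ncol(R)
  assert_that(is.numeric(q) && length(q) == 1 && q >= 1 && q < p,
              "q must satisfy 1 <= q < p")
  inv <- tryCatch(solve(R), error = function(e)
    stop_mefahrv("singular correlation matrix"))
  h <- 1 - 1 / diag(inv)                    # initial SMC communalities
  heywood <- FALSE
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rh <- R
    diag(Rh) <- h
    eg <- eigen(Rh, symmetric = TRUE)
    lam <- eg$values[1:q]
    L <- eg$vectors[, 1:q, drop = FALSE] %*% diag(sqrt(pmax(lam, 0)), q)
    h_new <- rowSums(L^2)
    if (any(h_new > 1 + heywood_tol)) {
      heywood <- TRUE
      h <- h_new
      break
    }
    h_new <- pmin(h_new, 1)
    if (max(abs(h_new - h)) < tol) {
      h <- h_new
      dimnames(L) <- list(colnames(R), paste0("F", 1:q))
      return(list(loadings = L, communalities = h, heywood = FALSE,
                  iterations = it, converged = TRUE))
    }
    h <- h_new
  }
  dimnames(L) <- list(colnames(R), paste0("F", 1:q))
  if (!heywood) {
    stop_mefahrv("principal-axis iteration did not converge in %d steps (last max change %.2e)",
                 max_iter, max(abs(rowSums(L^2) - h)))
  }
  list(loadings = L, communalities = h, heywood = TRUE,
       iterations = it, converged = FALSE)
}

#' Varimax rotation with deterministic ordering and sign convention
#'
#' Orthogonal rotation maximizing the varimax criterion with Kaiser row
#' normalization. Row sums of squares (communalities) are preserved. Columns
#' are reordered by decreasing explained variance and each column's sign is
#' fixed so its largest-magnitude loading is positive, which makes rotated
#' tables reproducible. With a single factor the input is returned unchanged.
#'
#' @param loadings p x q loading matrix.
#' @return rotated loading matrix.
#' @export
varimax_rotate <- function(loadings) {
  L <- as.matrix(loadings)
  if (ncol(L) >= 2) {
    L <- unclass(stats::varimax(L, normalize = TRUE, eps = 1e-10)$loadings)
  }
  ord <- order(colSums(L^2), decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  for (k in seq_len(ncol(L))) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) L[, k] <- -L[, k]
  }
  colnames(L) <- paste0("F", seq_len(ncol(L)))
  L
}

#' Choose the number of factors to retain
#'
#' Default rule: candidate factors are those whose eigenvalue of the
#' correlation matrix exceeds `eigen_threshold`; the candidate count is then
#' reduced until every retained, rotated factor is interpretable (at least one
#' loading with absolute value `>= marker_threshold`). A cumulative-variance
#' floor can additionally be required. All knobs are explicit and the returned
#' rationale records each decision.
#'
#' @param R correlation matrix.
#' @param eigen_threshold Kaiser-style eigenvalue cut (default 1).
#' @param cum_variance_floor minimum cumulative share (of p) explained by the
#'   retained rotated factors, in [0, 1]; 0 disables the check.
#' @param marker_threshold interpretability marker |loading| cut (default 0.6).
#' @return integer q with attribute `rationale`.
#' @export
choose_n_factors <- function(R, eigen_threshold = 1, cum_variance_floor = 0,
                             marker_threshold = 0.6) {
  R <- as.matrix(R)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  q <- sum(ev > eigen_threshold)
  notes <- sprintf("%d eigenvalue(s) > %.3g", q, eigen_threshold)
  while (q >= 1) {
    fit <- tryCatch(principal_factor(R, q), error = function(e) NULL)
    if (is.null(fit) || fit$heywood) {
      notes <- c(notes, sprintf("q = %d rejected (inadmissible fit)", q))
      q <- q - 1
      next
    }
    L <- varimax_rotate(fit$loadings)
    markers <- apply(abs(L) >= marker_threshold, 2, any)
    if (!all(markers)) {
      notes <- c(notes, sprintf("q = %d rejected (%d factor(s) without a |loading| >= %.2g marker)",
                                q, sum(!markers), marker_threshold))
      q <- q - 1
      next
    }
    cum <- sum(L^2) / nrow(L)
    if (cum < cum_variance_floor) {
      stop_mefahrv("retained factors explain %.1f%% < required %.1f%%: relax the thresholds",
                   100 * cum, 100 * cum_variance_floor)
    }
    notes <- c(notes, sprintf("q = %d accepted (cumulative variance %.1f%%)", q, 100 * cum))
    return(structure(as.integer(q), rationale = notes))
  }
  stop_mefahrv("no factor qualifies under the current thresholds: %s",
               paste(notes, collapse = "; "))
}

#' Regression (Thurstone) factor scores
#'
#' `scores = Z R^{-1} L` for standardized data `Z`, inverse correlation
#' matrix and loading matrix `L`.
#'
#' @param data numeric matrix (rows = observations).
#' @param loadings p x q loading matrix.
#' @param R the level's correlation matrix.
#' @param center,scale standardization statistics; defaults to the column
#'   means and standard deviations of `data`.
#' @return n x q score matrix.
#' @export
factor_scores <- function(data, loadings, R, center = NULL, scale = NULL) {
  X <- as.matrix(data)
  center <- center %||% colMeans(X)
  scale <- scale %||% apply(X, 2, stats::sd)
  assert_that(all(scale > 0), "zero-variance column: cannot standardize")
  Z <- sweep(sweep(X, 2, center), 2, scale, "/")
  W <- tryCatch(solve(as.matrix(R), as.matrix(loadings)),
                error = function(e) stop_mefahrv("singular correlation matrix in factor scoring"))
  S <- Z %*% W
  colnames(S) <- colnames(loadings)
  S
}

#' Kernel-CDF (PKDE) transform of factor scores to [0, 100]
#'
#' The indicator is `100 * Fhat(x)` where `Fhat` is the cumulative
#' distribution of a Gaussian-kernel density estimate of the score sample
#' (Sheather-Jones plug-in bandwidth). The transform is strictly monotone, so
#' it preserves score ranks exactly while mapping onto the [0, 100] scale.
#'
#' @param scores numeric vector of factor scores (>= 5 distinct values).
#' @param eval values to transform; defaults to `scores` themselves.
#' @return numeric vector of indicator scores in [0, 100].
#' @export
pkde_transform <- function(scores, eval = scores) {
  x <- as.numeric(scores)
  assert_that(length(unique(x)) >= 5,
              "need at least 5 distinct scores for the kernel-CDF transform")
  h <- tryCatch(stats::bw.SJ(x), error = function(e) stats::bw.nrd0(x))
  vapply(as.numeric(eval),
         function(v) 100 * mean(stats::pnorm((v - x) / h)), numeric(1))
}

#' Variance and communality summary of a loading matrix
#'
#' Per factor: percent of total variance `100 * SSQ(column) / p`, the running
#' cumulative percent, and the share of the total communality; plus the total
#' communality (total reproduced variance) `sum(loadings^2)`.
#'
#' @param loadings p x q loading matrix.
#' @return list `variance_pct`, `cumulative_pct`, `total_communality`,
#'   `communality_share_pct`, `cumulative_communality_pct`.
#' @export
summarize_solution <- function(loadings) {
  L <- as.matrix(loadings)
  ssq <- colSums(L^2)
  p <- nrow(L)
  total <- sum(ssq)
  list(variance_pct = 100 * ssq / p,
       cumulative_pct = cumsum(100 * ssq / p),
       total_communality = total,
       communality_share_pct = 100 * ssq / total,
       cumulative_communality_pct = cumsum(100 * ssq / total))
}

#' Label factors by the typology of their marker proxies
#'
#' Markers are loadings with absolute value at least `marker_threshold`. A
#' factor whose markers are all time-based proxies is the Amplitude domain;
#' markers confined to the regularity / 0V-pattern pair are Signal
#' Self-Similarity; opposite-signed markers on the LF/HF normalized units are
#' the Oscillatory domain; markers mixing those ratio-based subsets indicate
#' the broader Frequency domain. Anything else gets a generic label with a
#' warning.
#'
#' @param loadings rotated loading matrix with proxy row names.
#' @param marker_threshold marker cut (default 0.6).
#' @return character vector of labels, one per factor.
#' @export
label_factors <- function(loadings, marker_threshold = 0.6) {
  L <- as.matrix(loadings)
  assert_that(!is.null(rownames(L)), "loadings need proxy row names")
  sss_set <- c("RR_Ro", "P0v")
  osc_set <- c("RR_LFnu", "RR_HFnu")
  vapply(seq_len(ncol(L)), function(k) {
    mk <- rownames(L)[abs(L[, k]) >= marker_threshold]
    if (length(mk) == 0) {
      warning(sprintf("factor %d has no marker loadings; generic label used", k))
      return(sprintf("Factor %d", k))
    }
    if (all(mk %in% TIME_BASED_PROXIES)) return("Amplitude")
    if (all(mk %in% sss_set)) return("Signal Self-Similarity")
    if (all(mk %in% osc_set) &&
        length(mk) == 2 && prod(L[mk, k]) < 0) return("Oscillatory")
    if (all(mk %in% RATIO_BASED_PROXIES)) return("Frequency")
    warning(sprintf("factor %d mixes proxy typologies; generic label used", k))
    sprintf("Factor %d", k)
  }, character(1))
}

# Short indicator code from a label and level, e.g. AMP-BS-Ind, SSS-WS-Ind.
indicator_code <- function(labels, level) {
  code <- c("Amplitude" = "AMP", "Frequency" = "FRE",
            "Signal Self-Similarity" = "SSS", "Oscillatory" = "OSC")
  out <- ifelse(labels %in% names(code), code[labels],
                paste0("F", seq_along(labels)))
  paste0(out, "-", level, "-Ind")
}

#' Fit the full two-level factor model and derive indicators
#'
#' Runs [decompose_panel()], chooses (or accepts) the factor counts, extracts
#' and rotates the loadings at both levels, computes regression factor scores
#' (BS scores from the subject averages, WS scores from all subject-epoch
#' centred rows), and re-expresses each factor's scores through the kernel-CDF
#' transform as indicators on [0, 100].
#'
#' @param panel proxy panel data.frame.
#' @param q_b,q_w factor counts; `NULL` invokes [choose_n_factors()].
#' @param proxies proxy column names.
#' @param marker_threshold interpretability/label marker cut.
#' @return object of class `mefa_fit`: `decomposition`, `bs`/`ws` (each a
#'   `factor_solution` with loadings, communalities, variance summary, labels,
#'   Heywood flag), `bs_scores`, `ws_scores` (raw factor scores),
#'   `bs_indicators` (subject x qB data.frame), `ws_indicators`
#'   (subject-epoch x qW data.frame).
#' @export
mefa_fit <- function(panel, q_b = NULL, q_w = NULL, proxies = PROXY_NAMES,
                     marker_threshold = 0.6) {
  dec <- decompose_panel(panel, proxies)
  q_b <- as.vector(q_b %||% choose_n_factors(dec$R_B, marker_threshold = marker_threshold))
  q_w <- as.vector(q_w %||% choose_n_factors(dec$R_W, marker_threshold = marker_threshold))

  fit_level <- function(R, q, level) {
    pf <- principal_factor(R, q)
    if (pf$heywood) {
      stop_mefahrv("%s principal-axis solution is a Heywood case (max communality %.3f)",
                   level, max(pf$communalities))
    }
    L <- varimax_rotate(pf$loadings)
    structure(list(level = level, q = q, loadings = L,
                   communalities = rowSums(L^2),
                   summary = summarize_solution(L),
                   labels = label_factors(L, marker_threshold),
                   heywood = FALSE),
              class = "factor_solution")
  }
  bs <- fit_level(dec$R_B, q_b, "BS")
  ws <- fit_level(dec$R_W, q_w, "WS")

  s_b <- factor_scores(dec$xbar, bs$loadings, dec$R_B)
  s_w <- factor_scores(dec$xtilde, ws$loadings, dec$R_W)

  bs_ind <- as.data.frame(apply(s_b, 2, pkde_transform))
  names(bs_ind) <- indicator_code(bs$labels, "BS")
  bs_ind <- cbind(data.frame(subject_id = rownames(dec$xbar),
                             group = unname(dec$groups)), bs_ind)
  ws_ind <- as.data.frame(apply(s_w, 2, pkde_transform))
  names(ws_ind) <- indicator_code(ws$labels, "WS")
  ws_ind <- cbind(data.frame(subject_id = attr(dec$xtilde, "subject_id"),
                             group = unname(dec$groups[attr(dec$xtilde, "subject_id")]),
                             epoch_index = attr(dec$xtilde, "epoch_index")),
                  ws_ind)
  structure(list(decomposition = dec, bs = bs, ws = ws,
                 bs_scores = s_b, ws_scores = s_w,
                 bs_indicators = bs_ind, ws_indicators = ws_ind),
            class = "mefa_fit")
}

#' @export
print.mefa_fit <- function(x, ...) {
  cat(sprintf("<mefa_fit> %d subjects x %d epochs, KMO BS %.3f / WS %.3f\n",
              x$decomposition$n, x$decomposition$T,
              x$decomposition$kmo_b, x$decomposition$kmo_w))
  cat(sprintf("  BS: q = %d (%s), %.1f%% of variance\n", x$bs$q,
              paste(x$bs$labels, collapse = ", "),
              max(x$bs$summary$cumulative_pct)))
  cat(sprintf("  WS: q = %d (%s), %.1f%% of variance\n", x$ws$q,
              paste(x$ws$labels, collapse = ", "),
              max(x$ws$summary$cumulative_pct)))
  invisible(x)
}

#' Tucker congruence between two loading matrices
#'
#' Column-wise congruence after greedy matching with sign flips: each column
#' of `L` is matched to the reference column with the largest absolute
#' congruence, without replacement.
#'
#' @param L,ref loading matrices with equal row counts.
#' @return list `congruence` (per matched reference column), `perm` (matched
#'   column of `L` for each reference column), `signs`.
#' @export
tucker_congruence <- function(L, ref) {
  L <- as.matrix(L); ref <- as.matrix(ref)
  assert_that(nrow(L) == nrow(ref), "row mismatch")
  phi <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  qr_ <- ncol(ref)
  C <- outer(seq_len(qr_), seq_len(ncol(L)),
             Vectorize(function(i, j) phi(ref[, i], L[, j])))
  perm <- integer(qr_); signs <- numeric(qr_); cong <- numeric(qr_)
  col_free <- rep(TRUE, ncol(L))
  row_free <- rep(TRUE, qr_)
  for (step in seq_len(qr_)) {
    A <- abs(C)
    A[!row_free, ] <- -Inf
    A[, !col_free] <- -Inf
    best <- which(A == max(A), arr.ind = TRUE)[1, ]
    i <- best[1]; j <- best[2]
    perm[i] <- j; signs[i] <- sign(C[i, j]); cong[i] <- abs(C[i, j])
    col_free[j] <- FALSE
    row_free[i] <- FALSE
  }
  list(congruence = cong, perm = perm, signs = signs)
}
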