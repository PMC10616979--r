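#' @keywords internal
"_PACKAGE"

# Canonical proxy names, in the panel column order used throughout.
PROXY_NAMES <- c("HR", "RR_RMS", "RR_TP", "RR_LFa", "RR_HFa", "RR_LFnu",
                 "RR_HFnu", "RMSSD", "AC", "DC", "RR_Ro", "P0v")

# Proxy typologies used for factor labelling: values carrying a time unit vs
# normalized (ratio) values.
TIME_BASED_PROXIES  <- c("HR", "RR_RMS", "RR_TP", "RR_LFa", "RR_HFa",
                         "RMSSD", "AC", "DC")
RATIO_BASED_PROXIES <- c("RR_LFnu", "RR_HFnu", "RR_Ro", "P0v")

#' Derive a child RNG seed from a base seed and a counter
#'
#' A counter-based scheme so that any subject-epoch subset of a simulated
#' study is reproducible on its own: the child seed depends only on the base
#' seed and the (subject, epoch) counter, never on how many other series were
#' generated before it. Kept strictly below 2^31 - 1.
#'
#' @param seed integer base seed.
#' @param counter non-negative integer stream index.
#' @return an integer seed.
#' @export
child_seed <- function(seed, counter) {
  stopifnot(is.numeric(seed), length(seed) == 1L,
            is.numeric(counter), length(counter) == 1L, counter >= 0)
  # affine hash in double precision; all intermediates < 2^52 so exact
  m <- 2147483629
  as.integer(((abs(seed) %% m) * 48271 + 65537 * (counter %% 32003)) %% m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reference rotated loading matrices from a published athlete study
#'
#' Varimax-rotated loading matrices reported for two groups of athletes
#' measured over the nine epochs of a graded cycling protocol: a 12 x 2
#' between-subject solution (amplitude, frequency) and a 12 x 3
#' within-subject solution (amplitude, signal self-similarity, oscillatory).
#' Used as congruence references and in worked examples of the
#' factor-summary arithmetic.
#'
#' @param level `"between"` or `"within"`.
#' @return numeric loadings matrix with proxy rownames.
#' @export
load_reference_loadings <- function(level = c("between", "within")) {
  level <- match.arg(level)
  file <- if (level == "between") "reference_bs_loadings.csv" else "reference_ws_loadings.csv"
  path <- system.file("extdata", file, package = "mefahrv", mustWork = TRUE)
  df <- utils::read.csv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$proxy
  m
}

stop_mefahrv <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_mefahrv(fmt, ...)
  invisible(TRUE)
}
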