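#' Build functional connectomes from processed time series
#'
#' Edge weights are pairwise partial correlations between regional time
#' series (conditioning on all other regions), obtained from the inverse
#' sample covariance `P`: `r_ij = -P_ij / sqrt(P_ii * P_jj)`, then
#' variance-stabilized by Fisher's z-transformation `atanh(r)`. Negative
#' partial correlations are excluded (graph measures are not defined for
#' signed edges): weights are `atanh(r)` where `r > 0` and 0 otherwise.
#' The binary functional connectome marks connections where `z > 0`.
#'
#' @param ts regions x volumes processed matrix (from
#'   [preprocess_timeseries()]); needs more volumes than regions unless
#'   shrinkage is enabled.
#' @param shrinkage diagonal shrinkage intensity `lambda` in `[0, 1)`:
#'   the covariance is replaced by
#'   `(1 - lambda) * S + lambda * mean(diag(S)) * I`. Default 0 (direct
#'   inversion; appropriate when volumes greatly exceed regions).
#' @param subject_id,timepoint_index optional provenance tags.
#' @return Named list of `connectome` objects `func_w` and `func_binary`.
#' @examples
#' x <- matrix(rnorm(5 * 300), 5, 300,
#'             dimnames = list(paste0("r", 1:5), NULL))
#' fc <- build_functional(x)
#' fc$func_w$kind
#' @export
build_functional <- function(ts, shrinkage = 0,
                             subject_id = NA_character_,
                             timepoint_index = NA_integer_) {
  ts <- as.matrix(ts)
  p <- nrow(ts)
  nvol <- ncol(ts)
  if (p < 2) stop("need at least 2 regions")
  if (shrinkage < 0 || shrinkage >= 1) stop("shrinkage must be in [0, 1)")
  if (shrinkage == 0 && nvol <= p)
    stop("covariance is singular with volumes <= regions; ",
         "enable diagonal shrinkage (shrinkage > 0) or supply more volumes")
  nodes <- rownames(ts) %||% sprintf("node%03d", seq_len(p))

  S <- cov(t(ts))
  if (shrinkage > 0)
    S <- (1 - shrinkage) * S + shrinkage * mean(diag(S)) * diag(p)
  P <- tryCatch(solve(S), error = function(e)
    stop("sample covariance is numerically singular; ",
         "enable diagonal shrinkage (shrinkage > 0)", call. = FALSE))

  d <- sqrt(diag(P))
  R <- -P / tcrossprod(d)
  diag(R) <- 0
  R[R < 0] <- 0
  z <- atanh(pmin(R, 1 - 1e-12))
  bin <- (z > 0) * 1

  list(
    func_w = connectome(z, nodes, "func_w", subject_id, timepoint_index),
    func_binary = connectome(bin, nodes, "func_binary", subject_id,
                             timepoint_index)
  )
}
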