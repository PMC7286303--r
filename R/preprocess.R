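#' Preprocess regional time series
#'
#' Per region: linear detrend, z-score (mean 0, sd 1), zero-phase
#' band-pass to the resting-state band, then least-squares
#' residualization against the nuisance regressors (motion parameters,
#' white-matter and CSF mean signals). Constant (degenerate) regions
#' come out as all-zero rows.
#'
#' The band-pass is a 4th-order Butterworth applied forward and backward
#' (zero phase) via [signal::filtfilt()]. Note that a recursive filter is
#' not an exact projection: re-running the pipeline on its own output
#' reproduces the signal up to a per-region rescaling and slight
#' attenuation near the band edges (shape-idempotent, not elementwise
#' idempotent).
#'
#' @param ts regions x volumes numeric matrix (>= 3 volumes).
#' @param nuisance optional volumes x k matrix of nuisance regressors.
#' @param band passband in Hz, default `c(0.01, 0.1)`; the upper edge
#'   must be below the Nyquist frequency `1 / (2 * tr)`.
#' @param tr repetition time in seconds (default 2).
#' @return processed matrix, same shape and dimnames as `ts`.
#' @examples
#' x <- matrix(rnorm(2 * 200), 2, 200)
#' p <- preprocess_timeseries(x, tr = 2)
#' dim(p)
#' @export
preprocess_timeseries <- function(ts, nuisance = NULL, band = c(0.01, 0.1),
                                  tr = 2) {
  ts <- as.matrix(ts)
  nvol <- ncol(ts)
  if (nvol < 3) stop("need at least 3 volumes")
  nyq <- 1 / (2 * tr)
  if (band[2] >= nyq)
    stop("band upper edge (", band[2], " Hz) must be below Nyquist (",
         nyq, " Hz)")
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != nvol)
      stop("nuisance row count must match the number of volumes")
  }

  tt <- seq_len(nvol)
  Xd <- cbind(1, tt - mean(tt))
  Qd <- qr.Q(qr(Xd))
  detr <- ts - (ts %*% Qd) %*% t(Qd)     # remove mean + linear trend

  rs <- apply(detr, 1, sd)
  keep <- rs > 1e-10
  out <- matrix(0, nrow(ts), nvol, dimnames = dimnames(ts))
  if (any(keep)) {
    z <- detr[keep, , drop = FALSE] / rs[keep]
    bf <- signal::butter(2, band / nyq, type = "pass")
    z <- t(apply(z, 1, function(r) signal::filtfilt(bf, r)))
    if (!is.null(nuisance)) {
      Qn <- qr.Q(qr(cbind(1, scale(nuisance, scale = FALSE))))
      z <- z - (z %*% Qn) %*% t(Qn)
    }
    out[keep, ] <- z
  }
  out
}
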