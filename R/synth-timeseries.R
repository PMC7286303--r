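#' Generate synthetic regional resting-state time series
#'
#' Samples gray-matter regional time series from a multivariate normal
#' with a specified partial-correlation (precision) structure: a uniform
#' background partial correlation plus optional planted positive partial
#' correlations on chosen pairs. The sampled series are band-limited to
#' the resting-state band before nuisance contamination, so their
#' spectral content concentrates in `band`. Six motion-like regressors
#' (random walks) and two tissue-mean series (white matter, CSF;
#' autoregressive) contaminate the signal additively with random
#' loadings; [preprocess_timeseries()] removes them by regression.
#'
#' @param atlas a `region_atlas`; only gray-matter regions get series.
#' @param subject_obs one cohort row (`subject_id`, `group`,
#'   `timepoint_index`, `age`).
#' @param spec an [effect_spec()] (fields `func_*`, `nuisance_sd`).
#' @param n_volumes number of volumes (default 600, i.e. 20 min at a
#'   2-s repetition time); must be at least twice the number of
#'   gray-matter regions so the partial correlation is estimable without
#'   shrinkage.
#' @param tr repetition time in seconds (default 2).
#' @param band passband in Hz (default `c(0.01, 0.1)`).
#' @param seed master integer seed.
#' @return A list with `ts` (gray-matter regions x volumes matrix, row
#'   names = region names), `nuisance` (volumes x 8 matrix: `motion1..6`,
#'   `wm_mean`, `csf_mean`) and `tr`.
#' @examples
#' atl <- generate_atlas(20, 12, seed = 1)
#' coh <- generate_cohort(2, c(6, 9), dropout_prob = 0, seed = 1)
#' sim <- generate_timeseries(atl, coh[1, ], effect_spec(), n_volumes = 120,
#'                            seed = 1)
#' dim(sim$ts)
#' @export
generate_timeseries <- function(atlas, subject_obs, spec, n_volumes = 600,
                                tr = 2, band = c(0.01, 0.1), seed = 1) {
  stopifnot(inherits(spec, "effect_spec"))
  obs <- as.list(subject_obs)
  gm <- atlas[atlas$is_gray_matter, , drop = FALSE]
  p <- nrow(gm)
  if (p < 2) stop("need at least 2 gray-matter regions")
  if (n_volumes < 2 * p)
    stop("n_volumes must be >= 2 x number of gray-matter regions (",
         2 * p, ")")
  check_planted(spec$func_planted_pairs, p)

  tg <- as.numeric(obs$group %in% c("tg", 1, TRUE))
  agec <- as.numeric(obs$age) - spec$age_center
  bg <- spec$func_background_pcor + spec$func_group * tg +
    spec$func_age * agec + spec$func_interaction * tg * agec

  R <- matrix(bg, p, p)
  if (!is.null(spec$func_planted_pairs)) {
    pp <- spec$func_planted_pairs
    R[cbind(pp[, 1], pp[, 2])] <- spec$func_planted_pcor
    R[cbind(pp[, 2], pp[, 1])] <- spec$func_planted_pcor
  }
  P <- -R
  diag(P) <- 1
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8)
    stop("specified precision matrix is not positive definite")
  Sigma <- solve(P)

  set.seed(substream_seed(seed,
    string_stream(obs$subject_id) * 37 + as.numeric(obs$timepoint_index) * 11))
  Z <- matrix(rnorm(p * n_volumes), p, n_volumes)
  X <- crossprod(chol(Sigma), Z)          # p x n, cov = Sigma

  # band-limit the neural signal (same filter every region preserves the
  # cross-sectional partial-correlation structure)
  X <- bandpass_rows(X, band, tr)
  rs <- apply(X, 1, sd)
  rs[rs < 1e-12] <- 1
  X <- X / rs

  # per-region slow drift the detrending step should remove
  drift <- rnorm(p, 0, 0.2)
  tt <- seq_len(n_volumes) / n_volumes - 0.5
  X <- X + outer(drift, tt)

  motion <- sapply(seq_len(6), function(k) cumsum(rnorm(n_volumes, 0, 1)))
  tissue <- sapply(seq_len(2), function(k)
    as.numeric(filter(rnorm(n_volumes), 0.9, method = "recursive")))
  nuis <- cbind(motion, tissue)
  nuis <- scale(nuis)
  colnames(nuis) <- c(paste0("motion", 1:6), "wm_mean", "csf_mean")

  B <- matrix(rnorm(ncol(nuis) * p, 0, spec$nuisance_sd), ncol(nuis), p)
  X <- X + t(nuis %*% B)
  rownames(X) <- gm$name

  list(ts = X, nuisance = nuis, tr = tr)
}

# Zero-phase 4th-order Butterworth band-pass applied to each row.
bandpass_rows <- function(X, band, tr) {
  nyq <- 1 / (2 * tr)
  if (band[2] >= nyq)
    stop("band upper edge must be below the Nyquist frequency ", nyq, " Hz")
  bf <- signal::butter(2, band / nyq, type = "pass")
  t(apply(X, 1, function(r) signal::filtfilt(bf, r)))
}
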