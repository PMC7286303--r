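#' Specify the generative effect structure of a synthetic cohort
#'
#' Collects every parameter of the synthetic-data generators into one
#' validated object: baseline edge-weight parameters per connectome kind,
#' additive group / age / group-by-age effects, subject random-intercept
#' spreads, observation noise, an optional planted subnetwork carrying a
#' localized extra effect (the target the network-based statistic should
#' recover), and the functional precision structure.
#'
#' Fractional-anisotropy (FA) effects are in FA units and enter linearly
#' in uncentered age (months), the generative counterpart of the
#' longitudinal fixed-effect model fitted downstream. Streamline-count
#' effects act multiplicatively on the negative-binomial mean, on the log
#' scale, with age centered at `age_center` so multipliers stay moderate.
#'
#' @param profile `"null"` (all effects zero; groups exchangeable) or
#'   `"ad_like"`, a preset emulating progressive transgenic pathology:
#'   an early FA deficit in the transgenic group, and a transgenic-only
#'   positive age slope on streamline counts (hence on fiber-density and
#'   binary network measures).
#' @param ... named overrides of any field listed below.
#' @return A list of class `effect_spec`.
#'
#' @section Fields:
#' \describe{
#'   \item{fa_baseline, fa_group, fa_age, fa_interaction}{mean edge FA and
#'     its additive group (tg), age (per month) and interaction effects.}
#'   \item{fa_subject_sd, fa_pair_sd, fa_noise_sd}{subject random
#'     intercept, per-pair tract heterogeneity, and per-streamline noise
#'     spreads (FA units).}
#'   \item{count_group, count_age, count_interaction, count_subject_sd}{
#'     log-scale multiplicative effects on streamline-count means.}
#'   \item{density_target}{expected binary structural density (fraction);
#'     default 0.62, the regime reported for whole-brain structural
#'     connectomes at this parcellation scale.}
#'   \item{total_streamlines}{optional total streamline count per
#'     subject; when set it replaces `density_target` as the scale
#'     calibration.}
#'   \item{nb_dispersion}{negative-binomial size parameter.}
#'   \item{distance_decay}{mm scale of the exponential distance decay in
#'     the gravity-style count means.}
#'   \item{planted_component}{2-column matrix of region indices carrying
#'     a localized extra effect.}
#'   \item{planted_fa_boost, planted_count_boost}{extra FA shift (FA
#'     units) and log-count shift on planted pairs, applied to the
#'     transgenic group.}
#'   \item{func_background_pcor}{background partial correlation among
#'     gray-matter regions; the weakly negative default is calibrated so
#'     positive-edge functional density lands near 28\% at 600 volumes.}
#'   \item{func_planted_pairs, func_planted_pcor}{gray-matter region
#'     index pairs with a planted positive partial correlation.}
#'   \item{func_group, func_age, func_interaction}{additive shifts of the
#'     background partial correlation (per month for age terms).}
#'   \item{nuisance_sd}{loading spread of the additive motion/tissue
#'     nuisance contamination of the generated time series.}
#'   \item{age_center}{centering age (months) for count-model effects.}
#' }
#' @examples
#' effect_spec()                       # exchangeable null cohort
#' effect_spec("ad_like")              # progressive transgenic pathology
#' effect_spec(fa_group = -0.05)       # custom FA group deficit
#' @export
effect_spec <- function(profile = c("null", "ad_like"), ...) {
  profile <- match.arg(profile)
  spec <- list(
    fa_baseline = 0.42, fa_group = 0, fa_age = 0, fa_interaction = 0,
    fa_subject_sd = 0.01, fa_pair_sd = 0.05, fa_noise_sd = 0.04,
    count_group = 0, count_age = 0, count_interaction = 0,
    count_subject_sd = 0.05,
    density_target = 0.62, total_streamlines = NULL,
    nb_dispersion = 2, distance_decay = 8,
    planted_component = NULL, planted_fa_boost = 0, planted_count_boost = 0,
    func_background_pcor = -0.06, func_planted_pairs = NULL,
    func_planted_pcor = 0, func_group = 0, func_age = 0,
    func_interaction = 0, nuisance_sd = 0.3,
    age_center = 12
  )
  if (profile == "ad_like") {
    spec$fa_group <- -0.04
    spec$fa_age <- 0.0015
    spec$count_group <- -0.18
    spec$count_interaction <- 0.02
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(spec))
  if (length(unknown))
    stop("unknown effect_spec fields: ", paste(unknown, collapse = ", "))
  spec[names(overrides)] <- overrides
  validate_effect_spec(spec)
  class(spec) <- "effect_spec"
  spec
}

validate_effect_spec <- function(spec) {
  sds <- c("fa_subject_sd", "fa_pair_sd", "fa_noise_sd",
           "count_subject_sd", "nuisance_sd")
  for (f in sds)
    if (spec[[f]] < 0) stop(f, " must be >= 0")
  if (spec$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (!is.null(spec$density_target) &&
      (spec$density_target <= 0 || spec$density_target >= 1))
    stop("density_target must be in (0, 1)")
  if (!is.null(spec$planted_component)) {
    pc <- spec$planted_component
    if (!is.matrix(pc) || ncol(pc) != 2)
      stop("planted_component must be a 2-column matrix of region indices")
    if (any(pc[, 1] == pc[, 2]))
      stop("planted_component must not contain self-pairs")
  }
  invisible(spec)
}

# Check planted pairs against an atlas (indices must be valid rows).
check_planted <- function(pairs, n) {
  if (is.null(pairs)) return(invisible(NULL))
  if (any(pairs < 1) || any(pairs > n))
    stop("planted pairs reference regions outside the atlas (1..", n, ")")
  invisible(NULL)
}
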