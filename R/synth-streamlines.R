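#' Generate a synthetic streamline table for one subject observation
#'
#' Emulates the output of whole-brain deterministic tractography reduced
#' to endpoint regions: for every unordered region pair a streamline
#' count is drawn from a negative binomial around a gravity-style mean
#' (product of region volumes with exponential distance decay), so
#' realistic density and strength heterogeneity arises. The count scale
#' is calibrated numerically so the expected binary density matches
#' `spec$density_target` (or, if `spec$total_streamlines` is set, so the
#' expected total count matches it). Per-streamline mean FA carries the
#' group / age / interaction / subject effects of the [effect_spec()];
#' count means carry the log-scale count effects. Pairs listed in
#' `spec$planted_component` receive the planted boosts when the subject
#' is transgenic.
#'
#' Subject-level random effects are drawn from a substream keyed on the
#' subject id, so they are identical across that subject's timepoints;
#' observation-level draws use a substream keyed on subject and
#' timepoint. Identical inputs therefore reproduce byte-identical tables.
#'
#' @param atlas a `region_atlas` from [generate_atlas()].
#' @param subject_obs one cohort row (list or 1-row data frame) with
#'   `subject_id`, `group`, `timepoint_index`, `age`.
#' @param spec an [effect_spec()].
#' @param seed master integer seed.
#' @return A `data.frame` with columns `subject_id`, `timepoint_index`,
#'   `region_a`, `region_b`, `length_mm`, `mean_fa`; one row per
#'   streamline.
#' @examples
#' atl <- generate_atlas(20, 14, seed = 1)
#' coh <- generate_cohort(2, c(6, 9), dropout_prob = 0, seed = 1)
#' st <- generate_streamline_table(atl, coh[1, ], effect_spec(), seed = 1)
#' head(st)
#' @export
generate_streamline_table <- function(atlas, subject_obs, spec, seed = 1) {
  stopifnot(inherits(spec, "effect_spec"))
  obs <- as.list(subject_obs)
  n <- nrow(atlas)
  if (n < 2) {
    return(empty_streamline_table(obs))
  }
  check_planted(spec$planted_component, n)

  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ii <- ut[, 1]; jj <- ut[, 2]
  d <- as.matrix(dist(atlas[, c("x", "y", "z")]))
  dvec <- d[ut]
  g <- (atlas$volume[ii] * atlas$volume[jj]) * exp(-dvec / spec$distance_decay)
  g <- g / mean(g)

  tg <- as.numeric(obs$group %in% c("tg", 1, TRUE))
  age <- as.numeric(obs$age)
  agec <- age - spec$age_center

  # subject-level random effects: constant across timepoints
  set.seed(substream_seed(seed, string_stream(obs$subject_id)))
  z <- rnorm(2)
  re_count <- z[1] * spec$count_subject_sd
  re_fa <- z[2] * spec$fa_subject_sd

  mult <- exp(spec$count_group * tg + spec$count_age * agec +
                spec$count_interaction * tg * agec + re_count)

  boost_count <- numeric(length(g))
  boost_fa <- numeric(length(g))
  if (!is.null(spec$planted_component) && tg == 1) {
    pid <- planted_pair_index(spec$planted_component, n)
    keep <- pid %in% pair_index(ii, jj, n)
    m <- match(pid, pair_index(ii, jj, n))
    boost_count[m] <- spec$planted_count_boost
    boost_fa[m] <- spec$planted_fa_boost
  }

  scale0 <- calibrate_count_scale(g, spec)
  mu <- scale0 * g * mult * exp(boost_count)

  # atlas-level per-pair FA heterogeneity: shared by all subjects
  set.seed(substream_seed(seed, 999983L))
  pair_off <- rnorm(length(g), 0, spec$fa_pair_sd)
  fa_pair <- clamp(spec$fa_baseline + spec$fa_group * tg +
                     spec$fa_age * age + spec$fa_interaction * tg * age +
                     re_fa + pair_off + boost_fa, 0.05, 0.95)

  # observation-level draws
  set.seed(substream_seed(seed,
    string_stream(obs$subject_id) * 31 + as.numeric(obs$timepoint_index) * 7))
  counts <- rnbinom(length(g), mu = mu, size = spec$nb_dispersion)
  if (sum(counts) == 0) return(empty_streamline_table(obs))

  idx <- rep(seq_along(g), counts)
  len_mean <- pmax(dvec[idx] + 2, 1)
  length_mm <- round(rgamma(length(idx), shape = 4, rate = 4 / len_mean), 3)
  length_mm <- pmax(length_mm, 0.1)
  mean_fa <- round(clamp(rnorm(length(idx), fa_pair[idx], spec$fa_noise_sd),
                         0.02, 0.98), 4)

  out <- data.frame(
    subject_id = obs$subject_id,
    timepoint_index = as.integer(obs$timepoint_index),
    region_a = atlas$name[ii[idx]],
    region_b = atlas$name[jj[idx]],
    length_mm = length_mm,
    mean_fa = mean_fa,
    stringsAsFactors = FALSE
  )
  class(out) <- c("streamline_table", "data.frame")
  out
}

empty_streamline_table <- function(obs) {
  out <- data.frame(
    subject_id = character(0), timepoint_index = integer(0),
    region_a = character(0), region_b = character(0),
    length_mm = numeric(0), mean_fa = numeric(0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("streamline_table", "data.frame")
  out
}

# Linear index of unordered pairs (i < j) in an n-node graph.
pair_index <- function(i, j, n) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  (lo - 1) * n + hi
}

planted_pair_index <- function(pairs, n) {
  pair_index(pairs[, 1], pairs[, 2], n)
}

# Solve for the count-scale multiplier so either the expected total
# streamline count or the expected binary density hits its target at the
# reference condition (control group, centered age, no random effect).
calibrate_count_scale <- function(g, spec) {
  if (!is.null(spec$total_streamlines))
    return(spec$total_streamlines / sum(g))
  th <- spec$nb_dispersion
  target <- spec$density_target
  f <- function(logc) {
    mean(1 - dnbinom(0, mu = exp(logc) * g, size = th)) - target
  }
  uniroot(f, lower = -20, upper = 20, tol = 1e-10)$root |> exp()
}
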