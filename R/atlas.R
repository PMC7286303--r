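#' Generate a synthetic brain region atlas
#'
#' Creates a parcellation table emulating a rodent whole-brain atlas:
#' `n_regions` regions with unique contiguous ids, region volumes,
#' hemisphere assignment, 3-D centroid coordinates (mm) and a gray-matter
#' flag for exactly `n_gm` regions. Structural connectomes use all
#' regions as nodes; functional connectomes use only the gray-matter
#' subset, mirroring the convention that resting-state signal is
#' restricted to gray matter.
#'
#' @param n_regions total number of regions (default 76).
#' @param n_gm number of gray-matter regions (default 54); must not
#'   exceed `n_regions`.
#' @param seed integer seed; the atlas is deterministic given the seed.
#' @return A `data.frame` of class `region_atlas` with columns
#'   `region_id`, `name`, `volume` (mm^3), `is_gray_matter`,
#'   `hemisphere`, and centroid coordinates `x`, `y`, `z` (mm).
#' @examples
#' atl <- generate_atlas(76, 54, seed = 1)
#' sum(atl$is_gray_matter)
#' @export
generate_atlas <- function(n_regions = 76, n_gm = 54, seed = 1) {
  if (!is.numeric(n_regions) || length(n_regions) != 1L || n_regions < 1)
    stop("n_regions must be a positive count")
  if (!is.numeric(n_gm) || n_gm < 1 || n_gm > n_regions)
    stop("n_gm must satisfy 0 < n_gm <= n_regions")
  n_regions <- as.integer(n_regions)
  n_gm <- as.integer(n_gm)
  set.seed(seed)

  # hemisphere layout: bilateral pairs plus a small midline block
  n_mid <- if (n_regions >= 6L) 2L + n_regions %% 2L else n_regions %% 2L
  n_pair <- (n_regions - n_mid) %/% 2L
  hemisphere <- c(rep(c("left", "right"), n_pair), rep("midline", n_mid))

  volume <- round(rlnorm(n_regions, meanlog = log(40), sdlog = 0.6), 3)
  lat <- runif(n_regions, 0.5, 8)
  x <- ifelse(hemisphere == "left", -lat, ifelse(hemisphere == "right", lat, 0))
  y <- round(runif(n_regions, -10, 6), 3)
  z <- round(runif(n_regions, 0, 10), 3)

  is_gm <- rep(FALSE, n_regions)
  is_gm[sample.int(n_regions, n_gm)] <- TRUE
  name <- sprintf("%s_%03d_%s", ifelse(is_gm, "GM", "WM"),
                  seq_len(n_regions), substr(hemisphere, 1, 1))

  atlas <- data.frame(
    region_id = seq_len(n_regions),
    name = name,
    volume = volume,
    is_gray_matter = is_gm,
    hemisphere = hemisphere,
    x = round(x, 3), y = y, z = z,
    stringsAsFactors = FALSE
  )
  class(atlas) <- c("region_atlas", "data.frame")
  atlas
}

#' Generate a synthetic longitudinal cohort
#'
#' Two groups (`control`, `tg`) observed at up to `length(ages)`
#' timepoints. Every subject is observed at the first timepoint; each
#' later observation is independently retained with probability
#' `1 - dropout_prob` (missing-at-random dropout, mirroring unequal
#' per-timepoint sample sizes in longitudinal animal studies). Ages are
#' jittered uniformly around the nominal schedule while remaining
#' strictly increasing within subject.
#'
#' @param n_per_group subjects per group (default 9).
#' @param ages nominal acquisition ages in months, strictly increasing
#'   (default `c(6, 9, 12, 15, 18)`).
#' @param dropout_prob probability in `[0, 1)` that any observation after
#'   the first is missing.
#' @param seed integer seed.
#' @param age_jitter half-width (months) of the uniform age jitter
#'   (default 0.3); shrunk automatically if the schedule is tight.
#' @return A `data.frame` of class `cohort_table` with columns
#'   `subject_id`, `group`, `timepoint_index`, `age`.
#' @examples
#' coh <- generate_cohort(9, c(6, 9, 12, 15, 18), dropout_prob = 0, seed = 1)
#' table(coh$group, coh$timepoint_index)
#' @export
generate_cohort <- function(n_per_group = 9, ages = c(6, 9, 12, 15, 18),
                            dropout_prob = 0.1, seed = 1, age_jitter = 0.3) {
  if (length(ages) == 0) stop("ages must be non-empty")
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing")
  if (any(ages <= 0)) stop("ages must be positive (months)")
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must be in [0, 1)")
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  set.seed(seed)

  if (length(ages) > 1)
    age_jitter <- min(age_jitter, 0.45 * min(diff(ages)))
  n_tp <- length(ages)
  ids <- c(sprintf("ctrl%02d", seq_len(n_per_group)),
           sprintf("tg%02d", seq_len(n_per_group)))
  grp <- rep(c("control", "tg"), each = n_per_group)

  rows <- lapply(seq_along(ids), function(i) {
    keep <- c(TRUE, rbinom(n_tp - 1L, 1L, 1 - dropout_prob) == 1L)[seq_len(n_tp)]
    jit <- runif(n_tp, -age_jitter, age_jitter)
    data.frame(
      subject_id = ids[i], group = grp[i],
      timepoint_index = seq_len(n_tp)[keep],
      age = round(ages + jit, 3)[keep],
      stringsAsFactors = FALSE
    )
  })
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}
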