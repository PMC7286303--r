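#' Generate synthetic working-memory outcomes from network metrics
#'
#' Emulates delayed nonmatch-to-sample (DNMS) session outcomes driven by
#' connectivity: for each subject-timepoint,
#' `trials = b0 + b1 * metric + b2 * tg + b3 * metric * tg + subject + noise`,
#' truncated to `[0, 90]` (a session ends after 90 trials) and rounded;
#' percent correct is generated analogously in `[0, 100]`. This is the
#' generative counterpart of the connectivity-cognition mixed-effects
#' model fitted by [fit_cognition()].
#'
#' @param metrics data frame with one row per subject-timepoint:
#'   `subject_id`, `group`, `timepoint_index`, `value` (the network
#'   metric driving behavior).
#' @param betas_trials numeric length 4: intercept, metric slope, group
#'   shift, metric-by-group interaction for the trials outcome.
#' @param betas_pct same for percent correct (defaults to a flat 70\%).
#' @param subject_sd random-intercept spread (trials / percentage units).
#' @param noise_sd residual spread.
#' @param seed master integer seed.
#' @return A `data.frame` of class `behavior_table`: `subject_id`,
#'   `timepoint_index`, `trials` (integer 0-90), `pct_correct` (0-100).
#' @examples
#' m <- data.frame(subject_id = c("a", "a", "b", "b"),
#'                 group = c("control", "control", "tg", "tg"),
#'                 timepoint_index = c(1, 2, 1, 2), value = c(1, 1.1, 0.9, 1))
#' generate_behavior(m, betas_trials = c(45, 0, 0, 0), subject_sd = 0,
#'                   noise_sd = 0, seed = 1)
#' @export
generate_behavior <- function(metrics, betas_trials = c(45, 0, 0, 0),
                              betas_pct = c(70, 0, 0, 0),
                              subject_sd = 5, noise_sd = 5, seed = 1) {
  need <- c("subject_id", "group", "timepoint_index", "value")
  if (!all(need %in% names(metrics)))
    stop("metrics must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(metrics[, c("subject_id", "timepoint_index")]))
    stop("metrics must have one value per subject-timepoint")
  stopifnot(length(betas_trials) == 4, length(betas_pct) == 4,
            subject_sd >= 0, noise_sd >= 0)

  tg <- as.numeric(metrics$group %in% c("tg", 1, TRUE))
  v <- metrics$value
  subs <- unique(metrics$subject_id)
  re <- setNames(vapply(subs, function(s) {
    set.seed(substream_seed(seed, string_stream(s) * 13))
    rnorm(1) * subject_sd
  }, numeric(1)), subs)
  re_pct <- setNames(vapply(subs, function(s) {
    set.seed(substream_seed(seed, string_stream(s) * 13 + 1))
    rnorm(1) * subject_sd
  }, numeric(1)), subs)

  set.seed(substream_seed(seed, 424243L))
  lin <- function(b, re_s) {
    b[1] + b[2] * v + b[3] * tg + b[4] * v * tg + re_s +
      rnorm(nrow(metrics), 0, noise_sd)
  }
  trials <- round(clamp(lin(betas_trials, re[metrics$subject_id]), 0, 90))
  pct <- round(clamp(lin(betas_pct, re_pct[metrics$subject_id]), 0, 100), 2)

  out <- data.frame(
    subject_id = metrics$subject_id,
    timepoint_index = as.integer(metrics$timepoint_index),
    trials = as.integer(trials),
    pct_correct = pct,
    stringsAsFactors = FALSE
  )
  class(out) <- c("behavior_table", "data.frame")
  out
}
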