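#' Kruskal-Wallis two-group comparison with eta-squared
#'
#' Rank-based H statistic with tie correction (via
#' [stats::kruskal.test()]), chi-square p-value with `k - 1` degrees of
#' freedom, and the effect size `eta^2 = (H - k + 1) / (N - k)`. With
#' all values identical the test is degenerate: `H = 0`, `p = 1`.
#' Note `eta^2` can be slightly negative for small H; that is a known
#' property of this estimator.
#'
#' @param values_a,values_b numeric vectors (each of length >= 2).
#' @return list with `H`, `p_value`, `eta_squared`.
#' @examples
#' kw <- kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
#' round(kw$H, 3)            # 3.857
#' round(kw$eta_squared, 3)  # 0.714
#' @export
kruskal_wallis <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop("each group needs at least 2 observations")
  x <- c(values_a, values_b)
  N <- length(x)
  k <- 2
  if (diff(range(x)) == 0)
    return(list(H = 0, p_value = 1, eta_squared = (0 - k + 1) / (N - k)))
  kt <- kruskal.test(list(values_a, values_b))
  H <- unname(kt$statistic)
  list(H = H, p_value = kt$p.value, eta_squared = (H - k + 1) / (N - k))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement,
#' capped at 1, input order preserved. Thin, validated wrapper over
#' [stats::p.adjust()].
#'
#' @param p_values numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
fdr_bh <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Per-timepoint group comparison of network metrics
#'
#' For every (timepoint, connectome kind, metric) cell with both groups
#' present, compares control versus transgenic values with
#' [kruskal_wallis()]; adjusts p-values with [fdr_bh()] within the
#' declared family and flags `p_fdr < alpha`. Cells with a single group
#' are skipped with a warning.
#'
#' @param metrics long-format metric table (`subject_id`, `group`,
#'   `timepoint_index`, `kind`, `metric`, `value`).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param family FDR family scope: `"per_timepoint"` (all kind x metric
#'   tests within one timepoint, the default), `"per_kind"` (timepoint x
#'   metric within one kind) or `"global"` (all tests).
#' @return `data.frame` of class `crosssectional_result`: one row per
#'   test with `timepoint_index`, `kind`, `metric`, `n_control`, `n_tg`,
#'   `H`, `p_raw`, `p_fdr`, `eta_squared`, `significant`.
#' @export
crosssectional_analysis <- function(metrics, alpha = 0.05,
                                    family = c("per_timepoint", "per_kind",
                                               "global")) {
  family <- match.arg(family)
  need <- c("subject_id", "group", "timepoint_index", "kind", "metric",
            "value")
  if (!all(need %in% names(metrics)))
    stop("metrics must have columns ", paste(need, collapse = ", "))

  cells <- unique(metrics[, c("timepoint_index", "kind", "metric")])
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    cell <- cells[r, ]
    sub <- metrics[metrics$timepoint_index == cell$timepoint_index &
                     metrics$kind == cell$kind &
                     metrics$metric == cell$metric, ]
    va <- sub$value[sub$group == "control"]
    vb <- sub$value[sub$group == "tg"]
    if (length(va) < 2 || length(vb) < 2) {
      warning(sprintf(
        "timepoint %s, %s/%s: fewer than 2 observations in a group; skipped",
        cell$timepoint_index, cell$kind, cell$metric))
      return(NULL)
    }
    kw <- kruskal_wallis(va, vb)
    data.frame(timepoint_index = cell$timepoint_index, kind = cell$kind,
               metric = cell$metric, n_control = length(va),
               n_tg = length(vb), H = kw$H, p_raw = kw$p_value,
               eta_squared = kw$eta_squared, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable cells (need both groups present)")

  fam <- switch(family,
                per_timepoint = as.character(out$timepoint_index),
                per_kind = out$kind,
                global = rep("all", nrow(out)))
  out$p_fdr <- NA_real_
  for (f in unique(fam)) {
    idx <- fam == f
    out$p_fdr[idx] <- fdr_bh(out$p_raw[idx])
  }
  out$significant <- out$p_fdr < alpha
  out <- out[, c("timepoint_index", "kind", "metric", "n_control", "n_tg",
                 "H", "p_raw", "p_fdr", "eta_squared", "significant")]
  rownames(out) <- NULL
  class(out) <- c("crosssectional_result", "data.frame")
  out
}
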