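#' Linear mixed-effects models for longitudinal network metrics
#'
#' The longitudinal cascade regresses each network metric on group, age
#' and their interaction with a subject random intercept
#' (`y = b0 + b1 group + b2 age + b3 group x age + b_subject + error`),
#' refits each group separately (age only) when the interaction is
#' significant after FDR, and links connectivity to cognitive outcomes
#' with the analogous
#' `DNMS = b0 + b1 metric + b2 group + b3 metric x group + b_subject + error`.
#' Estimation is restricted maximum likelihood (lme4) with Wald t-tests
#' on the fixed effects using Satterthwaite degrees of freedom
#' (lmerTest). Group is coded control = 0, tg = 1; age is in months,
#' uncentered. Unbalanced panels (dropout) are handled by the
#' likelihood; no imputation.
#'
#' @name longitudinal_models
NULL

#' Numeric group coding
#'
#' Control is coded 0, transgenic (`tg`) 1 — the reference coding of all
#' fixed-effect models in the package.
#'
#' @param group vector of group labels.
#' @return numeric 0/1 vector.
#' @export
group_code <- function(group) {
  as.numeric(group %in% c("tg", "TG", 1, TRUE))
}

# Core fitter: y on precomputed numeric covariate columns plus a subject
# random intercept. Falls back to ordinary least squares when the
# mixed fit fails or when method = "ols".
lme_fit_core <- function(y, fixed, subject, model_id,
                         method = c("reml", "ols")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(fixed))
  ok <- stats::complete.cases(cbind(y, fixed))
  y <- y[ok]; fixed <- fixed[ok, , drop = FALSE]; subject <- subject[ok]
  n <- length(y)
  if (n < ncol(fixed) + 2) stop("too few observations")

  X <- cbind(`(Intercept)` = 1, as.matrix(fixed))
  if (qr(X)$rank < ncol(X))
    stop("singular fixed-effect design (rank-deficient)")

  tab <- table(subject)
  if (method == "reml" && sum(tab >= 2) < 2)
    stop("random intercept unidentifiable: need at least 2 subjects ",
         "with repeated observations")

  dat <- data.frame(.y = y, fixed, .subject = factor(subject),
                    check.names = FALSE)
  rhs <- if (ncol(fixed))
    paste(sprintf("`%s`", names(fixed)), collapse = " + ") else "1"

  converged <- TRUE
  if (method == "reml") {
    form <- stats::as.formula(paste(".y ~", rhs, "+ (1 | .subject)"))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lmerTest::lmer(form, data = dat, REML = TRUE)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      co <- coef(summary(fit))
      fe <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                       se = co[, "Std. Error"], df = co[, "df"],
                       t = co[, "t value"], p_value = co[, "Pr(>|t|)"],
                       stringsAsFactors = FALSE, row.names = NULL)
      vc <- lme4::VarCorr(fit)
      tau <- attr(vc$.subject, "stddev")[[1]]
      sig <- sigma(fit)
      converged <- is.null(fit@optinfo$conv$lme4$messages)
    }
  }
  if (method == "ols" || (method == "reml" && is.null(fit))) {
    form <- stats::as.formula(paste(".y ~", rhs))
    fit <- lm(form, data = dat)
    co <- coef(summary(fit))
    fe <- data.frame(term = rownames(co), estimate = co[, "Estimate"],
                     se = co[, "Std. Error"],
                     df = rep(fit$df.residual, nrow(co)),
                     t = co[, "t value"], p_value = co[, "Pr(>|t|)"],
                     stringsAsFactors = FALSE, row.names = NULL)
    tau <- 0
    sig <- sigma(fit)
    converged <- method == "ols"
  }
  fe$term <- gsub("`", "", fe$term)

  beta <- setNames(fe$estimate, fe$term)
  pred <- as.vector(X %*% beta[colnames(X)])
  varf <- var(pred) * (n - 1) / n
  r2 <- varf / (varf + tau^2 + sig^2)

  structure(
    list(model_id = model_id, fixed_effects = fe,
         random_intercept_sd = unname(tau), residual_sd = unname(sig),
         r2_marginal = unname(r2), n_obs = n,
         n_subjects = length(unique(subject)), converged = converged,
         data = dat, method = method),
    class = "lme_result"
  )
}

#' @export
print.lme_result <- function(x, ...) {
  cat(sprintf("<lme_result> %s  (%d obs, %d subjects, %s)\n", x$model_id,
              x$n_obs, x$n_subjects,
              if (x$converged) "converged" else "NOT converged"))
  print(x$fixed_effects, digits = 4)
  cat(sprintf("random intercept sd %.4g, residual sd %.4g, marginal R2 %.3f\n",
              x$random_intercept_sd, x$residual_sd, x$r2_marginal))
  invisible(x)
}

#' Fit the group-by-age mixed model to a network metric
#'
#' `y = b0 + b1 group + b2 age + b3 group x age + b_subject + error`,
#' with a random intercept per subject, fitted by REML. Wald p-values
#' use Satterthwaite degrees of freedom. Terms are labeled
#' `(Intercept)`, `group`, `age`, `group:age`.
#'
#' @param response numeric metric values, one per observation.
#' @param group group labels (`control` / `tg`, coded 0/1).
#' @param age ages in months.
#' @param subject subject identifiers (repeated measures).
#' @param method `"reml"` (default) or `"ols"` (no random intercept;
#'   reduces to ordinary least squares).
#' @return an `lme_result`.
#' @examples
#' coh <- generate_cohort(6, c(6, 9, 12), dropout_prob = 0, seed = 1)
#' y <- 10 - 2 * group_code(coh$group) + 0.5 * coh$age + rnorm(nrow(coh), 0, .1)
#' fit_lme(y, coh$group, coh$age, coh$subject_id)
#' @export
fit_lme <- function(response, group, age, subject,
                    method = c("reml", "ols")) {
  g <- group_code(group)
  fixed <- data.frame(group = g, age = age, `group:age` = g * age,
                      check.names = FALSE)
  lme_fit_core(response, fixed, subject, "group_age", match.arg(method))
}

#' Fit the within-group age model
#'
#' `y = b0 + b1 age + b_subject + error` within a single group — the
#' conditional refit run when the group-by-age interaction is
#' significant.
#'
#' @param response metric values for subjects of one group.
#' @param age ages in months.
#' @param subject subject identifiers.
#' @param group_label `"control"` or `"tg"` (names the result).
#' @inheritParams fit_lme
#' @return an `lme_result` with model id `age_control` or `age_tg`.
#' @export
fit_group_age <- function(response, age, subject,
                          group_label = c("control", "tg"),
                          method = c("reml", "ols")) {
  group_label <- match.arg(group_label)
  fixed <- data.frame(age = age)
  lme_fit_core(response, fixed, subject, paste0("age_", group_label),
               match.arg(method))
}

#' Fit the connectivity-cognition mixed model
#'
#' `DNMS = b0 + b1 metric + b2 group + b3 metric x group + b_subject +
#' error` for a chosen cognitive outcome (trials completed or percent
#' correct) against a chosen network metric. When the interaction
#' p-value supplied via `interaction_p` (e.g. an FDR-adjusted value from
#' the family-level analysis; defaults to the model's own raw
#' interaction p) falls below `alpha`, the model is refitted separately
#' per group to report the group-specific metric effect.
#'
#' @param outcome cognitive outcome values, one per observation.
#' @param connectivity matched network metric values.
#' @param group group labels.
#' @param subject subject identifiers.
#' @param alpha gating level for the per-group refits (default 0.05).
#' @param interaction_p optional externally adjusted interaction
#'   p-value used for gating.
#' @inheritParams fit_lme
#' @return an `lme_result` (model id `cognition`, terms `(Intercept)`,
#'   `connectivity`, `group`, `connectivity:group`) with, when gated, a
#'   `group_fits` element holding `cognition_control` / `cognition_tg` refits of
#'   `outcome ~ connectivity + (1 | subject)`.
#' @export
fit_cognition <- function(outcome, connectivity, group, subject,
                          alpha = 0.05, interaction_p = NULL,
                          method = c("reml", "ols")) {
  method <- match.arg(method)
  g <- group_code(group)
  fixed <- data.frame(connectivity = connectivity, group = g,
                      `connectivity:group` = connectivity * g,
                      check.names = FALSE)
  res <- lme_fit_core(outcome, fixed, subject, "cognition", method)
  p_int <- interaction_p %||%
    res$fixed_effects$p_value[res$fixed_effects$term == "connectivity:group"]
  if (isTRUE(p_int < alpha)) {
    res$group_fits <- lapply(c(control = 0, tg = 1), function(gi) {
      sel <- g == gi
      lme_fit_core(outcome[sel],
                   data.frame(connectivity = connectivity[sel]),
                   subject[sel],
                   paste0("cognition_", if (gi == 0) "control" else "tg"),
                   method)
    })
  }
  res
}

#' Cohen's f-squared and marginal R-squared for nested fits
#'
#' `f2 = (R2_full - R2_reduced) / (1 - R2_full)`, where R-squared is the
#' marginal (fixed-effects) variance fraction of each fit. An R2_full of
#' 1 yields infinite f2 (flagged with a warning).
#'
#' @param full,reduced `lme_result` objects fitted to identical data,
#'   the reduced model nested in the full one.
#' @return list with `f2`, `r2_full`, `r2_reduced`.
#' @examples
#' # pure arithmetic: R2 0.4 vs 0.3 gives f2 = 0.1 / 0.6
#' @export
effect_sizes <- function(full, reduced) {
  stopifnot(inherits(full, "lme_result"), inherits(reduced, "lme_result"))
  if (full$n_obs != reduced$n_obs)
    stop("full and reduced fits must use identical data")
  r2f <- full$r2_marginal
  r2r <- reduced$r2_marginal
  if (r2f >= 1 - 1e-12) {
    warning("R2_full = 1: infinite f2")
    return(list(f2 = Inf, r2_full = r2f, r2_reduced = r2r))
  }
  list(f2 = (r2f - r2r) / (1 - r2f), r2_full = r2f, r2_reduced = r2r)
}

# f2 per fixed-effect term by refitting without that term's column.
cohens_f2_terms <- function(result, terms = NULL) {
  fe_terms <- setdiff(result$fixed_effects$term, "(Intercept)")
  terms <- terms %||% fe_terms
  dat <- result$data
  vapply(terms, function(tm) {
    keep <- setdiff(fe_terms, tm)
    red <- lme_fit_core(dat$.y,
                        dat[, keep, drop = FALSE],
                        dat$.subject, paste0(result$model_id, "_red"),
                        result$method)
    effect_sizes(result, red)$f2
  }, numeric(1))
}

#' Longitudinal mixed-effects analysis of a metric table
#'
#' Runs the full cascade: the group-by-age model per connectome kind and
#' metric; Benjamini-Hochberg FDR per fixed-effect term across all
#' responses (the term family); conditional within-group age refits
#' wherever the interaction survives FDR; and, when behavior is
#' supplied, the connectivity-cognition model per metric and outcome
#' (trials, percent correct) with the same term-family FDR and gated
#' per-group refits.
#'
#' @param metrics long-format metric table (`subject_id`, `group`,
#'   `timepoint_index`, `kind`, `metric`, `value`) with ages attached as
#'   column `age` or supplied via `cohort`.
#' @param behavior optional `behavior_table` (`subject_id`,
#'   `timepoint_index`, `trials`, `pct_correct`).
#' @param cohort optional `cohort_table` used to attach ages/groups.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param compute_f2 also compute Cohen's f2 per term by reduced refits
#'   (default TRUE).
#' @return list of class `longitudinal_result` with data frames
#'   `group_age` (one row per response x term), `conditional_age` (the
#'   gated within-group age refits), `cognition` and
#'   `cognition_by_group` (when behavior is given), plus `alpha`.
#' @export
longitudinal_analysis <- function(metrics, behavior = NULL, cohort = NULL,
                                  alpha = 0.05, compute_f2 = TRUE) {
  if (!"age" %in% names(metrics)) {
    if (is.null(cohort))
      stop("metrics lacks an age column; supply cohort")
    metrics <- merge(metrics,
                     cohort[, c("subject_id", "timepoint_index", "age")],
                     by = c("subject_id", "timepoint_index"), sort = FALSE)
  }

  responses <- unique(metrics[, c("kind", "metric")])
  fits <- list()
  rows <- list()
  for (r in seq_len(nrow(responses))) {
    kd <- responses$kind[r]; mt <- responses$metric[r]
    sub <- metrics[metrics$kind == kd & metrics$metric == mt, ]
    fit <- fit_lme(sub$value, sub$group, sub$age, sub$subject_id)
    key <- paste(kd, mt, sep = ".")
    fits[[key]] <- list(fit = fit, data = sub)
    fe <- fit$fixed_effects
    fe$kind <- kd; fe$metric <- mt
    fe$r2_marginal <- fit$r2_marginal
    if (compute_f2) {
      f2 <- cohens_f2_terms(fit)
      fe$f2 <- unname(f2[fe$term])
    } else fe$f2 <- NA_real_
    rows[[key]] <- fe
  }
  ga_tab <- do.call(rbind, rows)
  rownames(ga_tab) <- NULL
  ga_tab$p_fdr <- NA_real_
  for (tm in setdiff(unique(ga_tab$term), "(Intercept)")) {
    idx <- ga_tab$term == tm
    ga_tab$p_fdr[idx] <- fdr_bh(ga_tab$p_value[idx])
  }
  ga_tab$significant <- !is.na(ga_tab$p_fdr) & ga_tab$p_fdr < alpha
  ga_tab <- ga_tab[, c("kind", "metric", "term", "estimate", "se", "df", "t",
                 "p_value", "p_fdr", "significant", "f2", "r2_marginal")]

  # conditional within-group age refits where interaction survives FDR
  cond_rows <- list()
  gate <- ga_tab[ga_tab$term == "group:age" & ga_tab$significant, , drop = FALSE]
  for (r in seq_len(nrow(gate))) {
    key <- paste(gate$kind[r], gate$metric[r], sep = ".")
    sub <- fits[[key]]$data
    for (gl in c("control", "tg")) {
      s2 <- sub[sub$group == gl, ]
      gfit <- tryCatch(
        fit_group_age(s2$value, s2$age, s2$subject_id, gl),
        error = function(e) NULL)
      if (is.null(gfit)) next
      age_row <- gfit$fixed_effects[gfit$fixed_effects$term == "age", ]
      cond_rows[[paste(key, gl)]] <- data.frame(
        kind = gate$kind[r], metric = gate$metric[r], group = gl,
        estimate = age_row$estimate, se = age_row$se,
        p_value = age_row$p_value, r2_marginal = gfit$r2_marginal,
        f2_age = if (compute_f2) unname(cohens_f2_terms(gfit, "age"))
        else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  cond_tab <- if (length(cond_rows)) do.call(rbind, cond_rows) else NULL
  if (!is.null(cond_tab)) rownames(cond_tab) <- NULL

  cog_tab <- NULL; cog_group_tab <- NULL
  if (!is.null(behavior)) {
    outcomes <- intersect(c("trials", "pct_correct"), names(behavior))
    rows3 <- list(); fits3 <- list()
    for (r in seq_len(nrow(responses))) {
      kd <- responses$kind[r]; mt <- responses$metric[r]
      key <- paste(kd, mt, sep = ".")
      sub <- merge(fits[[key]]$data, behavior,
                   by = c("subject_id", "timepoint_index"), sort = FALSE)
      for (oc in outcomes) {
        fit <- tryCatch(
          fit_cognition(sub[[oc]], sub$value, sub$group, sub$subject_id,
                        alpha = alpha, interaction_p = 1),  # gate later, on FDR
          error = function(e) NULL)
        if (is.null(fit)) next
        k3 <- paste(key, oc, sep = ".")
        fits3[[k3]] <- list(fit = fit, data = sub, outcome = oc,
                            kind = kd, metric = mt)
        fe <- fit$fixed_effects
        fe$kind <- kd; fe$metric <- mt; fe$outcome <- oc
        fe$r2_marginal <- fit$r2_marginal
        fe$f2 <- if (compute_f2) unname(cohens_f2_terms(fit)[fe$term])
        else NA_real_
        rows3[[k3]] <- fe
      }
    }
    cog_tab <- do.call(rbind, rows3)
    if (!is.null(cog_tab)) {
      rownames(cog_tab) <- NULL
      cog_tab$p_fdr <- NA_real_
      for (tm in setdiff(unique(cog_tab$term), "(Intercept)")) {
        idx <- cog_tab$term == tm
        cog_tab$p_fdr[idx] <- fdr_bh(cog_tab$p_value[idx])
      }
      cog_tab$significant <- !is.na(cog_tab$p_fdr) & cog_tab$p_fdr < alpha
      cog_tab <- cog_tab[, c("kind", "metric", "outcome", "term", "estimate", "se",
                     "df", "t", "p_value", "p_fdr", "significant", "f2",
                     "r2_marginal")]

      g3 <- cog_tab[cog_tab$term == "connectivity:group" & cog_tab$significant, ,
                drop = FALSE]
      rows3g <- list()
      for (r in seq_len(nrow(g3))) {
        k3 <- paste(g3$kind[r], g3$metric[r], g3$outcome[r], sep = ".")
        sub <- fits3[[k3]]$data
        for (gl in c("control", "tg")) {
          s2 <- sub[sub$group == gl, ]
          gfit <- tryCatch(
            lme_fit_core(s2[[g3$outcome[r]]],
                         data.frame(connectivity = s2$value),
                         s2$subject_id, paste0("cognition_", gl)),
            error = function(e) NULL)
          if (is.null(gfit)) next
          cr <- gfit$fixed_effects[
            gfit$fixed_effects$term == "connectivity", ]
          rows3g[[paste(k3, gl)]] <- data.frame(
            kind = g3$kind[r], metric = g3$metric[r],
            outcome = g3$outcome[r], group = gl,
            estimate = cr$estimate, se = cr$se, p_value = cr$p_value,
            r2_marginal = gfit$r2_marginal, stringsAsFactors = FALSE)
        }
      }
      cog_group_tab <- if (length(rows3g)) do.call(rbind, rows3g) else NULL
      if (!is.null(cog_group_tab)) rownames(cog_group_tab) <- NULL
    }
  }

  structure(list(group_age = ga_tab, conditional_age = cond_tab, cognition = cog_tab,
                 cognition_by_group = cog_group_tab,
                 alpha = alpha),
            class = "longitudinal_result")
}

#' @export
print.longitudinal_result <- function(x, ...) {
  cat("<longitudinal_result>\n")
  sig <- x$group_age[x$group_age$significant, c("kind", "metric", "term", "p_fdr")]
  cat(sprintf("group-by-age model: %d responses, %d significant terms\n",
              length(unique(paste(x$group_age$kind, x$group_age$metric))), nrow(sig)))
  if (nrow(sig)) print(sig, digits = 3)
  if (!is.null(x$conditional_age))
    cat(sprintf("conditional age refits: %d\n", nrow(x$conditional_age)))
  if (!is.null(x$cognition)) {
    s3 <- sum(x$cognition$significant)
    cat(sprintf("connectivity-cognition model: %d terms significant\n", s3))
  }
  invisible(x)
}
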