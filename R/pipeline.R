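#' Configure a full pipeline run
#'
#' Collects every setting of the generate -> build -> measure -> test ->
#' model pipeline into one validated list. The `"canonical"`
#' profile pins the canonical analysis settings: 76-region atlas with 54
#' gray-matter regions, five acquisitions from ~6 to ~18 months, 600
#' volumes at a 2-s repetition time, 0.01-0.1 Hz band, strict positive-z
#' rule for functional edges, network-based statistic at t > 3.1 with
#' 5000 permutations at alpha 0.05, and FDR-gated mixed-model refits at
#' alpha 0.05. The `"fast"` profile shrinks the permutation count (1000)
#' for desk-scale runs.
#'
#' @param profile `"canonical"` or `"fast"`.
#' @param seed master seed; every stage derives its substreams from it.
#' @param ... overrides of any config field (see the default list in the
#'   function body; unknown names error).
#' @return list of class `run_config`.
#' @export
run_config <- function(profile = c("canonical", "fast"), seed = 1,
                       ...) {
  profile <- match.arg(profile)
  cfg <- list(
    seed = seed,
    n_regions = 76, n_gm = 54,
    n_per_group = 9, ages = c(6, 9, 12, 15, 18), dropout_prob = 0.1,
    effects = effect_spec(),
    n_volumes = 600, tr = 2, band = c(0.01, 0.1), shrinkage = 0,
    nbs_t_threshold = 3.1, nbs_n_perm = 5000, nbs_alpha = 0.05,
    nbs_kind = "fa_w",
    fdr_family = "per_timepoint", alpha = 0.05, compute_f2 = TRUE,
    behavior_metric = list(kind = "fa_w", metric = "strength"),
    behavior_betas_trials = c(45, 0, 0, 0),
    behavior_betas_pct = c(70, 0, 0, 0),
    behavior_subject_sd = 5, behavior_noise_sd = 5,
    write_timeseries = TRUE
  )
  if (profile == "fast") cfg$nbs_n_perm <- 1000
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  if (!inherits(cfg$effects, "effect_spec"))
    stop("effects must be an effect_spec")
  cfg$profile <- profile
  class(cfg) <- "run_config"
  cfg
}

stage_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes every stage in order — generate (atlas, cohort, streamline
#' tables, time series, behavior), build (five connectomes per
#' observation), measure (network metric table), test (per-timepoint
#' Kruskal-Wallis with FDR; network-based statistic per timepoint) and
#' model (the longitudinal mixed-effects cascade) — writing every
#' intermediate table plus a machine-readable results bundle and a run
#' manifest under `out_dir`. Rerunning with the same config reproduces
#' all numeric outputs.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return (invisibly) list with the in-memory results: `atlas`,
#'   `cohort`, `metrics`, `behavior`, `crosssectional`, `nbs`,
#'   `longitudinal`, and `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("streamlines", "timeseries", "connectomes", "nbs"))
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  t0 <- Sys.time()

  # ---- generate ----
  stage_msg("generate", "atlas (%d regions, %d GM)", config$n_regions,
            config$n_gm)
  atlas <- generate_atlas(config$n_regions, config$n_gm, config$seed)
  cohort <- generate_cohort(config$n_per_group, config$ages,
                            config$dropout_prob,
                            substream_seed(config$seed, 2L))
  write.csv(atlas, file.path(out_dir, "atlas.csv"), row.names = FALSE)
  write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  writeLines(yaml::as.yaml(unclass_config(config)),
             file.path(out_dir, "config.yaml"))

  stage_msg("generate", "%d subject-timepoints", nrow(cohort))
  connectomes <- list()
  for (r in seq_len(nrow(cohort))) {
    obs <- cohort[r, ]
    tag <- sprintf("%s_tp%d", obs$subject_id, obs$timepoint_index)

    st <- generate_streamline_table(atlas, obs, config$effects,
                                    config$seed)
    write_streamline_tsv(st, file.path(out_dir, "streamlines",
                                       paste0(tag, ".tsv")))
    cs <- build_structural(st, atlas)

    sim <- generate_timeseries(atlas, obs, config$effects,
                               config$n_volumes, config$tr, config$band,
                               config$seed)
    if (isTRUE(config$write_timeseries)) {
      write.csv(sim$ts, file.path(out_dir, "timeseries",
                                  paste0(tag, "_ts.csv")))
      write.csv(sim$nuisance, file.path(out_dir, "timeseries",
                                        paste0(tag, "_nuisance.csv")),
                row.names = FALSE)
    }
    proc <- preprocess_timeseries(sim$ts, sim$nuisance, config$band,
                                  config$tr)
    cf <- build_functional(proc, config$shrinkage, obs$subject_id,
                           obs$timepoint_index)

    obs_cons <- c(cs, cf)
    for (k in names(obs_cons))
      write_connectome_csv(obs_cons[[k]],
                           file.path(out_dir, "connectomes",
                                     sprintf("%s_%s.csv", tag, k)))
    connectomes <- c(connectomes, unname(obs_cons))
  }

  # ---- measure ----
  stage_msg("metrics", "computing network summaries")
  metrics <- compute_metric_table(connectomes, cohort)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)

  bm <- config$behavior_metric
  msub <- metrics[metrics$kind == bm$kind & metrics$metric == bm$metric, ]
  behavior <- generate_behavior(
    msub, config$behavior_betas_trials, config$behavior_betas_pct,
    config$behavior_subject_sd, config$behavior_noise_sd,
    substream_seed(config$seed, 5L))
  write.csv(behavior, file.path(out_dir, "behavior.csv"),
            row.names = FALSE)

  # ---- per-timepoint group tests ----
  stage_msg("stats", "cross-sectional Kruskal-Wallis (+FDR)")
  crosssec <- crosssectional_analysis(metrics, config$alpha,
                                      config$fdr_family)
  write.csv(crosssec, file.path(out_dir, "crosssectional.csv"),
            row.names = FALSE)

  # ---- network-based statistic per timepoint ----
  nbs_results <- list()
  for (tp in sort(unique(cohort$timepoint_index))) {
    sel <- vapply(connectomes, function(c_)
      c_$kind == config$nbs_kind && c_$timepoint_index == tp, logical(1))
    cons <- connectomes[sel]
    grp <- cohort$group[match(
      vapply(cons, function(c_) c_$subject_id, character(1)),
      cohort$subject_id)]
    if (sum(grp == "tg") < 2 || sum(grp == "control") < 2) next
    stage_msg("nbs", "timepoint %d (%s, %d perms)", tp, config$nbs_kind,
              config$nbs_n_perm)
    res <- nbs_test(cons[grp == "tg"], cons[grp == "control"],
                    config$nbs_t_threshold, config$nbs_n_perm,
                    config$nbs_alpha, "both",
                    substream_seed(config$seed, 100L + tp))
    nbs_results[[as.character(tp)]] <- res
    jsonlite::write_json(nbs_summary_json(res),
                         file.path(out_dir, "nbs",
                                   sprintf("tp%d.json", tp)),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (d in names(res$directions)) {
      comps <- res$directions[[d]]$components
      if (length(comps)) {
        edges <- do.call(rbind, lapply(comps, function(co) co$edges))
        write.csv(edges, file.path(out_dir, "nbs",
                                   sprintf("tp%d_%s_edges.csv", tp, d)),
                  row.names = FALSE)
      }
    }
  }

  # ---- longitudinal models ----
  stage_msg("model", "mixed-effects cascade")
  longi <- longitudinal_analysis(metrics, behavior, cohort, config$alpha,
                                 compute_f2 = config$compute_f2)
  write.csv(longi$group_age, file.path(out_dir, "longitudinal_group_age.csv"),
            row.names = FALSE)
  if (!is.null(longi$conditional_age))
    write.csv(longi$conditional_age, file.path(out_dir, "longitudinal_conditional_age.csv"),
              row.names = FALSE)
  if (!is.null(longi$cognition))
    write.csv(longi$cognition, file.path(out_dir, "longitudinal_cognition.csv"),
              row.names = FALSE)
  if (!is.null(longi$cognition_by_group))
    write.csv(longi$cognition_by_group,
              file.path(out_dir, "longitudinal_cognition_by_group.csv"),
              row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("longconn")),
    seed = config$seed,
    config = unclass_config(config),
    n_observations = nrow(cohort),
    n_connectomes = length(connectomes)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage_msg("done", "completed in %.1f s",
            as.numeric(difftime(Sys.time(), t0, units = "secs")))

  invisible(list(atlas = atlas, cohort = cohort, metrics = metrics,
                 behavior = behavior, crosssectional = crosssec,
                 nbs = nbs_results, longitudinal = longi,
                 paths = list(out_dir = out_dir)))
}

unclass_config <- function(config) {
  cfg <- unclass(config)
  cfg$effects <- unclass(cfg$effects)
  cfg$effects$planted_component <-
    if (is.null(cfg$effects$planted_component)) NULL
  else as.data.frame(cfg$effects$planted_component)
  cfg
}

nbs_summary_json <- function(res) {
  list(
    settings = res$settings,
    directions = lapply(res$directions, function(r) {
      list(n_components = length(r$components),
           extents = vapply(r$components, function(co) co$extent,
                            numeric(1)),
           p_values = r$p_values,
           significant = r$significant)
    })
  )
}

#' Validate pipeline inputs
#'
#' Schema and consistency checks over any subset of the pipeline's
#' tables: connectome symmetry and label consistency, subjects present
#' in metrics or behavior but absent from the cohort, group and
#' timepoint coverage, behavior ranges. Problems are reported, not
#' thrown.
#'
#' @param atlas,cohort,connectomes,metrics,behavior optional objects to
#'   check (`connectomes` is a list).
#' @return `data.frame` with columns `level` (`"fatal"`/`"warning"`),
#'   `check`, `message`; zero rows when everything is clean.
#' @export
validate_inputs <- function(atlas = NULL, cohort = NULL, connectomes = NULL,
                            metrics = NULL, behavior = NULL) {
  issues <- list()
  add <- function(level, check, msg)
    issues[[length(issues) + 1]] <<- data.frame(
      level = level, check = check, message = msg, stringsAsFactors = FALSE)

  if (!is.null(atlas)) {
    if (anyDuplicated(atlas$region_id))
      add("fatal", "atlas", "duplicated region ids")
    if (!identical(as.integer(atlas$region_id), seq_len(nrow(atlas))))
      add("fatal", "atlas", "region ids not contiguous from 1")
    if (any(atlas$volume <= 0))
      add("fatal", "atlas", "non-positive region volumes")
  }
  if (!is.null(cohort)) {
    if (!all(c("control", "tg") %in% cohort$group))
      add("fatal", "cohort", "both groups must be non-empty")
    bad_age <- vapply(split(cohort, cohort$subject_id),
                      function(s) any(diff(s$age[order(s$timepoint_index)])
                                      <= 0), logical(1))
    if (any(bad_age))
      add("fatal", "cohort", paste("ages not strictly increasing for:",
                                   paste(names(bad_age)[bad_age],
                                         collapse = ", ")))
  }
  if (!is.null(connectomes)) {
    for (i in seq_along(connectomes)) {
      c_ <- connectomes[[i]]
      w <- if (inherits(c_, "connectome")) c_$weights else as.matrix(c_)
      if (nrow(w) != ncol(w) || max(abs(w - t(w))) > 1e-8)
        add("fatal", "connectome", sprintf("connectome %d not symmetric", i))
      else if (any(diag(w) != 0))
        add("warning", "connectome",
            sprintf("connectome %d has nonzero diagonal", i))
      if (!is.null(atlas) && inherits(c_, "connectome") &&
          !all(c_$nodes %in% atlas$name))
        add("fatal", "connectome",
            sprintf("connectome %d has labels outside the atlas", i))
    }
  }
  if (!is.null(metrics) && !is.null(cohort)) {
    orphan <- setdiff(unique(metrics$subject_id), cohort$subject_id)
    if (length(orphan))
      add("fatal", "metrics", paste("subjects absent from cohort:",
                                    paste(orphan, collapse = ", ")))
  }
  if (!is.null(behavior)) {
    if (any(behavior$trials < 0 | behavior$trials > 90))
      add("fatal", "behavior", "trials outside [0, 90]")
    if (any(behavior$pct_correct < 0 | behavior$pct_correct > 100))
      add("fatal", "behavior", "pct_correct outside [0, 100]")
    if (!is.null(cohort)) {
      orphan <- setdiff(unique(behavior$subject_id), cohort$subject_id)
      if (length(orphan))
        add("fatal", "behavior", paste("subjects absent from cohort:",
                                       paste(orphan, collapse = ", ")))
    }
  }
  if (!length(issues))
    return(data.frame(level = character(0), check = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, issues)
}
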