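# End-to-end orchestration: synth -> preprocess -> association ->
# netmetrics -> permtests -> models, with cached stage outputs.

#' Export an association matrix as GraphML
#'
#' Writes the weighted network with edge attribute `weight` (association
#' index); zero-weight dyads are omitted as edges.
#'
#' @param E Association matrix.
#' @param path Output file path.
#' @export
write_graphml <- function(E, path) {
  g <- igraph::graph_from_adjacency_matrix(E, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Default pipeline configuration
#'
#' One list consumed by every stage of [run_pipeline()]. The defaults are
#' the study conditions (1 m / 3 min / 4-day thresholds, 10-s smoothing,
#' 10,000 permutations); `cohorts` entries are passed to [cohort_spec()]
#' and the `social` block to [social_params()].
#'
#' @param n_cohorts Number of synthetic cohorts.
#' @param monitoring_days Days monitored per cohort (grid starts after the
#'   censored first day).
#' @param sample_hz Positional sampling rate.
#' @param n_perm Permutations for the stability and differentiation tests.
#' @param n_iter,burn_in,thin Dyadic MCMC settings.
#' @param ... Overrides for threshold fields (`d_m`, `window_s`,
#'   `period_days`, `smooth_window_s`, `seen_frac`, `prox_frac`) or the
#'   `social` list.
#' @return A named list.
#' @export
default_config <- function(n_cohorts = 2, monitoring_days = 9, sample_hz = 0.05,
                           n_perm = 1000, n_iter = 6000, burn_in = 1000,
                           thin = 5, ...) {
  cfg <- list(
    n_cohorts = n_cohorts, n_calves = 16, monitoring_days = monitoring_days,
    sample_hz = sample_hz, d_m = 1.0, window_s = 180, period_days = 4,
    smooth_window_s = 10, seen_frac = 0.5, prox_frac = 0.9,
    first_day_censored = TRUE, n_perm = n_perm,
    n_iter = n_iter, burn_in = burn_in, thin = thin,
    social = list()
  )
  utils::modifyList(cfg, list(...))
}

stage_cached <- function(dir, stage, key, files) {
  hfile <- file.path(dir, paste0(".", stage, ".hash"))
  ok <- file.exists(hfile) && readLines(hfile, warn = FALSE)[1] == key &&
    all(file.exists(file.path(dir, files)))
  ok
}

stage_mark <- function(dir, stage, key) {
  writeLines(key, file.path(dir, paste0(".", stage, ".hash")))
}

#' Run the full analysis pipeline on synthetic cohorts
#'
#' Generates the configured cohorts, cleans and smooths the positions,
#' accumulates dyadic window counts into 4-day association matrices, computes
#' node metrics, runs the stability and differentiation permutation tests,
#' fits the dyadic assortment model and the node-level mixed models, and
#' writes every stage table plus a JSON run report under `out_dir`. Stages
#' are cached: outputs are reused when the stage's config hash is unchanged.
#'
#' @param config List from [default_config()].
#' @param out_dir Output directory.
#' @param seed Master seed; all stage seeds derive from it.
#' @return Invisibly, a list with the main stage results and the report.
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  social <- do.call(social_params, config$social)
  interval <- 1 / config$sample_hz
  t0 <- if (config$first_day_censored) 86400 else 0
  usable_days <- config$monitoring_days - t0 / 86400

  cohort_ids <- sprintf("C%d", seq_len(config$n_cohorts))
  specs <- lapply(seq_len(config$n_cohorts), function(k)
    cohort_spec(cohort_id = cohort_ids[k], n_calves = config$n_calves,
                monitoring_days = config$monitoring_days,
                sample_hz = config$sample_hz, seed = seed + 100L * k))

  key_synth <- rlang::hash(list(config, seed, "synth"))
  synth_files <- as.vector(outer(cohort_ids, c("positions.csv", "cohort.csv",
    "familiarity.csv", "health.csv", "events.csv"), file.path))
  if (!stage_cached(out_dir, "synth", key_synth, synth_files)) {
    for (k in seq_len(config$n_cohorts))
      write_synthetic_cohort(specs[[k]], social,
                             dir = file.path(out_dir, cohort_ids[k]),
                             seed = seed + 100L * k)
    stage_mark(out_dir, "synth", key_synth)
  }

  report <- list(seed = seed, cohorts = list())
  metrics_all <- list(); dyads_all <- list()
  stab_rows <- list(); diff_rows <- list()
  for (k in seq_len(config$n_cohorts)) {
    cdir <- file.path(out_dir, cohort_ids[k])
    pos <- utils::read.csv(file.path(cdir, "positions.csv"))
    ev <- utils::read.csv(file.path(cdir, "events.csv"))
    meta <- utils::read.csv(file.path(cdir, "cohort.csv"))
    health <- utils::read.csv(file.path(cdir, "health.csv"))
    fam_long <- utils::read.csv(file.path(cdir, "familiarity.csv"))
    animals <- sort(meta$animal_id)
    fam <- matrix(0, length(animals), length(animals),
                  dimnames = list(animals, animals))
    fam[cbind(fam_long$a, fam_long$b)] <- fam_long$familiarity_days
    fam[cbind(fam_long$b, fam_long$a)] <- fam_long$familiarity_days

    cl <- clean_positions(pos, pen = c(specs[[k]]$pen_width_m,
                                       specs[[k]]$pen_length_m),
                          events = ev,
                          first_day_s = if (config$first_day_censored)
                            c(0, 86400) else NULL)
    sm <- smooth_positions(cl$positions, window_s = config$smooth_window_s)
    utils::write.csv(cl$log, file.path(cdir, "censor_log.csv"), row.names = FALSE)
    utils::write.csv(sm, file.path(cdir, "positions_clean.csv"), row.names = FALSE)

    counts <- accumulate_counts(sm, animals = animals,
                                monitoring_days = usable_days,
                                sample_interval_s = interval,
                                period_days = config$period_days,
                                window_s = config$window_s, d_m = config$d_m,
                                seen_frac = config$seen_frac,
                                prox_frac = config$prox_frac, t0 = t0)
    counts$E <- as.numeric(association_index(counts$X, counts$Y_AB,
                                             counts$Y_A, counts$Y_B))
    counts$SE <- index_standard_error(counts$E, counts$X)
    counts$cohort <- cohort_ids[k]
    utils::write.csv(counts, file.path(cdir, "dyad_counts.csv"), row.names = FALSE)
    mats <- build_matrices(counts, animals = animals)
    for (p in names(mats)) {
      utils::write.csv(mats[[p]],
                       file.path(cdir, sprintf("adjacency_period%s.csv", p)))
      write_graphml(mats[[p]], file.path(cdir, sprintf("network_period%s.graphml", p)))
    }

    nm <- node_metrics(mats, counts, meta, health,
                       period_days = config$period_days,
                       window_min = config$window_s / 60)
    utils::write.csv(nm, file.path(cdir, "node_metrics.csv"), row.names = FALSE)
    metrics_all[[k]] <- nm

    if (length(mats) >= 2) {
      st <- stability_summary(mats, n_perm = config$n_perm,
                              seed = seed + 11L * k)
      st$table$cohort <- cohort_ids[k]
      stab_rows[[k]] <- st$table
    }
    for (p in seq_along(mats)) {
      gs <- window_group_stream(sm, animals = animals, period = p,
                                monitoring_days = usable_days,
                                sample_interval_s = interval,
                                period_days = config$period_days,
                                window_s = config$window_s, d_m = config$d_m,
                                seen_frac = config$seen_frac,
                                prox_frac = config$prox_frac, t0 = t0)
      dt <- social_differentiation_test(gs, n_perm = config$n_perm,
                                        seed = seed + 101L * k + p)
      diff_rows[[length(diff_rows) + 1]] <- data.frame(
        cohort = cohort_ids[k], period = p, cv_obs = dt$cv_observed,
        cv_corrected = dt$cv_corrected, p = dt$p_value,
        n_perm = dt$n_perm, seed = dt$seed)
    }
    dyads_all[[k]] <- build_dyad_table(mats, meta, fam, health,
                                       period_days = config$period_days)
  }

  stability <- if (length(stab_rows)) do.call(rbind, stab_rows) else data.frame()
  differentiation <- do.call(rbind, diff_rows)
  utils::write.csv(stability, file.path(out_dir, "stability.csv"), row.names = FALSE)
  utils::write.csv(differentiation, file.path(out_dir, "differentiation.csv"),
                   row.names = FALSE)

  dyads <- do.call(rbind, dyads_all)
  assort <- fit_dyadic_assortment(dyads, n_iter = config$n_iter,
                                  burn_in = config$burn_in,
                                  thin = config$thin, seed = seed + 7L)
  utils::write.csv(assort$summary, file.path(out_dir, "assortment_fit.csv"),
                   row.names = FALSE)

  metrics <- do.call(rbind, metrics_all)
  utils::write.csv(metrics, file.path(out_dir, "node_metrics.csv"), row.names = FALSE)
  lmm <- fit_node_lmms(metrics)
  for (mn in unique(lmm$coefficients$metric))
    utils::write.csv(lmm$coefficients[lmm$coefficients$metric == mn, ],
                     file.path(out_dir, sprintf("lmm_%s.csv", mn)),
                     row.names = FALSE)

  report$config <- config
  report$periods_per_cohort <- floor(usable_days / config$period_days)
  report$stability_share_significant_pct <-
    if (nrow(stability)) 100 * mean(stability$significant) else NA
  report$differentiation_p <- differentiation$p
  report$assortment <- assort$summary
  report$lmm <- lmm$coefficients
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(stability = stability, differentiation = differentiation,
                 assortment = assort, lmm = lmm, metrics = metrics,
                 report = report))
}
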