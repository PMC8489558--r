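# End-to-end pipeline: simulate -> qc -> pairs -> connect -> topology ->
# tuning -> dynamics, with a JSON summary report.

PIPELINE_STAGES <- c("simulate", "qc", "pairs", "connect", "topology",
                     "tuning", "dynamics")

#' Pipeline configuration
#'
#' Collects every tunable of the analysis in one validated list: the
#' generator's study conditions (see [session_config()]), the
#' quality-control thresholds ([qc_config()]), the connectivity criteria
#' ([connectivity_criteria()]), the pairwise binning parameters and the
#' dynamics grid. Any stage subset can be run; later stages require the
#' earlier ones.
#'
#' @param out_dir Output directory for stage artifacts and `summary.json`.
#' @param seed Integer master seed; recorded in the summary.
#' @param protocol `"ramp_hold"` or `"artificial_whisking"`.
#' @param n_trials,n_units Session size.
#' @param stages Stage names to run (subset of
#'   `simulate, qc, pairs, connect, topology, tuning, dynamics`).
#' @param session Extra arguments passed to [session_config()].
#' @param qc A [qc_config()].
#' @param criteria A [connectivity_criteria()].
#' @param bin_s,max_lag_ms,ccg_bin_ms Pairwise-metric parameters.
#' @param dynamics_window_s,dynamics_step_s Dynamics grid parameters.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1,
                            protocol = c("ramp_hold", "artificial_whisking"),
                            n_trials = 600, n_units = 16,
                            stages = PIPELINE_STAGES,
                            session = list(), qc = qc_config(),
                            criteria = connectivity_criteria(),
                            bin_s = 0.01, max_lag_ms = 50, ccg_bin_ms = 1,
                            dynamics_window_s = 0.5, dynamics_step_s = 0.1) {
  protocol <- match.arg(protocol)
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 protocol = protocol, n_trials = n_trials,
                 n_units = n_units, stages = stages, session = session,
                 qc = qc, criteria = criteria, bin_s = bin_s,
                 max_lag_ms = max_lag_ms, ccg_bin_ms = ccg_bin_ms,
                 dynamics_window_s = dynamics_window_s,
                 dynamics_step_s = dynamics_step_s),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Executes the configured stages on a synthetic session (stage
#' `simulate`) or, in future extensions, on loaded tables, writing the
#' standard artifacts (`spike_table.csv`, `events.csv`, `unit_meta.csv`,
#' `qc_report.csv`, `pair_metrics.csv`, `edges_<state>.csv`,
#' `connectivity_index.csv`, `ci_timeseries.csv`) and a `summary.json`
#' with the headline statistics: per-state mean pairwise correlation and
#' connectivity index, evoked/spontaneous edge overlap, common-neighbor
#' topology, tuning congruence, and the recovery time constant. The whole
#' run is reproducible from the master seed.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return The summary list, invisibly; artifacts are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  summary <- list(seed = config$seed, protocol = config$protocol,
                  n_trials = config$n_trials, n_units = config$n_units)
  st <- function(s) s %in% config$stages

  cfg <- do.call(session_config,
                 c(list(seed = config$seed, n_units = config$n_units),
                   config$session))
  ses <- NULL
  if (st("simulate")) {
    say("[simulate] %s session: %d units, %d trials, seed %d",
        config$protocol, config$n_units, config$n_trials, config$seed)
    ses <- generate_session(cfg$assembly, cfg$modulation, cfg$tuning,
                            protocol = config$protocol,
                            n_trials = config$n_trials,
                            seed = config$seed + 1L,
                            waveform_streams = TRUE)
    write_spike_table(ses$spikes, file.path(config$out_dir, "spike_table.csv"))
    write_events(ses$events, file.path(config$out_dir, "events.csv"))
    write_unit_meta(ses$meta, file.path(config$out_dir, "unit_meta.csv"))
  } else {
    stop("pipeline currently starts at the `simulate` stage", call. = FALSE)
  }
  windows <- make_state_windows(ses$events)

  accepted_units <- ses$spikes$units
  if (st("qc")) {
    qc_res <- apply_qc(ses$spikes, ses$meta, windows, config$qc)
    utils::write.csv(qc_res$report,
                     file.path(config$out_dir, "qc_report.csv"),
                     row.names = FALSE)
    accepted_units <- qc_res$accepted$units
    say("[qc] %d/%d units accepted", length(accepted_units),
        length(ses$spikes$units))
    summary$n_units_accepted <- length(accepted_units)
    if (length(accepted_units) < 2)
      stop("stage qc: fewer than 2 accepted units", call. = FALSE)
  }

  metrics <- NULL
  if (st("pairs")) {
    metrics <- pair_metrics(ses$spikes, windows, units = accepted_units,
                            bin_s = config$bin_s,
                            max_lag_ms = config$max_lag_ms,
                            ccg_bin_ms = config$ccg_bin_ms)
    say("[pairs] %d pair-state records", nrow(metrics))
    for (s2 in c("spontaneous", "evoked"))
      summary[[paste0("mean_r_", s2)]] <-
        mean(metrics$pearson_r[metrics$state == s2], na.rm = TRUE)
  }

  graphs <- list()
  if (st("connect")) {
    if (is.null(metrics)) stop("stage connect requires stage pairs",
                               call. = FALSE)
    for (s2 in c("spontaneous", "evoked"))
      graphs[[s2]] <- build_graph(metrics, s2, config$criteria,
                                  nodes = sort(accepted_units))
    idx_tab <- connectivity_index_table(graphs$spontaneous, graphs$evoked)
    ov <- overlap_fraction(graphs$evoked, graphs$spontaneous)
    write_results(list(pair_metrics = metrics,
                       connectivity_index = idx_tab,
                       edges_spontaneous = graphs$spontaneous$edges,
                       edges_evoked = graphs$evoked$edges),
                  config$out_dir)
    say("[connect] edges: %d spontaneous, %d evoked; overlap %.2f",
        nrow(graphs$spontaneous$edges), nrow(graphs$evoked$edges), ov)
    summary$mean_index_spontaneous <- mean(graphs$spontaneous$index)
    summary$mean_index_evoked <- mean(graphs$evoked$index)
    rel <- idx_tab$relative_change
    summary$mean_relative_change <- mean(rel[is.finite(rel)])
    summary$overlap_fraction <- ov
  }

  if (st("topology")) {
    if (!length(graphs)) stop("stage topology requires stage connect",
                              call. = FALSE)
    topo <- lapply(graphs, common_neighbor_stats)
    summary$topology <- lapply(topo, function(x)
      x[c("p_common", "p_nocommon", "p_expected")])
    dp <- distance_profile(graphs$spontaneous, graphs$evoked, ses$meta)
    utils::write.csv(dp$bins, file.path(config$out_dir, "distance_profile.csv"),
                     row.names = FALSE)
    summary$mean_connected_distance_um <-
      as.list(dp$mean_connected_distance)
    ls_tab <- layer_stats(graphs$spontaneous, graphs$evoked, ses$meta)
    utils::write.csv(ls_tab, file.path(config$out_dir, "layer_stats.csv"),
                     row.names = FALSE)
    say("[topology] p_common %.3f vs expected %.3f (spontaneous)",
        topo$spontaneous$p_common, topo$spontaneous$p_expected)
  }

  if (st("tuning")) {
    prefs <- vapply(accepted_units, function(u) {
      tc <- tryCatch({
        if (config$protocol == "ramp_hold")
          angular_tuning(ses$spikes$spike_times[[u]], ses$events)
        else coarseness_preference(ses$spikes$spike_times[[u]], ses$events)
      }, error = function(e) NULL)
      if (is.null(tc)) NA_character_ else as.character(tc$preferred)
    }, character(1))
    tun_tab <- data.frame(unit_id = accepted_units, preferred = prefs,
                          stringsAsFactors = FALSE)
    utils::write.csv(tun_tab, file.path(config$out_dir, "tuning.csv"),
                     row.names = FALSE)
    if (length(graphs) && !anyNA(prefs)) {
      cg <- lapply(graphs, congruence_stats,
                   preferences = stats::setNames(prefs, accepted_units))
      summary$congruence <- lapply(cg, function(x)
        x[c("observed", "expected")])
      say("[tuning] spontaneous congruence %.3f vs expected %.3f",
          cg$spontaneous$observed, cg$spontaneous$expected)
    }
  }

  if (st("dynamics")) {
    series <- time_resolved_index(ses$spikes, ses$events,
                                  window_s = config$dynamics_window_s,
                                  step_s = config$dynamics_step_s,
                                  criteria = config$criteria,
                                  units = accepted_units,
                                  bin_s = config$bin_s,
                                  max_lag_ms = config$max_lag_ms,
                                  ccg_bin_ms = config$ccg_bin_ms)
    utils::write.csv(as.data.frame(series),
                     file.path(config$out_dir, "ci_timeseries.csv"),
                     row.names = FALSE)
    t_off <- ses$events$offset_s[1] - ses$events$onset_s[1]
    fit <- tryCatch(fit_recovery(series, t_offset = t_off),
                    error = function(e) list(tau = NA_real_,
                                             tau_se = NA_real_,
                                             ci_0 = NA_real_,
                                             ci_inf = NA_real_,
                                             converged = FALSE,
                                             message = conditionMessage(e)))
    summary$recovery <- list(tau_s = fit$tau, tau_se = fit$tau_se,
                             ci_0 = fit$ci_0, ci_inf = fit$ci_inf,
                             converged = fit$converged)
    say("[dynamics] recovery tau = %.2f s (converged: %s)",
        fit$tau, fit$converged)
  }

  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(summary)
}
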