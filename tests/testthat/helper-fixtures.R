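# Shared fixtures, generated in code.

# small Poisson train (optionally refractory-filtered for QC fixtures)
poisson_train <- function(rate_hz, duration_s, seed, refractory_ms = 0) {
  tt <- synconn:::with_seed(seed, sort(stats::runif(
    stats::rpois(1, rate_hz * duration_s), 0, duration_s)))
  enforce_refractory(tt, refractory_ms)
}

# hand-computable two-cluster geometry: {(0,0),(0,1)} and {(10,0),(10,1)}
two_cluster_fixture <- function() {
  list(features = matrix(c(0, 0, 0, 1, 10, 0, 10, 1),
                         ncol = 2, byrow = TRUE),
       labels = c("a", "a", "b", "b"))
}

# a pair_metrics-style table with one pair in one state, all criteria
# controllable; spontaneous row mirrors the evoked counts so the
# both-state floors can be exercised from a single row's fields
fake_metrics <- function(r = 0.25, peak_z = 3, total = 5000,
                         n_spont = 1500, n_evoked = 1500,
                         state = "evoked", evaluable = TRUE) {
  df <- data.frame(unit_id_a = "u1", unit_id_b = "u2", state = state,
                   pearson_r = r, pearson_p = 0.01, n_bins = 1000,
                   peak_z = peak_z,
                   n_spont_a = n_spont, n_spont_b = n_spont,
                   n_evoked_a = n_evoked, n_evoked_b = n_evoked,
                   total_a = total, total_b = total,
                   evaluable = evaluable, stringsAsFactors = FALSE)
  class(df) <- c("pair_metrics", "data.frame")
  df
}

# small whisking session with given desynchronization factor
whisk_session <- function(seed, gamma = 0.9, n_trials = 200, ...) {
  cfg <- session_config(seed = seed, gamma = gamma, ...)
  generate_session(cfg$assembly, cfg$modulation, cfg$tuning,
                   protocol = "artificial_whisking", n_trials = n_trials,
                   seed = seed + 1000L)
}

ramp_session <- function(seed, n_trials = 600, ...) {
  cfg <- session_config(seed = seed, ...)
  generate_session(cfg$assembly, cfg$modulation, cfg$tuning,
                   protocol = "ramp_hold", n_trials = n_trials,
                   seed = seed + 1000L)
}

session_graphs <- function(ses, criteria = connectivity_criteria()) {
  w <- make_state_windows(ses$events)
  pm <- pair_metrics(ses$spikes, w)
  list(metrics = pm,
       spont = build_graph(pm, "spontaneous", criteria),
       evoked = build_graph(pm, "evoked", criteria))
}
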