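# Synthetic sessions: correlated spike trains from latent "mother" Poisson
# processes with per-unit thinning, stimulus-locked desynchronization, tuned
# evoked rate gain, and exponential post-stimulus recovery of synchrony.

#' Assembly configuration for the correlated-train generator
#'
#' Each assembly owns a latent homogeneous Poisson *mother* process of rate
#' `mother_rate_hz`; every member unit independently inherits each mother
#' spike with probability `copy_prob`, jittered by a zero-mean Gaussian of SD
#' `jitter_sd_ms`, and adds an independent Poisson background of rate
#' `background_rate_hz`. This multiple-interaction-process construction gives
#' a closed-form expected pairwise count correlation
#' ([expected_pair_correlation()]) used as the generator's oracle.
#'
#' @param membership Integer vector mapping unit -> assembly (1-based); its
#'   length sets the number of units. Use `0` for units in no assembly.
#' @param mother_rate_hz Mother-process rate, Hz (scalar, or one per
#'   assembly).
#' @param copy_prob Per-unit copy probability in \[0, 1\] (scalar or one per
#'   unit).
#' @param jitter_sd_ms Gaussian jitter SD applied to inherited spikes, ms.
#' @param background_rate_hz Independent per-unit background rate, Hz
#'   (scalar or one per unit).
#' @param refractory_ms Absolute refractory period enforced on every
#'   generated train (spikes closer than this to the previous kept spike
#'   are deleted), ms. Default 0 so the bare generator matches the
#'   closed-form correlation exactly; [session_config()] turns it on
#'   (2.5 ms) so generated units are compatible with the minimum-ISI
#'   quality criterion of real single units.
#' @param unit_ids Optional unit identifiers (default `u01`, `u02`, ...).
#' @return An object of class `assembly_config`.
#' @export
assembly_config <- function(membership, mother_rate_hz = 10, copy_prob = 0.7,
                            jitter_sd_ms = 1.5, background_rate_hz = 5,
                            refractory_ms = 0, unit_ids = NULL) {
  membership <- as.integer(membership)
  n <- length(membership)
  if (n < 1) stop("at least one unit required", call. = FALSE)
  n_assemblies <- max(membership, 0L)
  if (any(membership < 0))
    stop("membership must be >= 0 (0 = no assembly)", call. = FALSE)
  mother_rate_hz <- rep_len(as.numeric(mother_rate_hz), max(n_assemblies, 1L))
  copy_prob <- rep_len(as.numeric(copy_prob), n)
  background_rate_hz <- rep_len(as.numeric(background_rate_hz), n)
  if (any(copy_prob < 0 | copy_prob > 1))
    stop("copy_prob must lie in [0, 1]", call. = FALSE)
  if (any(mother_rate_hz < 0) || any(background_rate_hz < 0))
    stop("rates must be >= 0", call. = FALSE)
  if (length(jitter_sd_ms) != 1 || jitter_sd_ms < 0)
    stop("jitter_sd_ms must be a single value >= 0", call. = FALSE)
  if (length(refractory_ms) != 1 || refractory_ms < 0)
    stop("refractory_ms must be a single value >= 0", call. = FALSE)
  if (is.null(unit_ids)) unit_ids <- sprintf("u%02d", seq_len(n))
  unit_ids <- as.character(unit_ids)
  stopifnot(length(unit_ids) == n, !anyDuplicated(unit_ids))
  structure(list(unit_ids = unit_ids, membership = membership,
                 n_assemblies = n_assemblies,
                 mother_rate_hz = mother_rate_hz, copy_prob = copy_prob,
                 jitter_sd_ms = as.numeric(jitter_sd_ms),
                 background_rate_hz = background_rate_hz,
                 refractory_ms = as.numeric(refractory_ms)),
            class = "assembly_config")
}

#' Enforce an absolute refractory period on a spike train
#'
#' Greedy forward pass: a spike is kept only when at least `refractory_ms`
#' after the previously kept spike.
#'
#' @param times Sorted spike times, seconds.
#' @param refractory_ms Minimum inter-spike interval, ms.
#' @return The filtered spike-time vector.
#' @export
enforce_refractory <- function(times, refractory_ms = 2.5) {
  n <- length(times)
  if (n < 2 || refractory_ms <= 0) return(times)
  ref <- refractory_ms / 1000
  keep <- logical(n)
  last <- -Inf
  for (i in seq_len(n)) {
    if (times[i] - last >= ref) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Stimulus-state modulation of assembly synchrony
#'
#' During an evoked window every unit's copy probability is multiplied by an
#' effective factor `gamma_eff = evoked_copy_factor *
#' (1 - distance_penalty * d/100) * (1 - incongruence_penalty * I)`, where
#' `d` is the unit's depth distance (micrometres) to its assembly's centre
#' and `I` indicates that the unit's tuning preference differs from its
#' assembly's. After stimulus offset the factor relaxes back to 1 as
#' `1 - (1 - gamma_eff) * exp(-t / recovery_tau_s)`, applied in 100 ms
#' piecewise-constant steps.
#'
#' @param evoked_copy_factor Multiplier on copy probability during evoked
#'   windows, in \[0, 1\] (1 = no desynchronization).
#' @param distance_penalty Additional multiplicative reduction per 100 um of
#'   unit-to-assembly-centre depth distance, in \[0, 1\].
#' @param incongruence_penalty Multiplicative reduction applied when the
#'   unit's tuning preference differs from its assembly's, in \[0, 1\].
#' @param recovery_tau_s Time constant (s) of post-offset relaxation, > 0.
#' @return An object of class `state_modulation`.
#' @export
state_modulation <- function(evoked_copy_factor = 0.9, distance_penalty = 0.05,
                             incongruence_penalty = 0.2, recovery_tau_s = 1.2) {
  vals <- c(evoked_copy_factor, distance_penalty, incongruence_penalty)
  if (any(vals < 0 | vals > 1))
    stop("modulation factors must lie in [0, 1]", call. = FALSE)
  if (recovery_tau_s <= 0) stop("recovery_tau_s must be > 0", call. = FALSE)
  structure(list(evoked_copy_factor = evoked_copy_factor,
                 distance_penalty = distance_penalty,
                 incongruence_penalty = incongruence_penalty,
                 recovery_tau_s = recovery_tau_s),
            class = "state_modulation")
}

#' Tuning configuration for evoked rate gain
#'
#' Each unit has a preferred deflection angle (8 directions, 45 degree
#' spacing) and a preferred texture grade (5 categories). During an evoked
#' window the unit gains an independent Poisson rate component
#' `evoked_gain_hz * exp(-delta^2 / (2 * width^2))`, where `delta` is the
#' circular angle distance in degrees (ramp-and-hold) or the grade-index
#' distance with width 1 category (whisking). Rate tuning and synchrony
#' modulation are separate mechanisms, so the evoked firing rate can rise
#' while pairwise synchrony falls.
#'
#' @param preferred_angle Per-unit preferred angle, degrees in
#'   `{0, 45, ..., 315}`.
#' @param preferred_coarseness Per-unit preferred texture grade.
#' @param evoked_gain_hz Added rate at the preferred condition, Hz, >= 0.
#' @param tuning_width_deg Angular falloff scale, degrees.
#' @return An object of class `tuning_config`.
#' @export
tuning_config <- function(preferred_angle, preferred_coarseness,
                          evoked_gain_hz = 4, tuning_width_deg = 60) {
  preferred_angle <- as.numeric(preferred_angle)
  preferred_coarseness <- as.character(preferred_coarseness)
  if (length(preferred_angle) != length(preferred_coarseness))
    stop("preference vectors must have equal length", call. = FALSE)
  if (!all(preferred_angle %in% ANGLE_DIRECTIONS))
    stop("preferred_angle outside the 8 canonical directions", call. = FALSE)
  if (!all(preferred_coarseness %in% TEXTURE_GRADES))
    stop("preferred_coarseness outside the 5 canonical grades", call. = FALSE)
  if (evoked_gain_hz < 0) stop("evoked_gain_hz must be >= 0", call. = FALSE)
  if (tuning_width_deg <= 0) stop("tuning_width_deg must be > 0", call. = FALSE)
  structure(list(preferred_angle = preferred_angle,
                 preferred_coarseness = preferred_coarseness,
                 evoked_gain_hz = evoked_gain_hz,
                 tuning_width_deg = tuning_width_deg),
            class = "tuning_config")
}

#' Expected pairwise count correlation under the thinning model
#'
#' Closed form for the binned-count Pearson correlation of two units sharing
#' one mother process of rate `lambda_m`: each bin's counts are sums of a
#' common thinned component and independent backgrounds, so
#' `rho = (p_i * p_j * lambda_m) / sqrt((p_i*lambda_m + b_i) *
#' (p_j*lambda_m + b_j))`. The approximation is valid for count bins much
#' wider than the spike-time jitter.
#'
#' @param p_i,p_j Copy probabilities of the two units, in \[0, 1\].
#' @param lambda_m Mother-process rate, Hz.
#' @param b_i,b_j Background rates, Hz.
#' @return Expected correlation in \[0, 1\].
#' @export
#' @examples
#' expected_pair_correlation(0.5, 0.5, 10, 5, 5)  # 0.25
expected_pair_correlation <- function(p_i, p_j, lambda_m, b_i, b_j) {
  stopifnot(p_i >= 0, p_i <= 1, p_j >= 0, p_j <= 1,
            lambda_m >= 0, b_i >= 0, b_j >= 0)
  di <- p_i * lambda_m + b_i
  dj <- p_j * lambda_m + b_j
  if (di == 0 && dj == 0)
    stop("correlation undefined: both units have zero rate", call. = FALSE)
  if (di == 0 || dj == 0) return(0)
  (p_i * p_j * lambda_m) / sqrt(di * dj)
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate correlated spike trains (no stimulation)
#'
#' Simulates a spontaneous session under an [assembly_config()]: one latent
#' Poisson mother process per assembly, independent per-unit thinning with
#' Gaussian jitter, plus independent Poisson background. Same-assembly pairs
#' have expected binned-count correlation [expected_pair_correlation()];
#' cross-assembly pairs are independent.
#'
#' @param config An [assembly_config()].
#' @param duration_s Session length, seconds (> 0).
#' @param seed Integer seed; the result is fully reproducible from
#'   `(config, duration_s, seed)`.
#' @return A list with elements `spikes` (a [spike_train_set()]) and
#'   `ground_truth` (a `synthetic_ground_truth` object carrying the config,
#'   seed, expected per-pair correlations and the same-assembly pair list).
#' @export
generate_correlated_trains <- function(config, duration_s, seed) {
  stopifnot(inherits(config, "assembly_config"), duration_s > 0)
  with_seed(seed, {
    n <- length(config$unit_ids)
    trains <- rep(list(numeric(0)), n)
    jit <- config$jitter_sd_ms / 1000
    for (a in seq_len(config$n_assemblies)) {
      members <- which(config$membership == a)
      if (!length(members)) next
      rate <- config$mother_rate_hz[a]
      n_m <- stats::rpois(1, rate * duration_s)
      mother <- sort(stats::runif(n_m, 0, duration_s))
      for (u in members) {
        keep <- stats::runif(n_m) < config$copy_prob[u]
        tt <- mother[keep]
        if (jit > 0 && length(tt)) tt <- tt + stats::rnorm(length(tt), 0, jit)
        trains[[u]] <- tt[tt >= 0 & tt <= duration_s]
      }
    }
    for (u in seq_len(n)) {
      b <- config$background_rate_hz[u]
      if (b > 0) {
        bg <- stats::runif(stats::rpois(1, b * duration_s), 0, duration_s)
        trains[[u]] <- c(trains[[u]], bg)
      }
      trains[[u]] <- enforce_refractory(sort(trains[[u]]),
                                        config$refractory_ms)
    }
    names(trains) <- config$unit_ids
    spikes <- spike_train_set(trains, session_duration = duration_s)
    gt <- ground_truth(config, seed = seed)
    list(spikes = spikes, ground_truth = gt)
  })
}

# Ground-truth container: expected correlations + same-assembly pairs.
ground_truth <- function(config, modulation = NULL, tuning = NULL, seed,
                         gamma_eff = NULL, meta = NULL) {
  n <- length(config$unit_ids)
  exp_r <- matrix(0, n, n, dimnames = list(config$unit_ids, config$unit_ids))
  pairs <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && config$membership[i] > 0 &&
        config$membership[i] == config$membership[j]) {
      lam <- config$mother_rate_hz[config$membership[i]]
      r <- expected_pair_correlation(config$copy_prob[i], config$copy_prob[j],
                                     lam, config$background_rate_hz[i],
                                     config$background_rate_hz[j])
      exp_r[i, j] <- exp_r[j, i] <- r
      pairs[[length(pairs) + 1L]] <-
        c(config$unit_ids[i], config$unit_ids[j])
    }
  }
  same <- if (length(pairs)) do.call(rbind, pairs) else
    matrix(character(0), 0, 2)
  colnames(same) <- c("unit_id_a", "unit_id_b")
  structure(list(assembly = config, modulation = modulation, tuning = tuning,
                 seed = seed, expected_spont_r = exp_r,
                 same_assembly_pairs = as.data.frame(same,
                                                     stringsAsFactors = FALSE),
                 gamma_eff = gamma_eff, meta = meta),
            class = "synthetic_ground_truth")
}

# Build the stimulus event table for a protocol.
build_protocol_events <- function(protocol, n_trials, start_s, conditions,
                                  whisk_period_s) {
  if (protocol == "ramp_hold") {
    period <- 2       # 0.5 Hz stimulus delivery
    dur <- 0.2        # 200 ms ramp-and-hold
  } else {
    period <- whisk_period_s
    dur <- 10 / 5.5   # 10 protraction-retraction cycles at 5.5 Hz
  }
  onsets <- start_s + period * (seq_len(n_trials) - 1)
  list(onsets = onsets, offsets = onsets + dur, period = period, dur = dur)
}

# Block-randomized condition order: each condition's repetitions are split
# into two equal blocks and blocks are applied in random (seeded) order.
block_randomize <- function(conditions, n_trials) {
  k <- length(conditions)
  if (k == 1) return(rep(conditions, n_trials))
  per_block <- ceiling(n_trials / (2 * k))
  blocks <- rep(rep(conditions, each = 1), times = 2)
  blocks <- sample(blocks)
  out <- rep(blocks, each = per_block)[seq_len(n_trials)]
  out
}

#' Generate a full synthetic stimulation session
#'
#' Builds a stimulus protocol (`ramp_hold`: 200 ms deflections delivered at
#' 0.5 Hz; `artificial_whisking`: 10 cycles at 5.5 Hz, about 1.82 s per
#' train), simulates correlated spike trains whose assembly synchrony is
#' suppressed during evoked windows and relaxes back exponentially after
#' offset (see [state_modulation()]), adds a tuned evoked rate gain (see
#' [tuning_config()]), and lays the units out on a 16-contact, 50 um-pitch
#' linear probe spanning 200--950 um depth.
#'
#' @param assembly An [assembly_config()].
#' @param modulation A [state_modulation()].
#' @param tuning A [tuning_config()] with per-unit preferences matching the
#'   assembly's unit count.
#' @param protocol `"ramp_hold"` or `"artificial_whisking"`.
#' @param n_trials Number of stimulus events (>= 1).
#' @param seed Integer seed.
#' @param angles Deflection angles cycled over trials (ramp-and-hold only);
#'   default all 8 directions.
#' @param textures Texture grades cycled over trials (whisking only);
#'   default all 5 grades.
#' @param start_s Time of the first stimulus onset, seconds.
#' @param whisk_period_s Trial period for the whisking protocol, seconds.
#' @param waveform_streams If `TRUE`, attach stationary per-spike amplitude
#'   and half-width streams (for quality-control exercises).
#' @return A list with `spikes` ([spike_train_set()]), `events`
#'   ([session_events()]), `meta` ([unit_meta()]) and `ground_truth`.
#' @export
generate_session <- function(assembly, modulation = state_modulation(),
                             tuning = NULL,
                             protocol = c("ramp_hold", "artificial_whisking"),
                             n_trials, seed, angles = ANGLE_DIRECTIONS,
                             textures = TEXTURE_GRADES, start_s = 5,
                             whisk_period_s = 6, waveform_streams = FALSE) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(assembly, "assembly_config"),
            inherits(modulation, "state_modulation"), n_trials >= 1)
  n <- length(assembly$unit_ids)
  if (is.null(tuning))
    tuning <- tuning_config(
      preferred_angle = rep(ANGLE_DIRECTIONS, length.out = n),
      preferred_coarseness = rep(TEXTURE_GRADES, length.out = n),
      evoked_gain_hz = 0)
  stopifnot(inherits(tuning, "tuning_config"))
  if (length(tuning$preferred_angle) != n)
    stop("tuning preferences must cover every unit", call. = FALSE)
  if (protocol == "ramp_hold" && !all(angles %in% ANGLE_DIRECTIONS))
    stop("angles outside the 8 canonical directions", call. = FALSE)
  if (protocol == "artificial_whisking" && !all(textures %in% TEXTURE_GRADES))
    stop("unknown texture grade", call. = FALSE)
  if (protocol == "artificial_whisking" && !missing(angles) &&
      !identical(angles, ANGLE_DIRECTIONS))
    stop("angles are a ramp-and-hold condition; whisking trials take textures",
         call. = FALSE)
  if (protocol == "ramp_hold" && !missing(textures) &&
      !identical(textures, TEXTURE_GRADES))
    stop("textures are a whisking condition; ramp-and-hold trials take angles",
         call. = FALSE)

  prot <- build_protocol_events(protocol, n_trials, start_s, NULL,
                                whisk_period_s)
  duration_s <- max(prot$offsets) + prot$period

  # probe layout: contacts 0..15 at 200 + 50 * contact um, units round-robin
  contact <- (seq_len(n) - 1L) %% 16L
  depth <- 200 + 50 * contact
  meta <- unit_meta(assembly$unit_ids, contact, depth,
                    preferred_angle = tuning$preferred_angle,
                    preferred_coarseness = tuning$preferred_coarseness)

  # per-unit effective evoked copy factor (distance + incongruence penalties)
  centre <- vapply(seq_len(max(assembly$n_assemblies, 1L)), function(a) {
    m <- which(assembly$membership == a)
    if (length(m)) mean(depth[m]) else NA_real_
  }, numeric(1))
  gamma_eff <- rep(1, n)
  asm_pref_angle <- vapply(seq_len(max(assembly$n_assemblies, 1L)),
    function(a) {
      m <- which(assembly$membership == a)
      if (!length(m)) return(NA_real_)
      tab <- table(tuning$preferred_angle[m])
      as.numeric(names(tab)[which.max(tab)])
    }, numeric(1))
  asm_pref_tex <- vapply(seq_len(max(assembly$n_assemblies, 1L)),
    function(a) {
      m <- which(assembly$membership == a)
      if (!length(m)) return(NA_character_)
      tab <- table(tuning$preferred_coarseness[m])
      names(tab)[which.max(tab)]
    }, character(1))
  for (u in seq_len(n)) {
    a <- assembly$membership[u]
    if (a == 0) next
    d <- abs(depth[u] - centre[a])
    incong <- if (protocol == "ramp_hold")
      tuning$preferred_angle[u] != asm_pref_angle[a]
    else tuning$preferred_coarseness[u] != asm_pref_tex[a]
    g <- modulation$evoked_copy_factor *
      max(0, 1 - modulation$distance_penalty * d / 100) *
      (1 - modulation$incongruence_penalty * as.numeric(incong))
    gamma_eff[u] <- min(max(g, 0), 1)
  }

  with_seed(seed, {
    cond <- if (protocol == "ramp_hold") block_randomize(angles, n_trials)
            else block_randomize(textures, n_trials)
    events <- if (protocol == "ramp_hold")
      session_events(prot$onsets, prot$offsets, protocol, angle_deg = cond)
    else session_events(prot$onsets, prot$offsets, protocol, texture = cond)

    # shared desynchronization time-course g(t): 0 before the first onset,
    # 1 inside evoked windows, exp(-t_since_offset / tau) afterwards in
    # 100 ms piecewise-constant steps; f_u(t) = 1 - (1 - gamma_eff_u) g(t)
    g_at <- function(t) {
      g <- numeric(length(t))
      idx_ev <- findInterval(t, prot$onsets)
      inside <- idx_ev >= 1 & t < prot$offsets[pmax(idx_ev, 1L)]
      g[inside] <- 1
      after <- idx_ev >= 1 & !inside
      if (any(after)) {
        dt <- t[after] - prot$offsets[idx_ev[after]]
        dt_step <- floor(dt / 0.1) * 0.1
        g[after] <- exp(-dt_step / modulation$recovery_tau_s)
      }
      g
    }

    jit <- assembly$jitter_sd_ms / 1000
    trains <- rep(list(numeric(0)), n)
    for (a in seq_len(assembly$n_assemblies)) {
      members <- which(assembly$membership == a)
      if (!length(members)) next
      n_m <- stats::rpois(1, assembly$mother_rate_hz[a] * duration_s)
      mother <- sort(stats::runif(n_m, 0, duration_s))
      g_m <- g_at(mother)
      for (u in members) {
        f_u <- 1 - (1 - gamma_eff[u]) * g_m
        keep <- stats::runif(n_m) < assembly$copy_prob[u] * f_u
        tt <- mother[keep]
        if (jit > 0 && length(tt)) tt <- tt + stats::rnorm(length(tt), 0, jit)
        trains[[u]] <- tt[tt >= 0 & tt <= duration_s]
      }
    }

    # independent background + tuned evoked gain
    width <- tuning$tuning_width_deg
    for (u in seq_len(n)) {
      b <- assembly$background_rate_hz[u]
      if (b > 0) {
        bg <- stats::runif(stats::rpois(1, b * duration_s), 0, duration_s)
        trains[[u]] <- c(trains[[u]], bg)
      }
      if (tuning$evoked_gain_hz > 0) {
        gain <- if (protocol == "ramp_hold") {
          delta <- abs(cond - tuning$preferred_angle[u])
          delta <- pmin(delta, 360 - delta)
          tuning$evoked_gain_hz * exp(-delta^2 / (2 * width^2))
        } else {
          di <- match(cond, TEXTURE_GRADES) -
            match(tuning$preferred_coarseness[u], TEXTURE_GRADES)
          tuning$evoked_gain_hz * exp(-di^2 / 2)
        }
        n_extra <- stats::rpois(n_trials, gain * prot$dur)
        if (sum(n_extra) > 0) {
          ev_idx <- rep(seq_len(n_trials), n_extra)
          extra <- prot$onsets[ev_idx] +
            stats::runif(sum(n_extra), 0, prot$dur)
          trains[[u]] <- c(trains[[u]], extra)
        }
      }
      trains[[u]] <- enforce_refractory(sort(trains[[u]]),
                                        assembly$refractory_ms)
    }
    names(trains) <- assembly$unit_ids

    amp <- hw <- NULL
    if (waveform_streams) {
      amp <- lapply(trains, function(tt)
        stats::rnorm(length(tt), 100, 8))
      hw <- lapply(trains, function(tt)
        stats::rnorm(length(tt), 0.30, 0.03))
    }
    spikes <- spike_train_set(trains, session_duration = duration_s,
                              amplitudes = amp, half_widths = hw)
    gt <- ground_truth(assembly, modulation, tuning, seed = seed,
                       gamma_eff = stats::setNames(gamma_eff,
                                                   assembly$unit_ids),
                       meta = meta)
    list(spikes = spikes, events = events, meta = meta, ground_truth = gt)
  })
}

#' Draw a heterogeneous session configuration
#'
#' Convenience constructor for the generator's default study conditions:
#' `n_units` units on the 16-contact probe, assigned round-robin to
#' `n_assemblies` assemblies (so each assembly spans the probe depth), with
#' per-unit copy probabilities drawn uniformly from `copy_prob_range`,
#' log-normal background rates (median `background_median_hz`) clipped to
#' `background_range_hz`, and per-unit tuning preferences equal to their
#' assembly's preference with probability `1 - pref_mismatch_prob`.
#'
#' @param seed Integer seed for the configuration draw.
#' @param n_units,n_assemblies Population layout.
#' @param mother_rate_hz,copy_prob_range,jitter_sd_ms,background_median_hz,background_sdlog,background_range_hz,refractory_ms
#'   Assembly-process parameters (see [assembly_config()]).
#' @param gamma,distance_penalty,incongruence_penalty,recovery_tau_s State
#'   modulation (see [state_modulation()]).
#' @param evoked_gain_hz,tuning_width_deg,pref_mismatch_prob Tuning
#'   parameters (see [tuning_config()]).
#' @return A list with elements `assembly`, `modulation`, `tuning`.
#' @export
session_config <- function(seed, n_units = 16, n_assemblies = 4,
                           mother_rate_hz = 10,
                           copy_prob_range = c(0.55, 0.9),
                           jitter_sd_ms = 1.5,
                           background_median_hz = 5, background_sdlog = 0.4,
                           background_range_hz = c(2, 20),
                           refractory_ms = 2.5,
                           gamma = 0.9, distance_penalty = 0.05,
                           incongruence_penalty = 0.2, recovery_tau_s = 1.2,
                           evoked_gain_hz = 2, tuning_width_deg = 60,
                           pref_mismatch_prob = 0.25) {
  with_seed(seed, {
    membership <- rep(seq_len(n_assemblies), length.out = n_units)
    p <- stats::runif(n_units, copy_prob_range[1], copy_prob_range[2])
    b <- stats::rlnorm(n_units, log(background_median_hz), background_sdlog)
    b <- pmin(pmax(b, background_range_hz[1]), background_range_hz[2])
    asm_angle <- rep(ANGLE_DIRECTIONS[c(1, 3, 5, 7)],
                     length.out = n_assemblies)
    asm_tex <- rep(TEXTURE_GRADES, length.out = n_assemblies)
    pref_angle <- asm_angle[membership]
    pref_tex <- asm_tex[membership]
    flip <- stats::runif(n_units) < pref_mismatch_prob
    if (any(flip)) {
      pref_angle[flip] <- vapply(pref_angle[flip], function(a)
        sample(setdiff(ANGLE_DIRECTIONS, a), 1), numeric(1))
      pref_tex[flip] <- vapply(pref_tex[flip], function(tx)
        sample(setdiff(TEXTURE_GRADES, tx), 1), character(1))
    }
    list(assembly = assembly_config(membership, mother_rate_hz, p,
                                    jitter_sd_ms, b, refractory_ms),
         modulation = state_modulation(gamma, distance_penalty,
                                       incongruence_penalty, recovery_tau_s),
         tuning = tuning_config(pref_angle, pref_tex, evoked_gain_hz,
                                tuning_width_deg))
  })
}

#' Generate labelled Gaussian feature clouds
#'
#' Fixture generator for the cluster-validity battery: `n_clusters` Gaussian
#' clouds in 2--3 dimensions with known labels.
#'
#' @param n_clusters Number of clusters.
#' @param n_per_cluster Points per cluster (scalar or per cluster, >= 2).
#' @param centers Numeric matrix, `n_clusters` x `d` (d = 2 or 3).
#' @param covariances A single `d` x `d` covariance matrix, or a list of one
#'   per cluster. Must be non-singular unless exactly zero.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `unit_id` (cluster label `c1`, ...),
#'   `spike_index` and features `f1..fd`.
#' @export
generate_feature_clusters <- function(n_clusters, n_per_cluster, centers,
                                      covariances, seed) {
  centers <- as.matrix(centers)
  d <- ncol(centers)
  if (nrow(centers) != n_clusters || !(d %in% 2:3))
    stop("`centers` must be n_clusters x d with d in {2, 3}", call. = FALSE)
  n_per_cluster <- rep_len(as.integer(n_per_cluster), n_clusters)
  if (any(n_per_cluster < 2))
    stop("n_per_cluster must be >= 2", call. = FALSE)
  if (!is.list(covariances))
    covariances <- rep(list(as.matrix(covariances)), n_clusters)
  covariances <- lapply(covariances, as.matrix)
  for (S in covariances) {
    if (!all(dim(S) == d)) stop("covariance dimension mismatch", call. = FALSE)
    if (any(S != 0) && abs(det(S)) < .Machine$double.eps * 100)
      stop("singular covariance matrix", call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(seq_len(n_clusters), function(k) {
      S <- covariances[[k]]
      pts <- if (all(S == 0))
        matrix(rep(centers[k, ], each = n_per_cluster[k]), ncol = d)
      else MASS::mvrnorm(n_per_cluster[k], centers[k, ], S)
      pts <- matrix(pts, ncol = d)
      df <- data.frame(unit_id = sprintf("c%d", k),
                       spike_index = seq_len(n_per_cluster[k]))
      for (jj in seq_len(d)) df[[paste0("f", jj)]] <- pts[, jj]
      df
    })
    do.call(rbind, rows)
  })
}
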