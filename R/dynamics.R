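# Time-resolved connectivity index around stimulation and mono-exponential
# recovery fitting after stimulus offset.

#' Time-resolved connectivity index
#'
#' For a grid of latencies relative to stimulus onset, pools the
#' `window_s`-long window at that latency across all trials, recomputes the
#' pairwise metrics (binned-count Pearson correlation and cross-correlogram
#' peak score) from the pooled bins, builds the connectivity graph (the
#' correlation and correlogram thresholds applied within the latency
#' window, the spike-count floors at the session level), and reports the
#' mean per-unit connectivity index.
#'
#' @param set A [spike_train_set()].
#' @param events A [session_events()] table (>= 2 events).
#' @param window_s Pooling window length, seconds (default 0.5).
#' @param step_s Grid step, seconds (default 0.1).
#' @param t_min,t_max Latency range relative to onset, seconds; `t_max`
#'   defaults to the trial period minus `window_s`.
#' @param criteria A [connectivity_criteria()].
#' @param units Units to analyse (default all).
#' @param bin_s,max_lag_ms,ccg_bin_ms Pairwise-metric parameters.
#' @param spont_s Pre-stimulus window used for the session-level state
#'   floors.
#' @return A `data.frame` of class `connectivity_timeseries` with columns
#'   `time_s` (window start relative to onset), `ci_mean`, `ci_sem`,
#'   `n_edges`, `n_units`; attributes `window_s`, `step_s`.
#' @export
time_resolved_index <- function(set, events, window_s = 0.5, step_s = 0.1,
                                t_min = -1, t_max = NULL,
                                criteria = connectivity_criteria(),
                                units = NULL, bin_s = 0.01, max_lag_ms = 50,
                                ccg_bin_ms = 1, spont_s = 0.6) {
  stopifnot(inherits(set, "spike_train_set"),
            inherits(events, "session_events"), nrow(events) >= 2,
            window_s > 0, step_s > 0)
  if (is.null(units)) units <- set$units
  units <- sort(units)
  set <- subset_units(set, units)
  n <- length(units)
  if (n < 2) stop("at least 2 units required", call. = FALSE)
  period <- stats::median(diff(events$onset_s))
  if (is.null(t_max)) t_max <- period - window_s
  grid <- seq(t_min, t_max, by = step_s)

  # session-level spike-count floors evaluated once
  sw <- make_state_windows(events, spont_s = spont_s)
  totals <- n_spikes(set)
  st_counts <- lapply(c("spontaneous", "evoked"), function(st) {
    w <- sw[sw$label == st, , drop = FALSE]
    vapply(units, function(u)
      sum(spikes_in_windows(set$spike_times[[u]], w)), numeric(1))
  })
  unit_floor_ok <- totals > criteria$min_total_spikes &
    st_counts[[1]] >= criteria$min_state_spikes &
    st_counts[[2]] >= criteria$min_state_spikes

  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  pair_ok <- unit_floor_ok[ii] & unit_floor_ok[jj]

  dropped <- FALSE
  rows <- lapply(grid, function(t0) {
    ws <- events$onset_s + t0
    we <- ws + window_s
    keep <- ws >= 0 & we <= set$session_duration
    if (!all(keep)) dropped <<- TRUE
    if (sum(keep) < 2)
      return(data.frame(time_s = t0, ci_mean = NA_real_, ci_sem = NA_real_,
                        n_edges = NA_integer_, n_units = n))
    w <- data.frame(start_s = ws[keep], end_s = we[keep], label = "lat",
                    event = which(keep))
    bc <- bin_counts(set, w, bin_s = bin_s, states = "lat")
    m <- bc$states[["lat"]]
    connected <- logical(length(ii))
    for (k in seq_along(ii)) {
      if (!pair_ok[k]) next
      pr <- pearson_r(m[ii[k], ], m[jj[k], ])
      if (!pr$defined || is.na(pr$r) || pr$r < criteria$r_min) next
      pz <- tryCatch(
        cross_correlogram(set$spike_times[[ii[k]]],
                          set$spike_times[[jj[k]]], windows = w,
                          max_lag_ms = max_lag_ms,
                          bin_ms = ccg_bin_ms)$peak_z,
        error = function(e) NA_real_)
      connected[k] <- !is.na(pz) && pz > criteria$peak_z_min
    }
    deg <- tabulate(c(ii[connected], jj[connected]), nbins = n)
    idx <- 100 * deg / (n - 1)
    data.frame(time_s = t0, ci_mean = mean(idx),
               ci_sem = stats::sd(idx) / sqrt(n),
               n_edges = sum(connected), n_units = n)
  })
  if (dropped)
    warning("latency windows extending past the session were dropped",
            call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "window_s") <- window_s
  attr(out, "step_s") <- step_s
  class(out) <- c("connectivity_timeseries", "data.frame")
  out
}

#' Fit a mono-exponential recovery to a connectivity time series
#'
#' Least-squares fit of `CI(t) = CI_inf - (CI_inf - CI_0) *
#' exp(-(t - t_offset) / tau)` to the grid points at `t >= t_offset`
#' (the recovery limb after stimulus offset). The time constant is
#' initialised at 1 s and bounded to (0.01, 30\] s; parameter standard
#' errors come from the fit's curvature (the Jacobian-based covariance).
#'
#' @param series A [time_resolved_index()] result, or any `data.frame` with
#'   `time_s` and `ci_mean`.
#' @param t_offset Stimulus-offset latency (s); only later points enter
#'   the fit (>= 5 required).
#' @return A list of class `recovery_fit`: `tau`, `tau_se`, `ci_inf`,
#'   `ci_0`, `residual_rms`, `converged`, `n_points`, and `message` when
#'   the optimiser failed (a failure is reported, not raised).
#' @export
fit_recovery <- function(series, t_offset) {
  df <- as.data.frame(series)
  stopifnot(all(c("time_s", "ci_mean") %in% names(df)))
  sel <- df$time_s >= t_offset & !is.na(df$ci_mean)
  t <- df$time_s[sel] - t_offset
  y <- df$ci_mean[sel]
  if (length(t) < 5)
    stop("at least 5 grid points after t_offset required", call. = FALSE)
  if (stats::sd(y) == 0)
    stop("series is constant after t_offset; nothing to fit", call. = FALSE)
  n_tail <- max(3, ceiling(length(y) / 4))
  start <- list(ci_inf = mean(utils::tail(y, n_tail)), ci_0 = y[1], tau = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ ci_inf - (ci_inf - ci_0) * exp(-t / tau),
                      start = start,
                      lower = c(ci_inf = -Inf, ci_0 = -Inf, tau = 0.01),
                      upper = c(ci_inf = Inf, ci_0 = Inf, tau = 30),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(tau = NA_real_, tau_se = NA_real_,
                          ci_inf = NA_real_, ci_0 = NA_real_,
                          residual_rms = NA_real_, converged = FALSE,
                          n_points = length(t),
                          message = conditionMessage(fit)),
                     class = "recovery_fit"))
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit)))[["tau"]],
                 error = function(e) NA_real_)
  structure(list(tau = unname(cf[["tau"]]), tau_se = se,
                 ci_inf = unname(cf[["ci_inf"]]), ci_0 = unname(cf[["ci_0"]]),
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 converged = TRUE, n_points = length(t), message = NULL),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  if (!x$converged)
    cat("<recovery_fit> did not converge:", x$message, "\n")
  else
    cat(sprintf(
      "<recovery_fit> tau = %.3f s (SE %.3f), CI_0 = %.2f, CI_inf = %.2f, RMS %.3f\n",
      x$tau, x$tau_se, x$ci_0, x$ci_inf, x$residual_rms))
  invisible(x)
}
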