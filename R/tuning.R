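# Per-unit stimulus tuning: evoked response quantification, angular tuning
# over 8 deflection directions, coarseness preference over 5 textures.

#' Baseline-subtracted evoked response
#'
#' Mean number of spikes per stimulus above baseline: for each event the
#' spikes in `(onset, onset + response_window_s)` are counted, and the
#' baseline expectation `baseline_rate * response_window_s` is subtracted,
#' with the baseline rate pooled over the pre-stimulus windows
#' (`baseline_window_s` before each onset).
#'
#' @param train Spike times, seconds.
#' @param events A [session_events()] table (or subset; >= 1 event).
#' @param response_window_s Response window after onset, seconds; defaults
#'   to the stimulus duration of the first event.
#' @param baseline_window_s Pre-stimulus baseline window, seconds.
#' @return A list: `response` (spikes/stimulus above baseline),
#'   `baseline_rate_hz`, `n_events`.
#' @export
evoked_response <- function(train, events, response_window_s = NULL,
                            baseline_window_s = 0.6) {
  stopifnot(inherits(events, "session_events"))
  if (nrow(events) == 0) stop("no events", call. = FALSE)
  if (is.null(response_window_s))
    response_window_s <- events$offset_s[1] - events$onset_s[1]
  stopifnot(response_window_s > 0, baseline_window_s > 0)
  train <- sort(as.numeric(train))
  n_resp <- vapply(seq_len(nrow(events)), function(i)
    sum(train > events$onset_s[i] &
          train <= events$onset_s[i] + response_window_s), numeric(1))
  base_start <- pmax(events$onset_s - baseline_window_s, 0)
  n_base <- vapply(seq_len(nrow(events)), function(i)
    sum(train > base_start[i] & train <= events$onset_s[i]), numeric(1))
  base_time <- sum(events$onset_s - base_start)
  baseline_rate <- if (base_time > 0) sum(n_base) / base_time else 0
  list(response = mean(n_resp) - baseline_rate * response_window_s,
       baseline_rate_hz = baseline_rate, n_events = nrow(events))
}

tuning_curve_impl <- function(train, events, categories, cond,
                              response_window_s, baseline_window_s) {
  per_cat <- lapply(categories, function(cat) {
    ev <- events[which(cond == cat), , drop = FALSE]
    if (nrow(ev) == 0)
      return(list(mean = NA_real_, sem = NA_real_, n = 0L))
    rw <- response_window_s %||% (ev$offset_s[1] - ev$onset_s[1])
    n_resp <- vapply(seq_len(nrow(ev)), function(i)
      sum(train > ev$onset_s[i] & train <= ev$onset_s[i] + rw), numeric(1))
    base_start <- pmax(ev$onset_s - baseline_window_s, 0)
    n_base <- vapply(seq_len(nrow(ev)), function(i)
      sum(train > base_start[i] & train <= ev$onset_s[i]), numeric(1))
    bt <- sum(ev$onset_s - base_start)
    br <- if (bt > 0) sum(n_base) / bt else 0
    resp <- n_resp - br * rw
    list(mean = mean(resp),
         sem = if (length(resp) > 1) stats::sd(resp) / sqrt(length(resp))
               else NA_real_,
         n = nrow(ev))
  })
  means <- vapply(per_cat, `[[`, numeric(1), "mean")
  sems <- vapply(per_cat, `[[`, numeric(1), "sem")
  ns <- vapply(per_cat, `[[`, integer(1), "n")
  avail <- which(!is.na(means))
  if (length(avail) < 2)
    stop("responses available for fewer than 2 categories", call. = FALSE)
  best <- avail[which.max(means[avail])]     # ties -> first (lowest) category
  tie <- sum(abs(means[avail] - means[best]) < 1e-12) > 1
  others <- means[setdiff(avail, best)]
  sel <- if (max(means[avail]) + mean(others) != 0)
    (means[best] - mean(others)) / (means[best] + mean(others)) else NA_real_
  structure(list(categories = categories, mean_response = means,
                 sem = sems, n_trials = ns,
                 preferred = categories[best], tie = tie,
                 selectivity = sel),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> preferred %s%s, selectivity %.2f\n",
              x$preferred, if (x$tie) " (tie)" else "", x$selectivity))
  invisible(x)
}

#' Angular tuning curve over the 8 deflection directions
#'
#' Baseline-subtracted evoked response (spikes/stimulus) per deflection
#' angle; the preferred angle is the argmax, with ties broken
#' deterministically toward the smallest angle and flagged.
#'
#' @param train Spike times, seconds.
#' @param events A [session_events()] table with `angle_deg` labels on at
#'   least 2 distinct angles.
#' @param response_window_s Response window, seconds (default: the stimulus
#'   duration).
#' @param baseline_window_s Pre-stimulus baseline window, seconds.
#' @return A `tuning_curve` object (fields `categories`, `mean_response`,
#'   `sem`, `n_trials`, `preferred`, `tie`, `selectivity`).
#' @export
angular_tuning <- function(train, events, response_window_s = NULL,
                           baseline_window_s = 0.6) {
  stopifnot(inherits(events, "session_events"))
  if (is.null(events$angle_deg) || all(is.na(events$angle_deg)))
    stop("events carry no angle labels", call. = FALSE)
  if (length(unique(stats::na.omit(events$angle_deg))) < 2)
    stop("at least 2 distinct angles required", call. = FALSE)
  tuning_curve_impl(sort(as.numeric(train)), events, ANGLE_DIRECTIONS,
                    events$angle_deg, response_window_s, baseline_window_s)
}

#' Coarseness preference over the 5 texture grades
#'
#' Analogue of [angular_tuning()] for artificial-whisking trials against
#' textured surfaces; the response window defaults to the whisking-train
#' duration.
#'
#' @inheritParams angular_tuning
#' @param events A [session_events()] table with `texture` labels.
#' @return A `tuning_curve` object over
#'   `P120, P320, P600, P1000, smooth`.
#' @export
coarseness_preference <- function(train, events, response_window_s = NULL,
                                  baseline_window_s = 0.6) {
  stopifnot(inherits(events, "session_events"))
  if (is.null(events$texture) || all(is.na(events$texture)))
    stop("events carry no texture labels", call. = FALSE)
  bad <- setdiff(unique(stats::na.omit(events$texture)), TEXTURE_GRADES)
  if (length(bad))
    stop("unknown texture grade: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(unique(stats::na.omit(events$texture))) < 2)
    stop("at least 2 distinct textures required", call. = FALSE)
  tuning_curve_impl(sort(as.numeric(train)), events, TEXTURE_GRADES,
                    events$texture, response_window_s, baseline_window_s)
}
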