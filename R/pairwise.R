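# Per-pair, per-state synchrony metrics: state segmentation, spike-count
# binning, Pearson correlation of binned counts, cross-correlogram peak
# score.

#' Build state windows from stimulus events
#'
#' Segments the session into per-trial states: `spontaneous` is the
#' pre-stimulus window (`spont_s`, default 600 ms, truncated at the previous
#' stimulus offset or session start with a warning), `evoked` is the
#' stimulus window itself, and `post` (optional, for recovery dynamics) is
#' the window after offset truncated at the next onset.
#'
#' @param events A [session_events()] table.
#' @param spont_s Spontaneous window length before each onset, seconds.
#' @param post_s Post-stimulus window length after each offset, seconds
#'   (0 = no post windows).
#' @return A `data.frame` of class `state_windows` with columns `start_s`,
#'   `end_s`, `label`, `event` (the owning event's row index).
#' @export
make_state_windows <- function(events, spont_s = 0.6, post_s = 0) {
  stopifnot(inherits(events, "session_events"), spont_s > 0, post_s >= 0)
  n <- nrow(events)
  if (n == 0) {
    w <- data.frame(start_s = numeric(), end_s = numeric(),
                    label = character(), event = integer())
    class(w) <- c("state_windows", "data.frame")
    return(w)
  }
  prev_off <- c(0, events$offset_s[-n])
  spont_start <- pmax(events$onset_s - spont_s, prev_off)
  if (any(spont_start > events$onset_s - spont_s + 1e-12))
    warning("spontaneous window(s) truncated by preceding stimulus",
            call. = FALSE)
  w <- data.frame(start_s = spont_start, end_s = events$onset_s,
                  label = "spontaneous", event = seq_len(n))
  w <- rbind(w, data.frame(start_s = events$onset_s, end_s = events$offset_s,
                           label = "evoked", event = seq_len(n)))
  if (post_s > 0) {
    next_on <- c(events$onset_s[-1], Inf)
    w <- rbind(w, data.frame(start_s = events$offset_s,
                             end_s = pmin(events$offset_s + post_s, next_on),
                             label = "post", event = seq_len(n)))
  }
  w <- w[w$end_s > w$start_s, , drop = FALSE]
  w <- w[order(w$start_s, w$label), , drop = FALSE]
  rownames(w) <- NULL
  class(w) <- c("state_windows", "data.frame")
  w
}

# count spikes falling inside a set of half-open windows [start, end)
spikes_in_windows <- function(tt, windows) {
  if (nrow(windows) == 0 || length(tt) == 0) return(logical(length(tt)))
  w <- windows[order(windows$start_s), , drop = FALSE]
  idx <- findInterval(tt, w$start_s)
  idx >= 1 & tt < w$end_s[pmax(idx, 1L)]
}

#' Bin spike counts inside state windows
#'
#' Each window is tiled with `floor(length / bin_s)` half-open bins starting
#' at the window start; the partial trailing bin is dropped. Bins are
#' concatenated across a state's windows in time order.
#'
#' @param set A [spike_train_set()].
#' @param windows A [make_state_windows()] table.
#' @param bin_s Bin width, seconds (default 0.01).
#' @param states State labels to bin (default: all present).
#' @return An object of class `binned_counts`: a list with `bin_size_s`,
#'   `states` (one units x bins integer matrix per state) and `provenance`
#'   (per state, the owning window row for every bin column).
#' @export
bin_counts <- function(set, windows, bin_s = 0.01, states = NULL) {
  stopifnot(inherits(set, "spike_train_set"), bin_s > 0)
  if (is.null(states)) states <- unique(windows$label)
  out <- list(); prov <- list()
  for (st in states) {
    w <- windows[windows$label == st, , drop = FALSE]
    if (nrow(w) == 0) stop("no windows for state: ", st, call. = FALSE)
    w <- w[order(w$start_s), , drop = FALSE]
    nb <- floor((w$end_s - w$start_s) / bin_s + 1e-9)
    if (sum(nb) == 0)
      stop("all windows shorter than one bin for state: ", st, call. = FALSE)
    off <- cumsum(c(0, nb[-length(nb)]))
    total <- sum(nb)
    mat <- matrix(0L, nrow = length(set$units), ncol = total,
                  dimnames = list(set$units, NULL))
    for (ui in seq_along(set$units)) {
      tt <- set$spike_times[[ui]]
      if (!length(tt)) next
      wi <- findInterval(tt, w$start_s)
      ok <- wi >= 1
      loc <- floor((tt[ok] - w$start_s[pmax(wi[ok], 1L)]) / bin_s)
      keep <- loc < nb[wi[ok]] & tt[ok] < w$end_s[wi[ok]]
      gidx <- off[wi[ok][keep]] + loc[keep] + 1
      if (length(gidx))
        mat[ui, ] <- tabulate(gidx, nbins = total)
    }
    out[[st]] <- mat
    prov[[st]] <- rep(which(windows$label == st)[order(w$start_s)], nb)
  }
  structure(list(bin_size_s = bin_s, states = out, provenance = prov),
            class = "binned_counts")
}

#' Pearson correlation of two count vectors
#'
#' Standard product-moment correlation with a two-sided p-value from the
#' t transform `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. A constant vector makes the correlation undefined; the result
#' is then flagged rather than raised as an error (such pairs are treated
#' as not connected downstream).
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return A list: `r`, `p`, `n`, `defined`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("at least 3 observations required", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, defined = FALSE))
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(r = r, p = p, n = n, defined = TRUE)
}

#' Cross-correlogram of two spike trains
#'
#' Histogram of spike-time differences `t_j - t_i` within `+/- max_lag_ms`,
#' restricted to spikes inside the given state windows, on a symmetric lag
#' grid of `bin_ms`-wide bins centred on zero. The peak score
#' `peak_z = (peak - mean) / SD` uses the mean and SD over all lag bins
#' (peak included).
#'
#' @param train_i,train_j Spike-time vectors, seconds.
#' @param windows Optional [make_state_windows()] subset; `NULL` uses the
#'   whole session.
#' @param max_lag_ms Maximum lag, ms (default 50).
#' @param bin_ms Lag bin width, ms (default 1).
#' @param method `"sorted"` (default; binary-search enumeration) or
#'   `"brute"` (all-pairs double loop; reference implementation).
#' @return An object of class `correlogram`: `lag_ms` (bin centres),
#'   `counts`, `mean`, `sd`, `peak`, `peak_lag_ms`, `peak_z` (`NA` when the
#'   lag-wise SD is zero).
#' @export
cross_correlogram <- function(train_i, train_j, windows = NULL,
                              max_lag_ms = 50, bin_ms = 1,
                              method = c("sorted", "brute")) {
  method <- match.arg(method)
  ti <- sort(as.numeric(train_i)); tj <- sort(as.numeric(train_j))
  if (!is.null(windows)) {
    ti <- ti[spikes_in_windows(ti, windows)]
    tj <- tj[spikes_in_windows(tj, windows)]
  }
  if (length(ti) == 0 || length(tj) == 0)
    stop("empty correlogram: a train has no spikes inside the windows",
         call. = FALSE)
  bin <- bin_ms / 1000
  L <- (max_lag_ms + bin_ms / 2) / 1000      # diffs taken on [-L, L)
  centers <- seq(-max_lag_ms, max_lag_ms, by = bin_ms)
  n_bins <- length(centers)

  diffs <- if (method == "brute") {
    d <- as.vector(outer(tj, ti, "-"))
    d[d >= -L & d < L]
  } else {
    lo <- findInterval(ti - L, tj, left.open = TRUE)
    hi <- findInterval(ti + L, tj, left.open = TRUE)
    m <- hi - lo
    take <- m > 0
    if (any(take)) {
      jidx <- sequence(m[take]) + rep(lo[take], m[take])
      tj[jidx] - rep(ti[take], m[take])
    } else numeric(0)
  }
  idx <- floor((diffs + L) / bin) + 1
  idx <- idx[idx >= 1 & idx <= n_bins]   # guard fp edge effects
  counts <- tabulate(idx, nbins = n_bins)

  mu <- mean(counts); sdev <- stats::sd(counts)
  pk <- max(counts); pk_lag <- centers[which.max(counts)]
  structure(list(lag_ms = centers, counts = counts, mean = mu, sd = sdev,
                 peak = pk, peak_lag_ms = pk_lag,
                 peak_z = if (sdev > 0) (pk - mu) / sdev else NA_real_),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat(sprintf("<correlogram> %d lag bins, peak %d at %+g ms, peak_z = %.2f\n",
              length(x$lag_ms), x$peak, x$peak_lag_ms, x$peak_z))
  invisible(x)
}

#' Per-pair, per-state synchrony metrics
#'
#' For every unordered unit pair and every requested state, computes the
#' binned-count Pearson correlation (one correlation per state, with
#' same-state windows pooled across trials) and the cross-correlogram peak
#' score, together with the spike counts that feed the connectivity
#' criteria. Pairs are reported in canonical order (`unit_id_a <
#' unit_id_b`).
#'
#' @param set A [spike_train_set()] (>= 2 units after `units` filtering).
#' @param windows A [make_state_windows()] table.
#' @param units Units to analyse (default: all units in `set`), e.g. the
#'   QC-accepted subset.
#' @param bin_s Pearson count-bin width, seconds (default 0.01).
#' @param max_lag_ms,ccg_bin_ms Cross-correlogram parameters.
#' @param states States to evaluate (default `spontaneous` and `evoked`).
#' @return A `data.frame` of class `pair_metrics`, one row per pair per
#'   state: `unit_id_a`, `unit_id_b`, `state`, `pearson_r`, `pearson_p`,
#'   `n_bins`, `peak_z`, per-state spike counts of both members
#'   (`n_spont_a`, `n_spont_b`, `n_evoked_a`, `n_evoked_b`), total counts
#'   (`total_a`, `total_b`) and the `evaluable` flag (undefined
#'   correlations, e.g. a unit silent in the state, are flagged and later
#'   treated as not connected).
#' @export
pair_metrics <- function(set, windows, units = NULL, bin_s = 0.01,
                         max_lag_ms = 50, ccg_bin_ms = 1,
                         states = c("spontaneous", "evoked")) {
  stopifnot(inherits(set, "spike_train_set"))
  if (is.null(units)) units <- set$units
  units <- sort(units)
  if (length(units) < 2) stop("at least 2 units required", call. = FALSE)
  set <- subset_units(set, units)
  bc <- bin_counts(set, windows, bin_s = bin_s, states = states)
  totals <- n_spikes(set)
  state_counts <- lapply(c("spontaneous", "evoked"), function(st) {
    w <- windows[windows$label == st, , drop = FALSE]
    vapply(units, function(u)
      sum(spikes_in_windows(set$spike_times[[u]], w)), numeric(1))
  })
  names(state_counts) <- c("spontaneous", "evoked")

  rows <- list()
  for (a_i in seq_len(length(units) - 1)) for (b_i in seq(a_i + 1, length(units))) {
    a <- units[a_i]; b <- units[b_i]
    for (st in states) {
      m <- bc$states[[st]]
      pr <- pearson_r(m[a, ], m[b, ])
      w_st <- windows[windows$label == st, , drop = FALSE]
      pz <- tryCatch(
        cross_correlogram(set$spike_times[[a]], set$spike_times[[b]],
                          windows = w_st, max_lag_ms = max_lag_ms,
                          bin_ms = ccg_bin_ms)$peak_z,
        error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        unit_id_a = a, unit_id_b = b, state = st,
        pearson_r = pr$r, pearson_p = pr$p, n_bins = pr$n, peak_z = pz,
        n_spont_a = state_counts$spontaneous[[a]],
        n_spont_b = state_counts$spontaneous[[b]],
        n_evoked_a = state_counts$evoked[[a]],
        n_evoked_b = state_counts$evoked[[b]],
        total_a = totals[[a]], total_b = totals[[b]],
        evaluable = pr$defined && !is.na(pz),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("pair_metrics", "data.frame")
  res
}
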