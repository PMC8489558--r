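# Unit quality control: firing-rate / ISI criteria, waveform stability,
# cluster-separation MANOVA, cluster-validity indices, duplicate exclusion.

#' Quality-control configuration
#'
#' Thresholds of the unit-acceptance battery. Defaults: firing rate above
#' 0.5 Hz; minimum inter-spike interval above 2 ms; a smooth exponential-like
#' ISI distribution (operationalised as R-squared >= `isi_exp_r2_min` of a
#' log-linear single-exponential fit to the > 2 ms ISI histogram); waveform
#' stability between the first and last 20% of spikes (ANOVA, alpha 0.05);
#' cluster separation p < 0.05 (MANOVA, Wilks' lambda); at least 3,000
#' spikes overall and 1,000 in each of the spontaneous and evoked states;
#' cluster-validity indices with "good"/"ok" bands (Dunn above 2 / 1;
#' Davies-Bouldin below 0.3 / 0.5; pseudo-F above 100,000 / 50,000; J3
#' above 2 / 1), of which at least two must be "good" and the rest "ok";
#' and exclusion of duplicate units whose zero-lag 1 ms-binned correlation
#' exceeds 0.9.
#'
#' @param min_rate_hz,min_isi_ms,min_total_spikes,min_state_spikes,
#'   duplicate_ccg_threshold,stability_alpha,manova_alpha,isi_exp_r2_min
#'   Scalar thresholds as described above.
#' @param index_thresholds Named list with elements `dunn_good`, `dunn_ok`,
#'   `db_good`, `db_ok`, `pseudof_good`, `pseudof_ok`, `j3_good`, `j3_ok`.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(min_rate_hz = 0.5, min_isi_ms = 2,
                      min_total_spikes = 3000, min_state_spikes = 1000,
                      duplicate_ccg_threshold = 0.9, stability_alpha = 0.05,
                      manova_alpha = 0.05, isi_exp_r2_min = 0.8,
                      index_thresholds = list(
                        dunn_good = 2, dunn_ok = 1,
                        db_good = 0.3, db_ok = 0.5,
                        pseudof_good = 1e5, pseudof_ok = 5e4,
                        j3_good = 2, j3_ok = 1)) {
  stopifnot(min_rate_hz > 0, min_isi_ms > 0, min_total_spikes > 0,
            min_state_spikes > 0, duplicate_ccg_threshold > 0,
            stability_alpha > 0, stability_alpha < 1,
            manova_alpha > 0, manova_alpha < 1)
  need <- c("dunn_good", "dunn_ok", "db_good", "db_ok",
            "pseudof_good", "pseudof_ok", "j3_good", "j3_ok")
  if (!all(need %in% names(index_thresholds)))
    stop("index_thresholds must name all eight bands", call. = FALSE)
  structure(list(min_rate_hz = min_rate_hz, min_isi_ms = min_isi_ms,
                 min_total_spikes = min_total_spikes,
                 min_state_spikes = min_state_spikes,
                 duplicate_ccg_threshold = duplicate_ccg_threshold,
                 stability_alpha = stability_alpha,
                 manova_alpha = manova_alpha,
                 isi_exp_r2_min = isi_exp_r2_min,
                 index_thresholds = index_thresholds),
            class = "qc_config")
}

#' Inter-spike-interval statistics
#'
#' Computes the minimum ISI, the fraction of ISIs below the refractory
#' threshold, and the goodness of a single-exponential fit to the ISI
#' histogram above that threshold (log-linear least squares on non-empty
#' bins), which operationalises the requirement of a smooth
#' exponential-like ISI distribution.
#'
#' @param train Numeric vector of spike times, seconds (>= 2 spikes).
#' @param refractory_ms ISI threshold, ms (default 2).
#' @param hist_bin_ms,hist_max_ms Histogram bin width and range for the
#'   exponential fit, ms (defaults 10 and 500).
#' @return A list: `min_isi_ms`, `violation_fraction`, `exp_fit_r2` (`NA`
#'   when fewer than 3 non-empty histogram bins exist).
#' @export
isi_statistics <- function(train, refractory_ms = 2, hist_bin_ms = 10,
                           hist_max_ms = 500) {
  train <- sort(as.numeric(train))
  if (length(train) < 2)
    stop("at least 2 spikes required for ISI statistics", call. = FALSE)
  isi_ms <- diff(train) * 1000
  min_isi <- min(isi_ms)
  viol <- mean(isi_ms < refractory_ms)
  sel <- isi_ms[isi_ms > refractory_ms & isi_ms <= hist_max_ms]
  r2 <- NA_real_
  if (length(sel) >= 3) {
    breaks <- seq(refractory_ms, hist_max_ms, by = hist_bin_ms)
    if (max(breaks) < hist_max_ms) breaks <- c(breaks, hist_max_ms)
    h <- graphics::hist(sel, breaks = breaks, plot = FALSE)
    keep <- h$counts > 0
    if (sum(keep) >= 3) {
      fit <- stats::lm(log(h$counts[keep]) ~ h$mids[keep])
      r2 <- summary(fit)$r.squared
    }
  }
  list(min_isi_ms = min_isi, violation_fraction = viol, exp_fit_r2 = r2)
}

#' Waveform stability between the beginning and end of a recording
#'
#' One-way two-group ANOVA comparing the first and last 20% of the
#' per-spike amplitude and half-width series. A unit is stable when neither
#' measure changed significantly.
#'
#' @param amplitudes,half_widths Per-spike series (parallel to the spike
#'   train; at least 50 spikes). Either may be `NULL`, in which case the
#'   criterion is reported as not evaluable.
#' @param alpha Significance level (default 0.05).
#' @param segment_fraction Fraction of spikes in each compared segment.
#' @return A list: `p_amplitude`, `p_halfwidth`, `stable` (logical, `NA`
#'   when not evaluable).
#' @export
waveform_stability <- function(amplitudes, half_widths, alpha = 0.05,
                               segment_fraction = 0.2) {
  seg_anova <- function(x) {
    n <- length(x)
    k <- floor(n * segment_fraction)
    g <- factor(rep(c("first", "last"), each = k))
    vals <- c(x[seq_len(k)], x[seq(n - k + 1, n)])
    if (stats::var(vals) == 0) return(1)  # zero between-group variance
    stats::anova(stats::lm(vals ~ g))[["Pr(>F)"]][1]
  }
  if (is.null(amplitudes) || is.null(half_widths) ||
      length(amplitudes) < 50 || length(half_widths) < 50)
    return(list(p_amplitude = NA_real_, p_halfwidth = NA_real_, stable = NA))
  p_a <- seg_anova(as.numeric(amplitudes))
  p_h <- seg_anova(as.numeric(half_widths))
  list(p_amplitude = p_a, p_halfwidth = p_h,
       stable = p_a >= alpha && p_h >= alpha)
}

check_clusters <- function(features, labels, min_per = 1) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  if (nrow(features) != length(labels))
    stop("features and labels must have equal length", call. = FALSE)
  if (nlevels(droplevels(labels)) < 2)
    stop("at least 2 clusters required", call. = FALSE)
  tab <- table(droplevels(labels))
  if (any(tab < min_per))
    stop("every cluster needs at least ", min_per, " points", call. = FALSE)
  list(x = features, g = droplevels(labels))
}

#' Cluster-separation p-value (one-way MANOVA)
#'
#' Wilks' lambda with its F approximation on the full feature space; the
#' statistical gate of the sorting-quality battery.
#'
#' @param features Numeric matrix (spikes x features).
#' @param labels Cluster labels, one per row.
#' @return The MANOVA p-value.
#' @export
cluster_separation_p <- function(features, labels) {
  cl <- check_clusters(features, labels, min_per = ncol(as.matrix(features)) + 1)
  fit <- tryCatch(stats::manova(cl$x ~ cl$g), error = function(e)
    stop("degenerate cluster geometry: ", conditionMessage(e), call. = FALSE))
  s <- tryCatch(summary(fit, test = "Wilks")$stats,
                error = function(e)
                  stop("degenerate cluster geometry: ",
                       conditionMessage(e), call. = FALSE))
  unname(s[1, "Pr(>F)"])
}

#' Dunn cluster-validity index
#'
#' Minimum inter-cluster point-to-point distance divided by the maximum
#' cluster diameter. Values above 2 indicate well-separated clusters,
#' above 1 intermediate quality.
#'
#' @inheritParams cluster_separation_p
#' @return Dunn index (>= 0).
#' @export
dunn_index <- function(features, labels) {
  cl <- check_clusters(features, labels)
  d <- as.matrix(stats::dist(cl$x))
  same <- outer(cl$g, cl$g, "==")
  diag(same) <- NA
  diam <- max(d[which(same)], 0)
  if (diam == 0)
    stop("Dunn index undefined: all cluster diameters are zero", call. = FALSE)
  min_inter <- min(d[which(!same)])
  min_inter / diam
}

#' Davies-Bouldin cluster-validity index
#'
#' Mean over clusters of the worst-case `(s_i + s_j) / d_ij` ratio, with
#' `s_i` the RMS distance of cluster members to their centroid and `d_ij`
#' the centroid distance. Lower is better; values below 0.3 indicate
#' well-separated clusters, below 0.5 intermediate quality.
#'
#' @inheritParams cluster_separation_p
#' @return Davies-Bouldin index (>= 0).
#' @export
davies_bouldin <- function(features, labels) {
  cl <- check_clusters(features, labels)
  levs <- levels(cl$g)
  cen <- sapply(levs, function(l) colMeans(cl$x[cl$g == l, , drop = FALSE]))
  cen <- t(matrix(cen, ncol = length(levs)))
  s <- vapply(seq_along(levs), function(i) {
    pts <- cl$x[cl$g == levs[i], , drop = FALSE]
    sqrt(mean(rowSums(sweep(pts, 2, cen[i, ])^2)))
  }, numeric(1))
  k <- length(levs)
  worst <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      dij <- sqrt(sum((cen[i, ] - cen[j, ])^2))
      if (dij == 0) stop("coincident cluster centroids", call. = FALSE)
      (s[i] + s[j]) / dij
    }, numeric(1)))
  }, numeric(1))
  mean(worst)
}

# within/between sum-of-squares scatter (J1, J2) shared by pseudo-F and J3
scatter_sums <- function(x, g) {
  grand <- colMeans(x)
  levs <- levels(g)
  j1 <- 0; j2 <- 0
  for (l in levs) {
    pts <- x[g == l, , drop = FALSE]
    cen <- colMeans(pts)
    j1 <- j1 + sum(sweep(pts, 2, cen)^2)
    j2 <- j2 + nrow(pts) * sum((cen - grand)^2)
  }
  list(j1 = j1, j2 = j2, k = length(levs), n = nrow(x))
}

#' Pseudo-F (Calinski-Harabasz) cluster-validity index
#'
#' `(J2 / (k - 1)) / (J1 / (n - k))` with `J1` the total within-cluster and
#' `J2` the between-cluster sum of squared distances. Computed on raw
#' (unstandardised) feature values, so its magnitude depends on the feature
#' units; the conventional acceptance bands (> 100,000 good, > 50,000
#' intermediate) assume vendor-scaled waveform features.
#'
#' @inheritParams cluster_separation_p
#' @return Pseudo-F value (>= 0).
#' @export
pseudo_f <- function(features, labels) {
  cl <- check_clusters(features, labels)
  s <- scatter_sums(cl$x, cl$g)
  if (s$n == s$k)
    stop("pseudo-F undefined when every cluster has a single point",
         call. = FALSE)
  (s$j2 / (s$k - 1)) / (s$j1 / (s$n - s$k))
}

#' J3 cluster-validity ratio
#'
#' `J2 / J1`, the between- over within-cluster scatter ratio; higher is
#' better (> 2 good, > 1 intermediate).
#'
#' @inheritParams cluster_separation_p
#' @return J3 value (>= 0).
#' @export
j3 <- function(features, labels) {
  cl <- check_clusters(features, labels)
  s <- scatter_sums(cl$x, cl$g)
  if (s$j1 == 0)
    stop("J3 undefined: zero within-cluster scatter", call. = FALSE)
  s$j2 / s$j1
}

#' Detect duplicate units by zero-lag correlation
#'
#' Flags unit pairs whose zero-lag binned-count Pearson correlation (1 ms
#' bins over the whole session) exceeds `threshold`; such pairs are treated
#' as the same neuron picked up twice, and the lower-count member of each
#' flagged pair is marked for exclusion.
#'
#' @param set A [spike_train_set()] (>= 2 units).
#' @param threshold Correlation threshold (default 0.9).
#' @param bin_ms Bin width, ms (default 1).
#' @return A `data.frame` with columns `unit_id_a`, `unit_id_b`, `r`,
#'   `exclude` (the lower-count unit of the pair).
#' @export
duplicate_pairs <- function(set, threshold = 0.9, bin_ms = 1) {
  stopifnot(inherits(set, "spike_train_set"))
  ids <- set$units
  if (length(ids) < 2)
    return(data.frame(unit_id_a = character(), unit_id_b = character(),
                      r = numeric(), exclude = character()))
  bin <- bin_ms / 1000
  n_bins <- max(1, ceiling(set$session_duration / bin))
  counts <- lapply(set$spike_times, function(tt)
    tabulate(pmin(floor(tt / bin) + 1L, n_bins), nbins = n_bins))
  cnt <- n_spikes(set)
  out <- list()
  for (i in seq_along(ids)[-length(ids)]) for (j in seq((i + 1), length(ids))) {
    xi <- counts[[i]]; xj <- counts[[j]]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    r <- stats::cor(xi, xj)
    if (r > threshold) {
      excl <- if (cnt[i] <= cnt[j]) ids[i] else ids[j]
      out[[length(out) + 1L]] <- data.frame(
        unit_id_a = ids[i], unit_id_b = ids[j], r = r, exclude = excl,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(unit_id_a = character(), unit_id_b = character(),
               r = numeric(), exclude = character())
}

index_grade <- function(value, good, ok, lower_is_better = FALSE) {
  if (is.na(value)) return(NA_character_)
  if (lower_is_better) {
    if (value < good) "good" else if (value < ok) "ok" else "poor"
  } else {
    if (value > good) "good" else if (value > ok) "ok" else "poor"
  }
}

#' Apply the full unit-acceptance battery
#'
#' A unit is accepted when all of the following hold: firing rate above
#' `min_rate_hz`; minimum ISI above `min_isi_ms`; a smooth exponential-like
#' ISI distribution; stable waveform statistics when amplitude/half-width
#' streams are present (not-evaluable units pass this criterion by default);
#' significant cluster separation (MANOVA) and a validity-index profile with
#' at least two "good" and no "poor" grades, evaluated per probe contact
#' when a feature table is supplied; at least `min_total_spikes` spikes
#' overall and `min_state_spikes` in each of the spontaneous and evoked
#' states. Duplicate units (see [duplicate_pairs()]) are removed last.
#'
#' @param set A [spike_train_set()].
#' @param meta A [unit_meta()] table covering the units (used to group units
#'   by probe contact for the cluster battery). Optional.
#' @param windows State windows from [make_state_windows()] (used for the
#'   per-state spike-count floors). Optional; the state floors are skipped
#'   when absent.
#' @param config A [qc_config()].
#' @param features Optional feature table (see [read_features()]) with
#'   columns `unit_id`, `f1`, `f2`\[, `f3`\].
#' @return A list: `accepted` (a [spike_train_set()] restricted to accepted
#'   units) and `report` (per-unit `data.frame` of criterion flags, index
#'   values and the overall `accept` flag), plus `duplicates`.
#' @export
apply_qc <- function(set, meta = NULL, windows = NULL, config = qc_config(),
                     features = NULL) {
  stopifnot(inherits(set, "spike_train_set"), inherits(config, "qc_config"))
  ids <- set$units
  dur <- set$session_duration
  counts <- n_spikes(set)
  rate <- counts / dur

  rep_df <- data.frame(unit_id = ids, n_spikes = as.integer(counts),
                       rate_hz = rate, stringsAsFactors = FALSE)
  rep_df$rate_ok <- rate > config$min_rate_hz
  rep_df$total_count_ok <- counts > config$min_total_spikes

  isi <- lapply(ids, function(u) {
    if (counts[[u]] < 2)
      return(list(min_isi_ms = NA_real_, violation_fraction = NA_real_,
                  exp_fit_r2 = NA_real_))
    isi_statistics(set$spike_times[[u]], refractory_ms = config$min_isi_ms)
  })
  rep_df$min_isi_ms <- vapply(isi, `[[`, numeric(1), "min_isi_ms")
  rep_df$isi_exp_r2 <- vapply(isi, `[[`, numeric(1), "exp_fit_r2")
  rep_df$isi_ok <- !is.na(rep_df$min_isi_ms) &
    rep_df$min_isi_ms > config$min_isi_ms
  rep_df$isi_shape_ok <- !is.na(rep_df$isi_exp_r2) &
    rep_df$isi_exp_r2 >= config$isi_exp_r2_min

  stab <- lapply(ids, function(u)
    waveform_stability(set$amplitudes[[u]], set$half_widths[[u]],
                       alpha = config$stability_alpha))
  rep_df$p_amplitude <- vapply(stab, `[[`, numeric(1), "p_amplitude")
  rep_df$p_halfwidth <- vapply(stab, `[[`, numeric(1), "p_halfwidth")
  rep_df$stable <- vapply(stab, function(s) {
    if (is.na(s$stable)) NA else s$stable
  }, logical(1))

  # per-state spike-count floors
  if (!is.null(windows)) {
    for (st in c("spontaneous", "evoked")) {
      w <- windows[windows$label == st, , drop = FALSE]
      n_state <- vapply(ids, function(u)
        sum(spikes_in_windows(set$spike_times[[u]], w)), numeric(1))
      rep_df[[paste0("n_", st)]] <- as.integer(n_state)
    }
    rep_df$state_count_ok <- rep_df$n_spontaneous >= config$min_state_spikes &
      rep_df$n_evoked >= config$min_state_spikes
  } else {
    rep_df$state_count_ok <- NA
  }

  # cluster battery, per probe contact
  rep_df$manova_p <- NA_real_
  rep_df$dunn <- rep_df$db <- rep_df$pseudo_f <- rep_df$j3_value <- NA_real_
  rep_df$separation_ok <- NA
  rep_df$indices_ok <- NA
  if (!is.null(features) && !is.null(meta)) {
    fcols <- intersect(c("f1", "f2", "f3"), names(features))
    contact_of <- stats::setNames(meta$contact_index, meta$unit_id)
    for (ct in unique(contact_of[ids])) {
      members <- ids[contact_of[ids] == ct]
      fsub <- features[features$unit_id %in% members, , drop = FALSE]
      labs <- fsub$unit_id
      if (length(unique(labs)) < 2) next
      x <- as.matrix(fsub[, fcols, drop = FALSE])
      vals <- tryCatch(list(
        p = cluster_separation_p(x, labs),
        dunn = dunn_index(x, labs), db = davies_bouldin(x, labs),
        pf = pseudo_f(x, labs), j3v = j3(x, labs)),
        error = function(e) NULL)
      if (is.null(vals)) next
      th <- config$index_thresholds
      grades <- c(index_grade(vals$dunn, th$dunn_good, th$dunn_ok),
                  index_grade(vals$db, th$db_good, th$db_ok, TRUE),
                  index_grade(vals$pf, th$pseudof_good, th$pseudof_ok),
                  index_grade(vals$j3v, th$j3_good, th$j3_ok))
      idx_ok <- sum(grades == "good") >= 2 && !any(grades == "poor")
      sel <- rep_df$unit_id %in% members
      rep_df$manova_p[sel] <- vals$p
      rep_df$dunn[sel] <- vals$dunn
      rep_df$db[sel] <- vals$db
      rep_df$pseudo_f[sel] <- vals$pf
      rep_df$j3_value[sel] <- vals$j3v
      rep_df$separation_ok[sel] <- vals$p < config$manova_alpha
      rep_df$indices_ok[sel] <- idx_ok
    }
  }

  pass_or_na <- function(x) is.na(x) | x  # not-evaluable criteria pass
  rep_df$accept <- rep_df$rate_ok & rep_df$total_count_ok & rep_df$isi_ok &
    rep_df$isi_shape_ok & pass_or_na(rep_df$stable) &
    pass_or_na(rep_df$state_count_ok) & pass_or_na(rep_df$separation_ok) &
    pass_or_na(rep_df$indices_ok)

  dups <- duplicate_pairs(set, threshold = config$duplicate_ccg_threshold)
  rep_df$duplicate <- rep_df$unit_id %in% dups$exclude
  rep_df$accept <- rep_df$accept & !rep_df$duplicate

  keep <- rep_df$unit_id[rep_df$accept]
  if (!length(keep))
    warning("no unit passed quality control", call. = FALSE)
  accepted <- if (length(keep)) subset_units(set, keep) else
    spike_train_set(stats::setNames(list(), character()), dur)
  list(accepted = accepted, report = rep_df, duplicates = dups)
}
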