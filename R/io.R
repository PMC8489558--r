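#' Construct a spike-train set
#'
#' A `spike_train_set` holds the sorted spike times of every unit in a
#' recording session, in seconds from session start, together with optional
#' per-spike waveform summaries (peak amplitude in microvolts, half-width in
#' milliseconds) kept parallel to the spike times.
#'
#' Spike times are sorted on construction; the optional per-spike series are
#' reordered alongside them. Duplicate spike times within a unit are retained
#' with a warning -- refractory-period violations are a quality-control
#' concern, not an I/O one.
#'
#' @param spike_times Named list, one numeric vector of spike times (s) per
#'   unit. Names are the unit identifiers.
#' @param session_duration Session length in seconds. Defaults to the latest
#'   spike time.
#' @param amplitudes,half_widths Optional named lists parallel to
#'   `spike_times` (same units, same lengths).
#' @return An object of class `spike_train_set` with fields `units`,
#'   `spike_times`, `session_duration`, `amplitudes`, `half_widths`.
#' @export
#' @examples
#' sts <- spike_train_set(list(u1 = c(0.1, 0.25), u2 = 0.11),
#'                        session_duration = 1)
#' n_spikes(sts)
spike_train_set <- function(spike_times, session_duration = NULL,
                            amplitudes = NULL, half_widths = NULL) {
  if (!is.list(spike_times))
    stop("`spike_times` must be a named list of numeric vectors", call. = FALSE)
  if (length(spike_times) > 0 && is.null(names(spike_times)))
    stop("`spike_times` must be named by unit id", call. = FALSE)
  units <- names(spike_times)
  if (anyDuplicated(units))
    stop("duplicate unit ids in `spike_times`", call. = FALSE)
  spike_times <- lapply(spike_times, as.numeric)
  if (any(vapply(spike_times, anyNA, logical(1))))
    stop("spike times must not contain NA", call. = FALSE)

  check_parallel <- function(x, what) {
    if (is.null(x)) return(NULL)
    if (!is.list(x) || !setequal(names(x), units))
      stop(sprintf("`%s` must be a named list covering the same units", what),
           call. = FALSE)
    x <- x[units]
    len_ok <- vapply(units, function(u)
      length(x[[u]]) == length(spike_times[[u]]), logical(1))
    if (!all(len_ok))
      stop(sprintf("`%s` must be parallel to `spike_times` (equal lengths)",
                   what), call. = FALSE)
    x
  }
  amplitudes <- check_parallel(amplitudes, "amplitudes")
  half_widths <- check_parallel(half_widths, "half_widths")

  for (u in units) {
    o <- order(spike_times[[u]])
    if (is.unsorted(spike_times[[u]])) {
      spike_times[[u]] <- spike_times[[u]][o]
      if (!is.null(amplitudes)) amplitudes[[u]] <- amplitudes[[u]][o]
      if (!is.null(half_widths)) half_widths[[u]] <- half_widths[[u]][o]
    }
    if (anyDuplicated(spike_times[[u]]))
      warning(sprintf("unit %s has duplicate spike times (retained)", u),
              call. = FALSE)
  }

  tmax <- if (length(spike_times)) max(c(0, unlist(spike_times, use.names = FALSE))) else 0
  if (is.null(session_duration)) session_duration <- tmax
  session_duration <- as.numeric(session_duration)
  if (length(session_duration) != 1 || is.na(session_duration) ||
      session_duration < 0)
    stop("`session_duration` must be a single non-negative number", call. = FALSE)
  if (any(unlist(spike_times, use.names = FALSE) < 0) || tmax > session_duration)
    stop("spike times must lie in [0, session_duration]", call. = FALSE)

  structure(list(units = units, spike_times = spike_times,
                 session_duration = session_duration,
                 amplitudes = amplitudes, half_widths = half_widths),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf("<spike_train_set> %d units, %d spikes, %.3f s\n",
              length(x$units), sum(n_spikes(x)), x$session_duration))
  invisible(x)
}

#' Per-unit spike counts
#' @param set A [spike_train_set()].
#' @return Named integer vector of spike counts.
#' @export
n_spikes <- function(set) {
  stopifnot(inherits(set, "spike_train_set"))
  vapply(set$spike_times, length, integer(1))
}

#' Restrict a spike-train set to a subset of units
#' @param set A [spike_train_set()].
#' @param units Character vector of unit ids to keep.
#' @return A [spike_train_set()] over `units`.
#' @export
subset_units <- function(set, units) {
  stopifnot(inherits(set, "spike_train_set"))
  missing <- setdiff(units, set$units)
  if (length(missing))
    stop("unknown unit ids: ", paste(missing, collapse = ", "), call. = FALSE)
  suppressWarnings(spike_train_set(
    set$spike_times[units], set$session_duration,
    if (!is.null(set$amplitudes)) set$amplitudes[units],
    if (!is.null(set$half_widths)) set$half_widths[units]))
}

#' Construct a stimulus event table
#'
#' Stimulus events define the state segmentation of a session: each event is
#' an `(onset, offset)` interval with a stimulus type and, depending on the
#' paradigm, a deflection angle (ramp-and-hold) or a sandpaper texture grade
#' (artificial whisking).
#'
#' @param onset_s,offset_s Event boundaries in seconds; onsets must be
#'   strictly increasing and events must not overlap.
#' @param stim_type `"ramp_hold"` or `"artificial_whisking"` (recycled).
#' @param angle_deg Optional deflection angle per event, degrees in
#'   `{0, 45, ..., 315}`.
#' @param texture Optional texture grade per event, one of `"P120"`,
#'   `"P320"`, `"P600"`, `"P1000"`, `"smooth"`.
#' @return A `data.frame` of class `session_events`.
#' @export
session_events <- function(onset_s, offset_s, stim_type,
                           angle_deg = NULL, texture = NULL) {
  onset_s <- as.numeric(onset_s); offset_s <- as.numeric(offset_s)
  n <- length(onset_s)
  if (length(offset_s) != n)
    stop("`onset_s` and `offset_s` must have equal length", call. = FALSE)
  stim_type <- as.character(rep_len(stim_type, max(n, 1L)))[seq_len(n)]
  bad <- setdiff(unique(stim_type), STIM_TYPES)
  if (length(bad))
    stop("unknown stim_type: ", paste(bad, collapse = ", "), call. = FALSE)
  if (n > 1 && any(diff(onset_s) <= 0))
    stop("event onsets must be strictly increasing", call. = FALSE)
  if (any(offset_s <= onset_s))
    stop("every event must have offset > onset", call. = FALSE)
  if (n > 1 && any(onset_s[-1] < offset_s[-n]))
    stop("events must not overlap", call. = FALSE)
  ev <- data.frame(onset_s = onset_s, offset_s = offset_s,
                   stim_type = stim_type, stringsAsFactors = FALSE)
  if (!is.null(angle_deg)) {
    angle_deg <- as.numeric(rep_len(angle_deg, max(n, 1L)))[seq_len(n)]
    ok <- is.na(angle_deg) | angle_deg %in% ANGLE_DIRECTIONS
    if (!all(ok))
      stop("angle_deg must be one of {0, 45, ..., 315}", call. = FALSE)
    ev$angle_deg <- angle_deg
  }
  if (!is.null(texture)) {
    texture <- as.character(rep_len(texture, max(n, 1L)))[seq_len(n)]
    ok <- is.na(texture) | texture %in% TEXTURE_GRADES
    if (!all(ok))
      stop("texture must be one of {",
           paste(TEXTURE_GRADES, collapse = ", "), "}", call. = FALSE)
    ev$texture <- texture
  }
  class(ev) <- c("session_events", "data.frame")
  ev
}

#' Canonical stimulus types, deflection angles and texture grades
#'
#' `STIM_TYPES` are the two whisker-activation paradigms (passive
#' ramp-and-hold deflection; electrically induced artificial whisking
#' against sandpaper). `ANGLE_DIRECTIONS` are the 8 deflection directions
#' separated by 45 degrees and `TEXTURE_GRADES` the 5 surface-coarseness
#' categories (sandpaper grit grades plus a smooth surface).
#' @name stimulus-vocabulary
#' @export
STIM_TYPES <- c("ramp_hold", "artificial_whisking")

#' @rdname stimulus-vocabulary
#' @export
ANGLE_DIRECTIONS <- seq(0, 315, by = 45)

#' @rdname stimulus-vocabulary
#' @export
TEXTURE_GRADES <- c("P120", "P320", "P600", "P1000", "smooth")

#' Canonical cortical layer labels spanned by the 16-contact probe
#' @export
LAYER_LABELS <- c("L2/3", "L4", "L5")

#' Assign a cortical layer label from recording depth
#'
#' Default boundaries span the probe geometry (contacts from 200 to
#' 1050 micrometres below the pia): L2/3 = \[200, 550), L4 = \[550, 750),
#' L5 = \[750, 1050\].
#'
#' @param depth_um Numeric vector of depths below the pia (micrometres).
#' @param boundaries Two inner boundaries (micrometres).
#' @return Character vector of layer labels.
#' @export
layer_from_depth <- function(depth_um, boundaries = c(550, 750)) {
  stopifnot(length(boundaries) == 2, diff(boundaries) > 0)
  cut(depth_um, breaks = c(-Inf, boundaries, Inf), labels = LAYER_LABELS,
      right = FALSE) |> as.character()
}

#' Construct and validate a unit metadata table
#'
#' @param unit_id Unit identifiers.
#' @param contact_index Probe contact (integer 0--15; 16-contact single-shaft
#'   probe, 50 um pitch).
#' @param depth_um Depth below the pia, micrometres, in \[200, 1050\];
#'   must equal `depth of contact 0 + 50 * contact_index`.
#' @param layer Layer label; derived from depth when omitted.
#' @param preferred_angle,preferred_coarseness Optional tuning preferences.
#' @return A `data.frame` of class `unit_meta`.
#' @export
unit_meta <- function(unit_id, contact_index, depth_um, layer = NULL,
                      preferred_angle = NULL, preferred_coarseness = NULL) {
  unit_id <- as.character(unit_id)
  contact_index <- as.integer(contact_index)
  depth_um <- as.numeric(depth_um)
  n <- length(unit_id)
  stopifnot(length(contact_index) == n, length(depth_um) == n)
  if (anyDuplicated(unit_id))
    stop("duplicate unit ids in metadata", call. = FALSE)
  if (any(contact_index < 0 | contact_index > 15))
    stop("contact_index must be in 0..15", call. = FALSE)
  if (any(depth_um < 200 | depth_um > 1050))
    stop("depth_um must be in [200, 1050]", call. = FALSE)
  base <- depth_um - 50 * contact_index
  if (n > 0 && diff(range(base)) > 1e-6)
    stop("depths inconsistent with 50 um contact pitch", call. = FALSE)
  if (is.null(layer)) layer <- layer_from_depth(depth_um)
  layer <- as.character(layer)
  if (!all(layer %in% LAYER_LABELS))
    stop("layer must be one of ", paste(LAYER_LABELS, collapse = ", "),
         call. = FALSE)
  m <- data.frame(unit_id = unit_id, contact_index = contact_index,
                  depth_um = depth_um, layer = layer, stringsAsFactors = FALSE)
  if (!is.null(preferred_angle)) {
    preferred_angle <- as.numeric(preferred_angle)
    ok <- is.na(preferred_angle) | preferred_angle %in% ANGLE_DIRECTIONS
    if (!all(ok)) stop("preferred_angle outside the 8 canonical directions",
                       call. = FALSE)
    m$preferred_angle <- preferred_angle
  }
  if (!is.null(preferred_coarseness)) {
    preferred_coarseness <- as.character(preferred_coarseness)
    ok <- is.na(preferred_coarseness) | preferred_coarseness %in% TEXTURE_GRADES
    if (!all(ok)) stop("preferred_coarseness outside the 5 canonical grades",
                       call. = FALSE)
    m$preferred_coarseness <- preferred_coarseness
  }
  class(m) <- c("unit_meta", "data.frame")
  m
}

# -- CSV dialect ------------------------------------------------------------
# All tables are comma-separated UTF-8 with a mandatory header row; times are
# written in seconds with 6 decimal places so write -> read roundtrips.

read_table_checked <- function(path, required, numeric_cols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  for (col in intersect(numeric_cols, names(df))) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !(df[[col]] %in% c("", "NA")))
    if (length(bad))
      stop(sprintf("%s: non-numeric value in column '%s' at data row %d ('%s')",
                   path, col, bad[1], df[[col]][bad[1]]), call. = FALSE)
    vals[df[[col]] %in% c("", "NA")] <- NA_real_
    df[[col]] <- vals
  }
  df
}

#' Read a spike table
#'
#' Reads a `spike_table.csv` with columns `unit_id`, `spike_time_s` and
#' optional `amplitude_uV`, `half_width_ms`. Times are sorted per unit on
#' load; no rows are dropped.
#'
#' @param path Path to the CSV file.
#' @param session_duration Optional session length (s); defaults to the last
#'   spike time.
#' @return A [spike_train_set()].
#' @export
read_spike_table <- function(path, session_duration = NULL) {
  df <- read_table_checked(path, c("unit_id", "spike_time_s"),
                           c("spike_time_s", "amplitude_uV", "half_width_ms"))
  if (nrow(df) == 0)
    return(spike_train_set(stats::setNames(list(), character()),
                           session_duration = session_duration %||% 0))
  if (anyNA(df$spike_time_s))
    stop(path, ": missing spike_time_s value", call. = FALSE)
  ids <- unique(df$unit_id)  # preserve file order of first appearance
  times <- split(df$spike_time_s, factor(df$unit_id, levels = ids))
  amp <- hw <- NULL
  if ("amplitude_uV" %in% names(df) && !all(is.na(df$amplitude_uV)))
    amp <- split(df$amplitude_uV, factor(df$unit_id, levels = ids))
  if ("half_width_ms" %in% names(df) && !all(is.na(df$half_width_ms)))
    hw <- split(df$half_width_ms, factor(df$unit_id, levels = ids))
  spike_train_set(times, session_duration = session_duration,
                  amplitudes = amp, half_widths = hw)
}

#' Write a spike table
#'
#' Inverse of [read_spike_table()]: `read_spike_table(write_spike_table(x, p))`
#' reproduces `x` (times to 6 decimal places).
#'
#' @param set A [spike_train_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(set, path) {
  stopifnot(inherits(set, "spike_train_set"))
  counts <- n_spikes(set)
  df <- data.frame(
    unit_id = rep(set$units, counts),
    spike_time_s = sprintf("%.6f", unlist(set$spike_times, use.names = FALSE)),
    stringsAsFactors = FALSE)
  if (!is.null(set$amplitudes))
    df$amplitude_uV <- sprintf("%.6f", unlist(set$amplitudes, use.names = FALSE))
  if (!is.null(set$half_widths))
    df$half_width_ms <- sprintf("%.6f", unlist(set$half_widths, use.names = FALSE))
  if (nrow(df) == 0)
    df <- data.frame(unit_id = character(), spike_time_s = character())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a stimulus event table
#'
#' Reads `events.csv` (`onset_s`, `offset_s`, `stim_type` and optional
#' `angle_deg`, `texture`) and validates the event invariants (increasing
#' onsets, positive durations, no overlap).
#'
#' @param path Path to the CSV file.
#' @return A [session_events()] table.
#' @export
read_events <- function(path) {
  df <- read_table_checked(path, c("onset_s", "offset_s", "stim_type"),
                           c("onset_s", "offset_s", "angle_deg"))
  session_events(df$onset_s, df$offset_s, df$stim_type,
                 angle_deg = if ("angle_deg" %in% names(df)) df$angle_deg,
                 texture = if ("texture" %in% names(df)) df$texture)
}

#' Write a stimulus event table
#' @param events A [session_events()] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "session_events"))
  df <- as.data.frame(events)
  df$onset_s <- sprintf("%.6f", df$onset_s)
  df$offset_s <- sprintf("%.6f", df$offset_s)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a unit metadata table
#' @param path Path to `unit_meta.csv` (`unit_id`, `contact_index`,
#'   `depth_um`, optional `layer`, `preferred_angle`, `preferred_coarseness`).
#' @return A [unit_meta()] table.
#' @export
read_unit_meta <- function(path) {
  df <- read_table_checked(path, c("unit_id", "contact_index", "depth_um"),
                           c("contact_index", "depth_um", "preferred_angle"))
  unit_meta(df$unit_id, df$contact_index, df$depth_um,
            layer = if ("layer" %in% names(df)) df$layer,
            preferred_angle = if ("preferred_angle" %in% names(df)) df$preferred_angle,
            preferred_coarseness =
              if ("preferred_coarseness" %in% names(df)) df$preferred_coarseness)
}

#' Write a unit metadata table
#' @param meta A [unit_meta()] table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_unit_meta <- function(meta, path) {
  stopifnot(inherits(meta, "unit_meta"))
  utils::write.csv(as.data.frame(meta), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a waveform-feature table
#'
#' Feature clouds used by the cluster-validity battery: one row per spike
#' with columns `unit_id`, `spike_index` and feature coordinates `f1`,
#' `f2`\[, `f3`\].
#'
#' @param path Path to `features.csv`.
#' @return A `data.frame` with numeric feature columns.
#' @export
read_features <- function(path) {
  df <- read_table_checked(path, c("unit_id", "spike_index", "f1", "f2"),
                           c("spike_index", "f1", "f2", "f3"))
  df
}

#' Write analysis result tables to a directory
#'
#' Emits the standard result artifacts: `pair_metrics.csv`, per-unit
#' `connectivity_index.csv`, and one canonical edge list per state
#' (`edges_<state>.csv`, rows ordered with `unit_id_a < unit_id_b`).
#'
#' @param tables Named list; recognised names are `pair_metrics`,
#'   `connectivity_index` and `edges_<state>` (any state suffix).
#' @param dir Output directory (created if needed).
#' @return Character vector of written file paths.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    if (grepl("^edges", nm) && all(c("unit_id_a", "unit_id_b") %in% names(tab))
        && nrow(tab) > 0) {
      swap <- tab$unit_id_a > tab$unit_id_b
      tmp <- tab$unit_id_a[swap]
      tab$unit_id_a[swap] <- tab$unit_id_b[swap]
      tab$unit_id_b[swap] <- tmp
      tab <- tab[order(tab$unit_id_a, tab$unit_id_b), , drop = FALSE]
    }
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  paths
}

`%||%` <- function(a, b) if (is.null(a)) b else a
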