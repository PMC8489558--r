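# Three-criterion functional-connectivity classification, per-state graphs,
# per-neuron connectivity index.

#' Functional-connectivity criteria
#'
#' A pair is functionally connected in a state when all three criteria
#' hold: (1) binned-count Pearson correlation of at least `r_min` (default
#' 0.2, which yields p < 0.05 at the bin counts involved); (2)
#' cross-correlogram peak more than `peak_z_min` SDs above the lag-wise
#' correlogram mean (default 2); (3) both members fired more than
#' `min_total_spikes` spikes over the session (default 3,000) with at least
#' `min_state_spikes` spikes in each of the spontaneous and evoked states
#' (default 1,000).
#'
#' @param r_min,peak_z_min,min_total_spikes,min_state_spikes Thresholds as
#'   above (all positive).
#' @return An object of class `connectivity_criteria`.
#' @export
connectivity_criteria <- function(r_min = 0.2, peak_z_min = 2,
                                  min_total_spikes = 3000,
                                  min_state_spikes = 1000) {
  stopifnot(r_min > 0, peak_z_min > 0, min_total_spikes > 0,
            min_state_spikes > 0)
  structure(list(r_min = r_min, peak_z_min = peak_z_min,
                 min_total_spikes = min_total_spikes,
                 min_state_spikes = min_state_spikes),
            class = "connectivity_criteria")
}

#' Classify a pair as functionally connected in a state
#'
#' Applies the three-criterion rule to the rows of a [pair_metrics()] table
#' for the given state. The correlation and correlogram thresholds are
#' applied within the classified state; the spike-count floors are applied
#' to both members in both the spontaneous and evoked states. Non-evaluable
#' metrics (undefined correlation or correlogram) classify as not
#' connected.
#'
#' @param metrics A [pair_metrics()] table.
#' @param state State label to classify.
#' @param criteria A [connectivity_criteria()].
#' @return Logical vector, one flag per pair of the state's rows, named
#'   `"a|b"`.
#' @export
classify_pair <- function(metrics, state, criteria = connectivity_criteria()) {
  stopifnot(inherits(criteria, "connectivity_criteria"))
  m <- metrics[metrics$state == state, , drop = FALSE]
  if (nrow(m) == 0) return(stats::setNames(logical(0), character(0)))
  ok <- m$evaluable & !is.na(m$pearson_r) & !is.na(m$peak_z) &
    m$pearson_r >= criteria$r_min &
    m$peak_z > criteria$peak_z_min &
    m$total_a > criteria$min_total_spikes &
    m$total_b > criteria$min_total_spikes &
    m$n_spont_a >= criteria$min_state_spikes &
    m$n_spont_b >= criteria$min_state_spikes &
    m$n_evoked_a >= criteria$min_state_spikes &
    m$n_evoked_b >= criteria$min_state_spikes
  ok[is.na(ok)] <- FALSE
  stats::setNames(ok, paste(m$unit_id_a, m$unit_id_b, sep = "|"))
}

#' Build the per-state functional-connectivity graph
#'
#' Undirected graph over the analysed units with an edge for every pair
#' passing [classify_pair()], plus the per-neuron *connectivity index*: the
#' percentage of the other recorded neurons a unit is functionally
#' connected to, `100 * degree / (N - 1)`.
#'
#' @param metrics A [pair_metrics()] table.
#' @param state State label.
#' @param criteria A [connectivity_criteria()].
#' @param nodes Node set (default: all units occurring in `metrics`).
#' @return An object of class `connectivity_graph`: `state`, `nodes`,
#'   `edges` (a canonical `data.frame` with `unit_id_a < unit_id_b`, plus
#'   `pearson_r` and `peak_z` attributes), `index` (named percent vector)
#'   and `graph` (the underlying `igraph` object).
#' @export
build_graph <- function(metrics, state, criteria = connectivity_criteria(),
                        nodes = NULL) {
  if (is.null(nodes))
    nodes <- sort(unique(c(metrics$unit_id_a, metrics$unit_id_b)))
  if (length(nodes) < 2) stop("at least 2 nodes required", call. = FALSE)
  conn <- classify_pair(metrics, state, criteria)
  m <- metrics[metrics$state == state, , drop = FALSE]
  sel <- which(conn)
  edges <- data.frame(unit_id_a = m$unit_id_a[sel],
                      unit_id_b = m$unit_id_b[sel],
                      pearson_r = m$pearson_r[sel],
                      peak_z = m$peak_z[sel], stringsAsFactors = FALSE)
  edges <- edges[order(edges$unit_id_a, edges$unit_id_b), , drop = FALSE]
  rownames(edges) <- NULL
  connectivity_graph(nodes, edges, state = state)
}

#' Construct a connectivity graph from a node set and an edge list
#'
#' Low-level constructor used by [build_graph()] and by topology null
#' models. Edges are canonicalised (`unit_id_a < unit_id_b`); self-loops
#' are rejected.
#'
#' @param nodes Character vector of unit ids.
#' @param edges `data.frame` with columns `unit_id_a`, `unit_id_b` (other
#'   columns are kept as edge attributes).
#' @param state State label carried by the graph.
#' @return An object of class `connectivity_graph`.
#' @export
connectivity_graph <- function(nodes, edges, state = "unknown") {
  nodes <- as.character(nodes)
  stopifnot(!anyDuplicated(nodes))
  edges <- as.data.frame(edges)
  if (nrow(edges) > 0) {
    a <- as.character(edges$unit_id_a); b <- as.character(edges$unit_id_b)
    if (any(a == b)) stop("self-loops are not allowed", call. = FALSE)
    if (!all(c(a, b) %in% nodes))
      stop("edge endpoints outside the node set", call. = FALSE)
    swap <- a > b
    edges$unit_id_a <- ifelse(swap, b, a)
    edges$unit_id_b <- ifelse(swap, a, b)
    edges <- edges[order(edges$unit_id_a, edges$unit_id_b), , drop = FALSE]
    if (anyDuplicated(paste(edges$unit_id_a, edges$unit_id_b)))
      stop("duplicate edges", call. = FALSE)
    rownames(edges) <- NULL
  }
  g <- igraph::graph_from_data_frame(
    edges[, intersect(c("unit_id_a", "unit_id_b"), names(edges)),
          drop = FALSE],
    directed = FALSE, vertices = data.frame(name = nodes))
  deg <- igraph::degree(g)
  idx <- if (length(nodes) > 1) 100 * deg / (length(nodes) - 1) else
    stats::setNames(numeric(length(nodes)), nodes)
  structure(list(state = state, nodes = nodes, edges = edges,
                 index = idx[nodes], graph = g),
            class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("<connectivity_graph> state=%s, %d nodes, %d edges, mean index %.1f%%\n",
              x$state, length(x$nodes), nrow(x$edges), mean(x$index)))
  invisible(x)
}

edge_keys <- function(g) {
  if (nrow(g$edges) == 0) character(0)
  else paste(g$edges$unit_id_a, g$edges$unit_id_b, sep = "|")
}

#' Per-unit connectivity-index table across states
#'
#' Pairs the spontaneous and evoked connectivity indices of every unit and
#' computes the relative change `(evoked - spont) / spont` (the per-unit
#' relative desynchronization; negative values mean stimulation reduced
#' connectivity). Units with a zero spontaneous index are flagged as not
#' evaluable (`NA`) and should be excluded from averages of the relative
#' change.
#'
#' @param g_spont,g_evoked [connectivity_graph()]s on the same node set.
#' @return A `data.frame`: `unit_id`, `index_spont`, `index_evoked`,
#'   `relative_change`.
#' @export
connectivity_index_table <- function(g_spont, g_evoked) {
  stopifnot(inherits(g_spont, "connectivity_graph"),
            inherits(g_evoked, "connectivity_graph"))
  if (!identical(sort(g_spont$nodes), sort(g_evoked$nodes)))
    stop("graphs must share the same node set", call. = FALSE)
  nodes <- g_spont$nodes
  s <- g_spont$index[nodes]; e <- g_evoked$index[nodes]
  rel <- ifelse(s > 0, (e - s) / s, NA_real_)
  data.frame(unit_id = nodes, index_spont = unname(s),
             index_evoked = unname(e), relative_change = unname(rel),
             stringsAsFactors = FALSE)
}

#' Fraction of evoked edges also present in the spontaneous graph
#'
#' `|E_evoked intersect E_spont| / |E_evoked|`; values near 1 mean
#' stimulation only removes functional connections and (almost) never
#' creates new ones.
#'
#' @param g_evoked,g_spont [connectivity_graph()]s on the same node set.
#' @return Fraction in \[0, 1\], or `NA` when the evoked graph has no
#'   edges.
#' @export
overlap_fraction <- function(g_evoked, g_spont) {
  stopifnot(inherits(g_evoked, "connectivity_graph"),
            inherits(g_spont, "connectivity_graph"))
  if (!identical(sort(g_evoked$nodes), sort(g_spont$nodes)))
    stop("graphs must share the same node set", call. = FALSE)
  ee <- edge_keys(g_evoked)
  if (length(ee) == 0) return(NA_real_)
  mean(ee %in% edge_keys(g_spont))
}
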