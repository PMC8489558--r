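# Network-topology statistics on per-state connectivity graphs:
# common-neighbor connection probability vs. a random null, distance and
# layer dependence, tuning-congruence probabilities.

adjacency_of <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g$graph, sparse = FALSE))
  A[g$nodes, g$nodes, drop = FALSE]
}

#' Common-neighbor connection statistics
#'
#' Partitions all unordered node pairs by whether they share at least one
#' common neighbor in the graph, and reports the fraction of connected
#' pairs within each partition (`p_common`, `p_nocommon`) together with the
#' connection probability expected under random (Erdos-Renyi) connectivity
#' with the observed edge count, i.e. the graph density
#' `2|E| / (N (N - 1))`. In clustered (small-world-like) networks
#' `p_common > p_expected > p_nocommon`. Optionally a degree-preserving
#' rewiring null is reported as well.
#'
#' @param g A [connectivity_graph()] with at least 3 nodes.
#' @param rewire_null Number of edge rewires for an optional
#'   degree-preserving null (0 = skip).
#' @param seed Seed for the rewiring null.
#' @return A list of class `topology_stats`: `p_common`, `p_nocommon`
#'   (`NA` when a partition is empty), `p_expected`, `n_common_pairs`,
#'   `n_nocommon_pairs`, and `p_rewired` when requested.
#' @export
common_neighbor_stats <- function(g, rewire_null = 0, seed = 1) {
  stopifnot(inherits(g, "connectivity_graph"))
  n <- length(g$nodes)
  if (n < 3) stop("at least 3 nodes required", call. = FALSE)
  A <- adjacency_of(g)
  cn <- A %*% A          # cn[i, j] = number of common neighbors
  up <- upper.tri(A)
  shares <- cn[up] > 0
  connected <- A[up] > 0
  p_common <- if (any(shares)) mean(connected[shares]) else NA_real_
  p_nocommon <- if (any(!shares)) mean(connected[!shares]) else NA_real_
  out <- list(p_common = p_common, p_nocommon = p_nocommon,
              p_expected = mean(connected),
              n_common_pairs = sum(shares),
              n_nocommon_pairs = sum(!shares))
  if (rewire_null > 0) {
    out$p_rewired <- with_seed(seed, {
      gr <- igraph::rewire(g$graph,
                           igraph::keeping_degseq(niter = rewire_null))
      Ar <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
      Ar <- Ar[g$nodes, g$nodes]
      cnr <- (Ar %*% Ar)[up] > 0
      if (any(cnr)) mean(Ar[up][cnr]) else NA_real_
    })
  }
  class(out) <- "topology_stats"
  out
}

#' Distance dependence of functional connectivity
#'
#' Pairwise distance is the absolute depth difference between the two units
#' (single-shaft vertical probe), binned at the 50 um contact pitch; bin 0
#' holds same-contact pairs. For each bin the connection probability is the
#' fraction of connected pairs among all pairs at that distance, per state,
#' together with the evoked/spontaneous ratio and the mean distance among
#' connected pairs.
#'
#' @param g_spont A [connectivity_graph()].
#' @param g_evoked Optional second graph on the same node set.
#' @param meta A [unit_meta()] table covering all nodes.
#' @param bin_um Distance bin width, micrometres (default 50).
#' @return A list of class `distance_profile`: `bins` (a `data.frame` with
#'   `distance_um`, `n_pairs`, `p_spont`\[, `p_evoked`, `ratio`\]) and
#'   `mean_connected_distance` (named per state, `NA` for an edgeless
#'   state).
#' @export
distance_profile <- function(g_spont, g_evoked = NULL, meta, bin_um = 50) {
  stopifnot(inherits(g_spont, "connectivity_graph"))
  depth <- stats::setNames(meta$depth_um, meta$unit_id)
  if (!all(g_spont$nodes %in% names(depth)))
    stop("metadata missing for some nodes", call. = FALSE)
  nodes <- g_spont$nodes
  n <- length(nodes)
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  d <- abs(depth[nodes[ii]] - depth[nodes[jj]])
  bin <- floor(d / bin_um + 0.5) * bin_um   # snap to the contact pitch grid

  conn_flags <- function(g) {
    keys <- paste(pmin(nodes[ii], nodes[jj]), pmax(nodes[ii], nodes[jj]),
                  sep = "|")
    keys %in% edge_keys(g)
  }
  cs <- conn_flags(g_spont)
  levels_um <- sort(unique(bin))
  tab <- data.frame(distance_um = levels_um,
                    n_pairs = as.integer(table(factor(bin, levels_um))))
  tab$p_spont <- vapply(levels_um, function(b) mean(cs[bin == b]), numeric(1))
  mcd <- c(spontaneous = if (any(cs)) mean(d[cs]) else NA_real_)
  if (!is.null(g_evoked)) {
    stopifnot(inherits(g_evoked, "connectivity_graph"))
    if (!identical(sort(g_evoked$nodes), sort(nodes)))
      stop("graphs must share the same node set", call. = FALSE)
    ce <- conn_flags(g_evoked)
    tab$p_evoked <- vapply(levels_um, function(b) mean(ce[bin == b]),
                           numeric(1))
    tab$ratio <- ifelse(tab$p_spont > 0, tab$p_evoked / tab$p_spont,
                        NA_real_)
    mcd <- c(mcd, evoked = if (any(ce)) mean(d[ce]) else NA_real_)
  }
  structure(list(bins = tab, mean_connected_distance = mcd,
                 bin_um = bin_um),
            class = "distance_profile")
}

#' Layer-resolved connectivity statistics
#'
#' Connection probabilities per cortical layer (both members in the layer)
#' and for intra- versus inter-layer pairs, in the spontaneous and evoked
#' states, together with the relative desynchronization
#' `(evoked - spont) / spont` of each grouping.
#'
#' @param g_spont,g_evoked [connectivity_graph()]s on the same node set.
#' @param meta A [unit_meta()] table with layer labels for all nodes.
#' @return A `data.frame` with one row per grouping (`L2/3`, `L4`, `L5`,
#'   `intra`, `inter`): `n_pairs`, `p_spont`, `p_evoked`,
#'   `relative_change`. Groupings with fewer than one pair are reported
#'   with `NA`.
#' @export
layer_stats <- function(g_spont, g_evoked, meta) {
  stopifnot(inherits(g_spont, "connectivity_graph"),
            inherits(g_evoked, "connectivity_graph"))
  if (!identical(sort(g_spont$nodes), sort(g_evoked$nodes)))
    stop("graphs must share the same node set", call. = FALSE)
  nodes <- g_spont$nodes
  layer <- stats::setNames(meta$layer, meta$unit_id)
  if (!all(nodes %in% names(layer)) || anyNA(layer[nodes]))
    stop("layer labels missing for some nodes", call. = FALSE)
  n <- length(nodes)
  ii <- rep(seq_len(n - 1), times = (n - 1):1)
  jj <- unlist(lapply(seq_len(n - 1), function(i) seq(i + 1, n)))
  la <- layer[nodes[ii]]; lb <- layer[nodes[jj]]
  keys <- paste(pmin(nodes[ii], nodes[jj]), pmax(nodes[ii], nodes[jj]),
                sep = "|")
  cs <- keys %in% edge_keys(g_spont)
  ce <- keys %in% edge_keys(g_evoked)

  group_row <- function(name, sel) {
    if (!any(sel))
      return(data.frame(group = name, n_pairs = 0L, p_spont = NA_real_,
                        p_evoked = NA_real_, relative_change = NA_real_))
    ps <- mean(cs[sel]); pe <- mean(ce[sel])
    data.frame(group = name, n_pairs = sum(sel), p_spont = ps, p_evoked = pe,
               relative_change = if (ps > 0) (pe - ps) / ps else NA_real_)
  }
  rows <- lapply(LAYER_LABELS, function(l) group_row(l, la == l & lb == l))
  rows <- c(rows, list(group_row("intra", la == lb),
                       group_row("inter", la != lb)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tuning-congruence connection statistics
#'
#' Observed fraction of functionally connected pairs whose members share
#' the same tuning preference, against the fraction expected under random
#' pairing given the preference distribution of the same unit set:
#' `sum_k n_k (n_k - 1) / (N (N - 1))`.
#'
#' @param g A [connectivity_graph()].
#' @param preferences Named vector (unit -> category) covering all nodes.
#' @param categories Allowed category set (default: values present).
#' @return A list of class `congruence_stats`: `observed` (`NA` for an
#'   edgeless graph), `expected`, `n_edges`, `degenerate` (single
#'   category).
#' @export
congruence_stats <- function(g, preferences, categories = NULL) {
  stopifnot(inherits(g, "connectivity_graph"))
  if (!all(g$nodes %in% names(preferences)))
    stop("preference missing for some nodes", call. = FALSE)
  pref <- preferences[g$nodes]
  if (anyNA(pref)) stop("preference missing for some nodes", call. = FALSE)
  if (!is.null(categories) && !all(pref %in% categories))
    stop("preference outside the allowed categories", call. = FALSE)
  n <- length(pref)
  nk <- table(pref)
  expected <- sum(nk * (nk - 1)) / (n * (n - 1))
  degenerate <- length(nk) == 1
  observed <- if (nrow(g$edges) == 0) NA_real_ else
    mean(pref[g$edges$unit_id_a] == pref[g$edges$unit_id_b])
  structure(list(observed = observed, expected = expected,
                 n_edges = nrow(g$edges), degenerate = degenerate),
            class = "congruence_stats")
}

#' Sample a random (Erdos-Renyi) connectivity graph
#'
#' Null-model generator used for topology calibration: each pair is
#' connected independently with probability `p`.
#'
#' @param n Number of nodes.
#' @param p Connection probability.
#' @param seed Integer seed.
#' @return A [connectivity_graph()] labelled `state = "null"`.
#' @export
random_graph <- function(n, p, seed) {
  nodes <- sprintf("u%03d", seq_len(n))
  with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    el <- igraph::as_edgelist(g)
    connectivity_graph(nodes,
                       data.frame(unit_id_a = nodes[el[, 1]],
                                  unit_id_b = nodes[el[, 2]],
                                  stringsAsFactors = FALSE),
                       state = "null")
  })
}

#' Sample a planted-partition connectivity graph
#'
#' Two-probability stochastic block model: pairs inside a block connect
#' with `p_in`, pairs across blocks with `p_out`. Used to verify that the
#' common-neighbor statistic detects clustered topology.
#'
#' @param block_sizes Integer vector of block sizes.
#' @param p_in,p_out Within- and between-block connection probabilities.
#' @param seed Integer seed.
#' @return A [connectivity_graph()] labelled `state = "null"`.
#' @export
planted_partition_graph <- function(block_sizes, p_in, p_out, seed) {
  k <- length(block_sizes)
  n <- sum(block_sizes)
  pm <- matrix(p_out, k, k); diag(pm) <- p_in
  nodes <- sprintf("u%03d", seq_len(n))
  with_seed(seed, {
    g <- igraph::sample_sbm(n, pref.matrix = pm, block.sizes = block_sizes)
    el <- igraph::as_edgelist(g)
    connectivity_graph(nodes,
                       data.frame(unit_id_a = nodes[el[, 1]],
                                  unit_id_b = nodes[el[, 2]],
                                  stringsAsFactors = FALSE),
                       state = "null")
  })
}
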