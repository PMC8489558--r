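test_that("common-neighbor statistics match hand enumeration", {
  # triangle a-b-c plus isolated d: all 3 triangle pairs share a neighbor
  # and are connected; the 3 pairs involving d share none and are not
  g <- connectivity_graph(c("a", "b", "c", "d"),
                          data.frame(unit_id_a = c("a", "a", "b"),
                                     unit_id_b = c("b", "c", "c")))
  ts <- common_neighbor_stats(g)
  expect_equal(ts$p_common, 1.0)
  expect_equal(ts$p_nocommon, 0.0)
  expect_equal(ts$p_expected, 0.5)
  expect_equal(ts$n_common_pairs, 3)
  expect_error(common_neighbor_stats(
    connectivity_graph(c("a", "b"),
                       data.frame(unit_id_a = "a", unit_id_b = "b"))),
    "at least 3 nodes")
})

test_that("clustered graphs separate p_common from p_nocommon", {
  ok <- 0
  for (seed in 1:20) {
    g <- planted_partition_graph(rep(15, 4), p_in = 0.5, p_out = 0.02,
                                 seed = seed)
    ts <- common_neighbor_stats(g)
    if (!is.na(ts$p_common) && !is.na(ts$p_nocommon) &&
        ts$p_common > ts$p_expected && ts$p_expected > ts$p_nocommon)
      ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("statistics are invariant to node relabeling", {
  g <- planted_partition_graph(c(8, 8), 0.6, 0.05, seed = 3)
  perm <- synconn:::with_seed(4, sample(g$nodes))
  relab <- stats::setNames(sprintf("w%02d", seq_along(perm)), perm)
  g2 <- connectivity_graph(unname(relab[g$nodes]),
                           data.frame(unit_id_a = relab[g$edges$unit_id_a],
                                      unit_id_b = relab[g$edges$unit_id_b]))
  a <- common_neighbor_stats(g); b <- common_neighbor_stats(g2)
  expect_equal(a$p_common, b$p_common)
  expect_equal(a$p_nocommon, b$p_nocommon)
  expect_equal(a$p_expected, b$p_expected)
})

test_that("distance profile bins pairs at the contact pitch", {
  meta <- unit_meta(c("a", "b", "c"), c(2, 3, 6), c(300, 350, 500))
  g <- connectivity_graph(c("a", "b", "c"),
                          data.frame(unit_id_a = "a", unit_id_b = "b"))
  dp <- distance_profile(g, meta = meta)
  expect_equal(dp$bins$distance_um, c(50, 150, 200))
  expect_equal(dp$bins$n_pairs, rep(1L, 3))
  expect_equal(dp$bins$p_spont, c(1, 0, 0))
  expect_equal(unname(dp$mean_connected_distance["spontaneous"]), 50)

  # edgeless evoked graph -> mean connected distance not evaluable
  e0 <- connectivity_graph(c("a", "b", "c"),
                           data.frame(unit_id_a = character(0),
                                      unit_id_b = character(0)))
  dp2 <- distance_profile(g, e0, meta)
  expect_true(is.na(dp2$mean_connected_distance["evoked"]))
  expect_error(distance_profile(g, meta = meta[1:2, ]), "missing")
})

test_that("per-bin probabilities average back to graph density", {
  for (seed in 1:5) {
    g <- random_graph(16, 0.25, seed)
    meta <- unit_meta(g$nodes, rep(0:15, length.out = 16),
                      200 + 50 * rep(0:15, length.out = 16))
    dp <- distance_profile(g, meta = meta)
    dens <- 2 * nrow(g$edges) / (16 * 15)
    expect_equal(sum(dp$bins$p_spont * dp$bins$n_pairs) / sum(dp$bins$n_pairs),
                 dens)
  }
})

test_that("layer statistics match exhaustive pair counting", {
  # 6 units: 3 in L2/3 (a,b,c), 3 in L5 (d,e,f)
  meta <- unit_meta(letters[1:6], c(0:2, 11:13),
                    c(200, 250, 300, 750, 800, 850))
  nodes <- letters[1:6]
  gs <- connectivity_graph(nodes, data.frame(
    unit_id_a = c("a", "a", "d", "a"),
    unit_id_b = c("b", "c", "e", "d")))   # 2 intra-L2/3, 1 intra-L5, 1 inter
  ge <- connectivity_graph(nodes, data.frame(unit_id_a = "a",
                                             unit_id_b = "b"))
  tab <- layer_stats(gs, ge, meta)
  l23 <- tab[tab$group == "L2/3", ]
  expect_equal(l23$p_spont, 2 / 3)
  expect_equal(l23$p_evoked, 1 / 3)
  expect_equal(l23$relative_change, -0.5)
  intra <- tab[tab$group == "intra", ]
  expect_equal(intra$n_pairs, 6L)         # 3 + 3 within-layer pairs
  expect_equal(intra$p_spont, 3 / 6)
  inter <- tab[tab$group == "inter", ]
  expect_equal(inter$n_pairs, 9L)
  expect_equal(inter$p_spont, 1 / 9)
  # absent layer -> not evaluable rows
  expect_true(is.na(tab$p_spont[tab$group == "L4"]))
})

test_that("congruence statistics match the finite-sample expectation", {
  nodes <- c("a", "b", "c", "d")
  prefs <- stats::setNames(c("A", "A", "B", "B"), nodes)
  g <- connectivity_graph(nodes, data.frame(unit_id_a = "a",
                                            unit_id_b = "b"))
  cs <- congruence_stats(g, prefs)
  expect_equal(cs$expected, 2 / 6)
  expect_equal(cs$observed, 1.0)

  # brute-force equality of the expectation by full pair enumeration
  for (seed in 1:5) {
    n <- 40
    pr <- synconn:::with_seed(seed,
      sample(LETTERS[1:8], n, replace = TRUE))
    names(pr) <- sprintf("u%02d", 1:n)
    g2 <- random_graph(n, 0.2, seed)
    names(pr) <- g2$nodes
    cs2 <- congruence_stats(g2, pr)
    pairs <- utils::combn(g2$nodes, 2)
    brute <- mean(pr[pairs[1, ]] == pr[pairs[2, ]])
    expect_equal(cs2$expected, brute)
  }

  # single category is degenerate
  cs3 <- congruence_stats(g, stats::setNames(rep("A", 4), nodes))
  expect_true(cs3$degenerate)
  expect_equal(cs3$expected, 1)
})

test_that("random graphs show no congruence or common-neighbor structure", {
  # joint null calibration at moderate scale (full version in acceptance)
  diffs <- t(vapply(1:30, function(seed) {
    g <- random_graph(60, 0.2, seed)
    ts <- common_neighbor_stats(g)
    pr <- synconn:::with_seed(seed + 900,
      stats::setNames(sample(LETTERS[1:8], 60, TRUE), g$nodes))
    cs <- congruence_stats(g, pr)
    c(ts$p_common - ts$p_expected, cs$observed - cs$expected)
  }, numeric(2)))
  for (k in 1:2) {
    ci <- stats::t.test(diffs[, k])$conf.int
    expect_true(ci[1] < 0 && ci[2] > 0)
  }
})
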