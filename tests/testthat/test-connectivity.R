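test_that("graphs, indices and the index identity behave", {
  # 9 nodes, u1 connected to exactly 2 others -> index 25%
  nodes <- sprintf("u%d", 1:9)
  g <- connectivity_graph(nodes,
                          data.frame(unit_id_a = c("u1", "u1"),
                                     unit_id_b = c("u2", "u3")))
  expect_equal(unname(g$index["u1"]), 25.0)
  expect_equal(unname(g$index["u9"]), 0.0)

  # sum of degrees = 2|E| (via the index identity)
  for (seed in 1:5) {
    rg <- random_graph(20, 0.3, seed)
    expect_equal(sum(rg$index) * (20 - 1) / 100, 2 * nrow(rg$edges))
  }

  expect_error(connectivity_graph("a", data.frame(unit_id_a = "a",
                                                  unit_id_b = "a")),
               "self-loops")
})

test_that("the three-criterion rule classifies boundary metrics exactly", {
  crit <- connectivity_criteria()
  pass <- function(m) unname(classify_pair(m, "evoked", crit))
  expect_true(pass(fake_metrics()))
  # r boundary: 0.2 or greater passes, 0.19 fails
  expect_true(pass(fake_metrics(r = 0.20)))
  expect_false(pass(fake_metrics(r = 0.19)))
  # correlogram peak must exceed 2 SD
  expect_false(pass(fake_metrics(peak_z = 1.5)))
  # count floors: overall above 3,000; per-state at least 1,000
  expect_false(pass(fake_metrics(total = 2999)))
  expect_false(pass(fake_metrics(n_spont = 999)))
  expect_false(pass(fake_metrics(n_evoked = 999)))
  expect_true(pass(fake_metrics(n_spont = 1000, n_evoked = 1000)))
  # non-evaluable metrics are not connected, never errors
  expect_false(pass(fake_metrics(r = NA, evaluable = FALSE)))
})

test_that("relaxing any single criterion never removes an edge", {
  base <- connectivity_criteria()
  relaxed <- list(connectivity_criteria(r_min = 0.1),
                  connectivity_criteria(peak_z_min = 1),
                  connectivity_criteria(min_total_spikes = 1000),
                  connectivity_criteria(min_state_spikes = 500))
  synconn:::with_seed(14, {
    for (i in 1:50) {
      m <- fake_metrics(r = runif(1, 0, 0.4), peak_z = runif(1, 0, 4),
                        total = sample(1000:6000, 1),
                        n_spont = sample(400:2000, 1),
                        n_evoked = sample(400:2000, 1))
      was <- unname(classify_pair(m, "evoked", base))
      for (cr in relaxed)
        if (was) expect_true(unname(classify_pair(m, "evoked", cr)))
    }
  })
})

test_that("index table computes relative desynchronization per unit", {
  nodes <- sprintf("u%d", 1:6)
  gs <- connectivity_graph(nodes, data.frame(
    unit_id_a = c("u1", "u1", "u2"), unit_id_b = c("u2", "u3", "u3")),
    state = "spontaneous")
  ge <- connectivity_graph(nodes, data.frame(
    unit_id_a = "u1", unit_id_b = "u2"), state = "evoked")
  tab <- connectivity_index_table(gs, ge)
  u1 <- tab[tab$unit_id == "u1", ]
  expect_equal(u1$index_spont, 40)
  expect_equal(u1$index_evoked, 20)
  expect_equal(u1$relative_change, -0.5)
  # spont = 0 -> flagged not evaluable
  expect_true(is.na(tab$relative_change[tab$unit_id == "u4"]))
  # equal graphs -> 0
  expect_equal(connectivity_index_table(gs, gs)$relative_change[1], 0)
  # mismatched node sets -> error
  g2 <- connectivity_graph(nodes[1:5], data.frame(
    unit_id_a = character(0), unit_id_b = character(0)))
  expect_error(connectivity_index_table(gs, g2), "same node set")
})

test_that("overlap fraction is plain edge-set arithmetic", {
  nodes <- sprintf("u%d", 1:6)
  mk <- function(a, b) connectivity_graph(nodes,
    data.frame(unit_id_a = a, unit_id_b = b))
  gs <- mk(c("u1", "u1", "u2", "u4"), c("u2", "u3", "u3", "u5"))
  # subset -> 1
  expect_equal(overlap_fraction(mk("u1", "u2"), gs), 1.0)
  # disjoint -> 0
  expect_equal(overlap_fraction(mk("u5", "u6"), gs), 0.0)
  # 3 of 4 evoked edges also spontaneous
  ge <- mk(c("u1", "u1", "u2", "u1"), c("u2", "u3", "u3", "u6"))
  expect_equal(overlap_fraction(ge, gs), 0.75)
  # edgeless evoked graph -> not evaluable
  e0 <- mk(character(0), character(0))
  expect_true(is.na(overlap_fraction(e0, gs)))
})

test_that("evoked connectivity drops below spontaneous under gamma < 1", {
  # deep 20-seed version lives in the acceptance suite
  for (s in 1:3) {
    ses <- whisk_session(seed = s, gamma = 0.3)
    g <- session_graphs(ses)
    expect_lt(mean(g$evoked$index), mean(g$spont$index))
  }
})
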