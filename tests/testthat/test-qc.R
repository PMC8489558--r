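test_that("ISI statistics match hand counts and distribution shape", {
  s <- isi_statistics(c(0, 0.001, 0.05))
  expect_equal(s$min_isi_ms, 1)
  expect_equal(s$violation_fraction, 0.5)
  expect_error(isi_statistics(0.5), "at least 2 spikes")

  # Poisson ISIs are exponential -> high R^2 of the log-linear fit
  for (seed in 1:3) {
    tr <- poisson_train(5, 600, seed)
    expect_gt(isi_statistics(tr)$exp_fit_r2, 0.9)
  }
  # periodic train: delta-like ISI histogram, nothing exponential about it
  per <- isi_statistics(seq(0, 60, by = 0.1))
  expect_false(isTRUE(per$exp_fit_r2 >= 0.5))
})

test_that("waveform stability compares first and last spike segments", {
  # identical segments by construction -> p = 1, stable
  x <- rep(c(1, 2, 3, 4, 5), 20)
  s <- waveform_stability(x, x)
  expect_equal(s$p_amplitude, 1)
  expect_true(s$stable)

  # strong amplitude drift -> unstable
  synconn:::with_seed(42, {
    n <- 1000
    drift <- 100 * (1 + 0.3 * seq_len(n) / n) + rnorm(n, 0, 10)
    flat <- rnorm(n, 0.3, 0.03)
    expect_false(waveform_stability(drift, flat)$stable)
  })

  # missing series -> not evaluable
  expect_true(is.na(waveform_stability(NULL, NULL)$stable))
})

test_that("MANOVA separation p-value behaves at the extremes", {
  synconn:::with_seed(7, {
    far <- rbind(MASS::mvrnorm(100, c(0, 0), diag(2)),
                 MASS::mvrnorm(100, c(10, 10), diag(2)))
    labs <- rep(c("a", "b"), each = 100)
    expect_lt(cluster_separation_p(far, labs), 1e-6)
    expect_error(cluster_separation_p(far, rep("a", 200)),
                 "at least 2 clusters")
  })
  # oracle cross-check against summary.manova on a random cloud
  synconn:::with_seed(8, {
    x <- MASS::mvrnorm(60, c(0, 0), diag(2))
    g <- rep(c("a", "b"), each = 30)
    expected <- summary(stats::manova(x ~ factor(g)),
                        test = "Wilks")$stats[1, "Pr(>F)"]
    expect_equal(cluster_separation_p(x, g), unname(expected))
  })
})

test_that("validity indices reproduce the hand-computed fixture", {
  fx <- two_cluster_fixture()
  expect_equal(dunn_index(fx$features, fx$labels), 10.0)
  s <- synconn:::scatter_sums(fx$features, factor(fx$labels))
  expect_equal(s$j1, 1.0)
  expect_equal(s$j2, 100.0)
  expect_equal(j3(fx$features, fx$labels), 100.0)
  expect_equal(pseudo_f(fx$features, fx$labels), 200.0)
  # Davies-Bouldin: s_i = mean centroid distance = 0.5 each, d = 10
  expect_equal(davies_bouldin(fx$features, fx$labels), 0.1)
})

test_that("interleaved duplicate labelings score as poorly sorted", {
  synconn:::with_seed(12, {
    cloud <- MASS::mvrnorm(200, c(0, 0), diag(2))
    labs <- rep(c("a", "b"), 100)  # one cloud split arbitrarily in two
    expect_lt(dunn_index(cloud, labs), 1)
    expect_lt(j3(cloud, labs), 1)
  })
})

test_that("validity indices are invariant to translation and scaling", {
  for (seed in 1:3) {
    fc <- generate_feature_clusters(3, 30,
                                    rbind(c(0, 0), c(6, 0), c(0, 6)),
                                    diag(2), seed = seed)
    x <- as.matrix(fc[, c("f1", "f2")])
    labs <- fc$unit_id
    for (tf in list(function(z) z + 17.3, function(z) z * 4.2,
                    function(z) (z - 5) * 0.31)) {
      y <- tf(x)
      expect_equal(dunn_index(y, labs), dunn_index(x, labs))
      expect_equal(davies_bouldin(y, labs), davies_bouldin(x, labs))
      expect_equal(j3(y, labs), j3(x, labs))
      expect_equal(pseudo_f(y, labs), pseudo_f(x, labs))
    }
  }
})

test_that("duplicate detection flags near-copies and spares thinned pairs", {
  tr <- poisson_train(8, 300, seed = 31)
  # exact copy -> flagged, lower-count unit marked
  set1 <- spike_train_set(list(a = tr, b = tr, c = poisson_train(8, 300, 32)),
                          session_duration = 300)
  d <- duplicate_pairs(set1)
  expect_equal(nrow(d), 1)
  expect_setequal(c(d$unit_id_a, d$unit_id_b), c("a", "b"))
  expect_equal(d$r, 1.0)

  # 50% thinned copy: expected zero-lag r ~ sqrt(0.5) ~ 0.71 -> not flagged
  synconn:::with_seed(33, {
    thin <- tr[runif(length(tr)) < 0.5]
    set2 <- spike_train_set(list(a = tr, b = thin), session_duration = 300)
    d2 <- duplicate_pairs(set2)
    expect_equal(nrow(d2), 0)
  })
})

test_that("the acceptance battery gates on rate, counts and duplicates", {
  dur <- 1000
  good <- poisson_train(6, dur, seed = 41, refractory_ms = 2.5)
  slow <- poisson_train(0.4, dur, seed = 42, refractory_ms = 2.5)
  sparse <- poisson_train(2.5, dur, seed = 43, refractory_ms = 2.5)
  set <- spike_train_set(list(good = good, slow = slow, sparse = sparse),
                         session_duration = dur)
  res <- apply_qc(set, config = qc_config())
  rep <- res$report
  expect_false(rep$rate_ok[rep$unit_id == "slow"])
  expect_false(rep$accept[rep$unit_id == "slow"])
  expect_false(rep$total_count_ok[rep$unit_id == "sparse"])
  expect_false(rep$accept[rep$unit_id == "sparse"])
  expect_true(rep$accept[rep$unit_id == "good"])
  expect_identical(res$accepted$units, "good")
})

test_that("QC acceptance is monotone in added compliant spikes", {
  dur <- 1000
  base <- poisson_train(4, dur, seed = 51, refractory_ms = 2.5)
  set1 <- spike_train_set(list(u = base), session_duration = dur)
  r1 <- suppressWarnings(apply_qc(set1))$report
  expect_true(r1$rate_ok && r1$total_count_ok)
  # add well-separated extra spikes: rate/count flags cannot flip to fail
  extra <- base + 0.010  # 10 ms after each existing spike
  set2 <- spike_train_set(list(u = enforce_refractory(sort(c(base, extra)),
                                                      2.5)),
                          session_duration = dur)
  r2 <- suppressWarnings(apply_qc(set2))$report
  expect_true(r2$rate_ok && r2$total_count_ok)
})

test_that("full QC on a synthetic session accepts clean units", {
  ses <- whisk_session(seed = 6, n_trials = 200)
  w <- make_state_windows(ses$events)
  # well-separated per-contact feature clouds for every unit
  feats <- do.call(rbind, lapply(seq_along(ses$spikes$units), function(i) {
    fc <- generate_feature_clusters(1, 400, matrix(c(0, 0), 1), diag(2) * 0.01,
                                    seed = 600 + i)
    fc$unit_id <- ses$spikes$units[i]
    fc
  }))
  # place two units per synthetic contact so the battery has >= 2 clusters
  meta2 <- ses$meta
  meta2$contact_index <- rep(0:7, each = 2)[seq_len(nrow(meta2))]
  meta2$depth_um <- 200 + 50 * meta2$contact_index
  offs <- rep(c(0, 8), 8)[seq_len(nrow(meta2))]
  feats$f1 <- feats$f1 + offs[match(feats$unit_id, meta2$unit_id)]
  res <- apply_qc(ses$spikes, meta2, w, qc_config(), features = feats)
  expect_gt(sum(res$report$accept), 0)
  expect_true(all(res$report$indices_ok[res$report$accept]))
  expect_true(all(res$report$separation_ok[res$report$accept]))
})
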