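test_that("state windows follow the pre-stimulus/evoked arithmetic", {
  ev <- session_events(c(2, 4), c(2.2, 4.2), "ramp_hold")
  w <- make_state_windows(ev)
  sp <- w[w$label == "spontaneous", ]
  expect_equal(sp$start_s, c(1.4, 3.4))
  expect_equal(sp$end_s, c(2.0, 4.0))
  evw <- w[w$label == "evoked", ]
  expect_equal(evw$start_s, c(2.0, 4.0))
  expect_equal(evw$end_s, c(2.2, 4.2))

  # early first onset truncates the spontaneous window with a warning
  ev2 <- session_events(0.3, 0.5, "ramp_hold")
  expect_warning(w2 <- make_state_windows(ev2), "truncated")
  expect_equal(w2$start_s[w2$label == "spontaneous"], 0)

  # no events -> empty windows, no error
  ev0 <- session_events(numeric(0), numeric(0), character(0))
  expect_equal(nrow(make_state_windows(ev0)), 0)

  # post windows stop at the next onset
  w3 <- make_state_windows(session_events(c(2, 4), c(2.2, 4.2), "ramp_hold"),
                           post_s = 5)
  post <- w3[w3$label == "post", ]
  expect_equal(post$end_s[1], 4.0)
})

test_that("binning is half-open, trailing-partial-dropping and conservative", {
  set <- spike_train_set(list(u = c(0.005, 0.015)), session_duration = 1)
  w <- data.frame(start_s = 0, end_s = 0.02, label = "s", event = 1L)
  bc <- bin_counts(set, w, bin_s = 0.01, states = "s")
  expect_equal(as.vector(bc$states$s), c(1L, 1L))

  # boundary spike joins the bin it starts (half-open convention)
  set2 <- spike_train_set(list(u = 0.01), session_duration = 1)
  bc2 <- bin_counts(set2, w, bin_s = 0.01, states = "s")
  expect_equal(as.vector(bc2$states$s), c(0L, 1L))

  # conservation on random trains: bins hold exactly the retained spikes
  for (seed in 1:4) {
    tt <- poisson_train(20, 10, seed)
    set3 <- spike_train_set(list(u = tt), session_duration = 10)
    w3 <- data.frame(start_s = c(1, 4.25), end_s = c(2.55, 6),
                     label = "s", event = 1:2)
    bc3 <- bin_counts(set3, w3, bin_s = 0.1, states = "s")
    nb <- floor((w3$end_s - w3$start_s) / 0.1)
    inside <- sum(tt >= 1 & tt < 1 + nb[1] * 0.1) +
      sum(tt >= 4.25 & tt < 4.25 + nb[2] * 0.1)
    expect_equal(sum(bc3$states$s), inside)
    expect_equal(ncol(bc3$states$s), sum(nb))
  }
})

test_that("pearson_r matches the closed form and the t-based p-value", {
  expect_equal(pearson_r(1:10, 1:10)$r, 1.0)
  # hand case: cov = 3.0, var = 5/3 each (sample), r = 0.6
  h <- pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(h$r, 0.6)
  # oracle: cor.test on random vectors
  synconn:::with_seed(2, {
    x <- rnorm(50); y <- x + rnorm(50, 0, 2)
    ct <- stats::cor.test(x, y)
    pr <- pearson_r(x, y)
    expect_equal(pr$r, unname(ct$estimate))
    expect_equal(pr$p, ct$p.value)
  })
  # the r >= 0.2 at n = 100 threshold sits just under p = 0.05
  r <- 0.2; n <- 100
  t <- r * sqrt((n - 2) / (1 - r^2))
  expect_lt(2 * stats::pt(-t, n - 2), 0.05)
  # constant vector -> flagged, not an error
  flag <- pearson_r(rep(1, 10), rnorm(10))
  expect_false(flag$defined)
  # affine invariance with positive slope
  synconn:::with_seed(3, {
    x <- rpois(100, 3); y <- rpois(100, 3) + x
    expect_equal(pearson_r(2 * x + 7, 0.5 * y - 1)$r, pearson_r(x, y)$r)
  })
})

test_that("cross-correlogram counts exact lag differences", {
  cc <- cross_correlogram(c(0.010, 0.020), c(0.012, 0.030))
  nz <- cc$lag_ms[cc$counts > 0]
  expect_setequal(nz, c(2, 20, -8, 10))
  expect_true(all(cc$counts[cc$counts > 0] == 1))

  # autocorrelogram: the zero-lag bin holds every spike's self-coincidence
  tr <- seq(0.5, 9.5, by = 0.5)
  ac <- cross_correlogram(tr, tr)
  expect_equal(ac$counts[ac$lag_ms == 0], length(tr))

  # symmetry: ccg(i, j) reversed equals ccg(j, i)
  a <- poisson_train(10, 30, 1); b <- poisson_train(10, 30, 2)
  expect_equal(rev(cross_correlogram(a, b)$counts),
               cross_correlogram(b, a)$counts)

  expect_error(cross_correlogram(numeric(0), a), "empty correlogram")
})

test_that("optimized and brute-force correlograms agree exactly", {
  for (seed in 1:10) {
    a <- poisson_train(6, 25, seed)
    b <- poisson_train(6, 25, seed + 100)
    fast <- cross_correlogram(a, b, method = "sorted")
    slow <- cross_correlogram(a, b, method = "brute")
    expect_identical(fast$counts, slow$counts)
  }
})

test_that("independent trains are never classified as connected", {
  # The correlogram peak is a maximum over ~101 lag bins, so under
  # independence peak_z concentrates near the expected maximum of that
  # many standardized draws (~2.5): the 2-SD criterion is permissive on
  # its own and the classification relies on the conjunction with the
  # r >= 0.2 criterion. Check both calibration facts.
  zs <- rs <- numeric(25)
  w <- data.frame(start_s = 0, end_s = 60, label = "all", event = 1L)
  for (seed in 1:25) {
    a <- poisson_train(8, 60, seed)
    b <- poisson_train(8, 60, seed + 500)
    zs[seed] <- cross_correlogram(a, b)$peak_z
    set <- spike_train_set(list(a = a, b = b), session_duration = 60)
    m <- bin_counts(set, w, bin_s = 0.01, states = "all")$states$all
    rs[seed] <- pearson_r(m[1, ], m[2, ])$r
  }
  expect_lt(mean(zs), 4)            # no genuine synchrony peaks
  expect_true(all(rs < 0.2))        # conjunctive rule rejects every pair
})

test_that("pair_metrics covers all pairs and flags degenerate states", {
  ses <- whisk_session(seed = 9, n_trials = 60, n_units = 6)
  w <- make_state_windows(ses$events)
  pm <- pair_metrics(ses$spikes, w)
  expect_equal(nrow(pm), choose(6, 2) * 2)
  expect_true(all(pm$unit_id_a < pm$unit_id_b))

  # a unit silent in the evoked state -> pair not evaluable there
  tt <- ses$spikes$spike_times
  spont_w <- w[w$label == "spontaneous", ]
  tt$mute <- tt[[1]][synconn:::spikes_in_windows(tt[[1]], spont_w)][1:50]
  set2 <- spike_train_set(tt, ses$spikes$session_duration)
  pm2 <- pair_metrics(set2, w)
  ev_mute <- pm2[pm2$state == "evoked" &
                   (pm2$unit_id_a == "mute" | pm2$unit_id_b == "mute"), ]
  expect_true(all(!ev_mute$evaluable))
})
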