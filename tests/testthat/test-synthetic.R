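test_that("expected pair correlation matches the closed form", {
  # perfect common source
  expect_equal(expected_pair_correlation(1, 1, 10, 0, 0), 1.0)
  # independence when one unit never copies
  expect_equal(expected_pair_correlation(0, 0.5, 10, 3, 5), 0.0)
  # symmetric mid case: (0.25 * 10) / (0.5 * 10 + 5) = 0.25
  expect_equal(expected_pair_correlation(0.5, 0.5, 10, 5, 5), 0.25)
  expect_error(expected_pair_correlation(0, 0, 10, 0, 0), "undefined")
})

test_that("generator is deterministic and respects degenerate configs", {
  cfg <- assembly_config(c(1, 1, 2), copy_prob = 0.6)
  a <- generate_correlated_trains(cfg, 30, seed = 11)
  b <- generate_correlated_trains(cfg, 30, seed = 11)
  expect_identical(a$spikes$spike_times, b$spikes$spike_times)

  # copies: p = 1, no jitter, no background -> identical trains
  cfg1 <- assembly_config(c(1, 1), copy_prob = 1, jitter_sd_ms = 0,
                          background_rate_hz = 0)
  x <- generate_correlated_trains(cfg1, 60, seed = 3)
  expect_identical(x$spikes$spike_times$u01, x$spikes$spike_times$u02)

  # p = 0 for all units: independent Poisson, r within 3 SE of 0
  cfg0 <- assembly_config(c(1, 1), copy_prob = 0, background_rate_hz = 8)
  y <- generate_correlated_trains(cfg0, 300, seed = 5)
  w <- data.frame(start_s = 0, end_s = 300, label = "all", event = 1L)
  m <- bin_counts(y$spikes, w, bin_s = 0.02, states = "all")$states$all
  r <- stats::cor(m[1, ], m[2, ])
  expect_lt(abs(r), 3 / sqrt(ncol(m)))
})

test_that("realized unit rates match p * lambda_m + b within 3 SE", {
  cfg <- assembly_config(c(1, 1, 2, 2), copy_prob = c(0.3, 0.8, 0.5, 0.9),
                         mother_rate_hz = 10,
                         background_rate_hz = c(2, 5, 8, 1))
  x <- generate_correlated_trains(cfg, 400, seed = 21)
  target <- cfg$copy_prob * 10 + cfg$background_rate_hz
  counts <- n_spikes(x$spikes)
  for (i in 1:4) {
    se <- sqrt(target[i] * 400)
    expect_lt(abs(counts[i] - target[i] * 400), 3 * se)
  }
})

test_that("empirical binned correlation matches the closed-form oracle", {
  # moderate run; the full-scale check lives in the acceptance suite
  cfg <- assembly_config(c(1, 1), copy_prob = 0.5, mother_rate_hz = 10,
                         background_rate_hz = 5)
  x <- generate_correlated_trains(cfg, 300, seed = 9)
  w <- data.frame(start_s = 0, end_s = 300, label = "all", event = 1L)
  m <- bin_counts(x$spikes, w, bin_s = 0.02, states = "all")$states$all
  expect_lt(abs(stats::cor(m[1, ], m[2, ]) - 0.25), 0.05)
})

test_that("increasing jitter monotonically attenuates fine-timescale r", {
  mean_r <- vapply(c(0, 5, 20), function(sig) {
    rs <- vapply(1:6, function(s) {
      cfg <- assembly_config(c(1, 1), copy_prob = 0.6, jitter_sd_ms = sig,
                             background_rate_hz = 3)
      x <- generate_correlated_trains(cfg, 120, seed = 100 + s)
      w <- data.frame(start_s = 0, end_s = 120, label = "all", event = 1L)
      m <- bin_counts(x$spikes, w, bin_s = 0.002, states = "all")$states$all
      stats::cor(m[1, ], m[2, ])
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(mean_r[1] > mean_r[2] && mean_r[2] > mean_r[3])
})

test_that("stimulus protocols produce the specified event geometry", {
  cfg <- session_config(seed = 1, n_units = 4)
  ses <- generate_session(cfg$assembly, cfg$modulation, cfg$tuning,
                          protocol = "ramp_hold", n_trials = 3, seed = 2,
                          start_s = 5)
  # 200 ms ramp-and-hold delivered at 0.5 Hz
  expect_equal(ses$events$onset_s, c(5.0, 7.0, 9.0))
  expect_equal(ses$events$offset_s, c(5.2, 7.2, 9.2))

  sesw <- generate_session(cfg$assembly, cfg$modulation, cfg$tuning,
                           protocol = "artificial_whisking", n_trials = 2,
                           seed = 2)
  # 10 protraction-retraction cycles at 5.5 Hz
  expect_equal(sesw$events$offset_s - sesw$events$onset_s,
               rep(10 / 5.5, 2), tolerance = 1e-9)

  # probe geometry: 50 um pitch from 200 um
  expect_equal(ses$meta$depth_um, 200 + 50 * ses$meta$contact_index)

  # condition/protocol mismatch
  expect_error(generate_session(cfg$assembly, cfg$modulation, cfg$tuning,
                                protocol = "artificial_whisking",
                                n_trials = 2, seed = 2, angles = c(0, 90)),
               "ramp-and-hold")
})

test_that("sessions are byte-reproducible from the seed", {
  cfg <- session_config(seed = 4, n_units = 6)
  a <- generate_session(cfg$assembly, cfg$modulation, cfg$tuning,
                        protocol = "ramp_hold", n_trials = 10, seed = 7)
  b <- generate_session(cfg$assembly, cfg$modulation, cfg$tuning,
                        protocol = "ramp_hold", n_trials = 10, seed = 7)
  expect_identical(a$spikes$spike_times, b$spikes$spike_times)
  expect_identical(a$events, b$events)
})

test_that("null modulation leaves evoked and spontaneous synchrony equal", {
  cfg <- session_config(seed = 3, gamma = 1, distance_penalty = 0,
                        incongruence_penalty = 0, evoked_gain_hz = 0)
  ses <- generate_session(cfg$assembly, cfg$modulation, cfg$tuning,
                          protocol = "artificial_whisking", n_trials = 120,
                          seed = 31)
  w <- make_state_windows(ses$events)
  pm <- pair_metrics(ses$spikes, w)
  gt <- ses$ground_truth$same_assembly_pairs
  key <- function(m) paste(m$unit_id_a, m$unit_id_b)
  sp <- pm[pm$state == "spontaneous", ]
  ev <- pm[pm$state == "evoked", ]
  same <- key(sp) %in% paste(gt$unit_id_a, gt$unit_id_b)
  # paired comparison across same-assembly pairs: any state difference is
  # bounded by the window-edge jitter leakage (short spontaneous windows
  # lose slightly more boundary coincidences), far below the 0.2
  # classification threshold
  d <- ev$pearson_r[same] - sp$pearson_r[same]
  expect_lt(abs(mean(d)), 0.02)
})

test_that("feature-cloud generator honours its contract", {
  a <- generate_feature_clusters(2, 50, rbind(c(0, 0), c(10, 0)),
                                 diag(2), seed = 5)
  b <- generate_feature_clusters(2, 50, rbind(c(0, 0), c(10, 0)),
                                 diag(2), seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 100)
  # degenerate: zero covariance reproduces the exact centers
  z <- generate_feature_clusters(2, 2, rbind(c(1, 2), c(3, 4)),
                                 matrix(0, 2, 2), seed = 1)
  expect_equal(unique(z$f1[z$unit_id == "c1"]), 1)
  expect_equal(unique(z$f2[z$unit_id == "c2"]), 4)
  expect_error(generate_feature_clusters(
    2, 10, rbind(c(0, 0), c(1, 1)),
    matrix(c(1, 1, 1, 1), 2, 2), seed = 1), "singular")
})
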