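test_that("effect sequences hit their target geometry", {
  # static: all patterns identical
  st <- make_effect_sequence(8, 50, "static", magnitude = 25, seed = 1)
  expect_equal(st$adjacent_cos, rep(1, 7))
  expect_equal(st$effects[1, ], st$effects[8, ])
  expect_equal(mean(abs(st$effects[1, ])), 25)

  # rotating with target cosine 0: adjacent cosines exactly 0
  r0 <- make_effect_sequence(8, 50, "rotating", rotation_cos = 0,
                             magnitude = 25, seed = 2)
  expect_true(all(abs(r0$adjacent_cos) < 0.01))

  # rotating with target cosine c: adjacent exactly c, lag-2 about c^2
  for (seed in 1:5) {
    r <- make_effect_sequence(8, 80, "rotating", rotation_cos = 0.5,
                              magnitude = 20, seed = seed)
    expect_equal(r$adjacent_cos, rep(0.5, 7), tolerance = 1e-10)
    lag2 <- vapply(1:6, function(w) {
      sum(r$patterns[w, ] * r$patterns[w + 2, ])
    }, numeric(1))
    expect_lt(abs(mean(lag2) - 0.25), 0.08)
  }

  # out-of-reach magnitudes are refused rather than clipped
  expect_error(make_effect_sequence(4, 3, "static", magnitude = 90,
                                    seed = 1),
               "-100")
})

test_that("simulation is exactly reproducible and conserves rates", {
  cfg <- sim_config(n_source = 4, n_target = 6, n_control = 30,
                    n_silencing_per_window = 8, seed = 99)
  s1 <- simulate_session(cfg)
  s2 <- simulate_session(cfg)
  expect_identical(s1$session$spikes, s2$session$spikes)
  expect_identical(s1$session$trials, s2$session$trials)

  # conservation: pre-stimulus rate of an unsilenced neuron matches its
  # configured baseline within Poisson error (pooled across neurons)
  cfg2 <- sim_config(n_source = 2, n_target = 30, n_control = 300,
                     n_silencing_per_window = 2, latent_rank = 0,
                     baseline_log_mean = log(8), baseline_log_sd = 0.3,
                     seed = 7)
  sim <- simulate_session(cfg2)
  pre <- window_counts(sim$session, -500, 500)
  rate_hat <- colMeans(pre$counts) / 0.5
  rel <- rate_hat / sim$truth$baseline_rates
  # per-neuron relative error ~ 1/sqrt(lambda * 150) < 3%
  expect_lt(max(abs(rel - 1)), 0.1)
  expect_lt(abs(mean(rel) - 1), 0.01)
})

test_that("silencing scales source and target rates as configured", {
  # total source suppression: zero source spikes inside the window
  cfg <- sim_config(n_source = 8, n_target = 4, n_control = 10,
                    n_silencing_per_window = 12,
                    source_silencing_factor = 0, seed = 3)
  sim <- simulate_session(cfg)
  x <- sim$session
  src <- x$neurons$neuron_id[x$neurons$area == "source"]
  for (w in c(1, 5, 8)) {
    sil_ids <- x$trials$trial_id[!is.na(x$trials$silencing_window) &
                                   x$trials$silencing_window == w]
    cm <- window_counts(x, x$silencing_onsets[w], 150,
                        trial_ids = sil_ids, neuron_ids = src)
    expect_true(all(cm$counts == 0))
  }
  # control trials keep source spikes
  ctrl_ids <- x$trials$trial_id[x$trials$condition == "control"]
  cm_c <- window_counts(x, 0, 150, trial_ids = ctrl_ids, neuron_ids = src)
  expect_gt(sum(cm_c$counts), 0)
})

test_that("independent-noise sessions show no trial-to-trial correlations", {
  cfg <- sim_config(n_source = 2, n_target = 12, n_control = 400,
                    n_silencing_per_window = 2, latent_rank = 0,
                    baseline_log_mean = log(10), seed = 13)
  x <- simulate_session(cfg)$session
  nc <- pairwise_noise_correlations(
    x, "go", neuron_ids = x$neurons$neuron_id[x$neurons$area == "target"]
  )
  expect_lt(abs(mean(nc$r)), 0.02)
})

test_that("behavioral generator matches its configured rates", {
  cfg <- sim_config(n_source = 2, n_target = 2, n_control = 5000,
                    n_silencing_per_window = 2,
                    hit_rate = 0.5, fa_rate = 0.5,
                    rt_shift_ms = 150, seed = 17)
  x <- simulate_session(cfg)$session
  bs <- behavior_summary(x)
  expect_lt(abs(bs$dprime), 0.06)
  # no lick before the shift
  expect_true(all(is.na(x$trials$lick_time_ms) |
                    x$trials$lick_time_ms >= 150))
})
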