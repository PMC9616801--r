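test_that("window counting is exact and half-open", {
  x <- tiny_session()
  cm <- window_counts(x, 0, 150)
  # neuron a, trial t1: spikes at 10, 60 in [0,150); 200 outside
  expect_equal(cm$counts[cm$trial_id == "t1", "a"][[1]], 2L)
  # spike exactly at 150 belongs to the next window
  expect_equal(cm$counts[cm$trial_id == "t2", "a"][[1]], 0L)
  cm2 <- window_counts(x, 150, 150)
  expect_equal(cm2$counts[cm2$trial_id == "t2", "a"][[1]], 1L)
  expect_equal(cm2$counts[cm2$trial_id == "t1", "a"][[1]], 1L)
  # pre-stimulus spikes are reachable
  pre <- window_counts(x, -500, 500)
  expect_equal(pre$counts[pre$trial_id == "t1", "b"][[1]], 1L)
})

test_that("disjoint windows tiling the stimulus partition its spikes", {
  sim <- static_sim()
  x <- sim$session
  total <- window_counts(x, 0, x$stimulus_duration)
  tiles <- lapply(seq(0, 400, by = 100), function(o) {
    window_counts(x, o, 100)$counts
  })
  expect_identical(Reduce(`+`, tiles), total$counts)
})

test_that("window errors: empty selection and out-of-range windows", {
  x <- tiny_session()
  expect_error(window_counts(x, 0, 150, trial_ids = "zz"), "empty trial")
  expect_error(window_counts(x, -900, 100), "outside recorded range")
  expect_error(window_counts(x, 600, 100), "outside recorded range")
})

test_that("session validation enforces the trial/condition contract", {
  x <- tiny_session()
  bad_trials <- x$trials
  bad_trials$silencing_window[1] <- 3L # control trial with a window
  expect_error(
    session(x$spikes, bad_trials, x$neurons),
    "control"
  )
  bad2 <- x$trials
  bad2$silencing_window[3] <- 99L
  expect_error(session(x$spikes, bad2, x$neurons), "1\\.\\.8")
  expect_error(
    session(x$spikes, x$trials, x$neurons, silencing_onsets = c(100, 50)),
    "strictly increasing"
  )
})

test_that("rate threshold masks low-rate neurons and is monotone", {
  x <- tiny_session()
  cm <- window_counts(x, 0, 150)
  # neuron a: mean 0.75 spikes / 150 ms = 5 Hz; neuron b: 0 Hz here
  m1 <- apply_rate_threshold(cm, 2.5)
  expect_true(all(m1$mask[, "a"]))
  expect_false(any(m1$mask[, "b"]))
  # threshold 0 masks nothing
  m0 <- apply_rate_threshold(cm, 0)
  expect_true(all(m0$mask))
  # monotone: every entry masked at 2.5 Hz stays masked at 10 Hz
  m2 <- apply_rate_threshold(cm, 10)
  expect_true(all(m2$mask[!m1$mask] == FALSE))
})

test_that("responsive-neuron filter keeps driven cells, drops silent ones", {
  # simulated neurons with 3x stimulus gain are detected essentially always
  cfg <- sim_config(
    n_source = 2, n_target = 12, n_control = 50,
    n_silencing_per_window = 5,
    baseline_log_mean = log(5), baseline_log_sd = 0.2,
    stim_gain_log_mean = log(3), stim_gain_log_sd = 0.05,
    latent_rank = 0, seed = 11
  )
  x <- simulate_session(cfg)$session
  resp <- select_responsive_neurons(x)
  tgt <- x$neurons$neuron_id[x$neurons$area == "target"]
  expect_gte(length(intersect(resp, tgt)), 11)

  # a neuron with no spikes at all is excluded
  trials <- tibble::tibble(
    trial_id = sprintf("t%d", 1:8),
    stimulus = rep(c("go", "nogo"), 4),
    condition = "control",
    silencing_window = NA_integer_,
    lick_time_ms = NA_real_
  )
  spikes <- tidyr::expand_grid(trial_id = trials$trial_id, k = 1:4) |>
    dplyr::mutate(neuron_id = "a", t_ms = 100 + 10 * k) |>
    dplyr::select("neuron_id", "trial_id", "t_ms")
  x2 <- session(spikes, trials,
                tibble::tibble(neuron_id = c("a", "b"),
                               area = c("target", "target")))
  expect_false("b" %in% select_responsive_neurons(x2))
})

test_that("balanced subsampling equalizes groups without duplication", {
  tr <- tibble::tibble(
    trial_id = sprintf("t%02d", 1:95),
    stimulus = rep(c("go", "nogo"), c(40, 55))
  )
  out <- subsample_balanced(tr, "stimulus", seed = 5)
  expect_equal(unname(table(out$stimulus)), c(40L, 40L),
               ignore_attr = TRUE)
  expect_false(anyDuplicated(out$trial_id) > 0)
  # identity case
  tr2 <- tibble::tibble(trial_id = as.character(1:40),
                        g = rep(letters[1:4], each = 10))
  expect_equal(nrow(subsample_balanced(tr2, "g", seed = 1)), 40)
  # determinism contract
  s1 <- subsample_balanced(tr, "stimulus", seed = 7)
  s2 <- subsample_balanced(tr, "stimulus", seed = 7)
  s3 <- subsample_balanced(tr, "stimulus", seed = 8)
  expect_identical(s1, s2)
  expect_false(identical(s1, s3))
  # required group missing
  expect_error(subsample_balanced(tr, "stimulus", required = "catch"),
               "catch")
})

test_that("session inclusion gate: control-trial count and chance behavior", {
  cfg <- sim_config(n_source = 3, n_target = 6, n_control = 9,
                    n_silencing_per_window = 3, seed = 21)
  x <- simulate_session(cfg)$session
  inc <- include_session(x, check_behavior = FALSE)
  expect_false(inc$include)
  expect_match(inc$reason, "control trial count")

  # chance-level behavior (hit rate == false-alarm rate) is excluded
  cfg2 <- sim_config(n_source = 3, n_target = 6, n_control = 100,
                     n_silencing_per_window = 12,
                     hit_rate = 0.5, fa_rate = 0.5, seed = 22)
  x2 <- simulate_session(cfg2)$session
  inc2 <- include_session(x2, n_shuffles = 1000, seed = 1)
  expect_false(inc2$include)

  # clearly above-chance behavior is included
  x3 <- static_sim()$session
  inc3 <- include_session(x3, n_shuffles = 1000, seed = 1)
  expect_true(inc3$include)
})

test_that("sessions round-trip through the plain-text container", {
  x <- static_sim()$session
  dir <- withr::local_tempdir()
  write_session(x, dir)
  y <- read_session(dir)
  expect_equal(y$trials$stimulus, x$trials$stimulus)
  expect_equal(y$silencing_onsets, x$silencing_onsets)
  cm_x <- window_counts(x, 0, 150)
  cm_y <- window_counts(y, 0, 150)
  expect_identical(cm_x$counts, cm_y$counts)
})
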