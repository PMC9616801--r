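test_that("percent change follows its defining formula", {
  expect_equal(percent_change(2, 4), -50)
  expect_equal(percent_change(4, 4), 0)
  expect_equal(percent_change(6, 4), 50)
  expect_true(is.na(percent_change(3, 0)))
})

test_that("bootstrap effect significance behaves at the extremes", {
  # identical constant counts: observed 0, never significant
  res <- effect_significance(rep(3L, 20), rep(3L, 20), n_boot = 200,
                             seed = 1)
  expect_equal(res$percent_change, 0)
  expect_false(res$significant)

  # planted -90% effect at decent rates: always significant
  set.seed(2)
  sig <- replicate(30, {
    ctrl <- rpois(50, 3)
    sil <- rpois(50, 0.3)
    effect_significance(ctrl, sil, n_boot = 500,
                        seed = sample.int(1e6, 1))$significant
  })
  expect_true(all(sig))

  # all-zero control counts are masked
  res0 <- effect_significance(rep(0L, 10), rpois(10, 1), n_boot = 100,
                              seed = 3)
  expect_true(is.na(res0$percent_change))

  # bootstrap null is centered near zero
  set.seed(4)
  meds <- replicate(20, {
    ctrl <- rpois(60, 4)
    r <- effect_significance(ctrl, rpois(60, 4), n_boot = 500,
                             seed = sample.int(1e6, 1))
    (r$ci_lo + r$ci_hi) / 2
  })
  expect_lt(abs(mean(meds)), 3)
})

test_that("Bonferroni significance implies raw significance", {
  set.seed(5)
  res <- purrr::map_dfr(1:200, function(i) {
    ctrl <- rpois(40, 3)
    sil <- rpois(40, 3 * runif(1, 0.3, 1.4))
    effect_significance(ctrl, sil, n_boot = 400, seed = i)
  })
  expect_true(all(!res$significant_bonf | res$significant))
})

test_that("planted multiplicative effects are recovered from sessions", {
  # constant -50% on every target neuron; estimator pooled over windows
  n_t <- 10
  ev <- matrix(-50, 8, n_t)
  cfg <- sim_config(n_source = 2, n_target = n_t, n_control = 400,
                    n_silencing_per_window = 50, latent_rank = 0,
                    baseline_log_mean = log(8), baseline_log_sd = 0.2,
                    effect_vectors = ev, seed = 31)
  x <- simulate_session(cfg)$session
  tgt <- x$neurons$neuron_id[x$neurons$area == "target"]
  eff <- effect_table(x, neuron_ids = tgt, n_boot = 100, seed = 1)
  est <- mean(eff$percent_change, na.rm = TRUE)
  expect_lt(abs(est + 50), 3)
})

test_that("window-restricted effects give the right significant-window count", {
  # strong suppression planted only in windows 3-4
  n_t <- 8
  ev <- matrix(0, 8, n_t)
  ev[3:4, ] <- -85
  cfg <- sim_config(n_source = 2, n_target = n_t, n_control = 150,
                    n_silencing_per_window = 60, latent_rank = 0,
                    baseline_log_mean = log(10), baseline_log_sd = 0.2,
                    effect_vectors = ev, seed = 33)
  x <- simulate_session(cfg)$session
  tgt <- x$neurons$neuron_id[x$neurons$area == "target"]
  eff <- effect_table(x, neuron_ids = tgt, n_boot = 400, seed = 2)
  cnt <- count_significant_windows(eff)
  expect_equal(unname(stats::median(cnt$n_significant_windows)), 2)
})

test_that("selectivity indices reproduce their closed forms", {
  # synthetic session with controlled outcome rates: build by hand
  trials <- tibble::tibble(
    trial_id = sprintf("t%02d", 1:40),
    stimulus = rep(c("go", "nogo"), each = 20),
    condition = "control",
    silencing_window = NA_integer_,
    lick_time_ms = c(rep(300, 10), rep(NA, 10), rep(300, 10), rep(NA, 10))
  )
  # neuron fires 3 spikes in hits (first 150 ms), 1 in correct rejections
  hit_ids <- trials$trial_id[1:10]
  cr_ids <- trials$trial_id[31:40]
  spikes <- dplyr::bind_rows(
    tidyr::expand_grid(neuron_id = "n1", trial_id = hit_ids, k = 1:3) |>
      dplyr::mutate(t_ms = 50 + k),
    tidyr::expand_grid(neuron_id = "n1", trial_id = cr_ids, k = 1) |>
      dplyr::mutate(t_ms = 60)
  )[, c("neuron_id", "trial_id", "t_ms")]
  x <- session(spikes, trials,
               tibble::tibble(neuron_id = "n1", area = "target"))
  si <- selectivity_indices(x)
  # rH = 3, rC = 1 -> stimulus index 0.5, preferred +1
  expect_equal(si$stimulus_index, 0.5)
  expect_equal(si$preferred_stimulus, 1)
  # RH > 0, RM = 0, RF = 0, RC > 0 -> terms 1 and -1 -> choice index 0
  expect_equal(si$choice_index, 0)
})
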