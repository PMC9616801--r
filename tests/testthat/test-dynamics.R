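test_that("decay fit recovers noiseless parameters exactly", {
  t <- seq(0, 455, by = 65)
  y <- 1 * (exp(-t / 100) + 0.2)
  f <- fit_decay(t, y, n_boot = 0)
  expect_equal(f$A, 1, tolerance = 1e-6)
  expect_equal(f$tau, 100, tolerance = 1e-4)
  expect_equal(f$B, 0.2, tolerance = 1e-5)
  expect_true(f$converged)
})

test_that("decay fit flags degenerate constant profiles", {
  t <- seq(0, 455, by = 65)
  f <- fit_decay(t, rep(0.5, length(t)), n_boot = 0)
  expect_false(f$converged)
  expect_error(fit_decay(c(0, 65, 130), c(1, 0.5, 0.3)), "4 distinct lags")
})

test_that("near-linear regimes agree with the linear closed form", {
  # for t << tau, y ~ A(1 + B) - (A/tau) t: the fitted curve should track
  # the generating line over the sampled range
  t <- seq(0, 455, by = 65)
  y <- 1 * (exp(-t / 5000) + 0.2)
  f <- fit_decay(t, y, n_boot = 0)
  pred <- commdyn:::decay_predict(f, t)
  expect_lt(max(abs(pred - y)), 1e-6)
  # initial slope of the fitted curve matches -A/tau ~ the linear slope
  lin <- stats::lm(y ~ t)
  expect_equal(-f$A / f$tau, unname(stats::coef(lin)[2]), tolerance = 0.05)
})

test_that("bootstrap CI covers the true decay constant at nominal rate", {
  # moderate check at 150 profiles; the acceptance suite runs 500
  set.seed(33)
  t <- seq(0, 455, by = 65)
  cover <- vapply(1:150, function(i) {
    y <- 1 * (exp(-t / 120) + 0.2) + rnorm(length(t), 0, 0.05)
    f <- fit_decay(t, y, method = "grid", n_boot = 100,
                   seed = sample.int(1e6, 1))
    ci <- f$ci[f$ci$term == "tau", ]
    ci$conf_low <= 120 && 120 <= ci$conf_high
  }, logical(1))
  expect_gt(mean(cover), 0.88)
  expect_lt(mean(cover), 1)
})

test_that("initial slope reads lag 0 to lag 1", {
  expect_equal(initial_slope(c(0.8, 0.6, 0.5)), -0.2)
  expect_equal(initial_slope(rep(0.4, 5)), 0)
  pr <- tibble::tibble(lag = 0:3, similarity = c(0.9, 0.7, 0.6, 0.55))
  expect_equal(initial_slope(pr), -0.2)
})

test_that("permutation test guards and p-value floor", {
  x <- static_sim()$session
  expect_error(permutation_test_tau(x, n_perm = 0), "n_perm")
  pt <- permutation_test_tau(x, n_perm = 9, n_splits = 2, seed = 1)
  expect_gte(pt$p_value, 1 / 10)
  expect_lte(pt$p_value, 1)
  expect_equal(pt$n_perm_used + pt$n_dropped, 9)
})

test_that("autocorrelation vanishes for trial-constant rates", {
  # deterministic rate profile + Poisson emission: no across-trial
  # covariance at positive lags
  cfg <- sim_config(n_source = 2, n_target = 8, n_control = 600,
                    n_silencing_per_window = 2, latent_rank = 0,
                    baseline_log_mean = log(12), seed = 71)
  x <- simulate_session(cfg)$session
  tgt <- x$neurons$neuron_id[x$neurons$area == "target"]
  ac <- spike_autocorrelation(x, neuron_ids = tgt, seed = 1)
  pos <- ac[ac$lag > 0, ]
  expect_lt(max(abs(pos$r)), 0.12)
  expect_lt(abs(mean(pos$r)), 0.02)
  # identical counts across bins within trial -> r = 1 at all lags
  trials <- tibble::tibble(trial_id = sprintf("t%02d", 1:30),
                           stimulus = rep(c("go", "nogo"), 15),
                           condition = "control",
                           silencing_window = NA_integer_,
                           lick_time_ms = NA_real_)
  spikes <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    k <- i %% 5 + 1 # trial-varying count, constant across bins
    tibble::tibble(neuron_id = "a", trial_id = trials$trial_id[i],
                   t_ms = as.vector(outer(seq(10, 60, length.out = k),
                                          seq(0, 455, 65), `+`)))
  })
  x2 <- session(spikes, trials,
                tibble::tibble(neuron_id = "a", area = "target"))
  ac2 <- spike_autocorrelation(x2, neuron_ids = "a", seed = 1)
  expect_true(all(ac2$r > 0.999))
})

test_that("correlations match the doubly-stochastic Poisson oracle", {
  # shared log-normal latent factor across two bins/neurons:
  # counts N_i ~ Pois(mu exp(s z - s^2/2)); law of total covariance gives
  # cov = mu^2 (exp(s^2) - 1), var = mu + mu^2 (exp(s^2) - 1)
  mu <- 1.2
  s <- 0.4
  rho_oracle <- mu^2 * (exp(s^2) - 1) /
    (mu + mu^2 * (exp(s^2) - 1))
  set.seed(77)
  n <- 2e4
  z <- rnorm(n)
  lam <- mu * exp(s * z - s^2 / 2)
  n1 <- rpois(n, lam)
  n2 <- rpois(n, lam)
  expect_lt(abs(cor(n1, n2) - rho_oracle), 0.02)

  # the same structure through the simulator + estimators: one trial-level
  # latent factor, loadings from the exported ground truth, bins aligned
  # with the 65-ms window grid
  cfg <- sim_config(n_source = 2, n_target = 8, n_control = 1500,
                    n_silencing_per_window = 2,
                    baseline_log_mean = log(12), baseline_log_sd = 0,
                    stim_gain_log_mean = 0, stim_gain_log_sd = 0,
                    temporal_envelope = rep(1, 8),
                    silencing_onsets = seq(0, 455, by = 65),
                    latent_rank = 1, latent_strengths = 1.2,
                    seed = 72)
  sim <- simulate_session(cfg)
  x <- sim$session
  tgt <- x$neurons$neuron_id[x$neurons$area == "target"]
  L <- sim$truth$latent_loadings[[1]][, 1]
  names(L) <- x$neurons$neuron_id
  mu <- 12 * 0.065 # counts per 65-ms bin (baseline, unit gain/envelope)
  var_o <- function(i) mu + mu^2 * (exp(L[i]^2) - 1)
  cov_o <- function(i, j) mu^2 * (exp(L[i] * L[j]) - 1)

  # noise correlations per pair vs oracle
  nc <- pairwise_noise_correlations(x, "go", neuron_ids = tgt) |>
    dplyr::group_by(neuron_i, neuron_j) |>
    dplyr::summarise(r = mean(r), .groups = "drop")
  r_oracle <- purrr::map2_dbl(nc$neuron_i, nc$neuron_j, function(i, j) {
    cov_o(i, j) / sqrt(var_o(i) * var_o(j))
  })
  expect_lt(mean(abs(nc$r - r_oracle)), 0.03)
  expect_gt(stats::cor(nc$r, r_oracle), 0.9)

  # autocorrelations at positive lags share the same oracle (the latent
  # coordinate is constant within a trial)
  ac <- spike_autocorrelation(x, neuron_ids = tgt, seed = 2) |>
    dplyr::filter(lag > 0) |>
    dplyr::group_by(neuron_id) |>
    dplyr::summarise(r = mean(r), .groups = "drop")
  ac_oracle <- vapply(ac$neuron_id, function(i) {
    mu^2 * (exp(L[i]^2) - 1) / var_o(i)
  }, numeric(1))
  expect_lt(mean(abs(ac$r - ac_oracle)), 0.03)
})
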