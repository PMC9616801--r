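# brute-force oracle: explicit shrunken covariance and linear solve via QR
oracle_lda <- function(a, b, gamma) {
  na <- nrow(a)
  nb <- nrow(b)
  S <- ((na - 1) * stats::cov(a) + (nb - 1) * stats::cov(b)) / (na + nb - 2)
  Sg <- (1 - gamma) * S + gamma * diag(diag(S), ncol(S))
  w <- qr.solve(Sg, colMeans(a) - colMeans(b))
  w / sqrt(sum(w^2))
}

test_that("regularized LDA matches hand-computable cases", {
  # identity covariance: direction = normalized mean difference
  set.seed(1)
  z <- matrix(rnorm(400), 200, 2)
  a <- sweep(z, 2, c(1, 0), `+`)
  b <- matrix(rnorm(400), 200, 2)
  w <- regularized_lda_direction(a, b, gamma = 1, delta = 0)
  # gamma = 1: diagonal covariance, elementwise division oracle
  S <- commdyn:::pooled_covariance(a, b)
  w_o <- (colMeans(a) - colMeans(b)) / diag(S)
  expect_equal(w, w_o / sqrt(sum(w_o^2)), tolerance = 1e-12)

  # diag(1,4) covariance with dmu = (1,2) gives (0.8944, 0.4472)
  set.seed(2)
  n <- 2e5
  a2 <- cbind(rnorm(n, 1, 1), rnorm(n, 2, 2))
  b2 <- cbind(rnorm(n, 0, 1), rnorm(n, 0, 2))
  w2 <- regularized_lda_direction(a2, b2, gamma = 0, delta = 0)
  expect_equal(w2, c(0.8944, 0.4472), tolerance = 0.01)
})

test_that("LDA equals the brute-force solve oracle on random instances", {
  set.seed(42)
  for (i in 1:200) {
    p <- sample(2:8, 1)
    n <- sample((p + 2):30, 1)
    gamma <- runif(1)
    a <- matrix(rnorm(n * p), n, p) %*% matrix(rnorm(p * p), p, p)
    b <- matrix(rnorm(n * p), n, p)
    expect_equal(regularized_lda_direction(a, b, gamma, 0),
                 oracle_lda(a, b, gamma), tolerance = 1e-8)
  }
})

test_that("LDA is equivariant under neuron permutation", {
  set.seed(3)
  a <- matrix(rnorm(120), 20, 6)
  b <- matrix(rnorm(120), 20, 6) + 0.5
  w <- regularized_lda_direction(a, b, 0.3, 0)
  perm <- sample(6)
  wp <- regularized_lda_direction(a[, perm], b[, perm], 0.3, 0)
  expect_equal(wp, w[perm], tolerance = 1e-12)
})

test_that("delta zeroes small coefficients and can empty the vector", {
  set.seed(4)
  a <- cbind(rnorm(50, 2), rnorm(50, 0.01))
  b <- cbind(rnorm(50, 0), rnorm(50, 0))
  w <- regularized_lda_direction(a, b, 0.5, delta = 0.5)
  expect_equal(w[2], 0)
  expect_equal(sqrt(sum(w^2)), 1)
  # singular covariance at gamma = 0 is diagnosed
  one <- matrix(rep(c(1, 2), each = 6), 6, 2) # perfectly collinear
  expect_error(regularized_lda_direction(one, one + 1, 0, 0), "gamma")
})

test_that("parameter tuning prefers shrinkage when trials are scarce", {
  # n_trials < n_neurons with a planted mean shift: gamma > 0 should win
  set.seed(5)
  hits <- replicate(10, {
    p <- 20
    a <- matrix(rnorm(15 * p), 15, p) + 0.8
    b <- matrix(rnorm(15 * p), 15, p)
    tuned <- tune_lda_params(a, b, gamma_grid = c(0.05, 0.3, 0.7, 1),
                             delta_grid = 0, k = 5,
                             seed = sample.int(1e6, 1))
    tuned$gamma > 0.05
  })
  expect_gte(mean(hits), 0.6)

  # identical classes: test error is near chance everywhere
  set.seed(6)
  a <- matrix(rnorm(200), 50, 4)
  b <- matrix(rnorm(200), 50, 4)
  tuned <- tune_lda_params(a, b, seed = 1)
  expect_gt(tuned$test_error, 0.3)

  # perfectly separable classes: zero error, smallest gamma/delta win ties
  a2 <- matrix(rnorm(100), 25, 4) + 10
  b2 <- matrix(rnorm(100), 25, 4)
  tuned2 <- tune_lda_params(a2, b2, gamma_grid = c(0.1, 0.5),
                            delta_grid = c(0, 0.1), seed = 2)
  expect_equal(tuned2$test_error, 0)
  expect_equal(tuned2$gamma, 0.1)
  expect_equal(tuned2$delta, 0)
})

test_that("stimulus decoding collapses when silencing erases the signal", {
  # target neurons have distinct go/no-go gains; silencing the source is
  # simulated by strong target suppression, pushing decoding toward chance
  cfg <- sim_config(n_source = 4, n_target = 25, n_control = 120,
                    n_silencing_per_window = 40,
                    baseline_log_mean = log(10), baseline_log_sd = 0.3,
                    stim_gain_log_sd = 0.6, latent_rank = 0,
                    effect_vectors = matrix(-95, 8, 25),
                    hit_rate = 0.95, fa_rate = 0.05, seed = 51)
  x <- simulate_session(cfg)$session
  tgt <- x$neurons$neuron_id[x$neurons$area == "target"]
  dec <- stimulus_decoder(x, gamma = 0.5, n_splits = 10, seed = 1,
                          neuron_ids = tgt)
  expect_gt(mean(dec$per_window$accuracy_control), 0.85)
  expect_lt(mean(dec$per_window$accuracy_silencing), 0.65)

  # null effect: control and silencing accuracies agree
  cfg0 <- sim_config(n_source = 4, n_target = 25, n_control = 120,
                     n_silencing_per_window = 40,
                     baseline_log_mean = log(10), baseline_log_sd = 0.3,
                     stim_gain_log_sd = 0.6, latent_rank = 0,
                     effect_vectors = matrix(0, 8, 25),
                     hit_rate = 0.95, fa_rate = 0.05, seed = 52)
  x0 <- simulate_session(cfg0)$session
  dec0 <- stimulus_decoder(x0, gamma = 0.5, n_splits = 10, seed = 1,
                           neuron_ids = tgt)
  expect_lt(abs(mean(dec0$per_window$accuracy_control) -
                  mean(dec0$per_window$accuracy_silencing)), 0.1)
})
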