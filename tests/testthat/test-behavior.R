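test_that("trial outcomes follow the response-window rule", {
  x <- classify_trials(tiny_session())
  oc <- x$trials$outcome
  expect_equal(oc[x$trials$trial_id == "t1"], "hit")
  expect_equal(oc[x$trials$trial_id == "t2"], "correct_rejection")
  # lick at 50 ms precedes the window: miss
  expect_equal(oc[x$trials$trial_id == "t3"], "miss")
  expect_equal(oc[x$trials$trial_id == "t4"], "correct_rejection")
})

test_that("d-prime matches the quantile closed form and is antisymmetric", {
  expect_equal(dprime(0.8, 0.2), qnorm(0.8) - qnorm(0.2), tolerance = 1e-6)
  expect_equal(dprime(0.8, 0.2), 1.6832, tolerance = 1e-4)
  expect_equal(dprime(0.9, 0.1), 2.5631, tolerance = 1e-4)
  expect_equal(dprime(0.5, 0.5), 0)
  for (h in c(0.3, 0.6, 0.9)) {
    expect_equal(dprime(h, 0.2), -dprime(0.2, h))
  }
  # boundary rates stay finite via 1/(2N) clipping
  expect_true(is.finite(dprime(1, 0, n_go = 50, n_nogo = 50)))
})

test_that("shuffle chance level calibrates to its nominal 1% rate", {
  # stimulus-independent licking: observed d' exceeds the 99th-percentile
  # null in about 1% of sessions
  above <- vapply(1:120, function(i) {
    cfg <- sim_config(n_source = 2, n_target = 2, n_control = 100,
                      n_silencing_per_window = 12,
                      hit_rate = 0.5, fa_rate = 0.5, seed = 7000 + i)
    x <- simulate_session(cfg)$session
    bs <- behavior_summary(x)
    ch <- dprime_chance(x, n_shuffles = 400, seed = 100 + i)
    bs$dprime > ch
  }, logical(1))
  expect_lte(mean(above), 0.05)

  # deterministic perfect performance always clears chance
  cfg <- sim_config(n_source = 2, n_target = 2, n_control = 80,
                    n_silencing_per_window = 10,
                    hit_rate = 1, fa_rate = 0, seed = 5)
  x <- simulate_session(cfg)$session
  expect_gt(behavior_summary(x)$dprime,
            dprime_chance(x, n_shuffles = 500, seed = 2))
})

test_that("onset correction drops trials licking before the window onset", {
  cfg <- sim_config(n_source = 2, n_target = 4, n_control = 60,
                    n_silencing_per_window = 30, seed = 9)
  x <- classify_trials(simulate_session(cfg)$session)
  om <- onset_corrected_metrics(x, seed = 3)
  pw <- om$per_window
  # assertable rule: corrected cells only use licks after the onset; the
  # mean corrected RT in late windows must exceed the onset
  late <- pw[pw$corrected & pw$window == 8 & !is.na(pw$rt_ms), ]
  expect_true(all(late$rt_ms > x$silencing_onsets[8]))
  # all RTs equal -> zero percent change everywhere it is defined
  x2 <- x
  x2$trials$lick_time_ms[!is.na(x2$trials$lick_time_ms)] <- 300
  x2$trials$outcome <- NULL
  x2 <- classify_trials(x2)
  om2 <- onset_corrected_metrics(x2, seed = 3)
  expect_true(all(abs(stats::na.omit(om2$per_window$rt_pct_change)) < 1e-9))
})

test_that("planted early RT slowdown appears in the early contrast only", {
  cfg <- sim_config(n_source = 2, n_target = 4, n_control = 300,
                    n_silencing_per_window = 150,
                    silencing_rt_shift_ms = 60,
                    silencing_rt_windows = 1:2,
                    hit_rate = 0.85, fa_rate = 0.1, seed = 41)
  x <- classify_trials(simulate_session(cfg)$session)
  om <- onset_corrected_metrics(x, seed = 11)
  el <- om$early_late[om$early_late$corrected, ]
  ctr <- function(ep) {
    el$rt_pct_change[el$epoch == ep & el$condition == "silencing"] -
      el$rt_pct_change[el$epoch == ep & el$condition == "control"]
  }
  # late-window cells have few onset-qualifying licks, so only require the
  # contrast to be clearly concentrated in the early epoch
  expect_gt(ctr("early"), 5)
  expect_lt(ctr("late"), ctr("early") - 3)
})
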