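# Shared fixtures: tiny hand-built session and cached simulated sessions.

# A deterministic 2-neuron, 4-trial session for exact windowing checks.
tiny_session <- function() {
  session(
    spikes = tibble::tibble(
      neuron_id = c("a", "a", "a", "a", "b", "b"),
      trial_id = c("t1", "t1", "t1", "t2", "t1", "t3"),
      t_ms = c(10, 60, 200, 150, -100, 499.5)
    ),
    trials = tibble::tibble(
      trial_id = c("t1", "t2", "t3", "t4"),
      stimulus = c("go", "nogo", "go", "nogo"),
      condition = c("control", "control", "silencing", "silencing"),
      silencing_window = c(NA, NA, 1L, 2L),
      lick_time_ms = c(300, NA, 50, NA)
    ),
    neurons = tibble::tibble(
      neuron_id = c("a", "b"),
      area = c("target", "source")
    )
  )
}

# memoised simulated sessions so several test files can share one
sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, cfg) {
  if (!exists(key, envir = sim_cache)) {
    assign(key, simulate_session(cfg), envir = sim_cache)
  }
  get(key, envir = sim_cache)
}

# mid-sized session with static effects used across direction tests
static_sim <- function() {
  cached_sim("static", sim_config(
    n_source = 10, n_target = 20, n_control = 60,
    n_silencing_per_window = 30, seed = 401
  ))
}
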