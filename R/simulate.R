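#' Configuration of the synthetic two-area session simulator
#'
#' The simulator emulates the statistical structure the pipeline assumes: two
#' areas of Poisson-spiking neurons driven by log-normal baseline rates,
#' per-stimulus multiplicative gains, a slow shared temporal envelope, and a
#' low-rank log-rate latent factor producing trial-to-trial noise
#' correlations. On silencing trials, source-area rates are scaled down to a
#' residual fraction during the silencing window and target-area rates are
#' scaled by per-neuron percent-change effect vectors that are either static
#' across silencing windows or rotate at a controlled adjacent-window cosine.
#' Go/no-go lick behavior is drawn from hit/false-alarm rates with a shifted
#' log-normal reaction-time distribution.
#'
#' Defaults mirror the in-vivo design this pipeline targets: ~97 control and
#' 78 silencing trials per window, a 500-ms stimulus, 150-ms silencing pulses
#' at 8 onsets tiling the stimulus in ~65-ms steps, near-complete source
#' suppression (residual fraction 0.05), and behavior around d-prime 1.7.
#'
#' @param n_source,n_target Neuron counts in the silenced (source) and
#'   recorded-effect (target) area.
#' @param n_control Number of control trials.
#' @param n_silencing_per_window Silencing trials per window.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of
#'   per-neuron baseline rates (Hz).
#' @param stim_gain_log_mean,stim_gain_log_sd Log-normal parameters of
#'   per-neuron, per-stimulus multiplicative stimulus gains.
#' @param temporal_envelope Per-window rate multiplier shared by all neurons;
#'   default a mild onset transient decaying from 1.3 to 0.9.
#' @param latent_rank Number of latent log-rate factors (0 disables them).
#' @param latent_strengths Vector norms of the factor loadings (recycled to
#'   `latent_rank`); loading direction is random over neurons.
#' @param latent_rotation_rad Radians by which the first factor's loading
#'   direction rotates from one window to the next (plants PC rotation).
#' @param effect_mode `"static"` (one effect vector for all windows) or
#'   `"rotating"`; may be a named vector `c(go = , nogo = )`.
#' @param effect_rotation_cos Target cosine between adjacent-window effect
#'   patterns in rotating mode; may be named per stimulus.
#' @param effect_magnitude Mean absolute percent change over target neurons.
#' @param effect_vectors Optional explicit effect matrix (windows x target
#'   neurons, percent change), or a named list with `go` and `nogo`
#'   matrices; overrides the generated sequences.
#' @param source_silencing_factor Residual fraction of source-area rate
#'   during the silencing window (0.05 emulates ~-95% suppression).
#' @param hit_rate,fa_rate Lick probabilities on go / no-go trials.
#' @param rt_meanlog,rt_sdlog,rt_shift_ms Shifted log-normal reaction-time
#'   parameters (ms); licks are truncated to >= 100 ms.
#' @param silencing_rt_shift_ms Additive RT shift (ms) on silencing trials.
#' @param silencing_rt_windows Window indices receiving the RT shift
#'   (default all).
#' @param stimulus_duration,silencing_duration,silencing_onsets,pre_window
#'   Timing parameters, ms (see [session()]).
#' @param seed Master seed; every stream of randomness derives from it.
#' @return A `commdyn_sim_config` list.
#' @export
sim_config <- function(n_source = 40, n_target = 35,
                       n_control = 97, n_silencing_per_window = 78,
                       baseline_log_mean = log(5), baseline_log_sd = 0.5,
                       stim_gain_log_mean = log(1.6), stim_gain_log_sd = 0.4,
                       temporal_envelope = NULL,
                       latent_rank = 3,
                       latent_strengths = c(0.6, 0.4, 0.3),
                       latent_rotation_rad = 0,
                       effect_mode = "static",
                       effect_rotation_cos = 0.2,
                       effect_magnitude = 25,
                       effect_vectors = NULL,
                       source_silencing_factor = 0.05,
                       hit_rate = 0.75, fa_rate = 0.15,
                       rt_meanlog = log(180), rt_sdlog = 0.35,
                       rt_shift_ms = 100,
                       silencing_rt_shift_ms = 0,
                       silencing_rt_windows = NULL,
                       stimulus_duration = 500,
                       silencing_duration = 150,
                       silencing_onsets = c(0, 56, 123, 189, 256, 323, 390, 456),
                       pre_window = 500,
                       seed = 1) {
  n_windows <- length(silencing_onsets)
  if (is.null(temporal_envelope)) {
    temporal_envelope <- seq(1.3, 0.9, length.out = n_windows)
  }
  stopifnot(length(temporal_envelope) == n_windows,
            all(temporal_envelope > 0),
            hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1,
            all(abs(effect_rotation_cos) <= 1),
            source_silencing_factor >= 0,
            baseline_log_sd >= 0, latent_rank >= 0)
  per_stim <- function(x) {
    if (length(x) == 1) {
      c(go = unname(x[1]), nogo = unname(x[1]))
    } else {
      stopifnot(all(c("go", "nogo") %in% names(x)))
      x[c("go", "nogo")]
    }
  }
  cfg <- list(
    n_source = n_source, n_target = n_target,
    n_control = n_control,
    n_silencing_per_window = n_silencing_per_window,
    baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
    stim_gain_log_mean = stim_gain_log_mean,
    stim_gain_log_sd = stim_gain_log_sd,
    temporal_envelope = temporal_envelope,
    latent_rank = latent_rank,
    latent_strengths = rep_len(latent_strengths, max(latent_rank, 1)),
    latent_rotation_rad = latent_rotation_rad,
    effect_mode = per_stim(effect_mode),
    effect_rotation_cos = per_stim(effect_rotation_cos),
    effect_magnitude = effect_magnitude,
    effect_vectors = effect_vectors,
    source_silencing_factor = source_silencing_factor,
    hit_rate = hit_rate, fa_rate = fa_rate,
    rt_meanlog = rt_meanlog, rt_sdlog = rt_sdlog, rt_shift_ms = rt_shift_ms,
    silencing_rt_shift_ms = silencing_rt_shift_ms,
    silencing_rt_windows = silencing_rt_windows %||% seq_len(n_windows),
    stimulus_duration = stimulus_duration,
    silencing_duration = silencing_duration,
    silencing_onsets = silencing_onsets,
    pre_window = pre_window,
    seed = seed
  )
  structure(cfg, class = "commdyn_sim_config")
}

# standard-normal draws truncated to |z| <= 2.5; keeps scaled percent-change
# patterns away from the -100% boundary
rtnorm <- function(n, bound = 2.5) {
  z <- stats::rnorm(n)
  while (any(bad <- abs(z) > bound)) {
    z[bad] <- stats::rnorm(sum(bad))
  }
  z
}

#' Per-window silencing-effect vector sequence
#'
#' Builds the sequence of per-target-neuron percent-change effect patterns
#' whose dynamics the communication-direction analysis estimates. In
#' `"static"` mode every window shares one pattern. In `"rotating"` mode
#' unit patterns form a Markov rotation: each next pattern equals
#' `cos * previous + sqrt(1 - cos^2) * q` with `q` a fresh random unit vector
#' orthogonal to the previous pattern, so the adjacent-window cosine is
#' exactly the target and the lag-`k` cosine is approximately `cos^k`.
#' Patterns are scaled so the mean absolute percent change equals
#' `effect_magnitude`.
#'
#' @param n_windows Number of silencing windows.
#' @param n_target Number of target neurons (>= 2).
#' @param mode `"static"` or `"rotating"`.
#' @param rotation_cos Target adjacent-window cosine (rotating mode).
#' @param magnitude Mean absolute percent change.
#' @param seed Seed.
#' @return List with `effects` (windows x neurons percent-change matrix),
#'   `patterns` (unit-vector rows), and `adjacent_cos` (achieved cosines,
#'   length `n_windows - 1`).
#' @export
make_effect_sequence <- function(n_windows, n_target, mode = "static",
                                 rotation_cos = 0.2, magnitude = 25,
                                 seed = NULL) {
  stopifnot(n_target >= 2, n_windows >= 1, abs(rotation_cos) <= 1)
  mode <- match.arg(mode, c("static", "rotating"))
  with_seed(seed, {
    u <- matrix(NA_real_, n_windows, n_target)
    u[1, ] <- unit_vector(rtnorm(n_target))
    if (n_windows > 1) {
      for (w in 2:n_windows) {
        if (mode == "static") {
          u[w, ] <- u[1, ]
        } else {
          z <- rtnorm(n_target)
          q <- z - sum(z * u[w - 1, ]) * u[w - 1, ]
          q <- unit_vector(q)
          u[w, ] <- rotation_cos * u[w - 1, ] +
            sqrt(1 - rotation_cos^2) * q
        }
      }
    }
    effects <- t(apply(u, 1, function(v) v * magnitude / mean(abs(v))))
    if (n_windows == 1) effects <- matrix(effects, 1, n_target)
    if (any(effects <= -100)) {
      stop("effect magnitude places some neurons below -100% (rate would be ",
           "negative); reduce `effect_magnitude`", call. = FALSE)
    }
    adjacent <- if (n_windows > 1) {
      vapply(seq_len(n_windows - 1), function(w) {
        pairwise_cosine(u[w, ], u[w + 1, ])
      }, numeric(1))
    } else {
      numeric(0)
    }
    list(effects = effects, patterns = u, adjacent_cos = adjacent)
  })
}

# rotate the first latent loading column through a fixed random plane
latent_loadings <- function(n_neurons, rank, strengths, rotation_rad,
                            n_windows) {
  if (rank == 0) {
    return(NULL)
  }
  base <- matrix(stats::rnorm(n_neurons * rank), n_neurons, rank)
  base <- apply(base, 2, unit_vector)
  base <- matrix(base, n_neurons, rank)
  # the leading factor is a common gain (non-negative loadings), giving
  # the positive-mean pairwise noise correlations typical of cortex
  base[, 1] <- abs(base[, 1])
  partner <- stats::rnorm(n_neurons)
  partner <- unit_vector(partner - sum(partner * base[, 1]) * base[, 1])
  lapply(seq_len(n_windows), function(w) {
    L <- base
    th <- (w - 1) * rotation_rad
    L[, 1] <- cos(th) * base[, 1] + sin(th) * partner
    sweep(L, 2, strengths[seq_len(rank)], `*`)
  })
}

#' Simulate a two-area silencing session with known ground truth
#'
#' Draws a full session from a [sim_config()]: trial structure (interleaved
#' control and silencing trials with randomized window assignment and go /
#' no-go stimuli), inhomogeneous-Poisson spike trains whose rates are
#' piecewise constant over the window grid, and lick behavior. During a
#' silencing trial's window, source-area rates are multiplied by the
#' residual `source_silencing_factor` and target-area rates by
#' `1 + effect/100` for that window's effect vector. Identical
#' `(config, seed)` gives an identical session.
#'
#' @param config A `commdyn_sim_config`.
#' @return List with `session` (a [session()]) and `truth` (effect vectors
#'   and unit patterns per stimulus, achieved adjacent-window cosines,
#'   latent loadings per window, baseline rates, stimulus gains, behavioral
#'   parameters).
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "commdyn_sim_config"))
  cfg <- config
  seeds <- derive_seeds(cfg$seed, 8)
  n_windows <- length(cfg$silencing_onsets)
  n_total <- cfg$n_source + cfg$n_target
  areas <- rep(c("source", "target"), c(cfg$n_source, cfg$n_target))
  neuron_id <- sprintf("n%03d", seq_len(n_total))

  # neuron-level parameters
  pars <- with_seed(seeds[1], {
    list(
      baseline = stats::rlnorm(n_total, cfg$baseline_log_mean,
                               cfg$baseline_log_sd),
      gain = matrix(stats::rlnorm(n_total * 2, cfg$stim_gain_log_mean,
                                  cfg$stim_gain_log_sd),
                    n_total, 2, dimnames = list(NULL, c("go", "nogo"))),
      depth = stats::runif(n_total, -400, 600),
      rf_distance = abs(stats::rnorm(n_total, 0, 15))
    )
  })

  # effect sequences per stimulus (shared when parameters coincide)
  tgt <- seq(cfg$n_source + 1, n_total)
  truth_eff <- list()
  if (!is.null(cfg$effect_vectors)) {
    ev <- cfg$effect_vectors
    if (is.matrix(ev)) ev <- list(go = ev, nogo = ev)
    stopifnot(all(dim(ev$go) == c(n_windows, cfg$n_target)),
              all(dim(ev$nogo) == c(n_windows, cfg$n_target)))
    safe_unit <- function(v) {
      n <- sqrt(sum(v^2))
      if (n == 0) v else v / n
    }
    truth_eff <- lapply(ev, function(m) {
      list(effects = m, patterns = t(apply(m, 1, safe_unit)),
           adjacent_cos = if (n_windows > 1) {
             vapply(seq_len(n_windows - 1), function(w) {
               pairwise_cosine(m[w, ], m[w + 1, ])
             }, numeric(1))
           } else {
             numeric(0)
           })
    })
  } else {
    shared <- cfg$effect_mode[["go"]] == cfg$effect_mode[["nogo"]] &&
      cfg$effect_rotation_cos[["go"]] == cfg$effect_rotation_cos[["nogo"]]
    truth_eff$go <- make_effect_sequence(
      n_windows, cfg$n_target, cfg$effect_mode[["go"]],
      cfg$effect_rotation_cos[["go"]], cfg$effect_magnitude, seeds[2]
    )
    truth_eff$nogo <- if (shared) {
      truth_eff$go
    } else {
      make_effect_sequence(
        n_windows, cfg$n_target, cfg$effect_mode[["nogo"]],
        cfg$effect_rotation_cos[["nogo"]], cfg$effect_magnitude, seeds[3]
      )
    }
  }

  # latent loadings per window
  loadings <- with_seed(seeds[4], latent_loadings(
    n_total, cfg$latent_rank, cfg$latent_strengths,
    cfg$latent_rotation_rad, n_windows
  ))

  # trial table
  trials <- with_seed(seeds[5], {
    n_sil <- cfg$n_silencing_per_window * n_windows
    n_tr <- cfg$n_control + n_sil
    cond <- sample(rep(c("control", "silencing"),
                       c(cfg$n_control, n_sil)))
    win <- rep(NA_integer_, n_tr)
    win[cond == "silencing"] <- sample(rep(seq_len(n_windows),
                                           cfg$n_silencing_per_window))
    # go/no-go equiprobable, balanced within condition x window strata as
    # in a counterbalanced experimental design
    stim <- character(n_tr)
    stratum <- ifelse(cond == "control", 0L, win)
    for (st in unique(stratum)) {
      i <- which(stratum == st)
      stim[i] <- sample(rep_len(c("go", "nogo"), length(i)))
    }
    tibble::tibble(
      trial_id = sprintf("t%04d", seq_len(n_tr)),
      stimulus = stim,
      condition = cond,
      silencing_window = win
    )
  })

  trials <- with_seed(seeds[6],
                      simulate_behavior(cfg, trials))

  spikes <- with_seed(seeds[7],
                      emit_spikes(cfg, trials, pars, truth_eff, loadings,
                                  areas))

  neurons <- tibble::tibble(
    neuron_id = neuron_id,
    area = areas,
    depth_um = pars$depth,
    rf_distance_deg = pars$rf_distance
  )
  sess <- session(
    spikes, trials, neurons,
    stimulus_duration = cfg$stimulus_duration,
    silencing_duration = cfg$silencing_duration,
    silencing_onsets = cfg$silencing_onsets,
    pre_window = cfg$pre_window,
    animal_id = sprintf("sim-seed%d", cfg$seed)
  )
  truth <- list(
    effect_vectors = lapply(truth_eff, `[[`, "effects"),
    effect_patterns = lapply(truth_eff, `[[`, "patterns"),
    adjacent_cos = lapply(truth_eff, `[[`, "adjacent_cos"),
    latent_loadings = loadings,
    baseline_rates = pars$baseline,
    stimulus_gains = pars$gain,
    target_ids = neuron_id[tgt],
    source_ids = neuron_id[seq_len(cfg$n_source)],
    behavior = list(hit_rate = cfg$hit_rate, fa_rate = cfg$fa_rate)
  )
  list(session = sess, truth = truth)
}

#' Simulated lick behavior for a trial table
#'
#' Go trials lick with probability `hit_rate`, no-go trials with `fa_rate`;
#' lick times are a shifted log-normal truncated to >= 100 ms, with an
#' optional additive shift on silencing trials in selected windows. Assumes
#' the caller has set the RNG state.
#'
#' @param cfg A `commdyn_sim_config`.
#' @param trials Trial tibble with `stimulus`, `condition`,
#'   `silencing_window`.
#' @return The trial tibble with a `lick_time_ms` column.
#' @export
simulate_behavior <- function(cfg, trials) {
  n <- nrow(trials)
  p <- ifelse(trials$stimulus == "go", cfg$hit_rate, cfg$fa_rate)
  licks <- stats::runif(n) < p
  rt <- cfg$rt_shift_ms + stats::rlnorm(n, cfg$rt_meanlog, cfg$rt_sdlog)
  shift_ok <- trials$condition == "silencing" &
    trials$silencing_window %in% cfg$silencing_rt_windows
  rt <- rt + ifelse(shift_ok, cfg$silencing_rt_shift_ms, 0)
  rt <- pmax(rt, 100)
  trials$lick_time_ms <- ifelse(licks, rt, NA_real_)
  trials
}

# Emit spike times as an exact piecewise-constant-rate Poisson process:
# per trial-group segment, Poisson counts at rate*duration then uniform
# times within the segment.
emit_spikes <- function(cfg, trials, pars, truth_eff, loadings, areas) {
  n_total <- length(areas)
  n_windows <- length(cfg$silencing_onsets)
  onsets <- cfg$silencing_onsets
  grid <- unique(sort(c(0, onsets, cfg$stimulus_duration)))
  end_rec <- cfg$stimulus_duration + cfg$silencing_duration
  src <- areas == "source"
  tgt_idx <- which(areas == "target")

  # latent coordinates per trial
  z <- if (cfg$latent_rank > 0) {
    matrix(stats::rnorm(nrow(trials) * cfg$latent_rank),
           nrow(trials), cfg$latent_rank)
  } else {
    NULL
  }

  out <- vector("list", 64)
  oi <- 0
  groups <- split(seq_len(nrow(trials)),
                  list(trials$stimulus,
                       ifelse(is.na(trials$silencing_window), 0,
                              trials$silencing_window)),
                  drop = TRUE)
  for (g in groups) {
    stim <- trials$stimulus[g[1]]
    w <- trials$silencing_window[g[1]]
    sil <- !is.na(w)
    bounds <- c(-cfg$pre_window, grid, end_rec)
    if (sil) {
      bounds <- c(bounds, onsets[w], onsets[w] + cfg$silencing_duration)
    }
    bounds <- unique(sort(bounds))
    bounds <- bounds[bounds <= end_rec]
    gain <- pars$gain[, stim]
    for (s in seq_len(length(bounds) - 1)) {
      a <- bounds[s]
      b <- bounds[s + 1]
      dur_s <- (b - a) / 1000
      in_stim <- a >= 0 && a < cfg$stimulus_duration
      # base rate vector over neurons
      lam_n <- pars$baseline
      gseg <- NA_integer_
      if (in_stim) {
        gseg <- findInterval(a, grid)
        gseg <- min(gseg, n_windows)
        lam_n <- lam_n * gain * cfg$temporal_envelope[gseg]
      }
      # trial x neuron rate matrix (latent factors during stimulus only)
      lam <- matrix(lam_n, length(g), n_total, byrow = TRUE)
      if (in_stim && !is.null(z)) {
        L <- loadings[[gseg]]
        lf <- z[g, , drop = FALSE] %*% t(L)
        lam <- lam * exp(sweep(lf, 2, 0.5 * rowSums(L^2), `-`))
      }
      if (sil && a >= onsets[w] && b <= onsets[w] + cfg$silencing_duration) {
        lam[, src] <- lam[, src] * cfg$source_silencing_factor
        eff <- truth_eff[[stim]]$effects[w, ]
        lam[, tgt_idx] <- sweep(lam[, tgt_idx, drop = FALSE], 2,
                                1 + eff / 100, `*`)
      }
      if (any(lam < 0)) {
        stop("negative rate encountered (effect below -100%)", call. = FALSE)
      }
      cnt <- stats::rpois(length(lam), lam * dur_s)
      tot <- sum(cnt)
      if (tot > 0) {
        dim(cnt) <- dim(lam)
        nz <- which(cnt > 0, arr.ind = TRUE)
        reps <- cnt[nz]
        oi <- oi + 1
        if (oi > length(out)) out <- c(out, vector("list", length(out)))
        out[[oi]] <- tibble::tibble(
          neuron_id = rep(sprintf("n%03d", nz[, 2]), reps),
          trial_id = rep(trials$trial_id[g][nz[, 1]], reps),
          t_ms = stats::runif(tot, a, b)
        )
      }
    }
  }
  sp <- dplyr::bind_rows(out[seq_len(oi)])
  dplyr::arrange(sp, .data$trial_id, .data$neuron_id, .data$t_ms)
}
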