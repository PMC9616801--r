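#' Windowed principal components and their similarity over time
#'
#' Computes the first `n_components` principal components of target-area
#' population activity separately for each 150-ms time window, stimulus and
#' condition, using an equal number of trials across the four
#' (stimulus x condition) groups. PC similarity across windows is assessed
#' with the absolute value of the cross-validated cosine (PC signs are
#' arbitrary), estimated from half-trial splits; variances along each PC
#' use all balanced trials.
#'
#' @param x A `commdyn_session`.
#' @param n_components Number of leading PCs (default 3).
#' @param neuron_ids Neuron subset (default responsive target neurons).
#' @param window_duration PCA window length, ms (default the silencing
#'   duration).
#' @param threshold_hz Per-window rate threshold.
#' @param n_splits Half-trial partitions for the similarity matrices
#'   (default 100).
#' @param seed Seed (balancing + splits).
#' @param conditions Conditions to analyze (default control and silencing).
#' @return A `commdyn_pcs` list: `variance` tibble (window, stimulus,
#'   condition, component, variance, var_total_top = top-k sum,
#'   var_total = full trace) and `similarity`, a
#'   tibble of `commdyn_similarity` objects per (stimulus, condition,
#'   component).
#' @export
window_pcs <- function(x, n_components = 3, neuron_ids = NULL,
                       window_duration = NULL, threshold_hz = 2.5,
                       n_splits = 100, seed = NULL,
                       conditions = c("control", "silencing")) {
  stopifnot(inherits(x, "commdyn_session"))
  neuron_ids <- neuron_ids %||% default_target_neurons(x)
  wd <- window_data(x, neuron_ids, window_duration = window_duration,
                    threshold_hz = threshold_hz)
  n_w <- length(wd$windows)
  seeds <- derive_seeds(seed %||% 0, 2)

  # balanced quota across the 4 stimulus x condition groups
  qs <- c(
    vapply(c("go", "nogo"), function(s) {
      sum(wd$windows[[1]]$ctrl_stim == s)
    }, numeric(1)),
    if ("silencing" %in% conditions) {
      vapply(c("go", "nogo"), function(s) {
        min(vapply(wd$windows, function(w) sum(w$sil_stim == s), numeric(1)))
      }, numeric(1))
    }
  )
  quota <- min(qs)
  if (quota < 4) {
    stop("need at least 4 trials in each stimulus x condition group",
         call. = FALSE)
  }

  groups <- tidyr::expand_grid(stimulus = c("go", "nogo"),
                               condition = conditions)
  rows_for <- function(w, stimulus, condition) {
    win <- wd$windows[[w]]
    if (condition == "control") {
      which(win$ctrl_stim == stimulus)
    } else {
      which(win$sil_stim == stimulus)
    }
  }
  counts_for <- function(w, rows, condition) {
    win <- wd$windows[[w]]
    m <- if (condition == "control") win$ctrl else win$sil
    m[rows, win$active, drop = FALSE]
  }

  pc_fit <- function(m, k) {
    pr <- stats::prcomp(m, center = TRUE, scale. = FALSE)
    k <- min(k, ncol(pr$rotation))
    list(vectors = pr$rotation[, seq_len(k), drop = FALSE],
         variance = pr$sdev[seq_len(k)]^2,
         var_total = sum(pr$sdev^2))
  }

  variance <- list()
  sims <- list()
  with_seed(seeds[1], {
    for (gi in seq_len(nrow(groups))) {
      stimulus <- groups$stimulus[gi]
      condition <- groups$condition[gi]
      cand <- lapply(seq_len(n_w), function(w) {
        cc <- rows_for(w, stimulus, condition)
        if (length(cc) > quota) sample(cc, quota) else cc
      })
      # variances from all balanced trials
      for (w in seq_len(n_w)) {
        m <- counts_for(w, cand[[w]], condition)
        if (ncol(m) < 2) next
        fit <- pc_fit(m, n_components)
        variance[[length(variance) + 1]] <- tibble::tibble(
          window = w, stimulus = stimulus, condition = condition,
          component = seq_along(fit$variance),
          variance = fit$variance,
          var_total_top = sum(fit$variance),
          var_total = fit$var_total
        )
      }
      # cross-validated |cos| per component
      split_fun <- function(s) {
        h <- lapply(cand, function(cc) sample(cc, floor(length(cc) / 2)))
        list(h1 = h, h2 = purrr::map2(cand, h, setdiff))
      }
      for (comp in seq_len(n_components)) {
        dirs_fun <- function(h, half) {
          rows <- if (half == 1) h$h1 else h$h2
          D <- matrix(NA_real_, n_w, length(wd$neuron_id))
          for (w in seq_len(n_w)) {
            m <- counts_for(w, rows[[w]], condition)
            if (ncol(m) < 2 || nrow(m) < 3) next
            fit <- pc_fit(m, comp)
            if (ncol(fit$vectors) < comp) next
            D[w, wd$windows[[w]]$active] <- fit$vectors[, comp]
          }
          D
        }
        M <- crossval_engine(n_w, split_fun, dirs_fun, n_splits,
                             seed = NULL, absolute = TRUE)
        sims[[length(sims) + 1]] <- tibble::tibble(
          stimulus = stimulus, condition = condition, component = comp,
          similarity = list(new_similarity(M, wd$onsets, "pc", stimulus,
                                           condition, n_splits,
                                           absolute = TRUE))
        )
      }
    }
  })
  structure(
    list(variance = dplyr::bind_rows(variance),
         similarity = dplyr::bind_rows(sims)),
    class = "commdyn_pcs"
  )
}

#' Bhattacharyya distance between two population-activity distributions
#'
#' Equal-covariance multivariate-normal form: with pooled covariance `S`
#' (regularized as for LDA) the distance is
#' `D = (1/8) * t(dmu) %*% solve(Sg) %*% dmu`; the log-determinant term of
#' the general form vanishes because the covariance is assumed shared.
#'
#' @param a,b Count matrices (trials x neurons).
#' @param gamma Shrinkage toward the diagonal, as in
#'   [regularized_lda_direction()].
#' @return Non-negative scalar distance.
#' @export
bhattacharyya_distance <- function(a, b, gamma = 0) {
  stopifnot(ncol(a) == ncol(b))
  S <- pooled_covariance(a, b)
  Sg <- (1 - gamma) * S + gamma * diag(diag(S), ncol(S))
  dmu <- colMeans(a) - colMeans(b)
  v <- tryCatch(
    solve(Sg, dmu),
    error = function(e) {
      stop("pooled covariance is singular; use gamma > 0 (",
           conditionMessage(e), ")", call. = FALSE)
    }
  )
  as.numeric(dmu %*% v) / 8
}

#' Magnitude of population-level influence per silencing window
#'
#' The Bhattacharyya distance between target-area population activity in
#' control trials and in source-silencing trials of each window, with a
#' noise floor: the average distance between two bootstrap resamples of the
#' control trials alone (sizes matching the observed control/silencing
#' split), which is the distance expected from trial-to-trial noise in the
#' absence of any silencing effect.
#'
#' @param x A `commdyn_session`.
#' @param stimulus Optional `"go"`/`"nogo"` restriction (default: both).
#' @param gamma Covariance regularization.
#' @param n_boot Bootstrap resamples for the noise floor (default 100).
#' @param seed Seed.
#' @param neuron_ids,threshold_hz See [communication_directions()].
#' @return Tibble: `window`, `onset`, `distance`, `noise_floor`, `n_control`,
#'   `n_silencing`.
#' @export
influence_magnitude <- function(x, stimulus = NULL, gamma = 0.2,
                                n_boot = 100, seed = NULL,
                                neuron_ids = NULL, threshold_hz = 2.5) {
  neuron_ids <- neuron_ids %||% default_target_neurons(x)
  wd <- window_data(x, neuron_ids, threshold_hz = threshold_hz)
  seeds <- derive_seeds(seed %||% 0, length(wd$windows))
  purrr::map_dfr(seq_along(wd$windows), function(w) {
    win <- wd$windows[[w]]
    keep_c <- if (is.null(stimulus)) {
      rep(TRUE, nrow(win$ctrl))
    } else {
      win$ctrl_stim == stimulus
    }
    keep_s <- if (is.null(stimulus)) {
      rep(TRUE, nrow(win$sil))
    } else {
      win$sil_stim == stimulus
    }
    a <- win$ctrl[keep_c, win$active, drop = FALSE]
    b <- win$sil[keep_s, win$active, drop = FALSE]
    d <- bhattacharyya_distance(a, b, gamma)
    floor_d <- with_seed(seeds[w], {
      mean(vapply(seq_len(n_boot), function(i) {
        i1 <- sample.int(nrow(a), nrow(a), replace = TRUE)
        i2 <- sample.int(nrow(a), nrow(b), replace = TRUE)
        bhattacharyya_distance(a[i1, , drop = FALSE],
                               a[i2, , drop = FALSE], gamma)
      }, numeric(1)))
    })
    tibble::tibble(window = w, onset = wd$onsets[w], distance = d,
                   noise_floor = floor_d,
                   n_control = nrow(a), n_silencing = nrow(b))
  })
}

#' Time-invariant influence null simulation
#'
#' Surrogate datasets in which each target neuron's silencing effect is held
#' constant across windows while preserving its observed effect
#' distribution, mean control activity per window, and Poisson
#' trial-to-trial variability. Per repeat and neuron, one window's observed
#' effect `E_T = 100 (RsT - RcT) / RcT` is drawn at random and applied to
#' all windows: simulated silencing counts are Poisson samples at the
#' control-trial mean of the window, scaled by `1 + E/100` (means at or
#' below -100% clamp to zero). Each repeat's surrogate silencing trials
#' replace the observed ones and the communication-direction similarity is
#' recomputed.
#'
#' @inheritParams communication_similarity
#' @param n_repeats Number of effect randomizations (default 100).
#' @param per_stimulus_effects Draw each neuron's effects within stimulus
#'   (default TRUE, matching the per-stimulus CD analysis).
#' @return List with `similarity`: list over repeats of
#'   `commdyn_similarity`, and `observed`: the same statistic on the real
#'   data.
#' @export
simulate_time_invariant <- function(x, stimulus = c("go", "nogo"),
                                    gamma = 0.5, delta = 0,
                                    neuron_ids = NULL, threshold_hz = 2.5,
                                    n_splits = 100, n_repeats = 100,
                                    seed = NULL,
                                    per_stimulus_effects = TRUE) {
  stimulus <- match.arg(stimulus)
  neuron_ids <- neuron_ids %||% default_target_neurons(x)
  wd <- window_data(x, neuron_ids, threshold_hz = threshold_hz)
  seeds <- derive_seeds(seed %||% 0, n_repeats + 1)
  observed <- communication_similarity(
    x, stimulus, gamma, delta, n_splits = n_splits, seed = seeds[1],
    window_data_cache = wd
  )
  n_w <- length(wd$windows)
  p <- length(wd$neuron_id)
  # observed per-window effects and control means for the chosen stimulus
  eff <- matrix(NA_real_, n_w, p)
  mu_c <- matrix(NA_real_, n_w, p)
  for (w in seq_len(n_w)) {
    win <- wd$windows[[w]]
    kc <- if (per_stimulus_effects) win$ctrl_stim == stimulus else TRUE
    ks <- if (per_stimulus_effects) win$sil_stim == stimulus else TRUE
    rc <- colMeans(win$ctrl[kc, , drop = FALSE])
    rs <- colMeans(win$sil[ks, , drop = FALSE])
    mu_c[w, ] <- rc
    eff[w, ] <- percent_change(rs, rc)
  }
  eff[!is.finite(eff)] <- 0

  sims <- lapply(seq_len(n_repeats), function(r) {
    rs <- derive_seeds(seeds[r + 1], 2)
    wd_r <- wd
    with_seed(rs[1], {
      E <- eff[cbind(sample.int(n_w, p, replace = TRUE), seq_len(p))]
      for (w in seq_len(n_w)) {
        n_sil <- nrow(wd$windows[[w]]$sil)
        lam <- matrix(mu_c[w, ], n_sil, p, byrow = TRUE)
        sim_counts <- matrix(stats::rpois(n_sil * p, lam), n_sil, p) *
          matrix(pmax(1 + E / 100, 0), n_sil, p, byrow = TRUE)
        colnames(sim_counts) <- wd$neuron_id
        wd_r$windows[[w]]$sil <- sim_counts
      }
    })
    M <- cd_similarity_matrix(wd_r, stimulus, gamma, delta, n_splits,
                              seed = rs[2])
    new_similarity(M, wd$onsets, "communication-null", stimulus,
                   n_splits = n_splits)
  })
  list(similarity = sims, observed = observed)
}

#' Most temporally dynamic source-area neurons
#'
#' Z-scores every source neuron's trial-averaged activity within each time
#' window across the population, ranks neurons by the standard deviation of
#' their z-scored activity over windows, and returns the top fraction
#' (ties broken by neuron order). These are the source cells deviating most
#' from the average population time course.
#'
#' @param x A `commdyn_session`.
#' @param fraction Fraction of source neurons to keep (default 0.2; subset
#'   size is `ceiling(fraction * n)`).
#' @param window_duration Window length in ms (default 65, matching
#'   activity directions).
#' @param neuron_ids Source-neuron subset to rank (default: all source
#'   neurons).
#' @return Tibble ranked by descending SD: `neuron_id`, `sd_z`, `selected`.
#' @export
top_dynamic_source_subset <- function(x, fraction = 0.2,
                                      window_duration = 65,
                                      neuron_ids = NULL) {
  stopifnot(inherits(x, "commdyn_session"))
  neuron_ids <- neuron_ids %||%
    x$neurons$neuron_id[x$neurons$area == "source"]
  if (length(neuron_ids) < 5) {
    stop("need at least 5 source neurons", call. = FALSE)
  }
  wd <- window_data(x, neuron_ids, window_duration = window_duration,
                    threshold_hz = 0)
  A <- vapply(wd$windows, function(w) colMeans(w$ctrl),
              numeric(length(neuron_ids)))
  # z-score across neurons within each window
  Z <- scale(A)
  sd_z <- apply(Z, 1, stats::sd)
  ord <- order(-sd_z, seq_along(sd_z))
  k <- ceiling(fraction * length(neuron_ids))
  tibble::tibble(
    neuron_id = neuron_ids[ord],
    sd_z = sd_z[ord],
    selected = seq_along(ord) <= k
  )
}

#' CD similarity recomputed on random target subsets
#'
#' Companion to [top_dynamic_source_subset()]: recomputes the
#' communication-direction similarity matrix from randomly selected
#' subpopulations of a fraction of target neurons (default 20%), averaged
#' over repeats, so its dimensionality matches source-subset activity
#' directions.
#'
#' @inheritParams communication_similarity
#' @param fraction Fraction of target neurons per subset (default 0.2).
#' @param n_repeats Number of random subsets (default 100).
#' @return A `commdyn_similarity` (average over subsets).
#' @export
communication_similarity_subset <- function(x, stimulus = c("go", "nogo"),
                                            gamma = 0.5, delta = 0,
                                            fraction = 0.2, n_repeats = 100,
                                            neuron_ids = NULL,
                                            threshold_hz = 2.5,
                                            n_splits = 20, seed = NULL) {
  stimulus <- match.arg(stimulus)
  neuron_ids <- neuron_ids %||% default_target_neurons(x)
  wd <- window_data(x, neuron_ids, threshold_hz = threshold_hz)
  k <- ceiling(fraction * length(neuron_ids))
  seeds <- derive_seeds(seed %||% 0, n_repeats)
  Ms <- lapply(seq_len(n_repeats), function(r) {
    rs <- derive_seeds(seeds[r], 2)
    keep <- with_seed(rs[1], sample(neuron_ids, k))
    cd_similarity_matrix(wd, stimulus, gamma, delta, n_splits,
                         seed = rs[2], neuron_subset = keep)
  })
  M <- Reduce(`+`, Ms) / n_repeats
  new_similarity(M, wd$onsets, "communication-subset", stimulus,
                 n_splits = n_splits)
}
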