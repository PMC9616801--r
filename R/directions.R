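# Precompute per-window count matrices shared by every direction analysis.
#
# For each silencing window w: counts of all (non-excluded) control trials
# and of the silencing trials assigned to w, in the window's time bin, plus
# the per-window active-neuron mask from the rate threshold (pooled across
# conditions). Baseline subtraction removes each neuron's pre-stimulus rate
# (scaled to the window length) from every count.
window_data <- function(x, neuron_ids = NULL, window_duration = NULL,
                        threshold_hz = 2.5, baseline_subtract = FALSE,
                        onsets = NULL) {
  stopifnot(inherits(x, "commdyn_session"))
  neuron_ids <- neuron_ids %||% x$neurons$neuron_id
  window_duration <- window_duration %||% x$silencing_duration
  onsets <- onsets %||% x$silencing_onsets
  tr <- x$trials[!x$trials$excluded, ]
  ctrl <- tr[tr$condition == "control", ]
  base <- NULL
  if (baseline_subtract) {
    pre <- window_counts(x, -x$pre_window, x$pre_window,
                         trial_ids = tr$trial_id, neuron_ids = neuron_ids)
    base <- colMeans(pre$counts) * window_duration / x$pre_window
  }
  windows <- lapply(seq_along(onsets), function(w) {
    sil <- tr[tr$condition == "silencing" & tr$silencing_window == w, ]
    cm_c <- window_counts(x, onsets[w], window_duration,
                          trial_ids = ctrl$trial_id, neuron_ids = neuron_ids)
    ctrl_counts <- cm_c$counts
    sil_counts <- NULL
    sil_stim <- character(0)
    if (nrow(sil) > 0) {
      cm_s <- window_counts(x, onsets[w], window_duration,
                            trial_ids = sil$trial_id,
                            neuron_ids = neuron_ids)
      sil_counts <- cm_s$counts
      sil_stim <- sil$stimulus[match(cm_s$trial_id, sil$trial_id)]
    }
    pooled <- rbind(ctrl_counts, sil_counts)
    rate <- colMeans(pooled) / (window_duration / 1000)
    active <- rate >= threshold_hz
    if (baseline_subtract) {
      ctrl_counts <- sweep(ctrl_counts, 2, base)
      if (!is.null(sil_counts)) sil_counts <- sweep(sil_counts, 2, base)
    }
    list(
      ctrl = ctrl_counts,
      sil = sil_counts,
      active = active,
      ctrl_stim = ctrl$stimulus[match(cm_c$trial_id, ctrl$trial_id)],
      sil_stim = sil_stim
    )
  })
  list(windows = windows, neuron_id = neuron_ids, onsets = onsets,
       window_duration = window_duration)
}

# Split-half cross-validated cosine similarity engine.
#
# `split_fun(s)` draws the s-th random partition (opaque), `dirs_fun(h, half)`
# returns an n_windows x n_neurons matrix of directions estimated from one
# half (rows may contain NA for inactive neurons). For each partition the
# n_windows x n_windows matrix of pairwise cosines between half-1 and half-2
# directions is averaged with its transpose (the half-swap) and the result
# is averaged over partitions.
crossval_engine <- function(n_windows, split_fun, dirs_fun,
                            n_splits = 100, seed = NULL, absolute = FALSE) {
  acc <- matrix(0, n_windows, n_windows)
  nacc <- matrix(0, n_windows, n_windows)
  with_seed(seed, {
    for (s in seq_len(n_splits)) {
      h <- split_fun(s)
      D1 <- dirs_fun(h, 1)
      D2 <- dirs_fun(h, 2)
      M <- cosine_cross(D1, D2)
      # sign-ambiguous directions (PCs): rectify before the half-swap
      # average, otherwise opposite-sign estimates cancel
      if (absolute) M <- abs(M)
      M <- (M + t(M)) / 2
      ok <- is.finite(M)
      acc[ok] <- acc[ok] + M[ok]
      nacc <- nacc + ok
    }
  })
  out <- acc / nacc
  out[nacc == 0] <- NA_real_
  out
}

# all pairwise cosines between rows of D1 and rows of D2, NA-aware
cosine_cross <- function(D1, D2) {
  if (!anyNA(D1) && !anyNA(D2)) {
    n1 <- sqrt(rowSums(D1^2))
    n2 <- sqrt(rowSums(D2^2))
    return((D1 %*% t(D2)) / outer(n1, n2))
  }
  n <- nrow(D1)
  M <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      M[i, j] <- pairwise_cosine(D1[i, ], D2[j, ])
    }
  }
  M
}

new_similarity <- function(M, onsets, kind, stimulus = NA_character_,
                           condition = NA_character_, n_splits = NA_integer_,
                           absolute = FALSE) {
  dimnames(M) <- list(paste0("T", seq_len(nrow(M))),
                      paste0("T", seq_len(ncol(M))))
  structure(
    list(matrix = M, onsets = onsets, kind = kind, stimulus = stimulus,
         condition = condition, n_splits = n_splits, absolute = absolute),
    class = "commdyn_similarity"
  )
}

#' @export
print.commdyn_similarity <- function(x, ...) {
  cat(sprintf("<commdyn_similarity> %s%s, %d windows, %s splits\n",
              x$kind,
              if (!is.na(x$stimulus)) paste0(" (", x$stimulus, ")") else "",
              nrow(x$matrix), x$n_splits))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Lag profile of a similarity matrix
#'
#' Averages the cross-validated cosine similarities over all window pairs at
#' each time lag. Lag 0 (the diagonal) is the split-half reliability of the
#' directions; its shortfall from 1 reflects trial-to-trial variability.
#' Lags convert to ms using the mean silencing-onset spacing.
#'
#' @param sim A `commdyn_similarity` object.
#' @return Tibble with `lag`, `lag_ms`, `similarity`, `n_pairs`.
#' @export
lag_profile <- function(sim) {
  stopifnot(inherits(sim, "commdyn_similarity"))
  M <- sim$matrix
  n <- nrow(M)
  step <- mean(diff(sim$onsets))
  purrr::map_dfr(0:(n - 1), function(l) {
    v <- M[row(M) - col(M) == l | col(M) - row(M) == l]
    if (l == 0) v <- diag(M)
    tibble::tibble(lag = l, lag_ms = l * step,
                   similarity = mean(v, na.rm = TRUE),
                   n_pairs = sum(is.finite(v)))
  })
}

#' @rdname lag_profile
#' @param x A `commdyn_similarity` object.
#' @param ... Unused.
#' @export
tidy.commdyn_similarity <- function(x, ...) {
  M <- x$matrix
  tibble::tibble(
    window_i = rep(seq_len(nrow(M)), ncol(M)),
    window_j = rep(seq_len(ncol(M)), each = nrow(M)),
    similarity = as.vector(M)
  )
}

# ---- communication directions -----------------------------------------

# balanced per-stimulus trial quota: equal go / no-go counts within
# condition across the session
balanced_quota <- function(wd) {
  ctrl <- min(table(factor(wd$windows[[1]]$ctrl_stim,
                           levels = c("go", "nogo"))))
  sils <- vapply(wd$windows, function(w) {
    if (length(w$sil_stim) == 0) {
      return(Inf)
    }
    min(table(factor(w$sil_stim, levels = c("go", "nogo"))))
  }, numeric(1))
  list(ctrl = ctrl, sil = min(sils))
}

# estimate one CD per window for one stimulus from given control /
# silencing row indices (already stimulus-filtered); NA-pads inactive
# neurons
cd_matrix <- function(wd, ctrl_rows, sil_rows, gamma, delta) {
  p <- length(wd$neuron_id)
  D <- matrix(NA_real_, length(wd$windows), p)
  for (w in seq_along(wd$windows)) {
    win <- wd$windows[[w]]
    act <- win$active
    if (sum(act) < 2) next
    v <- lda_dir(win$ctrl[ctrl_rows, act, drop = FALSE],
                 win$sil[sil_rows[[w]], act, drop = FALSE],
                 gamma, delta)
    if (!is.null(v)) D[w, act] <- v
  }
  D
}

#' Communication directions per silencing window
#'
#' For each silencing window the communication direction (CD) is the
#' unit-length regularized-LDA direction separating target-area population
#' activity in control trials from that in source-silencing trials of the
#' same window, using 150-ms spike counts. Directions are computed per
#' stimulus with equal go and no-go trial counts; the sign convention is
#' control-mean minus silencing-mean. Neurons below the rate threshold in a
#' window carry `NA` coefficients there.
#'
#' @param x A `commdyn_session`.
#' @param stimulus `"go"` or `"nogo"`.
#' @param gamma,delta Regularization (tune per animal with
#'   [tune_lda_params()]).
#' @param neuron_ids Target-area neuron subset (default: responsive target
#'   neurons, see [select_responsive_neurons()]).
#' @param threshold_hz Per-window rate threshold (default 2.5 Hz).
#' @param seed Seed for the balanced trial subsample.
#' @return A `commdyn_directions` object: matrix `directions` (windows x
#'   neurons), window onsets, neuron ids, kind `"communication"`.
#' @export
communication_directions <- function(x, stimulus = c("go", "nogo"),
                                     gamma = 0.5, delta = 0,
                                     neuron_ids = NULL, threshold_hz = 2.5,
                                     seed = NULL) {
  stimulus <- match.arg(stimulus)
  neuron_ids <- neuron_ids %||% default_target_neurons(x)
  wd <- window_data(x, neuron_ids, threshold_hz = threshold_hz)
  q <- balanced_quota(wd)
  sel <- with_seed(seed, sample_stim_rows(wd, stimulus, q))
  D <- cd_matrix(wd, sel$ctrl, sel$sil, gamma, delta)
  out <- new_directions(D, wd, "communication", stimulus)
  out$gamma <- gamma
  out$delta <- delta
  out
}

default_target_neurons <- function(x) {
  resp <- select_responsive_neurons(x)
  tgt <- x$neurons$neuron_id[x$neurons$area == "target"]
  out <- intersect(resp, tgt)
  if (length(out) < 2) {
    stop("fewer than 2 responsive target neurons", call. = FALSE)
  }
  out
}

# row indices of `quota`-balanced control trials (shared across windows)
# and per-window silencing trials for one stimulus
sample_stim_rows <- function(wd, stimulus, quota) {
  ctrl_cand <- which(wd$windows[[1]]$ctrl_stim == stimulus)
  ctrl <- if (is.finite(quota$ctrl) && quota$ctrl < length(ctrl_cand)) {
    sample(ctrl_cand, quota$ctrl)
  } else {
    ctrl_cand
  }
  sil <- lapply(wd$windows, function(w) {
    cand <- which(w$sil_stim == stimulus)
    if (is.finite(quota$sil) && quota$sil < length(cand)) {
      sample(cand, quota$sil)
    } else {
      cand
    }
  })
  list(ctrl = ctrl, sil = sil)
}

new_directions <- function(D, wd, kind, stimulus = NA_character_,
                           condition = NA_character_) {
  rownames(D) <- paste0("T", seq_len(nrow(D)))
  colnames(D) <- wd$neuron_id
  structure(
    list(directions = D, onsets = wd$onsets, neuron_id = wd$neuron_id,
         kind = kind, stimulus = stimulus, condition = condition,
         window_duration = wd$window_duration),
    class = "commdyn_directions"
  )
}

#' @export
print.commdyn_directions <- function(x, ...) {
  cat(sprintf("<commdyn_directions> %s%s: %d windows x %d neurons\n",
              x$kind,
              if (!is.na(x$stimulus)) paste0(" (", x$stimulus, ")") else "",
              nrow(x$directions), ncol(x$directions)))
  invisible(x)
}

#' @rdname communication_directions
#' @param ... Unused.
#' @export
tidy.commdyn_directions <- function(x, ...) {
  D <- x$directions
  tibble::tibble(
    window = rep(seq_len(nrow(D)), ncol(D)),
    onset = rep(x$onsets, ncol(D)),
    neuron_id = rep(colnames(D), each = nrow(D)),
    coefficient = as.vector(D)
  )
}

#' Cross-validated similarity of communication directions
#'
#' Estimates the 8 x 8 matrix of cosine similarities between communication
#' directions of all window pairs, cross-validated against trial-to-trial
#' noise: control trials are randomly split in half (silencing trials
#' likewise), `CD_i` estimated from one half and `CD_j` from the other,
#' their dot product taken, the halves swapped and the products averaged;
#' the random partition is repeated `n_splits` times and averaged.
#'
#' @inheritParams communication_directions
#' @param n_splits Number of random half partitions (default 100).
#' @param seed Seed.
#' @param window_data_cache Internal: precomputed [window_data()] output.
#' @return A `commdyn_similarity` object (signed similarities).
#' @export
communication_similarity <- function(x, stimulus = c("go", "nogo"),
                                     gamma = 0.5, delta = 0,
                                     neuron_ids = NULL, threshold_hz = 2.5,
                                     n_splits = 100, seed = NULL,
                                     window_data_cache = NULL) {
  stimulus <- match.arg(stimulus)
  wd <- window_data_cache %||% {
    neuron_ids <- neuron_ids %||% default_target_neurons(x)
    window_data(x, neuron_ids, threshold_hz = threshold_hz)
  }
  M <- cd_similarity_matrix(wd, stimulus, gamma, delta, n_splits, seed)
  new_similarity(M, wd$onsets, "communication", stimulus,
                 n_splits = n_splits)
}

# engine wrapper shared by communication_similarity, the time-invariant
# null, the target-subset recomputation and the permutation test;
# `stim_ctrl` / `stim_sil` labels may be overridden (label permutation)
cd_similarity_matrix <- function(wd, stimulus, gamma, delta,
                                 n_splits, seed,
                                 ctrl_labels = NULL, sil_labels = NULL,
                                 neuron_subset = NULL) {
  ctrl_labels <- ctrl_labels %||% wd$windows[[1]]$ctrl_stim
  sil_labels <- sil_labels %||% lapply(wd$windows, `[[`, "sil_stim")
  if (!is.null(neuron_subset)) {
    wd <- subset_window_data(wd, neuron_subset)
  }
  ctrl_cand <- which(ctrl_labels == stimulus)
  sil_cand <- lapply(sil_labels, function(s) which(s == stimulus))
  if (length(ctrl_cand) < 4 || any(vapply(sil_cand, length, 1L) < 4)) {
    stop("need at least 4 trials per condition per window", call. = FALSE)
  }
  # equal go/no-go usage: cap candidate sets at the smaller stimulus count
  min_present <- function(s) {
    tbl <- table(s)
    if (length(tbl) == 0) Inf else min(tbl)
  }
  q_ctrl <- min_present(ctrl_labels)
  q_sil <- min(vapply(sil_labels, min_present, numeric(1)))
  seeds <- if (is.null(seed)) c(NULL, NULL) else derive_seeds(seed, 2)
  cap <- function() {
    if (length(ctrl_cand) > q_ctrl) {
      ctrl_cand <<- sample(ctrl_cand, q_ctrl)
    }
    sil_cand <<- lapply(sil_cand, function(cc) {
      if (length(cc) > q_sil) sample(cc, q_sil) else cc
    })
  }
  if (is.null(seed)) cap() else with_seed(seeds[1], cap())
  seed <- if (is.null(seed)) NULL else seeds[2]
  # compiled split-half engine (regularized LDA per window per half);
  # control rows are aligned across windows, so one split serves all
  ctrl_l <- lapply(wd$windows, function(w) {
    storage.mode(w$ctrl) <- "double"
    w$ctrl[ctrl_cand, , drop = FALSE]
  })
  sil_l <- lapply(seq_along(wd$windows), function(w) {
    m <- wd$windows[[w]]$sil[sil_cand[[w]], , drop = FALSE]
    storage.mode(m) <- "double"
    m
  })
  act_l <- lapply(wd$windows, function(w) which(w$active) - 1L)
  run <- function() {
    .cd_sim_kernel(ctrl_l, sil_l, act_l, gamma, delta, as.integer(n_splits))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

subset_window_data <- function(wd, keep_ids) {
  j <- match(keep_ids, wd$neuron_id)
  wd$windows <- lapply(wd$windows, function(w) {
    w$ctrl <- w$ctrl[, j, drop = FALSE]
    if (!is.null(w$sil)) w$sil <- w$sil[, j, drop = FALSE]
    w$active <- w$active[j]
    w
  })
  wd$neuron_id <- wd$neuron_id[j]
  wd
}

# ---- activity directions ----------------------------------------------

#' Activity directions and their cross-validated similarity
#'
#' The activity direction of a time window is the unit vector of
#' trial-averaged population activity (the center of the cloud of control
#' trials) in a 65-ms window starting at each silencing onset — shorter
#' than the 150-ms silencing windows to avoid temporal overlap between
#' successive time points. Optionally computed from baseline-subtracted
#' counts (each neuron's mean pre-stimulus rate removed).
#'
#' @param x A `commdyn_session`.
#' @param stimulus `"go"` or `"nogo"`.
#' @param condition Trials to use (default `"control"`).
#' @param window_duration Window length in ms (default 65).
#' @param baseline_subtract Subtract pre-stimulus rates first?
#' @param neuron_ids Neuron subset (default: responsive neurons of `area`).
#' @param area Which area's activity (default `"target"`).
#' @param threshold_hz Per-window rate threshold.
#' @return A `commdyn_directions` object of kind `"activity"`. Windows whose
#'   mean vector is all zero are `NA`.
#' @export
activity_directions <- function(x, stimulus = c("go", "nogo"),
                                condition = "control",
                                window_duration = 65,
                                baseline_subtract = FALSE,
                                neuron_ids = NULL, area = "target",
                                threshold_hz = 2.5) {
  stimulus <- match.arg(stimulus)
  neuron_ids <- neuron_ids %||% default_area_neurons(x, area)
  wd <- window_data(x, neuron_ids, window_duration = window_duration,
                    threshold_hz = threshold_hz,
                    baseline_subtract = baseline_subtract)
  rows <- activity_rows(wd, stimulus, condition)
  D <- activity_matrix(wd, rows, condition)
  new_directions(D, wd, "activity", stimulus, condition)
}

default_area_neurons <- function(x, area) {
  resp <- select_responsive_neurons(x)
  ids <- x$neurons$neuron_id[x$neurons$area == area]
  out <- intersect(resp, ids)
  if (length(out) < 2) {
    stop("fewer than 2 responsive neurons in area '", area, "'",
         call. = FALSE)
  }
  out
}

activity_rows <- function(wd, stimulus, condition) {
  if (condition == "control") {
    which(wd$windows[[1]]$ctrl_stim == stimulus)
  } else {
    lapply(wd$windows, function(w) which(w$sil_stim == stimulus))
  }
}

activity_matrix <- function(wd, rows, condition, rows_are_list = is.list(rows)) {
  p <- length(wd$neuron_id)
  D <- matrix(NA_real_, length(wd$windows), p)
  for (w in seq_along(wd$windows)) {
    win <- wd$windows[[w]]
    act <- win$active
    if (sum(act) < 2) next
    r <- if (rows_are_list) rows[[w]] else rows
    m <- if (condition == "control") {
      colMeans(win$ctrl[r, act, drop = FALSE])
    } else {
      colMeans(win$sil[r, act, drop = FALSE])
    }
    if (all(m == 0)) next
    D[w, act] <- m / sqrt(sum(m^2))
  }
  D
}

#' @rdname activity_directions
#' @inheritParams communication_similarity
#' @export
activity_similarity <- function(x, stimulus = c("go", "nogo"),
                                condition = "control",
                                window_duration = 65,
                                baseline_subtract = FALSE,
                                neuron_ids = NULL, area = "target",
                                threshold_hz = 2.5,
                                n_splits = 100, seed = NULL) {
  stimulus <- match.arg(stimulus)
  neuron_ids <- neuron_ids %||% default_area_neurons(x, area)
  wd <- window_data(x, neuron_ids, window_duration = window_duration,
                    threshold_hz = threshold_hz,
                    baseline_subtract = baseline_subtract)
  cand <- activity_rows(wd, stimulus, condition)
  is_list <- is.list(cand)
  if ((!is_list && length(cand) < 4) ||
      (is_list && any(vapply(cand, length, 1L) < 4))) {
    stop("need at least 4 trials per window", call. = FALSE)
  }
  split_fun <- function(s) {
    if (is_list) {
      h <- lapply(cand, function(cc) sample(cc, floor(length(cc) / 2)))
      list(h1 = h, h2 = purrr::map2(cand, h, setdiff))
    } else {
      h <- sample(cand, floor(length(cand) / 2))
      list(h1 = h, h2 = setdiff(cand, h))
    }
  }
  dirs_fun <- function(h, half) {
    activity_matrix(wd, if (half == 1) h$h1 else h$h2, condition,
                    rows_are_list = is_list)
  }
  M <- crossval_engine(length(wd$windows), split_fun, dirs_fun,
                       n_splits, seed)
  new_similarity(M, wd$onsets, "activity", stimulus, condition,
                 n_splits = n_splits)
}
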