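#' Permutation test on go/no-go decay-constant difference
#'
#' Tests whether communication directions rotate at different speeds during
#' go and no-go stimuli. The observed statistic is the difference in
#' exponential decay constants `tau(go) - tau(nogo)` of the pooled
#' cross-validated CD similarity lag profiles. The null distribution comes
#' from exchanging go/no-go trial labels at random within each animal
#' (separately within the control pool and within each window's silencing
#' pool, preserving per-condition trial counts), recomputing communication
#' directions, similarity profiles and decay fits each time. The p-value
#' uses the add-one correction `p = (1 + #{|null| >= |obs|}) / (n_perm + 1)`
#' and is therefore never exactly zero.
#'
#' @param sessions A `commdyn_session` or list of them (animals).
#' @param n_perm Number of permutations (default 1000; scale down for
#'   interactive runs).
#' @param gamma,delta LDA regularization.
#' @param n_splits Half partitions per similarity matrix (small values keep
#'   permutations affordable; the estimator is applied identically to
#'   observed and permuted data).
#' @param neuron_ids Optional list (per session) of target-neuron subsets;
#'   default responsive target neurons per session.
#' @param threshold_hz Rate threshold.
#' @param fit_method Decay fitter (default `"grid"`: deterministic profiled
#'   grid, identical for observed and null fits).
#' @param pooling `"points"` (default: fit on all animals' lag-profile
#'   points pooled) or `"mean"` (fit on the across-animal mean profile).
#' @param drop_lag0 Exclude lag 0 (split-half reliability) from the fits
#'   (default FALSE).
#' @param seed Seed.
#' @return A `commdyn_permtest` list: `observed` (tibble with tau_go,
#'   tau_nogo, delta_tau), `null` (vector of null delta-tau), `p_value`,
#'   `n_perm_used`, `n_dropped` (permutations with failed fits).
#' @export
permutation_test_tau <- function(sessions, n_perm = 1000,
                                 gamma = 0.5, delta = 0, n_splits = 10,
                                 neuron_ids = NULL, threshold_hz = 2.5,
                                 fit_method = c("grid", "nls"),
                                 pooling = c("points", "mean"),
                                 drop_lag0 = FALSE, seed = NULL) {
  fit_method <- match.arg(fit_method)
  pooling <- match.arg(pooling)
  if (inherits(sessions, "commdyn_session")) sessions <- list(sessions)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  wds <- lapply(seq_along(sessions), function(i) {
    ids <- if (is.null(neuron_ids)) {
      default_target_neurons(sessions[[i]])
    } else {
      neuron_ids[[i]]
    }
    window_data(sessions[[i]], ids, threshold_hz = threshold_hz)
  })
  seeds <- derive_seeds(seed %||% 0, 2 + n_perm)

  steps <- vapply(wds, function(wd) mean(diff(wd$onsets)), numeric(1))
  n_w <- length(wds[[1]]$onsets)
  lag_of <- abs(row(diag(n_w)) - col(diag(n_w)))
  ut <- upper.tri(lag_of, diag = TRUE)

  # per-animal per-stimulus similarity matrices, kept as plain numeric to
  # keep the permutation loop lean; "points" pooling fits on every window
  # pair (at its lag) so single-pair long lags are not over-weighted
  profile_pair <- function(label_sets, seed0) {
    ss <- derive_seeds(seed0, 2 * length(wds))
    lapply(c(go = "go", nogo = "nogo"), function(stim) {
      lapply(seq_along(wds), function(i) {
        cd_similarity_matrix(
          wds[[i]], stim, gamma, delta, n_splits,
          seed = ss[2 * (i - 1) + 1 + (stim == "nogo")],
          ctrl_labels = label_sets[[i]]$ctrl,
          sil_labels = label_sets[[i]]$sil
        )
      })
    })
  }

  fit_tau <- function(mats) {
    if (pooling == "mean") {
      prof <- colMeans(do.call(rbind, lapply(mats, lag_means)), na.rm = TRUE)
      t_ms <- (seq_len(n_w) - 1) * mean(steps)
      yv <- prof
    } else {
      t_ms <- unlist(lapply(seq_along(mats), function(i) {
        lag_of[ut] * steps[i]
      }))
      yv <- unlist(lapply(mats, function(M) M[ut]))
    }
    if (drop_lag0) {
      keep <- t_ms > 0
      t_ms <- t_ms[keep]
      yv <- yv[keep]
    }
    ok <- is.finite(yv)
    if (fit_method == "grid") {
      decay_grid(t_ms[ok], yv[ok], tau_max = 1e4)$tau
    } else {
      decay_fit_once(t_ms[ok], yv[ok], "nls", tau_max = 1e4)$tau
    }
  }

  observed_labels <- lapply(wds, function(wd) {
    list(ctrl = wd$windows[[1]]$ctrl_stim,
         sil = lapply(wd$windows, `[[`, "sil_stim"))
  })
  obs_prof <- profile_pair(observed_labels, seeds[1])
  tau_go <- fit_tau(obs_prof$go)
  tau_nogo <- fit_tau(obs_prof$nogo)
  obs_delta <- tau_go - tau_nogo

  null_delta <- rep(NA_real_, n_perm)
  for (pp in seq_len(n_perm)) {
    ps <- derive_seeds(seeds[2 + pp], 2)
    perm_labels <- with_seed(ps[1], {
      lapply(observed_labels, function(ls) {
        list(ctrl = sample(ls$ctrl),
             sil = lapply(ls$sil, sample))
      })
    })
    res <- tryCatch({
      pr <- profile_pair(perm_labels, ps[2])
      fit_tau(pr$go) - fit_tau(pr$nogo)
    }, error = function(e) NA_real_)
    null_delta[pp] <- res
  }
  ok <- is.finite(null_delta)
  p <- (1 + sum(abs(null_delta[ok]) >= abs(obs_delta))) / (sum(ok) + 1)
  structure(
    list(
      observed = tibble::tibble(tau_go = tau_go, tau_nogo = tau_nogo,
                                delta_tau = obs_delta),
      null = null_delta[ok],
      p_value = p,
      n_perm_used = sum(ok),
      n_dropped = sum(!ok),
      profiles = obs_prof
    ),
    class = "commdyn_permtest"
  )
}

#' @export
print.commdyn_permtest <- function(x, ...) {
  cat(sprintf(paste0("<commdyn_permtest> tau_go = %.3g ms, tau_nogo = %.3g ms, ",
                     "delta = %.3g ms\n  p = %.4g (%d permutations, %d dropped)\n"),
              x$observed$tau_go, x$observed$tau_nogo, x$observed$delta_tau,
              x$p_value, x$n_perm_used, x$n_dropped))
  invisible(x)
}
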