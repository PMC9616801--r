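#' Regularized linear-discriminant direction
#'
#' The unit-length normal to the LDA decision boundary separating two sets
#' of population count vectors: `w` proportional to `solve(Sg, mu_a - mu_b)`
#' where `Sg = (1 - gamma) * S + gamma * diag(S)` shrinks the pooled
#' within-class covariance `S` toward its diagonal. Coefficients smaller in
#' magnitude than `delta * max(|coef|)` are zeroed (dropping the
#' corresponding neurons), then the vector is renormalized to unit length.
#' With class a = control and class b = silencing the direction points from
#' the silenced toward the control mean.
#'
#' @param class_a,class_b Numeric matrices, trials x neurons (same columns).
#' @param gamma Shrinkage weight in \[0, 1\].
#' @param delta Coefficient threshold, relative to the largest absolute
#'   coefficient (default 0: keep all).
#' @return Unit-length numeric vector (one coefficient per column).
#' @export
regularized_lda_direction <- function(class_a, class_b, gamma, delta = 0) {
  stopifnot(is.matrix(class_a), is.matrix(class_b),
            ncol(class_a) == ncol(class_b),
            nrow(class_a) >= 2, nrow(class_b) >= 2,
            gamma >= 0, gamma <= 1, delta >= 0, delta < 1)
  w <- lda_dir(class_a, class_b, gamma, delta)
  if (is.null(w)) {
    # rerun the failing step for a precise error
    S <- pooled_covariance(class_a, class_b)
    Sg <- (1 - gamma) * S + gamma * diag(diag(S), ncol(S))
    dmu <- colMeans(class_a) - colMeans(class_b)
    ww <- tryCatch(solve(Sg, dmu), error = function(e) NULL)
    if (is.null(ww)) {
      stop("regularized covariance is singular",
           if (gamma == 0) " at gamma = 0; use gamma > 0" else "",
           call. = FALSE)
    }
    stop("all coefficients zeroed by delta threshold", call. = FALSE)
  }
  w
}

# lean core shared with the similarity engine: NULL on failure
lda_dir <- function(a, b, gamma, delta) {
  if (nrow(a) < 2 || nrow(b) < 2) {
    return(NULL)
  }
  S <- pooled_covariance(a, b)
  if (anyNA(S)) {
    return(NULL)
  }
  Sg <- (1 - gamma) * S + gamma * diag(diag(S), ncol(S))
  dmu <- colMeans(a) - colMeans(b)
  w <- tryCatch(solve(Sg, dmu), error = function(e) NULL)
  if (is.null(w) || !all(is.finite(w))) {
    return(NULL)
  }
  if (delta > 0) {
    w[abs(w) < delta * max(abs(w))] <- 0
  }
  nw <- sqrt(sum(w^2))
  if (nw == 0) {
    return(NULL)
  }
  w / nw
}

# within-class covariance pooled over the two classes, weighted by df
# (centered crossproducts; equivalent to df-weighted stats::cov)
pooled_covariance <- function(a, b) {
  na <- nrow(a)
  nb <- nrow(b)
  ca <- a - rep(colMeans(a), each = na)
  cb <- b - rep(colMeans(b), each = nb)
  (crossprod(ca) + crossprod(cb)) / (na + nb - 2)
}

# project onto the LDA direction and classify against the midpoint of the
# projected training means; returns misclassification rate on (ta, tb)
lda_test_error <- function(tr_a, tr_b, te_a, te_b, gamma, delta) {
  w <- tryCatch(
    regularized_lda_direction(tr_a, tr_b, gamma, delta),
    error = function(e) NULL
  )
  if (is.null(w)) {
    return(NA_real_)
  }
  thr <- (mean(tr_a %*% w) + mean(tr_b %*% w)) / 2
  err_a <- sum(te_a %*% w < thr)
  err_b <- sum(te_b %*% w >= thr)
  (err_a + err_b) / (nrow(te_a) + nrow(te_b))
}

#' Tune LDA regularization by cross-validated test error
#'
#' Grid search over the shrinkage `gamma` and relative coefficient threshold
#' `delta`, scored by mean misclassification over a k-fold cross validation
#' of the two classes; ties resolve to the smallest `gamma`, then the
#' smallest `delta`.
#'
#' @param control,silencing Count matrices (trials x neurons) of the two
#'   classes.
#' @param gamma_grid,delta_grid Non-empty candidate grids.
#' @param k Number of folds (default 10).
#' @param seed Seed for fold assignment.
#' @return One-row tibble: `gamma`, `delta`, `test_error`.
#' @export
tune_lda_params <- function(control, silencing,
                            gamma_grid = c(0.05, 0.1, 0.2, 0.4, 0.7, 1),
                            delta_grid = c(0, 0.05, 0.1, 0.2, 0.3),
                            k = 10, seed = NULL) {
  stopifnot(length(gamma_grid) > 0, length(delta_grid) > 0)
  folds_a <- with_seed(seed, sample(rep_len(seq_len(k), nrow(control))))
  folds_b <- with_seed(if (is.null(seed)) NULL else seed + 1,
                       sample(rep_len(seq_len(k), nrow(silencing))))
  grid <- tidyr::expand_grid(gamma = gamma_grid, delta = delta_grid)
  errs <- purrr::pmap_dbl(grid, function(gamma, delta) {
    fe <- vapply(seq_len(k), function(f) {
      lda_test_error(control[folds_a != f, , drop = FALSE],
                     silencing[folds_b != f, , drop = FALSE],
                     control[folds_a == f, , drop = FALSE],
                     silencing[folds_b == f, , drop = FALSE],
                     gamma, delta)
    }, numeric(1))
    mean(fe)
  })
  ok <- which(is.finite(errs))
  if (length(ok) == 0) {
    stop("no grid point produced a valid classifier", call. = FALSE)
  }
  best <- ok[order(errs[ok], grid$gamma[ok], grid$delta[ok])][1]
  tibble::tibble(gamma = grid$gamma[best], delta = grid$delta[best],
                 test_error = errs[best])
}

#' Stimulus decoding accuracy with and without source silencing
#'
#' For each silencing window, a regularized-LDA classifier is trained to
#' separate correct go from correct no-go trials using each neuron's spike
#' count in the 80-ms window following the silencing onset, on 80% of the
#' control trials (equal go/no-go counts). Control accuracy comes from the
#' held-out 20% of control trials and silencing accuracy from all silencing
#' trials of that window under the same classifier; both are averaged over
#' `n_splits` random 80/20 partitions. Windows with onset earlier than
#' `split_ms` aggregate as `early`, the rest as `late`.
#'
#' @param x A `commdyn_session` (outcomes classified if needed).
#' @param gamma,delta LDA regularization (see
#'   [regularized_lda_direction()]); tune per animal with
#'   [tune_lda_params()].
#' @param window_duration Decoding window length in ms (default 80).
#' @param n_splits Number of random 80/20 partitions (default 20).
#' @param seed Seed.
#' @param neuron_ids Neurons used (default: all in the session).
#' @param split_ms Early/late onset split (default 100 ms).
#' @param min_control_trials Inclusion guard (default 10).
#' @return List with `per_window` (tibble: window, onset, accuracy_control,
#'   accuracy_silencing) and `early_late` aggregates.
#' @export
stimulus_decoder <- function(x, gamma = 0.5, delta = 0,
                             window_duration = 80, n_splits = 20,
                             seed = NULL, neuron_ids = NULL,
                             split_ms = 100, min_control_trials = 10) {
  stopifnot(inherits(x, "commdyn_session"))
  if (!"outcome" %in% names(x$trials)) x <- classify_trials(x)
  tr <- x$trials[!x$trials$excluded &
                   x$trials$outcome %in% c("hit", "correct_rejection"), ]
  if (sum(tr$condition == "control") < min_control_trials) {
    stop("fewer than ", min_control_trials,
         " correct control trials; session excluded", call. = FALSE)
  }
  onsets <- x$silencing_onsets
  seeds <- derive_seeds(seed %||% 0, length(onsets))
  per_window <- purrr::map_dfr(seq_along(onsets), function(w) {
    cm <- window_counts(x, onsets[w], window_duration,
                        trial_ids = tr$trial_id, neuron_ids = neuron_ids)
    stim <- tr$stimulus[match(cm$trial_id, tr$trial_id)]
    cond <- tr$condition[match(cm$trial_id, tr$trial_id)]
    sil_w <- tr$silencing_window[match(cm$trial_id, tr$trial_id)]
    ctrl_go <- which(cond == "control" & stim == "go")
    ctrl_ng <- which(cond == "control" & stim == "nogo")
    sil_idx <- which(cond == "silencing" & sil_w == w)
    n_bal <- min(length(ctrl_go), length(ctrl_ng))
    accs <- with_seed(seeds[w], {
      vapply(seq_len(n_splits), function(s) {
        g <- sample(ctrl_go, n_bal)
        n <- sample(ctrl_ng, n_bal)
        n_tr <- max(2, floor(0.8 * n_bal))
        tr_g <- g[seq_len(n_tr)]
        tr_n <- n[seq_len(n_tr)]
        te_g <- setdiff(ctrl_go, tr_g)
        te_n <- setdiff(ctrl_ng, tr_n)
        wv <- tryCatch(
          regularized_lda_direction(cm$counts[tr_g, , drop = FALSE],
                                    cm$counts[tr_n, , drop = FALSE],
                                    gamma, delta),
          error = function(e) NULL
        )
        if (is.null(wv)) {
          return(c(NA_real_, NA_real_))
        }
        thr <- (mean(cm$counts[tr_g, , drop = FALSE] %*% wv) +
                  mean(cm$counts[tr_n, , drop = FALSE] %*% wv)) / 2
        acc <- function(ig, ing) {
          if (length(ig) + length(ing) == 0) {
            return(NA_real_)
          }
          hits <- sum(cm$counts[ig, , drop = FALSE] %*% wv >= thr) +
            sum(cm$counts[ing, , drop = FALSE] %*% wv < thr)
          hits / (length(ig) + length(ing))
        }
        c(acc(te_g, te_n),
          acc(intersect(sil_idx, which(stim == "go")),
              intersect(sil_idx, which(stim == "nogo"))))
      }, numeric(2))
    })
    tibble::tibble(
      window = w, onset = onsets[w],
      accuracy_control = mean(accs[1, ], na.rm = TRUE),
      accuracy_silencing = mean(accs[2, ], na.rm = TRUE)
    )
  })
  early <- per_window$onset < split_ms
  early_late <- tibble::tibble(
    epoch = c("early", "late"),
    accuracy_control = c(mean(per_window$accuracy_control[early]),
                         mean(per_window$accuracy_control[!early])),
    accuracy_silencing = c(mean(per_window$accuracy_silencing[early]),
                           mean(per_window$accuracy_silencing[!early]))
  )
  list(per_window = per_window, early_late = early_late)
}
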