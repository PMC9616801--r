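#' Spike-count autocorrelation across trials
#'
#' Divides the stimulus duration into successive bins (default 65 ms) and,
#' per neuron, computes the across-trial Pearson correlation between spike
#' counts at every pair of bins; the value at a lag is the mean over bin
#' pairs with that separation. Because correlations subtract the
#' across-trial mean per bin, a deterministic rate profile with independent
#' Poisson emission gives zero autocorrelation at all positive lags.
#'
#' @param x A `commdyn_session`.
#' @param bin_ms Bin width in ms (default 65).
#' @param neuron_ids Neuron subset (default: responsive target neurons).
#' @param stimulus Optional `"go"`/`"nogo"` restriction; by default the
#'   correlation is computed within each stimulus (on balanced trial
#'   counts) and averaged, so stimulus differences in mean rate do not
#'   masquerade as temporal dependence.
#' @param condition Trials to use (default `"control"`).
#' @param min_trials Minimum trials (default 10).
#' @param seed Seed for the go/no-go balancing subsample.
#' @return Tibble: `neuron_id`, `lag`, `lag_ms`, `r`, `n_pairs`,
#'   `n_skipped` (zero-variance bin pairs).
#' @export
spike_autocorrelation <- function(x, bin_ms = 65, neuron_ids = NULL,
                                  stimulus = NULL, condition = "control",
                                  min_trials = 10, seed = NULL) {
  stims <- stimulus %||% c("go", "nogo")
  per_stim <- lapply(stims, function(st) {
    bc <- binned_counts(x, bin_ms, neuron_ids, st, condition,
                        ceiling(min_trials / length(stims)), seed)
    n_bins <- length(bc$bins)
    purrr::map_dfr(seq_along(bc$neuron_id), function(j) {
      m <- bc$arr[, , j]
      suppressWarnings(C <- stats::cor(m))
      purrr::map_dfr(0:(n_bins - 1), function(l) {
        idx <- which(col(C) - row(C) == l)
        v <- C[idx]
        tibble::tibble(
          neuron_id = bc$neuron_id[j], lag = l, lag_ms = l * bin_ms,
          r = mean(v, na.rm = TRUE),
          n_pairs = sum(is.finite(v)), n_skipped = sum(!is.finite(v))
        )
      })
    })
  })
  dplyr::bind_rows(per_stim) |>
    dplyr::group_by(.data$neuron_id, .data$lag, .data$lag_ms) |>
    dplyr::summarise(r = mean(.data$r, na.rm = TRUE),
                     n_pairs = sum(.data$n_pairs),
                     n_skipped = sum(.data$n_skipped),
                     .groups = "drop")
}

#' Pairwise noise correlations
#'
#' Across-trial Pearson correlation between the spike counts of each
#' unordered neuron pair in a time bin, computed within stimulus condition
#' (so it captures noise, not signal, correlations), together with the mean
#' spike count of the pair in that bin; values from different bins are
#' returned long so they can be pooled.
#'
#' @inheritParams spike_autocorrelation
#' @param stimulus `"go"` or `"nogo"` (required: noise correlations are
#'   within-stimulus).
#' @return Tibble: `neuron_i`, `neuron_j`, `bin`, `r`, `mean_count`
#'   (zero-variance neuron-bins skipped).
#' @export
pairwise_noise_correlations <- function(x, stimulus, bin_ms = 65,
                                        neuron_ids = NULL,
                                        condition = "control",
                                        min_trials = 10) {
  stopifnot(stimulus %in% c("go", "nogo"))
  bc <- binned_counts(x, bin_ms, neuron_ids, stimulus, condition,
                      min_trials, seed = NULL)
  out <- list()
  for (b in seq_along(bc$bins)) {
    m <- bc$arr[, b, ]
    keep <- apply(m, 2, stats::sd) > 0
    if (sum(keep) < 2) next
    C <- stats::cor(m[, keep, drop = FALSE])
    mu <- colMeans(m[, keep, drop = FALSE])
    ids <- bc$neuron_id[keep]
    ut <- which(upper.tri(C), arr.ind = TRUE)
    out[[length(out) + 1]] <- tibble::tibble(
      neuron_i = ids[ut[, 1]], neuron_j = ids[ut[, 2]],
      bin = b, r = C[ut],
      mean_count = (mu[ut[, 1]] + mu[ut[, 2]]) / 2
    )
  }
  dplyr::bind_rows(out)
}

# trials x bins x neurons count array over the stimulus duration
binned_counts <- function(x, bin_ms, neuron_ids, stimulus, condition,
                          min_trials, seed) {
  stopifnot(inherits(x, "commdyn_session"))
  neuron_ids <- neuron_ids %||% default_target_neurons(x)
  tr <- x$trials[!x$trials$excluded & x$trials$condition == condition, ]
  if (!is.null(stimulus)) {
    tr <- tr[tr$stimulus %in% stimulus, ]
  } else {
    tr <- subsample_balanced(tr, "stimulus", seed = seed)
  }
  if (nrow(tr) < min_trials) {
    stop("need at least ", min_trials, " trials", call. = FALSE)
  }
  starts <- seq(0, x$stimulus_duration - bin_ms, by = bin_ms)
  if (length(starts) < 2) stop("need at least 2 bins", call. = FALSE)
  arr <- array(0L, c(nrow(tr), length(starts), length(neuron_ids)))
  for (b in seq_along(starts)) {
    cm <- window_counts(x, starts[b], bin_ms, trial_ids = tr$trial_id,
                        neuron_ids = neuron_ids)
    arr[, b, ] <- cm$counts
  }
  list(arr = arr, bins = starts, neuron_id = neuron_ids,
       trial_id = tr$trial_id)
}
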