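#' Percent change in firing caused by source silencing
#'
#' `100 * (Rs - Rc) / Rc`, where `Rs` is the mean spike count during the
#' silencing window over silencing trials and `Rc` the mean count in the
#' corresponding window of control trials. `Rc = 0` yields `NA` (such
#' neurons are masked upstream by the rate threshold).
#'
#' @param rs_mean,rc_mean Mean spike counts per window (vectorized).
#' @return Percent change (>= -100 whenever `rc_mean > 0`).
#' @export
percent_change <- function(rs_mean, rc_mean) {
  ifelse(rc_mean > 0, 100 * (rs_mean - rc_mean) / rc_mean, NA_real_)
}

#' Bootstrap significance of a single neuron's silencing effect
#'
#' The null distribution is built from control trials only: control counts
#' are resampled with replacement into two pseudo-condition groups of the
#' observed control / silencing sizes and the percent change between their
#' means is computed, `n_boot` times. The observed effect is significant
#' when it falls outside the \[2.5, 97.5\] percentile interval of this null;
#' the Bonferroni variant (for 8 window comparisons) uses the
#' \[100 * a, 100 * (1 - a)\] interval with `a = 0.05 / (2 * 8)`.
#'
#' @param control_counts,silencing_counts Integer spike counts per trial in
#'   the analysis window.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Seed.
#' @param n_comparisons Bonferroni correction factor (default 8 windows).
#' @param min_trials Guard: minimum trials per condition (default 5).
#' @return One-row tibble: `percent_change`, `ci_lo`, `ci_hi` (null
#'   interval), `significant`, `significant_bonf`, `n_control`,
#'   `n_silencing`. All-zero control counts give a masked (all-`NA`) row.
#' @export
effect_significance <- function(control_counts, silencing_counts,
                                n_boot = 1000, seed = NULL,
                                n_comparisons = 8, min_trials = 5) {
  nc <- length(control_counts)
  ns <- length(silencing_counts)
  if (nc < min_trials || ns < min_trials) {
    stop("need at least ", min_trials, " trials per condition", call. = FALSE)
  }
  rc <- mean(control_counts)
  if (rc == 0) {
    return(tibble::tibble(
      percent_change = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
      significant = NA, significant_bonf = NA,
      n_control = nc, n_silencing = ns
    ))
  }
  obs <- percent_change(mean(silencing_counts), rc)
  null <- with_seed(seed, {
    a <- matrix(sample(control_counts, nc * n_boot, replace = TRUE), nc)
    b <- matrix(sample(control_counts, ns * n_boot, replace = TRUE), ns)
    ma <- colMeans(a)
    percent_change(colMeans(b), ma)
  })
  null <- null[is.finite(null)]
  ci <- stats::quantile(null, c(0.025, 0.975), names = FALSE)
  a8 <- 0.05 / (2 * n_comparisons)
  ci_b <- stats::quantile(null, c(a8, 1 - a8), names = FALSE)
  tibble::tibble(
    percent_change = obs,
    ci_lo = ci[1], ci_hi = ci[2],
    significant = obs < ci[1] | obs > ci[2],
    significant_bonf = obs < ci_b[1] | obs > ci_b[2],
    n_control = nc, n_silencing = ns
  )
}

#' Per-neuron silencing-effect table across windows and stimuli
#'
#' For every (neuron, silencing window, stimulus) cell: the percent change
#' in the 150-ms silencing window relative to the same window in control
#' trials, with bootstrap significance (raw and Bonferroni-corrected for the
#' number of windows). Neurons whose trial-averaged window rate falls below
#' `threshold_hz` (pooled across conditions) are masked in that window.
#'
#' @param x A `commdyn_session`.
#' @param stimuli `"per_stimulus"` (default; one row per stimulus, matching
#'   the per-stimulus analyses) or `"pooled"` (go and no-go trials pooled).
#' @param neuron_ids Neurons to evaluate (default: all).
#' @param threshold_hz Rate threshold in the window (default 2.5 Hz).
#' @param n_boot,seed Bootstrap controls (see [effect_significance()]).
#' @param min_trials Guard on per-condition trial counts.
#' @return A tibble of class `commdyn_effects`: one row per neuron x window
#'   (x stimulus), with columns of [effect_significance()] plus `neuron_id`,
#'   `window`, `stimulus`, `masked`.
#' @export
effect_table <- function(x, stimuli = c("per_stimulus", "pooled"),
                         neuron_ids = NULL, threshold_hz = 2.5,
                         n_boot = 1000, seed = NULL, min_trials = 5) {
  stopifnot(inherits(x, "commdyn_session"))
  stimuli <- match.arg(stimuli)
  neuron_ids <- neuron_ids %||% x$neurons$neuron_id
  onsets <- x$silencing_onsets
  dur <- x$silencing_duration
  tr <- x$trials[!x$trials$excluded, ]
  stim_sets <- if (stimuli == "pooled") {
    list(pooled = c("go", "nogo"))
  } else {
    list(go = "go", nogo = "nogo")
  }
  seeds <- derive_seeds(seed %||% 0, length(onsets) * length(stim_sets))
  si <- 0
  rows <- list()
  for (w in seq_along(onsets)) {
    ctrl_ids <- tr$trial_id[tr$condition == "control"]
    sil_ids <- tr$trial_id[tr$condition == "silencing" &
                             tr$silencing_window == w]
    sil_ids <- sil_ids[!is.na(sil_ids)]
    cm <- window_counts(x, onsets[w], dur,
                        trial_ids = c(ctrl_ids, sil_ids),
                        neuron_ids = neuron_ids)
    cm <- apply_rate_threshold(cm, threshold_hz)
    masked <- !cm$mask[1, ]
    for (ss in seq_along(stim_sets)) {
      si <- si + 1
      stim <- stim_sets[[ss]]
      keep_stim <- tr$stimulus[match(cm$trial_id, tr$trial_id)] %in% stim
      is_ctrl <- cm$trial_id %in% ctrl_ids & keep_stim
      is_sil <- cm$trial_id %in% sil_ids & keep_stim
      nseeds <- derive_seeds(seeds[si], length(neuron_ids))
      res <- purrr::map_dfr(seq_along(neuron_ids), function(j) {
        if (masked[j]) {
          return(tibble::tibble(
            percent_change = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
            significant = NA, significant_bonf = NA,
            n_control = sum(is_ctrl), n_silencing = sum(is_sil)
          ))
        }
        effect_significance(cm$counts[is_ctrl, j], cm$counts[is_sil, j],
                            n_boot = n_boot, seed = nseeds[j],
                            n_comparisons = length(onsets),
                            min_trials = min_trials)
      })
      res$neuron_id <- neuron_ids
      res$window <- w
      res$stimulus <- names(stim_sets)[ss]
      res$masked <- masked
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::relocate("neuron_id", "window", "stimulus")
  class(out) <- c("commdyn_effects", class(out))
  out
}

#' Number of significantly affected windows per neuron
#'
#' Counts, per neuron, the silencing windows with a Bonferroni-significant
#' effect. When the table holds per-stimulus rows they are first averaged
#' across go and no-go (a window counts if significant for the averaged
#' criterion: significant in at least one stimulus by default, or `"both"`).
#'
#' @param effects A `commdyn_effects` table.
#' @param combine How per-stimulus significance is combined within a window:
#'   `"any"` (default) or `"both"`.
#' @return Tibble `neuron_id`, `n_significant_windows` (0..n windows).
#' @export
count_significant_windows <- function(effects, combine = c("any", "both")) {
  combine <- match.arg(combine)
  f <- if (combine == "any") any else all
  effects |>
    dplyr::group_by(.data$neuron_id, .data$window) |>
    dplyr::summarise(
      sig = f(stats::na.omit(.data$significant_bonf)) &&
        any(!is.na(.data$significant_bonf)),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(n_significant_windows = sum(.data$sig), .groups = "drop")
}

#' Choice and stimulus selectivity indices
#'
#' Per-neuron indices derived from outcome-sorted firing rates. With `RH`,
#' `RM`, `RF`, `RC` the mean rates over the full stimulus in hit, miss,
#' false-alarm and correct-rejection trials, and `rH`, `rC` the rates in the
#' first 150 ms of hit and correct-rejection trials:
#' * choice index `= ((RH-RM)/(RH+RM) + (RF-RC)/(RF+RC)) / 2`
#' * stimulus index `= |(rH-rC)/(rH+rC)|`
#' * preferred stimulus `= sign(rH-rC)`
#' * choice-matched stimulus index
#'   `= |((RH-RF)/(RH+RF) + (RM-RC)/(RM+RC)) / 2|`
#' A term whose denominator is zero is dropped from the average (both zero:
#' masked `NA`).
#'
#' @param x A `commdyn_session` (outcomes are classified if needed).
#' @param neuron_ids Neurons to evaluate (default all).
#' @param early_ms Length of the early window for the stimulus index
#'   (default 150 ms).
#' @param response_window Passed to [classify_trials()].
#' @return Tibble, one row per neuron: `choice_index`, `stimulus_index`,
#'   `preferred_stimulus`, `stimulus_index_choice_matched`.
#' @export
selectivity_indices <- function(x, neuron_ids = NULL, early_ms = 150,
                                response_window = c(100, 550)) {
  stopifnot(inherits(x, "commdyn_session"))
  if (!"outcome" %in% names(x$trials)) x <- classify_trials(x, response_window)
  neuron_ids <- neuron_ids %||% x$neurons$neuron_id
  tr <- x$trials[!x$trials$excluded & x$trials$condition == "control", ]
  mean_rate <- function(outcome, onset, dur) {
    ids <- tr$trial_id[tr$outcome == outcome]
    if (length(ids) == 0) {
      return(rep(NA_real_, length(neuron_ids)))
    }
    cm <- window_counts(x, onset, dur, trial_ids = ids,
                        neuron_ids = neuron_ids)
    unname(colMeans(cm$counts)) / (dur / 1000)
  }
  RH <- mean_rate("hit", 0, x$stimulus_duration)
  RM <- mean_rate("miss", 0, x$stimulus_duration)
  RF <- mean_rate("false_alarm", 0, x$stimulus_duration)
  RC <- mean_rate("correct_rejection", 0, x$stimulus_duration)
  rH <- mean_rate("hit", 0, early_ms)
  rC <- mean_rate("correct_rejection", 0, early_ms)
  nd <- function(a, b) ifelse(a + b > 0, (a - b) / (a + b), NA_real_)
  mean2 <- function(t1, t2) {
    m <- rowMeans(cbind(t1, t2), na.rm = TRUE)
    ifelse(is.nan(m), NA_real_, m)
  }
  tibble::tibble(
    neuron_id = neuron_ids,
    choice_index = mean2(nd(RH, RM), nd(RF, RC)),
    stimulus_index = abs(nd(rH, rC)),
    preferred_stimulus = sign(rH - rC),
    stimulus_index_choice_matched = abs(mean2(nd(RH, RF), nd(RM, RC)))
  )
}
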