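#' Classify trial outcomes from lick times
#'
#' Applies the go/no-go outcome rule: a lick inside the response window on a
#' go trial is a hit (otherwise miss); on a no-go trial a lick inside the
#' window is a false alarm (otherwise correct rejection).
#'
#' @param x A `commdyn_session`.
#' @param response_window Two-element numeric, ms after stimulus onset
#'   (default `c(100, 550)`; some animals are run with `c(100, 650)`).
#' @return The session with an `outcome` column
#'   (`hit`/`miss`/`false_alarm`/`correct_rejection`) added to the trial
#'   table.
#' @export
classify_trials <- function(x, response_window = c(100, 550)) {
  stopifnot(inherits(x, "commdyn_session"), length(response_window) == 2)
  lt <- x$trials$lick_time_ms
  licked <- !is.na(lt) & lt >= response_window[1] & lt <= response_window[2]
  go <- x$trials$stimulus == "go"
  x$trials$outcome <- dplyr::case_when(
    go & licked ~ "hit",
    go & !licked ~ "miss",
    !go & licked ~ "false_alarm",
    TRUE ~ "correct_rejection"
  )
  x
}

#' Behavioral discriminability (d-prime)
#'
#' `d' = Z(hit rate) - Z(false-alarm rate)` with `Z` the standard-normal
#' quantile function. Rates of exactly 0 or 1 are clipped by the 1/(2N) rule
#' (0 to `1/(2N)`, 1 to `1 - 1/(2N)`) so that d-prime stays finite;
#' antisymmetric in its arguments.
#'
#' @param hit_rate,fa_rate Proportions in \[0, 1\].
#' @param n_go,n_nogo Trial counts behind each rate, used for clipping;
#'   defaults keep unclipped rates untouched and clip boundary rates as if
#'   N = 20.
#' @return d-prime (numeric scalar, vectorized over rates).
#' @export
dprime <- function(hit_rate, fa_rate, n_go = 20, n_nogo = 20) {
  clip <- function(p, n) pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  stats::qnorm(clip(hit_rate, n_go)) - stats::qnorm(clip(fa_rate, n_nogo))
}

#' Session-level behavior summary
#'
#' Hit rate, false-alarm rate and d-prime from classified (or classifiable)
#' trials, control and silencing pooled.
#'
#' @param x A `commdyn_session`.
#' @param response_window Passed to [classify_trials()] when outcomes are not
#'   yet present.
#' @return One-row tibble: `n_go`, `n_nogo`, `hit_rate`, `fa_rate`, `dprime`.
#' @export
behavior_summary <- function(x, response_window = c(100, 550)) {
  if (!"outcome" %in% names(x$trials)) x <- classify_trials(x, response_window)
  tr <- x$trials[!x$trials$excluded, ]
  n_go <- sum(tr$stimulus == "go")
  n_nogo <- sum(tr$stimulus == "nogo")
  hr <- sum(tr$outcome == "hit") / n_go
  fr <- sum(tr$outcome == "false_alarm") / n_nogo
  tibble::tibble(
    n_go = n_go, n_nogo = n_nogo,
    hit_rate = hr, fa_rate = fr,
    dprime = dprime(hr, fr, n_go, n_nogo)
  )
}

#' Chance level of d-prime from trial shuffling
#'
#' Shuffles the go/no-go identity of trials (keeping lick behavior fixed),
#' recomputes d-prime each time, and returns the 99th percentile of the null
#' distribution. An animal is considered above chance when its observed
#' d-prime exceeds this level.
#'
#' @param x A `commdyn_session`.
#' @param n_shuffles Number of label shuffles (default 5000).
#' @param seed Seed for the shuffles.
#' @param response_window Passed to [classify_trials()].
#' @return The 99th-percentile null d-prime (numeric scalar).
#' @export
dprime_chance <- function(x, n_shuffles = 5000, seed = NULL,
                          response_window = c(100, 550)) {
  if (!"outcome" %in% names(x$trials)) x <- classify_trials(x, response_window)
  tr <- x$trials[!x$trials$excluded, ]
  stopifnot(sum(tr$stimulus == "go") >= 2, sum(tr$stimulus == "nogo") >= 2)
  licked <- tr$outcome %in% c("hit", "false_alarm")
  n_go <- sum(tr$stimulus == "go")
  n <- nrow(tr)
  null_dp <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      go_idx <- sample.int(n, n_go)
      is_go <- seq_len(n) %in% go_idx
      hr <- sum(licked & is_go) / n_go
      fr <- sum(licked & !is_go) / (n - n_go)
      dprime(hr, fr, n_go, n - n_go)
    }, numeric(1))
  })
  as.numeric(stats::quantile(null_dp, 0.99, type = 7))
}

#' Onset-corrected reaction-time and d-prime silencing contrasts
#'
#' For each silencing window only behavioral responses that could still be
#' influenced by the manipulation are informative, so trials whose lick
#' precedes the window onset are dropped from that window's statistic (the
#' onset correction). Control trials are assigned pseudo-onsets uniformly at
#' random from the silencing-onset grid so the same correction applies.
#' Reaction time is the first-lick time on correct (hit) go trials; percent
#' changes are relative to the session mean RT / mean d-prime. Windows with
#' onset earlier than `split_ms` are aggregated as `early`, the rest as
#' `late`. Raw (uncorrected) variants are included.
#'
#' @param x A `commdyn_session`.
#' @param split_ms Early/late split of window onsets (default 100 ms).
#' @param seed Seed for the control pseudo-onset assignment.
#' @param response_window Passed to [classify_trials()].
#' @return List with `per_window` (tibble: window, onset, condition,
#'   corrected, n_rt, rt_ms, rt_pct_change, dprime, dprime_pct_change) and
#'   `early_late` (the same aggregated over early/late windows).
#' @export
onset_corrected_metrics <- function(x, split_ms = 100, seed = NULL,
                                    response_window = c(100, 550)) {
  if (!"outcome" %in% names(x$trials)) x <- classify_trials(x, response_window)
  tr <- x$trials[!x$trials$excluded, ]
  onsets <- x$silencing_onsets
  # session-wide references
  rt_all <- tr$lick_time_ms[tr$outcome == "hit"]
  mean_rt <- mean(rt_all)
  bs <- behavior_summary(x, response_window)
  mean_dp <- bs$dprime
  # control pseudo-window assignment
  n_ctrl <- sum(tr$condition == "control")
  pseudo <- with_seed(seed, sample(seq_along(onsets), n_ctrl, replace = TRUE))
  tr$window_index <- tr$silencing_window
  tr$window_index[tr$condition == "control"] <- pseudo

  cell_stats <- function(d, corrected, onset) {
    if (corrected) {
      keep <- is.na(d$lick_time_ms) | d$lick_time_ms > onset
      d <- d[keep, ]
    }
    n_go <- sum(d$stimulus == "go")
    n_nogo <- sum(d$stimulus == "nogo")
    rts <- d$lick_time_ms[d$outcome == "hit"]
    dp <- if (n_go >= 1 && n_nogo >= 1) {
      dprime(sum(d$outcome == "hit") / n_go,
             sum(d$outcome == "false_alarm") / n_nogo, n_go, n_nogo)
    } else {
      NA_real_
    }
    tibble::tibble(
      n_rt = length(rts),
      rt_ms = if (length(rts) > 0) mean(rts) else NA_real_,
      rt_pct_change = if (length(rts) > 0) {
        100 * (mean(rts) - mean_rt) / mean_rt
      } else {
        NA_real_
      },
      dprime = dp,
      dprime_pct_change = 100 * (dp - mean_dp) / mean_dp
    )
  }

  grid <- tidyr::expand_grid(
    window = seq_along(onsets),
    condition = c("control", "silencing"),
    corrected = c(TRUE, FALSE)
  )
  per_window <- purrr::pmap_dfr(grid, function(window, condition, corrected) {
    d <- tr[tr$condition == condition & tr$window_index == window, ]
    dplyr::bind_cols(
      tibble::tibble(window = window, onset = onsets[window],
                     condition = condition, corrected = corrected),
      cell_stats(d, corrected, onsets[window])
    )
  })

  early_late <- purrr::pmap_dfr(
    tidyr::expand_grid(epoch = c("early", "late"),
                       condition = c("control", "silencing"),
                       corrected = c(TRUE, FALSE)),
    function(epoch, condition, corrected) {
      wins <- which(if (epoch == "early") onsets < split_ms else onsets >= split_ms)
      sub <- per_window[per_window$window %in% wins &
                          per_window$condition == condition &
                          per_window$corrected == corrected, ]
      tibble::tibble(
        epoch = epoch, condition = condition, corrected = corrected,
        rt_pct_change = mean(sub$rt_pct_change, na.rm = TRUE),
        dprime_pct_change = mean(sub$dprime_pct_change, na.rm = TRUE)
      )
    }
  )
  list(per_window = per_window, early_late = early_late)
}
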