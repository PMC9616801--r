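#' Assemble a two-area silencing session
#'
#' A session bundles the three tables describing one animal's simultaneous
#' two-area recording under interleaved optogenetic silencing: a spike-event
#' table, a trial table, and a neuron metadata table, together with the
#' stimulus/silencing timing. All spike times are in milliseconds relative to
#' visual stimulus onset (onset = 0); negative times are pre-stimulus
#' activity.
#'
#' @param spikes Tibble with columns `neuron_id`, `trial_id`, `t_ms` (one row
#'   per spike). Trials or neurons without spikes may be absent from this
#'   table; they still contribute zero counts.
#' @param trials Tibble with columns `trial_id`, `stimulus` (`"go"`/`"nogo"`),
#'   `condition` (`"control"`/`"silencing"`), `silencing_window` (integer
#'   window index, `NA` on control trials), `lick_time_ms` (`NA` if no lick),
#'   and optionally `excluded` (logical, default `FALSE`).
#' @param neurons Tibble with columns `neuron_id`, `area` (`"source"` or
#'   `"target"`), and optionally `depth_um`, `rf_distance_deg`,
#'   `waveform_class`. A `mean_rate_hz` column is computed over the recorded
#'   span if absent.
#' @param stimulus_duration Stimulus duration in ms (default 500).
#' @param silencing_duration Duration of each optogenetic pulse in ms
#'   (default 150).
#' @param silencing_onsets Strictly increasing silencing-onset times in ms
#'   relative to stimulus onset. Default: the eight onsets tiling the 500-ms
#'   stimulus in ~65-ms steps.
#' @param pre_window Length in ms of the recorded pre-stimulus span used for
#'   baseline statistics (default 500).
#' @param animal_id Opaque label for the animal/session.
#'
#' @return An object of class `commdyn_session`.
#' @export
session <- function(spikes, trials, neurons,
                    stimulus_duration = 500,
                    silencing_duration = 150,
                    silencing_onsets = c(0, 56, 123, 189, 256, 323, 390, 456),
                    pre_window = 500,
                    animal_id = "session") {
  spikes <- tibble::as_tibble(spikes)
  trials <- tibble::as_tibble(trials)
  neurons <- tibble::as_tibble(neurons)
  if (!all(c("neuron_id", "trial_id", "t_ms") %in% names(spikes))) {
    stop("`spikes` needs columns neuron_id, trial_id, t_ms", call. = FALSE)
  }
  need <- c("trial_id", "stimulus", "condition", "silencing_window")
  if (!all(need %in% names(trials))) {
    stop("`trials` needs columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!"lick_time_ms" %in% names(trials)) trials$lick_time_ms <- NA_real_
  if (!"excluded" %in% names(trials)) trials$excluded <- FALSE
  if (!all(c("neuron_id", "area") %in% names(neurons))) {
    stop("`neurons` needs columns neuron_id, area", call. = FALSE)
  }
  if (length(silencing_onsets) < 2 || any(diff(silencing_onsets) <= 0)) {
    stop("`silencing_onsets` must be strictly increasing, length >= 2",
         call. = FALSE)
  }
  if (!all(is.finite(spikes$t_ms))) {
    stop("spike times must be finite", call. = FALSE)
  }
  if (anyDuplicated(trials$trial_id)) {
    stop("duplicated trial_id in trial table", call. = FALSE)
  }
  if (anyDuplicated(neurons$neuron_id)) {
    stop("duplicated neuron_id in neuron table", call. = FALSE)
  }
  bad_ctrl <- trials$condition == "control" & !is.na(trials$silencing_window)
  bad_sil <- trials$condition == "silencing" & is.na(trials$silencing_window)
  if (any(bad_ctrl) || any(bad_sil)) {
    stop("condition == 'control' must coincide with silencing_window == NA",
         call. = FALSE)
  }
  w <- trials$silencing_window
  if (any(!is.na(w) & (w < 1 | w > length(silencing_onsets)))) {
    stop("silencing_window indices must lie in 1..", length(silencing_onsets),
         call. = FALSE)
  }
  if (!all(spikes$trial_id %in% trials$trial_id)) {
    stop("spike table references unknown trial_id", call. = FALSE)
  }
  if (!all(spikes$neuron_id %in% neurons$neuron_id)) {
    stop("spike table references unknown neuron_id", call. = FALSE)
  }
  if (!"mean_rate_hz" %in% names(neurons)) {
    span_s <- (pre_window + stimulus_duration + silencing_duration) / 1000
    rate <- spikes |>
      dplyr::count(.data$neuron_id) |>
      dplyr::mutate(mean_rate_hz = .data$n / (span_s * nrow(trials)))
    neurons <- neurons |>
      dplyr::left_join(rate[, c("neuron_id", "mean_rate_hz")], by = "neuron_id") |>
      dplyr::mutate(mean_rate_hz = dplyr::coalesce(.data$mean_rate_hz, 0))
  }
  structure(
    list(
      animal_id = animal_id,
      spikes = spikes,
      trials = trials,
      neurons = neurons,
      stimulus_duration = stimulus_duration,
      silencing_duration = silencing_duration,
      silencing_onsets = silencing_onsets,
      pre_window = pre_window
    ),
    class = "commdyn_session"
  )
}

#' @export
print.commdyn_session <- function(x, ...) {
  cat("<commdyn_session> ", x$animal_id, "\n", sep = "")
  cat("  neurons: ", nrow(x$neurons), " (",
      paste(sprintf("%s=%d", names(table(x$neurons$area)),
                    as.integer(table(x$neurons$area))), collapse = ", "),
      ")\n", sep = "")
  tb <- table(x$trials$condition)
  cat("  trials:  ", nrow(x$trials), " (",
      paste(sprintf("%s=%d", names(tb), as.integer(tb)), collapse = ", "),
      ")\n", sep = "")
  cat("  stimulus ", x$stimulus_duration, " ms; silencing ",
      x$silencing_duration, " ms at onsets ",
      paste(x$silencing_onsets, collapse = ", "), " ms\n", sep = "")
  invisible(x)
}

#' Spike counts of every neuron in one analysis window
#'
#' Counts spikes falling in the half-open window `[onset, onset + duration)`
#' (ms relative to stimulus onset) for each selected trial and neuron. A
#' spike exactly at the right edge belongs to the next window, so disjoint
#' windows tiling an interval partition its spikes exactly.
#'
#' @param x A `commdyn_session`.
#' @param onset,duration Window onset and duration in ms.
#' @param trial_ids Trial ids to include; default all non-excluded trials.
#' @param neuron_ids Neuron ids (columns); default all neurons.
#' @return A `commdyn_counts` object: integer matrix `counts`
#'   (trials x neurons), a logical validity `mask` of the same shape, the
#'   window, and back-references `trial_id`, `neuron_id` plus the matching
#'   slice of the trial table.
#' @export
window_counts <- function(x, onset, duration,
                          trial_ids = NULL, neuron_ids = NULL) {
  stopifnot(inherits(x, "commdyn_session"))
  lo <- -x$pre_window
  hi <- x$stimulus_duration + x$silencing_duration
  if (onset < lo || onset + duration > hi) {
    stop(sprintf("window [%g, %g) outside recorded range [%g, %g]",
                 onset, onset + duration, lo, hi), call. = FALSE)
  }
  trials <- x$trials[!x$trials$excluded, ]
  if (!is.null(trial_ids)) {
    trials <- trials[trials$trial_id %in% trial_ids, ]
  }
  if (nrow(trials) == 0) {
    stop("empty trial selection", call. = FALSE)
  }
  neuron_ids <- neuron_ids %||% x$neurons$neuron_id
  sp <- x$spikes
  sp <- sp[sp$t_ms >= onset & sp$t_ms < onset + duration &
             sp$trial_id %in% trials$trial_id &
             sp$neuron_id %in% neuron_ids, ]
  counts <- matrix(0L, nrow(trials), length(neuron_ids),
                   dimnames = list(NULL, as.character(neuron_ids)))
  if (nrow(sp) > 0) {
    i <- match(sp$trial_id, trials$trial_id)
    j <- match(sp$neuron_id, neuron_ids)
    tab <- table(factor(i, levels = seq_len(nrow(trials))),
                 factor(j, levels = seq_along(neuron_ids)))
    counts[] <- as.integer(tab)
  }
  new_counts(counts, window = c(onset = onset, duration = duration),
             trial_id = trials$trial_id, neuron_id = neuron_ids,
             trials = trials)
}

new_counts <- function(counts, window, trial_id, neuron_id, trials,
                       mask = NULL) {
  structure(
    list(
      counts = counts,
      mask = mask %||% matrix(TRUE, nrow(counts), ncol(counts),
                              dimnames = dimnames(counts)),
      window = window,
      trial_id = trial_id,
      neuron_id = neuron_id,
      trials = trials
    ),
    class = "commdyn_counts"
  )
}

#' @export
print.commdyn_counts <- function(x, ...) {
  cat(sprintf("<commdyn_counts> %d trials x %d neurons, window [%g, %g) ms; %d masked entries\n",
              nrow(x$counts), ncol(x$counts), x$window[["onset"]],
              x$window[["onset"]] + x$window[["duration"]], sum(!x$mask)))
  invisible(x)
}

#' @describeIn window_counts Long tibble view of a count matrix (one row per
#'   trial x neuron, masked entries flagged).
#' @param ... Unused.
#' @export
tidy.commdyn_counts <- function(x, ...) {
  tibble::tibble(
    trial_id = rep(x$trial_id, times = ncol(x$counts)),
    neuron_id = rep(x$neuron_id, each = nrow(x$counts)),
    count = as.vector(x$counts),
    valid = as.vector(x$mask)
  )
}

#' Mask low-rate neurons in an analysis window
#'
#' Firing rates in windows where a neuron's trial-averaged rate falls below a
#' threshold are unreliable denominators for percent-change statistics, so
#' such neurons are masked (excluded from every downstream statistic in this
#' window). The default threshold of 2.5 Hz is the rate at which the window's
#' 95% confidence interval of the firing rate clears zero. The threshold is
#' evaluated on all trials pooled across conditions by default.
#'
#' @param cm A `commdyn_counts` object.
#' @param threshold_hz Minimum trial-averaged firing rate (Hz).
#' @param by `"pooled"` (default) evaluates one rate per neuron over all
#'   trials in `cm`; `"condition"` masks a neuron if its rate falls below
#'   threshold in either condition present.
#' @return The count matrix with an updated mask. Raising the threshold never
#'   unmasks an entry.
#' @export
apply_rate_threshold <- function(cm, threshold_hz = 2.5,
                                 by = c("pooled", "condition")) {
  stopifnot(inherits(cm, "commdyn_counts"), threshold_hz >= 0)
  by <- match.arg(by)
  dur_s <- cm$window[["duration"]] / 1000
  if (by == "pooled") {
    rate <- colMeans(cm$counts) / dur_s
    low <- rate < threshold_hz
  } else {
    cond <- cm$trials$condition
    low <- rep(FALSE, ncol(cm$counts))
    for (cc in unique(cond)) {
      rate <- colMeans(cm$counts[cond == cc, , drop = FALSE]) / dur_s
      low <- low | rate < threshold_hz
    }
  }
  cm$mask[, low] <- FALSE
  cm
}

#' Visually responsive neurons
#'
#' Keeps neurons that (a) spike at least once on average during the stimulus
#' for the go or the no-go stimulus and (b) show a significant two-sided
#' paired rank test (p < 0.05) between per-trial stimulus-window counts and
#' counts in an equal-length pre-stimulus window, for at least one stimulus.
#' Evaluated on control trials.
#'
#' @param x A `commdyn_session`.
#' @param alpha Significance level of the paired Wilcoxon signed-rank test.
#' @return Character vector of responsive neuron ids.
#' @export
select_responsive_neurons <- function(x, alpha = 0.05) {
  stopifnot(inherits(x, "commdyn_session"))
  ctrl <- x$trials[x$trials$condition == "control" & !x$trials$excluded, ]
  for (stim in c("go", "nogo")) {
    if (sum(ctrl$stimulus == stim) < 2) {
      stop("need at least 2 control trials per stimulus", call. = FALSE)
    }
  }
  dur <- min(x$pre_window, x$stimulus_duration)
  keep <- logical(nrow(x$neurons))
  for (stim in c("go", "nogo")) {
    ids <- ctrl$trial_id[ctrl$stimulus == stim]
    stim_cm <- window_counts(x, 0, dur, trial_ids = ids)
    pre_cm <- window_counts(x, -dur, dur, trial_ids = ids)
    mean_ok <- colMeans(stim_cm$counts) >= 1
    p <- vapply(seq_len(ncol(stim_cm$counts)), function(j) {
      a <- stim_cm$counts[, j]
      b <- pre_cm$counts[, j]
      if (all(a == b)) return(1)
      suppressWarnings(
        stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
      )
    }, numeric(1))
    keep <- keep | (mean_ok & !is.na(p) & p < alpha)
  }
  x$neurons$neuron_id[keep]
}

#' Balanced subsampling of trials across groups
#'
#' Downsamples every group, without replacement, to the size of the smallest
#' group, so that downstream direction estimates use equal numbers of trials
#' per group (e.g. equal go and no-go trials).
#'
#' @param trials A trial tibble.
#' @param groups Character vector of grouping column names.
#' @param seed Seed making the subsample reproducible.
#' @param required Optional character vector (or list, one element per
#'   grouping column) of group levels that must be present; a missing
#'   required group is an error naming the group.
#' @return The subsampled trial tibble (original row order within groups not
#'   preserved; no trial duplicated).
#' @export
subsample_balanced <- function(trials, groups, seed = NULL, required = NULL) {
  trials <- tibble::as_tibble(trials)
  stopifnot(all(groups %in% names(trials)), nrow(trials) > 0)
  key <- interaction(trials[groups], drop = TRUE, sep = "/")
  if (!is.null(required)) {
    have <- levels(key)
    miss <- setdiff(required, have)
    if (length(miss) > 0) {
      stop("required group(s) empty: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
  }
  n_min <- min(table(key))
  with_seed(seed, {
    idx <- unlist(lapply(split(seq_len(nrow(trials)), key), function(i) {
      if (length(i) == n_min) i else sample(i, n_min)
    }), use.names = FALSE)
    trials[sort(idx), ]
  })
}

#' Session inclusion check
#'
#' A session enters population analyses when it has at least 10 control
#' trials and, for trained-task analyses, the animal's behavioral d-prime
#' exceeds the 99th percentile of the trial-shuffled d-prime null.
#'
#' @param x A `commdyn_session`.
#' @param min_control_trials Minimum control-trial count (default 10).
#' @param check_behavior Whether to require above-chance d-prime.
#' @param n_shuffles,seed Passed to [dprime_chance()].
#' @return One-row tibble with `include` (logical) and `reason` (`NA` when
#'   included).
#' @export
include_session <- function(x, min_control_trials = 10, check_behavior = TRUE,
                            n_shuffles = 5000, seed = NULL) {
  stopifnot(inherits(x, "commdyn_session"))
  n_ctrl <- sum(x$trials$condition == "control" & !x$trials$excluded)
  if (n_ctrl < min_control_trials) {
    return(tibble::tibble(include = FALSE, reason = "control trial count"))
  }
  if (check_behavior) {
    bs <- behavior_summary(x)
    chance <- dprime_chance(x, n_shuffles = n_shuffles, seed = seed)
    if (!(bs$dprime > chance)) {
      return(tibble::tibble(include = FALSE, reason = "chance-level behavior"))
    }
  }
  tibble::tibble(include = TRUE, reason = NA_character_)
}
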