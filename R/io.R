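#' Read and write sessions as plain-text bundles
#'
#' A session directory holds four files: `trials.csv` (trial table),
#' `spikes.csv` (columns `neuron_id`, `trial_id`, `t_ms`), `neurons.csv`
#' (neuron metadata) and `meta.json` (timing parameters and animal id).
#' All times are ms relative to stimulus onset.
#'
#' @param x A `commdyn_session`.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_session()` returns `dir` invisibly; `read_session()`
#'   returns a `commdyn_session`.
#' @export
write_session <- function(x, dir) {
  stopifnot(inherits(x, "commdyn_session"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(x$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(x$spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(x$neurons, file.path(dir, "neurons.csv"),
                   row.names = FALSE)
  meta <- list(
    animal_id = x$animal_id,
    stimulus_duration = x$stimulus_duration,
    silencing_duration = x$silencing_duration,
    silencing_onsets = x$silencing_onsets,
    pre_window = x$pre_window
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  rd <- function(f) {
    tibble::as_tibble(utils::read.csv(file.path(dir, f),
                                      stringsAsFactors = FALSE))
  }
  trials <- rd("trials.csv")
  trials$silencing_window <- as.integer(trials$silencing_window)
  trials$lick_time_ms <- as.numeric(trials$lick_time_ms)
  session(
    spikes = rd("spikes.csv"),
    trials = trials,
    neurons = rd("neurons.csv"),
    stimulus_duration = meta$stimulus_duration,
    silencing_duration = meta$silencing_duration,
    silencing_onsets = meta$silencing_onsets,
    pre_window = meta$pre_window,
    animal_id = meta$animal_id
  )
}
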