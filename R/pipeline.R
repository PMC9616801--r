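#' Configure an end-to-end analysis run
#'
#' Collects the inputs, stage toggles, seeds and tuning parameters for
#' [run_pipeline()]. Either a session (or session directory) or a
#' [sim_config()] must be supplied; with a sim config the session is
#' generated first and its ground truth carried into the report.
#'
#' @param session A `commdyn_session`, a session directory path, or `NULL`.
#' @param sim A `commdyn_sim_config`, or `NULL`.
#' @param stages Character vector of stages to run, any of `"effects"`,
#'   `"behavior"`, `"glm"`, `"directions"`, `"decay"`, `"pcs"`,
#'   `"correlations"`, `"magnitude"`, `"null_sim"`.
#' @param gamma,delta LDA regularization; `NULL` tunes them per animal on
#'   the first window with [tune_lda_params()].
#' @param glm_covariate Covariate for the encoding model (default
#'   `"depth_um"`).
#' @param n_splits,n_boot,n_repeats,n_shuffles Monte-Carlo sizes.
#' @param threshold_hz Rate threshold.
#' @param force_include Skip the [include_session()] gate.
#' @param seed Master seed; each stage derives its own stream from it.
#' @return A `commdyn_pipeline_config` list.
#' @export
pipeline_config <- function(session = NULL, sim = NULL,
                            stages = c("effects", "behavior", "directions",
                                       "decay", "magnitude"),
                            gamma = NULL, delta = 0,
                            glm_covariate = "depth_um",
                            n_splits = 100, n_boot = 1000,
                            n_repeats = 100, n_shuffles = 5000,
                            threshold_hz = 2.5,
                            force_include = FALSE, seed = 1) {
  if (is.null(session) && is.null(sim)) {
    stop("supply a session or a sim config", call. = FALSE)
  }
  structure(
    list(session = session, sim = sim, stages = stages,
         gamma = gamma, delta = delta, glm_covariate = glm_covariate,
         n_splits = n_splits, n_boot = n_boot, n_repeats = n_repeats,
         n_shuffles = n_shuffles, threshold_hz = threshold_hz,
         force_include = force_include, seed = seed),
    class = "commdyn_pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages in dependency order on one session:
#' inclusion gate and responsive-neuron filter, per-neuron silencing
#' effects, behavioral metrics, encoding GLM, communication/activity
#' direction similarities per stimulus, exponential decay fits and initial
#' slopes, Bhattacharyya magnitudes, windowed PCs, correlations, and the
#' time-invariant null comparison. Identical configs give identical
#' numeric outputs; every stochastic stage derives its seed from the config
#' seed, recorded in the manifest.
#'
#' @param config A [pipeline_config()].
#' @return A `commdyn_report` list with one element per executed stage plus
#'   `manifest` (seeds, parameters, filter counts).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "commdyn_pipeline_config"))
  seeds <- derive_seeds(config$seed, 16)
  truth <- NULL
  x <- config$session
  if (is.null(x)) {
    sim <- simulate_session(config$sim)
    x <- sim$session
    truth <- sim$truth
  } else if (is.character(x)) {
    x <- read_session(x)
  }
  x <- classify_trials(x)
  report <- list()
  manifest <- list(seed = config$seed, stages = config$stages,
                   threshold_hz = config$threshold_hz,
                   n_trials = nrow(x$trials), n_neurons = nrow(x$neurons))

  inc <- include_session(x, check_behavior = !config$force_include,
                         n_shuffles = min(config$n_shuffles, 2000),
                         seed = seeds[1])
  report$inclusion <- inc
  if (!inc$include && !config$force_include) {
    stop("session excluded: ", inc$reason, call. = FALSE)
  }
  responsive <- select_responsive_neurons(x)
  target_ids <- intersect(responsive,
                          x$neurons$neuron_id[x$neurons$area == "target"])
  manifest$n_responsive <- length(responsive)
  manifest$n_target_used <- length(target_ids)

  gamma <- config$gamma
  delta <- config$delta
  if (is.null(gamma)) {
    wd1 <- window_data(x, target_ids, threshold_hz = config$threshold_hz)
    act <- wd1$windows[[1]]$active
    tuned <- tune_lda_params(wd1$windows[[1]]$ctrl[, act, drop = FALSE],
                             wd1$windows[[1]]$sil[, act, drop = FALSE],
                             seed = seeds[2])
    gamma <- tuned$gamma
    delta <- tuned$delta
    report$lda_tuning <- tuned
  }
  manifest$gamma <- gamma
  manifest$delta <- delta

  has <- function(s) s %in% config$stages
  if (has("effects")) {
    eff <- effect_table(x, neuron_ids = target_ids,
                        threshold_hz = config$threshold_hz,
                        n_boot = config$n_boot, seed = seeds[3])
    report$effects <- eff
    report$significant_windows <- count_significant_windows(eff)
  }
  if (has("behavior")) {
    report$behavior <- behavior_summary(x)
    report$behavior$chance_level <- dprime_chance(
      x, n_shuffles = config$n_shuffles, seed = seeds[4]
    )
    report$onset_corrected <- onset_corrected_metrics(x, seed = seeds[5])
    report$decoding <- stimulus_decoder(x, gamma = gamma, delta = delta,
                                        seed = seeds[6],
                                        neuron_ids = target_ids)
  }
  if (has("glm")) {
    obs <- glm_observations(x, config$glm_covariate,
                            neuron_ids = target_ids,
                            threshold_hz = config$threshold_hz)
    report$glm <- list(fit = fit_effect_glm(obs),
                       performance = excess_loglik(obs, seed = seeds[7]))
  }
  if (has("directions")) {
    report$cd_similarity <- lapply(
      c(go = "go", nogo = "nogo"),
      function(s) {
        communication_similarity(x, s, gamma, delta,
                                 neuron_ids = target_ids,
                                 threshold_hz = config$threshold_hz,
                                 n_splits = config$n_splits,
                                 seed = seeds[8])
      }
    )
    report$activity_similarity <- lapply(
      c(go = "go", nogo = "nogo"),
      function(s) {
        activity_similarity(x, s, neuron_ids = target_ids,
                            threshold_hz = config$threshold_hz,
                            n_splits = config$n_splits, seed = seeds[9])
      }
    )
  }
  if (has("decay") && !is.null(report$cd_similarity)) {
    report$decay <- lapply(report$cd_similarity, function(sim) {
      pr <- lag_profile(sim)
      fit_decay(pr$lag_ms, pr$similarity,
                n_boot = min(config$n_boot, 100), seed = seeds[10])
    })
    report$initial_slopes <- tibble::tibble(
      kind = rep(c("communication", "activity"), each = 2),
      stimulus = rep(c("go", "nogo"), 2),
      slope = c(vapply(report$cd_similarity, initial_slope, numeric(1)),
                vapply(report$activity_similarity, initial_slope,
                       numeric(1)))
    )
  }
  if (has("magnitude")) {
    report$magnitude <- influence_magnitude(
      x, gamma = max(gamma, 0.1), n_boot = config$n_repeats,
      seed = seeds[11], neuron_ids = target_ids,
      threshold_hz = config$threshold_hz
    )
  }
  if (has("pcs")) {
    report$pcs <- window_pcs(x, neuron_ids = target_ids,
                             threshold_hz = config$threshold_hz,
                             n_splits = config$n_splits, seed = seeds[12])
  }
  if (has("correlations")) {
    report$autocorrelation <- spike_autocorrelation(
      x, neuron_ids = target_ids, seed = seeds[13]
    )
    report$noise_correlations <- dplyr::bind_rows(
      go = pairwise_noise_correlations(x, "go", neuron_ids = target_ids),
      nogo = pairwise_noise_correlations(x, "nogo",
                                         neuron_ids = target_ids),
      .id = "stimulus"
    )
  }
  if (has("null_sim")) {
    report$null_sim <- lapply(
      c(go = "go", nogo = "nogo"),
      function(s) {
        simulate_time_invariant(x, s, gamma, delta,
                                neuron_ids = target_ids,
                                threshold_hz = config$threshold_hz,
                                n_splits = config$n_splits,
                                n_repeats = config$n_repeats,
                                seed = seeds[14])
      }
    )
  }
  report$truth <- truth
  report$manifest <- manifest
  class(report) <- "commdyn_report"
  report
}

#' @export
print.commdyn_report <- function(x, ...) {
  cat("<commdyn_report> stages:",
      paste(setdiff(names(x), c("manifest", "truth")), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Serializes the tabular stages as CSV, the fits and manifest as JSON,
#' and similarity matrices as CSV, under `dir`.
#'
#' @param report A `commdyn_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "commdyn_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wcsv <- function(d, f) {
    utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  }
  if (!is.null(report$effects)) wcsv(report$effects, "effects.csv")
  if (!is.null(report$behavior)) wcsv(report$behavior, "behavior.csv")
  if (!is.null(report$magnitude)) wcsv(report$magnitude, "magnitude.csv")
  if (!is.null(report$initial_slopes)) {
    wcsv(report$initial_slopes, "initial_slopes.csv")
  }
  if (!is.null(report$cd_similarity)) {
    for (s in names(report$cd_similarity)) {
      wcsv(as.data.frame(report$cd_similarity[[s]]$matrix),
           paste0("cd_similarity_", s, ".csv"))
      wcsv(lag_profile(report$cd_similarity[[s]]),
           paste0("cd_lag_profile_", s, ".csv"))
    }
  }
  if (!is.null(report$decay)) {
    jsonlite::write_json(
      lapply(report$decay, function(f) {
        list(A = f$A, tau = f$tau, B = f$B, converged = f$converged)
      }),
      file.path(dir, "decay.json"), auto_unbox = TRUE, digits = NA
    )
  }
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
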