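#' Plot a cross-validated similarity matrix
#'
#' Tile heatmap of the window-by-window cosine similarities, windows on
#' both axes in temporal order.
#'
#' @param object A `commdyn_similarity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.commdyn_similarity <- function(object, ...) {
  d <- tidy(object)
  lims <- if (object$absolute) c(0, 1) else c(-1, 1)
  ggplot2::ggplot(d, ggplot2::aes(.data$window_j, .data$window_i,
                                  fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = lims,
                                  midpoint = if (object$absolute) 0.5 else 0,
                                  oob = scales_squish) +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(object$matrix))) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(object$matrix))) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "time window", y = "time window",
                  fill = if (object$absolute) "|cos|" else "cos",
                  title = paste0(object$kind,
                                 if (!is.na(object$stimulus)) {
                                   paste0(" (", object$stimulus, ")")
                                 } else {
                                   ""
                                 })) +
    ggplot2::theme_minimal()
}

# minimal squish (avoids a scales dependency for one helper)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' Plot similarity lag profiles
#'
#' Lag profiles (mean similarity per time lag) of one or more similarity
#' matrices, optionally overlaid with their exponential decay fits.
#'
#' @param sims Named list of `commdyn_similarity` objects.
#' @param fits Optional named list of `commdyn_decay` fits (same names).
#' @return A ggplot object.
#' @export
plot_lag_profiles <- function(sims, fits = NULL) {
  if (inherits(sims, "commdyn_similarity")) sims <- list(profile = sims)
  d <- purrr::map_dfr(sims, lag_profile, .id = "profile")
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$lag_ms, .data$similarity,
                                       color = .data$profile)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "time lag (ms)", y = "cosine similarity") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    grid <- purrr::map_dfr(names(fits), function(nm) {
      f <- fits[[nm]]
      t <- seq(min(f$lag_ms), max(f$lag_ms), length.out = 100)
      tibble::tibble(profile = nm, lag_ms = t, similarity = decay_predict(f, t))
    })
    p <- p + ggplot2::geom_line(data = grid, linetype = 2)
  }
  p
}

#' Plot a decay fit
#'
#' @param object A `commdyn_decay`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.commdyn_decay <- function(object, ...) {
  d <- tibble::tibble(lag_ms = object$lag_ms, y = object$y)
  t <- seq(min(d$lag_ms), max(d$lag_ms), length.out = 200)
  fit <- tibble::tibble(lag_ms = t, y = decay_predict(object, t))
  ggplot2::ggplot(d, ggplot2::aes(.data$lag_ms, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fit, color = "#b2182b") +
    ggplot2::labs(
      x = "time lag (ms)", y = "similarity",
      subtitle = sprintf("A = %.3g, tau = %.3g ms, B = %.3g",
                         object$A, object$tau, object$B)
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of per-neuron silencing effects
#'
#' Distribution of percent changes in firing rate during source silencing,
#' significant effects highlighted, with the median marked.
#'
#' @param object A `commdyn_effects` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.commdyn_effects <- function(object, ...) {
  d <- object[is.finite(object$percent_change), ]
  med <- stats::median(d$percent_change)
  ggplot2::ggplot(d, ggplot2::aes(.data$percent_change,
                                  fill = .data$significant)) +
    ggplot2::geom_histogram(bins = 40, position = "stack") +
    ggplot2::geom_vline(xintercept = med, linetype = 2) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey75",
                                          `TRUE` = "#2166ac"),
                               na.value = "grey90") +
    ggplot2::labs(x = "silencing effect (% change in firing rate)",
                  y = "neuron x window x stimulus cells",
                  subtitle = sprintf("median = %.1f%%", med)) +
    ggplot2::theme_minimal()
}

#' Plot PC variance spectra
#'
#' Variance along the first PCs per condition and stimulus, averaged over
#' time windows.
#'
#' @param pcs A `commdyn_pcs` object from [window_pcs()].
#' @return A ggplot object.
#' @export
plot_pc_variance <- function(pcs) {
  d <- pcs$variance |>
    dplyr::group_by(.data$stimulus, .data$condition, .data$component) |>
    dplyr::summarise(variance = mean(.data$variance), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$component), .data$variance,
                                  fill = .data$condition)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~stimulus) +
    ggplot2::labs(x = "principal component", y = "variance") +
    ggplot2::theme_minimal()
}
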