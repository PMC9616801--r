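#' Observations for the silencing-effect encoding model
#'
#' Builds the (Rs, Rc, covariate) observations relating a target neuron's
#' silenced-window spike count to its control activity and one cell
#' property. The default unit is one observation per (neuron, silencing
#' trial) at each window, with `Rc` the neuron's control-trial mean count in
#' the same window and the covariate taken from the neuron metadata or a
#' supplied per-neuron table; `unit = "neuron_mean"` instead averages
#' silencing trials within neuron x window.
#'
#' @param x A `commdyn_session`.
#' @param covariate Name of the per-neuron covariate column (e.g.
#'   `"depth_um"`, `"rf_distance_deg"`, `"mean_rate_hz"`), looked up in
#'   `covariate_table` or the session's neuron table.
#' @param covariate_table Optional tibble `neuron_id` + covariate column
#'   (e.g. output of [selectivity_indices()]).
#' @param neuron_ids Target neurons (default: responsive target neurons).
#' @param unit `"trial"` (default) or `"neuron_mean"`.
#' @param threshold_hz Rate threshold per window.
#' @return Tibble: `neuron_id`, `window`, `rs`, `rc`, `covariate`.
#' @export
glm_observations <- function(x, covariate, covariate_table = NULL,
                             neuron_ids = NULL,
                             unit = c("trial", "neuron_mean"),
                             threshold_hz = 2.5) {
  unit <- match.arg(unit)
  neuron_ids <- neuron_ids %||% default_target_neurons(x)
  wd <- window_data(x, neuron_ids, threshold_hz = threshold_hz)
  covs <- covariate_table %||% x$neurons
  stopifnot(covariate %in% names(covs))
  cov_vec <- covs[[covariate]][match(neuron_ids, covs$neuron_id)]
  out <- list()
  for (w in seq_along(wd$windows)) {
    win <- wd$windows[[w]]
    act <- which(win$active & !is.na(cov_vec))
    if (length(act) == 0) next
    rc <- colMeans(win$ctrl[, act, drop = FALSE])
    if (unit == "neuron_mean") {
      rs <- colMeans(win$sil[, act, drop = FALSE])
      out[[w]] <- tibble::tibble(
        neuron_id = neuron_ids[act], window = w,
        rs = rs, rc = rc, covariate = cov_vec[act]
      )
    } else {
      n_sil <- nrow(win$sil)
      out[[w]] <- tibble::tibble(
        neuron_id = rep(neuron_ids[act], each = n_sil),
        window = w,
        rs = as.vector(win$sil[, act, drop = FALSE]),
        rc = rep(rc, each = n_sil),
        covariate = rep(cov_vec[act], each = n_sil)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Gaussian encoding model of silenced-window activity
#'
#' Fits `Rs ~ N(mu, sigma)` with
#' `mu = bd*d + b2d*d^2 + bc*Rc + b2c*Rc^2 + bi*d*Rc + b0`
#' (the full model) and the covariate-free null
#' `mu = bc*Rc + b2c*Rc^2 + b0`, by iteratively reweighted least squares
#' (for the Gaussian family this coincides with ordinary least squares).
#' Covariate and control activity are z-scored internally, which makes the
#' fit invariant to affine rescaling of the covariate and conditions the
#' quadratic terms.
#'
#' @param data Tibble with columns `rs`, `rc`, `covariate` (see
#'   [glm_observations()]).
#' @param min_obs Guard on the number of observations (default 50).
#' @return A `commdyn_glm`: fitted full and null models, tidy coefficient
#'   table, residual scale `sigma`, and the standardization used.
#' @export
fit_effect_glm <- function(data, min_obs = 50) {
  stopifnot(all(c("rs", "rc", "covariate") %in% names(data)))
  data <- data[stats::complete.cases(data[, c("rs", "rc", "covariate")]), ]
  if (nrow(data) < min_obs) {
    stop("need at least ", min_obs, " observations", call. = FALSE)
  }
  if (stats::sd(data$covariate) == 0) {
    stop("covariate is degenerate (zero variance)", call. = FALSE)
  }
  std <- list(
    d = c(mean = mean(data$covariate), sd = stats::sd(data$covariate)),
    rc = c(mean = mean(data$rc), sd = stats::sd(data$rc))
  )
  df <- tibble::tibble(
    rs = data$rs,
    d = (data$covariate - std$d["mean"]) / std$d["sd"],
    rc = (data$rc - std$rc["mean"]) / max(std$rc["sd"], .Machine$double.eps)
  )
  full <- stats::glm(rs ~ d + I(d^2) + rc + I(rc^2) + d:rc,
                     data = df, family = stats::gaussian())
  X <- stats::model.matrix(full)
  kappa_x <- kappa(X, exact = FALSE)
  if (!is.finite(kappa_x) || kappa_x > 1e10) {
    stop("singular design matrix (condition number ", format(kappa_x), ")",
         call. = FALSE)
  }
  null <- stats::glm(rs ~ rc + I(rc^2), data = df,
                     family = stats::gaussian())
  n <- nrow(df)
  sigma <- sqrt(sum(stats::residuals(full)^2) /
                  stats::df.residual(full))
  cf <- stats::coef(full)
  structure(
    list(
      full = full, null = null, sigma = sigma, std = std, n = n,
      coefficients = tibble::tibble(
        term = c("b0", "bd", "b2d", "bc", "b2c", "bi"),
        estimate = unname(cf[c("(Intercept)", "d", "I(d^2)", "rc",
                               "I(rc^2)", "d:rc")])
      )
    ),
    class = "commdyn_glm"
  )
}

#' @export
print.commdyn_glm <- function(x, ...) {
  cat("<commdyn_glm> Gaussian encoding model, n =", x$n, "\n")
  print(x$coefficients)
  cat("sigma =", format(x$sigma, digits = 4), "\n")
  invisible(x)
}

#' @rdname fit_effect_glm
#' @param x A `commdyn_glm` object.
#' @param ... Unused.
#' @export
tidy.commdyn_glm <- function(x, ...) x$coefficients

#' @rdname fit_effect_glm
#' @export
glance.commdyn_glm <- function(x, ...) {
  tibble::tibble(n = x$n, sigma = x$sigma,
                 aic_full = stats::AIC(x$full),
                 aic_null = stats::AIC(x$null))
}

#' Cross-validated excess log-likelihood of the encoding model
#'
#' 20-fold cross validation of the full versus null encoding model. Per
#' test fold the performance is
#' `(log2-likelihood(full) - log2-likelihood(null)) / N_test` bits/trial,
#' with the test likelihood evaluated at the training-fold residual SD.
#' Above-chance performance is assessed by a one-sided Wilcoxon signed-rank
#' test across folds. Standardization is recomputed on each training fold.
#'
#' @inheritParams fit_effect_glm
#' @param k_folds Number of folds (default 20); folds are stratified over
#'   observations (trials), not neurons.
#' @param seed Seed for fold assignment.
#' @return List: `folds` tibble (`fold`, `bits_per_trial`, `n_test`),
#'   `mean_bits`, `p_value` (one-sided signed-rank, alternative > 0).
#' @export
excess_loglik <- function(data, k_folds = 20, seed = NULL, min_obs = 50) {
  data <- data[stats::complete.cases(data[, c("rs", "rc", "covariate")]), ]
  n <- nrow(data)
  if (n < k_folds * 2) {
    stop("need at least 2 observations per fold", call. = FALSE)
  }
  folds <- with_seed(seed, sample(rep_len(seq_len(k_folds), n)))
  per_fold <- purrr::map_dfr(seq_len(k_folds), function(f) {
    train <- data[folds != f, ]
    test <- data[folds == f, ]
    fit <- fit_effect_glm(train, min_obs = min(min_obs, nrow(train)))
    std <- fit$std
    tt <- tibble::tibble(
      rs = test$rs,
      d = (test$covariate - std$d["mean"]) / std$d["sd"],
      rc = (test$rc - std$rc["mean"]) / max(std$rc["sd"],
                                            .Machine$double.eps)
    )
    mu_full <- stats::predict(fit$full, newdata = tt)
    mu_null <- stats::predict(fit$null, newdata = tt)
    sd_full <- fit$sigma
    sd_null <- sqrt(sum(stats::residuals(fit$null)^2) /
                      stats::df.residual(fit$null))
    l2 <- function(mu, sd) {
      sum(stats::dnorm(tt$rs, mu, sd, log = TRUE)) / log(2)
    }
    tibble::tibble(
      fold = f,
      bits_per_trial = (l2(mu_full, sd_full) - l2(mu_null, sd_null)) /
        nrow(tt),
      n_test = nrow(tt)
    )
  })
  p <- tryCatch(
    suppressWarnings(stats::wilcox.test(per_fold$bits_per_trial,
                                        alternative = "greater",
                                        mu = 0, exact = FALSE)$p.value),
    error = function(e) NA_real_
  )
  list(folds = per_fold, mean_bits = mean(per_fold$bits_per_trial),
       p_value = p)
}
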