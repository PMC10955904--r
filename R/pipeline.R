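# End-to-end pipeline: preprocess recordings, invert the Maxwell model,
# differentiate, fit the regime HMM per subject/trial, extract features.

#' Fit the excision force model to every subject/trial of a trial set
#'
#' Runs the full inference chain on each subject/trial group of profiles:
#' optional dataset-global normalization, force to virtual displacement
#' ([force_to_displacement()]), forward differences to virtual velocity
#' ([velocity_from_displacement()]), then multi-sequence EM over the group's
#' velocity profiles ([fit_regime_hmm()]). When the input was normalized here,
#' fitted velocity levels are rescaled back to the input force units using the
#' stored normalization constant, so recovered parameters are comparable with
#' the generating ones.
#'
#' @param ts A `trial_set` of force profiles.
#' @param p A [maxwell_params()].
#' @param normalize Normalize the dataset to its global maximum before
#'   inversion (default `TRUE`; skipped when all profiles are already flagged
#'   normalized).
#' @param rescale Undo that normalization on the fitted velocity scale
#'   (default `TRUE`).
#' @param K,max_iter,tol Passed to [fit_regime_hmm()].
#' @return A list of class `excision_fits`: `models` (one fitted
#'   `regime_model` per subject/trial, named `subject_trial`), and
#'   `normalization` (the constant divided out, 1 if none).
#' @export
fit_force_model <- function(ts, p = maxwell_params(), normalize = TRUE,
                            rescale = TRUE, K = 2, max_iter = 200,
                            tol = 1e-6) {
  stopifnot(inherits(ts, "trial_set"), inherits(p, "maxwell_params"))
  profiles <- ts$profiles
  const <- 1
  already <- all(vapply(profiles, function(x) x$normalized, logical(1)))
  if (normalize && !already) {
    nd <- normalize_dataset(profiles)
    profiles <- nd$profiles
    const <- nd$constant
  }
  key <- sprintf("%s_%s", ts$meta$subject, ts$meta$trial)
  groups <- split(seq_along(profiles), key)
  models <- lapply(groups, function(rows) {
    vels <- lapply(profiles[rows], function(f) {
      velocity_from_displacement(force_to_displacement(f, p))
    })
    m <- fit_regime_hmm(vels, K = K, max_iter = max_iter, tol = tol)
    if (rescale && const != 1) {
      m2 <- regime_model(m$v * const, m$sigma2 * const^2, m$Q, m$pi0,
                         relabel = FALSE)
      m2$loglik <- m$loglik; m2$niter <- m$niter
      m2$loglik_trace <- m$loglik_trace
      m <- m2
    }
    m$meta <- list(E = p$E, eta = p$eta, dt = p$dt, normalization = const,
                   n_profiles = length(rows), velocity_unit = "cm/s")
    m
  })
  structure(list(models = models, normalization = const),
            class = "excision_fits")
}

#' @export
print.excision_fits <- function(x, ...) {
  cat(sprintf("<excision_fits: %d subject/trial model(s), normalization %.4g>\n",
              length(x$models), x$normalization))
  invisible(x)
}

#' Parameter-vector table of a set of fitted models
#'
#' @param fits An `excision_fits` object or named list of two-regime
#'   `regime_model`s.
#' @return Data frame with one row per subject/trial: the six model
#'   parameters ([parameter_vector()] layout) plus the stationary upper-regime
#'   probability `pi_U`.
#' @export
feature_table <- function(fits) {
  models <- if (inherits(fits, "excision_fits")) fits$models else fits
  rows <- lapply(names(models), function(nm) {
    pv <- parameter_vector(models[[nm]])
    pi <- stationary_distribution(models[[nm]]$Q)
    cbind(data.frame(subject_trial = nm, stringsAsFactors = FALSE),
          as.data.frame(as.list(pv)), pi_U = unname(pi["U"]))
  })
  do.call(rbind, rows)
}

#' Run the full skill-feature extraction on a trial set
#'
#' Convenience wrapper: [fit_force_model()], [feature_table()],
#' [fit_feature_space()] and [skill_axes()] in one call.
#'
#' @inheritParams fit_force_model
#' @return A list with `fits`, `params` (the feature table), `space` (the
#'   fitted `feature_space`) and `axes` (abruptness/energy/confidence per
#'   subject/trial).
#' @export
extract_skill_features <- function(ts, p = maxwell_params(),
                                   normalize = TRUE, ...) {
  fits <- fit_force_model(ts, p, normalize = normalize, ...)
  params <- feature_table(fits)
  X <- as.matrix(params[, PARAM_VECTOR_NAMES])
  rownames(X) <- params$subject_trial
  space <- fit_feature_space(X)
  axes <- skill_axes(space)
  list(fits = fits, params = params, space = space, axes = axes)
}
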