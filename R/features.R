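# Skill features: descriptive force metrics, PCA of fitted model parameters,
# and the three named diagonal axes (abruptness, energy, confidence).

#' Descriptive force metrics of a single profile
#'
#' The six conventional force-based performance metrics:
#' mean force, force variability (standard deviation), peak force, scaled
#' force (mean divided by peak; low values indicate overshoot), force
#' derivative (mean absolute forward-difference slope, an indication of
#' aggressiveness, in profile units per second) and force integral (trapezoid
#' over the profile duration, an indication of cutting energy).
#'
#' @param f A [force_profile()] with at least 2 samples; typically normalized.
#' @return A named list of class `descriptive_metrics` with fields
#'   `mean_force`, `force_std`, `peak_force`, `scaled_force`,
#'   `force_derivative`, `force_integral`.
#' @examples
#' descriptive_metrics(force_profile(rep(0.4, 121), rate = 30))
#' @export
descriptive_metrics <- function(f) {
  stopifnot(inherits(f, "force_profile"))
  s <- f$samples
  n <- length(s)
  if (n < 2) stop("descriptive metrics require at least 2 samples")
  peak <- max(s)
  if (peak <= 0) {
    stop("profile has no positive samples: scaled force undefined")
  }
  dt <- 1 / f$rate
  out <- list(
    mean_force = mean(s),
    force_std = stats::sd(s),
    peak_force = peak,
    scaled_force = mean(s) / peak,
    force_derivative = mean(abs(diff(s))) / dt,
    force_integral = sum((s[-n] + s[-1]) / 2) * dt
  )
  class(out) <- "descriptive_metrics"
  out
}

#' @export
print.descriptive_metrics <- function(x, ...) {
  cat(sprintf(paste0("mean %.4g  sd %.4g  peak %.4g  scaled %.4g  ",
                     "deriv %.4g /s  integral %.4g\n"),
              x$mean_force, x$force_std, x$peak_force, x$scaled_force,
              x$force_derivative, x$force_integral))
  invisible(x)
}

# Canonical layout of the per-trial parameter vector.
PARAM_VECTOR_NAMES <- c("v_L", "v_U", "sigma2_L", "sigma2_U", "q12", "q21")

#' Parameter vector of a fitted two-regime model
#'
#' The fixed feature layout used for PCA:
#' `(v_L, v_U, sigma2_L, sigma2_U, q12, q21)`. The diagonal transition
#' probabilities are excluded: rows of `Q` sum to 1, so `q11` and `q22` are
#' exactly collinear with `q12` and `q21`.
#'
#' @param m A fitted `regime_model` with `K = 2`.
#' @return Named numeric vector of length 6.
#' @export
parameter_vector <- function(m) {
  stopifnot(inherits(m, "regime_model"))
  if (m$K != 2) {
    stop("the skill feature axes are defined only for the two-regime model")
  }
  stats::setNames(
    c(m$v[["L"]], m$v[["U"]], m$sigma2[["L"]], m$sigma2[["U"]],
      m$Q["L", "U"], m$Q["U", "L"]),
    PARAM_VECTOR_NAMES)
}

#' Principal-component feature space over parameter vectors
#'
#' Standardizes each coordinate of the per-trial parameter vectors to zero
#' mean and unit variance, performs PCA and retains the first three
#' components. Because a principal axis is defined only up to sign, a fixed
#' orientation is applied so the components carry their documented meaning:
#' PC1 loads positively on `q21` (frequent loss of applied force), PC2
#' positively on `q12` (sharp rises in force) and PC3 negatively on `v_U`
#' (reduction of the upper force level). Zero-variance coordinates are
#' dropped with a warning.
#'
#' @param vectors A matrix or data frame with one row per trial and columns
#'   named as in [parameter_vector()] (at least 4 rows).
#' @return An object of class `feature_space`: `loadings` (columns PC1-PC3,
#'   orthonormal), `scores` (per-trial component scores), `center`, `scale`,
#'   `sdev` (all component standard deviations), `explained` (proportion of
#'   variance per retained component) and `kept` (coordinate names used).
#' @export
fit_feature_space <- function(vectors) {
  X <- as.matrix(vectors)
  if (nrow(X) < 4) stop("PCA of parameter vectors requires at least 4 trials")
  if (is.null(colnames(X))) colnames(X) <- PARAM_VECTOR_NAMES[seq_len(ncol(X))]
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!all(keep)) {
    warning("dropping zero-variance coordinate(s): ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    sds <- sds[keep]
  }
  if (ncol(X) < 3) stop("fewer than 3 varying coordinates: cannot retain 3 components")
  ctr <- colMeans(X)
  Z <- scale(X, center = ctr, scale = sds)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  ncomp <- min(3, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(ncomp), drop = FALSE]
  # deterministic sign convention tied to the components' interpretation
  orient <- function(col, coord, sign) {
    if (col > ncol(rot)) return()
    load <- if (coord %in% rownames(rot)) rot[coord, col] else {
      rot[which.max(abs(rot[, col])), col]
    }
    if (sign * load < 0) rot[, col] <<- -rot[, col]
  }
  orient(1, "q21", +1)
  orient(2, "q12", +1)
  orient(3, "v_U", -1)
  scores <- Z %*% rot
  colnames(scores) <- colnames(rot) <- paste0("PC", seq_len(ncomp))
  structure(
    list(loadings = rot, scores = scores, center = ctr, scale = sds,
         sdev = pc$sdev, explained = pc$sdev[seq_len(ncomp)]^2 / sum(pc$sdev^2),
         kept = colnames(X)),
    class = "feature_space")
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space: %d trials, %d coordinates, %d components (%.1f%% variance)>\n",
              nrow(x$scores), length(x$kept), ncol(x$loadings),
              100 * sum(x$explained)))
  invisible(x)
}

#' Project new parameter vectors into a fitted feature space
#'
#' @param space A `feature_space`.
#' @param vectors Matrix/data frame of parameter vectors (same layout as used
#'   for fitting).
#' @return Matrix of PC scores.
#' @export
project_features <- function(space, vectors) {
  stopifnot(inherits(space, "feature_space"))
  X <- as.matrix(vectors)[, space$kept, drop = FALSE]
  Z <- scale(X, center = space$center, scale = space$scale)
  Z %*% space$loadings
}

#' Named skill axes from principal-component scores
#'
#' The three behavioural features are diagonal (45 degree) axes of the PC
#' score planes, unit-normalized:
#' \describe{
#'   \item{abruptness}{`(PC1 + PC2)/sqrt(2)` - degree of discontinuity of the
#'     task execution (simultaneous sudden drops and sharp rises in force).}
#'   \item{energy}{`-(PC1 + PC3)/sqrt(2)` - amplitude times duration of force
#'     application; large when both force levels are high and force loss is
#'     rare.}
#'   \item{confidence}{`(PC3 - PC1)/sqrt(2)` - steady, consistent force
#'     application with a narrow envelope; orthogonal to the energy axis by
#'     construction.}
#' }
#'
#' @param space A `feature_space`, or a matrix of scores with columns PC1-PC3.
#' @return Data frame with columns `abruptness`, `energy`, `confidence`, one
#'   row per trial.
#' @export
skill_axes <- function(space) {
  sc <- if (inherits(space, "feature_space")) space$scores else as.matrix(space)
  if (ncol(sc) < 3) stop("skill axes require 3 principal components")
  data.frame(
    abruptness = (sc[, 1] + sc[, 2]) / sqrt(2),
    energy = -(sc[, 1] + sc[, 3]) / sqrt(2),
    confidence = (sc[, 3] - sc[, 1]) / sqrt(2),
    row.names = rownames(sc)
  )
}
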