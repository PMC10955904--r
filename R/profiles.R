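# Core sequence containers: force, displacement and velocity profiles.
# All are lightweight S3 records around a numeric vector plus a sampling rate,
# mirroring how incision forces are recorded (fixed 30 Hz, one scalar per sample).

#' Construct a force profile
#'
#' A force profile is a fixed-rate sequence of scalar force samples, the basic
#' unit of analysis: one cut of an elliptical excision, typically 120 samples
#' at 30 Hz (4 s). Samples are either raw sensor newtons or normalized to the
#' dataset-global maximum (see [normalize_dataset()]).
#'
#' @param samples Numeric vector of force values. Must be finite.
#' @param rate Sampling rate in Hz (default 30, the instrument's rate).
#' @param normalized Logical; `TRUE` once the samples have been divided by a
#'   dataset-global maximum, in which case they must lie in `[0, 1]`.
#' @param label Optional identifier (e.g. `"H_1_cut03"`).
#' @return An object of class `force_profile`.
#' @examples
#' f <- force_profile(rep(0.4, 120))
#' length(f$samples)
#' @export
force_profile <- function(samples, rate = 30, normalized = FALSE, label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("force profile must contain at least one sample")
  if (!all(is.finite(samples))) stop("force samples must all be finite")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("sampling rate must be a single positive number")
  }
  if (isTRUE(normalized) && (min(samples) < 0 || max(samples) > 1 + 1e-12)) {
    stop("normalized force samples must lie in [0, 1]")
  }
  structure(
    list(samples = samples, rate = rate, normalized = isTRUE(normalized),
         label = label),
    class = "force_profile"
  )
}

#' @export
print.force_profile <- function(x, ...) {
  cat(sprintf("<force_profile%s: %d samples @ %g Hz (%.2f s)%s>\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              length(x$samples), x$rate, length(x$samples) / x$rate,
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Construct a displacement profile
#'
#' Displacement of the virtual blade through the Maxwell body, in cm. Usually
#' produced by [force_to_displacement()] rather than constructed directly.
#'
#' @param samples Numeric vector of displacement values (cm).
#' @param rate Sampling rate in Hz.
#' @param label Optional identifier.
#' @return An object of class `displacement_profile`.
#' @export
displacement_profile <- function(samples, rate = 30, label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("displacement profile must be non-empty")
  if (!all(is.finite(samples))) stop("displacement samples must all be finite")
  if (rate <= 0) stop("sampling rate must be positive")
  structure(list(samples = samples, rate = rate, label = label),
            class = "displacement_profile")
}

#' Construct a velocity profile
#'
#' Virtual blade velocity (cm/s), the observable that the regime HMM is fitted
#' to. Usually produced by [velocity_from_displacement()]; one sample shorter
#' than its source displacement profile (forward finite differences).
#'
#' @param samples Numeric vector of velocity values (cm/s).
#' @param rate Sampling rate in Hz.
#' @param label Optional identifier.
#' @return An object of class `velocity_profile`.
#' @export
velocity_profile <- function(samples, rate = 30, label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop("velocity profile must be non-empty")
  if (!all(is.finite(samples))) stop("velocity samples must all be finite")
  if (rate <= 0) stop("sampling rate must be positive")
  structure(list(samples = samples, rate = rate, label = label),
            class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("<velocity_profile%s: %d samples @ %g Hz>\n",
              if (is.null(x$label)) "" else paste0(" ", x$label),
              length(x$samples), x$rate))
  invisible(x)
}

# Internal: evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. NULL seed leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  seed <- as.integer(seed)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Internal: derive a stream of child seeds from one parent seed, keeping every
# value a valid 32-bit R integer.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max, n))
}
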