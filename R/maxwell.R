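# Maxwell viscoelastic model of scalpel-tissue interaction.
#
# A Maxwell body (spring E and damper eta in series) relates incision force
# f(t) to the blade's "virtual" velocity xdot(t):
#
#     eta * xdot(t) = f(t) + (eta/E) * fdot(t)
#
# In the Laplace domain the displacement-to-force transfer function is
# G(s) = eta*s / ((eta/E)*s + 1): high-pass, so a displacement step produces a
# force that decays exponentially with time constant eta/E, while a constant
# velocity v produces a step-like force settling at eta*v.

#' Maxwell model parameters and state-space constants
#'
#' Bundles the spring coefficient `E` (N/cm), the damping coefficient `eta`
#' (N s/cm) and the sample interval, together with the dimensionless constants
#' `(alpha, beta, gamma, delta)` of the first-order state-space realization of
#' the Maxwell transfer function (see [state_space_constants()]). The study
#' defaults, `E = 1` N/cm and `eta = 0.5` N s/cm, give
#' `(alpha, beta, gamma, delta) = (-2, 1, -2, 1)`.
#'
#' @param E Spring coefficient in N/cm. Must be positive.
#' @param eta Damping coefficient in N s/cm. Must be positive.
#' @param rate Sampling rate in Hz; the sample interval is `dt = 1/rate`.
#' @return An object of class `maxwell_params` with fields `E`, `eta`, `dt`,
#'   `rate`, `alpha`, `beta`, `gamma`, `delta`.
#' @examples
#' p <- maxwell_params()          # study defaults E = 1, eta = 0.5
#' c(p$alpha, p$beta, p$gamma, p$delta)
#' @export
maxwell_params <- function(E = 1, eta = 0.5, rate = 30) {
  k <- state_space_constants(E, eta)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("sampling rate must be a single positive number")
  }
  structure(
    list(E = E, eta = eta, rate = rate, dt = 1 / rate,
         alpha = k[["alpha"]], beta = k[["beta"]],
         gamma = k[["gamma"]], delta = k[["delta"]]),
    class = "maxwell_params"
  )
}

#' @export
print.maxwell_params <- function(x, ...) {
  cat(sprintf("<maxwell_params: E = %g N/cm, eta = %g N s/cm, dt = %.4g s>\n",
              x$E, x$eta, x$dt))
  cat(sprintf("  state space: alpha = %g, beta = %g, gamma = %g, delta = %g\n",
              x$alpha, x$beta, x$gamma, x$delta))
  invisible(x)
}

#' State-space constants of the Maxwell transfer function
#'
#' Realizes `G(s) = eta*s / ((eta/E)*s + 1)` as the single-state system
#' `dg/dt = alpha*g + beta*u`, `y = gamma*g + delta*u`. Polynomial division of
#' `G(s) = E*s/(s + E/eta)` gives `E - (E^2/eta)/(s + E/eta)`, hence
#' `alpha = -E/eta`, `beta = 1`, `gamma = -E^2/eta`, `delta = E`. With the
#' study defaults `E = 1`, `eta = 0.5` this is `(-2, 1, -2, 1)`.
#'
#' @param E Spring coefficient (N/cm), positive.
#' @param eta Damping coefficient (N s/cm), positive.
#' @return Named numeric vector `c(alpha, beta, gamma, delta)`.
#' @examples
#' state_space_constants(1, 0.5)  # -2, 1, -2, 1
#' @export
state_space_constants <- function(E, eta) {
  if (!is.numeric(E) || length(E) != 1 || !is.finite(E) || E <= 0) {
    stop("spring coefficient E must be a single positive number")
  }
  if (!is.numeric(eta) || length(eta) != 1 || !is.finite(eta) || eta <= 0) {
    stop("damping coefficient eta must be a single positive number")
  }
  c(alpha = -E / eta, beta = 1, gamma = -E^2 / eta, delta = E)
}

#' Virtual displacement implied by a force profile
#'
#' Inverts the Maxwell model: given a force profile `f(t)`, the virtual blade
#' displacement is
#' \deqn{x(t) = f(t)/E + (1/\eta) \int_0^t f \, d\tau,}
#' evaluated per sample with a cumulative trapezoid quadrature, so
#' `x(0) = f(0)/E`. Units are nominal cm: the displacement is the trajectory
#' the Maxwell body *implies*, not a measured kinematic quantity.
#'
#' @param f A [force_profile()].
#' @param p A [maxwell_params()]; its `rate` is ignored in favour of `f$rate`.
#' @return A [displacement_profile()] of the same length and rate as `f`.
#' @examples
#' f <- force_profile(rep(0.5, 61), rate = 30)
#' x <- force_to_displacement(f, maxwell_params())
#' tail(x$samples, 1)  # 0.5/E + 0.5*t/eta = 0.5 + 2 at t = 2 s
#' @export
force_to_displacement <- function(f, p = maxwell_params()) {
  stopifnot(inherits(f, "force_profile"), inherits(p, "maxwell_params"))
  y <- f$samples
  dt <- 1 / f$rate
  displacement_profile(y / p$E + cumtrapz(y, dt) / p$eta,
                       rate = f$rate, label = f$label)
}

# Cumulative trapezoid integral of y sampled at spacing dt; first element 0.
cumtrapz <- function(y, dt) {
  n <- length(y)
  if (n == 1) return(0)
  c(0, cumsum((y[-n] + y[-1]) / 2 * dt))
}

#' Virtual velocity by forward finite differences
#'
#' Differentiates a displacement profile with the forward finite-difference
#' quotient `(x[t+1] - x[t]) / dt`, `dt = 1/rate` (0.033 s at 30 Hz). The
#' result is one sample shorter than its input; no padding is applied.
#'
#' @param x A [displacement_profile()] with at least 2 samples.
#' @return A [velocity_profile()] of length `length(x$samples) - 1`.
#' @export
velocity_from_displacement <- function(x) {
  stopifnot(inherits(x, "displacement_profile"))
  if (length(x$samples) < 2) {
    stop("finite differencing requires at least 2 displacement samples")
  }
  velocity_profile(diff(x$samples) * x$rate, rate = x$rate, label = x$label)
}

#' Simulate incision force from a velocity profile
#'
#' Integrates the Maxwell force dynamics `df/dt = -(E/eta)*f + E*xdot` forward
#' from `f0`, driven by the virtual velocity samples. Two discretizations are
#' available:
#' \describe{
#'   \item{`"euler"`}{forward Euler at `dt = 1/rate`, the default; matches the
#'     discrete-time framing of the switching-system formulation.}
#'   \item{`"exact"`}{exact zero-order-hold discretization,
#'     `f[t+1] = e^{-dt E/\eta} f[t] + (1 - e^{-dt E/\eta}) \eta v[t]`, which
#'     reproduces the continuous-time exponential decay with no
#'     discretization error for piecewise-constant velocity.}
#' }
#' The steady-state response to a constant velocity `v` is `eta * v` under
#' either scheme.
#'
#' @param v A [velocity_profile()].
#' @param p A [maxwell_params()].
#' @param f0 Initial force (first output sample). Use the first measured force
#'   sample when round-tripping a recording, 0 when generating from scratch.
#' @param method `"euler"` or `"exact"`.
#' @return A [force_profile()] of the same length as `v`.
#' @examples
#' v <- velocity_profile(rep(0.5, 300), rate = 30)
#' f <- simulate_force(v, maxwell_params(), f0 = 0)
#' tail(f$samples, 1)  # ~ eta * v = 0.25
#' @export
simulate_force <- function(v, p = maxwell_params(), f0 = 0,
                           method = c("euler", "exact")) {
  stopifnot(inherits(v, "velocity_profile"), inherits(p, "maxwell_params"))
  method <- match.arg(method)
  if (!is.numeric(f0) || length(f0) != 1 || !is.finite(f0)) {
    stop("f0 must be a single finite number")
  }
  u <- v$samples
  n <- length(u)
  dt <- 1 / v$rate
  a <- p$E / p$eta           # decay rate 1/s; time constant eta/E
  f <- numeric(n)
  f[1] <- f0
  if (n > 1) {
    if (method == "euler") {
      decay <- 1 - a * dt
      if (decay < 0) {
        warning("forward Euler unstable at this rate (dt > eta/E); ",
                "consider method = \"exact\" or a higher sampling rate")
      }
      for (i in seq_len(n - 1)) {
        f[i + 1] <- decay * f[i] + p$E * dt * u[i]
      }
    } else {
      decay <- exp(-a * dt)
      gain <- (1 - decay) * p$eta
      for (i in seq_len(n - 1)) {
        f[i + 1] <- decay * f[i] + gain * u[i]
      }
    }
  }
  force_profile(f, rate = v$rate, label = v$label)
}

#' Round-trip a force profile through the Maxwell model
#'
#' Convenience composition used to assess discretization error:
#' force -> displacement ([force_to_displacement()]) -> velocity
#' ([velocity_from_displacement()]) -> force ([simulate_force()] from the
#' first measured sample). At 30 Hz the root-mean-square reconstruction error
#' is a small fraction of the peak force, attributable to discretization only.
#'
#' @inheritParams force_to_displacement
#' @param method Discretization passed to [simulate_force()].
#' @return A [force_profile()] of length `length(f$samples) - 1` (the forward
#'   difference drops one sample).
#' @export
maxwell_roundtrip <- function(f, p = maxwell_params(),
                              method = c("euler", "exact")) {
  v <- velocity_from_displacement(force_to_displacement(f, p))
  simulate_force(v, p, f0 = f$samples[1], method = match.arg(method))
}
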