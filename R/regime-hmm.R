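# Two-regime switching model of the virtual blade velocity.
#
# The excision is modelled as a switching linear dynamical system whose
# discrete state selects among K constant-velocity regimes; because the Maxwell
# model makes the virtual velocity observable, inference reduces to learning a
# Gaussian-emission hidden Markov model over the velocity samples. With K = 2
# the regimes are the lower (L) and upper (U) cutting-force levels, and the
# fitted parameters (v_L, v_U, sigma2_L, sigma2_U, Q) summarise one trial.

#' Construct a regime-switching velocity model
#'
#' A K-state Gaussian hidden Markov model over virtual blade velocities:
#' per-regime mean velocities `v`, per-regime velocity variances `sigma2`, a
#' row-stochastic K-by-K transition matrix `Q` and an initial distribution
#' `pi0`. States are canonically ordered by increasing mean velocity, so for
#' the default two-regime model `v[1] = v_L < v[2] = v_U` and
#' `Q["L","U"] = q12` is the probability of switching from the lower to the
#' upper force level.
#'
#' @param v Numeric vector of regime mean velocities (length K).
#' @param sigma2 Numeric vector of regime velocity variances (length K, all
#'   positive).
#' @param Q K-by-K transition probability matrix; rows must sum to 1.
#' @param pi0 Initial state distribution (defaults to uniform).
#' @param relabel Reorder states by increasing mean (default `TRUE`).
#' @return An object of class `regime_model`. For `K = 2` the states are named
#'   `"L"` and `"U"`.
#' @examples
#' m <- regime_model(v = c(1, 6), sigma2 = c(0.1225, 0.1225),
#'                   Q = matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE))
#' stationary_distribution(m$Q)
#' @export
regime_model <- function(v, sigma2, Q, pi0 = NULL, relabel = TRUE) {
  v <- as.numeric(v)
  sigma2 <- as.numeric(sigma2)
  K <- length(v)
  if (K < 1) stop("at least one regime is required")
  if (length(sigma2) != K) stop("v and sigma2 must have the same length")
  if (any(!is.finite(v)) || any(!is.finite(sigma2)) || any(sigma2 <= 0)) {
    stop("regime means must be finite and variances strictly positive")
  }
  Q <- as.matrix(Q)
  if (!all(dim(Q) == c(K, K))) stop("Q must be a K-by-K matrix")
  if (any(Q < -1e-12) || any(Q > 1 + 1e-12) ||
      any(abs(rowSums(Q) - 1) > 1e-8)) {
    stop("Q must be row-stochastic with entries in [0, 1]")
  }
  Q <- pmin(pmax(Q, 0), 1)
  Q <- Q / rowSums(Q)
  if (is.null(pi0)) pi0 <- rep(1 / K, K)
  pi0 <- as.numeric(pi0)
  if (length(pi0) != K || any(pi0 < 0) || abs(sum(pi0) - 1) > 1e-8) {
    stop("pi0 must be a length-K probability vector")
  }
  pi0 <- pi0 / sum(pi0)
  if (relabel) {
    ord <- order(v)
    v <- v[ord]; sigma2 <- sigma2[ord]
    Q <- Q[ord, ord, drop = FALSE]
    pi0 <- pi0[ord]
  }
  nm <- if (K == 2) c("L", "U") else paste0("S", seq_len(K))
  names(v) <- names(sigma2) <- names(pi0) <- nm
  dimnames(Q) <- list(nm, nm)
  structure(list(K = K, v = v, sigma2 = sigma2, Q = Q, pi0 = pi0,
                 loglik = NA_real_, niter = NA_integer_, meta = list()),
            class = "regime_model")
}

#' @export
print.regime_model <- function(x, ...) {
  cat(sprintf("<regime_model: K = %d>\n", x$K))
  cat("  v     :", paste(sprintf("%s = %.4g", names(x$v), x$v),
                         collapse = ", "), "\n")
  cat("  sigma2:", paste(sprintf("%.4g", x$sigma2), collapse = ", "), "\n")
  cat("  Q:\n")
  print(round(x$Q, 4))
  if (is.finite(x$loglik)) {
    cat(sprintf("  log-likelihood %.4f after %d EM iterations\n",
                x$loglik, x$niter))
  }
  invisible(x)
}

# Internal: coerce fit/decode input to a list of plain numeric vectors.
as_velocity_list <- function(velocities) {
  if (inherits(velocities, "velocity_profile")) velocities <- list(velocities)
  if (is.numeric(velocities)) velocities <- list(velocities)
  if (!is.list(velocities) || length(velocities) == 0) {
    stop("velocities must be one or more velocity profiles or numeric vectors")
  }
  lapply(velocities, function(v) {
    s <- if (inherits(v, "velocity_profile")) v$samples else as.numeric(v)
    if (length(s) < 1 || any(!is.finite(s))) {
      stop("each velocity sequence must be non-empty and finite")
    }
    s
  })
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Internal: log-space forward-backward for one sequence.
# Returns loglik, gamma (T x K posteriors) and the summed xi (K x K).
forward_backward <- function(y, v, sigma2, Q, pi0) {
  Tn <- length(y)
  K <- length(v)
  logB <- vapply(seq_len(K),
                 function(k) stats::dnorm(y, v[k], sqrt(sigma2[k]), log = TRUE),
                 numeric(Tn))
  logB <- matrix(logB, nrow = Tn, ncol = K)
  logQ <- log(Q)
  la <- matrix(-Inf, Tn, K)
  la[1, ] <- log(pi0) + logB[1, ]
  if (Tn > 1) {
    for (t in 2:Tn) {
      for (j in seq_len(K)) {
        la[t, j] <- logB[t, j] + logsumexp(la[t - 1, ] + logQ[, j])
      }
    }
  }
  loglik <- logsumexp(la[Tn, ])
  lb <- matrix(0, Tn, K)
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      for (i in seq_len(K)) {
        lb[t, i] <- logsumexp(logQ[i, ] + logB[t + 1, ] + lb[t + 1, ])
      }
    }
  }
  lgamma_ <- la + lb - loglik
  gamma <- exp(lgamma_)
  gamma <- gamma / rowSums(gamma)          # guard against rounding
  xi <- matrix(0, K, K)
  if (Tn > 1) {
    for (t in seq_len(Tn - 1)) {
      lxi <- outer(la[t, ], rep(0, K), "+") + logQ +
        matrix(logB[t + 1, ] + lb[t + 1, ], K, K, byrow = TRUE) - loglik
      xi <- xi + exp(lxi)
    }
  }
  list(loglik = loglik, gamma = gamma, xi = xi, logB = logB)
}

#' Fit the regime-switching velocity model by expectation-maximization
#'
#' Baum-Welch estimation of a Gaussian-emission HMM over one or more virtual
#' velocity sequences. Sequences are treated as independent realizations (not
#' concatenated into one chain): each trial is a separate execution of the
#' task. Initialization is a deterministic quantile split of the pooled
#' velocities (lower/upper terciles for `K = 2`), so repeated fits on the same
#' data are identical; `seed` only matters for optional random restarts.
#' States are relabelled so mean velocities increase (`v_L < v_U`).
#'
#' The per-iteration log-likelihood is recorded in `$loglik_trace` and is
#' non-decreasing up to numerical rounding, as EM guarantees.
#'
#' @param velocities A [velocity_profile()], numeric vector, or list of either.
#' @param K Number of regimes (default 2).
#' @param max_iter Maximum EM iterations.
#' @param tol Absolute log-likelihood improvement below which EM stops.
#' @param var_floor Lower bound on emission variances, preventing collapse on
#'   noiseless input.
#' @param n_restarts Additional EM runs from perturbed initializations; the
#'   best log-likelihood wins. Requires `seed` for reproducibility.
#' @param seed Integer seed for the random restarts (ignored when
#'   `n_restarts = 0`).
#' @return A fitted `regime_model` with `loglik`, `niter` and `loglik_trace`
#'   fields filled in.
#' @examples
#' m0 <- regime_model(c(1, 6), c(0.1, 0.1),
#'                    matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE))
#' sim <- sample_regime_hmm(m0, 500, seed = 1)
#' fit_regime_hmm(sim$velocity)
#' @export
fit_regime_hmm <- function(velocities, K = 2, max_iter = 200, tol = 1e-6,
                           var_floor = 1e-6, n_restarts = 0, seed = NULL) {
  ys <- as_velocity_list(velocities)
  if (K < 1) stop("K must be at least 1")
  pooled <- unlist(ys)
  if (length(unique(pooled)) < K) {
    warning("fewer distinct velocity values than regimes; ",
            "some regimes will coincide")
  }
  if (stats::var(pooled) < .Machine$double.eps && length(pooled) > 1) {
    warning("all velocity samples are identical; regime means coincide ",
            "and the transition matrix is unidentified")
  }
  inits <- list(quantile_init(pooled, K, var_floor))
  if (n_restarts > 0) {
    seeds <- derive_seeds(seed, n_restarts)
    for (r in seq_len(n_restarts)) {
      inits[[r + 1]] <- with_seed(seeds[[r]], perturb_init(inits[[1]]))
    }
  }
  fits <- lapply(inits, function(init) {
    em_gaussian_hmm(ys, init, max_iter = max_iter, tol = tol,
                    var_floor = var_floor)
  })
  best <- fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1)))]]
  m <- regime_model(best$v, best$sigma2, best$Q, best$pi0)
  m$loglik <- best$loglik
  m$niter <- best$niter
  m$loglik_trace <- best$trace
  m
}

# Deterministic initialization: split the pooled sample at K+1 quantiles and
# take chunk means/variances; for K = 2 this is the lower/upper tercile split.
quantile_init <- function(pooled, K, var_floor) {
  if (K == 2) {
    qs <- stats::quantile(pooled, c(1 / 3, 2 / 3), names = FALSE)
    lower <- pooled[pooled <= qs[1]]
    upper <- pooled[pooled >= qs[2]]
    v <- c(mean(lower), mean(upper))
    s2 <- c(stats::var(lower), stats::var(upper))
  } else {
    br <- stats::quantile(pooled, seq(0, 1, length.out = K + 1), names = FALSE)
    grp <- cut(pooled, unique(c(-Inf, br[-c(1, K + 1)], Inf)), labels = FALSE)
    v <- tapply(pooled, grp, mean)
    s2 <- tapply(pooled, grp, stats::var)
    if (length(v) < K) {        # degenerate quantiles: replicate
      v <- rep_len(as.numeric(v), K)
      s2 <- rep_len(as.numeric(s2), K)
    }
  }
  s2[!is.finite(s2)] <- stats::var(pooled)
  s2 <- pmax(s2, var_floor, na.rm = TRUE)
  s2[!is.finite(s2)] <- var_floor
  Q <- matrix(0.1 / max(1, length(v) - 1), length(v), length(v))
  diag(Q) <- 0.9
  Q <- Q / rowSums(Q)
  list(v = as.numeric(v), sigma2 = as.numeric(s2), Q = Q,
       pi0 = rep(1 / length(v), length(v)))
}

perturb_init <- function(init) {
  spread <- max(stats::sd(init$v), sqrt(max(init$sigma2)))
  init$v <- init$v + stats::rnorm(length(init$v), 0, 0.25 * spread + 1e-9)
  init
}

em_gaussian_hmm <- function(ys, init, max_iter, tol, var_floor) {
  v <- init$v; sigma2 <- init$sigma2; Q <- init$Q; pi0 <- init$pi0
  K <- length(v)
  trace <- numeric(0)
  prev <- -Inf
  niter <- 0L
  for (iter in seq_len(max_iter)) {
    fbs <- lapply(ys, forward_backward, v = v, sigma2 = sigma2, Q = Q,
                  pi0 = pi0)
    ll <- sum(vapply(fbs, function(f) f$loglik, numeric(1)))
    trace <- c(trace, ll)
    niter <- iter
    if (is.finite(prev) && ll - prev < tol) break
    prev <- ll
    # M-step, pooled over sequences
    gnum <- numeric(K); gden <- numeric(K)
    xi <- matrix(0, K, K); gtrans <- numeric(K)
    pi0new <- numeric(K)
    s2num <- numeric(K)
    for (i in seq_along(ys)) {
      g <- fbs[[i]]$gamma
      y <- ys[[i]]
      gnum <- gnum + colSums(g * y)
      gden <- gden + colSums(g)
      xi <- xi + fbs[[i]]$xi
      Tn <- nrow(g)
      if (Tn > 1) gtrans <- gtrans + colSums(g[-Tn, , drop = FALSE])
      pi0new <- pi0new + g[1, ]
    }
    v <- gnum / gden
    for (i in seq_along(ys)) {
      g <- fbs[[i]]$gamma
      y <- ys[[i]]
      s2num <- s2num + colSums(g * outer(y, v, "-")^2)
    }
    sigma2 <- pmax(s2num / gden, var_floor)
    if (any(gtrans > 0)) {
      newQ <- xi / ifelse(gtrans > 0, gtrans, 1)
      zero <- rowSums(newQ) <= 0
      newQ[zero, ] <- Q[zero, ]
      Q <- newQ / rowSums(newQ)
    }
    pi0 <- pi0new / sum(pi0new)
  }
  list(v = v, sigma2 = sigma2, Q = Q, pi0 = pi0, loglik = prev_or(trace),
       niter = niter, trace = trace)
}

prev_or <- function(trace) if (length(trace)) trace[length(trace)] else -Inf

#' Decode the regime path of a velocity profile
#'
#' Computes the maximum a posteriori state sequence (Viterbi) and the
#' per-sample regime posteriors (forward-backward) under a fitted model.
#'
#' @param m A `regime_model`.
#' @param v A [velocity_profile()] or numeric vector.
#' @return An object of class `state_path`: `states` (integer vector),
#'   `labels` (character, `"L"`/`"U"` for K = 2), `posteriors` (T-by-K matrix,
#'   rows summing to 1) and `loglik`.
#' @export
decode_regimes <- function(m, v) {
  stopifnot(inherits(m, "regime_model"))
  y <- as_velocity_list(v)[[1]]
  K <- m$K
  fb <- forward_backward(y, m$v, m$sigma2, m$Q, m$pi0)
  # Viterbi in log space
  Tn <- length(y)
  logB <- fb$logB
  logQ <- log(m$Q)
  dp <- matrix(-Inf, Tn, K)
  bp <- matrix(0L, Tn, K)
  dp[1, ] <- log(m$pi0) + logB[1, ]
  if (Tn > 1) {
    for (t in 2:Tn) {
      for (j in seq_len(K)) {
        cand <- dp[t - 1, ] + logQ[, j]
        bp[t, j] <- which.max(cand)
        dp[t, j] <- cand[bp[t, j]] + logB[t, j]
      }
    }
  }
  states <- integer(Tn)
  states[Tn] <- which.max(dp[Tn, ])
  if (Tn > 1) for (t in (Tn - 1):1) states[t] <- bp[t + 1, states[t + 1]]
  nm <- names(m$v)
  post <- fb$gamma
  colnames(post) <- nm
  structure(list(states = states, labels = nm[states], posteriors = post,
                 loglik = fb$loglik),
            class = "state_path")
}

#' @export
print.state_path <- function(x, ...) {
  cat(sprintf("<state_path: %d samples, %d switches, loglik %.3f>\n",
              length(x$states), sum(diff(x$states) != 0), x$loglik))
  invisible(x)
}

#' Stationary distribution of a regime transition matrix
#'
#' Solves `pi Q = pi`, `sum(pi) = 1`. For the two-regime model this is the
#' closed form `pi_U = q12 / (q12 + q21)`: the long-run fraction of time the
#' excision spends at the upper force level. For a reducible or absorbing
#' chain the absorbing distribution is returned with attribute
#' `reducible = TRUE`.
#'
#' @param Q Row-stochastic transition matrix, or a `regime_model` whose `Q` is
#'   used.
#' @return Named probability vector `pi` with `max |pi Q - pi|` at machine
#'   precision; attribute `reducible` flags chains that are not irreducible.
#' @examples
#' stationary_distribution(matrix(c(0.876, 0.124, 0.028, 0.972), 2,
#'                                byrow = TRUE))  # pi_U ~ 0.816
#' @export
stationary_distribution <- function(Q) {
  if (inherits(Q, "regime_model")) Q <- Q$Q
  Q <- as.matrix(Q)
  K <- nrow(Q)
  if (ncol(Q) != K) stop("Q must be square")
  if (any(Q < 0) || any(abs(rowSums(Q) - 1) > 1e-8)) {
    stop("Q must be row-stochastic")
  }
  nm <- rownames(Q)
  if (is.null(nm)) nm <- if (K == 2) c("L", "U") else paste0("S", seq_len(K))
  reducible <- !is_irreducible(Q)
  if (K == 2) {
    q12 <- Q[1, 2]; q21 <- Q[2, 1]
    if (q12 + q21 == 0) {
      pi <- c(0.5, 0.5)   # two absorbing states: no unique stationary law
    } else {
      pi <- c(q21, q12) / (q12 + q21)
    }
  } else {
    A <- rbind(t(Q) - diag(K), rep(1, K))
    b <- c(rep(0, K), 1)
    pi <- as.numeric(qr.solve(A, b))
    pi <- pmax(pi, 0)
    pi <- pi / sum(pi)
    # polish with power iterations to push the residual to machine precision
    for (i in 1:200) {
      nxt <- as.numeric(pi %*% Q)
      if (max(abs(nxt - pi)) < 1e-15) break
      pi <- nxt / sum(nxt)
    }
  }
  names(pi) <- nm
  attr(pi, "reducible") <- reducible
  pi
}

is_irreducible <- function(Q) {
  adj <- Q > 0
  reach <- adj | diag(nrow(Q)) > 0
  for (i in seq_len(nrow(Q))) {
    reach <- reach | (reach %*% reach) > 0
  }
  all(reach)
}

#' Sample a regime path and velocity profile from the model
#'
#' Draws a hidden state sequence from `pi0` and `Q`, then a velocity per
#' sample from the state's Gaussian emission. Used both for generating
#' synthetic cohorts and for posterior predictive checks.
#'
#' @param m A `regime_model`.
#' @param T Number of samples to draw.
#' @param seed Integer seed; identical seeds give identical draws.
#' @param rate Sampling rate attached to the returned profile (Hz).
#' @return A list with `states` (integer), `labels` (character) and `velocity`
#'   (a [velocity_profile()]).
#' @export
sample_regime_hmm <- function(m, T, seed = NULL, rate = 30) {
  stopifnot(inherits(m, "regime_model"))
  if (T < 1) stop("T must be at least 1")
  with_seed(seed, {
    states <- integer(T)
    states[1] <- sample.int(m$K, 1, prob = m$pi0)
    if (T > 1) {
      for (t in 2:T) {
        states[t] <- sample.int(m$K, 1, prob = m$Q[states[t - 1], ])
      }
    }
    vel <- stats::rnorm(T, mean = m$v[states], sd = sqrt(m$sigma2[states]))
    list(states = states, labels = names(m$v)[states],
         velocity = velocity_profile(vel, rate = rate))
  })
}
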