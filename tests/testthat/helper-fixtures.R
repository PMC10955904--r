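# Shared fixture builders and independent oracles.

# A smooth synthetic "measured" force profile: step-like rise with modulation,
# strictly positive, length n at 30 Hz.
smooth_step_profile <- function(n = 120, rate = 30, seed = 1) {
  t <- (seq_len(n) - 1) / rate
  base <- 0.4 * (1 - exp(-t / 0.4))
  wiggle <- with_fixed_seed(seed, cumsum(rnorm(n, 0, 0.004)))
  force_profile(pmax(base + wiggle + 0.02, 1e-3), rate = rate)
}

with_fixed_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Frequency-response oracle: the Maxwell transfer function evaluated on the
# imaginary axis, compared against the (alpha, beta, gamma, delta) realization
# gamma*beta/(s - alpha) + delta.
transfer_matches_realization <- function(E, eta, n_freq = 20) {
  k <- state_space_constants(E, eta)
  w <- 10^seq(-2, 2, length.out = n_freq)
  s <- complex(imaginary = w)
  G_ref <- eta * s / ((eta / E) * s + 1)
  G_real <- k[["gamma"]] * k[["beta"]] / (s - k[["alpha"]]) + k[["delta"]]
  max(Mod(G_ref - G_real))
}

# Brute-force joint log-probability of a full state path under a regime model;
# used to verify Viterbi by exhaustive enumeration for short sequences.
enumerate_best_path <- function(m, y) {
  K <- m$K
  Tn <- length(y)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tn)))
  lp <- apply(paths, 1, function(st) {
    p <- log(m$pi0[st[1]]) +
      sum(dnorm(y, m$v[st], sqrt(m$sigma2[st]), log = TRUE))
    if (Tn > 1) p <- p + sum(log(m$Q[cbind(st[-Tn], st[-1])]))
    p
  })
  paths[which.max(lp), ]
}

# Power-iteration oracle for the stationary distribution.
power_iteration_pi <- function(Q, iters = 10000) {
  pi <- rep(1 / nrow(Q), nrow(Q))
  for (i in seq_len(iters)) pi <- as.numeric(pi %*% Q)
  pi / sum(pi)
}

# Random grouped samples for the statistics oracles.
random_groups <- function(k = 3, n = 12, seed = 1, sd = 1:3) {
  with_fixed_seed(seed, {
    g <- lapply(seq_len(k), function(i) rnorm(n, mean = i / 2, sd = sd[i]))
    names(g) <- letters[seq_len(k)]
    g
  })
}
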