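truth_model <- function(q12 = 0.05, q21 = 0.05, v = c(1, 6), sigma = 0.35) {
  regime_model(v, rep(sigma^2, 2),
               matrix(c(1 - q12, q12, q21, 1 - q21), 2, byrow = TRUE))
}

test_that("EM recovers known parameters from sampled velocities", {
  m0 <- truth_model()
  vels <- lapply(1:12, function(i) {
    sample_regime_hmm(m0, 119, seed = 100 + i)$velocity
  })
  fit <- fit_regime_hmm(vels)
  expect_lt(abs(fit$v[["L"]] - 1), 0.15)
  expect_lt(abs(fit$v[["U"]] - 6), 0.15)
  expect_lt(abs(fit$Q["L", "U"] - 0.05), 0.03)
  expect_lt(abs(fit$Q["U", "L"] - 0.05), 0.03)
  # EM log-likelihood is monotonically non-decreasing
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("parameter recovery improves with more data", {
  m0 <- truth_model(q12 = 0.08, q21 = 0.04)
  err_at <- function(n_seq) {
    vels <- lapply(seq_len(n_seq), function(i) {
      sample_regime_hmm(m0, 119, seed = 400 + i)$velocity
    })
    fit <- fit_regime_hmm(vels)
    abs(fit$v[["L"]] - 1) + abs(fit$v[["U"]] - 6) +
      abs(fit$Q["L", "U"] - 0.08) + abs(fit$Q["U", "L"] - 0.04)
  }
  expect_lt(err_at(40), err_at(3))
})

test_that("degenerate inputs converge with a warning, never a crash", {
  w <- capture_warnings(fit <- fit_regime_hmm(rep(2, 60)))
  expect_true(any(grepl("identical", w)))
  expect_equal(unname(fit$v), c(2, 2), tolerance = 1e-6)
})

test_that("noiseless two-half sequence yields one transition of mass", {
  y <- c(rep(0, 30), rep(5, 30))
  fit <- fit_regime_hmm(y)
  # 29 L->L transitions and exactly one L->U: q12 = 1/30
  expect_equal(fit$Q["L", "U"], 1 / 30, tolerance = 1e-6)
  expect_equal(fit$Q["U", "L"], 0, tolerance = 1e-6)
  path <- decode_regimes(fit, y)
  expect_equal(sum(diff(path$states) != 0), 1)
  expect_equal(path$labels, c(rep("L", 30), rep("U", 30)))
})

test_that("Viterbi decoding matches exhaustive path enumeration", {
  m <- truth_model(q12 = 0.2, q21 = 0.3, v = c(0, 3), sigma = 1)
  for (seed in 1:3) {
    y <- with_fixed_seed(seed, rnorm(10, sample(c(0, 3), 10, TRUE), 1))
    expect_equal(decode_regimes(m, y)$states, unname(enumerate_best_path(m, y)))
  }
})

test_that("decoding posteriors behave at the extremes and at symmetry", {
  m <- truth_model()
  near_u <- decode_regimes(m, with_fixed_seed(8, rnorm(40, 6, 0.1)))
  expect_true(all(near_u$labels == "U"))
  # symmetric model, sample at the midpoint: posterior (0.5, 0.5)
  ms <- regime_model(c(0, 4), c(1, 1), matrix(0.5, 2, 2))
  mid <- decode_regimes(ms, 2)
  expect_equal(unname(mid$posteriors[1, ]), c(0.5, 0.5))
  expect_equal(rowSums(near_u$posteriors), rep(1, 40))
  expect_error(decode_regimes(m, numeric(0)), "non-empty")
})

test_that("stationary distribution: closed form, oracle, absorbing chains", {
  pi_sym <- stationary_distribution(matrix(c(0.963, 0.037, 0.037, 0.963), 2,
                                           byrow = TRUE))
  expect_equal(unname(pi_sym[["U"]]), 0.5)
  Qj <- matrix(c(0.876, 0.124, 0.028, 0.972), 2, byrow = TRUE)
  pij <- stationary_distribution(Qj)
  expect_equal(unname(pij[["U"]]), 0.124 / (0.124 + 0.028), tolerance = 1e-12)
  expect_equal(as.numeric(pij), power_iteration_pi(Qj), tolerance = 1e-12)
  expect_equal(max(abs(as.numeric(pij %*% Qj) - as.numeric(pij))), 0,
               tolerance = 1e-12)
  expect_equal(sum(pij), 1)
  # absorbing lower regime
  pa <- stationary_distribution(matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE))
  expect_equal(as.numeric(pa), c(1, 0))
  expect_true(attr(pa, "reducible"))
  # a 3-state chain against the power-iteration oracle
  Q3 <- matrix(c(0.8, 0.15, 0.05, 0.1, 0.8, 0.1, 0.2, 0.2, 0.6), 3,
               byrow = TRUE)
  expect_equal(as.numeric(stationary_distribution(Q3)), power_iteration_pi(Q3),
               tolerance = 1e-12)
})

test_that("sampling is reproducible and matches the stationary law", {
  m <- regime_model(c(1, 6), c(0.1, 0.1),
                    matrix(c(0.876, 0.124, 0.028, 0.972), 2, byrow = TRUE))
  s1 <- sample_regime_hmm(m, 200, seed = 9)
  s2 <- sample_regime_hmm(m, 200, seed = 9)
  expect_identical(s1$velocity$samples, s2$velocity$samples)
  expect_false(identical(
    s1$velocity$samples, sample_regime_hmm(m, 200, seed = 10)$velocity$samples))
  # deterministic chain stays put
  md <- regime_model(c(1, 6), c(1e-12, 1e-12), diag(2), pi0 = c(0, 1),
                     relabel = FALSE)
  sd_ <- sample_regime_hmm(md, 50, seed = 1)
  expect_equal(sd_$velocity$samples, rep(6, 50), tolerance = 1e-4)
  # long-run U fraction and per-state moments (T = 1e5)
  big <- sample_regime_hmm(m, 3e5, seed = 11)
  pi_u <- stationary_distribution(m$Q)[["U"]]
  expect_lt(abs(mean(big$states == 2) - pi_u), 0.01)
  for (k in 1:2) {
    v_k <- var(big$velocity$samples[big$states == k])
    expect_lt(abs(v_k - 0.1) / 0.1, 0.05)
  }
})

test_that("canonical relabeling is invariant to permuted initialization", {
  m0 <- truth_model()
  vels <- lapply(1:6, function(i) sample_regime_hmm(m0, 119, seed = i)$velocity)
  f1 <- fit_regime_hmm(vels)
  f2 <- fit_regime_hmm(rev(vels))
  expect_lt(f1$v[["L"]], f1$v[["U"]])
  expect_equal(f1$v, f2$v, tolerance = 1e-6)
  expect_equal(f1$Q, f2$Q, tolerance = 1e-6)
})
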