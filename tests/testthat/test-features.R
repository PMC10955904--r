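test_that("descriptive metrics match their closed forms", {
  # 121 samples at 30 Hz span exactly 4 s
  const <- descriptive_metrics(force_profile(rep(0.4, 121), rate = 30))
  expect_equal(const$mean_force, 0.4)
  expect_equal(const$force_std, 0)
  expect_equal(const$peak_force, 0.4)
  expect_equal(const$scaled_force, 1.0)
  expect_equal(const$force_derivative, 0)
  expect_equal(const$force_integral, 1.6)
  ramp <- descriptive_metrics(force_profile((0:120) / 120, rate = 30))
  expect_equal(ramp$mean_force, 0.5)
  expect_equal(ramp$peak_force, 1)
  expect_equal(ramp$scaled_force, 0.5)
  expect_equal(ramp$force_derivative, 0.25)
  expect_equal(ramp$force_integral, 2.0)
  expect_error(descriptive_metrics(force_profile(rep(0, 10))), "scaled force")
})

test_that("descriptive metrics match a one-pass brute-force recomputation", {
  s <- with_fixed_seed(31, runif(120, 0.05, 0.9))
  m <- descriptive_metrics(force_profile(s, rate = 30))
  dt <- 1 / 30
  expect_equal(m$mean_force, sum(s) / 120)
  expect_equal(m$force_std, sqrt(sum((s - mean(s))^2) / 119))
  expect_equal(m$peak_force, sort(s)[120])
  expect_equal(m$scaled_force, mean(s) / max(s))
  expect_equal(m$force_derivative,
               sum(abs(s[-1] - s[-120]) / dt) / 119)
  expect_equal(m$force_integral,
               sum(vapply(1:119, function(i) (s[i] + s[i + 1]) / 2 * dt,
                          numeric(1))))
  # scaling behaviour: x2 force doubles everything except scaled_force
  m2 <- descriptive_metrics(force_profile(2 * s, rate = 30))
  expect_equal(m2$mean_force, 2 * m$mean_force)
  expect_equal(m2$force_integral, 2 * m$force_integral)
  expect_equal(m2$force_derivative, 2 * m$force_derivative)
  expect_equal(m2$scaled_force, m$scaled_force)
})

test_that("parameter vector has the fixed documented layout", {
  m <- regime_model(c(1, 6), c(0.1225, 0.1225),
                    matrix(c(0.95, 0.05, 0.05, 0.95), 2, byrow = TRUE))
  pv <- parameter_vector(m)
  expect_named(pv, c("v_L", "v_U", "sigma2_L", "sigma2_U", "q12", "q21"))
  expect_equal(unname(pv), c(1, 6, 0.1225, 0.1225, 0.05, 0.05))
  # two models differing only in q21 differ only in position 6
  m2 <- regime_model(c(1, 6), c(0.1225, 0.1225),
                     matrix(c(0.95, 0.05, 0.10, 0.90), 2, byrow = TRUE))
  expect_equal(which(parameter_vector(m2) != pv), c(q21 = 6))
  # serialization round trip preserves the vector exactly
  path <- tempfile(fileext = ".json")
  write_regime_model(m, path)
  expect_identical(parameter_vector(read_regime_model(path)), pv)
  m3 <- regime_model(c(1, 3, 6), rep(0.1, 3), diag(3))
  expect_error(parameter_vector(m3), "two-regime")
})

test_that("PCA feature space: variance capture, orthonormality, signs", {
  # vectors on a 1-D line: PC1 captures ~100% of the variance
  t_ <- seq(-1, 1, length.out = 8)
  line <- outer(t_, c(1, 2, 0.5, 0.5, 1, -1)) +
    matrix(rep(c(3, 6, 1, 1, 0.3, 0.3), each = 8), 8)
  colnames(line) <- c("v_L", "v_U", "sigma2_L", "sigma2_U", "q12", "q21")
  sp <- fit_feature_space(line)
  expect_gt(sp$explained[1], 0.999)
  # orthonormal loadings
  G <- t(sp$loadings) %*% sp$loadings
  expect_equal(unname(G), diag(3), tolerance = 1e-12)
  # scores are centred with diagonal covariance
  X <- with_fixed_seed(41, matrix(rnorm(60), 10, 6,
                                  dimnames = list(NULL, colnames(line))))
  sp2 <- fit_feature_space(X)
  expect_equal(unname(colMeans(sp2$scores)), rep(0, 3), tolerance = 1e-12)
  cv <- cov(sp2$scores)
  expect_equal(unname(cv - diag(diag(cv))), matrix(0, 3, 3), tolerance = 1e-12)
  # documented sign convention
  expect_gte(sp2$loadings["q21", 1], 0)
  expect_gte(sp2$loadings["q12", 2], 0)
  expect_lte(sp2$loadings["v_U", 3], 0)
  # refitting the same vectors reproduces identical loadings
  expect_identical(sp2$loadings, fit_feature_space(X)$loadings)
  expect_error(fit_feature_space(X[1:3, ]), "at least 4")
})

test_that("constructed cohorts separate along the documented components", {
  base <- c(v_L = 3, v_U = 6, sigma2_L = 0.1, sigma2_U = 0.1,
            q12 = 0.1, q21 = 0.1)
  jitter_mat <- function(n, seed) {
    with_fixed_seed(seed, matrix(rnorm(n * 6, 0, 1e-3), n, 6))
  }
  # groups differing in q21 (and oppositely in v_L): PC1 separates
  g1 <- rbind(matrix(base, 6, 6, byrow = TRUE))
  colnames(g1) <- names(base)
  g1[4:6, "q21"] <- 0.4
  g1[4:6, "v_L"] <- 1
  sp1 <- fit_feature_space(g1 + jitter_mat(6, 1))
  expect_gt(min(sp1$scores[4:6, 1]), max(sp1$scores[1:3, 1]))
  # with the documented correlation structure - a 3-coordinate block
  # (v_L down with q21 and sigma2_U up) on PC1, a 2-coordinate block
  # (q12 with sigma2_L) on PC2 - an independent v_U contrast is the only
  # variance left for PC3, which then separates the v_U groups
  n <- 12
  f1 <- with_fixed_seed(3, rnorm(n))
  f2 <- with_fixed_seed(4, rnorm(n))
  f3 <- rep(c(-1, 1), each = n / 2)          # the v_U group contrast
  g3 <- cbind(v_L = 3 - f1, v_U = 6 - f3, sigma2_L = 0.1 + 0.05 * f2,
              sigma2_U = 0.1 + 0.05 * f1, q12 = 0.2 + 0.1 * f2,
              q21 = 0.2 + 0.1 * f1) + jitter_mat(n, 2)
  sp3 <- fit_feature_space(g3)
  expect_lt(sp3$loadings["v_U", 3], 0)
  # the reduced-v_U group (rows 7:12) sits at the high end of PC3
  expect_gt(min(sp3$scores[7:12, 3]), max(sp3$scores[1:6, 3]))
})

test_that("skill axes are the documented diagonal rotations", {
  sc <- matrix(c(0, 0, 0,   1, 1, 0,   2, 0, -2), 3, 3, byrow = TRUE)
  colnames(sc) <- paste0("PC", 1:3)
  ax <- skill_axes(sc)
  expect_equal(unname(unlist(ax[1, ])), c(0, 0, 0))
  expect_equal(ax$abruptness[2], sqrt(2))
  expect_equal(ax$energy[3], 0)
  expect_equal(ax$confidence[3], -2 * sqrt(2))
  # energy and confidence are orthogonal across any cohort
  sc2 <- with_fixed_seed(43, matrix(rnorm(300), 100, 3))
  ax2 <- skill_axes(sc2)
  e <- ax2$energy; cf <- ax2$confidence
  expect_equal(sum(e * cf),
               -sum((sc2[, 1] + sc2[, 3]) * (sc2[, 3] - sc2[, 1])) / 2)
  # rotation identity: -(a+c)(c-a)/2 summed = (sum a^2 - sum c^2)/2
  expect_equal(sum(e * cf), (sum(sc2[, 1]^2) - sum(sc2[, 3]^2)) / 2)
})

test_that("archetype with frequent switching scores highest on abruptness", {
  arch <- default_archetypes()
  coh <- generate_cohort(arch, trials_per_archetype = 2, seed = 29)
  res <- extract_skill_features(coh)
  ab <- tapply(res$axes$abruptness,
               sub("_[0-9]+$", "", res$params$subject_trial), mean)
  expect_equal(names(which.max(ab)), "abrupt_recovery")
})
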