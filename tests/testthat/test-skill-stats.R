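test_that("Levene's test: degenerate, heteroscedastic and oracle cases", {
  same <- list(a = c(1, 2, 3, 4), b = c(5, 6, 7, 8))  # identical spreads
  r <- levene_test(same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1)
  # two groups with variances 1 vs 100 (n = 50): decisively significant
  het <- with_fixed_seed(61, list(a = rnorm(50, sd = 1), b = rnorm(50, sd = 10)))
  expect_lt(levene_test(het)$p.value, 0.05)
  # from-scratch ANOVA-on-absolute-deviations oracle on random inputs
  for (seed in 1:3) {
    g <- random_groups(k = 3, n = 10 + seed, seed = seed)
    r2 <- levene_test(g)
    z <- unlist(lapply(g, function(x) abs(x - mean(x))))
    grp <- factor(rep(names(g), vapply(g, length, integer(1))))
    aov_f <- summary(aov(z ~ grp))[[1]]
    expect_equal(r2$statistic, aov_f[1, "F value"], tolerance = 1e-10)
    expect_equal(r2$p.value, aov_f[1, "Pr(>F)"], tolerance = 1e-10)
  }
  # median-centred variant agrees with the established implementation
  g <- random_groups(k = 3, n = 15, seed = 9)
  bf <- levene_test(g, center = "median")
  grp <- factor(rep(names(g), vapply(g, length, integer(1))))
  ref <- car::leveneTest(unlist(g), grp, center = median)
  expect_equal(bf$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(bf$p.value, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("Welch ANOVA: identity cases and the two-group t^2 reduction", {
  g0 <- with_fixed_seed(62, {
    base <- rnorm(20)
    list(a = base, b = base + rnorm(20, 0, 1e-8))
  })
  expect_gt(welch_anova(g0)$p.value, 0.99)
  # two groups: F equals Welch's t squared, df2 matches
  g2 <- random_groups(k = 2, n = 18, seed = 63, sd = c(1, 4))
  w <- welch_anova(g2)
  tt <- t.test(g2$a, g2$b)
  expect_equal(w$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(w$df2, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(w$p.value, tt$p.value, tolerance = 1e-10)
  # k groups: agrees with the established heteroscedastic ANOVA
  g3 <- random_groups(k = 4, n = 12, seed = 64, sd = c(1, 2, 3, 4))
  w3 <- welch_anova(g3)
  grp <- factor(rep(names(g3), vapply(g3, length, integer(1))))
  ref <- oneway.test(unlist(g3) ~ grp, var.equal = FALSE)
  expect_equal(w3$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(w3$df2, unname(ref$parameter[2]), tolerance = 1e-10)
  expect_equal(w3$p.value, ref$p.value, tolerance = 1e-10)
  expect_error(welch_anova(list(a = rep(1, 5), b = rep(2, 5))), "variance")
})

test_that("Games-Howell flags exactly the truly different pairs", {
  g <- with_fixed_seed(65, list(a = rnorm(30), b = rnorm(30),
                                c = rnorm(30, mean = 5)))
  gh <- games_howell(g)
  expect_equal(nrow(gh), 3)
  sig <- gh[gh$significant, ]
  expect_setequal(paste(sig$group1, sig$group2), c("a c", "b c"))
  # identical groups: nothing significant
  same <- with_fixed_seed(66, list(a = rnorm(25), b = rnorm(25), c = rnorm(25)))
  expect_false(any(games_howell(same)$significant))
  # singleton group: both pairs involving it skipped with warnings
  g1 <- with_fixed_seed(69, list(a = rnorm(10), b = 1, c = rnorm(10)))
  w <- capture_warnings(gh1 <- games_howell(g1))
  expect_length(w, 2)
  expect_match(w, "singleton", all = TRUE)
  expect_equal(nrow(gh1), 1)
})

test_that("Games-Howell recovers a monotone group ordering", {
  # score-ordered groups with increasing means, unequal variances
  g <- with_fixed_seed(67, lapply(setNames(0:3, paste0("score", 0:3)),
                                  function(s) rnorm(25, mean = 2 * s,
                                                    sd = 0.5 + 0.3 * s)))
  gh <- games_howell(g)
  expect_true(all(gh$significant))
  expect_true(all(gh$diff < 0))  # group1 mean below group2 mean throughout
})

test_that("statistics are invariant to group order and location shifts", {
  g <- random_groups(k = 3, n = 14, seed = 68)
  shifted <- lapply(g, function(x) x + 100)
  expect_equal(levene_test(g)$statistic, levene_test(rev(g))$statistic)
  expect_equal(levene_test(g)$statistic, levene_test(shifted)$statistic)
  expect_equal(welch_anova(g)$statistic, welch_anova(rev(g))$statistic)
  expect_equal(welch_anova(g)$statistic, welch_anova(shifted)$statistic)
  gh1 <- games_howell(g); gh2 <- games_howell(shifted)
  expect_equal(gh1$p.value, gh2$p.value)
})

test_that("Spearman rho and permutation critical value", {
  # monotone transform: rho exactly 1, and invariant to any monotone map
  r <- spearman_with_critical(1:15, (1:15)^3, n_perm = 2000, seed = 71)
  expect_equal(r$rho, 1)
  expect_true(r$significant)
  r_log <- spearman_with_critical(exp(1:10), 1:10, n_perm = 500, seed = 71)
  expect_equal(r_log$rho, 1)
  # n = 5: Monte-Carlo critical value matches exhaustive enumeration
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  exact_rhos <- apply(perms, 1, function(p) cor(1:5, p))
  exact_crit <- unname(quantile(exact_rhos, 0.95))
  mc <- spearman_with_critical(1:5, c(2, 1, 4, 3, 5), n_perm = 5e4, seed = 72)
  expect_equal(mc$critical_value, exact_crit, tolerance = 0.02)
  # two independent seeds agree at large n_perm
  c1 <- spearman_with_critical(1:15, 15:1, n_perm = 1e5, seed = 73)
  c2 <- spearman_with_critical(1:15, 15:1, n_perm = 1e5, seed = 74)
  expect_lt(abs(c1$critical_value - c2$critical_value), 0.01)
  expect_error(spearman_with_critical(rep(1, 10), 1:10, 100), "constant")
})

test_that("ICC(2,1): identity, null and sums-of-squares oracle", {
  ident <- cbind(a = c(3, 1, 0, 2, 1, 3), b = c(3, 1, 0, 2, 1, 3))
  expect_equal(icc_2_1(ident)$value, 1)
  # independent raters on 100 targets: ICC near 0
  noise <- with_fixed_seed(75, matrix(rnorm(400), 100, 4))
  expect_lt(abs(icc_2_1(noise)$value), 0.1)
  # 6x4 table against a brute-force two-way ANOVA oracle
  M <- with_fixed_seed(76, matrix(sample(0:3, 24, TRUE), 6, 4))
  r <- icc_2_1(M)
  n <- 6; k <- 4
  mu <- mean(M)
  msr <- sum((rowMeans(M) - mu)^2) * k / (n - 1)
  msc <- sum((colMeans(M) - mu)^2) * n / (k - 1)
  sse <- sum((M - outer(rowMeans(M), rep(1, k)) -
                outer(rep(1, n), colMeans(M)) + mu)^2)
  mse <- sse / ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(r$value, oracle, tolerance = 1e-10)
  expect_error(icc_2_1(matrix(2, 5, 3)), "zero total variance")
  expect_error(icc_2_1(cbind(c(1, NA), c(2, 3))), "complete")
})
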