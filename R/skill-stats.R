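# Statistical toolkit for grouped skill metrics and rater agreement:
# Levene's variance-homogeneity test, Welch's heteroscedastic ANOVA,
# Games-Howell pairwise post-hoc comparisons, Spearman correlation with a
# permutation-null critical value, and ICC(2,1) inter-rater agreement.
# All tests are written out from their defining formulas and return the full
# decision trail (statistic, degrees of freedom, p-value).

# Internal: validate and summarise grouped samples given as a named list of
# numeric vectors or a (value, group) pair.
as_grouped <- function(g, values = NULL) {
  if (!is.null(values)) g <- split(as.numeric(values), g)
  if (is.data.frame(g)) g <- split(as.numeric(g$value), g$group)
  if (!is.list(g) || length(g) < 2) stop("at least 2 groups are required")
  g <- lapply(g, as.numeric)
  if (any(vapply(g, length, integer(1)) == 0)) stop("empty group supplied")
  if (any(!vapply(g, function(x) all(is.finite(x)), logical(1)))) {
    stop("all observations must be finite")
  }
  if (is.null(names(g))) names(g) <- paste0("g", seq_along(g))
  g
}

#' Levene's test for homogeneity of variances
#'
#' One-way ANOVA on the absolute deviations of each observation from its
#' group centre: the classic mean-centred statistic by default, or the
#' median-centred Brown-Forsythe variant. Used to decide whether
#' variance-robust follow-up tests (Welch ANOVA, Games-Howell) are required.
#'
#' @param g Named list of numeric vectors (one per group), a data frame with
#'   columns `value` and `group`, or a factor-split via `values`.
#' @param values Optional numeric vector when `g` is a grouping vector.
#' @param center `"mean"` (Levene) or `"median"` (Brown-Forsythe).
#' @return A list of class `levene_test` with `statistic` (W), `df1`, `df2`,
#'   `p.value` and `center`.
#' @examples
#' levene_test(list(a = rnorm(30), b = rnorm(30, sd = 5)))
#' @export
levene_test <- function(g, values = NULL, center = c("mean", "median")) {
  g <- as_grouped(g, values)
  center <- match.arg(center)
  if (any(vapply(g, length, integer(1)) < 2)) {
    stop("each group needs at least 2 observations")
  }
  cfun <- if (center == "mean") mean else stats::median
  z <- lapply(g, function(x) abs(x - cfun(x)))
  k <- length(z)
  ni <- vapply(z, length, integer(1))
  N <- sum(ni)
  zbar_i <- vapply(z, mean, numeric(1))
  zbar <- sum(unlist(z)) / N
  ss_between <- sum(ni * (zbar_i - zbar)^2)
  ss_within <- sum(vapply(seq_len(k),
                          function(i) sum((z[[i]] - zbar_i[i])^2), numeric(1)))
  if (ss_within == 0) {
    W <- if (ss_between == 0) 0 else Inf
  } else {
    W <- (N - k) / (k - 1) * ss_between / ss_within
  }
  p <- if (W == 0) 1 else stats::pf(W, k - 1, N - k, lower.tail = FALSE)
  structure(list(statistic = W, df1 = k - 1, df2 = N - k, p.value = p,
                 center = center),
            class = "levene_test")
}

#' @export
print.levene_test <- function(x, ...) {
  cat(sprintf("Levene's test (%s-centred): W = %.4g, df = (%d, %d), p = %.4g\n",
              x$center, x$statistic, x$df1, x$df2, x$p.value))
  invisible(x)
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' Omnibus test of equal group means that does not assume equal variances:
#' groups are weighted by `n_i / s_i^2` and the statistic is referred to an F
#' distribution with Satterthwaite-type denominator degrees of freedom. With
#' two groups it reduces to Welch's t-test (`F = t^2`).
#'
#' @inheritParams levene_test
#' @return A list of class `welch_anova` with `statistic` (F), `df1`, `df2`,
#'   `p.value`.
#' @export
welch_anova <- function(g, values = NULL) {
  g <- as_grouped(g, values)
  if (any(vapply(g, length, integer(1)) < 2)) {
    stop("each group needs at least 2 observations")
  }
  ni <- vapply(g, length, numeric(1))
  mi <- vapply(g, mean, numeric(1))
  vi <- vapply(g, stats::var, numeric(1))
  if (all(vi == 0)) stop("all groups have zero within-group variance")
  if (any(vi == 0)) stop("a group has zero variance: Welch weights undefined")
  k <- length(g)
  wi <- ni / vi
  W <- sum(wi)
  mw <- sum(wi * mi) / W
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  lambda <- sum((1 - wi / W)^2 / (ni - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  Fstat <- A / B
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  structure(list(statistic = Fstat, df1 = df1, df2 = df2, p.value = p),
            class = "welch_anova")
}

#' @export
print.welch_anova <- function(x, ...) {
  cat(sprintf("Welch's ANOVA: F = %.4g, df = (%g, %.2f), p = %.4g\n",
              x$statistic, x$df1, x$df2, x$p.value))
  invisible(x)
}

#' Games-Howell pairwise post-hoc comparisons
#'
#' Pairwise tests of group means robust to unequal variances and sample
#' sizes: each pair's Welch-type t statistic is referred to the studentized
#' range distribution with Welch-Satterthwaite degrees of freedom, which
#' controls the family-wise error rate at `alpha` across all pairs.
#'
#' @inheritParams levene_test
#' @param alpha Family-wise significance level (default 0.05).
#' @return A data frame of class `games_howell` with one row per pair:
#'   `group1`, `group2`, `diff`, `se`, `t`, `df`, `p.value`, `significant`.
#'   Pairs involving singleton groups are skipped with a warning.
#' @export
games_howell <- function(g, values = NULL, alpha = 0.05) {
  g <- as_grouped(g, values)
  k <- length(g)
  ni <- vapply(g, length, numeric(1))
  mi <- vapply(g, mean, numeric(1))
  vi <- vapply(g, stats::var, numeric(1))
  rows <- list()
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (ni[i] < 2 || ni[j] < 2) {
        warning(sprintf("skipping pair (%s, %s): singleton group",
                        names(g)[i], names(g)[j]))
        next
      }
      se2 <- vi[i] / ni[i] + vi[j] / ni[j]
      if (se2 == 0) {
        warning(sprintf("skipping pair (%s, %s): zero variance in both groups",
                        names(g)[i], names(g)[j]))
        next
      }
      tstat <- (mi[i] - mi[j]) / sqrt(se2)
      df <- se2^2 / (vi[i]^2 / (ni[i]^2 * (ni[i] - 1)) +
                       vi[j]^2 / (ni[j]^2 * (ni[j] - 1)))
      p <- stats::ptukey(abs(tstat) * sqrt(2), nmeans = k, df = df,
                         lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        group1 = names(g)[i], group2 = names(g)[j],
        diff = mi[i] - mi[j], se = sqrt(se2), t = tstat, df = df,
        p.value = p, significant = p < alpha, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no comparable pairs")
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  class(out) <- c("games_howell", class(out))
  out
}

#' Spearman rank correlation with a permutation critical value
#'
#' Spearman's rho (ranked Pearson correlation with midranks for ties)
#' together with an empirical critical value: the `(1 - alpha)` quantile of
#' rho over random permutations of `y`, i.e. the one-sided permutation null.
#' For `N = 15` and `alpha = 0.05` the critical value is approximately 0.446
#' (the tabulated one-tailed 5% point). The correlation is declared
#' significant when `|rho|` exceeds the critical value.
#'
#' @param x,y Numeric vectors of equal length (at least 4).
#' @param n_perm Number of random permutations (default `1e5`).
#' @param alpha One-sided significance level (default 0.05).
#' @param seed Integer seed for the permutation draw.
#' @return A list of class `spearman_critical` with `rho`, `critical_value`,
#'   `significant`, `n`, `n_perm`, `alpha`.
#' @examples
#' r <- spearman_with_critical(1:15, (1:15)^3, n_perm = 2000, seed = 1)
#' r$rho   # exactly 1: rank correlation is invariant to monotone transforms
#' @export
spearman_with_critical <- function(x, y, n_perm = 1e5, alpha = 0.05,
                                   seed = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n != length(y)) stop("x and y must have equal length")
  if (n < 4) stop("at least 4 paired observations are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rho is undefined for a constant input vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  null_rho <- with_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) stats::cor(rx, ry[sample.int(n)]),
           numeric(1))
  })
  crit <- unname(stats::quantile(null_rho, 1 - alpha))
  structure(list(rho = rho, critical_value = crit,
                 significant = abs(rho) > crit, n = n,
                 n_perm = n_perm, alpha = alpha),
            class = "spearman_critical")
}

#' @export
print.spearman_critical <- function(x, ...) {
  cat(sprintf(
    "Spearman rho = %.4g (n = %d); one-sided %.0f%% permutation critical value = %.4g (%d permutations): %s\n",
    x$rho, x$n, 100 * (1 - x$alpha), x$critical_value, x$n_perm,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' Intraclass correlation ICC(2,1): two-way random effects, single measures
#'
#' Absolute-agreement intraclass correlation from the two-way ANOVA
#' decomposition of a complete targets-by-raters table:
#' \deqn{ICC(2,1) = \frac{MSR - MSE}{MSR + (k-1) MSE + \frac{k}{n}(MSC - MSE)}}
#' with `n` targets (rows), `k` raters (columns), `MSR` the between-target,
#' `MSC` the between-rater and `MSE` the residual mean square. The full ANOVA
#' table is returned for auditability.
#'
#' @param ratings Numeric matrix or data frame, rows = rated targets
#'   (subject/trials), columns = raters; complete (no missing cells), at
#'   least 2 rows and 2 columns.
#' @return A list of class `icc` with `value`, `n`, `k` and `anova` (a data
#'   frame of sums of squares, degrees of freedom and mean squares).
#' @examples
#' tbl <- cbind(r1 = c(3, 2, 1, 0), r2 = c(3, 2, 1, 0))
#' icc_2_1(tbl)$value   # identical raters: 1
#' @export
icc_2_1 <- function(ratings) {
  M <- as.matrix(ratings)
  if (anyNA(M)) stop("ICC(2,1) requires a complete rating table")
  n <- nrow(M); k <- ncol(M)
  if (n < 2 || k < 2) stop("at least 2 targets and 2 raters are required")
  grand <- mean(M)
  row_m <- rowMeans(M)
  col_m <- colMeans(M)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_total <- sum((M - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  if (ss_total == 0) stop("zero total variance: ICC undefined")
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  anova_tab <- data.frame(
    term = c("targets", "raters", "residual"),
    df = c(n - 1, k - 1, (n - 1) * (k - 1)),
    sum_sq = c(ss_rows, ss_cols, ss_err),
    mean_sq = c(msr, msc, mse))
  structure(list(value = icc, n = n, k = k, anova = anova_tab),
            class = "icc")
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.4g (%d targets, %d raters)\n", x$value, x$n, x$k))
  print(x$anova, row.names = FALSE)
  invisible(x)
}
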