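# Statistics stage: gated power transform, studentized-residual outlier
# screening, Dunnett and Duncan comparisons, paired t tests.

test_that("well-behaved data pass the screens untransformed", {
  set.seed(1)
  v <- rnorm(60, 10, 1); g <- rep(c("a", "b", "c"), each = 20)
  pt <- power_transform(v, g)
  expect_false(pt$applied)
  expect_equal(pt$lambda, 1)
  expect_identical(pt$values, v)
})

test_that("log-normal groups select lambda near zero (ML profile oracle)", {
  set.seed(42)
  g <- rep(c("a", "b", "c"), each = 40)
  v <- exp(rnorm(120, mean = rep(c(0, 0.5, 1), each = 40), sd = 0.6))
  pt <- power_transform(v, g)
  expect_true(pt$applied)
  expect_lt(abs(pt$lambda), 0.2)
  # independent profile-likelihood oracle on a lambda grid
  prof <- vapply(seq(-1, 1, by = 0.01), function(l) {
    y <- if (abs(l) < 1e-12) log(v) else (v^l - 1) / l
    r <- stats::resid(stats::lm(y ~ factor(g)))
    n <- length(v)
    -n / 2 * log(sum(r^2) / n) + (l - 1) * sum(log(v))
  }, numeric(1))
  l_star <- seq(-1, 1, by = 0.01)[which.max(prof)]
  expect_equal(pt$lambda, l_star, tolerance = 0.02)
})

test_that("non-positive data are shifted and the transform inverts", {
  set.seed(2)
  g <- rep(c("a", "b"), each = 30)
  v <- c(exp(rnorm(30, 0, 1)) - 1, exp(rnorm(30, 1, 1)))  # contains <= 0
  v[1] <- 0
  pt <- power_transform(v, g, force = TRUE)
  expect_gt(pt$shift, 0)
  back <- power_transform_inverse(pt$values, pt$lambda, pt$shift)
  expect_equal(back, v, tolerance = 1e-8)
})

test_that("studentized-residual screening flags exactly the planted outlier", {
  set.seed(9)
  v <- c(rnorm(20, 10, 1), 30, rnorm(15, 12, 1))
  g <- rep(c("a", "b"), c(21, 15))
  idx <- flag_outliers(v, g)
  expect_identical(idx, 21L)
  # direct-formula oracle: externally studentized residuals
  fit <- stats::lm(v ~ factor(g))
  r_oracle <- stats::rstudent(fit)
  expect_identical(sort(idx), unname(sort(which(abs(r_oracle) > 3))))
  # constant groups: nothing to flag
  expect_identical(flag_outliers(rep(c(1, 2), each = 10),
                                 rep(c("a", "b"), each = 10)), integer(0))
  # boundary: a point tuned to |r| = 2.9 must not be flagged
  base <- c(rnorm(20, 10, 1), NA, rnorm(15, 12, 1))
  f29 <- function(x) {
    vv <- base; vv[21] <- x
    abs(stats::rstudent(stats::lm(vv ~ factor(g)))[21]) - 2.9
  }
  x29 <- stats::uniroot(f29, c(10, 40))$root
  v29 <- base; v29[21] <- x29
  expect_identical(flag_outliers(v29, g), integer(0))
  expect_warning(flag_outliers(c(v, 5), c(g, "single")), "size 1")
})

test_that("Dunnett critical values match a brute-force multivariate-t simulation", {
  crit <- dunnett_critical(k = 3, df = 20, alpha = 0.05)
  # oracle: simulate max |t_i| for 3 many-to-one balanced comparisons
  set.seed(123)
  nrep <- 4e5
  z0 <- rnorm(nrep)
  zt <- matrix(rnorm(nrep * 3), ncol = 3)
  s <- sqrt(rchisq(nrep, df = 20) / 20)
  tmax <- apply(abs(zt - z0) / sqrt(2), 1, max) / s
  crit_mc <- unname(quantile(tmax, 0.95))
  expect_equal(crit, crit_mc, tolerance = 0.01 / crit)
})

test_that("ANOVA with Dunnett comparisons runs the fixed pipeline order", {
  set.seed(1)
  d <- data.frame(
    genotype = rep(c("WT", "mutA", "mutB"), times = c(12, 8, 8)),
    value = c(rnorm(12, 10, 1), rnorm(8, 14, 1), rnorm(8, 10, 1)))
  rep_ <- anova_dunnett(d, control = "WT")
  cmp <- rep_$comparisons
  expect_equal(nrow(cmp), 2)
  a_row <- grep("mutA", cmp$comparison)
  expect_true(cmp$significant[a_row])
  expect_false(cmp$significant[-a_row])
  expect_error(anova_dunnett(data.frame(genotype = "x", value = 1), "x"),
               "two groups")
  expect_error(anova_dunnett(d, control = "nope"), "not present")
  # identical groups: nothing significant
  d0 <- data.frame(genotype = rep(c("WT", "m"), each = 10),
                   value = rep(rnorm(10), 2))
  expect_false(any(anova_dunnett(d0, "WT")$comparisons$significant))
})

test_that("Duncan multiple-range subsets match a direct textbook oracle", {
  set.seed(8)
  # identical groups -> one subset
  v0 <- rep(rnorm(6, 10, 0.5), 3)
  g0 <- rep(c("a", "b", "c"), each = 6)
  expect_length(duncan_pairwise(v0, g0)$subsets, 1)
  # two groups, 10 pooled SDs apart -> two subsets
  v2 <- c(rnorm(8, 0, 1), rnorm(8, 10, 1))
  g2 <- rep(c("a", "b"), each = 8)
  expect_length(duncan_pairwise(v2, g2)$subsets, 2)
  # 4-group layout against an independent oracle implementation
  v4 <- c(rnorm(8, 0, 1), rnorm(8, 0.4, 1), rnorm(8, 4, 1), rnorm(8, 8, 1))
  g4 <- rep(c("g1", "g2", "g3", "g4"), each = 8)
  res <- duncan_pairwise(v4, g4, alpha = 0.05)
  # oracle: unprotected range tests computed pair-by-pair, then the same
  # containment rule applied by direct enumeration
  fit <- stats::aov(v4 ~ factor(g4))
  mse <- stats::anova(fit)[2, "Mean Sq"]; dfe <- stats::df.residual(fit)
  mns <- sort(tapply(v4, g4, mean)); k <- 4; nh <- 8
  sig_o <- matrix(FALSE, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    p <- j - i + 1
    rng <- stats::qtukey(0.95^(p - 1), p, dfe) * sqrt(mse / nh)
    sig_o[i, j] <- (mns[j] - mns[i]) > rng
  }
  # protection: a pair inside a non-significant wider range is cleared
  for (i in 1:(k - 1)) for (j in (i + 1):k) if (sig_o[i, j]) {
    for (a in 1:i) for (b in j:k)
      if ((a < i || b > j) && !sig_o[a, b]) sig_o[i, j] <- FALSE
  }
  subsets_o <- lapply(1:k, function(i) {
    j <- i
    while (j < k && !any(sig_o[i:j, j + 1])) j <- j + 1
    names(mns)[i:j]
  })
  subsets_o <- subsets_o[!duplicated(lapply(subsets_o, paste,
                                            collapse = ","))]
  keep <- vapply(seq_along(subsets_o), function(a)
    !any(vapply(seq_along(subsets_o), function(b)
      a != b && all(subsets_o[[a]] %in% subsets_o[[b]]), logical(1))),
    logical(1))
  expect_identical(res$subsets, subsets_o[keep])
})

test_that("paired t test matches the closed form and handles degeneracy", {
  x <- c(10.2, 11.5, 9.8, 12.1, 10.9)
  y <- c(11.0, 12.9, 10.1, 13.0, 11.2)
  res <- paired_t(x, y)
  d <- y - x
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(res$t, t_oracle, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p, 2 * pt(-abs(t_oracle), 4), tolerance = 1e-10)
  # identical vectors
  expect_warning(r0 <- paired_t(x, x), "zero variance")
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)
  # all differences +1 with tiny jitter: strongly significant, positive
  set.seed(3)
  jit <- rnorm(10, 0, 1e-3)
  r1 <- paired_t(1:10, 1:10 + 1 + jit)
  expect_lt(r1$p, 0.001)
  expect_gt(r1$t, 0)
  expect_error(paired_t(1:3, 1:4), "paired")
})
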