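test_that("exact linear data recovers the slope and eta^2 of 1", {
  set.seed(61)
  x <- rnorm(20L)
  y <- 3 + 2 * x + rnorm(20L, 0, 1e-12)
  f <- ols_hc3(y, x, n_boot = 0L)
  expect_equal(f$slope, 2, tolerance = 1e-6)
  expect_equal(f$intercept, 3, tolerance = 1e-6)
  expect_equal(f$eta_squared, 1, tolerance = 1e-6)
})

test_that("HC3 SE matches a fully hand-expanded sandwich on an n=5 dataset", {
  x <- c(1, 2, 3, 4, 10)
  y <- c(2.0, 2.9, 4.2, 4.8, 11.5)
  f <- ols_hc3(y, x, n_boot = 0L)
  # hand computation, written out term by term
  n <- 5
  sx <- sum(x); sxx <- sum(x^2)
  det_ <- n * sxx - sx^2
  b1 <- (n * sum(x * y) - sx * sum(y)) / det_
  b0 <- (sum(y) - b1 * sx) / n
  e <- y - b0 - b1 * x
  h <- numeric(n)
  for (i in 1:n) h[i] <- 1 / n + (x[i] - mean(x))^2 / sum((x - mean(x))^2)
  w <- e^2 / (1 - h)^2
  # V = (X'X)^-1 X' diag(w) X (X'X)^-1, element [2,2] expanded by hand
  XtXinv <- matrix(c(sxx, -sx, -sx, n), 2L) / det_
  M11 <- sum(w); M12 <- sum(w * x); M22 <- sum(w * x^2)
  meat <- matrix(c(M11, M12, M12, M22), 2L)
  V <- XtXinv %*% meat %*% XtXinv
  expect_equal(f$slope, b1, tolerance = 1e-12)
  expect_equal(f$hc3_se, sqrt(V[2L, 2L]), tolerance = 1e-10)
  # independent route: the established sandwich estimator
  lmfit <- lm(y ~ x)
  Vs <- sandwich::vcovHC(lmfit, type = "HC3")
  expect_equal(f$hc3_se, sqrt(Vs[2L, 2L]), tolerance = 1e-10)
})

test_that("eta^2 equals the squared Pearson correlation to machine precision", {
  set.seed(62)
  for (i in 1:10) {
    n <- sample(10:200, 1L)
    x <- rexp(n); y <- 5 - 0.3 * x + rnorm(n, 0, 2)
    f <- ols_hc3(y, x, n_boot = 0L)
    expect_equal(f$eta_squared, cor(x, y)^2, tolerance = 1e-12)
    # orientation swap: eta^2 unchanged, slope rescaled by var ratio
    g <- ols_hc3(x, y, n_boot = 0L)
    expect_equal(g$eta_squared, f$eta_squared, tolerance = 1e-12)
    expect_equal(g$slope * f$slope, cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("HC3 approaches the classical OLS SE under homoscedasticity", {
  set.seed(63)
  n <- 5000L
  x <- rnorm(n)
  y <- 1 + 0.4 * x + rnorm(n)
  f <- ols_hc3(y, x, n_boot = 0L)
  se_cls <- summary(lm(y ~ x))$coefficients["x", "Std. Error"]
  expect_lt(abs(f$hc3_se - se_cls) / se_cls, 0.05)
})

test_that("with equal leverages HC3 equals HC0 rescaled by (1-h)^-2", {
  # balanced two-point design: every leverage is identical
  x <- rep(c(0, 1), each = 10L)
  set.seed(64)
  y <- rnorm(20L)
  f <- ols_hc3(y, x, n_boot = 0L)
  lmfit <- lm(y ~ x)
  h <- unname(hatvalues(lmfit)[1L])
  se_hc0 <- sqrt(sandwich::vcovHC(lmfit, type = "HC0")[2L, 2L])
  expect_equal(f$hc3_se, se_hc0 / (1 - h), tolerance = 1e-10)
})

test_that("bootstrap CIs are seed-reproducible and ordered", {
  set.seed(65)
  x <- rnorm(60L); y <- 2 - 0.5 * x + rnorm(60L)
  f1 <- ols_hc3(y, x, n_boot = 500L, seed = 99L)
  f2 <- ols_hc3(y, x, n_boot = 500L, seed = 99L)
  expect_identical(f1$boot_ci, f2$boot_ci)
  expect_lte(f1$boot_ci[1L], f1$boot_ci[2L])
  f3 <- ols_hc3(y, x, n_boot = 500L, seed = 100L)
  expect_false(identical(f1$boot_ci, f3$boot_ci))
})

test_that("degenerate regression inputs are rejected", {
  expect_error(ols_hc3(c(1, 2), c(1, 2)), "at least 3")
  expect_error(ols_hc3(c(1, 2, 3), c(2, 2, 2)), "constant")
})

test_that("effect-size classification uses the half-open conventional bins", {
  expect_identical(classify_effect(0.05), "small")
  expect_identical(classify_effect(0.06), "small")
  expect_identical(classify_effect(0.10), "moderate")
  expect_identical(classify_effect(0.14), "large")
  expect_identical(classify_effect(0.22), "large")
  expect_identical(classify_effect(c(0, 1)), c("small", "large"))
  expect_error(classify_effect(1.2), "0, 1")
  expect_error(classify_effect(-0.1), "0, 1")
})

test_that("logistic occurrence model recovers a known odds ratio per mm", {
  set.seed(66)
  n <- 5000L
  d <- runif(n, 0, 60)
  beta <- log(0.97)
  p <- plogis(0.5 + beta * d)
  occ <- rbinom(n, 1L, p)
  f <- logistic_occurrence(occ, d)
  expect_gt(f$odds_ratio, 0.96)
  expect_lt(f$odds_ratio, 0.98)
  expect_lte(f$ci_low, f$odds_ratio)
  expect_gte(f$ci_high, f$odds_ratio)
  # null generator: CI covers 1 in about 95% of replicates
  cov <- replicate(200L, {
    d <- runif(400L, 0, 60)
    occ <- rbinom(400L, 1L, 0.3)
    ci <- logistic_occurrence(occ, d)
    ci$ci_low <= 1 && 1 <= ci$ci_high
  })
  expect_gt(mean(cov), 0.90)
  expect_lt(mean(cov), 0.99)
})

test_that("degenerate logistic inputs are rejected with a named condition", {
  expect_error(logistic_occurrence(rep(1L, 50L), rnorm(50L)), "degenerate outcome")
  # complete separation
  d <- c(1:10, 21:30)
  occ <- rep(c(0L, 1L), each = 10L)
  expect_error(logistic_occurrence(occ, d), "separation")
})

test_that("Welch's ANOVA: two-group F equals the squared Welch t", {
  set.seed(67)
  g1 <- rnorm(15L, 0, 1); g2 <- rnorm(25L, 0.5, 3)
  w <- welch_anova(list(g1, g2))
  tt <- t.test(g1, g2)
  expect_equal(w$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(w$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("Welch's ANOVA matches a hand-computed three-group statistic", {
  g <- list(c(6.2, 7.1, 7.8, 8.4, 9.0), c(5.1, 5.9, 6.3, 7.7),
            c(9.9, 10.2, 11.5, 12.0, 12.3, 13.1))
  w <- welch_anova(g)
  # hand computation of Welch's F with Satterthwaite df
  ni <- sapply(g, length); mi <- sapply(g, mean); vi <- sapply(g, var)
  wi <- ni / vi
  mw <- sum(wi * mi) / sum(wi)
  k <- 3
  A <- sum(wi * (mi - mw)^2) / (k - 1)
  lam <- sum((1 - wi / sum(wi))^2 / (ni - 1))
  B <- 1 + 2 * (k - 2) / (k^2 - 1) * lam
  Fh <- A / B
  dfd <- (k^2 - 1) / (3 * lam)
  expect_equal(w$F, Fh, tolerance = 1e-10)
  expect_equal(w$df_num, k - 1)
  expect_equal(w$df_den, dfd, tolerance = 1e-8)
})

test_that("Welch's ANOVA reduces to classical ANOVA for balanced equal variances", {
  # with equal group sizes and identical sample variances the Welch
  # numerator equals the classical F; the denominator correction
  # B = 1 + 2(k-2)/(k^2-1) * lambda is exactly computable and tends to 1,
  # so the two statistics agree up to that known factor
  set.seed(68)
  base <- rnorm(20L)
  g <- list(base, base + 1, base - 0.5)  # identical within-group variances
  w <- welch_anova(g)
  vals <- unlist(g); fac <- factor(rep(1:3, each = 20L))
  Fc <- summary(aov(vals ~ fac))[[1L]]$`F value`[1L]
  ni <- sapply(g, length); vi <- sapply(g, var); wi <- ni / vi
  lam <- sum((1 - wi / sum(wi))^2 / (ni - 1))
  B <- 1 + 2 * (3 - 2) / (3^2 - 1) * lam
  expect_equal(w$F, Fc / B, tolerance = 1e-8)
  expect_lt(abs(w$F - Fc) / Fc, 0.03)  # correction is < 3% at n = 20/group
  expect_error(welch_anova(list(c(1, 1, 1), rnorm(5L))), "zero-variance")
  expect_error(welch_anova(list(rnorm(3L))), "2 groups")
})
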