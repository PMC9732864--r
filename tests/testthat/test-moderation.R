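test_that("balanced two-level design: simple slopes equal per-level OLS slopes", {
  set.seed(71)
  x0 <- rnorm(40L)
  x <- c(x0, x0)  # identical predictor values in both groups
  g <- rep(c("a", "b"), each = 40L)
  y <- ifelse(g == "a", 1 + 0.3 * x, 2 - 0.6 * x) + rnorm(80L)
  m <- moderation(y, x, g)
  sa <- coef(lm(y[g == "a"] ~ x[g == "a"]))[2L]
  sb <- coef(lm(y[g == "b"] ~ x[g == "b"]))[2L]
  expect_equal(m$simple_slopes$slope[m$simple_slopes$level == "a"],
               unname(sa), tolerance = 1e-10)
  expect_equal(m$simple_slopes$slope[m$simple_slopes$level == "b"],
               unname(sb), tolerance = 1e-10)
})

test_that("categorical omnibus df and robust F agree with the established route", {
  set.seed(72)
  n <- 60L
  x <- rnorm(3L * n)
  g <- rep(c("a", "b", "c"), each = n)
  y <- 1 + 0.5 * x + (g == "b") * 0.8 * x + rnorm(3L * n, 0, 1 + (g == "c"))
  m <- moderation(y, x, g)
  expect_equal(m$df_num, 2L)  # k - 1 interaction terms
  # independent route: car::linearHypothesis with an HC3 covariance
  fit <- lm(y ~ x * factor(g))
  V <- sandwich::vcovHC(fit, type = "HC3")
  lh <- car::linearHypothesis(fit, c("x:factor(g)b = 0", "x:factor(g)c = 0"),
                              vcov. = V, test = "F")
  expect_equal(m$interaction_F, lh$F[2L], tolerance = 1e-8)
})

test_that("injected distinct slopes are detected and recovered", {
  set.seed(73)
  hits <- 0L; err <- c()
  for (i in 1:30) {
    n <- 300L
    x1 <- rexp(n, 1 / 6); x2 <- rexp(n, 1 / 6)
    y1 <- 20 - 0.25 * x1 + rnorm(n, 0, 8)
    y2 <- 15 + 0.65 * x2 + rnorm(n, 0, 8)
    m <- moderation(c(y1, y2), c(x1, x2), rep(c("g1", "g2"), each = n))
    if (m$p_value < 0.001) hits <- hits + 1L
    ss <- m$simple_slopes
    err <- c(err, ss$slope[ss$level == "g1"] - (-0.25),
             ss$slope[ss$level == "g2"] - 0.65)
  }
  expect_gte(hits, 29L)                 # p < 0.001 in nearly every replicate
  expect_lt(mean(abs(err)), 0.1)        # slopes recovered on average
})

test_that("null moderation rejects at about the nominal rate", {
  set.seed(74)
  p <- replicate(400L, {
    x <- rnorm(120L); g <- rep(c("a", "b"), each = 60L)
    y <- 1 + 0.4 * x + rnorm(120L)
    moderation(y, x, g)$p_value
  })
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("continuous moderator: probes at mean -1 SD, mean, mean +1 SD", {
  set.seed(75)
  n <- 500L
  x <- rnorm(n); mvar <- rnorm(n, 10, 3)
  y <- 1 + (0.5 + 0.2 * mvar) * x + rnorm(n)
  m <- moderation(y, x, mvar)
  expect_identical(m$moderator_kind, "continuous")
  expect_equal(m$df_num, 1L)
  expect_equal(m$simple_slopes$probe,
               mean(mvar) + c(-1, 0, 1) * sd(mvar))
  b <- coef(lm(y ~ x * mvar))
  want <- unname(b["x"] + m$simple_slopes$probe * b["x:mvar"])
  expect_equal(m$simple_slopes$slope, want, tolerance = 1e-10)
  expect_lt(m$p_value, 1e-6)
})

test_that("moderation preconditions are enforced", {
  x <- rnorm(30L); y <- rnorm(30L)
  expect_error(moderation(y, x, rep("a", 30L)), "at least 2 levels")
  g <- c(rep("a", 28L), "b", "b")
  expect_error(moderation(y, x, g), "at least 3")
  g2 <- rep(c("a", "b"), each = 15L)
  x2 <- x; x2[1:15] <- 1
  expect_error(moderation(y, x2, g2), "constant within level")
  expect_error(moderation(y, x, rep(2.5, 30L)), "constant")
})

test_that("visual slope table reports signs and flags degenerate groups", {
  # points exactly on a line: slope equals the coefficient
  d <- data.frame(patient_id = sprintf("p%d", 1:4), event_type = "spike",
                  max_rate = c(1, 2, 3, 4), distance_mm = 30 - 2 * c(1, 2, 3, 4),
                  channel_id = "c", pathology = "FCD", stringsAsFactors = FALSE)
  v <- visual_slope_table(d)
  expect_equal(v$slope, -2)
  expect_identical(v$sign, "-")
  # equal rates: undefined slope -> flagged, not fitted
  d2 <- data.frame(patient_id = c("p1", "p2"), event_type = "ripple",
                   max_rate = c(3, 3), distance_mm = c(5, 25),
                   channel_id = "c", pathology = "DNET", stringsAsFactors = FALSE)
  v2 <- visual_slope_table(d2)
  expect_true(v2$flagged)
  expect_true(is.na(v2$slope))
  # single patient -> flagged
  v3 <- visual_slope_table(d2[1L, ])
  expect_true(v3$flagged)
})

test_that("visual slopes recover the injected sign in most seeded cohorts", {
  ok <- 0L
  for (s in 1:20) {
    set.seed(800 + s)
    n <- 12L
    rate <- rexp(n, 1 / 8)
    dist <- 30 - 1.2 * rate + rnorm(n, 0, 6)
    d <- data.frame(patient_id = sprintf("p%d", 1:n), event_type = "spike",
                    max_rate = rate, distance_mm = dist, channel_id = "c",
                    pathology = "FCD", stringsAsFactors = FALSE)
    if (visual_slope_table(d)$sign == "-") ok <- ok + 1L
  }
  expect_gte(ok, 18L)
})
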