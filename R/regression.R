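# run `code` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}

# HC3 (Davidson-MacKinnon) covariance of OLS coefficients:
# (X'X)^-1 X' diag(e_i^2 / (1 - h_ii)^2) X (X'X)^-1
hc3_cov <- function(X, residuals) {
  XtXinv <- chol2inv(chol(crossprod(X)))
  h <- rowSums((X %*% XtXinv) * X)
  w <- residuals^2 / (1 - h)^2
  XtXinv %*% crossprod(X * w, X) %*% XtXinv
}

#' Univariable linear regression with HC3 robust errors
#'
#' Fits `y ~ x` by ordinary least squares and reports the slope with an
#' HC3 (Davidson-MacKinnon) heteroscedasticity consistent standard error,
#' a robust t test (t distribution with n - 2 df, equivalently F with
#' (1, n - 2) df), the effect size eta squared -- numerically equal to the
#' squared Pearson correlation in this simple-regression setting -- with
#' its conventional small/moderate/large classification, and a percentile
#' bootstrap confidence interval for the slope from case resampling.
#'
#' In the lesion-distance analyses the *distance* is the dependent
#' variable `y` (mm) and the biomarker *rate* is the predictor `x`
#' (events/min), so slopes are in mm per event/min.
#'
#' @param y numeric outcome (distance in mm per channel).
#' @param x numeric predictor (rate in events/min per channel).
#' @param n_boot bootstrap resamples (default 1000; 0 skips the bootstrap).
#' @param seed optional integer seed making the bootstrap reproducible.
#' @param conf confidence level (default 0.95).
#' @return An object of class `ecog_ols`: slope, intercept, `hc3_se`,
#'   `t`, `F`, `df_num`, `df_den`, `p_value`, `eta_squared`,
#'   `effect_class`, `boot_ci` (low/high), `n`.
#' @export
ols_hc3 <- function(y, x, n_boot = 1000L, seed = NULL, conf = 0.95) {
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n < 3L) stop("need at least 3 complete observations")
  if (stats::var(x) == 0) stop("predictor is constant; slope undefined")
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  slope <- sum((x - xb) * (y - yb)) / sxx
  intercept <- yb - slope * xb
  e <- y - intercept - slope * x
  X <- cbind(1, x)
  V <- hc3_cov(X, e)
  se <- sqrt(V[2L, 2L])
  tstat <- slope / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 2L)
  r2 <- stats::cor(x, y)^2
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0L) {
    bs <- with_seed(seed, {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
      xm <- matrix(x[idx], nrow = n)
      ym <- matrix(y[idx], nrow = n)
      mx <- colMeans(xm); my <- colMeans(ym)
      sxy <- colMeans(xm * ym) - mx * my
      sxx_b <- colMeans(xm * xm) - mx^2
      sxy / sxx_b  # NaN/Inf when a resample has constant x; dropped below
    })
    bs <- bs[is.finite(bs)]
    a <- (1 - conf) / 2
    ci <- unname(stats::quantile(bs, c(a, 1 - a), type = 7))
  }
  structure(list(slope = slope, intercept = intercept, hc3_se = se,
                 t = tstat, F = tstat^2, df_num = 1L, df_den = n - 2L,
                 p_value = p, eta_squared = r2,
                 effect_class = classify_effect(r2),
                 boot_ci = ci, n_boot = n_boot, conf = conf, n = n),
            class = "ecog_ols")
}

#' @export
print.ecog_ols <- function(x, ...) {
  cat(sprintf("slope %.4g mm per event/min (HC3 SE %.4g), F(%d,%d), p = %.3g\n",
              x$slope, x$hc3_se, x$df_num, x$df_den, x$p_value))
  cat(sprintf("eta^2 = %.3f (%s); bootstrap %d%% CI [%.4g, %.4g], n = %d\n",
              x$eta_squared, x$effect_class, round(100 * x$conf),
              x$boot_ci[1L], x$boot_ci[2L], x$n))
  invisible(x)
}

#' Classify an eta-squared effect size
#'
#' Conventional bins: eta^2 of 0.06 or less is *small*, up to (but
#' excluding) 0.14 is *moderate*, 0.14 or more is *large*. The boundary
#' 0.14 is assigned to *large*.
#'
#' @param eta_squared value in \[0, 1\].
#' @return `"small"`, `"moderate"` or `"large"` (vectorised).
#' @export
classify_effect <- function(eta_squared) {
  if (any(!is.finite(eta_squared)) || any(eta_squared < 0) || any(eta_squared > 1))
    stop("eta_squared must lie in [0, 1]")
  ifelse(eta_squared <= 0.06, "small",
         ifelse(eta_squared < 0.14, "moderate", "large"))
}

#' Binary logistic model for fast ripple occurrence
#'
#' Regresses the occurrence (vs non-occurrence) of fast ripples on a
#' channel on its distance to the lesion edge, and reports the odds ratio
#' for a 1 mm increase in distance with a Wald 95% confidence interval and
#' Wald chi-squared test.
#'
#' @param occurred logical or 0/1 vector per channel.
#' @param d_edge distance to the lesion edge (mm) per channel.
#' @param conf confidence level (default 0.95).
#' @return List: `odds_ratio` (per mm), `ci_low`, `ci_high`, `wald`, `df`,
#'   `p_value`, `beta`, `se`, `n`.
#' @export
logistic_occurrence <- function(occurred, d_edge, conf = 0.95) {
  occurred <- as.integer(as.logical(occurred))
  keep <- is.finite(occurred) & is.finite(d_edge)
  occurred <- occurred[keep]; d_edge <- d_edge[keep]
  if (length(unique(occurred)) < 2L)
    stop("degenerate outcome: both occurrence and non-occurrence must be present")
  fit <- suppressWarnings(stats::glm(occurred ~ d_edge, family = stats::binomial()))
  mu <- stats::fitted(fit)
  if (!fit$converged || any(mu > 1 - 1e-8) || any(mu < 1e-8))
    stop("complete (or quasi-complete) separation: logistic fit is degenerate")
  beta <- stats::coef(fit)[["d_edge"]]
  se <- sqrt(stats::vcov(fit)["d_edge", "d_edge"])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  wald <- (beta / se)^2
  list(odds_ratio = exp(beta), ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se), wald = wald, df = 1L,
       p_value = stats::pchisq(wald, df = 1L, lower.tail = FALSE),
       beta = beta, se = se, n = length(occurred))
}

#' Welch's one-way heteroscedastic ANOVA
#'
#' Compares group means without assuming equal variances, with the
#' Satterthwaite approximation for the denominator degrees of freedom
#' (delegates to [stats::oneway.test()]).
#'
#' @param groups list of numeric vectors, one per group (each with at
#'   least 2 values and positive variance).
#' @return List: `F`, `df_num`, `df_den`, `p_value`, `n`.
#' @export
welch_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need at least 2 groups")
  ns <- vapply(groups, length, integer(1L))
  if (any(ns < 2L)) stop("each group needs at least 2 observations")
  vs <- vapply(groups, stats::var, numeric(1L))
  if (any(vs <= 0)) stop("zero-variance group: Welch's ANOVA is undefined")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), ns))
  ft <- stats::oneway.test(values ~ g, var.equal = FALSE)
  list(F = unname(ft$statistic), df_num = unname(ft$parameter[1L]),
       df_den = unname(ft$parameter[2L]), p_value = unname(ft$p.value),
       n = sum(ns))
}
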