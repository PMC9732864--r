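#' Simple-slopes moderation analysis
#'
#' Tests whether a moderator changes the rate-distance slope by fitting
#' `y ~ x + m + x:m` with an HC3 robust covariance, reporting a robust
#' Wald F for the interaction term(s) (the omnibus moderation test), and
#' probing simple slopes: per level for a categorical moderator
#' (pathology type), or at mean - 1 SD / mean / mean + 1 SD for a
#' continuous moderator (lesion volume).
#'
#' With a categorical moderator of k levels the omnibus test has k - 1
#' numerator degrees of freedom. Simple slopes are the level-specific
#' slopes themselves (reference-level dummy coding), not contrasts
#' against the reference.
#'
#' @param y outcome (distance in mm per channel).
#' @param x predictor (biomarker rate, events/min).
#' @param m moderator: factor/character (pathology) or numeric (volume,
#'   cm^3).
#' @param ref_level reference level for a categorical moderator (default:
#'   first level in sort order).
#' @param probe_values probe points for a continuous moderator (default
#'   mean + c(-1, 0, 1) * SD, in increasing order).
#' @return An object of class `ecog_moderation`: `moderator_kind`,
#'   `interaction_F`, `df_num`, `df_den`, `p_value`, and a
#'   `simple_slopes` data frame with slope, HC3 SE, t and p per level or
#'   probe value.
#' @export
moderation <- function(y, x, m, ref_level = NULL, probe_values = NULL) {
  keep <- is.finite(y) & is.finite(x) & !is.na(m)
  y <- y[keep]; x <- x[keep]; m <- m[keep]
  n <- length(y)
  categorical <- is.factor(m) || is.character(m)
  if (categorical) {
    m <- as.character(m)
    levs <- sort(unique(m))
    if (length(levs) < 2L) stop("categorical moderator needs at least 2 levels")
    if (!is.null(ref_level)) {
      if (!ref_level %in% levs) stop("ref_level not among moderator levels")
      levs <- c(ref_level, setdiff(levs, ref_level))
    }
    sizes <- table(m)
    if (any(sizes < 3L)) stop("every moderator level needs at least 3 observations")
    for (l in levs) if (stats::var(x[m == l]) == 0)
      stop("predictor is constant within level '", l, "'")
    f <- factor(m, levels = levs)
    D <- stats::model.matrix(~f)[, -1L, drop = FALSE]  # k-1 dummies
    X <- cbind(1, x, D, D * x)
    k <- length(levs)
    int_idx <- (2L + k):(2L * k)  # x:dummy columns
  } else {
    m <- as.numeric(m)
    if (stats::var(m) == 0) stop("continuous moderator is constant")
    X <- cbind(1, x, m, x * m)
    int_idx <- 4L
  }
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) stop("rank-deficient moderation design (collinear predictor/moderator)")
  b <- qr.coef(qrX, y)
  e <- y - X %*% b
  V <- hc3_cov(X, as.vector(e))
  q <- length(int_idx)
  bi <- b[int_idx]
  Fstat <- as.numeric(t(bi) %*% solve(V[int_idx, int_idx, drop = FALSE]) %*% bi) / q
  df_den <- n - p
  pval <- stats::pf(Fstat, q, df_den, lower.tail = FALSE)
  slope_contrast <- function(a) {
    s <- sum(a * b)
    se <- sqrt(as.numeric(t(a) %*% V %*% a))
    tt <- s / se
    c(slope = s, se = se, t = tt, p = 2 * stats::pt(-abs(tt), df_den))
  }
  if (categorical) {
    ss <- do.call(rbind, lapply(seq_along(levs), function(i) {
      a <- numeric(p); a[2L] <- 1
      if (i > 1L) a[2L + (length(levs) - 1L) + (i - 1L)] <- 1
      slope_contrast(a)
    }))
    simple <- data.frame(level = levs, ss, row.names = NULL)
  } else {
    if (is.null(probe_values))
      probe_values <- mean(m) + c(-1, 0, 1) * stats::sd(m)
    probe_values <- sort(probe_values)
    ss <- do.call(rbind, lapply(probe_values, function(m0)
      slope_contrast(c(0, 1, 0, m0))))
    simple <- data.frame(probe = probe_values, ss, row.names = NULL)
  }
  structure(list(moderator_kind = if (categorical) "categorical" else "continuous",
                 interaction_F = Fstat, df_num = q, df_den = df_den,
                 p_value = pval, simple_slopes = simple,
                 coefficients = as.numeric(b), vcov = V, n = n),
            class = "ecog_moderation")
}

#' @export
print.ecog_moderation <- function(x, ...) {
  cat(sprintf("%s moderation: interaction F(%d,%d) = %.3f, p = %.3g\n",
              x$moderator_kind, x$df_num, x$df_den, x$interaction_F, x$p_value))
  print(x$simple_slopes, digits = 4)
  invisible(x)
}

#' Per-pathology trendline through patient-level maximum rates
#'
#' For each pathology and event type, fits an ordinary least-squares line
#' through one point per patient -- the highest rate recorded for that
#' patient against the distance of the channel on which it was recorded
#' -- and reports the slope's sign, for visual comparison with the
#' full-channel regression. Groups with fewer than 2 patients or without
#' rate variation are flagged rather than fitted.
#'
#' @param dmax_records output of [dmax()] augmented with a `pathology`
#'   column (one pathology per patient).
#' @return Data frame: pathology, event_type, n_patients, slope, sign
#'   (`"+"`, `"-"`, `"0"`), flagged.
#' @export
visual_slope_table <- function(dmax_records) {
  if (!"pathology" %in% names(dmax_records))
    stop("dmax_records must carry a 'pathology' column")
  combos <- unique(dmax_records[, c("pathology", "event_type")])
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    sel <- dmax_records$pathology == combos$pathology[i] &
      dmax_records$event_type == combos$event_type[i]
    d <- dmax_records[sel, , drop = FALSE]
    flagged <- nrow(d) < 2L || stats::var(d$max_rate) == 0
    slope <- NA_real_
    if (!flagged) {
      slope <- stats::cov(d$max_rate, d$distance_mm) / stats::var(d$max_rate)
    }
    data.frame(pathology = combos$pathology[i], event_type = combos$event_type[i],
               n_patients = nrow(d), slope = slope,
               sign = if (flagged) NA_character_ else
                 if (slope > 0) "+" else if (slope < 0) "-" else "0",
               flagged = flagged, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
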