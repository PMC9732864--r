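#' Default per-pathology cohort parameters
#'
#' Patient counts, lesion volume distributions (cm^3), included bipolar
#' channel counts, and the spread of channel-to-lesion-edge distances used
#' by the synthetic generator. Distance spreads are per pathology because
#' effect sizes observed clinically imply tighter or wider electrode
#' coverage relative to the lesion in different pathology groups.
#'
#' @return Data frame with one row per pathology.
#' @export
pathology_defaults <- function() {
  data.frame(
    pathology = PATHOLOGIES,
    n_patients = c(12L, 9L, 5L, 3L, 2L, 2L),
    n_channels = c(572L, 368L, 245L, 77L, 68L, 66L),
    volume_mean = c(2.5, 10.6, 12.6, 20.8, 7.0, 2.1),
    volume_sd = c(3.0, 9.7, 9.4, 28.6, 8.2, 0.01),
    d_mean = rep(18.9, 6L),
    d_sd = c(9.2, 16.0, 10.0, 9.9, 5.0, 8.9),
    stringsAsFactors = FALSE)
}

#' Default biomarker rate model per pathology and event type
#'
#' For each pathology and event type: the target distance-rate regression
#' slope `slope` (mm per event/min, the slope of distance regressed on
#' rate), the mean `rate_mean` and SD `rate_sd` of rates on *active*
#' channels (channels with at least one event), and the fraction
#' `active_frac` of channels that are active. Zero `active_frac` encodes
#' pathologies in which a biomarker does not occur at all (no fast
#' ripples for DNET, low-grade glioma and cavernoma).
#'
#' @return Data frame with one row per pathology x event type.
#' @export
biomarker_defaults <- function() {
  d <- rbind(
    c("FCD",              "spike",       -0.25, 9.4, 12.8, 1870),
    c("FCD",              "ripple",      -0.35, 6.0,  7.8, 1224),
    c("FCD",              "fast_ripple",  0.00, 4.4,  8.2,  154),
    c("ganglioglioma",    "spike",        0.00, 8.7, 10.1,  884),
    c("ganglioglioma",    "ripple",       0.00, 6.6,  7.3,  521),
    c("ganglioglioma",    "fast_ripple", -2.22, 2.0,  1.7,   22),
    c("DNET",             "spike",        0.00, 3.7,  3.3,  230),
    c("DNET",             "ripple",       0.00, 3.7,  4.7,  125),
    c("DNET",             "fast_ripple",  0.00, 0.0,  0.0,    0),
    c("low_grade_glioma", "spike",        0.65, 10.0, 11.9, 299),
    c("low_grade_glioma", "ripple",       2.67, 3.9,  3.8,   35),
    c("low_grade_glioma", "fast_ripple",  0.00, 0.0,  0.0,    0),
    c("PXA",              "spike",       -0.18, 13.9, 15.3, 167),
    c("PXA",              "ripple",       0.00, 4.2,  4.4,   54),
    c("PXA",              "fast_ripple",  0.00, 1.0,  0.0,    2),
    c("cavernoma",        "spike",       -1.37, 4.1,  4.9,   69),
    c("cavernoma",        "ripple",       0.00, 2.3,  1.7,   16),
    c("cavernoma",        "fast_ripple",  0.00, 0.0,  0.0,    0))
  out <- data.frame(pathology = d[, 1L], event_type = d[, 2L],
                    slope = as.numeric(d[, 3L]), rate_mean = as.numeric(d[, 4L]),
                    rate_sd = as.numeric(d[, 5L]), total_events = as.numeric(d[, 6L]),
                    stringsAsFactors = FALSE)
  nch <- pathology_defaults()
  out$active_frac <- ifelse(out$rate_mean > 0,
                            out$total_events /
                              (nch$n_channels[match(out$pathology, nch$pathology)] *
                                 out$rate_mean), 0)
  out
}

#' Synthetic cohort specification
#'
#' Bundles every tunable of the generator. Defaults reproduce the study
#' conditions the package emulates: 33 patients in the clinical pathology
#' proportions, 1-5 pre-resection recordings per patient, one 60 s epoch
#' per recording, a 10 mm electrode pitch, and rate/volume scales from
#' [biomarker_defaults()] and [pathology_defaults()].
#'
#' @param n_patients named integer vector of patients per pathology
#'   (default: clinical proportions, 33 in total).
#' @param pathology_params data frame as [pathology_defaults()].
#' @param biomarker_params data frame as [biomarker_defaults()].
#' @param grid_specs list of `c(n_rows, n_cols)` layouts sampled per
#'   recording.
#' @param hidden_fraction fraction of each array's electrodes hidden under
#'   the skull (coordinates withheld, to be extrapolated).
#' @param artifact_fraction fraction of bipolar channels excluded as
#'   artifactual.
#' @param recordings_range inclusive range of recordings per patient.
#' @param epoch_s epoch length in seconds.
#' @param surface_kind `"sphere"` or `"bumpy_sphere"`.
#' @param surface_radius sphere radius in mm.
#' @param surface_subdivisions icosphere subdivision level.
#' @param voxel_mm lesion voxel size in mm.
#' @param nominal_spacing electrode pitch in mm.
#' @param seed integer; fixes the entire generated stream.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = NULL,
                        pathology_params = pathology_defaults(),
                        biomarker_params = biomarker_defaults(),
                        grid_specs = list(c(4L, 5L), c(4L, 4L), c(1L, 8L)),
                        hidden_fraction = 0.25,
                        artifact_fraction = 0.106,
                        recordings_range = c(1L, 5L),
                        epoch_s = 60,
                        surface_kind = "sphere",
                        surface_radius = 60,
                        surface_subdivisions = 4L,
                        voxel_mm = 1,
                        nominal_spacing = 10,
                        seed = 1L) {
  if (is.null(n_patients)) {
    n_patients <- stats::setNames(pathology_params$n_patients,
                                  pathology_params$pathology)
  }
  if (any(n_patients < 0)) stop("n_patients must be non-negative")
  if (hidden_fraction < 0 || hidden_fraction >= 1)
    stop("hidden_fraction must be in [0, 1)")
  structure(list(n_patients = n_patients, pathology_params = pathology_params,
                 biomarker_params = biomarker_params, grid_specs = grid_specs,
                 hidden_fraction = hidden_fraction,
                 artifact_fraction = artifact_fraction,
                 recordings_range = recordings_range, epoch_s = epoch_s,
                 surface_kind = surface_kind, surface_radius = surface_radius,
                 surface_subdivisions = surface_subdivisions,
                 voxel_mm = voxel_mm, nominal_spacing = nominal_spacing,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cortical surface
#'
#' `"plane"` builds a regular triangulated square patch at z = 0 (useful
#' because grid extrapolation has a closed-form lattice solution there).
#' `"sphere"` builds an icosphere with known analytic geodesics
#' (great-circle arcs). `"bumpy_sphere"` perturbs the sphere radially with
#' a smooth seeded field, for tests that should not rely on perfect
#' symmetry.
#'
#' @param kind `"plane"`, `"sphere"` or `"bumpy_sphere"`.
#' @param radius sphere radius in mm.
#' @param subdivisions icosphere subdivision level (0 = icosahedron;
#'   vertex count is roughly `10 * 4^s + 2`).
#' @param extent plane side length in mm.
#' @param spacing plane vertex spacing in mm.
#' @param bump_amplitude radial amplitude of the bumps (mm).
#' @param seed seed for the bump field.
#' @return A [cortical_surface()].
#' @export
make_surface <- function(kind = c("plane", "sphere", "bumpy_sphere"),
                         radius = 60, subdivisions = 4L,
                         extent = 100, spacing = 5,
                         bump_amplitude = 1.5, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "plane") {
    xs <- seq(-extent / 2, extent / 2, by = spacing)
    nv <- length(xs)
    if (nv < 2L) stop("plane resolution too low")
    V <- cbind(rep(xs, times = nv), rep(xs, each = nv), 0)
    idx <- function(i, j) (j - 1L) * nv + i
    f <- list()
    for (j in seq_len(nv - 1L)) for (i in seq_len(nv - 1L)) {
      f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
      f[[length(f) + 1L]] <- c(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
    }
    return(cortical_surface(V, do.call(rbind, f)))
  }
  s <- icosphere(subdivisions)
  if (kind == "sphere") return(cortical_surface(s$vertices * radius, s$faces))
  # bumpy sphere: superpose a few long-wavelength cosine fields
  V <- with_seed(seed, {
    k <- 6L
    W <- matrix(stats::rnorm(3L * k), k, 3L)
    W <- W / sqrt(rowSums(W^2))
    ph <- stats::runif(k, 0, 2 * pi)
    fr <- stats::runif(k, 1.5, 3.5)
    bump <- rowSums(vapply(seq_len(k), function(i)
      cos(fr[i] * (s$vertices %*% W[i, ]) * pi + ph[i]), numeric(nrow(s$vertices))))
    s$vertices * (radius + bump_amplitude * bump / k)
  })
  cortical_surface(V, s$faces)
}

# unit icosphere by repeated 1-to-4 subdivision of an icosahedron
icosphere <- function(subdivisions = 3L) {
  t <- (1 + sqrt(5)) / 2
  V <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  V <- V / sqrt(rowSums(V^2))
  FF <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
              c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
              c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
              c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(V)
    E <- surface_edges(FF)
    mid <- (V[E[, 1L], ] + V[E[, 2L], ]) / 2
    mid <- mid / sqrt(rowSums(mid^2))
    key <- function(a, b) pmin(a, b) * (nv + 1) + pmax(a, b)
    ekey <- key(E[, 1L], E[, 2L])
    midx <- function(a, b) nv + match(key(a, b), ekey)
    a <- FF[, 1L]; b <- FF[, 2L]; cc <- FF[, 3L]
    ab <- midx(a, b); bc <- midx(b, cc); ac <- midx(a, cc)
    V <- rbind(V, mid)
    FF <- rbind(cbind(a, ab, ac), cbind(b, bc, ab), cbind(cc, ac, bc),
                cbind(ab, bc, ac))
  }
  list(vertices = V, faces = FF)
}

#' Generate a synthetic lesion mask abutting a surface
#'
#' Places a ball-shaped blob of foreground voxels just beneath a randomly
#' chosen surface location (emulating a neocortical lesion reaching the
#' cortex) and voxelizes it on a regular grid. The ball radius is
#' calibrated so the realized voxel volume is within 10% of the target.
#'
#' @param surface a [cortical_surface()].
#' @param volume_target_cm3 target lesion volume.
#' @param seed integer seed (fixes the lesion location).
#' @param voxel_mm voxel edge length in mm.
#' @param direction optional unit length-3 vector selecting the surface
#'   location (otherwise drawn at random).
#' @return A [lesion_volume()].
#' @export
make_lesion <- function(surface, volume_target_cm3, seed = 1L, voxel_mm = 1,
                        direction = NULL) {
  if (volume_target_cm3 * 1000 < voxel_mm^3)
    stop("volume target is smaller than one voxel")
  with_seed(seed, {
    if (is.null(direction)) {
      direction <- stats::rnorm(3L)
    }
    direction <- direction / sqrt(sum(direction^2))
    # surface point in that direction: project a distant point along it
    far <- direction * max(sqrt(rowSums(surface$vertices^2)))
    sp <- project_to_surface(far, surface)$point
    r <- (3 * volume_target_cm3 * 1000 / (4 * pi))^(1 / 3)
    inward <- -sp / sqrt(sum(sp^2))  # centre-directed for sphere-like surfaces
    center <- sp + inward * (1.05 * r)
    target_vox <- volume_target_cm3 * 1000 / voxel_mm^3
    for (it in 1:3) {
      half <- r + 2 * voxel_mm
      gx <- seq(center[1L] - half, center[1L] + half, by = voxel_mm)
      gy <- seq(center[2L] - half, center[2L] + half, by = voxel_mm)
      gz <- seq(center[3L] - half, center[3L] + half, by = voxel_mm)
      G <- as.matrix(expand.grid(gx, gy, gz))
      inside <- sqrt(rowSums(sweep(G, 2L, center)^2)) <= r
      cnt <- sum(inside)
      if (cnt > 0 && abs(cnt - target_vox) / target_vox <= 0.08) break
      r <- r * (target_vox / max(cnt, 1))^(1 / 3)
    }
    mask <- array(FALSE, dim = c(length(gx), length(gy), length(gz)))
    mask[matrix(c(match(G[inside, 1L], gx), match(G[inside, 2L], gy),
                  match(G[inside, 3L], gz)), ncol = 3L)] <- TRUE
    affine <- diag(c(voxel_mm, voxel_mm, voxel_mm, 1))
    affine[1:3, 4L] <- c(gx[1L], gy[1L], gz[1L])
    lesion_volume(mask, affine)
  })
}

#' Sample channel-to-lesion-edge distances for a pathology
#'
#' Truncated-normal model of the distance distribution of included
#' bipolar channels, with the cohort-wide mean (18.9 mm) and a
#' per-pathology spread.
#'
#' @param n number of channels.
#' @param pathology pathology label.
#' @param params data frame as [pathology_defaults()].
#' @param lower truncation bound in mm.
#' @return Numeric vector of distances (mm).
#' @export
sample_channel_distances <- function(n, pathology, params = pathology_defaults(),
                                     lower = 0.5) {
  i <- match(pathology, params$pathology)
  if (is.na(i)) stop("unknown pathology: ", pathology)
  mu <- params$d_mean[i]; sd <- params$d_sd[i]
  p0 <- stats::pnorm((lower - mu) / sd)
  mu + sd * stats::qnorm(stats::runif(n, p0, 1))
}

# Calibrate the rate model for one pathology x event type cell.
# Counts are zero-inflated negative binomial: an activity gate Z ~
# Bernoulli(pi(d)) times NB(mu(d), theta), mu(d) = max(0, M + beta*(d-dbar)).
# beta is chosen so that the population OLS slope of distance regressed on
# rate equals `b` over the *supplied* distances. When the required
# mean-channel signal exceeds the variance budget implied by the active
# rate SD and the Poisson floor, the remainder of the association is
# carried by a distance-dependent gate (occurrence gradient), solved
# numerically on the sample.
calibrate_rate_model <- function(d, b, M, S, pi0) {
  n <- length(d)
  delta <- d - mean(d)
  V <- mean(delta^2)
  out <- list(b = b, M = M, S = S, pi0 = pi0, beta = 0, theta = Inf,
              a0 = stats::qlogis(min(max(pi0, 1e-12), 1 - 1e-12)),
              a1 = 0, partial = FALSE)
  if (pi0 <= 0 || M <= 0) { out$pi0 <- max(pi0, 0); return(out) }
  S2 <- S^2
  theta_from_beta <- function(beta) {
    resid <- S2 - M - beta^2 * V
    if (resid <= 0) return(Inf)
    th <- (M^2 + beta^2 * V) / resid
    if (th <= 0 || th > 1e6) Inf else th
  }
  if (b == 0) {
    out$theta <- theta_from_beta(0)
    return(out)
  }
  A <- S2 + (1 - pi0) * M^2
  beta_exact <- b * A / max(V, 1e-12)
  budget <- 0.95 * max(S2 - M, 0)
  if (beta_exact^2 * V <= budget) {
    out$beta <- beta_exact
    out$theta <- theta_from_beta(beta_exact)
    return(out)
  }
  # cap the mean-channel slope; push the remaining association into the gate
  beta <- if (budget > 0) sign(b) * sqrt(budget / V) else 0
  out$beta <- beta
  out$theta <- theta_from_beta(beta)
  mu <- pmax(0, M + beta * delta)
  mu2f <- 1 + 1 / out$theta
  solve_a0 <- function(a1) {
    f <- function(a0) mean(stats::plogis(a0 + a1 * delta)) - pi0
    lo <- -max(a1 * delta) - 40  # all gate logits <= -40: mean ~ 0 < pi0
    hi <- -min(a1 * delta) + 40  # all gate logits >= +40: mean ~ 1 > pi0
    stats::uniroot(f, lower = lo, upper = hi, tol = 1e-10)$root
  }
  realized_slope <- function(a1) {
    a0 <- solve_a0(a1)
    p <- stats::plogis(a0 + a1 * delta)
    e <- p * mu
    cv <- mean(delta * e)  # mean(delta) == 0
    vr <- mean(p * (mu + mu^2 * mu2f)) - mean(e)^2
    if (vr <= 0) return(0)
    cv / vr
  }
  sdd <- sqrt(V)
  a1_max <- sign(b) * 20 / sdd
  grid <- seq(0, a1_max, length.out = 41L)[-1L]
  f0 <- realized_slope(0)
  if (abs(f0) >= abs(b)) { out$a1 <- 0; return(out) }  # cap alone suffices
  vals <- vapply(grid, realized_slope, numeric(1L))
  crossing <- which((vals - b) * (f0 - b) < 0)[1L]
  if (!is.na(crossing)) {
    lo <- if (crossing == 1L) 0 else grid[crossing - 1L]
    hi <- grid[crossing]
    out$a1 <- stats::uniroot(function(a) realized_slope(a) - b, lower = min(lo, hi),
                             upper = max(lo, hi), tol = 1e-8)$root
  } else {
    out$a1 <- grid[which.max(abs(vals))]  # slope not reachable; best effort
    out$partial <- TRUE
  }
  out$a0 <- solve_a0(out$a1)
  out
}

#' Generate per-channel biomarker event counts from distances
#'
#' Draws spike, ripple and fast ripple counts for one 60 s epoch per
#' channel, conditionally on each channel's distance to the lesion edge
#' (the causal direction: the lesion shapes the rates; the analysis then
#' regresses distance on rate, as in the clinical workflow). The count
#' law is a zero-inflated negative binomial whose activity fraction, mean
#' and overdispersion reproduce the per-pathology rate scales, and whose
#' distance dependence is calibrated so that the population regression
#' slope of distance on realized rate equals the configured slope for
#' that pathology and event type. Where the configured slope exceeds what
#' the rate scale can support given the count law's variance floor, the
#' generator attains the closest achievable slope of the correct sign and
#' flags the cell (`partial`).
#'
#' @param d_edge numeric vector of channel distances (mm).
#' @param pathology pathology label.
#' @param spec a [cohort_spec()] (only `biomarker_params` and `epoch_s`
#'   are used).
#' @param seed integer seed.
#' @return Data frame with `d_edge_mm`, count columns `spike`, `ripple`,
#'   `fast_ripple`, and rate columns (events/min). The calibration per
#'   event type is attached as attribute `"calibration"`.
#' @export
make_rates <- function(d_edge, pathology, spec = cohort_spec(), seed = 1L) {
  if (any(d_edge < 0)) stop("distances must be non-negative")
  bp <- spec$biomarker_params
  epoch_min <- spec$epoch_s / 60
  n <- length(d_edge)
  out <- data.frame(d_edge_mm = d_edge)
  calib <- list()
  # scramble the user seed so the count stream is decorrelated from any
  # caller stream that was itself seeded with the same integer
  seed <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L))[2L]
  with_seed(seed, {
    for (ty in EVENT_TYPES) {
      row <- bp[bp$pathology == pathology & bp$event_type == ty, , drop = FALSE]
      if (nrow(row) != 1L) stop("no biomarker parameters for ", pathology, "/", ty)
      cl <- calibrate_rate_model(d_edge, row$slope, row$rate_mean, row$rate_sd,
                                 row$active_frac)
      calib[[ty]] <- cl
      if (cl$pi0 <= 0 || cl$M <= 0) {
        cnt <- integer(n)
      } else {
        delta <- d_edge - mean(d_edge)
        p <- stats::plogis(cl$a0 + cl$a1 * delta)
        mu <- pmax(0, cl$M + cl$beta * delta) * epoch_min
        z <- stats::rbinom(n, 1L, p)
        cnt <- integer(n)
        act <- z == 1L & mu > 0
        if (any(act)) {
          cnt[act] <- if (is.finite(cl$theta)) {
            stats::rnbinom(sum(act), size = cl$theta * epoch_min, mu = mu[act])
          } else {
            stats::rpois(sum(act), mu[act])
          }
        }
      }
      out[[ty]] <- cnt
      out[[RATE_COLS[[ty]]]] <- cnt / epoch_min
    }
  })
  attr(out, "calibration") <- calib
  out
}

#' Simulate a channel table at realistic clinical cohort sizes (no geometry)
#'
#' Draws, per pathology, the default number of included bipolar channels
#' with distances from the pathology's distance model and rates from the
#' calibrated count model, plus per-patient lesion volumes from the
#' pathology's volume law. This is the fast, distribution-level
#' counterpart of [make_cohort()]: it skips surfaces, masks and
#' electrode placement and is the natural input for statistical
#' validation at realistic sample sizes.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed.
#' @return Channel-table data frame: `patient_id`, `pathology`,
#'   `d_edge_mm`, rate columns, `lesion_volume_cm3`.
#' @export
simulate_channel_cohort <- function(spec = cohort_spec(), seed = 1L) {
  pp <- spec$pathology_params
  with_seed(seed, {
    out <- list()
    pid <- 0L
    for (i in seq_len(nrow(pp))) {
      g <- pp$pathology[i]
      n <- pp$n_channels[i]
      npat <- max(1L, pp$n_patients[i])
      d <- sample_channel_distances(n, g, params = pp)
      rts <- make_rates(d, g, spec, seed = sample.int(2^30, 1L))
      m <- pp$volume_mean[i]; s <- max(pp$volume_sd[i], 1e-6)
      ml <- log(m^2 / sqrt(m^2 + s^2)); sl <- sqrt(log(1 + s^2 / m^2))
      vols <- pmin(pmax(stats::rlnorm(npat, ml, sl), 0.3), 60)
      pat <- rep(seq_len(npat), length.out = n)[order(stats::runif(n))]
      out[[g]] <- data.frame(
        patient_id = sprintf("p%02d", pid + pat), pathology = g,
        channel_id = sprintf("%s_c%04d", g, seq_len(n)),
        d_edge_mm = d,
        spike_rate = rts$spike_rate, ripple_rate = rts$ripple_rate,
        fr_rate = rts$fr_rate,
        lesion_volume_cm3 = vols[pat], stringsAsFactors = FALSE)
      pid <- pid + npat
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

# build one electrode array on the surface: seed corner + chord marching,
# delegating the fill to extrapolate_grid so that regeneration from any
# visible subset containing the anchors reproduces identical coordinates
make_grid_on_surface <- function(surface, center_dir, n_rows, n_cols, spacing,
                                 array_id, azimuth = 0) {
  center_dir <- center_dir / sqrt(sum(center_dir^2))
  far <- center_dir * max(sqrt(rowSums(surface$vertices^2))) * 1.5
  c0 <- project_to_surface(far, surface)$point
  # tangent basis at the centre, rotated by the azimuth
  ref <- if (abs(center_dir[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * center_dir) * center_dir
  u <- u / sqrt(sum(u^2))
  v <- c(center_dir[2L] * u[3L] - center_dir[3L] * u[2L],
         center_dir[3L] * u[1L] - center_dir[1L] * u[3L],
         center_dir[1L] * u[2L] - center_dir[2L] * u[1L])
  uu <- cos(azimuth) * u + sin(azimuth) * v
  vv <- -sin(azimuth) * u + cos(azimuth) * v
  corner <- c0 - uu * (n_cols - 1) * spacing / 2 - vv * (n_rows - 1) * spacing / 2
  X <- matrix(NA_real_, n_rows * n_cols, 3L)
  e11 <- project_to_surface(corner, surface)$point
  X[1L, ] <- e11
  X[2L, ] <- place_on_surface(e11 + uu * spacing, matrix(e11, 1L), surface, spacing)
  if (n_rows > 1L) {
    X[n_cols + 1L, ] <- place_on_surface(e11 + vv * spacing, matrix(e11, 1L),
                                         surface, spacing)
  }
  arr <- electrode_array(array_id, n_rows, n_cols, X,
                         nominal_spacing = spacing)
  extrapolate_grid(arr, surface)
}

#' Generate a complete synthetic cohort
#'
#' Builds, per patient: a cortical surface, a lesion mask sized from the
#' pathology's volume distribution, 1-5 recordings each with an electrode
#' array placed near the lesion (a fraction of electrodes hidden, to be
#' extrapolated downstream), bipolar channels with ground-truth distances
#' computed by the geometry functions on the same objects, artifact
#' flags, and timestamped event logs drawn from the calibrated rate
#' model. Optionally writes the full file set (NIfTI masks, PLY surfaces,
#' TSV electrode tables, CSV event/artifact/ground-truth tables) so the
#' analysis pipeline can be exercised end to end from disk.
#'
#' @param spec a [cohort_spec()].
#' @param out_dir optional output directory.
#' @param seed overrides `spec$seed` when given.
#' @return Invisibly, a list with `channels` (ground-truth channel
#'   table), `events`, `artifacts`, `patients`, and `dir` (or `NULL`).
#' @export
make_cohort <- function(spec = cohort_spec(), out_dir = NULL, seed = NULL) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  pp <- spec$pathology_params
  with_seed(spec$seed, {
    patients <- list(); channels <- list(); events <- list(); artifacts <- list()
    objects <- list()
    pid <- 0L
    for (gi in seq_along(spec$n_patients)) {
      pathology <- names(spec$n_patients)[gi]
      prow <- pp[pp$pathology == pathology, , drop = FALSE]
      if (nrow(prow) != 1L) stop("unknown pathology in n_patients: ", pathology)
      for (k in seq_len(spec$n_patients[[gi]])) {
        pid <- pid + 1L
        patient_id <- sprintf("p%02d", pid)
        surface <- if (spec$surface_kind == "bumpy_sphere") {
          make_surface("bumpy_sphere", radius = spec$surface_radius,
                       subdivisions = spec$surface_subdivisions,
                       seed = sample.int(2^30, 1L))
        } else {
          make_surface("sphere", radius = spec$surface_radius,
                       subdivisions = spec$surface_subdivisions)
        }
        # lesion volume from the pathology's lognormal volume law
        m <- prow$volume_mean; s <- max(prow$volume_sd, 1e-6)
        ml <- log(m^2 / sqrt(m^2 + s^2)); sl <- sqrt(log(1 + s^2 / m^2))
        vol <- min(max(stats::rlnorm(1L, ml, sl), 0.3), 60)
        wdir <- stats::rnorm(3L); wdir <- wdir / sqrt(sum(wdir^2))
        lesion <- make_lesion(surface, vol, seed = sample.int(2^30, 1L),
                              voxel_mm = spec$voxel_mm, direction = wdir)
        r_les <- (3 * lesion_volume_cm3(lesion) * 1000 / (4 * pi))^(1 / 3)
        n_rec <- sample(seq(spec$recordings_range[1L], spec$recordings_range[2L]), 1L)
        arrays <- list()
        for (rec in seq_len(n_rec)) {
          gs <- spec$grid_specs[[sample.int(length(spec$grid_specs), 1L)]]
          # grid centre: angular offset from the lesion, random side
          off_mm <- r_les + stats::runif(1L, 5, 30)
          ang <- off_mm / spec$surface_radius
          az <- stats::runif(1L, 0, 2 * pi)
          # rotate wdir by `ang` towards a random tangent direction
          ref <- if (abs(wdir[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
          t1 <- ref - sum(ref * wdir) * wdir; t1 <- t1 / sqrt(sum(t1^2))
          t2 <- c(wdir[2L] * t1[3L] - wdir[3L] * t1[2L],
                  wdir[3L] * t1[1L] - wdir[1L] * t1[3L],
                  wdir[1L] * t1[2L] - wdir[2L] * t1[1L])
          tdir <- cos(az) * t1 + sin(az) * t2
          cdir <- cos(ang) * wdir + sin(ang) * tdir
          array_id <- sprintf("%s_r%02d", patient_id, rec)
          arr <- make_grid_on_surface(surface, cdir, gs[1L], gs[2L],
                                      spec$nominal_spacing, array_id,
                                      azimuth = stats::runif(1L, 0, 2 * pi))
          # hide trailing electrodes (under the skull), keeping the anchors
          nel <- gs[1L] * gs[2L]
          n_hide <- min(floor(spec$hidden_fraction * nel),
                        nel - (gs[2L] + if (gs[1L] > 1L) 1L else 0L))
          visible <- rep(TRUE, nel)
          if (n_hide > 0L) visible[(nel - n_hide + 1L):nel] <- FALSE
          arr$visible <- visible
          arrays[[rec]] <- arr
        }
        objects[[patient_id]] <- list(surface = surface, lesion = lesion,
                                      arrays = arrays)
        patients[[patient_id]] <- data.frame(
          patient_id = patient_id, pathology = pathology,
          lesion_volume_cm3 = lesion_volume_cm3(lesion),
          n_recordings = n_rec, stringsAsFactors = FALSE)
        # ground-truth channels: montage + distances via the geometry module
        graph <- surface_graph(surface)
        for (rec in seq_len(n_rec)) {
          arr <- arrays[[rec]]
          mont <- build_montage(arr, direction = "row")
          mids <- as.matrix(mont[, c("mid_x", "mid_y", "mid_z")])
          ch <- data.frame(patient_id = patient_id,
                           recording_id = sprintf("r%02d", rec),
                           channel_id = mont$channel_id,
                           mid_x = mids[, 1L], mid_y = mids[, 2L], mid_z = mids[, 3L],
                           d_edge_mm = euclidean_edge_distance(mids, lesion),
                           d_com_mm = euclidean_com_distance(mids, lesion),
                           d_geo_mm = geodesic_distance(mids, lesion, surface,
                                                        graph = graph,
                                                        labels = mont$channel_id),
                           pathology = pathology,
                           lesion_volume_cm3 = lesion_volume_cm3(lesion),
                           artifact = stats::runif(nrow(mont)) < spec$artifact_fraction,
                           stringsAsFactors = FALSE)
          channels[[length(channels) + 1L]] <- ch
        }
      }
    }
    channels <- do.call(rbind, channels)
    patients <- do.call(rbind, patients)
    rownames(channels) <- rownames(patients) <- NULL
    # rates: calibrate per pathology over the pooled included channels
    for (ty in EVENT_TYPES) channels[[RATE_COLS[[ty]]]] <- 0
    for (pathology in unique(channels$pathology)) {
      sel <- which(channels$pathology == pathology & !channels$artifact)
      if (!length(sel)) next
      rts <- make_rates(channels$d_edge_mm[sel], pathology, spec,
                        seed = sample.int(2^30, 1L))
      for (ty in EVENT_TYPES) {
        channels[[RATE_COLS[[ty]]]][sel] <- rts[[RATE_COLS[[ty]]]]
        cnts <- rts[[ty]]
        has <- which(cnts > 0L)
        if (!length(has)) next
        ev <- data.frame(
          patient_id = rep(channels$patient_id[sel][has], cnts[has]),
          recording_id = rep(channels$recording_id[sel][has], cnts[has]),
          channel_id = rep(channels$channel_id[sel][has], cnts[has]),
          event_type = ty,
          time_s = NA_real_, epoch_length_s = spec$epoch_s,
          stringsAsFactors = FALSE)
        ev$time_s <- round(stats::runif(nrow(ev), 0, spec$epoch_s - 1e-3), 3L)
        events[[length(events) + 1L]] <- ev
      }
    }
    events <- if (length(events)) do.call(rbind, events) else
      data.frame(patient_id = character(), recording_id = character(),
                 channel_id = character(), event_type = character(),
                 time_s = numeric(), epoch_length_s = numeric())
    events <- events[order(events$patient_id, events$recording_id,
                           events$channel_id, events$event_type, events$time_s), ]
    rownames(events) <- NULL
    artifacts <- channels[channels$artifact,
                          c("patient_id", "recording_id", "channel_id")]
    rownames(artifacts) <- NULL
    res <- list(channels = channels, events = events, artifacts = artifacts,
                patients = patients, objects = objects, spec = spec,
                dir = out_dir)
    if (!is.null(out_dir)) write_cohort(res, out_dir)
    invisible(res)
  })
}

# serialize a generated cohort to the on-disk interchange formats
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (patient_id in names(cohort$objects)) {
    pdir <- file.path(out_dir, "patients", patient_id)
    dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
    obj <- cohort$objects[[patient_id]]
    write_lesion_nifti(obj$lesion, file.path(pdir, "lesion.nii.gz"))
    write_ply(obj$surface, file.path(pdir, "surface.ply"))
    tabs <- lapply(obj$arrays, function(arr) {
      n <- arr$n_rows * arr$n_cols
      r <- (seq_len(n) - 1L) %/% arr$n_cols + 1L
      cc <- (seq_len(n) - 1L) %% arr$n_cols + 1L
      co <- arr$coordinates
      co[!arr$visible, ] <- NA_real_  # hidden electrodes: coordinates withheld
      data.frame(patient_id = patient_id,
                 recording_id = sub(".*_(r[0-9]+)$", "\\1", arr$array_id),
                 array_id = arr$array_id, row = r, col = cc,
                 x_mm = co[, 1L], y_mm = co[, 2L], z_mm = co[, 3L],
                 visible = as.integer(arr$visible), stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, tabs)
    num <- c("x_mm", "y_mm", "z_mm")
    for (cn in num) tab[[cn]] <- ifelse(is.na(tab[[cn]]), "",
                                        sprintf("%.9f", tab[[cn]]))
    utils::write.table(tab, file.path(pdir, "electrodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.csv(cohort$events, file.path(out_dir, "events.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$artifacts, file.path(out_dir, "artifacts.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$patients, file.path(out_dir, "patients.csv"),
                   row.names = FALSE, quote = FALSE)
  gt <- cohort$channels
  gt$artifact <- as.integer(gt$artifact)
  utils::write.csv(format_channel_table(gt),
                   file.path(out_dir, "ground_truth_channels.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}

# fixed-precision formatting so equal-seed runs are byte-identical
format_channel_table <- function(df) {
  for (cn in names(df)) {
    if (is.numeric(df[[cn]]) && !is.integer(df[[cn]]))
      df[[cn]] <- sprintf("%.6f", df[[cn]])
  }
  df
}
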