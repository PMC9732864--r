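#' Electrode grid or strip
#'
#' Represents one ioECoG array: a `n_rows x n_cols` layout (4x5 and 4x4
#' grids, 1x8 strips are the common clinical sizes) with a 3-D coordinate
#' per electrode where known. Electrodes are numbered row-major: electrode
#' `(r, c)` is entry `(r - 1) * n_cols + c`. Rigid arrays have a fixed
#' inter-electrode (chord) spacing, 10 mm by default.
#'
#' @param array_id identifier string.
#' @param n_rows,n_cols layout dimensions.
#' @param coordinates `(n_rows*n_cols) x 3` matrix of mm coordinates; rows
#'   of `NA` mark electrodes not yet localized.
#' @param visible logical vector: electrode was visible on the
#'   intraoperative photograph (i.e. its coordinate is trusted input).
#' @param nominal_spacing inter-electrode chord spacing in mm.
#' @return An object of class `electrode_array`.
#' @export
electrode_array <- function(array_id, n_rows, n_cols, coordinates,
                            visible = NULL, nominal_spacing = 10) {
  n <- n_rows * n_cols
  if (n < 2L) stop("array must have at least 2 electrodes")
  if (nominal_spacing <= 0) stop("nominal_spacing must be positive")
  coordinates <- as.matrix(coordinates)
  if (nrow(coordinates) != n || ncol(coordinates) != 3L)
    stop("coordinates must be a (n_rows*n_cols) x 3 matrix")
  if (is.null(visible)) visible <- stats::complete.cases(coordinates)
  has_coord <- stats::complete.cases(coordinates)
  if (any(visible & !has_coord))
    stop("visible electrodes must carry coordinates")
  if (sum(visible & has_coord) < 2L)
    stop("at least 2 visible electrodes with coordinates are required")
  structure(list(array_id = array_id, n_rows = as.integer(n_rows),
                 n_cols = as.integer(n_cols), coordinates = coordinates,
                 visible = as.logical(visible),
                 nominal_spacing = nominal_spacing),
            class = "electrode_array")
}

#' @export
print.electrode_array <- function(x, ...) {
  cat(sprintf("electrode_array '%s': %dx%d, %d/%d localized (%d visible)\n",
              x$array_id, x$n_rows, x$n_cols,
              sum(stats::complete.cases(x$coordinates)),
              x$n_rows * x$n_cols, sum(x$visible)))
  invisible(x)
}

elec_index <- function(array, r, c) (r - 1L) * array$n_cols + c

#' Bipolar channel coordinate
#'
#' The bipolar montage locates each channel at the exact spatial midpoint
#' between its two neighbouring electrode coordinates.
#'
#' @param a,b length-3 vectors or `n x 3` matrices of electrode
#'   coordinates (mm).
#' @return Componentwise mean, same shape as the inputs.
#' @export
bipolar_midpoint <- function(a, b) {
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("electrode coordinates must be finite")
  (a + b) / 2
}

# chord-constrained placement of one electrode: start from `seed`, then
# alternate (i) rescaling to the nominal chord length from each anchor and
# (ii) projecting back onto the surface, until the chords settle.
place_on_surface <- function(seed, anchors, surface, spacing, max_iter = 100L) {
  x <- project_to_surface(seed, surface)$point
  for (it in seq_len(max_iter)) {
    x_old <- x
    for (k in seq_len(nrow(anchors))) {
      a <- anchors[k, ]
      d <- x - a
      nd <- sqrt(sum(d^2))
      if (nd < 1e-9) d <- x - colMeans(anchors) + 1e-6  # degenerate: nudge
      x <- a + d * (spacing / max(nd, 1e-12))
      x <- project_to_surface(x, surface)$point
    }
    if (sqrt(sum((x - x_old)^2)) < 1e-9) break
  }
  x
}

#' Fill in hidden electrodes of a partially localized array
#'
#' Electrodes hidden under the skull are extrapolated from the visible
#' ones by marching outward across the layout, taking the fixed 1 cm
#' inter-electrode distance and the curvature of the cortical surface into
#' account. Each missing electrode is seeded by linear continuation (two
#' collinear localized neighbours in its row or column) or parallelogram
#' completion (an L of three localized neighbours), then relaxed onto the
#' surface under the chord-spacing constraint. Visible electrodes are
#' never moved, and the fill of a given cell depends only on its parent
#' cells, so re-running on a fully localized array is a no-op and
#' regenerating a grid from any visible subset that contains the original
#' anchors reproduces identical coordinates.
#'
#' @param array an [electrode_array()] with at least one adjacent pair of
#'   visible electrodes.
#' @param surface a [cortical_surface()].
#' @param spacing_tol maximum tolerated deviation of an adjacent chord
#'   from `nominal_spacing`, in mm (default 0.2).
#' @param snap_tol maximum electrode-to-surface distance in mm (default 1).
#' @return The array with every electrode localized.
#' @export
extrapolate_grid <- function(array, surface, spacing_tol = 0.2, snap_tol = 1.0) {
  stopifnot(inherits(array, "electrode_array"))
  nr <- array$n_rows; nc <- array$n_cols
  s <- array$nominal_spacing
  X <- array$coordinates
  placed <- stats::complete.cases(X)
  vis_idx <- which(array$visible & placed)
  if (length(vis_idx) < 2L) stop("at least 2 visible electrodes are required")
  # check visible coordinates sit on the surface
  for (i in vis_idx) {
    ds <- project_to_surface(X[i, ], surface)$distance
    if (ds > snap_tol)
      stop(sprintf("visible electrode %d of '%s' is %.2f mm off the surface (snap tolerance %.2f mm)",
                   i, array$array_id, ds, snap_tol))
  }
  # an adjacent visible pair is needed to define the marching direction
  rc <- cbind((vis_idx - 1L) %/% nc + 1L, (vis_idx - 1L) %% nc + 1L)
  adj <- FALSE
  for (i in seq_along(vis_idx)) for (j in seq_along(vis_idx)) {
    if (sum(abs(rc[i, ] - rc[j, ])) == 1L) adj <- TRUE
  }
  if (!adj) stop("no adjacent pair of visible electrodes; direction undefined")

  at <- function(r, c) {
    if (r < 1L || r > nr || c < 1L || c > nc) return(NULL)
    i <- (r - 1L) * nc + c
    if (!placed[i]) return(NULL)
    X[i, ]
  }
  repeat {
    progress <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      i <- (r - 1L) * nc + c
      if (placed[i]) next
      seed <- NULL; anchors <- NULL
      # priority 1: linear continuation along the column, then the row
      lin <- list(list(at(r - 1L, c), at(r - 2L, c)),
                  list(at(r + 1L, c), at(r + 2L, c)),
                  list(at(r, c - 1L), at(r, c - 2L)),
                  list(at(r, c + 1L), at(r, c + 2L)))
      for (L in lin) {
        if (!is.null(L[[1L]]) && !is.null(L[[2L]])) {
          seed <- 2 * L[[1L]] - L[[2L]]
          anchors <- matrix(L[[1L]], nrow = 1L)
          break
        }
      }
      # priority 2: parallelogram completion from an L of three neighbours
      if (is.null(seed)) {
        par <- list(list(at(r - 1L, c), at(r, c - 1L), at(r - 1L, c - 1L)),
                    list(at(r - 1L, c), at(r, c + 1L), at(r - 1L, c + 1L)),
                    list(at(r + 1L, c), at(r, c - 1L), at(r + 1L, c - 1L)),
                    list(at(r + 1L, c), at(r, c + 1L), at(r + 1L, c + 1L)))
        for (L in par) {
          if (!any(vapply(L, is.null, logical(1L)))) {
            seed <- L[[1L]] + L[[2L]] - L[[3L]]
            anchors <- rbind(L[[1L]], L[[2L]])
            break
          }
        }
      }
      if (is.null(seed)) next
      x <- place_on_surface(seed, anchors, surface, s)
      chord_err <- max(abs(sqrt(rowSums(sweep(anchors, 2L, x)^2)) - s))
      surf_err <- project_to_surface(x, surface)$distance
      if (chord_err > spacing_tol || surf_err > snap_tol)
        stop(sprintf(paste0("placement infeasible for electrode (%d,%d) of '%s': ",
                            "chord error %.3f mm, surface error %.3f mm"),
                     r, c, array$array_id, chord_err, surf_err))
      X[i, ] <- x
      placed[i] <- TRUE
      progress <- TRUE
    }
    if (all(placed)) break
    if (!progress)
      stop("extrapolation stalled: remaining electrodes have no localized neighbours")
  }
  array$coordinates <- X
  array
}
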