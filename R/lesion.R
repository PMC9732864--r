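#' Binary lesion segmentation volume
#'
#' Wraps a 3-D binary voxel mask together with its voxel-index-to-world
#' affine. Voxel index `(i, j, k)` (1-based in R) maps to the *centre* of
#' the voxel at world position `affine %*% c(i-1, j-1, k-1, 1)` (0-based
#' indices, NIfTI convention), in mm.
#'
#' @param mask 3-D array; non-zero voxels are lesion (foreground).
#' @param affine 4x4 voxel-index-to-world matrix (mm).
#' @return An object of class `lesion_volume` with elements `mask`
#'   (logical array), `affine`, and `voxel_size` (mm per axis).
#' @export
lesion_volume <- function(mask, affine = diag(4)) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3-D array")
  mask <- array(mask != 0, dim = dim(mask))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < 1e-12) stop("affine must be invertible")
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(voxel_size <= 0)) stop("voxel sizes must be strictly positive")
  if (!any(mask)) stop("degenerate segmentation: lesion mask has no foreground voxels")
  structure(list(mask = mask, affine = affine, voxel_size = voxel_size),
            class = "lesion_volume")
}

#' @export
print.lesion_volume <- function(x, ...) {
  cat(sprintf("lesion_volume: %s grid, %d foreground voxels, %.2f cm^3\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask),
              lesion_volume_cm3(x)))
  invisible(x)
}

# world coordinates (mm) of all foreground voxel centres, n x 3
lesion_foreground_mm <- function(lesion) {
  idx <- which(lesion$mask, arr.ind = TRUE) - 1  # 0-based
  h <- cbind(idx, 1) %*% t(lesion$affine)
  h[, 1:3, drop = FALSE]
}

#' Centre of mass of a lesion
#'
#' Unweighted mean of the world coordinates of all foreground voxel
#' centres.
#'
#' @param lesion a [lesion_volume()].
#' @return Length-3 numeric vector (mm).
#' @export
center_of_mass <- function(lesion) {
  stopifnot(inherits(lesion, "lesion_volume"))
  colMeans(lesion_foreground_mm(lesion))
}

#' Lesion volume in cubic centimetres
#'
#' Foreground voxel count times the voxel volume.
#'
#' @param lesion a [lesion_volume()].
#' @return Volume in cm^3.
#' @export
lesion_volume_cm3 <- function(lesion) {
  stopifnot(inherits(lesion, "lesion_volume"))
  sum(lesion$mask) * prod(lesion$voxel_size) / 1000
}

#' Euclidean distance to the closest edge of the lesion
#'
#' The shortest possible straight-line distance from each query point to
#' any foreground voxel centre. A point that coincides with (or lies inside
#' the lesion at) a foreground voxel centre has distance 0; electrodes sit
#' on the cortex, so points inside the mask are rare in practice.
#'
#' @param points length-3 vector or `n x 3` matrix of world coordinates (mm).
#' @param lesion a [lesion_volume()].
#' @return Numeric vector of distances (mm).
#' @export
euclidean_edge_distance <- function(points, lesion) {
  stopifnot(inherits(lesion, "lesion_volume"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  if (any(!is.finite(points))) stop("query points must be finite")
  fg <- lesion_foreground_mm(lesion)
  # ||p - v||^2 = ||p||^2 - 2 p.v + ||v||^2, vectorised over all pairs
  fg2 <- rowSums(fg^2)
  out <- numeric(nrow(points))
  chunk <- max(1L, floor(2e7 / nrow(fg)))
  for (s in seq(1L, nrow(points), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(points))
    P <- points[s:e, , drop = FALSE]
    G <- outer(rowSums(P^2), fg2, "+") - 2 * P %*% t(fg)
    out[s:e] <- sqrt(pmax(0, apply(G, 1L, min)))
  }
  unname(out)
}

#' Euclidean distance to the lesion centre of mass
#'
#' @inheritParams euclidean_edge_distance
#' @return Numeric vector of distances (mm).
#' @export
euclidean_com_distance <- function(points, lesion) {
  stopifnot(inherits(lesion, "lesion_volume"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  points <- as.matrix(points)
  if (any(!is.finite(points))) stop("query points must be finite")
  com <- center_of_mass(lesion)
  unname(sqrt(rowSums(sweep(points, 2L, com)^2)))
}

#' Read a lesion mask from NIfTI
#'
#' Any integer/float dtype is accepted; non-zero voxels are foreground.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [lesion_volume()].
#' @export
read_lesion_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  lesion_volume(as.array(img), matrix(as.numeric(aff), 4L, 4L))
}

#' Write a lesion mask to NIfTI
#'
#' @param lesion a [lesion_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_lesion_nifti <- function(lesion, path) {
  img <- RNifti::asNifti(array(as.integer(lesion$mask), dim = dim(lesion$mask)))
  RNifti::sform(img) <- structure(lesion$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
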