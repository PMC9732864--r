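# Shared fixture builders. Everything is generated in code; no data files.

# random sparse binary mask with a random affine (axis scalings + offset)
random_lesion <- function(n_fg = 30L, dims = c(12L, 12L, 12L),
                          voxel = c(1, 1, 1), origin = c(0, 0, 0)) {
  mask <- array(FALSE, dims)
  idx <- sample.int(prod(dims), n_fg)
  mask[idx] <- TRUE
  aff <- diag(c(voxel, 1))
  aff[1:3, 4L] <- origin
  lesion_volume(mask, aff)
}

# brute-force world coordinates of foreground voxel centres (0-based index)
brute_fg_mm <- function(lesion) {
  idx <- which(lesion$mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(idx), 3L)
  for (i in seq_len(nrow(idx))) {
    h <- lesion$affine %*% c(idx[i, ] - 1L, 1)
    out[i, ] <- h[1:3]
  }
  out
}

# tiny two-triangle mesh in the z = 0 plane
tiny_mesh <- function() {
  cortical_surface(rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(0, 10, 0)),
                   rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
}

# point mass lesion at the world origin
origin_lesion <- function() {
  lesion_volume(array(1L, c(1L, 1L, 1L)), diag(4))
}

# random 3-D rotation matrix
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9L), 3L)))
  if (det(q) < 0) q[, 1L] <- -q[, 1L]
  q
}
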