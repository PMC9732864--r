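#' Triangulated cortical surface
#'
#' A `cortical_surface` is a triangulated mesh in world (mm) coordinates:
#' an `n x 3` matrix of vertices and an `m x 3` integer matrix of faces
#' (1-based vertex indices). It is the substrate for geodesic distances and
#' for placing/extrapolating electrode grids.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in mm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param check if `TRUE`, validate indices, edge lengths and connectivity.
#' @return An object of class `cortical_surface`.
#' @export
cortical_surface <- function(vertices, faces, check = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns (x, y, z in mm)")
  if (ncol(faces) != 3L) stop("faces must have 3 columns (triangles only)")
  if (check) {
    if (any(faces < 1L) || any(faces > nrow(vertices)))
      stop("face indices out of range")
    el <- edge_lengths(vertices, faces)
    if (any(!is.finite(el)) || any(el <= 0))
      stop("mesh has degenerate (zero-length) edges")
    if (surface_n_components(vertices, faces) != 1L)
      stop("mesh must be a single connected component")
  }
  structure(list(vertices = vertices, faces = faces),
            class = "cortical_surface")
}

#' @export
print.cortical_surface <- function(x, ...) {
  cat(sprintf("cortical_surface: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

# unique undirected edges of a triangulation, as a 2-column index matrix
surface_edges <- function(faces) {
  e <- rbind(faces[, c(1L, 2L)], faces[, c(2L, 3L)], faces[, c(1L, 3L)])
  e <- cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L]))
  e[!duplicated(e), , drop = FALSE]
}

edge_lengths <- function(vertices, faces) {
  e <- surface_edges(faces)
  sqrt(rowSums((vertices[e[, 1L], , drop = FALSE] -
                vertices[e[, 2L], , drop = FALSE])^2))
}

surface_n_components <- function(vertices, faces) {
  e <- surface_edges(faces)
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(vertices) - igraph::vcount(g)))
  igraph::components(g)$no
}

#' Nearest mesh vertex to a point
#'
#' Ties between equidistant vertices are broken by the lowest vertex index,
#' so results are deterministic.
#'
#' @param point numeric length-3 vector (mm).
#' @param surface a [cortical_surface()].
#' @return Integer vertex index.
#' @export
nearest_vertex <- function(point, surface) {
  d2 <- rowSums(sweep(surface$vertices, 2L, point)^2)
  which.min(d2)  # which.min returns the first (lowest-index) minimum
}

# Closest point on a single triangle (a, b, c) to p.
# Standard barycentric clamping (Ericson, Real-Time Collision Detection).
closest_point_on_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    v <- d1 / (d1 - d3); return(a + v * ab)
  }
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    w <- d2 / (d2 - d6); return(a + w * ac)
  }
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    w <- (d4 - d3) / ((d4 - d3) + (d5 - d6)); return(b + w * (c - b))
  }
  denom <- 1 / (va + vb + vc)
  v <- vb * denom; w <- vc * denom
  a + ab * v + ac * w
}

#' Project a point onto the surface
#'
#' Returns the closest point on any triangle of the mesh. Candidate faces
#' are pre-filtered by vertex proximity for speed; the projection is exact
#' on the polyhedral surface.
#'
#' @inheritParams nearest_vertex
#' @return List with `point` (length-3), `distance` (mm) and `face` index.
#' @export
project_to_surface <- function(point, surface) {
  V <- surface$vertices; FF <- surface$faces
  d2 <- rowSums(sweep(V, 2L, point)^2)
  dv <- sqrt(min(d2))
  # any face whose closest point beats the best vertex must have a vertex
  # within dv + longest-edge of the query; filter generously
  vmax <- sqrt(max(rowSums((V[FF[, 1L], , drop = FALSE] - V[FF[, 2L], , drop = FALSE])^2),
                   rowSums((V[FF[, 2L], , drop = FALSE] - V[FF[, 3L], , drop = FALSE])^2),
                   rowSums((V[FF[, 1L], , drop = FALSE] - V[FF[, 3L], , drop = FALSE])^2)))
  keep <- which(sqrt(d2) <= dv + vmax)
  cand <- which(FF[, 1L] %in% keep | FF[, 2L] %in% keep | FF[, 3L] %in% keep)
  best <- list(point = V[which.min(d2), ], distance = dv, face = NA_integer_)
  for (fi in cand) {
    q <- closest_point_on_triangle(point, V[FF[fi, 1L], ], V[FF[fi, 2L], ], V[FF[fi, 3L], ])
    dq <- sqrt(sum((q - point)^2))
    if (dq < best$distance - 1e-12) best <- list(point = q, distance = dq, face = fi)
  }
  best
}

#' Read a PLY surface file
#'
#' Supports ascii and binary_little_endian PLY with triangular faces.
#'
#' @param path file path.
#' @return A [cortical_surface()].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ascii lines terminated by \n
  hdr <- character()
  repeat {
    line <- readBinLine(con)
    hdr <- c(hdr, line)
    if (identical(line, "end_header")) break
    if (length(hdr) > 200L) stop("PLY header not terminated")
  }
  if (!identical(hdr[1L], "ply")) stop("not a PLY file: ", path)
  fmt <- strsplit(hdr[grepl("^format ", hdr)][1L], " +")[[1L]][2L]
  nv <- as.integer(strsplit(hdr[grepl("^element vertex ", hdr)][1L], " +")[[1L]][3L])
  nf <- as.integer(strsplit(hdr[grepl("^element face ", hdr)][1L], " +")[[1L]][3L])
  vprops <- grep("^property (float|double|float32|float64)", hdr, value = TRUE)
  if (length(vprops) < 3L) stop("PLY must carry x/y/z float vertex properties")
  if (identical(fmt, "ascii")) {
    txt <- readLines(con)
    vtx <- do.call(rbind, lapply(txt[seq_len(nv)], function(s)
      as.numeric(strsplit(trimws(s), " +")[[1L]][1:3])))
    fls <- lapply(txt[nv + seq_len(nf)], function(s)
      as.integer(strsplit(trimws(s), " +")[[1L]]))
    if (any(vapply(fls, `[`, 1L, i = 1L) != 3L)) stop("PLY faces must be triangles")
    fc <- do.call(rbind, lapply(fls, function(v) v[2:4])) + 1L
  } else if (identical(fmt, "binary_little_endian")) {
    double_vtx <- grepl("float64|double", vprops[1L])
    sz <- if (double_vtx) 8L else 4L
    vtx <- matrix(readBin(con, "numeric", n = nv * 3L, size = sz, endian = "little"),
                  ncol = 3L, byrow = TRUE)
    fc <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      k <- readBin(con, "integer", n = 1L, size = 1L, signed = FALSE)
      if (k != 3L) stop("PLY faces must be triangles")
      fc[i, ] <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
    }
    fc <- fc + 1L
  } else stop("unsupported PLY format: ", fmt)
  cortical_surface(vtx, fc)
}

readBinLine <- function(con) {
  out <- raw()
  repeat {
    ch <- readBin(con, "raw", n = 1L)
    if (length(ch) == 0L || ch == as.raw(10L)) break
    out <- c(out, ch)
  }
  rawToChar(out)
}

#' Write a PLY surface file (ascii)
#'
#' @param surface a [cortical_surface()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ply <- function(surface, path) {
  nv <- nrow(surface$vertices); nf <- nrow(surface$faces)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  vl <- sprintf("%.9g %.9g %.9g",
                surface$vertices[, 1L], surface$vertices[, 2L], surface$vertices[, 3L])
  fl <- sprintf("3 %d %d %d",
                surface$faces[, 1L] - 1L, surface$faces[, 2L] - 1L, surface$faces[, 3L] - 1L)
  writeLines(c(hdr, vl, fl), path)
  invisible(path)
}
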