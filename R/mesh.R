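#' Triangle mesh objects
#'
#' A `triangle_mesh` is a closed, oriented, triangulated surface embedded in
#' physical 3D space: a list with `vertices` (n x 3 numeric matrix) and
#' `faces` (m x 3 integer matrix of 1-based vertex indices, counter-clockwise
#' when seen from outside, so face normals point outward).
#'
#' @param vertices n x 3 numeric matrix of vertex positions.
#' @param faces m x 3 integer matrix of vertex indices (1-based).
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  structure(list(vertices = vertices, faces = faces),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces, chi = %d\n",
              nrow(x$vertices), nrow(x$faces), euler_characteristic(x)))
  invisible(x)
}

# unique undirected edges as a 2-column matrix
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Euler characteristic V - E + F of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return Integer Euler characteristic; 2 for a genus-zero closed surface.
#' @export
euler_characteristic <- function(mesh) {
  nrow(mesh$vertices) - nrow(mesh_edges(mesh)) + nrow(mesh$faces)
}

#' Check that a mesh is a closed 2-manifold
#'
#' Every undirected edge must be used by exactly two faces, once in each
#' direction (consistent orientation).
#'
#' @param mesh a `triangle_mesh`.
#' @return Logical scalar.
#' @export
is_closed_manifold <- function(mesh) {
  f <- mesh$faces
  if (nrow(f) == 0) return(FALSE)
  # directed edges; a closed consistently-oriented surface uses each
  # undirected edge exactly once in each direction
  de <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(de[, 1], de[, 2])
  rkey <- paste(de[, 2], de[, 1])
  if (anyDuplicated(key) > 0) return(FALSE)
  all(key %in% rkey)
}

#' Enclosed volume of a closed mesh
#'
#' Signed volume by the discrete divergence theorem: the sum of signed
#' tetrahedra spanned by the origin and each triangle. Positive for outward
#' orientation; translation-invariant for closed surfaces.
#'
#' @param mesh a closed `triangle_mesh`.
#' @param signed if `FALSE` (default) error when the signed volume is
#'   negative (inward orientation); if `TRUE` return the signed value.
#' @return Volume in cubic physical units.
#' @export
mesh_volume <- function(mesh, signed = FALSE) {
  if (!is_closed_manifold(mesh))
    stop("mesh_volume requires a closed manifold mesh")
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
             a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
             a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  if (!signed && vol < 0)
    stop("mesh has inward orientation (negative signed volume)")
  vol
}

#' Surface area of a mesh
#'
#' @param mesh a `triangle_mesh`.
#' @return Sum of triangle areas in squared physical units.
#' @export
mesh_surface_area <- function(mesh) {
  sum(triangle_areas(mesh))
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- u[, 2] * w[, 3] - u[, 3] * w[, 2]
  cy <- u[, 3] * w[, 1] - u[, 1] * w[, 3]
  cz <- u[, 1] * w[, 2] - u[, 2] * w[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

# per-face unit normals (outward for outward-wound meshes)
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
             u[, 3] * w[, 1] - u[, 1] * w[, 3],
             u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(n^2))
  n / pmax(len, .Machine$double.eps)
}

# area-weighted per-vertex unit normals
vertex_normals <- function(mesh) {
  fn <- face_normals(mesh)
  ar <- triangle_areas(mesh)
  n <- matrix(0, nrow(mesh$vertices), 3)
  for (c_ in 1:3) {
    for (d in 1:3) {
      n[, d] <- n[, d] + unname(tapply_add(mesh$faces[, c_], fn[, d] * ar,
                                           nrow(mesh$vertices)))
    }
  }
  len <- sqrt(rowSums(n^2))
  n / pmax(len, .Machine$double.eps)
}

# fast grouped sum into a length-n vector
tapply_add <- function(index, values, n) {
  out <- numeric(n)
  agg <- rowsum(values, index)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

mean_edge_length <- function(mesh) {
  e <- mesh_edges(mesh)
  d <- mesh$vertices[e[, 1], , drop = FALSE] - mesh$vertices[e[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' Subdivide every triangle into four
#'
#' Midpoint (Loop-connectivity, no smoothing) 1-to-4 subdivision. Used for
#' refinement-invariance checks: area and enclosed volume are unchanged.
#'
#' @param mesh a `triangle_mesh`.
#' @return The refined `triangle_mesh`.
#' @export
subdivide_mesh <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  e <- mesh_edges(mesh)
  ekey <- paste(e[, 1], e[, 2])
  mid <- (v[e[, 1], , drop = FALSE] + v[e[, 2], , drop = FALSE]) / 2
  midid <- nrow(v) + seq_len(nrow(e))
  names(midid) <- ekey
  key12 <- paste(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2]))
  key23 <- paste(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3]))
  key31 <- paste(pmin(f[, 3], f[, 1]), pmax(f[, 3], f[, 1]))
  m12 <- midid[key12]; m23 <- midid[key23]; m31 <- midid[key31]
  newf <- rbind(cbind(f[, 1], m12, m31),
                cbind(f[, 2], m23, m12),
                cbind(f[, 3], m31, m23),
                cbind(m12, m23, m31))
  triangle_mesh(rbind(v, mid), newf)
}

#' Generate a sphere mesh by octahedron subdivision
#'
#' Starts from a regular octahedron and repeatedly subdivides, re-projecting
#' vertices onto the sphere. Useful as an analytic reference surface.
#'
#' @param radius sphere radius (physical units).
#' @param subdivisions number of 1-to-4 refinement rounds (4 gives 1026
#'   vertices).
#' @param center length-3 numeric center.
#' @return A `triangle_mesh` approximating the sphere.
#' @export
sphere_mesh <- function(radius = 1, subdivisions = 4, center = c(0, 0, 0)) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
             c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  mesh <- triangle_mesh(v, f)
  for (i in seq_len(subdivisions)) {
    mesh <- subdivide_mesh(mesh)
    len <- sqrt(rowSums(mesh$vertices^2))
    mesh$vertices <- mesh$vertices / len
  }
  mesh$vertices <- sweep(mesh$vertices * radius, 2, center, `+`)
  mesh
}

#' Generate an ellipsoid mesh
#'
#' Anisotropic scaling of [sphere_mesh()] by the semi-axes.
#'
#' @param semi_axes length-3 positive semi-axes (a, b, c).
#' @param subdivisions refinement rounds, as in [sphere_mesh()].
#' @param center length-3 numeric center.
#' @return A `triangle_mesh`.
#' @export
ellipsoid_mesh <- function(semi_axes, subdivisions = 4, center = c(0, 0, 0)) {
  mesh <- sphere_mesh(1, subdivisions)
  mesh$vertices <- sweep(sweep(mesh$vertices, 2, semi_axes, `*`), 2, center, `+`)
  mesh
}

#' Taubin lambda/mu mesh smoothing
#'
#' Alternating shrink/inflate passes of uniform Laplacian smoothing
#' (lambda > 0, mu < -lambda), which damps voxel-discretization
#' (staircase) noise with negligible volume shrinkage. Used to condition
#' marching meshes before spectral processing and curvature estimation.
#'
#' @param mesh a `triangle_mesh`.
#' @param iterations number of lambda/mu pass pairs.
#' @param lambda,mu Taubin coefficients.
#' @return The smoothed `triangle_mesh` (connectivity unchanged).
#' @export
taubin_smooth <- function(mesh, iterations = 10, lambda = 0.5, mu = -0.53) {
  if (iterations < 1) return(mesh)
  e <- mesh_edges(mesh)
  n <- nrow(mesh$vertices)
  A <- Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                            x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  v <- mesh$vertices
  for (i in seq_len(iterations)) {
    v <- v + lambda * (as.matrix(A %*% v) / deg - v)
    v <- v + mu * (as.matrix(A %*% v) / deg - v)
  }
  mesh$vertices <- v
  mesh
}

#' Write a mesh to an ASCII PLY or OFF file
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file; format chosen by extension (`.ply` or `.off`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  vtx <- apply(mesh$vertices, 1, paste, collapse = " ")
  fac <- apply(mesh$faces - 1L, 1, function(r) paste(c(3, r), collapse = " "))
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nv),
             "property float x", "property float y", "property float z",
             sprintf("element face %d", nf),
             "property list uchar int vertex_indices", "end_header")
    writeLines(c(hdr, vtx, fac), path)
  } else if (grepl("\\.off$", path, ignore.case = TRUE)) {
    writeLines(c("OFF", sprintf("%d %d 0", nv, nf), vtx, fac), path)
  } else {
    stop("unsupported mesh format (use .ply or .off): ", path)
  }
  invisible(path)
}

#' Read an ASCII OFF mesh
#'
#' @param path an OFF file as written by [write_mesh()].
#' @return A `triangle_mesh`.
#' @export
read_mesh_off <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file: ", path)
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  v <- matrix(scan(text = paste(lines[3:(2 + nv)], collapse = "\n"),
                   quiet = TRUE), ncol = 3, byrow = TRUE)
  fraw <- matrix(scan(text = paste(lines[(3 + nv):(2 + nv + nf)], collapse = "\n"),
                      quiet = TRUE), ncol = 4, byrow = TRUE)
  triangle_mesh(v, fraw[, 2:4, drop = FALSE] + 1L)
}
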