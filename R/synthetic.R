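#' Specify a synthetic voxel phantom
#'
#' Phantoms are solid shapes with known analytic geometry, voxelized by
#' testing the shape's implicit inequality at voxel centers (matching the
#' binary-mask semantics of segmented microscopy data). Supported kinds:
#' \describe{
#'   \item{sphere}{`radius`}
#'   \item{ellipsoid}{`semi_axes` (a, b, c)}
#'   \item{cube}{`edge` (axis-aligned)}
#'   \item{octahedron}{`circumradius` c; L1 ball |x|+|y|+|z| <= c}
#'   \item{overlapping_spheres}{`radius` and `offset`: 3 spheres with
#'     linearly aligned centers spaced `offset` apart}
#' }
#'
#' @param shape_kind one of the five shape kinds.
#' @param grid_shape voxel dimensions of the carrier grid, length 3.
#' @param center shape center in voxel units; default grid center.
#' @param rotation optional 3x3 rotation matrix applied to the shape.
#' @param ... size parameters for the chosen kind (see Details).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape_kind = c("sphere", "ellipsoid", "cube",
                                        "octahedron", "overlapping_spheres"),
                         grid_shape = c(64, 64, 64), center = grid_shape / 2,
                         rotation = diag(3), ...) {
  shape_kind <- match.arg(shape_kind)
  pars <- list(...)
  need <- switch(shape_kind,
                 sphere = "radius", ellipsoid = "semi_axes", cube = "edge",
                 octahedron = "circumradius",
                 overlapping_spheres = c("radius", "offset"))
  miss <- setdiff(need, names(pars))
  if (length(miss) > 0)
    stop(shape_kind, " phantom needs parameter(s): ", paste(miss, collapse = ", "))
  if (any(unlist(pars[need]) <= 0)) stop("size parameters must be positive")
  if (shape_kind == "overlapping_spheres" && pars$offset >= 2 * pars$radius)
    stop("spheres must overlap: offset < 2 * radius")
  spec <- structure(list(shape_kind = shape_kind, grid_shape = grid_shape,
                         center = center, rotation = rotation, params = pars,
                         analytic_volume = NA_real_,
                         analytic_surface_area = NA_real_),
                    class = "phantom_spec")
  # half-extent along each local axis, for the fits-in-grid invariant
  ext <- phantom_extent(spec)
  if (any(center - ext < 2) || any(center + ext > grid_shape - 2))
    stop("shape must fit in the grid with a >= 2 voxel margin")
  spec
}

phantom_extent <- function(spec) {
  p <- spec$params
  r <- switch(spec$shape_kind,
              sphere = rep(p$radius, 3),
              ellipsoid = p$semi_axes,
              cube = rep(p$edge / 2 * sqrt(3), 3),     # allow any rotation
              octahedron = rep(p$circumradius, 3),
              overlapping_spheres = c(p$radius + p$offset, p$radius, p$radius))
  if (isTRUE(all.equal(spec$rotation, diag(3)))) r
  else rep(max(r), 3)  # conservative under rotation
}

phantom_inside <- function(spec, x, y, z) {
  # x, y, z: physical (voxel-unit) coordinates; returns logical membership
  u <- cbind(x - spec$center[1], y - spec$center[2], z - spec$center[3])
  u <- u %*% spec$rotation               # into the shape's local frame
  p <- spec$params
  switch(spec$shape_kind,
         sphere = rowSums(u^2) <= p$radius^2,
         ellipsoid = rowSums(sweep(u, 2, p$semi_axes, `/`)^2) <= 1,
         cube = apply(abs(u), 1, max) <= p$edge / 2,
         octahedron = rowSums(abs(u)) <= p$circumradius,
         overlapping_spheres = {
           d2 <- pmin((u[, 1] - p$offset)^2, u[, 1]^2, (u[, 1] + p$offset)^2)
           d2 + u[, 2]^2 + u[, 3]^2 <= p$radius^2
         })
}

#' Analytic surface area of a triaxial ellipsoid
#'
#' Gauss-Legendre quadrature of the parametric surface integral
#' \eqn{\int\int |r_\theta \times r_\phi| d\theta d\phi}; no elementary
#' closed form exists for three distinct semi-axes.
#'
#' @param semi_axes positive length-3 semi-axes.
#' @param n quadrature nodes per direction.
#' @return Surface area.
#' @export
ellipsoid_surface_area <- function(semi_axes, n = 200) {
  a <- semi_axes[1]; b <- semi_axes[2]; c <- semi_axes[3]
  gth <- pracma::gaussLegendre(n, 0, pi)
  gph <- pracma::gaussLegendre(n, 0, 2 * pi)
  th <- gth$x; ph <- gph$x
  st <- sin(th); ct <- cos(th)
  integrand <- outer(seq_along(th), seq_along(ph), function(i, j) {
    # |r_theta x r_phi| at (th[i], ph[j])
    sti <- st[i]; cti <- ct[i]; cpj <- cos(ph[j]); spj <- sin(ph[j])
    nx <- b * c * sti^2 * cpj
    ny <- a * c * sti^2 * spj
    nz <- a * b * sti * cti
    sqrt(nx^2 + ny^2 + nz^2)
  })
  as.numeric(gth$w %*% integrand %*% gph$w)
}

phantom_analytic <- function(spec) {
  p <- spec$params
  switch(spec$shape_kind,
         sphere = list(volume = 4 / 3 * pi * p$radius^3,
                       area = 4 * pi * p$radius^2),
         ellipsoid = list(volume = 4 / 3 * pi * prod(p$semi_axes),
                          area = ellipsoid_surface_area(p$semi_axes)),
         cube = list(volume = p$edge^3, area = 6 * p$edge^2),
         octahedron = list(volume = 4 / 3 * p$circumradius^3,
                           area = 4 * sqrt(3) * p$circumradius^2),
         overlapping_spheres = {
           r <- p$radius; d <- p$offset
           # inclusion-exclusion over the two adjacent lenses; the outer
           # spheres are 2*offset apart and must not intersect
           if (2 * d < 2 * r)
             stop("outer spheres intersect; offset must be >= radius")
           lens <- pi / 12 * (4 * r + d) * (2 * r - d)^2
           caph <- r - d / 2
           list(volume = 3 * (4 / 3 * pi * r^3) - 2 * lens,
                area = 3 * 4 * pi * r^2 - 4 * (2 * pi * r * caph))
         })
}

#' Voxelize a phantom
#'
#' Rasterizes the shape onto its grid by voxel-center membership and fills
#' in the closed-form volume and surface area references.
#'
#' @param spec a `phantom_spec`.
#' @param image_id,channel,condition metadata for the resulting volume.
#' @return A list with `volume` (binary [labeled_volume()]) and `spec` (the
#'   input with `analytic_volume` / `analytic_surface_area` filled).
#' @export
make_phantom <- function(spec, image_id = "phantom", channel = "nuclear",
                         condition = NA_character_) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid_shape
  cy <- seq_len(g[1]) - 0.5
  cx <- seq_len(g[2]) - 0.5
  cz <- seq_len(g[3]) - 0.5
  grid <- expand.grid(y = cy, x = cx, z = cz, KEEP.OUT.ATTRS = FALSE)
  inside <- phantom_inside(spec, grid$y, grid$x, grid$z)
  vox <- array(as.integer(inside), dim = g)
  an <- phantom_analytic(spec)
  spec$analytic_volume <- an$volume
  spec$analytic_surface_area <- an$area
  list(volume = labeled_volume(vox, c(1, 1, 1), image_id, channel, condition),
       spec = spec)
}

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed; uniform over SO(3)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a labeled two-class phantom population
#'
#' Emulates the structure of a two-condition 3D nuclear-mask dataset:
#' several "images" per condition, several nuclei per image, and 1 to
#' `max_nucleoli` small spherical nucleoli inside each nucleus. Nuclear
#' shape follows the per-class ellipsoid template with multiplicative
#' per-axis jitter drawn from U(1 - jitter, 1 + jitter); all randomness
#' comes from one generator seeded with `seed`, so output is deterministic.
#'
#' @param n_images_per_class images ("acquisition groups") per condition.
#' @param nuclei_per_image nuclei in each image.
#' @param class_a,class_b templates: lists with `condition` (label) and
#'   `semi_axes` (length 3). Defaults: spheres (10, 10, 10) vs volume-matched
#'   prolate ellipsoids (13, 10, 100/13).
#' @param jitter magnitude of the uniform per-axis scale jitter.
#' @param nucleoli_range integer range (min, max) of nucleoli per nucleus.
#' @param nucleolus_radius mean nucleolar radius in voxels.
#' @param cell_box voxel edge of the cubic region allotted to one nucleus.
#' @param seed integer seed.
#' @return A list of images; each image is a list with `image_id`,
#'   `condition`, `nuclear` and `nucleolar` (binary [labeled_volume()]s on a
#'   common grid).
#' @export
make_population <- function(n_images_per_class = 3, nuclei_per_image = 6,
                            class_a = list(condition = "A",
                                           semi_axes = c(10, 10, 10)),
                            class_b = list(condition = "B",
                                           semi_axes = c(13, 10, 100 / 13)),
                            jitter = 0.06,
                            nucleoli_range = c(1, 4),
                            nucleolus_radius = 3,
                            cell_box = 36, seed = 1) {
  stopifnot(jitter > 0)
  if (nucleolus_radius >= min(unlist(c(class_a$semi_axes, class_b$semi_axes))))
    stop("nucleolus radius must be smaller than the nucleus minor semi-axis")
  with_seed(seed, {
    images <- list()
    for (cls in list(class_a, class_b)) {
      for (im in seq_len(n_images_per_class)) {
        image_id <- sprintf("%s_img%02d", cls$condition, im)
        # lay nuclei on a lattice of cell_box-sized cells
        ncell <- ceiling(nuclei_per_image^(1 / 3))
        # grid: lattice of cells, one nucleus per cell
        nx <- ncell; ny <- ceiling(nuclei_per_image / ncell^2)
        nz <- ceiling(nuclei_per_image / (nx * ny))
        g <- c(ny, nx, nz) * cell_box
        nuc <- array(0L, g)
        ncl <- array(0L, g)
        placed <- 0
        for (ci in seq_len(ny)) for (cj in seq_len(nx)) for (ck in seq_len(nz)) {
          if (placed >= nuclei_per_image) break
          placed <- placed + 1
          base <- c(ci - 1, cj - 1, ck - 1) * cell_box
          centre <- base + cell_box / 2 + stats::runif(3, -1.5, 1.5)
          axes <- cls$semi_axes * stats::runif(3, 1 - jitter, 1 + jitter)
          rot <- random_rotation()
          sub <- voxelize_ellipsoid(g, centre, axes, rot)
          nuc[sub] <- 1L
          # nucleoli: small non-overlapping spheres well inside the nucleus
          n_nucl <- sample(seq(nucleoli_range[1], nucleoli_range[2]), 1)
          placed_nucl <- matrix(numeric(0), 0, 4)   # centre + radius
          for (q in seq_len(n_nucl)) {
            for (try_ in 1:25) {
              rr <- nucleolus_radius * stats::runif(1, 0.85, 1.15)
              # position inside the nucleus: local frame, within 45% of axes
              off <- stats::runif(3, -0.45, 0.45) * axes
              cn <- centre + as.numeric(rot %*% off)
              clear <- nrow(placed_nucl) == 0 ||
                all(sqrt(colSums((t(placed_nucl[, 1:3, drop = FALSE]) - cn)^2)) >
                      placed_nucl[, 4] + rr + 1.5)
              if (clear) {
                placed_nucl <- rbind(placed_nucl, c(cn, rr))
                ncl[voxelize_ellipsoid(g, cn, rep(rr, 3), diag(3))] <- 1L
                break
              }
            }
          }
        }
        images[[image_id]] <- list(
          image_id = image_id, condition = cls$condition,
          nuclear = labeled_volume(nuc, c(1, 1, 1), image_id, "nuclear",
                                   cls$condition),
          nucleolar = labeled_volume(ncl, c(1, 1, 1), image_id, "nucleolar",
                                     cls$condition))
      }
    }
    images
  })
}

# linear indices of voxels inside a rotated ellipsoid, restricted to its
# bounding box for speed
voxelize_ellipsoid <- function(grid_shape, centre, axes, rot) {
  rmax <- max(axes)
  lo <- pmax(1, floor(centre - rmax))
  hi <- pmin(grid_shape, ceiling(centre + rmax + 1))
  ys <- lo[1]:hi[1]; xs <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  grid <- expand.grid(y = ys - 0.5, x = xs - 0.5, z = zs - 0.5,
                      KEEP.OUT.ATTRS = FALSE)
  u <- cbind(grid$y - centre[1], grid$x - centre[2], grid$z - centre[3]) %*% rot
  inside <- rowSums(sweep(u, 2, axes, `/`)^2) <= 1
  idx <- expand.grid(y = ys, x = xs, z = zs, KEEP.OUT.ATTRS = FALSE)[inside, ]
  (idx$y) + (idx$x - 1L) * grid_shape[1] +
    (idx$z - 1L) * grid_shape[1] * grid_shape[2]
}

#' Write a population to TIFF files plus a manifest
#'
#' @param population result of [make_population()].
#' @param dir output directory (created if needed).
#' @return The manifest data.frame (also written to `dir/manifest.csv`).
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (img in population) {
    for (ch in c("nuclear", "nucleolar")) {
      fn <- sprintf("%s_%s.tif", img$image_id, ch)
      write_mask_volume(img[[ch]], file.path(dir, fn))
      rows[[length(rows) + 1]] <- data.frame(
        path = fn, image_id = img$image_id, channel = ch,
        condition = img$condition,
        spacing_y = 1, spacing_x = 1, spacing_z = 1)
    }
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}
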