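test_that("a solid block extracts to a closed genus-zero mesh at the right scale", {
  vox <- array(0L, c(14, 14, 14))
  vox[3:12, 3:12, 3:12] <- 1L
  mesh <- extract_boundary_mesh(labeled_volume(vox))
  expect_true(is_closed_manifold(mesh))
  expect_equal(euler_characteristic(mesh), 2)
  expect_equal(mesh_volume(mesh), 1000, tolerance = 0.1)
})

test_that("sphere boundary meshes land near the analytic surface", {
  ph <- make_phantom(phantom_spec("sphere", c(64, 64, 64), radius = 20))
  mesh <- extract_boundary_mesh(split_objects(ph$volume, min_voxels = 1)[[1]])
  expect_equal(mesh_surface_area(mesh), 4 * pi * 400, tolerance = 0.1)
  expect_equal(mesh_volume(mesh), 4 / 3 * pi * 8000, tolerance = 0.03)
})

test_that("internal cavities are filled before meshing", {
  vox <- array(0L, c(13, 13, 13))
  vox[3:11, 3:11, 3:11] <- 1L
  vox[7, 7, 7] <- 0L   # enclosed one-voxel cavity
  mesh <- extract_boundary_mesh(labeled_volume(vox))
  pv <- attr(mesh, "prepared_voxels")
  expect_equal(pv[7, 7, 7], 1L)
  expect_equal(euler_characteristic(mesh), 2)
  expect_equal(mesh_volume(mesh), 729, tolerance = 0.1)
})

test_that("tiny masks and disabled padding raise errors", {
  vox <- array(0L, c(6, 6, 6))
  vox[3, 3, 3] <- 1L
  expect_error(extract_boundary_mesh(labeled_volume(vox)), "too small")
  ph <- make_phantom(phantom_spec("sphere", c(24, 24, 24), radius = 8))
  obj <- split_objects(ph$volume, min_voxels = 1)[[1]]
  expect_error(extract_boundary_mesh(obj, pad = FALSE), "pad")
})

test_that("the full eigenbasis reproduces the surface and projection is idempotent", {
  ph <- make_phantom(phantom_spec("sphere", c(20, 20, 20), radius = 5))
  mesh <- extract_boundary_mesh(split_objects(ph$volume, min_voxels = 1)[[1]],
                                taubin_iterations = 0)
  n <- nrow(mesh$vertices)
  full <- lb_eigenprojection(mesh, k = n)
  expect_equal(full$vertices, mesh$vertices, tolerance = 1e-6)
  basis <- lb_eigenbasis(mesh, 30)
  once <- lb_eigenprojection(mesh, basis = basis)
  twice <- lb_eigenprojection(once, basis = basis)
  expect_equal(twice$vertices, once$vertices, tolerance = 1e-8)
  expect_identical(once$faces, mesh$faces)
})

test_that("eigenvalues ascend and the projection residual shrinks with k", {
  ph <- make_phantom(phantom_spec("sphere", c(24, 24, 24), radius = 7))
  mesh <- extract_boundary_mesh(split_objects(ph$volume, min_voxels = 1)[[1]],
                                taubin_iterations = 0)
  basis <- lb_eigenbasis(mesh, 60)
  expect_true(all(diff(basis$values) > -1e-9))
  expect_lt(basis$values[1], 1e-6)  # constant mode
  res <- vapply(c(8, 16, 32, 60), function(k) {
    pr <- lb_eigenprojection(mesh, k)
    sum(basis$mass * rowSums((mesh$vertices - pr$vertices)^2))
  }, numeric(1))
  expect_true(all(diff(res) < 0))
})

test_that("spectral projection denoises a rippled sphere", {
  set.seed(11)
  s <- sphere_mesh(1, subdivisions = 4)
  noisy <- s
  noisy$vertices <- s$vertices * (1 + stats::rnorm(nrow(s$vertices), sd = 0.05))
  proj <- lb_eigenprojection(noisy, 16)
  dev_before <- stats::sd(sqrt(rowSums(noisy$vertices^2)))
  dev_after <- stats::sd(sqrt(rowSums(proj$vertices^2)))
  expect_lt(dev_after, dev_before / 3)
  expect_true(is_closed_manifold(proj))
  expect_equal(euler_characteristic(proj), 2)
})

test_that("a k=4 projection is a smooth blob but still a closed surface", {
  ph <- make_phantom(phantom_spec("cube", c(24, 24, 24), edge = 10))
  mesh <- extract_boundary_mesh(split_objects(ph$volume, min_voxels = 1)[[1]])
  blob <- lb_eigenprojection(mesh, 4)
  expect_true(is_closed_manifold(blob))
  expect_equal(euler_characteristic(blob), 2)
})

test_that("metric distortion is zero at identity and constant under translation", {
  s <- sphere_mesh(5, subdivisions = 3)
  expect_equal(metric_distortion(s, s), rep(0, nrow(s$vertices)))
  moved <- s
  moved$vertices <- sweep(s$vertices, 2, c(1, 2, 3), `+`)
  d <- metric_distortion(s, moved)
  expect_equal(stats::sd(d), 0, tolerance = 1e-9)
  expect_equal(d[1], sqrt(14) / nucmorph3d:::mean_edge_length(s))
  other <- subdivide_mesh(s)
  expect_error(metric_distortion(s, other), "connectivity")
})

test_that("distortion peaks at a spike vertex", {
  s <- sphere_mesh(5, subdivisions = 3)
  h <- nucmorph3d:::mean_edge_length(s)
  spiky <- s
  iv <- 17
  dir <- s$vertices[iv, ] / sqrt(sum(s$vertices[iv, ]^2))
  spiky$vertices[iv, ] <- s$vertices[iv, ] + 5 * h * dir
  d <- metric_distortion(spiky, lb_eigenprojection(spiky, 16))
  # maximum attained at or adjacent to the spike vertex
  e <- nucmorph3d:::mesh_edges(s)
  ring <- c(iv, e[e[, 1] == iv, 2], e[e[, 2] == iv, 1])
  expect_true(which.max(d) %in% ring)
})

test_that("mask deformation is a no-op below threshold and removes spikes", {
  sp <- spiked_sphere_volume(radius = 12, grid = 48, spike = 5)
  obj <- split_objects(sp$volume, min_voxels = 1)[[1]]
  mesh <- extract_boundary_mesh(obj)
  mask <- obj
  mask$voxels <- attr(mesh, "prepared_voxels")
  proj <- lb_eigenprojection(mesh, 100)
  dist <- metric_distortion(mesh, proj)
  vv <- nucmorph3d:::nearest_voxels(mask, mesh)
  # huge threshold: nothing happens
  none <- deform_mask(mask, vv, dist, threshold = 1e6)
  expect_identical(none$mask$voxels, mask$voxels)
  expect_equal(none$n_flipped, 0L)
  # artifact-scale threshold: spike voxels go, the body stays intact
  res <- deform_mask(mask, vv, dist, threshold = 1.2)
  expect_gt(res$n_flipped, 0)
  removed <- which(mask$voxels > 0 & res$mask$voxels == 0, arr.ind = TRUE)
  c0 <- sp$center_idx - mask$offset
  expect_true(all(abs(removed[, 1] - c0[1]) <= 2 &
                  abs(removed[, 2] - c0[2]) <= 2))
  expect_true(all(removed[, 3] > c0[3]))  # only near the spike column
})

test_that("flips that would change topology are suppressed", {
  # dumbbell: two blocks joined by a single-voxel bridge
  vox <- array(0L, c(20, 9, 9))
  vox[3:8, 3:7, 3:7] <- 1L
  vox[12:17, 3:7, 3:7] <- 1L
  vox[9:11, 5, 5] <- 1L
  expect_false(nucmorph3d:::.is_simple_point(vox, 10L, 5L, 5L))
  # interior voxels are not simple either; a surface voxel is
  expect_false(nucmorph3d:::.is_simple_point(vox, 5L, 5L, 5L))
  expect_true(nucmorph3d:::.is_simple_point(vox, 3L, 3L, 3L))
})

test_that("reconstruction recovers the sphere volume and reports its loop", {
  ph <- make_phantom(phantom_spec("sphere", c(48, 48, 48), radius = 12))
  rec <- reconstruct_surface(ph$volume, fast_params())
  expect_true(is_closed_manifold(rec))
  expect_equal(euler_characteristic(rec), 2)
  expect_equal(mesh_volume(rec), ph$spec$analytic_volume, tolerance = 0.02)
  it <- attr(rec, "iterations")
  expect_lte(it$n_iterations, 10)
  expect_equal(length(it$flips_per_iteration), it$n_iterations)
  # anti-shrinkage contract: mesh volume close to final mask voxel volume
  expect_equal(mesh_volume(rec), it$final_mask_voxels, tolerance = 0.05)
})

test_that("reconstruction absorbs a spike without touching the body", {
  sp <- spiked_sphere_volume(radius = 12, grid = 48, spike = 5, width = 2)
  rec <- reconstruct_surface(sp$volume, recon_params())
  expect_true(is_closed_manifold(rec))
  expect_equal(mesh_volume(rec), sp$spec$analytic_volume, tolerance = 0.02)
  it <- attr(rec, "iterations")
  expect_gt(sum(it$flips_per_iteration), 0)
})
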