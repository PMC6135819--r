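test_that("shape index matches its closed form and limit conventions", {
  expect_equal(shape_index(0, 1), 0.5)
  expect_equal(shape_index(-1, 1), 0)
  expect_equal(shape_index(1, 1), 1)
  expect_equal(shape_index(-1, -1), -1)
  expect_equal(shape_index(0, 0), 0)
  expect_error(shape_index(1, 0), "k1 <= k2")
})

test_that("curvedness and mean curvature follow their closed forms", {
  expect_equal(curvedness(1, 1), 1)
  expect_equal(curvedness(0, 0), 0)
  expect_equal(curvedness(0, 1), 1 / sqrt(2))
  expect_equal(mean_curvature(1, 1), 1)
  expect_equal(mean_curvature(-1, 1), 0)
})

test_that("descriptor identities hold on random curvature pairs", {
  set.seed(3)
  a <- stats::rnorm(300); b <- stats::rnorm(300)
  k1 <- pmin(a, b); k2 <- pmax(a, b)
  expect_equal(mean_curvature(k1, k2), (k1 + k2) / 2)
  expect_equal(curvedness(k1, k2), sqrt((k1^2 + k2^2) / 2))
  si <- shape_index(k1, k2)
  expect_true(all(si >= -1 & si <= 1))
  expect_true(all(curvedness(k1, k2) >= 0))
  # swapping the roles flips the shape index sign
  expect_equal(shape_index(-k2, -k1), -si, tolerance = 1e-12)
})

test_that("principal curvatures recover the analytic sphere", {
  s <- sphere_mesh(2, subdivisions = 4)
  pc <- principal_curvatures(s)
  expect_true(all(pc$k1 <= pc$k2 + 1e-12))
  w <- pc$vertex_area / sum(pc$vertex_area)
  expect_equal(sum(w * pc$mean_curvature), 0.5, tolerance = 0.05)
  expect_equal(sum(w * pc$curvedness), 0.5, tolerance = 0.05)
  expect_gt(sum(w * pc$shape_index), 0.95)
})

test_that("sphere vs elongated ellipsoid orders MC, CV and SI as expected", {
  s <- sphere_mesh(20, subdivisions = 4)
  e <- ellipsoid_mesh(c(35, 15, 15), subdivisions = 4)
  sig_s <- compute_signature(s)
  sig_e <- compute_signature(e)
  expect_lt(sig_s$MeanCurvature, sig_e$MeanCurvature)
  expect_lt(sig_s$Curvedness, sig_e$Curvedness)
  expect_gt(sig_s$ShapeIndex, sig_e$ShapeIndex)
})

test_that("signatures of the unit sphere match analytic values", {
  s <- sphere_mesh(1, subdivisions = 4)
  sig <- compute_signature(s)
  expect_equal(sig$Volume, 4 / 3 * pi, tolerance = 0.01)
  expect_equal(sig$SurfaceArea, 4 * pi, tolerance = 0.01)
  expect_equal(sig$MeanCurvature, 1, tolerance = 0.05)
  expect_gt(sig$ShapeIndex, 0.95)
  expect_equal(sig$Curvedness, 1, tolerance = 0.05)
  expect_equal(sig$FractalDimension, 2, tolerance = 0.15)
})

test_that("signatures are invariant under rigid motion", {
  e <- ellipsoid_mesh(c(3, 2, 1.4), subdivisions = 4)
  th <- 0.7; ph <- 0.3
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3) %*%
       matrix(c(1, 0, 0, 0, cos(ph), -sin(ph), 0, sin(ph), cos(ph)), 3)
  rot <- e
  rot$vertices <- sweep(e$vertices %*% t(R), 2, c(5, -2, 1), `+`)
  a <- compute_signature(e)
  b <- compute_signature(rot)
  for (m in c("Volume", "SurfaceArea", "MeanCurvature", "ShapeIndex",
              "Curvedness", "FractalDimension"))
    expect_equal(b[[m]], a[[m]], tolerance = 0.01)
})

test_that("signatures are stable under mesh subdivision", {
  s <- sphere_mesh(2, subdivisions = 3)
  f <- subdivide_mesh(s)
  a <- compute_signature(s)
  b <- compute_signature(f)
  expect_equal(b$SurfaceArea, a$SurfaceArea, tolerance = 0.02)
  expect_equal(b$Volume, a$Volume, tolerance = 0.02)
  expect_equal(b$MeanCurvature, a$MeanCurvature, tolerance = 0.02)
})

test_that("the isoperimetric inequality holds for closed signatures", {
  meshes <- list(sphere_mesh(2, 4), ellipsoid_mesh(c(3, 2, 1), 4),
                 unit_cube_mesh())
  for (m in meshes) {
    v <- mesh_volume(m); sa <- mesh_surface_area(m)
    expect_gte(sa^3 / (36 * pi * v^2), 1 - 0.01)
  }
  s <- sphere_mesh(2, 4)
  expect_equal(mesh_surface_area(s)^3 / (36 * pi * mesh_volume(s)^2), 1,
               tolerance = 0.02)
})

test_that("box counting gives dimension 2 for flat and smooth surfaces", {
  # flat open square patch, triangulated on a 21x21 grid
  g <- expand.grid(x = 0:20, y = 0:20)
  v <- cbind(g$x, g$y, 0)
  id <- function(i, j) i + 21 * (j - 1)
  f <- do.call(rbind, lapply(1:20, function(j) {
    do.call(rbind, lapply(1:20, function(i) {
      rbind(c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
            c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
    }))
  }))
  patch <- triangle_mesh(v, f)
  fd_flat <- fractal_dimension(patch)
  expect_equal(as.numeric(fd_flat), 2, tolerance = 0.1)
  fd_sphere <- fractal_dimension(sphere_mesh(1, 4))
  expect_equal(as.numeric(fd_sphere), 2, tolerance = 0.15)
  expect_gt(attr(fd_sphere, "r_squared"), 0.98)
})

test_that("surface roughness raises the box-counting dimension", {
  set.seed(8)
  s <- sphere_mesh(1, subdivisions = 4)
  noisy <- s
  noisy$vertices <- s$vertices * (1 + stats::rnorm(nrow(s$vertices), sd = 0.03))
  expect_gt(as.numeric(fractal_dimension(noisy)),
            as.numeric(fractal_dimension(s)))
})

test_that("fractal dimension validates its scale ladder", {
  s <- sphere_mesh(1, 3)
  expect_error(fractal_dimension(s, scales = c(0.5, 0.25)), "4 dyadic")
  expect_error(fractal_dimension(s, scales = c(0.4, 0.3, 0.2, 0.1)),
               "8-fold")
})
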