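test_that("mask volumes round-trip through multi-page TIFF", {
  set.seed(1)
  vox <- array(as.integer(stats::runif(16 * 12 * 5) > 0.6), c(16, 12, 5))
  vol <- labeled_volume(vox, c(0.5, 0.5, 1), "imgA", "nuclear", "SS")
  path <- withr::local_tempfile(fileext = ".tif")
  write_mask_volume(vol, path)
  back <- read_mask_volume(path, spacing = c(0.5, 0.5, 1), image_id = "imgA",
                           channel = "nuclear", condition = "SS")
  expect_identical(back$voxels, vol$voxels)
  expect_equal(back$spacing, vol$spacing)
  expect_identical(back$image_id, "imgA")
  expect_identical(back$condition, "SS")
})

test_that("16-bit stacks with values {0, 65535} load as binary volumes", {
  pages <- lapply(1:4, function(k) {
    m <- matrix(0, 32, 32)
    m[8:24, 8:24] <- 1   # writeTIFF maps 1.0 -> 65535 at 16 bits
    m
  })
  path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  vol <- read_mask_volume(path)
  expect_equal(dim(vol$voxels), c(32, 32, 4))
  expect_setequal(unique(as.vector(vol$voxels)), c(0L, 1L))
  expect_equal(sum(vol$voxels), 4 * 17 * 17)
})

test_that("an all-zero stack is a valid volume yielding no objects", {
  vol <- labeled_volume(array(0L, c(8, 8, 4)))
  expect_equal(sum(vol$voxels), 0)
  expect_length(split_objects(vol, min_voxels = 1), 0)
})

test_that("missing files and bad manifests raise informative errors", {
  expect_error(read_mask_volume("/nonexistent/file.tif"), "no such file")
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(path = "x.tif"), bad, row.names = FALSE)
  expect_error(read_manifest(bad), "missing columns")
})

test_that("split_objects separates disjoint blocks and respects min size", {
  vox <- array(0L, c(16, 16, 16))
  vox[2:6, 2:6, 2:6] <- 1L
  vox[10:14, 10:14, 10:14] <- 1L
  vox[1, 16, 16] <- 1L   # single-voxel speck
  vol <- labeled_volume(vox)
  objs <- suppressMessages(split_objects(vol, min_voxels = 50))
  expect_length(objs, 2)
  expect_equal(sort(vapply(objs, function(o) sum(o$voxels), numeric(1))),
               c(125, 125))
  expect_message(split_objects(vol, min_voxels = 50), "discarded 1")
})

test_that("corner-touching blocks split under 6- but merge under 26-connectivity", {
  vox <- array(0L, c(10, 10, 10))
  vox[2:4, 2:4, 2:4] <- 1L
  vox[5:7, 5:7, 5:7] <- 1L   # touches only at the (4,4,4)/(5,5,5) corner
  vol <- labeled_volume(vox)
  expect_length(split_objects(vol, connectivity = 6, min_voxels = 1), 2)
  expect_length(split_objects(vol, connectivity = 26, min_voxels = 1), 1)
})

test_that("component labeling matches a brute-force BFS oracle", {
  set.seed(7)
  for (conn in c(6, 26)) {
    for (rep in 1:4) {
      vox <- array(as.integer(stats::runif(14^3) > 0.72), c(14, 14, 14))
      vol <- labeled_volume(vox)
      objs <- split_objects(vol, connectivity = conn, min_voxels = 1)
      # rebuild a labeling from the returned objects
      got <- lapply(objs, function(o) {
        idx <- which(o$voxels > 0, arr.ind = TRUE)
        idx <- sweep(idx, 2, o$offset, `+`)
        sort(idx[, 1] + 14 * (idx[, 2] - 1) + 14 * 14 * (idx[, 3] - 1))
      })
      want <- label_partition(bfs_label(vox, conn))
      key <- function(p) sort(vapply(p, function(s) paste(s, collapse = ","), ""))
      expect_identical(key(got), key(want))
    }
  }
})

test_that("nucleoli are assigned by centroid containment with exclusions", {
  nucvox <- array(0L, c(40, 40, 20))
  nucvox[4:16, 4:16, 4:16] <- 1L    # nucleus 1
  nucvox[24:36, 24:36, 4:16] <- 1L  # nucleus 2 (no nucleoli)
  nuc <- labeled_volume(nucvox, channel = "nuclear")
  nclvox <- array(0L, c(40, 40, 20))
  nclvox[6:8, 6:8, 6:8] <- 1L       # inside nucleus 1
  nclvox[12:14, 6:8, 6:8] <- 1L     # inside nucleus 1
  nclvox[6:8, 12:14, 12:14] <- 1L   # inside nucleus 1
  nclvox[30:32, 4:6, 18:19] <- 1L   # outside every nucleus
  ncl <- labeled_volume(nclvox, channel = "nucleolar")
  nuclei <- split_objects(nuc, min_voxels = 1)
  nucleoli <- split_objects(ncl, min_voxels = 1)
  mapping <- suppressMessages(assign_nucleoli(nuclei, nucleoli))
  expect_length(mapping, 1)
  expect_length(mapping[[1]]$nucleoli, 3)
  # every nucleolus lands in at most one nucleus
  total_assigned <- sum(vapply(mapping, function(m) length(m$nucleoli), 0L))
  expect_lte(total_assigned, length(nucleoli))
  expect_true(all(vapply(mapping, function(m) length(m$nucleoli) >= 1, TRUE)))
  expect_message(assign_nucleoli(nuclei, nucleoli), "dropped 1")
  expect_message(assign_nucleoli(nuclei, nucleoli), "excluded 1")
})

test_that("manifests round-trip through CSV", {
  man <- data.frame(path = c("a.tif", "b.tif"), image_id = c("i1", "i1"),
                    channel = c("nuclear", "nucleolar"),
                    condition = c("SS", "SS"),
                    spacing_y = 1, spacing_x = 1, spacing_z = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(man, path)
  expect_equal(read_manifest(path), man)
})
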