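# Shared fixtures and independent oracles, all built in code.

# independent brute-force BFS component labeling (oracle for split_objects)
bfs_label <- function(vox, connectivity) {
  d <- dim(vox)
  offs <- if (connectivity == 6) {
    rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))
  } else {
    as.matrix(expand.grid(-1:1, -1:1, -1:1))[-14, ]
  }
  lab <- array(0L, d)
  nxt <- 0L
  for (p in which(vox > 0)) {
    if (lab[p] != 0L) next
    nxt <- nxt + 1L
    queue <- p
    lab[p] <- nxt
    while (length(queue) > 0) {
      q <- queue[1]; queue <- queue[-1]
      k <- (q - 1) %/% (d[1] * d[2])
      j <- ((q - 1) %% (d[1] * d[2])) %/% d[1]
      i <- (q - 1) %% d[1]
      for (r in seq_len(nrow(offs))) {
        ii <- i + offs[r, 1]; jj <- j + offs[r, 2]; kk <- k + offs[r, 3]
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d[1] || jj >= d[2] || kk >= d[3])
          next
        np <- 1 + ii + d[1] * (jj + d[2] * kk)
        if (vox[np] > 0 && lab[np] == 0L) {
          lab[np] <- nxt
          queue <- c(queue, np)
        }
      }
    }
  }
  lab
}

# partition of foreground voxel indices induced by a labeling
label_partition <- function(lab) {
  fg <- which(lab > 0)
  unname(lapply(split(fg, lab[fg]), sort))
}

# exact 12-triangle unit cube mesh, outward-oriented
unit_cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  # faces as quads split into triangles, wound outward
  quads <- rbind(
    c(1, 3, 4, 2),  # z = 0 (normal -z)
    c(5, 6, 8, 7),  # z = 1 (+z)
    c(1, 2, 6, 5),  # y = 0 (-y)
    c(3, 7, 8, 4),  # y = 1 (+y)
    c(1, 5, 7, 3),  # x = 0 (-x)
    c(2, 4, 8, 6))  # x = 1 (+x)
  f <- do.call(rbind, lapply(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])
  }))
  triangle_mesh(v, f)
}

# sphere mask with an attached spike of the given length and width
spiked_sphere_volume <- function(radius = 12, grid = 48, spike = 5,
                                 width = 1) {
  ph <- make_phantom(phantom_spec("sphere", rep(grid, 3), radius = radius))
  vox <- ph$volume$voxels
  c0 <- grid / 2
  cols <- c0:(c0 + width - 1)
  ztop <- max(which(vox[c0, c0, ] > 0))
  vox[cols, cols, ztop:(ztop + spike)] <- 1L
  list(volume = labeled_volume(vox, c(1, 1, 1), "spiked"),
       spec = ph$spec, spike_z = (ztop + 1):(ztop + spike),
       center_idx = c0)
}

# synthetic 31-feature table with the required provenance columns; one
# feature carries the class signal, the rest are noise
fake_feature_table <- function(n_per_image = 12, images_a = 2, images_b = 2,
                               signal_feature = "ShapeIndex", delta = 2,
                               sd = 1, seed = 42) {
  set.seed(seed)
  rows <- list()
  for (cls in c("A", "B")) {
    n_img <- if (cls == "A") images_a else images_b
    for (im in seq_len(n_img)) {
      for (ce in seq_len(n_per_image)) {
        feats <- as.list(stats::rnorm(length(feature_names()), sd = sd))
        names(feats) <- feature_names()
        if (cls == "B")
          feats[[signal_feature]] <- feats[[signal_feature]] + delta
        rows[[length(rows) + 1]] <- data.frame(
          image_id = sprintf("%s%d", cls, im), condition = cls,
          object_id = ce, feats, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# quick reconstruction settings for small unit-test objects
fast_params <- function() recon_params(n_eigenfunctions = 60,
                                       taubin_iterations = 5)
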