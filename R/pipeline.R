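#' End-to-end morphometry pipeline
#'
#' Runs the full protocol on a manifest of nuclear/nucleolar mask volumes:
#' split objects, pair nucleoli with parent nuclei, reconstruct every
#' surface, compute the six-measure signatures, aggregate nucleus feature
#' vectors, and (optionally) classify conditions under L2OGO
#' cross-validation. Objects are processed independently in input order, so
#' results are deterministic and independent of any parallel scheduling of
#' the per-object stage.
#'
#' @param manifest manifest data.frame (see [read_manifest()]) or a
#'   population from [make_population()].
#' @param base_dir directory for relative manifest paths.
#' @param params [recon_params()] used for every object.
#' @param min_voxels minimum object size kept by [split_objects()].
#' @param classify if `TRUE`, run [evaluate_l2ogo()] on the feature table.
#' @param model [model_config()] for the classification stage.
#' @param set_sizes,n_bootstrap,seed classification settings.
#' @param output_dir optional directory; when given, feature tables,
#'   metrics, importances and a JSON run manifest are written there.
#' @return List with `features`, `signatures` (per-object table including
#'   nucleoli), `classification` (or `NULL`), and `log` (per-object notes).
#' @export
run_pipeline <- function(manifest, base_dir = ".", params = recon_params(),
                         min_voxels = 50, classify = TRUE,
                         model = model_config("fast-rf"),
                         set_sizes = seq(3, 31, by = 2), n_bootstrap = 1000,
                         seed = 1, output_dir = NULL) {
  images <- normalize_pipeline_input(manifest, base_dir)
  records <- list()
  sig_rows <- list()
  log <- list()
  for (img in images) {
    nuclei <- split_objects(img$nuclear, min_voxels = min_voxels)
    nucleoli <- if (!is.null(img$nucleolar))
      split_objects(img$nucleolar, min_voxels = min_voxels) else list()
    pairs <- assign_nucleoli(nuclei, nucleoli)
    log[[img$image_id]] <- sprintf(
      "%s: %d nuclei, %d nucleoli, %d nuclei retained",
      img$image_id, length(nuclei), length(nucleoli), length(pairs))
    for (pr in pairs) {
      nuc_mesh <- reconstruct_surface(pr$nucleus, params)
      nuc_sig <- compute_signature(nuc_mesh, pr$nucleus$object_id,
                                   img$image_id, img$condition)
      nucl_sigs <- lapply(pr$nucleoli, function(nc) {
        m <- reconstruct_surface(nc, params)
        compute_signature(m, nc$object_id, img$image_id, img$condition)
      })
      sig_rows <- c(sig_rows, list(cbind(channel = "nuclear", nuc_sig)),
                    lapply(nucl_sigs, function(s) cbind(channel = "nucleolar", s)))
      records[[length(records) + 1]] <- aggregate_features(nuc_sig, nucl_sigs)
    }
  }
  features <- build_feature_table(records)
  signatures <- if (length(sig_rows) > 0) do.call(rbind, sig_rows) else NULL
  classification <- NULL
  if (classify && nrow(features) > 0) {
    classification <- evaluate_l2ogo(features, model, set_sizes,
                                     n_bootstrap, seed)
  }
  out <- list(features = features, signatures = signatures,
              classification = classification, log = unlist(log))
  if (!is.null(output_dir)) write_pipeline_outputs(out, output_dir, seed)
  out
}

normalize_pipeline_input <- function(manifest, base_dir) {
  if (is.data.frame(manifest)) {
    vols <- load_manifest_volumes(manifest, base_dir)
    ids <- unique(manifest$image_id)
    images <- lapply(ids, function(id) {
      sel <- which(manifest$image_id == id)
      img <- list(image_id = id,
                  condition = manifest$condition[sel[1]],
                  nuclear = NULL, nucleolar = NULL)
      for (s in sel) img[[manifest$channel[s]]] <- vols[[s]]
      if (is.null(img$nuclear))
        stop("image ", id, " has no nuclear channel")
      img
    })
    return(images)
  }
  manifest  # already a population list
}

write_pipeline_outputs <- function(result, output_dir, seed) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$features, file.path(output_dir, "features.csv"),
                   row.names = FALSE)
  if (!is.null(result$signatures))
    utils::write.csv(result$signatures, file.path(output_dir, "signatures.csv"),
                     row.names = FALSE)
  if (!is.null(result$classification)) {
    utils::write.csv(result$classification$metrics,
                     file.path(output_dir, "metrics.csv"), row.names = FALSE)
    utils::write.csv(feature_importance(result$classification),
                     file.path(output_dir, "importance.csv"),
                     row.names = FALSE)
  }
  manifest <- list(package = "nucmorph3d",
                   version = as.character(utils::packageVersion("nucmorph3d")),
                   seed = seed, n_nuclei = nrow(result$features),
                   log = as.list(result$log))
  jsonlite::write_json(manifest, file.path(output_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(output_dir)
}

#' Validate reconstruction accuracy on analytic phantoms
#'
#' Voxelizes the five reference solids, reconstructs each surface, and
#' reports computed volume and surface area against the closed-form values,
#' together with the mean curvature / shape index / curvedness means used
#' for the qualitative shape ordering.
#'
#' The shape roster covers the two accuracy regimes (smooth nucleus-like
#' solids vs faceted solids with curvature singularities) plus the trio
#' used for the qualitative curvature ordering: a sphere, an elongated
#' ellipsoid, and three overlapping spheres with linearly aligned centers,
#' whose area-weighted mean curvature and curvedness increase in that
#' order while the shape index is highest for the sphere.
#'
#' @param grid grid dimension for each (cubic) phantom carrier.
#' @param params [recon_params()] used for reconstruction.
#' @param shapes subset of shape kinds to run: `"ellipsoid"` is the
#'   equal-volume triaxial accuracy case; `"ellipsoid_elongated"` the
#'   high-eccentricity prolate case used in the curvature ordering.
#' @return Data.frame: one row per shape with analytic and computed volume
#'   and area, relative errors (%), and the three curvature means.
#' @export
validate_synthetic <- function(grid = 128, params = recon_params(),
                               shapes = c("sphere", "ellipsoid", "cube",
                                          "octahedron", "ellipsoid_elongated",
                                          "overlapping_spheres")) {
  specs <- list(
    sphere = function(g) phantom_spec("sphere", rep(g, 3), radius = 20),
    ellipsoid = function(g) phantom_spec("ellipsoid", rep(g, 3),
                                         semi_axes = c(26, 20, 15.4)),
    cube = function(g) phantom_spec("cube", rep(g, 3), edge = 24),
    octahedron = function(g) phantom_spec("octahedron", rep(g, 3),
                                          circumradius = 24),
    ellipsoid_elongated = function(g)
      phantom_spec("ellipsoid", rep(g, 3), semi_axes = c(35, 15, 15)),
    overlapping_spheres = function(g)
      phantom_spec("overlapping_spheres", rep(g, 3), radius = 12,
                   offset = 16))
  rows <- lapply(shapes, function(sh) {
    spec <- tryCatch(specs[[sh]](grid), error = function(e) NULL)
    if (is.null(spec)) {
      message("validate_synthetic: skipping ", sh,
              " (does not fit a ", grid, "^3 grid)")
      return(NULL)
    }
    ph <- make_phantom(spec, image_id = sh)
    mesh <- reconstruct_surface(ph$volume, params)
    sig <- compute_signature(mesh, 1L, sh, NA_character_)
    data.frame(shape = sh,
               analytic_volume = ph$spec$analytic_volume,
               computed_volume = sig$Volume,
               volume_error_pct = 100 * abs(sig$Volume - ph$spec$analytic_volume) /
                 ph$spec$analytic_volume,
               analytic_area = ph$spec$analytic_surface_area,
               computed_area = sig$SurfaceArea,
               area_error_pct = 100 * abs(sig$SurfaceArea -
                 ph$spec$analytic_surface_area) / ph$spec$analytic_surface_area,
               mean_curvature = sig$MeanCurvature,
               shape_index = sig$ShapeIndex,
               curvedness = sig$Curvedness,
               fractal_dimension = sig$FractalDimension,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
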