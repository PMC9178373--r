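#' Morphometry pipeline parameters
#'
#' Bundles the tunable parameters of the image-to-record pipeline. The
#' defaults are the study-scale settings (2.5 mm grid, 5 mm VOIs, 1 mm mesh
#' edge); [miniature_params()] returns settings proportional to the
#' scaled-down synthetic metacarpals used in the package's own simulation
#' studies.
#'
#' @param binarize_method Passed to [binarize()].
#' @param closing_radius Cortex closing radius, mm.
#' @param grid_spacing Background grid spacing, mm.
#' @param voi_diameter Spherical VOI diameter, mm.
#' @param mesh_edge Tetrahedral mesh target edge length, mm.
#' @param n_directions MIL directions per VOI.
#' @param min_bone_voxels Minimum bone voxels for a valid fabric VOI.
#' @export
morph_params <- function(binarize_method = "global_otsu",
                         closing_radius = 0.3,
                         grid_spacing = 2.5,
                         voi_diameter = 5.0,
                         mesh_edge = 1.0,
                         n_directions = 128,
                         min_bone_voxels = 50) {
  list(binarize_method = binarize_method, closing_radius = closing_radius,
       grid_spacing = grid_spacing, voi_diameter = voi_diameter,
       mesh_edge = mesh_edge, n_directions = n_directions,
       min_bone_voxels = min_bone_voxels)
}

#' @rdname morph_params
#' @export
miniature_params <- function() {
  morph_params(grid_spacing = 0.4, voi_diameter = 1.0, mesh_edge = 0.3,
               n_directions = 32, min_bone_voxels = 50)
}

#' Process one specimen from greyscale volume to per-region records
#'
#' Runs the full analysis chain: binarisation, cortical/trabecular
#' separation, growth-plate handling (unfused specimens are split and the
#' two parts analysed as separate volumes; fused specimens are cut with the
#' supplied epiphysis boundary), the 70%-length region cutting, background
#' grid sampling of BV/TV and MIL anisotropy, sphere-fitting regional
#' thickness, tetrahedral meshing with interpolation, mesh means, and the
#' dorsopalmar concentration index of the epiphysis.
#'
#' @param x A `synthetic_specimen` or greyscale/binary `voxel_volume`.
#' @param params A [morph_params()] list.
#' @param epiphysis_start Optional explicit 0-based epiphysis boundary for
#'   fused specimens (taken from the specimen metadata when `x` is
#'   synthetic, emulating the visually identified cutting slices of real
#'   workflows).
#' @param metadata Metadata list when `x` is a raw volume.
#' @param keep_volumes Keep masks/meshes in the result (memory-heavy).
#' @return A `specimen_result`: `record` (tibble, one row per region with
#'   mesh-mean BV/TV and DA, voxel-count BV/TV, Tb.Th/Tb.Sp/Tb.N),
#'   `dorsopalmar_index`, `partitions`, and optionally the intermediates.
#' @export
process_specimen <- function(x, params = morph_params(),
                             epiphysis_start = NULL, metadata = list(),
                             keep_volumes = FALSE) {
  if (inherits(x, "synthetic_specimen")) {
    grey <- x$volume
    metadata <- x$metadata
    if (is.null(epiphysis_start) && isTRUE(metadata$fused))
      epiphysis_start <- metadata$gap_center
  } else grey <- x
  binary <- binarize(grey, params$binarize_method)

  split <- tryCatch(split_epiphysis(binary), error = function(e) NULL)
  pieces <- list()
  if (!is.null(split)) {
    pieces$proximal <- list(binary = split$metaphyseal, epiphysis = FALSE)
    if (sum(as_array3(split$epiphyseal)) > 0)
      pieces$epiphysis <- list(binary = split$epiphyseal, epiphysis = TRUE)
  } else {
    pieces$proximal <- list(binary = binary, epiphysis = FALSE)
  }

  records <- list()
  partitions <- list()
  details <- list()
  dp_index <- NA_real_
  for (nm in names(pieces)) {
    piece <- pieces[[nm]]
    masks <- separate_cortex(piece$binary, params$closing_radius)
    if (piece$epiphysis) {
      a <- slice_bone_area(piece$binary)
      inb <- which(a > 0)
      part <- new_region_partition(
        list(epiphysis = c(min(inb) - 1L, max(inb))), dim(piece$binary)[1])
    } else {
      part <- cut_regions(piece$binary,
                          epiphysis_start = if (is.null(split))
                            epiphysis_start else NULL)
    }
    partitions[[nm]] <- part

    grid <- build_grid(masks$inner_mask, params$grid_spacing,
                       params$voi_diameter)
    samples <- sample_grid(masks, grid, fabric = TRUE,
                           n_directions = params$n_directions,
                           min_bone_voxels = params$min_bone_voxels)
    mesh <- mesh_inner_region(masks$inner_mask, params$mesh_edge)
    mesh <- assign_mesh_regions(mesh, part)
    map_bvtv <- interpolate_to_mesh(samples, mesh, "bvtv")
    has_fabric <- any(samples$fabric_valid %in% TRUE)
    map_da <- if (has_fabric) {
      s2 <- samples
      s2$valid <- s2$valid & s2$fabric_valid %in% TRUE
      interpolate_to_mesh(s2, mesh, "da")
    } else NULL

    inner <- as_logical3(masks$inner_mask)
    trab <- as_logical3(masks$trabecular_bone)
    vs <- voxel_size(masks$inner_mask)
    # the marrow thickness map runs on the whole medullary cavity (solid
    # minus bone) so marrow slabs are not clipped at the inner-mask edge;
    # means are still taken over inner-mask marrow voxels
    cavity <- as_logical3(masks$solid) & !(as_logical3(piece$binary) == 1)
    maps <- list(bone = local_thickness_map(masks$trabecular_bone),
                 marrow = local_thickness_map(voxel_volume(cavity, vs)))
    # thickness means are taken over voxels away from the corticotrabecular
    # junction, where cut corners and wall wedges bias the local values;
    # the marrow phase needs a wider margin than the bone phase
    dcort <- sqrt(sq_edt_cpp(!as_logical3(masks$cortical_mask), dim(inner)))
    dim(dcort) <- dim(inner)
    away_bone <- dcort > 2
    away_marrow <- dcort > 4

    for (rg in intersect(names(part$intervals),
                         c("base", "metaphysis", "epiphysis"))) {
      rmask <- region_mask(part, rg, dim(inner))
      n_inner <- sum(inner & rmask)
      if (n_inner == 0) next
      bvtv_vox <- sum(trab & rmask) / n_inner
      th <- tryCatch(region_thickness(masks$trabecular_bone,
                                      masks$inner_mask, rmask & away_bone,
                                      maps,
                                      marrow_region = rmask & away_marrow),
                     error = function(e) NULL)
      bvtv_mesh <- tryCatch(mesh_mean(map_bvtv, mesh, rg),
                            error = function(e) NA_real_)
      da_mesh <- if (!is.null(map_da))
        tryCatch(mesh_mean(map_da, mesh, rg), error = function(e) NA_real_)
      else NA_real_
      records[[paste(nm, rg)]] <- data.frame(
        specimen_id = metadata$specimen_id %||% "spec",
        species = metadata$species %||% NA_character_,
        sex = metadata$sex %||% NA_character_,
        age_months = metadata$age_months %||% NA_real_,
        age_category = metadata$age_category %||% NA_character_,
        region = rg,
        bvtv = bvtv_mesh, bvtv_voxel = bvtv_vox,
        da = da_mesh,
        tb_th = if (is.null(th)) NA_real_ else th$tb_th,
        tb_sp = if (is.null(th)) NA_real_ else th$tb_sp,
        tb_n = if (is.null(th)) NA_real_ else th$tb_n)
      if (rg == "epiphysis")
        dp_index <- tryCatch(dorsopalmar_index(map_bvtv, mesh, "epiphysis"),
                             error = function(e) NA_real_)
    }
    if (keep_volumes)
      details[[nm]] <- list(masks = masks, grid = grid, samples = samples,
                            mesh = mesh, map_bvtv = map_bvtv,
                            map_da = map_da)
  }
  structure(list(record = tibble::as_tibble(do.call(rbind, records)),
                 dorsopalmar_index = dp_index,
                 partitions = partitions,
                 details = if (keep_volumes) details else NULL),
            class = "specimen_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate and process a synthetic cohort, one specimen at a time
#'
#' Streams through a [cohort_plan()]: renders each synthetic metacarpal,
#' runs [process_specimen()], and keeps only the per-region records, the
#' realised ground truth and the dorsopalmar index — so cohorts of dozens
#' of image-level specimens fit in memory.
#'
#' @inheritParams make_cohort
#' @param params Pipeline parameters; defaults to [miniature_params()],
#'   matching the scaled-down specimen geometry.
#' @param ... Passed to [make_synthetic_metacarpal()].
#' @return List with `measured` (pipeline records), `truth` (generator
#'   records) and `indices` (per-specimen dorsopalmar index and fusion
#'   state).
#' @export
process_generated_cohort <- function(n_per_category = c(4, 9, 12, 9, 18),
                                     trajectory = default_trajectory(),
                                     seed = 1L,
                                     species = c("Ggg", "Gbb"),
                                     fusion_age_months = 126,
                                     params = miniature_params(),
                                     ...) {
  plan <- cohort_plan(n_per_category, seed, species)
  measured <- list()
  truth <- list()
  idx <- list()
  for (i in seq_len(nrow(plan))) {
    pl <- plan[i, ]
    spec <- make_synthetic_metacarpal(
      pl$age_months, trajectory = trajectory_for(trajectory, pl$species),
      seed = pl$sub_seed, species = pl$species,
      fusion_age_months = fusion_age_months, ...)
    spec$metadata$specimen_id <- pl$specimen_id
    res <- process_specimen(spec, params)
    measured[[i]] <- res$record
    truth[[i]] <- truth_records(spec, pl$specimen_id)
    idx[[i]] <- data.frame(specimen_id = pl$specimen_id,
                           age_category = spec$metadata$age_category,
                           age_months = pl$age_months,
                           fused = spec$metadata$fused,
                           has_epiphysis = spec$metadata$has_epiphysis,
                           dorsopalmar_index = res$dorsopalmar_index)
  }
  fix <- function(x) {
    x <- tibble::as_tibble(do.call(rbind, x))
    if ("age_category" %in% names(x))
      x$age_category <- factor(x$age_category, levels = AGE_CATEGORIES)
    x
  }
  list(measured = fix(measured), truth = fix(truth), indices = fix(idx))
}
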