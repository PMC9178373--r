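#' Quasi-uniform hemisphere directions (Fibonacci lattice)
#'
#' Seed-free deterministic direction set used for the mean-intercept-length
#' scan.
#' @param n Number of directions.
#' @return `n` x 3 matrix of unit vectors with non-negative third component.
#' @export
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build the background grid of spherical VOIs
#'
#' Superimposes an axis-aligned lattice (default spacing 2.5 mm) on the
#' inner mask, anchored at the minimum corner of the mask's bounding box,
#' and keeps the nodes whose spherical volume of interest (default diameter
#' 5 mm) intersects the inner mask by at least `min_mask_fraction` of the
#' sphere volume.
#'
#' @param inner_mask Binary `voxel_volume`.
#' @param spacing Grid spacing, mm.
#' @param voi_diameter VOI sphere diameter, mm.
#' @param min_mask_fraction Minimum fraction of the VOI sphere inside the
#'   inner mask for a node to be retained.
#' @return A `background_grid`: `nodes` (physical mm coordinates, one row
#'   per node), `nodes_vox` (0-based continuous voxel coordinates),
#'   `spacing`, `voi_diameter`, `mask_fraction` per node.
#' @export
build_grid <- function(inner_mask, spacing = 2.5, voi_diameter = 5.0,
                       min_mask_fraction = 0.1) {
  if (spacing <= 0) stop("spacing must be positive")
  vs <- voxel_size(inner_mask)
  m <- as_array3(inner_mask) != 0
  if (!any(m)) stop("empty inner mask")
  idx <- which(m, arr.ind = TRUE)
  bb_lo <- apply(idx, 2, min)
  bb_hi <- apply(idx, 2, max)
  # physical coordinates of the bounding-box minimum corner
  corner <- (bb_lo - 1) * vs
  upper <- bb_hi * vs
  axes <- lapply(1:3, function(a) {
    k <- 0:floor((upper[a] - corner[a]) / spacing)
    corner[a] + k * spacing
  })
  nodes <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]],
                                 KEEP.OUT.ATTRS = FALSE))
  colnames(nodes) <- c("x1", "x2", "x3")
  r_vox <- (voi_diameter / 2) / vs
  sphere_n <- sphere_voxel_count(r_vox)
  mask_int <- as_int3(inner_mask)
  dims <- dim(m)
  frac <- vapply(seq_len(nrow(nodes)), function(i) {
    ctr <- nodes[i, ] / vs - 0.5  # 0-based voxel coords
    cnt <- voi_counts_cpp(mask_int, mask_int, dims, ctr, r_vox)
    cnt[2] / sphere_n
  }, numeric(1))
  keep <- frac >= min_mask_fraction
  structure(list(nodes = nodes[keep, , drop = FALSE],
                 nodes_vox = nodes[keep, , drop = FALSE] / vs - 0.5,
                 spacing = spacing, voi_diameter = voi_diameter,
                 mask_fraction = frac[keep]),
            class = "background_grid")
}

# number of integer lattice points within a sphere of radius r (voxels)
sphere_voxel_count <- function(r) {
  R <- floor(r)
  n <- 0
  for (dz in -R:R) for (dy in -R:R) {
    rem <- r * r - dz * dz - dy * dy
    if (rem >= 0) n <- n + 2 * floor(sqrt(rem)) + 1
  }
  n
}

#' Bone volume fraction within one spherical VOI
#'
#' Bone-voxel count over inner-mask-voxel count within the sphere. Returns
#' an invalid-flagged sample (not an error) when the sphere contains no
#' inner-mask voxels.
#'
#' @param trabecular_bone,inner_mask Binary `voxel_volume`s.
#' @param node Physical node coordinate (mm, length 3).
#' @param voi_diameter Sphere diameter, mm.
#' @return List: `bvtv`, `n_bone_voxels`, `n_mask_voxels`, `valid`.
#' @export
sample_bvtv <- function(trabecular_bone, inner_mask, node, voi_diameter = 5.0,
                        bone_int = as_int3(trabecular_bone),
                        mask_int = as_int3(inner_mask)) {
  vs <- voxel_size(inner_mask)
  ctr <- node / vs - 0.5
  cnt <- voi_counts_cpp(bone_int, mask_int,
                        dim(inner_mask), ctr, (voi_diameter / 2) / vs)
  if (cnt[2] == 0)
    return(list(bvtv = NA_real_, n_bone_voxels = 0, n_mask_voxels = 0,
                valid = FALSE))
  list(bvtv = cnt[1] / cnt[2], n_bone_voxels = cnt[1], n_mask_voxels = cnt[2],
       valid = TRUE)
}

#' Mean-intercept-length fabric of one spherical VOI
#'
#' Casts parallel test-line families through the VOI for `n_directions`
#' quasi-uniform hemisphere directions. Per direction, the mean intercept
#' length is the total in-mask test-line length divided by the number of
#' marrow-to-bone crossings. The MIL ellipsoid is fitted by least squares of
#' `1/MIL^2(w) = w' H w`; eigenvalues of the fitted form give the fabric
#' radii `lambda_i = 1/sqrt(eig_i(H))` (sorted descending) and the degree of
#' anisotropy `DA = 1 - lambda3/lambda1`, bounded in `[0, 1]` with 0
#' isotropic and 1 fully anisotropic. Directions with no crossings have
#' infinite MIL and enter the fit with `1/MIL^2 = 0`; a rank-deficient but
#' consistent fit therefore yields DA near 1 (unbounded intercepts in some
#' plane), while an indefinite fit is flagged invalid.
#'
#' @param trabecular_bone,inner_mask Binary `voxel_volume`s.
#' @param node Physical node coordinate (mm).
#' @param voi_diameter Sphere diameter, mm.
#' @param n_directions Number of hemisphere directions.
#' @param line_spacing Spacing between parallel lines, voxels.
#' @param step Sampling step along each line, voxels.
#' @param min_bone_voxels Minimum bone voxels in the VOI for a valid fit.
#' @param min_mask_fraction Minimum fraction of the sphere inside the mask.
#' @return A `fabric_result`: `mil_tensor` (symmetric 3x3 with eigenvalues
#'   `lambda`), `eigenvalues` (descending), `eigenvectors` (columns,
#'   orthonormal), `da`, `valid`, `reason`, plus per-direction `mil` data.
#' @export
mil_fabric <- function(trabecular_bone, inner_mask, node, voi_diameter = 5.0,
                       n_directions = 128, line_spacing = 1, step = 1,
                       min_bone_voxels = 50, min_mask_fraction = 0.1,
                       bone_int = as_int3(trabecular_bone),
                       mask_int = as_int3(inner_mask)) {
  vs <- voxel_size(inner_mask)
  dims <- dim(inner_mask)
  ctr <- node / vs - 0.5
  r_vox <- (voi_diameter / 2) / vs
  cnt <- voi_counts_cpp(bone_int, mask_int, dims, ctr, r_vox)
  invalid <- function(reason) {
    structure(list(mil_tensor = NULL, eigenvalues = rep(NA_real_, 3),
                   eigenvectors = NULL, da = NA_real_, valid = FALSE,
                   reason = reason, directions = NULL, mil = NULL),
              class = "fabric_result")
  }
  if (cnt[2] < min_mask_fraction * sphere_voxel_count(r_vox))
    return(invalid("VOI-mask overlap below minimum"))
  if (cnt[1] < min_bone_voxels)
    return(invalid("too few bone voxels"))
  if (cnt[1] == cnt[2])
    return(invalid("single phase: no marrow in VOI"))

  dirs <- fibonacci_hemisphere(n_directions)
  scan <- mil_scan_cpp(bone_int, mask_int, dims, ctr, r_vox, dirs,
                       line_spacing, step, 2)
  len <- scan[, 1]
  crossings <- scan[, 2]
  use <- len > 0
  if (sum(crossings) == 0)
    return(invalid("no phase crossings in any direction"))
  mil <- ifelse(crossings > 0, len / crossings, Inf)  # voxel units
  y <- ifelse(is.finite(mil), 1 / mil^2, 0)
  X <- cbind(dirs[, 1]^2, dirs[, 2]^2, dirs[, 3]^2,
             2 * dirs[, 1] * dirs[, 2], 2 * dirs[, 1] * dirs[, 3],
             2 * dirs[, 2] * dirs[, 3])
  fit <- tryCatch(qr.solve(X[use, , drop = FALSE], y[use]),
                  error = function(e) NULL)
  if (is.null(fit)) return(invalid("MIL ellipsoid fit failed"))
  H <- matrix(c(fit[1], fit[4], fit[5],
                fit[4], fit[2], fit[6],
                fit[5], fit[6], fit[3]), 3, 3)
  e <- eigen(H, symmetric = TRUE)  # eigenvalues descending
  h <- e$values
  if (h[1] <= 0) return(invalid("non-positive-definite MIL fit"))
  # eigenvalues near or slightly below zero mean (near-)unbounded
  # intercepts in that plane -- rank deficiency from strongly anisotropic
  # or VOI-clipped geometry -- and are clamped to a small floor (DA -> 1);
  # a clearly indefinite fit is flagged invalid instead
  if (h[3] < -0.05 * h[1]) return(invalid("indefinite MIL fit"))
  tol <- 5e-3 * h[1]
  h <- pmax(h, tol)  # rank-deficient directions: unbounded MIL, DA -> 1
  lambda <- 1 / sqrt(h)           # ascending h -> descending lambda
  lambda <- sort(lambda, decreasing = TRUE) * vs  # physical units (mm)
  vecs <- e$vectors[, 3:1, drop = FALSE]  # matched to descending lambda
  da <- 1 - lambda[3] / lambda[1]
  M <- vecs %*% diag(lambda) %*% t(vecs)
  structure(list(mil_tensor = M, eigenvalues = lambda, eigenvectors = vecs,
                 da = da, valid = TRUE, reason = NULL,
                 directions = dirs,
                 mil = data.frame(length = len * vs,
                                  crossings = crossings,
                                  mil = mil * vs)),
            class = "fabric_result")
}

#' Sample BV/TV and fabric at every grid node
#'
#' @param masks A `mask_set` from [separate_cortex()] (or a list with
#'   `trabecular_bone` and `inner_mask`).
#' @param grid A [build_grid()] result.
#' @param fabric Compute the MIL fabric per node (slower) or BV/TV only.
#' @param ... Passed to [mil_fabric()].
#' @return A tibble, one row per node: coordinates, `bvtv`, `da`,
#'   eigenvalues, `valid`.
#' @export
sample_grid <- function(masks, grid, fabric = TRUE, ...) {
  n <- nrow(grid$nodes)
  bone_int <- as_int3(masks$trabecular_bone)
  mask_int <- as_int3(masks$inner_mask)
  rows <- lapply(seq_len(n), function(i) {
    node <- grid$nodes[i, ]
    bv <- sample_bvtv(masks$trabecular_bone, masks$inner_mask, node,
                      grid$voi_diameter, bone_int = bone_int,
                      mask_int = mask_int)
    da <- NA_real_
    l <- rep(NA_real_, 3)
    fvalid <- NA
    if (fabric) {
      fr <- mil_fabric(masks$trabecular_bone, masks$inner_mask, node,
                       grid$voi_diameter, ...,
                       bone_int = bone_int, mask_int = mask_int)
      fvalid <- fr$valid
      if (fr$valid) {
        da <- fr$da
        l <- fr$eigenvalues
      }
    }
    data.frame(x1 = node[1], x2 = node[2], x3 = node[3],
               bvtv = bv$bvtv, n_bone_voxels = bv$n_bone_voxels,
               da = da, lambda1 = l[1], lambda2 = l[2], lambda3 = l[3],
               valid = bv$valid, fabric_valid = fvalid)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Sphere-fitting local thickness map
#'
#' Every foreground voxel's value is the diameter (mm) of the largest
#' sphere fully contained in the phase that covers the voxel, computed via
#' the Euclidean distance transform, the distance ridge, and sphere
#' coverage propagation. The volume boundary is treated as a continuation
#' of the phase, so a slab spanning the full extent maps to its true
#' thickness.
#'
#' @param phase Binary `voxel_volume`.
#' @return `voxel_volume` of thickness values in mm (0 outside the phase).
#' @export
local_thickness_map <- function(phase) {
  if (!is_binary(phase)) stop("local_thickness_map needs a binary volume")
  vs <- voxel_size(phase)
  fg <- as_logical3(phase)
  if (!any(fg)) return(voxel_volume(array(0, dim(fg)), vs))
  th <- local_thickness_cpp(fg, dim(fg))
  dim(th) <- dim(fg)
  voxel_volume(th * vs, vs)
}

#' Regional trabecular thickness, separation and number
#'
#' `Tb.Th` is the mean sphere-fitting local thickness of the bone phase over
#' the region's bone voxels; `Tb.Sp` the same for the marrow phase within
#' the inner mask; `Tb.N = 1/(Tb.Th + Tb.Sp)` exactly as computed.
#'
#' @param trabecular_bone,inner_mask Binary `voxel_volume`s.
#' @param region Logical array (same dims) restricting the region, or
#'   `NULL` for the whole inner mask.
#' @param maps Optional precomputed list with `bone` and `marrow` thickness
#'   maps (from [local_thickness_map()]) to avoid recomputation.
#' @param marrow_region Optional separate restriction for the marrow-phase
#'   mean (defaults to `region`); the pipeline uses a wider exclusion
#'   margin at the corticotrabecular junction for marrow than for bone.
#' @return A `thickness_summary` list: `tb_th`, `tb_sp` (mm), `tb_n` (1/mm),
#'   voxel counts.
#' @export
region_thickness <- function(trabecular_bone, inner_mask, region = NULL,
                             maps = NULL, marrow_region = region) {
  vs <- voxel_size(inner_mask)
  bone <- as_logical3(trabecular_bone)
  inner <- as_logical3(inner_mask)
  marrow <- inner & !bone
  if (is.null(region)) region <- inner
  bsel <- bone & region
  msel <- marrow & marrow_region
  if (!any(bsel)) stop("region has no bone phase")
  if (!any(msel)) stop("region has no marrow phase")
  if (is.null(maps)) {
    maps <- list(bone = local_thickness_map(voxel_volume(bone, vs)),
                 marrow = local_thickness_map(voxel_volume(marrow, vs)))
  }
  tb_th <- mean(as_array3(maps$bone)[bsel])
  tb_sp <- mean(as_array3(maps$marrow)[msel])
  structure(list(tb_th = tb_th, tb_sp = tb_sp, tb_n = 1 / (tb_th + tb_sp),
                 n_bone = sum(bsel), n_marrow = sum(msel)),
            class = "thickness_summary")
}
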