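#' Tetrahedral mesh of the inner trabecular region
#'
#' Decimates the inner mask to a structured lattice with the target edge
#' length and decomposes each retained cubic cell into six tetrahedra
#' sharing the cell's main diagonal (a Delaunay-consistent triangulation of
#' the lattice point set). Cells are retained by a centroid-in-mask test,
#' which is volume-unbiased at the boundary.
#'
#' @param inner_mask Binary `voxel_volume`.
#' @param target_edge_length Lattice cell edge, mm.
#' @return A `tet_mesh`: `vertices` (mm), `tetrahedra` (1-based vertex
#'   quadruples), `element_volumes` (mm^3), `element_centroids`,
#'   `element_region` (filled by [assign_mesh_regions()]), `edge_length`,
#'   `voxel_size`.
#' @export
mesh_inner_region <- function(inner_mask, target_edge_length = 1.0) {
  vs <- voxel_size(inner_mask)
  m <- as_array3(inner_mask) != 0
  if (!any(m)) stop("empty inner mask")
  h <- target_edge_length
  idx <- which(m, arr.ind = TRUE)
  lo <- (apply(idx, 2, min) - 1) * vs
  hi <- apply(idx, 2, max) * vs
  ncell <- pmax(1L, ceiling((hi - lo) / h))
  d <- dim(m)

  # lattice vertices (ncell+1 per axis)
  vgrid <- lapply(1:3, function(a) lo[a] + h * 0:ncell[a])
  vid <- function(i, j, k) i + (ncell[1] + 1L) * (j + (ncell[2] + 1L) * k) + 1L

  cells <- as.matrix(expand.grid(i = 0:(ncell[1] - 1L),
                                 j = 0:(ncell[2] - 1L),
                                 k = 0:(ncell[3] - 1L)))
  cen <- cbind(lo[1] + h * (cells[, 1] + 0.5),
               lo[2] + h * (cells[, 2] + 0.5),
               lo[3] + h * (cells[, 3] + 0.5))
  cvox <- pmin(pmax(floor(cen / vs) + 1L,
                    matrix(1L, nrow(cen), 3)),
               matrix(d, nrow(cen), 3, byrow = TRUE))
  keep <- m[cbind(cvox[, 1], cvox[, 2], cvox[, 3])]
  if (!any(keep)) stop("fewer than 4 non-coplanar points: mask too small to mesh")
  cells <- cells[keep, , drop = FALSE]

  # Kuhn decomposition: six tets around the main diagonal v000-v111
  tet_local <- rbind(c(0L, 1L, 3L, 7L), c(0L, 3L, 2L, 7L), c(0L, 2L, 6L, 7L),
                     c(0L, 6L, 4L, 7L), c(0L, 4L, 5L, 7L), c(0L, 5L, 1L, 7L))
  corner_off <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0),
                      c(0, 0, 1), c(1, 0, 1), c(0, 1, 1), c(1, 1, 1))
  nc <- nrow(cells)
  corner_ids <- matrix(0L, nc, 8)
  for (c8 in 1:8)
    corner_ids[, c8] <- vid(cells[, 1] + corner_off[c8, 1],
                            cells[, 2] + corner_off[c8, 2],
                            cells[, 3] + corner_off[c8, 3])
  tets <- do.call(rbind, lapply(1:6, function(t6)
    corner_ids[, tet_local[t6, ] + 1L, drop = FALSE]))

  used <- sort(unique(as.vector(tets)))
  remap <- integer(max(used))
  remap[used] <- seq_along(used)
  tets <- matrix(remap[tets], ncol = 4)
  # vertex coordinates from lattice id
  uid <- used - 1L
  vi <- uid %% (ncell[1] + 1L)
  vj <- (uid %/% (ncell[1] + 1L)) %% (ncell[2] + 1L)
  vk <- uid %/% ((ncell[1] + 1L) * (ncell[2] + 1L))
  verts <- cbind(vgrid[[1]][vi + 1L], vgrid[[2]][vj + 1L], vgrid[[3]][vk + 1L])

  centroids <- (verts[tets[, 1], ] + verts[tets[, 2], ] +
                  verts[tets[, 3], ] + verts[tets[, 4], ]) / 4
  structure(list(vertices = verts, tetrahedra = tets,
                 element_volumes = rep(h^3 / 6, nrow(tets)),
                 element_centroids = centroids,
                 element_region = rep(NA_character_, nrow(tets)),
                 edge_length = h, voxel_size = vs),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d vertices, %d tetrahedra, %.3g mm^3 total volume\n",
              nrow(x$vertices), nrow(x$tetrahedra), sum(x$element_volumes)))
  invisible(x)
}

#' Label mesh elements with anatomical regions
#'
#' @param mesh A `tet_mesh`.
#' @param partition A `region_partition` (0-based slice intervals).
#' @return The mesh with `element_region` filled from each element
#'   centroid's proximodistal slice.
#' @export
assign_mesh_regions <- function(mesh, partition) {
  slice0 <- floor(mesh$element_centroids[, 1] / mesh$voxel_size)
  reg <- rep(NA_character_, length(slice0))
  for (nm in names(partition$intervals)) {
    iv <- partition$intervals[[nm]]
    reg[slice0 >= iv[1] & slice0 < iv[2]] <- nm
  }
  mesh$element_region <- reg
  mesh
}

#' Interpolate grid samples onto mesh elements
#'
#' Element value = inverse-distance-weighted (power 2) mean of the k
#' nearest valid grid nodes to the element centroid; a convex combination,
#' so element values stay within the sample range.
#'
#' @param samples Data frame from [sample_grid()] (columns `x1 x2 x3`, the
#'   value column, and `valid`).
#' @param mesh A `tet_mesh`.
#' @param parameter Name of the sample column to interpolate.
#' @param k Number of nearest nodes.
#' @param power IDW exponent.
#' @return A `morphometric_map`: `parameter`, per-element `values`,
#'   `scale_mode`, `range`.
#' @export
interpolate_to_mesh <- function(samples, mesh, parameter = "bvtv", k = 8,
                                power = 2) {
  ok <- samples$valid & is.finite(samples[[parameter]])
  s <- samples[ok, , drop = FALSE]
  if (nrow(s) < 1) stop("no valid samples to interpolate")
  nodes <- as.matrix(s[, c("x1", "x2", "x3")])
  vals <- s[[parameter]]
  cen <- mesh$element_centroids
  k <- min(k, nrow(nodes))
  # squared distances element x node
  d2 <- outer(rowSums(cen^2), rowSums(nodes^2), "+") - 2 * cen %*% t(nodes)
  d2[d2 < 0] <- 0
  out <- vapply(seq_len(nrow(cen)), function(i) {
    di <- d2[i, ]
    nn <- order(di)[seq_len(k)]
    dn <- sqrt(di[nn])
    if (dn[1] < 1e-9) return(vals[nn[1]])
    w <- 1 / dn^power
    sum(w * vals[nn]) / sum(w)
  }, numeric(1))
  structure(list(parameter = parameter, values = out,
                 scale_mode = "per_specimen_range",
                 range = range(out)), class = "morphometric_map")
}

#' Element-volume-weighted mesh mean
#'
#' @param map A `morphometric_map`.
#' @param mesh The `tet_mesh` it lives on.
#' @param region Optional region name (or logical element filter).
#' @param weighted Volume-weighted (default) or unweighted mean.
#' @return Scalar mean.
#' @export
mesh_mean <- function(map, mesh, region = NULL, weighted = TRUE) {
  sel <- element_filter(mesh, region)
  if (!any(sel)) stop("empty element filter")
  if (weighted) {
    v <- mesh$element_volumes[sel]
    sum(map$values[sel] * v) / sum(v)
  } else mean(map$values[sel])
}

element_filter <- function(mesh, region) {
  if (is.null(region)) rep(TRUE, nrow(mesh$tetrahedra))
  else if (is.logical(region)) region
  else !is.na(mesh$element_region) & mesh$element_region %in% region
}

#' Dorsal/palmar concentration index of a morphometric map
#'
#' Splits the region's elements into dorsal and palmar halves by the plane
#' normal to the dorsopalmar axis through the region's volume-weighted
#' centroid, and returns the ratio of volume-weighted mean map values
#' (dorsal over palmar). Values above 1 indicate a dorsal concentration
#' (the adult pattern for BV/TV), below 1 a palmar concentration (the
#' infant pattern).
#'
#' @param map A `morphometric_map` (typically BV/TV).
#' @param mesh Its `tet_mesh`.
#' @param region Region name, default `"epiphysis"`.
#' @return Dimensionless ratio.
#' @export
dorsopalmar_index <- function(map, mesh, region = "epiphysis") {
  sel <- element_filter(mesh, region)
  if (!any(sel)) stop("no elements in region '", region, "'")
  v <- mesh$element_volumes[sel]
  y <- mesh$element_centroids[sel, 2]
  vals <- map$values[sel]
  yc <- sum(v * y) / sum(v)
  dorsal <- y < yc   # dim 2 index increases palmarly
  palmar <- !dorsal
  if (!any(dorsal) || !any(palmar)) stop("empty dorsal or palmar half")
  wmean <- function(sel2) sum(vals[sel2] * v[sel2]) / sum(v[sel2])
  wmean(dorsal) / wmean(palmar)
}

#' Export a morphometric map as a VTK unstructured grid
#'
#' Legacy ASCII VTK with per-element scalars; the colour limits are written
#' as field data (`scale_lo`, `scale_hi`), either the per-specimen map
#' range or a fixed range (the supplementary-style fixed BV/TV scale is
#' `c(0, 0.45)`).
#'
#' @param map A `morphometric_map`.
#' @param mesh Its `tet_mesh`.
#' @param path Output `.vtk` path.
#' @param scale `"per_specimen_range"` or `"fixed_range"`.
#' @param range Fixed colour limits when `scale = "fixed_range"`.
#' @return `path`, invisibly.
#' @export
export_colormap <- function(map, mesh, path,
                            scale = c("per_specimen_range", "fixed_range"),
                            range = c(0, 0.45)) {
  scale <- match.arg(scale)
  lims <- if (scale == "fixed_range") range else base::range(map$values)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open '", path, "' for writing: ", conditionMessage(e)))
  on.exit(close(con))
  wl <- function(...) writeLines(sprintf(...), con)
  wl("# vtk DataFile Version 3.0")
  wl("trabecula morphometric map: %s", map$parameter)
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  nv <- nrow(mesh$vertices)
  wl("POINTS %d double", nv)
  writeLines(apply(mesh$vertices, 1, function(p)
    sprintf("%.9g %.9g %.9g", p[1], p[2], p[3])), con)
  nt <- nrow(mesh$tetrahedra)
  wl("CELLS %d %d", nt, 5L * nt)
  writeLines(apply(mesh$tetrahedra - 1L, 1, function(t4)
    paste(c(4L, t4), collapse = " ")), con)
  wl("CELL_TYPES %d", nt)
  writeLines(rep("10", nt), con)
  wl("CELL_DATA %d", nt)
  wl("FIELD attributes 1")
  wl("scale_limits 1 2 double")
  wl("%.9g %.9g", lims[1], lims[2])
  wl("SCALARS %s double 1", map$parameter)
  wl("LOOKUP_TABLE default")
  writeLines(sprintf("%.9g", map$values), con)
  invisible(path)
}

#' Read back a VTK colour map written by [export_colormap()]
#'
#' @param path `.vtk` file.
#' @return List with `vertices`, `tetrahedra`, `values`, `scale_limits`,
#'   `parameter`.
#' @export
read_colormap <- function(path) {
  ln <- readLines(path)
  grab <- function(pat) grep(pat, ln)[1]
  np <- as.integer(sub("POINTS (\\d+).*", "\\1", ln[grab("^POINTS ")]))
  p0 <- grab("^POINTS ")
  verts <- matrix(scan(text = ln[(p0 + 1):(p0 + np)], quiet = TRUE),
                  ncol = 3, byrow = TRUE)
  c0 <- grab("^CELLS ")
  nt <- as.integer(sub("CELLS (\\d+).*", "\\1", ln[c0]))
  cells <- matrix(scan(text = ln[(c0 + 1):(c0 + nt)], quiet = TRUE),
                  ncol = 5, byrow = TRUE)[, 2:5, drop = FALSE] + 1L
  f0 <- grab("^scale_limits")
  lims <- scan(text = ln[f0 + 1], quiet = TRUE)
  s0 <- grab("^SCALARS ")
  param <- strsplit(ln[s0], " ")[[1]][2]
  vals <- scan(text = ln[(s0 + 2):(s0 + 1 + nt)], quiet = TRUE)
  list(vertices = verts, tetrahedra = cells, values = vals,
       scale_limits = lims, parameter = param)
}

#' Rasterise the mid-sagittal section of a morphometric map
#'
#' Returns the interpolated element values on a regular (proximodistal x
#' dorsopalmar) raster at the radioulnar mid-plane — the cross-section
#' layout used for whole-bone colour maps. `NA` where no element is close.
#'
#' @param map A `morphometric_map`.
#' @param mesh Its `tet_mesh`.
#' @param pixel Raster pixel size, mm.
#' @return Matrix (rows proximodistal, columns dorsopalmar) of map values.
#' @export
midsagittal_section <- function(map, mesh, pixel = NULL) {
  if (is.null(pixel)) pixel <- mesh$edge_length / 2
  cen <- mesh$element_centroids
  zmid <- (min(cen[, 3]) + max(cen[, 3])) / 2
  sel <- abs(cen[, 3] - zmid) <= mesh$edge_length
  if (!any(sel)) stop("no elements near the mid-sagittal plane")
  cs <- cen[sel, , drop = FALSE]
  vals <- map$values[sel]
  g1 <- seq(min(cs[, 1]), max(cs[, 1]), by = pixel)
  g2 <- seq(min(cs[, 2]), max(cs[, 2]), by = pixel)
  out <- matrix(NA_real_, length(g1), length(g2))
  lim2 <- (mesh$edge_length)^2
  for (i in seq_along(g1)) {
    d1 <- (cs[, 1] - g1[i])^2
    for (j in seq_along(g2)) {
      d <- d1 + (cs[, 2] - g2[j])^2
      m <- which.min(d)
      if (d[m] <= lim2) out[i, j] <- vals[m]
    }
  }
  out
}
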