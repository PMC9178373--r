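test_that("lattice tet mesh of a cube recovers its volume", {
  m <- voxel_volume(array(1L, c(40, 40, 40)), 0.05)  # 2 mm cube
  mesh <- mesh_inner_region(m, target_edge_length = 0.25)
  expect_lt(abs(sum(mesh$element_volumes) - 8) / 8, 0.05)
  expect_true(all(mesh$element_volumes > 0))
  # orientation consistency: signed volume of every tet is positive
  v <- mesh$vertices
  t4 <- mesh$tetrahedra
  sv <- vapply(seq_len(nrow(t4)), function(i) {
    a <- v[t4[i, 2], ] - v[t4[i, 1], ]
    b <- v[t4[i, 3], ] - v[t4[i, 1], ]
    cc <- v[t4[i, 4], ] - v[t4[i, 1], ]
    det(cbind(a, b, cc)) / 6
  }, numeric(1))
  expect_true(all(sv > 0))
})

test_that("mesh volume tracks the synthetic inner mask", {
  sp <- make_synthetic_metacarpal(200, seed = 2)
  ms <- separate_cortex(binarize(sp$volume))
  mesh <- mesh_inner_region(ms$inner_mask, 0.3)
  vox_vol <- sum(unclass(ms$inner_mask)) * 0.04^3
  expect_gt(sum(mesh$element_volumes) / vox_vol, 0.95)
  expect_lt(sum(mesh$element_volumes) / vox_vol, 1.05)
  expect_error(mesh_inner_region(voxel_volume(array(0L, c(8, 8, 8)), 0.1)),
               "empty")
})

make_samples <- function(nodes, values) {
  data.frame(x1 = nodes[, 1], x2 = nodes[, 2], x3 = nodes[, 3],
             bvtv = values, valid = TRUE)
}

test_that("interpolation preserves constants and bounds, tracks linear fields", {
  m <- voxel_volume(array(1L, c(40, 40, 40)), 0.05)
  mesh <- mesh_inner_region(m, 0.25)
  nodes <- as.matrix(expand.grid(seq(0, 2, 0.25), seq(0, 2, 0.25),
                                 seq(0, 2, 0.25)))
  cmap <- interpolate_to_mesh(make_samples(nodes, rep(0.37, nrow(nodes))),
                              mesh)
  expect_true(all(abs(cmap$values - 0.37) < 1e-12))
  lin <- 0.1 + 0.2 * nodes[, 1] + 0.05 * nodes[, 2]
  lmap <- interpolate_to_mesh(make_samples(nodes, lin), mesh)
  want <- 0.1 + 0.2 * mesh$element_centroids[, 1] +
    0.05 * mesh$element_centroids[, 2]
  expect_lt(max(abs(lmap$values - want) / want), 0.05)
  expect_gte(min(lmap$values), min(lin))
  expect_lte(max(lmap$values), max(lin))
  expect_error(interpolate_to_mesh(make_samples(nodes, lin)[0, ], mesh),
               "no valid samples")
})

test_that("mesh mean is a volume-weighted average", {
  m <- voxel_volume(array(1L, c(20, 20, 20)), 0.05)
  mesh <- mesh_inner_region(m, 0.5)
  map <- structure(list(parameter = "bvtv",
                        values = rep(0.2, nrow(mesh$tetrahedra)),
                        scale_mode = "per_specimen_range",
                        range = c(0.2, 0.2)), class = "morphometric_map")
  expect_equal(mesh_mean(map, mesh), 0.2)
  # two equal-volume elements with values 0.1 and 0.3 -> 0.2
  map$values <- rep(c(0.1, 0.3), length.out = nrow(mesh$tetrahedra))
  expect_equal(mesh_mean(map, mesh), 0.2)
  expect_error(mesh_mean(map, mesh, region = "epiphysis"), "empty")
})

test_that("mesh-mean BV/TV agrees with voxel counts on a phantom", {
  ph <- make_phantom(phantom_spec("plate", 0.025, 120, thickness = 0.25,
                                  period = 1.0))
  mask <- full_mask(ph$volume)
  grid <- build_grid(mask, spacing = 0.4, voi_diameter = 2.0)
  samples <- sample_grid(list(trabecular_bone = ph$volume,
                              inner_mask = mask), grid, fabric = FALSE)
  mesh <- mesh_inner_region(mask, 0.3)
  map <- interpolate_to_mesh(samples, mesh, "bvtv")
  expect_lt(abs(mesh_mean(map, mesh) - mean(as.vector(ph$volume))), 0.02)
})

test_that("dorsopalmar index reads map asymmetry correctly", {
  m <- voxel_volume(array(1L, c(30, 40, 30)), 0.05)
  mesh <- mesh_inner_region(m, 0.25)
  mesh$element_region <- rep("epiphysis", nrow(mesh$tetrahedra))
  sym <- structure(list(parameter = "bvtv",
                        values = rep(0.3, nrow(mesh$tetrahedra))),
                   class = "morphometric_map")
  expect_equal(dorsopalmar_index(sym, mesh), 1.0)
  # higher values dorsally (low dim-2 coordinate) -> index > 1
  grad <- structure(list(parameter = "bvtv",
                         values = 0.5 - 0.1 * mesh$element_centroids[, 2]),
                    class = "morphometric_map")
  expect_gt(dorsopalmar_index(grad, mesh), 1)
  # higher palmarly -> index < 1
  grad$values <- 0.1 + 0.1 * mesh$element_centroids[, 2]
  expect_lt(dorsopalmar_index(grad, mesh), 1)
})

test_that("VTK colour-map export round-trips with both scale modes", {
  m <- voxel_volume(array(1L, c(16, 16, 16)), 0.1)
  mesh <- mesh_inner_region(m, 0.4)
  vals <- seq(0.05, 0.4, length.out = nrow(mesh$tetrahedra))
  map <- structure(list(parameter = "bvtv", values = vals),
                   class = "morphometric_map")
  f <- tempfile(fileext = ".vtk")
  export_colormap(map, mesh, f, scale = "fixed_range", range = c(0, 0.45))
  back <- read_colormap(f)
  expect_equal(back$scale_limits, c(0, 0.45))
  expect_equal(back$values, vals, tolerance = 1e-7)
  expect_equal(nrow(back$tetrahedra), nrow(mesh$tetrahedra))
  export_colormap(map, mesh, f, scale = "per_specimen_range")
  expect_equal(read_colormap(f)$scale_limits, range(vals), tolerance = 1e-7)
})

test_that("mid-sagittal section rasterises the map", {
  m <- voxel_volume(array(1L, c(30, 20, 20)), 0.1)
  mesh <- mesh_inner_region(m, 0.4)
  map <- structure(list(parameter = "bvtv",
                        values = 0.1 + 0.1 * mesh$element_centroids[, 1]),
                   class = "morphometric_map")
  sec <- midsagittal_section(map, mesh)
  expect_true(any(is.finite(sec)))
  # values increase along the proximodistal rows
  rowmeans <- rowMeans(sec, na.rm = TRUE)
  expect_gt(cor(seq_along(rowmeans), rowmeans), 0.99)
})
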