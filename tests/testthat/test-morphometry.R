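test_that("background grid has exact spacing and matches enumeration", {
  # 10 mm solid cubic mask at 0.1 mm voxels
  m <- voxel_volume(array(1L, c(100, 100, 100)), 0.1)
  g <- build_grid(m, spacing = 2.5, voi_diameter = 5)
  # lattice anchored at the bounding-box corner: 5 nodes per axis at 0,2.5,..,10 -> partial spheres filtered
  nn <- as.matrix(dist(g$nodes))
  diag(nn) <- Inf
  expect_equal(min(nn), 2.5)
  # independent enumeration: nodes at 2.5 k inside [0,10] per axis with
  # >= 10% of the VOI sphere inside the cube
  cand <- expand.grid(x1 = 2.5 * 0:4, x2 = 2.5 * 0:4, x3 = 2.5 * 0:4)
  frac <- apply(cand, 1, function(p) {
    offs <- expand.grid(dx = -25:25, dy = -25:25, dz = -25:25)
    offs <- offs[rowSums(offs^2) <= 25^2, ]
    ctr <- p / 0.1 - 0.5
    inside <- (ctr[1] + offs$dx) >= 0 & (ctr[1] + offs$dx) <= 99 &
      (ctr[2] + offs$dy) >= 0 & (ctr[2] + offs$dy) <= 99 &
      (ctr[3] + offs$dz) >= 0 & (ctr[3] + offs$dz) <= 99
    mean(inside)
  })
  expect_equal(nrow(g$nodes), sum(frac >= 0.1))
})

test_that("grid rejects empty masks and survives degenerate spacing", {
  expect_error(build_grid(voxel_volume(array(0L, c(10, 10, 10)), 0.1)),
               "empty")
  m <- voxel_volume(array(1L, c(20, 20, 20)), 0.1)
  g <- build_grid(m, spacing = 50, voi_diameter = 2)
  expect_equal(nrow(g$nodes), 1L)
})

test_that("VOI BV/TV sampling covers the trivial and phantom cases", {
  vs <- 0.05
  solid <- make_phantom(phantom_spec("solid", vs, 48))$volume
  mask <- full_mask(solid)
  node <- c(1.2, 1.2, 1.2)
  expect_equal(sample_bvtv(solid, mask, node, 1.5)$bvtv, 1.0)
  empty <- make_phantom(phantom_spec("empty", vs, 48))$volume
  expect_equal(sample_bvtv(empty, mask, node, 1.5)$bvtv, 0.0)
  out <- sample_bvtv(empty, empty, node, 1.5)  # no mask voxels in sphere
  expect_false(out$valid)
  ph <- make_phantom(phantom_spec("plate", 0.025, 120, thickness = 0.25,
                                  period = 1.0))
  s <- sample_bvtv(ph$volume, full_mask(ph$volume), c(1.5, 1.5, 1.5), 2.5)
  expect_lt(abs(s$bvtv - 0.25), 0.02)
})

test_that("MIL scanner matches the brute-force crossing counter exactly", {
  dirs <- fibonacci_hemisphere(16)
  set.seed(4)
  rnd <- array(as.integer(runif(32^3) < 0.4), c(32, 32, 32))
  ph <- make_phantom(phantom_spec("plate", 0.05, 48, thickness = 0.25,
                                  period = 0.6))
  cases <- list(list(bone = rnd, mask = array(1L, dim(rnd)), r = 14),
                list(bone = unclass(ph$volume), mask = array(1L, c(48, 48, 48)),
                     r = 20))
  for (cs in cases) {
    ctr <- (dim(cs$bone) - 1) / 2
    got <- trabecula:::mil_scan_cpp(cs$bone, cs$mask, dim(cs$bone), ctr,
                                    cs$r, dirs, 1, 1, 2)
    want <- mil_bruteforce(cs$bone, cs$mask, ctr, cs$r, dirs)
    expect_equal(unname(got[, 1]), unname(want[, 1]))
    expect_equal(unname(got[, 2]), unname(want[, 2]))
  }
})

test_that("plate fabric is strongly anisotropic with in-plane long axis", {
  ph <- make_phantom(phantom_spec("plate", 0.025, 120, thickness = 0.25,
                                  period = 1.0))
  fr <- mil_fabric(ph$volume, full_mask(ph$volume), c(1.5, 1.5, 1.5),
                   voi_diameter = 2.5)
  expect_true(fr$valid)
  expect_gte(fr$da, 0.8)
  expect_lte(fr$da, 1)
  # plates repeat along axis 1: the major MIL axis lies in the plate plane
  expect_lt(abs(fr$eigenvectors[1, 1]), sin(5 * pi / 180))
  # eigenvalues sorted descending, tensor symmetric
  expect_true(all(diff(fr$eigenvalues) <= 0))
  expect_equal(fr$mil_tensor, t(fr$mil_tensor))
})

test_that("isotropic foam fabric has low anisotropy over seeds", {
  das <- sapply(1:6, function(sd) {
    f <- make_phantom(phantom_spec("sphere_foam", 0.05, 48,
                                   target_bvtv = 0.3, seed = sd))
    mil_fabric(f$volume, full_mask(f$volume), c(1.2, 1.2, 1.2),
               voi_diameter = 2.0)$da
  })
  expect_lte(mean(das), 0.15)
  expect_true(all(das >= 0 & das <= 1))
})

test_that("fabric flags invalid VOIs instead of failing", {
  vs <- 0.05
  solid <- make_phantom(phantom_spec("solid", vs, 48))$volume
  fr <- mil_fabric(solid, full_mask(solid), c(1.2, 1.2, 1.2), 1.5)
  expect_false(fr$valid)
  expect_match(fr$reason, "single phase")
  empty <- make_phantom(phantom_spec("empty", vs, 48))$volume
  fr2 <- mil_fabric(empty, full_mask(empty), c(1.2, 1.2, 1.2), 1.5)
  expect_false(fr2$valid)
})

test_that("DA is invariant under 90-degree rotation and eigenvectors follow", {
  f <- make_phantom(phantom_spec("plate", 0.05, 48, thickness = 0.2,
                                 period = 0.6, axis = c(0, 1, 0)))
  mask <- full_mask(f$volume)
  ctr <- c(1.2, 1.2, 1.2)
  fr <- mil_fabric(f$volume, mask, ctr, 2.0)
  rot <- rotate90_pd(f$volume)
  fr_rot <- mil_fabric(rot, full_mask(rot), ctr, 2.0)
  expect_lt(abs(fr$da - fr_rot$da), 0.02)
  # plate normal (minor axis) rotates from dim 2 into dim 3
  v3 <- abs(fr$eigenvectors[, 3])
  v3r <- abs(fr_rot$eigenvectors[, 3])
  expect_gt(v3[2], 0.98)
  expect_gt(v3r[3], 0.98)
})

test_that("local thickness reproduces slabs, balls and plate marrow", {
  # slab of 11 voxels spanning the volume
  fg <- array(FALSE, c(40, 40, 40))
  fg[, , 10:20] <- TRUE
  th <- trabecula:::local_thickness_cpp(fg, dim(fg))
  expect_true(all(abs(th[fg] - 11) <= 0.5))
  # single ball radius 8 (discrete EDT underestimates sphere diameters by
  # about a voxel)
  d <- as.matrix(expand.grid(1:40, 1:40, 1:40)) - 20.5
  ball <- array(rowSums(d^2) <= 64, c(40, 40, 40))
  thb <- trabecula:::local_thickness_cpp(ball, dim(ball))
  expect_lt(abs(max(thb) - 16), 2.5)
  # plate phantom marrow: map ~= period - thickness
  ph <- make_phantom(phantom_spec("plate", 0.025, 120, thickness = 0.25,
                                  period = 1.0))
  marrow <- voxel_volume(1L - unclass(ph$volume), 0.025)
  mp <- local_thickness_map(marrow)
  vals <- as_arr <- unclass(mp)[unclass(marrow) == 1]
  expect_lt(abs(mean(vals) - 0.75), 0.025)  # one voxel
})

test_that("empty phase yields an empty thickness map", {
  e <- voxel_volume(array(0L, c(16, 16, 16)), 0.1)
  expect_true(all(unclass(local_thickness_map(e)) == 0))
})

test_that("regional thickness summary matches plate closed forms", {
  ph <- make_phantom(phantom_spec("plate", 0.02, c(150, 60, 60),
                                  thickness = 0.2, period = 1.0))
  rt <- region_thickness(ph$volume, full_mask(ph$volume))
  expect_lt(abs(rt$tb_th - 0.2), 0.02)   # one voxel
  expect_lt(abs(rt$tb_sp - 0.8), 0.02)
  expect_lt(abs(rt$tb_n - 1.0), 0.08)
  # the defining identity holds to machine precision
  expect_equal(rt$tb_n * (rt$tb_th + rt$tb_sp), 1.0, tolerance = 1e-14)
})

test_that("thickness scales linearly with voxel size metadata", {
  ph <- make_phantom(phantom_spec("plate", 0.05, 48, thickness = 0.25,
                                  period = 0.6))
  a <- unclass(ph$volume)
  r1 <- region_thickness(voxel_volume(a, 0.05), full_mask(ph$volume))
  r2 <- region_thickness(voxel_volume(a, 0.10),
                         voxel_volume(array(1L, dim(a)), 0.10))
  expect_equal(r2$tb_th, 2 * r1$tb_th)
  expect_equal(r2$tb_sp, 2 * r1$tb_sp)
  expect_equal(r2$tb_n, r1$tb_n / 2)
})

test_that("single-phase regions raise informative errors", {
  vs <- 0.05
  solid <- make_phantom(phantom_spec("solid", vs, 32))$volume
  expect_error(region_thickness(solid, full_mask(solid)), "marrow")
  empty <- make_phantom(phantom_spec("empty", vs, 32))$volume
  expect_error(region_thickness(empty, full_mask(empty)), "bone")
})

test_that("bvtv and DA stay in bounds on random volumes", {
  set.seed(99)
  for (i in 1:5) {
    vol <- array(as.integer(runif(24^3) < runif(1, 0.2, 0.8)), c(24, 24, 24))
    v <- voxel_volume(vol, 0.05)
    m <- full_mask(v)
    s <- sample_bvtv(v, m, c(0.6, 0.6, 0.6), 1.0)
    expect_gte(s$bvtv, 0)
    expect_lte(s$bvtv, 1)
    fr <- mil_fabric(v, m, c(0.6, 0.6, 0.6), 1.0, n_directions = 64)
    if (fr$valid) {
      expect_gte(fr$da, 0)
      expect_lte(fr$da, 1)
    }
  }
})
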