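test_that("binarization recovers a clean two-level image exactly and is idempotent", {
  set.seed(2)
  truth <- array(as.integer(runif(30^3) < 0.4), c(30, 30, 30))
  grey <- voxel_volume(truth * 255, 0.05)
  for (m in c("global_otsu", "local_cluster")) {
    b <- binarize(grey, m, window = 16)
    expect_identical(as.vector(unclass(b)), as.vector(truth))
  }
  b2 <- binarize(binarize(grey), "global_otsu")
  expect_identical(as.vector(unclass(b2)), as.vector(truth))
  expect_error(binarize(voxel_volume(array(7, c(8, 8, 8)), 0.05)),
               "no threshold")
})

test_that("binarization of a blurred synthetic specimen matches truth labels", {
  sp <- make_synthetic_metacarpal(200, seed = 2)
  truth_bone <- unclass(sp$labels) %in% c(1L, 2L)
  dim(truth_bone) <- dim(sp$labels)
  b <- binarize(sp$volume, "local_cluster")
  expect_gte(dice(unclass(b) == 1, truth_bone), 0.95)
  b2 <- binarize(sp$volume, "global_otsu")
  expect_gte(dice(unclass(b2) == 1, truth_bone), 0.95)
})

test_that("cortex separation isolates the interior of a hollow tube", {
  tube <- hollow_tube()
  ms <- separate_cortex(tube, closing_radius = 0.3)
  inner <- unclass(ms$inner_mask) == 1
  trab <- unclass(ms$trabecular_bone) == 1
  cort <- unclass(ms$cortical_mask) == 1
  expect_equal(sum(trab), 0)  # empty interior: no trabecular bone
  expect_gt(sum(inner), 0)
  # disjointness and nesting
  expect_equal(sum(cort & inner), 0)
  expect_true(all(which(trab) %in% which(inner)))
  # interior voxels lie inside the tube wall
  ctr <- (dim(tube)[2] + 1) / 2
  idx <- which(inner, arr.ind = TRUE)
  rr <- sqrt((idx[, 2] - ctr)^2 + (idx[, 3] - ctr)^2)
  expect_true(all(rr < 15))
})

test_that("a solid block has no enclosed interior", {
  solid <- voxel_volume(array(1L, c(30, 30, 30)), 0.1)
  solid_arr <- unclass(solid)
  solid_arr[c(1, 30), , ] <- 0L
  solid_arr[, c(1, 30), ] <- 0L
  solid_arr[, , c(1, 30)] <- 0L
  expect_error(separate_cortex(voxel_volume(solid_arr, 0.1)),
               "no enclosed interior")
})

test_that("cortex separation recovers the synthetic inner region", {
  sp <- make_synthetic_metacarpal(200, seed = 2)
  ms <- separate_cortex(binarize(sp$volume))
  lab <- unclass(sp$labels)
  expect_gte(dice(unclass(ms$inner_mask) == 1, lab == 2L | lab == 3L), 0.9)
  # no cortex misassigned as trabecular bone
  trab <- unclass(ms$trabecular_bone) == 1
  expect_lt(sum(trab & lab == 1L) / sum(trab), 0.02)
})

test_that("masks partition the bounding volume", {
  sp <- make_synthetic_metacarpal(200, seed = 6)
  ms <- separate_cortex(binarize(sp$volume))
  cort <- unclass(ms$cortical_mask) == 1
  inner <- unclass(ms$inner_mask) == 1
  expect_equal(sum(cort & inner), 0)
})

test_that("cortex separation is equivariant under 90-degree rotation", {
  sp <- make_synthetic_metacarpal(60, seed = 9, epiphysis = FALSE)
  bin <- binarize(sp$volume)
  ms <- separate_cortex(bin)
  ms_rot <- separate_cortex(rotate90_pd(bin))
  want <- unclass(rotate90_pd(ms$inner_mask)) == 1
  got <- unclass(ms_rot$inner_mask) == 1
  expect_gte(dice(want, got), 0.999)
})

test_that("growth-plate split finds the gap and conserves voxels", {
  sp <- make_synthetic_metacarpal(50, seed = 11, epiphysis = TRUE)
  bin <- binarize(sp$volume)
  spl <- split_epiphysis(bin)
  gap_centre <- mean(sp$metadata$gap_slices)
  expect_lte(abs(spl$split_slice - gap_centre), 2)
  expect_identical(unclass(spl$metaphyseal) + unclass(spl$epiphyseal),
                   unclass(bin))
  # fused specimen: no gap
  fused <- make_synthetic_metacarpal(200, seed = 3)
  expect_error(split_epiphysis(binarize(fused$volume)), "fused")
  # explicit override partitions exactly
  spl2 <- split_epiphysis(bin, split_slice = 100)
  expect_identical(unclass(spl2$metaphyseal) + unclass(spl2$epiphyseal),
                   unclass(bin))
  expect_equal(sum(unclass(spl2$epiphyseal)[1:100, , ]), 0)
})

test_that("region cutting follows the 70% rule and explicit boundaries", {
  # 300 bone-bearing slices starting at slice 0
  a <- array(0L, c(300, 40, 40))
  a[, 15:25, 15:25] <- 1L
  a[1:40, 5:35, 5:35] <- 1L  # broad base so the breadth criterion fires
  vol <- voxel_volume(a, 0.1)
  part <- cut_regions(vol)
  expect_equal(part$intervals$metaphysis[1], 210)
  expect_equal(part$intervals$base[1], 0)
  expect_equal(part$intervals$metaphysis[2], 300)
  # explicit boundaries returned verbatim, half-open, covering 0-300
  p2 <- cut_regions(vol, boundaries = c(0, 60, 210, 280, 300))
  expect_equal(p2$intervals$base, c(0, 60))
  expect_equal(p2$intervals$shaft, c(60, 210))
  expect_equal(p2$intervals$metaphysis, c(210, 280))
  expect_equal(p2$intervals$epiphysis, c(280, 300))
  lens <- sum(vapply(p2$intervals, diff, numeric(1)))
  expect_equal(lens, 300)
  expect_error(cut_regions(vol, boundaries = c(0, 210, 60, 300)),
               "out of order")
})

test_that("truth epiphysis voxels fall inside the epiphysis interval", {
  sp <- make_synthetic_metacarpal(200, seed = 3)  # fused adult
  bin <- binarize(sp$volume)
  part <- cut_regions(bin, epiphysis_start = sp$metadata$gap_center)
  lab <- unclass(sp$labels)
  epi_truth <- sp$truth$epiphysis$interval
  sl <- region_slices(part, "epiphysis")
  inner_epi <- which(apply(lab == 2L, 1, any))
  inner_epi <- inner_epi[inner_epi - 1 >= epi_truth[1]]
  expect_true(all(inner_epi %in% sl))
})
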