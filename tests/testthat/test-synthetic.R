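test_that("age binning follows the half-open category bounds", {
  expect_equal(as.character(assign_age_category(4)), "Neonate")
  expect_equal(as.character(assign_age_category(96)), "Juvenile")
  expect_equal(as.character(assign_age_category(144)), "Adult")
  expect_equal(as.character(assign_age_category(c(0, 7, 36, 72))),
               c("Neonate", "Infant1", "Infant2", "Juvenile"))
  expect_error(assign_age_category(-1), "negative")
})

test_that("neonates have no ossified epiphysis; fused adults always do", {
  neo <- make_synthetic_metacarpal(4, seed = 1)
  expect_false(neo$metadata$has_epiphysis)
  expect_null(neo$truth$epiphysis)
  # every bone voxel lies proximal to the growth plate
  lab <- unclass(neo$labels)
  bone_slices <- which(apply(lab == 1L | lab == 2L, 1, any))
  expect_true(all(bone_slices - 1 <= neo$metadata$gap_center))
  ad <- make_synthetic_metacarpal(180, seed = 1)
  expect_true(ad$metadata$fused)
  expect_true(ad$metadata$has_epiphysis)
  expect_length(ad$metadata$gap_slices, 0)
})

test_that("adult epiphysis concentrates bone dorsally in the truth labels", {
  ad <- make_synthetic_metacarpal(180, seed = 4)
  lab <- unclass(ad$labels)
  iv <- ad$truth$epiphysis$interval
  sl <- (iv[1] + 1):iv[2]
  ny <- dim(lab)[2]
  dors <- lab[sl, 1:(ny %/% 2), ]
  palm <- lab[sl, (ny %/% 2 + 1):ny, ]
  bv <- function(x) sum(x == 2L) / sum(x == 2L | x == 3L)
  expect_gt(bv(dors), bv(palm))
  # infants show the opposite, distopalmar pattern
  inf <- make_synthetic_metacarpal(60, seed = 4, epiphysis = TRUE)
  labi <- unclass(inf$labels)
  ivi <- inf$truth$epiphysis$interval
  sli <- (ivi[1] + 1):ivi[2]
  expect_lt(bv(labi[sli, 1:(ny %/% 2), ]), bv(labi[sli, (ny %/% 2 + 1):ny, ]))
})

test_that("generation is bit-identical under the same seed", {
  a <- make_synthetic_metacarpal(100, seed = 5)
  b <- make_synthetic_metacarpal(100, seed = 5)
  expect_identical(unclass(a$volume), unclass(b$volume))
  expect_identical(unclass(a$labels), unclass(b$labels))
  cc <- make_synthetic_metacarpal(100, seed = 6)
  expect_false(identical(unclass(a$volume), unclass(cc$volume)))
})

test_that("labels and greyscale are co-registered with a closed cortex", {
  sp <- make_synthetic_metacarpal(150, seed = 7)
  expect_identical(dim(sp$volume), dim(sp$labels))
  lab <- unclass(sp$labels)
  # cortex is one 26-connected component enclosing the inner region
  cl <- trabecula:::label_components_cpp(lab == 1L, dim(lab), TRUE)
  expect_equal(max(cl), 1L)
  # inner voxels never touch the exterior: every inner cross-section is
  # surrounded by cortex
  for (z in which(apply(lab == 2L | lab == 3L, 1, any))) {
    sl <- lab[z, , ]
    inner_j <- which(apply(sl == 2L | sl == 3L, 1, any))
    cort_j <- which(apply(sl == 1L, 1, any))
    expect_true(min(cort_j) < min(inner_j) && max(cort_j) > max(inner_j))
  }
})

test_that("truth Tb.N satisfies the defining identity in every region", {
  sp <- make_synthetic_metacarpal(200, seed = 8)
  for (tr in sp$truth) {
    if (is.null(tr)) next
    expect_equal(tr$tb_n * (tr$tb_th + tr$tb_sp), 1.0, tolerance = 1e-12)
  }
})

test_that("default cohort mirrors the study's availability structure", {
  tab <- make_cohort(seed = 3)
  expect_equal(length(unique(tab$specimen_id)), 52)
  counts <- table(tab$age_category[tab$region == "base"])
  expect_equal(as.integer(counts), c(4, 9, 12, 9, 18))
  # neonates never carry an epiphysis record
  neo <- tab[tab$age_category == "Neonate", ]
  expect_false("epiphysis" %in% neo$region)
  # adults always do
  ad <- tab[tab$age_category == "Adult", ]
  expect_equal(sum(ad$region == "epiphysis"), 18)
  # both species present
  expect_setequal(unique(tab$species), c("Ggg", "Gbb"))
})

test_that("zero-noise cohorts reproduce the trajectory means exactly", {
  tr <- default_trajectory()
  tr$tb_th_sd <- 0
  tr$tb_sp_sd <- 0
  tr$da_sd <- 0
  tab <- make_cohort(c(2, 2, 2, 2, 2), trajectory = tr, seed = 5)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    want <- tr[tr$age_category == as.character(row$age_category) &
                 tr$region == row$region, ]
    expect_equal(row$tb_th, want$tb_th_mean)
    expect_equal(row$tb_sp, want$tb_sp_mean)
    expect_equal(row$bvtv, want$bvtv_mean)
  }
})

test_that("cohort category means are stable across seeds", {
  # different seeds draw different specimens but the same per-category
  # distribution: means agree within 3 standard errors
  tr <- default_trajectory()
  t1 <- make_cohort(c(4, 30, 4, 4, 4), seed = 101)
  t2 <- make_cohort(c(4, 30, 4, 4, 4), seed = 202)
  pick <- function(t) t$tb_th[t$age_category == "Infant1" & t$region == "base"]
  a <- pick(t1); b <- pick(t2)
  expect_false(identical(a, b))
  se <- sqrt(sd(a)^2 / length(a) + sd(b)^2 / length(b))
  expect_lt(abs(mean(a) - mean(b)), 3 * se + 1e-12)
  # and converge to the trajectory mean at large n (law of large numbers)
  t3 <- make_cohort(c(2, 200, 2, 2, 2), seed = 77)
  m <- mean(pick(t3))
  want <- tr$tb_th_mean[tr$age_category == "Infant1" & tr$region == "base"]
  expect_lt(abs(m - want), 3 * 0.02 / sqrt(200))
})

test_that("cohort specimens can be written to and read from disk", {
  co <- make_cohort(c(1, 1, 1, 1, 1), seed = 9, render = "image")
  dir <- tempfile()
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort_manifest.csv")))
  expect_equal(nrow(man), 5)
  sp <- co$specimens[[1]]
  back <- read_tiff_stack(man$grey_path[1], voxel_size = 0.04, scale = FALSE)
  expect_identical(dim(back), dim(sp$volume))
  expect_lt(max(abs(unclass(back) - unclass(sp$volume))), 1.01)
  side <- jsonlite::read_json(man$sidecar_path[1])
  expect_equal(side$metadata$age_months, sp$metadata$age_months)
})
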