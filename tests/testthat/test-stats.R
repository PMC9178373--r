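test_that("Kruskal-Wallis handles ties, identical groups and known data", {
  out <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(out$H, 0)
  expect_equal(out$p, 1)
  # hand-computed rank formula, no ties: H = 12/(N(N+1)) sum n_i Rbar_i^2 - 3(N+1)
  x <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("a", "b", "c"), each = 3)
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  H_manual <- 12 / (9 * 10) * sum(3 * rbar^2) - 3 * 10
  out2 <- kruskal_wallis(x, g)
  expect_equal(out2$H, H_manual)
  expect_equal(out2$df, 2)
  expect_lt(out2$p, 0.05)
})

test_that("Kruskal-Wallis detects the generated age trend reliably", {
  hits <- sapply(1:40, function(sd) {
    tab <- make_cohort(rep(10, 5), seed = sd)
    sub <- tab[tab$region == "base", ]
    kruskal_wallis(sub$bvtv, sub$age_category)$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
})

test_that("Nemenyi matrix is symmetric with sensible extremes", {
  x <- c(1, 2, 3, 4, 1.1, 2.1, 3.1, 4.1, 50, 60, 70, 80)
  g <- rep(c("a", "b", "c"), each = 4)
  P <- nemenyi_posthoc(x, g)
  expect_identical(P, t(P))
  expect_equal(unname(diag(P)), rep(1, 3))
  # the two similar groups are the least distinguishable pair
  expect_equal(unname(P["a", "b"]), max(P[upper.tri(P)]))
  # identical groups: off-diagonal p near 1
  P2 <- nemenyi_posthoc(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_gt(P2["a", "b"], 0.95)
  # studentized-range oracle for the two-group statistic, recomputed by hand
  rk <- rank(x)
  rbar <- tapply(rk, g, mean)
  n <- 4; N <- 12
  q <- abs(rbar["a"] - rbar["c"]) / sqrt(N * (N + 1) / 12 * (2 / n)) * sqrt(2)
  expect_equal(unname(P["a", "c"]),
               unname(ptukey(q, nmeans = 3, df = Inf, lower.tail = FALSE)))
})

test_that("small groups are flagged, not fatal", {
  x <- c(1, 5, 2, 6, 9)
  g <- c("a", "a", "b", "b", "c")
  P <- nemenyi_posthoc(x, g)
  expect_true(all(is.na(P["c", c("a", "b")])))
  expect_false(is.na(P["a", "b"]))
})

test_that("Shapiro gate separates normal from skewed samples", {
  verdicts <- sapply(1:50, function(sd) {
    set.seed(sd)
    c(normal = shapiro_gate(rnorm(500))$normal,
      expo = shapiro_gate(rexp(500))$normal)
  })
  expect_gte(mean(verdicts["normal", ]), 0.9)
  expect_lte(mean(verdicts["expo", ]), 0.1)
  degen <- shapiro_gate(rep(1, 10))
  expect_true(degen$degenerate)
  expect_false(degen$normal)
})

test_that("inter-region ratios use the fixed orientation and flag gaps", {
  rec <- data.frame(region = c("base", "metaphysis", "epiphysis"),
                    bvtv = c(0.3, 0.2, 0.1), da = c(0.5, 0.5, 0.5),
                    tb_th = c(0.2, 0.2, 0.2), tb_sp = c(0.6, 0.6, 0.6),
                    tb_n = c(1.25, 1.25, 1.25))
  r <- compute_ratios(rec)
  expect_equal(r$bvtv_base_metaphysis, 1.5)
  expect_equal(r$bvtv_base_epiphysis, 3)
  expect_equal(r$da_base_metaphysis, 1)
  # antisymmetry: forward x reverse = 1
  rev <- rec[c(2, 1, 3), ]
  rev$region <- c("base", "metaphysis", "epiphysis")
  r2 <- compute_ratios(rev)
  expect_equal(r$bvtv_base_metaphysis * r2$bvtv_base_metaphysis, 1)
  # unfused specimen: only base/metaphysis defined
  r3 <- compute_ratios(rec[1:2, ])
  expect_true(is.na(r3$bvtv_base_epiphysis))
  expect_false(is.na(r3$bvtv_base_metaphysis))
  expect_error(compute_ratios(rec[1, ]), "two regions")
  # zero denominator flagged, not infinite
  rec$bvtv[2] <- 0
  expect_true(is.na(compute_ratios(rec)$bvtv_base_metaphysis))
})

test_that("PCA centring, scaling, sign convention and reconstruction", {
  tab <- make_cohort(rep(6, 5), seed = 13)
  rep_bm <- run_pca(tab, "base_metaphysis")
  expect_equal(ncol(rep_bm$loadings), 10)
  # proportions non-increasing and summing to 1
  expect_true(all(diff(rep_bm$prop_variance) <= 1e-12))
  expect_equal(sum(rep_bm$prop_variance), 1)
  # sign convention: largest-magnitude loading entry positive
  for (j in seq_len(ncol(rep_bm$loadings))) {
    col <- rep_bm$loadings[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }
  # reconstruction: scores %*% t(loadings) equals the scaled matrix
  wide <- trabecula:::cohort_wide(tab, c("base", "metaphysis"),
                                  c("bvtv", "da", "tb_th", "tb_n", "tb_sp"))
  x <- scale(as.matrix(wide[, -1]))
  got <- as.matrix(rep_bm$scores[, -1]) %*% t(rep_bm$loadings)
  expect_equal(unname(got), unname(x[, rownames(rep_bm$loadings)]),
               tolerance = 1e-9)
  # epiphysis analysis uses complete cases only
  rep_ep <- run_pca(tab, "epiphysis")
  expect_equal(ncol(rep_ep$loadings), 5)
  expect_lt(rep_ep$n, length(unique(tab$specimen_id)))
})

test_that("constant columns are dropped with a warning", {
  tab <- make_cohort(rep(4, 5), seed = 21)
  tab$da <- 0.5
  expect_warning(rep_bm <- run_pca(tab, "base_metaphysis"), "constant")
  expect_equal(ncol(rep_bm$loadings), 8)
})

test_that("run_study produces the full report on a structured cohort", {
  tab <- make_cohort(c(2, 8, 8, 8, 8), seed = 31)
  rep <- run_study(tab)
  # strong generated age trends: pooled omnibus significant for BV/TV,
  # Tb.Th and Tb.N in base and metaphysis
  for (v in c("bvtv", "tb_th", "tb_n")) {
    for (rg in c("base", "metaphysis")) {
      row <- rep$pooled_age[rep$pooled_age$variable == v &
                              rep$pooled_age$region == rg, ]
      expect_lt(row$p, 0.05)
    }
  }
  # pairwise table covers all category pairs: 5 categories -> 10 pairs
  pw <- rep$pooled_pairwise
  expect_equal(sum(pw$variable == "bvtv" & pw$region == "base"), 10)
  expect_true(all(pw$p >= 0 & pw$p <= 1, na.rm = TRUE))
  # neonates merged into Infant 1 for the interspecific tests
  expect_true(any(rep$interspecific$age_category == "Neonate+Infant1"))
  # report writes cleanly
  dir <- tempfile()
  write_study_report(rep, dir)
  expect_true(file.exists(file.path(dir, "pooled_age.csv")))
  expect_true(file.exists(file.path(dir, "pca_base_metaphysis_loadings.csv")))
})

test_that("a cohort without epiphyses reports the gap explicitly", {
  tab <- make_cohort(rep(5, 5), seed = 41)
  tab <- tab[tab$region != "epiphysis", ]
  rep <- run_study(tab)
  expect_true(any(grepl("epiphysis", rep$notes)))
  expect_false("epiphysis" %in% rep$pooled_age$region)
})

test_that("interspecific flags appear when a species offset is generated", {
  trajs <- list(Ggg = default_trajectory(species_offset = 0.06),
                Gbb = default_trajectory())
  tab <- make_cohort(rep(10, 5), trajectory = trajs, seed = 51)
  rep <- run_study(tab)
  hits <- rep$interspecific[rep$interspecific$variable == "tb_th" &
                              rep$interspecific$region == "base", ]
  expect_gte(sum(hits$significant, na.rm = TRUE), 1)
})
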