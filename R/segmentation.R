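#' Binarize a greyscale volume
#'
#' `global_otsu` thresholds the whole volume at the maximum between-class
#' variance. `local_cluster` performs two-class (1D k-means) clustering of
#' intensities within overlapping subwindows and majority-votes the
#' overlapping decisions, which adapts the threshold to local intensity
#' drift. Already-binary input is returned unchanged. Both methods are
#' deterministic.
#'
#' @param grey Greyscale `voxel_volume`.
#' @param method `"global_otsu"` or `"local_cluster"`.
#' @param window Subwindow edge length in voxels (local_cluster).
#' @param overlap Fractional overlap between adjacent windows (local_cluster).
#' @return Binary `voxel_volume` (1 = bone).
#' @export
binarize <- function(grey, method = c("global_otsu", "local_cluster"),
                     window = 50, overlap = 0.5) {
  method <- match.arg(method)
  a <- as_array3(grey)
  if (is_binary(grey)) return(voxel_volume(a, voxel_size(grey)))
  rng <- range(a)
  if (diff(rng) < .Machine$double.eps)
    stop("constant-intensity volume: no threshold exists")
  gthr <- otsu_threshold(as.vector(a))
  if (method == "global_otsu") {
    out <- array(as.integer(a > gthr), dim(a))
    return(voxel_volume(out, voxel_size(grey)))
  }
  d <- dim(a)
  votes <- array(0, d)
  cnt <- array(0, d)
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  starts <- function(n) {
    if (n <= window) return(1L)
    s <- seq(1L, n - window + 1L, by = step)
    unique(c(s, n - window + 1L))
  }
  for (i0 in starts(d[1])) for (j0 in starts(d[2])) for (k0 in starts(d[3])) {
    ii <- i0:min(d[1], i0 + window - 1L)
    jj <- j0:min(d[2], j0 + window - 1L)
    kk <- k0:min(d[3], k0 + window - 1L)
    v <- a[ii, jj, kk]
    if (diff(range(v)) < 1e-9) {
      bone <- rep(as.numeric(v[1] > gthr), length(v))
    } else {
      thr <- kmeans2_threshold(as.vector(v))
      bone <- as.numeric(v > thr)
    }
    votes[ii, jj, kk] <- votes[ii, jj, kk] + bone
    cnt[ii, jj, kk] <- cnt[ii, jj, kk] + 1
  }
  frac <- votes / cnt
  out <- array(0L, d)
  out[frac > 0.5] <- 1L
  ties <- abs(frac - 0.5) < 1e-12
  out[ties] <- as.integer(a[ties] > gthr)
  voxel_volume(out, voxel_size(grey))
}

# Otsu threshold on a 256-bin histogram; returns an intensity value
otsu_threshold <- function(v) {
  rng <- range(v)
  br <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(v, br, all.inside = TRUE), 256)
  p <- h / sum(h)
  centers <- (br[-257] + br[-1]) / 2
  w1 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[256]
  sb <- (mu_t * w1 - mu)^2 / (w1 * (1 - w1))
  sb[!is.finite(sb)] <- 0
  centers[which.max(sb)]
}

# deterministic 1D two-means threshold (midpoint fixed-point iteration)
kmeans2_threshold <- function(v) {
  thr <- mean(range(v))
  for (i in 1:50) {
    lo <- v <= thr
    new <- (mean(v[lo]) + mean(v[!lo])) / 2
    if (!is.finite(new) || abs(new - thr) < 1e-9) break
    thr <- new
  }
  thr
}

#' Separate the cortical shell from the inner trabecular region
#'
#' The whole-bone solid is recovered by morphologically closing the binary
#' bone and filling enclosed cavities; its boundary is the periosteal
#' surface. The cortical band depth is estimated per slice from the bone
#' occupancy profile by depth below the surface (within a window of
#' neighbouring slices, occupancy stays near 1 through the compact shell and
#' drops to the trabecular fill fraction beyond it). The inner mask is the
#' enclosed interior beyond that band; trabecular bone is the bone phase
#' inside the inner mask.
#'
#' @param binary Binary bone `voxel_volume` with a closed outer shell.
#' @param closing_radius Morphological closing radius, mm.
#' @param occupancy Occupancy level (fraction of solid voxels that are bone)
#'   down to which a depth layer is still considered cortical.
#' @param window Half-width, in slices, of the proximodistal window used for
#'   the per-slice depth profile; should span at least one trabecular
#'   period.
#' @param band_margin Extra erosion (voxels) beyond the estimated band,
#'   guarding against the filled solid overhanging the bone surface.
#' @return A `mask_set` list: `cortical_mask`, `inner_mask`,
#'   `trabecular_bone` (binary `voxel_volume`s, pairwise disjoint except
#'   `trabecular_bone` inside `inner_mask`), plus the per-slice band depth
#'   estimate `band_voxels`.
#' @export
separate_cortex <- function(binary, closing_radius = 0.3, occupancy = 0.75,
                            window = 12L, band_margin = 1) {
  if (!is_binary(binary)) stop("separate_cortex needs a binary volume")
  vs <- voxel_size(binary)
  d <- dim(binary)
  bone <- as_logical3(binary)
  r <- closing_radius / vs
  # closing: dilate then erode, via distance transforms
  d2bone <- sq_edt_cpp(!bone, d)
  dil <- array(d2bone <= r * r, d)
  # the EDT treats the volume faces as phase continuation; clear the dilated
  # mask there so the erosion shrinks from the faces and cannot seal
  # exterior pockets (specimens are assumed surrounded by background)
  dil[c(1L, d[1]), , ] <- FALSE
  dil[, c(1L, d[2]), ] <- FALSE
  dil[, , c(1L, d[3])] <- FALSE
  d2out <- sq_edt_cpp(dil, d)
  closed <- array(d2out > r * r, d)
  closed <- closed | bone  # closing never removes original foreground
  ext <- flood_exterior_cpp(closed, d)
  solid <- array(!ext, d)
  dist_in <- sqrt(sq_edt_cpp(solid, d))
  dim(dist_in) <- d

  # per-slice bone-occupancy-by-depth profile
  dmax <- 40L
  db <- pmin(ceiling(dist_in), dmax)
  nz <- d[1]
  cnt_tot <- matrix(0, nz, dmax)
  cnt_bone <- matrix(0, nz, dmax)
  for (z in seq_len(nz)) {
    s <- solid[z, , ]
    if (!any(s)) next
    dep <- db[z, , ][s]
    bn <- bone[z, , ][s]
    cnt_tot[z, ] <- tabulate(dep, dmax)
    cnt_bone[z, ] <- tabulate(dep[bn], dmax)
  }
  band <- rep(NA_real_, nz)
  for (z in seq_len(nz)) {
    w <- max(1, z - window):min(nz, z + window)
    tot <- colSums(cnt_tot[w, , drop = FALSE])
    bn <- colSums(cnt_bone[w, , drop = FALSE])
    if (sum(tot) == 0) next
    frac <- ifelse(tot > 0, bn / tot, 0)
    # the filled solid can overhang the bone surface by a voxel or two, so
    # allow the compact band to start up to 3 layers below the surface
    k0 <- which(frac >= occupancy & tot > 0)[1]
    if (is.na(k0) || k0 > 3) {
      band[z] <- 1
    } else {
      k <- k0
      while (k < dmax && tot[k + 1] > 0 && frac[k + 1] >= occupancy)
        k <- k + 1
      band[z] <- k
    }
  }
  if (all(is.na(band))) stop("no bone found in volume")
  band <- round(approx(seq_len(nz), band, seq_len(nz), rule = 2)$y)

  band_arr <- array(band, d)  # recycles along dim 1
  inner <- solid & (dist_in > band_arr + band_margin + 0.5)

  # end caps (subchondral plates): walk inward from both ends of the solid
  # extent while the slice is almost entirely bone, and keep those slices
  # out of the inner mask; trabecular plates are fenestrated and stay
  # below the occupancy of compact bone
  occ_slice <- vapply(seq_len(nz), function(z) {
    s <- solid[z, , ]
    if (!any(s)) return(NA_real_)
    sum(bone[z, , ][s]) / sum(s)
  }, numeric(1))
  ext_z <- range(which(!is.na(occ_slice)))
  cap_occ <- 0.97
  z <- ext_z[1]
  while (z <= ext_z[2] && occ_slice[z] >= cap_occ) {
    inner[z, , ] <- FALSE
    z <- z + 1
  }
  z <- ext_z[2]
  while (z >= ext_z[1] && occ_slice[z] >= cap_occ) {
    inner[z, , ] <- FALSE
    z <- z - 1
  }
  cortex <- bone & !inner
  if (!any(inner)) {
    zr <- range(which(apply(solid, 1, any)))
    stop(sprintf(
      "no enclosed interior found in slices %d-%d (0-based %d-%d): open shell or solid volume",
      zr[1], zr[2], zr[1] - 1, zr[2] - 1))
  }
  trab <- bone & inner
  structure(list(
    cortical_mask = voxel_volume(cortex, vs),
    inner_mask = voxel_volume(inner, vs),
    trabecular_bone = voxel_volume(trab, vs),
    solid = voxel_volume(solid, vs),
    band_voxels = band), class = "mask_set")
}

slice_bone_area <- function(binary) {
  a <- as_array3(binary)
  apply(a != 0, 1, sum)
}

#' Split an unfused epiphysis from the metaphyseal part
#'
#' Finds the distal-most transverse gap — a run of slices whose bone
#' occupancy falls below `occ_threshold` times the specimen's median
#' per-slice bone area — and splits the volume at the gap centre. An
#' explicit `split_slice` (0-based) overrides detection. The two returned
#' parts partition the input exactly (voxelwise union reconstructs it).
#'
#' @param binary Binary `voxel_volume`.
#' @param split_slice Optional explicit 0-based split slice.
#' @param occ_threshold Occupancy fraction below which a slice counts as gap.
#' @return List with `metaphyseal` and `epiphyseal` parts, the 0-based
#'   `split_slice`, and the detected 0-based `gap_range` (or `NULL` when an
#'   explicit slice was supplied).
#' @export
split_epiphysis <- function(binary, split_slice = NULL, occ_threshold = 0.05) {
  if (!is_binary(binary)) stop("split_epiphysis needs a binary volume")
  a <- as_array3(binary)
  vs <- voxel_size(binary)
  nz <- dim(a)[1]
  area <- slice_bone_area(binary)
  gap_range <- NULL
  if (is.null(split_slice)) {
    inb <- which(area > 0)
    if (!length(inb)) stop("empty volume")
    s0 <- min(inb); s1 <- max(inb)
    ref <- median(area[inb])
    isgap <- area < occ_threshold * ref
    isgap[seq_len(nz) < s0 | seq_len(nz) > s1] <- FALSE
    r <- rle(isgap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    cand <- which(r$values)
    # keep runs strictly inside the bone extent
    cand <- cand[starts[cand] > s0 & ends[cand] < s1]
    if (!length(cand))
      stop("no transverse gap found: specimen appears fused; ",
           "use cut_regions() with an explicit epiphysis boundary, ",
           "or supply split_slice")
    gi <- cand[length(cand)]  # distal-most gap
    split1 <- round((starts[gi] + ends[gi]) / 2)  # 1-based
    gap_range <- c(starts[gi] - 1L, ends[gi] - 1L)
  } else {
    split1 <- split_slice + 1L
    if (split1 < 1 || split1 > nz) stop("split_slice outside volume")
  }
  met <- a; met[seq_len(nz) >= split1, , ] <- 0L
  epi <- a; epi[seq_len(nz) < split1, , ] <- 0L
  list(metaphyseal = voxel_volume(met, vs),
       epiphyseal = voxel_volume(epi, vs),
       split_slice = split1 - 1L,
       gap_range = gap_range)
}

#' Cut a bone volume into anatomical regions
#'
#' With automatic boundaries: the proximal border of the distal metaphysis
#' is placed at 70% of the bone's proximodistal length measured from the
#' proximal end; the distal border of the base is placed where the
#' dorsopalmar breadth of the bone has fallen to `base_breadth_frac` of the
#' maximal base breadth (emulating the visual criterion of the shaft
#' becoming more concave palmarly); the epiphysis boundary, when present,
#' must be supplied (`epiphysis_start`) from growth-plate detection, the
#' remnant epiphyseal line, or user input. Explicit `boundaries` override
#' everything and are returned verbatim.
#'
#' All slice indices are 0-based; intervals are half-open `[start, end)`,
#' ordered proximal to distal, non-overlapping, and jointly cover the
#' bone's slice extent.
#'
#' @param binary Binary `voxel_volume` (fused bone or metaphyseal part).
#' @param boundaries Optional explicit increasing 0-based cut points: length
#'   4 (`base`, `shaft`, `metaphysis`) or 5 (plus `epiphysis`).
#' @param epiphysis_start Optional 0-based slice of the epiphysis boundary.
#' @param base_breadth_frac Breadth fraction defining the base's distal
#'   border.
#' @param metaphysis_frac Fraction of total length at which the metaphysis
#'   begins.
#' @return A `region_partition`: named list of `c(start, end)` intervals.
#' @export
cut_regions <- function(binary, boundaries = NULL, epiphysis_start = NULL,
                        base_breadth_frac = 0.6, metaphysis_frac = 0.7) {
  a <- as_array3(binary)
  nz <- dim(a)[1]
  if (!is.null(boundaries)) {
    if (is.unsorted(boundaries, strictly = TRUE))
      stop("boundaries out of order")
    if (!length(boundaries) %in% c(4L, 5L))
      stop("boundaries must have 4 (no epiphysis) or 5 cut points")
    iv <- list(base = c(boundaries[1], boundaries[2]),
               shaft = c(boundaries[2], boundaries[3]),
               metaphysis = c(boundaries[3], boundaries[4]))
    if (length(boundaries) == 5L)
      iv$epiphysis <- c(boundaries[4], boundaries[5])
    return(new_region_partition(iv, nz))
  }
  area <- slice_bone_area(binary)
  inb <- which(area > 0)
  if (!length(inb)) stop("empty volume")
  s0 <- min(inb); s1 <- max(inb)
  start0 <- s0 - 1L; end0 <- s1  # 0-based half-open extent
  L <- s1 - s0 + 1L
  m0 <- start0 + round(metaphysis_frac * L)

  breadth <- vapply(seq_len(nz), function(z) {
    rows <- which(apply(a[z, , , drop = FALSE] != 0, 2, any))
    if (!length(rows)) 0L else diff(range(rows)) + 1L
  }, integer(1))
  search_end <- s0 + as.integer(round(0.4 * L))
  zmax <- which.max(breadth[s0:search_end]) + s0 - 1L
  bmax <- breadth[zmax]
  below <- which(breadth < base_breadth_frac * bmax &
                   seq_len(nz) > zmax & seq_len(nz) <= s1)
  if (length(below)) {
    b0 <- below[1] - 1L
  } else {
    warning("breadth criterion never met; base border set at 30% of length")
    b0 <- start0 + round(0.3 * L)
  }
  b0 <- min(b0, m0 - 1L)

  iv <- list(base = c(start0, b0), shaft = c(b0, m0))
  if (!is.null(epiphysis_start)) {
    e0 <- as.integer(epiphysis_start)
    if (e0 <= m0 || e0 >= end0) stop("boundaries out of order")
    iv$metaphysis <- c(m0, e0)
    iv$epiphysis <- c(e0, end0)
  } else {
    iv$metaphysis <- c(m0, end0)
  }
  new_region_partition(iv, nz)
}

new_region_partition <- function(intervals, n_slices) {
  starts <- vapply(intervals, `[`, numeric(1), 1)
  ends <- vapply(intervals, `[`, numeric(1), 2)
  if (any(ends < starts)) stop("boundaries out of order")
  if (any(starts[-1] != ends[-length(ends)]))
    stop("partition intervals must be contiguous")
  structure(list(intervals = intervals, n_slices = n_slices),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat("region_partition (0-based half-open slice intervals):\n")
  for (nm in names(x$intervals))
    cat(sprintf("  %-11s [%d, %d)\n", nm, x$intervals[[nm]][1],
                x$intervals[[nm]][2]))
  invisible(x)
}

#' 1-based slice indices of a partition region
#' @param partition A `region_partition`.
#' @param region Region name.
#' @export
region_slices <- function(partition, region) {
  iv <- partition$intervals[[region]]
  if (is.null(iv)) stop("partition has no region '", region, "'")
  if (iv[2] <= iv[1]) return(integer())
  (iv[1] + 1L):iv[2]
}

#' Logical region mask over a volume's slices
#' @param partition A `region_partition`.
#' @param region Region name.
#' @param dims Volume dimensions.
#' @export
region_mask <- function(partition, region, dims) {
  m <- array(FALSE, dims)
  m[region_slices(partition, region), , ] <- TRUE
  m
}
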