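#' Generate a synthetic metacarpal-like specimen
#'
#' Builds a scaled-down elongated bone with a closed cortical shell, a
#' trabecular (parallel-plate) fill in the base and distal end, a hollow
#' mid-shaft, and — before the fusion age — a transverse growth-plate gap
#' separating an epiphyseal secondary ossification centre from the
#' metaphysis. The epiphyseal fill carries a dorsopalmar BV/TV gradient
#' whose direction follows the age trajectory (distopalmar concentration in
#' infants, distodorsal in adults). A co-registered label volume records the
#' ground-truth phase of every voxel, and the per-region structural
#' parameters realised on the voxel grid are returned as ground truth.
#'
#' Label codes: 0 background/soft tissue, 1 cortical bone, 2 trabecular
#' bone, 3 marrow (inner region, non-bone).
#'
#' @param age_months Age of the simulated individual (months, >= 0).
#' @param trajectory Parameter trajectory, see [default_trajectory()].
#' @param seed Integer seed; output is bit-identical given the same inputs.
#' @param voxel_size,length_mm,width_mm Rendering geometry (mm).
#' @param fusion_age_months Age at which the epiphysis fuses (default 126
#'   months = 10.5 years, within the 10-11 year fusion window).
#' @param gap_voxels Width of the unfused growth-plate cartilage gap in
#'   slices (default 3; exceeds the binarisation smoothing support).
#' @param blur_sigma Gaussian partial-volume blur, voxels.
#' @param noise_sd Additive greyscale noise SD (8-bit scale).
#' @param species,sex Metadata tags.
#' @param epiphysis Force presence (`TRUE`)/absence (`FALSE`) of an ossified
#'   epiphysis; `NULL` draws it from the trajectory's presence probability.
#'   Fused specimens always have one.
#' @return A `synthetic_specimen` list: `volume` (8-bit greyscale
#'   `voxel_volume`), `labels` (`voxel_volume`, codes above), `truth`
#'   (per-region realised parameters and 0-based half-open region
#'   intervals), `metadata`.
#' @export
make_synthetic_metacarpal <- function(age_months,
                                      trajectory = default_trajectory(),
                                      seed = 1L,
                                      voxel_size = 0.04,
                                      length_mm = 9.6,
                                      width_mm = 2.56,
                                      fusion_age_months = 126,
                                      gap_voxels = 3,
                                      blur_sigma = 0.7,
                                      noise_sd = 8,
                                      species = "Ggg",
                                      sex = "U",
                                      epiphysis = NULL) {
  if (age_months < 0) stop("age must be >= 0")
  with_seed(seed, {
    category <- as.character(assign_age_category(age_months))
    draw <- draw_specimen_params(trajectory, category)
    fused <- age_months >= fusion_age_months
    has_epi <- if (!is.null(epiphysis)) isTRUE(epiphysis)
               else runif(1) < draw$epiphysis_prob
    if (fused) has_epi <- TRUE

    vs <- voxel_size
    nz <- round(length_mm / vs)
    ny <- nx <- round(width_mm / vs)
    L <- length_mm
    u <- voxel_centers(nz, vs) / L

    # outer shape: wide base, narrowed shaft (55% of base breadth), wide head
    sstep <- function(x) { x <- pmin(1, pmax(0, x)); x * x * (3 - 2 * x) }
    shape <- 1 - 0.45 * sstep((u - 0.2) / 0.2) * (1 - sstep((u - 0.6) / 0.2))
    ry <- (width_mm / 2 - vs) * shape
    rx <- 0.9 * ry
    ct <- 0.16 + 0.16 * (1 - shape) / 0.45  # cortical thickness profile (mm)

    # proximodistal layout (1-based slices)
    z_start <- 3L
    z_end <- nz - 2L
    gp_center <- as.integer(round(0.82 * nz))
    half_gap <- (gap_voxels - 1L) %/% 2L
    gap_slices <- if (fused) integer() else (gp_center - half_gap):(gp_center + half_gap)
    prox_end <- if (fused) z_end else min(gap_slices) - 1L
    epi_start <- if (fused) gp_center else max(gap_slices) + 1L
    pieces <- list(c(z_start, prox_end))
    if (has_epi && !fused) pieces <- c(pieces, list(c(epi_start, z_end)))

    # snapped plate-lattice parameters per region
    snap <- function(x) max(1L, as.integer(round(x / vs)))
    reg <- lapply(draw$regions, function(p) {
      t_vox <- snap(p$tb_th)
      s_vox <- snap(p$tb_sp)
      list(t_vox = t_vox, s_vox = s_vox, p_vox = t_vox + s_vox,
           t_mm = t_vox * vs, p_mm = (t_vox + s_vox) * vs,
           gradient = p$gradient, drawn = p)
    })
    # end caps (subchondral plates) thick enough that the cortical erosion
    # of the segmentation stage cannot clip the trabecular plates anchored
    # flush against them
    ncap <- snap(0.28)

    # Plate placement. Patterns are anchored at the end caps / growth plate
    # so that every bone plate and marrow slab lying inside a measured
    # region is full-size: the base pattern runs distally from the proximal
    # cap, the metaphyseal pattern runs proximally from the growth plate
    # (truncated structures land in the unanalysed mid-shaft), and the
    # epiphyseal pattern runs distally from the growth plate with the
    # leftover absorbed into a thicker distal (subchondral) cap.
    base_fill_end <- round(0.45 * nz)
    distal_fill_start <- round(0.52 * nz)
    plate_start <- integer(0)
    plate_region <- character(0)
    add_plate <- function(s, rg) {
      plate_start <<- c(plate_start, s)
      plate_region <<- c(plate_region, rg)
    }
    s <- z_start + ncap
    while (s <= base_fill_end) {
      add_plate(s, "base")
      s <- s + reg$base$p_vox
    }
    meta_end <- if (fused) gp_center - 1L else prox_end - ncap
    e <- meta_end
    while (e - reg$metaphysis$t_vox + 1L >= distal_fill_start) {
      add_plate(e - reg$metaphysis$t_vox + 1L, "metaphysis")
      e <- e - reg$metaphysis$p_vox
    }
    epi_cap_start <- NA_integer_
    if (has_epi) {
      efs <- if (fused) gp_center else epi_start + ncap
      usable <- (z_end - ncap) - efs + 1L
      p_e <- reg$epiphysis$p_vox
      k <- max(0L, usable %/% p_e)
      epi_cap_start <- efs + k * p_e
      if (k > 0)
        for (j in 0:(k - 1L))
          add_plate(efs + reg$epiphysis$s_vox + j * p_e, "epiphysis")
    }
    # per-slice lookup: 0 = marrow, otherwise index into the plate list
    slice_plate <- integer(nz)
    for (ip in seq_along(plate_start)) {
      rp <- reg[[plate_region[ip]]]
      ext <- if (plate_region[ip] == "epiphysis" && rp$gradient != 0)
        as.integer(ceiling(rp$t_vox * (1 + abs(rp$gradient)))) else rp$t_vox
      zz <- plate_start[ip]:(plate_start[ip] + ext - 1L)
      zz <- zz[zz >= 1 & zz <= nz]
      slice_plate[zz] <- ip
    }

    ymat <- matrix(voxel_centers(ny, vs), ny, nx)
    xmat <- matrix(voxel_centers(nx, vs), ny, nx, byrow = TRUE)
    y0 <- x0 <- width_mm / 2
    yfrac <- ymat / width_mm  # 0 dorsal -> 1 palmar

    # trabecular plates are fenestrated: each plate carries cylindrical
    # perforations (~15% of its area, radius 0.08 mm) through its
    # thickness, as real trabecular plates do; this also keeps the in-plane
    # mean intercept length finite
    hole_r <- max(2, round(0.12 / vs))
    min_gap2 <- (2 * hole_r + 8)^2  # keep inter-hole bridges >= plate thickness
    iy <- matrix(seq_len(ny), ny, nx)
    ix <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    plate_holes <- lapply(seq_along(plate_start), function(ip) {
      zmid <- plate_start[ip] + reg[[plate_region[ip]]]$t_vox %/% 2
      riny <- max(ry[zmid] - ct[zmid], vs) / vs
      rinx <- max(rx[zmid] - ct[zmid], vs) / vs
      n_holes <- max(1L, as.integer(round(0.15 * pi * riny * rinx /
                                            (pi * hole_r^2))))
      hy <- hx <- numeric(0)
      tries <- 0L
      while (length(hy) < n_holes && tries < 50L * n_holes) {
        tries <- tries + 1L
        cy <- runif(1, 0.5, ny + 0.5)
        cx <- runif(1, 0.5, nx + 0.5)
        if (((cy - ny / 2) / riny)^2 + ((cx - nx / 2) / rinx)^2 > 1) next
        if (!length(hy) || all((hy - cy)^2 + (hx - cx)^2 >= min_gap2)) {
          hy <- c(hy, cy)
          hx <- c(hx, cx)
        }
      }
      hole <- matrix(FALSE, ny, nx)
      for (h in seq_along(hy))
        hole <- hole | ((iy - hy[h])^2 + (ix - hx[h])^2 <= hole_r^2)
      hole
    })

    labels <- array(0L, c(nz, ny, nx))
    for (piece in pieces) {
      pz0 <- piece[1]; pz1 <- piece[2]
      has_epi_cap <- !is.na(epi_cap_start) &&
        epi_cap_start >= pz0 && epi_cap_start <= pz1
      for (z in pz0:pz1) {
        e_out <- ((ymat - y0) / ry[z])^2 + ((xmat - x0) / rx[z])^2 <= 1
        riny <- max(ry[z] - ct[z], 0)
        rinx <- max(rx[z] - ct[z], 0)
        cap <- (z - pz0 < ncap) ||
          (if (has_epi_cap) z >= epi_cap_start else pz1 - z < ncap)
        if (cap || riny <= vs || rinx <= vs) {
          sl <- matrix(0L, ny, nx)
          sl[e_out] <- 1L
        } else {
          e_in <- ((ymat - y0) / riny)^2 + ((xmat - x0) / rinx)^2 <= 1
          sl <- matrix(0L, ny, nx)
          sl[e_out] <- 1L
          ip <- slice_plate[z]
          if (ip == 0L) {
            sl[e_in] <- 3L
          } else {
            rp <- reg[[plate_region[ip]]]
            if (plate_region[ip] == "epiphysis" && rp$gradient != 0) {
              t_vs <- rp$t_vox * (1 + rp$gradient * (2 * yfrac - 1))
              bone_here <- (z - plate_start[ip]) + 0.5 < t_vs
            } else {
              bone_here <- matrix((z - plate_start[ip]) < rp$t_vox, ny, nx)
            }
            bone_here <- bone_here & !plate_holes[[ip]]
            sl[e_in] <- ifelse(bone_here[e_in], 2L, 3L)
          }
        }
        labels[z, , ] <- sl
      }
    }

    # ground-truth region intervals, 0-based half-open; the base's distal
    # border uses the same breadth criterion the region-cutting stage
    # applies (first slice below 60% of the maximal base breadth)
    bone0 <- z_start - 1L           # first bone slice, 0-based
    zb <- min(which(shape < 0.6))
    base_iv <- c(bone0, zb - 1L)
    if (fused) {
      extent <- z_end - z_start + 1L
      m0 <- bone0 + round(0.7 * extent)
      meta_iv <- c(m0, gp_center - 1L)
      epi_iv <- c(gp_center - 1L, z_end)
    } else {
      part_extent <- prox_end - z_start + 1L
      m0 <- bone0 + round(0.7 * part_extent)
      meta_iv <- c(m0, prox_end)
      epi_iv <- if (has_epi) c(epi_start - 1L, z_end) else NULL
    }

    region_truth <- function(iv, rname) {
      if (is.null(iv)) return(NULL)
      sl <- (iv[1] + 1L):iv[2]  # 1-based inclusive slices
      lab <- labels[sl, , , drop = FALSE]
      ninner <- sum(lab == 2L | lab == 3L)
      rp <- reg[[rname]]
      list(bvtv = if (ninner > 0) sum(lab == 2L) / ninner else NA_real_,
           tb_th = rp$t_mm, tb_sp = rp$p_mm - rp$t_mm,
           tb_n = 1 / rp$p_mm, gradient = rp$gradient,
           da = rp$drawn$da, da_class = "high", interval = iv)
    }
    truth <- list(base = region_truth(base_iv, "base"),
                  metaphysis = region_truth(meta_iv, "metaphysis"),
                  epiphysis = region_truth(epi_iv, "epiphysis"))

    # greyscale rendering: partial-volume blur + noise on phase intensities
    inten <- c(25, 230, 200, 60)[labels + 1L]
    dim(inten) <- dim(labels)
    g <- gauss_blur_cpp(as.numeric(inten), dim(labels), blur_sigma)
    g <- g + rnorm(length(g), 0, noise_sd)
    g <- round(pmin(255, pmax(0, g)))
    dim(g) <- dim(labels)

    structure(list(
      volume = voxel_volume(g, vs),
      labels = voxel_volume(labels, vs),
      truth = truth,
      metadata = list(species = species, sex = sex,
                      age_months = age_months, age_category = category,
                      seed = seed, fused = fused, has_epiphysis = has_epi,
                      gap_center = gp_center - 1L,  # 0-based
                      gap_slices = if (length(gap_slices)) gap_slices - 1L else integer(),
                      voxel_size = vs, length_mm = length_mm,
                      width_mm = width_mm)),
      class = "synthetic_specimen")
  })
}

#' @export
print.synthetic_specimen <- function(x, ...) {
  m <- x$metadata
  cat(sprintf("synthetic_specimen: %s, %.0f months (%s), %s, %s epiphysis\n",
              m$species, m$age_months, m$age_category,
              if (m$fused) "fused" else "unfused",
              if (m$has_epiphysis) "with" else "no"))
  invisible(x)
}

#' Generate an ontogenetic cohort
#'
#' Draws specimens per age category with Gaussian between-individual noise
#' around the trajectory means (truncated to valid ranges). The default
#' sample sizes mirror the study's per-region availability (4/9/12/9/18 from
#' Neonate to Adult, 52 records), with epiphyses present only where
#' ossified. Two species tags are supported with optional trajectory
#' offsets.
#'
#' @param n_per_category Named or positional integer vector of specimens per
#'   age category (Neonate, Infant1, Infant2, Juvenile, Adult).
#' @param trajectory A trajectory tibble, or a named list of per-species
#'   trajectories (`list(Ggg = ..., Gbb = ...)`).
#' @param seed Integer seed.
#' @param render `"table"` draws per-region parameter records directly;
#'   `"image"` additionally renders each specimen as a voxel volume via
#'   [make_synthetic_metacarpal()].
#' @param species Species tags cycled over specimens.
#' @param ... Passed to [make_synthetic_metacarpal()] when
#'   `render = "image"` (e.g. `voxel_size`).
#' @return For `render = "table"`: a cohort tibble (one row per specimen x
#'   region) with the drawn true parameters. For `render = "image"`: a list
#'   with `specimens` (list of `synthetic_specimen`) and `table` (the same
#'   cohort tibble built from the specimens' realised ground truth).
#' @export
make_cohort <- function(n_per_category = c(Neonate = 4, Infant1 = 9,
                                           Infant2 = 12, Juvenile = 9,
                                           Adult = 18),
                        trajectory = default_trajectory(),
                        seed = 1L,
                        render = c("table", "image"),
                        species = c("Ggg", "Gbb"),
                        fusion_age_months = 126,
                        ...) {
  render <- match.arg(render)
  plan <- cohort_plan(n_per_category, seed, species)
  rows <- list()
  specs <- list()
  for (i in seq_len(nrow(plan))) {
    pl <- plan[i, ]
    tr <- trajectory_for(trajectory, pl$species)
    if (render == "image") {
      spec <- make_synthetic_metacarpal(pl$age_months, trajectory = tr,
                                        seed = pl$sub_seed,
                                        species = pl$species,
                                        fusion_age_months = fusion_age_months,
                                        ...)
      specs[[pl$specimen_id]] <- spec
      rows[[pl$specimen_id]] <- truth_records(spec, pl$specimen_id)
    } else {
      rows[[pl$specimen_id]] <-
        table_records(pl, tr, fusion_age_months)
    }
  }
  tab <- tibble::as_tibble(do.call(rbind, rows))
  tab$age_category <- factor(tab$age_category, levels = AGE_CATEGORIES)
  if (render == "image") list(specimens = specs, table = tab, plan = plan)
  else tab
}

#' Sampling plan for a synthetic cohort
#'
#' Draws each specimen's age (uniform within its category's range), species
#' tag and generation sub-seed. Shared by the table- and image-rendered
#' cohort paths so that both draw identical specimen parameters from the
#' same seed.
#'
#' @inheritParams make_cohort
#' @return A data frame with one row per planned specimen.
#' @export
cohort_plan <- function(n_per_category = c(4, 9, 12, 9, 18), seed = 1L,
                        species = c("Ggg", "Gbb")) {
  n_per_category <- rep(n_per_category, length.out = 5)
  if (any(n_per_category < 1)) stop("need n >= 1 per used category")
  age_lo <- c(0, 7, 36, 72, 144)
  age_hi <- c(7, 36, 72, 144, 480)
  with_seed(seed, {
    rows <- list()
    id <- 0L
    for (ci in seq_along(AGE_CATEGORIES)) {
      for (i in seq_len(n_per_category[ci])) {
        id <- id + 1L
        rows[[id]] <- data.frame(
          specimen_id = sprintf("S%03d", id),
          age_category = AGE_CATEGORIES[ci],
          age_months = runif(1, age_lo[ci], age_hi[ci]),
          species = species[(id - 1L) %% length(species) + 1L],
          sub_seed = sample.int(.Machine$integer.max, 1))
      }
    }
    do.call(rbind, rows)
  })
}

trajectory_for <- function(trajectory, species) {
  if (is.data.frame(trajectory)) trajectory else trajectory[[species]]
}

# table-rendered record for one planned specimen; mirrors the draw sequence
# of make_synthetic_metacarpal under the same sub-seed
table_records <- function(pl, trajectory, fusion_age_months) {
  with_seed(pl$sub_seed, {
    category <- as.character(assign_age_category(pl$age_months))
    draw <- draw_specimen_params(trajectory, category)
    fused <- pl$age_months >= fusion_age_months
    has_epi <- runif(1) < draw$epiphysis_prob
    if (fused) has_epi <- TRUE
    regs <- c("base", "metaphysis", if (has_epi) "epiphysis")
    do.call(rbind, lapply(regs, function(rg) {
      p <- draw$regions[[rg]]
      data.frame(specimen_id = pl$specimen_id, species = pl$species,
                 sex = "U", age_months = pl$age_months,
                 age_category = category, region = rg,
                 bvtv = p$bvtv, da = p$da, tb_th = p$tb_th,
                 tb_sp = p$tb_sp, tb_n = p$tb_n)
    }))
  })
}

# cohort-table rows from a synthetic specimen's ground truth
truth_records <- function(spec, specimen_id = "S001") {
  m <- spec$metadata
  rows <- lapply(names(spec$truth), function(rg) {
    tr <- spec$truth[[rg]]
    if (is.null(tr)) return(NULL)
    data.frame(specimen_id = specimen_id, species = m$species, sex = m$sex,
               age_months = m$age_months, age_category = m$age_category,
               region = rg, bvtv = tr$bvtv, da = tr$da, tb_th = tr$tb_th,
               tb_sp = tr$tb_sp, tb_n = tr$tb_n)
  })
  do.call(rbind, rows)
}

#' Write a cohort of synthetic specimens to disk
#'
#' Greyscale and label volumes as multipage 8-bit TIFF stacks, ground truth
#' and metadata as JSON sidecars, and a cohort manifest CSV.
#'
#' @param cohort Result of `make_cohort(render = "image")`.
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- lapply(names(cohort$specimens), function(sid) {
    spec <- cohort$specimens[[sid]]
    gpath <- file.path(dir, paste0(sid, "_grey.tif"))
    lpath <- file.path(dir, paste0(sid, "_labels.tif"))
    jpath <- file.path(dir, paste0(sid, ".json"))
    write_tiff_stack(spec$volume, gpath)
    write_tiff_stack(spec$labels, lpath, range = c(0, 255))
    write_json_sidecar(list(metadata = spec$metadata, truth = spec$truth), jpath)
    m <- spec$metadata
    data.frame(specimen_id = sid, species = m$species,
               age_months = m$age_months, sex = m$sex, seed = m$seed,
               grey_path = gpath, labels_path = lpath, sidecar_path = jpath)
  })
  man <- do.call(rbind, man)
  write.csv(man, file.path(dir, "cohort_manifest.csv"), row.names = FALSE)
  invisible(man)
}
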