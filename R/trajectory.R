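#' Age categories of the ontogenetic series
#' @export
AGE_CATEGORIES <- c("Neonate", "Infant1", "Infant2", "Juvenile", "Adult")

#' Assign an age in months to an ontogenetic category
#'
#' Bins are half-open on the right and follow the continuous definition of
#' the developmental stages: Neonate `[0, 7)` months, Infant 1 `[7, 36)`,
#' Infant 2 `[36, 72)`, Juvenile `[72, 144)`, Adult `>= 144` (12+ years).
#'
#' @param age_months Numeric vector of ages in months (>= 0).
#' @return Factor with levels [AGE_CATEGORIES].
#' @export
assign_age_category <- function(age_months) {
  if (any(age_months < 0)) stop("negative age")
  cut(age_months, breaks = c(0, 7, 36, 72, 144, Inf),
      labels = AGE_CATEGORIES, right = FALSE)
}

#' Default ontogenetic trajectory of trabecular parameters
#'
#' Per age category and region (base, metaphysis, epiphysis): mean and
#' between-individual SD of trabecular thickness (Tb.Th) and separation
#' (Tb.Sp) in mm, mean/SD of the degree of anisotropy (DA), the probability
#' that an ossified epiphysis is present, and the dorsopalmar BV/TV gradient
#' of the epiphysis (positive = distopalmar concentration, negative =
#' distodorsal). BV/TV and Tb.N are derived: for the plate-structured
#' synthetic fill `BV/TV = Tb.Th / (Tb.Th + Tb.Sp)` and
#' `Tb.N = 1 / (Tb.Th + Tb.Sp)`.
#'
#' The defaults encode the qualitative ontogenetic pattern of the study
#' system: BV/TV and Tb.Th lowest at birth and increasing with age, Tb.N
#' decreasing, Tb.Sp near-constant with a slight adult increase, DA
#' near-constant, and an epiphyseal BV/TV gradient that shifts from
#' distopalmar in infants to distodorsal in adults. Thickness and separation
#' means are multiples of the default 0.04 mm rendering voxel so that
#' voxelisation does not bias category means. No quantitative per-category
#' values are published for the study sample, so these defaults are
#' qualitative by design.
#'
#' @param species_offset Additive offset applied to Tb.Th means (mm), used to
#'   generate interspecific differences; default 0 (no species effect).
#' @param flat If `TRUE`, return a null trajectory with no age effect (all
#'   categories share the Infant2 parameters) for calibration studies.
#' @return A tibble, one row per age category x region.
#' @export
default_trajectory <- function(species_offset = 0, flat = FALSE) {
  th_bm <- c(0.12, 0.16, 0.20, 0.24, 0.28)
  sp_bm <- c(0.40, 0.40, 0.40, 0.44, 0.48)
  th_ep <- c(0.12, 0.12, 0.16, 0.20, 0.28)
  sp_ep <- c(0.40, 0.44, 0.44, 0.44, 0.48)
  p_epi <- c(0, 1 / 9, 0.5, 7 / 9, 1)
  grad <- c(0.5, 0.5, 0.5, 0, -0.5)
  if (flat) {
    th_bm[] <- th_bm[3]; sp_bm[] <- sp_bm[3]
    th_ep[] <- th_ep[3]; sp_ep[] <- sp_ep[3]
    grad[] <- 0
  }
  tr <- rbind(
    data.frame(age_category = AGE_CATEGORIES, region = "base",
               tb_th_mean = th_bm, tb_sp_mean = sp_bm),
    data.frame(age_category = AGE_CATEGORIES, region = "metaphysis",
               tb_th_mean = th_bm, tb_sp_mean = sp_bm),
    data.frame(age_category = AGE_CATEGORIES, region = "epiphysis",
               tb_th_mean = th_ep, tb_sp_mean = sp_ep)
  )
  tr$tb_th_mean <- tr$tb_th_mean + species_offset
  tr$tb_th_sd <- 0.02
  tr$tb_sp_sd <- 0.04
  tr$da_mean <- 0.5
  tr$da_sd <- 0.05
  tr$epiphysis_present <- rep(p_epi, 3)
  tr$gradient <- rep(grad, 3)
  tr$bvtv_mean <- tr$tb_th_mean / (tr$tb_th_mean + tr$tb_sp_mean)
  tr$tb_n_mean <- 1 / (tr$tb_th_mean + tr$tb_sp_mean)
  tibble::as_tibble(tr)
}

trajectory_row <- function(trajectory, category, region) {
  r <- trajectory[trajectory$age_category == as.character(category) &
                    trajectory$region == region, ]
  if (nrow(r) != 1)
    stop("trajectory has no unique row for ", category, "/", region)
  r
}

# Draw one specimen's per-region structural parameters from a trajectory.
# Truncation keeps thickness/separation physically valid.
draw_specimen_params <- function(trajectory, category) {
  regions <- c("base", "metaphysis", "epiphysis")
  out <- lapply(regions, function(rg) {
    r <- trajectory_row(trajectory, category, rg)
    th <- max(0.04, rnorm(1, r$tb_th_mean, r$tb_th_sd))
    sp <- max(0.08, rnorm(1, r$tb_sp_mean, r$tb_sp_sd))
    da <- min(0.95, max(0.02, rnorm(1, r$da_mean, r$da_sd)))
    list(tb_th = th, tb_sp = sp, tb_n = 1 / (th + sp),
         bvtv = th / (th + sp), da = da, gradient = r$gradient)
  })
  names(out) <- regions
  r1 <- trajectory_row(trajectory, category, "epiphysis")
  list(regions = out, epiphysis_prob = r1$epiphysis_present)
}
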