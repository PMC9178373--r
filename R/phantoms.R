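#' Phantom specification
#'
#' Describes a binary test phantom with closed-form ground truth, used as an
#' oracle input for the morphometric estimators. Kinds:
#' \describe{
#'   \item{plate}{parallel plates of thickness `thickness` repeating with
#'     period `period` along `axis` (the plate normal).}
#'   \item{rod}{a square lattice of parallel cylinders of radius `rod_radius`
#'     spaced `rod_spacing` apart, running along `axis`.}
#'   \item{sphere_foam}{a statistically isotropic thresholded Gaussian random
#'     field with voxel fill fraction `target_bvtv`.}
#'   \item{solid}{all bone.}
#'   \item{empty}{all marrow.}
#' }
#'
#' @param kind One of `"plate"`, `"rod"`, `"sphere_foam"`, `"solid"`,
#'   `"empty"`.
#' @param voxel_size Voxel edge length, mm.
#' @param dims Integer vector of 3 voxel counts (>= 32 recommended for
#'   morphometry use).
#' @param thickness Plate thickness, mm (plate).
#' @param period Plate repeat period, mm (plate); must exceed `thickness`.
#' @param rod_radius Rod radius, mm (rod).
#' @param rod_spacing Rod lattice spacing, mm (rod); must exceed
#'   `2 * rod_radius`.
#' @param axis Unit orientation vector (plate normal / rod direction) in the
#'   package axis convention.
#' @param target_bvtv Foam fill fraction in (0, 1).
#' @param foam_scale Foam correlation length, mm (smoothing scale of the
#'   random field).
#' @param seed Integer seed (foam only); generation is deterministic given it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(kind, voxel_size, dims,
                         thickness = NULL, period = NULL,
                         rod_radius = NULL, rod_spacing = NULL,
                         axis = c(1, 0, 0), target_bvtv = NULL,
                         foam_scale = 0.1, seed = 1L) {
  kind <- match.arg(kind, c("plate", "rod", "sphere_foam", "solid", "empty"))
  dims <- as.integer(rep(dims, length.out = 3))
  if (any(dims < 8)) stop("phantom dims too small (< 8 voxels per axis)")
  if (voxel_size <= 0) stop("voxel_size must be positive")
  axis <- axis / sqrt(sum(axis^2))
  extent <- min(dims) * voxel_size
  if (kind == "plate") {
    if (is.null(thickness) || is.null(period))
      stop("plate phantoms need `thickness` and `period`")
    if (thickness >= period) stop("plate invariant violated: thickness < period required")
    if (extent < period)
      stop("dims too small to contain one structural period")
  }
  if (kind == "rod") {
    if (is.null(rod_radius) || is.null(rod_spacing))
      stop("rod phantoms need `rod_radius` and `rod_spacing`")
    if (2 * rod_radius >= rod_spacing)
      stop("rod invariant violated: 2 * rod_radius < rod_spacing required")
    if (extent < rod_spacing)
      stop("dims too small to contain one structural period")
  }
  if (kind == "sphere_foam") {
    if (is.null(target_bvtv) || target_bvtv <= 0 || target_bvtv >= 1)
      stop("foam phantoms need `target_bvtv` in (0, 1)")
  }
  structure(list(kind = kind, voxel_size = voxel_size, dims = dims,
                 thickness = thickness, period = period,
                 rod_radius = rod_radius, rod_spacing = rod_spacing,
                 axis = axis, target_bvtv = target_bvtv,
                 foam_scale = foam_scale, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a phantom volume with analytic ground truth
#'
#' @param spec A [phantom_spec()].
#' @return A list with `volume` (binary `voxel_volume`) and `truth`, a list
#'   with `bvtv`, `tb_th` (mm), `tb_sp` (mm), `tb_n` (1/mm, always
#'   `1/(tb_th + tb_sp)` where both are defined), `principal_axis` and
#'   `da_class` (`"high"`/`"low"`). Quantities without a closed form for a
#'   given kind (e.g. rod separation as a spatial mean) are `NA` and flagged.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  vs <- spec$voxel_size
  cx <- voxel_centers(d[1], vs)
  cy <- voxel_centers(d[2], vs)
  cz <- voxel_centers(d[3], vs)
  truth <- list(bvtv = NA_real_, tb_th = NA_real_, tb_sp = NA_real_,
                tb_n = NA_real_, principal_axis = spec$axis,
                da_class = NA_character_, flags = character())

  if (spec$kind == "solid") {
    arr <- array(1L, d)
    truth$bvtv <- 1
    truth$da_class <- "low"
    truth$flags <- "single_phase: tb_sp undefined"
  } else if (spec$kind == "empty") {
    arr <- array(0L, d)
    truth$bvtv <- 0
    truth$da_class <- "low"
    truth$flags <- "single_phase: tb_th undefined"
  } else if (spec$kind == "plate") {
    # phase shifted by half a plate so that the volume faces cut mid-plate:
    # marrow slabs are then fully interior and the local-thickness boundary
    # convention (faces continue the phase) stays unbiased
    co <- outer_coord(cx, cy, cz, spec$axis)
    arr <- array(as.integer(((co + spec$thickness / 2) %% spec$period) <
                              spec$thickness), d)
    truth$bvtv <- spec$thickness / spec$period
    truth$tb_th <- spec$thickness
    truth$tb_sp <- spec$period - spec$thickness
    truth$tb_n <- 1 / spec$period
    truth$da_class <- "high"
  } else if (spec$kind == "rod") {
    basis <- orthobasis(spec$axis)
    a <- outer_coord(cx, cy, cz, basis$u) - spec$rod_spacing / 2
    b <- outer_coord(cx, cy, cz, basis$v) - spec$rod_spacing / 2
    s <- spec$rod_spacing
    da_ <- a - s * round(a / s)
    db_ <- b - s * round(b / s)
    arr <- array(as.integer(da_^2 + db_^2 < spec$rod_radius^2), d)
    truth$bvtv <- pi * spec$rod_radius^2 / s^2
    truth$tb_th <- 2 * spec$rod_radius
    truth$flags <- "rod: tb_sp/tb_n spatial means have no closed form"
    truth$da_class <- "high"
  } else { # sphere_foam
    arr <- with_seed(spec$seed, {
      field <- array(rnorm(prod(d)), d)
      sm <- gauss_blur_cpp(as.numeric(field), d, spec$foam_scale / vs)
      thr <- quantile(sm, 1 - spec$target_bvtv, names = FALSE)
      array(as.integer(sm > thr), d)
    })
    truth$bvtv <- spec$target_bvtv
    truth$principal_axis <- c(NA_real_, NA_real_, NA_real_)
    truth$da_class <- "low"
  }
  list(volume = voxel_volume(arr, vs), truth = truth)
}

# coordinate of every voxel centre along a unit direction, as a 3D array
outer_coord <- function(cx, cy, cz, w) {
  a <- outer(cx * w[1], cy * w[2], "+")
  outer(a, cz * w[3], "+")
}

# deterministic orthonormal basis completing a unit vector
orthobasis <- function(w) {
  e <- diag(3)[, which.min(abs(w))]
  u <- c(w[2] * e[3] - w[3] * e[2],
         w[3] * e[1] - w[1] * e[3],
         w[1] * e[2] - w[2] * e[1])
  u <- u / sqrt(sum(u^2))
  v <- c(w[2] * u[3] - w[3] * u[2],
         w[3] * u[1] - w[1] * u[3],
         w[1] * u[2] - w[2] * u[1])
  list(u = u, v = v)
}
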