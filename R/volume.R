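#' Voxel volume
#'
#' A 3D scalar grid (greyscale intensity or binary phase) with an isotropic
#' voxel size in millimetres. Volumes follow the package anatomical
#' convention: dimension 1 is proximodistal (slice index increases distally),
#' dimension 2 dorsopalmar (index increases palmarly), dimension 3 radioulnar.
#'
#' @param data 3D numeric or logical array.
#' @param voxel_size Isotropic voxel edge length in mm.
#' @return A `voxel_volume`: the array with `voxel_size` attribute and class.
#' @export
voxel_volume <- function(data, voxel_size) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a single positive number (mm)")
  if (is.logical(data)) storage.mode(data) <- "integer"
  structure(data, voxel_size = voxel_size, class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("voxel_volume: %d x %d x %d voxels, %.4g mm/voxel%s\n",
              d[1], d[2], d[3], voxel_size(x),
              if (is_binary(x)) " (binary)" else ""))
  invisible(x)
}

#' Voxel size of a volume (mm)
#' @param vol A `voxel_volume`.
#' @export
voxel_size <- function(vol) {
  vs <- attr(vol, "voxel_size")
  if (is.null(vs)) stop("not a voxel_volume: no voxel_size attribute")
  vs
}

#' Is a volume binary (values exactly 0/1)?
#' @param vol A `voxel_volume` or array.
#' @export
is_binary <- function(vol) {
  u <- unique(as.vector(vol))
  all(u %in% c(0L, 1L, 0, 1))
}

# strip attributes, return plain array
as_array3 <- function(vol) {
  a <- unclass(vol)
  attr(a, "voxel_size") <- NULL
  a
}

# coerce to integer vector for the compiled routines
as_int3 <- function(vol) {
  a <- as_array3(vol)
  storage.mode(a) <- "integer"
  a
}

as_logical3 <- function(vol) {
  a <- as_array3(vol)
  storage.mode(a) <- "logical"
  a
}

same_geometry <- function(a, b) {
  identical(dim(a), dim(b)) &&
    isTRUE(all.equal(voxel_size(a), voxel_size(b)))
}

#' Read a TIFF image stack as a voxel volume
#'
#' Accepts a multipage TIFF file or a directory of per-slice TIFF files
#' (sorted by filename). Slices are stacked along dimension 1
#' (proximodistal). Pixel rows map to dimension 2, columns to dimension 3.
#'
#' @param path Multipage TIFF file or directory of single-slice TIFFs.
#' @param voxel_size Isotropic voxel size in mm.
#' @param scale If `TRUE` (default) keep the 0-1 scale returned by the TIFF
#'   reader; if `FALSE`, rescale to 0-255.
#' @return A `voxel_volume`.
#' @export
read_tiff_stack <- function(path, voxel_size, scale = TRUE) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(files)) stop("no TIFF files in ", path)
    slices <- lapply(files, tiff::readTIFF)
  } else {
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
  }
  slices <- lapply(slices, function(s) if (length(dim(s)) == 3L) s[, , 1] else s)
  d2 <- dim(slices[[1]])
  arr <- array(0, c(length(slices), d2[1], d2[2]))
  for (i in seq_along(slices)) arr[i, , ] <- slices[[i]]
  if (!scale) arr <- arr * 255
  voxel_volume(arr, voxel_size)
}

#' Write a voxel volume as a multipage 8-bit TIFF stack
#'
#' Greyscale values are linearly mapped from `range` to 0-1 before writing.
#' Binary volumes are written with `range = c(0, 1)`.
#'
#' @param vol A `voxel_volume`.
#' @param path Output file (multipage TIFF).
#' @param range Intensity range mapped onto the 8-bit scale.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(vol, path, range = NULL) {
  a <- as_array3(vol)
  if (is.null(range)) range <- if (is_binary(vol)) c(0, 1) else c(0, 255)
  a <- (a - range[1]) / (range[2] - range[1])
  a[a < 0] <- 0
  a[a > 1] <- 1
  slices <- lapply(seq_len(dim(a)[1]), function(i) a[i, , ])
  tiff::writeTIFF(slices, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write volume metadata (and optional ground truth) as a JSON sidecar
#' @param meta Named list.
#' @param path Output `.json` path.
#' @export
write_json_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

# physical coordinate (mm) of voxel centres along one axis, 1-based indices
voxel_centers <- function(n, vs) (seq_len(n) - 0.5) * vs

#' Rotate a volume 90 degrees about the proximodistal axis
#'
#' Used for equivariance checks: rotates dimensions 2 and 3
#' (dorsopalmar/radioulnar plane) counter-clockwise.
#' @param vol A `voxel_volume`.
#' @export
rotate90_pd <- function(vol) {
  a <- as_array3(vol)
  b <- aperm(a, c(1, 3, 2))
  b <- b[, dim(b)[2]:1, , drop = FALSE]
  voxel_volume(b, voxel_size(vol))
}
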