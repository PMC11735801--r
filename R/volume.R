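# Volume containers.
#
# Volumes are plain 3D arrays indexed [x, y, z]: x is the streamwise
# direction (flow towards +x), y cross-stream, z vertical with z increasing
# away from the substratum. Physical voxel sizes ride along as attributes:
# `voxel_lateral` (x and y, micrometres) and `voxel_axial` (z, micrometres).
# Defaults match the instrument: 12 um lateral, 2.1 um axial (in water).

#' Construct an intensity volume
#'
#' An 8-bit greyscale OCT-like scan on a regular voxel grid.
#'
#' @param data 3D numeric array, values in \[0, 255\], indexed \[x, y, z\].
#' @param voxel_lateral lateral voxel size (x and y), micrometres.
#' @param voxel_axial axial voxel size (z), micrometres.
#' @return an `intensity_volume` (a 3D array with voxel-size attributes).
#' @export
intensity_volume <- function(data, voxel_lateral = 12, voxel_axial = 2.1) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (voxel_lateral <= 0 || voxel_axial <= 0)
    stop("voxel sizes must be positive")
  rng <- range(data)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]")
  structure(data,
            voxel_lateral = voxel_lateral, voxel_axial = voxel_axial,
            class = c("intensity_volume", "array"))
}

#' Construct a binary volume
#'
#' Binarised biofilm indicator b(x, y, z) on the same grid convention as
#' [intensity_volume()]; after flattening, z = 0 (array layer 1) is the
#' substratum reference layer.
#'
#' @param data 3D array of 0/1 values.
#' @inheritParams intensity_volume
#' @return a `binary_volume`.
#' @export
binary_volume <- function(data, voxel_lateral = 12, voxel_axial = 2.1) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (voxel_lateral <= 0 || voxel_axial <= 0)
    stop("voxel sizes must be positive")
  if (!all(data == 0 | data == 1)) stop("binary volume must contain only 0/1")
  structure(data,
            voxel_lateral = voxel_lateral, voxel_axial = voxel_axial,
            class = c("binary_volume", "array"))
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<intensity_volume> %d x %d x %d voxels (%g um lateral, %g um axial)\n",
              d[1], d[2], d[3], voxel_lateral(x), voxel_axial(x)))
  cat(sprintf("  intensity range [%d, %d], mode %d\n",
              min(x), max(x), background_mode(x)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<binary_volume> %d x %d x %d voxels (%g um lateral, %g um axial)\n",
              d[1], d[2], d[3], voxel_lateral(x), voxel_axial(x)))
  cat(sprintf("  %d set voxels (%.3g%%)\n", sum(x), 100 * mean(x)))
  invisible(x)
}

#' Voxel sizes of a volume
#' @param vol an `intensity_volume` or `binary_volume`.
#' @return voxel size in micrometres.
#' @export
voxel_lateral <- function(vol) {
  v <- attr(vol, "voxel_lateral")
  if (is.null(v)) 12 else v
}

#' @rdname voxel_lateral
#' @export
voxel_axial <- function(vol) {
  v <- attr(vol, "voxel_axial")
  if (is.null(v)) 2.1 else v
}

# Rebuild a volume of the same class/voxel sizes with new data.
rewrap <- function(vol, data) {
  structure(data,
            voxel_lateral = voxel_lateral(vol), voxel_axial = voxel_axial(vol),
            class = class(vol))
}
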