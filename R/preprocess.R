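# Volume preparation: rotation, substratum detection, flattening,
# registration.
#
# The scan pipeline mirrors the acquisition geometry: channels sit on a base
# plate tilted by preset angles, so stacks are first rotated back, then the
# substratum (the brightest reflection in each A-scan) is detected, smoothed
# with a generous median filter, and each column is shifted so the substratum
# sits at the bottom of the scan. Consecutive scans of the same flow cell are
# aligned by cross-correlation of their maximum-intensity projections.

#' Rotate a volume about two axes
#'
#' Rotation is performed in physical coordinates (voxel sizes respected)
#' about the volume centre: `angle_a` rotates in the x-z plane (about the
#' cross-stream y axis), `angle_b` in the y-z plane (about x). Trilinear
#' interpolation; samples falling outside the input are filled with the
#' background mode.
#'
#' @param vol an [intensity_volume()].
#' @param angle_a,angle_b rotation angles in degrees, each in (-45, 45).
#' @return the rotated [intensity_volume()].
#' @export
rotate_volume <- function(vol, angle_a, angle_b = 0) {
  if (abs(angle_a) >= 45 || abs(angle_b) >= 45)
    stop("rotation angles must lie in (-45, 45) degrees")
  if (angle_a == 0 && angle_b == 0) return(vol)
  d <- dim(vol)
  lat <- voxel_lateral(vol); ax <- voxel_axial(vol)
  fill <- background_mode(vol)
  # sign convention: a substratum rising along +x at angle t is levelled by
  # rotate_volume(vol, -t); likewise for angle_b along +y
  a <- -angle_a * pi / 180
  b <- -angle_b * pi / 180
  # centre of the grid in physical units
  cx <- (d[1] + 1) / 2; cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  # output voxel centres, physical coordinates relative to the centre
  xs <- (seq_len(d[1]) - cx) * lat
  ys <- (seq_len(d[2]) - cy) * lat
  zs <- (seq_len(d[3]) - cz) * ax
  X <- rep(xs, times = d[2] * d[3])
  Y <- rep(rep(ys, each = d[1]), times = d[3])
  Z <- rep(zs, each = d[1] * d[2])
  # inverse map: rotate output coords by R^-1 = Ry(-a) then Rx(-b)
  # forward is Rx(b) %*% Ry(a); inverse applied as Ry(-a) %*% Rx(-b)
  y1 <- cos(b) * Y + sin(b) * Z
  z1 <- -sin(b) * Y + cos(b) * Z
  x1 <- cos(a) * X - sin(a) * z1
  z2 <- sin(a) * X + cos(a) * z1
  # back to fractional voxel indices
  fx <- x1 / lat + cx
  fy <- y1 / lat + cy
  fz <- z2 / ax + cz
  out <- trilinear_sample(unclass(vol), fx, fy, fz, fill)
  rewrap(vol, array(clip_quantise(out), d))
}

# Trilinear interpolation of arr at fractional indices (fx, fy, fz);
# out-of-range samples get `fill`.
trilinear_sample <- function(arr, fx, fy, fz, fill) {
  d <- dim(arr)
  eps <- 1e-9
  inside <- fx >= 1 - eps & fx <= d[1] + eps &
            fy >= 1 - eps & fy <= d[2] + eps &
            fz >= 1 - eps & fz <= d[3] + eps
  out <- rep(as.numeric(fill), length(fx))
  if (!any(inside)) return(out)
  # clamp in-range coordinates so grid-boundary samples stay valid
  cl <- function(v, n) pmin(pmax(v, 1), n)
  fx <- cl(fx[inside], d[1]); fy <- cl(fy[inside], d[2]); fz <- cl(fz[inside], d[3])
  x0 <- pmin(floor(fx), d[1] - 1); y0 <- pmin(floor(fy), d[2] - 1)
  z0 <- pmin(floor(fz), d[3] - 1)
  wx <- fx - x0; wy <- fy - y0; wz <- fz - z0
  idx <- function(i, j, k) arr[cbind(i, j, k)]
  acc <- idx(x0,     y0,     z0)     * (1 - wx) * (1 - wy) * (1 - wz) +
         idx(x0 + 1, y0,     z0)     * wx       * (1 - wy) * (1 - wz) +
         idx(x0,     y0 + 1, z0)     * (1 - wx) * wy       * (1 - wz) +
         idx(x0 + 1, y0 + 1, z0)     * wx       * wy       * (1 - wz) +
         idx(x0,     y0,     z0 + 1) * (1 - wx) * (1 - wy) * wz +
         idx(x0 + 1, y0,     z0 + 1) * wx       * (1 - wy) * wz +
         idx(x0,     y0 + 1, z0 + 1) * (1 - wx) * wy       * wz +
         idx(x0 + 1, y0 + 1, z0 + 1) * wx       * wy       * wz
  out[inside] <- acc
  out
}

#' Detect the substratum plane
#'
#' Per (x, y) column, the z-index of highest intensity (ties toward the
#' lowest z), followed by a 2D median filter over a disk of the given radius
#' (replicate padding at the borders). When the residual between the raw
#' argmax depths and the filtered map has a standard deviation above
#' `confidence_sd` voxels, the result is flagged low-confidence (attribute
#' `low_confidence`) with a warning -- typical of scans with no substratum
#' reflection. (A smoothly tilted plane has near-zero residual and is not
#' flagged.)
#'
#' @param vol an [intensity_volume()].
#' @param radius median filter radius in pixels (default 11).
#' @param confidence_sd residual standard deviation (voxels) above which the
#'   detection is flagged low-confidence.
#' @return integer matrix of 0-based substratum z-indices per (x, y).
#' @export
detect_substratum <- function(vol, radius = 11, confidence_sd = 5) {
  d <- dim(vol)
  m <- matrix(unclass(vol), d[1] * d[2], d[3])
  depth0 <- max.col(m, ties.method = "first") - 1L
  depth <- matrix(depth0, d[1], d[2])
  filtered <- median_filter_disk(depth, radius)
  if (stats::sd(depth - filtered) > confidence_sd) {
    warning("substratum detection is low-confidence (depth map too variable)")
    attr(filtered, "low_confidence") <- TRUE
  }
  filtered
}

# 2D median filter over a disk neighbourhood, replicate padding.
median_filter_disk <- function(m, radius) {
  nx <- nrow(m); ny <- ncol(m)
  offs <- expand.grid(dx = -radius:radius, dy = -radius:radius)
  offs <- offs[offs$dx^2 + offs$dy^2 <= radius^2, ]
  stack <- array(0L, c(nx, ny, nrow(offs)))
  xi <- seq_len(nx); yi <- seq_len(ny)
  for (i in seq_len(nrow(offs))) {
    sx <- pmin(pmax(xi + offs$dx[i], 1L), nx)
    sy <- pmin(pmax(yi + offs$dy[i], 1L), ny)
    stack[, , i] <- m[sx, sy]
  }
  out <- apply(stack, c(1, 2), stats::median)
  matrix(as.integer(round(out)), nx, ny)
}

#' Flatten a volume onto its substratum
#'
#' Each (x, y) column is shifted down by an integer so the detected
#' substratum voxel sits at z = 0 (array layer 1); vacated voxels at the top
#' are filled with the background mode. Integer shifts preserve the
#' intensities that binarisation sees, and column heights above the local
#' substratum exactly.
#'
#' @param vol an [intensity_volume()].
#' @param sub substratum depth map from [detect_substratum()] (0-based).
#' @return the flattened [intensity_volume()].
#' @export
flatten <- function(vol, sub) {
  d <- dim(vol)
  if (any(sub < 0) || any(sub >= d[3])) stop("invalid substratum depths")
  fill <- background_mode(vol)
  data <- unclass(vol)
  out <- array(as.integer(fill), d)
  for (dep in unique(as.vector(sub))) {
    cols <- which(sub == dep, arr.ind = TRUE)
    nzk <- d[3] - dep
    # column content from the substratum upward moves to layers 1..nzk
    for (k in seq_len(nzk)) {
      out[cbind(cols, k)] <- data[cbind(cols, dep + k)]
    }
  }
  rewrap(vol, out)
}

#' Drop the lowest z-layers of a volume
#'
#' Used after [flatten()] to discard the bright substratum plane itself so
#' that z = 0 becomes the first layer above the substratum (the layer Eq.
#' (2)-style substratum coverage reads).
#'
#' @param vol an intensity or binary volume.
#' @param n number of bottom layers to drop (default 1).
#' @return the cropped volume.
#' @export
strip_bottom <- function(vol, n = 1) {
  d <- dim(vol)
  if (n >= d[3]) stop("cannot strip all z layers")
  rewrap(vol, unclass(vol)[, , (n + 1):d[3], drop = FALSE])
}

#' Register two volumes or maps by cross-correlation
#'
#' Volumes are reduced to 2D maximum-intensity projections; the integer
#' (dx, dy) shift maximising their circular cross-correlation is returned,
#' with ties broken toward the smallest shift magnitude. The convention is
#' `b[x + dx, y + dy] == a[x, y]`. Featureless (constant) inputs, and pairs
#' whose normalised correlation peak falls below `min_corr`, yield (0, 0)
#' with a warning.
#'
#' @param a,b volumes or matrices on the same grid.
#' @param min_corr minimum normalised peak correlation to accept (default
#'   0.2).
#' @return integer vector `c(dx, dy)`.
#' @export
register_pair <- function(a, b, min_corr = 0.2) {
  proj <- function(v) {
    if (length(dim(v)) == 3) apply(unclass(v), c(1, 2), max) else unclass(v)
  }
  A <- proj(a); B <- proj(b)
  if (!all(dim(A) == dim(B))) stop("inputs must share grid dimensions")
  if (stats::sd(A) == 0 || stats::sd(B) == 0) {
    warning("featureless input; returning zero shift")
    return(c(dx = 0L, dy = 0L))
  }
  A0 <- A - mean(A); B0 <- B - mean(B)
  n <- length(A0)
  cc <- Re(stats::fft(Conj(stats::fft(A0)) * stats::fft(B0), inverse = TRUE)) / n
  norm <- sqrt(sum(A0^2) * sum(B0^2))
  peak <- max(cc) / norm
  if (peak < min_corr) {
    warning(sprintf("correlation peak %.3f below %.2f; returning zero shift",
                    peak, min_corr))
    return(c(dx = 0L, dy = 0L))
  }
  cand <- which(cc >= max(cc) - 1e-9 * abs(max(cc)), arr.ind = FALSE)
  nx <- nrow(A0); ny <- ncol(A0)
  sx <- (cand - 1) %% nx
  sy <- (cand - 1) %/% nx
  sx <- ifelse(sx > nx / 2, sx - nx, sx)
  sy <- ifelse(sy > ny / 2, sy - ny, sy)
  best <- which.min(sx^2 + sy^2)
  c(dx = as.integer(sx[best]), dy = as.integer(sy[best]))
}

#' Shift a matrix or volume in-plane by integer offsets
#'
#' Helper for registration tests and alignment: content moves by (dx, dy),
#' vacated entries filled with `fill`.
#'
#' @param v matrix or 3D array/volume.
#' @param dx,dy integer shifts along x and y.
#' @param fill fill value for vacated entries (default 0).
#' @return shifted object of the same shape and class.
#' @export
shift_xy <- function(v, dx, dy, fill = 0) {
  d <- dim(v)
  is3 <- length(d) == 3
  data <- unclass(v)
  out <- array(fill, d)
  xs <- seq_len(d[1]); ys <- seq_len(d[2])
  xs_to <- xs + dx; ys_to <- ys + dy
  okx <- xs_to >= 1 & xs_to <= d[1]
  oky <- ys_to >= 1 & ys_to <= d[2]
  if (is3) out[xs_to[okx], ys_to[oky], ] <- data[xs[okx], ys[oky], , drop = FALSE]
  else out[xs_to[okx], ys_to[oky]] <- data[xs[okx], ys[oky], drop = FALSE]
  if (is.object(v)) rewrap(v, out) else out
}
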