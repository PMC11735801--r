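# Histogram-inflexion thresholding, binarisation, removal-only denoising and
# trimming.
#
# Empty-volume OCT signal is Gaussian; biofilm signal sits above the mode of
# the intensity distribution. When there is too little biofilm to create a
# bimodal histogram, the onset of biofilm intensities still shows up as an
# inflexion to the right of the mode. The threshold is therefore the level
# right of the mode maximising the discrete second derivative of the
# (optionally smoothed) histogram, plus a fixed offset of three levels that
# reproduces manual thresholding.

#' Exact 256-bin intensity histogram
#'
#' @param vol an [intensity_volume()].
#' @return integer vector of length 256, counts for levels 0..255, with
#'   class `intensity_histogram`.
#' @export
compute_histogram <- function(vol) {
  counts <- tabulate(as.integer(vol) + 1L, nbins = 256L)
  structure(counts, levels = 0:255, class = "intensity_histogram")
}

#' Histogram-inflexion threshold
#'
#' Finds the histogram mode (ties toward the lowest level), smooths the
#' histogram with a centred moving average of width `smooth` (width 1
#' disables smoothing), locates the level strictly right of the mode that
#' maximises the central second difference `h(i-1) - 2 h(i) + h(i+1)` (ties
#' toward the lowest level), and returns that candidate plus an offset of
#' three intensity levels.
#'
#' @param hist an `intensity_histogram` (or plain 256-vector of counts).
#' @param smooth moving-average width for the second-difference scan
#'   (default 3; must be odd).
#' @param offset additive offset applied to the candidate (default 3).
#' @param min_gap smallest level-distance from the mode considered in the
#'   scan (default `max(3, smooth)`). Flattening fills vacated voxels with
#'   the background mode, which piles extra mass on the mode bin; after
#'   smoothing, that spike contaminates second differences up to
#'   `smooth - 1` levels to its right, so the scan starts beyond its reach.
#'   For a Gaussian background the second-difference maximum sits near
#'   mode + sigma * sqrt(3), well clear of the gap for any realistic sigma.
#' @return the threshold level, with attributes `mode` and `candidate`.
#' @export
find_threshold <- function(hist, smooth = 3, offset = 3, min_gap = max(3, smooth)) {
  counts <- as.numeric(hist)
  if (length(counts) != 256) stop("histogram must have 256 bins")
  if (sum(counts) == 0) stop("empty histogram")
  if (smooth %% 2 != 1) stop("smooth width must be odd")
  mode_level <- which.max(counts) - 1L
  if (mode_level + min_gap >= 255)
    stop("no intensity levels right of the mode to scan")
  h <- counts
  if (smooth > 1) {
    k <- rep(1 / smooth, smooth)
    h <- as.numeric(stats::filter(counts, k, sides = 2))
    # filter() leaves NAs at the ends; fall back to raw counts there
    h[is.na(h)] <- counts[is.na(h)]
  }
  # central second difference over interior levels right of the mode
  i <- (mode_level + min_gap + 1):255   # 1-based indices, levels >= mode+min_gap
  d2 <- h[i - 1] - 2 * h[i] + h[i + 1]
  candidate <- (mode_level + min_gap) + (which.max(d2) - 1L)
  thr <- min(candidate + offset, 255L)
  structure(as.integer(thr), mode = mode_level, candidate = as.integer(candidate))
}

#' Binarise a volume at a threshold
#'
#' Strict comparison: a voxel is biofilm when its intensity exceeds the
#' threshold; the threshold level itself stays background.
#'
#' @param vol an [intensity_volume()].
#' @param thr threshold level in \[0, 255\].
#' @return a [binary_volume()].
#' @export
binarise <- function(vol, thr) {
  if (thr < 0 || thr > 255) stop("threshold must lie in [0, 255]")
  b <- array(as.integer(unclass(vol) > thr), dim(vol))
  binary_volume(b, voxel_lateral(vol), voxel_axial(vol))
}

# Disk-neighbourhood sum applied slice-wise: for every z-slice, each pixel
# gets the sum over in-plane offsets with dx^2 + dy^2 <= r^2 (zero padding).
disk_sum_slices <- function(arr, r) {
  d <- dim(arr)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
  out <- array(0, d)
  for (i in seq_len(nrow(offs))) {
    dx <- offs$dx[i]; dy <- offs$dy[i]
    xs <- max(1, 1 - dx):min(d[1], d[1] - dx)
    ys <- max(1, 1 - dy):min(d[2], d[2] - dy)
    out[xs, ys, ] <- out[xs, ys, , drop = FALSE] +
      arr[xs + dx, ys + dy, , drop = FALSE]
  }
  attr(out, "n_kernel") <- nrow(offs)
  out
}

#' Removal-only outlier filter
#'
#' Slice-wise (per z-slice) majority filter, emulating an image-stack
#' remove-outliers pass: a set voxel is cleared when fewer than half of the
#' pixels in its in-plane disk neighbourhood of the given radius (zero
#' padding at the borders) are set. Background voxels are never set: the
#' filter removes small biofilm structures without filling in any gaps, so
#' the output is always a subset of the input.
#'
#' @param bvol a [binary_volume()].
#' @param radius in-plane disk radius in voxels (default 2).
#' @return the filtered [binary_volume()].
#' @export
remove_outliers <- function(bvol, radius = 2) {
  if (radius < 1) stop("radius must be >= 1")
  b <- unclass(bvol)
  counts <- disk_sum_slices(b, radius)
  keep <- counts >= attr(counts, "n_kernel") / 2
  rewrap(bvol, array(as.integer(b == 1L & keep), dim(b)))
}

#' Trim a binary volume above the biofilm
#'
#' Crops z so that `margin` empty layers remain above the highest set voxel;
#' all set voxels are preserved. An empty input yields a minimal-height empty
#' volume of `max(margin, 1)` layers.
#'
#' @param bvol a [binary_volume()].
#' @param margin empty layers to keep above the biofilm (default 3).
#' @return the trimmed [binary_volume()].
#' @export
trim_top <- function(bvol, margin = 3) {
  d <- dim(bvol)
  zsum <- apply(unclass(bvol), 3, sum)
  top <- if (any(zsum > 0)) max(which(zsum > 0)) else 0L
  nz <- max(min(top + margin, d[3]), 1L)
  rewrap(bvol, unclass(bvol)[, , seq_len(nz), drop = FALSE])
}

#' Segment an intensity volume
#'
#' Convenience wrapper chaining [compute_histogram()], [find_threshold()],
#' [binarise()], [remove_outliers()] and [trim_top()].
#'
#' @param vol an [intensity_volume()] (flattened, substratum removed).
#' @param filter_radius outlier-filter half-width; 0 disables denoising.
#' @param trim_margin empty layers kept above the biofilm; negative disables
#'   trimming.
#' @param smooth,offset passed to [find_threshold()].
#' @return list with `binary` (the segmented [binary_volume()]) and `report`
#'   (mode, candidate, threshold, voxel counts).
#' @export
segment_volume <- function(vol, filter_radius = 2, trim_margin = 3,
                           smooth = 3, offset = 3) {
  thr <- find_threshold(compute_histogram(vol), smooth = smooth, offset = offset)
  b <- binarise(vol, thr)
  raw_count <- sum(b)
  if (filter_radius >= 1) b <- remove_outliers(b, filter_radius)
  if (trim_margin >= 0) b <- trim_top(b, trim_margin)
  list(binary = b,
       report = list(mode = attr(thr, "mode"),
                     candidate = attr(thr, "candidate"),
                     threshold = as.integer(thr),
                     voxels_above_threshold = raw_count,
                     voxels_after_filter = sum(b)))
}
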