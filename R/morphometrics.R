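# Structural statistics of a binarised, flattened biofilm volume.
#
# Two vertical measures per (x, y) column: height h, the distance from the
# substratum to the highest voxel containing biofilm (voids included), and
# thickness T, the summed biofilm within the column (voids excluded). Their
# ratio T/h, the solidity, separates suspended material -- streamers, with
# voids beneath -- from solid base structure.

#' Per-column biofilm height map
#'
#' Top-face convention: a column whose highest set voxel has 0-based z-index
#' k has height (k + 1) * voxel_axial; empty columns have height 0.
#'
#' @param bvol a flattened [binary_volume()] (z = 0 at the substratum).
#' @return matrix of heights, micrometres.
#' @export
height_map <- function(bvol) {
  d <- dim(bvol)
  m <- matrix(unclass(bvol), d[1] * d[2], d[3])
  # index (1-based) of the highest set voxel == count implied by top face
  top <- max.col(m * rep(seq_len(d[3]), each = d[1] * d[2]),
                 ties.method = "last")
  top[rowSums(m) == 0] <- 0L
  matrix(top * voxel_axial(bvol), d[1], d[2])
}

#' Per-column biofilm thickness map
#'
#' Thickness excludes voids: the number of set voxels in the column times the
#' axial voxel size.
#'
#' @inheritParams height_map
#' @return matrix of thicknesses, micrometres.
#' @export
thickness_map <- function(bvol) {
  d <- dim(bvol)
  m <- matrix(unclass(bvol), d[1] * d[2], d[3])
  matrix(rowSums(m) * voxel_axial(bvol), d[1], d[2])
}

#' Solidity map T/h
#'
#' @param h height map from [height_map()].
#' @param T thickness map from [thickness_map()] on the same grid.
#' @return matrix of T/h in \[0, 1\]; 0 where h = 0 (no biofilm; such
#'   columns are excluded from streamer/base classification).
#' @export
solidity_map <- function(h, T) {
  stopifnot(all(dim(h) == dim(T)))
  s <- matrix(0, nrow(h), ncol(h))
  nz <- h > 0
  s[nz] <- T[nz] / h[nz]
  s
}

#' Classify streamer columns by solidity
#'
#' Columns with solidity T/h <= 2/3 (inclusive) are streamers; the
#' complement within the biofilm-bearing columns is base structure. Columns
#' without biofilm belong to neither class.
#'
#' @param solidity solidity map.
#' @param h height map (defines where biofilm exists).
#' @param threshold classification threshold (default 2/3).
#' @return logical matrix: TRUE where the column is streamer.
#' @export
classify_streamers <- function(solidity, h, threshold = 2 / 3) {
  # tolerance guards the inclusive boundary against voxel-size rounding
  h > 0 & solidity <= threshold * (1 + 1e-9)
}

#' Substratum coverage
#'
#' Default (`bottom-layer`): the fraction of (x, y) columns with biofilm in
#' the z = 0 voxel layer -- the proportion of the substratum directly
#' covered. The `max-projection` variant instead counts columns with biofilm
#' at any height (the definition used in earlier coverage studies), which is
#' never smaller.
#'
#' @param bvol a flattened [binary_volume()].
#' @param variant `"bottom-layer"` or `"max-projection"`.
#' @return coverage fraction in \[0, 1\].
#' @export
substratum_coverage <- function(bvol, variant = c("bottom-layer", "max-projection")) {
  variant <- match.arg(variant)
  b <- unclass(bvol)
  if (variant == "bottom-layer") mean(b[, , 1])
  else mean(apply(b, c(1, 2), max))
}

#' Biovolume
#'
#' Total binarised biofilm volume: set-voxel count times the voxel volume.
#'
#' @param bvol a [binary_volume()].
#' @return biovolume, cubic micrometres.
#' @export
biovolume <- function(bvol) {
  sum(bvol) * voxel_lateral(bvol)^2 * voxel_axial(bvol)
}

#' Mean biofilm thickness
#'
#' The biovolume normalised by the field-of-view area: T-bar = V_b / A.
#'
#' @param bvol a [binary_volume()].
#' @param A field-of-view area in square micrometres; defaults to the lateral
#'   extent of the volume.
#' @return mean thickness, micrometres.
#' @export
mean_thickness <- function(bvol, A = NULL) {
  d <- dim(bvol)
  if (is.null(A)) A <- d[1] * d[2] * voxel_lateral(bvol)^2
  if (A <= 0) stop("field area A must be positive")
  biovolume(bvol) / A
}

#' Surface maps bundle
#'
#' Computes height, thickness, solidity and the streamer mask in one pass.
#'
#' @param bvol a flattened [binary_volume()].
#' @param streamer_threshold solidity threshold for streamer classification.
#' @return list of class `surface_maps` with elements `h`, `T`, `solidity`,
#'   `streamer_mask`.
#' @export
surface_maps <- function(bvol, streamer_threshold = 2 / 3) {
  h <- height_map(bvol)
  T <- thickness_map(bvol)
  s <- solidity_map(h, T)
  structure(list(h = h, T = T, solidity = s,
                 streamer_mask = classify_streamers(s, h, streamer_threshold)),
            class = "surface_maps")
}

#' Connected-component labelling of a binary volume
#'
#' Utility only (the column statistics above do not require it): labels
#' 6-connected components by iterative flood fill.
#'
#' @param bvol a [binary_volume()].
#' @return integer array of component labels (0 = background).
#' @export
label_components <- function(bvol) {
  b <- unclass(bvol) == 1L
  d <- dim(b)
  labels <- array(0L, d)
  cur <- 0L
  todo <- which(b & labels == 0L)
  while (length(todo)) {
    cur <- cur + 1L
    frontier <- todo[1]
    labels[frontier] <- cur
    while (length(frontier)) {
      k <- frontier - 1L
      x <- k %% d[1]; y <- (k %/% d[1]) %% d[2]; z <- k %/% (d[1] * d[2])
      nb <- c(frontier[x > 0] - 1L, frontier[x < d[1] - 1] + 1L,
              frontier[y > 0] - d[1], frontier[y < d[2] - 1] + d[1],
              frontier[z > 0] - d[1] * d[2], frontier[z < d[3] - 1] + d[1] * d[2])
      nb <- unique(nb[b[nb] & labels[nb] == 0L])
      labels[nb] <- cur
      frontier <- nb
    }
    todo <- which(b & labels == 0L)
  }
  labels
}

#' Summarise one scan
#'
#' @param bvol a flattened, segmented [binary_volume()].
#' @param time scan time, hours.
#' @param tau_w wall shear stress the scan was grown under, Pa.
#' @param A field-of-view area, square micrometres (default: volume extent).
#' @return one-row data frame with time, tau_w, SC (both variants), V_b,
#'   T_bar, A, and the streamer column fraction.
#' @export
scan_summary <- function(bvol, time, tau_w, A = NULL) {
  d <- dim(bvol)
  if (is.null(A)) A <- d[1] * d[2] * voxel_lateral(bvol)^2
  maps <- surface_maps(bvol)
  covered <- maps$h > 0
  data.frame(
    time = time, tau_w = tau_w,
    SC = substratum_coverage(bvol, "bottom-layer"),
    SC_maxproj = substratum_coverage(bvol, "max-projection"),
    V_b = biovolume(bvol),
    T_bar = biovolume(bvol) / A,
    A = A,
    streamer_fraction = if (any(covered)) mean(maps$streamer_mask[covered]) else 0
  )
}
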