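# Synthetic OCT-like phantom volumes with known ground truth.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: Gaussian background noise on an 8-bit scale, a bright substratum
# plane tilted about the cross-stream axis, leaning-pillar microcolonies with
# hemispherical caps, and thin horizontal streamer filaments attached at the
# colony tip extending downstream (+x) with empty voxels beneath.
#
# Ground truth is kept in "flattened" coordinates: z index 0 is the first
# voxel layer above the local substratum plane, matching what the processing
# pipeline produces after flattening and dropping the substratum layer.

#' Background noise specification
#'
#' Empty-volume OCT signal is modelled as i.i.d. Gaussian noise, clipped and
#' quantised to the 8-bit range. The instrument's noise statistics are not
#' published; the defaults (mode 30, sigma 5 on the 0-255 scale) are chosen
#' once as a realistic low-signal background.
#'
#' @param mean_level mean intensity (0-255 scale).
#' @param sigma standard deviation (> 0), intensity levels.
#' @param seed optional integer seed.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(mean_level = 30, sigma = 5, seed = NULL) {
  if (sigma <= 0) stop("sigma must be > 0")
  if (mean_level < 0 || mean_level > 255) stop("mean_level must be in [0, 255]")
  structure(list(mean_level = mean_level, sigma = sigma, seed = seed),
            class = "noise_spec")
}

#' Microcolony specification
#'
#' A microcolony is a leaning pillar (circular footprint, axis tilted
#' downstream, hemispherical cap) optionally bearing a streamer: a thin
#' horizontal filament attached at the tip, aligned with the flow (+x), with
#' background voxels beneath it.
#'
#' @param centre (x, y) footprint centre, voxels.
#' @param radius footprint radius, voxels (>= 1).
#' @param height pillar height, voxels (>= 1).
#' @param lean_angle lean from vertical toward downstream, degrees.
#' @param streamer_length filament length, voxels (0 = no streamer).
#' @param streamer_thickness filament thickness, voxels.
#' @param intensity_mean,intensity_sigma biofilm voxel intensity
#'   distribution; the mean must exceed the background mode so that the
#'   biofilm signal sits above the noise mode.
#' @return a `colony_spec` list.
#' @export
colony_spec <- function(centre, radius, height, lean_angle = 20,
                        streamer_length = 0, streamer_thickness = 2,
                        intensity_mean = 120, intensity_sigma = 10) {
  if (radius < 1) stop("footprint radius must be >= 1 voxel")
  if (height < 1) stop("height must be >= 1 voxel")
  structure(list(centre = centre, radius = radius, height = height,
                 lean_angle = lean_angle, streamer_length = streamer_length,
                 streamer_thickness = streamer_thickness,
                 intensity_mean = intensity_mean,
                 intensity_sigma = intensity_sigma),
            class = "colony_spec")
}

#' Empty ground-truth container
#'
#' @param shape (nx, ny, nz) of the truth grid (flattened coordinates).
#' @param voxel_lateral,voxel_axial voxel sizes, micrometres.
#' @return a `phantom_truth` with an all-zero binary volume, zero height map,
#'   zero footprint area and an empty colony table.
#' @export
phantom_truth <- function(shape, voxel_lateral = 12, voxel_axial = 2.1) {
  shape <- check_shape(shape)
  structure(list(
    true_binary = binary_volume(array(0L, shape), voxel_lateral, voxel_axial),
    true_height_map = matrix(0L, shape[1], shape[2]),
    true_footprint = matrix(FALSE, shape[1], shape[2]),
    colony_table = list()
  ), class = "phantom_truth")
}

#' Footprint area of the ground truth, voxel^2
#' @param truth a `phantom_truth`.
#' @return number of substratum voxels covered by colony footprints.
#' @export
true_footprint_area <- function(truth) sum(truth$true_footprint)

#' Generate a pure-noise volume
#'
#' @param shape (nx, ny, nz) voxel counts.
#' @param noise a [noise_spec()].
#' @param voxel_lateral,voxel_axial voxel sizes, micrometres.
#' @return an [intensity_volume()] of i.i.d. clipped, quantised Gaussian
#'   draws; bit-identical for identical seeds.
#' @export
make_noise_volume <- function(shape, noise = noise_spec(),
                              voxel_lateral = 12, voxel_axial = 2.1) {
  shape <- check_shape(shape)
  vals <- with_seed(noise$seed,
                    stats::rnorm(prod(shape), noise$mean_level, noise$sigma))
  intensity_volume(array(clip_quantise(vals), shape),
                   voxel_lateral, voxel_axial)
}

#' Insert a bright tilted substratum plane
#'
#' The plane's depth varies linearly along x (the tilt emulates the tilted
#' base plate used to suppress specular reflections); each (x, y) column gets
#' its plane voxel set to `brightness` (the column's brightest voxel when
#' `brightness` = 255).
#'
#' @param vol an [intensity_volume()].
#' @param tilt_deg physical tilt about the cross-stream axis, degrees.
#' @param brightness plane intensity (default 255).
#' @param base_depth z-index (0-based) of the plane at x = 1; default 2.
#' @return list with `volume` (plane inserted) and `depth`, the exact
#'   per-(x, y) 0-based plane z-index (ground truth).
#' @export
add_substratum <- function(vol, tilt_deg = 5, brightness = 255, base_depth = 2) {
  d <- dim(vol)
  # physical slope tan(tilt) converts to axial voxels per lateral voxel
  slope <- tan(tilt_deg * pi / 180) * voxel_lateral(vol) / voxel_axial(vol)
  depth_x <- as.integer(round(base_depth + slope * (seq_len(d[1]) - 1)))
  if (any(depth_x < 0) || any(depth_x >= d[3]))
    stop("substratum plane exits the volume; reduce tilt or base_depth")
  data <- unclass(vol)
  for (x in seq_len(d[1])) data[x, , depth_x[x] + 1L] <- brightness
  list(volume = rewrap(vol, data),
       depth = matrix(depth_x, d[1], d[2]))
}

# Slice-wise geometry of a leaning pillar with a rounded cap. The cap is a
# spherical dome capped at a quarter of the pillar height: the body keeps a
# constant cross-section (the growth model approximates a microcolony as
# V = A_fp * h), while the tip stays rounded and well-defined for streamer
# attachment.
# Returns, for each height step k = 0..height-1, the centre x (may be
# fractional) and slice radius.
pillar_profile <- function(colony, voxel_lateral, voxel_axial) {
  k <- seq_len(colony$height) - 1
  lean_shift <- tan(colony$lean_angle * pi / 180) * k * voxel_axial / voxel_lateral
  cap_h <- min(colony$height - 1,
               max(1, round(colony$radius * voxel_lateral / voxel_axial)),
               max(1, round(0.25 * colony$height)))
  r <- rep(colony$radius, colony$height)
  if (colony$height > 1) {
    dk <- k - (colony$height - 1 - cap_h)
    cap <- dk > 0
    r[cap] <- colony$radius * sqrt(pmax(0, 1 - (dk[cap] / (cap_h + 1))^2))
  }
  list(cx = colony$centre[1] + lean_shift, cy = colony$centre[2],
       r = pmax(r, 0.5), k = k)
}

#' Paint a microcolony into a volume
#'
#' Colony voxels receive Gaussian intensities around the colony's intensity
#' mean (clipped and quantised). The colony sits on top of the local
#' substratum: its base occupies the first layer above the substratum plane.
#' Voxels beneath a streamer filament are left untouched (background).
#'
#' @param vol an [intensity_volume()].
#' @param colony a [colony_spec()].
#' @param noise a [noise_spec()] (its mean must be below the colony
#'   intensity mean); only used for validation here.
#' @param substratum_depth per-(x, y) 0-based substratum plane depth (matrix
#'   or single number); colony voxel at truth layer k sits at absolute
#'   z = depth + 1 + k. Default -1 places the base at absolute z = 0.
#' @param truth a `phantom_truth` to update (flattened coordinates), or NULL
#'   to create one matching `vol`.
#' @param seed optional seed for the colony's intensity draws.
#' @return list with `volume` and updated `truth`.
#' @export
add_colony <- function(vol, colony, noise = noise_spec(),
                       substratum_depth = -1L, truth = NULL, seed = NULL) {
  if (colony$intensity_mean <= noise$mean_level)
    stop("biofilm intensity mean must exceed the background mean")
  d <- dim(vol)
  if (is.null(truth))
    truth <- phantom_truth(d, voxel_lateral(vol), voxel_axial(vol))
  if (length(substratum_depth) == 1)
    substratum_depth <- matrix(as.integer(substratum_depth), d[1], d[2])
  prof <- pillar_profile(colony, voxel_lateral(vol), voxel_axial(vol))

  vox <- list()  # rows: x, y, k (truth layer, 0-based)
  for (i in seq_along(prof$k)) {
    r <- prof$r[i]
    xs <- seq(max(1, floor(prof$cx[i] - r)), min(d[1], ceiling(prof$cx[i] + r)))
    ys <- seq(max(1, floor(prof$cy - r)), min(d[2], ceiling(prof$cy + r)))
    if (!length(xs) || !length(ys)) next
    g <- expand.grid(x = xs, y = ys)
    keep <- (g$x - prof$cx[i])^2 + (g$y - prof$cy)^2 <= r^2
    if (!any(keep)) next
    vox[[length(vox) + 1]] <- cbind(g$x[keep], g$y[keep], prof$k[i])
  }
  # streamer: horizontal filament from the tip, extending downstream (+x)
  if (colony$streamer_length > 0) {
    tip_x <- round(prof$cx[length(prof$cx)])
    tip_k <- colony$height - 1
    th <- colony$streamer_thickness
    xs <- (tip_x + 1):(tip_x + colony$streamer_length)
    ys <- seq(floor(prof$cy - (th - 1) / 2), length.out = th)
    ks <- seq(tip_k - th + 1, tip_k)
    g <- expand.grid(x = xs, y = ys, k = ks)
    ok <- g$x >= 1 & g$x <= d[1] & g$y >= 1 & g$y <= d[2] & g$k >= 0
    vox[[length(vox) + 1]] <- cbind(g$x[ok], g$y[ok], g$k[ok])
  }
  vox <- do.call(rbind, vox)
  if (is.null(vox) || !nrow(vox)) stop("colony produced no voxels")
  # absolute z of each voxel: substratum depth of its column + 1 + k
  dep <- substratum_depth[cbind(vox[, 1], vox[, 2])]
  z_abs <- dep + 1L + vox[, 3]
  if (any(z_abs >= d[3]) || any(vox[, 3] >= dim(truth$true_binary)[3]))
    stop("colony does not fit within the volume above the substratum")

  data <- unclass(vol)
  vals <- with_seed(seed, stats::rnorm(nrow(vox), colony$intensity_mean,
                                       colony$intensity_sigma))
  data[cbind(vox[, 1], vox[, 2], z_abs + 1L)] <- clip_quantise(vals)

  tb <- unclass(truth$true_binary)
  tb[cbind(vox[, 1], vox[, 2], vox[, 3] + 1L)] <- 1L
  truth$true_binary <- rewrap(truth$true_binary, tb)
  tops <- tapply(vox[, 3] + 1L, list(factor(vox[, 1], levels = seq_len(d[1])),
                                     factor(vox[, 2], levels = seq_len(d[2]))),
                 max)
  tops[is.na(tops)] <- 0L
  truth$true_height_map <- pmax(truth$true_height_map, tops)
  base <- vox[vox[, 3] == 0, , drop = FALSE]
  truth$true_footprint[cbind(base[, 1], base[, 2])] <- TRUE
  truth$colony_table[[length(truth$colony_table) + 1]] <- colony
  list(volume = rewrap(vol, data), truth = truth)
}

#' Build a complete single-time phantom
#'
#' Convenience wrapper: noise volume + substratum plane + colonies.
#'
#' @param shape (nx, ny, nz).
#' @param colonies list of [colony_spec()].
#' @param noise a [noise_spec()].
#' @param tilt_deg substratum tilt, degrees.
#' @param base_depth substratum plane depth at x = 1 (0-based z).
#' @param seed master seed (split deterministically across noise/colonies).
#' @param voxel_lateral,voxel_axial voxel sizes, micrometres.
#' @return list with `volume`, `truth` and `substratum_depth`.
#' @export
make_phantom <- function(shape, colonies = list(), noise = noise_spec(),
                         tilt_deg = 5, base_depth = 2, seed = 1,
                         voxel_lateral = 12, voxel_axial = 2.1) {
  seeds <- split_seed(seed, length(colonies) + 1)
  ns <- noise_spec(noise$mean_level, noise$sigma, seeds[1])
  vol <- make_noise_volume(shape, ns, voxel_lateral, voxel_axial)
  sub <- add_substratum(vol, tilt_deg = tilt_deg, base_depth = base_depth)
  vol <- sub$volume
  truth <- NULL
  for (i in seq_along(colonies)) {
    res <- add_colony(vol, colonies[[i]], noise = ns,
                      substratum_depth = sub$depth, truth = truth,
                      seed = seeds[i + 1])
    vol <- res$volume
    truth <- res$truth
  }
  if (is.null(truth))
    truth <- phantom_truth(dim(vol), voxel_lateral, voxel_axial)
  list(volume = vol, truth = truth, substratum_depth = sub$depth)
}

#' Time-series specification for the growth phantom
#'
#' Colonies appear as a homogeneous Poisson process and each colony's height
#' follows the deterministic erosion-growth balance from its birth time,
#' saturating at the equilibrium height for the imposed wall shear stress.
#'
#' @param growth_params a [growth_params()].
#' @param tau_w wall shear stress, Pa.
#' @param times scan times, hours, strictly increasing.
#' @param shape (nx, ny, nz) of each volume.
#' @param noise a [noise_spec()].
#' @param seed master integer seed.
#' @param tilt_deg substratum tilt (default 0 for speed; the tilted variant
#'   exercises the flattening path).
#' @param base_depth substratum depth at x = 1.
#' @param streamer_onset fraction of the equilibrium height at which a
#'   colony's streamer appears (default 0.9, emulating the observed
#'   base-then-streamer sequence).
#' @param streamer_length,streamer_thickness streamer geometry, voxels.
#' @param voxel_lateral,voxel_axial voxel sizes, micrometres.
#' @return a `time_series_spec` list.
#' @export
time_series_spec <- function(growth_params, tau_w, times, shape = c(64, 64, 64),
                             noise = noise_spec(), seed = 1, tilt_deg = 0,
                             base_depth = 2, streamer_onset = 0.9,
                             streamer_length = 4, streamer_thickness = 2,
                             voxel_lateral = 12, voxel_axial = 2.1) {
  if (tau_w <= 0) stop("tau_w must be > 0")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(list(growth_params = growth_params, tau_w = tau_w, times = times,
                 shape = check_shape(shape), noise = noise, seed = seed,
                 tilt_deg = tilt_deg, base_depth = base_depth,
                 streamer_onset = streamer_onset,
                 streamer_length = streamer_length,
                 streamer_thickness = streamer_thickness,
                 voxel_lateral = voxel_lateral, voxel_axial = voxel_axial),
            class = "time_series_spec")
}

#' Generate a growth time series of phantom volumes
#'
#' Colony births follow a Poisson process whose rate is `beta` scaled from
#' the reference field area `A` (in the growth parameters) to this phantom's
#' field of view. Colony centres are placed uniformly with rejection of
#' footprint overlaps (capped at 200 attempts per colony; colonies that
#' cannot be placed are dropped with a warning). Heights follow the
#' closed-form erosion-growth solution; a streamer is attached once a colony
#' exceeds `streamer_onset` of its equilibrium height.
#'
#' @param spec a [time_series_spec()].
#' @return list of entries, one per time point, each a list with `time`,
#'   `tau_w`, `volume` (intensity volume), `truth` (ground truth in
#'   flattened coordinates) and `substratum_depth`.
#' @export
generate_time_series <- function(spec) {
  stopifnot(inherits(spec, "time_series_spec"))
  p <- spec$growth_params
  d <- spec$shape
  field_area <- d[1] * d[2] * spec$voxel_lateral^2    # um^2
  rate <- p$beta * field_area / p$A                   # colonies per hour here
  t_max <- max(spec$times)
  h_max <- equilibrium_height(p, spec$tau_w)          # um
  t_c <- characteristic_time(p, spec$tau_w)           # h
  r_vox <- max(1, round(sqrt(p$A_fp / pi) / spec$voxel_lateral))

  seeds <- split_seed(spec$seed, 2 + length(spec$times))
  births <- with_seed(seeds[1], {
    n <- stats::rpois(1, rate * t_max)
    sort(stats::runif(n, 0, t_max))
  })
  # uniform placement, rejection of overlapping footprints
  margin <- 2  # keep clear of the lateral border
  placed <- with_seed(seeds[2], {
    centres <- matrix(numeric(0), 0, 2)
    keep <- logical(length(births))
    for (i in seq_along(births)) {
      ok <- FALSE
      for (try in seq_len(200)) {
        cx <- stats::runif(1, r_vox + margin, d[1] - r_vox - margin)
        cy <- stats::runif(1, r_vox + margin, d[2] - r_vox - margin)
        if (!nrow(centres) ||
            all((centres[, 1] - cx)^2 + (centres[, 2] - cy)^2 > (2 * r_vox + 1)^2)) {
          centres <- rbind(centres, c(cx, cy))
          ok <- TRUE
          break
        }
      }
      keep[i] <- ok
    }
    if (!all(keep))
      warning(sprintf("dropped %d colonies after 200 placement attempts",
                      sum(!keep)))
    list(centres = centres, keep = keep)
  })
  births <- births[placed$keep]
  centres <- placed$centres

  lean <- 20  # degrees, fixed lean toward downstream
  out <- vector("list", length(spec$times))
  for (ti in seq_along(spec$times)) {
    t <- spec$times[ti]
    colonies <- list()
    live <- which(births <= t)
    for (j in live) {
      h_um <- h_max * (1 - exp(-(t - births[j]) / t_c))
      h_vox <- floor(h_um / spec$voxel_axial)
      # cap to the volume: tall colonies cannot exceed the grid
      h_vox <- min(h_vox, d[3] - spec$base_depth - 6)
      if (h_vox < 1) next
      has_streamer <- h_um >= spec$streamer_onset * h_max
      colonies[[length(colonies) + 1]] <- colony_spec(
        centre = centres[j, ], radius = r_vox, height = h_vox,
        lean_angle = lean,
        streamer_length = if (has_streamer) spec$streamer_length else 0,
        streamer_thickness = spec$streamer_thickness)
    }
    ph <- make_phantom(d, colonies, noise = spec$noise,
                       tilt_deg = spec$tilt_deg, base_depth = spec$base_depth,
                       seed = seeds[2 + ti],
                       voxel_lateral = spec$voxel_lateral,
                       voxel_axial = spec$voxel_axial)
    out[[ti]] <- list(time = t, tau_w = spec$tau_w, volume = ph$volume,
                      truth = ph$truth, substratum_depth = ph$substratum_depth)
  }
  out
}

#' Write a ground-truth JSON sidecar
#'
#' @param truth a `phantom_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  tb <- truth$true_binary
  obj <- list(
    shape = dim(tb),
    voxel_lateral = voxel_lateral(tb),
    voxel_axial = voxel_axial(tb),
    true_footprint_area_voxels = true_footprint_area(truth),
    biovolume_voxels = sum(tb),
    n_colonies = length(truth$colony_table),
    colony_table = lapply(truth$colony_table, function(co)
      co[c("centre", "radius", "height", "lean_angle", "streamer_length",
           "streamer_thickness")])
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
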