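# Fixture builders shared across test files. All fixtures are generated in
# code at test time; nothing is read from disk.

# Binary volume with prescribed set z-levels (0-based) in one (x, y) column.
column_volume <- function(levels0, nz = 8, nx = 3, ny = 3, at = c(2, 2),
                          voxel_axial = 2.1) {
  b <- array(0L, c(nx, ny, nz))
  b[at[1], at[2], levels0 + 1] <- 1L
  binary_volume(b, voxel_lateral = 12, voxel_axial = voxel_axial)
}

# The "standard phantom": tilted substratum, two pillars (one with a
# streamer), 5-sigma separation between biofilm mean and background mode.
standard_phantom <- function(seed = 42, shape = c(48, 48, 80)) {
  make_phantom(
    shape,
    colonies = list(
      colony_spec(c(16, 16), radius = 6, height = 28, lean_angle = 15,
                  streamer_length = 6, streamer_thickness = 2),
      colony_spec(c(34, 32), radius = 5, height = 20, lean_angle = 20)
    ),
    noise = noise_spec(30, 5),
    tilt_deg = 5, base_depth = 2, seed = seed
  )
}

# Compare a measured (flattened, substratum-stripped) binary volume to the
# phantom ground truth on their common z-extent.
truth_jaccard <- function(measured, truth) {
  tb <- unclass(truth$true_binary)
  bm <- unclass(measured)
  n <- min(dim(bm)[3], dim(tb)[3])
  inter <- sum(bm[, , 1:n] & tb[, , 1:n])
  extra <- sum(bm) + sum(tb) - sum(bm[, , 1:n]) - sum(tb[, , 1:n])
  union <- sum(bm[, , 1:n] | tb[, , 1:n]) + extra
  inter / union
}

# Small growth parameter set whose colonies fit comfortably in short test
# volumes (equilibrium height ~63 um at 0.67 Pa).
test_growth_params <- function() {
  growth_params(g = 12.5, C = 0.17, mu_b = 1000, beta = 15.8,
                A_fp = 1.13e4, A = 1e8)
}
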