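# Synthetic volume generator: noise statistics, substratum geometry, colony
# ground truth, growth time series.

test_that("noise volumes have the requested mode, are deterministic, and reject bad shapes", {
  v <- make_noise_volume(c(64, 64, 64), noise_spec(30, 5, seed = 1))
  hist <- tabulate(as.integer(v) + 1L, 256)
  expect_lte(abs((which.max(hist) - 1) - 30), 2)

  # degenerate sigma -> every voxel at the mean
  v0 <- make_noise_volume(c(8, 8, 8), noise_spec(30, 1e-9, seed = 1))
  expect_true(all(unclass(v0) == 30))

  # determinism under a fixed seed
  a <- make_noise_volume(c(16, 16, 16), noise_spec(30, 5, seed = 7))
  b <- make_noise_volume(c(16, 16, 16), noise_spec(30, 5, seed = 7))
  expect_identical(unclass(a), unclass(b))

  expect_error(make_noise_volume(c(0, 4, 4), noise_spec()), "positive")
  expect_error(noise_spec(sigma = 0))
  expect_error(noise_spec(mean_level = 300))
})

test_that("tail mass above mean + 3 sigma matches the Gaussian prediction", {
  # quantisation makes 'above 45' mean raw draws above 45.5
  v <- make_noise_volume(c(64, 64, 64), noise_spec(30, 5, seed = 11))
  p_exact <- stats::pnorm(45.5, 30, 5, lower.tail = FALSE)
  n <- length(v)
  frac <- mean(unclass(v) > 45)
  expect_lt(abs(frac - p_exact), 4 * sqrt(p_exact * (1 - p_exact) / n))
  # the nominal 3-sigma tail is the right order
  expect_lt(frac, 2 * 0.00135)
  expect_gt(frac, 0.00135 / 3)
})

test_that("substratum plane has the prescribed tilt and is the per-column argmax", {
  v <- make_noise_volume(c(40, 20, 40), noise_spec(30, 5, seed = 2))
  # zero tilt -> constant depth
  flat <- add_substratum(v, tilt_deg = 0, base_depth = 5)
  expect_true(all(flat$depth == 5))

  # 5 degrees with 12/2.1 um voxels -> ~0.5 axial voxels per lateral voxel
  tilted <- add_substratum(v, tilt_deg = 5, base_depth = 2)
  slope <- (tilted$depth[40, 1] - tilted$depth[1, 1]) / 39
  expect_equal(slope, tan(5 * pi / 180) * 12 / 2.1, tolerance = 0.05)

  # brightness 255 -> argmax along z equals the plane depth everywhere
  m <- matrix(unclass(tilted$volume), 40 * 20, 40)
  argmax <- matrix(max.col(m, ties.method = "first") - 1L, 40, 20)
  expect_identical(argmax, tilted$depth)

  expect_error(add_substratum(v, tilt_deg = 40, base_depth = 30), "exits")
})

test_that("colony ground truth: solid pillars, streamer solidity, additivity", {
  nz <- 40
  base <- make_noise_volume(c(40, 24, nz), noise_spec(30, 5, seed = 3))

  # vertical cylinder, no streamer -> solidity 1 over its footprint
  res <- add_colony(base, colony_spec(c(10, 12), radius = 3, height = 12,
                                      lean_angle = 0))
  tb <- res$truth$true_binary
  maps <- surface_maps(tb)
  fp <- res$truth$true_footprint
  expect_true(all(maps$solidity[fp] == 1))

  # streamer of thickness 1 at tip height h over empty space: solidity 1/h
  h <- 10
  res2 <- add_colony(base, colony_spec(c(10, 12), radius = 2, height = h,
                                       lean_angle = 0, streamer_length = 4,
                                       streamer_thickness = 1))
  t2 <- res2$truth
  sol <- surface_maps(t2$true_binary)$solidity
  streamer_cols <- unclass(t2$true_binary)[, , h] == 1 &
    apply(unclass(t2$true_binary)[, , 1:(h - 1), drop = FALSE], c(1, 2), sum) == 0
  expect_true(any(streamer_cols))
  expect_true(all(abs(sol[streamer_cols] - 1 / h) < 1e-12))
  expect_true(all(sol[streamer_cols] <= 2 / 3))

  # two disjoint colonies -> footprint areas add
  one <- add_colony(base, colony_spec(c(8, 8), radius = 3, height = 8, lean_angle = 0))
  two <- add_colony(one$volume, colony_spec(c(30, 16), radius = 4, height = 8,
                                            lean_angle = 0), truth = one$truth)
  a1 <- true_footprint_area(one$truth)
  solo2 <- add_colony(base, colony_spec(c(30, 16), radius = 4, height = 8,
                                        lean_angle = 0))
  expect_equal(true_footprint_area(two$truth),
               a1 + true_footprint_area(solo2$truth))
  # conservation: truth biovolume equals the sum of per-colony voxel counts
  expect_equal(sum(two$truth$true_binary),
               sum(one$truth$true_binary) + sum(solo2$truth$true_binary))

  expect_error(add_colony(base, colony_spec(c(10, 12), radius = 3, height = nz + 5,
                                            lean_angle = 0)), "fit")
})

test_that("beta = 0 yields sterile volumes (noise + substratum only)", {
  p0 <- growth_params(beta = 0)
  sp <- time_series_spec(p0, tau_w = 0.27, times = c(12, 24),
                         shape = c(24, 24, 32), tilt_deg = 5, seed = 2)
  ser <- generate_time_series(sp)
  expect_equal(sum(ser[[1]]$truth$true_binary), 0)
  expect_equal(length(ser[[2]]$truth$colony_table), 0)
})

test_that("time series: determinism, expected colony count, shear scaling", {
  p <- test_growth_params()
  spec <- time_series_spec(p, tau_w = 0.67, times = c(6, 24),
                           shape = c(32, 32, 48), seed = 5)
  s1 <- generate_time_series(spec)
  s2 <- generate_time_series(spec)
  expect_identical(unclass(s1[[2]]$volume), unclass(s2[[2]]$volume))
  expect_identical(unclass(s1[[1]]$truth$true_binary),
                   unclass(s2[[1]]$truth$true_binary))

  # expected number of colonies at time t is (scaled) beta * t
  field_frac <- 32 * 32 * 12^2 / p$A
  rate <- p$beta * field_frac
  t_end <- 40
  counts <- vapply(1:60, function(i) {
    sp <- time_series_spec(p, 0.67, times = t_end, shape = c(32, 32, 48),
                           seed = 1000 + i)
    length(generate_time_series(sp)[[1]]$truth$colony_table)
  }, 0)
  lambda <- rate * t_end
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 60))

  # doubling tau_w halves the saturated ground-truth colony height
  tall <- generate_time_series(time_series_spec(p, 0.2, times = 100,
                                                shape = c(32, 32, 120), seed = 9))
  short <- generate_time_series(time_series_spec(p, 0.4, times = 100,
                                                 shape = c(32, 32, 120), seed = 9))
  h_tall <- max(tall[[1]]$truth$true_height_map)
  h_short <- max(short[[1]]$truth$true_height_map)
  expect_gt(h_tall, 0)
  expect_equal(h_tall / h_short, 2, tolerance = 0.1)
  expect_equal(equilibrium_height(p, 0.2) / equilibrium_height(p, 0.4), 2)
})

test_that("ensemble ground-truth mean thickness tracks the arrival-integral prediction", {
  p <- test_growth_params()
  tau <- 0.67                      # t_c ~ 2.4 h, saturation well before t
  t_obs <- 24
  shape <- c(64, 64, 48)
  n_rep <- 100
  tbars <- vapply(seq_len(n_rep), function(i) {
    sp <- time_series_spec(p, tau, times = t_obs, shape = shape,
                           seed = 5000 + i)
    mean_thickness(generate_time_series(sp)[[1]]$truth$true_binary)
  }, 0)

  # oracle: continuous-arrival average of the painted colony volume at the
  # closed-form height for each birth time (pillar geometry from
  # add_colony; streamer attached above the onset fraction, as in the
  # generator's stated world)
  h_max_um <- equilibrium_height(p, tau)
  t_c <- characteristic_time(p, tau)
  r_vox <- max(1, round(sqrt(p$A_fp / pi) / 12))
  base <- intensity_volume(array(30L, c(26, 26, 18)))
  offs <- expand.grid(ox = (0:3) / 4, oy = (0:3) / 4)
  vox_at_height <- vapply(seq_len(floor(h_max_um / 2.1)), function(hv) {
    streamer <- (hv * 2.1) >= 0.9 * h_max_um
    # average the painted volume over sub-voxel centre positions, since the
    # generator places colonies at continuous uniform coordinates
    mean(vapply(seq_len(nrow(offs)), function(j) {
      proto <- colony_spec(c(10 + offs$ox[j], 13 + offs$oy[j]),
                           radius = r_vox, height = hv, lean_angle = 20,
                           streamer_length = if (streamer) 4 else 0,
                           streamer_thickness = 2)
      sum(add_colony(base, proto)$truth$true_binary)
    }, 0))
  }, 0)
  births <- seq(0.0005, 0.9995, by = 0.001) * t_obs
  h_at_birth <- floor(h_max_um * (1 - exp(-(t_obs - births) / t_c)) / 2.1)
  mean_vox <- mean(ifelse(h_at_birth >= 1, vox_at_height[pmax(h_at_birth, 1)], 0))
  rate <- p$beta * shape[1] * shape[2] * 12^2 / p$A
  pred <- rate * t_obs * mean_vox * 12^2 * 2.1 / (shape[1] * shape[2] * 12^2)
  expect_equal(mean(tbars), pred, tolerance = 0.10)

  # and it is the same order as the idealised equilibrium law K/A * t / tau
  eq <- population_biovolume(p, t_obs, tau, mode = "equilibrium")$T_bar
  expect_equal(mean(tbars), eq, tolerance = 0.30)
})
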