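# Friction-limited growth: the erosion-growth balance for a single
# microcolony, its population consequences, and power-law fitting of mean
# thickness against time and wall shear stress.
#
# Single colony: dh/dt = g - e with constant biological growth g and erosion
# e = (C / mu_b) h tau_w, a linear relaxation towards the equilibrium height
# h_max = g mu_b / (C tau_w) with time constant t_c = mu_b / (C tau_w).
# Population: colonies appear at constant rate beta and mature quickly, so
# with a common footprint A_fp the biovolume is V_b = beta t A_fp h_max =
# K t / tau_w, K = beta A_fp g mu_b / C, and the mean thickness over a field
# of area A is T_bar = (K / A) t / tau_w: time and shear stress enter only
# through t / tau_w.
#
# Unit system: heights in um, times in hours, stresses in Pa; mu_b is kept
# in Pa s and converted with 3600 s/h where the stress-over-viscosity strain
# rate enters.

#' Growth-model parameters
#'
#' @param g biological height growth rate, um/h.
#' @param C dimensionless erosion coefficient.
#' @param mu_b reference biofilm viscosity, Pa s.
#' @param beta colony appearance rate over the reference field, 1/h (zero
#'   allowed: a sterile field).
#' @param A_fp footprint area of one microcolony, um^2.
#' @param A reference field-of-view area, um^2.
#' @return a `growth_params` list.
#'
#' @details Defaults place the equilibrium height near 300 um and the
#' saturation time near one day at the lowest experimental wall shear stress
#' (0.068 Pa), with mu_b = 1000 Pa s from the streamer-fluidisation
#' estimate; beta and A_fp are set so a 10 x 10 mm field reaches a
#' substratum coverage of order 0.3 after a week.
#' @export
growth_params <- function(g = 12.5, C = 0.17, mu_b = 1000,
                          beta = 15.8, A_fp = 1.13e4, A = 1e8) {
  vals <- c(g = g, C = C, mu_b = mu_b, beta = beta, A_fp = A_fp, A = A)
  if (any(vals[names(vals) != "beta"] <= 0) || beta < 0)
    stop("growth parameters must be positive (beta may be zero)")
  structure(as.list(vals), class = "growth_params")
}

#' Erosion rate
#'
#' e = (C / mu_b) h_mc tau_w, converted to um/h.
#'
#' @param h_mc microcolony height, um (>= 0).
#' @param tau_w wall shear stress, Pa.
#' @param p a [growth_params()].
#' @return erosion rate, um/h.
#' @export
erosion_rate <- function(h_mc, tau_w, p) {
  if (any(h_mc < 0)) stop("h_mc must be >= 0")
  3600 * p$C * h_mc * tau_w / p$mu_b
}

#' Equilibrium microcolony height
#'
#' h_max = g mu_b / (C tau_w): growth balances erosion, giving a maximum
#' height inversely proportional to the wall shear stress.
#'
#' @param p a [growth_params()].
#' @param tau_w wall shear stress, Pa (> 0).
#' @return equilibrium height, um.
#' @export
equilibrium_height <- function(p, tau_w) {
  if (any(tau_w <= 0)) stop("tau_w must be > 0 (height unbounded otherwise)")
  p$g * p$mu_b / (3600 * p$C * tau_w)
}

#' Relaxation time of the height dynamics
#'
#' t_c = mu_b / (C tau_w), hours.
#'
#' @inheritParams equilibrium_height
#' @return characteristic time, hours.
#' @export
characteristic_time <- function(p, tau_w) {
  if (any(tau_w <= 0)) stop("tau_w must be > 0")
  p$mu_b / (3600 * p$C * tau_w)
}

#' Fluid velocity at the equilibrium tip height
#'
#' u_max = h_max (tau_w / mu) = (g / C)(mu_b / mu): independent of the wall
#' shear stress, a colony grows until it meets a fixed characteristic flow
#' velocity.
#'
#' @param p a [growth_params()].
#' @param mu medium dynamic viscosity, Pa s.
#' @return tip velocity, um/s.
#' @export
tip_velocity <- function(p, mu) {
  if (mu <= 0) stop("mu must be positive")
  (p$g / 3600) * p$mu_b / (p$C * mu)
}

#' Closed-form microcolony height
#'
#' h(t) = h_max + (h0 - h_max) exp(-t / t_c).
#'
#' @param p a [growth_params()].
#' @param tau_w wall shear stress, Pa.
#' @param t times, hours.
#' @param h0 initial height, um.
#' @return heights, um.
#' @export
closed_form_height <- function(p, tau_w, t, h0 = 0) {
  h_max <- equilibrium_height(p, tau_w)
  t_c <- characteristic_time(p, tau_w)
  h_max + (h0 - h_max) * exp(-t / t_c)
}

#' Numerically integrate the height balance
#'
#' Classical fourth-order Runge-Kutta on dh/dt = g - e(h), with substeps
#' sized well below the relaxation time so the solution matches the closed
#' form to better than 1e-6 relative error.
#'
#' @param p a [growth_params()].
#' @param tau_w wall shear stress, Pa.
#' @param t_grid increasing times, hours (first entry is the initial time).
#' @param h0 initial height, um.
#' @return data frame with columns t and h.
#' @export
solve_height <- function(p, tau_w, t_grid, h0 = 0) {
  if (any(diff(t_grid) <= 0)) stop("t_grid must be strictly increasing")
  t_c <- characteristic_time(p, tau_w)
  f <- function(h) p$g - erosion_rate(h, tau_w, p)
  h <- numeric(length(t_grid))
  h[1] <- h0
  for (i in seq_along(t_grid)[-1]) {
    dt_full <- t_grid[i] - t_grid[i - 1]
    n_sub <- max(1L, ceiling(dt_full / (t_c / 50)))
    dt <- dt_full / n_sub
    hi <- h[i - 1]
    for (s in seq_len(n_sub)) {
      k1 <- f(hi)
      k2 <- f(hi + dt / 2 * k1)
      k3 <- f(hi + dt / 2 * k2)
      k4 <- f(hi + dt * k3)
      hi <- hi + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    h[i] <- hi
  }
  data.frame(t = t_grid, h = h)
}

#' Composite growth constant K
#'
#' K = beta A_fp g mu_b / C (um^3 Pa / h): everything biological, material
#' and geometrical that multiplies t / tau_w in the biovolume law.
#'
#' @param p a [growth_params()].
#' @return K, um^3 Pa / h.
#' @export
growth_constant <- function(p) {
  p$beta * p$A_fp * p$g * p$mu_b / (3600 * p$C)
}

#' Population biovolume and mean thickness
#'
#' Equilibrium mode (the model's headline result): all colonies sit at their
#' equilibrium height, so V_b = beta t A_fp h_max = K t / tau_w and
#' T_bar = (K / A) t / tau_w. Integrated mode refines this by averaging the
#' closed-form transient height over the uniform arrival density, V_b =
#' beta A_fp h_max (t - t_c (1 - exp(-t / t_c))); it converges to the
#' equilibrium mode for t >> t_c.
#'
#' @param p a [growth_params()].
#' @param t time, hours (>= 0).
#' @param tau_w wall shear stress, Pa.
#' @param mode `"equilibrium"` or `"integrated"`.
#' @return data frame with columns t, tau_w, V_b (um^3) and T_bar (um).
#' @export
population_biovolume <- function(p, t, tau_w, mode = c("equilibrium", "integrated")) {
  mode <- match.arg(mode)
  if (any(t < 0)) stop("t must be >= 0")
  h_max <- equilibrium_height(p, tau_w)
  t_c <- characteristic_time(p, tau_w)
  V_b <- if (mode == "equilibrium") {
    p$beta * t * p$A_fp * h_max
  } else {
    p$beta * p$A_fp * h_max * (t - t_c * (1 - exp(-t / t_c)))
  }
  data.frame(t = t, tau_w = tau_w, V_b = V_b, T_bar = V_b / p$A)
}

#' Fit the power law T_bar = a t tau_w^k
#'
#' Unweighted nonlinear least squares on the original scale. The initial
#' guess comes from ordinary least squares of log(T_bar / t) on log(tau_w);
#' the objective is then minimised by BFGS and parameter standard deviations
#' are taken from the curvature of the residual sum of squares at the
#' optimum (cov = 2 s^2 H^-1 with s^2 the residual variance).
#'
#' @param points data frame with columns `t` (h), `tau_w` (Pa) and `T_bar`
#'   (um); needs >= 3 points spanning >= 2 distinct tau_w values, all with
#'   T_bar > 0 and t > 0.
#' @return list with `a`, `k`, `a_sd`, `k_sd`, `rss` and `n`.
#' @export
fit_power_law <- function(points) {
  req <- c("t", "tau_w", "T_bar")
  if (!all(req %in% names(points))) stop("points needs columns t, tau_w, T_bar")
  pts <- points[points$t > 0 & points$T_bar > 0, ]
  if (nrow(pts) < 3) stop("need at least 3 usable points (t > 0, T_bar > 0)")
  if (length(unique(pts$tau_w)) < 2)
    stop("exponent k is unidentifiable from a single tau_w value")
  init <- stats::lm(log(T_bar / t) ~ log(tau_w), data = pts)
  a0 <- exp(stats::coef(init)[1]); k0 <- stats::coef(init)[2]
  ssr <- function(par) {
    r <- pts$T_bar - par[1] * pts$t * pts$tau_w^par[2]
    sum(r^2)
  }
  opt <- stats::optim(c(a0, k0), ssr, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-14))
  s2 <- opt$value / max(nrow(pts) - 2, 1)
  cov <- tryCatch(2 * s2 * solve(opt$hessian), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  list(a = unname(opt$par[1]), k = unname(opt$par[2]),
       a_sd = sqrt(max(cov[1, 1], 0)), k_sd = sqrt(max(cov[2, 2], 0)),
       rss = opt$value, n = nrow(pts))
}

#' Recover the growth power law from pipeline summaries
#'
#' End-to-end path: scan summaries (as produced by [scan_summary()] /
#' [run_pipeline()]) for several shear conditions are pooled and passed to
#' [fit_power_law()].
#'
#' @param summaries data frame with columns `time`, `tau_w`, `T_bar` (one
#'   row per processed scan), covering >= 2 shear conditions.
#' @return the [fit_power_law()] result.
#' @export
recover_from_pipeline <- function(summaries) {
  pts <- data.frame(t = summaries$time, tau_w = summaries$tau_w,
                    T_bar = summaries$T_bar)
  fit_power_law(pts)
}
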