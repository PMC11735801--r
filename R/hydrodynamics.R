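# Channel hydrodynamics: plane Poiseuille wall shear stress, hydraulic
# diameter, Reynolds number, and the streamer-fluidisation viscosity
# estimate.
#
# All quantities are SI internally. The flow cells are wide rectangular
# ducts (aspect ratio >= 10) so the wall shear stress follows from plane
# Poiseuille flow: tau_w = 6 mu Q / (H^2 w).

#' Channel and fluid specification (SI units)
#'
#' @param H channel height, m.
#' @param w channel width, m.
#' @param Q volumetric flow rate, m^3/s.
#' @param mu dynamic viscosity, Pa s.
#' @param rho fluid density, kg/m^3 (default 997, water near 25 degrees C).
#' @return a `channel_spec` list.
#' @export
channel_spec <- function(H, w, Q, mu, rho = 997) {
  if (H <= 0 || w <= 0 || Q < 0 || mu <= 0 || rho <= 0)
    stop("channel geometry and fluid properties must be positive")
  if (w / H < 10)
    warning(sprintf("aspect ratio w/H = %.2f < 10; plane Poiseuille estimate degrades",
                    w / H))
  structure(list(H = H, w = w, Q = Q, mu = mu, rho = rho),
            class = "channel_spec")
}

#' Channel specification in laboratory units
#'
#' Accepts the units used on the bench: mm, mL/s, mPa s.
#'
#' @param H_mm channel height, mm.
#' @param w_mm channel width, mm.
#' @param Q_mL_s flow rate, mL/s.
#' @param mu_mPa_s dynamic viscosity, mPa s.
#' @param rho fluid density, kg/m^3.
#' @return a `channel_spec` (SI).
#' @export
channel_spec_lab <- function(H_mm, w_mm, Q_mL_s, mu_mPa_s, rho = 997) {
  channel_spec(H = H_mm * 1e-3, w = w_mm * 1e-3, Q = Q_mL_s * 1e-6,
               mu = mu_mPa_s * 1e-3, rho = rho)
}

#' Plane Poiseuille wall shear stress
#'
#' tau_w = 6 mu Q / (H^2 w).
#'
#' @param c a [channel_spec()].
#' @return wall shear stress, Pa.
#' @export
wall_shear_stress <- function(c) {
  6 * c$mu * c$Q / (c$H^2 * c$w)
}

#' Hydraulic diameter of a rectangular duct
#'
#' D_H = 2 H w / (H + w).
#'
#' @param H channel height, m (or any consistent unit).
#' @param w channel width, same unit.
#' @return hydraulic diameter, same unit.
#' @export
hydraulic_diameter <- function(H, w) {
  if (H <= 0 || w <= 0) stop("H and w must be positive")
  2 * H * w / (H + w)
}

#' Bulk velocity
#'
#' U_b = Q / (H w).
#'
#' @param c a [channel_spec()].
#' @return bulk velocity, m/s.
#' @export
bulk_velocity <- function(c) c$Q / (c$H * c$w)

#' Reynolds number
#'
#' Re = U_b D_H rho / mu.
#'
#' @param c a [channel_spec()].
#' @return Reynolds number (dimensionless).
#' @export
reynolds <- function(c) {
  bulk_velocity(c) * hydraulic_diameter(c$H, c$w) * c$rho / c$mu
}

#' All derived flow conditions for a channel
#'
#' @param c a [channel_spec()].
#' @return one-row data frame: tau_w (Pa), U_b (m/s), D_H (m), Re.
#' @export
flow_conditions <- function(c) {
  data.frame(tau_w = wall_shear_stress(c), U_b = bulk_velocity(c),
             D_H = hydraulic_diameter(c$H, c$w), Re = reynolds(c))
}

#' The six experimental flow configurations
#'
#' Channel geometry and fluid properties of the six cases (heights 1, sqrt 2
#' and 2 mm at flow rates 1 and 2.63 mL/s; viscosity 0.91 / 0.85 mPa s at
#' the two operating temperatures), together with the published reference
#' values of D_H, Re and tau_w for comparison. Note the published D_H
#' entries of cases 4 and 5 are inconsistent with their heights (they appear
#' transposed); the geometry columns are authoritative.
#'
#' @param rho fluid density used for derived quantities, kg/m^3.
#' @return data frame with columns case, H_mm, w_mm, Q_mL_s, mu_mPa_s and
#'   reference columns ref_D_H_mm, ref_Re, ref_tau_w.
#' @export
flow_cases <- function(rho = 997) {
  data.frame(
    case = 1:6,
    H_mm = c(2, sqrt(2), 2, 1, sqrt(2), 1),
    w_mm = 20,
    Q_mL_s = c(1, 1, 2.63, 1, 2.63, 2.63),
    mu_mPa_s = c(0.91, 0.91, 0.85, 0.91, 0.85, 0.85),
    rho = rho,
    ref_D_H_mm = c(3.63, 2.64, 3.63, 2.64, 1.9, 1.9),
    ref_Re = c(100, 100, 300, 100, 300, 300),
    ref_tau_w = c(0.068, 0.14, 0.17, 0.27, 0.34, 0.67)
  )
}

#' Flow conditions for all six cases
#'
#' @inheritParams flow_cases
#' @return [flow_cases()] augmented with computed tau_w, U_b, D_H_mm, Re.
#' @export
flow_case_conditions <- function(rho = 997) {
  tab <- flow_cases(rho)
  derived <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    c <- channel_spec_lab(tab$H_mm[i], tab$w_mm[i], tab$Q_mL_s[i],
                          tab$mu_mPa_s[i], rho)
    flow_conditions(c)
  }))
  derived$D_H_mm <- derived$D_H * 1e3
  cbind(tab, derived[c("tau_w", "U_b", "D_H_mm", "Re")])
}

#' Biofilm viscosity from streamer fluidisation
#'
#' A fluidised streamer elongates at a normal strain rate set by the local
#' shear stress over the biofilm viscosity: (1/L0) dL/dt = tau_s / mu_b.
#' Inverting over a finite stretch gives mu_b = tau_s dt L0 / (L - L0).
#'
#' @param L0 initial streamer length, m (> 0).
#' @param L final length, m (>= L0, strictly greater).
#' @param dt elapsed time, s (> 0).
#' @param tau_s local shear stress at the streamer, Pa.
#' @return biofilm viscosity, Pa s.
#' @export
streamer_viscosity <- function(L0, L, dt, tau_s) {
  if (L0 <= 0 || dt <= 0) stop("L0 and dt must be positive")
  if (L < L0) stop("final length must be >= initial length")
  if (L == L0) stop("zero elongation implies infinite viscosity")
  tau_s * dt * L0 / (L - L0)
}

#' Local shear stress at a microcolony tip
#'
#' Flow accelerating over the colony tip amplifies the driving wall shear
#' stress; the amplification factor (default 3, from flow simulation around
#' a tilted cylinder) is taken as a constant input.
#'
#' @param tau_w wall shear stress, Pa (>= 0).
#' @param amplification amplification factor (default 3).
#' @return local tip shear stress, Pa.
#' @export
tip_shear <- function(tau_w, amplification = 3) {
  if (tau_w < 0) stop("tau_w must be >= 0")
  amplification * tau_w
}
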