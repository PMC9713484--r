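#' Potential electron transport rate
#'
#' Light absorbed by photosystem II is `I_2 = beta * I_s * alpha * (1 - f) / 2`
#' and the potential electron transport rate `J` is the smaller root of the
#' non-rectangular hyperbola
#' `theta * J^2 - (I_2 + J_max) * J + I_2 * J_max = 0`,
#' so `J <= min(I_2, J_max)` with a smooth transition governed by `theta`.
#'
#' @param I_s Solar irradiance (W m^-2); vectorised.
#' @param J_max Maximum electron transport rate (umol m^-2 s^-1).
#' @param theta Curvature factor, in (0, 1).
#' @param alpha Leaf absorptance.
#' @param f Spectral light quality correction.
#' @param beta Irradiance-to-photon conversion (umol J^-1).
#' @return List with `J` and `I_2` (umol m^-2 s^-1).
#' @export
electron_transport <- function(I_s, J_max, theta = 0.7, alpha = 0.85,
                               f = 0.15, beta = 2.1) {
  if (!(theta > 0 && theta < 1)) stop("theta must be in (0, 1)", call. = FALSE)
  if (any(J_max <= 0)) stop("J_max must be positive", call. = FALSE)
  I_2 <- beta * I_s * alpha * (1 - f) / 2
  disc <- pmax((I_2 + J_max)^2 - 4 * theta * I_2 * J_max, 0)
  J <- (I_2 + J_max - sqrt(disc)) / (2 * theta)
  list(J = J, I_2 = I_2)
}

#' C3 assimilation rates
#'
#' RuBisCo-limited and electron-transport-limited assimilation for the C3
#' pathway:
#' `A_c = V_cmax * (C_m - gamma_star) / (C_m + K_C * (1 + O_m / K_O))` and
#' `A_j = (C_m - gamma_star) * J / (4 * C_m + 8 * gamma_star)`;
#' the realised rate is `A = min(A_c, A_j)` (phosphate limitation is assumed
#' absent). `A` excludes dark respiration.
#'
#' @param C_m Mesophyll CO2 concentration (umol/mol).
#' @param O_m Mesophyll O2 concentration, in the same units as `K_O`.
#' @param J Potential electron transport rate (umol m^-2 s^-1).
#' @param V_cmax Maximum carboxylation rate (umol m^-2 s^-1).
#' @param K_C,K_O RuBisCo Michaelis constants for CO2 and O2 (`K_O` in the
#'   same units as `O_m`).
#' @param gamma_star CO2 compensation point without dark respiration
#'   (umol/mol).
#' @return List with `A`, `A_c`, `A_j` (umol m^-2 s^-1).
#' @export
c3_assimilation <- function(C_m, O_m, J, V_cmax, K_C, K_O, gamma_star) {
  if (V_cmax <= 0 || K_C <= 0 || K_O <= 0 || gamma_star < 0) {
    stop("kinetic parameters must be positive", call. = FALSE)
  }
  A_c <- V_cmax * (C_m - gamma_star) / (C_m + K_C * (1 + O_m / K_O))
  A_j <- (C_m - gamma_star) * J / (4 * C_m + 8 * gamma_star)
  list(A = pmin(A_c, A_j), A_c = A_c, A_j = A_j)
}

#' PEP carboxylation rate
#'
#' Michaelis-Menten CO2 fixation by PEP carboxylase in the C4 mesophyll,
#' capped by the PEP regeneration rate:
#' `V_p = min(C_m * V_pmax / (C_m + K_P), V_pr)`.
#'
#' @param C_m Mesophyll CO2 concentration (umol/mol).
#' @param V_pmax Maximum PEP carboxylation rate (umol m^-2 s^-1).
#' @param K_P Michaelis constant for PEP carboxylation (umol/mol).
#' @param V_pr PEP regeneration rate (umol m^-2 s^-1).
#' @return `V_p` (umol m^-2 s^-1).
#' @export
pep_carboxylation <- function(C_m, V_pmax, K_P, V_pr) {
  if (V_pmax <= 0 || K_P <= 0 || V_pr <= 0) {
    stop("PEP parameters must be positive", call. = FALSE)
  }
  pmin(C_m * V_pmax / (C_m + K_P), V_pr)
}

#' C4 assimilation rates
#'
#' Bundle-sheath assimilation for the C4 pathway with
#' `gamma_bs = 0.5 / S_c/o` (half the reciprocal RuBisCo specificity):
#' `A_c = (C_s - gamma_bs * O_s) * V_cmax / (C_s + K_C * (1 + O_s / K_O))`,
#' `A_j = (C_s - gamma_bs * O_s) * (1 - x) * J / (3 * C_s + 7 * gamma_bs * O_s)`,
#' and `A = min(A_c, A_j)`. All concentrations in umol/mol (`K_O` and `O_s`
#' must be unit-consistent).
#'
#' @param C_s,O_s Bundle-sheath CO2 and O2 concentrations (umol/mol).
#' @param J Potential electron transport rate (umol m^-2 s^-1).
#' @param V_cmax Maximum carboxylation rate (umol m^-2 s^-1).
#' @param K_C,K_O RuBisCo Michaelis constants (umol/mol).
#' @param gamma_bs Half reciprocal RuBisCo specificity (dimensionless, for
#'   concentrations in umol/mol).
#' @param x Electron transport partitioning factor.
#' @return List with `A`, `A_c`, `A_j` (umol m^-2 s^-1).
#' @export
c4_assimilation <- function(C_s, O_s, J, V_cmax, K_C, K_O, gamma_bs, x = 0.4) {
  if (V_cmax <= 0 || K_C <= 0 || K_O <= 0 || gamma_bs <= 0 || x < 0 || x > 1) {
    stop("kinetic parameters must be positive and x in [0, 1]", call. = FALSE)
  }
  num <- C_s - gamma_bs * O_s
  A_c <- num * V_cmax / (C_s + K_C * (1 + O_s / K_O))
  A_j <- num * (1 - x) * J / (3 * C_s + 7 * gamma_bs * O_s)
  list(A = pmin(A_c, A_j), A_c = A_c, A_j = A_j)
}

#' Quasi-steady-state C3 leaf gas concentrations
#'
#' At steady state the stomatal CO2/O2 fluxes balance net assimilation:
#' `C_m = C_A - 1.6 * (A - R_d) / g_w` and
#' `O_m = O_A + 1.25 * (A - R_d) / g_w`
#' (1.6 and 1.25 are the water:CO2 and water:O2 diffusivity ratios).
#' All concentrations in umol/mol.
#'
#' @param g_w Stomatal conductance to water (mol m^-2 s^-1), positive.
#' @param A Assimilation rate excluding dark respiration (umol m^-2 s^-1).
#' @param R_d Dark respiration (umol m^-2 s^-1).
#' @param C_A,O_A Atmospheric CO2 and O2 concentrations (umol/mol).
#' @return List with `C_m` and `O_m` (umol/mol).
#' @export
c3_gas_steady_state <- function(g_w, A, R_d, C_A, O_A) {
  if (any(g_w <= 0)) stop("g_w must be positive for a steady state", call. = FALSE)
  list(
    C_m = C_A - 1.6 * (A - R_d) / g_w,
    O_m = O_A + 1.25 * (A - R_d) / g_w
  )
}

#' Quasi-steady-state C4 leaf gas concentrations
#'
#' Mesophyll and bundle sheath are connected gas reservoirs: the mesophyll
#' exchanges CO2/O2 with the atmosphere through stomata (conductances
#' `g_w/1.6` and `g_w/1.25`) and with the bundle sheath (conductances `g_s`
#' for CO2 and `0.047 * g_s` for O2); PEP carboxylation `V_p` pumps CO2 into
#' the bundle sheath where assimilation `A_r` consumes it. The steady state
#' of the four balance equations is linear in the concentrations and is
#' solved here as two 2x2 linear systems (CO2 side and O2 side).
#'
#' @param g_w Stomatal conductance to water (mol m^-2 s^-1).
#' @param g_s Mesophyll/bundle-sheath interface conductance to CO2
#'   (mol m^-2 s^-1).
#' @param A_r Bundle-sheath assimilation rate excluding dark respiration
#'   (umol m^-2 s^-1).
#' @param V_p PEP carboxylation rate (umol m^-2 s^-1).
#' @param R_m,R_s Mesophyll and bundle-sheath respiration (umol m^-2 s^-1).
#' @param C_A,O_A Atmospheric CO2 and O2 concentrations (umol/mol).
#' @return List with `C_m`, `C_s`, `O_m`, `O_s` (umol/mol).
#' @export
c4_gas_steady_state <- function(g_w, g_s, A_r, V_p, R_m, R_s, C_A, O_A) {
  if (any(g_w <= 0) || any(g_s <= 0)) {
    stop("conductances must be positive for a steady state", call. = FALSE)
  }
  # each 2x2 system is solved by elimination: summing the two balances
  # removes the inter-compartment exchange term, giving the mesophyll
  # concentration, and the bundle-sheath balance then gives the gradient
  gc <- g_w / 1.6
  C_m <- C_A + (R_m + R_s - A_r) / gc
  C_s <- C_m + (V_p - A_r + R_s) / g_s
  go <- g_w / 1.25
  gso <- 0.047 * g_s
  O_m <- O_A - (R_m + R_s - A_r) / go
  O_s <- O_m + (A_r - R_s) / gso
  list(C_m = C_m, C_s = C_s, O_m = O_m, O_s = O_s)
}

#' Ball-Berry-Leuning stomatal conductance
#'
#' A vapour-pressure-deficit form of the Ball-Berry model, scaled by the
#' drought stress factor `S_w`:
#' `g_w = m * S_w * (A - R_d) / (C_A - Gamma) * (1 + VPD/VPD_ref)^-1 + g_w0`,
#' floored at the residual conductance `g_w0` (full stress or net carbon
#' loss closes stomata only to the residual).
#'
#' @param A Assimilation rate excluding dark respiration (umol m^-2 s^-1).
#' @param R_d Dark respiration (umol m^-2 s^-1).
#' @param Gamma CO2 compensation point with dark respiration (umol/mol).
#' @param VPD Vapour pressure deficit (kPa).
#' @param S_w Water stress factor in `[0, 1]`, see [water_stress()].
#' @param C_A Atmospheric CO2 (umol/mol); must exceed `Gamma`.
#' @param m Slope parameter (dimensionless).
#' @param g_w0 Residual conductance (mol m^-2 s^-1).
#' @param VPD_ref Reference vapour pressure deficit (kPa).
#' @return `g_w` (mol m^-2 s^-1), at least `g_w0`.
#' @export
stomatal_conductance <- function(A, R_d, Gamma, VPD, S_w, C_A,
                                 m = 4.53, g_w0 = 0.017, VPD_ref = 10) {
  if (any(C_A <= Gamma)) {
    stop("C_A must exceed the compensation point Gamma", call. = FALSE)
  }
  g <- m * S_w * (A - R_d) / (C_A - Gamma) / (1 + VPD / VPD_ref) + g_w0
  pmax(g, g_w0)
}

#' CO2 compensation points with dark respiration
#'
#' For the C3 pathway the compensation point is
#' `Gamma = (gamma_star + K_C * (R_d/V_cmax) * (1 + O_m/K_O)) / (1 - R_d/V_cmax)`.
#' For the C4 pathway the bundle-sheath compensation point is
#' `Gamma_s = (gamma_bs * O_m + K_C * (R_d/V_cmax) * (1 + O_m/K_O)) / (1 + R_d/V_cmax)`
#' and the leaf-level point is `Gamma = (K_P / V_pmax) * (g_s * Gamma_s - R_m)`.
#' Both C4 forms are implemented exactly as stated in the source C4 model and
#' kept in one place so an alternative rendering can be swapped in.
#'
#' @param pathway `"C3"` or `"C4"`.
#' @param R_d Dark respiration (umol m^-2 s^-1); for C3, must be below
#'   `V_cmax`.
#' @param O_m Mesophyll O2 concentration (umol/mol, consistent with `K_O`).
#' @param V_cmax,K_C,K_O,gamma_star As in [c3_assimilation()].
#' @param gamma_bs,K_P,V_pmax,R_m,g_s C4-only parameters; see
#'   [c4_assimilation()], [pep_carboxylation()] and [c4_gas_steady_state()].
#' @return List with `Gamma` and (C4 only) `Gamma_s`, in umol/mol.
#' @export
compensation_points <- function(pathway, R_d, O_m, V_cmax, K_C, K_O,
                                gamma_star = NULL, gamma_bs = NULL, K_P = NULL,
                                V_pmax = NULL, R_m = NULL, g_s = NULL) {
  stopifnot(V_cmax > 0)
  if (pathway == "C3") {
    if (R_d >= V_cmax) {
      stop("R_d >= V_cmax: C3 compensation point undefined", call. = FALSE)
    }
    Gamma <- (gamma_star + K_C * (R_d / V_cmax) * (1 + O_m / K_O)) /
      (1 - R_d / V_cmax)
    list(Gamma = Gamma, Gamma_s = NULL)
  } else {
    Gamma_s <- (gamma_bs * O_m + K_C * (R_d / V_cmax) * (1 + O_m / K_O)) /
      (1 + R_d / V_cmax)
    Gamma <- (K_P / V_pmax) * (g_s * Gamma_s - R_m)
    list(Gamma = Gamma, Gamma_s = Gamma_s)
  }
}
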