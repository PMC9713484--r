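#' Thermal conductivity and kinematic viscosity of air
#'
#' Linear approximations valid between 273.15 and 323.15 K:
#' `K_air = 0.0243 + 0.00007 * (T_a - 273.15)` (W m^-1 K^-1) and
#' `nu = (1.415 + 0.09 * (T_a - 273.15)) * 1e-5` (m^2 s^-1). Outside the
#' stated range the fits are extrapolated with a warning. The coefficients
#' are configurable through [leaf_params()].
#'
#' @param T_a Air temperature (K); vectorised.
#' @param kair_ref,kair_slope Intercept and slope of the conductivity fit.
#' @param nu_ref,nu_slope Intercept and slope of the viscosity fit.
#' @return List with `K_air` (W m^-1 K^-1) and `nu` (m^2 s^-1).
#' @export
air_properties <- function(T_a, kair_ref = 0.0243, kair_slope = 7e-5,
                           nu_ref = 1.415e-5, nu_slope = 0.09e-5) {
  if (any(T_a < 273.15 | T_a > 323.15)) {
    warning("air temperature outside 273.15-323.15 K; extrapolating the linear fits",
      call. = FALSE
    )
  }
  dT <- T_a - 273.15
  list(K_air = kair_ref + kair_slope * dT, nu = nu_ref + nu_slope * dT)
}

#' Latent heat of vaporisation of water
#'
#' Linear fit `H_vap = 45060 - 425 * (T_a - 273.15)` in J mol^-1; strictly
#' decreasing in temperature. Coefficients are configurable.
#'
#' @param T_a Air temperature (K); vectorised.
#' @param hvap_ref,hvap_slope Intercept (J mol^-1) and slope (J mol^-1 K^-1).
#' @return `H_vap` (J mol^-1).
#' @export
latent_heat <- function(T_a, hvap_ref = 45060, hvap_slope = 425) {
  hvap_ref - hvap_slope * (T_a - 273.15)
}

#' Saturation vapour pressure (Tetens formula)
#'
#' @param T_K Temperature (K).
#' @return Saturation vapour pressure (kPa).
#' @export
saturation_vapor_pressure <- function(T_K) {
  tc <- T_K - 273.15
  0.61078 * exp(17.27 * tc / (tc + 237.3))
}

#' Leaf transpiration rate from stomatal conductance
#'
#' Diffusive water loss driven by the leaf-to-air vapour gradient:
#' `J_v = g_w * (e_sat(T_L) - e_air) / P` with
#' `e_air = e_sat(T_a) - VPD`, floored at zero. In the full root/soil model
#' this flux comes from the root hydraulic network; here it closes the leaf
#' energy balance from the leaf state alone.
#'
#' @param g_w Stomatal conductance to water (mol m^-2 s^-1).
#' @param T_L Leaf temperature (K).
#' @param T_a Air temperature (K).
#' @param VPD Vapour pressure deficit (kPa).
#' @param P Atmospheric pressure (Pa).
#' @return `J_v` (mol m^-2 s^-1), non-negative.
#' @export
leaf_transpiration <- function(g_w, T_L, T_a, VPD, P = 101325) {
  stopifnot(g_w >= 0, P > 0)
  e_air <- saturation_vapor_pressure(T_a) - VPD # kPa
  jv <- g_w * (saturation_vapor_pressure(T_L) - e_air) * 1000 / P
  pmax(jv, 0)
}

#' Leaf boundary-layer thickness
#'
#' `delta_bl = coef * sqrt(d * nu / v)`: thickness grows with leaf size and
#' air viscosity and shrinks with wind speed. The square-root form is the
#' dimensionally consistent laminar flat-plate scaling; the coefficient is
#' configurable.
#'
#' @param d Characteristic leaf length (m).
#' @param nu Kinematic viscosity of air (m^2 s^-1).
#' @param v Wind speed (m s^-1), positive.
#' @param coef Dimensionless coefficient.
#' @return `delta_bl` (m).
#' @export
boundary_layer_thickness <- function(d, nu, v, coef = 10.97) {
  stopifnot(d > 0, nu > 0, v > 0)
  coef * sqrt(d * nu / v)
}

#' Leaf energy balance residual
#'
#' Signed net energy flux into the leaf (W m^-2):
#' `E = alpha * I + alpha_IR * sigma * (T_surr^4 + T_sky^4)
#'    - 2 * alpha_IR * sigma * T_L^4
#'    - 2 * K_air * (T_L - T_a) / delta_bl
#'    - J_v * H_vap(T_a)`.
#' The surroundings radiate at air temperature and the effective sky
#' temperature is `T_a` minus a fixed offset (default 40 K); both can be
#' overridden for testing. Factors of two account for the two leaf faces.
#' At the solved leaf temperature the residual is zero.
#'
#' @param T_L Leaf temperature (K); vectorised.
#' @param T_a Air temperature (K).
#' @param I Absorbed-band solar irradiance (W m^-2).
#' @param J_v Transpiration rate (mol m^-2 s^-1).
#' @param v Wind speed (m s^-1).
#' @param params A [leaf_params()] object supplying `alpha`, `alpha_IR`,
#'   `sigma`, `d` and the air-property coefficients.
#' @param T_surr,T_sky Optional overrides of the surroundings and sky
#'   radiative temperatures (K).
#' @return Residual `E` (W m^-2).
#' @export
energy_residual <- function(T_L, T_a, I, J_v, v, params = leaf_params(),
                            T_surr = NULL, T_sky = NULL) {
  T_surr <- T_surr %||% T_a
  T_sky <- T_sky %||% (T_a - params$sky_offset)
  air <- air_properties(T_a,
    kair_ref = params$kair_ref, kair_slope = params$kair_slope,
    nu_ref = params$nu_ref, nu_slope = params$nu_slope
  )
  dbl <- boundary_layer_thickness(params$d, air$nu, v, coef = params$bl_coef)
  params$alpha * I +
    params$alpha_IR * params$sigma * (T_surr^4 + T_sky^4) -
    2 * params$alpha_IR * params$sigma * T_L^4 -
    2 * air$K_air * (T_L - T_a) / dbl -
    J_v * latent_heat(T_a, params$hvap_ref, params$hvap_slope)
}

#' Solve the leaf energy balance for leaf temperature
#'
#' Finds the leaf temperature at which the energy balance residual
#' ([energy_residual()]) vanishes. The residual is a quartic in `T_L`,
#' strictly decreasing over the physical range, solved by Newton-Raphson
#' starting from air temperature with an analytic derivative; a bisection
#' fallback on a +/- 50 K bracket guards against divergence.
#'
#' @inheritParams energy_residual
#' @param T_init Initial guess (K), defaults to `T_a`.
#' @param tol Convergence tolerance on `|E|` (W m^-2).
#' @param max_iter Maximum Newton iterations.
#' @param bracket Half-width of the fallback bisection bracket (K).
#' @return Leaf temperature `T_L` (K) with `|E(T_L)| < tol`.
#' @export
solve_leaf_temperature <- function(T_a, I, J_v, v, params = leaf_params(),
                                   T_init = T_a, tol = 1e-6, max_iter = 100,
                                   bracket = 50, T_surr = NULL, T_sky = NULL) {
  # fixed T_a-dependent pieces; derivative of E wrt T_L is analytic
  air <- air_properties(T_a,
    kair_ref = params$kair_ref, kair_slope = params$kair_slope,
    nu_ref = params$nu_ref, nu_slope = params$nu_slope
  )
  dbl <- boundary_layer_thickness(params$d, air$nu, v, coef = params$bl_coef)
  ts <- T_surr %||% T_a
  tk <- T_sky %||% (T_a - params$sky_offset)
  const <- params$alpha * I +
    params$alpha_IR * params$sigma * (ts^4 + tk^4) -
    J_v * latent_heat(T_a, params$hvap_ref, params$hvap_slope)
  resid <- function(T_L) {
    const - 2 * params$alpha_IR * params$sigma * T_L^4 -
      2 * air$K_air * (T_L - T_a) / dbl
  }
  dresid <- function(T_L) {
    -8 * params$alpha_IR * params$sigma * T_L^3 - 2 * air$K_air / dbl
  }
  lo <- T_a - bracket
  hi <- T_a + bracket
  T_L <- T_init
  for (i in seq_len(max_iter)) {
    e <- resid(T_L)
    if (abs(e) < tol) return(T_L)
    step <- e / dresid(T_L)
    T_new <- T_L - step
    if (!is.finite(T_new) || T_new < lo || T_new > hi) break
    T_L <- T_new
  }
  e_final <- resid(T_L)
  if (abs(e_final) < tol) return(T_L)
  # bisection fallback: residual is strictly decreasing in T_L
  if (resid(lo) < 0 || resid(hi) > 0) {
    stop("no root of the energy balance in the +/- ", bracket, " K bracket",
      call. = FALSE
    )
  }
  root <- stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
  # polish with Newton to drive |E| below tol
  for (i in 1:20) {
    e <- resid(root)
    if (abs(e) < tol) break
    root <- root - e / dresid(root)
  }
  root
}
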