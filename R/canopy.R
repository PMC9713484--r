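#' Solar declination and zenith angle
#'
#' Standard astronomical approximation: declination
#' `delta = 23.45 * pi/180 * sin(2*pi*(284 + doy)/365)` and zenith from the
#' hour-angle construction
#' `cos(zenith) = sin(lat) sin(delta) + cos(lat) cos(delta) cos(H)` with
#' `H = 15 degrees * (hour - 12)`.
#'
#' @param lat Latitude (degrees, positive north); `|lat| <= 90`.
#' @param doy Day of year (1-365).
#' @param hour Local solar time (h, 0-24).
#' @return List with `declination` and `zenith` (radians); zenith exceeds
#'   `pi/2` when the sun is below the horizon.
#' @export
solar_position <- function(lat, doy, hour) {
  stopifnot(abs(lat) <= 90)
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  lat_r <- lat * pi / 180
  H <- 15 * (hour - 12) * pi / 180
  cz <- sin(lat_r) * sin(decl) + cos(lat_r) * cos(decl) * cos(H)
  list(declination = decl, zenith = acos(pmin(pmax(cz, -1), 1)))
}

#' Day length
#'
#' `2/15 * acos(-tan(lat) * tan(declination))` in hours, with the argument
#' clipped for polar day/night.
#'
#' @inheritParams solar_position
#' @return Day length (h, 0-24).
#' @export
day_length <- function(lat, doy) {
  stopifnot(abs(lat) <= 90)
  decl <- 23.45 * pi / 180 * sin(2 * pi * (284 + doy) / 365)
  x <- -tan(lat * pi / 180) * tan(decl)
  2 / 15 * acos(pmin(pmax(x, -1), 1)) * 180 / pi
}

#' Clear-sky solar irradiance
#'
#' Beer-law atmospheric attenuation of the solar constant:
#' `I_s = S0 * E0 * tau^(1/cos(zenith)) * cos(zenith)` where `E0` is the
#' orbital eccentricity factor `1 + 0.033 * cos(2*pi*doy/365)`. Zero when
#' the sun is at or below the horizon.
#'
#' @param zenith Solar zenith angle (radians).
#' @param doy Day of year.
#' @param transmittance Atmospheric transmittance in (0, 1].
#' @param solar_constant Top-of-atmosphere irradiance (W m^-2).
#' @return Irradiance on a horizontal surface (W m^-2), non-negative.
#' @export
clear_sky_irradiance <- function(zenith, doy, transmittance = 0.75,
                                 solar_constant = 1361) {
  stopifnot(transmittance > 0, transmittance <= 1)
  cz <- cos(zenith)
  e0 <- 1 + 0.033 * cos(2 * pi * doy / 365)
  ifelse(cz <= 0, 0, solar_constant * e0 * transmittance^(1 / pmax(cz, 1e-9)) * cz)
}

#' Sunlit/shaded canopy partition
#'
#' Two-fraction canopy scaling with a spherical leaf-angle distribution:
#' black-leaf beam extinction `k_b = 0.5 / cos(zenith)`, sunlit leaf area
#' `LAI_sun = (1 - exp(-k_b * LAI)) / k_b`, remainder shaded. Sunlit leaves
#' receive the projected beam (`k_b * I_beam` per unit leaf area) plus the
#' per-leaf-area share of intercepted diffuse light; shaded leaves receive
#' the diffuse share only, so under fully diffuse light both fractions see
#' the same irradiance. Intercepted totals never exceed the incident flux.
#'
#' @param LAI Leaf area index (m^2 leaf per m^2 ground), non-negative.
#' @param zenith Solar zenith angle (radians).
#' @param I_beam Direct-beam irradiance on the ground plane (W m^-2).
#' @param I_diffuse Diffuse irradiance (W m^-2).
#' @param k_d Diffuse extinction coefficient.
#' @return List with `LAI_sun`, `LAI_shade`, per-leaf-area irradiances
#'   `I_sun` and `I_shade` (W m^-2), and the canopy-intercepted totals
#'   `absorbed_sun`, `absorbed_shade` (W m^-2 ground).
#' @export
sun_shade_partition <- function(LAI, zenith, I_beam, I_diffuse, k_d = 0.7) {
  stopifnot(LAI >= 0, I_beam >= 0, I_diffuse >= 0)
  night <- zenith >= pi / 2 || I_beam == 0
  if (LAI == 0) {
    return(list(
      LAI_sun = 0, LAI_shade = 0, I_sun = 0, I_shade = 0,
      absorbed_sun = 0, absorbed_shade = 0
    ))
  }
  if (night) {
    k_b <- Inf
    LAI_sun <- 0
  } else {
    k_b <- 0.5 / cos(zenith)
    LAI_sun <- (1 - exp(-k_b * LAI)) / k_b
  }
  LAI_shade <- LAI - LAI_sun
  dif_pa <- I_diffuse * (1 - exp(-k_d * LAI)) / (k_d * LAI) # per leaf area
  I_sun <- if (LAI_sun > 0) k_b * I_beam + dif_pa else 0
  I_shade <- dif_pa
  list(
    LAI_sun = LAI_sun, LAI_shade = LAI_shade,
    I_sun = I_sun, I_shade = I_shade,
    absorbed_sun = I_sun * LAI_sun, absorbed_shade = I_shade * LAI_shade
  )
}

#' Canopy assimilation by sun/shade scaling
#'
#' Splits incident irradiance into beam and diffuse components, partitions
#' the canopy into sunlit and shaded fractions ([sun_shade_partition()]),
#' solves the full coupled leaf state separately for each fraction
#' ([solve_leaf_state()]) and area-weights the results to per-ground-area
#' canopy totals.
#'
#' @param params A [leaf_params()] object.
#' @param LAI Leaf area index (m^2 m^-2).
#' @param T_a Air temperature (K).
#' @param I_s Incident solar irradiance (W m^-2).
#' @param VPD Vapour pressure deficit (kPa).
#' @param v Wind speed (m s^-1).
#' @param P Atmospheric pressure (Pa).
#' @param S_w Water stress factor.
#' @param zenith Solar zenith angle (radians).
#' @param diffuse_fraction Fraction of `I_s` that is diffuse.
#' @param init_sun,init_shade Optional warm starts for the two leaf solves.
#' @return List with canopy totals `A` (umol CO2 m^-2 ground s^-1) and
#'   `J_v` (mol H2O m^-2 ground s^-1), the partition, and the two
#'   `leaf_state` objects (`sun`, `shade`).
#' @export
canopy_assimilation <- function(params, LAI, T_a, I_s, VPD, v, P = 101325,
                                S_w = 1, zenith = 0, diffuse_fraction = 0.15,
                                init_sun = NULL, init_shade = NULL) {
  stopifnot(LAI >= 0, diffuse_fraction >= 0, diffuse_fraction <= 1)
  part <- sun_shade_partition(
    LAI, zenith,
    I_beam = I_s * (1 - diffuse_fraction),
    I_diffuse = I_s * diffuse_fraction
  )
  if (LAI == 0) {
    return(list(
      A = 0, J_v = 0, partition = part, sun = NULL, shade = NULL,
      converged = TRUE
    ))
  }
  sun <- if (part$LAI_sun > 0) {
    solve_leaf_state(params, T_a, part$I_sun, VPD, v,
      P = P, S_w = S_w,
      init = init_sun
    )
  } else {
    NULL
  }
  shade <- solve_leaf_state(params, T_a, part$I_shade, VPD, v,
    P = P, S_w = S_w,
    init = init_shade
  )
  A_sun <- if (is.null(sun)) 0 else sun$A * part$LAI_sun
  Jv_sun <- if (is.null(sun)) 0 else sun$J_v * part$LAI_sun
  list(
    A = A_sun + shade$A * part$LAI_shade,
    J_v = Jv_sun + shade$J_v * part$LAI_shade,
    partition = part, sun = sun, shade = shade,
    converged = (is.null(sun) || sun$converged) && shade$converged
  )
}
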