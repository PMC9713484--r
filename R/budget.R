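#' Leaf nitrogen content from plant nitrogen status
#'
#' Three-branch piecewise allocation of whole-plant nitrogen to the leaves:
#' at or below the minimal plant content the leaf holds its minimum; between
#' the minimal and optimal plant contents the leaf content interpolates
#' linearly between `leaf_min` and `leaf_opt`; above the optimum it scales
#' proportionally, `plant_N * leaf_opt / plant_opt`. Continuous at both
#' breakpoints.
#'
#' @param plant_N Total plant nitrogen content (g); vectorised.
#' @param plant_min,plant_opt Minimal and optimal plant nitrogen contents
#'   (g), with `plant_min < plant_opt`.
#' @param leaf_min,leaf_opt Minimal and optimal leaf nitrogen contents (g),
#'   with `leaf_min < leaf_opt`.
#' @return Leaf nitrogen content (g).
#' @export
leaf_nitrogen <- function(plant_N, plant_min, plant_opt, leaf_min, leaf_opt) {
  if (!(plant_min < plant_opt) || !(leaf_min < leaf_opt)) {
    stop("bounds must satisfy plant_min < plant_opt and leaf_min < leaf_opt",
      call. = FALSE
    )
  }
  ifelse(plant_N <= plant_min, leaf_min,
    ifelse(plant_N < plant_opt,
      (leaf_opt - leaf_min) * (plant_N - plant_min) / (plant_opt - plant_min) +
        leaf_min,
      plant_N * leaf_opt / plant_opt
    )
  )
}

#' Nitrogen-limited photosynthetic capacities
#'
#' Electron-transport and carboxylation capacities scale linearly with leaf
#' nitrogen concentration: `J_max = n1 * N_leaf` and `V_cmax = n2 * N_leaf`.
#' The default proportionality constants are calibrated so that a reference
#' leaf nitrogen concentration of 2 g N m^-2 reproduces the default 25 degC
#' capacities (`J_max25 = 299.6`, `V_cmax25 = 49` umol m^-2 s^-1). The
#' results are meant to replace the fixed capacities in
#' [electron_transport()] and the assimilation equations.
#'
#' @param N_leaf Leaf nitrogen concentration (g N m^-2 leaf); vectorised.
#' @param n1,n2 Proportionality constants (umol m^-2 s^-1 per g N m^-2).
#' @return List with `J_max` and `V_cmax` (umol m^-2 s^-1).
#' @export
n_limited_rates <- function(N_leaf, n1 = 299.6 / 2, n2 = 49 / 2) {
  stopifnot(n1 > 0, n2 > 0)
  list(J_max = n1 * N_leaf, V_cmax = n2 * N_leaf)
}

#' Carbon allocation to reserves and growth
#'
#' Splits the available carbon flux `C_a` (photosynthesis plus seed) between
#' costs `C_c`, growth and the starch reserve pool `C_p`. In surplus the
#' reserve flux is `C_r = C_a - C_c - C_g` and growth gets its full demand
#' `C_h = C_g`. In deficit, reserves are remobilised (`C_r < 0`) subject to
#' the binding cap: at night at most 95% of the reserves present at dusk may
#' be consumed over the night (`C_r >= -0.95 * C_p_night_start / t_n`);
#' during the day at most half the current reserves per day
#' (`C_r >= -C_p / 2`). A daytime hoarding rule protects the night budget:
#' if reserves at sunset are projected below 110% of the estimated night
#' carbon need `C_cN`, the reserve flux is raised to
#' `min(C_a - C_c, (1.1 * C_cN - C_p) / t_s)`, reducing growth. The returned
#' pair always satisfies `C_a - C_c - C_r - C_h = 0` exactly, and
#' `0 <= C_h <= C_g`.
#'
#' @param C_a Available carbon flux (g d^-1).
#' @param C_c Carbon costs: respiration and exudation (g d^-1).
#' @param C_g Potential growth demand (g d^-1).
#' @param C_p Current reserve pool (g), non-negative.
#' @param phase `"day"` or `"night"`.
#' @param t_s Time until sunset (d), day phase.
#' @param t_n Night duration (d), night phase.
#' @param C_cN Estimated carbon needed over the coming night (g).
#' @param C_p_night_start Reserve pool at the start of the current night
#'   (g); defaults to `C_p`.
#' @return List with `C_r` (g d^-1, negative when remobilising) and `C_h`
#'   (g d^-1, realised growth allocation).
#' @export
#' @examples
#' reserve_allocation(C_a = 10, C_c = 3, C_g = 5, C_p = 4, phase = "day", t_s = 0.3)
reserve_allocation <- function(C_a, C_c, C_g, C_p, phase = c("day", "night"),
                               t_s = NULL, t_n = NULL, C_cN = 0,
                               C_p_night_start = C_p) {
  phase <- match.arg(phase)
  stopifnot(C_a >= 0, C_c >= 0, C_g >= 0)
  if (C_p < 0) stop("corrupted state: negative reserve pool", call. = FALSE)
  C_r <- C_a - C_c - C_g
  C_h <- C_g
  if (C_r < 0) {
    cap <- if (phase == "night") {
      if (is.null(t_n) || t_n <= 0) stop("night phase requires t_n > 0", call. = FALSE)
      -0.95 * C_p_night_start / t_n
    } else {
      -C_p / 2
    }
    C_r <- max(C_r, cap)
    C_h <- C_a - C_c - C_r
  }
  if (phase == "day" && !is.null(t_s) && t_s > 0 &&
    C_p + C_r * t_s <= 1.1 * C_cN) {
    floor_r <- min(C_a - C_c, (1.1 * C_cN - C_p) / t_s)
    C_r <- max(C_r, floor_r)
    C_h <- C_a - C_c - C_r
  }
  if (C_h < 0) C_h <- 0
  if (C_h > C_g) C_h <- C_g
  C_r <- C_a - C_c - C_h # exact mass-balance identity
  list(C_r = C_r, C_h = C_h)
}

#' Growth-simulation configuration
#'
#' Whole-plant bookkeeping constants for [simulate_growth()]. The shoot is
#' non-geometric: structural carbon pools drive leaf area through a fixed
#' specific leaf area, and potential growth follows a logistic schedule.
#'
#' @param density Planting density (plants m^-2).
#' @param seed_carbon Initial reserve endowment from the seed (g C).
#' @param initial_structure Initial structural carbon (g C).
#' @param rgr Potential relative growth rate (g C per g C per day).
#' @param max_structure Logistic ceiling on structural carbon (g C).
#' @param maintenance Maintenance cost coefficient (g C per g C per day).
#' @param leaf_fraction Fraction of shoot carbon in leaves.
#' @param root_fraction Fraction of realised growth allocated to roots.
#' @param sla Specific leaf area (m^2 leaf per g leaf C).
#' @param lat Latitude (degrees) for solar geometry.
#' @param diffuse_fraction Diffuse fraction of incident light.
#' @param growth_stress If `TRUE`, growth demand is scaled by the water
#'   stress factor `S_w` (an optional stress transfer).
#' @return A list of class `growth_config`.
#' @export
growth_config <- function(density = 8, seed_carbon = 0.15,
                          initial_structure = 0.05, rgr = 0.18,
                          max_structure = 80, maintenance = 0.015,
                          leaf_fraction = 0.6, root_fraction = 0.35,
                          sla = 0.055, lat = 42.8, diffuse_fraction = 0.15,
                          growth_stress = FALSE) {
  stopifnot(density > 0, seed_carbon >= 0, initial_structure > 0, rgr > 0)
  structure(
    list(
      density = density, seed_carbon = seed_carbon,
      initial_structure = initial_structure, rgr = rgr,
      max_structure = max_structure, maintenance = maintenance,
      leaf_fraction = leaf_fraction, root_fraction = root_fraction,
      sla = sla, lat = lat, diffuse_fraction = diffuse_fraction,
      growth_stress = growth_stress
    ),
    class = "growth_config"
  )
}

# grams of carbon fixed per day per plant from a canopy assimilation rate in
# umol CO2 m^-2 ground s^-1
umol_co2_to_gC_per_day <- function(A_umol, ground_area) {
  A_umol * 12.011e-6 * 86400 * ground_area
}

#' Run a diurnal growth simulation
#'
#' Steps a whole plant through a weather series at the configured timestep:
#' each step computes the solar state, canopy assimilation over the sunlit
#' and shaded fractions (daylight) or a zero-assimilation night state, the
#' carbon fluxes, the reserve allocation with its day/night rules, and the
#' realised growth. Carbon mass balance closes identically at every step:
#' cumulative assimilation plus the seed endowment equals cumulative costs
#' plus growth plus the current reserve pool.
#'
#' @param weather Weather table from [synthetic_weather()] or
#'   [read_weather()]: columns `time` (d), `doy`, `hour`, `T_a` (K), `I_s`
#'   (W m^-2), `VPD` (kPa), `v` (m s^-1), `P` (Pa), at a uniform timestep.
#' @param params A [leaf_params()] object.
#' @param drought Optional [terminal_drought_schedule()]; omitted means well
#'   watered (`S_w = 1`).
#' @param config A [growth_config()].
#' @param curve A [water_stress_curve()].
#' @return An object of class `growth_simulation` with the per-step
#'   `timeseries` tibble (fluxes in g C d^-1, pools in g C, canopy
#'   assimilation in umol m^-2 ground s^-1), the configuration, and run
#'   totals. Use [tidy()] for the time series, [glance()] for totals and
#'   [ggplot2::autoplot()] for a summary figure.
#' @export
simulate_growth <- function(weather, params = leaf_params(), drought = NULL,
                            config = growth_config(),
                            curve = water_stress_curve()) {
  stopifnot(is.data.frame(weather), inherits(config, "growth_config"))
  validate_weather(weather)
  n <- nrow(weather)
  dt <- weather$time[2] - weather$time[1]
  ground_area <- 1 / config$density

  structure_C <- config$initial_structure
  shoot_C <- structure_C * (1 - config$root_fraction)
  root_C <- structure_C * config$root_fraction
  C_p <- config$seed_carbon
  C_p0 <- C_p
  cum_Ca <- 0
  cum_Cc <- 0
  cum_Ch <- 0
  cum_A <- 0
  cum_Jv <- 0
  C_p_night_start <- C_p
  prev_phase <- "day"
  init_sun <- NULL
  init_shade <- NULL

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    w <- weather[i, ]
    sol <- solar_position(config$lat, w$doy, w$hour)
    dl <- day_length(config$lat, w$doy)
    sunrise <- 12 - dl / 2
    sunset <- 12 + dl / 2
    daylight <- w$hour >= sunrise && w$hour < sunset && w$I_s > 0
    t_s <- max(sunset - w$hour, 0) / 24 # time until sunset, d
    t_n <- (24 - dl) / 24 # night duration, d

    psi_c <- if (is.null(drought)) -1000 else psi_at(drought, w$time)
    S_w <- water_stress(psi_c, curve)

    LAI <- shoot_C * config$leaf_fraction * config$sla * config$density

    if (daylight && LAI > 0) {
      can <- canopy_assimilation(params, LAI, w$T_a, w$I_s, w$VPD, w$v,
        P = w$P, S_w = S_w, zenith = sol$zenith,
        diffuse_fraction = config$diffuse_fraction,
        init_sun = init_sun, init_shade = init_shade
      )
      A_can <- can$A
      Jv_can <- can$J_v
      T_L_sun <- if (is.null(can$sun)) NA_real_ else can$sun$T_L
      T_L_shade <- if (is.null(can$shade)) NA_real_ else can$shade$T_L
      g_w_sun <- if (is.null(can$sun)) NA_real_ else can$sun$g_w
      conv <- can$converged
      if (!is.null(can$sun)) {
        init_sun <- c(can$sun$T_L, can$sun$g_w, can$sun$A)
      }
      if (!is.null(can$shade)) {
        init_shade <- c(can$shade$T_L, can$shade$g_w, can$shade$A)
      }
    } else {
      A_can <- 0
      Jv_can <- 0
      T_L_sun <- NA_real_
      T_L_shade <- NA_real_
      g_w_sun <- NA_real_
      conv <- TRUE
      init_sun <- NULL
      init_shade <- NULL
    }

    phase <- if (daylight) "day" else "night"
    if (phase == "night" && prev_phase == "day") C_p_night_start <- C_p
    prev_phase <- phase

    C_a <- umol_co2_to_gC_per_day(max(A_can, 0), ground_area)
    C_c <- config$maintenance * structure_C
    C_g <- config$rgr * structure_C * max(1 - structure_C / config$max_structure, 0)
    if (config$growth_stress) C_g <- C_g * S_w
    C_cN <- C_c * t_n # estimated night carbon need

    alloc <- reserve_allocation(C_a, C_c, C_g, C_p,
      phase = phase, t_s = t_s,
      t_n = t_n, C_cN = C_cN,
      C_p_night_start = C_p_night_start
    )

    C_p <- max(C_p + alloc$C_r * dt, 0)
    structure_C <- structure_C + alloc$C_h * dt
    shoot_C <- shoot_C + (1 - config$root_fraction) * alloc$C_h * dt
    root_C <- root_C + config$root_fraction * alloc$C_h * dt

    cum_Ca <- cum_Ca + C_a * dt
    cum_Cc <- cum_Cc + C_c * dt
    cum_Ch <- cum_Ch + alloc$C_h * dt
    cum_A <- cum_A + A_can * dt
    cum_Jv <- cum_Jv + Jv_can * dt
    balance <- cum_Ca + C_p0 - cum_Cc - cum_Ch - C_p

    rows[[i]] <- tibble::tibble(
      time = w$time, doy = w$doy, hour = w$hour, phase = phase,
      T_a = w$T_a, I_s = w$I_s, VPD = w$VPD,
      psi_c = psi_c, S_w = S_w, LAI = LAI,
      A_canopy = A_can, J_v_canopy = Jv_can,
      g_w_sun = g_w_sun, T_L_sun = T_L_sun, T_L_shade = T_L_shade,
      C_a = C_a, C_c = C_c, C_g = C_g, C_r = alloc$C_r, C_h = alloc$C_h,
      C_p = C_p, shoot_C = shoot_C, root_C = root_C,
      balance_error = balance, converged = conv
    )
  }

  ts <- dplyr::bind_rows(rows)
  structure(
    list(
      timeseries = ts, config = config, params = params,
      totals = tibble::tibble(
        days = n * dt,
        cumulative_assimilation_gC = cum_Ca,
        cumulative_transpiration_mol = cum_Jv * 86400 * ground_area,
        final_reserves_gC = C_p,
        final_shoot_gC = shoot_C,
        final_root_gC = root_C,
        max_abs_balance_error = max(abs(ts$balance_error)),
        fraction_converged = mean(ts$converged)
      )
    ),
    class = "growth_simulation"
  )
}

#' @export
print.growth_simulation <- function(x, ...) {
  cat(sprintf(
    "<growth_simulation> %g days, %d steps\n", x$totals$days,
    nrow(x$timeseries)
  ))
  print(x$totals)
  invisible(x)
}

#' Tidy a growth simulation
#'
#' @param x A `growth_simulation`.
#' @param ... Unused.
#' @return The per-timestep tibble.
#' @exportS3Method generics::tidy
tidy.growth_simulation <- function(x, ...) x$timeseries

#' One-row summary of a growth simulation
#'
#' @param x A `growth_simulation`.
#' @param ... Unused.
#' @return A one-row tibble of run totals.
#' @exportS3Method generics::glance
glance.growth_simulation <- function(x, ...) x$totals
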