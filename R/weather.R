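#' Synthetic diurnal weather series
#'
#' Generates a weather forcing table with a sinusoidal diurnal air
#' temperature cycle (coolest at 02:00, warmest at 14:00, range exactly
#' `T_mean +/- T_amplitude`), clear-sky irradiance from the solar geometry
#' model ([clear_sky_irradiance()]), vapour pressure deficit tracking
#' temperature up to `VPD_max`, and wind speed around `v_mean`. With a seed,
#' small multiplicative day-to-day noise is added to wind and VPD and the
#' series is reproducible; without one the series is fully deterministic.
#'
#' @param lat Latitude (degrees).
#' @param n_days Number of simulated days.
#' @param timestep Timestep (d); must divide one day evenly.
#' @param T_mean,T_amplitude Mean and half-range of air temperature (K).
#' @param transmittance Clear-sky atmospheric transmittance.
#' @param VPD_max Mid-afternoon vapour pressure deficit (kPa).
#' @param v_mean Mean wind speed (m s^-1).
#' @param P Atmospheric pressure (Pa).
#' @param doy_start Day of year of the first simulated day.
#' @param seed Optional integer seed for the noise terms.
#' @return A tibble with columns `time` (d), `doy`, `hour`, `T_a` (K),
#'   `I_s` (W m^-2), `VPD` (kPa), `v` (m s^-1), `P` (Pa).
#' @export
#' @examples
#' w <- synthetic_weather(n_days = 2, timestep = 0.1)
#' head(w)
synthetic_weather <- function(lat = 42.8, n_days = 42, timestep = 0.1,
                              T_mean = 298.15, T_amplitude = 6,
                              transmittance = 0.75, VPD_max = 1.8,
                              v_mean = 2, P = 101325, doy_start = 152,
                              seed = NULL) {
  steps_per_day <- 1 / timestep
  if (abs(steps_per_day - round(steps_per_day)) > 1e-9) {
    stop("timestep must divide one day evenly", call. = FALSE)
  }
  stopifnot(n_days >= 1, T_amplitude >= 0, v_mean > 0, P > 0)
  time <- seq(0, n_days - timestep, by = timestep)
  doy <- doy_start + floor(time + 1e-12)
  hour <- (time - floor(time + 1e-12)) * 24
  T_a <- T_mean - T_amplitude * cos(2 * pi * (hour - 2) / 24)
  zen <- solar_position(lat, doy, hour)$zenith
  I_s <- clear_sky_irradiance(zen, doy, transmittance)
  VPD <- pmax(VPD_max * (T_a - (T_mean - T_amplitude)) / (2 * T_amplitude), 0.05)
  v <- rep(v_mean, length(time))
  if (!is.null(seed)) {
    withr_seed <- function(expr) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      set.seed(seed)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      expr
    }
    noise <- withr_seed({
      day_noise <- stats::rlnorm(n_days, 0, 0.15)
      list(v = day_noise, vpd = stats::rlnorm(n_days, 0, 0.1))
    })
    day_idx <- floor(time + 1e-12) + 1
    v <- v * noise$v[day_idx]
    VPD <- VPD * noise$vpd[day_idx]
  }
  tibble::tibble(
    time = time, doy = doy, hour = hour, T_a = T_a, I_s = I_s,
    VPD = VPD, v = v, P = P
  )
}

validate_weather <- function(weather) {
  need <- c("time", "doy", "hour", "T_a", "I_s", "VPD", "v", "P")
  missing <- setdiff(need, names(weather))
  if (length(missing)) {
    stop("weather is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(weather) < 2) stop("weather needs at least two rows", call. = FALSE)
  dts <- diff(weather$time)
  if (any(dts <= 0)) {
    stop("weather timestamps must be strictly increasing", call. = FALSE)
  }
  if (max(dts) - min(dts) > 1e-9) {
    stop("weather timestep must be uniform", call. = FALSE)
  }
  if (any(weather$T_a < 230 | weather$T_a > 330)) {
    stop("air temperatures outside the physical range 230-330 K", call. = FALSE)
  }
  if (any(weather$I_s < 0) || any(weather$VPD < 0) || any(weather$v <= 0) ||
    any(weather$P <= 0)) {
    stop("weather contains non-physical irradiance, VPD, wind or pressure",
      call. = FALSE
    )
  }
  invisible(weather)
}

#' Terminal drought collar-potential schedule
#'
#' A piecewise-linear schedule of collar water potential standing in for the
#' root hydraulic model: well-watered (`psi_well` hPa) until `onset_day`,
#' then a linear decline to `end_psi` by `n_days`. Intended to emulate a
#' terminal vegetative-stage drought in which precipitation stops at onset.
#'
#' @param onset_day Drought onset (d); must precede `n_days`.
#' @param end_psi Collar potential at the final day (hPa, negative).
#' @param n_days Length of the simulation (d).
#' @param psi_well Well-watered collar potential (hPa).
#' @return An object of class `drought_schedule` (a tibble of `time`,
#'   `psi_c` breakpoints, linearly interpolated in between).
#' @export
#' @examples
#' sch <- terminal_drought_schedule(onset_day = 21, end_psi = -15000, n_days = 42)
#' water_stress(psi_at(sch, c(10, 30, 42)))
terminal_drought_schedule <- function(onset_day, end_psi = -15000, n_days = 42,
                                      psi_well = -1000) {
  stopifnot(onset_day < n_days, end_psi <= 0, psi_well <= 0)
  structure(
    tibble::tibble(
      time = c(0, onset_day, n_days),
      psi_c = c(psi_well, psi_well, end_psi)
    ),
    class = c("drought_schedule", "tbl_df", "tbl", "data.frame")
  )
}

#' Collar potential at given times
#'
#' Linear interpolation of a [terminal_drought_schedule()] (or any table of
#' `time`/`psi_c` breakpoints), held constant beyond the endpoints.
#'
#' @param schedule A `drought_schedule` or data frame with `time`, `psi_c`.
#' @param time Times (d); vectorised.
#' @return Collar water potential (hPa).
#' @export
psi_at <- function(schedule, time) {
  stopifnot(all(c("time", "psi_c") %in% names(schedule)))
  stats::approx(schedule$time, schedule$psi_c, xout = time, rule = 2)$y
}

#' Read a weather series from delimited text
#'
#' Reads a comma-separated weather file with a header naming the required
#' columns (`time`, `doy`, `hour`, `T_a`, `I_s`, `VPD`, `v`, `P`) and
#' validates timestamps and physical ranges. Missing columns are reported by
#' name.
#'
#' @param path File path.
#' @return A validated weather tibble.
#' @export
read_weather <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  validate_weather(tibble::as_tibble(df))
}

#' Write a time series as delimited text
#'
#' Plain UTF-8 CSV with '.' decimal separator and a header row; the
#' round-trip through [read_weather()] is lossless for weather tables.
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# YAML config keys -> leaf_params fields. One key per published constant
# symbol; temperature-response members address (p25 | E | D | S).
config_key_map <- function() {
  list(
    C_A = c("C_A", "scalar"), O_A = c("O_A", "scalar"),
    d_L = c("d_L", "cm"), d = c("d", "scalar"),
    m = c("m", "scalar"), g_w0 = c("g_w0", "scalar"),
    V_pr = c("V_pr", "scalar"), VPD_ref = c("VPD_ref", "scalar"),
    theta = c("theta", "scalar"), f = c("f", "scalar"),
    alpha = c("alpha", "scalar"), alpha_IR = c("alpha_IR", "scalar"),
    beta = c("beta", "scalar"), x = c("x", "scalar"),
    sigma = c("sigma", "scalar"),
    n1 = c("n1", "scalar"), n2 = c("n2", "scalar"),
    Gamma_star25 = c("gamma_star", "p25"), E_Gamma_star = c("gamma_star", "E"),
    K_C25 = c("K_C", "p25"), E_K_C = c("K_C", "E"),
    K_O25 = c("K_O", "p25"), E_K_O = c("K_O", "E"),
    K_P25 = c("K_P", "p25"), E_K_P = c("K_P", "E"),
    R_d25 = c("R_d", "p25"), E_R_d = c("R_d", "E"),
    R_m25 = c("R_m", "p25"), R_s25 = c("R_s", "p25"),
    S_c_o25 = c("gamma_bs", "spec"), E_S_c_o = c("gamma_bs", "E"),
    V_cmax25 = c("V_cmax", "p25"), E_V_cmax = c("V_cmax", "E"),
    J_max25 = c("J_max", "p25"), E_J_max = c("J_max", "E"),
    D_J_max = c("J_max", "D"), S_J_max = c("J_max", "S"),
    V_pmax25 = c("V_pmax", "p25"), E_V_pmax = c("V_pmax", "E"),
    D_V_pmax = c("V_pmax", "D"), S_V_pmax = c("V_pmax", "S"),
    g_s25 = c("g_s", "p25"), E_g_s = c("g_s", "E"),
    D_g_s = c("g_s", "D"), S_g_s = c("g_s", "S")
  )
}

#' Read a physiological configuration file
#'
#' Flat key-value YAML with one key per published constant symbol (e.g.
#' `K_C25`, `E_K_C`, `J_max25`, `D_J_max`, `m`, `g_w0`, ...), plus an
#' optional `pathway` key. Keys not in the accepted vocabulary are rejected;
#' omitted keys keep their defaults, and each applied default is reported via
#' a message. `d_L` is given in centimetres in the file (matching the
#' published constant table) and converted to metres on load; `S_c_o25` is
#' the RuBisCo specificity itself, converted to the internal half-reciprocal
#' form.
#'
#' @param path Path to a YAML file.
#' @param quiet Suppress the defaults message.
#' @return A [leaf_params()] object.
#' @export
read_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  map <- config_key_map()
  allowed <- c("pathway", names(map))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  pathway <- raw$pathway %||% "C4"
  params <- leaf_params(pathway)
  for (key in intersect(names(raw), names(map))) {
    target <- map[[key]]
    field <- target[1]
    kind <- target[2]
    val <- as.numeric(raw[[key]])
    if (kind == "scalar") {
      params[[field]] <- val
    } else if (kind == "cm") {
      params[[field]] <- val / 100
    } else if (kind == "spec") {
      params[[field]]$p25 <- 0.5 / val
    } else {
      params[[field]][[kind]] <- val
    }
  }
  defaults_used <- setdiff(names(map), names(raw))
  if (!quiet && length(defaults_used)) {
    message(
      "defaults applied for: ",
      paste(sort(defaults_used), collapse = ", ")
    )
  }
  validate_leaf_params(params)
}
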