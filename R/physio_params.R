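#' Temperature response of a physiological parameter
#'
#' Constructs a temperature-response record for a kinetic or capacity
#' parameter. Two forms are supported: the simple Arrhenius form (activation
#' energy `E` only) and the peaked Arrhenius form, which additionally takes a
#' deactivation energy `D` and entropy factor `S` so the response rises to an
#' interior optimum and declines beyond it. Both forms return exactly `p25`
#' at the reference temperature of 298.15 K.
#'
#' @param p25 Parameter value at 298.15 K (in the parameter's own units).
#' @param E Activation energy (J mol^-1).
#' @param D Deactivation energy (J mol^-1), peaked form only.
#' @param S Entropy factor (J K^-1 mol^-1), peaked form only.
#' @return An object of class `temperature_response`.
#' @seealso [arrhenius()], [peaked_arrhenius()]
#' @export
#' @examples
#' kc <- temperature_response(p25 = 485, E = 35600)
#' arrhenius(kc, 308.15)
temperature_response <- function(p25, E, D = NULL, S = NULL) {
  stopifnot(is.numeric(p25), length(p25) == 1L, is.numeric(E), length(E) == 1L)
  if (xor(is.null(D), is.null(S))) {
    stop("peaked form needs both `D` and `S`; simple form needs neither", call. = FALSE)
  }
  structure(
    list(p25 = p25, E = E, D = D, S = S),
    class = "temperature_response"
  )
}

#' @export
print.temperature_response <- function(x, ...) {
  form <- if (is.null(x$D)) "Arrhenius" else "peaked Arrhenius"
  cat(sprintf(
    "<temperature_response> %s: p25 = %g, E = %g J/mol%s\n",
    form, x$p25, x$E,
    if (is.null(x$D)) "" else sprintf(", D = %g J/mol, S = %g J/K/mol", x$D, x$S)
  ))
  invisible(x)
}

# reference temperature (K) and universal gas constant (J / K / mol)
T_REF <- 298.15
R_GAS <- 8.31446

#' Simple Arrhenius temperature scaling
#'
#' Evaluates `p25 * exp(E * (T_L - 298.15) / (298.15 * R * T_L))`, the
#' monotone Arrhenius temperature dependence used for Michaelis constants,
#' compensation points, respiration rates and RuBisCo capacity.
#'
#' @param tr A [temperature_response()] record.
#' @param T_L Leaf temperature (K); vectorised.
#' @return Parameter value at `T_L`, same units as `p25`.
#' @export
arrhenius <- function(tr, T_L) {
  stopifnot(inherits(tr, "temperature_response"))
  if (any(!is.finite(T_L)) || any(T_L <= 0)) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  tr$p25 * exp(tr$E * (T_L - T_REF) / (T_REF * R_GAS * T_L))
}

#' Peaked Arrhenius temperature scaling
#'
#' Evaluates the peaked Arrhenius form: the simple Arrhenius factor times a
#' deactivation correction
#' `(1 + exp((Tref*S - D)/(Tref*R))) / (1 + exp((T_L*S - D)/(R*T_L)))`,
#' used for the electron-transport capacity `J_max`, PEP carboxylation
#' capacity `V_pmax` and bundle-sheath conductance `g_s`, whose activity
#' declines beyond a thermal optimum. Equals `p25` exactly at 298.15 K.
#'
#' @inheritParams arrhenius
#' @return Parameter value at `T_L`.
#' @export
peaked_arrhenius <- function(tr, T_L) {
  stopifnot(inherits(tr, "temperature_response"))
  if (is.null(tr$D) || is.null(tr$S)) {
    stop("peaked form requires `D` and `S` in the temperature response", call. = FALSE)
  }
  if (any(!is.finite(T_L)) || any(T_L <= 0)) {
    stop("temperature must be positive (kelvin)", call. = FALSE)
  }
  base <- tr$p25 * exp(tr$E * (T_L - T_REF) / (T_REF * R_GAS * T_L))
  corr <- (1 + exp((T_REF * tr$S - tr$D) / (T_REF * R_GAS))) /
    (1 + exp((T_L * tr$S - tr$D) / (R_GAS * T_L)))
  base * corr
}

# dispatch on the stored form
eval_temperature_response <- function(tr, T_L) {
  if (is.null(tr$D)) arrhenius(tr, T_L) else peaked_arrhenius(tr, T_L)
}

#' Piecewise-linear drought response curve
#'
#' Maps collar water potential (hPa) to a water stress factor `S_w` between 0
#' (maximum stress) and 1 (no stress). The default breakpoints give `S_w = 1`
#' above -3000 hPa, a first linear decline to 0.4 at -8000 hPa, a second
#' linear decline to 0 at -12000 hPa, and 0 below. Custom curves may be
#' supplied as a data frame of breakpoints; the curve is clamped to its end
#' values outside the breakpoint range.
#'
#' @param breakpoints Data frame with columns `psi_c` (hPa, increasing) and
#'   `S_w` (in `[0, 1]`, non-decreasing in `psi_c`).
#' @return An object of class `water_stress_curve`.
#' @export
#' @examples
#' water_stress(c(-2000, -8000, -10000, -13000))
water_stress_curve <- function(breakpoints = NULL) {
  if (is.null(breakpoints)) {
    breakpoints <- data.frame(
      psi_c = c(-12000, -8000, -3000),
      S_w = c(0, 0.4, 1)
    )
  }
  stopifnot(
    is.data.frame(breakpoints),
    all(c("psi_c", "S_w") %in% names(breakpoints)),
    nrow(breakpoints) >= 2L
  )
  bp <- breakpoints[order(breakpoints$psi_c), c("psi_c", "S_w")]
  if (any(bp$S_w < 0 | bp$S_w > 1)) {
    stop("S_w breakpoints must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(bp$S_w)) {
    stop("S_w must be non-decreasing in psi_c", call. = FALSE)
  }
  structure(list(breakpoints = tibble::as_tibble(bp)), class = "water_stress_curve")
}

#' Water stress factor from collar water potential
#'
#' Evaluates a [water_stress_curve()] at collar water potential `psi_c`.
#' The result is a dimensionless stress factor `S_w` in `[0, 1]` that scales
#' stomatal conductance (and optionally growth demand) under drought.
#'
#' @param psi_c Collar water potential (hPa); vectorised. More negative is
#'   drier.
#' @param curve A [water_stress_curve()]; defaults to the standard curve.
#' @return Numeric vector of `S_w` values in `[0, 1]`.
#' @export
water_stress <- function(psi_c, curve = water_stress_curve()) {
  stopifnot(inherits(curve, "water_stress_curve"), is.numeric(psi_c))
  bp <- curve$breakpoints
  out <- stats::approx(bp$psi_c, bp$S_w, xout = psi_c, rule = 2, ties = "ordered")$y
  pmin(pmax(out, 0), 1)
}

# Table of default physiological constants. Kinetic/capacity parameters carry
# their temperature responses; the rest are plain scalars. O-side quantities
# (O_A, K_O25) are in mmol/mol and converted to umol/mol where they meet
# carbon-side fluxes.
default_constants <- function() {
  list(
    # temperature-dependent parameters, value at 298.15 K first
    gamma_star = temperature_response(38.6, 23400),      # umol/mol, C3 CO2 compensation point w/o R_d
    K_C = temperature_response(485, 35600),              # umol/mol
    K_O = temperature_response(146, 15100),              # mmol/mol
    K_P = temperature_response(40, 68100),               # umol/mol
    R_d = temperature_response(1.95, 41850),             # umol/m2/s
    R_m = temperature_response(0.975, 41850),            # umol/m2/s, mesophyll share of R_d
    R_s = temperature_response(0.975, 41850),            # umol/m2/s, bundle-sheath share of R_d
    gamma_bs = temperature_response(0.5 / 2862, 27400),  # dimensionless 0.5/S_c/o
    V_cmax = temperature_response(49, 53400),            # umol/m2/s
    J_max = temperature_response(299.6, 37000, D = 220000, S = 710),
    V_pmax = temperature_response(119.2, 37000, D = 214500, S = 663),
    g_s = temperature_response(0.00287, 116700, D = 264600, S = 860), # mol/m2/s
    # scalars
    m = 4.53,          # Ball-Berry-Leuning slope, dimensionless
    g_w0 = 0.017,      # residual stomatal conductance, mol/m2/s
    V_pr = 80,         # PEP regeneration rate, umol/m2/s
    VPD_ref = 10,      # reference vapour pressure deficit, kPa
    theta = 0.7,       # electron-transport curvature factor
    f = 0.15,          # spectral light quality factor
    alpha = 0.85,      # leaf absorptance, solar spectrum
    alpha_IR = 0.96,   # leaf infrared absorptance
    beta = 2.1,        # irradiance-to-photon conversion, umol/J
    x = 0.4,           # C4 electron transport partitioning factor
    d_L = 0.001,       # leaf thickness, m (0.1 cm)
    d = 0.05,          # characteristic leaf length, m
    C_A = 402.9,       # atmospheric CO2, umol/mol
    O_A = 209.46,      # atmospheric O2, mmol/mol
    sigma = 5.67e-8,   # Stefan-Boltzmann, W/m2/K4
    # leaf-nitrogen proportionality (capacity per leaf N concentration):
    # calibrated so N_leaf = 2 g N m^-2 reproduces J_max25 and V_cmax25
    n1 = 299.6 / 2,
    n2 = 49 / 2,
    # energy-balance auxiliaries (linear fits in T_a - 273.15)
    kair_ref = 0.0243, kair_slope = 7e-5,     # W/m/K
    nu_ref = 1.415e-5, nu_slope = 0.09e-5,    # m2/s
    hvap_ref = 45060, hvap_slope = 425,       # J/mol
    bl_coef = 10.97,   # boundary-layer thickness coefficient
    sky_offset = 40    # T_sky = T_a - sky_offset, K
  )
}

#' Leaf physiological parameter set
#'
#' Assembles the full constant set driving the leaf model: the photosynthetic
#' pathway, one [temperature_response()] per temperature-dependent parameter
#' (compensation points, Michaelis constants, respiration rates, RuBisCo and
#' electron-transport capacities, PEP carboxylation capacity, bundle-sheath
#' conductance) and the scalar constants (Ball-Berry-Leuning slope, residual
#' conductance, absorptances, leaf dimensions, atmospheric composition, and
#' the energy-balance auxiliaries). Defaults are the standard maize-oriented
#' set; any entry can be overridden by name.
#'
#' Unit conventions: `K_O` and `O_A` are in mmol/mol, every other gas
#' concentration in umol/mol; `d_L` and `d` in metres; `VPD_ref` in kPa.
#'
#' @param pathway `"C4"` (default) or `"C3"`.
#' @param ... Named overrides of any constant, e.g. `V_cmax =
#'   temperature_response(60, 53400)` or `m = 6`. Unknown names are an error.
#' @return An object of class `leaf_params`.
#' @export
#' @examples
#' p <- leaf_params("C3")
#' tidy(p)
leaf_params <- function(pathway = c("C4", "C3"), ...) {
  pathway <- match.arg(pathway)
  constants <- default_constants()
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(constants))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (nm in names(overrides)) {
      new <- overrides[[nm]]
      old <- constants[[nm]]
      if (inherits(old, "temperature_response") && is.numeric(new) && length(new) == 1L) {
        # convenience: a bare number replaces p25, keeping the energies
        old$p25 <- new
        new <- old
      }
      constants[[nm]] <- new
    }
  }
  validate_leaf_params(structure(c(list(pathway = pathway), constants),
    class = "leaf_params"
  ))
}

validate_leaf_params <- function(p) {
  stopifnot(inherits(p, "leaf_params"))
  if (!(p$alpha > 0 && p$alpha <= 1)) stop("alpha must be in (0, 1]", call. = FALSE)
  if (!(p$theta > 0 && p$theta < 1)) stop("theta must be in (0, 1)", call. = FALSE)
  if (p$g_w0 < 0) stop("g_w0 must be >= 0", call. = FALSE)
  if (p$d_L <= 0 || p$d <= 0) stop("leaf dimensions must be positive", call. = FALSE)
  p
}

#' @export
print.leaf_params <- function(x, ...) {
  cat(sprintf("<leaf_params> %s pathway\n", x$pathway))
  print(generics::tidy(x), n = 8)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a leaf parameter set
#'
#' One row per constant, with the 25 degC value and (where applicable) the
#' Arrhenius energies.
#'
#' @param x A [leaf_params()] object.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `value`, `E`, `D`, `S`,
#'   `temperature_dependent`.
#' @exportS3Method generics::tidy
tidy.leaf_params <- function(x, ...) {
  rows <- purrr::map(setdiff(names(x), "pathway"), function(nm) {
    v <- x[[nm]]
    if (inherits(v, "temperature_response")) {
      tibble::tibble(
        parameter = nm, value = v$p25,
        E = v$E, D = v$D %||% NA_real_, S = v$S %||% NA_real_,
        temperature_dependent = TRUE
      )
    } else {
      tibble::tibble(
        parameter = nm, value = as.numeric(v),
        E = NA_real_, D = NA_real_, S = NA_real_,
        temperature_dependent = FALSE
      )
    }
  })
  dplyr::bind_rows(rows)
}

# Evaluate every temperature-dependent parameter at leaf temperature T_L.
# K_O is converted from mmol/mol to umol/mol here so downstream biochemistry
# works in a single concentration unit.
kinetics_at <- function(params, T_L) {
  list(
    gamma_star = eval_temperature_response(params$gamma_star, T_L),
    K_C = eval_temperature_response(params$K_C, T_L),
    K_O = 1000 * eval_temperature_response(params$K_O, T_L),
    K_P = eval_temperature_response(params$K_P, T_L),
    R_d = eval_temperature_response(params$R_d, T_L),
    R_m = eval_temperature_response(params$R_m, T_L),
    R_s = eval_temperature_response(params$R_s, T_L),
    gamma_bs = eval_temperature_response(params$gamma_bs, T_L),
    V_cmax = eval_temperature_response(params$V_cmax, T_L),
    J_max = eval_temperature_response(params$J_max, T_L),
    V_pmax = eval_temperature_response(params$V_pmax, T_L),
    g_s = eval_temperature_response(params$g_s, T_L)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
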