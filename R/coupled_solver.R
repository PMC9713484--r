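#' Nested Newton-Raphson solver for fixed-point systems
#'
#' Solves `x_i = F_i(x_1, ..., x_n)` for all `i` simultaneously using a
#' nested scheme that never requires the whole system in one place: variable
#' 1 is outermost and variable `n` innermost. At each Newton iteration on
#' `x_i`, all inner variables `x_{i+1}, ..., x_n` are first re-solved to
#' their own tolerances, so the residual `F_i(x) - x_i` is evaluated on an
#' inner-consistent state. Derivatives are central finite differences with a
#' relative step of `1e-6`. The scheme is deterministic: identical inputs
#' give identical outputs.
#'
#' If any level fails to converge within `max_steps` Newton iterations, the
#' `fallback` vector (by default the initial values, in a time-stepping
#' context the previous step's solution) is returned with
#' `converged = FALSE`.
#'
#' @param F List of update functions; each takes the full numeric state
#'   vector and returns the updated value of its own variable.
#' @param x0 Numeric vector of initial values, one per function.
#' @param tol Per-variable convergence tolerances (recycled), in each
#'   variable's native units.
#' @param max_steps Maximum Newton iterations per level.
#' @param max_evals Global budget of residual evaluations; the solver aborts
#'   to the fallback when it is exhausted.
#' @param fallback Values returned on non-convergence; defaults to `x0`.
#' @return List with `x` (solution vector), `converged` (logical),
#'   `iterations` (total residual evaluations) and `residuals`
#'   (`|F_i(x) - x_i|` at the returned point).
#' @export
#' @examples
#' # a 2x2 linear fixed point with solution (2, 2)
#' F <- list(function(x) 0.5 * x[2] + 1, function(x) 0.5 * x[1] + 1)
#' nested_root_find(F, c(0, 0))$x
nested_root_find <- function(F, x0, tol = 1e-6, max_steps = 40,
                             max_evals = 20000, fallback = NULL) {
  n <- length(F)
  stopifnot(n >= 1L, length(x0) == n)
  tol <- rep_len(tol, n)
  stopifnot(all(tol > 0))
  fallback <- fallback %||% x0
  evals <- 0L
  failed <- FALSE

  residual <- function(i, x) {
    evals <<- evals + 1L
    if (evals > max_evals) {
      stop("shootphys_budget_exhausted", call. = FALSE)
    }
    val <- tryCatch(F[[i]](x), error = function(e) {
      if (conditionMessage(e) == "shootphys_budget_exhausted") stop(e)
      stop(sprintf("update map %d failed: %s", i, conditionMessage(e)),
        call. = FALSE
      )
    })
    val - x[i]
  }

  # solve variables i..n with variables 1..(i-1) held fixed; guarded Newton:
  # a step is accepted only if it reduces |F_i - x_i| (backtracking halves
  # it otherwise), which keeps the iteration stable across the min() kinks
  # of the assimilation and PEP-regeneration laws
  solve_from <- function(i, x) {
    if (i > n) return(x)
    x <- solve_from(i + 1L, x)
    g0 <- residual(i, x)
    for (step in seq_len(max_steps)) {
      if (abs(g0) < tol[i]) return(x)
      h <- 1e-6 * max(abs(x[i]), 1)
      xp <- x; xp[i] <- x[i] + h
      xp <- solve_from(i + 1L, xp)
      gp <- residual(i, xp)
      xm <- x; xm[i] <- x[i] - h
      xm <- solve_from(i + 1L, xm)
      gm <- residual(i, xm)
      dg <- (gp - gm) / (2 * h)
      delta <- if (!is.finite(dg) || abs(dg) < 1e-14) 0.5 * g0 else -g0 / dg
      accepted <- FALSE
      lambda <- 1
      for (bt in 1:5) {
        xt <- x; xt[i] <- x[i] + lambda * delta
        if (is.finite(xt[i])) {
          xt <- solve_from(i + 1L, xt)
          g1 <- residual(i, xt)
          if (abs(g1) < abs(g0)) {
            x <- xt; g0 <- g1; accepted <- TRUE
            break
          }
        }
        lambda <- lambda / 2
      }
      if (!accepted) {
        # no descent along the Newton direction: damped substitution step
        xt <- x; xt[i] <- x[i] + 0.5 * g0
        xt <- solve_from(i + 1L, xt)
        g0 <- residual(i, xt)
        x <- xt
      }
    }
    # Newton stalled (e.g. on a near-vertical stretch of the residual or at
    # a local minimum of |g| with the root beyond a fold): hunt outward for
    # a sign change and bisect; the global evaluation budget bounds the cost
    g_at <- function(xi) {
      xt <- x; xt[i] <- xi
      xt <- solve_from(i + 1L, xt)
      list(g = residual(i, xt), x = xt)
    }
    s <- max(abs(x[i]), 1)
    for (off in s * c(1e-3, 3e-3, 1e-2, 3e-2, 1e-1, 3e-1, 1, 3)) {
      for (sgn in c(1, -1)) {
        pr <- g_at(x[i] + sgn * off)
        if (is.finite(pr$g) && sign(pr$g) != sign(g0) && sign(pr$g) != 0) {
          lo <- x[i]; glo <- g0
          hi <- x[i] + sgn * off
          for (bis in 1:60) {
            mid <- (lo + hi) / 2
            pm <- g_at(mid)
            if (abs(pm$g) < tol[i] || abs(hi - lo) < 1e-13 * s) {
              return(pm$x)
            }
            if (sign(pm$g) == sign(glo)) {
              lo <- mid; glo <- pm$g
            } else {
              hi <- mid
            }
          }
          failed <<- TRUE
          return(pm$x)
        }
      }
    }
    failed <<- TRUE
    x
  }

  x <- tryCatch(solve_from(1L, x0), error = function(e) {
    if (conditionMessage(e) == "shootphys_budget_exhausted") {
      return(NULL)
    }
    stop(e)
  })
  if (is.null(x)) {
    res <- vapply(seq_len(n), function(i) {
      abs(F[[i]](fallback) - fallback[i])
    }, numeric(1))
    return(list(
      x = fallback, converged = FALSE, iterations = evals,
      residuals = res
    ))
  }
  # convergence is judged on the final simultaneous residuals alone, so a
  # transient stall at an inner level that later resolves does not matter
  res <- vapply(seq_len(n), function(i) abs(F[[i]](x) - x[i]), numeric(1))
  converged <- all(res < tol)
  if (!converged) {
    x_out <- fallback
    res <- vapply(seq_len(n), function(i) abs(F[[i]](x_out) - x_out[i]), numeric(1))
  } else {
    x_out <- x
  }
  list(x = x_out, converged = converged, iterations = evals, residuals = res)
}

#' Damped simultaneous fixed-point iteration
#'
#' A robust reference iteration for the same systems handled by
#' [nested_root_find()]: all variables are updated together as
#' `x <- (1 - lambda) * x + lambda * F(x)` until the largest residual falls
#' below `tol`. Slow but simple, it serves as an independent cross-check on
#' the nested Newton scheme.
#'
#' @inheritParams nested_root_find
#' @param lambda Damping factor in (0, 1].
#' @param max_iter Maximum sweeps.
#' @return List with `x`, `converged` and `iterations`.
#' @export
damped_fixed_point <- function(F, x0, lambda = 0.3, tol = 1e-9,
                               max_iter = 10000) {
  n <- length(F)
  x <- x0
  for (it in seq_len(max_iter)) {
    fx <- vapply(seq_len(n), function(i) F[[i]](x), numeric(1))
    res <- max(abs(fx - x))
    if (res < tol) {
      return(list(x = x, converged = TRUE, iterations = it))
    }
    x <- (1 - lambda) * x + lambda * fx
  }
  list(x = x, converged = FALSE, iterations = max_iter)
}

# Diagonally-damped substitution sweep x <- x + lambda * (F(x) - x), with
# per-variable damping chosen from the local diagonal slope of the map and a
# cap that halves when progress stalls. Used to follow the fixed-point flow
# from the initial state into the attraction basin of the branch continuous
# with it (the coupled stomatal/energy system can be bistable under strong
# radiative load), before Newton polishing takes over.
diag_damped_sweep <- function(state_fn, x0, scale, tol = 1e-6,
                              max_iter = 400, lam_cap = 0.2) {
  x <- x0
  x_best <- x0
  r_best <- Inf
  it_best <- 0L
  lam <- rep(lam_cap, length(x0))
  for (it in seq_len(max_iter)) {
    fx <- state_fn(x)
    r <- max(abs(fx - x) / scale)
    if (r < tol) return(x)
    if (r < r_best) {
      r_best <- r
      x_best <- x
      it_best <- it
    } else if (it - it_best > 60) {
      lam_cap <- lam_cap / 2
      x <- x_best
      it_best <- it
      if (lam_cap < 1e-5) break
      fx <- state_fn(x)
    }
    if (it %% 5 == 1) {
      for (j in seq_along(x)) {
        h <- 1e-5 * max(abs(x[j]), scale[j])
        xp <- x
        xp[j] <- x[j] + h
        slope <- (state_fn(xp)[j] - fx[j]) / h
        lam[j] <- min(lam_cap, 1 / max(1, abs(1 - slope)))
      }
    }
    lam <- pmin(lam, lam_cap)
    x <- x + lam * (fx - x)
  }
  x_best
}

# Consistent diagnostic state for a leaf given (T_L, g_w, A): evaluates the
# temperature responses, the gas steady states (linear given g_w and A) and
# the assimilation and conductance updates. Used both as the solver's update
# maps and to assemble the returned leaf state. Gas concentrations are
# clamped at zero: the raw quasi-steady-state forms can turn negative at the
# model's validity edge (tiny conductances with respiration exceeding
# assimilation), where the unclamped rational rate laws change sign
# spuriously.
leaf_system_state <- function(T_L, g_w, A, params, T_a, I_s, VPD, v, P, S_w,
                              C_A, O_A_umol, kin = NULL) {
  k <- kin %||% kinetics_at(params, T_L)
  et <- electron_transport(I_s, k$J_max,
    theta = params$theta, alpha = params$alpha,
    f = params$f, beta = params$beta
  )
  if (params$pathway == "C3") {
    gas <- c3_gas_steady_state(g_w, A, k$R_d, C_A, O_A_umol)
    gas$C_m <- max(gas$C_m, 0)
    gas$O_m <- max(gas$O_m, 0)
    asm <- c3_assimilation(gas$C_m, gas$O_m, et$J, k$V_cmax, k$K_C, k$K_O,
      gamma_star = k$gamma_star
    )
    cp <- compensation_points("C3", k$R_d, gas$O_m, k$V_cmax, k$K_C, k$K_O,
      gamma_star = k$gamma_star
    )
    extra <- list(C_s = NA_real_, O_s = NA_real_, V_p = NA_real_,
      Gamma_s = NA_real_)
  } else {
    # A_r excludes dark respiration, so A_r = A; C_m is independent of V_p
    gas0 <- c4_gas_steady_state(g_w, k$g_s, A, 0, k$R_m, k$R_s, C_A, O_A_umol)
    V_p <- pep_carboxylation(max(gas0$C_m, 0), k$V_pmax, k$K_P, params$V_pr)
    gas <- c4_gas_steady_state(g_w, k$g_s, A, V_p, k$R_m, k$R_s, C_A, O_A_umol)
    gas$C_m <- max(gas$C_m, 0)
    gas$C_s <- max(gas$C_s, 0)
    gas$O_m <- max(gas$O_m, 0)
    gas$O_s <- max(gas$O_s, 0)
    asm <- c4_assimilation(gas$C_s, gas$O_s, et$J, k$V_cmax, k$K_C, k$K_O,
      gamma_bs = k$gamma_bs, x = params$x
    )
    cp <- compensation_points("C4", k$R_d, gas$O_m, k$V_cmax, k$K_C, k$K_O,
      gamma_bs = k$gamma_bs, K_P = k$K_P, V_pmax = k$V_pmax,
      R_m = k$R_m, g_s = k$g_s
    )
    extra <- list(C_s = gas$C_s, O_s = gas$O_s, V_p = V_p,
      Gamma_s = cp$Gamma_s)
  }
  g_w_new <- stomatal_conductance(asm$A, k$R_d, cp$Gamma, VPD, S_w, C_A,
    m = params$m, g_w0 = params$g_w0, VPD_ref = params$VPD_ref
  )
  J_v <- leaf_transpiration(g_w, T_L, T_a, VPD, P)
  c(
    list(
      kin = k, J = et$J, I_2 = et$I_2,
      C_m = gas$C_m, O_m = gas$O_m,
      A = asm$A, A_c = asm$A_c, A_j = asm$A_j,
      Gamma = cp$Gamma, g_w_new = g_w_new, J_v = J_v
    ),
    extra
  )
}

#' Solve the coupled leaf state
#'
#' Solves the full leaf fixed-point system — assimilation, quasi-steady-state
#' gas concentrations, stomatal conductance, transpiration and the leaf
#' energy balance — for a single environment, using the nested Newton scheme
#' of [nested_root_find()]. The nesting order is leaf temperature outermost,
#' then stomatal conductance, then assimilation; the gas concentrations are
#' linear given those three and are solved exactly inside the assimilation
#' update, so the converged state satisfies every balance equation
#' simultaneously.
#'
#' On non-convergence the initial state (by default the night state: `A = 0`,
#' `g_w = g_w0`, `T_L = T_a`; in time stepping, the previous step's state) is
#' returned with `converged = FALSE`.
#'
#' @param params A [leaf_params()] object.
#' @param T_a Air temperature (K).
#' @param I_s Solar irradiance on the leaf (W m^-2).
#' @param VPD Vapour pressure deficit (kPa).
#' @param v Wind speed (m s^-1), positive.
#' @param P Atmospheric pressure (Pa).
#' @param S_w Water stress factor in `[0, 1]`.
#' @param C_A Atmospheric CO2 (umol/mol); defaults to the parameter set's.
#' @param O_A Atmospheric O2 (mmol/mol); defaults to the parameter set's.
#' @param init Optional named vector `c(T_L, g_w, A)` of starting values
#'   (e.g. the previous timestep's solution).
#' @param tol Per-variable tolerance (K, mol m^-2 s^-1, umol m^-2 s^-1).
#' @param max_steps Newton iterations per nesting level.
#' @return An object of class `leaf_state`: a list with the solved `A`,
#'   `A_c`, `A_j`, `J`, `I_2`, `g_w`, `C_m`, `O_m` (and `C_s`, `O_s`, `V_p`,
#'   `Gamma_s` for C4), `Gamma`, `T_L`, `J_v`, the kinetic parameters at
#'   `T_L`, and solver diagnostics (`converged`, `iterations`). All gas
#'   concentrations are reported in umol/mol.
#' @export
#' @examples
#' st <- solve_leaf_state(leaf_params("C4"),
#'   T_a = 298.15, I_s = 500,
#'   VPD = 1.5, v = 2, S_w = 1
#' )
#' round(c(A = st$A, g_w = st$g_w, T_L = st$T_L), 3)
solve_leaf_state <- function(params, T_a, I_s, VPD, v, P = 101325, S_w = 1,
                             C_A = params$C_A, O_A = params$O_A,
                             init = NULL, tol = 1e-6, max_steps = 40) {
  stopifnot(inherits(params, "leaf_params"), P > 0, I_s >= 0, VPD >= 0, v > 0)
  O_A_umol <- O_A * 1000
  # One shared model path: the update maps evaluate leaf_system_state (the
  # same code that assembles the returned state and that tests exercise),
  # with temperature responses cached per T_L since they are constant within
  # the inner (g_w, A) nesting levels.
  cache <- new.env(parent = emptyenv())
  cache$T_L <- NA_real_
  kin_at <- function(T_L) {
    if (isTRUE(T_L == cache$T_L)) return(cache$kin)
    k <- kinetics_at(params, T_L)
    cache$T_L <- T_L
    cache$kin <- k
    k
  }
  # clamp transient Newton overshoot to the physical domain; the converged
  # state always lies strictly inside these bounds
  clamp_x <- function(x) {
    x[1] <- min(max(x[1], T_a - 60), T_a + 60)
    x[2] <- max(x[2], params$g_w0, 1e-6)
    x[3] <- min(max(x[3], -20), 150)
    x
  }
  state_at <- function(x) {
    x <- clamp_x(x)
    leaf_system_state(x[1], x[2], x[3], params, T_a, I_s, VPD, v, P, S_w,
      C_A, O_A_umol,
      kin = kin_at(x[1])
    )
  }
  F <- list(
    function(x) { # leaf temperature from the energy balance at current J_v
      x <- clamp_x(x)
      J_v <- leaf_transpiration(x[2], x[1], T_a, VPD, P)
      solve_leaf_temperature(T_a, I_s, J_v, v, params)
    },
    function(x) state_at(x)$g_w_new,
    function(x) state_at(x)$A
  )
  x0 <- init %||% c(T_L = T_a, g_w = params$g_w0, A = 0)
  # inner variables are solved tighter than the outer ones so that inner
  # solution noise stays below the outer residual tolerances
  tol3 <- if (length(tol) == 3L) tol else tol * c(1, 1e-3, 1e-2)
  # a damped pre-iteration follows the fixed-point flow from the initial
  # state into its attraction basin (selecting the branch continuous with
  # that state when the system is bistable); the nested Newton scheme then
  # converges in a handful of steps
  state_vec <- function(x) {
    st <- state_at(x)
    c(F[[1]](x), st$g_w_new, st$A)
  }
  # run the flow-following pre-iteration unless the start is already close
  # (e.g. a warm start from a nearby previous state); Newton alone thrashes
  # from distant starts, while the damped flow reaches the right basin
  scale <- c(1, 0.017, 1)
  x_start <- unname(x0)
  r0 <- max(abs(state_vec(x_start) - x_start) / scale)
  pre_x <- if (r0 > 0.3) {
    diag_damped_sweep(state_vec, x_start, scale = scale,
      tol = 1e-5, max_iter = 400
    )
  } else {
    x_start
  }
  sol <- nested_root_find(F, pre_x,
    tol = tol3, max_steps = max_steps,
    fallback = unname(x0)
  )
  st <- state_at(sol$x)
  structure(
    list(
      pathway = params$pathway,
      A = st$A, A_c = st$A_c, A_j = st$A_j, J = st$J, I_2 = st$I_2,
      g_w = sol$x[2], C_m = st$C_m, O_m = st$O_m,
      C_s = st$C_s, O_s = st$O_s, V_p = st$V_p,
      Gamma = st$Gamma, Gamma_s = st$Gamma_s,
      gamma_star = st$kin$gamma_star,
      T_L = sol$x[1], J_v = st$J_v,
      R_d = st$kin$R_d, R_m = st$kin$R_m, R_s = st$kin$R_s,
      V_cmax = st$kin$V_cmax, J_max = st$kin$J_max,
      V_pmax = st$kin$V_pmax, g_s = st$kin$g_s,
      S_w = S_w, T_a = T_a, I_s = I_s, VPD = VPD, v = v, P = P, C_A = C_A,
      converged = sol$converged, iterations = sol$iterations,
      residuals = sol$residuals
    ),
    class = "leaf_state"
  )
}

#' @export
print.leaf_state <- function(x, ...) {
  cat(sprintf(
    "<leaf_state> %s  A = %.3f umol/m2/s  g_w = %.4f mol/m2/s  T_L = %.2f K%s\n",
    x$pathway, x$A, x$g_w, x$T_L,
    if (x$converged) "" else "  [not converged]"
  ))
  invisible(x)
}

#' Tidy a solved leaf state
#'
#' @param x A `leaf_state` from [solve_leaf_state()].
#' @param ... Unused.
#' @return A one-row tibble of the solved quantities.
#' @exportS3Method generics::tidy
tidy.leaf_state <- function(x, ...) {
  tibble::tibble(
    pathway = x$pathway, A = x$A, A_c = x$A_c, A_j = x$A_j, J = x$J,
    g_w = x$g_w, C_m = x$C_m, O_m = x$O_m, C_s = x$C_s, O_s = x$O_s,
    V_p = x$V_p, Gamma = x$Gamma, T_L = x$T_L, J_v = x$J_v, R_d = x$R_d,
    S_w = x$S_w, converged = x$converged
  )
}

#' Solve leaf states over a table of environments
#'
#' Maps [solve_leaf_state()] over the rows of an environment table (columns
#' `T_a`, `I_s`, `VPD`, `v`, and optionally `P`, `S_w` or `psi_c`), binding
#' the solved state onto the input so calls chain with the pipe.
#'
#' @param data Data frame of environments; one row per leaf environment.
#' @param params A [leaf_params()] object.
#' @param curve [water_stress_curve()] used when `psi_c` is supplied
#'   instead of `S_w`.
#' @param ... Passed to [solve_leaf_state()].
#' @return The input as a tibble with columns `A`, `g_w`, `C_m`, `Gamma`,
#'   `T_L`, `J_v` and `converged` appended.
#' @export
solve_leaf_states <- function(data, params = leaf_params(),
                              curve = water_stress_curve(), ...) {
  stopifnot(is.data.frame(data))
  need <- c("T_a", "I_s", "VPD", "v")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("missing environment column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  data <- tibble::as_tibble(data)
  P <- if ("P" %in% names(data)) data$P else rep(101325, nrow(data))
  S_w <- if ("S_w" %in% names(data)) {
    data$S_w
  } else if ("psi_c" %in% names(data)) {
    water_stress(data$psi_c, curve)
  } else {
    rep(1, nrow(data))
  }
  sol <- purrr::pmap(
    list(data$T_a, data$I_s, data$VPD, data$v, P, S_w),
    function(T_a, I_s, VPD, v, P, S_w) {
      st <- solve_leaf_state(params, T_a, I_s, VPD, v, P = P, S_w = S_w, ...)
      tibble::tibble(
        A = st$A, g_w = st$g_w, C_m = st$C_m, Gamma = st$Gamma,
        T_L = st$T_L, J_v = st$J_v, converged = st$converged
      )
    }
  )
  dplyr::bind_cols(data, dplyr::bind_rows(sol))
}

#' Leaf response curves
#'
#' Convenience transect generator: solves the coupled leaf state along a
#' light-response (varying `I_s`) or CO2-response (varying `C_A`) gradient
#' with everything else fixed, returning a tidy table ready for plotting.
#'
#' @param params A [leaf_params()] object.
#' @param over `"light"` or `"co2"`.
#' @param values Gradient values: `I_s` in W m^-2 or `C_A` in umol/mol.
#' @param T_a,VPD,v,P,S_w Fixed environment.
#' @return A tibble with the gradient column, `A`, `A_c`, `A_j`, `g_w`,
#'   `C_m`, `T_L`, `limiting` (`"carbon"` or `"light"`) and `converged`.
#' @export
leaf_response_curve <- function(params = leaf_params(),
                                over = c("light", "co2"),
                                values = NULL, T_a = 298.15, VPD = 1.5,
                                v = 2, P = 101325, S_w = 1) {
  over <- match.arg(over)
  values <- values %||% switch(over,
    light = seq(0, 1000, by = 50),
    co2 = seq(50, 1000, by = 50)
  )
  rows <- purrr::map(values, function(val) {
    st <- if (over == "light") {
      solve_leaf_state(params, T_a, I_s = val, VPD = VPD, v = v, P = P, S_w = S_w)
    } else {
      solve_leaf_state(params, T_a,
        I_s = 500, VPD = VPD, v = v, P = P,
        S_w = S_w, C_A = val
      )
    }
    tibble::tibble(
      value = val, A = st$A, A_c = st$A_c, A_j = st$A_j, g_w = st$g_w,
      C_m = st$C_m, T_L = st$T_L,
      limiting = ifelse(st$A_c <= st$A_j, "carbon", "light"),
      converged = st$converged
    )
  })
  out <- dplyr::bind_rows(rows)
  names(out)[1] <- if (over == "light") "I_s" else "C_A"
  out
}
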