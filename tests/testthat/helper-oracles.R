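# Shared oracles and fixtures, built from the package's public module
# functions (not the solver's internal fast path), so solver results are
# always cross-checked against an independently assembled system.

# Fixed-point update maps for the coupled leaf system, assembled from the
# public biochemistry/energy functions. Gas concentrations are clamped at
# zero (a model invariant): without the clamp the rational assimilation
# forms admit spurious fixed points with negative concentrations.
leaf_fixed_point_maps <- function(params, T_a, I_s, VPD, v, P = 101325,
                                  S_w = 1) {
  O_A_umol <- params$O_A * 1000
  kin_cache <- new.env(parent = emptyenv())
  kin_cache$T <- NA_real_
  kin_memo <- function(T_L) {
    if (isTRUE(T_L == kin_cache$T)) return(kin_cache$k)
    k <- shootphys:::kinetics_at(params, T_L)
    kin_cache$T <- T_L
    kin_cache$k <- k
    k
  }
  state <- function(x) {
    T_L <- min(max(x[1], T_a - 60), T_a + 60)
    g_w <- max(x[2], params$g_w0)
    A <- x[3]
    k <- kin_memo(T_L)
    J <- electron_transport(I_s, k$J_max, params$theta, params$alpha,
      params$f, params$beta
    )$J
    if (params$pathway == "C3") {
      gas <- c3_gas_steady_state(g_w, A, k$R_d, params$C_A, O_A_umol)
      C_m <- max(gas$C_m, 0)
      O_m <- max(gas$O_m, 0)
      asm <- c3_assimilation(C_m, O_m, J, k$V_cmax, k$K_C, k$K_O, k$gamma_star)
      cp <- compensation_points("C3", k$R_d, O_m, k$V_cmax, k$K_C, k$K_O,
        gamma_star = k$gamma_star
      )
    } else {
      gas0 <- c4_gas_steady_state(g_w, k$g_s, A, 0, k$R_m, k$R_s,
        params$C_A, O_A_umol
      )
      V_p <- pep_carboxylation(max(gas0$C_m, 0), k$V_pmax, k$K_P, params$V_pr)
      gas <- c4_gas_steady_state(g_w, k$g_s, A, V_p, k$R_m, k$R_s,
        params$C_A, O_A_umol
      )
      C_s <- max(gas$C_s, 0)
      O_s <- max(gas$O_s, 0)
      O_m <- max(gas$O_m, 0)
      asm <- c4_assimilation(C_s, O_s, J, k$V_cmax, k$K_C, k$K_O, k$gamma_bs,
        params$x
      )
      cp <- compensation_points("C4", k$R_d, O_m, k$V_cmax, k$K_C, k$K_O,
        gamma_bs = k$gamma_bs, K_P = k$K_P, V_pmax = k$V_pmax,
        R_m = k$R_m, g_s = k$g_s
      )
    }
    gw_new <- stomatal_conductance(asm$A, k$R_d, cp$Gamma, VPD, S_w,
      params$C_A, params$m, params$g_w0, params$VPD_ref
    )
    J_v <- leaf_transpiration(g_w, T_L, T_a, VPD, P)
    c(solve_leaf_temperature(T_a, I_s, J_v, v, params), gw_new, asm$A)
  }
  state
}

# Damped-iteration reference solution of the coupled leaf system,
# independent of the package's nested Newton scheme. Phase 1 is a damped
# simultaneous sweep x <- x + lambda (F(x) - x) with per-variable damping
# from the local diagonal slope. When the fixed point sits on the
# near-vertical stretch of the assimilation map (severe drought), no
# simultaneous damping converges; phase 2 then eliminates A by pure
# bisection inside a damped two-variable (T_L, g_w) sweep - bisection is
# indifferent to the slope of the residual.
leaf_state_oracle <- function(params, T_a, I_s, VPD, v, P = 101325, S_w = 1,
                              tol = 1e-9, max_iter = 20000) {
  state <- leaf_fixed_point_maps(params, T_a, I_s, VPD, v, P, S_w)
  scale <- c(1, 0.017, 1)
  # phase 1: damped simultaneous sweep
  x <- c(T_a, params$g_w0, 0)
  lam_cap <- 0.2
  lam <- rep(lam_cap, 3)
  x_best <- x
  r_best <- Inf
  it_best <- 0L
  for (it in seq_len(max_iter)) {
    fx <- state(x)
    r <- max(abs(fx - x) / scale)
    if (r < tol) {
      return(list(x = x, converged = TRUE, iterations = it, phase = 1))
    }
    if (r < r_best) {
      r_best <- r
      x_best <- x
      it_best <- it
    } else if (it - it_best > 200) {
      lam_cap <- lam_cap / 2
      x <- x_best
      it_best <- it
      if (lam_cap < 1e-6) break
      fx <- state(x)
    }
    if (it %% 5 == 1) {
      for (j in 1:3) {
        hh <- 1e-5 * max(abs(x[j]), scale[j])
        xp <- x
        xp[j] <- x[j] + hh
        slope <- (state(xp)[j] - fx[j]) / hh
        lam[j] <- min(lam_cap, 1 / max(1, abs(1 - slope)))
      }
    }
    lam <- pmin(lam, lam_cap)
    x <- x + lam * (fx - x)
  }
  # phase 2: bisect the assimilation fixed point exactly, damp the rest
  A_solve <- function(T_L, g_w) {
    g_of <- function(A) state(c(T_L, g_w, A))[3] - A
    lo <- -20
    hi <- 150
    glo <- g_of(lo)
    ghi <- g_of(hi)
    if (sign(glo) == sign(ghi)) return(NA_real_)
    for (b in 1:60) {
      mid <- (lo + hi) / 2
      gm <- g_of(mid)
      if (sign(gm) == sign(glo)) {
        lo <- mid
        glo <- gm
      } else {
        hi <- mid
      }
    }
    (lo + hi) / 2
  }
  y <- c(T_a, params$g_w0)
  A <- A_solve(y[1], y[2])
  for (it in seq_len(3000)) {
    if (is.na(A)) break
    fx <- state(c(y, A))
    r <- max(abs(c(fx[1] - y[1], fx[2] - y[2], fx[3] - A)) / scale)
    if (r < tol) {
      return(list(x = c(y, A), converged = TRUE, iterations = it, phase = 2))
    }
    y <- y + 0.3 * (fx[1:2] - y)
    A <- A_solve(y[1], y[2])
  }
  list(x = x_best, converged = FALSE, iterations = max_iter, phase = 2)
}

# relative difference with a floor scale so near-zero quantities are
# compared on their natural unit scale
rel_diff <- function(a, b, floor_scale) {
  abs(a - b) / max(abs(b), floor_scale)
}

# largest scaled difference between a solved leaf state and an oracle vector
leaf_state_disagreement <- function(st, x_oracle) {
  max(
    rel_diff(st$T_L, x_oracle[1], 1),
    rel_diff(st$g_w, x_oracle[2], 0.017),
    rel_diff(st$A, x_oracle[3], 1)
  )
}

# random leaf environments spanning the test envelope
random_environments <- function(n, seed) {
  set.seed(seed)
  tibble::tibble(
    c4 = rep(c(TRUE, FALSE), length.out = n),
    T_a = runif(n, 278, 318),
    I_s = runif(n, 0, 1000),
    VPD = runif(n, 0.1, 4),
    v = runif(n, 0.3, 8),
    S_w = runif(n)
  )
}

# residuals of the printed quasi-steady-state gas balance equations at a
# solved leaf state (umol/mol/s scale before the R*T/(P*d_L) prefactor,
# which is strictly positive and does not move the zero)
c3_ode_rhs <- function(C_m, O_m, g_w, A, R_d, C_A, O_A_umol) {
  c(
    g_w / 1.6 * (C_A - C_m) - A + R_d,
    g_w / 1.25 * (O_A_umol - O_m) + A - R_d
  )
}

c4_ode_rhs <- function(C_m, C_s, O_m, O_s, g_w, g_s, A_r, V_p, R_m, R_s,
                       C_A, O_A_umol) {
  c(
    g_w / 1.6 * (C_A - C_m) + g_s * (C_s - C_m) - V_p + R_m,
    V_p - A_r - g_s * (C_s - C_m) + R_s,
    g_w / 1.25 * (O_A_umol - O_m) + 0.047 * g_s * (O_s - O_m) - R_m,
    A_r - R_s - 0.047 * g_s * (O_s - O_m)
  )
}
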