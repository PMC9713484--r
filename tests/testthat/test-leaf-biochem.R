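p25 <- list(
  V_cmax = 49, K_C = 485, K_O = 146000, gamma_star = 38.6, R_d = 1.95,
  O_A = 209460, C_A = 402.9
)

test_that("electron transport saturates correctly and matches the quadratic root", {
  expect_equal(electron_transport(0, 299.6)$J, 0)
  # saturation: huge irradiance drives J to J_max
  expect_equal(electron_transport(1e7, 299.6)$J, 299.6, tolerance = 1e-3)
  # at I_2 = J_max the smaller quadratic root has the closed form
  # J_max * (2 - sqrt(4 - 4*theta)) / (2*theta)
  J_max <- 299.6
  theta <- 0.7
  I_s <- 2 * J_max / (2.1 * 0.85 * (1 - 0.15)) # makes I_2 = J_max
  et <- electron_transport(I_s, J_max, theta = theta)
  expect_equal(et$I_2, J_max)
  expect_equal(et$J, J_max * (2 - sqrt(4 - 4 * theta)) / (2 * theta))
  # J never exceeds either limit and grows with light
  Js <- vapply(seq(0, 1200, by = 40), function(i) electron_transport(i, 299.6)$J, 0)
  expect_true(all(diff(Js) >= 0))
  expect_true(all(Js <= 299.6 + 1e-9))
  expect_error(electron_transport(100, 300, theta = 1.2), "theta")
})

test_that("C3 assimilation reproduces direct evaluation of the rate laws", {
  # numerator vanishes at the compensation point
  a0 <- c3_assimilation(38.6, p25$O_A, 150, p25$V_cmax, p25$K_C, p25$K_O, 38.6)
  expect_equal(a0$A, 0)
  # light limitation vanishes with J
  aj <- c3_assimilation(242.9, p25$O_A, 0, p25$V_cmax, p25$K_C, p25$K_O, 38.6)
  expect_equal(aj$A_j, 0)
  expect_equal(aj$A, 0)
  # carbon-limited worked value at C_m = 242.9 with saturating J
  a <- c3_assimilation(242.9, p25$O_A, 1e4, p25$V_cmax, p25$K_C, p25$K_O, 38.6)
  expected_Ac <- 49 * (242.9 - 38.6) /
    (242.9 + 485 * (1 + 209460 / 146000))
  expect_equal(a$A_c, expected_Ac)
  expect_equal(a$A, expected_Ac)
  # min law on random draws
  set.seed(7)
  for (i in 1:20) {
    r <- c3_assimilation(
      runif(1, 10, 800), p25$O_A, runif(1, 0, 300),
      p25$V_cmax, p25$K_C, p25$K_O, 38.6
    )
    expect_lte(r$A, r$A_c)
    expect_lte(r$A, r$A_j)
  }
})

test_that("PEP carboxylation follows Michaelis-Menten capped by regeneration", {
  expect_equal(pep_carboxylation(0, 119.2, 40, 80), 0)
  # half saturation at C_m = K_P
  expect_equal(pep_carboxylation(40, 119.2, 40, 80), 59.6)
  # large C_m limit is the regeneration cap
  expect_equal(pep_carboxylation(1e9, 119.2, 40, 80), 80)
})

test_that("C4 assimilation vanishes at the bundle-sheath compensation point", {
  gamma_bs <- 0.5 / 2862
  O_s <- 209460
  a0 <- c4_assimilation(gamma_bs * O_s, O_s, 200, 49, 485, 146000, gamma_bs)
  expect_equal(a0$A, 0, tolerance = 1e-10)
  # full electron partitioning to the mesophyll kills the light-limited rate
  a1 <- c4_assimilation(1000, O_s, 200, 49, 485, 146000, gamma_bs, x = 1)
  expect_equal(a1$A_j, 0)
  # direct evaluation of both rate laws
  a <- c4_assimilation(100, O_s, 200, 49, 485, 146000, gamma_bs, x = 0.4)
  num <- 100 - gamma_bs * O_s
  expect_equal(a$A_c, num * 49 / (100 + 485 * (1 + O_s / 146000)))
  expect_equal(a$A_j, num * 0.6 * 200 / (3 * 100 + 7 * gamma_bs * O_s))
  expect_equal(a$A, min(a$A_c, a$A_j))
})

test_that("C3 gas steady state matches the closed form and the integrated ODEs", {
  # A = R_d leaves the leaf interior at atmospheric composition
  eq <- c3_gas_steady_state(0.2, 1.95, 1.95, p25$C_A, p25$O_A)
  expect_equal(eq$C_m, p25$C_A)
  expect_equal(eq$O_m, p25$O_A)
  # worked value: 402.9 - 1.6*20/0.2
  g <- c3_gas_steady_state(0.2, 21.95, 1.95, p25$C_A, p25$O_A)
  expect_equal(g$C_m, 242.9)
  expect_error(c3_gas_steady_state(0, 5, 1, p25$C_A, p25$O_A), "positive")

  # the steady state zeroes the printed balance equations and agrees with
  # numerically integrating them to equilibrium
  skip_if_not_installed("deSolve")
  pref <- 8.31446 * 298.15 / (101325 * 0.001) # R*T/(P*d_L) prefactor
  rhs <- function(t, y, parms) {
    list(pref * c3_ode_rhs(y[1], y[2], parms$g_w, parms$A, parms$R_d,
      p25$C_A, p25$O_A))
  }
  set.seed(11)
  for (i in 1:6) {
    parms <- list(g_w = runif(1, 0.05, 0.6), A = runif(1, 0, 30),
      R_d = runif(1, 0.5, 3))
    ss <- c3_gas_steady_state(parms$g_w, parms$A, parms$R_d, p25$C_A, p25$O_A)
    expect_lt(max(abs(c3_ode_rhs(ss$C_m, ss$O_m, parms$g_w, parms$A,
      parms$R_d, p25$C_A, p25$O_A))), 1e-9)
    out <- deSolve::lsoda(c(p25$C_A, p25$O_A), c(0, 5000), rhs, parms,
      rtol = 1e-10, atol = 1e-10)
    expect_equal(unname(out[2, 2]), ss$C_m, tolerance = 1e-6)
    expect_equal(unname(out[2, 3]), ss$O_m, tolerance = 1e-6)
  }
})

test_that("C4 gas steady state solves the coupled reservoirs exactly", {
  # all fluxes zero: both compartments at atmospheric composition
  z <- c4_gas_steady_state(0.2, 0.003, 0, 0, 0, 0, p25$C_A, p25$O_A)
  expect_equal(z$C_m, p25$C_A)
  expect_equal(z$C_s, p25$C_A)
  expect_equal(z$O_m, p25$O_A)
  expect_equal(z$O_s, p25$O_A)
  expect_error(
    c4_gas_steady_state(0, 0.003, 1, 1, 1, 1, p25$C_A, p25$O_A),
    "positive"
  )

  skip_if_not_installed("deSolve")
  pref <- 8.31446 * 298.15 / (101325 * 0.001)
  rhs <- function(t, y, q) {
    list(pref * c4_ode_rhs(y[1], y[2], y[3], y[4], q$g_w, q$g_s, q$A_r,
      q$V_p, q$R_m, q$R_s, p25$C_A, p25$O_A))
  }
  set.seed(13)
  for (i in 1:6) {
    q <- list(
      g_w = runif(1, 0.05, 0.5), g_s = runif(1, 0.002, 0.01),
      A_r = runif(1, 0, 40), V_p = runif(1, 0, 80),
      R_m = runif(1, 0.3, 1.5), R_s = runif(1, 0.3, 1.5)
    )
    ss <- c4_gas_steady_state(q$g_w, q$g_s, q$A_r, q$V_p, q$R_m, q$R_s,
      p25$C_A, p25$O_A)
    res <- c4_ode_rhs(ss$C_m, ss$C_s, ss$O_m, ss$O_s, q$g_w, q$g_s, q$A_r,
      q$V_p, q$R_m, q$R_s, p25$C_A, p25$O_A)
    expect_lt(max(abs(res)), 1e-9)
    out <- deSolve::lsoda(rep(c(p25$C_A, p25$O_A), each = 2), c(0, 2e5), rhs,
      q, rtol = 1e-11, atol = 1e-9)
    expect_equal(unname(out[2, 2:5]),
      c(ss$C_m, ss$C_s, ss$O_m, ss$O_s),
      tolerance = 1e-6
    )
  }
})

test_that("stomatal conductance follows the VPD-modified Ball-Berry form", {
  # no net assimilation or full stress: residual conductance only
  expect_equal(stomatal_conductance(1.95, 1.95, 52.9, 1, 1, 402.9), 0.017)
  expect_equal(stomatal_conductance(25, 1.95, 52.9, 1, 0, 402.9), 0.017)
  # hand arithmetic: m*(A-Rd)/(CA-Gamma)/(1+VPD/VPDr) + gw0
  g <- stomatal_conductance(21.95, 1.95, 52.9, 1, 1, 402.9)
  expect_equal(g, 4.53 * 20 / 350 / (1 + 1 / 10) + 0.017)
  expect_equal(round(g, 4), 0.2523)
  # monotone: drier air closes stomata
  gs <- vapply(seq(0, 5, by = 0.5), function(d) {
    stomatal_conductance(21.95, 1.95, 52.9, d, 1, 402.9)
  }, 0)
  expect_true(all(diff(gs) < 0))
  expect_error(stomatal_conductance(10, 1, 500, 1, 1, 402.9), "compensation")
})

test_that("compensation points collapse to their no-respiration limits", {
  # C3 with no dark respiration: Gamma reduces to gamma_star
  c3 <- compensation_points("C3", 0, p25$O_A, 49, 485, 146000,
    gamma_star = 38.6
  )
  expect_equal(c3$Gamma, 38.6)
  # respiration raises the C3 compensation point
  c3r <- compensation_points("C3", 1.95, p25$O_A, 49, 485, 146000,
    gamma_star = 38.6
  )
  expect_gt(c3r$Gamma, 38.6)
  expect_equal(
    c3r$Gamma,
    (38.6 + 485 * (1.95 / 49) * (1 + 209460 / 146000)) / (1 - 1.95 / 49)
  )
  expect_error(
    compensation_points("C3", 50, p25$O_A, 49, 485, 146000, gamma_star = 38.6),
    "undefined"
  )
  # C4 with no respiration: bundle-sheath point is gamma_bs * O_m
  gamma_bs <- 0.5 / 2862
  c4 <- compensation_points("C4", 0, p25$O_A, 49, 485, 146000,
    gamma_bs = gamma_bs, K_P = 40, V_pmax = 119.2, R_m = 0, g_s = 0.00287
  )
  expect_equal(c4$Gamma_s, gamma_bs * p25$O_A)
  expect_equal(c4$Gamma, (40 / 119.2) * 0.00287 * gamma_bs * p25$O_A)
})
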