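test_that("nested root finder solves linear fixed points exactly", {
  # single variable: x = (x + 2)/2 has fixed point 2
  r1 <- nested_root_find(list(function(x) (x[1] + 2) / 2), 0)
  expect_true(r1$converged)
  expect_equal(r1$x, 2, tolerance = 1e-6)
  # two coupled linear maps with solution (2, 2)
  F2 <- list(function(x) 0.5 * x[2] + 1, function(x) 0.5 * x[1] + 1)
  r2 <- nested_root_find(F2, c(0, 0))
  expect_true(r2$converged)
  expect_equal(r2$x, c(2, 2), tolerance = 1e-6)
  # three-variable system against its algebraic solution:
  # x = (y + z)/4 + 1, y = x/2, z = y/2 + 1  =>  z - ... solve by hand:
  # x = (x/2 + x/4 + 1)/4 + 1 => x (1 - 3/16) = 5/4 => x = 20/13
  F3 <- list(
    function(x) (x[2] + x[3]) / 4 + 1,
    function(x) x[1] / 2,
    function(x) x[2] / 2 + 1
  )
  r3 <- nested_root_find(F3, c(0, 0, 0))
  expect_true(r3$converged)
  expect_equal(r3$x, c(20 / 13, 10 / 13, 18 / 13), tolerance = 1e-6)
})

test_that("a map with no fixed point returns the fallback, not converged", {
  r <- nested_root_find(list(function(x) x[1] + 1), 5, fallback = 5)
  expect_false(r$converged)
  expect_equal(r$x, 5)
})

test_that("variable order changes iterations but not the solution", {
  Fa <- list(
    function(x) 0.3 * x[2] + 0.1 * x[3] + 1,
    function(x) 0.2 * x[1] - 0.1 * x[3] + 2,
    function(x) 0.1 * x[1] + 0.2 * x[2] - 1
  )
  ra <- nested_root_find(Fa, c(0, 0, 0))
  # permuted order (3, 1, 2): remap the state vector accordingly
  Fb <- list(
    function(x) 0.1 * x[2] + 0.2 * x[3] - 1,
    function(x) 0.3 * x[3] + 0.1 * x[1] + 1,
    function(x) 0.2 * x[2] - 0.1 * x[1] + 2
  )
  rb <- nested_root_find(Fb, c(0, 0, 0))
  expect_true(ra$converged && rb$converged)
  expect_equal(ra$x, rb$x[c(2, 3, 1)], tolerance = 1e-5)
})

test_that("solver is deterministic and reports evaluation counts", {
  F <- list(function(x) cos(x[1]))
  r1 <- nested_root_find(F, 0)
  r2 <- nested_root_find(F, 0)
  expect_identical(r1, r2)
  expect_gt(r1$iterations, 0)
  expect_equal(r1$x, 0.7390851332, tolerance = 1e-6) # Dottie number
})

test_that("update-map failures are reported with the variable index", {
  F <- list(
    function(x) 0.5 * x[2],
    function(x) stop("boom")
  )
  expect_error(nested_root_find(F, c(0, 0)), "update map 2")
})

test_that("damped iteration agrees with the nested scheme on smooth systems", {
  F <- list(
    function(x) 0.4 * x[2] + 1,
    function(x) -0.3 * x[1] + 2
  )
  rn <- nested_root_find(F, c(0, 0))
  rd <- damped_fixed_point(F, c(0, 0), lambda = 0.5, tol = 1e-12)
  expect_true(rn$converged && rd$converged)
  expect_equal(rn$x, rd$x, tolerance = 1e-6)
})

test_that("the night leaf state has zero assimilation at residual conductance", {
  for (pw in c("C4", "C3")) {
    st <- solve_leaf_state(leaf_params(pw),
      T_a = 290, I_s = 0, VPD = 0.5,
      v = 1, S_w = 1
    )
    expect_true(st$converged)
    expect_equal(st$A, 0, tolerance = 1e-6)
    expect_equal(st$g_w, 0.017, tolerance = 1e-8)
  }
})

test_that("full water stress closes stomata to the residual conductance", {
  st <- solve_leaf_state(leaf_params(),
    T_a = 298.15, I_s = 500, VPD = 1.5,
    v = 2, S_w = 0
  )
  expect_true(st$converged)
  expect_equal(st$g_w, 0.017)
  # with stomata nearly shut, supply pins the gas steady state near the
  # closed-form C_m at g_w0
  expect_equal(st$C_m, st$C_A + 1.6 * (st$R_m + st$R_s - st$A) / 0.017,
    tolerance = 1e-6
  )
})

test_that("the solved C4 leaf state zeroes every printed balance equation", {
  p <- leaf_params()
  st <- solve_leaf_state(p, T_a = 298.15, I_s = 500, VPD = 1.5, v = 2, S_w = 1)
  expect_true(st$converged)
  O_A_umol <- p$O_A * 1000
  # gas reservoir balances
  res <- c4_ode_rhs(
    st$C_m, st$C_s, st$O_m, st$O_s, st$g_w, st$g_s, st$A,
    st$V_p, st$R_m, st$R_s, st$C_A, O_A_umol
  )
  expect_lt(max(abs(res)), 1e-6)
  # assimilation law
  asm <- c4_assimilation(
    st$C_s, st$O_s, st$J, st$V_cmax,
    arrhenius(p$K_C, st$T_L), 1000 * arrhenius(p$K_O, st$T_L),
    arrhenius(p$gamma_bs, st$T_L), p$x
  )
  expect_equal(st$A, asm$A, tolerance = 1e-6)
  # stomatal conductance law
  gw <- stomatal_conductance(st$A, st$R_d, st$Gamma, st$VPD, st$S_w, st$C_A)
  expect_equal(st$g_w, gw, tolerance = 1e-6)
  # energy balance at the solved leaf temperature
  expect_lt(abs(energy_residual(st$T_L, st$T_a, st$I_s, st$J_v, st$v, p)), 1e-4)
  # PEP carboxylation law
  expect_equal(st$V_p,
    pep_carboxylation(st$C_m, st$V_pmax, arrhenius(p$K_P, st$T_L), p$V_pr))
})

test_that("the solved C3 leaf state satisfies its subsystem simultaneously", {
  p <- leaf_params("C3")
  st <- solve_leaf_state(p, T_a = 295, I_s = 600, VPD = 1, v = 3, S_w = 0.8)
  expect_true(st$converged)
  res <- c3_ode_rhs(st$C_m, st$O_m, st$g_w, st$A, st$R_d, st$C_A, p$O_A * 1000)
  expect_lt(max(abs(res)), 1e-6)
  asm <- c3_assimilation(
    st$C_m, st$O_m, st$J, st$V_cmax,
    arrhenius(p$K_C, st$T_L), 1000 * arrhenius(p$K_O, st$T_L),
    arrhenius(p$gamma_star, st$T_L)
  )
  expect_equal(st$A, asm$A, tolerance = 1e-6)
})

test_that("assimilation rises with light and the limiting state flips once", {
  curve <- leaf_response_curve(leaf_params(),
    over = "light",
    values = seq(0, 900, by = 60)
  )
  expect_true(all(curve$converged))
  expect_true(all(diff(curve$A) > -1e-6))
  flips <- sum(diff(curve$limiting == "carbon") != 0)
  expect_lte(flips, 1)
  # light-limited at the dark end, carbon-limited when bright
  expect_equal(curve$limiting[1], "light")
  expect_equal(curve$limiting[nrow(curve)], "carbon")
})

test_that("stomata close as the air dries, all else equal", {
  p <- leaf_params()
  gws <- vapply(c(0.5, 1, 2, 3, 4), function(d) {
    solve_leaf_state(p, T_a = 298.15, I_s = 500, VPD = d, v = 2, S_w = 1)$g_w
  }, 0)
  expect_true(all(diff(gws) < 0))
})

test_that("nested solutions match the damped-iteration oracle", {
  envs <- random_environments(12, seed = 99)
  for (i in seq_len(nrow(envs))) {
    e <- envs[i, ]
    p <- leaf_params(if (e$c4) "C4" else "C3")
    st <- solve_leaf_state(p,
      T_a = e$T_a, I_s = e$I_s, VPD = e$VPD, v = e$v,
      S_w = e$S_w
    )
    o <- leaf_state_oracle(p,
      T_a = e$T_a, I_s = e$I_s, VPD = e$VPD, v = e$v,
      S_w = e$S_w
    )
    expect_true(st$converged)
    expect_true(o$converged)
    expect_lt(leaf_state_disagreement(st, o$x), 1e-4)
  }
})

test_that("the tabular interface returns one solved row per environment", {
  env <- tibble::tibble(
    T_a = c(290, 298.15), I_s = c(200, 700), VPD = c(0.8, 2),
    v = c(1, 3), psi_c = c(-1000, -9000)
  )
  out <- solve_leaf_states(env, leaf_params())
  expect_equal(nrow(out), 2)
  expect_true(all(c("A", "g_w", "T_L", "J_v", "converged") %in% names(out)))
  expect_true(all(out$converged))
  # the droughted row is stressed: lower conductance than well-watered
  expect_lt(out$g_w[2], out$g_w[1] + 0.3)
  expect_error(
    solve_leaf_states(env[, c("T_a", "I_s")], leaf_params()),
    "missing environment column"
  )
})
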