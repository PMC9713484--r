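test_that("leaf nitrogen allocation is piecewise linear and continuous", {
  b <- list(plant_min = 1, plant_opt = 3, leaf_min = 0.2, leaf_opt = 0.9)
  ln <- function(x) leaf_nitrogen(x, b$plant_min, b$plant_opt, b$leaf_min, b$leaf_opt)
  expect_equal(ln(1), 0.2) # lower boundary
  expect_equal(ln(0.5), 0.2) # below minimum
  expect_equal(ln(3), 0.9) # optimum: middle and upper branch agree
  expect_equal(ln(2), (0.2 + 0.9) / 2) # midpoint linearity
  expect_equal(ln(6), 6 * 0.9 / 3) # proportional above optimum
  # continuity at both breakpoints
  eps <- 1e-9
  expect_lt(abs(ln(1 + eps) - ln(1 - eps)), 1e-6)
  expect_lt(abs(ln(3 + eps) - ln(3 - eps)), 1e-6)
  expect_error(leaf_nitrogen(1, 3, 1, 0.2, 0.9), "bounds")
})

test_that("nitrogen-limited capacities are linear and hit the calibration", {
  expect_equal(n_limited_rates(0)$J_max, 0)
  expect_equal(n_limited_rates(0)$V_cmax, 0)
  r1 <- n_limited_rates(1.3)
  r2 <- n_limited_rates(2.6)
  expect_equal(r2$J_max, 2 * r1$J_max)
  expect_equal(r2$V_cmax, 2 * r1$V_cmax)
  # the default constants reproduce the reference capacities at 2 g N/m2
  cal <- n_limited_rates(2)
  expect_equal(cal$J_max, 299.6)
  expect_equal(cal$V_cmax, 49)
})

test_that("surplus carbon goes to reserves after costs and growth", {
  a <- reserve_allocation(C_a = 10, C_c = 3, C_g = 5, C_p = 2, phase = "day",
    t_s = 0.2)
  expect_equal(a$C_r, 2)
  expect_equal(a$C_h, 5)
  # exact balance: nothing to store
  b <- reserve_allocation(C_a = 8, C_c = 3, C_g = 5, C_p = 2, phase = "day",
    t_s = 0.2)
  expect_equal(b$C_r, 0)
  expect_equal(b$C_h, 5)
  expect_error(
    reserve_allocation(1, 1, 1, -0.1, phase = "day"),
    "negative reserve"
  )
})

test_that("night remobilisation is capped at 95% of dusk reserves", {
  # huge deficit, C_p = 10 g at dusk, half-day night: cap = -0.95*10/0.5
  a <- reserve_allocation(C_a = 0, C_c = 1, C_g = 30, C_p = 10,
    phase = "night", t_n = 0.5, C_p_night_start = 10)
  expect_equal(a$C_r, -19)
  expect_equal(a$C_h, -a$C_r + 0 - 1) # C_h = C_a - C_c - C_r = 18
  # stepping the pool through the night at the capped rate consumes
  # exactly 95% of the dusk reserves
  C_p <- 10
  dt <- 0.05
  for (i in seq_len(round(0.5 / dt))) {
    al <- reserve_allocation(0, 1, 30, C_p, phase = "night", t_n = 0.5,
      C_p_night_start = 10)
    C_p <- C_p + al$C_r * dt
  }
  expect_equal(C_p, 0.5, tolerance = 1e-12)
})

test_that("daytime remobilisation cannot exceed half the current reserves", {
  a <- reserve_allocation(C_a = 1, C_c = 2, C_g = 10, C_p = 6, phase = "day",
    t_s = 0.3)
  expect_equal(a$C_r, -3) # floor -C_p/2
  expect_equal(a$C_h, 1 - 2 - (-3))
})

test_that("the hoarding rule protects the projected night budget", {
  # ample income but low reserves close to sunset: growth is curtailed so
  # that reserves reach 110% of the night need
  a <- reserve_allocation(C_a = 10, C_c = 2, C_g = 8, C_p = 0.5,
    phase = "day", t_s = 0.25, C_cN = 2)
  # unconstrained C_r would be 0; required floor = min(8, (2.2-0.5)/0.25)
  expect_equal(a$C_r, min(10 - 2, (1.1 * 2 - 0.5) / 0.25))
  expect_equal(a$C_h, 10 - 2 - a$C_r)
  expect_lt(a$C_h, 8)
})

test_that("allocation always balances and respects growth bounds", {
  set.seed(5)
  for (i in 1:50) {
    C_a <- runif(1, 0, 10)
    C_c <- runif(1, 0, 4)
    C_g <- runif(1, 0, 6)
    C_p <- runif(1, 0, 12)
    night <- runif(1) < 0.5
    al <- reserve_allocation(C_a, C_c, C_g, C_p,
      phase = if (night) "night" else "day",
      t_s = runif(1, 0.01, 0.5), t_n = runif(1, 0.2, 0.6),
      C_cN = runif(1, 0, 2)
    )
    expect_equal(C_a - C_c - al$C_r - al$C_h, 0, tolerance = 1e-12)
    expect_gte(al$C_h, 0)
    expect_lte(al$C_h, C_g + 1e-12)
  }
})

test_that("a short well-watered run conserves carbon and grows at demand", {
  w <- synthetic_weather(n_days = 4, timestep = 0.1)
  sim <- simulate_growth(w)
  ts <- tidy(sim)
  expect_equal(nrow(ts), 40)
  expect_lt(max(abs(ts$balance_error)), 1e-8)
  expect_true(all(ts$converged))
  # ample light and water: growth never carbon-limited, day or night
  expect_true(all(abs(ts$C_h - ts$C_g) < 1e-9))
  expect_true(all(ts$C_p >= 0))
  g <- glance(sim)
  expect_gt(g$cumulative_assimilation_gC, 0)
  expect_equal(g$max_abs_balance_error, max(abs(ts$balance_error)))
})

test_that("a dark world can only run down its seed reserves", {
  w <- synthetic_weather(n_days = 3, timestep = 0.1)
  w$I_s <- 0
  sim <- simulate_growth(w)
  cp <- tidy(sim)$C_p
  expect_true(all(diff(cp) <= 1e-12))
  expect_gte(min(cp), 0)
})

test_that("terminal drought lowers cumulative assimilation", {
  w <- synthetic_weather(n_days = 6, timestep = 0.1)
  ctrl <- simulate_growth(w)
  dr <- simulate_growth(w,
    drought = terminal_drought_schedule(onset_day = 1, end_psi = -15000,
      n_days = 6)
  )
  expect_lt(
    glance(dr)$cumulative_assimilation_gC,
    glance(ctrl)$cumulative_assimilation_gC
  )
  # stress factor actually declined
  expect_lt(min(tidy(dr)$S_w), 0.2)
  expect_equal(min(tidy(ctrl)$S_w), 1)
})

test_that("growth demand reduction propagates when photosynthesis is short", {
  # weak light and a large plant: 24-h photosynthesis cannot cover
  # maintenance + growth, so realised growth drops below demand somewhere
  w <- synthetic_weather(n_days = 3, timestep = 0.1, transmittance = 0.3)
  cfg <- growth_config(initial_structure = 8, seed_carbon = 0.3)
  sim <- simulate_growth(w, config = cfg)
  ts <- tidy(sim)
  expect_true(any(ts$C_h < ts$C_g - 1e-9))
  expect_lt(max(abs(ts$balance_error)), 1e-8)
})
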