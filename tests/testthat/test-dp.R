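# Solved once and reused across this file's tests.
base_params <- model_params()
base_policy <- solve_policy(base_params)

test_that("terminal values are the horizon-step immediate fitness", {
  p <- model_params()
  g <- state_grid(p)
  # base schedule: last reproduction at t = 48 < T = 50, so the slice is zero
  expect_true(all(terminal_values(g, p) == 0))

  # schedule where the horizon is reproductive: hand-evaluated corner
  p8 <- model_params(horizon = 8, repro_first = 8)
  g8 <- state_grid(p8)
  tv <- terminal_values(g8, p8)
  e_prime <- 20 - (0.2 * 20 + 2)            # 14
  expect_equal(tv[21, 21], 0.3 * e_prime * 0.2 * 20)
  # below the density threshold the slice is zero
  expect_true(all(tv[, 1:6] == 0))
})

test_that("bilinear interpolation is exact at nodes and linear within cells", {
  p <- model_params()
  g <- state_grid(p)
  z <- outer(g$e, g$w, function(e, w) sin(e / 3) + 0.1 * w)
  expect_equal(interpolate_value(z, g, g$e[5], g$w[9]), z[5, 9])
  # cell-centre value of a function linear along one axis
  z2 <- matrix(rep(c(0, 4), each = 21), 21, 2)
  g2 <- list(e = g$e, w = c(0, 1))
  expect_equal(bilinear(g2$e, g2$w, z2, 3, 0.5), 2)
  # interpolation of a bilinear function is exact everywhere
  zb <- outer(g$e, g$w, function(e, w) 2 + 0.5 * e - 0.25 * w + 0.05 * e * w)
  withr::with_seed(7, {
    e <- runif(50, 0, 20); w <- runif(50, 0, 20)
    expect_equal(interpolate_value(zb, g, e, w),
                 2 + 0.5 * e - 0.25 * w + 0.05 * e * w)
  })
})

test_that("expected objective reduces to B when continuation is worthless", {
  p <- model_params()
  g <- state_grid(p)
  v0 <- matrix(0, 21, 21)
  h <- expected_objective(10, 8, 8, 3, v0, g, p)
  expect_equal(h, 2.88)  # hand-chained from the step example
  # extinct symbiont: survival is zero, so only B remains
  v1 <- matrix(5, 21, 21)
  expect_equal(expected_objective(10, 0, 3, 2, v1, g, p), 0)
})

test_that("best action ties break toward the largest allocation", {
  # gamma = 0: no transfer is ever possible, so H = 0 for every action
  p <- model_params(gamma = 0)
  g <- state_grid(p)
  ba <- best_action(10, 10, 5, matrix(0, 21, 21), g, p)
  expect_equal(ba$u_star, p$n_intake)
  expect_equal(ba$h_star, 0)
})

test_that("the optimal policy allocates fully at high E / low W and withholds at low E / high W", {
  pol <- tidy(base_policy)
  corner_hi <- dplyr::filter(pol, t == 4, e == 20, w == 1)
  expect_equal(corner_hi$u_star, 8)
  corner_lo <- dplyr::filter(pol, t == 4, e == 1, w == 20)
  expect_equal(corner_lo$u_star, 0)
})

test_that("no transmission means no reproductive value anywhere", {
  p <- model_params(horizon = 12, gamma = 0)
  pol <- solve_policy(p, grid = coarse_grid(p))
  expect_true(all(pol$value == 0))
})

test_that("backward induction matches the exhaustive enumeration oracle exactly on closed grids", {
  fx <- make_fixture("tiny-T4")
  dp <- solve_policy(fx$params, fx$scenario, fx$grid)
  expect_lt(max(abs(dp$value - fx$oracle_value)), 1e-12)
  # and the fixture is not degenerate
  expect_gt(sum(fx$oracle_value > 0), 20)
})

test_that("off-grid successors only introduce bounded interpolation error", {
  fx <- make_fixture("tiny-T3-offgrid")
  dp <- solve_policy(fx$params, fx$scenario, fx$grid)
  expect_lt(max(abs(dp$value - fx$oracle_value)), 0.25)
})

test_that("value tables are monotone in reserves and density for base-case defaults", {
  v <- base_policy$value
  for (t in seq_len(dim(v)[3])) {
    expect_true(all(diff(v[, , t]) >= 0))          # along E
    expect_true(all(apply(v[, , t], 1, diff) >= 0)) # along W
  }
})

test_that("the converged policy repeats with the reproductive period", {
  u <- base_policy$policy
  for (t in 8:41) {
    frac_same <- mean(abs(u[, , t] - u[, , t + 4]) <= 0.1 + 1e-9)
    expect_gte(frac_same, 0.9)
  }
})

test_that("solving is deterministic", {
  p <- model_params(horizon = 10)
  g <- coarse_grid(p)
  a <- solve_policy(p, grid = g)
  b <- solve_policy(p, grid = g)
  expect_identical(a$value, b$value)
  expect_identical(a$policy, b$policy)
})

test_that("tidy and glance expose the solved tables faithfully", {
  td <- tidy(base_policy)
  expect_equal(nrow(td), 21 * 21 * 50)
  row <- dplyr::filter(td, t == 4, e == 20, w == 1)
  expect_equal(row$u_star, base_policy$policy[21, 2, 4])
  expect_equal(row$value, base_policy$value[21, 2, 4])
  expect_true(all(is.na(dplyr::filter(td, t == 50)$u_star)))
  g <- glance(base_policy)
  expect_equal(g$horizon, 50L)
  expect_equal(g$value_max, max(base_policy$value))
})
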