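base_params <- model_params()
base_policy <- solve_policy(base_params)

test_that("strategies decide allocations as specified", {
  p <- model_params()
  # fixed: constant regardless of state
  expect_equal(decide_allocation(strategy_fixed(3), e = c(1, 20), w = c(1, 20),
                                 t = 5, params = p), c(3, 3))
  # proportional: u = factor * W, clamped to [0, N]
  expect_equal(decide_allocation(strategy_proportional(0.3), 10, 10, 5, p), 3)
  expect_equal(decide_allocation(strategy_proportional(0.5), 10, 19, 5, p), 8)
  # optimal: policy lookup at a grid node
  expect_equal(decide_allocation(strategy_optimal(base_policy), 20, 1, 4, p),
               8)
  # imperfect with u* = 0: draws clamp into [0, 1]
  withr::with_seed(5, {
    u <- replicate(50, decide_allocation(strategy_imperfect(base_policy),
                                         1, 20, 4, p))
  })
  expect_true(all(u >= 0 & u <= 1))
  expect_gt(var(u), 0)
  # policy-based strategies refuse to run without a policy
  s <- strategy_optimal(base_policy)
  s$policy <- NULL
  expect_error(decide_allocation(s, 10, 10, 5, p), "policy")
})

test_that("cohorts have replicates-per-state hosts and are seed-deterministic", {
  p <- tiny_params()
  pol <- solve_policy(p, grid = coarse_grid(p))
  init <- tidyr::expand_grid(e = c(5, 10), w = c(5, 10))
  coh <- simulate_cohort(p, strategy_optimal(pol), replicates = 1,
                         init = init, seed = 1)
  expect_equal(nrow(coh$fitness), 4)
  coh10 <- simulate_cohort(p, strategy_optimal(pol), replicates = 10,
                           init = init, seed = 1)
  expect_equal(nrow(coh10$fitness), 40)

  a <- simulate_cohort(p, strategy_imperfect(pol), replicates = 2, seed = 99)
  b <- simulate_cohort(p, strategy_imperfect(pol), replicates = 2, seed = 99)
  expect_identical(a$W, b$W)
  expect_identical(a$fitness, b$fitness)
  # and default initial states cover the full positive integer grid
  expect_equal(nrow(initial_states(model_params())), 400)
})

test_that("lifetime fitnesses are the sums of per-step contributions", {
  p <- tiny_params()
  pol <- solve_policy(p, grid = coarse_grid(p))
  coh <- simulate_cohort(p, strategy_optimal(pol), replicates = 2, seed = 3,
                         survival = "stochastic")
  tr <- tidy(coh)
  by_host <- dplyr::summarise(dplyr::group_by(tr, host),
                              vh = sum(b), vs = sum(w_rep))
  merged <- dplyr::left_join(coh$fitness, by_host, by = "host")
  merged$vh[is.na(merged$vh)] <- 0
  merged$vs[is.na(merged$vs)] <- 0
  expect_equal(merged$v_host, merged$vh)
  expect_equal(merged$v_symb, merged$vs)
})

test_that("proportional allocation without reproduction decays density by factor 0.9", {
  p <- model_params(horizon = 10, repro_first = 100)
  coh <- simulate_cohort(p, strategy_proportional(0.3), replicates = 1,
                         init = tibble::tibble(e = 10, w = 16),
                         survival = "deterministic")
  w <- coh$W[1, ]
  expect_equal(w[-1] / w[-length(w)], rep(0.9, 9))
})

test_that("an extinct symbiont dooms the host", {
  p <- tiny_params()
  pol <- solve_policy(p, grid = coarse_grid(p))
  coh <- simulate_cohort(p, strategy_optimal(pol), replicates = 1,
                         init = tibble::tibble(e = 10, w = 0),
                         survival = "stochastic", seed = 2)
  expect_equal(coh$fitness$v_host, 0)
  expect_equal(coh$fitness$v_symb, 0)
  # S = 0 at every step, so the host cannot reach t = 2
  expect_equal(coh$fitness$lifespan, 1)
  expect_true(all(coh$W[1, !is.na(coh$W[1, ])] == 0))
})

test_that("no transmission means zero host and symbiont fitness in simulation", {
  p <- model_params(horizon = 12, gamma = 0)
  pol <- solve_policy(p, grid = coarse_grid(p))
  coh <- simulate_cohort(p, strategy_optimal(pol), replicates = 1,
                         survival = "deterministic")
  expect_true(all(coh$fitness$v_host == 0))
  expect_true(all(coh$fitness$v_symb == 0))
})

test_that("perturbation with no times is a no-op and resets act before the step", {
  p <- tiny_params()
  pol <- solve_policy(p, grid = coarse_grid(p))
  plain <- simulate_cohort(p, strategy_optimal(pol), replicates = 1, seed = 8)
  noop <- simulate_perturbed_cohort(p, strategy_optimal(pol),
                                    times = integer(0), replicates = 1,
                                    seed = 8)
  expect_identical(plain$W, noop$W)

  # a perturbation at every step pins the recorded state at its t = 1 value
  every <- simulate_perturbed_cohort(p, strategy_optimal(pol),
                                     times = 1:12, replicates = 1,
                                     survival = "deterministic")
  expect_true(all(every$W == every$W[, 1]))
  expect_error(simulate_perturbed_cohort(p, strategy_optimal(pol),
                                         times = 99), "horizon")
})

test_that("perturbed cohorts re-converge on the unperturbed trajectory", {
  coh <- simulate_cohort(base_params, strategy_optimal(base_policy),
                         replicates = 1, survival = "deterministic")
  pert <- simulate_perturbed_cohort(base_params, strategy_optimal(base_policy),
                                    times = 24, replicates = 1,
                                    survival = "deterministic")
  sm <- cohort_summary(coh)
  smp <- cohort_summary(pert)
  # the reset spans the full initial range (cohort mean jumps to 10.5); the
  # gap to the unperturbed trajectory then shrinks every reproductive cycle
  # and closes within a few cycles
  gap <- abs(smp$w_mean - sm$w_mean)
  cycle_gap <- vapply(list(25:28, 29:32, 33:36, 37:40), function(ts)
    mean(gap[ts]), numeric(1))
  expect_true(all(diff(cycle_gap) < 0))
  expect_lt(max(gap[37:44]), 0.1)
  # while at the perturbation step itself the cohort mean sits far away
  expect_gt(gap[24], 2)
})

test_that("the optimal strategy collapses the initial density range by t = 8", {
  coh <- simulate_cohort(base_params, strategy_optimal(base_policy),
                         replicates = 1, survival = "deterministic")
  r8 <- max(coh$W[, 8]) - min(coh$W[, 8])
  expect_lt(r8, 5)   # a small fraction of the initial range of 19
  expect_equal(max(coh$W[, 1]) - min(coh$W[, 1]), 19)
})

test_that("cohort summaries aggregate surviving hosts per time step", {
  W <- matrix(6, 3, 5)
  coh <- fake_cohort(W)
  sm <- cohort_summary(coh)
  expect_equal(sm$w_mean, rep(6, 5))
  expect_equal(sm$w_min, sm$w_max)
  expect_equal(sm$frac_alive, rep(1, 5))
  expect_equal(plateau_density(fake_cohort(matrix(7, 2, 12))), 7)
})
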