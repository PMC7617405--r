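test_that("metabolic expenditure follows E' = E - (mu*E + omega)", {
  p <- model_params()
  expect_equal(energy_after_expenditure(10, p), 6)
  # intermediate values may go negative before clamping
  expect_equal(energy_after_expenditure(0, p), -2)
  p0 <- model_params(mu = 0, omega = 0)
  expect_equal(energy_after_expenditure(7, p0), 7)
})

test_that("reproduction transfers lambda of reserves and gamma of density when gated", {
  p <- model_params()
  r <- reproduction_event(e_prime = 10, w = 8, t = 8, p)
  expect_true(r$reproduced)
  expect_equal(r$e_rep, 3)
  expect_equal(r$w_rep, 1.6)
  expect_equal(r$e_dprime, 7)
  expect_equal(r$w_prime, 6.4)

  # off-schedule step: no transfers, states unchanged
  r7 <- reproduction_event(10, 8, t = 7, p)
  expect_false(r7$reproduced)
  expect_equal(r7$e_rep, 0)
  expect_equal(r7$e_dprime, 10)
  expect_equal(r7$w_prime, 8)

  # threshold gates
  expect_false(reproduction_event(5, 10, t = 8, p)$reproduced)
  expect_false(reproduction_event(10, 5, t = 8, p)$reproduced)

  # the non-essential variant drops the density threshold
  expect_true(reproduction_event(10, 0.5, t = 8, p,
                                 scenario_config("non_essential"))$reproduced)
})

test_that("symbiont transition grows with allocation and is absorbing at zero", {
  p <- model_params()
  # zero allocation shrinks the population by alpha*beta = 25%
  expect_equal(symbiont_transition(4, 0, p), 3)
  expect_equal(symbiont_transition(0, 8, p), 0)
  expect_equal(symbiont_transition(1, 8, p), 4.75)
  expect_error(symbiont_transition(4, 9, p), "allocation")
  expect_error(symbiont_transition(4, -1, p), "allocation")
})

test_that("reserve transition stores unallocated intake, clamped at the bound", {
  p <- model_params()
  expect_equal(reserve_transition(7, 3, p), 12)
  expect_equal(reserve_transition(5, 8, p), 5)   # u = N: all income allocated
  expect_equal(reserve_transition(14, 0, p), 20) # clamped from 22
})

test_that("survival probability is the product of saturating state factors", {
  p <- model_params()
  expect_equal(survival_probability(10, 10, 5, p), (1 - exp(-3))^2)
  expect_equal(survival_probability(10, 0, 5, p), 0)
  # temporary-benefit variant: density factor dropped from maturation on
  sc <- scenario_config("temporary_benefit")
  expect_equal(survival_probability(10, 0, 9, p, sc), 1 - exp(-3))
  expect_equal(survival_probability(10, 0, 7, p, sc), 0)
  # non-essential variant offsets the density factor
  expect_equal(survival_probability(10, 1, 5, p, scenario_config("non_essential")),
               (1 - exp(-3)) * (1 - exp(-0.3 * 3)))
  # bounded in [0, 1] even for negative intermediates
  for (e in c(-5, 0, 3, 40)) {
    for (w in c(-8, 0, 2, 40)) {
      s <- survival_probability(e, w, 5, p)
      expect_gte(s, 0)
      expect_lte(s, 1)
    }
  }
})

test_that("immediate fitness is the transfer product, with the non-essential offset", {
  expect_equal(immediate_fitness(3, 1.6), 4.8)
  expect_equal(immediate_fitness(0, 0), 0)
  # literal non-essential form: the offset accrues every step
  expect_equal(immediate_fitness(0, 0, scenario_config("non_essential")), 5)
  expect_equal(immediate_fitness(4, 2, scenario_config("non_essential")), 9)
})

test_that("a full step chains the six events in order", {
  p <- model_params()
  st <- host_step(e = 10, w = 8, t = 8, u = 3, params = p)
  expect_equal(st$e_prime, 6)
  expect_true(st$reproduced)
  expect_equal(st$e_rep, 1.8)
  expect_equal(st$e_dprime, 4.2)
  expect_equal(st$w_rep, 1.6)
  expect_equal(st$w_prime, 6.4)
  expect_equal(st$w_dprime, 6.3)
  expect_equal(st$e_tprime, 9.2)
  expect_equal(st$fitness, 2.88)
  expect_equal(st$e_next, 9.2)
  expect_equal(st$w_next, 6.3)
  expect_equal(st$survival, (1 - exp(-0.3 * 9.2)) * (1 - exp(-0.3 * 6.3)))

  # withholding on a non-reproductive step: 25% density reduction
  st0 <- host_step(e = 10, w = 8, t = 3, u = 0, params = p)
  expect_equal(st0$w_next, 6)

  expect_error(host_step(10, 8, 3, 0, p, alive = FALSE), "living")
})

test_that("energy is conserved through the step when no clamp triggers", {
  p <- model_params()
  withr::with_seed(42, {
    for (i in 1:200) {
      e <- runif(1, 0, 20); w <- runif(1, 0, 20)
      t <- sample(1:50, 1); u <- runif(1, 0, 8)
      st <- host_step(e, w, t, u, params = p)
      if (st$e_tprime >= 0 && st$e_tprime <= p$e_max) {
        expect_equal(st$e_next - e, p$n_intake - u - st$e_exp - st$e_rep)
      }
    }
  })
})

test_that("withheld allocation decays density geometrically by (1 - alpha*beta)", {
  p <- model_params(repro_first = 100)  # no reproduction in horizon
  w <- 16
  for (k in 1:6) {
    w_next <- symbiont_transition(w, 0, p)
    expect_equal(w_next, w * 0.75)
    w <- w_next
  }
})

test_that("density above N/alpha declines under every admissible allocation", {
  p <- model_params()
  u <- state_grid(p)$u
  for (w in c(16.01, 17, 19, 20)) {
    expect_true(all(symbiont_growth(w, u, p) < w))
  }
})

test_that("symbiont extinction is absorbing", {
  p <- model_params()
  withr::with_seed(1, {
    for (u in runif(20, 0, 8)) {
      expect_equal(symbiont_transition(0, u, p), 0)
    }
  })
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(model_params(gamma = 1.5), "gamma")
  expect_error(model_params(lambda = 0), "lambda")
  expect_error(model_params(n_intake = 0), "n_intake")
  expect_error(model_params(e_crit = 30), "e_crit")
})
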