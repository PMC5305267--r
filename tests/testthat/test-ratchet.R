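test_that("ratchet factor follows the Boltzmann load law", {
  expect_equal(ratchet_factor(0, p64), 1)
  expect_equal(ratchet_factor(log(2) * p64$kBT / p64$delta, p64), 0.5,
               tolerance = 1e-12)
  mts <- seq(0, 5, length.out = 50)
  fac <- ratchet_factor(mts, p64)
  expect_true(all(diff(fac) < 0))
  expect_true(all(fac > 0 & fac <= 1))
  expect_error(ratchet_factor(-1, p64), "non-negative")
})

test_that("flat model shares the well-mixed Rac fixed points when decoupled", {
  # with lam = 0 and no actin feedback the u/v kinetics of the two model
  # variants are literally the same rate law
  p <- modify_params(p64, lam = 0, c2 = 0)
  fp <- well_mixed_fixed_points(p, f_level = 0)
  g <- make_disk_mask(p)
  s0 <- initial_state(g, p)
  s0$u <- matrix(fp$u[1], p$N, p$N)
  tr <- simulate_traditional(s0, g, p, stimulus_protocol("none"),
                             solver_config(t_end = 5))
  inside <- g$phi > 0.5
  expect_equal(max(abs(tr$final_state$u[inside] - fp$u[1])), 0,
               tolerance = 1e-6)
})

test_that("flat model conserves total Rac on the mask", {
  p <- modify_params(p64, c2 = 0)
  g <- make_disk_mask(p)
  tr <- simulate_traditional(initial_state(g, p), g, p,
                             stimulus_protocol("none"),
                             solver_config(t_end = 5))
  tot <- tr$metrics$mass_u + tr$metrics$mass_v
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-9)
})

test_that("flat model rests low and polarizes under a supra stimulus", {
  g <- make_disk_mask(p64)
  tr0 <- simulate_traditional(initial_state(g, p64), g, p64,
                              stimulus_protocol("none"),
                              solver_config(t_end = 120, snapshot_every = 20))
  expect_lt(tail(tr0$metrics$max_u, 1), 0.1)
  tr1 <- simulate_traditional(initial_state(g, p64), g, p64,
                              stimulus_protocol("graded", ks_amp = 0.004,
                                                ks_dur = 20),
                              solver_config(t_end = 150, snapshot_every = 25))
  expect_gt(tail(tr1$metrics$max_u, 1), 0.9 * u_high(p64))
})
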