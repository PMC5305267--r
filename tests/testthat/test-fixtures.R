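test_that("diffusion fixtures carry the analytic decay law", {
  fix <- make_diffusion_fixture(D = 1, mode_index = 1, L = 40, N = 64)
  expect_equal(fix$amplitude_at(1), exp(-(2 * pi / 40)^2))
  fix2 <- make_diffusion_fixture(D = 1, mode_index = 2, L = 40, N = 64)
  expect_equal(log(fix2$amplitude_at(1)), 4 * log(fix$amplitude_at(1)),
               tolerance = 1e-12)
  expect_equal(make_diffusion_fixture(D = 0)$amplitude_at(5), 1)
  expect_error(make_diffusion_fixture(mode_index = 40, N = 64), "aliased")
})

test_that("noisy initial states have the requested statistics and seeds", {
  s0 <- make_noise_initial_state(seed = 1, noise_var = 0, params = p64,
                                 geometry = g64)
  expect_true(all(s0$u == p64$u0))
  s1 <- make_noise_initial_state(seed = 1, noise_var = 0.01, params = p64,
                                 geometry = g64)
  inside <- g64$phi > 0.5
  expect_equal(var(s1$u[inside]), 0.01, tolerance = 0.1)
  expect_equal(mean(s1$u[inside]), p64$u0, tolerance = 0.01)
  expect_true(all(s1$u >= 0))
  s1b <- make_noise_initial_state(seed = 1, noise_var = 0.01, params = p64,
                                  geometry = g64)
  expect_identical(s1$u, s1b$u)
  s2 <- make_noise_initial_state(seed = 2, noise_var = 0.01, params = p64,
                                 geometry = g64)
  expect_false(identical(s1$u, s2$u))
})

test_that("polarization fixtures encode the expected outcome", {
  fx <- make_polarization_fixture(p64, supra = TRUE, threshold = 0.002)
  expect_equal(fx$protocol$ks_amp, 0.0024)
  expect_true(fx$expect_polarized)
  fx2 <- make_polarization_fixture(p64, supra = FALSE, threshold = 0.002)
  expect_equal(fx2$protocol$ks_amp, 0.0016)
  expect_false(fx2$expect_polarized)
})
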