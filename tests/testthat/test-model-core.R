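test_that("hill function matches hand-computed values and bounds", {
  expect_equal(hill(0, c = 5, K = 1), 0)
  expect_equal(hill(1, c = 1, K = 1), 0.5)   # half-saturation at x = K
  expect_equal(hill(3, c = 2, K = 1), 1.8)   # 2 * 9 / 10
  x <- seq(0, 50, length.out = 200)
  y <- hill(x, c = 2, K = 0.7)
  expect_true(all(y >= 0 & y < 2))
  expect_true(all(diff(y) > 0))
  expect_error(hill(-1, 1, 1), "non-negative")
  expect_error(hill(1, 1, 0), "positive")
})

test_that("local Rac conversion is exactly conservative for any state", {
  set.seed(11)
  for (i in 1:20) {
    u <- runif(1, 0, 3); v <- runif(1, 0, 10); f <- runif(1, 0, 5)
    rr <- reaction_rates(u, v, f, mt = runif(1, 0.1, 3),
                         k_s = runif(1, 0, 0.1), params = p64)
    expect_identical(rr$R_u + rr$R_v, 0)
  }
  # matrix inputs too
  u <- matrix(runif(16, 0, 2), 4)
  rr <- reaction_rates(u, u + 1, u / 2, mt = 0.5, params = p64)
  expect_true(all(rr$R_u + rr$R_v == 0))
})

test_that("reaction rates vanish at the origin and respect limits", {
  rr <- reaction_rates(0, 0, 0, mt = 1, k_s = 0, params = p64)
  expect_equal(rr$R_u, 0)
  expect_equal(rr$R_f, 0)
  # infinite tension shuts down polymerization: R_f -> -d_f * f
  rr <- reaction_rates(1, 2, 3, mt = 1e12, params = p64)
  expect_equal(rr$R_f, -p64$d_f * 3, tolerance = 1e-9)
  # boundedness of the production terms
  vmax <- 10; ksmax <- 0.5
  rr <- reaction_rates(100, vmax, 100, mt = 0.2, k_s = ksmax, params = p64)
  expect_lt(rr$R_u, (p64$b + p64$c1 + p64$c2 + ksmax) * vmax)
})

test_that("membrane tension integral matches a trapezoid oracle and is monotone", {
  expect_equal(membrane_tension(matrix(0, 64, 64), g64, p64), p64$mt0)
  p_dec <- modify_params(p64, lam = 0)
  f <- matrix(runif(64^2), 64)
  expect_equal(membrane_tension(f, g64, p_dec), p64$mt0)
  # uniform f chosen so the phi-weighted integral is 100 -> mt0 (1 + lam*100)
  p_ref <- modify_params(p64, mt0 = 0.2, lam = 0.01)
  f100 <- matrix(100 / (sum(g64$phi) * g64$dA), 64, 64)
  expect_equal(membrane_tension(f100, g64, p_ref), 0.4, tolerance = 1e-12)
  # independent quadrature oracle on a non-trivial field
  f2 <- 1 + g64$xc^2 / 100
  oracle <- sum(g64$phi * f2) * g64$dA        # same rule, computed outside
  expect_equal(membrane_tension(f2, g64, p64), p64$mt0 * (1 + p64$lam * oracle))
  # pointwise monotonicity
  bump <- f2; bump[30, 30] <- bump[30, 30] + 1
  expect_gt(membrane_tension(bump, g64, p64), membrane_tension(f2, g64, p64))
  expect_error(membrane_tension(matrix(0, 8, 8), g64, p64), "mismatch")
})

test_that("well-mixed fixed points: linear balance without feedback", {
  # c1, c2 effectively off -> single root at b v0 / r
  p <- modify_params(p64, c1 = 1e-12, c2 = 0, b = 0.1, r = 1, v0 = 6)
  fp <- well_mixed_fixed_points(p, f_level = 0)
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$u, 0.6, tolerance = 1e-6)
  expect_true(fp$stable)
})

test_that("default kinetics are bistable, agreeing with a dense-scan oracle", {
  fp <- well_mixed_fixed_points(p64)
  expect_equal(nrow(fp), 3L)
  expect_equal(fp$stable, c(TRUE, FALSE, TRUE))

  # brute-force oracle: dense sign-change scan of the same rate law
  g <- function(u) {
    fq <- hill(u, p64$c3, p64$K3) * p64$K_F / ((p64$K_F + p64$mt0) * p64$d_f)
    (p64$b + hill(u, p64$c1, p64$K1) + hill(fq, p64$c2, p64$K2)) * p64$v0 -
      p64$r * u
  }
  us <- seq(1e-6, 20, length.out = 200001)
  gs <- g(us)
  flips <- which(gs[-1] * gs[-length(gs)] < 0)
  expect_equal(length(flips), 3L)
  brackets <- cbind(us[flips], us[flips + 1])
  for (i in 1:3) {
    expect_gte(fp$u[i], brackets[i, 1] - 1e-6)
    expect_lte(fp$u[i], brackets[i, 2] + 1e-6)
  }
  # stability of the outer roots by sign perturbation
  expect_lt(g(fp$u[3] + 1e-4), 0)
  expect_gt(g(fp$u[1] - 1e-4), 0)
  expect_gt(u_high(p64), u_low(p64))
})

test_that("parameter validation enforces the model invariants", {
  expect_error(polar_params(D_u = 5, D_f = 1), "D_u < D_f")
  expect_error(polar_params(D_v = 0.5), "D_f << D_v")
  expect_error(polar_params(R = 30), "R < L/2")
  expect_error(polar_params(r = -1), "positive")
  expect_error(polar_params(nonsense = 1), "unknown parameter")
  expect_silent(validate_params(polar_params(mt0 = 1)))
})
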