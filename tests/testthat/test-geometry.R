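test_that("disk phase field has the right profile and area", {
  p <- polar_params(N = 128)
  g <- make_disk(p)
  ic <- which.min(abs(g$xs))
  expect_equal(g$phi[ic, ic], 0.5 * (tanh(p$R / p$eps) + 1), tolerance = 1e-6)
  # phi = 1/2 on the circle rho = R
  iR <- which.min(abs(g$xs - p$R))
  expect_equal(g$phi[iR, ic], 0.5, tolerance = 0.05)
  expect_equal(g$area, pi * p$R^2, tolerance = 0.02)
  expect_true(all(g$phi >= 0 & g$phi <= 1))
  expect_error(make_disk(polar_params(N = 16, eps = 0.2)), "unresolved")
  expect_error(make_disk(polar_params(R = 18, L = 40)), "does not fit")
})

test_that("membrane measures match the analytic tanh-layer values", {
  expect_equal(0.5^2 * (1 - 0.5)^2, 0.0625)   # B at mid-interface
  p <- polar_params(N = 256)                  # fine grid for the derivative
  g <- make_disk(p)
  mm <- membrane_measures(g$phi, p$L)
  expect_equal(max(mm$Bphi), 0.0625, tolerance = 1e-3)
  expect_equal(min(mm$Bphi), 0)
  # max |grad phi| = 1/(2 eps) for the tanh profile
  expect_equal(max(mm$grad_phi_mag), 1 / (2 * p$eps), tolerance = 0.02)
  # both vanish away from the interface
  interior <- g$phi > 0.99
  expect_lt(max(mm$Bphi[interior]), 1e-3)
  expect_lt(max(mm$grad_phi_mag[interior]), 0.02)
  expect_error(membrane_measures(matrix(2, 4, 4), 40), "0, 1")
})

test_that("phi-weighted area converges with grid refinement at fixed eps", {
  # reference: the same diffuse-disk integral on a very fine grid (the
  # finite-eps area differs from pi R^2 by a fixed curvature bias, so
  # refinement in N must be measured against the eps-continuum value)
  area_at <- function(N) make_disk(polar_params(N = N))$area
  ref <- area_at(512)
  err40 <- abs(area_at(40) - ref)
  err80 <- abs(area_at(80) - ref)
  expect_lt(err80, err40 / 4)            # at least second order in h
  expect_equal(ref, pi * 100, tolerance = 0.02)
})

test_that("tethered geometry matches its construction", {
  p <- polar_params(N = 128)
  g <- make_tethered(p)
  ib <- which.min(abs(g$xs - g$body_center[["x"]]))
  ic <- which.min(abs(g$xs))
  expect_gt(g$phi[ib, ic], 0.99)        # deep inside the body
  # neck midline is interior, off-midline is exterior
  im <- which.min(abs(g$xs - mean(g$neck_interval)))
  expect_gt(g$phi[im, ic], 0.9)
  ioff <- which.min(abs(g$xs - (1.5 + 3 * p$eps)))
  expect_lt(g$phi[im, ioff], 0.05)
  expect_error(make_tethered(polar_params(N = 32), neck_halfwidth = 0.5),
               "unresolved")
})

test_that("degenerate tethered shape area agrees with a Monte-Carlo oracle", {
  p <- polar_params(N = 128)
  R1 <- 5
  g <- make_tethered(p, body_radius = R1, neck_length = 0,
                     neck_halfwidth = 1.5, pseudopod_radius = R1)
  # analytic shape: two disks of radius R1 whose rims touch, plus the
  # bridging strip; Monte-Carlo the union area
  set.seed(42)
  n <- 2e5
  xs <- runif(n, -2 * R1 - 1, 2 * R1 + 1)
  ys <- runif(n, -R1 - 1, R1 + 1)
  b1 <- (xs + R1)^2 + ys^2 <= R1^2
  b2 <- (xs - R1)^2 + ys^2 <= R1^2
  b3 <- abs(xs) <= R1 & abs(ys) <= 1.5
  mc_area <- mean(b1 | b2 | b3) * (4 * R1 + 2) * (2 * R1 + 2)
  expect_equal(g$area, mc_area, tolerance = 0.02)
})

test_that("severing partitions the support and conserves the split mass", {
  p <- polar_params(N = 128)
  g <- make_tethered(p)
  pieces <- sever(g, params = p)
  expect_equal(pieces$front$phi + pieces$body$phi, g$phi, tolerance = 1e-12)
  # cytosolic content of a field is split without loss
  v <- matrix(6, p$N, p$N) + g$yc / 50
  tot0 <- sum(g$phi * v) * g$dA
  tot1 <- sum(pieces$front$phi * v) * g$dA + sum(pieces$body$phi * v) * g$dA
  expect_equal(tot1, tot0, tolerance = 1e-10)
  expect_error(sever(g, cut_x = 10, params = p), "outside the neck")
})

test_that("severing a disk through the center gives equal halves", {
  g <- make_disk(p64)
  pieces <- sever(g, cut_x = 0, params = p64)
  expect_equal(pieces$front$area, pieces$body$area, tolerance = 0.02)
  expect_equal(pieces$front$area + pieces$body$area, g$area, tolerance = 1e-9)
})

test_that("interface measure of B(phi) scales linearly with eps", {
  tot <- vapply(c(0.75, 1.5), function(e) {
    g <- make_disk(polar_params(N = 256, eps = e))
    sum(g$Bphi) * g$dA
  }, numeric(1))
  expect_equal(tot[2] / tot[1], 2, tolerance = 0.05)
})
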