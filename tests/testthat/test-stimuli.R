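test_that("graded field spans [0, 2R amp], mirrors, and expires", {
  pr <- stimulus_protocol("graded", ks_amp = 0.01, ks_dur = 20, direction = 0)
  f <- graded_field(pr, g64, p64, t = 10)
  expect_true(all(f >= 0))
  expect_lte(max(f), 2 * p64$R * 0.01 + 1e-12)
  # rear pole ~0, front pole ~2 R amp
  ic <- which.min(abs(g64$xs))
  ifr <- which.min(abs(g64$xs - (p64$R - 1)))
  irr <- which.min(abs(g64$xs + (p64$R - 1)))
  expect_equal(f[ifr, ic], 0.01 * (p64$R + g64$xs[ifr]), tolerance = 1e-9)
  expect_lt(f[irr, ic], f[ifr, ic] / 10)
  expect_equal(max(graded_field(pr, g64, p64, t = 25)), 0)  # t > ks_dur
  # flipping the direction mirrors the field
  pr180 <- stimulus_protocol("graded", ks_amp = 0.01, ks_dur = 20, direction = 180)
  f180 <- graded_field(pr180, g64, p64, t = 10)
  expect_equal(f180[irr, ic], f[ifr, ic], tolerance = 1e-9)
  expect_error(stimulus_protocol("graded", direction = 45), "0, 90, 180, 270")
})

test_that("local random field is confined, uniform in [0, amp], reproducible", {
  pr <- stimulus_protocol("local_random", ks_amp = 0.1, ks_dur = 10,
                          direction = 0, seed = 7)
  f <- local_random_field(pr, g64, p64, t = 5)
  xi <- g64$xc - g64$center[["x"]]
  outside <- xi < 0 | xi > 0.25 * p64$R | g64$phi <= 0.5
  expect_true(all(f[outside] == 0))
  band <- f[!outside]
  expect_true(all(band >= 0 & band <= 0.1))
  expect_equal(mean(band) / 0.1, 0.5, tolerance = 0.1)   # mean of U(0,1)
  f2 <- local_random_field(pr, g64, p64, t = 5)
  expect_identical(f, f2)
  pr2 <- stimulus_protocol("local_random", ks_amp = 0.1, ks_dur = 10, seed = 8)
  expect_false(identical(f, local_random_field(pr2, g64, p64, t = 5)))
  expect_equal(max(local_random_field(pr, g64, p64, t = 11)), 0)
})

test_that("switching schedules draw axis directions uniformly", {
  sch <- switching_schedule(seed = 3, n_events = 4000,
                            amp_range = c(0.001, 0.002), dur_range = c(5, 10),
                            gap = 1)
  counts <- table(factor(sch$direction, levels = c(0, 90, 180, 270)))
  chi <- suppressWarnings(stats::chisq.test(counts))
  expect_gt(chi$p.value, 1e-4)
  expect_true(all(sch$ks_amp >= 0.001 & sch$ks_amp <= 0.002))
  expect_true(all(diff(sch$onset) >= sch$ks_dur[-4000] - 1e-9))
  expect_identical(sch, switching_schedule(seed = 3, n_events = 4000,
                                           amp_range = c(0.001, 0.002),
                                           dur_range = c(5, 10), gap = 1))
})

test_that("overlapping schedules are rejected when compiled", {
  sch <- switching_schedule(seed = 1, n_events = 3, gap = 5)
  sch$onset[2] <- sch$onset[1] + 1   # force overlap
  pr <- stimulus_protocol("switching_sequence", schedule = sch)
  expect_error(polartension:::protocol_segments(pr, g64, p64, t_end = 200),
               "overlap")
})

test_that("every stimulus field is non-negative and vanishes after expiry", {
  kinds <- list(
    stimulus_protocol("graded", ks_amp = 0.01, ks_dur = 7),
    stimulus_protocol("local_random", ks_amp = 0.05, ks_dur = 7, seed = 1),
    stimulus_protocol("dual_gradient", ks_amp = 0.01, ks_amp2 = 0.005,
                      ks_dur = 7))
  for (pr in kinds) {
    segs <- polartension:::protocol_segments(pr, g64, p64, t_end = 20)
    for (i in seq_len(nrow(segs))) {
      fld <- segs$field[[i]]
      if (!is.null(fld)) expect_true(all(fld >= 0))
      if (segs$t0[i] >= 7) expect_true(is.null(fld) || max(fld) == 0)
    }
  }
})
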