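test_that("tidiers return the documented shapes", {
  tr <- simulate(initial_state(g64, p64), g64, p64,
                 stimulus_protocol("graded", ks_amp = 0.003, ks_dur = 2),
                 solver_config(t_end = 5))
  td <- tidy(tr)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("t", "max_u", "total_u", "mt") %in% names(td)))
  gl <- glance(tr)
  expect_equal(nrow(gl), 1L)
  expect_true(all(c("t_end", "max_u", "polarized", "clipped") %in% names(gl)))
})

test_that("autoplot methods return ggplot objects", {
  tr <- simulate(initial_state(g64, p64), g64, p64,
                 stimulus_protocol("graded", ks_amp = 0.003, ks_dur = 2),
                 solver_config(t_end = 4))
  expect_s3_class(autoplot(tr), "ggplot")
  expect_s3_class(plot_field(tr$final_state$u, g64), "ggplot")
})

test_that("threshold and stability objects have tidy/glance methods", {
  fit <- structure(list(threshold = 0.002, vary = "amp", mt0 = 0.2,
                        tol_rel = 0.05,
                        probes = tibble::tibble(x = c(0.001, 0.004),
                                                polarized = c(FALSE, TRUE))),
                   class = "polar_threshold_fit")
  expect_equal(glance(fit)$threshold, 0.002)
  expect_equal(nrow(tidy(fit)), 2)
  cv <- structure(list(points = tibble::tibble(ks_dur = c(5, 10),
                                               ks_amp = c(0.004, 0.002),
                                               product = c(0.02, 0.02)),
                       mt0 = 0.2),
                  class = "polar_threshold_curve")
  expect_equal(glance(cv)$n_points, 2)
  expect_s3_class(autoplot(cv), "ggplot")
})
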