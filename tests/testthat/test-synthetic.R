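test_that("a zero-fiber stack is pure background and generation is deterministic", {
  cfg <- small_stack(n_fibers = 0L, background_level = 10)
  st <- generate_fiber_stack(cfg)
  expect_true(all(st$intensities == 10))

  cfg2 <- small_stack(n_fibers = 40L, noise_sigma = 3, seed = 99L)
  a <- generate_fiber_stack(cfg2)
  b <- generate_fiber_stack(cfg2)
  expect_identical(a$intensities, b$intensities)
  expect_identical(attr(a, "ground_truth")$angles,
                   attr(b, "ground_truth")$angles)
})

test_that("generation does not disturb the session RNG stream", {
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_fiber_stack(small_stack(seed = 5)))
  expect_identical(runif(3), before)
})

test_that("invalid configurations are rejected", {
  expect_error(stack_config(width = 0), ">= 1")
  expect_error(stack_config(orientation_sigma = -0.1), ">= 0")
  expect_error(stack_config(fiber_intensity = 250, background_level = 10),
               "representable")
  expect_error(timecourse_config(sigma_intercept = 0.3, sigma_slope = -0.03,
                                 days = c(0, 15)), "positive")
})

test_that("zero-spread fibers produce a histogram peaking at the distraction axis", {
  cfg <- stack_config(width = 256L, height = 256L, n_fibers = 200L,
                      orientation_sigma = 0, orientation_mean = 0,
                      noise_sigma = 0, seed = 2L)
  st <- generate_fiber_stack(cfg)
  expect_true(all(abs(attr(st, "ground_truth")$angles) < 1e-12))
  h <- orientation_histogram(
    structure_tensor_orientation(sum_projection(st)), n_bins = 36)
  peak <- h$angles[which.max(h$density)]
  expect_lt(abs(peak), pi / 36 + 1e-9)  # within one bin of 0 rad
})

test_that("a single-day timecourse reduces to one stack generation", {
  tmpl <- small_stack()
  tc_cfg <- timecourse_config(days = 0, sigma_intercept = 0.5, sigma_slope = 0,
                              intensity_intercept = 25, intensity_slope = 0,
                              template = tmpl, seed = 4L)
  tc <- generate_timecourse(tc_cfg)
  expect_length(tc, 1L)
  gt <- attr(tc, "ground_truth")
  direct <- tmpl
  direct$orientation_sigma <- 0.5
  direct$n_fibers <- gt$n_fibers[1]
  direct$seed <- 4L
  expect_identical(tc[[1]]$stack$intensities,
                   generate_fiber_stack(direct)$intensities)
})

test_that("a narrowing spread law narrows the drawn angle distributions", {
  tc <- generate_timecourse(timecourse_config(
    days = c(0, 15), sigma_intercept = 0.9, sigma_slope = -0.03,
    template = small_stack(n_fibers = 400L), seed = 8L))
  sd0 <- sd(attr(tc[[1]]$stack, "ground_truth")$angles)
  sd15 <- sd(attr(tc[[2]]$stack, "ground_truth")$angles)
  expect_lt(sd15, sd0)
})

test_that("a rising intensity law yields strictly increasing noise-free mean gray values", {
  tc <- generate_timecourse(timecourse_config(
    days = c(0, 3, 5, 10, 15), template = small_stack(n_fibers = 100L),
    seed = 6L))
  gt <- attr(tc, "ground_truth")
  expect_true(all(diff(gt$target_intensity) > 0))  # analytic expectation
  mgv <- vapply(tc, function(e)
    mean_gray_value(max_projection(e$stack, n_planes(e$stack)))$mean_gray_value,
    numeric(1))
  expect_true(all(diff(mgv) > 0))
  expect_equal(mgv, gt$target_intensity, tolerance = 0.05)
})

test_that("sum-projection mean gray value is linear in fiber count", {
  ns <- c(40L, 80L, 120L, 160L, 200L)
  mgv <- vapply(ns, function(n) {
    st <- generate_fiber_stack(stack_config(
      width = 256L, height = 256L, n_planes = 3L, n_fibers = n,
      noise_sigma = 0, seed = 31L))
    mean_gray_value(sum_projection(st))$mean_gray_value
  }, numeric(1))
  expect_gt(fit_linear(ns, mgv)$r_squared, 0.99)
})

test_that("noise-free stiffness series equals the forward trajectory", {
  cfg <- stiffness_config(noise_sd = 0, seed = 1L)
  s <- generate_stiffness_series(cfg)
  truth <- attr(s, "truth")
  expect_equal(s$stiffness, truth$trajectory$K, tolerance = 1e-12)
})

test_that("with all coefficients forced to one the series is constant at K1", {
  idm <- identity_model()
  s <- generate_stiffness_series(stiffness_config(
    params = idm$params, laws = idm$laws, days = 1:10, noise_sd = 0))
  expect_equal(s$stiffness, rep(idm$params$K1, 10), tolerance = 1e-10)
})

test_that("the reference model reaches about 50 N/mm at the end of distraction", {
  s <- generate_stiffness_series(stiffness_config(noise_sd = 0))
  k15 <- s$stiffness[s$day == 15]
  expect_lt(abs(k15 - 50) / 50, 0.05)
})

test_that("stiffness series validation enforces the protocol window", {
  expect_error(stiffness_series(c(2, 1), c(5, 5)), "sorted")
  expect_error(stiffness_series(c(0, 20), c(5, 5)), "window")
  expect_error(stiffness_series(c(0, 1), c(5, -1)), "> 0")
})
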