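test_that("linear fits reproduce exact and degenerate cases", {
  f <- fit_linear(1:6, 2 * (1:6) + 1)
  expect_equal(f$slope, 2, tolerance = 1e-12)
  expect_equal(f$intercept, 1, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  g <- fit_linear(1:5, rep(4, 5))
  expect_equal(g$slope, 0, tolerance = 1e-12)
  expect_equal(g$r_squared, 0, tolerance = 1e-12)
  expect_true(g$p_value > 0 && g$p_value <= 1)

  expect_error(fit_linear(rep(1, 4), 1:4), "distinct")
  expect_error(fit_linear(1:2, 1:2), "3 points")
})

test_that("linear fit matches the closed-form normal equations", {
  set.seed(21)
  x <- c(0, 3, 5, 10, 15, 22)
  y <- 0.8 - 0.02 * x + rnorm(6, 0, 0.05)
  f <- fit_linear(x, y)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  expect_equal(f$slope, slope, tolerance = 1e-10)
  expect_equal(f$intercept, intercept, tolerance = 1e-10)
  expect_equal(f$r_squared, cor(x, y)^2, tolerance = 1e-10)
})

test_that("goodness of fit matches direct sum-of-squares evaluation", {
  obs <- c(3, 5, 4, 8, 7)
  expect_equal(goodness_of_fit(obs, obs)$r_squared, 1)
  expect_equal(goodness_of_fit(rep(mean(obs), 5), obs)$r_squared, 0)
  set.seed(9)
  mod <- obs + rnorm(5, 0, 0.5)
  g <- goodness_of_fit(mod, obs)
  expect_equal(g$r_squared,
               1 - sum((obs - mod)^2) / sum((obs - mean(obs))^2),
               tolerance = 1e-12)
  expect_error(goodness_of_fit(1:3, rep(2, 3)), "variance")
})

test_that("noise-free forward-simulated series are inverted essentially exactly", {
  obs <- generate_stiffness_series(stiffness_config(noise_sd = 0))
  fit <- callus_fit(stiffness ~ day, obs, laws = reference_laws(),
                    params = model_params(rho0 = 20))
  cf <- coef(fit)
  expect_equal(unname(cf["C1"]), 0.92, tolerance = 0.01)
  expect_equal(unname(cf["t_prime"]), 0.15, tolerance = 0.01 * 0.15)
  expect_equal(unname(cf["K1"]), 23.87, tolerance = 0.01 * 23.87)
  expect_gt(fit$r_squared, 0.9999)
  expect_true(fit$diagnostics$converged)
  expect_equal(fit$product_C1K1, 0.92 * 23.87, tolerance = 1e-6)
})

test_that("the stiffness scale is recovered within 10% under 5% proportional noise", {
  errs <- sapply(1:50, function(s) {
    fit <- callus_fit(stiffness ~ day,
                      generate_stiffness_series(stiffness_config(
                        noise_frac = 0.05, seed = s)),
                      laws = reference_laws(), params = model_params(rho0 = 20))
    c(K1 = abs(coef(fit)[["K1"]] / 23.87 - 1),
      product = abs(fit$product_C1K1 / (0.92 * 23.87) - 1))
  })
  expect_lt(median(errs["K1", ]), 0.10)
  expect_lt(median(errs["product", ]), 0.10)
})

test_that("the fitted maturation time always respects its latency bounds", {
  tps <- sapply(1:100, function(s) {
    obs <- generate_stiffness_series(stiffness_config(
      days = seq(0, 15, by = 3), noise_frac = 0.10, seed = 1000 + s))
    coef(callus_fit(stiffness ~ day, obs, laws = reference_laws(),
                    params = model_params(rho0 = 20)))["t_prime"]
  })
  expect_true(all(tps >= 0 & tps <= 7))
})

test_that("constant observations are flagged as degenerate, not silently fitted", {
  obs <- data.frame(day = 0:7, stiffness = rep(10, 8))
  fit <- callus_fit(stiffness ~ day, obs, laws = reference_laws(),
                    params = model_params(rho0 = 20))
  expect_true(fit$diagnostics$degenerate)
  expect_true(is.na(fit$r_squared))
})

test_that("fit methods are mutually consistent", {
  obs <- generate_stiffness_series(stiffness_config(noise_frac = 0.03,
                                                    seed = 12))
  fit <- callus_fit(stiffness ~ day, obs, laws = reference_laws(),
                    params = model_params(rho0 = 20))
  expect_equal(fitted(fit) + residuals(fit), obs$stiffness, tolerance = 1e-12)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-9)
  traj <- predict(fit, newdata = data.frame(day = c(0, 15)),
                  type = "coefficients")
  expect_equal(traj$eta_theta[1], 1)
  sims <- simulate(fit, nsim = 3, seed = 2)
  expect_identical(dim(sims), c(nrow(obs), 4L))
  expect_identical(simulate(fit, nsim = 3, seed = 2), sims)
  expect_output(print(summary(fit)), "product")
})
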