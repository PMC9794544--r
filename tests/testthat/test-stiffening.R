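test_that("theta pdf honours both normalization contracts", {
  lit <- theta_pdf(0.3, normalization = "literal")
  expect_equal(sum(lit$density * lit$weights), 1, tolerance = 1e-9)
  sol <- theta_pdf(0.3, normalization = "solid_angle")
  expect_equal(2 * pi * sum(sol$density * sin(sol$angles) * sol$weights), 1,
               tolerance = 1e-9)
  expect_error(theta_pdf(0), "sigma")
})

test_that("a smaller sigma concentrates more mass near the distraction axis", {
  near_mass <- function(s) {
    d <- theta_pdf(s, normalization = "literal")
    sel <- d$angles <= 0.3
    sum(d$density[sel] * d$weights[sel])
  }
  expect_gt(near_mass(0.3), near_mass(0.6))
})

test_that("solid-angle orientation integral has the aligned and isotropic limits", {
  iso <- orientation_integral_solid(theta_pdf(Inf))
  expect_equal(iso, 1 / (12 * pi), tolerance = 1e-6)
  aligned <- orientation_integral_solid(theta_pdf(0.005))
  expect_equal(aligned, 1 / (4 * pi), tolerance = 1e-4)
  # very wide kernels converge to the isotropic value
  expect_equal(orientation_integral_solid(theta_pdf(500)), iso,
               tolerance = 1e-4)
})

test_that("literal orientation sum has limits 1/2 (aligned) and 1/4 (uniform)", {
  n <- 10000L
  w <- pi / n
  ang <- (seq_len(n) - 0.5) * w
  delta <- orientation_distribution(ang, c(1 / w, rep(0, n - 1)), rep(w, n),
                                    frame = "sphere_elevation")
  expect_equal(orientation_integral_literal(delta), 0.5, tolerance = 1e-7)
  unif <- theta_pdf(Inf, normalization = "literal")
  expect_equal(orientation_integral_literal(unif), 0.25, tolerance = 1e-9)
  for (s in c(0.2, 0.7, 2)) {
    v <- orientation_integral_literal(theta_pdf(s, normalization = "literal"))
    expect_gt(v, 0); expect_lte(v, 0.5)
  }
})

test_that("orientation integrals are monotone non-increasing over physiological spreads", {
  sigmas <- seq(0.1, 1.5, by = 0.1)
  for (mode in c("solid_angle", "literal")) {
    f <- if (mode == "solid_angle") {
      function(s) orientation_integral_solid(theta_pdf(s, 4000, mode))
    } else function(s) orientation_integral_literal(theta_pdf(s, 4000, mode))
    vals <- vapply(sigmas, f, numeric(1))
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("doubling the quadrature size leaves eta_theta unchanged to 1e-6", {
  laws <- reference_laws()
  a <- eta_theta_trajectory(laws, c(5, 15), model_params(N_quad = 10000L))
  b <- eta_theta_trajectory(laws, c(5, 15), model_params(N_quad = 20000L))
  expect_lt(max(abs(a - b)), 1e-6)
})

test_that("eta_theta is 1 at day 0, flat for constant laws, increasing for narrowing laws", {
  flat <- temporal_laws(c(0.6, 0), c(20, 0.5))
  expect_equal(eta_theta_trajectory(flat, 0:5), rep(1, 6), tolerance = 1e-12)
  narrowing <- reference_laws()
  traj <- eta_theta_trajectory(narrowing, 0:15)
  expect_equal(traj[1], 1)
  expect_true(all(diff(traj) > 0))
})

test_that("eta_theta approaches the aligned limit as the spread law collapses", {
  laws <- temporal_laws(c(0.8, (0.001 - 0.8) / 15), c(20, 0))
  v15 <- eta_theta_trajectory(laws, c(0, 15))[2]
  i0 <- orientation_integral_solid(theta_pdf(0.8))
  expect_equal(v15, (1 / (4 * pi)) / i0, tolerance = 1e-3)
})

test_that("density coefficient is quadratic in relative density", {
  expect_equal(eta_d(30, 30, C1 = 1), 1)
  expect_equal(eta_d(30, 30, C1 = 0.92), 0.92)
  expect_equal(eta_d(1.574, 1, C1 = 0.92), 2.28, tolerance = 1e-3)
  expect_error(eta_d(-1, 1), "> 0")
})

test_that("maturation closed form matches an independent ODE integration", {
  skip_if_not_installed("deSolve")
  sol <- deSolve::ode(y = c(m = 0), times = seq(0, 20, by = 0.5),
                      func = function(t, y, p) list(p$K2 * (1 - y[1])),
                      parms = list(K2 = 0.1), method = "ode45",
                      atol = 1e-12, rtol = 1e-12)
  closed <- maturation_solve(sol[, "time"], K2 = 0.1)
  expect_lt(max(abs(closed$m_c - sol[, "m"])), 1e-8)
})

test_that("maturation state is a saturating partition of naive and mature collagen", {
  st <- maturation_solve(seq(0, 80, by = 0.5), K2 = 0.1)
  expect_equal(st$m_c[1], 0)
  expect_true(all(abs(st$n_c + st$m_c - 1) < 1e-12))
  expect_true(all(diff(st$m_c) > 0))
  expect_equal(st$m_c[nrow(st)], 1, tolerance = 1e-3)
  expect_equal(maturation_solve(7, K2 = 0.1)$m_c, 1 - exp(-0.7),
               tolerance = 1e-12)
  expect_error(maturation_solve(-1), ">= 0")
})

test_that("maturation coefficient starts at zero and saturates within [0, 1]", {
  p0 <- model_params(t_prime = 0)
  expect_equal(eta_m(0, params = p0), 0)
  pc <- model_params(t_prime = 0, maturation_mode = "cohort_weighted")
  expect_equal(eta_m(0, laws = reference_laws(), params = pc), 0)
  for (mode in c("tissue_clock", "cohort_weighted")) {
    p <- model_params(t_prime = 0.5, maturation_mode = mode)
    v <- eta_m(0:15, laws = reference_laws(), params = p)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v) >= 0))
  }
})

test_that("cohort-weighted maturation equals a brute-force daily summation", {
  laws <- reference_laws()
  p <- model_params(t_prime = 0.6, K2 = 0.1,
                    maturation_mode = "cohort_weighted")
  for (t in c(3, 9, 15)) {
    idx <- seq(p$t_prime, t, by = 1)
    rho <- 19.891 + 0.7726 * idx
    mc <- 1 - exp(-p$K2 * (t + p$t_prime - idx))
    expect_equal(eta_m(t, laws, p), sum(rho * mc) / sum(rho),
                 tolerance = 1e-12)
  }
})

test_that("with constant density the cohort coefficient is the mean cohort maturation", {
  laws <- temporal_laws(c(0.5, 0), c(25, 0))
  p <- model_params(t_prime = 0, K2 = 0.1, maturation_mode = "cohort_weighted")
  t <- 40
  ages <- t - seq(0, t, by = 1)
  expect_equal(eta_m(t, laws, p), mean(1 - exp(-0.1 * ages)), tolerance = 1e-12)
})

test_that("stiffness trajectory is the pointwise coefficient product, linear in K1", {
  laws <- reference_laws()
  p <- model_params(rho0 = 20)
  tr <- stiffness_trajectory(laws, 0:15, p)
  expect_equal(tr$K, tr$eta_theta * tr$eta_d * tr$eta_m * p$K1,
               tolerance = 1e-12)
  p2 <- p; p2$K1 <- 2 * p$K1
  expect_equal(stiffness_trajectory(laws, 0:15, p2)$K, 2 * tr$K,
               tolerance = 1e-12)

  idm <- identity_model()
  tri <- stiffness_trajectory(idm$laws, 1:10, idm$params)
  expect_equal(tri$K, rep(idm$params$K1, 10), tolerance = 1e-9)
})

test_that("brute-force stress averaging respects alignment, isotropy and trace", {
  aligned <- macroscopic_stress(theta_pdf(0.005), 1)
  expect_equal(aligned[3, 3], 1, tolerance = 1e-3)

  iso <- macroscopic_stress(theta_pdf(Inf), 1)
  expect_equal(iso, diag(3) / 3, tolerance = 1e-6)

  for (s in c(0.2, 0.5, 1.1)) {
    m <- macroscopic_stress(theta_pdf(s, 2000), 3.5)
    expect_equal(sum(diag(m)), 3.5, tolerance = 1e-9)
  }
  expect_error(macroscopic_stress(theta_pdf(0.3, normalization = "literal")),
               "solid-angle")
})
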