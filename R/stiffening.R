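#' Stiffening model parameters
#'
#' Parameters of the multiplicative callus stiffening model
#' `K(t) = eta_theta(t) * eta_d(t) * eta_m(t) * K1`. Defaults are the
#' packaged reference values of the fitted model (C1 = 0.92, t' = 0.15 days,
#' K1 = 23.87 N/mm) and the fixed collagen maturation rate K2 = 0.1 per day.
#'
#' @param K1 apparent stiffness of mature, day-0-organized fibers, N/mm (> 0).
#' @param C1 density-coefficient constant, dimensionless (> 0); close to 1
#'   for open-cell cellular solids.
#' @param t_prime maturation time already accrued before distraction starts,
#'   days, bounded to the latency interval `[0, 7]`.
#' @param K2 naive-to-mature collagen conversion rate, 1/day (> 0).
#' @param rho0 reference (day-0) fiber density in mean-gray-value units, or
#'   `NA` to use the fitted density law evaluated at day 0.
#' @param N_quad number of elevation-angle quadrature nodes (>= 100).
#' @param orientation_mode `"solid_angle"` (default; unit-sphere measure with
#'   the `sin(theta)` weight, reproducing the 1/(12 pi) random and 1/(4 pi)
#'   aligned limits and their factor-3 ratio) or `"literal"` (plain
#'   equispaced sum without the solid-angle weight, whose limits are 1/4 and
#'   1/2 with ratio 2).
#' @param maturation_mode `"tissue_clock"` (default: one shared maturation
#'   clock started t' days before distraction) or `"cohort_weighted"`
#'   (density-weighted average over daily fiber cohorts, a Miner-rule style
#'   accumulation).
#' @return A `model_params` list.
#' @export
model_params <- function(K1 = 23.87, C1 = 0.92, t_prime = 0.15, K2 = 0.1,
                         rho0 = NA_real_, N_quad = 10000L,
                         orientation_mode = c("solid_angle", "literal"),
                         maturation_mode = c("tissue_clock", "cohort_weighted")) {
  orientation_mode <- match.arg(orientation_mode)
  maturation_mode <- match.arg(maturation_mode)
  if (!is.numeric(K1) || K1 <= 0) stop("K1 must be > 0")
  if (!is.numeric(C1) || C1 <= 0) stop("C1 must be > 0")
  if (!is.numeric(t_prime) || t_prime < 0 || t_prime > 7)
    stop("t_prime must lie in [0, 7] days")
  if (!is.numeric(K2) || K2 <= 0) stop("K2 must be > 0")
  if (!is.na(rho0) && rho0 <= 0) stop("rho0 must be > 0")
  N_quad <- as.integer(N_quad)
  if (N_quad < 100L) stop("N_quad must be >= 100")
  structure(list(K1 = K1, C1 = C1, t_prime = t_prime, K2 = K2, rho0 = rho0,
                 N_quad = N_quad, orientation_mode = orientation_mode,
                 maturation_mode = maturation_mode),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  cat(sprintf("  K1 = %g N/mm, C1 = %g, t' = %g d, K2 = %g /d, rho0 = %s\n",
              x$K1, x$C1, x$t_prime, x$K2,
              if (is.na(x$rho0)) "rho-law(0)" else format(x$rho0)))
  cat(sprintf("  N_quad = %d, orientation '%s', maturation '%s'\n",
              x$N_quad, x$orientation_mode, x$maturation_mode))
  invisible(x)
}

coef_or_law <- function(x, what) {
  if (inherits(x, "linear_law"))
    c(intercept = unname(x$intercept), slope = unname(x$slope))
  else if (is.numeric(x) && length(x) == 2L)
    c(intercept = unname(x[1]), slope = unname(x[2]))
  else stop(sprintf("'%s' must be a linear_law or c(intercept, slope)", what))
}

#' Temporal laws for orientation spread and fiber density
#'
#' Affine laws `sigma(t) = a + b t` (radians) for the standard deviation of
#' the in-plane fiber orientation distribution and `rho(t) = c + d t`
#' (mean-gray-value units) for the fiber density proxy, both functions of
#' days after latency. They can be supplied directly or as [fit_linear()]
#' results, whose R^2 and p-value are carried along as diagnostics.
#'
#' @param sigma_law a [fit_linear()] result or `c(intercept, slope)`.
#' @param rho_law a [fit_linear()] result or `c(intercept, slope)`.
#' @param check_window both laws must stay positive on this day interval.
#' @return A `temporal_laws` object.
#' @export
temporal_laws <- function(sigma_law, rho_law, check_window = c(0, 15)) {
  sl <- coef_or_law(sigma_law, "sigma_law")
  rl <- coef_or_law(rho_law, "rho_law")
  ends <- check_window
  if (any(sl["intercept"] + sl["slope"] * ends <= 0))
    stop("sigma law must be positive over the distraction window")
  if (any(rl["intercept"] + rl["slope"] * ends <= 0))
    stop("rho law must be positive over the distraction window")
  diag_of <- function(x) if (inherits(x, "linear_law"))
    list(r_squared = x$r_squared, p_value = x$p_value) else NULL
  structure(list(sigma = sl, rho = rl,
                 sigma_diag = diag_of(sigma_law), rho_diag = diag_of(rho_law),
                 window = check_window),
            class = "temporal_laws")
}

#' @export
print.temporal_laws <- function(x, ...) {
  fmt <- function(cf) sprintf("%.5g %+.5g * t", cf["intercept"], cf["slope"])
  cat("<temporal_laws>\n")
  cat("  sigma(t) =", fmt(x$sigma), "rad")
  if (!is.null(x$sigma_diag))
    cat(sprintf("  (R^2 = %.4f, p = %.3g)", x$sigma_diag$r_squared,
                x$sigma_diag$p_value))
  cat("\n  rho(t)   =", fmt(x$rho), "gray")
  if (!is.null(x$rho_diag))
    cat(sprintf("  (R^2 = %.4f, p = %.3g)", x$rho_diag$r_squared,
                x$rho_diag$p_value))
  cat("\n")
  invisible(x)
}

sigma_at <- function(laws, t) laws$sigma["intercept"] + laws$sigma["slope"] * t
rho_at <- function(laws, t) laws$rho["intercept"] + laws$rho["slope"] * t

#' Elevation-angle probability density of fiber orientation
#'
#' Builds the discretized density of the fiber elevation angle theta in
#' `[0, pi]` for a given angular spread: a normal kernel of standard
#' deviation `sigma` centered on the distraction axis, with symmetric mass at
#' both poles (theta = 0 and theta = pi), since a fiber and its reverse are
#' the same structure. `sigma = Inf` yields the exact isotropic density.
#' Azimuth is uniform throughout.
#'
#' @param sigma angular spread, radians (> 0; `Inf` for isotropic).
#' @param n number of midpoint quadrature nodes on `[0, pi]`.
#' @param normalization `"solid_angle"` (density integrates to 1 over the
#'   unit sphere) or `"literal"` (plain `sum(p w) = 1`).
#' @return An [orientation_distribution()] in the `sphere_elevation` frame.
#' @export
theta_pdf <- function(sigma, n = 10000L,
                      normalization = c("solid_angle", "literal")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  n <- as.integer(n)
  w <- pi / n
  theta <- (seq_len(n) - 0.5) * w
  q <- if (is.infinite(sigma)) rep(1, n)
       else exp(-theta^2 / (2 * sigma^2)) + exp(-(theta - pi)^2 / (2 * sigma^2))
  p <- if (normalization == "literal") q / sum(q * w)
       else q / (2 * pi * sum(q * sin(theta) * w))
  orientation_distribution(theta, p, rep(w, n), frame = "sphere_elevation",
                           normalization = normalization)
}

#' Orientation integral over the unit sphere
#'
#' Evaluates `(1/(4 pi)) * Int Int cos^2(theta) p(theta) sin(theta) dtheta dphi`
#' with uniform azimuth, i.e. the un-normalized orientation efficiency of a
#' fibered composite loaded along the distraction axis. Equals `1/(12 pi)`
#' for an isotropic fiber arrangement and `1/(4 pi)` for full alignment, a
#' factor of 3.
#'
#' @param dist a solid-angle-normalized [orientation_distribution()] in the
#'   `sphere_elevation` frame.
#' @return dimensionless scalar.
#' @export
orientation_integral_solid <- function(dist) {
  stopifnot(inherits(dist, "orientation_distribution"))
  if (dist$frame != "sphere_elevation" || dist$normalization != "solid_angle")
    stop("a solid-angle-normalized sphere_elevation distribution is required")
  0.5 * sum(cos(dist$angles)^2 * dist$density * sin(dist$angles) * dist$weights)
}

#' Orientation sum without the solid-angle weight
#'
#' Evaluates `(1/2) * sum(cos^2(theta_i) p(theta_i) w_i)` on an equispaced
#' grid with `w_i = pi/N` and plain normalization `sum(p w) = 1`. This is the
#' literal flat-measure reading of the discretized orientation sum; its
#' aligned and isotropic limits are 1/2 and 1/4 (ratio 2), versus the
#' factor-3 ratio of the solid-angle form, which is why the solid-angle form
#' is the package default.
#'
#' @param dist a literal-normalized [orientation_distribution()] in the
#'   `sphere_elevation` frame on an equispaced grid.
#' @return dimensionless scalar in `(0, 1/2]`.
#' @export
orientation_integral_literal <- function(dist) {
  stopifnot(inherits(dist, "orientation_distribution"))
  if (dist$frame != "sphere_elevation" || dist$normalization != "literal")
    stop("a literal-normalized sphere_elevation distribution is required")
  if (diff(range(diff(dist$angles))) > 1e-9 ||
      diff(range(dist$weights)) > 1e-12)
    stop("an equispaced grid with uniform weights is required")
  0.5 * sum(cos(dist$angles)^2 * dist$density * dist$weights)
}

theta_integral <- function(sigma, params) {
  if (params$orientation_mode == "solid_angle")
    orientation_integral_solid(theta_pdf(sigma, params$N_quad, "solid_angle"))
  else
    orientation_integral_literal(theta_pdf(sigma, params$N_quad, "literal"))
}

#' Orientation coefficient trajectory
#'
#' Normalized orientation coefficient `eta_theta(t) = I(sigma(t)) / I(sigma(0))`
#' where `I` is the selected orientation integral and `sigma(t)` the fitted
#' angular-spread law; equals 1 at day 0 by construction and grows as the
#' distribution narrows around the distraction axis.
#'
#' @param laws a [temporal_laws()] object.
#' @param days numeric vector of days after latency.
#' @param params a [model_params()] object.
#' @return numeric vector, one value per day.
#' @export
eta_theta_trajectory <- function(laws, days, params = model_params()) {
  stopifnot(inherits(laws, "temporal_laws"))
  sig <- sigma_at(laws, days)
  if (any(sig <= 0)) stop("sigma law is non-positive over the requested days")
  i0 <- theta_integral(unname(sigma_at(laws, 0)), params)
  vapply(sig, function(s) theta_integral(unname(s), params), numeric(1)) / i0
}

#' Density coefficient
#'
#' `eta_d = C1 * (rho / rho0)^2`: quadratic dependence of stiffness on
#' relative fiber density, the scaling of open-cell cellular solids.
#'
#' @param rho_t density (mean-gray-value units) at the evaluation time.
#' @param rho0 reference day-0 density, same units.
#' @param C1 dimensionless constant.
#' @return dimensionless value(s).
#' @export
eta_d <- function(rho_t, rho0, C1 = 0.92) {
  if (any(rho_t <= 0) || any(rho0 <= 0)) stop("densities must be > 0")
  if (C1 <= 0) stop("C1 must be > 0")
  C1 * (rho_t / rho0)^2
}

#' Collagen maturation state
#'
#' Closed-form solution of the first-order maturation equation
#' `dm_c/dt = K2 * n_c` with all fibers initially naive: the matured fraction
#' is `m_c(age) = 1 - exp(-K2 * age)` and `n_c = 1 - m_c`. With the fixed
#' K2 = 0.1 per day about half of the fibers are matured after one week.
#'
#' @param age fiber age(s), days (>= 0).
#' @param K2 conversion rate, 1/day.
#' @return A `maturation_state` data frame with columns `age`, `n_c`, `m_c`.
#' @export
maturation_solve <- function(age, K2 = 0.1) {
  if (any(age < 0)) stop("age must be >= 0")
  if (K2 <= 0) stop("K2 must be > 0")
  m <- 1 - exp(-K2 * age)
  structure(data.frame(age = age, n_c = 1 - m, m_c = m),
            class = c("maturation_state", "data.frame"))
}

#' Maturation coefficient
#'
#' Global maturation coefficient of the callus at distraction day `t`. In
#' the default `tissue_clock` mode all fibers share one maturation clock
#' started `t'` days before distraction:
#' `eta_m(t) = 1 - exp(-K2 (t + t'))`. In `cohort_weighted` mode the fibers
#' induced on each distraction day form a cohort, and the coefficient is the
#' density-weighted mean of the cohort maturation fractions (a Miner-rule
#' style accumulation with a 1-day step, matching the per-day distraction
#' protocol):
#' `eta_m(t) = sum_i rho(i) m_c(t + t' - i) / sum_i rho(i)` for `i` from
#' `t'` to `t`.
#'
#' @param t day(s) after latency (>= 0).
#' @param laws a [temporal_laws()] object (used by the cohort mode for the
#'   density weights).
#' @param params a [model_params()] object (provides `t_prime`, `K2` and
#'   `maturation_mode`).
#' @return values in `[0, 1]`, non-decreasing in `t`.
#' @export
eta_m <- function(t, laws = NULL, params = model_params()) {
  if (any(t < 0)) stop("t must be >= 0")
  tp <- params$t_prime
  if (params$maturation_mode == "tissue_clock")
    return(1 - exp(-params$K2 * (t + tp)))
  stopifnot(inherits(laws, "temporal_laws"))
  vapply(t, function(ti) {
    if (ti < tp) return(0)
    i <- seq(tp, ti, by = 1)
    rho <- rho_at(laws, i)
    if (any(rho <= 0)) stop("rho law non-positive inside the cohort window")
    mc <- 1 - exp(-params$K2 * (ti + tp - i))
    sum(rho * mc) / sum(rho)
  }, numeric(1))
}

#' Apparent stiffness trajectory of the fibrous callus
#'
#' Evaluates the full multiplicative model
#' `K(t) = eta_theta(t) * eta_d(t) * eta_m(t) * K1` over the requested days,
#' returning all component coefficients.
#'
#' @inheritParams eta_theta_trajectory
#' @return A `coefficient_trajectory` data frame with columns `day`,
#'   `eta_theta`, `eta_d`, `eta_m`, `K`.
#' @export
stiffness_trajectory <- function(laws, days, params = model_params()) {
  stopifnot(inherits(laws, "temporal_laws"))
  rho0 <- if (is.na(params$rho0)) unname(rho_at(laws, 0)) else params$rho0
  et <- eta_theta_trajectory(laws, days, params)
  ed <- unname(eta_d(rho_at(laws, days), rho0, params$C1))
  em <- eta_m(days, laws, params)
  structure(data.frame(day = days, eta_theta = et, eta_d = ed, eta_m = em,
                       K = et * ed * em * params$K1),
            class = c("coefficient_trajectory", "data.frame"))
}

#' @export
plot.coefficient_trajectory <- function(x, which = c("coefficients", "stiffness"),
                                        ...) {
  which <- match.arg(which)
  if (which == "coefficients") {
    matplot(x$day, cbind(x$eta_theta, x$eta_d, x$eta_m), type = "l",
            lty = c(3, 2, 1), col = c("blue", "red", "goldenrod"),
            xlab = "days after latency", ylab = "coefficient", ...)
    legend("topleft", c(expression(eta[theta]), expression(eta[d]),
                        expression(eta[m])),
           lty = c(3, 2, 1), col = c("blue", "red", "goldenrod"), bty = "n")
  } else {
    plot(x$day, x$K, type = "l", xlab = "days after latency",
         ylab = "apparent stiffness K (N/mm)", ...)
  }
  invisible(x)
}

#' Macroscopic stress tensor by brute-force unit-sphere averaging
#'
#' Independent cross-check of the scalar orientation integral: rotates a
#' uniaxial fiber stress (along the local fiber axis) to the global frame for
#' every `(theta, phi)` quadrature node and averages against the orientation
#' density over the unit sphere,
#' `sigma_U = Int Int R sigma_local R^T p(theta) sin(theta) dtheta dphi`,
#' with the fiber direction `(sin(theta) cos(phi), sin(theta) sin(phi),
#' cos(theta))` (the distraction axis is z). The rotation preserves the
#' trace, an isotropic density yields `I/3`, and the zz-component equals
#' `4 pi` times [orientation_integral_solid()] times the fiber stress.
#'
#' @param dist a solid-angle-normalized [orientation_distribution()] in the
#'   `sphere_elevation` frame.
#' @param fiber_axial_stress scalar uniaxial stress carried along the local
#'   fiber axis.
#' @param n_phi number of uniform azimuth nodes.
#' @return 3x3 numeric matrix (global stress tensor).
#' @export
macroscopic_stress <- function(dist, fiber_axial_stress = 1, n_phi = 72L) {
  stopifnot(inherits(dist, "orientation_distribution"))
  if (dist$frame != "sphere_elevation" || dist$normalization != "solid_angle")
    stop("a solid-angle-normalized sphere_elevation distribution is required")
  n_phi <- as.integer(n_phi)
  wphi <- 2 * pi / n_phi
  phi <- (seq_len(n_phi) - 0.5) * wphi
  theta <- dist$angles
  mass <- dist$density * sin(theta) * dist$weights  # per-theta sphere mass
  out <- matrix(0, 3, 3)
  st <- sin(theta); ct <- cos(theta)
  for (k in seq_len(n_phi)) {
    d1 <- st * cos(phi[k]); d2 <- st * sin(phi[k]); d3 <- ct
    # sum over theta of mass * (d %o% d), assembled componentwise
    out <- out + wphi * matrix(c(
      sum(mass * d1 * d1), sum(mass * d1 * d2), sum(mass * d1 * d3),
      sum(mass * d2 * d1), sum(mass * d2 * d2), sum(mass * d2 * d3),
      sum(mass * d3 * d1), sum(mass * d3 * d2), sum(mass * d3 * d3)), 3, 3)
  }
  fiber_axial_stress * out
}
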