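#' Configuration for a synthetic fibered image stack
#'
#' Describes a phantom confocal z-stack of straight, anti-aliased fiber
#' segments whose in-plane angles are drawn from a normal law wrapped to
#' `(-pi/2, pi/2]` (0 rad = distraction axis = image x-axis). Defaults
#' emulate an 8-bit 40x acquisition; per-day spread and intensity values are
#' illustrative choices, not measured ones.
#'
#' @param width,height image size, pixels. The default 768 px field keeps
#'   500 fibers sparse enough that fiber crossings in the sum projection do
#'   not distort the recovered orientation statistics.
#' @param n_planes number of focal planes.
#' @param pixel_size in-plane calibration, um/pixel.
#' @param z_spacing plane spacing, um.
#' @param n_fibers number of fiber segments distributed across planes.
#' @param orientation_mean,orientation_sigma mean and standard deviation
#'   (radians) of the normal law the fiber angles are drawn from.
#' @param fiber_length_range min/max fiber length, pixels.
#' @param fiber_width fiber thickness, pixels.
#' @param fiber_intensity peak added gray level per fiber.
#' @param background_level constant background gray level.
#' @param noise_sigma additive Gaussian noise standard deviation, gray levels.
#' @param bit_depth 8 or 16.
#' @param seed RNG seed for reproducibility.
#' @return A `stack_config` list.
#' @export
stack_config <- function(width = 768L, height = 768L, n_planes = 9L,
                         pixel_size = 0.1444, z_spacing = 4.89,
                         n_fibers = 500L, orientation_mean = 0,
                         orientation_sigma = 0.5,
                         fiber_length_range = c(40, 80), fiber_width = 2,
                         fiber_intensity = 120, background_level = 10,
                         noise_sigma = 5, bit_depth = 8L, seed = 1L) {
  cfg <- list(width = as.integer(width), height = as.integer(height),
              n_planes = as.integer(n_planes), pixel_size = pixel_size,
              z_spacing = z_spacing, n_fibers = as.integer(n_fibers),
              orientation_mean = orientation_mean,
              orientation_sigma = orientation_sigma,
              fiber_length_range = fiber_length_range,
              fiber_width = fiber_width, fiber_intensity = fiber_intensity,
              background_level = background_level, noise_sigma = noise_sigma,
              bit_depth = as.integer(bit_depth), seed = seed)
  if (cfg$width < 1L || cfg$height < 1L || cfg$n_planes < 1L)
    stop("width, height and n_planes must be >= 1")
  if (cfg$n_fibers < 0L) stop("n_fibers must be >= 0")
  if (cfg$orientation_sigma < 0) stop("orientation_sigma must be >= 0")
  if (length(cfg$fiber_length_range) != 2L ||
      any(cfg$fiber_length_range <= 0) ||
      diff(cfg$fiber_length_range) < 0)
    stop("fiber_length_range must be an increasing positive pair")
  if (cfg$fiber_width <= 0) stop("fiber_width must be > 0")
  if (!cfg$bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16")
  if (cfg$background_level < 0 || cfg$fiber_intensity < 0 ||
      cfg$fiber_intensity + cfg$background_level > 2^cfg$bit_depth - 1)
    stop("fiber_intensity + background_level must be representable in the bit depth")
  structure(cfg, class = "stack_config")
}

# wrap angles to (-pi/2, pi/2]
wrap_half <- function(a) {
  a <- (a + pi / 2) %% pi - pi / 2
  a[a <= -pi / 2 + 1e-15] <- pi / 2
  a
}

# Add one anti-aliased segment (center cx,cy in x=col/y=row coords, angle a,
# half-length h, width w) to an image plane. Coverage falls off linearly
# within half a pixel of the fiber edge transversally, and the intensity is
# tapered over `taper` pixels at both ends so fibers fade out rather than
# terminate in a step (a hard end would contribute strong gradients of
# arbitrary direction and contaminate the orientation statistics).
draw_segment <- function(plane, cx, cy, a, h, w, intensity, taper = 6) {
  ux <- cos(a); uy <- sin(a)
  reach <- h + w / 2 + 1
  c0 <- max(1L, floor(cx - reach)); c1 <- min(ncol(plane), ceiling(cx + reach))
  r0 <- max(1L, floor(cy - reach)); r1 <- min(nrow(plane), ceiling(cy + reach))
  if (c0 > c1 || r0 > r1) return(plane)
  cols <- c0:c1; rows <- r0:r1
  px <- matrix(cols, length(rows), length(cols), byrow = TRUE) - cx
  py <- matrix(rows, length(rows), length(cols)) - cy
  tp <- px * ux + py * uy
  d <- sqrt((px - tp * ux)^2 + (py - tp * uy)^2)
  cov <- pmin(1, pmax(0, w / 2 + 0.5 - d))
  long <- pmin(1, pmax(0, (h + 0.5 - abs(tp)) / max(taper, 1)))
  plane[rows, cols] <- plane[rows, cols] + intensity * cov * long
  plane
}

#' Generate a synthetic fibered z-stack
#'
#' Draws `n_fibers` straight anti-aliased segments with angles from
#' `Normal(orientation_mean, orientation_sigma)` wrapped to `(-pi/2, pi/2]`,
#' distributes them uniformly across focal planes, adds the constant
#' background and optional Gaussian noise, and clips/rounds to the bit
#' depth. The same configuration and seed reproduce the stack bit for bit.
#' The drawn ground truth (angles, planes, centers, lengths) is attached as
#' attribute `"ground_truth"`.
#'
#' @param config a [stack_config()].
#' @return A [fiber_stack()] with a `ground_truth` attribute.
#' @export
generate_fiber_stack <- function(config) {
  stopifnot(inherits(config, "stack_config"))
  with_seed(config$seed, {
    n <- config$n_fibers
    arr <- array(0, dim = c(config$n_planes, config$height, config$width))
    truth <- list(angles = numeric(0), plane = integer(0),
                  cx = numeric(0), cy = numeric(0), length = numeric(0))
    if (n > 0L) {
      ang <- wrap_half(rnorm(n, config$orientation_mean,
                             config$orientation_sigma))
      pl <- sample.int(config$n_planes, n, replace = TRUE)
      cx <- runif(n, 1, config$width)
      cy <- runif(n, 1, config$height)
      len <- runif(n, config$fiber_length_range[1], config$fiber_length_range[2])
      for (i in seq_len(n))
        arr[pl[i], , ] <- draw_segment(arr[pl[i], , ], cx[i], cy[i], ang[i],
                                       len[i] / 2, config$fiber_width,
                                       config$fiber_intensity)
      truth <- list(angles = ang, plane = pl, cx = cx, cy = cy, length = len)
    }
    arr <- arr + config$background_level
    if (config$noise_sigma > 0)
      arr <- arr + rnorm(length(arr), 0, config$noise_sigma)
    maxval <- 2^config$bit_depth - 1
    arr <- round(pmin(pmax(arr, 0), maxval))
    st <- fiber_stack(arr, pixel_size = config$pixel_size,
                      z_spacing = config$z_spacing,
                      bit_depth = config$bit_depth)
    attr(st, "ground_truth") <- truth
    attr(st, "config") <- config
    st
  })
}

#' Configuration for a synthetic imaging time course
#'
#' Per-day stacks whose orientation spread follows the affine law
#' `sigma(t) = sigma_intercept + sigma_slope * t` and whose expected mean
#' gray value follows `I(t) = intensity_intercept + intensity_slope * t`
#' (achieved by scaling the fiber count). Days are counted after latency.
#' Default day set 0, 3, 5, 10, 15 mirrors a sparse distraction-phase
#' sampling; law defaults are illustrative.
#'
#' @param days time points, days after latency.
#' @param sigma_intercept,sigma_slope spread law, radians and radians/day.
#' @param intensity_intercept,intensity_slope mean-intensity law, gray and
#'   gray/day.
#' @param template a [stack_config()] providing geometry, intensity and
#'   noise settings; its `orientation_sigma` and `n_fibers` are overridden
#'   per day.
#' @param seed RNG seed; each day uses `seed + day` for its stack.
#' @return A `timecourse_config` list.
#' @export
timecourse_config <- function(days = c(0, 3, 5, 10, 15),
                              sigma_intercept = 0.85, sigma_slope = -0.03,
                              intensity_intercept = 20, intensity_slope = 2.2,
                              template = stack_config(), seed = 1L) {
  stopifnot(inherits(template, "stack_config"))
  if (anyDuplicated(days)) stop("days must be unique")
  sig <- sigma_intercept + sigma_slope * days
  if (any(sig <= 0)) stop("sigma law must stay positive over the requested days")
  ints <- intensity_intercept + intensity_slope * days
  if (any(ints < template$background_level) ||
      any(ints > 2^template$bit_depth - 1))
    stop("intensity law leaves the representable range")
  structure(list(days = days, sigma_intercept = sigma_intercept,
                 sigma_slope = sigma_slope,
                 intensity_intercept = intensity_intercept,
                 intensity_slope = intensity_slope,
                 template = template, seed = seed),
            class = "timecourse_config")
}

# Expected gray-value sum contributed by one fiber: visible length x
# anti-aliased cross-section (integrates to fiber_width) x intensity. The
# end taper costs one taper length; boundary clipping (centers uniform in
# the image) removes an expected L^2 * (1/(8 W) + 1/(8 H)) of length.
fiber_pixel_sum <- function(template, taper = 6) {
  L <- mean(template$fiber_length_range)
  visible <- L - taper -
    L^2 * (1 / (8 * template$width) + 1 / (8 * template$height))
  visible * template$fiber_width * template$fiber_intensity
}

# Fiber count whose expected maximum-projection mean gray value hits
# `target`: pixels covered in several planes count once in the maximum, so
# the needed per-plane coverage follows 1 - (1 - a)^P = needed fraction,
# treating coverage as binary at the fiber intensity.
solve_n_fibers <- function(target, template, taper = 6) {
  f <- (target - template$background_level) / template$fiber_intensity
  if (f <= 0) return(0L)
  if (f >= 1) stop("target intensity unreachable with this fiber intensity")
  P <- template$n_planes
  a <- 1 - (1 - f)^(1 / P)
  area <- fiber_pixel_sum(template, taper) / template$fiber_intensity
  as.integer(round(a * P * template$width * template$height / area))
}

#' Generate a synthetic imaging time course
#'
#' One stack per requested day, with the orientation spread set by the
#' configured sigma law and the fiber count chosen so the expected mean gray
#' value follows the configured intensity law.
#'
#' @param config a [timecourse_config()].
#' @return A list with one element per day: `list(day =, stack =)`; ground
#'   truth (per-day sigma, target intensity, fiber count) attached as
#'   attribute `"ground_truth"`.
#' @export
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "timecourse_config"))
  out <- vector("list", length(config$days))
  sig <- config$sigma_intercept + config$sigma_slope * config$days
  target <- config$intensity_intercept + config$intensity_slope * config$days
  nf <- vapply(target, solve_n_fibers, integer(1), template = config$template)
  for (i in seq_along(config$days)) {
    cfg <- config$template
    cfg$orientation_sigma <- sig[i]
    cfg$n_fibers <- nf[i]
    cfg$seed <- config$seed + config$days[i]
    out[[i]] <- list(day = config$days[i], stack = generate_fiber_stack(cfg))
  }
  attr(out, "ground_truth") <- data.frame(day = config$days, sigma = sig,
                                          target_intensity = target,
                                          n_fibers = nf)
  out
}

#' In vivo-like stiffness observations
#'
#' Validated container for (day, stiffness) observations during the
#' distraction phase.
#'
#' @param day days after latency, sorted, within `window`.
#' @param stiffness apparent stiffness, N/mm (> 0).
#' @param source character tag describing provenance.
#' @param window allowed day range (distraction protocol window).
#' @return A `stiffness_series` data frame.
#' @export
stiffness_series <- function(day, stiffness, source = "unspecified",
                             window = c(0, 15)) {
  if (length(day) != length(stiffness)) stop("day/stiffness length mismatch")
  if (is.unsorted(day)) stop("days must be sorted")
  if (any(day < window[1] | day > window[2]))
    stop("days outside the protocol window")
  if (any(stiffness <= 0)) stop("stiffness must be > 0")
  structure(data.frame(day = day, stiffness = stiffness),
            source = source, window = window,
            class = c("stiffness_series", "data.frame"))
}

#' Default temporal laws of the packaged reference model
#'
#' Angular-spread and density laws calibrated once so that the forward model
#' with the packaged [model_params()] spans the reference coefficient ranges
#' (orientation about 1 to 1.16, density about 0.91 to 2.28 over a 15-day
#' distraction, with a measured day-0 density of 20 gray):
#' `sigma(t) = 0.80 - 0.0087 t` rad and `rho(t) = 19.891 + 0.7726 t` gray.
#'
#' @return A [temporal_laws()] object.
#' @export
reference_laws <- function() {
  temporal_laws(sigma_law = c(0.80, -0.0087), rho_law = c(19.891, 0.7726))
}

#' Configuration for forward-simulated stiffness series
#'
#' @param params true [model_params()] (note `rho0`: `NA` means the density
#'   law evaluated at day 0; the packaged reference uses 20).
#' @param laws a [temporal_laws()] object.
#' @param days observation days after latency.
#' @param noise_sd additive Gaussian observation noise, N/mm.
#' @param noise_frac proportional noise: each observation also receives
#'   Gaussian noise with sd `noise_frac * K(t)`.
#' @param seed RNG seed.
#' @return A `stiffness_config` list.
#' @export
stiffness_config <- function(params = model_params(rho0 = 20),
                             laws = reference_laws(), days = 0:15,
                             noise_sd = 0, noise_frac = 0, seed = 1L) {
  stopifnot(inherits(params, "model_params"), inherits(laws, "temporal_laws"))
  if (noise_sd < 0 || noise_frac < 0) stop("noise levels must be >= 0")
  if (any(days < 0 | days > 15)) stop("days must lie in [0, 15]")
  structure(list(params = params, laws = laws, days = days,
                 noise_sd = noise_sd, noise_frac = noise_frac, seed = seed),
            class = "stiffness_config")
}

#' Forward-simulate a stiffness series
#'
#' Evaluates the multiplicative stiffening model at the configured days and
#' adds seeded Gaussian noise. The generating parameters and the noise-free
#' trajectory are attached as attribute `"truth"`.
#'
#' @param config a [stiffness_config()].
#' @return A [stiffness_series()] with a `truth` attribute.
#' @export
generate_stiffness_series <- function(config) {
  stopifnot(inherits(config, "stiffness_config"))
  traj <- stiffness_trajectory(config$laws, config$days, config$params)
  k <- traj$K
  with_seed(config$seed, {
    if (config$noise_sd > 0) k <- k + rnorm(length(k), 0, config$noise_sd)
    if (config$noise_frac > 0)
      k <- k + rnorm(length(k), 0, config$noise_frac * traj$K)
    out <- stiffness_series(config$days, k, source = "synthetic")
    attr(out, "truth") <- list(params = config$params, trajectory = traj)
    out
  })
}
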