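#' Discretized orientation probability distribution
#'
#' A probability density over an angle range, carried on bin centers with
#' quadrature weights. Two frames are used: `"image_2d"` for in-plane image
#' angles on `(-pi/2, pi/2]` and `"sphere_elevation"` for the elevation angle
#' of a fiber to the distraction axis on `[0, pi]`. Normalization is either
#' `"literal"` (`sum(density * weights) == 1`) or `"solid_angle"`
#' (`2*pi * sum(density * sin(angles) * weights) == 1`, i.e. the density
#' integrates to one over the unit sphere with uniform azimuth).
#'
#' @param angles bin centers, radians.
#' @param density density values per radian at the bin centers.
#' @param weights quadrature weights (bin widths), radians.
#' @param frame `"image_2d"` or `"sphere_elevation"`.
#' @param normalization `"literal"` or `"solid_angle"`.
#' @return An `orientation_distribution` object.
#' @export
orientation_distribution <- function(angles, density, weights,
                                     frame = c("image_2d", "sphere_elevation"),
                                     normalization = c("literal", "solid_angle")) {
  frame <- match.arg(frame)
  normalization <- match.arg(normalization)
  stopifnot(length(angles) == length(density),
            length(angles) == length(weights))
  if (any(density < -1e-12)) stop("density must be non-negative")
  total <- if (normalization == "literal") sum(density * weights)
           else 2 * pi * sum(density * sin(angles) * weights)
  if (abs(total - 1) > 1e-6)
    stop(sprintf("distribution not normalized (%s mass = %.8g)",
                 normalization, total))
  structure(list(angles = angles, density = pmax(density, 0),
                 weights = weights, frame = frame,
                 normalization = normalization),
            class = "orientation_distribution")
}

#' @export
print.orientation_distribution <- function(x, ...) {
  cat(sprintf("<orientation_distribution> %d bins on [%.4f, %.4f] rad, frame '%s', %s-normalized\n",
              length(x$angles), min(x$angles), max(x$angles), x$frame,
              x$normalization))
  invisible(x)
}

#' Weighted orientation histogram of a structure-tensor field
#'
#' Bins the per-pixel orientations over `(-pi/2, pi/2]` into a normalized
#' density. By default each pixel contributes its gradient energy, the usual
#' convention for structure-tensor orientation distributions; coherency-times-
#' energy and unweighted modes are available. Pixels with undefined
#' orientation are excluded.
#'
#' @param field an `orientation_field` from [structure_tensor_orientation()].
#' @param n_bins number of equal-width bins (>= 2), default 90 (2-degree bins).
#' @param weight_mode `"energy"`, `"coherency_energy"` or `"unweighted"`.
#' @return An [orientation_distribution()] in the `image_2d` frame.
#' @export
orientation_histogram <- function(field, n_bins = 90L,
                                  weight_mode = c("energy", "coherency_energy",
                                                  "unweighted")) {
  stopifnot(inherits(field, "orientation_field"))
  weight_mode <- match.arg(weight_mode)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  ok <- !is.na(field$orientation)
  if (!any(ok)) stop("all pixels have undefined orientation")
  ang <- field$orientation[ok]
  w <- switch(weight_mode,
              energy = field$energy[ok],
              coherency_energy = field$energy[ok] * field$coherency[ok],
              unweighted = rep(1, length(ang)))
  breaks <- seq(-pi / 2, pi / 2, length.out = n_bins + 1L)
  bin <- findInterval(ang, breaks, left.open = TRUE, all.inside = TRUE)
  mass <- vapply(seq_len(n_bins), function(b) sum(w[bin == b]), numeric(1))
  if (sum(mass) <= 0) stop("all pixels have zero weight")
  width <- pi / n_bins
  density <- mass / (sum(mass) * width)
  orientation_distribution(angles = (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2,
                           density = density,
                           weights = rep(width, n_bins),
                           frame = "image_2d", normalization = "literal")
}

#' Linear mean of an orientation distribution
#' @param dist an [orientation_distribution()] (literal normalization).
#' @return mean angle, radians.
#' @export
distribution_mean <- function(dist) {
  stopifnot(inherits(dist, "orientation_distribution"))
  if (dist$normalization != "literal")
    stop("linear statistics require a literal-normalized distribution")
  sum(dist$density * dist$weights * dist$angles)
}

#' Linear standard deviation of an orientation distribution
#'
#' Square root of the quadrature variance
#' `sum(p_i w_i (theta_i - mu)^2)` with `mu` the linear mean. Linear (not
#' circular) statistics are used deliberately: the quantity tracks the
#' narrowing of a fiber distribution about the distraction axis.
#'
#' @param dist an [orientation_distribution()] with literal normalization.
#' @return standard deviation, radians.
#' @export
distribution_std <- function(dist) {
  mu <- distribution_mean(dist)
  sqrt(sum(dist$density * dist$weights * (dist$angles - mu)^2))
}
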