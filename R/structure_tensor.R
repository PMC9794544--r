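# 1D convolution as an n x n matrix with reflective borders. Applying
# Kr %*% X %*% t(Kc) filters rows then columns; exact (non-FFT), adequate
# for the image sizes this package targets.
conv_matrix <- function(n, offs, w) {
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + offs
    idx[idx < 1L] <- 1L - (idx[idx < 1L] - 1L)   # reflect below
    idx[idx > n] <- 2L * n + 1L - idx[idx > n]   # reflect above
    idx[idx < 1L] <- 1L; idx[idx > n] <- n       # guard tiny images
    for (k in seq_along(idx)) K[i, idx[k]] <- K[i, idx[k]] + w[k]
  }
  K
}

gauss_conv_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  offs <- (-r):r
  w <- dnorm(offs, sd = sigma)
  conv_matrix(n, offs, w / sum(w))
}

# Derivative-of-Gaussian kernel, normalized to unit response on a ramp.
# A plain centered difference has a strongly anisotropic response that
# biases estimated orientations toward the image diagonals; the Gaussian
# derivative (default sd 1 px) is nearly rotation-invariant.
deriv_conv_matrix <- function(n, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  offs <- (-r):r
  w <- offs * dnorm(offs, sd = sigma)
  conv_matrix(n, offs, w / sum(offs * w))
}

#' Per-pixel fiber orientation from the gradient structure tensor
#'
#' Computes the 2x2 gradient structure tensor
#' `J = G_sigma * [Ix^2, Ix Iy; Ix Iy, Iy^2]` at every pixel, where the
#' gradients are Gaussian derivatives of standard deviation `deriv_sigma`
#' (nearly rotation-invariant, unlike plain centered differences, which
#' pull orientation estimates toward the image diagonals) and `G_sigma` is
#' a Gaussian window of standard deviation `window_sigma`; all filtering
#' uses reflective borders. The reported angle runs ALONG the local
#' structure (perpendicular to the dominant gradient direction), wrapped to
#' `(-pi/2, pi/2]` in array coordinates (x = columns, y = rows increasing
#' downward); 0 rad is the image x-axis. Mapping the image frame to the
#' distraction axis is a metadata rotation applied downstream.
#'
#' @param image numeric matrix, at least 3x3.
#' @param window_sigma Gaussian window standard deviation, pixels (> 0).
#'   Default 2 px: wide enough to pool gradients across a fiber cross
#'   section, narrow enough to keep nearby fibers distinct.
#' @param deriv_sigma standard deviation of the Gaussian-derivative
#'   gradient filter, pixels (> 0), default 1 px.
#' @return An `orientation_field` list with matrices `orientation` (radians;
#'   `NA` where the tensor trace vanishes), `energy` (trace of J) and
#'   `coherency` ((l1 - l2)/(l1 + l2), in `[0, 1]`, 0 where undefined).
#' @export
structure_tensor_orientation <- function(image, window_sigma = 2,
                                         deriv_sigma = 1) {
  if (!is.matrix(image) || nrow(image) < 3L || ncol(image) < 3L)
    stop("image must be a matrix of at least 3 x 3 pixels")
  if (!is.numeric(window_sigma) || window_sigma <= 0)
    stop("window_sigma must be > 0")
  if (!is.numeric(deriv_sigma) || deriv_sigma <= 0)
    stop("deriv_sigma must be > 0")
  Sr <- gauss_conv_matrix(nrow(image), deriv_sigma)
  Sc <- gauss_conv_matrix(ncol(image), deriv_sigma)
  Dr <- deriv_conv_matrix(nrow(image), deriv_sigma)
  Dc <- deriv_conv_matrix(ncol(image), deriv_sigma)
  ix <- Sr %*% image %*% t(Dc)   # d/dx (columns), smoothed along rows
  iy <- Dr %*% image %*% t(Sc)   # d/dy (rows), smoothed along columns
  Kr <- gauss_conv_matrix(nrow(image), window_sigma)
  Kc <- gauss_conv_matrix(ncol(image), window_sigma)
  smooth <- function(m) Kr %*% m %*% t(Kc)
  jxx <- smooth(ix * ix)
  jyy <- smooth(iy * iy)
  jxy <- smooth(ix * iy)
  energy <- jxx + jyy
  # undefined where the tensor trace is negligible against the image dynamic
  # range (a purely max(energy)-relative cutoff would keep rounding noise on
  # constant images)
  tol <- 1e-20 + 1e-12 * diff(range(image))^2
  defined <- energy > tol
  # gradient-axis angle, then +pi/2 so the angle runs along the structure
  ang <- 0.5 * atan2(2 * jxy, jxx - jyy) + pi / 2
  ang[ang > pi / 2] <- ang[ang > pi / 2] - pi
  ang[!defined] <- NA_real_
  coh <- matrix(0, nrow(image), ncol(image))
  coh[defined] <- sqrt((jxx - jyy)[defined]^2 + 4 * jxy[defined]^2) /
    energy[defined]
  coh <- pmin(pmax(coh, 0), 1)
  structure(list(orientation = ang, energy = energy, coherency = coh,
                 window_sigma = window_sigma),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  nd <- sum(!is.na(x$orientation))
  cat(sprintf("<orientation_field> %d x %d px, window sigma %g px, %d defined px\n",
              nrow(x$orientation), ncol(x$orientation), x$window_sigma, nd))
  if (nd > 0)
    cat(sprintf("  mean coherency %.3f (over defined pixels)\n",
                mean(x$coherency[!is.na(x$orientation)])))
  invisible(x)
}
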