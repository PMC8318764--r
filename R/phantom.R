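# Piecewise-constant brain phantoms and simulated undersampled acquisitions.
#
# The phantom is a sum of constant-intensity ellipses (the classic head
# phantom construction) with an optional stroke-like lesion disk; it is
# piecewise constant, i.e. sparse in the total-variation sense, which is the
# structure TV-regularized recovery exploits.

#' Phantom specification
#'
#' Describes a 2D head-like phantom as a list of ellipses on the unit square
#' `[-1, 1]^2` plus an optional circular lesion. Rendering is deterministic;
#' the `seed` field only seeds downstream noise.
#'
#' @param grid_size pixels per side (>= 8).
#' @param ellipses data.frame with columns `cx`, `cy` (center, in `[-1,1]`),
#'   `a`, `b` (semi-axes), `phi` (rotation, radians), `value` (additive
#'   intensity). `NULL` means the default 10-ellipse head.
#' @param lesion `NULL`, or list with `cx`, `cy`, `radius` (fraction of the
#'   half-width, i.e. in units of the unit square) and `delta` (added
#'   intensity, > 0).
#' @param seed integer, carried to acquisition simulation.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size = 64L, ellipses = NULL, lesion = NULL, seed = 1L) {
  grid_size <- as.integer(grid_size)
  if (grid_size < 8L) stop_param("grid_size must be >= 8")
  if (is.null(ellipses)) ellipses <- default_head_ellipses()
  ellipses <- as.data.frame(ellipses)
  need <- c("cx", "cy", "a", "b", "phi", "value")
  if (nrow(ellipses) > 0 && !all(need %in% names(ellipses)))
    stop_param(paste("ellipses must have columns", paste(need, collapse = ", ")))
  if (nrow(ellipses) > 0) {
    if (any(abs(ellipses$cx) > 1 | abs(ellipses$cy) > 1))
      stop_param("ellipse centers must lie in [-1,1]^2")
    if (any(ellipses$a <= 0 | ellipses$b <= 0))
      stop_param("ellipse semi-axes must be positive")
  }
  if (!is.null(lesion)) {
    if (!all(c("cx", "cy", "radius", "delta") %in% names(lesion)))
      stop_param("lesion needs cx, cy, radius, delta")
    if (lesion$radius <= 0 || lesion$delta <= 0)
      stop_param("lesion radius and delta must be positive")
  }
  structure(list(grid_size = grid_size, ellipses = ellipses,
                 lesion = lesion, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Default 10-ellipse head geometry (Toft's contrast-improved variant of the
# standard head phantom); intensities are additive and the rendered image is
# clipped to [0, 1].
default_head_ellipses <- function() {
  data.frame(
    cx    = c(0,      0,      0.22,  -0.22,   0,      0,      0,     -0.08,   0,      0.06),
    cy    = c(0,     -0.0184, 0,      0,      0.35,   0.1,   -0.1,   -0.605, -0.605, -0.605),
    a     = c(0.69,   0.6624, 0.11,   0.16,   0.21,   0.046,  0.046,  0.046,  0.023,  0.023),
    b     = c(0.92,   0.874,  0.31,   0.41,   0.25,   0.046,  0.046,  0.023,  0.023,  0.046),
    phi   = c(0,      0,     -18,     18,     0,      0,      0,      0,      0,      0) * pi / 180,
    value = c(1,     -0.8,   -0.2,   -0.2,    0.1,    0.1,    0.1,    0.1,    0.1,    0.1)
  )
}

#' Default stroke lesion
#'
#' A small hyperintense disk in deep white matter, standing in for the
#' diffusion-restricted core of an acute ischemic infarct.
#' @export
default_lesion <- function() list(cx = 0.25, cy = 0.2, radius = 0.12, delta = 0.4)

#' Render a phantom image
#'
#' Sums ellipse intensities over pixel centers, adds the lesion delta inside
#' its disk, and clips the result to `[0, 1]`. Deterministic: the spec's
#' seed is not consumed.
#'
#' @param spec a [phantom_spec()].
#' @return `grid_size` x `grid_size` numeric matrix; row 1 is the top of the
#'   image (y = +1).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  # pixel-center coordinates in [-1, 1]
  xs <- (2 * (seq_len(n) - 0.5)) / n - 1
  ys <- rev(xs)                        # row 1 = top = y close to +1
  X <- matrix(xs, n, n, byrow = TRUE)
  Y <- matrix(ys, n, n, byrow = FALSE)
  img <- matrix(0, n, n)
  el <- spec$ellipses
  for (i in seq_len(nrow(el))) {
    ct <- cos(el$phi[i]); st <- sin(el$phi[i])
    xr <- (X - el$cx[i]) * ct + (Y - el$cy[i]) * st
    yr <- -(X - el$cx[i]) * st + (Y - el$cy[i]) * ct
    inside <- (xr / el$a[i])^2 + (yr / el$b[i])^2 <= 1
    img <- img + el$value[i] * inside
  }
  if (!is.null(spec$lesion)) {
    les <- spec$lesion
    inside <- (X - les$cx)^2 + (Y - les$cy)^2 <= les$radius^2
    img <- img + les$delta * inside
  }
  pmin(pmax(img, 0), 1)
}

#' Simulate an undersampled k-space acquisition
#'
#' Applies the centered unitary Fourier transform, keeps the coefficients
#' selected by the mask, and adds circular complex Gaussian noise of total
#' standard deviation `noise_level` per sampled coefficient (so each of the
#' real and imaginary parts has sd `noise_level / sqrt(2)`). Noise is added
#' in k-space only, matching the acquisition physics. Unsampled positions
#' are exactly zero.
#'
#' @param true_image real-valued matrix.
#' @param mask a [sampling_mask()] on the same grid.
#' @param noise_level non-negative noise standard deviation (the noise
#'   pollution level the reconstruction constraint is allowed to match).
#' @param seed integer RNG seed for the noise draw.
#' @return object of class `acquisition` with fields `true_image`, `mask`,
#'   `kspace_observed`, `noise_level`, `seed`.
#' @export
simulate_acquisition <- function(true_image, mask, noise_level = 0, seed = 1L) {
  true_image <- as.matrix(true_image)
  if (!inherits(mask, "sampling_mask")) stop_param("mask must be a sampling_mask")
  if (!all(dim(true_image) == dim(mask$grid)))
    stop_dim("mask grid does not match image dimensions")
  if (noise_level < 0) stop_param("noise_level must be >= 0")
  k <- ft2c(true_image)
  kobs <- matrix(0 + 0i, nrow(k), ncol(k))
  idx <- which(mask$grid)
  kobs[idx] <- k[idx]
  if (noise_level > 0 && length(idx) > 0) {
    noise <- with_seed(seed, complex(
      real      = stats::rnorm(length(idx), sd = noise_level / sqrt(2)),
      imaginary = stats::rnorm(length(idx), sd = noise_level / sqrt(2))))
    kobs[idx] <- kobs[idx] + noise
  }
  structure(list(true_image = true_image, mask = mask, kspace_observed = kobs,
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "acquisition")
}

#' Generate an exactly k-sparse test signal
#'
#' Support positions are drawn uniformly without replacement; nonzero values
#' have magnitude in `[0.5, 1.5]` with random sign, so the support is
#' unambiguous at any reasonable zero tolerance.
#'
#' @param n signal length. @param k number of nonzeros (`0 <= k <= n`).
#' @param seed integer seed.
#' @return numeric vector of length `n` with exactly `k` nonzero entries.
#' @export
generate_sparse_signal <- function(n, k, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 0 || k > n) stop_param("need 0 <= k <= n")
  x <- numeric(n)
  if (k > 0) {
    draw <- with_seed(seed, list(
      pos = sample.int(n, k),
      val = sample(c(-1, 1), k, replace = TRUE) * stats::runif(k, 0.5, 1.5)))
    x[draw$pos] <- draw$val
  }
  x
}
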