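# Measurement model: B = Theta A in explicit-matrix form for small systems
# (theory, oracles) and masked-unitary-Fourier operator form for images.
# Masks are stored zero-frequency-centered (see fourier.R for the
# convention).

#' Generate a k-space sampling mask
#'
#' Three undersampling dialects plus full sampling:
#' \describe{
#'   \item{vd-random}{variable-density random: pointwise Bernoulli-style
#'     selection with probability decreasing in k-space radius, and the
#'     central 4\% of the radius always fully sampled (low frequencies carry
#'     most image energy).}
#'   \item{radial}{straight spokes through the k-space center at
#'     golden-angle increments, trimmed/extended to hit the requested
#'     fraction exactly.}
#'   \item{cartesian-lines}{fully sampled phase-encode rows, drawn with a
#'     variable-density preference for central rows.}
#'   \item{full}{every position sampled.}
#' }
#' The achieved fraction is exact to within one sample of
#' `round(fraction * grid_size^2)`, well inside the 2-percentage-point
#' contract. Deterministic per `(dialect, fraction, seed)`.
#'
#' @param grid_size pixels per side.
#' @param dialect one of `"vd-random"`, `"radial"`, `"cartesian-lines"`, `"full"`.
#' @param fraction target sampled fraction in `(0, 1]`.
#' @param seed integer seed.
#' @return object of class `sampling_mask` with fields `grid` (logical
#'   matrix), `dialect`, `fraction` (requested), `seed`.
#' @export
generate_mask <- function(grid_size, dialect = c("vd-random", "radial", "cartesian-lines", "full"),
                          fraction = 0.3, seed = 1L) {
  dialect <- match.arg(dialect)
  n <- as.integer(grid_size)
  if (!is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop_param("fraction must be in (0, 1]")
  target <- max(1L, as.integer(round(fraction * n * n)))
  # centered k-space radius per position, in pixels
  ctr <- n %/% 2 + 1
  kx <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
  ky <- matrix(seq_len(n) - ctr, n, n, byrow = FALSE)
  r <- sqrt(kx^2 + ky^2)
  rmax <- max(r)
  grid <- matrix(FALSE, n, n)
  if (dialect == "full" || fraction >= 1) {
    grid[] <- TRUE
  } else if (dialect == "vd-random") {
    core <- r <= 0.04 * rmax
    grid[core] <- TRUE
    need <- target - sum(grid)
    if (need > 0) {
      cand <- which(!core)
      w <- (1 - r[cand] / (rmax + 1)) ^ 4 + 1e-6
      pick <- with_seed(seed, sample(cand, min(need, length(cand)), prob = w))
      grid[pick] <- TRUE
    }
  } else if (dialect == "cartesian-lines") {
    nl <- max(1L, as.integer(round(fraction * n)))
    rowd <- abs(seq_len(n) - ctr)
    w <- (1 - rowd / (max(rowd) + 1)) ^ 4 + 1e-6
    rows <- with_seed(seed, sample.int(n, nl, prob = w))
    grid[rows, ] <- TRUE
  } else { # radial
    # golden-angle spokes until the target count is reached, then trim the
    # last spoke's outermost points so the count is exact
    ga <- pi * (3 - sqrt(5))
    tt <- seq(-1, 1, length.out = 2 * n)   # radial parameter
    i <- 0L
    order_added <- integer(0)
    while (sum(grid) < target && i < 4L * n) {
      ang <- (i * ga) %% pi
      px <- round(ctr + tt * (n / 2 - 1) * cos(ang))
      py <- round(ctr + tt * (n / 2 - 1) * sin(ang))
      ok <- px >= 1 & px <= n & py >= 1 & py <= n
      idx <- unique((px[ok] - 1L) * n + py[ok])  # column-major linear index
      # sort spoke points center-out so trimming removes the periphery first
      idx <- idx[order(r[idx])]
      newpts <- idx[!grid[idx]]
      grid[newpts] <- TRUE
      order_added <- c(order_added, newpts)
      i <- i + 1L
    }
    excess <- sum(grid) - target
    if (excess > 0) {
      # drop the most peripheral of the most recently added points
      last <- order_added[(length(order_added) - excess + 1L):length(order_added)]
      grid[last] <- FALSE
    }
  }
  structure(list(grid = grid, dialect = dialect, fraction = fraction,
                 seed = as.integer(seed)),
            class = "sampling_mask")
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> %dx%d dialect=%s requested=%.3f achieved=%.3f seed=%d\n",
              nrow(x$grid), ncol(x$grid), x$dialect, x$fraction,
              mean(x$grid), x$seed))
  invisible(x)
}

#' Achieved sampling fraction of a mask
#' @param mask a `sampling_mask`.
#' @return sampled positions / total positions.
#' @export
mask_fraction <- function(mask) mean(mask$grid)

#' Explicit sensing system
#'
#' Small dense measurement model `B = Theta A` with `Theta = Pi %*% Omega`.
#' `Omega` defaults to the identity: for TV recovery the image itself is the
#' sparse object, so the measurement matrix acts on it directly.
#'
#' @param Pi M x N measurement matrix (real or complex), `M <= N`.
#' @param Omega N x N sparse-mapping matrix, default identity.
#' @return object of class `sensing_system`, mode `"explicit"`.
#' @export
sensing_explicit <- function(Pi, Omega = NULL) {
  Pi <- as.matrix(Pi)
  M <- nrow(Pi); N <- ncol(Pi)
  if (M > N) stop_param("explicit system requires M <= N")
  if (N > 1024L) stop_resource("explicit systems are capped at N = 1024 columns")
  if (is.null(Omega)) Omega <- diag(N)
  Omega <- as.matrix(Omega)
  if (!all(dim(Omega) == c(N, N))) stop_dim("Omega must be N x N")
  structure(list(mode = "explicit", Pi = Pi, Omega = Omega,
                 Theta = Pi %*% Omega, M = M, N = N),
            class = "sensing_system")
}

#' Operator-form sensing system (masked centered unitary Fourier transform)
#'
#' @param mask a [sampling_mask()]; the measurement is the vector of sampled
#'   k-space coefficients in column-major order over the mask.
#' @return object of class `sensing_system`, mode `"operator"`.
#' @export
sensing_operator <- function(mask) {
  if (!inherits(mask, "sampling_mask")) stop_param("mask must be a sampling_mask")
  n <- nrow(mask$grid)
  structure(list(mode = "operator", mask = mask, grid_size = n,
                 M = sum(mask$grid), N = n * n),
            class = "sensing_system")
}

#' @export
print.sensing_system <- function(x, ...) {
  cat(sprintf("<sensing_system> mode=%s M=%d N=%d\n", x$mode, x$M, x$N))
  invisible(x)
}

#' Forward measurement
#'
#' Explicit mode: `Theta %*% x` on a length-N coefficient vector. Operator
#' mode: sampled coefficients of the centered unitary Fourier transform of
#' an image, in column-major order over the mask.
#'
#' @param system a [sensing_explicit()] or [sensing_operator()] system.
#' @param x length-N vector (explicit) or image matrix (operator).
#' @return complex measurement vector of length M.
#' @export
cs_forward <- function(system, x) {
  stopifnot(inherits(system, "sensing_system"))
  if (system$mode == "explicit") {
    x <- as.vector(x)
    if (length(x) != system$N) stop_dim("x must have length N")
    as.vector(system$Theta %*% x)
  } else {
    x <- as.matrix(x)
    if (length(x) != system$N) stop_dim("image does not match mask grid")
    k <- ft2c(x)
    k[system$mask$grid]
  }
}

#' Adjoint (conjugate-transpose) of the forward measurement
#'
#' Satisfies the inner-product identity
#' `<cs_forward(x), y> == <x, cs_adjoint(y)>` for all `x`, `y`. For
#' row-orthonormal operators (masked unitary Fourier) this is the
#' zero-filled reconstruction of `y`.
#'
#' @param system a sensing system. @param y length-M measurement vector.
#' @return length-N vector (explicit) or complex image matrix (operator).
#' @export
cs_adjoint <- function(system, y) {
  stopifnot(inherits(system, "sensing_system"))
  y <- as.vector(y)
  if (length(y) != system$M) stop_dim("y must have length M")
  if (system$mode == "explicit") {
    as.vector(Conj(t(system$Theta)) %*% y)
  } else {
    n <- system$grid_size
    k <- matrix(0 + 0i, n, n)
    k[system$mask$grid] <- y
    ift2c(k)
  }
}

#' Materialize an operator-form system as an explicit matrix
#'
#' Applies the operator to every coordinate basis image; guarded to small
#' grids because the result is dense M x N with N = grid^2.
#'
#' @param system operator-mode sensing system with `grid_size <= 32`.
#' @return explicit-mode `sensing_system` whose `Theta` reproduces the
#'   operator's action on flattened (column-major) images.
#' @export
materialize_system <- function(system) {
  stopifnot(inherits(system, "sensing_system"))
  if (system$mode == "explicit") return(system)
  n <- system$grid_size
  if (n > 32L) stop_resource("materialization is limited to grid_size <= 32")
  Theta <- matrix(0 + 0i, system$M, system$N)
  e <- matrix(0, n, n)
  for (j in seq_len(system$N)) {
    e[j] <- 1
    Theta[, j] <- cs_forward(system, e)
    e[j] <- 0
  }
  sys <- sensing_explicit(Theta)
  sys$materialized_from <- system$mask$dialect
  sys
}
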