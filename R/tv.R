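# Total-variation machinery: the exported seminorm (replicate boundary, the
# usual definition for image metrics) and the periodic difference operators
# used inside the solvers, where circulant structure makes the quadratic
# subproblems diagonal in k-space.

#' Total-variation seminorm of an image
#'
#' Forward differences with replicate (Neumann) boundary handling, so a
#' constant image has TV exactly 0.
#' \itemize{
#'   \item anisotropic: `sum(|dx| + |dy|)`
#'   \item isotropic:   `sum(sqrt(dx^2 + dy^2))`
#' }
#'
#' @param image numeric (or complex) matrix or vector.
#' @param flavor `"isotropic"` (default) or `"anisotropic"`.
#' @return non-negative scalar.
#' @export
tv_seminorm <- function(image, flavor = c("isotropic", "anisotropic")) {
  flavor <- match.arg(flavor)
  m <- as.matrix(image)
  if (!all(is.finite(Mod(m)))) stop_param("image must be finite")
  nr <- nrow(m); nc <- ncol(m)
  dx <- if (nc > 1) m[, c(2:nc, nc), drop = FALSE] - m else m * 0
  dy <- if (nr > 1) m[c(2:nr, nr), , drop = FALSE] - m else m * 0
  if (flavor == "anisotropic") sum(Mod(dx)) + sum(Mod(dy))
  else sum(sqrt(Mod(dx)^2 + Mod(dy)^2))
}

# ---- periodic (circulant) difference operators -----------------------------

shift_idx <- function(n, by) ((seq_len(n) - 1 + by) %% n) + 1
grad_x <- function(m) m[, shift_idx(ncol(m), 1), drop = FALSE] - m
grad_y <- function(m) m[shift_idx(nrow(m), 1), , drop = FALSE] - m
# adjoints (negative divergence): t(D) y
grad_x_adj <- function(y) y[, shift_idx(ncol(y), -1), drop = FALSE] - y
grad_y_adj <- function(y) y[shift_idx(nrow(y), -1), , drop = FALSE] - y

tv_periodic <- function(m, flavor = "isotropic") {
  dx <- grad_x(m); dy <- grad_y(m)
  if (flavor == "anisotropic") sum(Mod(dx)) + sum(Mod(dy))
  else sum(sqrt(Mod(dx)^2 + Mod(dy)^2))
}

# eigenvalues of the periodic Laplacian D1'D1 + D2'D2 on an nr x nc grid,
# arranged to match the centered k-space storage of ft2c(); a size-1 axis
# contributes zero (its periodic difference is identically zero)
laplacian_symbol_centered <- function(nr, nc = nr) {
  wr <- 4 * sin(pi * (0:(nr - 1)) / nr)^2
  wc <- 4 * sin(pi * (0:(nc - 1)) / nc)^2
  fftshift2(outer(wr, wc, `+`))
}

# isotropic/anisotropic shrinkage of a gradient-field pair
shrink_pair <- function(dx, dy, thresh, flavor) {
  if (flavor == "anisotropic") {
    sx <- Mod(dx); sy <- Mod(dy)
    list(x = dx / pmax(sx, 1e-300) * pmax(sx - thresh, 0),
         y = dy / pmax(sy, 1e-300) * pmax(sy - thresh, 0))
  } else {
    s <- sqrt(Mod(dx)^2 + Mod(dy)^2)
    scale <- pmax(s - thresh, 0) / pmax(s, 1e-300)
    list(x = dx * scale, y = dy * scale)
  }
}

# ---- proximal operator of the TV seminorm (Chambolle dual projection) ------

# prox_{tau * TV}(z): projected gradient ascent on the dual gradient field;
# `flavor` selects the dual-ball geometry (per-pixel pair norm for isotropic,
# per-component clamp for anisotropic). Periodic boundary, consistent with
# the solver operators. The primal iterate is u = z - tau * D' p.
prox_tv <- function(z, tau, flavor = "isotropic", iters = 60L) {
  if (tau <= 0) return(z)
  px <- z * 0; py <- z * 0
  step <- 1 / (8 * tau)     # 1/L for the dual gradient (||D D'|| <= 8)
  u <- z
  for (i in seq_len(iters)) {
    u <- z - tau * (grad_x_adj(px) + grad_y_adj(py))
    px_new <- px + step * grad_x(u)
    py_new <- py + step * grad_y(u)
    if (flavor == "anisotropic") {
      px <- px_new / pmax(1, Mod(px_new))
      py <- py_new / pmax(1, Mod(py_new))
    } else {
      nrm <- sqrt(Mod(px_new)^2 + Mod(py_new)^2)
      px <- px_new / pmax(1, nrm)
      py <- py_new / pmax(1, nrm)
    }
  }
  z - tau * (grad_x_adj(px) + grad_y_adj(py))
}

# ---- orthonormal 2D Haar transform -----------------------------------------
# Hand-rolled because the deployment image ships no wavelet package; Haar is
# orthonormal so the L1-wavelet prox is exact soft-thresholding in the
# transform domain. Requires dyadic grid sizes.

haar_step <- function(v) {
  n <- length(v)
  a <- (v[seq(1, n, 2)] + v[seq(2, n, 2)]) / sqrt(2)
  d <- (v[seq(1, n, 2)] - v[seq(2, n, 2)]) / sqrt(2)
  c(a, d)
}
haar_step_inv <- function(v) {
  n <- length(v)
  a <- v[1:(n / 2)]; d <- v[(n / 2 + 1):n]
  out <- v
  out[seq(1, n, 2)] <- (a + d) / sqrt(2)
  out[seq(2, n, 2)] <- (a - d) / sqrt(2)
  out
}

#' Orthonormal 2D Haar wavelet transform
#'
#' Full-depth separable Haar decomposition; exactly orthonormal, so
#' `haar2_inverse(haar2(x))` recovers `x` and energy is conserved.
#'
#' @param x matrix whose side lengths are powers of two.
#' @return coefficient matrix of the same shape.
#' @export
haar2 <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n != ncol(x) || bitwAnd(n, n - 1L) != 0L)
    stop_param("haar2 requires a square dyadic grid")
  len <- n
  while (len > 1) {
    for (j in 1:len) x[1:len, j] <- haar_step(x[1:len, j])
    for (i in 1:len) x[i, 1:len] <- haar_step(x[i, 1:len])
    len <- len / 2
  }
  x
}

#' @rdname haar2
#' @export
haar2_inverse <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  len <- 2
  while (len <= n) {
    for (i in 1:len) x[i, 1:len] <- haar_step_inv(x[i, 1:len])
    for (j in 1:len) x[1:len, j] <- haar_step_inv(x[1:len, j])
    len <- len * 2
  }
  x
}
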