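# Independent oracles. Each deliberately uses a different algorithm/code
# path than the package implementation it checks.

# exhaustive spark by subset rank in increasing size order, using base
# qr()'s rank (package uses svd)
oracle_spark <- function(Theta) {
  M <- nrow(Theta); N <- ncol(Theta)
  for (s in seq_len(min(M + 1L, N))) {
    subs <- utils::combn(N, s)
    for (j in seq_len(ncol(subs))) {
      if (qr(Theta[, subs[, j], drop = FALSE])$rank < s) return(s)
    }
  }
  "full"
}

# brute-force double-loop TV with replicate boundary
oracle_tv <- function(img, flavor) {
  nr <- nrow(img); nc <- ncol(img)
  tot <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    dx <- if (j < nc) img[i, j + 1] - img[i, j] else 0
    dy <- if (i < nr) img[i + 1, j] - img[i, j] else 0
    tot <- tot + if (flavor == "anisotropic") abs(dx) + abs(dy) else sqrt(dx^2 + dy^2)
  }
  tot
}

pinv <- function(A, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d)
  sv$v[, keep, drop = FALSE] %*% (t(Conj(sv$u[, keep, drop = FALSE])) / sv$d[keep])
}

# KKT oracle for min ||D x||^2 s.t. Theta x = B (real systems), via the
# stationarity system [2 D'D, Theta'; Theta, 0] [x; nu] = [0; B]
oracle_kkt_l2 <- function(Theta, B, D) {
  N <- ncol(Theta); M <- nrow(Theta)
  K <- rbind(cbind(2 * crossprod(D), t(Theta)),
             cbind(Theta, matrix(0, M, M)))
  rhs <- c(rep(0, N), B)
  sol <- pinv(K) %*% rhs
  as.vector(Re(sol[seq_len(N)]))
}

# Chambolle-Pock primal-dual oracle for min ||D x||_1 s.t. A x = b on
# explicit real matrices (complex rows split into real/imaginary parts).
# Completely independent of the package's FFT split-Bregman route.
oracle_pdhg_tv <- function(A_complex, b_complex, D, iters = 30000L) {
  A <- rbind(Re(A_complex), Im(A_complex))
  b <- c(Re(b_complex), Im(b_complex))
  N <- ncol(A)
  # projection onto {x: Ax = b}
  Ap <- pinv(A)
  proj <- function(x) x - as.vector(Ap %*% (A %*% x - b))
  Lk <- svd(D, nu = 0, nv = 0)$d[1]
  sigma <- 1 / Lk; tau <- 1 / Lk
  x <- proj(rep(0, N)); xbar <- x
  y <- rep(0, nrow(D))
  for (i in seq_len(iters)) {
    y <- pmin(pmax(y + sigma * as.vector(D %*% xbar), -1), 1)
    x_new <- proj(x - tau * as.vector(t(D) %*% y))
    xbar <- 2 * x_new - x
    x <- x_new
  }
  x
}

# dense 1D periodic difference matrix (n x n)
oracle_diff1d <- function(n) {
  Dm <- matrix(0, n, n)
  for (i in seq_len(n)) {
    Dm[i, i] <- -1
    Dm[i, if (i < n) i + 1 else 1] <- Dm[i, if (i < n) i + 1 else 1] + 1
  }
  Dm
}

# materialize the centered unitary Fourier + mask operator row by row using
# only ft2c (used against cs_forward/materialize_system)
oracle_materialize <- function(mask) {
  nr <- nrow(mask$grid); nc <- ncol(mask$grid)
  M <- sum(mask$grid)
  Theta <- matrix(0 + 0i, M, nr * nc)
  e <- matrix(0, nr, nc)
  for (j in seq_len(nr * nc)) {
    e[j] <- 1
    Theta[, j] <- ft2c(e)[mask$grid]
    e[j] <- 0
  }
  Theta
}

rand_system <- function(M, N, seed) {
  set.seed(seed)
  matrix(stats::rnorm(M * N), M, N)
}
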