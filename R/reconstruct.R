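# Reconstruction solvers for undersampled Fourier data.
#
# Two routes, matching the two program forms:
#  * reconstruct_l1_tv / reconstruct_l2 solve the constrained programs
#    (minimize variation subject to data consistency) — the L1 route by
#    split-Bregman/augmented-Lagrangian iterations whose quadratic step is
#    diagonal in k-space, the L2 route by a closed form.
#  * reconstruct_lagrangian solves the penalized form
#    (1/2)||EA - C||^2 + sum_i eta_i phi_i(A) by monotone proximal-gradient
#    iterations supporting several simultaneous sparsity terms.

#' Solver configuration
#'
#' @param max_iterations iteration budget (>= 1).
#' @param tolerance relative-change stopping tolerance (> 0); also sets the
#'   data-consistency target `max(lambda, tolerance * ||C||)` for the
#'   constrained solver.
#' @param step_size_rule `"fixed"` (1/L) or `"backtracking"`.
#' @param seed integer (initialization bookkeeping; solvers are
#'   deterministic from the zero-filled start).
#' @return object of class `solver_config`.
#' @export
solver_config <- function(max_iterations = 2000L, tolerance = 1e-6,
                          step_size_rule = c("fixed", "backtracking"),
                          seed = 1L) {
  step_size_rule <- match.arg(step_size_rule)
  max_iterations <- as.integer(max_iterations)
  if (max_iterations < 1L) stop_param("max_iterations must be >= 1")
  if (!is.finite(tolerance) || tolerance <= 0) stop_param("tolerance must be > 0")
  structure(list(max_iterations = max_iterations, tolerance = tolerance,
                 step_size_rule = step_size_rule, seed = as.integer(seed)),
            class = "solver_config")
}

#' Regularizer specification for the penalized (Lagrangian) solver
#'
#' Supported sparse constraint terms and their weights `eta_i`:
#' `tv` (total variation, isotropic by default), `l1-identity`
#' (entrywise L1 on the image), `l1-wavelet` (L1 of orthonormal Haar
#' coefficients), `l2-tv` (quadratic gradient energy, smooth).
#'
#' @param ... named weights, e.g. `regularizer_spec(tv = 1e-2)` or
#'   `regularizer_spec("l1-wavelet" = 5e-3, "l2-tv" = 1e-3)`.
#' @param tv_flavor `"isotropic"` or `"anisotropic"` for the `tv` term.
#' @return object of class `regularizer_spec`.
#' @export
regularizer_spec <- function(..., tv_flavor = c("isotropic", "anisotropic")) {
  tv_flavor <- match.arg(tv_flavor)
  w <- list(...)
  if (length(w) == 0) stop_param("at least one regularizer term is required")
  kinds <- names(w)
  ok <- c("tv", "l1-identity", "l1-wavelet", "l2-tv")
  if (is.null(kinds) || any(!kinds %in% ok))
    stop_param(paste("regularizer kinds must be among:", paste(ok, collapse = ", ")))
  weights <- vapply(w, as.numeric, numeric(1))
  if (any(!is.finite(weights) | weights <= 0))
    stop_param("all regularizer weights must be finite and > 0")
  structure(list(terms = Map(function(k, e) list(kind = k, weight = e), kinds, weights),
                 tv_flavor = tv_flavor),
            class = "regularizer_spec")
}

new_recon_result <- function(image, trace, residual, iters, converged, method,
                             lambda = NA_real_, wall = NA_real_) {
  structure(list(image = image, objective_trace = trace, data_residual = residual,
                 iterations_run = iters, converged = converged, method = method,
                 lambda = lambda, wall_time_seconds = wall),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf("<recon_result> method=%s iters=%d residual=%.3e converged=%s\n",
              x$method, x$iterations_run, x$data_residual, x$converged))
  invisible(x)
}

# residual ||E A - C||_2 for an acquisition and a candidate image
data_residual_op <- function(acq, A) {
  k <- ft2c(A)
  idx <- which(acq$mask$grid)
  sqrt(sum(Mod(k[idx] - acq$kspace_observed[idx])^2))
}

#' Minimum-variation L2 reconstruction
#'
#' Solves `min ||D A||_2^2  s.t.  E A = C` (D = periodic finite
#' differences). On a masked unitary Fourier system the quadratic form is
#' diagonal in k-space, so every unsampled coefficient minimizes at zero and
#' the solution is exactly the zero-filled reconstruction (the DC tie, when
#' unsampled, is broken at zero). This is the closed form of the vanishing
#' data-penalty limit and explains why pure L2 recovery shows aliasing: no
#' energy is ever assigned to unmeasured frequencies.
#'
#' @param acquisition an [simulate_acquisition()] bundle.
#' @return a `recon_result`; `image` is the real part of the zero-filled
#'   inverse transform.
#' @export
reconstruct_l2 <- function(acquisition) {
  stopifnot(inherits(acquisition, "acquisition"))
  if (!any(acquisition$mask$grid)) stop_param("empty mask: system is fully under-determined")
  t0 <- proc.time()[["elapsed"]]
  A <- ift2c(acquisition$kspace_observed)
  res <- data_residual_op(acquisition, A)
  obj <- sum(Mod(grad_x(A))^2 + Mod(grad_y(A))^2)
  new_recon_result(Re(A), trace = obj, residual = res, iters = 1L,
                   converged = TRUE, method = "l2",
                   wall = proc.time()[["elapsed"]] - t0)
}

#' Zero-filled reconstruction
#'
#' Inverse transform with unsampled k-space entries at zero; numerically
#' identical to [reconstruct_l2()] on operator-form systems, kept as its own
#' method name for pipelines.
#' @param acquisition an acquisition bundle.
#' @return a `recon_result`.
#' @export
reconstruct_zero_fill <- function(acquisition) {
  out <- reconstruct_l2(acquisition)
  out$method <- "zero-fill"
  out
}

# dense periodic difference matrix (2N x N) for an nr x nc grid,
# column-major flattening; used by the explicit-mode L2 solver
diff_matrix <- function(nr, nc) {
  N <- nr * nc
  idx <- matrix(seq_len(N), nr, nc)
  Dx <- matrix(0, N, N); Dy <- matrix(0, N, N)
  right <- idx[, c(2:nc, 1)]
  down <- idx[c(2:nr, 1), ]
  for (j in seq_len(N)) {
    Dx[j, right[j]] <- Dx[j, right[j]] + 1; Dx[j, j] <- Dx[j, j] - 1
    Dy[j, down[j]]  <- Dy[j, down[j]] + 1;  Dy[j, j] <- Dy[j, j] - 1
  }
  rbind(Dx, Dy)
}

#' Minimum-variation L2 reconstruction for explicit systems
#'
#' Equality-constrained quadratic minimization
#' `min ||D x||^2 s.t. Theta x = B`, solved by null-space parametrization
#' (particular least-squares solution plus a least-squares fit over the null
#' basis). Small systems only.
#'
#' @param system explicit-mode [sensing_explicit()] system.
#' @param B measurement vector. @param grid `c(nr, nc)` image shape with
#'   `nr * nc == N`, used to build the difference operator.
#' @return list with `x` (length-N solution) and `objective`.
#' @export
reconstruct_l2_explicit <- function(system, B, grid) {
  stopifnot(inherits(system, "sensing_system"), system$mode == "explicit")
  if (prod(grid) != system$N) stop_dim("grid does not match N")
  Theta <- system$Theta
  D <- diff_matrix(grid[1], grid[2])
  x0 <- ls_solve(Theta, B)
  sv <- svd(Theta, nv = system$N)
  tolr <- 1e-10 * max(sv$d)
  nullcols <- which(c(sv$d, rep(0, system$N - length(sv$d))) <= tolr)
  if (length(nullcols) > 0) {
    Z <- sv$v[, nullcols, drop = FALSE]
    c0 <- ls_solve(D %*% Z, -(D %*% x0))
    x <- x0 + as.vector(Z %*% c0)
  } else x <- x0
  list(x = x, objective = sum(Mod(D %*% x)^2))
}

#' L1 total-variation reconstruction (split Bregman)
#'
#' Solves the TV-regularized recovery `min TV(A)  s.t.  ||E A - C||_2 <=
#' lambda` (`lambda = 0` targets equality up to the solver tolerance) by the
#' split-Bregman scheme: the TV term is decoupled through an auxiliary
#' gradient field with shrinkage updates, the quadratic image update is
#' solved exactly in k-space (the operator is diagonal there), and
#' augmented-Lagrangian/Bregman updates of the data term drive the residual
#' below the target `max(lambda, tolerance * ||C||)`. Initialization is the
#' zero-filled image; the run is deterministic given the configuration.
#'
#' @param acquisition acquisition bundle.
#' @param lambda noise pollution level: the residual the constraint is
#'   allowed to retain (>= 0).
#' @param config a [solver_config()].
#' @param flavor TV flavor for the shrinkage step.
#' @param eta internal TV weight of the penalized objective recorded in the
#'   trace (does not change the constrained solution, only the path).
#' @param real_image if `TRUE` (default) the solve is restricted to
#'   real-valued images by projection each iteration. MR magnitude truth is
#'   real, and over the complex field the isotropic-TV minimizer can
#'   genuinely undercut the true image's TV by storing structure in the
#'   phase; the real restriction removes that freedom. Set `FALSE` to
#'   reconstruct a complex image.
#' @return a `recon_result`; `converged = FALSE` flags a run that hit
#'   `max_iterations` before meeting the residual target (returned, not
#'   raised).
#' @export
reconstruct_l1_tv <- function(acquisition, lambda = 0, config = solver_config(),
                              flavor = c("isotropic", "anisotropic"), eta = 0.05,
                              real_image = TRUE) {
  stopifnot(inherits(acquisition, "acquisition"))
  flavor <- match.arg(flavor)
  if (lambda < 0) stop_param("lambda must be >= 0")
  if (!any(acquisition$mask$grid)) stop_param("empty mask: system is fully under-determined")
  t0 <- proc.time()[["elapsed"]]
  maskc <- acquisition$mask$grid
  nr <- nrow(maskc); nc <- ncol(maskc)
  idx <- which(maskc)
  C <- acquisition$kspace_observed[idx]
  normC <- sqrt(sum(Mod(C)^2))
  target <- max(lambda, config$tolerance * normC)
  # drive the residual to a slightly tighter level than the user-facing
  # constraint so the returned iterate satisfies it strictly (discrepancy
  # principle with partial Bregman add-back, no freeze/unfreeze cycling)
  drive <- if (lambda > 0) max(0.98 * lambda, 0.5 * config$tolerance * normC)
           else 0.5 * config$tolerance * normC

  mu <- 1; beta <- 1
  w <- laplacian_symbol_centered(nr, nc)
  denom <- mu * maskc + beta * w
  zero_denom <- denom == 0

  # warm start: zero-filled image and matching gradient field
  Kc <- matrix(0 + 0i, nr, nc); Kc[idx] <- C
  A <- ift2c(Kc)
  dx <- grad_x(A); dy <- grad_y(A)
  bx <- dx * 0; by <- dy * 0
  Ck <- C
  trace <- numeric(0)
  converged <- FALSE
  res <- Inf
  iters <- 0L
  for (it in seq_len(config$max_iterations)) {
    iters <- it
    A_old <- A
    # A-update: (mu E'E + beta D'D) A = mu E' Ck + beta D'(d - b)
    rhs_img <- grad_x_adj(dx - bx) + grad_y_adj(dy - by)
    Kck <- matrix(0 + 0i, nr, nc); Kck[idx] <- Ck
    num <- mu * Kck + beta * ft2c(rhs_img)
    Ah <- num / denom
    Ah[zero_denom] <- 0
    A <- ift2c(Ah)
    if (real_image) A <- Re(A)
    # d-update (shrinkage) and Bregman variable
    gx <- grad_x(A); gy <- grad_y(A)
    sh <- shrink_pair(gx + bx, gy + by, eta / beta, flavor)
    dx <- sh$x; dy <- sh$y
    bx <- bx + gx - dx
    by <- by + gy - dy
    # data Bregman add-back, frozen once the residual target is met
    EA <- ft2c(A)[idx]
    res <- sqrt(sum(Mod(EA - C)^2))
    if (res > drive) Ck <- Ck + (1 - drive / max(res, 1e-300)) * (C - EA)
    trace <- c(trace, 0.5 * res^2 + eta * tv_periodic(A, flavor))
    relchg <- sqrt(sum(Mod(A - A_old)^2)) / max(sqrt(sum(Mod(A)^2)), 1e-300)
    # splitting gap ||DA - d||: exactly zero at the ADMM fixed point, so it
    # guards against stopping before the shrinkage has acted
    gap <- sqrt(sum(Mod(gx - dx)^2 + Mod(gy - dy)^2)) /
      max(sqrt(sum(Mod(gx)^2 + Mod(gy)^2)), 1e-300)
    if (res <= target && relchg <= config$tolerance &&
        gap <= max(config$tolerance, 1e-6)) { converged <- TRUE; break }
  }
  new_recon_result(Re(A), trace = trace, residual = res, iters = iters,
                   converged = converged, method = "l1tv", lambda = lambda,
                   wall = proc.time()[["elapsed"]] - t0)
}

# internal penalized objective for the Lagrangian solver (periodic TV so the
# traced objective matches what the proximal steps minimize)
lagrangian_phi <- function(A, term, tv_flavor, is_image) {
  switch(term$kind,
    "tv" = tv_periodic(A, tv_flavor),
    "l1-identity" = sum(Mod(A)),
    "l1-wavelet" = sum(Mod(haar2(Re(A))) ) + if (is.complex(A)) sum(Mod(haar2(Im(A)))) else 0,
    "l2-tv" = 0.5 * sum(Mod(grad_x(as.matrix(A)))^2 + Mod(grad_y(as.matrix(A)))^2))
}

soft_threshold <- function(z, t) z / pmax(Mod(z), 1e-300) * pmax(Mod(z) - t, 0)

#' Penalized (Lagrangian) reconstruction with multiple sparsity terms
#'
#' Minimizes `(1/2) ||E A - C||_2^2 + sum_i eta_i phi_i(A)` by monotone
#' proximal-gradient iterations: a gradient step on the smooth part (data
#' term plus any `l2-tv` term) followed by proximal steps for each
#' nonsmooth term, with a descent check that never accepts an
#' objective increase, so the objective trace is non-increasing after the
#' first iteration by construction. Supports simultaneous terms, reflecting
#' that MR images are sparse in several structures at once; with more than
#' one nonsmooth term the composite prox is applied sequentially (an
#' approximation, guarded by the descent check).
#'
#' @param problem an acquisition bundle (operator mode) or a list
#'   `list(system = <explicit sensing_system>, B = <measurement vector>,
#'   grid = c(nr, nc))` for explicit mode.
#' @param regularizers a [regularizer_spec()].
#' @param config a [solver_config()].
#' @return a `recon_result` (`image` is a matrix in operator mode, a
#'   length-N vector in explicit mode).
#' @export
reconstruct_lagrangian <- function(problem, regularizers, config = solver_config()) {
  stopifnot(inherits(regularizers, "regularizer_spec"))
  t0 <- proc.time()[["elapsed"]]
  is_op <- inherits(problem, "acquisition")
  if (is_op) {
    idx <- which(problem$mask$grid)
    C <- problem$kspace_observed[idx]
    nr <- nrow(problem$mask$grid); nc <- ncol(problem$mask$grid)
    fwd <- function(A) ft2c(A)[idx]
    adj <- function(y) { K <- matrix(0 + 0i, nr, nc); K[idx] <- y; ift2c(K) }
    A <- adj(C)
    L <- 1                                   # ||E'E|| = 1 (projection)
    reshape <- function(A) as.matrix(A)
  } else {
    system <- problem$system; C <- as.vector(problem$B)
    stopifnot(inherits(system, "sensing_system"), system$mode == "explicit")
    Theta <- system$Theta
    grid <- problem$grid %||% c(system$N, 1L)
    fwd <- function(A) as.vector(Theta %*% as.vector(A))
    adj <- function(y) matrix(as.vector(Conj(t(Theta)) %*% y), grid[1], grid[2])
    A <- adj(C)
    L <- max(svd(Theta, nu = 0, nv = 0)$d)^2
    reshape <- function(A) matrix(A, grid[1], grid[2])
  }
  terms <- regularizers$terms
  smooth_terms <- Filter(function(t) t$kind == "l2-tv", terms)
  prox_terms <- Filter(function(t) t$kind != "l2-tv", terms)
  for (tm in smooth_terms) L <- L + 8 * tm$weight
  step <- 1 / L
  objective <- function(A) {
    r <- fwd(A) - C
    val <- 0.5 * sum(Mod(r)^2)
    for (tm in terms) val <- val + tm$weight * lagrangian_phi(reshape(A), tm, regularizers$tv_flavor, is_op)
    val
  }
  apply_prox <- function(Z) {
    for (tm in prox_terms) {
      Z <- switch(tm$kind,
        "tv" = prox_tv(Z, step * tm$weight, regularizers$tv_flavor),
        "l1-identity" = soft_threshold(Z, step * tm$weight),
        "l1-wavelet" = {
          if (is.complex(Z))
            haar2_inverse(soft_threshold(haar2(Re(Z)), step * tm$weight)) +
              1i * haar2_inverse(soft_threshold(haar2(Im(Z)), step * tm$weight))
          else haar2_inverse(soft_threshold(haar2(Z), step * tm$weight))
        })
    }
    Z
  }
  obj <- objective(A)
  trace <- numeric(0)
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(config$max_iterations)) {
    iters <- it
    g <- adj(fwd(A) - C)
    for (tm in smooth_terms) {
      Am <- reshape(A)
      g <- g + tm$weight * reshape(grad_x_adj(grad_x(Am)) + grad_y_adj(grad_y(Am)))
    }
    cand <- apply_prox(A - step * g)
    obj_cand <- objective(cand)
    if (obj_cand <= obj + 1e-12) {          # monotone acceptance
      relchg <- sqrt(sum(Mod(cand - A)^2)) / max(sqrt(sum(Mod(A)^2)), 1e-300)
      A <- cand; obj <- obj_cand
      trace <- c(trace, obj)
      if (relchg <= config$tolerance) { converged <- TRUE; break }
    } else {                                 # reject: keep iterate, stop
      trace <- c(trace, obj)
      converged <- TRUE
      break
    }
  }
  resid <- sqrt(sum(Mod(fwd(A) - C)^2))
  img <- if (is_op) Re(as.matrix(A)) else {
    v <- as.vector(A); if (is.complex(C) || is.complex(A)) v else Re(v)
  }
  new_recon_result(img, trace = trace, residual = resid, iters = iters,
                   converged = converged, method = "lagrangian",
                   wall = proc.time()[["elapsed"]] - t0)
}

#' Basis pursuit on an explicit system
#'
#' `min ||x||_1  s.t.  Theta x = B` by ADMM alternating soft-thresholding
#' with projection onto the affine constraint set. Used to document the
#' L1/L0 relationship against [l0_decode()].
#'
#' @param Theta explicit matrix (rows linearly independent).
#' @param B measurement vector. @param iters ADMM iterations. @param rho
#'   ADMM penalty.
#' @return length-N solution vector.
#' @export
basis_pursuit <- function(Theta, B, iters = 2000L, rho = 1) {
  Theta <- as.matrix(Theta); B <- as.vector(B)
  sv <- svd(Theta)
  keep <- sv$d > 1e-12 * max(sv$d)
  U <- sv$u[, keep, drop = FALSE]; V <- sv$v[, keep, drop = FALSE]; d <- sv$d[keep]
  # projection onto {x : Theta x = B}
  proj <- function(v) {
    r <- as.vector(Theta %*% v) - B
    v - as.vector(V %*% ((Conj(t(U)) %*% r) / d))
  }
  N <- ncol(Theta)
  z <- proj(rep(if (is.complex(Theta) || is.complex(B)) 0 + 0i else 0, N))
  x <- z; u <- z * 0
  for (i in seq_len(iters)) {
    x <- soft_threshold(z - u, 1 / rho)
    z <- proj(x + u)
    u <- u + x - z
  }
  x
}

#' Reconstruction quality metrics
#'
#' @param reference ground-truth image.
#' @param reconstruction recovered image of the same shape.
#' @return list with `psnr` (dB, `Inf` for an exact match; peak = reference
#'   dynamic range), `ssim` (mean structural similarity, 11x11 Gaussian
#'   window, sigma 1.5, K1 = 0.01, K2 = 0.03), `relative_l2`
#'   (`||rec - ref|| / ||ref||`).
#' @export
evaluate_reconstruction <- function(reference, reconstruction) {
  ref <- as.matrix(reference); rec <- as.matrix(reconstruction)
  if (!all(dim(ref) == dim(rec))) stop_dim("reference and reconstruction differ in shape")
  err <- rec - ref
  rel <- sqrt(sum(err^2)) / sqrt(sum(ref^2))
  peak <- diff(range(ref))
  if (peak == 0) stop_param("reference must be nonconstant")
  mse <- mean(err^2)
  psnr <- if (mse == 0) Inf else 20 * log10(peak) - 10 * log10(mse)
  list(psnr = psnr, ssim = ssim_index(ref, rec, L = peak), relative_l2 = rel)
}

# separable Gaussian smoothing matrix with reflect boundary
gauss_smoother_matrix <- function(n, size = 11L, sigma = 1.5) {
  half <- size %/% 2
  g <- exp(-((-half):half)^2 / (2 * sigma^2)); g <- g / sum(g)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (k in (-half):half) {
      j <- i + k
      if (j < 1) j <- 1 - j              # symmetric (reflect) boundary
      if (j > n) j <- 2 * n + 1 - j
      j <- min(max(j, 1), n)
      G[i, j] <- G[i, j] + g[k + half + 1]
    }
  }
  G
}

ssim_index <- function(x, y, L, K1 = 0.01, K2 = 0.03) {
  n1 <- nrow(x); n2 <- ncol(x)
  G1 <- gauss_smoother_matrix(n1); G2 <- gauss_smoother_matrix(n2)
  sm <- function(m) G1 %*% m %*% t(G2)
  mx <- sm(x); my <- sm(y)
  sxx <- sm(x * x) - mx^2; syy <- sm(y * y) - my^2; sxy <- sm(x * y) - mx * my
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  smap <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
    ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(smap)
}
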