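# Uniqueness theory for k-sparse recovery on small explicit systems.
#
# The spark of Theta (smallest number of linearly dependent columns) governs
# uniqueness: if spark(Theta) > 2k, a k-sparse solution of B = Theta A is
# unique, because the difference of two k-sparse solutions is a <=2k-sparse
# null-space vector and no such nonzero vector exists. All computations here
# are exhaustive and guarded to small N; spark is NP-hard in general.

# svd-based least squares; works uniformly for real and complex matrices
# (base qr() does not accept complex input)
ls_solve <- function(A, b, rel_tol = 1e-12) {
  sv <- svd(A)
  d <- sv$d
  keep <- d > rel_tol * max(d, 0)
  if (!any(keep)) return(rep(if (is.complex(A)) 0 + 0i else 0, ncol(A)))
  ub <- Conj(t(sv$u[, keep, drop = FALSE])) %*% b
  as.vector(sv$v[, keep, drop = FALSE] %*% (ub / d[keep]))
}

# rank of a (possibly complex) matrix at a relative singular-value tolerance
rank_tol <- function(A, rel_tol = 1e-10) {
  s <- svd(A, nu = 0, nv = 0)$d
  if (length(s) == 0 || s[1] == 0) return(0L)
  sum(s > rel_tol * s[1])
}

#' Spark of an explicit matrix
#'
#' Smallest subset size `s` such that some `s` columns are linearly
#' dependent (rank < s at a relative singular-value tolerance of 1e-10).
#' For an M x N matrix with N > M the spark is at most M + 1. If every
#' subset that exists (up to `min(M + 1, N)` columns) is independent, the
#' sentinel `"full"` is returned rather than an invented number.
#'
#' @param Theta explicit matrix with at most 16 columns (exhaustive search).
#' @param max_size optional cap on the subset size searched; if the search
#'   is capped and finds no dependent subset, `"full"` here only certifies
#'   spark > `max_size`.
#' @return integer subset size, or the character sentinel `"full"`.
#' @export
spark <- function(Theta, max_size = NULL) {
  Theta <- as.matrix(Theta)
  if (!all(is.finite(Mod(Theta)))) stop_param("matrix must be finite")
  M <- nrow(Theta); N <- ncol(Theta)
  if (N > 16L) stop_resource("spark() is exhaustive; N <= 16 required")
  smax <- min(M + 1L, N)
  if (!is.null(max_size)) smax <- min(smax, as.integer(max_size))
  # a zero column is a dependent "subset" of size 1
  for (s in seq_len(smax)) {
    subsets <- utils::combn(N, s)
    for (j in seq_len(ncol(subsets))) {
      if (rank_tol(Theta[, subsets[, j], drop = FALSE]) < s) return(s)
    }
  }
  "full"
}

# TRUE iff a spark value (integer or "full") exceeds threshold
spark_exceeds <- function(spark_value, threshold) {
  identical(spark_value, "full") || spark_value > threshold
}

#' Certify uniqueness of k-sparse solutions
#'
#' A k-sparse solution of `B = Theta A` is unique iff `spark(Theta) > 2k`.
#' Only subsets up to size `2k` are enumerated, so certification stays
#' tractable even when the full spark would be expensive. When uniqueness
#' fails, a witness pair of distinct at-most-k-sparse vectors with equal
#' measurements is constructed by splitting a null-space vector supported on
#' the smallest dependent subset into two halves.
#'
#' @param Theta explicit matrix (N <= 16). @param k target sparsity, >= 0.
#' @return object of class `uniqueness_certificate`: `spark_value` (exact
#'   spark if <= 2k, otherwise `"full"` meaning "> 2k"), `k`, `unique`,
#'   `witness` (list of `a1`, `a2` or `NULL`), `tolerances`.
#' @export
certify_uniqueness <- function(Theta, k) {
  Theta <- as.matrix(Theta)
  k <- as.integer(k)
  if (k < 0) stop_param("k must be >= 0")
  sp <- spark(Theta, max_size = 2L * k)
  unique <- spark_exceeds(sp, 2L * k)
  witness <- NULL
  if (!unique) {
    s <- sp
    # null vector supported on a smallest dependent subset
    subsets <- utils::combn(ncol(Theta), s)
    v <- NULL; supp <- NULL
    for (j in seq_len(ncol(subsets))) {
      S <- subsets[, j]
      sub <- Theta[, S, drop = FALSE]
      sv <- svd(sub)
      if (sv$d[length(sv$d)] <= 1e-10 * sv$d[1]) {
        vi <- sv$v[, ncol(sv$v)]
        supp <- S; v <- vi / sqrt(sum(Mod(vi)^2))
        break
      }
    }
    half <- ceiling(s / 2)
    a1 <- a2 <- rep(if (is.complex(Theta)) 0 + 0i else 0, ncol(Theta))
    a1[supp[seq_len(half)]] <- v[seq_len(half)]
    if (half < s) a2[supp[(half + 1):s]] <- -v[(half + 1):s]
    # a1 - a2 = null vector on supp  =>  Theta a1 = Theta a2
    witness <- list(a1 = a1, a2 = a2)
  }
  structure(list(spark_value = sp, k = k, unique = unique, witness = witness,
                 tolerances = list(rank_rel_tol = 1e-10, witness_tol = 1e-8)),
            class = "uniqueness_certificate")
}

#' @export
print.uniqueness_certificate <- function(x, ...) {
  cat(sprintf("<uniqueness_certificate> spark=%s k=%d unique=%s witness=%s\n",
              as.character(x$spark_value), x$k, x$unique,
              if (is.null(x$witness)) "none" else "yes"))
  invisible(x)
}

#' Exhaustive L0 decoding
#'
#' Searches supports of size 0, 1, ..., `k_max` in increasing order,
#' least-squares fits each support, and returns the sparsest solution whose
#' residual is at most `1e-8 * ||B||`. Ties at equal sparsity are broken by
#' smallest residual, then by lexicographic support order.
#'
#' @param B measurement vector. @param Theta explicit matrix (N <= 16).
#' @param k_max largest support size to try.
#' @return list with `values` (length-N solution or `NULL`), `k` (achieved
#'   sparsity or `NA`), `residual`, `found` (FALSE means no support met the
#'   residual bound — a no-solution signal, not a solver error).
#' @export
l0_decode <- function(B, Theta, k_max) {
  Theta <- as.matrix(Theta)
  B <- as.vector(B)
  N <- ncol(Theta)
  if (N > 16L) stop_resource("l0_decode is exhaustive; N <= 16 required")
  if (k_max > N) stop_param("k_max must be <= N")
  if (length(B) != nrow(Theta)) stop_dim("B must have length M")
  nb <- sqrt(sum(Mod(B)^2))
  bound <- 1e-8 * nb
  zero <- rep(if (is.complex(Theta) || is.complex(B)) 0 + 0i else 0, N)
  if (nb <= bound) return(list(values = zero, k = 0L, residual = nb, found = TRUE))
  for (k in seq_len(k_max)) {
    best <- NULL
    subsets <- utils::combn(N, k)
    for (j in seq_len(ncol(subsets))) {
      S <- subsets[, j]
      sub <- Theta[, S, drop = FALSE]
      coef <- ls_solve(sub, B)
      res <- sqrt(sum(Mod(sub %*% coef - B)^2))
      if (is.null(best) || res < best$res - 1e-15) best <- list(S = S, coef = coef, res = res)
    }
    if (!is.null(best) && best$res <= bound) {
      x <- zero
      x[best$S] <- best$coef
      return(list(values = x, k = k, residual = best$res, found = TRUE))
    }
  }
  list(values = NULL, k = NA_integer_, residual = NA_real_, found = FALSE)
}

#' Count the nonzero entries of a signal
#' @param x numeric or complex vector. @param tol zero tolerance (default 1e-12).
#' @return integer sparsity.
#' @export
sparsity <- function(x, tol = 1e-12) sum(Mod(x) > tol)
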