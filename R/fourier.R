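# Centered unitary 2D Fourier transforms.
#
# Convention (documented because mask dialects depend on it): image index
# (1,1) is the top-left pixel; k-space is stored with the zero frequency at
# the grid center, index (floor(n/2)+1, floor(n/2)+1). Transforms are
# unitary, so Parseval/adjoint identities hold exactly (up to float error).

# Circularly shift a matrix by (r, c).
circshift2 <- function(m, r, c) {
  n1 <- nrow(m); n2 <- ncol(m)
  m[((seq_len(n1) - 1 - r) %% n1) + 1, ((seq_len(n2) - 1 - c) %% n2) + 1, drop = FALSE]
}

fftshift2 <- function(m) circshift2(m, nrow(m) %/% 2, ncol(m) %/% 2)
ifftshift2 <- function(m) circshift2(m, -(nrow(m) %/% 2), -(ncol(m) %/% 2))

#' Centered unitary 2D FFT
#'
#' Forward transform from image space to k-space with the zero-frequency
#' coefficient at the grid center. Unitary scaling (`1/sqrt(N)`), so
#' `sum(Mod(ft2c(x))^2) == sum(Mod(x)^2)`.
#'
#' @param x numeric or complex matrix.
#' @return complex matrix of the same shape.
#' @export
ft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(as.matrix(x)))) / sqrt(length(x))
}

#' Centered unitary inverse 2D FFT
#'
#' Exact inverse of [ft2c()].
#'
#' @param k complex matrix with centered zero frequency.
#' @return complex matrix of the same shape.
#' @export
ift2c <- function(k) {
  fftshift2(stats::fft(ifftshift2(as.matrix(k)), inverse = TRUE)) / sqrt(length(k))
}
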