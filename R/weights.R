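#' Coherence factor of an aperture vector
#'
#' `W_CF = |sum_n x_n|^2 / (N * sum_n |x_n|^2)`: 1 for perfectly coherent
#' entries, 0 for completely misaligned ones.  An all-zero vector returns 0.
#'
#' @param x aperture vector (real or complex).
#' @return scalar in \[0, 1\].
#' @export
coherence_factor <- function(x) {
  den <- sum(Mod(x)^2)
  if (den == 0) return(0)
  min(1, Mod(sum(x))^2 / (length(x) * den))
}

#' Generalized coherence factor
#'
#' Ratio of the spectral energy of the aperture vector in the low-spatial-
#' frequency region `k in [-M0, M0]` to its total energy, via the unitary
#' DFT over the aperture.  An all-zero vector returns 0.
#'
#' @param x aperture vector (length N).
#' @param M0 cutoff frequency, 0 <= M0 <= N/2.
#' @return scalar in \[0, 1\].
#' @export
generalized_cf <- function(x, M0) {
  N <- length(x)
  if (M0 < 0 || M0 > N / 2) stop("need 0 <= M0 <= N/2")
  s2 <- Mod(fft(x))^2 / N
  den <- sum(s2)
  if (den == 0) return(0)
  ks <- unique(((-M0):M0) %% N) + 1L
  min(1, sum(s2[ks]) / den)
}

#' Amplitude standard deviation (ASD) of an aperture vector
#'
#' Population standard deviation of the entries about their mean,
#' `sigma = sqrt((1/N) sum_n |x_n - xbar|^2)`; complex deviations enter
#' through their squared modulus, which reduces to the plain formula for
#' real data.
#'
#' @param x aperture vector, length >= 2.
#' @return nonnegative scalar.
#' @export
aperture_asd <- function(x) {
  if (length(x) < 2L) stop("aperture vector must have length >= 2")
  sqrt(mean(Mod(x - mean(x))^2))
}

#' Image-wide normalization of ASD reciprocals
#'
#' Two-pass operation over the whole sigma map: `t = sigma^(-exponent)` per
#' pixel (sigma clamped below at `1e-12 * max(sigma)`), then
#' `sigma' = t / max(t)`, so `sigma'` lies in (0, 1\] with image maximum 1
#' and ordering reverse to sigma.
#'
#' @param sigma per-pixel ASD values (any shape; at least one > 0).
#' @param exponent reciprocal exponent (default 1/3).
#' @return sigma-prime map of the same shape.
#' @export
normalize_asd <- function(sigma, exponent = 1 / 3) {
  mx <- max(sigma)
  if (!is.finite(mx) || mx <= 0) stop("degenerate image: all ASD values zero")
  t <- pmax(sigma, 1e-12 * mx)^(-exponent)
  t / max(t)
}

#' Dynamic subarray length
#'
#' `L' = floor(sigma' * L_max)`, clamped below at 2 to keep a matrix form.
#'
#' @param sigma_prime normalized reciprocal ASD, in (0, 1\].
#' @param L_max maximum subarray length.
#' @return integer subarray length(s) in \[2, L_max\].
#' @export
dynamic_subarray_length <- function(sigma_prime, L_max) {
  pmax(2L, as.integer(floor(sigma_prime * L_max)))
}

#' Spatial-only smoothed covariance at dynamic subarray length
#'
#' `R = (1/(N-L'+1)) sum_l x_l x_l^H` over the N-L'+1 sliding subarrays of
#' the single center aperture vector (no temporal term).
#'
#' @param x aperture vector (length N).
#' @param L_prime subarray length, 2 <= L' <= N.
#' @return Hermitian `L' x L'` complex matrix.
#' @export
smooth_covariance <- function(x, L_prime) {
  N <- length(x)
  L_prime <- as.integer(L_prime)
  if (L_prime > N) stop("subarray length exceeds aperture size")
  if (L_prime < 2L) stop("subarray length must be >= 2")
  ns <- N - L_prime + 1L
  S <- matrix(0+0i, L_prime, ns)
  for (l in seq_len(ns)) S[, l] <- x[l:(l + L_prime - 1L)]
  S %*% Conj(t(S)) / ns
}

#' Rotary averaging of a covariance matrix
#'
#' The four-term symmetrization with the exchange matrix J (anti-diagonal
#' identity): `Rhat = (R + J R^T + J R J + R^T J) / 4`, exactly as printed
#' (plain transpose).  `mode = "classic_fb"` gives the classic
#' forward-backward alternative `(R + J Conj(R) J) / 2`.
#'
#' @param R square matrix.
#' @param mode `"printed"` (default) or `"classic_fb"`.
#' @return matrix of the same size.
#' @export
rotary_average <- function(R, mode = c("printed", "classic_fb")) {
  mode <- match.arg(mode)
  if (nrow(R) != ncol(R)) stop("rotary averaging needs a square matrix")
  n <- nrow(R)
  J <- diag(n)[n:1, , drop = FALSE]
  if (mode == "printed")
    (R + J %*% t(R) + J %*% R %*% J + t(R) %*% J) / 4
  else
    (R + J %*% Conj(R) %*% J) / 2
}

#' Diagonal reducing
#'
#' Subtracts a fraction delta of the diagonal part:
#' `Rtilde = Rhat - delta * diag(Rhat)`.  delta = 0 is the identity,
#' delta = 1 zeroes the diagonal and leaves off-diagonals untouched.
#'
#' @param Rhat square matrix.
#' @param delta reducing factor in \[0, 1\].
#' @return matrix of the same size.
#' @export
diagonal_reduce <- function(Rhat, delta) {
  if (delta < 0 || delta > 1) stop("diagonal reducing factor must be in [0, 1]")
  Rhat - delta * diag(diag(Rhat), nrow = nrow(Rhat))
}

#' Mean-to-standard-deviation ratio of a matrix
#'
#' Mean of all L'^2 entries divided by their population standard deviation;
#' complex entries enter through their real parts (the diagonal is real and
#' off-diagonals of the symmetrized covariance are near-real).  Degenerate
#' spread (`Std < 1e-12 * |mean|`) returns `cap`; the exactly-zero matrix
#' returns 0.
#'
#' @param M square matrix (L' >= 2).
#' @param cap value returned in the degenerate all-equal branch.
#' @return scalar.
#' @export
matrix_msr <- function(M, cap = 1e6) {
  v <- Re(M)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))
  if (s <= 1e-12 * abs(m)) {
    if (m == 0) return(0)
    return(cap)
  }
  m / s
}

#' Coherence-adaptive diagonal-reducing factor
#'
#' `delta_ac = W_CF^(sigma') * delta_max`, in \[0, delta_max\].  `w_cf = 0`
#' maps to 0; `sigma'` is clamped at 1e-6 so 0^0 never evaluates.
#'
#' @param w_cf coherence factor, in \[0, 1\].
#' @param sigma_prime normalized reciprocal ASD, in (0, 1\].
#' @param delta_max maximum reducing factor, in \[0, 1\].
#' @return scalar in \[0, delta_max\].
#' @export
adaptive_delta <- function(w_cf, sigma_prime, delta_max) {
  if (w_cf <= 0) return(0)
  w_cf^max(sigma_prime, 1e-6) * delta_max
}

#' CMSF pixel weight
#'
#' Covariance-matrix statistical factor: dynamic subarray length from
#' `sigma'`, spatial-only covariance smoothing, rotary averaging, constant
#' diagonal reducing with `cfg$delta`, then the matrix MSR.
#'
#' @param x aperture vector (length N).
#' @param sigma_prime the pixel's normalized reciprocal ASD.
#' @param cfg a [bf_config()].
#' @return scalar weight.
#' @export
cmsf_weight <- function(x, sigma_prime, cfg) {
  Lp <- dynamic_subarray_length(sigma_prime, cfg$L_max)
  R <- smooth_covariance(x, Lp)
  Rh <- rotary_average(R, cfg$rotary)
  M <- diagonal_reduce(Rh, cfg$delta)
  matrix_msr(M, cfg$msr_cap)
}

#' CMSAW pixel weight
#'
#' Same chain as [cmsf_weight()] but with the coherence-adaptive reducing
#' factor `delta_ac = W_CF(x)^(sigma') * delta_max` in place of the constant
#' delta.
#'
#' @inheritParams cmsf_weight
#' @return scalar weight.
#' @export
cmsaw_weight <- function(x, sigma_prime, cfg) {
  Lp <- dynamic_subarray_length(sigma_prime, cfg$L_max)
  R <- smooth_covariance(x, Lp)
  Rh <- rotary_average(R, cfg$rotary)
  dac <- adaptive_delta(coherence_factor(x), sigma_prime, cfg$delta_max)
  M <- diagonal_reduce(Rh, dac)
  matrix_msr(M, cfg$msr_cap)
}

#' Apply a per-pixel weight map to a beamformed image
#'
#' Element-wise product, applied to the complex beamformed output before
#' envelope detection.
#'
#' @param weight_map numeric matrix of per-pixel weights.
#' @param image complex matrix of the same dimensions.
#' @return weighted complex image.
#' @export
apply_pixel_weight <- function(weight_map, image) {
  if (!identical(dim(weight_map), dim(image)))
    stop("weight map and image dimensions differ")
  weight_map * image
}
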