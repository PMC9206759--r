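#' Beamformer configuration
#'
#' Collects every tunable of the per-pixel beamformers.  Defaults follow the
#' standard settings for an N-element STA acquisition: subarray length
#' L = N/2, diagonal-loading scale 0.1/L, 9-point temporal window (K = 4),
#' eigen threshold 0.5, GCF cutoff M0 = 1, diagonal-reducing factors
#' delta = delta_max = 1, maximum dynamic subarray length L_max = L.
#'
#' @param n_elements aperture size N.
#' @param L MV subarray length (2 <= L <= N).
#' @param K half temporal window; 2K+1 axial points enter the covariance.
#' @param delta_load diagonal-loading scale (epsilon = delta_load * trace(R)).
#' @param gamma eigen threshold for ESBMV, in (0, 1].
#' @param window transmit/receive apodization, `"rectangular"` or
#'   `"hamming"`.
#' @param f_number aperture f-number (0 = full aperture).
#' @param M0 GCF low-frequency cutoff (0 <= M0 <= N/2).
#' @param delta constant diagonal-reducing factor of CMSF, in \[0, 1\].
#' @param delta_max maximum adaptive diagonal-reducing factor of CMSAW.
#' @param L_max maximum dynamic subarray length (2 <= L_max <= N).
#' @param asd_exponent exponent of the ASD reciprocal normalization
#'   (default 1/3).
#' @param msr_cap value returned by [matrix_msr()] in its degenerate branch.
#' @param rotary `"printed"` (four-term exchange-matrix average) or
#'   `"classic_fb"` (forward-backward average), see [rotary_average()].
#' @return an object of class `bf_config`.
#' @export
bf_config <- function(n_elements,
                      L = max(2L, n_elements %/% 2L),
                      K = 4L,
                      delta_load = 0.1 / L,
                      gamma = 0.5,
                      window = "rectangular",
                      f_number = 0,
                      M0 = 1L,
                      delta = 1,
                      delta_max = 1,
                      L_max = L,
                      asd_exponent = 1 / 3,
                      msr_cap = 1e6,
                      rotary = "printed") {
  n_elements <- as.integer(n_elements); L <- as.integer(L)
  K <- as.integer(K); L_max <- as.integer(L_max)
  if (L < 2L || L > n_elements) stop("need 2 <= L <= N")
  if (K < 0L) stop("K must be >= 0")
  if (delta_load <= 0) stop("delta_load must be positive")
  if (gamma <= 0 || gamma > 1) stop("gamma must be in (0, 1]")
  if (M0 < 0 || M0 > n_elements / 2) stop("need 0 <= M0 <= N/2")
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  if (delta_max < 0 || delta_max > 1) stop("delta_max must be in [0, 1]")
  if (L_max < 2L || L_max > n_elements) stop("need 2 <= L_max <= N")
  window <- match.arg(window, c("rectangular", "hamming"))
  rotary <- match.arg(rotary, c("printed", "classic_fb"))
  structure(list(n_elements = n_elements, L = L, K = K,
                 delta_load = delta_load, gamma = gamma, window = window,
                 f_number = f_number, M0 = as.integer(M0), delta = delta,
                 delta_max = delta_max, L_max = L_max,
                 asd_exponent = asd_exponent, msr_cap = msr_cap,
                 rotary = rotary),
            class = "bf_config")
}

#' Delay-and-sum pixel value
#'
#' Outer (transmit) weighted sum of the receive-synthesized aperture vector,
#' `Y_DAS(p) = sum_i w_i x_i(p)`.
#'
#' @param x aperture vector (length N).
#' @param element_x element positions (needed only for `f_number > 0`).
#' @param pixel_x,pixel_z image point (for the aperture-growth rule).
#' @param window,f_number transmit apodization rule, see [aperture_window()].
#' @param weights optional explicit weight vector overriding the rule.
#' @return complex (or real) scalar.
#' @export
das_pixel <- function(x, element_x = NULL, pixel_x = 0, pixel_z = Inf,
                      window = "rectangular", f_number = 0, weights = NULL) {
  w <- if (!is.null(weights)) weights
       else aperture_window(if (is.null(element_x)) seq_along(x) else element_x,
                            pixel_x, pixel_z, window, f_number)
  if (length(w) != length(x)) stop("weight length must match aperture vector")
  sum(w * x)
}

#' Spatially and temporally smoothed covariance estimate
#'
#' `R = sum_k sum_l x_l(p+k) x_l(p+k)^H / ((2K+1)(N-L+1))`: the average of
#' outer products of all length-L sliding subarrays of each of the 2K+1
#' axially neighboring aperture vectors.
#'
#' @param x_stack matrix `N x (2K+1)` whose columns are the aperture vectors
#'   of the axial neighbors (a plain vector is treated as K = 0).
#' @param L subarray length (2 <= L <= N).
#' @return Hermitian `L x L` complex matrix with attributes `L`,
#'   `n_subarrays`, `n_temporal`.
#' @export
mv_covariance <- function(x_stack, L) {
  if (is.vector(x_stack)) x_stack <- matrix(x_stack, ncol = 1L)
  N <- nrow(x_stack)
  L <- as.integer(L)
  if (L > N) stop("subarray length L exceeds aperture size")
  if (L < 1L) stop("L must be >= 1")
  ns <- N - L + 1L
  nt <- ncol(x_stack)
  S <- matrix(0+0i, L, ns * nt)
  col <- 0L
  for (k in seq_len(nt)) {
    xk <- x_stack[, k]
    for (l in seq_len(ns)) {
      col <- col + 1L
      S[, col] <- xk[l:(l + L - 1L)]
    }
  }
  R <- S %*% Conj(t(S)) / (ns * nt)
  attr(R, "L") <- L; attr(R, "n_subarrays") <- ns; attr(R, "n_temporal") <- nt
  R
}

#' Diagonal loading
#'
#' `Rhat = R + delta_load * trace(R) * I`.  A zero-trace R (pure-zero pixel)
#' is returned unchanged with a warning.
#'
#' @param R Hermitian covariance matrix.
#' @param delta_load positive loading scale.
#' @return loaded matrix.
#' @export
diagonal_load <- function(R, delta_load) {
  if (delta_load <= 0) stop("delta_load must be positive")
  tr <- Re(sum(diag(R)))
  if (tr == 0) {
    warning("zero-trace covariance: returning unchanged")
    return(R)
  }
  R + delta_load * tr * diag(nrow(R))
}

#' Minimum-variance (Capon) weights
#'
#' `w = Rhat^{-1} a / (a^H Rhat^{-1} a)` with steering vector a = ones
#' (delays already compensated), via a linear solve.  A solve failure falls
#' back to the uniform vector a/L (flagged in attribute `"fallback"`).
#'
#' @param Rhat diagonally loaded covariance.
#' @param a steering vector (default ones).
#' @return weight vector satisfying `w^H a = 1`.
#' @export
mv_weights <- function(Rhat, a = rep(1, nrow(Rhat))) {
  s <- tryCatch(solve(Rhat, a), error = function(e) NULL)
  if (is.null(s) || !all(is.finite(Mod(s)))) {
    w <- a / length(a)
    attr(w, "fallback") <- TRUE
    return(w)
  }
  d <- sum(Conj(a) * s)
  s / d
}

#' Minimum-variance pixel value
#'
#' Applies the MV weights to every length-L subarray of the center aperture
#' vector and averages: `Y_MV = (1/(N-L+1)) sum_l w^H x_l`.
#'
#' @param x_stack aperture-vector stack as in [mv_covariance()]; the center
#'   column (K+1 for 2K+1 columns) is the pixel's own vector.
#' @param cfg a [bf_config()].
#' @return complex scalar.
#' @export
mv_pixel <- function(x_stack, cfg) {
  if (is.vector(x_stack)) x_stack <- matrix(x_stack, ncol = 1L)
  R <- mv_covariance(x_stack, cfg$L)
  Rhat <- diagonal_load(R, cfg$delta_load)
  w <- mv_weights(Rhat)
  xc <- x_stack[, (ncol(x_stack) + 1L) %/% 2L]
  m <- subarray_mean(xc, cfg$L)
  sum(Conj(w) * m)
}

# average of all length-L sliding subarrays of x
subarray_mean <- function(x, L) {
  ns <- length(x) - L + 1L
  m <- numeric(L) + 0i
  for (l in seq_len(ns)) m <- m + x[l:(l + L - 1L)]
  m / ns
}

#' Eigenspace-based minimum-variance pixel value
#'
#' Decomposes the loaded covariance, keeps the signal subspace of
#' eigenvectors with `lambda_j >= gamma * lambda_max` (the largest always
#' included), projects the MV weights onto it, and beamforms with the
#' projected weights.  When every eigenvalue passes the threshold the
#' projection is the identity and the MV weights are reused exactly.
#'
#' @inheritParams mv_pixel
#' @return complex scalar.
#' @export
esbmv_pixel <- function(x_stack, cfg) {
  if (is.vector(x_stack)) x_stack <- matrix(x_stack, ncol = 1L)
  R <- mv_covariance(x_stack, cfg$L)
  Rhat <- diagonal_load(R, cfg$delta_load)
  w <- mv_weights(Rhat)
  e <- eigen(Rhat, symmetric = TRUE)
  sel <- e$values >= cfg$gamma * e$values[1L]
  sel[1L] <- TRUE
  w_es <- if (all(sel)) w else {
    Es <- e$vectors[, sel, drop = FALSE]
    as.vector(Es %*% (Conj(t(Es)) %*% w))
  }
  xc <- x_stack[, (ncol(x_stack) + 1L) %/% 2L]
  m <- subarray_mean(xc, cfg$L)
  sum(Conj(w_es) * m)
}
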