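#' STA channel-data cube
#'
#' Container for raw synthetic-transmit-aperture RF data: one trace per
#' (transmit element, receive element) pair.  `rf[i, j, ]` is the trace
#' received by element j on the i-th single-element transmission.
#'
#' @param rf numeric array `N x N x T` of RF samples, all finite.
#' @param geometry an [array_geometry()].
#' @return an object of class `channel_data_cube`.
#' @export
channel_data_cube <- function(rf, geometry) {
  stopifnot(inherits(geometry, "array_geometry"))
  d <- dim(rf)
  if (length(d) != 3L || d[1L] != geometry$n_elements || d[2L] != geometry$n_elements)
    stop("rf must be an N x N x T array with N = geometry$n_elements")
  if (!all(is.finite(rf))) stop("rf contains non-finite values")
  structure(list(rf = rf, geometry = geometry, n_samples = d[3L]),
            class = "channel_data_cube")
}

#' @export
print.channel_data_cube <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("STA channel-data cube: %d tx x %d rx x %d samples\n",
              g$n_elements, g$n_elements, x$n_samples))
  cat(sprintf("  f0 = %.3g MHz, fs = %.3g MHz, c = %g m/s, t0 = %.3g us\n",
              g$f0 / 1e6, g$fs / 1e6, g$c, g$t0 * 1e6))
  invisible(x)
}

#' Delay-compensate a channel-data cube onto an imaging grid
#'
#' For every grid pixel p, samples every (tx, rx) trace at its two-way delay,
#' yielding the full N x N focused data matrix X(p).  Linear interpolation in
#' time; delays outside the recorded window give zero (counted in the
#' `"n_zero_filled"` attribute).  This is the plain reference implementation;
#' the image pipeline uses the fused compiled path ([aperture_field()]).
#'
#' @param cube a [channel_data_cube()].
#' @param grid an [imaging_grid()].
#' @param interp interpolation rule; only `"linear"` is supported.
#' @return numeric array `N x N x P` (P = pixels, axial index fastest) with
#'   attribute `n_zero_filled`.
#' @export
delay_compensate <- function(cube, grid, interp = "linear") {
  stopifnot(inherits(cube, "channel_data_cube"), inherits(grid, "imaging_grid"))
  interp <- match.arg(interp, "linear")
  g <- cube$geometry
  N <- g$n_elements
  T_ <- cube$n_samples
  np <- grid$n_axial * grid$n_lateral
  out <- array(0, dim = c(N, N, np))
  rfm <- matrix(aperm(cube$rf, c(3L, 1L, 2L)), nrow = T_)  # column (i,j): i fastest
  nzero <- 0L
  p <- 0L
  for (ix in seq_len(grid$n_lateral)) {
    px <- grid$lateral_x[ix]
    for (iz in seq_len(grid$n_axial)) {
      pz <- grid$axial_z[iz]
      p <- p + 1L
      d <- sqrt((g$element_x - px)^2 + pz^2)
      tau <- outer(d, d, "+") / g$c            # [i, j]
      s <- (tau - g$t0) * g$fs + 1             # fractional sample index (1-based)
      k0 <- floor(s)
      fr <- s - k0
      ok <- k0 >= 1 & k0 <= T_ - 1
      nzero <- nzero + sum(!ok)
      if (any(ok)) {
        cols <- matrix(rep(seq_len(N), times = N) +
                         N * rep(seq_len(N) - 1L, each = N), N, N) # (i,j) -> col
        idx <- which(ok)
        v0 <- rfm[cbind(k0[idx], cols[idx])]
        v1 <- rfm[cbind(k0[idx] + 1L, cols[idx])]
        Xp <- matrix(0, N, N)
        Xp[idx] <- v0 + fr[idx] * (v1 - v0)
        out[, , p] <- Xp
      }
    }
  }
  attr(out, "n_zero_filled") <- nzero
  out
}

#' Synthesize the receive aperture of one focused data matrix
#'
#' Inner (receive) delay-and-sum of the focused N x N matrix X(p): returns
#' the length-N aperture vector with one entry per transmission,
#' `x_i(p) = sum_j w_j X(p)[i, j]`.
#'
#' @param X_p focused data matrix (N x N), real or complex.
#' @param element_x element lateral positions, meters.
#' @param pixel_x,pixel_z image point (used only when `f_number > 0`).
#' @param window receive apodization, see [aperture_window()].
#' @param f_number receive f-number; 0 = full aperture.
#' @param rx_window optional explicit weight vector overriding
#'   `window`/`f_number`.
#' @return aperture vector of length N.
#' @export
synthesize_receive <- function(X_p, element_x, pixel_x = 0, pixel_z = Inf,
                               window = "rectangular", f_number = 0,
                               rx_window = NULL) {
  N <- nrow(X_p)
  w <- if (!is.null(rx_window)) rx_window
       else aperture_window(element_x, pixel_x, pixel_z, window, f_number)
  if (length(w) != ncol(X_p)) stop("window length must match ncol(X_p)")
  if (any(w < 0)) stop("receive window weights must be nonnegative")
  if (all(w == 0)) stop("all-zero receive window")
  as.vector(X_p %*% w)
}
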