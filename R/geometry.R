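#' Linear-array geometry and acquisition parameters
#'
#' Describes a 1-D linear transducer array used both to transmit (one element
#' at a time, STA mode) and to receive, together with the acquisition timing.
#' Coordinates: lateral `x` centered on the array (x = 0 at the array center),
#' axial `z` positive into the medium, elements at z = 0; meters throughout.
#'
#' @param n_elements number of elements N (>= 2).
#' @param pitch element spacing in meters.
#' @param f0 center frequency in Hz.
#' @param fs sampling frequency in Hz; must exceed 2*f0.
#' @param c speed of sound in m/s.
#' @param t0 time of the first recorded sample, seconds.
#' @param element_x optional explicit lateral element positions (length
#'   `n_elements`, strictly increasing, uniformly spaced at `pitch`).
#' @return an object of class `array_geometry`.
#' @export
array_geometry <- function(n_elements, pitch, f0, fs, c = 1540, t0 = 0,
                           element_x = NULL) {
  n_elements <- as.integer(n_elements)
  if (n_elements < 2L) stop("n_elements must be >= 2")
  if (pitch <= 0) stop("pitch must be positive")
  if (fs <= 2 * f0) stop("fs must exceed 2*f0 (Nyquist)")
  if (c <= 0) stop("speed of sound must be positive")
  if (is.null(element_x))
    element_x <- (seq_len(n_elements) - (n_elements + 1) / 2) * pitch
  if (length(element_x) != n_elements)
    stop("element_x must have length n_elements")
  d <- diff(element_x)
  if (any(d <= 0) || any(abs(d - pitch) > 1e-12))
    stop("element_x must be strictly increasing, uniformly spaced at pitch")
  structure(list(n_elements = n_elements, pitch = pitch,
                 element_x = as.numeric(element_x),
                 f0 = f0, fs = fs, c = c, t0 = t0),
            class = "array_geometry")
}

#' Rectangular imaging grid
#'
#' @param lateral_x lateral pixel positions in meters (monotone increasing).
#' @param axial_z axial pixel positions in meters (monotone increasing, > 0).
#' @return an object of class `imaging_grid` with `n_lateral`/`n_axial` counts.
#' @export
imaging_grid <- function(lateral_x, axial_z) {
  if (length(lateral_x) < 1L || length(axial_z) < 1L)
    stop("empty imaging grid")
  if (any(diff(lateral_x) <= 0) || any(diff(axial_z) <= 0))
    stop("grid axes must be monotone increasing")
  if (any(axial_z <= 0)) stop("axial positions must be positive")
  structure(list(lateral_x = as.numeric(lateral_x),
                 axial_z = as.numeric(axial_z),
                 n_lateral = length(lateral_x), n_axial = length(axial_z)),
            class = "imaging_grid")
}

#' Two-way propagation delay for one transmit/receive element pair
#'
#' Time of flight from a transmitting element at `(tx_x, 0)` to the image
#' point `(pixel_x, pixel_z)` and back to a receiving element at `(rx_x, 0)`.
#' Vectorized over all arguments; symmetric under tx/rx exchange.
#'
#' @param tx_x,rx_x lateral element positions, meters.
#' @param pixel_x,pixel_z image point position, meters (`pixel_z > 0`).
#' @param c speed of sound, m/s.
#' @param pixel_y optional elevation offset of the point, meters.
#' @return delay in seconds.
#' @export
two_way_delay <- function(tx_x, rx_x, pixel_x, pixel_z, c, pixel_y = 0) {
  if (any(c <= 0)) stop("invalid geometry: speed of sound must be positive")
  if (any(pixel_z <= 0)) stop("invalid geometry: pixel depth must be positive")
  d_tx <- sqrt((tx_x - pixel_x)^2 + pixel_y^2 + pixel_z^2)
  d_rx <- sqrt((rx_x - pixel_x)^2 + pixel_y^2 + pixel_z^2)
  (d_tx + d_rx) / c
}

#' Complex analytic signal of a real RF trace
#'
#' Frequency-domain one-sided spectrum doubling: the real part equals the
#' input and the imaginary part is its quadrature component.  Columns of a
#' matrix are converted independently.
#'
#' @param rf real vector (length >= 2) or matrix with traces in columns.
#' @return complex vector/matrix of the same shape.
#' @export
analytic_signal <- function(rf) {
  if (is.matrix(rf)) {
    if (!all(is.finite(rf))) stop("non-finite input to analytic_signal")
    n <- nrow(rf)
    if (n < 2L) stop("trace length must be >= 2")
    h <- one_sided_weights(n)
    return(mvfft(mvfft(rf) * h, inverse = TRUE) / n)
  }
  if (!all(is.finite(rf))) stop("non-finite input to analytic_signal")
  n <- length(rf)
  if (n < 2L) stop("trace length must be >= 2")
  h <- one_sided_weights(n)
  fft(fft(rf) * h, inverse = TRUE) / n
}

one_sided_weights <- function(n) {
  h <- numeric(n)
  h[1L] <- 1
  if (n %% 2L == 0L) {
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[2L:((n + 1L) / 2L)] <- 2
  }
  h
}

#' Apodization window over the active aperture
#'
#' Window weights for the N array elements at a given image point.  With
#' `f_number = 0` the full aperture is active; with `f_number > 0` only
#' elements with `|element_x - pixel_x| <= pixel_z / (2 * f_number)` are
#' active and the window spans the active run.
#'
#' @param element_x element lateral positions, meters.
#' @param pixel_x,pixel_z image point, meters (`pixel_z` ignored when
#'   `f_number = 0`).
#' @param window `"rectangular"` or `"hamming"`.
#' @param f_number receive f-number (0 = full aperture).
#' @return nonnegative weight vector of length `length(element_x)`.
#' @export
aperture_window <- function(element_x, pixel_x = 0, pixel_z = Inf,
                            window = c("rectangular", "hamming"),
                            f_number = 0) {
  window <- match.arg(window)
  n <- length(element_x)
  active <- if (f_number > 0)
    abs(element_x - pixel_x) <= pixel_z / (2 * f_number) else rep(TRUE, n)
  w <- numeric(n)
  m <- sum(active)
  if (m == 0L) return(w)
  if (window == "rectangular") {
    w[active] <- 1
  } else {
    k <- seq_len(m) - 1L
    w[active] <- if (m == 1L) 1 else 0.54 - 0.46 * cos(2 * pi * k / (m - 1L))
  }
  w
}
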