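#' Transmit pulse model
#'
#' Gaussian-enveloped cosine at the array center frequency.  The fractional
#' bandwidth is the -6 dB full width of the spectral envelope divided by f0.
#'
#' @param f0 center frequency, Hz.
#' @param fractional_bandwidth dimensionless, in (0, 2).
#' @param envelope only `"gaussian"` is supported.
#' @return an object of class `pulse_model` with derived `sigma_t` (envelope
#'   time constant, s) and `half_width` (truncation half-width, s).
#' @export
pulse_model <- function(f0, fractional_bandwidth = 0.6, envelope = "gaussian") {
  envelope <- match.arg(envelope, "gaussian")
  if (fractional_bandwidth <= 0 || fractional_bandwidth >= 2)
    stop("fractional_bandwidth must be in (0, 2)")
  bw <- fractional_bandwidth * f0
  sigma_f <- bw / (2 * sqrt(2 * log(2)))
  sigma_t <- 1 / (2 * pi * sigma_f)
  structure(list(f0 = f0, fractional_bandwidth = fractional_bandwidth,
                 envelope = envelope, sigma_t = sigma_t,
                 half_width = 4 * sigma_t),
            class = "pulse_model")
}

#' Evaluate the transmit pulse
#' @param pulse a [pulse_model()].
#' @param t times in seconds (0 = pulse center).
#' @return pulse amplitude at `t`.
#' @export
pulse_eval <- function(pulse, t) {
  ifelse(abs(t) > pulse$half_width, 0,
         exp(-t^2 / (2 * pulse$sigma_t^2)) * cos(2 * pi * pulse$f0 * t))
}

#' Phantom specification
#'
#' @param extent list with ranges `x`, `y`, `z`, each `c(min, max)` in meters.
#' @param scatterer_density scatterers per resolution cell (> 0).
#' @param point_targets list of `list(position = c(x, y, z), amplitude = a)`.
#' @param cyst_regions list of `list(center = c(x, y, z), radius = r,
#'   amplitude_scale = s)`; scale 0 = anechoic, < 1 hypoechoic, > 1
#'   hyperechoic.
#' @param rng_seed integer seed controlling scatterer placement.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(extent, scatterer_density, point_targets = list(),
                         cyst_regions = list(), rng_seed = 1L) {
  stopifnot(is.list(extent), all(c("x", "y", "z") %in% names(extent)))
  for (ax in c("x", "y", "z"))
    if (length(extent[[ax]]) != 2L || diff(extent[[ax]]) < 0)
      stop("extent ranges must be c(min, max)")
  if (scatterer_density <= 0) stop("scatterer_density must be positive")
  for (cy in cyst_regions) {
    if (cy$radius <= 0) stop("cyst radius must be positive")
    if (cy$amplitude_scale < 0) stop("cyst amplitude_scale must be >= 0")
  }
  structure(list(extent = extent, scatterer_density = scatterer_density,
                 point_targets = point_targets, cyst_regions = cyst_regions,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

#' Resolution-cell volume of the imaging system
#'
#' Cell = (lateral beam width at mid-depth) x (elevation extent) x (axial
#' pulse length): `(lambda * z_mid / D) * e_y * (c / (2 * B))` with
#' `B = f0 * fractional_bandwidth`.  Used to convert "scatterers per
#' resolution cell" into a scatterer count.
#'
#' @param geom an [array_geometry()].
#' @param pulse a [pulse_model()].
#' @param z_mid mid-depth of the phantom, meters.
#' @param elev_extent elevation slab thickness, meters.
#' @return volume in cubic meters.
#' @export
resolution_cell_volume <- function(geom, pulse, z_mid, elev_extent) {
  lambda <- geom$c / geom$f0
  D <- geom$n_elements * geom$pitch
  B <- pulse$f0 * pulse$fractional_bandwidth
  (lambda * z_mid / D) * elev_extent * (geom$c / (2 * B))
}

#' Draw the scatterer field of a phantom
#'
#' Positions i.i.d. uniform over the extent; amplitudes i.i.d. N(0, 1)
#' multiplied by the cyst region scale (0 inside anechoic regions); point
#' targets appended with their stated amplitudes.  Deterministic given
#' `spec$rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @param geom an [array_geometry()].
#' @param pulse a [pulse_model()].
#' @return object of class `scatterer_field`: `positions` (n x 3 matrix,
#'   meters) and `amplitudes` (length n).
#' @export
make_scatterers <- function(spec, geom, pulse) {
  stopifnot(inherits(spec, "phantom_spec"))
  ex <- spec$extent
  vol <- diff(ex$x) * diff(ex$y) * diff(ex$z)
  if (vol <= 0) stop("zero-volume phantom extent")
  z_mid <- mean(ex$z)
  cell <- resolution_cell_volume(geom, pulse, z_mid, diff(ex$y))
  n <- max(1L, round(spec$scatterer_density * vol / cell))
  with_seed(spec$rng_seed, {
    pos <- cbind(runif(n, ex$x[1], ex$x[2]),
                 runif(n, ex$y[1], ex$y[2]),
                 runif(n, ex$z[1], ex$z[2]))
    amp <- rnorm(n)
    for (cy in spec$cyst_regions) {
      inside <- (pos[, 1] - cy$center[1])^2 + (pos[, 2] - cy$center[2])^2 +
        (pos[, 3] - cy$center[3])^2 <= cy$radius^2
      amp[inside] <- amp[inside] * cy$amplitude_scale
    }
    for (pt in spec$point_targets) {
      pos <- rbind(pos, pt$position)
      amp <- c(amp, pt$amplitude)
    }
    structure(list(positions = unname(pos), amplitudes = amp,
                   n_background = n),
              class = "scatterer_field")
  })
}

#' Simulate STA channel data from a scatterer field
#'
#' Each trace is the superposition of Gaussian-enveloped cosine echoes,
#' `rf[i, j, t] = sum_s a_s g(t - tau_ij(s))` with the exact two-way delays,
#' optionally attenuated by geometric spreading `1/(d_tx * d_rx)`.  Computed
#' in compiled code from an oversampled pulse table; tx/rx reciprocity halves
#' the work.
#'
#' @param field a [make_scatterers()] result.
#' @param geom an [array_geometry()].
#' @param pulse a [pulse_model()].
#' @param n_samples trace length; default covers the farthest echo.  An
#'   explicit value too short to contain all echoes is an error.
#' @param spreading logical; apply `1/(d_tx*d_rx)` amplitude spreading.
#' @return a [channel_data_cube()].
#' @export
simulate_sta <- function(field, geom, pulse, n_samples = NULL,
                         spreading = TRUE) {
  stopifnot(inherits(field, "scatterer_field"))
  if (nrow(field$positions) == 0L) stop("empty scatterer field")
  dmax <- max(sqrt((outer(field$positions[, 1], geom$element_x, "-"))^2 +
                     field$positions[, 2]^2 + field$positions[, 3]^2))
  t_need <- 2 * dmax / geom$c + pulse$half_width
  n_need <- ceiling((t_need - geom$t0) * geom$fs) + 2L
  if (is.null(n_samples)) n_samples <- n_need
  if (n_samples < n_need)
    stop(sprintf("time window too short: need at least %d samples", n_need))
  keep <- field$amplitudes != 0
  if (!any(keep)) {
    rf <- array(0, c(geom$n_elements, geom$n_elements, n_samples))
    return(channel_data_cube(rf, geom))
  }
  a <- sim_sta_cpp(field$positions[keep, , drop = FALSE],
                   field$amplitudes[keep], geom$element_x,
                   geom$fs, geom$t0, as.integer(n_samples), geom$c,
                   pulse$f0, pulse$fractional_bandwidth,
                   isTRUE(spreading), 32L)
  channel_data_cube(aperm(a, c(3L, 2L, 1L)), geom)   # (t,rx,tx) -> (tx,rx,t)
}

#' Add Gaussian channel noise at a prescribed SNR
#'
#' i.i.d. zero-mean Gaussian samples with variance equal to the mean power of
#' the nonzero signal support divided by `10^(snr_db/10)`.  `snr_db = Inf`
#' returns the cube unchanged.
#'
#' @param cube a [channel_data_cube()] (not all-zero).
#' @param snr_db desired channel SNR in dB.
#' @param rng_seed integer seed; output is deterministic given the seed.
#' @return noisy [channel_data_cube()].
#' @export
add_channel_noise <- function(cube, snr_db, rng_seed = 1L) {
  stopifnot(inherits(cube, "channel_data_cube"))
  if (is.infinite(snr_db) && snr_db > 0) return(cube)
  nz <- cube$rf != 0
  if (!any(nz)) stop("all-zero cube: SNR undefined")
  p_sig <- mean(cube$rf[nz]^2)
  v <- p_sig / 10^(snr_db / 10)
  rf <- with_seed(rng_seed, cube$rf + array(rnorm(length(cube$rf), sd = sqrt(v)),
                                            dim = dim(cube$rf)))
  channel_data_cube(rf, cube$geometry)
}

#' Study presets: full-scale simulation and reduced toy configuration
#'
#' `simulation` reproduces the reference simulation conditions: 64-element,
#' 0.24 mm pitch, 3.33 MHz linear array sampled at 40 MHz, c = 1540 m/s; a
#' 22 x 0.5 x 15 mm speckle phantom at 40 scatterers per resolution cell
#' with three point targets and a 5 mm diameter anechoic cyst; 10 dB channel
#' SNR; beamformer settings L = N/2, DL scale 0.1/L, 9-point temporal window,
#' eigen threshold 0.5, GCF cutoff 1, diagonal-reducing factors delta =
#' delta_max = 1.  `toy` is a reduced N = 32 variant (density 10/cell,
#' smaller phantom) for fast tests; same parameter rules.
#'
#' @return list with elements `simulation` and `toy`, each containing
#'   `geometry`, `pulse`, `phantom`, `speckle_phantom` (no targets),
#'   `snr_db`, `config`, and `rois`.
#' @export
sta_presets <- function() {
  sim_geom <- array_geometry(64L, 0.24e-3, 3.33e6, 40e6, 1540)
  sim_pulse <- pulse_model(3.33e6, 0.6)
  sim_extent <- list(x = c(-11e-3, 11e-3), y = c(-0.25e-3, 0.25e-3),
                     z = c(17e-3, 32e-3))
  pts <- lapply(c(20e-3, 24e-3, 28e-3), function(z)
    list(position = c(-7e-3, 0, z), amplitude = 80))
  cyst <- list(list(center = c(5.5e-3, 0, 24e-3), radius = 2.5e-3,
                    amplitude_scale = 0))
  sim_phantom <- phantom_spec(sim_extent, 40, pts, cyst, rng_seed = 1L)
  sim_speckle <- phantom_spec(sim_extent, 40, rng_seed = 1L)
  sim_cfg <- bf_config(64L)
  sim_rois <- list(
    cyst = roi_circle(5.5e-3, 24e-3, 1.7e-3),
    background = roi_rect(c(-2e-3, 2e-3), c(21.75e-3, 26.25e-3)),
    point = roi_rect(c(-8.2e-3, -5.8e-3), c(23.6e-3, 24.4e-3)))

  toy_geom <- array_geometry(32L, 0.24e-3, 3.33e6, 40e6, 1540)
  toy_extent <- list(x = c(-7e-3, 7e-3), y = c(-0.25e-3, 0.25e-3),
                     z = c(16e-3, 24e-3))
  toy_pts <- lapply(c(18e-3, 20e-3, 22e-3), function(z)
    list(position = c(-4.5e-3, 0, z), amplitude = 80))
  toy_cyst <- list(list(center = c(3e-3, 0, 20e-3), radius = 2e-3,
                        amplitude_scale = 0))
  toy_phantom <- phantom_spec(toy_extent, 10, toy_pts, toy_cyst, rng_seed = 1L)
  toy_speckle <- phantom_spec(toy_extent, 10, rng_seed = 1L)
  toy_cfg <- bf_config(32L)
  toy_rois <- list(
    cyst = roi_circle(3e-3, 20e-3, 1.2e-3),
    background = roi_rect(c(-3e-3, 0e-3), c(18.4e-3, 21.6e-3)),
    point = roi_rect(c(-6e-3, -3e-3), c(19.6e-3, 20.4e-3)))

  list(simulation = list(geometry = sim_geom, pulse = sim_pulse,
                         phantom = sim_phantom, speckle_phantom = sim_speckle,
                         snr_db = 10, config = sim_cfg, rois = sim_rois),
       toy = list(geometry = toy_geom, pulse = sim_pulse,
                  phantom = toy_phantom, speckle_phantom = toy_speckle,
                  snr_db = 10, config = toy_cfg, rois = toy_rois))
}
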