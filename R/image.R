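#' Per-pixel analytic aperture vectors for an imaging grid
#'
#' Fused focusing front end: converts every RF trace to its analytic signal,
#' delay-compensates it at each grid pixel (linear interpolation, zero
#' outside the recorded window), and synthesizes the receive aperture,
#' yielding the length-N complex aperture vector x(p) per pixel.
#'
#' @param cube a [channel_data_cube()].
#' @param grid an [imaging_grid()].
#' @param window receive apodization (`"rectangular"` or `"hamming"`).
#' @param f_number receive f-number (0 = full aperture); aperture growth
#'   applies to the receive synthesis only.
#' @return object of class `aperture_field`: complex matrix `A` (N x pixels,
#'   axial index fastest), the grid and geometry, and the zero-fill count.
#' @export
aperture_field <- function(cube, grid, window = "rectangular", f_number = 0) {
  stopifnot(inherits(cube, "channel_data_cube"), inherits(grid, "imaging_grid"))
  g <- cube$geometry
  N <- g$n_elements
  T_ <- cube$n_samples
  # analytic signal per trace: traces in columns of a T x N^2 matrix
  rfm <- matrix(aperm(cube$rf, c(3L, 2L, 1L)), nrow = T_)  # (t, rx, tx)
  an <- analytic_signal(rfm)
  acube <- array(an, dim = c(T_, N, N))
  rxw <- aperture_window(g$element_x, window = window, f_number = 0)
  res <- afield_cpp(acube, g$element_x, g$fs, g$t0, g$c,
                    grid$lateral_x, grid$axial_z, rxw, f_number,
                    if (window == "hamming") 1L else 0L)
  structure(list(A = res$A, grid = grid, geometry = g,
                 n_zero_filled = res$n_zero_filled,
                 window = window, f_number = f_number),
            class = "aperture_field")
}

#' Beamform an STA channel-data cube with the selected methods
#'
#' Runs the full per-pixel chain on an imaging grid: receive synthesis,
#' DAS, MV with spatial/temporal smoothing and diagonal loading, ESBMV,
#' coherence-factor and generalized-coherence-factor maps, the image-wide
#' ASD normalization pass, and the CMSF/CMSAW weight maps applied to the MV
#' output.  The adaptive stage always uses all N transmit-synthesized
#' entries; the DAS transmit window follows `cfg$window`/`cfg$f_number`.
#'
#' @param cube a [channel_data_cube()].
#' @param grid an [imaging_grid()].
#' @param cfg a [bf_config()].
#' @param methods subset of `c("DAS", "MV", "ESBMV", "GCF-MV", "CMSF-MV",
#'   "CMSAW-MV")`.
#' @return object of class `sta_image_set`: named list `images` of complex
#'   matrices (axial x lateral), weight/diagnostic maps in `weights`, the
#'   grid, config, and a `log` of per-pixel failure counters.
#' @export
beamform_image <- function(cube, grid, cfg,
                           methods = c("DAS", "MV", "ESBMV", "GCF-MV",
                                       "CMSF-MV", "CMSAW-MV")) {
  stopifnot(inherits(cfg, "bf_config"))
  methods <- match.arg(methods, several.ok = TRUE)
  g <- cube$geometry
  if (g$n_elements != cfg$n_elements)
    stop("config n_elements does not match cube geometry")
  af <- aperture_field(cube, grid)   # receive synthesis by direct summing
  Pz <- grid$n_axial; Px <- grid$n_lateral
  shape <- function(v) matrix(v, Pz, Px)

  need_adaptive <- any(methods %in% c("MV", "ESBMV", "GCF-MV", "CMSF-MV",
                                      "CMSAW-MV"))
  txw <- rep(1, g$n_elements)
  p1 <- pass1_cpp(af$A, txw, cfg$M0)
  sigma <- shape(p1$sigma)
  images <- list()
  weights <- list(cf = shape(p1$cf), gcf = shape(p1$gcf), sigma = sigma)
  log <- list(n_zero_filled = af$n_zero_filled)

  if ("DAS" %in% methods) {
    if (cfg$window == "rectangular" && cfg$f_number == 0) {
      images$DAS <- shape(p1$das)
    } else {
      # DAS with its own apodization on both stages
      afd <- aperture_field(cube, grid, cfg$window, cfg$f_number)
      das <- complex(length(afd$A[1, ]))
      p <- 0L
      for (ix in seq_len(Px)) for (iz in seq_len(Pz)) {
        p <- p + 1L
        w <- aperture_window(g$element_x, grid$lateral_x[ix],
                             grid$axial_z[iz], cfg$window, cfg$f_number)
        das[p] <- sum(w * afd$A[, p])
      }
      images$DAS <- shape(das)
    }
  }

  if (need_adaptive) {
    sp <- normalize_asd(sigma, cfg$asd_exponent)
    weights$sigma_prime <- sp
    p2 <- pass2_cpp(af$A, Pz, Px, as.vector(sp), p1$cf,
                    cfg$L, cfg$K, cfg$delta_load, cfg$gamma,
                    cfg$L_max, cfg$delta, cfg$delta_max, cfg$msr_cap,
                    cfg$rotary == "printed",
                    "ESBMV" %in% methods,
                    "CMSF-MV" %in% methods, "CMSAW-MV" %in% methods)
    mv <- shape(p2$mv)
    if ("MV" %in% methods) images$MV <- mv
    if ("ESBMV" %in% methods) images$ESBMV <- shape(p2$esbmv)
    if ("GCF-MV" %in% methods)
      images$`GCF-MV` <- apply_pixel_weight(weights$gcf, mv)
    if ("CMSF-MV" %in% methods) {
      weights$cmsf <- shape(p2$w_cmsf)
      images$`CMSF-MV` <- apply_pixel_weight(weights$cmsf, mv)
    }
    if ("CMSAW-MV" %in% methods) {
      weights$cmsaw <- shape(p2$w_cmsaw)
      weights$delta_ac <- shape(p2$delta_ac)
      images$`CMSAW-MV` <- apply_pixel_weight(weights$cmsaw, mv)
    }
    weights$l_prime <- shape(p2$l_prime)
    log$n_solve_fallback <- p2$n_solve_fallback
    log$n_lprime_clamped <- p2$n_lprime_clamped
    log$n_msr_capped <- p2$n_msr_capped
  }
  images <- images[intersect(methods, names(images))]
  structure(list(images = images, weights = weights, grid = grid,
                 config = cfg, log = log),
            class = "sta_image_set")
}

#' Envelope of a complex beamformed image
#' @param image complex matrix (or `sta_image_set` entry).
#' @return nonnegative matrix of the same shape.
#' @export
envelope <- function(image) Mod(image)

#' Log-compressed display image
#'
#' `20*log10(envelope / max(envelope))`, clipped to `[-dynamic_range_db, 0]`.
#'
#' @param env envelope matrix with a positive maximum.
#' @param dynamic_range_db display dynamic range in dB (default 60).
#' @return matrix of dB values in `[-dynamic_range_db, 0]`.
#' @export
log_compress <- function(env, dynamic_range_db = 60) {
  mx <- max(env)
  if (!is.finite(mx) || mx <= 0) stop("all-zero image cannot be log-compressed")
  pmax(20 * log10(pmax(env, mx * 10^(-dynamic_range_db / 20 - 2)) / mx),
       -dynamic_range_db)
}

#' @export
print.sta_image_set <- function(x, ...) {
  cat(sprintf("STA image set: %d x %d pixels, methods: %s\n",
              x$grid$n_axial, x$grid$n_lateral,
              paste(names(x$images), collapse = ", ")))
  if (!is.null(x$log$n_solve_fallback))
    cat(sprintf("  per-pixel fallbacks: solve %g, L' clamps %g, MSR caps %g\n",
                x$log$n_solve_fallback, x$log$n_lprime_clamped,
                x$log$n_msr_capped))
  invisible(x)
}

#' @export
summary.sta_image_set <- function(object, rois = NULL, ...) {
  if (!is.null(rois)) return(image_metrics(object, rois))
  data.frame(method = names(object$images),
             peak = vapply(object$images, function(im) max(Mod(im)), 0),
             row.names = NULL)
}

#' Display a beamformed image
#'
#' Log-compressed gray-scale display with depth running downward.
#'
#' @param x an `sta_image_set`.
#' @param method which image to show (default first).
#' @param dynamic_range_db display range in dB.
#' @param ... passed to [graphics::image()].
#' @export
plot.sta_image_set <- function(x, method = names(x$images)[1],
                               dynamic_range_db = 60, ...) {
  db <- log_compress(envelope(x$images[[method]]), dynamic_range_db)
  image(x = x$grid$lateral_x * 1e3, y = x$grid$axial_z * 1e3,
        z = t(db), col = gray.colors(256, 0, 1), ylim = rev(range(x$grid$axial_z * 1e3)),
        xlab = "lateral [mm]", ylab = "depth [mm]",
        main = sprintf("%s (%g dB)", method, dynamic_range_db),
        useRaster = TRUE, ...)
  box()
  invisible(x)
}
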