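#' Region-of-interest constructors
#'
#' `roi_circle` is a disc in the image plane; `roi_rect` an axis-aligned box.
#' Positions in meters.
#'
#' @param center_x,center_z disc center.
#' @param radius disc radius.
#' @return an object of class `roi`.
#' @export
roi_circle <- function(center_x, center_z, radius) {
  if (radius <= 0) stop("roi radius must be positive")
  structure(list(type = "circle", center = c(center_x, center_z),
                 radius = radius), class = "roi")
}

#' @rdname roi_circle
#' @param x_range,z_range box extents, each `c(min, max)`.
#' @export
roi_rect <- function(x_range, z_range) {
  structure(list(type = "rect", x_range = sort(x_range),
                 z_range = sort(z_range)), class = "roi")
}

#' Logical pixel mask of an ROI on a grid
#' @param grid an [imaging_grid()].
#' @param roi an ROI from [roi_circle()] or [roi_rect()].
#' @return logical matrix (axial x lateral).
#' @export
roi_mask <- function(grid, roi) {
  X <- matrix(grid$lateral_x, grid$n_axial, grid$n_lateral, byrow = TRUE)
  Z <- matrix(grid$axial_z, grid$n_axial, grid$n_lateral)
  if (roi$type == "circle")
    (X - roi$center[1])^2 + (Z - roi$center[2])^2 <= roi$radius^2
  else
    X >= roi$x_range[1] & X <= roi$x_range[2] &
      Z >= roi$z_range[1] & Z <= roi$z_range[2]
}

#' Lateral -6 dB full-width at half-maximum of a point target
#'
#' Finds the envelope peak inside the ROI, extracts the lateral profile
#' through the peak's axial row, and measures the width between the two
#' -6 dB crossings relative to the peak, interpolating linearly in dB
#' between grid samples.
#'
#' @param env envelope matrix (axial x lateral).
#' @param grid an [imaging_grid()].
#' @param point_roi ROI containing the point target.
#' @return width in millimeters.
#' @export
lateral_fwhm <- function(env, grid, point_roi) {
  m <- roi_mask(grid, point_roi)
  if (!any(m)) stop("empty point ROI")
  e <- env
  e[!m] <- -Inf
  pk <- arrayInd(which.max(e), dim(e))
  iz <- pk[1]; ixp <- pk[2]
  cols <- which(apply(m, 2, any))
  prof <- env[iz, cols]
  x <- grid$lateral_x[cols]
  ip <- which(cols == ixp)
  db <- 20 * log10(pmax(prof, .Machine$double.xmin) / prof[ip])
  cross <- function(idx_seq) {
    prev <- ip
    for (i in idx_seq) {
      if (db[i] <= -6) {
        # linear interpolation in dB between samples i and prev
        f <- (-6 - db[prev]) / (db[i] - db[prev])
        return(x[prev] + f * (x[i] - x[prev]))
      }
      prev <- i
    }
    NULL
  }
  xr <- if (ip < length(db)) cross((ip + 1):length(db)) else NULL
  xl <- if (ip > 1) cross((ip - 1):1) else NULL
  if (is.null(xl) || is.null(xr))
    stop("unresolved point: no -6 dB crossing inside ROI")
  (xr - xl) * 1e3
}

#' Contrast ratio in dB
#'
#' `CR = 20*log10(mu_cyst / mu_bck)` with means of the pre-compression
#' envelope; negative for anechoic/hypoechoic targets.  `mu_cyst = 0`
#' returns `-Inf`.
#'
#' @param env_cyst,env_bck envelope pixels of the two regions.
#' @return scalar in dB.
#' @export
contrast_ratio <- function(env_cyst, env_bck) {
  if (length(env_cyst) == 0L || length(env_bck) == 0L) stop("empty ROI")
  mu_b <- mean(env_bck)
  if (mu_b <= 0) stop("background mean must be positive")
  mu_c <- mean(env_cyst)
  if (mu_c == 0) return(-Inf)
  20 * log10(mu_c / mu_b)
}

#' Generalized contrast-to-noise ratio
#'
#' `gCNR = 1 - sum_b min(p_cyst(b), p_bck(b))` with PDFs estimated on a
#' common equal-width binning spanning the pooled range of the two
#' pre-compression envelope samples.
#'
#' @param env_cyst,env_bck envelope pixels of the two regions.
#' @param n_bins number of histogram bins (default 256).
#' @return scalar in \[0, 1\].
#' @export
gcnr <- function(env_cyst, env_bck, n_bins = 256L) {
  if (length(env_cyst) == 0L || length(env_bck) == 0L) stop("empty ROI")
  if (length(env_cyst) < 100L || length(env_bck) < 100L)
    warning("fewer than 100 pixels in an ROI: gCNR estimate is noisy")
  r <- range(c(env_cyst, env_bck))
  if (r[1] == r[2]) return(0)   # identical constant sets overlap fully
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  pc <- tabulate(pmin(findInterval(env_cyst, breaks, rightmost.closed = TRUE),
                      n_bins), n_bins) / length(env_cyst)
  pb <- tabulate(pmin(findInterval(env_bck, breaks, rightmost.closed = TRUE),
                      n_bins), n_bins) / length(env_bck)
  1 - sum(pmin(pc, pb))
}

#' Speckle signal-to-noise ratio
#'
#' `sSNR = mu_bck / sigma_bck` of the pre-compression envelope in a
#' homogeneous speckle region (population standard deviation); about 1.91
#' for fully developed (Rayleigh) speckle.
#'
#' @param env_bck envelope pixels of the speckle region (>= 2).
#' @return dimensionless scalar.
#' @export
ssnr <- function(env_bck) {
  if (length(env_bck) < 2L) stop("need at least 2 pixels")
  mu <- mean(env_bck)
  s <- sqrt(mean((env_bck - mu)^2))
  if (s == 0) stop("zero variance in speckle region")
  mu / s
}

#' Image-quality metrics for every method of an image set
#'
#' Computes lateral FWHM at the point ROI, CR and gCNR between cyst and
#' background ROIs, and background sSNR, per method, on the pre-compression
#' envelope.
#'
#' @param imgset an `sta_image_set` from [beamform_image()].
#' @param rois list with entries `cyst`, `background`, and optionally
#'   `point` (ROIs).
#' @param n_bins gCNR histogram bins.
#' @return data frame of class `sta_metrics` with one row per method.
#' @export
image_metrics <- function(imgset, rois, n_bins = 256L) {
  grid <- imgset$grid
  mc <- roi_mask(grid, rois$cyst)
  mb <- roi_mask(grid, rois$background)
  if (any(mc & mb)) stop("cyst and background ROIs overlap")
  rows <- lapply(names(imgset$images), function(meth) {
    env <- envelope(imgset$images[[meth]])
    fw <- if (!is.null(rois$point))
      tryCatch(lateral_fwhm(env, grid, rois$point), error = function(e) NA_real_)
    else NA_real_
    data.frame(method = meth,
               fwhm_mm = fw,
               cr_db = contrast_ratio(env[mc], env[mb]),
               gcnr = gcnr(env[mc], env[mb], n_bins),
               ssnr = ssnr(env[mb]))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sta_metrics", "data.frame")
  out
}

#' @export
print.sta_metrics <- function(x, ...) {
  y <- as.data.frame(x)
  y$cr_db <- ifelse(is.infinite(y$cr_db) & y$cr_db < 0, "< -100",
                    sprintf("%.1f", y$cr_db))
  print(y, row.names = FALSE, ...)
  invisible(x)
}
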