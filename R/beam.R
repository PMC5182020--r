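# 2-D beam profiles: reconstruction from aperture scans and analytic models.
# Beam-plane coordinates: horizontal = x (along the capillary axis),
# vertical = y; the beam propagates along z. Fluence outside the grid is
# taken as zero.

#' Beam profile
#'
#' A rectangular grid of relative fluence (unitless, maximum 1) with the
#' total flux it carries. `grid[i, j]` is the fluence at vertical position
#' `y_um[i]`, horizontal position `x_um[j]`.
#'
#' @param grid Numeric matrix of non-negative relative fluence values; it is
#'   rescaled so its maximum is 1.
#' @param x_um,y_um Strictly increasing centre coordinates of the grid
#'   columns/rows, micrometres.
#' @param total_flux Total photons s^-1 carried by the beam (> 0).
#' @param photon_energy_kev Optional photon energy in keV.
#' @return An object of class `beam_profile`.
#' @export
beam_profile <- function(grid, x_um, y_um, total_flux,
                         photon_energy_kev = NULL) {
  grid <- as.matrix(grid)
  if (any(grid < 0)) stop("grid values must be >= 0")
  if (max(grid) <= 0) stop("grid must contain a positive value")
  if (!is.numeric(total_flux) || total_flux <= 0) {
    stop("total_flux must be > 0")
  }
  if (length(x_um) != ncol(grid) || length(y_um) != nrow(grid)) {
    stop("axis lengths must match grid dimensions")
  }
  if (any(diff(x_um) <= 0) || any(diff(y_um) <= 0)) {
    stop("axes must be strictly increasing")
  }
  structure(list(grid = grid / max(grid), x_um = as.numeric(x_um),
                 y_um = as.numeric(y_um),
                 pixel_size_um = c(horizontal = mean(diff(x_um)),
                                   vertical = mean(diff(y_um))),
                 total_flux = total_flux,
                 photon_energy_kev = photon_energy_kev),
            class = "beam_profile")
}

#' @export
print.beam_profile <- function(x, ...) {
  cat(sprintf(
    "<beam_profile: %d x %d grid, %.4g x %.4g um pixels, %.3g ph/s>\n",
    nrow(x$grid), ncol(x$grid), x$pixel_size_um[1L], x$pixel_size_um[2L],
    x$total_flux))
  invisible(x)
}

#' Aperture scan of the beam
#'
#' Diode readings recorded while a small circular aperture is stepped across
#' the beam in one direction (typically 10 um steps with a 100 um aperture).
#'
#' @param axis `"horizontal"` or `"vertical"`.
#' @param positions_um Strictly monotone scan positions, micrometres
#'   (>= 3 points).
#' @param readings Non-negative diode readings (arbitrary units).
#' @param aperture_diameter_um Aperture diameter, micrometres (default 100).
#' @return An object of class `aperture_scan`.
#' @export
aperture_scan <- function(axis = c("horizontal", "vertical"), positions_um,
                          readings, aperture_diameter_um = 100) {
  axis <- match.arg(axis)
  if (length(positions_um) < 3L) stop("a scan needs at least 3 points")
  d <- diff(positions_um)
  if (!(all(d > 0) || all(d < 0))) {
    stop("positions must be strictly monotone")
  }
  if (length(readings) != length(positions_um)) {
    stop("readings and positions lengths differ")
  }
  if (any(readings < 0)) stop("diode readings must be >= 0")
  if (all(d < 0)) {  # store ascending
    positions_um <- rev(positions_um)
    readings <- rev(readings)
  }
  structure(list(axis = axis, positions_um = as.numeric(positions_um),
                 readings = as.numeric(readings),
                 aperture_diameter_um = aperture_diameter_um),
            class = "aperture_scan")
}

#' Read a 2-column aperture-scan file
#'
#' Plain ASCII `position_um reading` rows; `#` comments tolerated.
#'
#' @param path File path.
#' @inheritParams aperture_scan
#' @return An [aperture_scan].
#' @export
read_aperture_scan <- function(path, axis = c("horizontal", "vertical"),
                               aperture_diameter_um = 100) {
  axis <- match.arg(axis)
  tab <- utils::read.table(path, comment.char = "#")
  if (ncol(tab) < 2L) stop("expected 2 columns in ", path)
  aperture_scan(axis, tab[[1L]], tab[[2L]],
                aperture_diameter_um = aperture_diameter_um)
}

scan_profile_fun <- function(scan) {
  # smooth 1-D interpolant of one scan; zero outside the measured range
  p <- scan$positions_um
  r <- scan$readings
  if (length(p) >= 4L) {
    f <- stats::splinefun(p, r, method = "natural")
  } else {
    warning("scan has < 4 points; falling back to linear interpolation")
    f <- stats::approxfun(p, r, rule = 1)
  }
  rng <- range(p)
  function(x) {
    y <- ifelse(x < rng[1L] | x > rng[2L], 0, f(x))
    pmax(y, 0)  # fluence is physical; clip spline undershoot
  }
}

axis_mean_profile <- function(scans, grid) {
  vals <- vapply(scans, function(s) {
    v <- scan_profile_fun(s)(grid)
    m <- max(v)
    if (m <= 0) stop("scan carries no positive reading")
    v / m
  }, numeric(length(grid)))
  rowMeans(matrix(vals, ncol = length(scans)))
}

#' Reconstruct a 2-D beam profile from aperture scans
#'
#' Repeat scans along each axis are spline-interpolated (natural cubic;
#' linear with a warning below 4 points), rescaled to unit maximum and
#' averaged into one horizontal and one vertical mean profile. The 2-D
#' profile is their separable (outer) product on a rectangular grid bounded
#' by the edges of the measurement positions, with negative interpolants
#' clipped to zero and the grid maximum normalized to 1. Fluence beyond the
#' grid is zero. The 100 um aperture smooths the true profile; no
#' deconvolution is attempted.
#'
#' @param h_scans,v_scans Lists of [aperture_scan]s (>= 1 each) along the
#'   horizontal and vertical axes.
#' @param total_flux Total photons s^-1 to attach.
#' @param pixel_size_um Output grid pitch; defaults to half the median scan
#'   spacing.
#' @param photon_energy_kev Optional photon energy, keV.
#' @return A [beam_profile].
#' @export
beam_from_scans <- function(h_scans, v_scans, total_flux,
                            pixel_size_um = NULL, photon_energy_kev = NULL) {
  if (inherits(h_scans, "aperture_scan")) h_scans <- list(h_scans)
  if (inherits(v_scans, "aperture_scan")) v_scans <- list(v_scans)
  if (length(h_scans) < 1L || length(v_scans) < 1L) {
    stop("at least one scan per axis is required")
  }
  spacing <- stats::median(unlist(lapply(c(h_scans, v_scans),
                                         function(s) diff(s$positions_um))))
  if (is.null(pixel_size_um)) pixel_size_um <- spacing / 2
  hx_rng <- range(unlist(lapply(h_scans, function(s) s$positions_um)))
  vy_rng <- range(unlist(lapply(v_scans, function(s) s$positions_um)))
  hx <- seq(hx_rng[1L], hx_rng[2L], by = pixel_size_um)
  vy <- seq(vy_rng[1L], vy_rng[2L], by = pixel_size_um)
  hprof <- axis_mean_profile(h_scans, hx)
  vprof <- axis_mean_profile(v_scans, vy)
  beam_profile(outer(vprof, hprof), x_um = hx, y_um = vy,
               total_flux = total_flux,
               photon_energy_kev = photon_energy_kev)
}

#' Analytic beam profiles
#'
#' Lets dose calculations run without measured scan files: a separable
#' Gaussian with given FWHMs (gridded out to +/- 2 FWHM) or a uniform
#' top-hat rectangle.
#'
#' @param shape `"gaussian"` or `"tophat"`.
#' @param fwhm_or_size_um Length-2 vector: Gaussian FWHMs or top-hat edge
#'   lengths (horizontal, vertical), micrometres. A scalar is recycled.
#' @param total_flux Total photons s^-1.
#' @param pixel_size_um Grid pitch, micrometres (default 1).
#' @param photon_energy_kev Optional photon energy, keV.
#' @return A [beam_profile].
#' @export
#' @examples
#' analytic_beam("tophat", c(100, 100), total_flux = 1e12)
analytic_beam <- function(shape = c("gaussian", "tophat"), fwhm_or_size_um,
                          total_flux, pixel_size_um = 1,
                          photon_energy_kev = NULL) {
  shape <- match.arg(shape)
  sz <- rep(as.numeric(fwhm_or_size_um), length.out = 2L)
  if (any(sz <= 0) || pixel_size_um <= 0) stop("dimensions must be > 0")
  p <- pixel_size_um
  if (shape == "tophat") {
    nx <- max(round(sz[1L] / p), 1L)
    ny <- max(round(sz[2L] / p), 1L)
    hx <- (seq_len(nx) - (nx + 1) / 2) * p
    vy <- (seq_len(ny) - (ny + 1) / 2) * p
    grid <- matrix(1, nrow = ny, ncol = nx)
  } else {
    half_n <- function(f) ceiling(2 * f / p)
    nxh <- half_n(sz[1L]); nyh <- half_n(sz[2L])
    hx <- (-nxh:nxh) * p
    vy <- (-nyh:nyh) * p
    sx <- sz[1L] / (2 * sqrt(2 * log(2)))
    sy <- sz[2L] / (2 * sqrt(2 * log(2)))
    grid <- outer(exp(-vy^2 / (2 * sy^2)), exp(-hx^2 / (2 * sx^2)))
  }
  beam_profile(grid, x_um = hx, y_um = vy, total_flux = total_flux,
               photon_energy_kev = photon_energy_kev)
}

#' Peak flux density implied by a beam profile
#'
#' The scale that converts the relative grid to photons s^-1 um^-2 such
#' that the grid integral reproduces `total_flux`.
#'
#' @param beam A [beam_profile].
#' @return Photons s^-1 um^-2 at grid value 1.
#' @export
beam_flux_density_scale <- function(beam) {
  stopifnot(inherits(beam, "beam_profile"))
  px <- prod(beam$pixel_size_um)
  beam$total_flux / (sum(beam$grid) * px)
}

#' Relative fluence of a beam at arbitrary points
#'
#' Bilinear interpolation of the beam grid; zero at and beyond the grid
#' boundaries.
#'
#' @param beam A [beam_profile].
#' @param x_um,y_um Numeric vectors of horizontal/vertical coordinates
#'   (recycled to a common length), micrometres.
#' @return Numeric vector of relative fluence values in `[0, 1]`.
#' @export
beam_relative_fluence <- function(beam, x_um, y_um) {
  stopifnot(inherits(beam, "beam_profile"))
  n <- max(length(x_um), length(y_um))
  x <- rep_len(as.numeric(x_um), n)
  y <- rep_len(as.numeric(y_um), n)
  hx <- beam$x_um; vy <- beam$y_um
  out <- numeric(n)
  ok <- x >= hx[1L] & x <= hx[length(hx)] & y >= vy[1L] & y <= vy[length(vy)]
  if (!any(ok)) return(out)
  xi <- pmin(findInterval(x[ok], hx), length(hx) - 1L)
  yi <- pmin(findInterval(y[ok], vy), length(vy) - 1L)
  tx <- (x[ok] - hx[xi]) / (hx[xi + 1L] - hx[xi])
  ty <- (y[ok] - vy[yi]) / (vy[yi + 1L] - vy[yi])
  g <- beam$grid
  v <- g[cbind(yi, xi)] * (1 - tx) * (1 - ty) +
    g[cbind(yi, xi + 1L)] * tx * (1 - ty) +
    g[cbind(yi + 1L, xi)] * (1 - tx) * ty +
    g[cbind(yi + 1L, xi + 1L)] * tx * ty
  out[ok] <- v
  out
}

#' Export a beam grid as a plain-text matrix or PNG image
#'
#' @param beam A [beam_profile].
#' @param path Output path; `.png` gives a linear-greyscale raster,
#'   anything else a whitespace-separated text matrix (rows = vertical).
#' @return `path`, invisibly.
#' @export
write_beam <- function(beam, path) {
  stopifnot(inherits(beam, "beam_profile"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    grDevices::png(path, width = 480, height = 480)
    on.exit(grDevices::dev.off())
    graphics::image(beam$x_um, beam$y_um, t(beam$grid),
                    col = grDevices::gray.colors(256, start = 0, end = 1),
                    xlab = "horizontal (um)", ylab = "vertical (um)",
                    main = "beam profile", useRaster = TRUE)
  } else {
    utils::write.table(format(beam$grid, digits = 6), path,
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
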