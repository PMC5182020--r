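#' One-dimensional scattering curve
#'
#' Container for a single azimuthally averaged SAXS frame: momentum transfer
#' `q` (nm^-1, strictly increasing), scattered intensity `I(q)` and, when
#' available, the per-point intensity uncertainty `sigma`.
#'
#' @param q Numeric vector of momentum transfer values in nm^-1, strictly
#'   increasing, length >= 2.
#' @param intensity Numeric vector of scattered intensities, same length as
#'   `q`. Units are arbitrary unless the data were calibrated to an absolute
#'   scale upstream.
#' @param sigma Optional numeric vector of non-negative intensity
#'   uncertainties, same length as `q`.
#' @param label Optional frame identifier (single string).
#'
#' @return An object of class `scatter_curve`: a list with elements `q`,
#'   `intensity`, `sigma` (may be `NULL`) and `label`.
#' @export
#' @examples
#' sc <- scatter_curve(q = c(0.1, 0.2, 0.3), intensity = c(5, 4, 3))
scatter_curve <- function(q, intensity, sigma = NULL, label = NULL) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) < 2L) {
    stop("a scatter_curve needs at least 2 points, got ", length(q))
  }
  if (length(intensity) != length(q)) {
    stop("q and intensity lengths differ (", length(q), " vs ",
         length(intensity), ")")
  }
  if (any(!is.finite(q)) || any(!is.finite(intensity))) {
    stop("q and intensity must be finite")
  }
  if (any(diff(q) <= 0)) {
    stop("q must be strictly increasing")
  }
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) {
      stop("sigma length differs from q length")
    }
    if (any(!is.finite(sigma)) || any(sigma < 0)) {
      stop("sigma must be finite and >= 0")
    }
  }
  structure(
    list(q = q, intensity = intensity, sigma = sigma,
         label = if (is.null(label)) NULL else as.character(label)[1L]),
    class = "scatter_curve"
  )
}

#' @export
print.scatter_curve <- function(x, ...) {
  cat(sprintf("<scatter_curve%s: %d points, q = [%.4g, %.4g] nm^-1%s>\n",
              if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) ", no sigma" else ""))
  invisible(x)
}

#' @export
length.scatter_curve <- function(x) length(x$q)

is_scatter_curve <- function(x) inherits(x, "scatter_curve")

stop_if_grid_mismatch <- function(a, b) {
  if (length(a$q) != length(b$q) || !identical(a$q, b$q)) {
    stop("curves do not share an identical q grid; ",
         "frames from different integration grids cannot be combined ",
         "(no interpolation is performed)")
  }
  invisible(TRUE)
}

#' Ordered series of scattering frames
#'
#' Holds the frames of one exposure run in acquisition order. All curves must
#' share a bit-identical q grid (frames of a run come off one azimuthal
#' integration grid; resampling would alter the CorMap statistic).
#'
#' @param curves List of [scatter_curve] objects on one common q grid.
#' @param exposure_time_per_frame Exposure time per frame in seconds
#'   (optional until the dose step).
#' @param flux_per_frame Optional numeric vector, photons s^-1 for each
#'   frame.
#' @param dose_per_frame Optional numeric vector, cumulative
#'   diffraction-weighted dose in kGy at the end of each frame
#'   (non-decreasing).
#'
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(curves, exposure_time_per_frame = NULL,
                         flux_per_frame = NULL, dose_per_frame = NULL) {
  if (!is.list(curves) || length(curves) < 1L ||
      !all(vapply(curves, is_scatter_curve, logical(1)))) {
    stop("curves must be a non-empty list of scatter_curve objects")
  }
  q0 <- curves[[1L]]$q
  for (i in seq_along(curves)) {
    if (!identical(curves[[i]]$q, q0)) {
      stop("frame ", i, " is not on the same q grid as frame 1")
    }
  }
  m <- length(curves)
  if (!is.null(flux_per_frame) && length(flux_per_frame) != m) {
    stop("flux_per_frame length must equal the number of frames")
  }
  if (!is.null(dose_per_frame)) {
    if (length(dose_per_frame) != m) {
      stop("dose_per_frame length must equal the number of frames")
    }
    if (any(diff(dose_per_frame) < 0)) {
      stop("cumulative dose_per_frame must be non-decreasing")
    }
  }
  structure(
    list(curves = curves,
         exposure_time_per_frame = exposure_time_per_frame,
         flux_per_frame = flux_per_frame,
         dose_per_frame = dose_per_frame),
    class = "frame_series"
  )
}

#' @export
length.frame_series <- function(x) length(x$curves)

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series: %d frames x %d points%s>\n",
              length(x$curves), length(x$curves[[1L]]$q),
              if (is.null(x$dose_per_frame)) "" else ", doses attached"))
  invisible(x)
}

#' Read an ATSAS-style 3-column ASCII scattering curve
#'
#' Parses the whitespace-separated `q I [sigma]` format consumed by the ATSAS
#' tools (DATCMP dialect). Leading text headers and `#` comment lines are
#' tolerated; data rows must have 2 or 3 numeric columns.
#'
#' @param path Path to the file.
#' @param q_unit Unit of the q column: `"nm^-1"` (default, stored as-is) or
#'   `"A^-1"` (converted to nm^-1 by multiplying by 10).
#' @return A [scatter_curve]; `sigma` is `NULL` for 2-column files. The file
#'   base name becomes the label.
#' @export
read_dat <- function(path, q_unit = c("nm^-1", "A^-1")) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  ncol_seen <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    toks <- strsplit(ln, "[[:space:]]+")[[1L]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      # header lines (all non-numeric) are tolerated before data starts;
      # a partially numeric row after data begins is a real parse error
      if (length(rows) == 0L && all(is.na(vals))) next
      stop("malformed numeric row at line ", i, " of ", path, ": '", ln, "'")
    }
    if (!length(vals) %in% c(2L, 3L)) {
      if (length(rows) == 0L) next
      stop("row with ", length(vals), " columns at line ", i, " of ", path,
           "; expected 2 or 3")
    }
    if (is.na(ncol_seen)) ncol_seen <- length(vals)
    if (length(vals) != ncol_seen) {
      stop("inconsistent column count at line ", i, " of ", path)
    }
    rows[[length(rows) + 1L]] <- vals
  }
  if (length(rows) < 2L) {
    stop("file ", path, " contains fewer than 2 data rows")
  }
  m <- do.call(rbind, rows)
  q <- m[, 1L]
  if (q_unit == "A^-1") q <- q * 10
  if (any(diff(q) <= 0)) {
    stop("non-monotonic q column in ", path)
  }
  scatter_curve(
    q = q, intensity = m[, 2L],
    sigma = if (ncol_seen == 3L) m[, 3L] else NULL,
    label = sub("\\.[^.]*$", "", basename(path))
  )
}

#' Write a scattering curve as 3-column ASCII
#'
#' Emits the same `q I [sigma]` dialect that [read_dat()] reads, with values
#' in 12-significant-digit scientific notation and q in nm^-1, so a write
#' followed by a read reproduces the curve to better than 1e-9 relative.
#'
#' @param curve A [scatter_curve].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dat <- function(curve, path) {
  stopifnot(is_scatter_curve(curve))
  hdr <- sprintf("# %s  (q in nm^-1)",
                 if (is.null(curve$label)) "scattering curve" else curve$label)
  fmt <- function(v) formatC(v, format = "e", digits = 11)
  if (is.null(curve$sigma)) {
    body <- paste(fmt(curve$q), fmt(curve$intensity))
  } else {
    body <- paste(fmt(curve$q), fmt(curve$intensity), fmt(curve$sigma))
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Average scattering curves pointwise
#'
#' Used to build the buffer reference: the buffer-only frames of a run are
#' averaged before subtraction. Sigmas, when present on every input, are
#' propagated as (1/m) sqrt(sum sigma_i^2); otherwise the output has none.
#'
#' @param curves Non-empty list of [scatter_curve]s on one q grid.
#' @return A [scatter_curve] with the pointwise mean intensity.
#' @export
average_curves <- function(curves) {
  if (!is.list(curves) || length(curves) < 1L ||
      !all(vapply(curves, is_scatter_curve, logical(1)))) {
    stop("curves must be a non-empty list of scatter_curve objects")
  }
  for (cu in curves[-1L]) stop_if_grid_mismatch(curves[[1L]], cu)
  m <- length(curves)
  imat <- vapply(curves, function(cu) cu$intensity,
                 numeric(length(curves[[1L]]$q)))
  imat <- matrix(imat, ncol = m)
  have_sigma <- all(vapply(curves, function(cu) !is.null(cu$sigma), logical(1)))
  sig <- NULL
  if (have_sigma) {
    smat <- matrix(vapply(curves, function(cu) cu$sigma,
                          numeric(length(curves[[1L]]$q))), ncol = m)
    sig <- sqrt(rowSums(smat^2)) / m
  }
  scatter_curve(curves[[1L]]$q, rowMeans(imat), sigma = sig,
                label = sprintf("mean_of_%d", m))
}

#' Subtract a buffer curve from a sample curve
#'
#' Pointwise intensity difference on a shared q grid; sigmas combine in
#' quadrature when both curves carry them.
#'
#' @param sample,buffer [scatter_curve]s on identical q grids.
#' @return A [scatter_curve] of the difference.
#' @export
subtract_buffer <- function(sample, buffer) {
  stopifnot(is_scatter_curve(sample), is_scatter_curve(buffer))
  stop_if_grid_mismatch(sample, buffer)
  sig <- NULL
  if (!is.null(sample$sigma) && !is.null(buffer$sigma)) {
    sig <- sqrt(sample$sigma^2 + buffer$sigma^2)
  }
  scatter_curve(sample$q, sample$intensity - buffer$intensity, sigma = sig,
                label = sample$label)
}

#' Crop a curve to a closed q interval
#'
#' Retains exactly the points with `q_min <= q <= q_max`. Crop bounds are a
#' user choice (typically by inspection of the noisy extremes); no automatic
#' criterion is applied.
#'
#' @param curve A [scatter_curve].
#' @param q_min,q_max Closed interval bounds in nm^-1, `q_min < q_max`.
#' @return The cropped [scatter_curve] (>= 2 points must survive).
#' @export
crop_curve <- function(curve, q_min, q_max) {
  stopifnot(is_scatter_curve(curve))
  if (!(q_min < q_max)) stop("q_min must be < q_max")
  keep <- curve$q >= q_min & curve$q <= q_max
  if (sum(keep) < 2L) {
    stop("cropping [", q_min, ", ", q_max, "] leaves ", sum(keep),
         " point(s); at least 2 required")
  }
  scatter_curve(curve$q[keep], curve$intensity[keep],
                sigma = if (is.null(curve$sigma)) NULL else curve$sigma[keep],
                label = curve$label)
}

#' Apply a curve operation to every frame of a series
#'
#' @param series A [frame_series].
#' @param f Function taking and returning a [scatter_curve].
#' @return A new [frame_series] with the same metadata.
#' @export
map_frames <- function(series, f) {
  stopifnot(inherits(series, "frame_series"))
  frame_series(lapply(series$curves, f),
               exposure_time_per_frame = series$exposure_time_per_frame,
               flux_per_frame = series$flux_per_frame,
               dose_per_frame = series$dose_per_frame)
}
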