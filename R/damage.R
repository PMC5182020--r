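# Damage-onset detection, threshold dose, RDOT ranking and the low-angle
# signal-reduction metric.

#' Pre-flight similarity check of the first three frames
#'
#' Before any damage analysis, the first three frames are compared pairwise
#' (1-2, 1-3, 2-3); the run qualifies when every pair has p > alpha, i.e.
#' the experiment starts from mutually consistent frames.
#'
#' @param series A [frame_series] with >= 3 frames.
#' @param alpha Significance level (default 0.01).
#' @return `TRUE` when all three pairwise tests give p > alpha.
#' @export
preflight_check <- function(series, alpha = 0.01) {
  stopifnot(inherits(series, "frame_series"))
  if (length(series$curves) < 3L) {
    stop("preflight check needs at least 3 frames")
  }
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  all(vapply(pairs, function(ij) {
    compare_pair(series$curves[[ij[1L]]], series$curves[[ij[2L]]],
                 alpha = alpha)$p_value > alpha
  }, logical(1)))
}

#' Detect radiation-damage onset
#'
#' Damage is taken to be significant at the earliest run of `k_consecutive`
#' consecutive frames all classified dissimilar from the reference (three by
#' default, to exclude single-frame outliers such as bubbles or particles
#' crossing the beam). The threshold dose D_t is the cumulative dose at the
#' first frame of that run.
#'
#' @param results A `cormap_frame_results` table from
#'   [compare_to_reference()] (frames in acquisition order).
#' @param doses Optional cumulative dose (kGy) for every frame of the
#'   original series, indexed by frame number (i.e. `doses[f]` is the dose
#'   at frame `f`, reference frame included).
#' @param k_consecutive Number of consecutive dissimilar frames required
#'   (default 3).
#' @param alpha Significance level used for the dissimilar calls (default
#'   0.01; classifications are recomputed from the stored p-values).
#' @param preflight_ok Optional logical flag from [preflight_check()];
#'   stamped onto the result. A failed pre-flight does not abort detection,
#'   it marks the result unreliable.
#' @return An object of class `onset_result`: `onset_frame` (frame number
#'   or `NA`), `threshold_dose_kgy` (`NA` unless onset found and doses
#'   supplied), `preflight_ok`, `k_consecutive`, `alpha`.
#' @export
detect_onset <- function(results, doses = NULL, k_consecutive = 3L,
                         alpha = 0.01, preflight_ok = NA) {
  stopifnot(inherits(results, "cormap_frame_results"))
  k_consecutive <- as.integer(k_consecutive)
  stopifnot(k_consecutive >= 1L)
  frames <- results$frame
  if (!is.null(doses) && max(frames) > length(doses)) {
    stop("doses vector (length ", length(doses),
         ") does not cover frame ", max(frames))
  }
  dis <- results$p < alpha
  onset <- NA_integer_
  m <- length(dis)
  if (m >= k_consecutive) {
    run <- 0L
    for (i in seq_len(m)) {
      # require consecutive frame numbers, not merely consecutive tests
      contiguous <- i > 1L && frames[i] == frames[i - 1L] + 1L
      run <- if (dis[i]) (if (contiguous) run + 1L else 1L) else 0L
      if (run >= k_consecutive) {
        onset <- frames[i - k_consecutive + 1L]
        break
      }
    }
  }
  d_t <- if (!is.na(onset) && !is.null(doses)) doses[onset] else NA_real_
  structure(list(onset_frame = onset, threshold_dose_kgy = d_t,
                 preflight_ok = preflight_ok,
                 k_consecutive = k_consecutive, alpha = alpha),
            class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  if (is.na(x$onset_frame)) {
    cat("<onset_result: no onset detected>\n")
  } else {
    cat(sprintf("<onset_result: onset at frame %d%s%s>\n", x$onset_frame,
                if (is.na(x$threshold_dose_kgy)) "" else
                  sprintf(", D_t = %.4g kGy", x$threshold_dose_kgy),
                if (isFALSE(x$preflight_ok)) " [preflight FAILED]" else ""))
  }
  invisible(x)
}

#' Radiation damage onset threshold (RDOT) ratio
#'
#' Ratio of the median threshold dose with an additive radioprotectant to
#' the median threshold dose of the same sample without protection. Values
#' above 1 indicate improved radiation tolerance, below 1 a reduction. The
#' median of an even number of repeats is the mean of the two central
#' values.
#'
#' @param thresholds_with Positive threshold doses (kGy) of the protected
#'   repeats.
#' @param thresholds_without Positive threshold doses (kGy) of the
#'   unprotected repeats.
#' @return An object of class `rdot_result`: `ratio`, `n_with`,
#'   `n_without`, and the two medians.
#' @export
#' @examples
#' rdot(c(10, 20, 30), c(5, 10, 15))  # ratio 2
rdot <- function(thresholds_with, thresholds_without) {
  if (length(thresholds_with) < 1L || length(thresholds_without) < 1L) {
    stop("both threshold lists must be non-empty")
  }
  if (any(thresholds_with <= 0) || any(thresholds_without <= 0)) {
    stop("threshold doses must be positive")
  }
  mw <- stats::median(thresholds_with)
  mo <- stats::median(thresholds_without)
  structure(list(ratio = mw / mo,
                 median_with_kgy = mw, median_without_kgy = mo,
                 n_with = length(thresholds_with),
                 n_without = length(thresholds_without)),
            class = "rdot_result")
}

#' @export
print.rdot_result <- function(x, ...) {
  cat(sprintf("<rdot: %.3g (median %.4g / %.4g kGy, n = %d/%d)>\n",
              x$ratio, x$median_with_kgy, x$median_without_kgy,
              x$n_with, x$n_without))
  invisible(x)
}

#' Low-angle scattered-signal reduction
#'
#' Quantifies how much an additive dims the useful signal: the mean of the
#' pointwise intensity ratio protected/unprotected over the first
#' `n_low_q` points (lowest q, after any cropping), subtracted from 1.
#' Zero means no reduction; 0.2 means a 20% loss.
#'
#' @param protected,unprotected [scatter_curve]s on identical q grids with
#'   >= `n_low_q` points; unprotected intensities must be non-zero over the
#'   window.
#' @param n_low_q Window length (default 20 points).
#' @return The fractional reduction (<= 1; negative when the signal
#'   increases).
#' @export
signal_reduction <- function(protected, unprotected, n_low_q = 20L) {
  stopifnot(is_scatter_curve(protected), is_scatter_curve(unprotected))
  stop_if_grid_mismatch(protected, unprotected)
  n_low_q <- as.integer(n_low_q)
  if (n_low_q < 1L) stop("n_low_q must be >= 1")
  if (length(protected$q) < n_low_q) {
    stop("curves have ", length(protected$q), " points; need >= ", n_low_q)
  }
  idx <- seq_len(n_low_q)
  denom <- unprotected$intensity[idx]
  if (any(denom == 0)) {
    stop("unprotected intensity is zero inside the low-q window")
  }
  1 - mean(protected$intensity[idx] / denom)
}
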