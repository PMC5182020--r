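# The three visual analytics: pairwise correlation map, reference scatter
# of C against frame/dose, and the all-pairwise class heat map. Colour
# semantics live in one place: similar -> blue, borderline -> green,
# dissimilar -> orange; the classification itself comes from the
# statistics module.

#' Plot style for similarity classes
#'
#' @param similar,borderline,dissimilar Colours for the three classes.
#' @return A named character vector of class colours.
#' @export
cormap_style <- function(similar = "#2166ac", borderline = "#4dac26",
                         dissimilar = "#e66101") {
  cols <- c(similar = similar, borderline = borderline,
            dissimilar = dissimilar)
  if (anyDuplicated(cols)) stop("the three class colours must be distinct")
  cols
}

open_png <- function(out, width, height) {
  grDevices::png(out, width = width, height = height)
}

#' Render the pairwise correlation map of two frames
#'
#' An n x n black/white raster of sign(d_i) * sign(d_j): similar frames
#' give a randomized lattice, systematic differences give large uniform
#' blocks whose edge length is the longest-run statistic C.
#'
#' @param a,b [scatter_curve]s on identical q grids.
#' @param out Output PNG path.
#' @return `out`, invisibly.
#' @export
plot_cormap <- function(a, b, out) {
  m <- cormap_matrix(a, b)
  n <- nrow(m)
  open_png(out, 480, 480)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  col = c("black", "white"), zlim = c(-1, 1),
                  xlab = "point index", ylab = "point index",
                  main = "pairwise correlation map", useRaster = TRUE)
  invisible(out)
}

#' Scatter plot of C against frame number (and dose)
#'
#' One point per frame compared with the reference: circles for similar,
#' squares for borderline, triangles for dissimilar, coloured by class.
#' When cumulative doses are supplied, a secondary dose axis is drawn on
#' top.
#'
#' @param results A `cormap_frame_results` table from
#'   [compare_to_reference()].
#' @param doses Optional cumulative dose (kGy) per frame of the original
#'   series, indexed by frame number.
#' @param out Output PNG path.
#' @param style Class colours from [cormap_style()].
#' @return `out`, invisibly.
#' @export
plot_reference_scatter <- function(results, doses = NULL, out,
                                   style = cormap_style()) {
  stopifnot(inherits(results, "cormap_frame_results"))
  cls <- results$classification
  pch <- c(similar = 21, borderline = 22, dissimilar = 24)[cls]
  col <- style[cls]
  open_png(out, 640, 480)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, if (is.null(doses)) 2 else 4, 1))
  graphics::plot(results$frame, results$C, pch = pch, bg = col, col = col,
                 xlab = "frame number", ylab = "longest run C",
                 main = sprintf("CorMap vs frame %d", attr(results, "ref_index")))
  if (!is.null(doses)) {
    at <- pretty(results$frame)
    at <- at[at >= 1 & at <= length(doses)]
    graphics::axis(3, at = at, labels = signif(doses[pmax(at, 1)], 3))
    graphics::mtext("cumulative DWD (kGy)", side = 3, line = 2.2,
                    cex = 0.9)
  }
  graphics::legend("topleft", legend = names(style), pt.bg = style,
                   col = style, pch = c(21, 22, 24), bty = "n",
                   title = sprintf("alpha = %.3g", attr(results, "alpha")))
  invisible(out)
}

#' Heat map of all pairwise frame comparisons
#'
#' An m x m raster coloured by similarity class; row/column 1 holds the
#' comparisons with the first frame; the image is symmetric.
#'
#' @param pm A `pairwise_matrix` from [all_pairwise()].
#' @param out Output PNG path.
#' @param style Class colours from [cormap_style()].
#' @return `out`, invisibly.
#' @export
plot_pairwise_heatmap <- function(pm, out, style = cormap_style()) {
  stopifnot(inherits(pm, "pairwise_matrix"))
  codes <- matrix(match(pm$class_matrix,
                        c("similar", "borderline", "dissimilar")),
                  pm$m, pm$m)
  open_png(out, 560, 520)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::image(seq_len(pm$m), seq_len(pm$m),
                  t(codes[pm$m:1, , drop = FALSE]),
                  col = unname(style), zlim = c(1, 3),
                  xlab = "frame", ylab = "reference frame",
                  main = "all pairwise CorMap comparisons",
                  useRaster = TRUE, axes = FALSE)
  graphics::axis(1)
  at <- pretty(seq_len(pm$m))
  at <- at[at >= 1 & at <= pm$m]
  graphics::axis(2, at = pm$m - at + 1, labels = at)
  graphics::legend("topright", legend = names(style), fill = style,
                   bty = "n", bg = "white",
                   title = sprintf("alpha = %.3g", pm$alpha))
  invisible(out)
}
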