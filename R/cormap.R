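# CorMap frame-similarity test: sign-difference vectors, longest-run
# statistic C, and exact longest-run (Schilling) tail probabilities under
# the fair-coin null.

#' Sign vector of the difference of two curves
#'
#' Elementwise sign of `I_a - I_b` on a shared q grid. Under the null that
#' both frames come from the same distribution each sign is a fair coin.
#' Exact zero differences are tie cases: a zero inherits the sign of the
#' previous non-zero difference (run-extending); leading zeros inherit the
#' first non-zero sign; an all-zero difference returns all +1 (the identical
#' frames special case handled by [compare_pair()]).
#'
#' @param a,b [scatter_curve]s on identical q grids.
#' @return Integer vector of +1/-1 values.
#' @export
sign_vector <- function(a, b) {
  stopifnot(is_scatter_curve(a), is_scatter_curve(b))
  stop_if_grid_mismatch(a, b)
  d <- a$intensity - b$intensity
  s <- sign(d)
  nz <- which(s != 0)
  if (length(nz) == 0L) return(rep(1L, length(s)))
  if (length(nz) < length(s)) {
    # carry last non-zero sign forward; leading zeros take the first sign
    filled <- cumsum(s != 0)
    carried <- s[nz][pmax(filled, 1L)]
    s <- carried
  }
  as.integer(s)
}

#' Longest constant-sign run
#'
#' @param signs Non-empty vector of +1/-1 values.
#' @return Integer length C of the longest contiguous constant stretch.
#' @export
longest_run <- function(signs) {
  if (length(signs) == 0L) stop("signs must be non-empty")
  max(rle(as.vector(signs))$lengths)
}

.schilling_cache <- new.env(parent = emptyenv())

compositions_leq <- function(n, k) {
  # number of compositions of n into parts of size <= k,
  # F_k(i) = sum_{j=1..min(i,k)} F_k(i-j), F_k(0) = 1; exact in doubles
  # while F stays below 2^53 (guaranteed for n <= 50 since F <= 2^(n-1))
  f <- numeric(n + 1L)
  f[1L] <- 1
  for (i in seq_len(n)) {
    jmax <- min(i, k)
    f[i + 1L] <- sum(f[(i - jmax + 1L):i])
  }
  f[n + 1L]
}

prob_max_run_geq <- function(n, C) {
  # direct tail recurrence, equivalent to 1 - 2 F_{C-1}(n) / 2^n but free
  # of cancellation (only non-negative terms are added):
  #   t(i) = 0 for i <= C - 1
  #   t(i) = 2^-(C-1) + sum_{j=1..C-1} 2^-j t(i-j) for i >= C
  k <- C - 1L
  t <- numeric(n + 1L)  # t[i + 1] holds t(i)
  pow <- 2^-(1:k)
  base <- 2^-k
  for (i in C:n) {
    t[i + 1L] <- base + sum(t[i:(i - k + 1L)] * pow)
  }
  t[n + 1L]
}

#' Exact longest-run (Schilling) tail probability
#'
#' P(longest run >= C) among n fair-coin outcomes:
#' `1 - 2 F_{C-1}(n) / 2^n`, where `F_k(n)` counts compositions of n into
#' parts <= k. For n <= 50 the count recurrence is carried out exactly in
#' double precision (all intermediates < 2^53 and the division is by a
#' power of two); larger n use the equivalent probability-space recurrence,
#' stable to ~1e-15.
#'
#' @param n Number of points (>= 1).
#' @param C Observed longest run, `1 <= C <= n + 1`.
#' @return The tail probability in `[0, 1]`. `C = 1` gives exactly 1;
#'   `C = n + 1` gives exactly 0.
#' @export
#' @examples
#' schilling_pvalue(10, 5)  # 222/1024
schilling_pvalue <- function(n, C) {
  n <- as.integer(n); C <- as.integer(C)
  if (n < 1L) stop("n must be >= 1")
  if (C < 1L || C > n + 1L) {
    stop("C must satisfy 1 <= C <= n + 1 (got C = ", C, ", n = ", n, ")")
  }
  if (C == 1L) return(1)
  if (C == n + 1L) return(0)
  key <- paste0(n, ":", C)
  hit <- .schilling_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- C - 1L
  p <- if (n <= 50L) {
    1 - 2 * compositions_leq(n, k) / 2^n
  } else if (2L * C > n) {
    # runs of length >= C cannot overlap or repeat: counting sequences by
    # the unique start of their single long run gives (n - C + 2) * 2^-C,
    # exact in doubles and free of the cancellation of the 1 - P form
    (n - C + 2) * 2^-C
  } else {
    prob_max_run_geq(n, C)
  }
  p <- min(max(p, 0), 1)
  assign(key, p, envir = .schilling_cache)
  p
}

classify_pvalue <- function(p, alpha) {
  # colour semantics of the similarity classes:
  # similar (blue)   <=> p == 1
  # dissimilar       <=> p < alpha
  # borderline       <=> alpha <= p < 1
  ifelse(p == 1, "similar", ifelse(p < alpha, "dissimilar", "borderline"))
}

cormap_result <- function(n_points, C, p_value, alpha) {
  structure(list(n_points = as.integer(n_points), C = as.integer(C),
                 p_value = p_value, alpha = alpha,
                 classification = classify_pvalue(p_value, alpha)),
            class = "cormap_result")
}

#' @export
print.cormap_result <- function(x, ...) {
  cat(sprintf("<cormap: n = %d, C = %d, p = %.4g -> %s>\n",
              x$n_points, x$C, x$p_value, x$classification))
  invisible(x)
}

#' CorMap test between two frames
#'
#' Chains [sign_vector()] -> [longest_run()] -> [schilling_pvalue()] and
#' classifies the pair: similar if p = 1, dissimilar if p < alpha,
#' borderline otherwise. Two exactly identical frames (all-zero difference)
#' are similar by definition (C = n, p = 1).
#'
#' @param a,b [scatter_curve]s on identical q grids.
#' @param alpha Significance level (default 0.01).
#' @return A `cormap_result` with fields `n_points`, `C`, `p_value`,
#'   `classification`.
#' @export
compare_pair <- function(a, b, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  d <- a$intensity - b$intensity
  n <- length(a$q)
  stop_if_grid_mismatch(a, b)
  if (all(d == 0)) {
    return(cormap_result(n, n, 1, alpha))
  }
  s <- sign_vector(a, b)
  C <- longest_run(s)
  cormap_result(n, C, schilling_pvalue(n, C), alpha)
}

#' Compare every frame of a series with a reference frame
#'
#' @param series A [frame_series] (>= 2 frames).
#' @param ref_index Reference frame index (default 1).
#' @param alpha Significance level.
#' @return A data frame of class `cormap_frame_results` with one row per
#'   non-reference frame, in acquisition order: `frame`, `n`, `C`, `p`,
#'   `classification`; the reference index is kept as attribute
#'   `ref_index`.
#' @export
compare_to_reference <- function(series, ref_index = 1L, alpha = 0.01) {
  stopifnot(inherits(series, "frame_series"))
  m <- length(series$curves)
  if (m < 2L) stop("series must contain at least 2 frames")
  if (ref_index < 1L || ref_index > m) {
    stop("ref_index ", ref_index, " out of range [1, ", m, "]")
  }
  ref <- series$curves[[ref_index]]
  others <- setdiff(seq_len(m), ref_index)
  rows <- lapply(others, function(i) {
    r <- compare_pair(series$curves[[i]], ref, alpha = alpha)
    data.frame(frame = i, n = r$n_points, C = r$C, p = r$p_value,
               classification = r$classification,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "ref_index") <- as.integer(ref_index)
  attr(out, "alpha") <- alpha
  class(out) <- c("cormap_frame_results", class(out))
  out
}

#' All pairwise CorMap comparisons of a series
#'
#' Full symmetric m x m matrices of C, p and classification codes. Row (and
#' column) 1 reproduces the reference comparisons of
#' [compare_to_reference()] with `ref_index = 1`.
#'
#' @param series A [frame_series] (>= 2 frames).
#' @param alpha Significance level.
#' @return An object of class `pairwise_matrix`: list with `m`, `C_matrix`,
#'   `p_matrix`, `class_matrix` (character), `alpha`. Diagonal p = 1.
#' @export
all_pairwise <- function(series, alpha = 0.01) {
  stopifnot(inherits(series, "frame_series"))
  m <- length(series$curves)
  if (m < 2L) stop("series must contain at least 2 frames")
  Cm <- matrix(NA_integer_, m, m)
  Pm <- matrix(NA_real_, m, m)
  n <- length(series$curves[[1L]]$q)
  diag(Cm) <- n  # self-comparison: all-zero difference
  diag(Pm) <- 1
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      r <- compare_pair(series$curves[[i]], series$curves[[j]],
                        alpha = alpha)
      Cm[i, j] <- Cm[j, i] <- r$C
      Pm[i, j] <- Pm[j, i] <- r$p_value
    }
  }
  cls <- matrix(classify_pvalue(Pm, alpha), m, m)
  structure(list(m = m, C_matrix = Cm, p_matrix = Pm, class_matrix = cls,
                 alpha = alpha),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat(sprintf("<pairwise_matrix: %d x %d frames, %.0f%% dissimilar pairs>\n",
              x$m, x$m,
              100 * mean(x$class_matrix[upper.tri(x$class_matrix)] ==
                           "dissimilar")))
  invisible(x)
}

#' Pairwise correlation-map image matrix
#'
#' The n x n outer product sign(d_i) * sign(d_j) of the sign-difference
#' vector of two frames: the black/white lattice whose largest uniform
#' patch has edge length C. A visualization of the same statistic; carries
#' no additional information.
#'
#' @param a,b [scatter_curve]s on identical q grids.
#' @return An n x n matrix of +1/-1 values.
#' @export
cormap_matrix <- function(a, b) {
  s <- sign_vector(a, b)
  outer(s, s)
}

#' Tidy table of CorMap results
#'
#' @param x A `cormap_frame_results` or `pairwise_matrix`.
#' @param path Optional CSV output path.
#' @return A data frame `frame_i, frame_j, n, C, p, classification`
#'   (invisibly when `path` is given).
#' @export
cormap_table <- function(x, path = NULL) {
  if (inherits(x, "cormap_frame_results")) {
    out <- data.frame(frame_i = attr(x, "ref_index"), frame_j = x$frame,
                      n = x$n, C = x$C, p = x$p,
                      classification = x$classification,
                      stringsAsFactors = FALSE)
  } else if (inherits(x, "pairwise_matrix")) {
    idx <- which(upper.tri(x$C_matrix, diag = TRUE), arr.ind = TRUE)
    out <- data.frame(frame_i = idx[, 1L], frame_j = idx[, 2L],
                      n = NA_integer_, C = x$C_matrix[idx],
                      p = x$p_matrix[idx],
                      classification = x$class_matrix[idx],
                      stringsAsFactors = FALSE)
  } else {
    stop("unsupported input for cormap_table")
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
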