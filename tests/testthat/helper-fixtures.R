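# Shared fixtures: small curves, noise series, and the brute-force
# longest-run enumeration oracle.

make_curve <- function(intensity, q = seq_along(intensity) / 10,
                       sigma = NULL, label = NULL) {
  scatter_curve(q, intensity, sigma = sigma, label = label)
}

noise_curve <- function(n = 100, base = 10, sd = 1) {
  make_curve(base + rnorm(n, sd = sd))
}

noise_series <- function(m, n = 100, base = 10, sd = 1) {
  frame_series(lapply(seq_len(m), function(i) noise_curve(n, base, sd)))
}

# build a cormap_frame_results table directly from p-values (frames 2..m)
fake_results <- function(p, alpha = 0.01, frames = seq_along(p) + 1L) {
  out <- data.frame(frame = frames, n = 100L, C = 10L, p = p,
                    classification = ifelse(p == 1, "similar",
                                            ifelse(p < alpha, "dissimilar",
                                                   "borderline")),
                    stringsAsFactors = FALSE)
  attr(out, "ref_index") <- 1L
  attr(out, "alpha") <- alpha
  class(out) <- c("cormap_frame_results", class(out))
  out
}

# independent oracle: exhaustive longest-run tail probability over all 2^n
# fair-coin sequences
enumerate_longest_run_tail <- function(n, C) {
  m <- 2^n
  ks <- 0:(m - 1)
  bits <- vapply(seq_len(n) - 1L, function(j) ks %/% 2^j %% 2,
                 numeric(m))
  bits <- matrix(bits, nrow = m)
  runs <- apply(bits, 1L, function(b) max(rle(b)$lengths))
  sum(runs >= C) / m
}
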