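test_that("sign_vector signs differences and applies the tie rule", {
  a <- make_curve(c(2, 2, 2, 2))
  b <- make_curve(c(1, 3, 1, 3))
  expect_identical(sign_vector(a, b), c(1L, -1L, 1L, -1L))
  expect_identical(sign_vector(make_curve(c(2, 2)), make_curve(c(1, 1))),
                   c(1L, 1L))

  # zeros inherit the previous non-zero sign (run-extending)
  x <- make_curve(c(2, 2, 1))
  y <- make_curve(c(1, 2, 2))   # d = (1, 0, -1)
  expect_identical(sign_vector(x, y), c(1L, 1L, -1L))
  # leading zeros take the first non-zero sign
  y2 <- make_curve(c(2, 1, 2))  # d = (0, 1, -1)
  expect_identical(sign_vector(x, y2), c(1L, 1L, -1L))
  # all ties
  expect_identical(sign_vector(a, a), rep(1L, 4))

  expect_error(sign_vector(a, make_curve(c(1, 2))), "q grid")
})

test_that("longest_run finds the maximal constant stretch", {
  expect_identical(longest_run(c(1, -1, 1, -1)), 1L)
  expect_identical(longest_run(rep(1, 7)), 7L)
  expect_identical(longest_run(c(1, 1, -1, -1, -1, 1)), 3L)
})

test_that("schilling_pvalue matches closed forms and the enumeration oracle", {
  expect_identical(schilling_pvalue(10, 1), 1)
  expect_identical(schilling_pvalue(5, 5), 2 / 32)
  expect_identical(schilling_pvalue(10, 5), 222 / 1024)
  expect_identical(schilling_pvalue(7, 8), 0)
  expect_error(schilling_pvalue(5, 7), "C must satisfy")
  expect_error(schilling_pvalue(0, 1), "n must be")

  # brute-force enumeration for a spread of small n, all valid C
  for (n in c(3L, 6L, 9L, 12L)) {
    for (C in seq_len(n)) {
      expect_identical(schilling_pvalue(n, C),
                       enumerate_longest_run_tail(n, C))
    }
  }

  # p non-increasing in C at fixed n, in both arithmetic regimes
  for (n in c(20L, 300L)) {
    p <- vapply(seq_len(n), function(C) schilling_pvalue(n, C), numeric(1))
    expect_true(all(diff(p) <= 0))
    expect_true(all(p >= 0 & p <= 1))
  }

  # the exact-count and tail-recurrence branches agree where they meet
  for (C in c(2L, 5L, 12L, 25L)) {
    expect_equal(schilling_pvalue(50L, C),
                 saxsdose:::prob_max_run_geq(50L, C),
                 tolerance = 1e-12)
  }
  # ... and the tail recurrence matches the non-overlap closed form at the
  # large-C boundary
  expect_equal(saxsdose:::prob_max_run_geq(301L, 151L),
               (301 - 151 + 2) * 2^-151, tolerance = 1e-9)
})

test_that("compare_pair classifies identical, offset and noisy pairs", {
  set.seed(42)
  a <- noise_curve(100)
  r_same <- compare_pair(a, a)
  expect_identical(r_same$p_value, 1)
  expect_identical(r_same$classification, "similar")
  expect_identical(r_same$C, 100L)

  b <- make_curve(a$intensity + 5, q = a$q)
  r_off <- compare_pair(a, b)
  expect_identical(r_off$C, 100L)
  expect_identical(r_off$p_value, 2 / 2^100)
  expect_identical(r_off$classification, "dissimilar")

  # symmetry: swapping the arguments flips every sign, same C and p
  set.seed(7)
  for (i in 1:10) {
    x <- noise_curve(60)
    y <- noise_curve(60)
    rx <- compare_pair(x, y)
    ry <- compare_pair(y, x)
    expect_identical(rx$C, ry$C)
    expect_identical(rx$p_value, ry$p_value)
  }
})

test_that("compare_to_reference orders results and flags a changepoint", {
  flat <- frame_series(lapply(1:5, function(i) make_curve(rep(c(3, 4), 10))))
  res <- compare_to_reference(flat)
  expect_equal(nrow(res), 4L)
  expect_true(all(res$classification == "similar"))
  expect_equal(res$frame, 2:5)

  # deterministic damage from frame 4: dissimilar exactly from there
  sc <- damage_scenario(n_frames = 8, onset_frame = 4, noise_sigma = 0,
                        noise_floor = 0)
  g <- generate_series(sc, seed = 1)
  res2 <- compare_to_reference(g$series)
  expect_true(all(res2$classification[res2$frame < 4] == "similar"))
  expect_true(all(res2$classification[res2$frame >= 4] == "dissimilar"))

  expect_error(compare_to_reference(flat, ref_index = 9), "out of range")
})

test_that("all_pairwise is symmetric with a reference first row", {
  set.seed(11)
  sc <- damage_scenario(n_frames = 10, n_points = 120, onset_frame = 6)
  series <- generate_series(sc, seed = 3)$series
  pm <- all_pairwise(series)
  expect_identical(pm$C_matrix, t(pm$C_matrix))
  expect_identical(pm$p_matrix, t(pm$p_matrix))
  expect_true(all(diag(pm$p_matrix) == 1))

  ref <- compare_to_reference(series)
  expect_identical(unname(pm$C_matrix[1, -1]), ref$C)
  expect_identical(unname(pm$p_matrix[1, -1]), ref$p)

  # identical frames: everything similar
  flat <- frame_series(lapply(1:4, function(i) make_curve(c(5, 4, 3, 2))))
  pm_flat <- all_pairwise(flat)
  expect_true(all(pm_flat$class_matrix == "similar"))
})

test_that("a stable late block shows up as a non-dissimilar submatrix", {
  # piecewise-stationary series: frames 1-3 around shape A, 4-12 around a
  # clearly different shape B; the 4-12 block should contain no dissimilar
  # pair while row 1 flags the change
  set.seed(5)
  qv <- seq(0.1, 3, length.out = 150)
  shapeA <- sphere_form_factor(qv, 4.3, 100)
  shapeB <- shapeA + 60 * (0.1 / qv)^2
  mk <- function(base) scatter_curve(qv, base + rnorm(150, sd = 1))
  series <- frame_series(c(lapply(1:3, function(i) mk(shapeA)),
                           lapply(4:12, function(i) mk(shapeB))))
  pm <- all_pairwise(series)
  # within the stable block only chance-level dissimilarity remains, and
  # no onset can be declared when frame 4 is taken as the reference
  block <- pm$class_matrix[4:12, 4:12]
  expect_lte(mean(block == "dissimilar"), 0.05)
  stable <- frame_series(series$curves[4:12])
  o <- detect_onset(compare_to_reference(stable))
  expect_true(is.na(o$onset_frame))
  expect_true(all(pm$class_matrix[1, 4:12] == "dissimilar"))
})

test_that("cormap_table produces tidy rows for both result shapes", {
  flat <- frame_series(lapply(1:4, function(i) make_curve(c(5, 4, 3))))
  tab <- cormap_table(compare_to_reference(flat))
  expect_named(tab, c("frame_i", "frame_j", "n", "C", "p", "classification"))
  expect_equal(nrow(tab), 3L)
  tab2 <- cormap_table(all_pairwise(flat))
  expect_equal(nrow(tab2), 4 * 5 / 2)
  f <- withr::local_tempfile(fileext = ".csv")
  cormap_table(all_pairwise(flat), f)
  expect_true(file.exists(f))
})
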