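test_that("cylinder_vertices places evenly spaced circles at +/- h/2", {
  s <- cylinder_sample(100, 80)
  v <- cylinder_vertices(s)
  expect_equal(nrow(v), 64L)  # 32 per end circle by default

  r <- sqrt(v[, "y"]^2 + v[, "z"]^2)
  expect_equal(r, rep(50, 64), tolerance = 1e-9)
  expect_equal(sort(unique(v[, "x"])), c(-40, 40))

  # centroid of each end circle lies on the axis
  for (xe in c(-40, 40)) {
    circ <- v[v[, "x"] == xe, ]
    expect_lt(abs(mean(circ[, "y"])), 1e-9 * 50)
    expect_lt(abs(mean(circ[, "z"])), 1e-9 * 50)
  }

  # angular gaps are exactly 2*pi/n
  s8 <- cylinder_sample(100, 80, n_circle_points = 8)
  v8 <- cylinder_vertices(s8)
  circ <- v8[v8[, "x"] < 0, ]
  ang <- atan2(circ[, "z"], circ[, "y"])
  gaps <- diff(ang) %% (2 * pi)
  expect_equal(gaps, rep(2 * pi / 8, 7), tolerance = 1e-12)

  expect_error(cylinder_sample(100, 80, n_circle_points = 4), ">= 8")
  expect_error(cylinder_sample(100, 80, voxel_size_um = 50), "diameter/4")
})

test_that("voxelize recovers the cylinder volume and converges", {
  s <- cylinder_sample(100, 100, voxel_size_um = 5)  # d/20
  v <- voxelize(s)
  truth <- pi * 50^2 * 100
  err <- function(vx) abs(sum(vx$inside) * vx$voxel_volume_um3 / truth - 1)
  expect_lt(err(v), 0.02)

  # centre voxel is inside; a far corner is outside
  cen <- v$centers
  i0 <- which.min(rowSums(cen^2))
  expect_true(v$inside[i0])
  far <- which.max(cen[, "y"]^2 + cen[, "z"]^2)
  expect_false(v$inside[far])

  # error shrinks monotonically with voxel size
  errs <- vapply(c(20, 10, 5), function(vs) {
    err(voxelize(cylinder_sample(100, 100, voxel_size_um = vs)))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))

  expect_error(voxelize(cylinder_sample(1e5, 1e5, voxel_size_um = 10)),
               "voxel budget")
})

test_that("beam_from_scans reconstructs flat, symmetric and Gaussian beams", {
  pos <- seq(-100, 100, by = 10)

  flat <- function(axis) aperture_scan(axis, pos, rep(7, length(pos)))
  b <- beam_from_scans(flat("horizontal"), flat("vertical"), 1e12)
  expect_true(all(abs(b$grid - 1) < 1e-9))

  # mirror-symmetric readings give a mirror-symmetric grid
  readings <- exp(-abs(pos) / 50)
  bs <- beam_from_scans(aperture_scan("horizontal", pos, readings),
                        aperture_scan("vertical", pos, readings), 1e12)
  expect_equal(bs$grid, bs$grid[nrow(bs$grid):1, ], tolerance = 1e-9)
  expect_equal(bs$grid, bs$grid[, ncol(bs$grid):1], tolerance = 1e-9)

  # separable Gaussian sampled at 10 um: <= 2% RMS inside the scanned box
  g <- function(x) exp(-x^2 / (2 * 40^2))
  pos2 <- seq(-150, 150, by = 10)
  bg <- beam_from_scans(aperture_scan("horizontal", pos2, g(pos2)),
                        aperture_scan("vertical", pos2, 3.7 * g(pos2)),
                        1e12)
  truth <- outer(g(bg$y_um), g(bg$x_um))
  expect_lt(sqrt(mean((bg$grid - truth)^2)), 0.02)

  # invariance to uniform rescaling of the diode readings
  bg2 <- beam_from_scans(aperture_scan("horizontal", pos2, 100 * g(pos2)),
                         aperture_scan("vertical", pos2, 0.5 * g(pos2)),
                         1e12)
  expect_equal(bg2$grid, bg$grid, tolerance = 1e-12)

  # averaging repeat scans
  two <- beam_from_scans(list(aperture_scan("horizontal", pos2, g(pos2)),
                              aperture_scan("horizontal", pos2, 2 * g(pos2))),
                         aperture_scan("vertical", pos2, g(pos2)), 1e12)
  expect_equal(two$grid, bg$grid, tolerance = 1e-12)

  expect_warning(
    beam_from_scans(aperture_scan("horizontal", c(-10, 0, 10), c(1, 2, 1)),
                    aperture_scan("vertical", pos, rep(1, length(pos))),
                    1e12),
    "linear")
})

test_that("analytic beams match their closed forms", {
  th <- analytic_beam("tophat", c(100, 100), total_flux = 1e12,
                      pixel_size_um = 1)
  expect_identical(sum(th$grid > 0), 100L * 100L)
  expect_true(all(th$grid %in% c(0, 1)))
  # grid integral x pixel area x density scale reproduces the total flux
  expect_equal(sum(th$grid) * prod(th$pixel_size_um) *
                 beam_flux_density_scale(th),
               1e12, tolerance = 1e-3)

  ga <- analytic_beam("gaussian", c(100, 60), total_flux = 5e11,
                      pixel_size_um = 1)
  expect_equal(beam_relative_fluence(ga, 0, 0), 1)           # centre
  expect_equal(beam_relative_fluence(ga, 50, 0), 0.5,        # FWHM/2
               tolerance = 1e-9)
  expect_equal(beam_relative_fluence(ga, 0, 30), 0.5, tolerance = 1e-9)
  expect_equal(sum(ga$grid) * prod(ga$pixel_size_um) *
                 beam_flux_density_scale(ga),
               5e11, tolerance = 1e-3)

  # fluence at and beyond the boundary is zero
  expect_identical(beam_relative_fluence(ga, 1e4, 0), 0)
  expect_identical(beam_relative_fluence(th, 0, -1e4), 0)
})

test_that("aperture scans validate and read from disk", {
  expect_error(aperture_scan("horizontal", c(0, 10), c(1, 1)), "3 points")
  expect_error(aperture_scan("horizontal", c(0, 10, 5), c(1, 1, 1)),
               "monotone")
  expect_error(aperture_scan("horizontal", c(0, 10, 20), c(1, -1, 1)),
               ">= 0")
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# position reading", "-10 1.0", "0 2.0", "10 1.0", "20 0.5"),
             f)
  sc <- read_aperture_scan(f, "vertical")
  expect_equal(sc$positions_um, c(-10, 0, 10, 20))
  expect_equal(sc$readings, c(1, 2, 1, 0.5))
})
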