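water_comp <- function(energy = 12.5) build_composition(list(), list(), energy)

test_that("transmission follows the Beer-Lambert exponential law", {
  expect_identical(transmission_fraction(quartz_capillary_wall(0), 12.5), 1)

  t1 <- transmission_fraction(quartz_capillary_wall(50), 12.5)
  t2 <- transmission_fraction(quartz_capillary_wall(100), 12.5)
  expect_equal(t2, t1^2, tolerance = 1e-12)
  # 50 um fused quartz at 12.5 keV transmits ~90%
  expect_equal(t1, 0.90, tolerance = 0.02)
})

test_that("capillary attenuation is a rotation-independent scalar", {
  cap <- quartz_capillary_wall(50)
  expect_identical(capillary_attenuation(quartz_capillary_wall(0), 12.5), 1)
  expect_identical(capillary_attenuation(cap, 12.5),
                   transmission_fraction(cap, 12.5))
  for (rot in c(0, 45, 90, 360)) {
    expect_identical(capillary_attenuation(cap, 12.5, rotation_deg = rot),
                     capillary_attenuation(cap, 12.5))
  }
})

test_that("flux_from_diode scales readings and preserves relative decay", {
  expect_equal(flux_from_diode(rep(3, 5), 2e11), rep(6e11, 5))
  expect_identical(flux_from_diode(c(1, 2, 3), 1), c(1, 2, 3))
  # a 0.54% decay over the run stays a 0.54% decay in flux
  readings <- seq(1, 1 - 0.0054, length.out = 120)
  flux <- flux_from_diode(readings, 7.5e11)
  expect_equal(flux[120] / flux[1], 1 - 0.0054, tolerance = 1e-12)
  expect_error(flux_from_diode(c(1, -0.1), 1), ">= 0")
  expect_error(flux_from_diode(c(1, 2), 0), "> 0")
})

test_that("dose accumulates linearly over identical frames and is bracketed", {
  samp <- cylinder_sample(100, 100, voxel_size_um = 5)
  beam <- analytic_beam("tophat", c(150, 150), total_flux = 1e12,
                        pixel_size_um = 2.5)
  ds <- accumulate_dose(samp, water_comp(), beam, quartz_capillary_wall(50),
                        exposure_plan(3, 1, 1e12, 12.5))
  dwd <- ds$dwd_per_frame_kgy
  expect_equal(dwd[2], 2 * dwd[1], tolerance = 1e-12)
  expect_equal(dwd[3], 3 * dwd[1], tolerance = 1e-12)
  expect_true(all(diff(dwd) >= 0))

  ill <- ds$fluence_weight > 0
  expect_gte(dwd[3] * 1000, min(ds$voxel_dose[ill]))
  expect_lte(dwd[3] * 1000, max(ds$voxel_dose[ill]))
})

test_that("per-frame deposited energy respects the attenuation bound", {
  samp <- cylinder_sample(100, 100, voxel_size_um = 5)
  beam <- analytic_beam("gaussian", c(80, 60), total_flux = 2e12,
                        pixel_size_um = 2)
  flux <- seq(1e12, 0.9946e12, length.out = 5)  # slowly decaying ring
  ds <- accumulate_dose(samp, water_comp(), beam, quartz_capillary_wall(50),
                        exposure_plan(5, 1, flux, 12.5))
  expect_true(all(ds$deposited_J <= ds$absorbable_bound_J * (1 + 1e-6)))
  expect_true(all(ds$absorbable_bound_J <= ds$incident_J))
  expect_true(all(ds$deposited_J > 0))
})

test_that("a uniform field with negligible attenuation doses all voxels equally", {
  samp <- cylinder_sample(100, 100, voxel_size_um = 5)
  beam <- analytic_beam("tophat", c(200, 200), total_flux = 1e12,
                        pixel_size_um = 2)
  # dilute the sample so mu_att * d << 1 and the dose field is flat
  comp <- water_comp()
  comp$element_number_density <- comp$element_number_density * 1e-4
  ds <- accumulate_dose(samp, comp, beam,
                        quartz_capillary_wall(0),
                        exposure_plan(1, 1, 1e12, 12.5))
  ill <- ds$fluence_weight > 0
  doses <- ds$voxel_dose[ill]
  expect_lt(diff(range(doses)) / mean(doses), 1e-4)
  expect_equal(ds$dwd_per_frame_kgy[1] * 1000, mean(doses),
               tolerance = 1e-6)
})

test_that("entrance-voxel dose matches the closed-form hand oracle", {
  samp <- cylinder_sample(40, 40, voxel_size_um = 2)
  beam <- analytic_beam("tophat", c(100, 100), total_flux = 1e10,
                        pixel_size_um = 1)
  comp <- water_comp()
  plan <- exposure_plan(1, 1, 1e10, 12.5)
  ds <- accumulate_dose(samp, comp, beam, quartz_capillary_wall(0), plan)

  # hand formula for a most-upstream voxel (no in-sample attenuation):
  # dose = flux_density * s^2 * E_J * (1 - exp(-mu_abs s)) / (rho s^3 1e-15)
  s <- 2
  dens <- 1e10 / (100 * 100)           # uniform photons/s/um^2
  E_J <- 12.5 * 1.602177e-16           # 2.0027e-15 J
  mu_abs <- absorption_coefficient(comp)
  expected <- dens * s^2 * E_J * (1 - exp(-mu_abs * s)) /
    (comp$mass_density * s^3 * 1e-15)

  cen <- ds$voxel_centers
  central <- abs(cen[, "y"]) < 1.01 & cen[, "x"] > 0
  first <- which(central)[which.min(cen[central, "z"])]
  expect_equal(ds$voxel_dose[first], expected, tolerance = 1e-9)
})

test_that("DWD converges under grid refinement and a missed beam errors", {
  comp <- water_comp()
  beam <- analytic_beam("gaussian", c(60, 60), total_flux = 1e12,
                        pixel_size_um = 2)
  plan <- exposure_plan(1, 1, 1e12, 12.5)
  cap <- quartz_capillary_wall(50)
  d20 <- accumulate_dose(cylinder_sample(100, 100, voxel_size_um = 5),
                         comp, beam, cap, plan)$dwd_per_frame_kgy[1]
  d40 <- accumulate_dose(cylinder_sample(100, 100, voxel_size_um = 2.5),
                         comp, beam, cap, plan)$dwd_per_frame_kgy[1]
  expect_lt(abs(d40 / d20 - 1), 0.01)

  off_beam <- beam_profile(matrix(1, 3, 3), x_um = c(5000, 5010, 5020),
                           y_um = c(0, 10, 20), total_flux = 1e12)
  expect_error(
    accumulate_dose(cylinder_sample(100, 100, voxel_size_um = 5), comp,
                    off_beam, cap, plan),
    "misses")
})

test_that("uniform illumination of a weak absorber matches the closed form", {
  # beam fully inside a large sample, mu_att * d << 1:
  # DWD ~ flux * E * mu_abs * t / (rho * A_beam)
  comp <- water_comp()
  comp$element_number_density <- comp$element_number_density * 0.01
  mu_abs <- absorption_coefficient(comp)
  samp <- cylinder_sample(200, 200, voxel_size_um = 10)
  beam <- analytic_beam("tophat", c(80, 80), total_flux = 1e12,
                        pixel_size_um = 2)
  ds <- accumulate_dose(samp, comp, beam, quartz_capillary_wall(0),
                        exposure_plan(1, 1, 1e12, 12.5))
  closed <- 1e12 * (12.5 * 1.602177e-16) * mu_abs * 1 /
    (comp$mass_density * 1e-15 * 80 * 80)
  expect_equal(ds$dwd_per_frame_kgy[1] * 1000, closed, tolerance = 0.02)
})

test_that("exposure_plan validates its frame table", {
  expect_error(exposure_plan(2, -1, 1e12, 12.5), "> 0")
  expect_error(exposure_plan(2, 1, -1, 12.5), ">= 0")
  expect_error(exposure_plan(2, 1, 1e12, 0), "> 0")
  p <- exposure_plan(3, c(1, 2, 1), 1e12, 12.5)
  expect_equal(p$frames$exposure_s, c(1, 2, 1))
  expect_equal(nrow(p$frames), 3L)
})

test_that("dwd tables round-trip through CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_dwd_table(c(0.5, 1.0, 1.7), f)
  expect_equal(read_dwd_table(f), c(0.5, 1.0, 1.7))
})
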