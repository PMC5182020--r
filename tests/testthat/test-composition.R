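test_that("molarity is concentration over molecular mass", {
  # 1 mg/ml of the 172 kDa tetramer
  expect_equal(molarity(1, 172000), 5.813953e-6, tolerance = 1e-6)
  expect_equal(molarity(110, 110), 1)
  expect_equal(molarity(0.5, 1000), 5e-4)
  expect_error(molarity(-1, 10), "> 0")
  expect_error(molarity(1, 0), "> 0")
})

test_that("molecular_mass applies the average-residue rules and formulas", {
  prot <- molecule_spec("protein", 1, residue_count = 1552)
  expect_identical(molecular_mass(prot), 1552 * 110.0)
  expect_identical(
    molecular_mass(molecule_spec("RNA", 1, residue_count = 2)), 679.0)
  expect_identical(
    molecular_mass(molecule_spec("DNA", 1, residue_count = 3)), 3 * 327.0)
  expect_equal(
    molecular_mass(molecule_spec("small_molecule", 1, formula = "H2O")),
    18.015, tolerance = 1e-3)
  # sequence route: glycine-only chain uses the residue table
  g5 <- molecule_spec("protein", 1, sequence = "GGGGG")
  expect_equal(molecular_mass(g5), 5 * 57.0519, tolerance = 1e-6)
  expect_error(
    molecular_mass(molecule_spec("protein", 1, sequence = "GGXZG")),
    "X")
})

test_that("molecule_count rounds molarity x volume x Avogadro", {
  expect_identical(molecule_count(0, 1), 0)
  expect_equal(molecule_count(1e-6, 1e-6), 6.022e11)
  expect_identical(molecule_count(1 / 6.022e23, 1), 1)
  # monotone in both arguments
  ms <- c(0, 1e-9, 1e-6, 1e-3)
  vs <- c(1e-9, 1e-6, 1e-3, 1)
  for (v in vs) expect_true(all(diff(molecule_count(ms, v)) >= 0))
  for (m in ms) {
    expect_true(all(diff(vapply(vs, function(v) molecule_count(m, v),
                                numeric(1))) >= 0))
  }
})

test_that("build_composition reproduces water stoichiometry and closes mass", {
  pw <- build_composition(list(), list(), 12.5)
  nd <- pw$element_number_density
  expect_equal(unname(nd["H"] / nd["O"]), 2)
  # mass closure: density recomputed from the inventory matches the field
  recomputed <- sum(nd * atomic_weight(names(nd))) / (6.022e23 / 1e24 * 1000)
  expect_equal(recomputed, pw$mass_density, tolerance = 1e-6)

  # a zero-concentration limit: tiny protein concentration ~ pure water
  tiny <- build_composition(
    list(molecule_spec("protein", 1e-9, residue_count = 1552)), list(), 12.5)
  expect_equal(tiny$element_number_density[["O"]], nd[["O"]],
               tolerance = 1e-8)

  # 1 mg/ml protein perturbs hydrogen density by < 0.1%
  gi <- build_composition(
    list(molecule_spec("protein", 1, residue_count = 1552)), list(), 12.5)
  expect_lt(abs(gi$element_number_density[["H"]] / nd[["H"]] - 1), 1e-3)

  expect_error(
    build_composition(
      list(molecule_spec("protein", 5000, residue_count = 1552)),
      list(), 12.5),
    "volume fraction")
  expect_error(build_composition(list(), list(), 200), "\\[1, 100\\]")
})

test_that("absorption and attenuation coefficients behave physically", {
  comp <- build_composition(
    list(molecule_spec("protein", 1, residue_count = 1552)),
    list(molecule_spec("small_molecule", 0.01, unit = "mol_per_L",
                       formula = "MgCl2")),
    12.5)
  mu_abs <- absorption_coefficient(comp)
  mu_att <- attenuation_coefficient(comp)
  expect_gt(mu_abs, 0)
  expect_gte(mu_att, mu_abs)

  # linearity: doubling every number density doubles both coefficients
  comp2 <- comp
  comp2$element_number_density <- comp$element_number_density * 2
  expect_equal(absorption_coefficient(comp2), 2 * mu_abs, tolerance = 1e-12)
  expect_equal(attenuation_coefficient(comp2), 2 * mu_att, tolerance = 1e-12)

  # water mass attenuation at 12.5 keV vs the standard tabulated value
  pw <- build_composition(list(), list(), 12.5)
  mu_rho_water <- attenuation_coefficient(pw) * 1e4 / pw$mass_density
  expect_equal(mu_rho_water, 2.82, tolerance = 0.05)
})

test_that("mixture rule weights elements by mass fraction", {
  # single-element material returns the element value
  expect_equal(mixture_mass_attenuation("Si", 12.5),
               element_mu_rho("Si", 12.5))
  # quartz at 12.5 keV, standard-table reference
  expect_equal(mixture_mass_attenuation("SiO2", 12.5), 9.7,
               tolerance = 0.05)
  # invariance to scaling all stoichiometric counts
  expect_equal(mixture_mass_attenuation("Si3O6", 12.5),
               mixture_mass_attenuation("SiO2", 12.5), tolerance = 1e-12)
  expect_error(mixture_mass_attenuation("Xx2O", 12.5), "Xx")
})

test_that("cross-section interpolation is exact at the tabulated knots", {
  tab <- read.csv(system.file("extdata", "xray_mass_attenuation.csv",
                              package = "saxsdose"))
  sub <- tab[tab$element == "O", ]
  for (i in c(1L, 5L, nrow(sub))) {
    expect_equal(element_mu_rho("O", sub$energy_kev[i], "photoelectric"),
                 sub$photoelectric[i], tolerance = 1e-12)
    expect_equal(element_mu_rho("O", sub$energy_kev[i], "total"),
                 sub$photoelectric[i] + sub$incoherent[i] + sub$coherent[i],
                 tolerance = 1e-12)
  }
  expect_error(element_mu_rho("O", 1000), "outside")
  expect_error(element_mu_rho("Zz", 12.5), "not in the cross-section table")
})

test_that("parse_formula handles counts and passthrough", {
  expect_equal(parse_formula("C6H12O6"), c(C = 6, H = 12, O = 6))
  expect_equal(parse_formula("NaCl"), c(Na = 1, Cl = 1))
  expect_equal(parse_formula(c(Si = 1, O = 2)), c(Si = 1, O = 2))
  expect_error(parse_formula("2HO"), "parse")
})
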