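# Sample composition: from a wet-lab recipe (protein mg/ml, buffer solutes,
# capillary material) to an atomic inventory and X-ray coefficients.

AVOGADRO <- 6.022e23  # mol^-1, value used throughout dose bookkeeping

# average residue masses, Da
AVG_RESIDUE_MASS <- c(protein = 110.0, RNA = 339.5, DNA = 327.0)

# average amino-acid residue masses (Da), residue = amino acid minus water
.RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, V = 99.1326, W = 186.2132, Y = 163.1760
)

# per-residue elemental formulas (residue = amino acid minus water)
.RESIDUE_FORMULA <- list(
  A = c(C = 3, H = 5, N = 1, O = 1),
  R = c(C = 6, H = 12, N = 4, O = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  D = c(C = 4, H = 5, N = 1, O = 3),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  E = c(C = 5, H = 7, N = 1, O = 3),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  G = c(C = 2, H = 3, N = 1, O = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  K = c(C = 6, H = 12, N = 2, O = 1),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  F = c(C = 9, H = 9, N = 1, O = 1),
  P = c(C = 5, H = 7, N = 1, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  T = c(C = 4, H = 7, N = 1, O = 2),
  V = c(C = 5, H = 9, N = 1, O = 1),
  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2)
)

# average-residue elemental stoichiometry used when only a residue count is
# known (RADDOSE-3D convention); configurable via options(saxsdose.avg_residue)
.AVG_RESIDUE_ELEMENTS <- c(C = 4.98, H = 7.68, N = 1.35, O = 1.48, S = 0.04)

WATER_MOLARITY <- 55.555          # mol/L
PROTEIN_PSV <- 0.73               # protein partial specific volume, cm^3/g
SMALL_MOLECULE_PSV <- 0.60        # nominal solute partial specific volume

#' Molecule specification
#'
#' Describes one dissolved species: a protein/nucleic acid given by sequence
#' or residue count, or a small molecule given by formula.
#'
#' @param kind One of `"protein"`, `"RNA"`, `"DNA"`, `"small_molecule"`.
#' @param concentration Concentration value, units per `unit`.
#' @param unit `"g_per_L"` (= mg/ml) or `"mol_per_L"`.
#' @param sequence Optional one-letter residue string (proteins).
#' @param residue_count Optional integer residue/nucleotide count.
#' @param formula Optional chemical formula (string or named counts) for
#'   small molecules.
#' @return An object of class `molecule_spec`.
#' @export
molecule_spec <- function(kind = c("protein", "RNA", "DNA", "small_molecule"),
                          concentration, unit = c("g_per_L", "mol_per_L"),
                          sequence = NULL, residue_count = NULL,
                          formula = NULL) {
  kind <- match.arg(kind)
  unit <- match.arg(unit)
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("concentration must be > 0")
  }
  if (is.null(sequence) && is.null(residue_count) && is.null(formula)) {
    stop("at least one of sequence, residue_count, formula is required")
  }
  if (!is.null(formula)) formula <- parse_formula(formula)
  structure(list(kind = kind, concentration = concentration, unit = unit,
                 sequence = sequence, residue_count = residue_count,
                 formula = formula),
            class = "molecule_spec")
}

#' Material specification (capillary walls, windows)
#'
#' @param formula Chemical formula, e.g. `"SiO2"`.
#' @param density Density in g cm^-3 (> 0).
#' @param thickness_um Thickness in micrometres (>= 0).
#' @return An object of class `material_spec`.
#' @export
#' @examples
#' quartz_capillary_wall(50)
material_spec <- function(formula, density, thickness_um = 0) {
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  if (!is.numeric(thickness_um) || thickness_um < 0) {
    stop("thickness_um must be >= 0")
  }
  structure(list(formula = parse_formula(formula), density = density,
                 thickness_um = thickness_um),
            class = "material_spec")
}

#' @describeIn material_spec Fused-quartz wall (SiO2, 2.203 g cm^-3), the
#'   default BioSAXS capillary material.
#' @export
quartz_capillary_wall <- function(thickness_um = 50) {
  material_spec("SiO2", density = 2.203, thickness_um = thickness_um)
}

#' Molarity from mass concentration
#'
#' @param concentration Mass concentration in g L^-1 (equivalently mg/ml).
#' @param molecular_mass Molecular mass in g mol^-1.
#' @return Molarity in mol L^-1.
#' @export
#' @examples
#' molarity(1, 172000)  # 1 mg/ml of a 172 kDa tetramer
molarity <- function(concentration, molecular_mass) {
  if (!is.numeric(concentration) || any(concentration <= 0)) {
    stop("concentration must be > 0")
  }
  if (!is.numeric(molecular_mass) || any(molecular_mass <= 0)) {
    stop("molecular_mass must be > 0")
  }
  concentration / molecular_mass
}

#' Molecular mass of a molecule specification
#'
#' With a sequence: sums average residue masses from the built-in 20
#' amino-acid table. With only a residue count: count x 110.0 Da (protein),
#' x 339.5 Da (RNA) or x 327.0 Da (DNA). With a formula: sums standard
#' atomic weights.
#'
#' @param spec A [molecule_spec].
#' @return Molecular mass in g mol^-1.
#' @export
molecular_mass <- function(spec) {
  stopifnot(inherits(spec, "molecule_spec"))
  if (!is.null(spec$sequence) && spec$kind == "protein") {
    res <- strsplit(toupper(gsub("[[:space:]]", "", spec$sequence)), "")[[1L]]
    bad <- setdiff(unique(res), names(.RESIDUE_MASS))
    if (length(bad)) {
      stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
    }
    return(sum(.RESIDUE_MASS[res]))
  }
  if (!is.null(spec$residue_count)) {
    key <- if (spec$kind %in% c("RNA", "DNA")) spec$kind else "protein"
    return(spec$residue_count * AVG_RESIDUE_MASS[[key]])
  }
  if (!is.null(spec$formula)) {
    return(sum(spec$formula * atomic_weight(names(spec$formula))))
  }
  stop("molecule_spec carries no sequence, residue_count or formula")
}

#' Number of molecules in a volume
#'
#' molarity x volume x Avogadro's number (6.022e23 mol^-1), rounded to the
#' nearest integer (half away from zero).
#'
#' @param molarity Molarity in mol L^-1 (>= 0).
#' @param volume Volume in litres (> 0).
#' @return Integer-valued count (as numeric; may exceed .Machine$integer.max).
#' @export
molecule_count <- function(molarity, volume) {
  if (!is.numeric(molarity) || any(molarity < 0)) stop("molarity must be >= 0")
  if (!is.numeric(volume) || any(volume <= 0)) stop("volume must be > 0")
  x <- molarity * volume * AVOGADRO
  # round half away from zero (x >= 0 here)
  floor(x + 0.5)
}

molecule_elements <- function(spec) {
  # element counts per molecule
  if (!is.null(spec$formula)) return(spec$formula)
  if (spec$kind == "protein" && !is.null(spec$sequence)) {
    res <- strsplit(toupper(gsub("[[:space:]]", "", spec$sequence)), "")[[1L]]
    bad <- setdiff(unique(res), names(.RESIDUE_FORMULA))
    if (length(bad)) {
      stop("unknown residue letter(s): ", paste(bad, collapse = ", "))
    }
    out <- c(C = 0, H = 0, N = 0, O = 0, S = 0)
    for (r in res) {
      f <- .RESIDUE_FORMULA[[r]]
      out[names(f)] <- out[names(f)] + f
    }
    return(out[out > 0])
  }
  if (!is.null(spec$residue_count)) {
    avg <- getOption("saxsdose.avg_residue", .AVG_RESIDUE_ELEMENTS)
    return(avg * spec$residue_count)
  }
  stop("cannot derive elemental composition for this molecule_spec")
}

molecule_molarity <- function(spec) {
  if (spec$unit == "mol_per_L") return(spec$concentration)
  spec$concentration / molecular_mass(spec)
}

#' Build the atomic composition of an aqueous sample
#'
#' Defines 1 L of solution, places protein and solute atoms according to
#' their molarities, and fills the residual solvent volume with water at
#' 55.555 mol L^-1. Displaced solvent volume is computed from partial
#' specific volumes (0.73 cm^3/g for protein, 0.60 cm^3/g for small
#' molecules). The stored mass density is the closure
#' sum(element density x atomic mass).
#'
#' @param molecules List of [molecule_spec]s for macromolecules (may be
#'   empty).
#' @param solutes List of [molecule_spec]s for buffer solutes (may be empty).
#' @param photon_energy_kev Photon energy in keV, within `[1, 100]`.
#' @return An object of class `sample_composition` with fields
#'   `element_number_density` (atoms per nm^3), `mass_density` (g cm^-3) and
#'   `photon_energy_kev`.
#' @export
#' @examples
#' build_composition(list(), list(), 12.5)  # pure water
build_composition <- function(molecules = list(), solutes = list(),
                              photon_energy_kev) {
  if (!is.numeric(photon_energy_kev) ||
      photon_energy_kev < 1 || photon_energy_kev > 100) {
    stop("photon_energy_kev must lie in [1, 100]")
  }
  if (inherits(molecules, "molecule_spec")) molecules <- list(molecules)
  if (inherits(solutes, "molecule_spec")) solutes <- list(solutes)

  dens <- c(H = 0, O = 0)  # atoms per nm^3
  per_nm3 <- AVOGADRO / 1e24  # mol/L -> molecules per nm^3
  occupied_fraction <- 0

  add_species <- function(spec, psv) {
    M <- molecule_molarity(spec)
    n_mol_nm3 <- M * per_nm3
    f <- molecule_elements(spec)
    for (el in names(f)) {
      dens[el] <<- (if (el %in% names(dens)) dens[[el]] else 0) +
        n_mol_nm3 * f[[el]]
    }
    mass_conc <- M * molecular_mass(spec)  # g/L
    occupied_fraction <<- occupied_fraction + mass_conc * psv / 1000
  }

  for (sp in molecules) add_species(sp, PROTEIN_PSV)
  for (sp in solutes) add_species(sp, SMALL_MOLECULE_PSV)

  if (occupied_fraction > 1) {
    stop("protein + solute volume fraction exceeds 1 (",
         signif(occupied_fraction, 4), "); recipe is unphysical")
  }
  solvent_fraction <- 1 - occupied_fraction
  n_water <- WATER_MOLARITY * solvent_fraction * per_nm3
  dens[["O"]] <- dens[["O"]] + n_water
  dens[["H"]] <- dens[["H"]] + 2 * n_water

  mass_density <- sum(dens * atomic_weight(names(dens))) / (per_nm3 * 1000)
  # per_nm3*1000 converts (atoms nm^-3)(g mol^-1) to g cm^-3 via Avogadro
  if (mass_density < 0.9 || mass_density > 1.5) {
    stop("computed mass density ", signif(mass_density, 4),
         " g cm^-3 outside the [0.9, 1.5] aqueous sanity band")
  }
  structure(list(element_number_density = dens,
                 mass_density = mass_density,
                 photon_energy_kev = photon_energy_kev),
            class = "sample_composition")
}

#' @export
print.sample_composition <- function(x, ...) {
  cat(sprintf("<sample_composition at %.4g keV, density %.4f g/cm^3>\n",
              x$photon_energy_kev, x$mass_density))
  print(signif(x$element_number_density, 5))
  invisible(x)
}

comp_mu_um <- function(comp, part) {
  # linear coefficient in um^-1 from number densities (atoms/nm^3) and
  # per-element mass coefficients: sigma_atom = (mu/rho) * A / N_A
  els <- names(comp$element_number_density)
  mu_cm <- 0
  for (el in els) {
    mr <- element_mu_rho(el, comp$photon_energy_kev, part)
    n_cm3 <- comp$element_number_density[[el]] * 1e21
    mu_cm <- mu_cm + n_cm3 * mr * atomic_weight(el) / AVOGADRO
  }
  mu_cm / 1e4
}

#' Linear absorption coefficient of a sample
#'
#' Photoelectric part only: the channel through which photon energy is
#' deposited locally at BioSAXS energies.
#'
#' @param comp A [build_composition()] result.
#' @return Linear absorption coefficient in um^-1.
#' @export
absorption_coefficient <- function(comp) {
  stopifnot(inherits(comp, "sample_composition"))
  comp_mu_um(comp, "photoelectric")
}

#' Linear attenuation coefficient of a sample
#'
#' Full attenuation (photoelectric + incoherent + coherent): governs how the
#' beam decays along its path through the sample. Always >= the absorption
#' coefficient.
#'
#' @inheritParams absorption_coefficient
#' @return Linear attenuation coefficient in um^-1.
#' @export
attenuation_coefficient <- function(comp) {
  stopifnot(inherits(comp, "sample_composition"))
  comp_mu_um(comp, "total")
}

#' Mass attenuation coefficient of a mixture
#'
#' The weighted mixture rule: mu/rho = sum_i w_i (mu/rho)_i with w_i the
#' fractions by weight from the stoichiometric formula and standard atomic
#' weights.
#'
#' @param material A [material_spec] (or anything with a `formula` field),
#'   or a formula string.
#' @param energy_kev Photon energy in keV.
#' @return Mass attenuation coefficient in cm^2 g^-1.
#' @export
#' @examples
#' mixture_mass_attenuation(quartz_capillary_wall(50), 12.5)
mixture_mass_attenuation <- function(material, energy_kev) {
  f <- if (inherits(material, "material_spec")) material$formula
       else parse_formula(material)
  if (length(f) == 0L) stop("empty formula")
  w <- f * atomic_weight(names(f))
  w <- w / sum(w)
  sum(vapply(names(f), function(el) {
    w[[el]] * element_mu_rho(el, energy_kev, "total")
  }, numeric(1)))
}
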