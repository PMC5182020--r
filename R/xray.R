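# Element data and photon cross-section lookups.
# The bundled table (inst/extdata/xray_mass_attenuation.csv) holds per-element
# mass attenuation coefficients split into photoelectric, incoherent and
# coherent parts on a fixed energy grid; lookups log-log interpolate in
# energy and reproduce the grid points exactly.

.saxsdose_env <- new.env(parent = emptyenv())

# standard atomic weights, g/mol
.ATOMIC_WEIGHTS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, Na = 22.990, Mg = 24.305,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098, Ca = 40.078
)

#' Standard atomic weight of an element
#'
#' @param element Character vector of element symbols (e.g. `"O"`).
#' @return Numeric vector of atomic weights in g/mol.
#' @export
atomic_weight <- function(element) {
  w <- .ATOMIC_WEIGHTS[element]
  if (anyNA(w)) {
    stop("no atomic weight for element(s): ",
         paste(element[is.na(w)], collapse = ", "))
  }
  unname(w)
}

xs_table <- function() {
  if (is.null(.saxsdose_env$xs)) {
    path <- system.file("extdata", "xray_mass_attenuation.csv",
                        package = "saxsdose", mustWork = TRUE)
    .saxsdose_env$xs <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  .saxsdose_env$xs
}

loglog_interp <- function(x, y, x0) {
  # linear interpolation of log(y) in log(x); exact at the knots
  lx <- log(x)
  ly <- log(pmax(y, 1e-300))
  exp(stats::approx(lx, ly, xout = log(x0), rule = 1)$y)
}

#' Element mass attenuation coefficient
#'
#' Looks up the bundled per-element photon cross-section table and log-log
#' interpolates in energy. The `"total"` part is the sum of the
#' photoelectric, incoherent (Compton) and coherent (Rayleigh) parts; the
#' photoelectric part alone drives energy deposition in the dose engine.
#'
#' @param element Element symbol.
#' @param energy_kev Photon energy in keV (must lie within the table range).
#' @param part One of `"total"`, `"photoelectric"`, `"incoherent"`,
#'   `"coherent"`.
#' @return Mass attenuation coefficient in cm^2 g^-1.
#' @export
#' @examples
#' element_mu_rho("O", 12.5)
element_mu_rho <- function(element, energy_kev,
                           part = c("total", "photoelectric",
                                    "incoherent", "coherent")) {
  part <- match.arg(part)
  tab <- xs_table()
  sub <- tab[tab$element == element, ]
  if (nrow(sub) == 0L) {
    stop("element '", element, "' is not in the cross-section table ",
         "(available: ", paste(unique(tab$element), collapse = ", "), ")")
  }
  if (energy_kev < min(sub$energy_kev) || energy_kev > max(sub$energy_kev)) {
    stop("energy ", energy_kev, " keV outside tabulated range [",
         min(sub$energy_kev), ", ", max(sub$energy_kev), "] for ", element)
  }
  y <- switch(part,
    total = sub$photoelectric + sub$incoherent + sub$coherent,
    photoelectric = sub$photoelectric,
    incoherent = sub$incoherent,
    coherent = sub$coherent
  )
  loglog_interp(sub$energy_kev, y, energy_kev)
}

#' Parse a chemical formula into element counts
#'
#' Accepts simple formulas without parentheses, e.g. `"H2O"`, `"SiO2"`,
#' `"C6H12O6"`. A named numeric vector passes through unchanged.
#'
#' @param formula Formula string or named numeric vector of element counts.
#' @return Named numeric vector of stoichiometric counts.
#' @export
parse_formula <- function(formula) {
  if (is.numeric(formula)) {
    if (is.null(names(formula)) || any(names(formula) == "")) {
      stop("numeric formula must be a fully named vector of element counts")
    }
    return(formula)
  }
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("[[:space:]]", "", formula)
  if (s == "") stop("empty formula")
  toks <- regmatches(s, gregexpr("([A-Z][a-z]?)([0-9]*\\.?[0-9]*)", s))[[1L]]
  if (sum(nchar(toks)) != nchar(s)) {
    stop("cannot parse formula '", formula, "'")
  }
  out <- numeric(0)
  for (tk in toks) {
    el <- sub("([A-Z][a-z]?).*", "\\1", tk)
    cnt <- sub("^[A-Z][a-z]?", "", tk)
    n <- if (cnt == "") 1 else as.numeric(cnt)
    out[el] <- (if (el %in% names(out)) out[[el]] else 0) + n
  }
  out
}
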