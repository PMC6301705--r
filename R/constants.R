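#' Physical constants and unit conventions
#'
#' All energies in this package are kcal/mol; temperatures in kelvin;
#' imaginary frequencies in cm^-1 (stored as positive magnitudes). The
#' standard-state factor converts a bimolecular rate constant from the
#' 1 atm ideal-gas standard state to the 1 M solution standard state, and
#' the Wigner coefficient (cm K) enters the tunneling correction. Both are
#' kept at their conventional printed precision (24.3 and 1.44) so that
#' published rate tables are reproduced; physically exact alternatives
#' (24.465 and 1.43877, with a ~0.2-1% effect on rates) can be supplied
#' through the arguments.
#'
#' @param T temperature in K.
#' @param std_state_factor dimensionless 1 atm -> 1 M conversion multiplier.
#' @param wigner_coeff coefficient of the Wigner tunneling factor, cm K.
#' @param R_cal molar gas constant in cal mol^-1 K^-1.
#'
#' @return An object of class `thermo_constants`: a list with fields
#'   `T`, `kB` (J/K), `h` (J s), `R_cal`, `std_state_factor`,
#'   `wigner_coeff`, `hartree_to_kcal`, and `G_proton` (named vector of
#'   proton free energies per phase, kcal/mol; `NA` for heptane, where no
#'   literature value exists and paired protonation/deprotonation summaries
#'   must be used instead).
#' @export
#' @examples
#' cst <- thermo_constants()
#' cst$G_proton[["water"]]
thermo_constants <- function(T = 298.15, std_state_factor = 24.3,
                             wigner_coeff = 1.44, R_cal = 1.987204) {
  stopifnot(T > 0, std_state_factor > 0, wigner_coeff > 0, R_cal > 0)
  structure(list(
    T = T,
    kB = 1.380649e-23,
    h = 6.62607015e-34,
    R_cal = R_cal,
    std_state_factor = std_state_factor,
    wigner_coeff = wigner_coeff,
    hartree_to_kcal = 627.509474,
    G_proton = c(gas = -6.28, heptane = NA_real_, water = -272.18)
  ), class = "thermo_constants")
}

#' @export
print.thermo_constants <- function(x, ...) {
  cat("Thermochemical constants (energies kcal/mol)\n")
  cat(sprintf("  T = %.2f K, R = %.6f cal/mol/K\n", x$T, x$R_cal))
  cat(sprintf("  standard-state factor = %.3g, Wigner coefficient = %.3g cm K\n",
              x$std_state_factor, x$wigner_coeff))
  cat(sprintf("  G(H+): gas %.2f, water %.2f, heptane unavailable\n",
              x$G_proton[["gas"]], x$G_proton[["water"]]))
  invisible(x)
}

#' Solvation phases of the analysis
#'
#' Every phase-indexed quantity names one of the three phases: the gas
#' phase, heptane (a hydrophobic lipid-like continuum) or water.
#'
#' @return Character vector `c("gas", "heptane", "water")`.
#' @export
phases <- function() c("gas", "heptane", "water")

#' Monomer compounds of the dimerization network
#'
#' 2-aminophenol (`2AP`), L-3-hydroxykynurenine (`L3HOK`),
#' 3-hydroxyanthranilic acid in neutral (`3HAA`) and carboxylate-ionized
#' (`3HAAi`, net charge -1) form.
#'
#' @return Character vector of the four compound labels.
#' @export
compounds <- function() c("2AP", "L3HOK", "3HAA", "3HAAi")

check_phase <- function(phase) {
  if (length(phase) != 1L || !phase %in% phases())
    stop("unknown phase '", paste(phase, collapse = ","),
         "'; must be one of ", paste(phases(), collapse = ", "), call. = FALSE)
  phase
}

check_compound <- function(compound) {
  ok <- c(compounds(), "shared")
  if (length(compound) != 1L || !compound %in% ok)
    stop("unknown compound '", paste(compound, collapse = ","),
         "'; must be one of ", paste(ok, collapse = ", "), call. = FALSE)
  compound
}

#' Convert energies between hartree and kcal/mol
#'
#' @param x numeric energies.
#' @return Converted energies (conversion factor 627.509474 kcal/mol per
#'   hartree).
#' @export
kcal_from_hartree <- function(x) x * 627.509474

#' @rdname kcal_from_hartree
#' @export
hartree_from_kcal <- function(x) x / 627.509474
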