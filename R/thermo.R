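#' Create a species thermochemistry record
#'
#' One record describes one chemical species in one phase: its total
#' (single-point) energy `E_T` -- a total energy in the gas phase or a
#' total free energy in solution -- together with the thermal correction
#' to the Gibbs energy `G_CORR` and, optionally, the thermal enthalpy
#' correction `H_CORR`, all in kcal/mol unless `units = "hartree"`.
#'
#' @param species_id unique species identifier, e.g. `"2AP.D3"`.
#' @param compound one of [compounds()] or `"shared"` for small species
#'   (H*, H+, O2, NH3, ...) common to all columns.
#' @param form structural form label (e.g. `"M"`, `"Mstar"`, `"Mq"`,
#'   `"D1"`..`"D10"`, `"D1p"`..`"D6p"`, `"D4H"`, `"XAN"`, `"Hstar"`).
#' @param phase one of [phases()].
#' @param E_T,G_CORR,H_CORR energies; `H_CORR` may be `NA` when only free
#'   energies are needed.
#' @param charge integer net charge.
#' @param multiplicity positive integer spin multiplicity.
#' @param optimized_in phase in which the geometry/Hessian was obtained
#'   (`"gas"` or `"water"`); bookkeeping for ion-radicals that are unstable
#'   in the gas phase.
#' @param level theory-level tag for `E_T` (e.g. `"II"`, `"III"`).
#' @param units `"kcal_per_mol"` (default) or `"hartree"`; hartree input is
#'   converted on construction.
#'
#' @return A one-row `data.frame` with class `thermo_record`.
#' @export
#' @examples
#' h <- thermo_record("H", "shared", "Hstar", "gas", E_T = -313.93, G_CORR = -3.93)
#' free_energy(h)
thermo_record <- function(species_id, compound, form, phase, E_T, G_CORR,
                          H_CORR = NA_real_, charge = 0L, multiplicity = 1L,
                          optimized_in = "gas", level = "III",
                          units = c("kcal_per_mol", "hartree")) {
  units <- match.arg(units)
  check_phase(phase)
  check_compound(compound)
  if (!is.finite(E_T)) stop("E_T must be finite for ", species_id, call. = FALSE)
  if (!is.finite(G_CORR))
    stop("G_CORR must be finite for ", species_id, call. = FALSE)
  if (multiplicity < 1) stop("multiplicity must be >= 1", call. = FALSE)
  if (!optimized_in %in% c("gas", "water"))
    stop("optimized_in must be 'gas' or 'water'", call. = FALSE)
  if (units == "hartree") {
    E_T <- kcal_from_hartree(E_T)
    G_CORR <- kcal_from_hartree(G_CORR)
    H_CORR <- kcal_from_hartree(H_CORR)
  }
  out <- data.frame(species_id = species_id, compound = compound, form = form,
                    phase = phase, E_T = E_T, G_CORR = G_CORR, H_CORR = H_CORR,
                    charge = as.integer(charge),
                    multiplicity = as.integer(multiplicity),
                    optimized_in = optimized_in, level = level,
                    stringsAsFactors = FALSE)
  class(out) <- c("thermo_record", "data.frame")
  out
}

#' Gibbs free energy of a species record
#'
#' Composes the free energy as `G = E_T + G_CORR`: the single-point total
#' (free) energy plus the thermal correction to the Gibbs energy from the
#' frequency calculation. Vectorized over the rows of a species table.
#'
#' @param record a `thermo_record` or any data.frame with `E_T` and
#'   `G_CORR` columns (kcal/mol).
#' @return Numeric vector of free energies, kcal/mol.
#' @export
free_energy <- function(record) {
  stopifnot(is.data.frame(record), all(c("E_T", "G_CORR") %in% names(record)))
  bad <- !is.finite(record$G_CORR)
  if (any(bad)) {
    who <- record[bad, , drop = FALSE]
    stop("missing G_CORR for species ",
         paste(sprintf("%s (%s)", who$species_id, who$phase), collapse = ", "),
         call. = FALSE)
  }
  record$E_T + record$G_CORR
}

#' Enthalpy of a species record
#'
#' `H = E_T + H_CORR`, with the thermal enthalpy correction in place of
#' the Gibbs correction; used to form homolytic bond-dissociation
#' enthalpies (BDE) alongside the free-energy variant (BDG). For X-H
#' dissociation the Gibbs correction is roughly 5.7 kcal/mol more negative
#' than the enthalpy correction, which is why a BDG runs ~5 kcal/mol below
#' the matching BDE.
#'
#' @inheritParams free_energy
#' @return Numeric vector of enthalpies, kcal/mol.
#' @export
enthalpy <- function(record) {
  stopifnot(is.data.frame(record), all(c("E_T", "H_CORR") %in% names(record)))
  bad <- !is.finite(record$H_CORR)
  if (any(bad)) {
    who <- record[bad, , drop = FALSE]
    stop("missing H_CORR for species ",
         paste(sprintf("%s (%s)", who$species_id, who$phase), collapse = ", "),
         call. = FALSE)
  }
  record$E_T + record$H_CORR
}

#' Proton free energy by phase
#'
#' Literature proton free energies: -6.28 kcal/mol in the gas phase and
#' -272.18 kcal/mol in water. No literature value exists for heptane;
#' requesting it is an error, and heptane protonation/deprotonation stages
#' must be evaluated as paired summaries in which the proton cancels.
#'
#' @param phase one of [phases()].
#' @param constants a [thermo_constants()] object.
#' @return Proton free energy in kcal/mol.
#' @export
#' @examples
#' proton_free_energy("gas")
proton_free_energy <- function(phase, constants = thermo_constants()) {
  check_phase(phase)
  g <- constants$G_proton[[phase]]
  if (is.na(g))
    stop("proton free energy unavailable in heptane; ",
         "use paired-stage summaries (e.g. stage 'N7+8')", call. = FALSE)
  g
}
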