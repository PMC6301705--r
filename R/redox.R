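#' Adiabatic ionization potential from neutral and cation free energies
#'
#' `IP = G(cation) - G(neutral)`: the free-energy cost of one-electron
#' abstraction, with both species separately optimized (adiabatic values).
#' Inputs may be free energies (numeric) or species records. When records
#' are given their phases must match unless `allow_phase_mismatch = TRUE`;
#' a provenance mix (ion optimized in water, neutral in the gas phase --
#' the bold cells of the published tables) is computed as a plain G
#' difference with a warning noting the mix.
#'
#' @param neutral,ion free energies in kcal/mol or one-row species
#'   records/data.frames.
#' @param allow_phase_mismatch set `TRUE` to override the same-phase
#'   check.
#' @return IP (or EA) in kcal/mol.
#' @export
#' @examples
#' ionization_potential(-150, -50)  # 100 kcal/mol
ionization_potential <- function(neutral, ion, allow_phase_mismatch = FALSE) {
  g <- redox_pair(neutral, ion, allow_phase_mismatch)
  g$ion - g$neutral
}

#' @rdname ionization_potential
#' @export
electron_affinity <- function(neutral, ion, allow_phase_mismatch = FALSE) {
  g <- redox_pair(neutral, ion, allow_phase_mismatch)
  g$neutral - g$ion
}

redox_pair <- function(neutral, ion, allow_phase_mismatch) {
  as_g <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(nrow(x) == 1L)
      list(G = free_energy(x), phase = x$phase,
           opt = if ("optimized_in" %in% names(x)) x$optimized_in else NA)
    } else {
      stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
      list(G = x, phase = NA, opt = NA)
    }
  }
  n <- as_g(neutral); i <- as_g(ion)
  if (!is.na(n$phase) && !is.na(i$phase) && n$phase != i$phase &&
      !allow_phase_mismatch)
    stop("neutral (", n$phase, ") and ion (", i$phase, ") phases differ; ",
         "set allow_phase_mismatch = TRUE to override", call. = FALSE)
  if (!is.na(n$opt) && !is.na(i$opt) && n$opt != i$opt)
    warning("mixed provenance: neutral optimized in ", n$opt,
            ", ion in ", i$opt, call. = FALSE)
  list(neutral = n$G, ion = i$G)
}

#' Mulliken electronegativity
#'
#' `chi = (IP + EA) / 2`: the arithmetic mean of the ionization potential
#' and the electron affinity, a summary index of electron-donating versus
#' electron-accepting power.
#'
#' @param IP,EA values in kcal/mol.
#' @return chi in kcal/mol.
#' @export
electronegativity <- function(IP, EA) {
  stopifnot(is.finite(IP), is.finite(EA))
  (IP + EA) / 2
}

#' Redox descriptor table from the reference data
#'
#' Joins the ionization-potential and electron-affinity reference tables
#' and adds the Mulliken electronegativity, with the ion-optimization
#' provenance flags carried through.
#'
#' @param ref reference tables from [load_reference_data()].
#' @return data.frame with `form`, `compound`, `phase`, `IP`, `EA`, `chi`,
#'   `cation_optimized_in`, `anion_optimized_in`.
#' @export
#' @examples
#' rt <- redox_table()
#' subset(rt, form == "D7" & compound == "3HAAi" & phase == "water")
redox_table <- function(ref = load_reference_data()) {
  m <- merge(ref$ip, ref$ea, by = c("form", "compound", "phase"))
  m$chi <- (m$IP + m$EA) / 2
  m[order(m$phase, m$compound, m$form),
    c("form", "compound", "phase", "IP", "EA", "chi",
      "cation_optimized_in", "anion_optimized_in")]
}

#' Rank species by a redox descriptor
#'
#' Stable ascending sort of redox records by IP, EA or chi within one
#' phase (and optionally one compound); ties broken by form label.
#'
#' @param records a data.frame as returned by [redox_table()].
#' @param by `"IP"`, `"EA"` or `"chi"`.
#' @param phase one of [phases()].
#' @param compound optional compound filter.
#' @return The filtered records ordered by the descriptor.
#' @export
rank_species <- function(records, by = c("IP", "EA", "chi"), phase,
                         compound = NULL) {
  by <- match.arg(by)
  check_phase(phase)
  r <- records[records$phase == phase, , drop = FALSE]
  if (!is.null(compound)) r <- r[r$compound == compound, , drop = FALSE]
  if (!nrow(r)) stop("no records for the requested phase/compound",
                     call. = FALSE)
  r[order(r[[by]], r$form), , drop = FALSE]
}
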