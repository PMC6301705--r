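#' The dimerization reaction registry (stages N1-N26)
#'
#' Loads the packaged stoichiometric registry of the 26 network stages.
#' Stages N1-N14 form the "classic" enzymatic route from two monomers to
#' the phenoxazinone dimer D10 (H-atom abstractions N1, N2, N5, N6, N11,
#' N12; conjugations N3, N9; tautomerizations N4, N10; the
#' protonation/deprotonation pairs N7/N8 and N13/N14). N15-N25 are the
#' redundant non-enzymatic stages via the primed dimers D1'-D6' (ASCII
#' `D1p`..`D6p`), and N26 (L-3HOK only) is the final cyclization of D10 to
#' xanthommatin releasing two H atoms, encoded in both printed product
#' variants (`N26_NH4`, `N26_NH3`).
#'
#' @return A data.frame of class `reaction_registry` in long format:
#'   `stage`, `rclass`, `role` (reactant/product), `species` (form label),
#'   `count`, `compounds` (applicability, `|`-separated).
#' @export
reaction_registry <- function() {
  reg <- utils::read.csv(ref_path("reactions.csv"), stringsAsFactors = FALSE)
  structure(reg, class = c("reaction_registry", "data.frame"))
}

#' @export
print.reaction_registry <- function(x, ...) {
  cat("Reaction registry:", length(unique(x$stage)), "stages\n")
  for (s in unique(x$stage)) {
    r <- x[x$stage == s & x$role == "reactant", ]
    p <- x[x$stage == s & x$role == "product", ]
    term <- function(d) paste(ifelse(d$count > 1, paste0(d$count, " "), ""),
                              d$species, sep = "", collapse = " + ")
    cat(sprintf("  %-8s %-15s %s -> %s\n", s, r$rclass[1], term(r), term(p)))
  }
  invisible(x)
}

# species forms ordered so signed counts can be accumulated
reaction_terms <- function(reactions, stage) {
  r <- reactions[reactions$stage == stage, , drop = FALSE]
  if (!nrow(r)) stop("unknown stage '", stage, "'", call. = FALSE)
  sign <- ifelse(r$role == "product", 1, -1)
  stats::setNames(sign * r$count, r$species)
}

# Net signed species counts for a weighted stage list; pair stages expand
# to their member reactions (proton cancels).
pair_members <- list("N7+8" = c("N7", "N8"), "N13+14" = c("N13", "N14"))

net_stoichiometry <- function(stages, mult, reactions) {
  acc <- numeric()
  add <- function(terms, w) {
    for (sp in names(terms)) {
      acc[sp] <<- (if (is.na(acc[sp])) 0 else acc[sp]) + w * terms[[sp]]
    }
  }
  for (i in seq_along(stages)) {
    s <- stages[i]
    members <- if (s %in% names(pair_members)) pair_members[[s]] else s
    for (m in members) add(reaction_terms(reactions, m), mult[i])
  }
  acc[abs(acc) > 1e-12]
}

#' Count H atoms released by a stage list
#'
#' Net `Hstar` production of a weighted stage list; a complete route from
#' two monomers to D10 releases six H atoms (six-electron oxidation), and
#' N26 releases two more.
#'
#' @param stages character vector of stage ids (pair ids allowed).
#' @param mult multiplicities, recycled to `length(stages)`.
#' @param reactions a [reaction_registry()].
#' @return Net number of H atoms produced.
#' @export
h_atoms_released <- function(stages, mult = 1, reactions = reaction_registry()) {
  mult <- rep_len(mult, length(stages))
  net <- net_stoichiometry(stages, mult, reactions)
  if (is.na(net["Hstar"])) 0 else unname(net[["Hstar"]])
}

# G value for one species form of one compound/phase from a species_table.
# Small shared species are looked up under compound "shared"; the proton
# falls back to the literature constant.
species_G <- function(registry, form, compound, phase, constants) {
  i <- registry$form == form & registry$phase == phase &
    registry$compound %in% c(compound, "shared")
  if (!any(i)) {
    if (form == "Hplus") return(proton_free_energy(phase, constants))
    stop("species '", form, "' (", compound, ", ", phase,
         ") missing from registry", call. = FALSE)
  }
  free_energy(registry[which(i)[1], , drop = FALSE])
}

#' Free-energy change of one network stage
#'
#' Computes the stage reaction free energy as the difference of product
#' and reactant species free energies,
#' `dG = sum G(products) - sum G(reactants)` (the H-dissociation and
#' dimerization formulas are the two- and three-term special cases),
#' either from a species registry (`source = "species"`) or from the
#' packaged reference table (`source = "fixture"`). Protons are valued by
#' [proton_free_energy()]; in heptane the individual protonation stages
#' are unavailable and the pair summaries `"N7+8"`/`"N13+14"` must be
#' requested instead.
#'
#' @param stage stage id (`"N1"`..`"N25"`, `"N26_NH4"`, `"N26_NH3"`, or a
#'   pair id).
#' @param compound one of [compounds()].
#' @param phase one of [phases()].
#' @param source `"fixture"` or `"species"`.
#' @param registry a [species_table()] (required for `source = "species"`).
#' @param ref reference tables (for `source = "fixture"`).
#' @param reactions a [reaction_registry()].
#' @param constants a [thermo_constants()].
#' @return A list of class `stage_energy`: `stage`, `compound`, `phase`,
#'   `dG` (kcal/mol), `rclass`, `components` (named signed G terms, for
#'   species-derived values), `source`.
#' @export
stage_free_energy <- function(stage, compound, phase,
                              source = c("fixture", "species"),
                              registry = NULL, ref = NULL,
                              reactions = reaction_registry(),
                              constants = thermo_constants()) {
  source <- match.arg(source)
  check_phase(phase); check_compound(compound)
  members <- if (stage %in% names(pair_members)) pair_members[[stage]] else stage
  rcl <- unique(reactions$rclass[reactions$stage %in% members])
  appl <- unique(reactions$compounds[reactions$stage %in% members])
  if (!length(rcl)) stop("unknown stage '", stage, "'", call. = FALSE)
  if (!compound %in% strsplit(appl, "|", fixed = TRUE)[[1]])
    stop("stage ", stage, " is not defined for compound ", compound,
         call. = FALSE)

  if (source == "fixture") {
    if (is.null(ref)) ref <- load_reference_data()
    dG <- fixture_stage_dG(ref, stage, compound, phase)
    comp <- NULL
  } else {
    if (is.null(registry)) stop("source = 'species' needs a registry",
                                call. = FALSE)
    terms <- net_stoichiometry(stage, 1, reactions)
    comp <- vapply(names(terms), function(f)
      terms[[f]] * species_G(registry, f, compound, phase, constants), 0)
    dG <- sum(comp)
  }
  structure(list(stage = stage, compound = compound, phase = phase,
                 dG = dG, rclass = paste(rcl, collapse = "+"),
                 components = comp, source = source),
            class = "stage_energy")
}

#' @export
print.stage_energy <- function(x, ...) {
  cat(sprintf("%s [%s] %s/%s: dG = %.3f kcal/mol (%s)\n", x$stage, x$rclass,
              x$compound, x$phase, x$dG, x$source))
  if (!is.null(attr(x, "bsse")))
    cat(sprintf("  BSSE-corrected from %.3f by %.3f\n",
                attr(x, "bsse")$original, attr(x, "bsse")$correction))
  invisible(x)
}

#' Stage lists for the two complete dimerization routes
#'
#' The enzymatic ("classic") route is N1-N14; in heptane the
#' protonation/deprotonation stages appear as pair summaries. The
#' non-enzymatic route doubles the monomer H-abstractions (N1, N2) and
#' proceeds through the quinoneimine conjugate: 2x(N1+N2), N15, N16, N17.
#'
#' @param phase one of [phases()].
#' @return A data.frame with columns `stage` and `mult`.
#' @export
enzymatic_route <- function(phase = "gas") {
  check_phase(phase)
  st <- if (phase == "heptane") {
    c(paste0("N", 1:6), "N7+8", paste0("N", 9:12), "N13+14")
  } else paste0("N", 1:14)
  data.frame(stage = st, mult = 1, stringsAsFactors = FALSE)
}

#' @rdname enzymatic_route
#' @export
nonenzymatic_route <- function(phase = "gas") {
  check_phase(phase)
  data.frame(stage = c("N1", "N2", "N15", "N16", "N17"),
             mult = c(2, 2, 1, 1, 1), stringsAsFactors = FALSE)
}

as_route <- function(stages) {
  if (is.data.frame(stages)) {
    stopifnot(all(c("stage", "mult") %in% names(stages)))
    stages
  } else {
    data.frame(stage = as.character(stages), mult = rep(1, length(stages)),
               stringsAsFactors = FALSE)
  }
}

#' Sum stage free energies along a pathway
#'
#' Multiplicity-weighted sum of stage free-energy changes; equals the
#' free energy of the route's net transformation by Hess's law.
#'
#' @param stages character vector of stage ids, or a data.frame with
#'   `stage` and `mult` columns (see [enzymatic_route()]).
#' @inheritParams stage_free_energy
#' @return A list of class `pathway_result`: `stages` (per-stage table),
#'   `total` (kcal/mol), `pair_summaries_used`.
#' @export
#' @examples
#' ref <- load_reference_data()
#' pathway_sum(enzymatic_route("gas"), "2AP", "gas", ref = ref)$total
pathway_sum <- function(stages, compound, phase,
                        source = c("fixture", "species"), registry = NULL,
                        ref = NULL, reactions = reaction_registry(),
                        constants = thermo_constants()) {
  source <- match.arg(source)
  route <- as_route(stages)
  if (source == "fixture" && is.null(ref)) ref <- load_reference_data()
  dG <- vapply(seq_len(nrow(route)), function(i)
    stage_free_energy(route$stage[i], compound, phase, source,
                      registry = registry, ref = ref, reactions = reactions,
                      constants = constants)$dG, 0)
  out <- data.frame(stage = route$stage, mult = route$mult, dG = dG,
                    stringsAsFactors = FALSE)
  structure(list(stages = out, compound = compound, phase = phase,
                 total = sum(out$mult * out$dG),
                 pair_summaries_used = any(route$stage %in% names(pair_members))),
            class = "pathway_result")
}

#' @export
print.pathway_result <- function(x, ...) {
  cat(sprintf("Pathway (%s, %s): %d stage(s), total dG = %.3f kcal/mol%s\n",
              x$compound, x$phase, nrow(x$stages), x$total,
              if (x$pair_summaries_used) " [pair summaries used]" else ""))
  invisible(x)
}

#' @export
as.data.frame.pathway_result <- function(x, ...) {
  df <- x$stages
  df$compound <- x$compound
  df$phase <- x$phase
  rbind(df, data.frame(stage = "SUM", mult = 1, dG = x$total,
                       compound = x$compound, phase = x$phase))
}

#' Hess path-independence check between two routes
#'
#' Verifies that two stage lists share the same net stoichiometry (an
#' error otherwise, before any energy arithmetic) and compares their
#' summed free energies. With a self-consistent species registry the
#' difference is numerically zero; with printed (rounded) reference values
#' it is zero to printed precision except for documented
#' conformer-inconsistent cells.
#'
#' @param route_a,route_b stage vectors or `stage`/`mult` data.frames.
#' @param tolerance pass threshold on `|total_a - total_b|` (kcal/mol);
#'   defaults to 1e-6 for species-derived routes and 0.01 against printed
#'   fixtures.
#' @inheritParams stage_free_energy
#' @return A list of class `hess_check`: `delta`, `pass`, `total_a`,
#'   `total_b`, `tolerance`.
#' @export
hess_check <- function(route_a, route_b, compound, phase,
                       source = c("fixture", "species"), registry = NULL,
                       ref = NULL, reactions = reaction_registry(),
                       constants = thermo_constants(), tolerance = NULL) {
  source <- match.arg(source)
  if (is.null(tolerance)) tolerance <- if (source == "species") 1e-6 else 0.01
  a <- as_route(route_a); b <- as_route(route_b)
  na <- net_stoichiometry(a$stage, a$mult, reactions)
  nb <- net_stoichiometry(b$stage, b$mult, reactions)
  sp <- union(names(na), names(nb))
  ca <- stats::setNames(rep(0, length(sp)), sp); ca[names(na)] <- na
  cb <- stats::setNames(rep(0, length(sp)), sp); cb[names(nb)] <- nb
  if (any(abs(ca - cb) > 1e-9)) {
    off <- sp[abs(ca - cb) > 1e-9]
    stop("routes differ in net stoichiometry for: ",
         paste(off, collapse = ", "), call. = FALSE)
  }
  ta <- pathway_sum(a, compound, phase, source, registry, ref, reactions,
                    constants)$total
  tb <- pathway_sum(b, compound, phase, source, registry, ref, reactions,
                    constants)$total
  structure(list(delta = abs(ta - tb), pass = abs(ta - tb) <= tolerance,
                 total_a = ta, total_b = tb, tolerance = tolerance,
                 compound = compound, phase = phase),
            class = "hess_check")
}

#' @export
print.hess_check <- function(x, ...) {
  cat(sprintf("Hess check (%s, %s): |%.3f - %.3f| = %.2e kcal/mol -> %s\n",
              x$compound, x$phase, x$total_a, x$total_b, x$delta,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' Stages whose free-energy change is a homolytic X-H BDG
#'
#' The eleven H-atom abstraction stages entering the bond-dissociation
#' free-energy statistics; D6' -> D10 (N24) is an H migration, not an
#' abstraction, and is excluded.
#'
#' @return Character vector of stage ids.
#' @export
bdg_stages <- function() c("N1", "N2", "N5", "N6", "N11", "N12",
                           "N16", "N17", "N19", "N21", "N22")

#' Summary statistics of the homolytic X-H BDG values
#'
#' Mean, sample SD and t-based 95% confidence half-width over the 44
#' bond-dissociation free energies (eleven abstraction stages times four
#' compounds) in one phase. The published "mean +/- x" summaries for this
#' quantity correspond to the 95% CI half-width, not the SD; both are
#' returned.
#'
#' @inheritParams stage_free_energy
#' @return List of class `bdg_summary`: `mean`, `sd`, `ci95`, `n`,
#'   `values`.
#' @export
#' @examples
#' ref <- load_reference_data()
#' bdg_summary("gas", ref = ref)$mean
bdg_summary <- function(phase, source = c("fixture", "species"),
                        registry = NULL, ref = NULL,
                        reactions = reaction_registry(),
                        constants = thermo_constants()) {
  source <- match.arg(source)
  check_phase(phase)
  if (source == "fixture" && is.null(ref)) ref <- load_reference_data()
  cells <- expand.grid(stage = bdg_stages(), compound = compounds(),
                       stringsAsFactors = FALSE)
  v <- numeric(nrow(cells)); missing <- character()
  for (i in seq_len(nrow(cells))) {
    v[i] <- tryCatch(
      stage_free_energy(cells$stage[i], cells$compound[i], phase, source,
                        registry = registry, ref = ref,
                        reactions = reactions, constants = constants)$dG,
      error = function(e) {
        missing <<- c(missing, paste0(cells$stage[i], "/", cells$compound[i]))
        NA_real_
      })
  }
  if (length(missing))
    stop("BDG value set incomplete; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- length(v)
  ci <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(v) / sqrt(n) else NA_real_
  structure(list(mean = mean(v), sd = if (n > 1) stats::sd(v) else NA_real_,
                 ci95 = ci, n = n, phase = phase, values = v),
            class = "bdg_summary")
}

#' @export
print.bdg_summary <- function(x, ...) {
  cat(sprintf("BDG (%s): %.3f +/- %.3f kcal/mol (95%% CI, n = %d; SD %.3f)\n",
              x$phase, x$mean, x$ci95, x$n, x$sd))
  invisible(x)
}

#' Apply a basis-set superposition error correction to a stage energy
#'
#' BSSE corrections are stored as printed (negative). Applying one makes
#' the corrected association *less* favorable: for a dimerization stage
#' the correction's magnitude is added to dG (the uncorrected value
#' overbinds), and for an H-abstraction BDG it is subtracted (the
#' uncorrected BDG is too positive). The original value and the applied
#' correction are retained in the `bsse` attribute; a second application
#' is an error.
#'
#' @param stage_energy a `stage_energy` from [stage_free_energy()].
#' @param correction BSSE correction in kcal/mol, negative by convention.
#' @return The corrected `stage_energy`.
#' @export
apply_bsse <- function(stage_energy, correction) {
  stopifnot(inherits(stage_energy, "stage_energy"))
  if (!is.null(attr(stage_energy, "bsse")))
    stop("BSSE correction already applied to stage ", stage_energy$stage,
         call. = FALSE)
  if (correction > 0)
    warning("BSSE corrections are conventionally negative", call. = FALSE)
  orig <- stage_energy$dG
  cls <- stage_energy$rclass
  delta <- if (grepl("H_ABSTRACTION", cls)) correction else -correction
  stage_energy$dG <- orig + delta
  attr(stage_energy, "bsse") <- list(original = orig, correction = correction,
                                     applied = delta)
  stage_energy
}
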