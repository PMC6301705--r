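# Constructive generator of self-consistent fictitious registries. Stage
# free-energy targets are sampled for a spanning set of the network (one
# new species per sampled stage) and species free energies are assigned
# to meet them, so every Hess identity holds exactly by construction; the
# remaining stages (N17, N19, N21, N24, N25, and the second member of
# each protonation pair) are then determined, not free.

#' Configuration for the synthetic-data generator
#'
#' Default stage-energy ranges span the values observed across the real
#' network (H abstraction 19-77 kcal/mol, conjugation -5-60,
#' tautomerization -66-7, cyclization 4-37, protonation -380..-225 in gas
#' and -18..5 in water, pair summaries -16..7), barriers 5-40 kcal/mol and
#' imaginary frequencies 1000-2500 cm^-1, and the two-theory-level linear
#' relation slope 0.977, intercept -0.916, unit Gaussian scatter at
#' n = 36.
#'
#' @param seed integer RNG seed (mandatory).
#' @param compounds,phases subsets of [compounds()] / [phases()].
#' @param ranges named list of `c(lo, hi)` stage-energy ranges; partial
#'   overrides are merged into the defaults.
#' @param ts list with `n`, `barrier`, `nu_i` ranges for TS records.
#' @param two_level list with `slope`, `intercept`, `sigma`, `n`,
#'   `x_range` for the theory-level pair generator.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(seed, compounds = kynox::compounds(),
                         phases = kynox::phases(), ranges = list(),
                         ts = list(), two_level = list()) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  def_ranges <- list(
    h_abstraction = c(19, 77), conjugation = c(-5, 60),
    tautomerization = c(-66, 7), cyclization = c(4, 37),
    protonation_gas = c(-380, -225), protonation_water = c(-18, 5),
    pair = c(-16, 7), xan = c(76, 145))
  def_ts <- list(n = 10L, barrier = c(5, 40), nu_i = c(1000, 2500))
  def_tl <- list(slope = 0.977, intercept = -0.916, sigma = 1, n = 36L,
                 x_range = c(20, 80))
  ranges <- utils::modifyList(def_ranges, ranges)
  ts <- utils::modifyList(def_ts, ts)
  two_level <- utils::modifyList(def_tl, two_level)
  for (r in ranges) stopifnot(length(r) == 2, r[1] <= r[2])
  structure(list(seed = as.integer(seed), compounds = compounds,
                 phases = phases, ranges = ranges, ts = ts,
                 two_level = two_level),
            class = "synth_config")
}

# sampled ("tree") stages and their class ranges; everything else derives
tree_stage_class <- c(
  N1 = "h_abstraction", N2 = "h_abstraction", N3 = "conjugation",
  N4 = "tautomerization", N5 = "h_abstraction", N6 = "h_abstraction",
  N9 = "cyclization", N10 = "tautomerization", N11 = "h_abstraction",
  N12 = "h_abstraction", N15 = "conjugation", N16 = "h_abstraction",
  N18 = "tautomerization", N20 = "cyclization", N22 = "h_abstraction",
  N23 = "cyclization", `N7+8` = "pair", `N13+14` = "pair",
  N7 = "protonation", N13 = "protonation", N26_NH3 = "xan")

monomer_charge <- c(`2AP` = 0L, L3HOK = 0L, `3HAA` = 0L, `3HAAi` = -1L)

#' Generate a self-consistent synthetic species registry
#'
#' Assigns a free energy to every species of the dimerization network
#' (all dimer, radical, protonated and quinoneimine forms, plus the
#' shared H atom and proton) such that each sampled stage free-energy
#' change falls in its configured class range. Because species energies
#' are constructed, every Hess path identity holds to machine precision,
#' and charge/H-atom bookkeeping is consistent with the reaction
#' registry. Heptane carries no proton species, mirroring the missing
#' literature value, so heptane protonation is only available as the pair
#' summaries.
#'
#' @param config a [synth_config()].
#' @param pins optional data.frame `stage`, `compound`, `phase`, `dG`
#'   pinning sampled stages to fixed values (e.g. published ones);
#'   pinning a Hess-determined stage is an error.
#' @return A [species_table()] with `G_CORR`/`H_CORR` splits and
#'   provenance columns filled in.
#' @export
#' @examples
#' reg <- generate_registry(synth_config(seed = 1))
#' stage_free_energy("N16", "2AP", "gas", "species", registry = reg)$dG
generate_registry <- function(config, pins = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  if (!is.null(pins)) {
    bad <- setdiff(pins$stage, names(tree_stage_class))
    if (length(bad))
      stop("cannot pin Hess-determined stage(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  runif1 <- function(r) stats::runif(1, r[1], r[2])
  rows <- list()
  emit <- function(compound, form, phase, G, charge, mult) {
    id <- if (compound == "shared") form else paste(compound, form, sep = ".")
    g_corr <- stats::runif(1, -20, 5)
    rows[[length(rows) + 1L]] <<- data.frame(
      species_id = id, compound = compound, form = form, phase = phase,
      E_T = G - g_corr, G_CORR = g_corr,
      H_CORR = g_corr + 5.678 + stats::rnorm(1, 0, 0.3),
      charge = as.integer(charge), multiplicity = as.integer(mult),
      optimized_in = "gas", level = "III", stringsAsFactors = FALSE)
    G
  }
  cst <- thermo_constants()

  for (phase in config$phases) {
    G_H <- stats::runif(1, -314.5, -313.5)
    rows[[length(rows) + 1L]] <- data.frame(
      species_id = "H", compound = "shared", form = "Hstar", phase = phase,
      E_T = G_H + 3.9, G_CORR = -3.9, H_CORR = 1.48, charge = 0L,
      multiplicity = 2L, optimized_in = "gas", level = "III",
      stringsAsFactors = FALSE)
    has_proton <- phase != "heptane"
    G_Hp <- if (has_proton) cst$G_proton[[phase]] else NA_real_
    if (has_proton)
      rows[[length(rows) + 1L]] <- data.frame(
        species_id = "Hplus", compound = "shared", form = "Hplus",
        phase = phase, E_T = G_Hp, G_CORR = 0, H_CORR = NA_real_,
        charge = 1L, multiplicity = 1L, optimized_in = "gas", level = "III",
        stringsAsFactors = FALSE)

    for (cp in config$compounds) {
      tgt <- function(stage) {
        if (!is.null(pins)) {
          i <- pins$stage == stage & pins$compound == cp & pins$phase == phase
          if (any(i)) return(pins$dG[which(i)[1]])
        }
        cls <- tree_stage_class[[stage]]
        if (cls == "protonation")
          cls <- paste0("protonation_", phase)  # gas/water only
        runif1(config$ranges[[cls]])
      }
      ch <- monomer_charge[[cp]]
      G_M <- emit(cp, "M", phase, stats::runif(1, -450000, -250000), ch, 1)
      G_Ms <- emit(cp, "Mstar", phase, G_M - G_H + tgt("N1"), ch, 2)
      G_Mq <- emit(cp, "Mq", phase, G_Ms - G_H + tgt("N2"), ch, 1)
      G_D1 <- emit(cp, "D1", phase, G_M + G_Mq + tgt("N3"), 2 * ch, 1)
      G_D2 <- emit(cp, "D2", phase, G_D1 + tgt("N4"), 2 * ch, 1)
      G_D3 <- emit(cp, "D3", phase, G_D2 - G_H + tgt("N5"), 2 * ch, 2)
      G_D4 <- emit(cp, "D4", phase, G_D3 - G_H + tgt("N6"), 2 * ch, 1)
      pair7 <- tgt("N7+8")
      if (has_proton) {
        G_D4H <- emit(cp, "D4H", phase, G_D4 + G_Hp + tgt("N7"),
                      2 * ch + 1, 1)
      }
      G_D5 <- emit(cp, "D5", phase, G_D4 + pair7, 2 * ch, 1)
      G_D6 <- emit(cp, "D6", phase, G_D5 + tgt("N9"), 2 * ch, 1)
      G_D7 <- emit(cp, "D7", phase, G_D6 + tgt("N10"), 2 * ch, 1)
      G_D8 <- emit(cp, "D8", phase, G_D7 - G_H + tgt("N11"), 2 * ch, 2)
      G_D9 <- emit(cp, "D9", phase, G_D8 - G_H + tgt("N12"), 2 * ch, 1)
      pair13 <- tgt("N13+14")
      if (has_proton) {
        G_D9H <- emit(cp, "D9H", phase, G_D9 + G_Hp + tgt("N13"),
                      2 * ch + 1, 1)
      }
      G_D10 <- emit(cp, "D10", phase, G_D9 + pair13, 2 * ch, 1)
      G_D1p <- emit(cp, "D1p", phase, 2 * G_Mq + tgt("N15"), 2 * ch, 1)
      G_D3p <- emit(cp, "D3p", phase, G_D1p - G_H + tgt("N16"), 2 * ch, 2)
      G_D2p <- emit(cp, "D2p", phase, G_D1p + tgt("N18"), 2 * ch, 1)
      G_D5p <- emit(cp, "D5p", phase, G_D3p + tgt("N20"), 2 * ch, 2)
      G_D4p <- emit(cp, "D4p", phase, G_D3p - G_H + tgt("N22"), 2 * ch, 1)
      emit(cp, "D6p", phase, G_D4p + tgt("N23"), 2 * ch, 3)
      if (cp == "L3HOK") {
        G_NH3 <- emit(cp, "NH3", phase, stats::runif(1, -35500, -35000), 0, 1)
        emit(cp, "NH4p", phase, G_NH3 + stats::runif(1, -270, -200), 1, 1)
        emit(cp, "XAN", phase, G_D10 - G_NH3 - 2 * G_H + tgt("N26_NH3"),
             2 * ch, 1)
      }
    }
  }
  species_table(do.call(rbind, rows))
}

#' Generate synthetic transition-state records with known rates
#'
#' Barrier pairs are drawn from the configured range, imaginary
#' frequencies from theirs, and the implied forward/reverse TST rates are
#' stored alongside as ground truth for oracle comparisons.
#'
#' @param config a [synth_config()].
#' @return data.frame of TS records with `k_forward_truth`,
#'   `k_reverse_truth` columns.
#' @export
generate_ts_records <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  n <- config$ts$n
  ts <- data.frame(
    label = sprintf("TS%02d", seq_len(n)),
    phase = sample(config$phases, n, replace = TRUE),
    dG_TS_R = stats::runif(n, config$ts$barrier[1], config$ts$barrier[2]),
    dG_TS_P = stats::runif(n, config$ts$barrier[1], config$ts$barrier[2]),
    nu_i = stats::runif(n, config$ts$nu_i[1], config$ts$nu_i[2]),
    I = 1L, stringsAsFactors = FALSE)
  cst <- thermo_constants()
  ts$k_forward_truth <- tst_rate(ts$dG_TS_R, ts$nu_i, ts$I, constants = cst)
  ts$k_reverse_truth <- tst_rate(ts$dG_TS_P, ts$nu_i, ts$I, constants = cst)
  ts
}

#' Generate paired energies at two theory levels
#'
#' Level-II energies are uniform over a realistic X-H dissociation-energy
#' range; level-III values follow the configured linear relation with
#' Gaussian scatter, emulating the comparison of single-point refinements
#' against optimization-level energies.
#'
#' @param config a [synth_config()].
#' @return data.frame with `level_II` and `level_III` columns (kcal/mol);
#'   attributes `slope`, `intercept`, `sigma` record the generating truth.
#' @export
generate_two_level <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 2L)
  tl <- config$two_level
  x <- stats::runif(tl$n, tl$x_range[1], tl$x_range[2])
  y <- tl$slope * x + tl$intercept + stats::rnorm(tl$n, 0, tl$sigma)
  structure(data.frame(level_II = x, level_III = y),
            slope = tl$slope, intercept = tl$intercept, sigma = tl$sigma)
}
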