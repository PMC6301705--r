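# Registry and reference-table input/output. The delimited species/TS
# registry format is the package boundary: raw quantum-chemistry log files
# are out of scope.

# Parse energy values that may carry decimal commas (e.g. "-431,358");
# normalized to decimal points with a collected warning.
parse_energy <- function(x, what = "energy") {
  x <- trimws(as.character(x))
  x <- gsub("−", "-", x)  # unicode minus
  x[x %in% c("", "NA")] <- NA_character_
  comma <- grepl("^-?[0-9]+,[0-9]+$", x)
  if (any(comma)) {
    warning(sprintf("%d %s value(s) used a decimal comma (e.g. '%s'); normalized to points",
                    sum(comma), what, x[which(comma)[1]]), call. = FALSE)
    x[comma] <- sub(",", ".", x[comma], fixed = TRUE)
  }
  out <- suppressWarnings(as.numeric(x))
  if (anyNA(out) && !anyNA(x))
    stop("non-numeric ", what, " value(s): ",
         paste(unique(x[is.na(out)]), collapse = ", "), call. = FALSE)
  out
}

#' Validate a species registry table
#'
#' Checks a data.frame of species thermochemistry rows: required columns,
#' known phases, finite energies, and uniqueness of
#' `(species_id, phase, level)`. Hartree input is converted to kcal/mol.
#'
#' @param df data.frame with at least `species_id`, `compound`, `form`,
#'   `phase`, `E_T`, `G_CORR`; optional `H_CORR`, `charge`, `multiplicity`,
#'   `optimized_in`, `level`.
#' @param units `"kcal_per_mol"` or `"hartree"`.
#' @return The validated table with class `species_table`, energies in
#'   kcal/mol, attribute `units` recording the declared input units.
#' @export
species_table <- function(df, units = c("kcal_per_mol", "hartree")) {
  units <- match.arg(units)
  need <- c("species_id", "compound", "form", "phase", "E_T", "G_CORR")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("species table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"H_CORR" %in% names(df)) df$H_CORR <- NA_real_
  if (!"charge" %in% names(df)) df$charge <- 0L
  if (!"multiplicity" %in% names(df)) df$multiplicity <- 1L
  if (!"optimized_in" %in% names(df)) df$optimized_in <- "gas"
  if (!"level" %in% names(df)) df$level <- "III"

  badp <- !df$phase %in% phases()
  if (any(badp))
    stop("unknown phase in row(s) ", paste(which(badp), collapse = ", "),
         ": ", paste(unique(df$phase[badp]), collapse = ", "), call. = FALSE)
  for (col in c("E_T", "G_CORR")) {
    bad <- !is.finite(df[[col]])
    if (any(bad))
      stop("non-finite ", col, " in row(s) ",
           paste(which(bad), collapse = ", "), call. = FALSE)
  }
  if (any(df$multiplicity < 1))
    stop("multiplicity must be >= 1", call. = FALSE)
  keyv <- paste(df$species_id, df$phase, df$level)
  if (anyDuplicated(keyv)) {
    dup <- unique(keyv[duplicated(keyv)])
    stop("duplicate (species_id, phase, level) key(s): ",
         paste(dup, collapse = "; "), call. = FALSE)
  }
  if (units == "hartree") {
    df$E_T <- kcal_from_hartree(df$E_T)
    df$G_CORR <- kcal_from_hartree(df$G_CORR)
    df$H_CORR <- kcal_from_hartree(df$H_CORR)
  }
  structure(df, class = c("species_table", "data.frame"), units = units)
}

#' Read a species registry from delimited text
#'
#' Accepts comma- or tab-delimited files with a header naming the
#' [species_table()] columns. Decimal commas in energy fields are
#' normalized with a warning; duplicate keys, unknown phases and
#' non-numeric energies are errors naming the offending rows.
#'
#' @param path file path.
#' @param units energy units declared for the file.
#' @return A validated [species_table()].
#' @export
read_species_table <- function(path, units = c("kcal_per_mol", "hartree")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", strip.white = TRUE,
                          stringsAsFactors = FALSE)
  for (col in intersect(c("E_T", "G_CORR", "H_CORR"), names(df)))
    df[[col]] <- parse_energy(df[[col]], col)
  for (col in intersect(c("charge", "multiplicity"), names(df)))
    df[[col]] <- as.integer(df[[col]])
  species_table(df, units = units)
}

#' Write a species registry or result table to delimited text
#'
#' @param x data.frame (a species table, stage table, rate table, ...).
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_report <- function(x, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(x, "pathway_result")) x <- as.data.frame(x)
  stopifnot(is.data.frame(x))
  if (format == "csv") {
    utils::write.csv(x, path, row.names = FALSE)
  } else {
    jsonlite::write_json(x, path, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

ref_path <- function(file) {
  p <- system.file("extdata", file, package = "kynox")
  if (p == "") {
    # during development (pkgload) fall back to the source tree
    p <- file.path("inst", "extdata", file)
  }
  if (!file.exists(p)) stop("packaged reference file missing: ", file,
                            call. = FALSE)
  p
}

#' Load the curated reference energy tables
#'
#' Loads the packaged reference dataset for the dimerization network:
#' stage free energies for the 26 stages (including the heptane
#' protonation/deprotonation pair summaries `N7+8` and `N13+14`, and both
#' product variants of the final xanthommatin stage `N26_NH4`/`N26_NH3`),
#' printed pathway totals, ionization potentials, electron affinities,
#' transition-state barrier/frequency records, the O2 reduction
#' half-reaction energies, and the published feasibility membership lists
#' used for cross-checking. Text-level normalizations applied while
#' loading (decimal commas, the water `3 O2` stoichiometry slip) are
#' collected in the `normalizations` attribute.
#'
#' @return A list of class `kynox_ref` with elements `stage_dG`,
#'   `pathway_sums`, `ip`, `ea`, `ts`, `o2_reduction`, `ros_membership`,
#'   `superoxide_donors`.
#' @export
#' @examples
#' ref <- load_reference_data()
#' subset(ref$stage_dG, stage == "N1" & compound == "2AP")
load_reference_data <- function() {
  log <- character()
  note <- function(msg) log <<- c(log, msg)

  stage_dG <- utils::read.csv(ref_path("stage_free_energies.csv"),
                              stringsAsFactors = FALSE)
  pathway_sums <- utils::read.csv(ref_path("pathway_sums.csv"),
                                  stringsAsFactors = FALSE)
  ip <- utils::read.csv(ref_path("ionization_potentials.csv"),
                        stringsAsFactors = FALSE)
  ea <- utils::read.csv(ref_path("electron_affinities.csv"),
                        stringsAsFactors = FALSE)
  ts <- utils::read.csv(ref_path("ts_records.csv"), stringsAsFactors = FALSE)

  o2 <- utils::read.csv(ref_path("o2_reduction.csv"),
                        colClasses = "character", stringsAsFactors = FALSE)
  dg <- withCallingHandlers(
    parse_energy(o2$dG, "O2-reduction dG"),
    warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    })
  o2$dG <- dg
  o2$n_h <- as.integer(o2$n_h)
  slip <- grepl("^3O2", o2$half_reaction)
  if (any(slip)) {
    note("water full-reduction half-reaction printed as '3O2 + 6H*'; read as the stoichiometrically consistent 1.5 O2 + 6H* -> 3H2O")
    o2$half_reaction[slip] <- "1.5 O2 + 6H* -> 3H2O"
  }

  memb <- utils::read.csv(ref_path("ros_membership.csv"),
                          stringsAsFactors = FALSE)
  sox <- utils::read.csv(ref_path("superoxide_donors.csv"),
                         stringsAsFactors = FALSE)

  # shape checks: phases complete where the source prints them
  stopifnot(nrow(ts) == 30L, nrow(o2) == 12L,
            nrow(ip) == 183L, nrow(ea) == 183L,
            sum(stage_dG$stage %in% paste0("N", 1:25)) == 25L * 12L - 16L,
            nrow(pathway_sums) == 12L)

  structure(list(stage_dG = stage_dG, pathway_sums = pathway_sums,
                 ip = ip, ea = ea, ts = ts, o2_reduction = o2,
                 ros_membership = memb, superoxide_donors = sox),
            class = "kynox_ref", normalizations = log)
}

#' @export
print.kynox_ref <- function(x, ...) {
  cat("kynox reference tables\n")
  cat(sprintf("  stage dG rows: %d; IP/EA rows: %d/%d; TS rows: %d\n",
              nrow(x$stage_dG), nrow(x$ip), nrow(x$ea), nrow(x$ts)))
  nrm <- attr(x, "normalizations")
  if (length(nrm)) cat("  normalizations applied:\n",
                       paste("   -", nrm, collapse = "\n"), "\n")
  invisible(x)
}

# Fixture lookup: dG of one stage for one compound/phase.
fixture_stage_dG <- function(ref, stage, compound, phase) {
  i <- ref$stage_dG$stage == stage & ref$stage_dG$compound == compound &
    ref$stage_dG$phase == phase
  if (!any(i)) {
    if (stage %in% c("N7", "N8", "N13", "N14") && phase == "heptane")
      stop("stage ", stage, " has no individual heptane value (proton free ",
           "energy unavailable in heptane); request the pair summary '",
           if (stage %in% c("N7", "N8")) "N7+8" else "N13+14", "'",
           call. = FALSE)
    stop("no reference value for stage ", stage, ", compound ", compound,
         ", phase ", phase, call. = FALSE)
  }
  ref$stage_dG$dG[i]
}
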