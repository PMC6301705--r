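#' Wigner tunneling correction factor
#'
#' `A(T) = 1 + (1/24) * (c * nu_i / T)^2`, the leading-order quantum
#' tunneling multiplier for a parabolic barrier whose imaginary frequency
#' is `nu_i` (cm^-1, positive magnitude). The coefficient `c` defaults to
#' the conventional printed 1.44 cm K.
#'
#' @param nu_i imaginary frequency magnitude, cm^-1 (>= 0).
#' @param T temperature, K.
#' @param constants a [thermo_constants()].
#' @return Dimensionless factor >= 1.
#' @export
#' @examples
#' wigner_factor(1702.2)  # ~3.82 at 298.15 K
wigner_factor <- function(nu_i, T = NULL, constants = thermo_constants()) {
  if (is.null(T)) T <- constants$T
  stopifnot(all(nu_i >= 0), T > 0)
  1 + (constants$wigner_coeff * nu_i / T)^2 / 24
}

#' Transition-state-theory rate constant with Wigner tunneling
#'
#' Conventional TST for a bimolecular H-atom transfer:
#' `k(T) = I * (kB*T/h) * exp(-dG/ (R*T)) * f * A(T)` with the barrier
#' `dG` in kcal/mol, the reaction-path degeneracy `I`, the 1 atm -> 1 M
#' standard-state factor `f` (24.3) and the Wigner factor `A(T)`. A
#' negative barrier is allowed but flagged as barrierless via a warning.
#'
#' @param dG_barrier activation free energy, kcal/mol.
#' @param nu_i imaginary frequency magnitude, cm^-1 (0 disables
#'   tunneling).
#' @param I reaction pathway degeneracy (positive integer).
#' @param T temperature, K; defaults to the constants' temperature.
#' @param constants a [thermo_constants()].
#' @return Rate constant in M^-1 s^-1.
#' @export
#' @examples
#' tst_rate(21.684, nu_i = 1702.2)  # ~7.3e-2 M^-1 s^-1
tst_rate <- function(dG_barrier, nu_i = 0, I = 1, T = NULL,
                     constants = thermo_constants()) {
  if (is.null(T)) T <- constants$T
  stopifnot(all(is.finite(dG_barrier)), T > 0, all(I >= 1))
  if (any(dG_barrier < 0))
    warning("negative barrier(s): treating as barrierless", call. = FALSE)
  I * (constants$kB * T / constants$h) *
    exp(-dG_barrier * 1000 / (constants$R_cal * T)) *
    constants$std_state_factor * wigner_factor(nu_i, T, constants)
}

#' Forward and reverse rates from a transition-state record
#'
#' A TS record carries the reactant-side and product-side barriers
#' (`dG_TS_R = G_TS - G_R`, `dG_TS_P = G_TS - G_P`) and the imaginary
#' frequency. The reaction free energy follows as
#' `dG_P_R = dG_TS_R - dG_TS_P`, whose sign decides the favored
#' direction; the Wigner and standard-state factors cancel in the ratio
#' so detailed balance `k_f/k_r = exp(-dG_P_R/(R*T))` holds exactly.
#'
#' @param ts a one-row data.frame or list with `dG_TS_R`, `dG_TS_P`,
#'   `nu_i`, optionally `I` and `T`.
#' @param constants a [thermo_constants()].
#' @return List of class `rate_result`: `k_forward`, `k_reverse`
#'   (M^-1 s^-1), `wigner_A`, `dG_P_R`, `K_eq_direction`.
#' @export
rate_pair <- function(ts, constants = thermo_constants()) {
  need <- c("dG_TS_R", "dG_TS_P", "nu_i")
  miss <- setdiff(need, names(ts))
  if (length(miss))
    stop("TS record lacks ", paste(miss, collapse = ", "), call. = FALSE)
  if (!all(is.finite(c(ts$dG_TS_R, ts$dG_TS_P))))
    stop("missing barrier in TS record", call. = FALSE)
  I <- if (!is.null(ts$I)) ts$I else 1
  T <- if (!is.null(ts$T)) ts$T else constants$T
  dG_P_R <- ts$dG_TS_R - ts$dG_TS_P
  structure(list(
    k_forward = tst_rate(ts$dG_TS_R, ts$nu_i, I, T, constants),
    k_reverse = tst_rate(ts$dG_TS_P, ts$nu_i, I, T, constants),
    wigner_A = wigner_factor(ts$nu_i, T, constants),
    dG_P_R = dG_P_R,
    K_eq_direction = if (dG_P_R < 0) "products_favored" else "reactants_favored"
  ), class = "rate_result")
}

#' @export
print.rate_result <- function(x, ...) {
  cat(sprintf("k_f = %.3g, k_r = %.3g M^-1 s^-1 (A = %.3f, dG_P-R = %.3f, %s)\n",
              x$k_forward, x$k_reverse, x$wigner_A, x$dG_P_R,
              x$K_eq_direction))
  invisible(x)
}

#' Rate table for a set of transition-state records
#'
#' Evaluates forward/reverse TST rates for every row of a TS table (such
#' as the packaged O2 H-abstraction records for the non-enzymatic dimers
#' D1', D2', D5').
#'
#' @param ts data.frame with `dG_TS_R`, `dG_TS_P`, `nu_i` columns and any
#'   identifier columns, e.g. `load_reference_data()$ts`.
#' @param constants a [thermo_constants()].
#' @return The input with `wigner_A`, `k_forward`, `k_reverse`, `dG_P_R`
#'   and `direction` columns appended.
#' @export
#' @examples
#' rt <- rate_table(load_reference_data()$ts)
#' subset(rt, form == "D1p" & compound == "2AP" & phase == "gas")
rate_table <- function(ts, constants = thermo_constants()) {
  out <- ts
  rp <- lapply(seq_len(nrow(ts)), function(i)
    rate_pair(ts[i, , drop = FALSE], constants))
  out$wigner_A <- vapply(rp, `[[`, 0, "wigner_A")
  out$k_forward <- vapply(rp, `[[`, 0, "k_forward")
  out$k_reverse <- vapply(rp, `[[`, 0, "k_reverse")
  out$dG_P_R <- vapply(rp, `[[`, 0, "dG_P_R")
  out$direction <- vapply(rp, `[[`, "", "K_eq_direction")
  out
}
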