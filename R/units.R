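# Physical constants in the MD unit system (nm, ps, kJ/mol, e, K).

#' Physical constants used throughout the package
#'
#' Boltzmann constant in kJ/mol/K and kcal/mol/K, the kJ/kcal ratio, the
#' Coulomb prefactor \eqn{1/(4\pi\epsilon_0)} in kJ mol\eqn{^{-1}} nm
#' e\eqn{^{-2}}, and the force conversion between the MD unit kJ/mol/nm
#' and piconewtons.
#'
#' @format A named list.
#' @export
rk_constants <- list(
  kB_kJ      = 0.008314462618,   # kJ/mol/K
  kB_kcal    = 0.008314462618 / 4.184,
  kJ_per_kcal = 4.184,
  coulomb_kJ = 138.935458,       # kJ mol^-1 nm e^-2
  pN_per_kJ_mol_nm = 1e24 / 6.02214076e23  # = 1.660539...
)

#' Convert a force from kJ/mol/nm to piconewtons
#'
#' MD engines report pulling forces in kJ/mol/nm; single-molecule work is
#' conventionally quoted in pN. One kJ/mol/nm equals
#' \eqn{10^3 / N_A} J per \eqn{10^{-9}} m = 1.660539 pN.
#'
#' @param x numeric, force in kJ/mol/nm.
#' @return Force in pN.
#' @examples
#' force_to_pN(600)  # ~996.3 pN
#' @export
force_to_pN <- function(x) x * rk_constants$pN_per_kJ_mol_nm

#' Convert an energy from kJ/mol to kcal/mol
#' @param x numeric, kJ/mol.
#' @return kcal/mol.
#' @export
kJ_to_kcal <- function(x) x / rk_constants$kJ_per_kcal

# Standard atomic weights (u), keyed by uppercase element symbol.
.atomic_masses <- c(
  H = 1.008, D = 2.014, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  NA. = 22.990, K = 39.098, MG = 24.305, CA = 40.078, ZN = 65.38,
  FE = 55.845, MN = 54.938, CU = 63.546, SE = 78.971, B = 10.81,
  SI = 28.085, LI = 6.94
)

#' Atomic mass lookup by element symbol
#'
#' @param element character vector of element symbols (case-insensitive).
#' @return numeric vector of atomic masses in u. Unknown elements error.
#' @export
atomic_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."  # sodium; "NA" is reserved in R names
  m <- .atomic_masses[key]
  if (anyNA(m)) {
    bad <- unique(element[is.na(m)])
    stop("no atomic mass for element(s): ", paste(bad, collapse = ", "))
  }
  unname(m)
}
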