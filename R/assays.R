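#' Alpha-amino group dissociation degree
#'
#' `alpha = 10^(pH - pK) / (1 + 10^(pH - pK))`, the fraction of alpha-amino
#' groups dissociated at the reaction pH. `pK` defaults to 9.0, the average
#' amino-group pK used for pH-stat hydrolysis monitoring.
#'
#' @param ph Reaction pH.
#' @param pk Average amino-group pK (default 9.0).
#' @return Fraction in (0, 1); strictly increasing in `ph`.
#' @export
alpha_dissociation <- function(ph, pk = 9.0) {
  stopifnot(is.finite(ph), is.finite(pk))
  r <- 10^(ph - pk)
  r / (1 + r)
}

#' Degree of hydrolysis by the pH-stat method
#'
#' `DH = (V_NaOH * N_NaOH) / (alpha * M_p * h_tot) * 100`, with the titrant
#' volume in mL and concentration in mol/L (so the numerator is mmol of
#' base), protein mass in g, and `h_tot` the total peptide bonds per gram of
#' protein in mmol/g (7.69 for wheat germ protein by default).
#'
#' @param v_naoh Titrant volume consumed (mL), >= 0.
#' @param n_naoh Titrant concentration (mol/L), >= 0.
#' @param m_protein Protein mass (g), > 0.
#' @param ph Reaction pH.
#' @param h_tot Peptide bonds per gram (mmol/g), > 0; default 7.69.
#' @param pk Average amino-group pK, default 9.0.
#' @return Degree of hydrolysis in percent.
#' @export
degree_of_hydrolysis <- function(v_naoh, n_naoh, m_protein, ph,
                                 h_tot = 7.69, pk = 9.0) {
  stopifnot(v_naoh >= 0, n_naoh >= 0)
  if (!(m_protein > 0) || !(h_tot > 0)) {
    stop("m_protein and h_tot must be positive", call. = FALSE)
  }
  a <- alpha_dissociation(ph, pk)
  if (!(a > 0)) stop("alpha dissociation degree is zero at pH ", ph,
                     " (denominator vanishes)", call. = FALSE)
  (v_naoh * n_naoh) / (a * m_protein * h_tot) * 100
}

#' Average peptide chain length from the degree of hydrolysis
#'
#' `PLC = 100 / DH` with DH in percent: complete hydrolysis (DH = 100)
#' leaves free amino acids (length 1).
#'
#' @param dh Degree of hydrolysis in percent, > 0.
#' @return Average chain length in residues.
#' @export
average_chain_length <- function(dh) {
  if (!(dh > 0)) stop("DH must be positive", call. = FALSE)
  100 / dh
}

#' ACE-inhibition from plate-reader absorbances
#'
#' With the FAPGG substrate, ACE activity shows as an absorbance decrease at
#' 340 nm. Given initial/final absorbances of the uninhibited blank
#' (`a1`, `a2`) and of the sample (`b1`, `b2`), the decreases are
#' `A = a1 - a2` and `B = b1 - b2` and the inhibition is
#' `I = (A - B) / A`. Negative inhibition (sample accelerates the reaction)
#' is reported as-is with a warning, not clamped.
#'
#' @param a1,a2 Blank initial and final absorbance (AU).
#' @param b1,b2 Sample initial and final absorbance (AU).
#' @return List with `fraction` (I) and `percent` (100 I). `I` depends only
#'   on the two decreases A and B.
#' @export
ace_inhibition <- function(a1, a2, b1, b2) {
  stopifnot(is.finite(a1), is.finite(a2), is.finite(b1), is.finite(b2))
  A <- a1 - a2
  B <- b1 - b2
  if (!(A > 0)) stop("invalid blank: absorbance decrease A = a1 - a2 must be ",
                     "positive (got ", A, ")", call. = FALSE)
  I <- (A - B) / A
  if (I < 0) warning("negative inhibition (sample accelerated the reaction)")
  list(fraction = I, percent = 100 * I)
}
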