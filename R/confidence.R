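#' Convert pLDDT confidence to a pseudo B factor
#'
#' Maps AlphaFold-style per-residue pLDDT scores (0-100) to isotropic
#' pseudo B factors via the empirical confidence-to-rmsd relation:
#' pseudo B = (8 pi^2 / 3) * (1.5 * exp(4 * (0.7 - 0.01 * pLDDT)))^2.
#' Strictly decreasing in pLDDT; pLDDT = 70 gives (8 pi^2 / 3) * 1.5^2
#' (about 59.2 A^2).
#'
#' @param plddt Numeric vector in [0, 100].
#' @return Pseudo B factors in A^2.
#' @export
plddt_to_pseudob <- function(plddt) {
  if (any(plddt < 0 | plddt > 100)) stop("pLDDT values must lie in [0, 100]")
  (8 * pi^2 / 3) * (1.5 * exp(4 * (0.7 - 0.01 * plddt)))^2
}

# derivative used by the analytic gradient chain of the refinement engine
plddt_to_pseudob_grad <- function(plddt) {
  plddt_to_pseudob(plddt) * 2 * 4 * (-0.01)
}

#' Alignment weight from a pseudo B factor
#'
#' Piecewise confidence weight used in the weighted Kabsch alignment and
#' the L2 restraint: 1 for pseudo B <= 11.5, a linear ramp from 1 to 0.5 on
#' (11.5, 40], and 0.5 exp(-sqrt(pseudo B - 40)) beyond 40 A^2; continuous
#' at both breakpoints.
#'
#' @param pseudo_b Pseudo B factors (A^2), > 0.
#' @return Weights in (0, 1].
#' @examples
#' kabsch_weight(c(5, 11.5, 40, 41))
#' @export
kabsch_weight <- function(pseudo_b) {
  if (any(pseudo_b <= 0)) stop("pseudo B must be positive")
  w <- numeric(length(pseudo_b))
  lo <- pseudo_b <= 11.5
  mid <- pseudo_b > 11.5 & pseudo_b <= 40
  hi <- pseudo_b > 40
  w[lo] <- 1
  w[mid] <- 1 - 0.5 * (pseudo_b[mid] - 11.5) / (40 - 11.5)
  w[hi] <- 0.5 * exp(-sqrt(pseudo_b[hi] - 40))
  w
}
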