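#' Equilibrium 1:1 complex concentration with ligand depletion
#'
#' Solves the exact mass-balance quadratic for a 1:1 binding equilibrium,
#' \deqn{[PL]^2 - (P_0 + L_0 + K_D)[PL] + P_0 L_0 = 0,}
#' returning the physically admissible root (the one with
#' \eqn{[PL] \le \min(P_0, L_0)}). This is the depletion-corrected bound
#' concentration that underlies fast-exchange CSP binding curves; no
#' ligand-excess (hyperbolic) approximation is ever made.
#'
#' The root is evaluated in the numerically stable product/sum form
#' \eqn{[PL] = 2 P_0 L_0 / (b + \sqrt{b^2 - 4 P_0 L_0})} with
#' \eqn{b = P_0 + L_0 + K_D}, which avoids catastrophic cancellation in the
#' stoichiometric limit \eqn{K_D \to 0}.
#'
#' @param receptor_total total receptor concentration \eqn{P_0}, mol/L.
#' @param ligand_total total ligand concentration \eqn{L_0}, mol/L
#'   (vectorised).
#' @param kd dissociation constant, mol/L.
#' @return complex concentration \eqn{[PL]} in mol/L, same length as
#'   `ligand_total`.
#' @seealso [solve_two_site()] for the two-equivalent-site analogue.
#' @examples
#' # weak peptide binding: 0.3 mM receptor, 17 mM peptide, Kd 17 mM
#' solve_1to1_complex(0.3e-3, 17e-3, 17e-3)
#' @export
solve_1to1_complex <- function(receptor_total, ligand_total, kd) {
  check_positive(receptor_total, "receptor_total", allow_zero = TRUE)
  check_positive(ligand_total, "ligand_total", allow_zero = TRUE)
  check_positive(kd, "kd")
  b <- receptor_total + ligand_total + kd
  pl <- 2 * receptor_total * ligand_total /
    (b + sqrt(b^2 - 4 * receptor_total * ligand_total))
  pmin(pl, pmin(receptor_total, ligand_total))
}

#' Two-equivalent-site (2:1) binding equilibrium
#'
#' Solves the mass balance for a receptor carrying two equivalent, independent
#' ligand sites (e.g. a nucleosome with its two H3 tails binding a reader
#' domain). Free ligand `x` satisfies
#' \deqn{x + 2 N_0 \frac{x}{K_D + x} = L_0,}
#' a quadratic solved in stable form. Site occupancy is
#' \eqn{\theta = x/(K_D + x)} and, because the sites are independent, the
#' species fractions carrying 0/1/2 ligands are binomial:
#' \eqn{((1-\theta)^2,\; 2\theta(1-\theta),\; \theta^2)}.
#'
#' @param receptor_total total receptor (two-site particle) concentration
#'   \eqn{N_0}, mol/L.
#' @param ligand_total total ligand concentration \eqn{L_0}, mol/L
#'   (vectorised).
#' @param kd_micro microscopic (per-site) dissociation constant, mol/L.
#' @return a data frame of class `"mixture_state"` with one row per
#'   `ligand_total`: columns `receptor_total`, `ligand_total`, `free_ligand`,
#'   `occupancy` (\eqn{\theta}), and species fractions `f0`, `f1`, `f2`.
#' @examples
#' solve_two_site(116e-6, 232e-6, 1.5e-6)  # near-stoichiometric titration
#' @export
solve_two_site <- function(receptor_total, ligand_total, kd_micro) {
  check_positive(receptor_total, "receptor_total", allow_zero = TRUE)
  check_positive(ligand_total, "ligand_total", allow_zero = TRUE)
  check_positive(kd_micro, "kd_micro")
  # x^2 + (kd + 2 N0 - L0) x - kd L0 = 0, positive root in stable form
  b <- kd_micro + 2 * receptor_total - ligand_total
  x <- 2 * kd_micro * ligand_total /
    (b + sqrt(b^2 + 4 * kd_micro * ligand_total))
  stopifnot(all(x >= 0), all(x <= ligand_total + 1e-12 * ligand_total))
  theta <- x / (kd_micro + x)
  out <- data.frame(
    receptor_total = receptor_total,
    ligand_total = ligand_total,
    free_ligand = x,
    occupancy = theta,
    f0 = (1 - theta)^2,
    f1 = 2 * theta * (1 - theta),
    f2 = theta^2
  )
  class(out) <- c("mixture_state", "data.frame")
  out
}

#' Avidity as an effective concentration
#'
#' For a bivalent interaction in which two weak epitope affinities combine
#' into one tight complex, the enhancement can be expressed as an effective
#' concentration \eqn{C_{eff} = (K_{D,tail} \times K_{D,DNA}) / K_{D,complex}}
#' — the apparent local concentration one epitope presents to its partner
#' when the other is already engaged.
#'
#' @param kd_tail dissociation constant of the first isolated epitope, mol/L.
#' @param kd_dna dissociation constant of the second isolated epitope, mol/L.
#' @param kd_nucleosome dissociation constant of the assembled bivalent
#'   complex, mol/L.
#' @return effective concentration, mol/L.
#' @examples
#' effective_concentration(1.7e-2, 1.5e-4, 1.5e-6)  # 1.7 M
#' @export
effective_concentration <- function(kd_tail, kd_dna, kd_nucleosome) {
  check_positive(kd_tail, "kd_tail")
  check_positive(kd_dna, "kd_dna")
  check_positive(kd_nucleosome, "kd_nucleosome")
  kd_tail * kd_dna / kd_nucleosome
}

#' Affinity enhancement between two binding modes
#'
#' @param kd_reference dissociation constant of the weaker reference
#'   interaction, mol/L.
#' @param kd_complex dissociation constant of the enhanced interaction, mol/L.
#' @return list with `ratio` (\eqn{K_{D,ref}/K_{D,complex}}) and
#'   `nearest_power_of_ten` (\eqn{10^{\mathrm{round}(\log_{10} ratio)}}).
#' @examples
#' fold_enhancement(17e-3, 1.5e-6)  # ~11333-fold, i.e. ~10^4
#' @export
fold_enhancement <- function(kd_reference, kd_complex) {
  check_positive(kd_reference, "kd_reference")
  check_positive(kd_complex, "kd_complex")
  ratio <- kd_reference / kd_complex
  list(ratio = ratio, nearest_power_of_ten = 10^round(log10(ratio)))
}

#' Mean lifetime of a complex from its dissociation rate
#'
#' @param koff first-order dissociation rate, 1/s.
#' @return lifetime \eqn{1/k_{off}} in seconds.
#' @examples
#' complex_lifetime(500)  # 2 ms
#' @export
complex_lifetime <- function(koff) {
  check_positive(koff, "koff")
  1 / koff
}
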