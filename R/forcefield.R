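# Force-field state: Lennard-Jones + Coulomb reference potentials and
# tabulated empirical pair potentials over the heavy atom types (C, OG, OW).

EP_PAIR_NAMES <- c("C-C", "C-OG", "C-OW", "OG-OG", "OG-OW", "OW-OW")

#' Reference force-field state for a simulation box
#'
#' Lennard-Jones parameters (Lorentz-Berthelot combining) and Coulomb
#' charges come from the box's molecular templates; Coulomb interactions
#' use shifted-force truncation at the cutoff. Empirical potentials — one
#' tabulated energy-vs-distance curve per heavy-atom type pair (C, OG, OW;
#' hydrogens excluded, as X-ray data carry little hydrogen information) —
#' start at zero and are bounded by `amplitude_cap`.
#'
#' @param box A `simulation_box`.
#' @param cutoff Interaction cutoff in A; defaults to min(9, L/2).
#' @param ep_dr Grid spacing of the empirical-potential tables in A.
#' @param amplitude_cap Bound on |empirical potential| in kJ/mol.
#' @return An object of class `forcefield`.
#' @export
reference_forcefield <- function(box, cutoff = NULL, ep_dr = 0.05,
                                 amplitude_cap = 12) {
  cutoff <- cutoff %||% min(9, box$box_length / 2)
  if (cutoff > box$box_length / 2 + 1e-9) {
    rlang::abort("cutoff may not exceed half the box length")
  }
  nr <- ceiling(cutoff / ep_dr) + 1L
  structure(
    list(
      types = box$types,
      cutoff = cutoff,
      ep = matrix(0, nr, 6, dimnames = list(NULL, EP_PAIR_NAMES)),
      ep_dr = ep_dr,
      amplitude_cap = amplitude_cap
    ),
    class = "forcefield"
  )
}

ff_check_types <- function(box, ff) {
  if (!identical(box$types$type, ff$types$type)) {
    rlang::abort("box and forcefield atom typing disagree")
  }
}

# intramolecular harmonic bond energy, U = sum k/2 (d - d0)^2
bond_energy <- function(box) {
  e <- 0
  for (m in seq_along(box$template_of_mol)) {
    tpl <- box$templates[[box$template_of_mol[m]]]
    if (!nrow(tpl$bonds)) next
    off <- box$mol_start[m]
    di <- box$coords[off + tpl$bonds$i, , drop = FALSE] -
      box$coords[off + tpl$bonds$j, , drop = FALSE]
    d <- sqrt(rowSums(di^2))
    e <- e + sum(0.5 * tpl$bonds$k * (d - tpl$bonds$length)^2)
  }
  e
}

#' Total potential energy of a box
#'
#' Intermolecular Lennard-Jones + shifted-force Coulomb + empirical terms
#' under the minimum-image convention, plus intramolecular harmonic bond
#' terms. Overlaps below the hard-core distance give an effectively infinite
#' (1e12 kJ/mol) energy rather than an error, so Monte Carlo rejection works.
#'
#' @param box A `simulation_box`.
#' @param ff A `forcefield` sharing the box's atom typing.
#' @return Energy in kJ/mol.
#' @export
total_energy <- function(box, ff) {
  ff_check_types(box, ff)
  inter <- cpp_total_inter_energy(
    box$coords, box$box_length, box_ljtype(box), box$atoms$charge,
    ff$types$epsilon, ff$types$sigma, box_heavy(box),
    box$mol_start, box$mol_len, ff$ep, ff$ep_dr, ff$cutoff
  )
  inter + bond_energy(box)
}

#' @export
print.forcefield <- function(x, ...) {
  cat(sprintf(
    "<forcefield> %d atom types, cutoff %.2f A, empirical potentials %s (cap %.1f kJ/mol)\n",
    nrow(x$types), x$cutoff,
    if (all(x$ep == 0)) "zero" else "active", x$amplitude_cap
  ))
  invisible(x)
}
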