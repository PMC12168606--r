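# Metropolis Monte Carlo of semi-rigid molecules: rigid translations and
# rotations plus dihedral rotations of the hydroxyl C-O-H groups.

#' Monte Carlo move set
#'
#' Maximum displacements per move type and the attempt weights. Move sizes
#' can be auto-tuned during equilibration toward 30-50% acceptance.
#'
#' @param translation Maximum translation in A.
#' @param rotation Maximum rigid rotation in radians.
#' @param dihedral Maximum C-O-H dihedral rotation in radians.
#' @param weights Attempt probabilities (translation, rotation, dihedral);
#'   must sum to 1.
#' @return A `move_set`.
#' @export
move_set <- function(translation = 0.25, rotation = 0.3, dihedral = 0.8,
                     weights = c(translation = 0.5, rotation = 0.3, dihedral = 0.2)) {
  if (any(c(translation, rotation, dihedral) < 0)) {
    rlang::abort("move maxima must be non-negative")
  }
  if (abs(sum(weights) - 1) > 1e-9) rlang::abort("move weights must sum to 1")
  structure(
    list(
      max = c(
        translation = translation, rotation = rotation,
        dihedral = dihedral
      ),
      weights = unname(weights)
    ),
    class = "move_set"
  )
}

run_engine <- function(box, ff, moves, temperature, n_sweeps, seed,
                       snapshot_every = 0, tune = FALSE) {
  ff_check_types(box, ff)
  cpp_mc_run(
    box$coords, box$box_length, box_ljtype(box), box$atoms$charge,
    ff$types$epsilon, ff$types$sigma, box_heavy(box),
    box$mol_start, box$mol_len, box_rot_groups(box),
    ff$ep, ff$ep_dr, ff$cutoff, temperature, as.integer(n_sweeps),
    unname(moves$max), moves$weights, as.numeric(seed),
    as.integer(snapshot_every), tune
  )
}

#' One (or more) Metropolis Monte Carlo sweeps
#'
#' Attempts on average one move per molecule per sweep with Metropolis
#' acceptance min(1, exp(-dE / kB T)). Molecular skeletons are propagated
#' rigidly, so intramolecular bond lengths are preserved exactly; hydroxyl
#' hydrogens additionally rotate about their C-O axes.
#'
#' @param box A `simulation_box`.
#' @param ff A `forcefield`.
#' @param moves A [move_set()].
#' @param temperature Temperature in K (> 0); defaults to the box value.
#' @param seed Integer seed for the engine's random stream.
#' @param n_sweeps Number of sweeps.
#' @return List with the updated `box`, named `acceptance` fractions per
#'   move type, and the per-sweep intermolecular `energy_trace` (kJ/mol).
#' @export
mc_sweep <- function(box, ff, moves = move_set(), temperature = box$temperature,
                     seed = 1, n_sweeps = 1) {
  if (temperature <= 0) rlang::abort("temperature must be positive")
  res <- run_engine(box, ff, moves, temperature, n_sweeps, seed)
  box$coords <- res$coords
  box$atoms$x <- res$coords[, 1]
  box$atoms$y <- res$coords[, 2]
  box$atoms$z <- res$coords[, 3]
  list(
    box = box,
    acceptance = stats::setNames(
      as.numeric(res$acceptance), c("translation", "rotation", "dihedral")
    ),
    attempts = as.numeric(res$attempts),
    energy_trace = as.numeric(res$energy_trace),
    energy_initial = res$energy_initial,
    energy_final = res$energy_final,
    delta_e_accumulated = res$delta_e_accumulated
  )
}

#' Equilibrate then sample an ensemble
#'
#' Runs `n_equil` sweeps with move-size auto-tuning (target 30-50%
#' acceptance), then `n_production` sweeps collecting a snapshot every
#' `snapshot_every` sweeps.
#'
#' @inheritParams mc_sweep
#' @param n_equil,n_production Sweep counts for the two phases.
#' @param snapshot_every Sampling interval in sweeps.
#' @return An `ensemble`: snapshot list, final box, acceptance fractions and
#'   energy trace.
#' @export
simulate_ensemble <- function(box, ff, n_equil = 200, n_production = 60,
                              snapshot_every = 2, moves = move_set(),
                              temperature = box$temperature, seed = 1) {
  eq <- run_engine(box, ff, moves, temperature, n_equil, seed, tune = TRUE)
  moves$max <- stats::setNames(as.numeric(eq$move_max), names(moves$max))
  box$coords <- eq$coords
  pr <- run_engine(
    box, ff, moves, temperature, n_production, seed + 1,
    snapshot_every = snapshot_every
  )
  box$coords <- pr$coords
  box$atoms$x <- pr$coords[, 1]
  box$atoms$y <- pr$coords[, 2]
  box$atoms$z <- pr$coords[, 3]
  new_ensemble(
    snapshots = pr$snapshots, box = box,
    snapshot_every = snapshot_every,
    acceptance = stats::setNames(
      as.numeric(pr$acceptance), c("translation", "rotation", "dihedral")
    ),
    energy_trace = c(as.numeric(eq$energy_trace), as.numeric(pr$energy_trace)),
    moves = moves
  )
}

new_ensemble <- function(snapshots, box, snapshot_every, acceptance = NULL,
                         energy_trace = NULL, moves = NULL, run_log = NULL) {
  if (!length(snapshots)) rlang::abort("an ensemble needs at least one snapshot")
  structure(
    list(
      snapshots = snapshots, box = box, snapshot_every = snapshot_every,
      acceptance = acceptance, energy_trace = energy_trace, moves = moves,
      run_log = run_log
    ),
    class = "ensemble"
  )
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf(
    "<ensemble> %d snapshots of %d molecules (X_W = %.1f mol%%, T = %.0f K)\n",
    length(x$snapshots), length(x$box$mol_len), x$box$x_w, x$box$temperature
  ))
  invisible(x)
}
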