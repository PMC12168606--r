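# Empirical-potential refinement: iteratively perturb the pair potentials so
# the model's X-ray S(Q) approaches a target pattern.

#' Update the empirical potentials from a structure-factor misfit
#'
#' The difference S_model(Q) - S_target(Q) is sine-transformed to real space
#' and added, scaled by `feedback * kB * T`, to every heavy-atom-pair
#' empirical potential (excess model correlation at r becomes a repulsive
#' perturbation there). The updated tables are clipped at the force field's
#' amplitude cap and tapered to zero at the cutoff. A zero misfit leaves the
#' force field exactly unchanged.
#'
#' @param model_sq,target_sq Tibbles (`q`, `s`) on the same Q grid.
#' @param ff A `forcefield`.
#' @param feedback Dimensionless feedback factor (> 0).
#' @param rho Total atomic number density of the model, atoms/A^3.
#' @param temperature Temperature in K used to scale the perturbation.
#' @return The updated `forcefield`.
#' @export
refine_empirical_potential <- function(model_sq, target_sq, ff, feedback = 0.5,
                                       rho, temperature = 298) {
  if (nrow(model_sq) != nrow(target_sq) ||
    max(abs(model_sq$q - target_sq$q)) > 1e-9) {
    rlang::abort("model and target structure factors must share a Q grid")
  }
  ds <- model_sq$s - target_sq$s
  if (all(ds == 0)) {
    return(ff)
  }
  kB <- 0.008314462618
  nr <- nrow(ff$ep)
  r <- (seq_len(nr) - 1) * ff$ep_dr
  dq <- diff(model_sq$q)
  dq <- c(dq, dq[length(dq)])
  w <- lorch_window(model_sq$q, max(model_sq$q))
  integrand <- model_sq$q * ds * w * dq
  dg <- rep(0, nr)
  pos <- r > 0
  dg[pos] <- as.numeric(sin(outer(r[pos], model_sq$q)) %*% integrand) /
    (2 * pi^2 * rho * r[pos])
  dg[1] <- dg[2]
  # taper smoothly to zero over the last Angstrom before the cutoff
  taper <- rep(1, nr)
  edge <- r > ff$cutoff - 1
  taper[edge] <- pmax(0, 0.5 * (1 + cos(pi * (r[edge] - (ff$cutoff - 1)))))
  du <- feedback * kB * temperature * dg * taper
  ep <- ff$ep + du
  ep[ep > ff$amplitude_cap] <- ff$amplitude_cap
  ep[ep < -ff$amplitude_cap] <- -ff$amplitude_cap
  ff$ep <- ep
  ff
}

sq_misfit <- function(model_sq, target_sq, q_range = c(0.4, 15)) {
  sel <- model_sq$q >= q_range[1] & model_sq$q <= q_range[2]
  mean((model_sq$s[sel] - target_sq$s[sel])^2)
}

#' Refinement run configuration
#'
#' Collects the composition, temperature, box size, sweep counts and
#' feedback settings of a refinement run. Defaults are desk-scale: a few
#' hundred molecules and short cycles, adequate for the short-ranged
#' observables the pipeline extracts.
#'
#' @param x_w Composition, mol% water.
#' @param temperature Temperature in K.
#' @param n_molecules Total molecules in the box.
#' @param seed Master seed; packing, Monte Carlo and refinement draw from
#'   streams derived from it.
#' @param n_equil Equilibration sweeps under the reference potential.
#' @param n_cycles Refinement cycles (sweep + potential update).
#' @param sweeps_per_cycle Sweeps between potential updates.
#' @param n_production,snapshot_every Production sweeps and snapshot
#'   interval.
#' @param snapshots_per_cycle Snapshots averaged into each cycle's model
#'   S(Q); more averaging stabilizes the per-cycle misfit estimate.
#' @param feedback Feedback factor of the empirical-potential update.
#' @param amplitude_cap Bound on the empirical potentials, kJ/mol.
#' @param q_grid Q grid for the model/target comparison.
#' @param tolerance Target misfit (mean squared S(Q) difference) used only
#'   for reporting convergence.
#' @param patience Cycles without misfit improvement before a warning.
#' @return A `refinement_config` list.
#' @export
refinement_config <- function(x_w, temperature = 298, n_molecules = 200,
                              seed = 1, n_equil = 150, n_cycles = 8,
                              sweeps_per_cycle = 25, n_production = 60,
                              snapshot_every = 2, snapshots_per_cycle = 10,
                              feedback = 0.4,
                              amplitude_cap = 12, q_grid = default_q_grid(),
                              tolerance = 5e-4, patience = 4) {
  structure(
    list(
      x_w = x_w, temperature = temperature, n_molecules = n_molecules,
      seed = seed, n_equil = n_equil, n_cycles = n_cycles,
      sweeps_per_cycle = sweeps_per_cycle, n_production = n_production,
      snapshot_every = snapshot_every,
      snapshots_per_cycle = snapshots_per_cycle, feedback = feedback,
      amplitude_cap = amplitude_cap, q_grid = q_grid,
      tolerance = tolerance, patience = patience
    ),
    class = "refinement_config"
  )
}

#' Read a refinement configuration from a YAML file
#'
#' @param path YAML file whose keys match the [refinement_config()]
#'   arguments.
#' @return A `refinement_config`.
#' @export
read_refinement_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(refinement_config, vals)
}

#' Refine a structural model against a target S(Q)
#'
#' Full pipeline: pack a box at the configured composition and density,
#' equilibrate under the reference potentials, then alternate Monte Carlo
#' sweeps with empirical-potential updates that drive the model S(Q) toward
#' the target, and finally collect production snapshots. The per-cycle
#' misfit and acceptance fractions are logged; a misfit that fails to
#' improve over the patience window triggers a warning, not a failure.
#'
#' @param target_sq Target structure factor, tibble (`q`, `s`).
#' @param config A [refinement_config()].
#' @return An `ensemble` whose `run_log` records cycle, misfit and
#'   acceptance, with the refined `forcefield` attached as attribute `ff`.
#' @export
run_refinement <- function(target_sq, config) {
  box <- pack_box(
    config$x_w, config$n_molecules, config$temperature,
    seed = config$seed
  )
  ff <- reference_forcefield(box, amplitude_cap = config$amplitude_cap)
  target <- tibble::tibble(q = config$q_grid, s = stats::approx(
    target_sq$q, target_sq$s,
    xout = config$q_grid, rule = 2
  )$y)

  moves <- move_set()
  eq <- run_engine(box, ff, moves, config$temperature, config$n_equil,
    seed = config$seed + 1, tune = TRUE
  )
  moves$max <- stats::setNames(as.numeric(eq$move_max), names(moves$max))
  box$coords <- eq$coords

  log_rows <- list()
  best <- Inf
  stall <- 0
  for (cycle in seq_len(config$n_cycles)) {
    res <- run_engine(box, ff, moves, config$temperature,
      config$sweeps_per_cycle,
      seed = config$seed + 10 + cycle,
      snapshot_every = max(1, floor(
        config$sweeps_per_cycle / (config$snapshots_per_cycle %||% 10)
      ))
    )
    box$coords <- res$coords
    cyc_ens <- new_ensemble(res$snapshots, box, snapshot_every = 1)
    model <- ensemble_sq(cyc_ens, q_grid = config$q_grid)
    misfit <- sq_misfit(model, target)
    log_rows[[cycle]] <- tibble::tibble(
      cycle = cycle, misfit = misfit,
      acc_translation = res$acceptance[1],
      acc_rotation = res$acceptance[2],
      acc_dihedral = res$acceptance[3]
    )
    if (misfit < best - 1e-12) {
      best <- misfit
      stall <- 0
    } else {
      stall <- stall + 1
      if (stall >= config$patience) {
        rlang::warn(sprintf(
          "misfit has not improved over %d cycles (current %.3g)",
          stall, misfit
        ))
        stall <- 0
      }
    }
    ff <- refine_empirical_potential(model, target, ff,
      feedback = config$feedback,
      rho = box$rho, temperature = config$temperature
    )
  }

  pr <- run_engine(box, ff, moves, config$temperature, config$n_production,
    seed = config$seed + 1000, snapshot_every = config$snapshot_every
  )
  box$coords <- pr$coords
  box$atoms$x <- pr$coords[, 1]
  box$atoms$y <- pr$coords[, 2]
  box$atoms$z <- pr$coords[, 3]
  ens <- new_ensemble(
    pr$snapshots, box,
    snapshot_every = config$snapshot_every,
    acceptance = stats::setNames(
      as.numeric(pr$acceptance),
      c("translation", "rotation", "dihedral")
    ),
    energy_trace = as.numeric(pr$energy_trace),
    moves = moves,
    run_log = dplyr::bind_rows(log_rows)
  )
  attr(ens, "ff") <- ff
  attr(ens, "final_misfit") <- best
  attr(ens, "converged") <- is.finite(best) && best <= config$tolerance
  ens
}
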