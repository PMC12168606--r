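# Synthetic data: reference ensembles and "measured" patterns at known
# composition, with optional noise and a chitin-like diffuse background, so
# the full pipeline runs without any external data.

#' Specification of a synthetic measurement
#'
#' Conditions of the emulated experiment: composition, temperature, box
#' size, relative noise, chitin-background amplitude, seed, and the Monte
#' Carlo effort used to realize the ensemble.
#'
#' @param x_w Composition, mol% water.
#' @param temperature Temperature in K (275 K is the reference measurement
#'   temperature of the supercooling experiments).
#' @param n_molecules Total molecules in the simulation box.
#' @param noise Relative Gaussian noise level on S(Q) (1% default, typical
#'   of counting statistics at a high-flux beamline).
#' @param chitin_amplitude Relative amplitude of the chitin-like background
#'   (0 = clean standard).
#' @param seed Integer seed; everything derived from the spec is
#'   reproducible under it.
#' @param n_equil,n_production,snapshot_every Monte Carlo effort.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(x_w, temperature = 275, n_molecules = 220,
                           noise = 0.01, chitin_amplitude = 0, seed = 1,
                           n_equil = 180, n_production = 40,
                           snapshot_every = 2) {
  if (noise < 0) rlang::abort("noise must be non-negative")
  if (chitin_amplitude < 0) rlang::abort("chitin amplitude must be non-negative")
  structure(
    list(
      x_w = x_w, temperature = temperature, n_molecules = n_molecules,
      noise = noise, chitin_amplitude = chitin_amplitude, seed = seed,
      n_equil = n_equil, n_production = n_production,
      snapshot_every = snapshot_every
    ),
    class = "synthetic_spec"
  )
}

#' Generate a glycerol-water standard: ensemble plus noisy S(Q)
#'
#' Packs and equilibrates a box at the spec conditions under the reference
#' potentials, computes the forward X-ray S(Q) from the sampled ensemble
#' and adds Gaussian noise at the stated relative level.
#'
#' @param spec A [synthetic_spec()].
#' @param q_grid Q grid of the pattern.
#' @return List with `ensemble` and `sq`; the pattern carries its ground
#'   truth (`x_w`, noise, seed) in the `truth` attribute.
#' @export
generate_standard <- function(spec, q_grid = default_q_grid()) {
  box <- pack_box(spec$x_w, spec$n_molecules, spec$temperature,
    seed = spec$seed
  )
  ff <- reference_forcefield(box)
  ens <- simulate_ensemble(box, ff,
    n_equil = spec$n_equil, n_production = spec$n_production,
    snapshot_every = spec$snapshot_every, seed = spec$seed + 1
  )
  sq <- ensemble_sq(ens, q_grid = q_grid)
  if (spec$noise > 0) {
    sq$s <- sq$s + with_local_seed(
      spec$seed + 2,
      stats::rnorm(nrow(sq), sd = spec$noise)
    )
  }
  attr(sq, "provenance") <- "measured-synthetic"
  attr(sq, "truth") <- list(
    x_w = box$x_w, temperature = spec$temperature, noise = spec$noise,
    chitin_amplitude = 0, seed = spec$seed
  )
  list(ensemble = ens, sq = sq)
}

#' Chitin-like diffuse background shape
#'
#' Two broad Gaussians at 1.3 and 1.9 1/A emulating the diffuse 110
#' reflections of poorly crystallized larval cuticle chitin.
#'
#' @param q Q grid, 1/A.
#' @param amplitude Overall scale.
#' @return Tibble (`q`, `s`) holding additive intensity.
#' @export
chitin_background <- function(q, amplitude = 1) {
  s <- amplitude * (0.8 * exp(-(q - 1.3)^2 / (2 * 0.15^2)) +
    exp(-(q - 1.9)^2 / (2 * 0.25^2)))
  out <- tibble::tibble(q = q, s = s)
  attr(out, "provenance") <- "background"
  out
}

#' Generate a synthetic larval pattern (liquid + chitin background)
#'
#' A standard pattern at the spec conditions with the chitin-like
#' background added at `chitin_amplitude`, emulating an in vivo
#' measurement through the exoskeleton.
#'
#' @inheritParams generate_standard
#' @return A structure-factor tibble whose `truth` attribute records the
#'   composition and injected background amplitude.
#' @export
generate_larva_pattern <- function(spec, q_grid = default_q_grid()) {
  std <- generate_standard(spec, q_grid = q_grid)
  sq <- std$sq
  if (spec$chitin_amplitude > 0) {
    sq$s <- sq$s + chitin_background(q_grid, spec$chitin_amplitude)$s
  }
  attr(sq, "provenance") <- "measured-synthetic"
  attr(sq, "truth") <- list(
    x_w = std$ensemble$box$x_w, temperature = spec$temperature,
    noise = spec$noise, chitin_amplitude = spec$chitin_amplitude,
    seed = spec$seed
  )
  sq
}

#' Ensembles of one composition across a cooling series
#'
#' One equilibrated ensemble per temperature, each at the density the
#' mixture model assigns to that temperature (denser on cooling), with
#' sequential seeding.
#'
#' @param x_w Composition, mol% water.
#' @param temperatures Temperatures in K, descending (a cooling ramp).
#' @param seed Master seed.
#' @param n_molecules,n_equil,n_production,snapshot_every Monte Carlo
#'   effort per temperature.
#' @return List of `ensemble`s, one per temperature.
#' @export
generate_temperature_series <- function(x_w, temperatures, seed = 1,
                                        n_molecules = 220, n_equil = 180,
                                        n_production = 40,
                                        snapshot_every = 2) {
  if (is.unsorted(rev(temperatures), strictly = FALSE)) {
    rlang::abort("temperatures must be given in descending order (cooling)")
  }
  lapply(seq_along(temperatures), function(i) {
    spec <- synthetic_spec(
      x_w = x_w, temperature = temperatures[i],
      n_molecules = n_molecules, noise = 0, seed = seed + (i - 1) * 101,
      n_equil = n_equil, n_production = n_production,
      snapshot_every = snapshot_every
    )
    generate_standard(spec)$ensemble
  })
}

#' Calibration standards at the experimental mole ratios
#'
#' The six standard solutions used for the calibration curve: 0, 20, 40,
#' 60, 80 and 100 mol% water.
#'
#' @param x_w Compositions to generate.
#' @param seed Master seed (each standard uses a derived seed).
#' @param ... Passed to [synthetic_spec()].
#' @return Tibble with columns `x_w` and `sq` (list-column), ready for
#'   [build_calibration_curve()].
#' @export
calibration_standards <- function(x_w = c(0, 20, 40, 60, 80, 100), seed = 1,
                                  ...) {
  sqs <- lapply(seq_along(x_w), function(i) {
    spec <- synthetic_spec(x_w = x_w[i], seed = seed + i * 17, ...)
    generate_standard(spec)$sq
  })
  tibble::tibble(x_w = x_w, sq = sqs)
}
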