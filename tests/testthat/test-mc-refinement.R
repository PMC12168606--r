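two_particle_box <- function(r, L = 24, epsilon = 1.0, sigma = 3.4) {
  tpl <- cryostruct:::lj_sphere_template(epsilon = epsilon, sigma = sigma)
  coords <- rbind(c(0, 0, 0), c(r, 0, 0))
  assemble_box(list(tpl), c(1L, 1L), coords, L, temperature = 150)
}

test_that("Lennard-Jones energy has its zero at sigma and minimum at 2^(1/6) sigma", {
  sig <- 3.4
  b0 <- two_particle_box(sig)
  ff <- reference_forcefield(b0, cutoff = 11)
  # remove the truncation shift for the textbook values
  shift <- 4 * 1.0 * ((sig / 11)^12 - (sig / 11)^6)
  expect_equal(total_energy(b0, ff) + shift, 0, tolerance = 1e-10)
  bmin <- two_particle_box(2^(1 / 6) * sig)
  expect_equal(total_energy(bmin, ff) + shift, -1.0, tolerance = 1e-3)
})

test_that("zero empirical potentials leave the reference energy untouched", {
  box <- fixture_mixture_ensemble()$box
  ff <- reference_forcefield(box)
  e_ref <- total_energy(box, ff)
  expect_true(all(ff$ep == 0))
  ff2 <- ff
  ff2$ep[, "OW-OW"] <- 0.5 # a non-zero table must change the energy
  expect_false(isTRUE(all.equal(total_energy(box, ff2), e_ref)))
})

test_that("total energy is invariant under a rigid shift of all coordinates", {
  box <- fixture_mixture_ensemble()$box
  ff <- reference_forcefield(box)
  e1 <- total_energy(box, ff)
  box2 <- box
  box2$coords <- sweep(box$coords, 2, c(3.17, -8.2, 14.9), `+`)
  e2 <- total_energy(box2, ff)
  expect_equal(e1, e2, tolerance = 1e-9)
})

test_that("overlapping atoms give an effectively infinite energy, not a crash", {
  b <- two_particle_box(0.2)
  ff <- reference_forcefield(b, cutoff = 11)
  expect_gte(total_energy(b, ff), 1e12)
})

test_that("a frozen move set leaves the box unchanged with acceptance 1", {
  box <- fixture_mixture_ensemble()$box
  ff <- reference_forcefield(box)
  res <- mc_sweep(box, ff,
    moves = move_set(0, 0, 0),
    n_sweeps = 3, seed = 5
  )
  expect_equal(res$box$coords, box$coords)
  expect_equal(unname(res$acceptance), rep(1, 3))
})

test_that("acceptance approaches 1 in the high-temperature limit", {
  box <- fixture_mixture_ensemble()$box
  ff <- reference_forcefield(box)
  res <- mc_sweep(box, ff,
    moves = move_set(0.05, 0.05, 0.05),
    temperature = 1e7, n_sweeps = 5, seed = 6
  )
  expect_gt(res$acceptance[["translation"]], 0.97)
})

test_that("incremental energy bookkeeping matches a full recomputation", {
  box <- fixture_mixture_ensemble()$box
  ff <- reference_forcefield(box)
  res <- mc_sweep(box, ff, n_sweeps = 25, seed = 7)
  expect_equal(
    res$energy_initial + res$delta_e_accumulated, res$energy_final,
    tolerance = 1e-9
  )
  full <- cryostruct:::cpp_total_inter_energy(
    res$box$coords, box$box_length, cryostruct:::box_ljtype(box),
    box$atoms$charge, ff$types$epsilon, ff$types$sigma,
    cryostruct:::box_heavy(box), box$mol_start, box$mol_len,
    ff$ep, ff$ep_dr, ff$cutoff
  )
  expect_equal(res$energy_final, full, tolerance = 1e-6 * abs(full))
})

test_that("Monte Carlo runs are deterministic under a fixed seed", {
  box <- fixture_mixture_ensemble()$box
  ff <- reference_forcefield(box)
  r1 <- mc_sweep(box, ff, n_sweeps = 5, seed = 11)
  r2 <- mc_sweep(box, ff, n_sweeps = 5, seed = 11)
  expect_identical(r1$box$coords, r2$box$coords)
})

test_that("Monte Carlo preserves intramolecular bond lengths exactly", {
  box <- fixture_mixture_ensemble()$box
  ff <- reference_forcefield(box)
  res <- mc_sweep(box, ff, n_sweeps = 10, seed = 12)
  b2 <- res$box
  for (m in seq_along(b2$template_of_mol)) {
    tpl <- b2$templates[[b2$template_of_mol[m]]]
    off <- b2$mol_start[m]
    d <- sqrt(rowSums((b2$coords[off + tpl$bonds$i, , drop = FALSE] -
      b2$coords[off + tpl$bonds$j, , drop = FALSE])^2))
    expect_equal(d, tpl$bonds$length, tolerance = 1e-9)
  }
})

test_that("two-particle sampling reproduces the Boltzmann distance distribution", {
  # independent oracle: direct numeric quadrature of r^2 exp(-U(r)/kT)
  sig <- 3.4
  eps <- 1.0
  L <- 24
  rc <- 11
  temp <- 150
  kT <- 0.008314462618 * temp
  u <- function(r) {
    out <- ifelse(r < rc, 4 * eps * ((sig / r)^12 - (sig / r)^6) -
      4 * eps * ((sig / rc)^12 - (sig / rc)^6), 0)
    out
  }
  box <- two_particle_box(3.8, L = L)
  ff <- reference_forcefield(box, cutoff = rc)
  moves <- move_set(1.6, 0, 0, weights = c(1, 0, 0))
  # long run, distances recorded every few sweeps
  res <- cryostruct:::run_engine(box, ff, moves, temp, 60000,
    seed = 1234,
    snapshot_every = 3
  )
  d <- vapply(res$snapshots, function(sn) {
    dd <- sn[1, ] - sn[2, ]
    dd <- dd - L * round(dd / L)
    sqrt(sum(dd^2))
  }, numeric(1))
  breaks <- seq(3.0, 9.0, by = 0.5)
  d <- d[d >= min(breaks) & d <= max(breaks)]
  obs <- table(cut(d, breaks))
  probs <- vapply(seq_len(length(breaks) - 1), function(i) {
    stats::integrate(function(r) r^2 * exp(-u(r) / kT), breaks[i], breaks[i + 1])$value
  }, numeric(1))
  norm_all <- stats::integrate(function(r) r^2 * exp(-u(r) / kT),
    min(breaks), max(breaks)
  )$value
  p <- chisq.test(as.vector(obs), p = probs / norm_all)$p.value
  expect_gt(p, 0.01)
})
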