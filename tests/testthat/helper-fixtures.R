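# Shared fixtures, built once per test run and memoised. All fixtures are
# generated in code; sizes are kept small so the whole suite stays fast.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small near-pure-water ensemble with decent local structure
fixture_water_ensemble <- function() {
  fixture("water_ens", function() {
    box <- pack_box(99, 150, 275, seed = 101)
    ff <- reference_forcefield(box)
    simulate_ensemble(box, ff,
      n_equil = 500, n_production = 60,
      snapshot_every = 3, seed = 102
    )
  })
}

# small glycerol-water mixture ensemble (15 mol% water)
fixture_mixture_ensemble <- function() {
  fixture("mix_ens", function() {
    box <- pack_box(15, 80, 275, seed = 103)
    ff <- reference_forcefield(box)
    simulate_ensemble(box, ff,
      n_equil = 300, n_production = 40,
      snapshot_every = 2, seed = 104
    )
  })
}

# quick calibration standards (small boxes, short runs, no noise)
fixture_standards <- function() {
  fixture("standards", function() {
    calibration_standards(
      x_w = c(0, 20, 40, 60, 80, 100), seed = 301,
      n_molecules = 100, noise = 0, n_equil = 300, n_production = 30,
      snapshot_every = 2
    )
  })
}

# a box of ideal-gas points (single-atom molecules, no interactions)
ideal_gas_box <- function(n = 400, L = 20, seed = 7) {
  tpl <- cryostruct:::lj_sphere_template(epsilon = 0, sigma = 0, label = "ID")
  coords <- cryostruct:::with_local_seed(
    seed,
    matrix(stats::runif(3 * n, 0, L), ncol = 3)
  )
  assemble_box(list(tpl), rep(1L, n), coords, L, temperature = 300)
}

# simple-cubic lattice of single-site atoms
sc_lattice_box <- function(ncell = 5, a = 3) {
  tpl <- cryostruct:::lj_sphere_template(epsilon = 0, sigma = 0, label = "LAT")
  g <- as.matrix(expand.grid(0:(ncell - 1), 0:(ncell - 1), 0:(ncell - 1))) * a
  assemble_box(list(tpl), rep(1L, nrow(g)), g, ncell * a, temperature = 300)
}

# hand-placed water molecules at given oxygen positions (H's attached)
waters_at <- function(oxygens, L, temperature = 275) {
  wt <- water_template()
  base <- as.matrix(wt$atoms[, c("x", "y", "z")])
  coords <- do.call(rbind, lapply(seq_len(nrow(oxygens)), function(i) {
    sweep(base, 2, oxygens[i, ], `+`)
  }))
  assemble_box(list(water_template()), rep(1L, nrow(oxygens)), coords, L,
    temperature = temperature
  )
}

# brute-force reference clustering (BFS over the periodic adjacency matrix)
bfs_cluster_sizes <- function(pts, L, cutoff) {
  n <- nrow(pts)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- pts[i, ] - pts[j, ]
      d <- d - L * round(d / L)
      adj[i, j] <- sqrt(sum(d^2)) <= cutoff
    }
  }
  seen <- rep(FALSE, n)
  sizes <- integer()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    comp <- 0L
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      comp <- comp + 1L
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    sizes <- c(sizes, comp)
  }
  sort(sizes)
}
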