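test_that("a hand-placed water chain forms one cluster matching brute force", {
  ox <- cbind(seq(0, 12, by = 3.0), rep(10, 5), rep(10, 5))
  box <- waters_at(ox, L = 40)
  cd <- water_clusters(box, cutoff = 3.5)
  expect_equal(cd$max_size, 5L)
  expect_equal(nrow(cd$histogram), 1)
  expect_equal(
    sort(rep(cd$histogram$size, cd$histogram$count)),
    bfs_cluster_sizes(ox, 40, 3.5)
  )
})

test_that("waters further apart than the cutoff stay isolated", {
  ox <- as.matrix(expand.grid(c(5, 15), c(5, 15), c(5, 15)))
  box <- waters_at(ox, L = 30)
  cd <- water_clusters(box, cutoff = 3.5)
  expect_equal(cd$max_size, 1L)
  expect_equal(cd$histogram$count, 8L)
})

test_that("clustering honours periodic boundaries", {
  ox <- rbind(c(0.5, 10, 10), c(27.5, 10, 10)) # 3.0 A across the boundary
  box <- waters_at(ox, L = 30)
  cd <- water_clusters(box, cutoff = 3.5)
  expect_equal(cd$max_size, 2L)
})

test_that("cluster analysis equals brute-force BFS on random boxes", {
  for (seed in 1:4) {
    ox <- cryostruct:::with_local_seed(
      seed,
      matrix(stats::runif(3 * 80, 0, 18), ncol = 3)
    )
    box <- waters_at(ox, L = 18)
    cd <- water_clusters(box, cutoff = 3.5)
    expect_equal(
      sort(rep(cd$histogram$size, cd$histogram$count)),
      bfs_cluster_sizes(ox, 18, 3.5)
    )
    # mass conservation
    expect_equal(sum(cd$histogram$size * cd$histogram$count), 80)
  }
})

test_that("coordination of zero-g functions is zero", {
  pf <- tibble::tibble(r = seq(0.025, 5, by = 0.05), g = 0)
  expect_equal(coordination_number(pf, 3.2, rho_partner = 0.1)$n, 0)
})

test_that("hydrogen-bond counting agrees with the g(r) integral form", {
  ens <- fixture_mixture_ensemble()
  hb <- hbonds_per_glycerol(ens, cutoff = 3.2)
  gg <- partial_gr(ens, "OG-OG", dr = 0.02)
  gw <- partial_gr(ens, "OG-OW", dr = 0.02)
  n_gg <- coordination_number(gg, 3.2)$n
  # rho_partner recorded by partial_gr is the OW density for the OG-OW pair
  n_gw <- coordination_number(gw, 3.2)$n
  integral_form <- 3 * (n_gg + n_gw)
  expect_lt(abs(hb$mean - integral_form), 0.05)
})

test_that("an isolated glycerol molecule has no hydrogen bonds", {
  tpl <- glycerol_template()
  box <- assemble_box(
    list(tpl), 1L, as.matrix(tpl$atoms[, c("x", "y", "z")]) + 10, 40
  )
  ens <- cryostruct:::new_ensemble(list(box$coords), box, 1)
  hb <- hbonds_per_glycerol(ens)
  expect_equal(hb$mean, 0)
})

test_that("crystallization composition interpolates the threshold crossing", {
  data <- tibble::tibble(
    x_w = c(40, 45, 50, 55, 60, 65),
    max_cluster = c(20, 40, 100, 220, 340, 800)
  )
  xc <- crystallization_composition(data, threshold = 275)
  expect_equal(xc, 55 + 5 * (275 - 220) / (340 - 220), tolerance = 1e-9)
  # threshold 1 crosses at the lowest composition with any water
  expect_lt(crystallization_composition(data, threshold = 1), 40.1)
  # no bracketing is an error, not an extrapolation
  expect_error(
    crystallization_composition(data[1:2, ], threshold = 275),
    "not bracketed"
  )
})

test_that("coordination crossover interpolates n(OG-OG) = n(OG-OW)", {
  data <- tibble::tibble(
    x_w = c(20, 40, 60, 80),
    n_gg = c(1.6, 1.2, 0.7, 0.3),
    n_gw = c(0.3, 0.8, 1.3, 1.7)
  )
  xc <- coordination_crossover(data)
  # linear segments cross between 40 and 60
  d40 <- 0.8 - 1.2
  d60 <- 1.3 - 0.7
  expect_equal(xc, 40 + 20 * (0 - d40) / (d60 - d40), tolerance = 1e-9)
  expect_error(
    coordination_crossover(data[data$x_w <= 40, ]),
    "not bracketed"
  )
})

test_that("mean maximum cluster size increases with water content", {
  stats_by_comp <- vapply(seq(10, 100, by = 10), function(xw) {
    box <- pack_box(xw, 120, 275, seed = 700 + xw)
    ff <- reference_forcefield(box)
    ens <- simulate_ensemble(box, ff,
      n_equil = 150, n_production = 20,
      snapshot_every = 2, seed = 800 + xw
    )
    mean(max_cluster_sizes(ens)$max_size)
  }, numeric(1))
  rho <- stats::cor(seq(10, 100, by = 10), stats_by_comp, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("spatial density of an isotropic gas is flat and mass-consistent", {
  # random neighbor waters around a grid of central waters
  set.seed(42)
  n <- 250
  ox <- matrix(stats::runif(3 * n, 0, 24), ncol = 3)
  box <- waters_at(ox, L = 24)
  ens <- cryostruct:::new_ensemble(list(box$coords), box, 1)
  sdm <- spatial_density(ens, "water", "OW", shell = c(2.0, 6.0), grid = 1.0)
  # integral over the map equals the mean neighbor count in the shell
  expect_equal(sum(sdm$density) * sdm$grid^3, sdm$integral, tolerance = 1e-9)
  expected <- (n - 1) / 24^3 * 4 / 3 * pi * (6^3 - 2^3)
  expect_equal(sdm$integral, expected, tolerance = 0.25)
})

test_that("the spatial map integral matches the coordination number", {
  ens <- fixture_water_ensemble()
  pf <- partial_gr(ens, "OW-OW", dr = 0.02)
  sdm <- spatial_density(ens, "water", "OW", shell = c(0.1, 3.4), grid = 0.4)
  n_int <- coordination_number(pf, 3.4)$n
  expect_equal(sdm$integral, n_int, tolerance = 0.05)
})

test_that("water neighbors concentrate at tetrahedral directions", {
  ens <- fixture_water_ensemble()
  sdm <- spatial_density(ens, "water", "OW", shell = c(2.4, 3.2), grid = 0.4)
  ax <- sdm$axes
  grid3 <- expand.grid(x = ax, y = ax, z = ax)
  r <- sqrt(grid3$x^2 + grid3$y^2 + grid3$z^2)
  dens <- as.vector(aperm(sdm$density, c(1, 2, 3)))
  shell_sel <- r > 2.4 & r < 3.2
  shell_mean <- mean(dens[shell_sel])
  # donor lobes lie along the O-H directions (in the xz-plane, z > 0)
  half <- (109.47 / 2) * pi / 180
  lobes <- rbind(
    c(sin(half), 0, cos(half)), c(-sin(half), 0, cos(half)),
    c(0, sin(half), -cos(half)), c(0, -sin(half), -cos(half))
  )
  for (k in 1:4) {
    u <- cbind(grid3$x, grid3$y, grid3$z) / pmax(r, 1e-9)
    cone <- shell_sel & (u %*% lobes[k, ] > cos(30 * pi / 180))
    expect_gt(mean(dens[cone]), 1.3 * shell_mean)
  }
})
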