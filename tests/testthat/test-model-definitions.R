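test_that("glycerol template has the right topology and geometry", {
  tpl <- glycerol_template()
  expect_equal(nrow(tpl$atoms), 14)
  expect_equal(sum(tpl$atoms$element == "C"), 3)
  expect_equal(sum(tpl$atoms$element == "O"), 3)
  expect_equal(sum(tpl$atoms$element == "H"), 8)
  expect_length(tpl$rotatable_groups, 3)
  expect_equal(sum(tpl$atoms$charge), 0, tolerance = 1e-12)
  # C1-C2 bond close to the standard sp3 C-C length
  d12 <- sqrt(sum((unlist(tpl$atoms[1, c("x", "y", "z")]) -
    unlist(tpl$atoms[2, c("x", "y", "z")]))^2))
  expect_equal(d12, 1.526, tolerance = 0.01)
  # every rotated set hangs off its axis only
  for (g in tpl$rotatable_groups) {
    expect_true(all(g$moved > 11)) # hydroxyl hydrogens
    expect_length(g$axis, 2)
  }
})

test_that("water template is rigid, neutral, with an LJ site on oxygen only", {
  tpl <- water_template()
  expect_equal(nrow(tpl$atoms), 3)
  expect_length(tpl$rotatable_groups, 0)
  expect_equal(sum(tpl$atoms$charge), 0, tolerance = 1e-12)
  oh <- sqrt(sum((unlist(tpl$atoms[1, c("x", "y", "z")]) -
    unlist(tpl$atoms[2, c("x", "y", "z")]))^2))
  expect_equal(oh, 1.0, tolerance = 0.01)
  expect_gt(tpl$atoms$epsilon[1], 0)
  expect_equal(tpl$atoms$epsilon[2:3], c(0, 0))
})

test_that("template validation rejects broken molecules", {
  tpl <- glycerol_template()
  bad <- tpl$atoms
  bad$charge[1] <- bad$charge[1] + 0.1
  expect_error(
    cryostruct:::new_molecule_template("bad", bad, tpl$bonds, tpl$rotatable_groups),
    "neutral"
  )
  # disconnected bond graph
  bonds2 <- tpl$bonds[-(1:2), ]
  expect_error(
    cryostruct:::new_molecule_template("bad2", tpl$atoms, bonds2, list()),
    "connected"
  )
})

test_that("density model reproduces pure-component endpoints and non-ideality", {
  m <- density_model()
  # water: 0.997 g/cm^3 -> about 0.100 atoms/A^3; glycerol 1.26 -> 0.115
  expect_equal(density_lookup(100, 298, m), 0.0999, tolerance = 0.01)
  expect_equal(density_lookup(0, 298, m), 0.1153, tolerance = 0.01)
  # intermediate compositions denser than ideal molar-volume mixing
  ideal <- function(x) {
    v <- x / 100 * m$v_water + (1 - x / 100) * m$v_glycerol
    (3 * x / 100 + 14 * (1 - x / 100)) / (v * 1e24 / 6.02214076e23)
  }
  for (x in c(25, 50, 75)) {
    expect_gt(density_lookup(x, 298, m), ideal(x))
  }
  expect_error(density_lookup(120, 298, m), "0, 100")
  # cooling makes the mixture denser
  expect_gt(density_lookup(15, 250, m), density_lookup(15, 298, m))
})

test_that("pack_box splits molecule counts to the nearest integer", {
  box <- pack_box(15, 300, 275, seed = 1)
  expect_equal(box$n_water, 45)
  expect_equal(box$n_glycerol, 255)
  box0 <- pack_box(0, 10, 275, seed = 1)
  expect_equal(box0$n_water, 0)
})

test_that("packed boxes satisfy density, neutrality and separation", {
  box <- pack_box(100, 64, 298, seed = 2)
  # box length consistent with the density model
  expect_equal(box$box_length, (64 * 3 / density_lookup(100, 298))^(1 / 3),
    tolerance = 1e-10
  )
  # rho * V equals the atom count
  expect_equal(box$rho * box$box_length^3, nrow(box$coords), tolerance = 1e-6)
  expect_equal(sum(box$atoms$charge), 0, tolerance = 1e-9)
  mind <- cryostruct:::cpp_min_inter_dist(
    box$coords, box$box_length, cryostruct:::box_mol_id0(box)
  )
  expect_gte(mind, 1.5 - 1e-9)
})

test_that("an unsatisfiable separation demand fails cleanly after bounded retries", {
  expect_error(
    pack_box(50, 40, 298, seed = 5, dmin = 3.5, max_relax_sweeps = 40),
    "packing failed"
  )
})

test_that("packing is reproducible under a fixed seed and varies across seeds", {
  b1 <- pack_box(50, 30, 298, seed = 9)
  b2 <- pack_box(50, 30, 298, seed = 9)
  b3 <- pack_box(50, 30, 298, seed = 10)
  expect_identical(b1$coords, b2$coords)
  expect_false(isTRUE(all.equal(b1$coords, b3$coords)))
  expect_equal(b1$box_length, b3$box_length)
  expect_equal(b1$n_water, b3$n_water)
})

test_that("packed molecules keep their template bond lengths within 5%", {
  box <- pack_box(20, 40, 298, seed = 3)
  for (m in seq_along(box$template_of_mol)) {
    tpl <- box$templates[[box$template_of_mol[m]]]
    off <- box$mol_start[m]
    d <- sqrt(rowSums((box$coords[off + tpl$bonds$i, , drop = FALSE] -
      box$coords[off + tpl$bonds$j, , drop = FALSE])^2))
    expect_true(all(abs(d - tpl$bonds$length) / tpl$bonds$length < 0.05))
  }
})
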