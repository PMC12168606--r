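test_that("momentum transfer follows Q = 4 pi sin(theta)/lambda", {
  expect_equal(q_from_angle(0, 0.124), 0)
  expect_equal(q_from_angle(pi, 0.124), 4 * pi / 0.124, tolerance = 1e-12)
  expect_equal(q_from_angle(pi, 0.124), 101.34, tolerance = 1e-3)
  expect_error(q_from_angle(0.5, -1), "positive")
})

test_that("form factors reproduce atomic numbers at Q = 0", {
  expect_equal(form_factor("H", 0), 1, tolerance = 1e-3)
  expect_equal(form_factor("C", 0), 6, tolerance = 1e-3)
  expect_equal(form_factor("O", 0), 8, tolerance = 1e-3)
  expect_error(form_factor("Zr", 0), "no form factor")
})

test_that("g(r) of an ideal gas is 1 within statistical error", {
  box <- ideal_gas_box(n = 500, L = 20, seed = 8)
  pf <- partial_gr(box, "ID-ID", dr = 0.25, r_max = 9)
  sel <- pf$r > 2 # skip the smallest shells (few counts)
  counts_scale <- 500 * 499 / 2 / (20^3)
  se <- 1 / sqrt(counts_scale * 4 * pi * pf$r[sel]^2 * 0.25)
  expect_true(all(abs(pf$g[sel] - 1) < 4 * se))
  expect_lt(abs(mean(pf$g[sel]) - 1), 0.015)
})

test_that("two fixed atoms give a single-bin spike at their separation", {
  tpl <- cryostruct:::lj_sphere_template(epsilon = 0, sigma = 0, label = "P")
  box <- assemble_box(
    list(tpl), c(1L, 1L),
    rbind(c(1, 1, 1), c(1, 1, 5.21)), 30
  )
  pf <- partial_gr(box, "P-P", dr = 0.1, r_max = 10)
  expect_equal(sum(pf$g > 0), 1)
  expect_equal(pf$r[pf$g > 0], 4.25, tolerance = 0.051)
})

test_that("simple-cubic shell counts are recovered exactly by integration", {
  box <- sc_lattice_box(ncell = 5, a = 3)
  pf <- partial_gr(box, "LAT-LAT", dr = 0.05, r_max = 7)
  n <- coordination_number(pf, 3.6, rho_partner = 125 / box$box_length^3)
  expect_equal(n$n, 6, tolerance = 1e-9) # first shell of the SC lattice
  n2 <- coordination_number(pf, 4.8, rho_partner = 125 / box$box_length^3)
  expect_equal(n2$n, 18, tolerance = 1e-9) # plus 12 second-shell neighbors
})

test_that("structureless systems give S(Q) = 1", {
  r <- seq(0.01, 10, by = 0.02)
  flat <- tibble::tibble(r = r, g = rep(1, length(r)))
  partials <- list("O-O" = flat)
  sq <- xray_weighted_sq(partials, c(O = 1), rho = 0.1)
  expect_true(all(abs(sq$s - 1) < 1e-10))
})

test_that("single-component weights collapse to 1 regardless of form factor", {
  r <- seq(0.01, 12, by = 0.02)
  g <- 1 + 0.4 * exp(-(r - 3)^2 / 0.5)
  rho <- 0.05
  for (el in c("C", "O")) {
    partials <- stats::setNames(list(tibble::tibble(r = r, g = g)), paste(el, el, sep = "-"))
    sq <- xray_weighted_sq(partials, stats::setNames(1, el), rho = rho)
    direct <- 1 + (4 * pi * rho / sq$q) *
      as.numeric(sin(outer(sq$q, r)) %*% (r * (g - 1) * 0.02))
    expect_equal(sq$s, direct, tolerance = 1e-10)
  }
})

test_that("G -> S -> G round trip reproduces a band-limited input", {
  r <- seq(0.005, 25, by = 0.005)
  g <- 1 + 0.5 * exp(-(r - 3.2)^2 / (2 * 0.35^2)) - 0.25 * exp(-(r - 4.5)^2 / (2 * 0.5^2))
  rho <- 0.1
  gr <- tibble::tibble(r = r, g = g)
  q <- seq(0.02, 40, by = 0.02)
  sq <- gr_to_sq(gr, rho, q_grid = q)
  back <- sq_to_gr(sq, rho, r_grid = r, window = "none")
  sel <- r > 1 & r < 20
  rms <- sqrt(mean((back$g[sel] - g[sel])^2))
  expect_lt(rms, 1e-3)
})

test_that("histogram route agrees with a direct Debye sum on a small box", {
  ens <- fixture_water_ensemble()
  box <- ens$box
  snap <- ens$snapshots[[1]]
  single <- box
  single$coords <- snap
  q <- seq(1, 15, by = 0.05)
  sq <- ensemble_sq(cryostruct:::new_ensemble(list(snap), box, 1), q_grid = q, dr = 0.005)
  # independent oracle: pairwise Debye formula over minimum-image distances
  # within r_max, with the analytic uniform-background term removed
  L <- box$box_length
  rmax <- L / 2
  f <- lapply(c(C = "C", O = "O", H = "H"), function(el) form_factor(el, q))
  fi <- do.call(cbind, lapply(box$atoms$element, function(el) f[[el]]))
  fmean <- rowMeans(fi)
  N <- nrow(snap)
  acc <- rep(0, length(q))
  for (i in seq_len(N - 1)) {
    d <- sweep(snap[(i + 1):N, , drop = FALSE], 2, snap[i, ])
    d <- d - L * round(d / L)
    rr <- sqrt(rowSums(d^2))
    keep <- rr < rmax
    if (!any(keep)) next
    rr <- rr[keep]
    fj <- fi[, (i + 1):N, drop = FALSE][, keep, drop = FALSE]
    sinc <- sin(outer(q, rr)) / outer(q, rr)
    acc <- acc + rowSums(sinc * sweep(fj, 1, fi[, i], `*`))
  }
  bg <- 4 * pi * (N / L^3) * (sin(q * rmax) - q * rmax * cos(q * rmax)) / q^3
  s_debye <- 1 + 2 * acc / (N * fmean^2) - bg
  sel <- q >= 1 & q <= 15
  rms <- sqrt(mean((sq$s[sel] - s_debye[sel])^2)) / sqrt(mean(s_debye[sel]^2))
  expect_lt(rms, 0.02)
  # first diffraction peak positions agree closely
  low <- q < 4
  pk_model <- q[low][which.max(sq$s[low])]
  pk_debye <- q[low][which.max(s_debye[low])]
  expect_lt(abs(pk_model - pk_debye), 0.1)
})

test_that("low-r correction zeroes G below 1.2 A and is idempotent", {
  r <- seq(0.01, 5, by = 0.01)
  gr <- tibble::tibble(r = r, g = 1 + 0.5 * sin(5 * r))
  c1 <- apply_low_r_correction(gr)
  expect_true(all(c1$g[c1$r < 1.2] == 0))
  expect_equal(c1$g[c1$r >= 1.2], gr$g[gr$r >= 1.2])
  expect_identical(apply_low_r_correction(c1), c1)
})

test_that("T(r) = 4 pi r rho G(r) with T(0) = 0", {
  r <- seq(0, 6, by = 0.01)
  rho <- 0.09
  gr <- tibble::tibble(r = r, g = 1 + exp(-(r - 2.8)^2))
  tr <- gr_to_tr(gr, rho)
  expect_equal(tr$t, 4 * pi * r * rho * gr$g)
  expect_equal(tr$t[1], 0)
  # zero-G regions map to zero T
  gr2 <- apply_low_r_correction(gr)
  tr2 <- gr_to_tr(gr2, rho)
  expect_true(all(tr2$t[tr2$r < 1.2] == 0))
})
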