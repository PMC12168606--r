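# Reciprocal/real-space transforms: partial g(r), X-ray weighted S(Q),
# total G(r) and T(r). Conventions: all pair functions oscillate around 1 at
# large r; S(Q) -> 1 at high Q; rho is the total atomic number density.

#' Momentum transfer from scattering angle
#'
#' Q = 4 pi sin(theta) / lambda with 2 theta the scattering angle.
#'
#' @param two_theta Scattering angle 2theta in radians.
#' @param wavelength X-ray wavelength in A.
#' @return Momentum transfer in 1/A.
#' @examples
#' q_from_angle(pi, 0.124) # backscattering limit, ~101.3
#' @export
q_from_angle <- function(two_theta, wavelength) {
  if (any(wavelength <= 0)) rlang::abort("wavelength must be positive")
  4 * pi * sin(two_theta / 2) / wavelength
}

#' Default momentum-transfer grid
#'
#' 0.3-23 1/A, the synchrotron-typical range covering the chitin region and
#' the intramolecular peaks.
#' @param dq Grid spacing in 1/A.
#' @return Numeric vector of Q values.
#' @export
default_q_grid <- function(dq = 0.02) seq(0.3, 23, by = dq)

# atom selection by group label: specific site labels, force-field types or
# chemical elements
atom_group_index <- function(atoms, label) {
  if (label %in% c("C1", "C2", "C3")) {
    atoms$label == label
  } else if (label %in% atoms$type) {
    atoms$type == label
  } else if (label %in% c("C", "O", "H")) {
    atoms$element == label
  } else {
    rlang::abort(sprintf("unknown atom selection '%s'", label))
  }
}

ensemble_snapshots <- function(x) {
  if (inherits(x, "ensemble")) x$snapshots else list(x$coords)
}

ensemble_box <- function(x) if (inherits(x, "ensemble")) x$box else x

#' Partial pair distribution function from an ensemble
#'
#' Shell-histogram estimator of g_ab(r), normalized by the ideal-gas shell
#' count and averaged over snapshots. Pair members are chosen by site label
#' (`"OW"`, `"OG"`, `"C1"`, ...) or element (`"C"`, `"O"`, `"H"`).
#'
#' @param ensemble An `ensemble` or a single `simulation_box`.
#' @param pair Pair specification such as `"OW-OW"` or `c("OG", "OW")`.
#' @param dr Bin width in A.
#' @param r_max Histogram range; defaults to half the box edge and may not
#'   exceed it.
#' @param include_intra Include same-molecule pairs (needed for total
#'   scattering; excluded for intermolecular coordination analysis).
#' @return A tibble with columns `r` (bin centres) and `g`, carrying the
#'   pair label, partner density `rho_partner` (atoms/A^3) and bin width as
#'   attributes.
#' @export
partial_gr <- function(ensemble, pair = "OW-OW", dr = 0.02, r_max = NULL,
                       include_intra = FALSE) {
  box <- ensemble_box(ensemble)
  snaps <- ensemble_snapshots(ensemble)
  L <- box$box_length
  r_max <- r_max %||% (L / 2)
  if (r_max > L / 2 + 1e-9) rlang::abort("r_max may not exceed half the box length")
  if (dr <= 0) rlang::abort("dr must be positive")
  if (length(pair) == 1) pair <- strsplit(pair, "-", fixed = TRUE)[[1]]
  if (length(pair) != 2) rlang::abort("pair must name two atom groups")

  selA <- atom_group_index(box$atoms, pair[1])
  selB <- atom_group_index(box$atoms, pair[2])
  same <- identical(pair[1], pair[2])
  group <- rep(-1L, nrow(box$atoms))
  group[selA] <- 0L
  ngroups <- 1L
  if (!same) {
    if (any(selA & selB)) rlang::abort("pair groups overlap")
    group[selB] <- 1L
    ngroups <- 2L
  }
  hist <- cpp_pair_histogram(
    snaps, L, group, ngroups, dr, r_max, box_mol_id0(box), include_intra
  )
  counts <- if (same) 2 * hist[, 1] else hist[, 2]
  nA <- sum(selA)
  nB <- if (same) nA else sum(selB)
  nbins <- nrow(hist)
  edges <- (0:nbins) * dr
  vshell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbins + 1)]^3)
  V <- L^3
  g <- V * counts / (length(snaps) * nA * nB * vshell)
  out <- tibble::tibble(r = (seq_len(nbins) - 0.5) * dr, g = g)
  attr(out, "pair") <- paste(pair, collapse = "-")
  attr(out, "dr") <- dr
  attr(out, "rho_partner") <- nB / V
  attr(out, "n_central") <- nA
  attr(out, "box_length") <- L
  attr(out, "n_snapshots") <- length(snaps)
  out
}

# all element-pair partials (including intramolecular pairs) for the X-ray
# forward model
element_partials <- function(ensemble, dr = 0.02, r_max = NULL) {
  box <- ensemble_box(ensemble)
  snaps <- ensemble_snapshots(ensemble)
  L <- box$box_length
  r_max <- r_max %||% (L / 2)
  elements <- intersect(c("C", "O", "H"), unique(box$atoms$element))
  group <- match(box$atoms$element, elements) - 1L
  ng <- length(elements)
  hist <- cpp_pair_histogram(
    snaps, L, group, ng, dr, r_max, box_mol_id0(box), TRUE
  )
  nbins <- nrow(hist)
  edges <- (0:nbins) * dr
  vshell <- 4 / 3 * pi * (edges[-1]^3 - edges[-(nbins + 1)]^3)
  V <- L^3
  counts_of <- table(factor(box$atoms$element, levels = elements))
  partials <- list()
  for (a in seq_len(ng)) {
    for (b in a:ng) {
      pidx <- (a - 1) * ng - (a - 1) * (a - 2) / 2 + (b - a) + 1
      cnt <- hist[, pidx]
      mult <- if (a == b) 2 else 1
      g <- V * mult * cnt / (length(snaps) * counts_of[a] * counts_of[b] * vshell)
      key <- paste(elements[a], elements[b], sep = "-")
      partials[[key]] <- tibble::tibble(r = (seq_len(nbins) - 0.5) * dr, g = as.numeric(g))
    }
  }
  list(
    partials = partials,
    concentration = as.numeric(counts_of) / sum(counts_of),
    elements = elements,
    rho = box$rho,
    n_atoms = nrow(box$atoms)
  )
}

#' X-ray weighted total structure factor from partial pair functions
#'
#' Faber-Ziman combination: each partial g_ab(r) is sine-transformed and
#' summed with concentration and Q-dependent form-factor weights normalized
#' by the squared mean form factor, so S(Q) -> 1 at high Q and a
#' single-component system has unit weight.
#'
#' @param partials Named list of partial tibbles (`r`, `g`), names like
#'   `"C-O"`; or the result of the internal element-partial builder.
#' @param composition Named numeric vector of atomic concentrations per
#'   element (fractions summing to 1).
#' @param rho Total atomic number density, atoms/A^3.
#' @param q_grid Q grid in 1/A.
#' @return Tibble with columns `q` and `s`, provenance attribute `"model"`.
#' @export
xray_weighted_sq <- function(partials, composition, rho,
                             q_grid = default_q_grid()) {
  elements <- names(composition)
  f <- lapply(elements, function(el) form_factor(el, q_grid))
  names(f) <- elements
  fmean <- Reduce(`+`, Map(function(el) composition[[el]] * f[[el]], elements))
  s <- rep(0, length(q_grid))
  for (ai in seq_along(elements)) {
    for (bi in ai:length(elements)) {
      a <- elements[ai]; b <- elements[bi]
      key <- paste(a, b, sep = "-")
      alt <- paste(b, a, sep = "-")
      p <- partials[[key]] %||% partials[[alt]]
      if (is.null(p)) rlang::abort(sprintf("missing partial '%s'", key))
      dr <- p$r[2] - p$r[1]
      integrand <- p$r * (p$g - 1) * dr
      sab <- (4 * pi * rho / q_grid) * as.numeric(sin(outer(q_grid, p$r)) %*% integrand)
      w <- (if (ai == bi) 1 else 2) * composition[[a]] * composition[[b]] *
        f[[a]] * f[[b]] / fmean^2
      s <- s + w * sab
    }
  }
  out <- tibble::tibble(q = q_grid, s = 1 + s)
  attr(out, "provenance") <- "model"
  attr(out, "rho") <- rho
  out
}

#' Total S(Q) of an ensemble
#'
#' Convenience wrapper: computes all element-pair partials of the ensemble
#' (including intramolecular correlations) and combines them with X-ray
#' weights into the total structure factor.
#'
#' @inheritParams partial_gr
#' @param q_grid Q grid in 1/A.
#' @return Tibble with columns `q`, `s`.
#' @export
ensemble_sq <- function(ensemble, q_grid = default_q_grid(), dr = 0.02) {
  ep <- element_partials(ensemble, dr = dr)
  comp <- stats::setNames(ep$concentration, ep$elements)
  xray_weighted_sq(ep$partials, comp, ep$rho, q_grid)
}

lorch_window <- function(x, x_max) {
  w <- rep(1, length(x))
  nz <- x > 0
  arg <- pi * x[nz] / x_max
  w[nz] <- sin(arg) / arg
  w
}

#' Total pair distribution function G(r) from S(Q)
#'
#' Sine Fourier transform of Q [S(Q) - 1]; the result oscillates around 1.
#' A Lorch modification window damps truncation ripple by default.
#'
#' @param sq Tibble with columns `q` and `s`.
#' @param rho Total atomic number density, atoms/A^3.
#' @param r_grid Output grid in A.
#' @param window `"lorch"` (default) or `"none"`.
#' @return Tibble with columns `r` and `g` (total G(r)).
#' @export
sq_to_gr <- function(sq, rho, r_grid = seq(0.01, 10, by = 0.01),
                     window = c("lorch", "none")) {
  window <- match.arg(window)
  if (rho <= 0) rlang::abort("rho must be positive")
  dq <- diff(sq$q)
  dq <- c(dq, dq[length(dq)])
  w <- if (window == "lorch") lorch_window(sq$q, max(sq$q)) else rep(1, nrow(sq))
  integrand <- sq$q * (sq$s - 1) * w * dq
  gr <- 1 + as.numeric(sin(outer(r_grid, sq$q)) %*% integrand) / (2 * pi^2 * rho * r_grid)
  out <- tibble::tibble(r = r_grid, g = gr)
  attr(out, "rho") <- rho
  out
}

#' S(Q) from a total pair distribution function
#'
#' Inverse companion of [sq_to_gr()]: S(Q) = 1 + (4 pi rho / Q)
#' integral r (G - 1) sin(Qr) dr. No window by default.
#'
#' @param gr Tibble with columns `r` and `g`.
#' @inheritParams sq_to_gr
#' @param q_grid Output grid in 1/A.
#' @return Tibble with columns `q`, `s`.
#' @export
gr_to_sq <- function(gr, rho, q_grid = default_q_grid(),
                     window = c("none", "lorch")) {
  window <- match.arg(window)
  dr <- diff(gr$r)
  dr <- c(dr, dr[length(dr)])
  w <- if (window == "lorch") lorch_window(gr$r, max(gr$r)) else rep(1, nrow(gr))
  integrand <- gr$r * (gr$g - 1) * w * dr
  s <- 1 + (4 * pi * rho / q_grid) * as.numeric(sin(outer(q_grid, gr$r)) %*% integrand)
  out <- tibble::tibble(q = q_grid, s = s)
  attr(out, "rho") <- rho
  out
}

#' Zero the unphysical low-r region of a total G(r)
#'
#' Long-wavelength systematic errors in measured S(Q) leak into G(r) below
#' the shortest physical interatomic distance; they are removed by setting
#' G(r < r_min) = 0. Idempotent.
#'
#' @param gr Tibble with columns `r` and `g` (and optionally `t`).
#' @param r_min Cut radius in A (default 1.2).
#' @return The corrected tibble.
#' @export
apply_low_r_correction <- function(gr, r_min = 1.2) {
  if (min(gr$r) > r_min) rlang::abort("r grid must cover the corrected region")
  gr$g[gr$r < r_min] <- 0
  if ("t" %in% names(gr)) gr$t[gr$r < r_min] <- 0
  gr
}

#' Total correlation function T(r)
#'
#' T(r) = 4 pi r rho G(r), the representation whose peak heights drive the
#' composition calibration.
#'
#' @param gr Tibble with columns `r`, `g`.
#' @param rho Total atomic number density, atoms/A^3.
#' @return The input tibble with a `t` column added.
#' @export
gr_to_tr <- function(gr, rho = attr(gr, "rho")) {
  if (is.null(rho)) rlang::abort("rho required")
  gr$t <- 4 * pi * gr$r * rho * gr$g
  attr(gr, "rho") <- rho
  gr
}
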