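#' @useDynLib cryostruct, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn .data `%||%`
#' @importFrom stats predict
NULL

# place atom X bonded to B with |X-B| = r, angle X-B-A = theta (deg) and
# dihedral X-B-A-C = phi (deg, cis = 0 convention)
zmat_place <- function(B, A, C, r, theta, phi) {
  theta <- theta * pi / 180
  phi <- phi * pi / 180
  u <- B - A
  u <- u / sqrt(sum(u^2))
  v <- C - A
  w <- v - sum(v * u) * u
  nw <- sqrt(sum(w^2))
  if (nw < 1e-8) abort("degenerate z-matrix reference (collinear atoms)")
  w <- w / nw
  n <- c(
    u[2] * w[3] - u[3] * w[2],
    u[3] * w[1] - u[1] * w[3],
    u[1] * w[2] - u[2] * w[1]
  )
  B + r * (-cos(theta) * u + sin(theta) * (cos(phi) * w + sin(phi) * n))
}

load_forcefield_parameters <- function(path = NULL) {
  path <- path %||% system.file("extdata", "forcefield_glycerol_water.yaml",
    package = "cryostruct"
  )
  yaml::read_yaml(path)
}

validate_template <- function(tpl) {
  at <- tpl$atoms
  if (abs(sum(at$charge)) > 1e-9) {
    abort(sprintf("template '%s' is not charge neutral", tpl$name))
  }
  # bond graph connectivity
  n <- nrow(at)
  if (n > 1) {
    adj <- vector("list", n)
    for (k in seq_len(nrow(tpl$bonds))) {
      i <- tpl$bonds$i[k]; j <- tpl$bonds$j[k]
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
    seen <- rep(FALSE, n); queue <- 1L; seen[1] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    if (!all(seen)) abort(sprintf("bond graph of '%s' is not connected", tpl$name))
  }
  # each rotated set may touch the rest of the molecule only through its axis
  for (g in tpl$rotatable_groups) {
    for (m in g$moved) {
      nb <- unique(c(tpl$bonds$j[tpl$bonds$i == m], tpl$bonds$i[tpl$bonds$j == m]))
      if (!all(nb %in% c(g$moved, g$axis))) {
        abort(sprintf("rotated atoms of '%s' are bonded outside their axis", tpl$name))
      }
    }
  }
  # stored coordinates must honour the bond lengths
  for (k in seq_len(nrow(tpl$bonds))) {
    i <- tpl$bonds$i[k]; j <- tpl$bonds$j[k]
    d <- sqrt(sum((unlist(at[i, c("x", "y", "z")]) - unlist(at[j, c("x", "y", "z")]))^2))
    if (abs(d - tpl$bonds$length[k]) > 0.02) {
      abort(sprintf("template '%s' coordinates violate bond %d-%d", tpl$name, i, j))
    }
  }
  invisible(tpl)
}

new_molecule_template <- function(name, atoms, bonds, rotatable_groups = list()) {
  tpl <- structure(
    list(
      name = name, atoms = atoms, bonds = bonds,
      rotatable_groups = rotatable_groups
    ),
    class = "molecule_template"
  )
  validate_template(tpl)
}

#' Glycerol molecular template
#'
#' Builds the 14-atom (3 C, 3 O, 8 H) semi-rigid glycerol template:
#' reference geometry, partial charges, Lennard-Jones parameters, harmonic
#' bond terms and the three rotatable C-O-H hydroxyl groups. Parameters come
#' from the package force-field file (OPLS-derived charges as used in
#' published structure-refinement work on glycerol-water; see
#' `inst/extdata/forcefield_glycerol_water.yaml` for sources).
#'
#' @param parameters Optional parameter list as returned by
#'   [load_forcefield_parameters()]; defaults to the shipped file.
#' @return A `molecule_template` with fields `atoms` (tibble with label,
#'   type, element, charge, epsilon, sigma and reference coordinates),
#'   `bonds` and `rotatable_groups`.
#' @examples
#' tpl <- glycerol_template()
#' nrow(tpl$atoms) # 14
#' @export
glycerol_template <- function(parameters = NULL) {
  p <- parameters %||% load_forcefield_parameters()
  g <- p$geometry$glycerol
  cc <- g$cc_bond; co <- g$co_bond; ch <- g$ch_bond; oh <- g$oh_bond

  crd <- matrix(NA_real_, 14, 3)
  # backbone in the xy-plane
  crd[1, ] <- c(0, 0, 0)                       # C1
  crd[2, ] <- c(cc, 0, 0)                      # C2
  alpha <- (180 - g$ccc_angle) * pi / 180
  crd[3, ] <- crd[2, ] + cc * c(cos(alpha), sin(alpha), 0) # C3
  # oxygens
  crd[4, ] <- zmat_place(crd[1, ], crd[2, ], crd[3, ], co, g$cco_angle, 180) # O1
  crd[5, ] <- zmat_place(crd[2, ], crd[1, ], crd[3, ], co, g$cco_angle, 120) # O2
  crd[6, ] <- zmat_place(crd[3, ], crd[2, ], crd[1, ], co, g$cco_angle, 180) # O3
  # aliphatic hydrogens
  crd[7, ] <- zmat_place(crd[1, ], crd[2, ], crd[3, ], ch, 109.5, 60)   # H11
  crd[8, ] <- zmat_place(crd[1, ], crd[2, ], crd[3, ], ch, 109.5, 300)  # H12
  crd[9, ] <- zmat_place(crd[2, ], crd[1, ], crd[3, ], ch, 109.5, 240)  # H2
  crd[10, ] <- zmat_place(crd[3, ], crd[2, ], crd[1, ], ch, 109.5, 60)  # H31
  crd[11, ] <- zmat_place(crd[3, ], crd[2, ], crd[1, ], ch, 109.5, 300) # H32
  # hydroxyl hydrogens (one per rotatable C-O-H group)
  crd[12, ] <- zmat_place(crd[4, ], crd[1, ], crd[2, ], oh, g$coh_angle, 180) # HO1
  crd[13, ] <- zmat_place(crd[5, ], crd[2, ], crd[1, ], oh, g$coh_angle, 180) # HO2
  crd[14, ] <- zmat_place(crd[6, ], crd[3, ], crd[2, ], oh, g$coh_angle, 180) # HO3

  q <- p$charges$glycerol
  lj <- p$atom_types
  atoms <- tibble(
    label = c(
      "C1", "C2", "C3", "OG", "OG", "OG",
      "HC", "HC", "HC", "HC", "HC", "HG", "HG", "HG"
    ),
    type = c("C", "C", "C", "OG", "OG", "OG", rep("HC", 5), rep("HG", 3)),
    element = c(rep("C", 3), rep("O", 3), rep("H", 8)),
    charge = c(
      q$C_terminal, q$C_central, q$C_terminal, rep(q$OG, 3),
      rep(q$HC, 5), rep(q$HG, 3)
    ),
    epsilon = c(
      rep(lj$C$epsilon, 3), rep(lj$OG$epsilon, 3),
      rep(lj$HC$epsilon, 5), rep(lj$HG$epsilon, 3)
    ),
    sigma = c(
      rep(lj$C$sigma, 3), rep(lj$OG$sigma, 3),
      rep(lj$HC$sigma, 5), rep(lj$HG$sigma, 3)
    ),
    x = crd[, 1], y = crd[, 2], z = crd[, 3]
  )
  kb <- p$bond_force_constants
  bonds <- tibble(
    i = c(1L, 2L, 1L, 2L, 3L, 1L, 1L, 2L, 3L, 3L, 4L, 5L, 6L),
    j = c(2L, 3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L, 11L, 12L, 13L, 14L),
    length = c(cc, cc, co, co, co, rep(ch, 5), rep(oh, 3)),
    k = c(kb$cc, kb$cc, kb$co, kb$co, kb$co, rep(kb$ch, 5), rep(kb$oh, 3))
  )
  groups <- list(
    list(axis = c(1L, 4L), moved = 12L),
    list(axis = c(2L, 5L), moved = 13L),
    list(axis = c(3L, 6L), moved = 14L)
  )
  new_molecule_template("glycerol", atoms, bonds, groups)
}

#' Water molecular template
#'
#' Rigid 3-site SPC/E water: charges on all sites, a single Lennard-Jones
#' site on oxygen, no rotatable groups.
#'
#' @inheritParams glycerol_template
#' @return A `molecule_template` with 3 atoms.
#' @examples
#' water_template()$atoms$charge # sums to zero
#' @export
water_template <- function(parameters = NULL) {
  p <- parameters %||% load_forcefield_parameters()
  g <- p$geometry$water
  oh <- g$oh_bond
  half <- g$hoh_angle / 2 * pi / 180
  crd <- rbind(
    c(0, 0, 0),
    c(oh * sin(half), 0, oh * cos(half)),
    c(-oh * sin(half), 0, oh * cos(half))
  )
  lj <- p$atom_types
  q <- p$charges$water
  atoms <- tibble(
    label = c("OW", "HW", "HW"),
    type = c("OW", "HW", "HW"),
    element = c("O", "H", "H"),
    charge = c(q$OW, q$HW, q$HW),
    epsilon = c(lj$OW$epsilon, 0, 0),
    sigma = c(lj$OW$sigma, 0, 0),
    x = crd[, 1], y = crd[, 2], z = crd[, 3]
  )
  bonds <- tibble(
    i = c(1L, 1L), j = c(2L, 3L),
    length = c(oh, oh), k = rep(p$bond_force_constants$oh, 2)
  )
  new_molecule_template("water", atoms, bonds, list())
}

# single Lennard-Jones site, used for toy systems and sampling checks
lj_sphere_template <- function(epsilon = 0.997, sigma = 3.4, charge = 0,
                               label = "AR") {
  atoms <- tibble(
    label = label, type = label, element = "C", charge = charge,
    epsilon = epsilon, sigma = sigma, x = 0, y = 0, z = 0
  )
  bonds <- tibble(
    i = integer(), j = integer(), length = numeric(), k = numeric()
  )
  new_molecule_template(label, atoms, bonds, list())
}

#' @export
print.molecule_template <- function(x, ...) {
  cat(sprintf(
    "<molecule_template> %s: %d atoms, %d bonds, %d rotatable group(s)\n",
    x$name, nrow(x$atoms), nrow(x$bonds), length(x$rotatable_groups)
  ))
  invisible(x)
}
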