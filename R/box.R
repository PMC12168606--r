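# Periodic simulation boxes: construction, packing and bookkeeping.

# run code under a temporary RNG state so callers' streams are untouched
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_rotation_matrix <- function() {
  # uniform random rotation via QR of a Gaussian matrix
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

heavy_type_of <- function(type) {
  h <- unname(c(C = 0L, OG = 1L, OW = 2L)[type])
  h[is.na(h)] <- -1L
  h
}

#' Assemble a simulation box from templates and molecule placements
#'
#' Low-level constructor used by [pack_box()] and by hand-built test
#' configurations. Molecule coordinates are taken as given; no overlap
#' checks are applied.
#'
#' @param templates List of `molecule_template`s.
#' @param template_of_mol Integer vector, one entry per molecule, indexing
#'   into `templates`.
#' @param coords Numeric matrix (total atoms x 3) with molecules stored
#'   contiguously in template atom order.
#' @param box_length Cubic box edge in A.
#' @param temperature Temperature in K.
#' @param x_w,rho Optional composition (mol% water) and atomic number
#'   density metadata; derived from counts/volume when missing.
#' @param seed Seed recorded for provenance.
#' @return A `simulation_box`.
#' @export
assemble_box <- function(templates, template_of_mol, coords, box_length,
                         temperature = 298, x_w = NULL, rho = NULL,
                         seed = NA_integer_) {
  nat <- vapply(templates, function(t) nrow(t$atoms), integer(1))
  mol_len <- nat[template_of_mol]
  mol_start <- cumsum(c(0L, mol_len[-length(mol_len)]))
  n_atoms <- sum(mol_len)
  stopifnot(nrow(coords) == n_atoms, ncol(coords) == 3)

  atoms <- dplyr::bind_rows(lapply(seq_along(template_of_mol), function(m) {
    a <- templates[[template_of_mol[m]]]$atoms
    a$mol_id <- m
    a
  }))
  atoms$x <- coords[, 1]; atoms$y <- coords[, 2]; atoms$z <- coords[, 3]

  tpl_names <- vapply(templates, function(t) t$name, character(1))
  n_water <- sum(tpl_names[template_of_mol] == "water")
  n_glycerol <- sum(tpl_names[template_of_mol] == "glycerol")
  if (is.null(x_w)) {
    x_w <- if (n_water + n_glycerol > 0) 100 * n_water / (n_water + n_glycerol) else NA_real_
  }
  if (is.null(rho)) rho <- n_atoms / box_length^3

  types <- unique(atoms$type)
  type_table <- dplyr::distinct(atoms[, c("type", "epsilon", "sigma")])
  type_table <- type_table[match(types, type_table$type), ]

  structure(
    list(
      coords = coords,
      atoms = atoms[, c("label", "type", "element", "charge", "mol_id")],
      types = type_table,
      templates = templates,
      template_of_mol = as.integer(template_of_mol),
      mol_start = as.integer(mol_start),
      mol_len = as.integer(mol_len),
      box_length = box_length,
      temperature = temperature,
      x_w = x_w,
      rho = rho,
      n_water = n_water,
      n_glycerol = n_glycerol,
      seed = seed
    ),
    class = "simulation_box"
  )
}

# per-atom integer vectors used by the C++ engine
box_ljtype <- function(box) match(box$atoms$type, box$types$type) - 1L
box_heavy <- function(box) heavy_type_of(box$atoms$type)
box_mol_id0 <- function(box) as.integer(box$atoms$mol_id) - 1L

# global rotatable-group matrix: columns mol, group, axis_a, axis_b, moved
# (all 0-based)
box_rot_groups <- function(box) {
  rows <- list()
  for (m in seq_along(box$template_of_mol)) {
    tpl <- box$templates[[box$template_of_mol[m]]]
    off <- box$mol_start[m]
    for (gi in seq_along(tpl$rotatable_groups)) {
      g <- tpl$rotatable_groups[[gi]]
      for (mv in g$moved) {
        rows[[length(rows) + 1L]] <- c(
          m - 1L, gi - 1L,
          off + g$axis[1] - 1L, off + g$axis[2] - 1L, off + mv - 1L
        )
      }
    }
  }
  if (!length(rows)) {
    return(matrix(integer(), 0, 5))
  }
  do.call(rbind, rows)
}

#' Pack a periodic glycerol-water box at a requested composition
#'
#' Builds a cubic periodic box whose edge reproduces the mixture atomic
#' number density and whose molecule counts are the nearest-integer split of
#' the requested mol% water. Molecules are seeded on a jittered lattice with
#' random orientations and relaxed by greedy soft-core moves until no two
#' intermolecular atoms are closer than `dmin`.
#'
#' @param x_w Composition in mol% water.
#' @param n_molecules Total number of molecules (>= 2).
#' @param temperature Temperature in K (sets the density).
#' @param seed Integer seed; packing is reproducible under a fixed seed.
#' @param model A [density_model()].
#' @param dmin Minimum allowed intermolecular atom-atom distance in A.
#' @param max_relax_sweeps Bound on relaxation sweeps before the packing is
#'   declared failed.
#' @return A `simulation_box`.
#' @examples
#' box <- pack_box(100, 32, 298, seed = 1)
#' box$box_length
#' @export
pack_box <- function(x_w, n_molecules, temperature = 298, seed = 1,
                     model = density_model(), dmin = 1.5,
                     max_relax_sweeps = 400) {
  if (n_molecules < 2) rlang::abort("n_molecules must be >= 2")
  if (x_w < 0 || x_w > 100) rlang::abort("x_w must lie in [0, 100]")
  n_water <- as.integer(round(x_w / 100 * n_molecules))
  n_glycerol <- n_molecules - n_water
  x_actual <- 100 * n_water / n_molecules
  rho <- density_lookup(x_actual, temperature, model)
  n_atoms <- 3L * n_water + 14L * n_glycerol
  box_length <- (n_atoms / rho)^(1 / 3)

  templates <- list(glycerol = glycerol_template(), water = water_template())
  tpl_centered <- lapply(templates, function(t) {
    xyz <- as.matrix(t$atoms[, c("x", "y", "z")])
    sweep(xyz, 2, colMeans(xyz))
  })

  n_types <- length(unique(unlist(lapply(templates, function(t) t$atoms$type))))
  all_types <- unique(unlist(lapply(templates, function(t) t$atoms$type)))

  for (attempt in 1:4) {
    # start dilute (about 78% of the target density), where the jittered
    # lattice relaxes easily, then compress stepwise to the target edge
    L_start <- box_length * 1.086
    coords <- with_local_seed(seed + (attempt - 1L) * 100003L, {
      template_of_mol <- sample(c(rep(1L, n_glycerol), rep(2L, n_water)))
      ns <- ceiling(n_molecules^(1 / 3))
      spacing <- L_start / ns
      sites <- as.matrix(expand.grid(0:(ns - 1), 0:(ns - 1), 0:(ns - 1)))
      sites <- (sites + 0.5) * spacing
      sites <- sites[sample(nrow(sites), n_molecules), , drop = FALSE]
      jitter <- matrix(stats::runif(3 * n_molecules, -0.15, 0.15) * spacing,
        ncol = 3
      )
      pieces <- lapply(seq_len(n_molecules), function(m) {
        base <- tpl_centered[[template_of_mol[m]]]
        rot <- base %*% t(random_rotation_matrix())
        sweep(rot, 2, sites[m, ] + jitter[m, ], `+`)
      })
      structure(do.call(rbind, pieces), template_of_mol = template_of_mol)
    })
    template_of_mol <- attr(coords, "template_of_mol")
    nat <- c(14L, 3L)[template_of_mol]
    mol_start <- cumsum(c(0L, nat[-length(nat)]))
    mol_id <- rep(seq_len(n_molecules), nat) - 1L
    crd <- unclass(coords)[, , drop = FALSE]
    ljt <- unlist(lapply(template_of_mol, function(ti) {
      match(templates[[ti]]$atoms$type, all_types) - 1L
    }))
    zero_q <- rep(0, nrow(crd))
    rot <- matrix(integer(), 0, 5)
    ep0 <- matrix(0, 0, 6)

    # thermal Metropolis relaxation under a purely repulsive soft-sphere
    # potential on every atom (charges off); cooperative moves resolve
    # overlaps where greedy descent jams
    relax <- function(crd, L, n_sweeps, temp, sigma, blk) {
      cpp_mc_run(
        crd, L, ljt, zero_q, rep(0.12, n_types), rep(sigma, n_types),
        rep(-1L, nrow(crd)), mol_start, nat, rot, ep0, 0.05,
        min(4, L / 2), temp, n_sweeps,
        c(0.5, 0.6, 0), c(0.6, 0.4, 0),
        seed + attempt * 7919 + blk * 131, 0L, TRUE
      )$coords
    }
    scale_centres <- function(crd, f) {
      for (m in seq_len(n_molecules)) {
        idx <- mol_start[m] + seq_len(nat[m])
        ctr <- colMeans(crd[idx, , drop = FALSE])
        crd[idx, ] <- sweep(crd[idx, , drop = FALSE], 2, ctr * (f - 1), `+`)
      }
      crd
    }

    # dilute stage: unjam the lattice start
    blk <- 0L
    dmin_seen <- 0
    while (blk < 8L && dmin_seen < dmin - 1e-9) {
      crd <- relax(crd, L_start, 20L, if (blk < 2) 450 else 120, 2.2, blk)
      blk <- blk + 1L
      dmin_seen <- cpp_min_inter_dist(crd, L_start, mol_id)
    }
    # compression stage: shrink molecule centres toward the target edge in
    # small steps with relaxation in between
    L_cur <- L_start
    steps <- 8L
    for (k in seq_len(steps)) {
      L_next <- L_start * (box_length / L_start)^(k / steps)
      crd <- scale_centres(crd, L_next / L_cur)
      L_cur <- L_next
      crd <- relax(crd, L_cur, 12L, 300, 2.2, blk + k)
    }
    # polish stage: cold blocks push the closest contacts past dmin; a
    # stall escalates the soft-sphere diameter, then reheats
    dmin_seen <- cpp_min_inter_dist(crd, box_length, mol_id)
    sweeps_left <- max(max_relax_sweeps, ceiling(n_molecules / 3))
    stall <- 0L
    sigma <- 2.2
    blk <- blk + steps
    while (sweeps_left > 0 && dmin_seen < dmin - 1e-9) {
      crd <- relax(crd, box_length, 20L, 120, sigma, blk)
      blk <- blk + 1L
      sweeps_left <- sweeps_left - 20L
      prev <- dmin_seen
      dmin_seen <- cpp_min_inter_dist(crd, box_length, mol_id)
      if (dmin_seen < prev + 0.005) {
        stall <- stall + 1L
        if (stall == 2L) sigma <- 2.45
        if (stall >= 4L) {
          crd <- relax(crd, box_length, 20L, 450, 2.2, blk)
          blk <- blk + 1L
          sweeps_left <- sweeps_left - 20L
          sigma <- 2.2
          stall <- 0L
        }
      } else {
        stall <- 0L
      }
    }
    if (dmin_seen >= dmin - 1e-9) {
      return(assemble_box(
        unname(templates), template_of_mol, crd, box_length,
        temperature = temperature, x_w = x_actual, rho = rho, seed = seed
      ))
    }
  }
  rlang::abort(sprintf(
    "packing failed: could not reach %.2f A separation at rho = %.4f",
    dmin, rho
  ))
}

#' @export
print.simulation_box <- function(x, ...) {
  cat(sprintf(
    "<simulation_box> %d molecules (%d glycerol, %d water), L = %.2f A, X_W = %.1f mol%%, T = %.0f K, rho = %.4f atoms/A^3\n",
    length(x$mol_len), x$n_glycerol, x$n_water, x$box_length, x$x_w,
    x$temperature, x$rho
  ))
  invisible(x)
}
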