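# Structural observables: coordination numbers, hydrogen bonds per
# glycerol, water-cluster statistics and spatial density maps.

#' Coordination number by integration of g(r)
#'
#' n = 4 pi rho_partner * integral_0^rcut r^2 g(r) dr, evaluated with exact
#' spherical-shell volumes on the stored grid (so a histogram-derived g(r)
#' integrates back to the exact mean neighbor count).
#'
#' @param pf Partial pair function tibble from [partial_gr()].
#' @param r_cut Integration cutoff in A.
#' @param rho_partner Partner-atom number density in atoms/A^3; defaults to
#'   the value recorded by [partial_gr()].
#' @param pair Pair label for the result row.
#' @return One-row tibble (`pair`, `cutoff`, `n`).
#' @export
coordination_number <- function(pf, r_cut, rho_partner = attr(pf, "rho_partner"),
                                pair = attr(pf, "pair") %||% NA_character_) {
  dr <- pf$r[2] - pf$r[1]
  edges_lo <- pf$r - dr / 2
  edges_hi <- pf$r + dr / 2
  if (r_cut > max(edges_hi) + 1e-9) {
    rlang::abort("r_cut lies beyond the stored g(r) grid")
  }
  hi <- pmin(edges_hi, r_cut)
  vshell <- 4 / 3 * pi * pmax(0, hi^3 - pmin(edges_lo, r_cut)^3)
  n <- rho_partner * sum(pf$g * vshell)
  tibble::tibble(pair = pair, cutoff = r_cut, n = n)
}

# first minimum of g(r) after its first peak: first sign change of the
# slope of the smoothed curve (a global minimum in a window is unreliable
# when the post-peak region is flat and noisy)
first_minimum <- function(pf, peak_window = c(2.4, 3.4), search_width = 1.4) {
  dr <- pf$r[2] - pf$r[1]
  k <- max(3L, 2L * floor(0.12 / dr) + 1L)
  g <- as.numeric(stats::filter(pf$g, rep(1 / k, k), sides = 2))
  g[is.na(g)] <- pf$g[is.na(g)]
  sel <- pf$r >= peak_window[1] & pf$r <= peak_window[2]
  if (!any(sel)) rlang::abort("peak window outside grid")
  ipk <- which(sel)[which.max(g[sel])]
  idx <- which(pf$r > pf$r[ipk] & pf$r <= pf$r[ipk] + search_width)
  slope <- diff(g[c(idx, max(idx) + 1)])
  turn <- which(slope[-length(slope)] < 0 & slope[-1] >= 0)
  if (length(turn)) pf$r[idx[turn[1] + 1]] else pf$r[idx[which.min(g[idx])]]
}

first_peak_position <- function(pf, window = c(2.0, 3.4)) {
  g <- as.numeric(stats::filter(pf$g, rep(1 / 5, 5), sides = 2))
  g[is.na(g)] <- pf$g[is.na(g)]
  sel <- pf$r >= window[1] & pf$r <= window[2]
  pf$r[which(sel)[which.max(g[sel])]]
}

# per-snapshot count of intermolecular pairs within cutoff between two site
# selections
snapshot_pair_counts <- function(ensemble, labelA, labelB, cutoff) {
  box <- ensemble_box(ensemble)
  selA <- which(atom_group_index(box$atoms, labelA)) - 1L
  selB <- which(atom_group_index(box$atoms, labelB)) - 1L
  same <- identical(labelA, labelB)
  mol0 <- box_mol_id0(box)
  vapply(
    ensemble_snapshots(ensemble),
    function(sn) cpp_pair_count(sn, box$box_length, selA, selB, cutoff, mol0, same),
    numeric(1)
  )
}

#' Hydrogen bonds per glycerol molecule
#'
#' The operative X-ray criterion: every intermolecular O-O contact within
#' `cutoff` counts as one hydrogen bond (no hydrogen-position or angular
#' condition, since X-rays are largely insensitive to hydrogen). Counts
#' OG-OG plus OG-OW pairs per snapshot — equivalent to integrating the
#' corresponding partial g(r) to the cutoff — and reports the per-glycerol
#' mean and the spread across snapshots.
#'
#' @param ensemble An `ensemble` containing glycerol.
#' @param cutoff O-O distance criterion in A (default 3.2).
#' @return One-row tibble: `mean`, `sd` (across snapshots), `n_snapshots`,
#'   `cutoff`.
#' @export
hbonds_per_glycerol <- function(ensemble, cutoff = 3.2) {
  box <- ensemble_box(ensemble)
  if (box$n_glycerol == 0) rlang::abort("ensemble contains no glycerol")
  gg <- snapshot_pair_counts(ensemble, "OG", "OG", cutoff)
  gw <- if (box$n_water > 0) {
    snapshot_pair_counts(ensemble, "OG", "OW", cutoff)
  } else {
    rep(0, length(gg))
  }
  per_gly <- (2 * gg + gw) / box$n_glycerol
  tibble::tibble(
    mean = mean(per_gly),
    sd = stats::sd(per_gly),
    n_snapshots = length(per_gly),
    cutoff = cutoff
  )
}

#' Water-cluster size distribution of a configuration
#'
#' Two water molecules belong to the same cluster when their oxygen atoms
#' lie within `cutoff` (periodic minimum-image distance); clusters are the
#' connected components of that relation.
#'
#' @param box A `simulation_box` (or `ensemble`, whose final box is used).
#' @param cutoff Oxygen-oxygen connectivity distance in A (default 3.5).
#' @return A `cluster_distribution`: histogram tibble (`size`, `count`),
#'   `max_size`, `n_water` and the cutoff.
#' @export
water_clusters <- function(box, cutoff = 3.5) {
  box <- ensemble_box(box)
  sel <- box$atoms$type == "OW"
  n_water <- sum(sel)
  if (n_water == 0) {
    sizes <- integer()
  } else {
    sizes <- cpp_cluster_sizes(
      box$coords[sel, , drop = FALSE], box$box_length, cutoff
    )
  }
  tab <- table(sizes)
  histogram <- tibble::tibble(
    size = as.integer(names(tab)), count = as.integer(tab)
  )
  stopifnot(sum(histogram$size * histogram$count) == n_water)
  structure(
    list(
      histogram = histogram,
      max_size = if (n_water) max(sizes) else 0L,
      n_water = n_water,
      cutoff = cutoff
    ),
    class = "cluster_distribution"
  )
}

#' @export
print.cluster_distribution <- function(x, ...) {
  cat(sprintf(
    "<cluster_distribution> %d waters, %d cluster(s), largest %d (cutoff %.2f A)\n",
    x$n_water, sum(x$histogram$count), x$max_size, x$cutoff
  ))
  invisible(x)
}

#' Per-snapshot maximum water-cluster size
#'
#' @param ensemble An `ensemble`.
#' @param cutoff Connectivity cutoff in A.
#' @return Tibble (`snapshot`, `max_size`).
#' @export
max_cluster_sizes <- function(ensemble, cutoff = 3.5) {
  box <- ensemble_box(ensemble)
  sel <- box$atoms$type == "OW"
  snaps <- ensemble_snapshots(ensemble)
  ms <- vapply(snaps, function(sn) {
    if (!any(sel)) {
      return(0L)
    }
    max(cpp_cluster_sizes(sn[sel, , drop = FALSE], box$box_length, cutoff))
  }, integer(1))
  tibble::tibble(snapshot = seq_along(snaps), max_size = ms)
}

interpolate_crossing <- function(x, y, threshold, increasing = TRUE) {
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  d <- y - threshold
  if (!increasing) d <- -d
  j <- which(d >= 0)[1]
  if (is.na(j)) {
    rlang::abort("threshold crossing is not bracketed by the data")
  }
  if (j == 1) {
    # already past the threshold at the lowest composition
    return(x[1])
  }
  i <- j - 1
  x[i] + (x[j] - x[i]) * (0 - d[i]) / (d[j] - d[i])
}

#' Composition at which the largest water cluster reaches a threshold size
#'
#' Interpolates (monotone piecewise-linear in composition) the mol% water at
#' which the ensemble-mean maximum cluster size crosses `threshold` — by
#' default the 275-molecule crystallization limit, the smallest water
#' cluster able to support ice-crystal formation.
#'
#' @param data Tibble with columns `x_w` (mol% water) and `max_cluster`
#'   (ensemble-mean per-snapshot maximum cluster size).
#' @param threshold Cluster-size threshold in molecules.
#' @return The interpolated composition in mol% water.
#' @export
crystallization_composition <- function(data, threshold = 275) {
  stopifnot(all(c("x_w", "max_cluster") %in% names(data)))
  agg <- dplyr::summarise(dplyr::group_by(data, .data$x_w),
    max_cluster = mean(.data$max_cluster), .groups = "drop"
  )
  interpolate_crossing(agg$x_w, agg$max_cluster, threshold, increasing = TRUE)
}

#' Composition at which glycerol-glycerol and glycerol-water bonding are
#' equally likely
#'
#' Interpolates the mol% water at which the OG-OG coordination number equals
#' the OG-OW coordination number at the hydrogen-bond cutoff.
#'
#' @param data Tibble with columns `x_w`, `n_gg` and `n_gw`.
#' @return The crossover composition in mol% water.
#' @export
coordination_crossover <- function(data) {
  stopifnot(all(c("x_w", "n_gg", "n_gw") %in% names(data)))
  ord <- order(data$x_w)
  interpolate_crossing(
    data$x_w[ord], data$n_gw[ord] - data$n_gg[ord], 0,
    increasing = TRUE
  )
}

#' OG-OG and OG-OW coordination numbers of an ensemble
#'
#' Direct intermolecular pair counting at the O-O cutoff, expressed per
#' glycerol oxygen (the quantity whose crossover locates the
#' glycerol-to-water bonding switch).
#'
#' @param ensemble An `ensemble` containing glycerol.
#' @param cutoff O-O cutoff in A.
#' @return One-row tibble (`x_w`, `n_gg`, `n_gw`).
#' @export
glycerol_coordination <- function(ensemble, cutoff = 3.2) {
  box <- ensemble_box(ensemble)
  if (box$n_glycerol == 0) rlang::abort("ensemble contains no glycerol")
  n_og <- 3 * box$n_glycerol
  gg <- snapshot_pair_counts(ensemble, "OG", "OG", cutoff)
  gw <- if (box$n_water > 0) {
    snapshot_pair_counts(ensemble, "OG", "OW", cutoff)
  } else {
    rep(0, length(gg))
  }
  tibble::tibble(
    x_w = box$x_w,
    n_gg = mean(2 * gg / n_og),
    n_gw = mean(gw / n_og)
  )
}

# orthonormal molecular frames for spatial density maps
molecular_frame <- function(coords) {
  # water: rows O, H1, H2 -> z along the dipole bisector, x in the plane
  o <- coords[1, ]
  if (nrow(coords) == 3) {
    zv <- 0.5 * (coords[2, ] + coords[3, ]) - o
    xv <- coords[2, ] - coords[3, ]
  } else {
    # glycerol template order: C1 C2 C3 ... -> z along C1->C3, x toward C2
    zv <- coords[3, ] - coords[1, ]
    xv <- coords[2, ] - 0.5 * (coords[1, ] + coords[3, ])
    o <- coords[2, ]
  }
  zv <- zv / sqrt(sum(zv^2))
  xv <- xv - sum(xv * zv) * zv
  xv <- xv / sqrt(sum(xv^2))
  yv <- c(
    zv[2] * xv[3] - zv[3] * xv[2],
    zv[3] * xv[1] - zv[1] * xv[3],
    zv[1] * xv[2] - zv[2] * xv[1]
  )
  list(origin = o, R = rbind(xv, yv, zv))
}

#' Spatial density map of neighbors around a central species
#'
#' Accumulates neighbor-site positions in the molecular frame of each
#' central molecule (water: z along the dipole bisector, x in the molecular
#' plane; glycerol: z along C1-C3, x toward C2) over all snapshots,
#' normalized per central molecule and snapshot. The map integrates to the
#' mean neighbor count within the shell.
#'
#' @param ensemble An `ensemble`.
#' @param central `"water"` or `"glycerol"`.
#' @param neighbor Neighbor site selection (e.g. `"OW"`, `"OG"`).
#' @param shell Radial range in A, e.g. `c(2.0, 3.5)`.
#' @param grid Voxel edge in A.
#' @return A `spatial_density_map`: 3D `density` array (probability per
#'   A^3), axis coordinates, and the shell-mean neighbor count `integral`.
#' @export
spatial_density <- function(ensemble, central = "water", neighbor = "OW",
                            shell = c(2.0, 3.5), grid = 0.5) {
  box <- ensemble_box(ensemble)
  tpl_names <- vapply(box$templates, function(t) t$name, character(1))
  cent_mols <- which(tpl_names[box$template_of_mol] == central)
  if (!length(cent_mols)) rlang::abort(sprintf("no '%s' molecules present", central))
  nb_sel <- which(atom_group_index(box$atoms, neighbor))
  if (!length(nb_sel)) rlang::abort("empty neighbor selection")
  L <- box$box_length
  rmax <- shell[2]
  nbin <- ceiling(2 * rmax / grid)
  half <- nbin * grid / 2
  dens <- array(0, dim = c(nbin, nbin, nbin))
  snaps <- ensemble_snapshots(ensemble)
  n_count <- 0
  total_in_shell <- 0
  for (sn in snaps) {
    nb_xyz <- sn[nb_sel, , drop = FALSE]
    for (m in cent_mols) {
      idx <- box$mol_start[m] + seq_len(box$mol_len[m])
      fr <- molecular_frame(sn[idx, , drop = FALSE])
      d <- sweep(nb_xyz, 2, fr$origin)
      d <- d - L * round(d / L)
      r <- sqrt(rowSums(d^2))
      keep <- r >= shell[1] & r <= shell[2]
      keep[nb_sel %in% idx] <- FALSE
      total_in_shell <- total_in_shell + sum(keep)
      if (any(keep)) {
        local <- d[keep, , drop = FALSE] %*% t(fr$R)
        ix <- floor((local + half) / grid) + 1
        ok <- rowSums(ix >= 1 & ix <= nbin) == 3
        for (k in which(ok)) dens[ix[k, 1], ix[k, 2], ix[k, 3]] <- dens[ix[k, 1], ix[k, 2], ix[k, 3]] + 1
      }
      n_count <- n_count + 1
    }
  }
  if (total_in_shell == 0) rlang::abort("no neighbors found in the shell")
  voxel <- grid^3
  dens <- dens / (n_count * voxel)
  axes <- (seq_len(nbin) - 0.5) * grid - half
  structure(
    list(
      density = dens, axes = axes, grid = grid, shell = shell,
      central = central, neighbor = neighbor,
      integral = total_in_shell / n_count
    ),
    class = "spatial_density_map"
  )
}

#' @export
print.spatial_density_map <- function(x, ...) {
  cat(sprintf(
    "<spatial_density_map> %s around %s, shell %.1f-%.1f A, mean neighbors %.2f\n",
    x$neighbor, x$central, x$shell[1], x$shell[2], x$integral
  ))
  invisible(x)
}
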