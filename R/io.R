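# Text I/O: extended-XYZ configurations, two-column S(Q)/G(r) tables and
# run logs.

#' Write a simulation box as extended XYZ
#'
#' The comment line carries `box_length`, `x_w`, `temperature` and `rho`;
#' atom labels distinguish OW/OG/C1/C2/C3 and the hydrogen classes.
#'
#' @param box A `simulation_box`.
#' @param path Output file.
#' @export
write_xyz <- function(box, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(box$coords)), con)
  writeLines(sprintf(
    'box_length=%.6f x_w=%.4f temperature=%.2f rho=%.6f Properties=species:S:1:pos:R:3',
    box$box_length, box$x_w, box$temperature, box$rho
  ), con)
  writeLines(sprintf(
    "%-3s %14.6f %14.6f %14.6f",
    box$atoms$label, box$coords[, 1], box$coords[, 2], box$coords[, 3]
  ), con)
  invisible(path)
}

#' Read an extended-XYZ configuration written by [write_xyz()]
#'
#' Molecules are reconstructed from the label sequence (a `C1` label opens
#' a 14-atom glycerol, an `OW` label a 3-atom water).
#'
#' @param path Input file.
#' @return A `simulation_box`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  meta <- lines[2]
  get_num <- function(key) {
    m <- regmatches(meta, regexpr(paste0(key, "=[-0-9.eE+]+"), meta))
    as.numeric(sub(paste0(key, "="), "", m))
  }
  rows <- strsplit(trimws(lines[3:(2 + n)]), "\\s+")
  labels <- vapply(rows, `[`, character(1), 1)
  coords <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))),
    ncol = 3, byrow = TRUE
  )
  templates <- list(glycerol_template(), water_template())
  template_of_mol <- integer()
  i <- 1
  while (i <= n) {
    if (labels[i] == "C1") {
      template_of_mol <- c(template_of_mol, 1L)
      i <- i + 14
    } else if (labels[i] == "OW") {
      template_of_mol <- c(template_of_mol, 2L)
      i <- i + 3
    } else {
      rlang::abort(sprintf("unexpected atom label '%s' at line %d", labels[i], i + 2))
    }
  }
  assemble_box(
    templates, template_of_mol, coords,
    box_length = get_num("box_length"),
    temperature = get_num("temperature"),
    x_w = get_num("x_w"), rho = get_num("rho")
  )
}

#' Write an ensemble as a directory of extended-XYZ snapshots
#'
#' @param ensemble An `ensemble`.
#' @param dir Output directory (created if needed); snapshots are
#'   `snapshot_0001.xyz`, ... plus `run_log.tsv` when a run log exists.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  box <- ensemble$box
  for (i in seq_along(ensemble$snapshots)) {
    b <- box
    b$coords <- ensemble$snapshots[[i]]
    write_xyz(b, file.path(dir, sprintf("snapshot_%04d.xyz", i)))
  }
  if (!is.null(ensemble$run_log)) {
    utils::write.table(ensemble$run_log,
      file.path(dir, "run_log.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE
    )
  }
  invisible(dir)
}

#' Write a structure factor or pair function as TSV
#'
#' Two or more numeric columns under a commented header carrying density,
#' composition and provenance metadata.
#'
#' @param x Tibble (e.g. `q`/`s` or `r`/`g`/`t`).
#' @param path Output file.
#' @export
write_pattern_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  truth <- attr(x, "truth")
  writeLines(sprintf(
    "# provenance=%s rho=%s x_w=%s",
    attr(x, "provenance") %||% "model",
    format(attr(x, "rho") %||% NA),
    format(if (!is.null(truth)) truth$x_w else NA)
  ), con)
  utils::write.table(as.data.frame(x), con,
    sep = "\t", row.names = FALSE,
    quote = FALSE
  )
  invisible(path)
}

#' Read a TSV pattern written by [write_pattern_tsv()]
#'
#' @param path Input file.
#' @return A tibble with the file's numeric columns.
#' @export
read_pattern_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#"))
}
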