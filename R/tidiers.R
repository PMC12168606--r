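# broom-style tidiers for the fitted/derived objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.calibration_curve <- function(x, ...) x$points

#' @export
glance.calibration_curve <- function(x, ...) {
  tibble::tibble(
    n_standards = nrow(x$points),
    x_w_min = min(x$points$x_w), x_w_max = max(x$points$x_w),
    ratio_min = min(x$points$ratio), ratio_max = max(x$points$ratio)
  )
}

#' @export
tidy.composition_estimate <- function(x, ...) {
  tibble::tibble(
    iteration = seq_along(x$history),
    x_w = x$history
  )
}

#' @export
glance.composition_estimate <- function(x, ...) {
  tibble::tibble(
    x_w = x$x_w, iterations = x$iterations, converged = x$converged
  )
}

#' @export
tidy.cluster_distribution <- function(x, ...) x$histogram

#' @export
glance.cluster_distribution <- function(x, ...) {
  tibble::tibble(
    n_water = x$n_water, n_clusters = sum(x$histogram$count),
    max_size = x$max_size, cutoff = x$cutoff
  )
}

#' @export
glance.ensemble <- function(x, ...) {
  tibble::tibble(
    n_snapshots = length(x$snapshots),
    n_molecules = length(x$box$mol_len),
    x_w = x$box$x_w,
    temperature = x$box$temperature,
    box_length = x$box$box_length,
    rho = x$box$rho
  )
}
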