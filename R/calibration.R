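# Composition calibration: mole-percent water of an unknown pattern from
# the relative height of the glycerol intramolecular peak in T(r).

# peak prominence: signal integrated above the window chord. The chord
# removes the flank of neighbouring features (a pure convex flank has no
# mass above its chord and scores zero), and the integral is linear in the
# signal, so zero-mean noise does not bias it the way a max-based height
# would.
window_peak_height <- function(r, v, window) {
  sel <- which(r >= window[1] & r <= window[2])
  if (length(sel) < 5) rlang::abort("peak window not covered by the grid")
  chord <- stats::approx(
    r[c(sel[1], sel[length(sel)])], v[c(sel[1], sel[length(sel)])],
    xout = r[sel]
  )$y
  dr <- r[2] - r[1]
  h <- sum(v[sel] - chord) * dr
  if (h <= 1e-8 * max(abs(v[sel])) * dr) {
    return(NA_real_)
  }
  h
}

#' Peak-height ratio of a total correlation function T(r)
#'
#' Prominence of the glycerol intramolecular C1-C2/C-O bond-distance peak
#' (around 1.5 A) divided by the prominence of the first intermolecular O-O
#' peak (around 2.8 A), both measured above a linear in-window chord after
#' the low-r correction. The ratio decreases monotonically with water
#' content, which makes it a composition probe. A missing glycerol peak
#' (pure water) gives ratio 0; a missing O-O peak is an error. The window
#' `c(2.2, 2.65)` targets the two-bond C1-C3 distance instead and serves as
#' the alternative estimator.
#'
#' @param tr Tibble with columns `r` and `t` (see [gr_to_tr()]).
#' @param numerator_window,denominator_window Search windows in A.
#' @return Dimensionless peak-height ratio.
#' @export
peak_height_ratio <- function(tr, numerator_window = c(1.3, 1.8),
                              denominator_window = c(2.65, 3.15)) {
  if (!"t" %in% names(tr)) rlang::abort("input lacks a T(r) column; use gr_to_tr()")
  # light smoothing suppresses histogram noise; the common attenuation of
  # both peaks cancels in the ratio
  dr <- tr$r[2] - tr$r[1]
  k <- max(1L, 2L * floor(0.02 / dr) + 1L)
  t_s <- as.numeric(stats::filter(tr$t, rep(1 / k, k), sides = 2))
  t_s[is.na(t_s)] <- tr$t[is.na(t_s)]
  num <- window_peak_height(tr$r, t_s, numerator_window)
  den <- window_peak_height(tr$r, t_s, denominator_window)
  if (is.na(den) || den <= 0) {
    rlang::abort("no detectable intermolecular O-O peak in the denominator window")
  }
  if (is.na(num)) {
    return(0)
  }
  num / den
}

#' Prominence of the glycerol intramolecular peak in T(r)
#'
#' Integrated signal above the in-window chord around the glycerol C1-C2 /
#' C-O bond distance. Because the peak is intramolecular (rigid geometry)
#' its prominence in a normalized pattern is nearly noise-free and directly
#' proportional to the glycerol content, which makes it the most precise
#' composition statistic at desk-scale simulation sizes; unlike the
#' O-O-normalized ratio it presumes the pattern is on an absolute S(Q)
#' scale.
#'
#' @param tr Tibble with columns `r` and `t`.
#' @param window Search window in A.
#' @return Non-negative prominence (0 when no glycerol peak is present).
#' @export
peak_prominence <- function(tr, window = c(1.3, 1.8)) {
  if (!"t" %in% names(tr)) rlang::abort("input lacks a T(r) column; use gr_to_tr()")
  h <- window_peak_height(tr$r, tr$t, window)
  if (is.na(h)) 0 else h
}

calibration_statistic <- function(tr, statistic, ...) {
  switch(statistic,
    prominence = peak_prominence(tr, ...),
    ratio = peak_height_ratio(tr, ...),
    rlang::abort(sprintf("unknown statistic '%s'", statistic))
  )
}

reduce_to_tr <- function(sq, x_w, model, r_grid = seq(0.01, 6, by = 0.01)) {
  rho <- density_lookup(x_w, 298, model)
  gr <- sq_to_gr(sq, rho, r_grid = r_grid, window = "lorch")
  gr <- apply_low_r_correction(gr)
  gr_to_tr(gr, rho)
}

#' Build a composition calibration curve from standards
#'
#' Each standard pattern is reduced to T(r) at its known composition and
#' density; the peak-height ratios are fitted with a monotone interpolant
#' against mol% water. Non-monotone or duplicated point sets are refused.
#'
#' @param standards Tibble with columns `x_w` and `sq` (list-column of
#'   structure-factor tibbles), or a list of `list(x_w=, sq=)` pairs.
#' @param model A [density_model()].
#' @param statistic `"prominence"` (default; absolute prominence of the
#'   glycerol bond-distance peak, see [peak_prominence()]) or `"ratio"`
#'   (O-O-normalized, see [peak_height_ratio()]).
#' @param ... Peak windows forwarded to the statistic.
#' @return A `calibration_curve`.
#' @export
build_calibration_curve <- function(standards, model = density_model(),
                                    statistic = c("prominence", "ratio"),
                                    ...) {
  statistic <- match.arg(statistic)
  if (!is.data.frame(standards)) {
    standards <- tibble::tibble(
      x_w = vapply(standards, function(s) s$x_w, numeric(1)),
      sq = lapply(standards, function(s) s$sq)
    )
  }
  if (nrow(standards) < 4) rlang::abort("need at least 4 standards")
  if (anyDuplicated(standards$x_w)) {
    rlang::abort("duplicated standard compositions make the fit ill-posed")
  }
  ord <- order(standards$x_w)
  standards <- standards[ord, ]
  ratio <- vapply(seq_len(nrow(standards)), function(i) {
    calibration_statistic(
      reduce_to_tr(standards$sq[[i]], standards$x_w[i], model), statistic, ...
    )
  }, numeric(1))
  if (any(diff(ratio) >= 0)) {
    rlang::abort("peak-height ratios are not strictly decreasing with water content")
  }
  points <- tibble::tibble(x_w = standards$x_w, ratio = ratio)
  structure(
    list(
      points = points,
      statistic = statistic,
      fit = stats::splinefun(points$x_w, points$ratio, method = "hyman"),
      inverse = stats::splinefun(rev(points$ratio), rev(points$x_w),
        method = "hyman"
      )
    ),
    class = "calibration_curve"
  )
}

#' Evaluate a calibration curve
#'
#' @param object A `calibration_curve`.
#' @param x_w Compositions (mol% water) at which to evaluate the fitted
#'   ratio.
#' @param ... Unused.
#' @return Predicted peak-height ratios.
#' @export
predict.calibration_curve <- function(object, x_w, ...) {
  object$fit(pmin(pmax(x_w, min(object$points$x_w)), max(object$points$x_w)))
}

curve_invert <- function(curve, ratio) {
  rng <- range(curve$points$ratio)
  curve$inverse(pmin(pmax(ratio, rng[1]), rng[2]))
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %d standards, %.0f-%.0f mol%% water, ratio %.3f-%.3f\n",
    nrow(x$points), min(x$points$x_w), max(x$points$x_w),
    min(x$points$ratio), max(x$points$ratio)
  ))
  invisible(x)
}

#' Iteratively estimate the water content of a pattern
#'
#' Mirrors the iterative reduction procedure: assume a composition, reduce
#' the pattern to T(r) at that composition's density, measure the
#' peak-height ratio, read the implied composition off the calibration
#' curve, and repeat until composition and calibration are consistent.
#'
#' @param raw Background-subtracted structure factor, tibble (`q`, `s`).
#' @param curve A [build_calibration_curve()] result.
#' @param model A [density_model()].
#' @param tolerance Convergence tolerance in mol% water.
#' @param max_iterations Iteration cap; exceeding it flags non-convergence.
#' @param x0 Starting composition; defaults to the curve midpoint.
#' @param ... Peak windows forwarded to the curve's statistic.
#' @return A `composition_estimate` with fields `x_w`, `iterations`,
#'   `converged` and the per-iteration `history`.
#' @export
estimate_composition <- function(raw, curve, model = density_model(),
                                 tolerance = 0.5, max_iterations = 20,
                                 x0 = NULL, ...) {
  x <- x0 %||% mean(range(curve$points$x_w))
  statistic <- curve$statistic %||% "prominence"
  history <- numeric()
  converged <- FALSE
  for (it in seq_len(max_iterations)) {
    tr <- reduce_to_tr(raw, x, model)
    ratio <- calibration_statistic(tr, statistic, ...)
    x_new <- curve_invert(curve, ratio)
    history <- c(history, x_new)
    if (abs(x_new - x) < tolerance) {
      x <- x_new
      converged <- TRUE
      break
    }
    x <- x_new
  }
  if (!converged) {
    rlang::warn("composition estimate did not converge; inspect the history")
  }
  structure(
    list(
      x_w = x, iterations = length(history), converged = converged,
      history = history
    ),
    class = "composition_estimate"
  )
}

#' @export
print.composition_estimate <- function(x, ...) {
  cat(sprintf(
    "<composition_estimate> X_W = %.1f mol%% water (%d iteration(s), %s)\n",
    x$x_w, x$iterations, if (x$converged) "converged" else "NOT converged"
  ))
  invisible(x)
}

#' Subtract a (chitin-like) background from a pattern
#'
#' Computes raw - scale * background and renormalizes so S(Q) -> 1 at high
#' Q. When `scale` is missing it is fitted by least squares of the
#' background shape plus a smooth quadratic baseline against the raw
#' pattern over `fit_range` (the diffuse-chitin region). Degenerate or
#' over-subtracted results are flagged with a warning and an attribute.
#'
#' @param raw,background Tibbles (`q`, `s`) on a common Q grid; the
#'   background's `s` column holds additive intensity (zero far from its
#'   peaks).
#' @param scale Background scale; fitted when `NULL`.
#' @param fit_range Q range used for the fit, 1/A.
#' @return The corrected structure factor with attributes `scale` and
#'   `flagged`.
#' @export
subtract_background <- function(raw, background, scale = NULL,
                                fit_range = c(1.0, 2.2)) {
  if (nrow(raw) != nrow(background) ||
    max(abs(raw$q - background$q)) > 1e-9) {
    rlang::abort("raw and background must share a Q grid")
  }
  if (is.null(scale)) {
    # least squares on high-passed signals: a running-mean filter removes
    # the broad liquid features so the fit sees mostly the sharp diffuse
    # chitin peaks. Accuracy is limited (tens of percent) when liquid and
    # background features overlap; supply `scale` when it is known.
    dq <- raw$q[2] - raw$q[1]
    k <- max(5L, 2L * floor(0.3 / dq) + 1L)
    hp <- function(x) {
      sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
      sm[is.na(sm)] <- x[is.na(sm)]
      x - sm
    }
    sel <- raw$q >= fit_range[1] & raw$q <= fit_range[2]
    hr <- hp(raw$s)[sel]
    hb <- hp(background$s)[sel]
    scale <- sum(hr * hb) / sum(hb * hb)
    if (!is.finite(scale)) scale <- 0
    # the liquid's own features in the chitin region bias the fit low by a
    # roughly constant offset; the estimate grows with the true amplitude
    # but is only indicative — supply the scale whenever it is known
    scale <- max(scale, 0)
  }
  s <- raw$s - scale * background$s
  flagged <- FALSE
  # extended negative-intensity stretches signal over-subtraction
  neg <- s < 0
  if (any(neg)) {
    runs <- rle(neg)
    dq <- raw$q[2] - raw$q[1]
    if (max(runs$lengths[runs$values]) * dq > 0.2) {
      rlang::warn("extended negative intensity after subtraction")
      flagged <- TRUE
    }
  }
  tail_sel <- raw$q >= stats::quantile(raw$q, 0.9)
  tail_mean <- mean(s[tail_sel])
  if (abs(tail_mean) < 0.2) {
    rlang::warn("degenerate subtraction: high-Q level collapsed")
    flagged <- TRUE
    tail_mean <- 1
  }
  out <- tibble::tibble(q = raw$q, s = 1 + (s - tail_mean) / tail_mean)
  attr(out, "scale") <- scale
  attr(out, "flagged") <- flagged
  out
}
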