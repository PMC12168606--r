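# Analytic X-ray atomic form factors: five-Gaussian parameterization
# (Waasmaier & Kirfel, Acta Cryst. A51, 416 (1995)) for the elements in the
# glycerol-water system. f(Q) = c + sum_i a_i exp(-b_i (Q/4pi)^2); f(0) = Z.

FORM_FACTOR_TABLE <- list(
  H = list(
    a = c(0.413048, 0.294953, 0.187491, 0.080701, 0.023736),
    b = c(15.569946, 32.398468, 5.711404, 61.889874, 1.334118),
    c = 0.000049
  ),
  C = list(
    a = c(2.657506, 1.078079, 1.490909, -4.241070, 0.713791),
    b = c(14.780758, 0.776775, 42.086843, -0.000294, 0.239535),
    c = 4.297983
  ),
  O = list(
    a = c(2.960427, 2.508818, 0.637853, 0.722838, 1.142756),
    b = c(14.182259, 5.936858, 0.112726, 34.958481, 0.390240),
    c = 0.027014
  )
)

#' X-ray atomic form factor
#'
#' @param element `"H"`, `"C"` or `"O"`.
#' @param q Momentum transfer in 1/A.
#' @return f(Q) in electron units; f(0) equals the atomic number.
#' @export
form_factor <- function(element, q) {
  p <- FORM_FACTOR_TABLE[[element]]
  if (is.null(p)) rlang::abort(sprintf("no form factor for element '%s'", element))
  s2 <- (q / (4 * pi))^2
  f <- rep(p$c, length(q))
  for (i in 1:5) f <- f + p$a[i] * exp(-p$b[i] * s2)
  f
}
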