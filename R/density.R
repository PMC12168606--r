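# Mixture density model.
#
# The atomic number density of glycerol-water mixtures is represented as a
# smooth function of composition and temperature: ideal molar-volume mixing
# between the pure-component endpoints plus a negative excess-volume term,
# so that intermediate compositions are denser than the ideal solution
# (ideal densities are known to leave unphysical voids in refined models of
# these mixtures). Pure-component mass densities at 298 K: water
# 0.997 g/cm^3, glycerol 1.261 g/cm^3.

AVOGADRO <- 6.02214076e23
M_WATER <- 18.015   # g/mol
M_GLYCEROL <- 92.094

#' Glycerol-water density model
#'
#' Returns a density model mapping composition (mol% water) and temperature
#' to the atomic number density in atoms/A^3. The model mixes pure-component
#' molar volumes with a symmetric negative excess-volume term and linear
#' thermal expansion of the components, so the mixture is always at least as
#' dense as ideal mixing and densities grow on cooling.
#'
#' @param excess_volume Minimum of the excess molar volume in cm^3/mol
#'   (negative; reached at 50 mol%). Default -0.45, typical of
#'   glycerol-water at ambient conditions.
#' @param alpha_water,alpha_glycerol Volumetric thermal expansivities (1/K)
#'   applied to the component molar volumes around the 298 K reference.
#' @param rho_water,rho_glycerol Pure-component mass densities at 298 K in
#'   g/cm^3.
#' @return An object of class `density_model`.
#' @examples
#' m <- density_model()
#' density_lookup(100, 298, m) # about 0.100 atoms/A^3
#' @export
density_model <- function(excess_volume = -0.45,
                          alpha_water = 2.1e-4, alpha_glycerol = 4.9e-4,
                          rho_water = 0.997, rho_glycerol = 1.261) {
  structure(
    list(
      excess_volume = excess_volume,
      alpha_water = alpha_water, alpha_glycerol = alpha_glycerol,
      v_water = M_WATER / rho_water,        # cm^3/mol at 298 K
      v_glycerol = M_GLYCEROL / rho_glycerol
    ),
    class = "density_model"
  )
}

#' Atomic number density of a glycerol-water mixture
#'
#' @param x_w Composition in mol% water (0-100).
#' @param temperature Temperature in K.
#' @param model A [density_model()].
#' @return Atomic number density in atoms/A^3.
#' @export
density_lookup <- function(x_w, temperature = 298, model = density_model()) {
  if (any(x_w < 0 | x_w > 100)) {
    rlang::abort("x_w must lie in [0, 100] mol% water")
  }
  x <- x_w / 100
  vw <- model$v_water * (1 + model$alpha_water * (temperature - 298))
  vg <- model$v_glycerol * (1 + model$alpha_glycerol * (temperature - 298))
  v_excess <- model$excess_volume * 4 * x * (1 - x)
  v_molar <- x * vw + (1 - x) * vg + v_excess    # cm^3 per mol of molecules
  v_molecule <- v_molar * 1e24 / AVOGADRO        # A^3 per molecule
  atoms_per_molecule <- 3 * x + 14 * (1 - x)
  atoms_per_molecule / v_molecule
}

#' @export
print.density_model <- function(x, ...) {
  cat(sprintf(
    "<density_model> excess volume %.2f cm^3/mol; endpoints %.4f / %.4f atoms/A^3 at 298 K\n",
    x$excess_volume, density_lookup(0, 298, x), density_lookup(100, 298, x)
  ))
  invisible(x)
}
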