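#' Boltzmann constant in kcal/(mol K)
#'
#' Fixed convention used throughout the package.
#' @export
KB_KCAL_MOL_K <- 0.0019872041

#' Thermodynamic specification
#'
#' Bundles the temperature with the Boltzmann-constant convention and the
#' derived inverse temperature `beta = 1 / (kB * T)` in mol/kcal. All energies
#' in this package are in kcal/mol and temperatures in Kelvin.
#'
#' @param temperature Temperature in Kelvin (default 300).
#' @param boltzmann_constant Boltzmann constant in kcal/(mol K).
#' @return An object of class `"thermo"`: a list with elements `temperature`,
#'   `kB`, `kT` (kcal/mol) and `beta` (mol/kcal).
#' @examples
#' th <- thermo(300)
#' th$beta * th$kT  # 1
#' @export
thermo <- function(temperature = 300, boltzmann_constant = KB_KCAL_MOL_K) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.finite(temperature), temperature > 0,
            is.numeric(boltzmann_constant), boltzmann_constant > 0)
  kT <- boltzmann_constant * temperature
  structure(list(temperature = temperature, kB = boltzmann_constant,
                 kT = kT, beta = 1 / kT),
            class = "thermo")
}

#' @export
print.thermo <- function(x, ...) {
  cat(sprintf("thermo: T = %g K, kB = %.10g kcal/(mol K), kT = %.6g kcal/mol, beta = %.6g mol/kcal\n",
              x$temperature, x$kB, x$kT, x$beta))
  invisible(x)
}

as_thermo <- function(th) {
  if (inherits(th, "thermo")) return(th)
  if (is.numeric(th) && length(th) == 1L) return(thermo(th))
  stop("'th' must be a thermo object or a temperature in Kelvin")
}
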