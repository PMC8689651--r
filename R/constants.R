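#' Physical constants used throughout the package
#'
#' CODATA 2018 exact values. Energies are handled internally in J mol^-1;
#' user-facing parameters are kJ mol^-1 (enthalpies, free energies) and
#' kJ mol^-1 K^-1 (entropies, heat capacities).
#'
#' @return Named list with `kB` (Boltzmann constant, J K^-1), `h` (Planck
#'   constant, J s) and `R` (molar gas constant, J mol^-1 K^-1).
#' @export
#' @examples
#' phys_constants()$R
phys_constants <- function() {
  list(
    kB = 1.380649e-23,
    h  = 6.62607015e-34,
    R  = 8.314462618
  )
}

# internal shorthand
.kB <- 1.380649e-23
.h  <- 6.62607015e-34
.Rgas <- 8.314462618

#' Convert degrees Celsius to kelvin
#' @param x numeric, temperature in degrees Celsius
#' @return temperature in kelvin
#' @export
celsius_to_kelvin <- function(x) x + 273.15

#' Convert per-minute rates to per-second
#' @param x numeric, rate in min^-1
#' @return rate in s^-1
#' @export
per_min_to_per_s <- function(x) x / 60
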