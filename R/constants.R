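#' Physical constants for Goldman-Hodgkin-Katz computations
#'
#' Bundles the Faraday constant, the gas constant, and the absolute
#' temperature used by every thermodynamic expression in the package.
#' Recording temperature for oocyte two-electrode voltage clamp is typically
#' room temperature, so the default is 293.15 K; it is the one constant a
#' user routinely overrides.
#'
#' @param temperature Absolute temperature in kelvin. Must be positive.
#' @param faraday Faraday constant in C mol^-1.
#' @param gas_constant Molar gas constant in J mol^-1 K^-1.
#'
#' @return An object of class `phys_constants`: a list with elements
#'   `faraday`, `gas_constant`, and `temperature`.
#'
#' @examples
#' phys_constants()
#' phys_constants(temperature = 298.15)
#' @export
phys_constants <- function(temperature = 293.15, faraday = 9.65e4,
                           gas_constant = 8.314) {
  check_number(temperature, "temperature", positive = TRUE)
  check_number(faraday, "faraday", positive = TRUE)
  check_number(gas_constant, "gas_constant", positive = TRUE)
  structure(
    list(faraday = faraday, gas_constant = gas_constant,
         temperature = temperature),
    class = "phys_constants"
  )
}

#' @export
print.phys_constants <- function(x, ...) {
  cat(sprintf(
    "<phys_constants> F = %g C/mol, R = %g J/(mol K), T = %g K\n",
    x$faraday, x$gas_constant, x$temperature
  ))
  invisible(x)
}

as_phys_constants <- function(x) {
  if (inherits(x, "phys_constants")) return(x)
  if (is.list(x)) {
    return(phys_constants(
      temperature = x$temperature %||% 293.15,
      faraday = x$faraday %||% 9.65e4,
      gas_constant = x$gas_constant %||% 8.314
    ))
  }
  abort_invalid("`constants` must be created with phys_constants().")
}

# F / (R T), in V^-1: the reciprocal thermal voltage.
beta_per_volt <- function(constants) {
  constants$faraday / (constants$gas_constant * constants$temperature)
}
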