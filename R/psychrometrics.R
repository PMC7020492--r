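# Physical constants used throughout the energy budget.
# Units follow the molar convention of Campbell & Norman-style leaf physics.
STEFAN_BOLTZMANN <- 5.67e-8   # W m-2 K-4
CP_AIR <- 29.3                # J mol-1 C-1, specific heat of air (molar)
LAMBDA_VAP <- 44000           # J mol-1, latent heat of vaporisation of water
GAMMA_101 <- 6.66e-4          # C-1, psychrometric constant at 101.3 kPa
P_STANDARD <- 101.3           # kPa

# Tetens-form coefficients for saturation vapour pressure (kPa over water)
ESAT_A <- 0.611
ESAT_B <- 17.502
ESAT_C <- 240.97

#' Saturation vapour pressure of water
#'
#' Closed-form saturation vapour pressure over liquid water,
#' \eqn{e_s(T) = 0.611 \exp(17.502\,T/(T + 240.97))} kPa, valid for leaf-scale
#' temperatures.
#'
#' @param t Air or leaf temperature (degrees C). Must lie in \[-20, 60\].
#' @return Saturation vapour pressure (kPa).
#' @examples
#' saturation_vapor_pressure(25)
#' @export
saturation_vapor_pressure <- function(t) {
  stopifnot(is.numeric(t))
  if (any(t < -20 | t > 60))
    stop("temperature outside validity range [-20, 60] degC", call. = FALSE)
  ESAT_A * exp(ESAT_B * t / (t + ESAT_C))
}

# analytic derivative d esat / dT (kPa per degC); internal
esat_slope <- function(t) {
  saturation_vapor_pressure(t) * ESAT_B * ESAT_C / (t + ESAT_C)^2
}

#' Slope of the saturation mole-fraction function
#'
#' Derivative of the saturation mole fraction of water vapour with respect to
#' temperature, \eqn{s = (de_s/dT)/P_a}, the "s" of the Penman linearization.
#'
#' @param t Temperature (degrees C).
#' @param pressure Atmospheric pressure (kPa), default 101.3.
#' @return Slope (per degree C).
#' @export
slope_s <- function(t, pressure = P_STANDARD) {
  if (any(pressure <= 0)) stop("pressure must be positive", call. = FALSE)
  esat_slope(t) / pressure
}

#' Vapour pressure deficit
#'
#' @param t Air temperature (degrees C).
#' @param rh Relative humidity (percent, 0-100).
#' @return Vapour pressure deficit D (kPa), non-negative.
#' @export
vapor_pressure_deficit <- function(t, rh) {
  if (any(rh < 0 | rh > 100))
    stop("relative humidity must be within [0, 100] %", call. = FALSE)
  saturation_vapor_pressure(t) * (1 - rh / 100)
}

#' Psychrometric constant
#'
#' Thermodynamic psychrometric constant in mole-fraction units,
#' 6.66e-4 C^-1 at 101.3 kPa, scaled linearly with pressure.
#'
#' @param pressure Atmospheric pressure (kPa).
#' @return gamma (per degree C).
#' @export
psychrometric_constant <- function(pressure = P_STANDARD) {
  if (any(pressure <= 0)) stop("pressure must be positive", call. = FALSE)
  GAMMA_101 * pressure / P_STANDARD
}
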