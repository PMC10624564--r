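#' Default inert-gas registry
#'
#' Returns the registry of inert gases used throughout the package: nitrous
#' oxide (the "first" gas, whose large-volume washout drives the second gas
#' effect) and thirteen trace "second" gases spanning the clinically relevant
#' solubility spectrum from sulfur hexafluoride (\eqn{\lambda} = 0.0076) to
#' methoxyflurane (\eqn{\lambda} = 13).
#'
#' @details
#' `lambda` is the Ostwald blood/gas partition coefficient: the equilibrium
#' ratio of gas content per unit blood volume to the dry-gas fraction, assuming
#' a linear dissociation curve. Values for sulfur hexafluoride (0.0076),
#' nitrous oxide (0.47), sevoflurane (0.59), halothane (2.3), diethyl ether
#' (12) and methoxyflurane (13) are the model's canonical values; the
#' remaining gases carry standard literature Ostwald coefficients chosen to
#' preserve the solubility ordering of the series (nitrogen 0.0147, ethylene
#' 0.089, xenon 0.115, desflurane 0.42, isoflurane 1.4, enflurane 1.9,
#' trichloroethylene 9.0, chloroform 10.3). All are overridable through the
#' configuration interface (see [load_config()]).
#'
#' @return A `data.frame` with columns `name` (unique identifier), `lambda`
#'   (blood/gas partition coefficient, dimensionless, > 0) and `role`
#'   (`"first"` for nitrous oxide, `"second"` otherwise), ordered by
#'   increasing `lambda`.
#' @seealso [default_second_gases()], [gas_lambda()]
#' @export
#' @examples
#' reg <- default_gases()
#' gas_lambda("sevoflurane", reg)
default_gases <- function() {
  reg <- data.frame(
    name = c(
      "sulfur hexafluoride", "nitrogen", "ethylene", "xenon", "desflurane",
      "N2O", "sevoflurane", "isoflurane", "enflurane", "halothane",
      "trichloroethylene", "chloroform", "diethyl ether", "methoxyflurane"
    ),
    lambda = c(
      0.0076, 0.0147, 0.089, 0.115, 0.42,
      0.47, 0.59, 1.4, 1.9, 2.3,
      9.0, 10.3, 12, 13
    ),
    role = c(
      "second", "second", "second", "second", "second",
      "first", "second", "second", "second", "second",
      "second", "second", "second", "second"
    ),
    stringsAsFactors = FALSE
  )
  validate_gas_registry(reg)
  reg
}

#' Default second-gas series
#'
#' The thirteen trace gases of the solubility series, i.e. [default_gases()]
#' without nitrous oxide, ordered by increasing blood/gas partition
#' coefficient.
#'
#' @return A `data.frame` with columns `name`, `lambda`, `role`.
#' @export
default_second_gases <- function() {
  reg <- default_gases()
  reg[reg$role == "second", , drop = FALSE]
}

#' Look up a blood/gas partition coefficient by gas name
#'
#' @param name Gas name (exact match against the registry `name` column).
#' @param registry A gas registry, by default [default_gases()].
#' @return The scalar blood/gas partition coefficient \eqn{\lambda}.
#' @export
gas_lambda <- function(name, registry = default_gases()) {
  i <- match(name, registry$name)
  if (is.na(i)) {
    stop("unknown gas: '", name, "'", call. = FALSE)
  }
  registry$lambda[i]
}

validate_gas_registry <- function(registry) {
  stopifnot(
    is.data.frame(registry),
    all(c("name", "lambda") %in% names(registry))
  )
  if (anyDuplicated(registry$name)) {
    stop("gas names must be unique within a registry", call. = FALSE)
  }
  if (any(!is.finite(registry$lambda)) || any(registry$lambda <= 0)) {
    stop("all partition coefficients must be finite and > 0", call. = FALSE)
  }
  invisible(registry)
}

#' Pressure constants for fraction/partial-pressure conversion
#'
#' Barometric pressure and saturated water vapor pressure at body temperature
#' (37 degrees C), used only to convert between partial pressures and dry-gas
#' fractions. All core computations work in dry-gas fractions, so these
#' constants never enter the exchange model itself.
#'
#' @param PB Barometric pressure, mmHg. Default 760 (sea level).
#' @param PH2O Saturated water vapor pressure at 37 degrees C, mmHg. Default 47.
#' @return A list with elements `PB` and `PH2O`.
#' @export
pressure_constants <- function(PB = 760, PH2O = 47) {
  if (!(is.numeric(PB) && is.numeric(PH2O) && PB > PH2O && PH2O > 0)) {
    stop("require PB > PH2O > 0", call. = FALSE)
  }
  list(PB = PB, PH2O = PH2O)
}

#' Convert a partial pressure to a dry-gas fraction
#'
#' The dry-gas fraction of a gas at partial pressure `P` is
#' `P / (PB - PH2O)`.
#'
#' @param P Partial pressure, mmHg; must lie in `[0, PB - PH2O]`.
#' @param constants A [pressure_constants()] list.
#' @return Dry-gas fraction in `[0, 1]`. Vectorized over `P`.
#' @export
#' @examples
#' fraction_from_partial_pressure(356.5) # 0.5 at default constants
fraction_from_partial_pressure <- function(P, constants = pressure_constants()) {
  dry <- constants$PB - constants$PH2O
  if (any(!is.finite(P)) || any(P < 0) || any(P > dry)) {
    stop("partial pressure must lie in [0, PB - PH2O]", call. = FALSE)
  }
  P / dry
}

#' Convert a dry-gas fraction to a partial pressure
#'
#' Inverse of [fraction_from_partial_pressure()].
#'
#' @param Fr Dry-gas fraction in `[0, 1]`.
#' @param constants A [pressure_constants()] list.
#' @return Partial pressure in mmHg. Vectorized over `Fr`.
#' @export
partial_pressure_from_fraction <- function(Fr, constants = pressure_constants()) {
  if (any(!is.finite(Fr)) || any(Fr < 0) || any(Fr > 1)) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  Fr * (constants$PB - constants$PH2O)
}
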