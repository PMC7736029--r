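# Moist-air property calculations. All internal units are SI: kelvin, Pa,
# kg, s. Celsius and percent belong at I/O boundaries only.

#' Thermophysical constants of a dry-gas / water-vapor pair
#'
#' Bundles the gas-phase constants used by the dryer energy balance. The
#' defaults describe dry air and water vapor near ambient conditions.
#'
#' @param dry_gas_heat_capacity Specific heat of the dry gas, J/(kg K).
#' @param vapor_heat_capacity Specific heat of the vapor, J/(kg K).
#' @param latent_heat_vaporization Latent heat of vaporization of the
#'   solvent, J/kg. The default is water near 40 degC.
#' @param molar_mass_ratio Molar mass of the vapor over that of the dry
#'   gas (0.622 for water in air).
#' @return An object of class `gas_properties`.
#' @export
gas_properties <- function(dry_gas_heat_capacity = 1006,
                           vapor_heat_capacity = 1860,
                           latent_heat_vaporization = 2.40e6,
                           molar_mass_ratio = 0.622) {
  vals <- c(dry_gas_heat_capacity, vapor_heat_capacity,
            latent_heat_vaporization, molar_mass_ratio)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all gas properties must be finite and strictly positive")
  if (abs(molar_mass_ratio - 0.622) > 0.05)
    warning("molar_mass_ratio far from 0.622; not a water/air pair?")
  structure(list(dry_gas_heat_capacity = dry_gas_heat_capacity,
                 vapor_heat_capacity = vapor_heat_capacity,
                 latent_heat_vaporization = latent_heat_vaporization,
                 molar_mass_ratio = molar_mass_ratio),
            class = "gas_properties")
}

#' Saturation vapor pressure of water
#'
#' Magnus-type (Buck) correlation over liquid water,
#' `p_sat = 611.21 exp((18.678 - t/234.5) t / (257.14 + t))` with `t` in
#' degrees Celsius. Accurate to well under 1% between 0 and 100 degC
#' (611 Pa at the triple point, 101.3 kPa at normal boiling); steam
#' tables are used only as a test oracle, never at run time.
#'
#' @param temperature Dry-bulb temperature, K. Valid range (173, 473) K.
#' @return Saturation pressure, Pa.
#' @export
saturation_vapor_pressure <- function(temperature) {
  if (any(!is.finite(temperature)) ||
      any(temperature <= 173) || any(temperature >= 473))
    stop("temperature outside the valid range (173 K, 473 K)")
  tc <- temperature - 273.15
  611.21 * exp((18.678 - tc / 234.5) * tc / (257.14 + tc))
}

#' Specific humidity from relative humidity
#'
#' `Y = ratio * p_v / (p - p_v)` with `p_v = RH * p_sat(T)`: mass of
#' water vapor per mass of dry gas.
#'
#' @param temperature Dry-bulb temperature, K.
#' @param relative_humidity Fraction in \[0, 1\].
#' @param total_pressure Total pressure, Pa.
#' @param gas A [gas_properties()] object (for the molar-mass ratio).
#' @return Specific humidity, kg water per kg dry gas.
#' @export
specific_humidity_from_rh <- function(temperature, relative_humidity,
                                      total_pressure = 101325,
                                      gas = gas_properties()) {
  if (any(relative_humidity < 0) || any(relative_humidity > 1))
    stop("relative_humidity must lie in [0, 1]")
  if (any(total_pressure <= 0)) stop("total_pressure must be positive")
  pv <- relative_humidity * saturation_vapor_pressure(temperature)
  if (any(pv >= total_pressure))
    stop("vapor partial pressure reaches total pressure: infeasible state")
  gas$molar_mass_ratio * pv / (total_pressure - pv)
}

#' Relative humidity from specific humidity
#'
#' Exact algebraic inverse of [specific_humidity_from_rh()]. The result
#' may exceed 1 for supersaturated states; it is reported as-is (with a
#' `"supersaturated"` attribute), never clipped, because condensation in
#' the cyclone is a failure mode worth detecting.
#'
#' @inheritParams specific_humidity_from_rh
#' @param specific_humidity kg water vapor per kg dry gas, >= 0.
#' @return Relative humidity as a fraction; attribute `supersaturated`
#'   is `TRUE` where the value exceeds 1.
#' @export
rh_from_specific_humidity <- function(temperature, specific_humidity,
                                      total_pressure = 101325,
                                      gas = gas_properties()) {
  if (any(specific_humidity < 0)) stop("specific_humidity must be >= 0")
  r <- gas$molar_mass_ratio
  pv <- total_pressure * specific_humidity / (r + specific_humidity)
  rh <- pv / saturation_vapor_pressure(temperature)
  attr(rh, "supersaturated") <- rh > 1
  rh
}

#' One point on the psychrometric chart
#'
#' A moist-air state: dry-bulb temperature, specific humidity, total
#' pressure and the derived relative humidity. Exactly one of
#' `specific_humidity` and `relative_humidity` must be given; the other
#' is derived. Supersaturated states (RH > 1) are allowed and flagged.
#'
#' @param dry_bulb_temperature K.
#' @param specific_humidity kg water vapor / kg dry gas.
#' @param relative_humidity fraction.
#' @param total_pressure Pa.
#' @param gas A [gas_properties()] object.
#' @return An object of class `moist_air_state` with fields
#'   `dry_bulb_temperature`, `specific_humidity`, `total_pressure`,
#'   `relative_humidity`, `supersaturated`.
#' @export
moist_air_state <- function(dry_bulb_temperature,
                            specific_humidity = NULL,
                            relative_humidity = NULL,
                            total_pressure = 101325,
                            gas = gas_properties()) {
  if (is.null(specific_humidity) == is.null(relative_humidity))
    stop("give exactly one of specific_humidity and relative_humidity")
  if (total_pressure <= 0) stop("total_pressure must be positive")
  if (is.null(specific_humidity)) {
    specific_humidity <- specific_humidity_from_rh(
      dry_bulb_temperature, relative_humidity, total_pressure, gas)
  }
  if (specific_humidity < 0) stop("specific_humidity must be >= 0")
  rh <- rh_from_specific_humidity(dry_bulb_temperature, specific_humidity,
                                  total_pressure, gas)
  structure(list(dry_bulb_temperature = dry_bulb_temperature,
                 specific_humidity = specific_humidity,
                 total_pressure = total_pressure,
                 relative_humidity = as.numeric(rh),
                 supersaturated = as.logical(attr(rh, "supersaturated"))),
            class = "moist_air_state")
}

#' @export
print.moist_air_state <- function(x, ...) {
  cat(sprintf(
    "moist air: T_db = %.2f K (%.2f degC), Y = %.5f kg/kg, RH = %.1f%%%s, p = %.0f Pa\n",
    x$dry_bulb_temperature, x$dry_bulb_temperature - 273.15,
    x$specific_humidity, 100 * x$relative_humidity,
    if (isTRUE(x$supersaturated)) " [SUPERSATURATED]" else "",
    x$total_pressure))
  invisible(x)
}

#' Humidity pickup of a gas stream absorbing evaporated water
#'
#' Water mass balance over a drying section:
#' `Y_out = Y_in + m_evap / m_dry_gas`. Temperature is left unchanged;
#' the associated temperature drop is handled by
#' [evaporative_cooling()].
#'
#' @param inlet A [moist_air_state()].
#' @param water_evaporation_rate kg water / s, >= 0.
#' @param dry_gas_mass_flow kg dry gas / s, > 0.
#' @return The outlet `moist_air_state`.
#' @export
humidity_gain <- function(inlet, water_evaporation_rate, dry_gas_mass_flow) {
  stopifnot(inherits(inlet, "moist_air_state"))
  if (dry_gas_mass_flow <= 0) stop("dry_gas_mass_flow must be positive")
  if (water_evaporation_rate < 0) stop("water_evaporation_rate must be >= 0")
  moist_air_state(
    dry_bulb_temperature = inlet$dry_bulb_temperature,
    specific_humidity = inlet$specific_humidity +
      water_evaporation_rate / dry_gas_mass_flow,
    total_pressure = inlet$total_pressure)
}

#' Temperature drop from evaporative cooling
#'
#' Energy balance over a section where all latent heat is drawn from the
#' gas: `dT = m_evap * h_vap / (m_gas * cp_humid)` with the humid heat
#' capacity `cp_humid = cp_dry + Y_in * cp_vapor` evaluated at the inlet
#' humidity (the inlet-vs-mean difference is below sensor noise at
#' typical dryer humidities).
#'
#' @inheritParams humidity_gain
#' @param gas A [gas_properties()] object.
#' @return Temperature drop, K (>= 0).
#' @export
evaporative_cooling <- function(inlet, gas, water_evaporation_rate,
                                dry_gas_mass_flow) {
  stopifnot(inherits(inlet, "moist_air_state"),
            inherits(gas, "gas_properties"))
  if (dry_gas_mass_flow <= 0) stop("dry_gas_mass_flow must be positive")
  if (water_evaporation_rate < 0) stop("water_evaporation_rate must be >= 0")
  cp_humid <- gas$dry_gas_heat_capacity +
    inlet$specific_humidity * gas$vapor_heat_capacity
  water_evaporation_rate * gas$latent_heat_vaporization /
    (dry_gas_mass_flow * cp_humid)
}
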