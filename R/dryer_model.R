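# Station-by-station model of an open-loop lab spray dryer (B-290 style),
# the exhaust-humidity response surface, operation limit band, cyclone
# cut-off and yield accounting.
#
# Station ids follow the instrument layout: P1 ambient intake, P3 heated
# inlet / nozzle, P4 drying column after atomisation, P5 column outlet,
# P7 product collection, P9 exhaust after the fine-particle filter.

#' Dryer configuration
#'
#' @param dry_gas_mass_flow Dry-gas mass flow, kg/s.
#' @param inlet_set_temperature Inlet (drying) temperature set point, K.
#' @param feed_rate Liquid feed rate, m^3/s.
#' @param feed_water_fraction Water mass fraction of the feed in \[0, 1\].
#' @param feed_solids_concentration Solute concentration of the feed,
#'   kg/m^3.
#' @param feed_density Feed density, kg/m^3.
#' @param heat_loss_p4_p5,heat_loss_p5_p9 Lumped wall heat-loss
#'   coefficients for the drying-column and cyclone/filter segments,
#'   W/K. The loss is only quantifiable empirically; calibrate from
#'   dry-air data.
#' @param ambient_state Ambient air as a [moist_air_state()].
#' @param gas A [gas_properties()] object.
#' @return An object of class `dryer_config`.
#' @export
dryer_config <- function(dry_gas_mass_flow,
                         inlet_set_temperature,
                         feed_rate,
                         feed_water_fraction = 1,
                         feed_solids_concentration = 0,
                         feed_density = 1000,
                         heat_loss_p4_p5 = 0,
                         heat_loss_p5_p9 = 0,
                         ambient_state = moist_air_state(298.15,
                                                         relative_humidity = 0.4),
                         gas = gas_properties()) {
  stopifnot(inherits(ambient_state, "moist_air_state"),
            inherits(gas, "gas_properties"))
  if (dry_gas_mass_flow <= 0) stop("dry_gas_mass_flow must be positive")
  if (feed_rate < 0 || feed_solids_concentration < 0 || feed_density <= 0)
    stop("flows, concentrations and densities must be non-negative")
  if (feed_water_fraction < 0 || feed_water_fraction > 1)
    stop("feed_water_fraction must lie in [0, 1]")
  if (heat_loss_p4_p5 < 0 || heat_loss_p5_p9 < 0)
    stop("heat-loss coefficients must be >= 0")
  structure(list(dry_gas_mass_flow = dry_gas_mass_flow,
                 inlet_set_temperature = inlet_set_temperature,
                 feed_rate = feed_rate,
                 feed_water_fraction = feed_water_fraction,
                 feed_solids_concentration = feed_solids_concentration,
                 feed_density = feed_density,
                 heat_loss_p4_p5 = heat_loss_p4_p5,
                 heat_loss_p5_p9 = heat_loss_p5_p9,
                 ambient_state = ambient_state,
                 gas = gas),
            class = "dryer_config")
}

#' Steady-state moist-air states along the dryer
#'
#' Propagates the ambient state through the dryer: P3 is the heated
#' inlet at the set temperature with ambient humidity; P4 applies the
#' full evaporative cooling and humidity gain (solvent evaporation is
#' taken as complete close to the nozzle); P5 and P9 apply lumped wall
#' heat losses towards ambient; P7 sits midway between them. When
#' Gordon-Taylor and sorption parameters are supplied each station also
#' carries a stickiness-zone label; supersaturated stations are flagged
#' but do not stop the pipeline.
#'
#' @param config A [dryer_config()].
#' @param gt Optional [gordon_taylor_params()] for zone labels.
#' @param isotherm Optional [sorption_isotherm()] for zone labels.
#' @param offset Sticky-point offset, K.
#' @return A data frame of class `station_states` with columns
#'   `station_id`, `dry_bulb_temperature`, `specific_humidity`,
#'   `relative_humidity`, `supersaturated`, `zone`.
#' @export
station_states <- function(config, gt = NULL, isotherm = NULL, offset = 10) {
  stopifnot(inherits(config, "dryer_config"))
  amb <- config$ambient_state
  gas <- config$gas
  m_evap <- config$feed_rate * config$feed_density * config$feed_water_fraction
  mg <- config$dry_gas_mass_flow
  cp_humid <- gas$dry_gas_heat_capacity +
    amb$specific_humidity * gas$vapor_heat_capacity

  p1 <- amb
  p3 <- moist_air_state(config$inlet_set_temperature,
                        specific_humidity = amb$specific_humidity,
                        total_pressure = amb$total_pressure)
  dt_evap <- evaporative_cooling(p3, gas, m_evap, mg)
  p4 <- moist_air_state(p3$dry_bulb_temperature - dt_evap,
                        specific_humidity = p3$specific_humidity + m_evap / mg,
                        total_pressure = amb$total_pressure)
  wall_drop <- function(t_in, ua) ua * (t_in - amb$dry_bulb_temperature) /
    (mg * cp_humid)
  t5 <- p4$dry_bulb_temperature - wall_drop(p4$dry_bulb_temperature,
                                            config$heat_loss_p4_p5)
  p5 <- moist_air_state(t5, specific_humidity = p4$specific_humidity,
                        total_pressure = amb$total_pressure)
  t9 <- t5 - wall_drop(t5, config$heat_loss_p5_p9)
  p9 <- moist_air_state(t9, specific_humidity = p5$specific_humidity,
                        total_pressure = amb$total_pressure)
  p7 <- moist_air_state((t5 + t9) / 2,
                        specific_humidity = p5$specific_humidity,
                        total_pressure = amb$total_pressure)

  sts <- list(P1 = p1, P3 = p3, P4 = p4, P5 = p5, P7 = p7, P9 = p9)
  zone <- vapply(sts, function(s) {
    if (is.null(gt) || is.null(isotherm) || isTRUE(s$supersaturated))
      return(NA_character_)
    as.character(classify_zone(s, gt, isotherm, offset))
  }, character(1))
  out <- data.frame(
    station_id = names(sts),
    dry_bulb_temperature = vapply(sts, `[[`, 0, "dry_bulb_temperature"),
    specific_humidity = vapply(sts, `[[`, 0, "specific_humidity"),
    relative_humidity = vapply(sts, `[[`, 0, "relative_humidity"),
    supersaturated = vapply(sts, `[[`, TRUE, "supersaturated"),
    zone = zone,
    row.names = NULL)
  class(out) <- c("station_states", "data.frame")
  out
}

#' Quadratic response surface of exhaust relative humidity
#'
#' Ordinary least squares of exhaust RH on the full quadratic in feed
#' rate and inlet temperature, using only the runs that passed (stable
#' drying); failed runs are stored for the operation limit band.
#'
#' @param steady_points Data frame with columns `feed_rate`,
#'   `inlet_temperature`, `rh` (fractions) and logical `passed`.
#' @return An object of class `rh_response_surface` with the
#'   coefficients, fitted model, and the excluded (failed) points.
#' @export
fit_rh_response_surface <- function(steady_points) {
  need <- c("feed_rate", "inlet_temperature", "rh", "passed")
  if (!all(need %in% names(steady_points)))
    stop("steady_points needs columns: ", paste(need, collapse = ", "))
  ok <- steady_points[steady_points$passed, , drop = FALSE]
  if (nrow(ok) < 6)
    stop("at least 6 passed points are required for the quadratic fit")
  fit <- stats::lm(rh ~ feed_rate + inlet_temperature +
                     I(feed_rate^2) + I(inlet_temperature^2) +
                     I(feed_rate * inlet_temperature), data = ok)
  if (any(is.na(stats::coef(fit))))
    stop("design is rank deficient: passed points are collinear")
  structure(list(coefficients = stats::coef(fit),
                 model = fit,
                 training = ok,
                 excluded_points = steady_points[!steady_points$passed, ,
                                                 drop = FALSE],
                 sigma = summary(fit)$sigma),
            class = "rh_response_surface")
}

#' Predict exhaust RH from a fitted response surface
#'
#' @param object An `rh_response_surface`.
#' @param feed_rate,inlet_temperature New conditions.
#' @param ... Unused.
#' @return Predicted exhaust relative humidity (fraction).
#' @export
predict.rh_response_surface <- function(object, feed_rate,
                                        inlet_temperature, ...) {
  nd <- data.frame(feed_rate = feed_rate,
                   inlet_temperature = inlet_temperature)
  unname(stats::predict(object$model, newdata = nd))
}

#' Operation limit band from passed and failed runs
#'
#' The feasible-operation transition band is bracketed by the highest
#' exhaust RH observed among passed runs and the lowest among failed
#' runs. If the classes overlap (a failed run drier than a passed one)
#' the band is still returned, with a warning.
#'
#' @param surface An `rh_response_surface` (or a data frame with `rh`
#'   and `passed` columns).
#' @return Named numeric `c(rh_low, rh_high)`, in the units of the
#'   supplied RH values.
#' @export
operation_limit_band <- function(surface) {
  pts <- if (inherits(surface, "rh_response_surface"))
    rbind(surface$training[c("rh", "passed")],
          surface$excluded_points[c("rh", "passed")])
  else surface[c("rh", "passed")]
  passed <- pts$rh[pts$passed]
  failed <- pts$rh[!pts$passed]
  if (length(passed) == 0 || length(failed) == 0)
    stop("need at least one passed and one failed run")
  rh_low <- max(passed)
  rh_high <- min(failed)
  if (rh_low > rh_high)
    warning(sprintf("passed/failed RH ranges overlap (max passed %.4g > min failed %.4g)",
                    rh_low, rh_high))
  c(rh_low = rh_low, rh_high = rh_high)
}

#' Cyclone geometry and operating conditions
#'
#' @param inlet_width,inlet_height Rectangular inlet dimensions, m.
#' @param body_diameter Cyclone body diameter, m.
#' @param vortex_finder_diameter Gas outlet tube diameter, m.
#' @param vortex_length Effective length of the inner vortex, m.
#' @param gas_volumetric_flow m^3/s.
#' @param gas_viscosity Pa s.
#' @param particle_density,gas_density kg/m^3.
#' @return An object of class `cyclone_config`.
#' @export
cyclone_config <- function(inlet_width, inlet_height, body_diameter,
                           vortex_finder_diameter, vortex_length,
                           gas_volumetric_flow,
                           gas_viscosity = 1.85e-5,
                           particle_density = 1500,
                           gas_density = 1.2) {
  vals <- c(inlet_width, inlet_height, body_diameter,
            vortex_finder_diameter, vortex_length, gas_volumetric_flow,
            gas_viscosity, particle_density, gas_density)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all cyclone parameters must be finite and positive")
  if (particle_density <= gas_density)
    stop("particle_density must exceed gas_density")
  if (inlet_width >= body_diameter / 2)
    stop("inlet_width must be smaller than the body radius")
  if (vortex_finder_diameter >= body_diameter)
    stop("vortex finder cannot be wider than the body")
  structure(list(inlet_width = inlet_width, inlet_height = inlet_height,
                 body_diameter = body_diameter,
                 vortex_finder_diameter = vortex_finder_diameter,
                 vortex_length = vortex_length,
                 gas_volumetric_flow = gas_volumetric_flow,
                 gas_viscosity = gas_viscosity,
                 particle_density = particle_density,
                 gas_density = gas_density),
            class = "cyclone_config")
}

#' Cyclone cut-off size (d50) by the Barth equilibrium-orbit model
#'
#' Balances Stokes centrifugal settling against the inward radial drift
#' at the edge of the inner vortex: the tangential velocity there is
#' obtained from the inlet velocity by friction-free angular-momentum
#' conservation, `u_i = u_e r_e / r_i` with `r_e = (D - b)/2`, the
#' radial velocity is `v_r = Q / (2 pi r_i h_i)`, and
#' `d50 = sqrt(18 mu v_r r_i / ((rho_p - rho_g) u_i^2))`.
#' The cut size scales as `Q^(-1/2)` and `(rho_p - rho_g)^(-1/2)`.
#'
#' @param config A [cyclone_config()].
#' @return Cut-off diameter, m.
#' @export
cyclone_cutoff <- function(config) {
  stopifnot(inherits(config, "cyclone_config"))
  q <- config$gas_volumetric_flow
  r_i <- config$vortex_finder_diameter / 2
  r_e <- (config$body_diameter - config$inlet_width) / 2
  u_e <- q / (config$inlet_width * config$inlet_height)
  u_i <- u_e * r_e / r_i
  v_r <- q / (2 * pi * r_i * config$vortex_length)
  drho <- config$particle_density - config$gas_density
  sqrt(18 * config$gas_viscosity * v_r * r_i / (drho * u_i^2))
}

#' Moisture-compensated process yield
#'
#' `yield = product_mass (1 - rm180) / (concentration volume)`: the
#' recovered dry solute mass over the solute mass sprayed, with the
#' product mass corrected for its residual moisture at 180 degC.
#'
#' @param product_mass Collected product mass, kg.
#' @param rm180 Residual moisture at 180 degC as a mass fraction.
#' @param feed_solute_concentration kg/m^3.
#' @param feed_volume Sprayed feed volume, m^3.
#' @return Yield as a fraction. Values above 1 indicate an accounting
#'   anomaly and raise a warning (attribute `anomaly`).
#' @export
process_yield <- function(product_mass, rm180, feed_solute_concentration,
                          feed_volume) {
  if (product_mass < 0 || rm180 < 0 || rm180 > 1 ||
      feed_solute_concentration < 0)
    stop("masses and fractions must be non-negative (rm180 in [0, 1])")
  if (feed_volume <= 0 || feed_solute_concentration == 0)
    stop("feed solute mass is zero: yield undefined")
  y <- product_mass * (1 - rm180) /
    (feed_solute_concentration * feed_volume)
  if (y > 1) {
    warning("yield exceeds 100%: accounting anomaly")
    attr(y, "anomaly") <- TRUE
  }
  y
}

#' Parse a dryer sensor log into SI units
#'
#' Accepts a data frame or a CSV path with columns `time_s`,
#' `T_P3_R_C`, `T_P5_R_C`, `T_P9_R_C`, `RH_P9_R_pct`, `p_P9_R_Pa`,
#' `FR_P11_R_mL_min` and optional `phase`. Temperatures are converted
#' to kelvin, RH to a fraction and the feed rate to m^3/s.
#'
#' @param x Data frame or path to a CSV file (header required, UTF-8,
#'   decimal point).
#' @return A data frame of class `sensor_log` with columns `time_s`,
#'   `t_p3`, `t_p5`, `t_p9`, `rh_p9`, `p_p9`, `feed_rate` and `phase`
#'   (factor or NA).
#' @export
parse_sensor_log <- function(x) {
  if (is.character(x)) x <- utils::read.csv(x, stringsAsFactors = FALSE)
  need <- c("time_s", "T_P3_R_C", "T_P5_R_C", "T_P9_R_C",
            "RH_P9_R_pct", "p_P9_R_Pa", "FR_P11_R_mL_min")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("sensor log is missing channel(s): ", paste(miss, collapse = ", "))
  if (is.unsorted(x$time_s, strictly = TRUE))
    stop("time_s must be strictly increasing")
  out <- data.frame(
    time_s = x$time_s,
    t_p3 = x$T_P3_R_C + 273.15,
    t_p5 = x$T_P5_R_C + 273.15,
    t_p9 = x$T_P9_R_C + 273.15,
    rh_p9 = x$RH_P9_R_pct / 100,
    p_p9 = x$p_P9_R_Pa,
    feed_rate = x$FR_P11_R_mL_min * 1e-6 / 60,
    phase = if ("phase" %in% names(x))
      factor(x$phase, levels = c("DAP", "PSP", "PrP", "S"))
    else factor(rep(NA_character_, nrow(x)),
                levels = c("DAP", "PSP", "PrP", "S")))
  class(out) <- c("sensor_log", "data.frame")
  out
}

#' Segment a sensor log into process phases
#'
#' Phases follow the standard run structure: a dry-air phase (DAP), a
#' pure-solvent phase (PSP), the production phase (PrP) and shut-down
#' (S). The feed channel is the only automatic discriminator: DAP ends
#' at the first sustained non-zero feed and shut-down starts when the
#' feed is sustainedly off again. No sensor distinguishes solvent from
#' solution, so the PSP to PrP switch is taken from the log's `phase`
#' column when present, else from `solution_switch_time`.
#'
#' @param log A `sensor_log`.
#' @param feed_threshold Feed rate (m^3/s) above which the pump counts
#'   as running. Default: 5% of the maximum feed rate.
#' @param persistence Number of consecutive samples a change must hold.
#' @param solution_switch_time Operator-supplied PSP to PrP switch time,
#'   s (ignored if the log has a `phase` column).
#' @return A list with `phase` (factor per sample) and `boundaries`
#'   (named numeric of phase start times).
#' @export
segment_phases <- function(log, feed_threshold = NULL, persistence = 5,
                           solution_switch_time = NULL) {
  stopifnot(inherits(log, "sensor_log"))
  n <- nrow(log)
  if (all(!is.na(log$phase))) {
    ph <- log$phase
  } else {
    if (is.null(feed_threshold))
      feed_threshold <- 0.05 * max(log$feed_rate)
    on <- log$feed_rate > feed_threshold
    sustained <- function(flag) {
      r <- rle(flag)
      ends <- cumsum(r$lengths)
      idx <- which(r$values & r$lengths >= persistence)
      if (!length(idx)) return(NA_integer_)
      ends[idx[1]] - r$lengths[idx[1]] + 1L
    }
    i_feed_on <- sustained(on)
    if (is.na(i_feed_on)) stop("no sustained feed detected: cannot segment")
    after_on <- rep(FALSE, n)
    after_on[seq_len(n) > i_feed_on] <- TRUE
    i_feed_off <- sustained(!on & after_on)
    ph <- factor(rep("DAP", n), levels = c("DAP", "PSP", "PrP", "S"))
    ph[seq_len(n) >= i_feed_on] <- "PSP"
    if (!is.null(solution_switch_time))
      ph[log$time_s >= solution_switch_time & as.integer(ph) >= 2] <- "PrP"
    if (!is.na(i_feed_off)) ph[seq_len(n) >= i_feed_off] <- "S"
  }
  idx <- which(diff(as.integer(ph)) != 0) + 1L
  b <- c(log$time_s[1], log$time_s[idx])
  names(b) <- as.character(ph[c(1L, idx)])
  list(phase = ph, boundaries = b)
}

#' Steady-state statistics of a phase window
#'
#' Means and standard deviations of every channel over the trailing
#' window of a phase, plus a stationarity check: the window counts as
#' steady when sd(RH) < 1 %RH and every temperature sd < 1 K.
#'
#' @param log A `sensor_log`.
#' @param phase One of `"DAP"`, `"PSP"`, `"PrP"`, `"S"`.
#' @param window Window length, s (default 300, a rolling 5 min).
#' @param phases Optional result of [segment_phases()]; computed from
#'   the log's own phase column otherwise.
#' @param rh_sd_max,t_sd_max Stationarity thresholds (fraction RH, K).
#' @return A data frame with one row per channel: `mean`, `sd`, and a
#'   `stationary` attribute for the whole window.
#' @export
steady_state_extract <- function(log, phase, window = 300, phases = NULL,
                                 rh_sd_max = 0.01, t_sd_max = 1) {
  stopifnot(inherits(log, "sensor_log"))
  ph <- if (is.null(phases)) log$phase else phases$phase
  sel <- which(ph == phase)
  if (!length(sel)) stop("phase not present in log: ", phase)
  t_end <- log$time_s[max(sel)]
  sel <- sel[log$time_s[sel] > t_end - window]
  if (length(sel) < 2) stop("fewer than 2 samples in the steady window")
  ch <- c("t_p3", "t_p5", "t_p9", "rh_p9", "p_p9", "feed_rate")
  m <- vapply(ch, function(k) mean(log[[k]][sel]), 0)
  s <- vapply(ch, function(k) stats::sd(log[[k]][sel]), 0)
  out <- data.frame(channel = ch, mean = unname(m), sd = unname(s))
  stationary <- s[["rh_p9"]] < rh_sd_max &&
    all(s[c("t_p3", "t_p5", "t_p9")] < t_sd_max)
  attr(out, "stationary") <- stationary
  attr(out, "n") <- length(sel)
  out
}

#' Trans-filter pressure drift check
#'
#' Fines accumulating in the outlet filter raise its flow resistance
#' and shift the exhaust pressure. Computes
#' `dp(t) = p(0) - p(t)` against the baseline-window mean and reports
#' the maximum relative change with a pass/fail against a threshold
#' (default 5%).
#'
#' @param log A `sensor_log`.
#' @param baseline_window Length of the initial baseline window, s.
#' @param threshold Maximum tolerated relative pressure change.
#' @return A list with `max_relative_change`, `pass`, `baseline`.
#' @export
filter_pressure_check <- function(log, baseline_window = 60,
                                  threshold = 0.05) {
  stopifnot(inherits(log, "sensor_log"))
  base_sel <- log$time_s <= log$time_s[1] + baseline_window
  if (!any(base_sel)) stop("empty baseline window")
  p0 <- mean(log$p_p9[base_sel])
  rel <- abs(p0 - log$p_p9) / p0
  list(max_relative_change = max(rel), pass = max(rel) < threshold,
       baseline = p0)
}
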