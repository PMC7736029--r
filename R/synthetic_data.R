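# Seeded generators for every input the pipeline consumes, so the full
# analysis chain is testable without any instrument data.
#
# Seeding: one top-level seed fans out to per-generator substreams via
# a fixed counter per generator (droplet = 1, process log = 2, TGA = 3,
# PSD = 4, sorption = 5), so adding a generator never perturbs the
# fixtures of another. All generators restore the caller's RNG state.

.substream_seed <- function(seed, counter) {
  (abs(as.integer(seed)) %% 1000003L) * 2011L + counter * 7919L
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  expr
}

#' Generate a synthetic levitated-droplet drying series
#'
#' The squared volume-equivalent diameter shrinks linearly at rate
#' `kappa` (d2-law) until the lock point, and is constant after it.
#' Ellipse axes follow from the volume and a fixed aspect ratio
#' (`major/minor`); optional multiplicative Gaussian noise emulates the
#' optical axis measurement.
#'
#' @param d0 Initial volume-equivalent diameter, m.
#' @param kappa Evaporation rate, m^2/s.
#' @param lock_time Lock point time, s (> 0; the droplet must not fully
#'   evaporate before it).
#' @param aspect_ratio Major over minor axis (>= 1).
#' @param noise_sigma Relative axis noise standard deviation.
#' @param sampling_rate Frames per second.
#' @param duration Total duration, s (default 1.5 x `lock_time`).
#' @param solute_concentration Initial solute concentration, kg/m^3.
#' @param seed Integer seed.
#' @return A [droplet_series()].
#' @export
gen_droplet_series <- function(d0 = 2e-3, kappa = 4.5e-9, lock_time = 400,
                               aspect_ratio = 1.2, noise_sigma = 0,
                               sampling_rate = 1, duration = NULL,
                               solute_concentration = 30, seed = 1) {
  if (lock_time <= 0) stop("lock_time must be positive")
  if (d0 <= 0 || kappa <= 0) stop("d0 and kappa must be positive")
  if (aspect_ratio < 1) stop("aspect_ratio must be >= 1")
  if (d0^2 - kappa * lock_time <= 0)
    stop("droplet fully evaporates before the lock point")
  if (is.null(duration)) duration <- 1.5 * lock_time
  tt <- seq(0, duration, by = 1 / sampling_rate)
  d2 <- pmax(d0^2 - kappa * pmin(tt, lock_time), 0)
  d <- sqrt(d2)
  major <- d * aspect_ratio^(1 / 3)
  minor <- d * aspect_ratio^(-2 / 3)
  if (noise_sigma > 0) {
    .with_seed(.substream_seed(seed, 1L), {
      major <- major * (1 + stats::rnorm(length(tt), 0, noise_sigma))
      minor <- minor * (1 + stats::rnorm(length(tt), 0, noise_sigma))
    })
    swap <- minor > major
    tmp <- major[swap]; major[swap] <- minor[swap]; minor[swap] <- tmp
  }
  droplet_series(tt, major, minor, solute_concentration)
}

#' Generate a synthetic dryer sensor log
#'
#' Builds channel trajectories for the standard run structure (dry-air,
#' pure-solvent, production and shut-down phases) from the
#' station-state model evaluated per phase, connects the phase
#' set-point changes with first-order lag transitions, and adds
#' Gaussian sensor noise. The true phase boundaries are attached as an
#' attribute for recovery tests.
#'
#' @param config A [dryer_config()] describing the production phase.
#' @param phase_durations Named numeric, s, for DAP, PSP, PrP, S.
#' @param sensor_noise List of additive noise standard deviations:
#'   `t` (K), `rh` (fraction), `p` (Pa), `fr` (m^3/s).
#' @param lag_time First-order response time constant, s.
#' @param sample_interval Sampling interval, s.
#' @param seed Integer seed.
#' @return A `sensor_log` (see [parse_sensor_log()]) with attribute
#'   `true_boundaries` (named phase start times, s).
#' @export
gen_process_log <- function(config,
                            phase_durations = c(DAP = 600, PSP = 900,
                                                PrP = 1800, S = 300),
                            sensor_noise = list(t = 0.1, rh = 0.002,
                                                p = 15, fr = 0),
                            lag_time = 20, sample_interval = 1, seed = 1) {
  stopifnot(inherits(config, "dryer_config"))
  if (any(phase_durations <= 0)) stop("phase durations must be positive")
  amb <- config$ambient_state
  cfg_phase <- list(
    DAP = within_config(config, feed_rate = 0),
    PSP = within_config(config, feed_water_fraction = 1,
                        feed_solids_concentration = 0),
    PrP = config,
    S = within_config(config, feed_rate = 0,
                      inlet_set_temperature = amb$dry_bulb_temperature))
  target <- lapply(cfg_phase, function(cf) {
    st <- station_states(cf)
    c(t_p3 = st$dry_bulb_temperature[st$station_id == "P3"],
      t_p5 = st$dry_bulb_temperature[st$station_id == "P5"],
      t_p9 = st$dry_bulb_temperature[st$station_id == "P9"],
      rh_p9 = st$relative_humidity[st$station_id == "P9"],
      p_p9 = amb$total_pressure,
      feed_rate = cf$feed_rate)
  })
  bounds <- cumsum(c(0, unname(phase_durations)))
  tt <- seq(0, bounds[5] - sample_interval, by = sample_interval)
  phase_of <- cut(tt, breaks = bounds, labels = names(phase_durations),
                  right = FALSE, include.lowest = TRUE)
  raw <- t(vapply(as.character(phase_of), function(ph) target[[ph]],
                  numeric(6)))
  # first-order lag on the continuous channels; feed switches instantly
  alpha <- 1 - exp(-sample_interval / lag_time)
  sm <- raw
  for (i in 2:nrow(sm))
    sm[i, 1:5] <- sm[i - 1, 1:5] + alpha * (raw[i, 1:5] - sm[i - 1, 1:5])
  .with_seed(.substream_seed(seed, 2L), {
    n <- length(tt)
    sm[, 1] <- sm[, 1] + stats::rnorm(n, 0, sensor_noise$t)
    sm[, 2] <- sm[, 2] + stats::rnorm(n, 0, sensor_noise$t)
    sm[, 3] <- sm[, 3] + stats::rnorm(n, 0, sensor_noise$t)
    sm[, 4] <- pmax(sm[, 4] + stats::rnorm(n, 0, sensor_noise$rh), 0)
    sm[, 5] <- sm[, 5] + stats::rnorm(n, 0, sensor_noise$p)
    sm[, 6] <- pmax(sm[, 6] + stats::rnorm(n, 0, sensor_noise$fr), 0)
  })
  log <- parse_sensor_log(data.frame(
    time_s = tt,
    T_P3_R_C = sm[, 1] - 273.15,
    T_P5_R_C = sm[, 2] - 273.15,
    T_P9_R_C = sm[, 3] - 273.15,
    RH_P9_R_pct = sm[, 4] * 100,
    p_P9_R_Pa = sm[, 5],
    FR_P11_R_mL_min = sm[, 6] * 6e7))
  attr(log, "true_boundaries") <- stats::setNames(bounds[1:4],
                                                  names(phase_durations))
  log
}

#' Rebuild a dryer configuration with some fields replaced
#'
#' Convenience for sweeping process parameters: returns a revalidated
#' [dryer_config()] with the named fields substituted.
#'
#' @param config A [dryer_config()].
#' @param ... Named fields to replace.
#' @return A new `dryer_config`.
#' @export
within_config <- function(config, ...) {
  stopifnot(inherits(config, "dryer_config"))
  f <- unclass(config)
  repl <- list(...)
  f[names(repl)] <- repl
  do.call(dryer_config, f)
}

#' Generate a synthetic multi-step TGA curve
#'
#' Superposes sigmoidal mass-loss steps (logistic in temperature) on a
#' flat baseline: each component releases `loss_wt_pct` of the initial
#' mass around `release_temp_C` over a characteristic `width_C`. With
#' the default width, [residual_moisture_at()] recovers each cumulative
#' loss at temperatures >= 20 degC away from the steps to better than
#' 0.01 wt%.
#'
#' @param components Data frame with columns `loss_wt_pct`,
#'   `release_temp_C`, `width_C` (may have zero rows for a flat curve).
#' @param temp_range_c Start and end temperature, degC.
#' @param step_c Temperature grid step, degC.
#' @param noise_sd Additive relative-mass noise (before renormalizing
#'   the start to 1).
#' @param seed Integer seed.
#' @return A [tga_curve()] (temperatures in kelvin).
#' @export
gen_tga_curve <- function(components, temp_range_c = c(20, 200),
                          step_c = 0.5, noise_sd = 0, seed = 1) {
  stopifnot(is.data.frame(components))
  tc <- seq(temp_range_c[1], temp_range_c[2], by = step_c)
  rm <- rep(1, length(tc))
  if (nrow(components) > 0) {
    need <- c("loss_wt_pct", "release_temp_C", "width_C")
    if (!all(need %in% names(components)))
      stop("components needs columns: ", paste(need, collapse = ", "))
    if (sum(components$loss_wt_pct) >= 100)
      stop("total mass loss must stay below 100%")
    if (any(components$width_C <= 0)) stop("step widths must be positive")
    cm <- components[order(components$release_temp_C), ]
    if (nrow(cm) > 1 &&
        any(diff(cm$release_temp_C) < 2 * (cm$width_C[-nrow(cm)] +
                                           cm$width_C[-1])))
      warning("overlapping release steps: cumulative losses will blur")
    for (i in seq_len(nrow(cm)))
      rm <- rm - cm$loss_wt_pct[i] / 100 *
        stats::plogis((tc - cm$release_temp_C[i]) / cm$width_C[i])
  }
  if (noise_sd > 0)
    rm <- .with_seed(.substream_seed(seed, 3L),
                     rm + stats::rnorm(length(rm), 0, noise_sd))
  rm <- pmin(rm / rm[1], 1)
  tga_curve(tc + 273.15, rm)
}

#' Generate a lognormal-mixture volume-weighted PSD
#'
#' Bins a mixture of lognormal volume-density modes on a log-spaced
#' size grid. A single narrow mode emulates well-dispersed primary
#' particles; adding a coarse mode emulates agglomeration.
#'
#' @param modes Data frame with columns `median` (m), `geometric_sd`
#'   (> 1) and `volume_fraction` (summing to 1).
#' @param grid Size grid, m; default 200 log-spaced bins over
#'   0.1-300 um.
#' @param stage Protocol stage label passed to [psd_sample()].
#' @return A [psd_sample()].
#' @export
gen_psd <- function(modes, grid = NULL, stage = "LD0") {
  stopifnot(is.data.frame(modes))
  need <- c("median", "geometric_sd", "volume_fraction")
  if (!all(need %in% names(modes)))
    stop("modes needs columns: ", paste(need, collapse = ", "))
  if (abs(sum(modes$volume_fraction) - 1) > 1e-9)
    stop("volume fractions must sum to 1")
  if (any(modes$geometric_sd <= 1)) stop("geometric_sd must exceed 1")
  if (is.null(grid))
    grid <- exp(seq(log(1e-7), log(3e-4), length.out = 200))
  lx <- log(grid)
  k <- length(lx)
  mid <- (lx[-1] + lx[-k]) / 2
  lo <- c(2 * lx[1] - mid[1], mid)
  hi <- c(mid, 2 * lx[k] - mid[k - 1])
  dens <- rep(0, k)
  for (i in seq_len(nrow(modes)))
    dens <- dens + modes$volume_fraction[i] *
      (stats::pnorm(hi, log(modes$median[i]), log(modes$geometric_sd[i])) -
       stats::pnorm(lo, log(modes$median[i]), log(modes$geometric_sd[i])))
  psd_sample(grid, dens / sum(dens), stage = stage)
}

#' Generate a synthetic sorption dataset
#'
#' GAB equilibrium moisture on a water-activity grid with optional
#' multiplicative Gaussian noise; a stand-in for gravimetric
#' moisture-sorption measurements of an amorphous solid.
#'
#' @param isotherm A [sorption_isotherm()].
#' @param n Number of points (>= 4), on an activity grid 0.05-0.9.
#' @param noise_sigma Relative noise standard deviation.
#' @param seed Integer seed.
#' @return Data frame with columns `water_activity`, `moisture`.
#' @export
gen_sorption_dataset <- function(isotherm = default_trehalose_isotherm(),
                                 n = 15, noise_sigma = 0, seed = 1) {
  if (n < 4) stop("need at least 4 sorption points")
  aw <- seq(0.05, 0.9, length.out = n)
  x <- equilibrium_moisture(aw, isotherm)
  if (noise_sigma > 0)
    x <- .with_seed(.substream_seed(seed, 5L),
                    x * (1 + stats::rnorm(n, 0, noise_sigma)))
  data.frame(water_activity = aw, moisture = pmax(x, 0))
}
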