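# Glass-transition prediction, moisture sorption, and the stickiness-curve
# machinery of the spray-drying design space.

#' Gordon-Taylor parameters for a binary amorphous solid / water system
#'
#' @param tg_solid Glass-transition temperature of the dry solid, K.
#'   Default 389 K (amorphous trehalose).
#' @param tg_water Glass-transition temperature of water, K (136 K).
#' @param k_constant Gordon-Taylor mixing constant K > 0. The default
#'   6.04 is a fit for the trehalose-water system; published values for
#'   that pair span roughly 5.2-7.9 depending on the endpoint Tg values.
#' @return An object of class `gordon_taylor_params`.
#' @export
gordon_taylor_params <- function(tg_solid = 389, tg_water = 136,
                                 k_constant = 6.04) {
  if (!(tg_solid > tg_water)) stop("tg_solid must exceed tg_water")
  if (k_constant <= 0) stop("k_constant must be positive")
  structure(list(tg_solid = tg_solid, tg_water = tg_water,
                 k_constant = k_constant),
            class = "gordon_taylor_params")
}

#' Glass-transition temperature of a plasticized amorphous solid
#'
#' Gordon-Taylor mixing rule
#' `Tg = (w_s Tg_s + K w_w Tg_w) / (w_s + K w_w)` with `w_s = 1 - w_w`.
#' Strictly decreasing in the water mass fraction and bounded by the two
#' component values.
#'
#' @param water_mass_fraction Wet-basis water mass fraction in \[0, 1\].
#' @param params A [gordon_taylor_params()] object.
#' @return Predicted glass-transition temperature, K.
#' @export
gordon_taylor_tg <- function(water_mass_fraction,
                             params = gordon_taylor_params()) {
  stopifnot(inherits(params, "gordon_taylor_params"))
  if (any(water_mass_fraction < 0) || any(water_mass_fraction > 1))
    stop("water_mass_fraction must lie in [0, 1]")
  ws <- 1 - water_mass_fraction
  ww <- water_mass_fraction
  (ws * params$tg_solid + params$k_constant * ww * params$tg_water) /
    (ws + params$k_constant * ww)
}

#' Fit the Gordon-Taylor constant from (moisture, Tg) data
#'
#' Least-squares estimate of the mixing constant K with the two endpoint
#' glass-transition temperatures held fixed. Returns the fitted
#' parameters together with the residual sum of squares and a
#' linearized standard error for K.
#'
#' @param water_mass_fraction Wet-basis water mass fractions in (0, 1).
#' @param tg Measured glass-transition temperatures, K.
#' @param tg_solid,tg_water Fixed endpoint Tg values, K.
#' @return A `gordon_taylor_params` object with extra fields `rss`,
#'   `k_se`, `n`.
#' @export
fit_gordon_taylor <- function(water_mass_fraction, tg,
                              tg_solid = 389, tg_water = 136) {
  w <- water_mass_fraction
  if (length(w) != length(tg)) stop("input lengths differ")
  if (length(w) < 3) stop("at least 3 (moisture, Tg) pairs are required")
  if (any(w <= 0) || any(w >= 1)) stop("fractions must lie strictly in (0, 1)")
  if (diff(range(w)) < .Machine$double.eps^0.5)
    stop("degenerate data: all water fractions identical")
  rss_of <- function(k) {
    p <- gordon_taylor_params(tg_solid, tg_water, k)
    sum((tg - gordon_taylor_tg(w, p))^2)
  }
  opt <- stats::optimize(rss_of, interval = c(1e-6, 1e3), tol = 1e-12)
  k <- opt$minimum
  # delta-method SE from the analytic gradient dTg/dK
  ws <- 1 - w
  denom <- ws + k * w
  grad <- w * ws * (tg_water - tg_solid) / denom^2
  sigma2 <- opt$objective / max(length(w) - 1, 1)
  k_se <- sqrt(sigma2 / sum(grad^2))
  out <- gordon_taylor_params(tg_solid, tg_water, k)
  out$rss <- opt$objective
  out$k_se <- k_se
  out$n <- length(w)
  out
}

#' GAB moisture sorption isotherm
#'
#' Guggenheim-Anderson-de Boer model of equilibrium moisture uptake of
#' an amorphous solid versus water activity,
#' `X(a_w) = Xm C k a_w / ((1 - k a_w)(1 - k a_w + C k a_w))`,
#' on a dry basis (kg water per kg dry solid).
#'
#' @param monolayer_capacity GAB monolayer capacity Xm, kg/kg dry solid.
#' @param energy_constant_c GAB energy constant C > 0.
#' @param correction_constant_k GAB correction constant k in (0, 1.05\].
#' @param model_name Only `"GAB"` is implemented.
#' @return An object of class `sorption_isotherm`.
#' @export
sorption_isotherm <- function(monolayer_capacity, energy_constant_c,
                              correction_constant_k, model_name = "GAB") {
  model_name <- match.arg(model_name)
  if (monolayer_capacity <= 0) stop("monolayer_capacity must be positive")
  if (energy_constant_c <= 0) stop("energy_constant_c must be positive")
  if (correction_constant_k <= 0 || correction_constant_k > 1.05)
    stop("correction_constant_k must lie in (0, 1.05]")
  structure(list(model_name = model_name,
                 monolayer_capacity = monolayer_capacity,
                 energy_constant_c = energy_constant_c,
                 correction_constant_k = correction_constant_k),
            class = "sorption_isotherm")
}

#' Default GAB parameters for amorphous trehalose
#'
#' Calibration placeholders of the right order of magnitude for
#' amorphous trehalose near room temperature. They are meant to be
#' refit from user sorption data with [fit_isotherm()]; no claim of
#' instrument-grade accuracy is made.
#'
#' @return A [sorption_isotherm()] object.
#' @export
default_trehalose_isotherm <- function() {
  sorption_isotherm(monolayer_capacity = 0.062,
                    energy_constant_c = 8.0,
                    correction_constant_k = 0.95)
}

#' Equilibrium moisture content at a given water activity
#'
#' @param water_activity Fraction in \[0, 1).
#' @param isotherm A [sorption_isotherm()] object.
#' @return Dry-basis moisture, kg water / kg dry solid.
#' @export
equilibrium_moisture <- function(water_activity,
                                 isotherm = default_trehalose_isotherm()) {
  stopifnot(inherits(isotherm, "sorption_isotherm"))
  if (any(water_activity < 0) || any(water_activity >= 1))
    stop("water_activity must lie in [0, 1)")
  xm <- isotherm$monolayer_capacity
  cc <- isotherm$energy_constant_c
  k <- isotherm$correction_constant_k
  ka <- k * water_activity
  xm * cc * ka / ((1 - ka) * (1 - ka + cc * ka))
}

#' Fit a GAB isotherm to sorption data
#'
#' Initialization uses the classical quadratic transformation
#' `a_w / X = alpha + beta a_w + gamma a_w^2`, whose coefficients map
#' back to (Xm, C, k); the estimate is then refined by nonlinear least
#' squares (Levenberg-Marquardt).
#'
#' @param water_activity Water activities in \[0, 1), spanning a range of
#'   at least 0.3.
#' @param moisture Dry-basis equilibrium moisture, kg/kg.
#' @return A `sorption_isotherm` with extra fields `rss` and `n`.
#' @export
fit_isotherm <- function(water_activity, moisture) {
  aw <- water_activity
  x <- moisture
  if (length(aw) != length(x)) stop("input lengths differ")
  if (length(aw) < 4) stop("at least 4 sorption points are required")
  if (diff(range(aw)) < 0.3)
    stop("water-activity span must be at least 0.3 for a stable GAB fit")
  if (all(x <= 0)) stop("moisture values are all non-positive")
  keep <- x > 0
  qf <- stats::lm(I(aw[keep] / x[keep]) ~ aw[keep] + I(aw[keep]^2))
  cf <- stats::coef(qf)
  alpha <- cf[[1]]; beta <- cf[[2]]; gamma <- cf[[3]]
  # invert the transformation; fall back to generic starts if degenerate
  disc <- beta^2 - 4 * alpha * gamma
  if (is.finite(disc) && disc > 0 && alpha > 0) {
    k0 <- (sqrt(disc) - beta) / (2 * alpha)
    c0 <- beta / (alpha * k0) + 2
    xm0 <- 1 / (alpha * k0 * c0)
  } else {
    k0 <- 0.9; c0 <- 10; xm0 <- max(stats::median(x[keep]), 1e-3)
  }
  if (!is.finite(k0) || k0 <= 0 || k0 > 1.04) k0 <- 0.9
  if (!is.finite(c0) || c0 <= 0) c0 <- 10
  if (!is.finite(xm0) || xm0 <= 0) xm0 <- max(stats::median(x[keep]), 1e-3)
  fit <- minpack.lm::nlsLM(
    x ~ xm * cc * k * aw / ((1 - k * aw) * (1 - k * aw + cc * k * aw)),
    start = list(xm = xm0, cc = c0, k = min(k0, 1.0)),
    lower = c(1e-8, 1e-8, 1e-8), upper = c(10, 1e6, 1.05),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  out <- sorption_isotherm(est[["xm"]], est[["cc"]], est[["k"]])
  out$rss <- sum(stats::residuals(fit)^2)
  out$n <- length(aw)
  out
}

#' Convert dry-basis moisture to wet-basis mass fraction
#'
#' Sorption isotherms report kg water per kg dry solid; the
#' Gordon-Taylor rule wants the wet-basis water mass fraction
#' `w_w = X / (1 + X)`.
#'
#' @param dry_basis_moisture kg water / kg dry solid, >= 0.
#' @return Wet-basis water mass fraction.
#' @export
wet_basis_fraction <- function(dry_basis_moisture) {
  if (any(dry_basis_moisture < 0)) stop("moisture must be >= 0")
  dry_basis_moisture / (1 + dry_basis_moisture)
}

# material Tg at equilibrium with gas at given RH
.tg_at_rh <- function(rh, gt, isotherm) {
  gordon_taylor_tg(wet_basis_fraction(equilibrium_moisture(rh, isotherm)), gt)
}

#' Stickiness curve on the psychrometric chart
#'
#' For each dry-bulb temperature on a grid, finds the relative humidity
#' at which the material's plasticized glass-transition temperature
#' (via sorption equilibrium and Gordon-Taylor) plus a sticky-point
#' offset equals that temperature, and converts it to specific
#' humidity. The root is found by bisection on RH in (1e-6, 0.999)
#' (the problem is monotone, so convergence is guaranteed); grid points
#' with no root are omitted with a warning.
#'
#' @param gt A [gordon_taylor_params()] object.
#' @param isotherm A [sorption_isotherm()] object.
#' @param offset Sticky-point offset above Tg, K. Default 10 K; the
#'   sticky-point literature reports 15 +/- 5 K.
#' @param pressure Total pressure, Pa.
#' @param temperature_grid Dry-bulb temperatures, K.
#' @param tol Bisection tolerance on RH.
#' @return An object of class `stickiness_curve`: a data frame with
#'   columns `dry_bulb_temperature`, `relative_humidity`,
#'   `specific_humidity`, plus attributes `offset` and `pressure`.
#' @export
build_stickiness_curve <- function(gt = gordon_taylor_params(),
                                   isotherm = default_trehalose_isotherm(),
                                   offset = 10, pressure = 101325,
                                   temperature_grid, tol = 1e-8) {
  stopifnot(is.numeric(temperature_grid), length(temperature_grid) >= 1)
  temperature_grid <- sort(temperature_grid)
  f <- function(rh, tdb) .tg_at_rh(rh, gt, isotherm) + offset - tdb
  lo <- 1e-6; hi <- 0.999
  rows <- lapply(temperature_grid, function(tdb) {
    flo <- f(lo, tdb); fhi <- f(hi, tdb)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NULL)
    a <- lo; b <- hi
    while (b - a > tol) {
      m <- (a + b) / 2
      if (f(a, tdb) * f(m, tdb) <= 0) b <- m else a <- m
    }
    rh <- (a + b) / 2
    data.frame(dry_bulb_temperature = tdb,
               relative_humidity = rh,
               specific_humidity = specific_humidity_from_rh(tdb, rh, pressure))
  })
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0)
    warning(sprintf("%d grid point(s) had no sticky-point root in RH (0, 1) and were omitted",
                    dropped))
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0)
    stop("no stickiness-curve point could be computed on this grid")
  structure(out, offset = offset, pressure = pressure,
            class = c("stickiness_curve", "data.frame"))
}

#' Classify a moist-air state against the stickiness design space
#'
#' Computes the material glass-transition temperature at the state's
#' equilibrium moisture and returns `"safe"` if `T_db < T_g`,
#' `"transition"` if `T_g <= T_db <= T_g + offset`, and `"risk"` if
#' `T_db > T_g + offset`. Boundary equality falls into the transition
#' zone (conservative for product safety). Supersaturated states are
#' rejected: they are in the condensation regime, outside the chart.
#'
#' @param state A [moist_air_state()].
#' @inheritParams build_stickiness_curve
#' @return A character scalar: `"safe"`, `"transition"` or `"risk"`,
#'   with attribute `tg` (the plasticized glass-transition temperature, K).
#' @export
classify_zone <- function(state, gt = gordon_taylor_params(),
                          isotherm = default_trehalose_isotherm(),
                          offset = 10) {
  stopifnot(inherits(state, "moist_air_state"))
  if (isTRUE(state$supersaturated))
    stop("supersaturated state: condensation regime, outside the design space")
  tg <- .tg_at_rh(state$relative_humidity, gt, isotherm)
  lab <- if (state$dry_bulb_temperature < tg) "safe"
         else if (state$dry_bulb_temperature <= tg + offset) "transition"
         else "risk"
  structure(lab, tg = tg)
}

#' Dihydrate nucleation risk flag
#'
#' Crystalline trehalose dihydrate can nucleate when the local relative
#' humidity exceeds a threshold (default 44%). The comparison is a
#' strict inequality: exactly at the threshold is not flagged.
#'
#' @param state A [moist_air_state()].
#' @param rh_threshold Fraction, default 0.44.
#' @return Logical flag.
#' @export
dihydrate_risk <- function(state, rh_threshold = 0.44) {
  stopifnot(inherits(state, "moist_air_state"))
  state$relative_humidity > rh_threshold
}
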