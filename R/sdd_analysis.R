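# Single-droplet drying analysis: mask -> ellipse extraction, oblate
# spheroid geometry, d2-law drying curve, lock point, Peclet number,
# surface enrichment and solute diffusivity.

#' Fit an ellipse to a binary droplet mask by image moments
#'
#' Returns the axes of the ellipse whose second-order central moments
#' equal those of the mask (the standard moment-equivalent ellipse).
#' If the mask has several connected foreground components the largest
#' is used, with a warning.
#'
#' @param binary_mask Logical or 0/1 matrix; TRUE/1 is foreground.
#' @param pixel_size Physical edge length of one pixel, m.
#' @return A list with `major_axis`, `minor_axis` (full axis lengths, in
#'   the units implied by `pixel_size`), `centroid` (x, y in pixels) and
#'   `orientation` (radians of the major axis).
#' @export
ellipse_from_moments <- function(binary_mask, pixel_size = 1) {
  m <- binary_mask != 0
  if (!any(m)) stop("empty mask: no foreground pixels")
  comp <- .label_largest_component(m)
  if (comp$n_components > 1) {
    warning(sprintf("mask has %d connected components; using the largest",
                    comp$n_components))
    m <- comp$mask
  }
  idx <- which(m, arr.ind = TRUE)
  x <- idx[, 2]; y <- idx[, 1]
  cx <- mean(x); cy <- mean(y)
  # +1/12: second moment of the unit pixel itself
  mxx <- mean((x - cx)^2) + 1 / 12
  myy <- mean((y - cy)^2) + 1 / 12
  mxy <- mean((x - cx) * (y - cy))
  cov <- matrix(c(mxx, mxy, mxy, myy), 2)
  eig <- eigen(cov, symmetric = TRUE)
  # full axis of the moment-equivalent ellipse: 4 sqrt(eigenvalue)
  axes <- 4 * sqrt(eig$values)
  orientation <- atan2(eig$vectors[2, 1], eig$vectors[1, 1])
  list(major_axis = axes[1] * pixel_size,
       minor_axis = axes[2] * pixel_size,
       centroid = c(x = cx, y = cy),
       orientation = orientation)
}

# 8-connectivity labelling of the largest foreground component,
# by iterative frontier dilation (no dependencies).
.label_largest_component <- function(m) {
  n_fg <- sum(m)
  lab <- matrix(0L, nrow(m), ncol(m))
  remaining <- m
  comp <- 0L
  best <- NULL; best_size <- 0L
  while (any(remaining)) {
    comp <- comp + 1L
    seedidx <- which(remaining)[1]
    cur <- matrix(FALSE, nrow(m), ncol(m))
    cur[seedidx] <- TRUE
    repeat {
      grown <- .dilate8(cur) & remaining
      if (sum(grown) == sum(cur)) break
      cur <- grown
    }
    sz <- sum(cur)
    if (sz > best_size) { best <- cur; best_size <- sz }
    remaining <- remaining & !cur
  }
  list(mask = best, n_components = comp)
}

.dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  pad <- function(dr, dc) {
    res <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    res[rs, cs] <- m[rs - dr, cs - dc]
    res
  }
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) out <- out | pad(dr, dc)
  out
}

#' Surface area and volume of an oblate spheroid
#'
#' A levitated droplet flattens along the acoustic axis; its shape is
#' modelled as an oblate spheroid with equatorial diameter `a` (the
#' image major axis) and polar diameter `b` (the minor axis):
#' `V = pi/6 a^2 b`, and the closed-form oblate surface area with the
#' eccentricity log term (a series branch near `a = b` avoids the 0/0).
#'
#' @param major_axis,minor_axis Full diameters, m; `major >= minor > 0`.
#' @return A list with `area` (m^2) and `volume` (m^3).
#' @export
spheroid_surface_volume <- function(major_axis, minor_axis) {
  if (any(minor_axis <= 0) || any(major_axis <= 0))
    stop("axes must be positive")
  if (any(major_axis < minor_axis))
    stop("major_axis must be >= minor_axis")
  ae <- major_axis / 2   # equatorial semi-axis
  cp <- minor_axis / 2   # polar semi-axis
  e2 <- 1 - (cp / ae)^2
  e2 <- pmax(e2, 0)
  e <- sqrt(e2)
  area <- ifelse(
    e < 1e-3,
    # 2 pi ae^2 + 2 pi cp^2 (1 + e^2/3 + e^4/5 + ...)
    2 * pi * ae^2 + 2 * pi * cp^2 * (1 + e2 / 3 + e2^2 / 5 + e2^3 / 7),
    2 * pi * ae^2 + pi * cp^2 / e * log((1 + e) / (1 - e)))
  list(area = area, volume = pi / 6 * major_axis^2 * minor_axis)
}

#' Droplet axis time series from a levitation experiment
#'
#' @param time Seconds, strictly increasing.
#' @param major_axis,minor_axis Full ellipse axes per frame, m.
#' @param solute_concentration Initial solute concentration c0, kg/m^3.
#' @return An object of class `droplet_series`.
#' @export
droplet_series <- function(time, major_axis, minor_axis,
                           solute_concentration) {
  if (length(time) != length(major_axis) ||
      length(time) != length(minor_axis))
    stop("time and axis vectors must have equal length")
  if (is.unsorted(time, strictly = TRUE))
    stop("time must be strictly increasing")
  if (any(major_axis <= 0) || any(minor_axis <= 0))
    stop("axes must be positive")
  if (any(major_axis < minor_axis - 1e-12))
    stop("major_axis must be >= minor_axis")
  if (solute_concentration <= 0)
    stop("solute_concentration must be positive")
  structure(data.frame(time = time, major_axis = major_axis,
                       minor_axis = pmin(minor_axis, major_axis)),
            solute_concentration = solute_concentration,
            class = c("droplet_series", "data.frame"))
}

#' Drying curve: surface, volume and normalized d-squared
#'
#' Converts an axis time series to surface area, volume and the squared
#' volume-equivalent diameter `d_eq = (6 V / pi)^(1/3)`, the regression
#' variable of the d2-law.
#'
#' @param series A [droplet_series()].
#' @return An object of class `drying_curve`: data frame with columns
#'   `time`, `area`, `volume`, `d_eq2`, `normalized_d2`; attributes
#'   `solute_mass` (kg) and `initial_volume` (m^3).
#' @export
drying_curve <- function(series) {
  stopifnot(inherits(series, "droplet_series"))
  g <- spheroid_surface_volume(series$major_axis, series$minor_axis)
  d_eq2 <- (6 * g$volume / pi)^(2 / 3)
  out <- data.frame(time = series$time, area = g$area, volume = g$volume,
                    d_eq2 = d_eq2, normalized_d2 = d_eq2 / d_eq2[1])
  structure(out,
            solute_mass = attr(series, "solute_concentration") * g$volume[1],
            initial_volume = g$volume[1],
            class = c("drying_curve", "data.frame"))
}

#' Evaporation rate kappa from the d2-law window
#'
#' Ordinary least squares of the squared volume-equivalent diameter on
#' time over a fit window; under steady-state evaporation the slope is
#' `-kappa`.
#'
#' @param curve A [drying_curve()].
#' @param fit_window Numeric `c(t_start, t_end)`, s. Default: the first
#'   30% of the observed time span (early, pre-lock-point shrinkage).
#' @return A list with `kappa` (m^2/s), `se`, `n`, `window`.
#' @export
fit_evaporation_rate <- function(curve, fit_window = NULL) {
  stopifnot(inherits(curve, "drying_curve"))
  if (is.null(fit_window)) {
    t0 <- curve$time[1]
    fit_window <- c(t0, t0 + 0.3 * diff(range(curve$time)))
  }
  sel <- curve$time >= fit_window[1] & curve$time <= fit_window[2]
  if (sum(sel) < 5)
    stop("fewer than 5 samples in the fit window")
  fit <- stats::lm(d_eq2 ~ time, data = curve[sel, ])
  slope <- stats::coef(fit)[["time"]]
  if (slope >= 0)
    stop("non-negative d2 slope in window: droplet is not evaporating")
  list(kappa = -slope,
       se = summary(fit)$coefficients["time", "Std. Error"],
       n = sum(sel), window = fit_window)
}

#' Detect the lock point of a drying curve
#'
#' The lock point is the moment a solid skin forms at the droplet
#' surface and shrinkage stops. Detected as the earliest time from
#' which the local d2 slope magnitude stays below
#' `slope_fraction * kappa` for at least `persistence` consecutive
#' samples; the local slope is measured over a `persistence`-sample
#' window, which suppresses frame noise without delaying detection on
#' clean plateaus.
#'
#' @param curve A [drying_curve()].
#' @param kappa Fitted d2-law evaporation rate, m^2/s.
#' @param slope_fraction Plateau threshold as a fraction of kappa.
#' @param persistence Required consecutive qualifying samples.
#' @return An object of class `lock_point`: list with `found`, `time`,
#'   `volume_at_lock`, `mean_concentration` (solute mass over lock
#'   volume, kg/m^3). When no plateau qualifies (droplet evaporates to
#'   the end, or the series is truncated) `found` is `FALSE`.
#' @export
detect_lock_point <- function(curve, kappa, slope_fraction = 0.1,
                              persistence = 5) {
  stopifnot(inherits(curve, "drying_curve"))
  if (kappa <= 0) stop("kappa must be positive")
  n <- nrow(curve)
  if (n < persistence + 1) stop("series shorter than the persistence window")
  p <- as.integer(persistence)
  idx <- seq_len(n - p)
  slope <- (curve$d_eq2[idx + p] - curve$d_eq2[idx]) /
    (curve$time[idx + p] - curve$time[idx])
  ok <- abs(slope) < slope_fraction * kappa
  run <- rle(ok)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  hit <- which(run$values & run$lengths >= persistence)
  if (!length(hit))
    return(structure(list(found = FALSE, time = NA_real_,
                          volume_at_lock = NA_real_,
                          mean_concentration = NA_real_),
                     class = "lock_point"))
  i <- starts[hit[1]]
  structure(list(found = TRUE,
                 time = curve$time[i],
                 volume_at_lock = curve$volume[i],
                 mean_concentration =
                   attr(curve, "solute_mass") / curve$volume[i]),
            class = "lock_point")
}

#' Peclet number of droplet drying
#'
#' `Pe = kappa / (8 D_s)`: surface recession against solute diffusion.
#'
#' @param kappa d2-law evaporation rate, m^2/s.
#' @param diffusivity Solute diffusion coefficient D_s, m^2/s.
#' @return Dimensionless Peclet number.
#' @export
peclet_number <- function(kappa, diffusivity) {
  if (any(kappa <= 0) || any(diffusivity <= 0))
    stop("kappa and diffusivity must be positive")
  kappa / (8 * diffusivity)
}

#' Surface enrichment from the Peclet number
#'
#' Steady-state d2-law result for the surface-to-mean concentration
#' ratio: `E = 1 + Pe/5 + Pe^2/100 + Pe^3/4000`. The truncation is
#' stated for Pe below 20; larger values give a warning, not an error
#' (estimates just under the bound are routine).
#'
#' @param peclet Pe >= 0.
#' @return Enrichment E = c_s / c_m (>= 1).
#' @export
surface_enrichment <- function(peclet) {
  if (any(peclet < 0)) stop("peclet must be non-negative")
  if (any(peclet > 20))
    warning("Pe > 20: the polynomial enrichment model is outside its stated validity")
  1 + peclet / 5 + peclet^2 / 100 + peclet^3 / 4000
}

#' Invert the enrichment polynomial for the Peclet number
#'
#' The cubic is strictly increasing for Pe >= 0, so the root is unique;
#' found by bisection to 1e-10.
#'
#' @param enrichment E >= 1.
#' @return Pe with `surface_enrichment(Pe) = E`.
#' @export
invert_enrichment <- function(enrichment) {
  if (any(enrichment < 1)) stop("enrichment must be >= 1")
  vapply(enrichment, function(e) {
    if (e == 1) return(0)
    hi <- 1
    while (suppressWarnings(surface_enrichment(hi)) < e) hi <- hi * 2
    lo <- 0
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (suppressWarnings(surface_enrichment(mid)) < e) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, 0)
}

#' Estimate solute diffusivity from a lock point
#'
#' With the surface concentration at skin formation (e.g. the
#' tomography-derived solid density) as `c_s`, the enrichment
#' `E = c_s / c_m` is inverted for Pe, and `D_s = kappa / (8 Pe)`.
#'
#' @param kappa d2-law evaporation rate, m^2/s.
#' @param lock A found [detect_lock_point()] result.
#' @param surface_concentration c_s at the lock point, kg/m^3. Must be
#'   at least the mean concentration.
#' @param kappa_se,cs_se Optional standard errors of `kappa` and of the
#'   surface concentration; when given, first-order (delta-method)
#'   standard errors for Pe and D_s are propagated through the
#'   enrichment inversion.
#' @return An object of class `peclet_estimate`: list with `kappa`,
#'   `peclet`, `enrichment`, `surface_concentration`,
#'   `mean_concentration`, `diffusivity`, `flat_profile`, and (when
#'   input uncertainties are supplied) `peclet_se`, `diffusivity_se`.
#'   A flat profile (`c_s = c_m`) gives Pe = 0 and an unbounded
#'   diffusivity, flagged rather than an error.
#' @export
estimate_diffusivity <- function(kappa, lock, surface_concentration,
                                 kappa_se = 0, cs_se = 0) {
  stopifnot(inherits(lock, "lock_point"))
  if (!isTRUE(lock$found)) stop("lock point was not found; cannot estimate")
  if (kappa <= 0) stop("kappa must be positive")
  cm <- lock$mean_concentration
  if (surface_concentration < cm)
    stop("surface concentration below mean concentration: non-physical enrichment")
  e <- surface_concentration / cm
  if (e == 1) {
    return(structure(list(kappa = kappa, peclet = 0, enrichment = 1,
                          surface_concentration = surface_concentration,
                          mean_concentration = cm,
                          diffusivity = Inf, flat_profile = TRUE),
                     class = "peclet_estimate"))
  }
  pe <- invert_enrichment(e)
  out <- list(kappa = kappa, peclet = pe, enrichment = e,
              surface_concentration = surface_concentration,
              mean_concentration = cm,
              diffusivity = kappa / (8 * pe), flat_profile = FALSE)
  if (kappa_se > 0 || cs_se > 0) {
    # delta method: dE/dc_s = 1/c_m; dPe/dE = 1 / E'(Pe)
    de_dpe <- 1 / 5 + 2 * pe / 100 + 3 * pe^2 / 4000
    pe_se <- (cs_se / cm) / de_dpe
    # D_s = kappa / (8 Pe): independent first-order contributions
    ds_se <- out$diffusivity *
      sqrt((kappa_se / kappa)^2 + (pe_se / pe)^2)
    out$peclet_se <- pe_se
    out$diffusivity_se <- ds_se
  }
  structure(out, class = "peclet_estimate")
}

#' @export
print.peclet_estimate <- function(x, ...) {
  cat(sprintf(
    "Peclet estimate: kappa = %.3g m^2/s, Pe = %.3g, E = %.3g, D_s = %.3g m^2/s%s\n",
    x$kappa, x$peclet, x$enrichment, x$diffusivity,
    if (x$flat_profile) " [flat profile]" else ""))
  invisible(x)
}
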