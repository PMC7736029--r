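# Off-line product characterisation: thermogravimetric residual
# moisture accounting, dihydrate estimation, vacuum-drying removal,
# PSD quantiles and dip-test agglomeration scoring.

#' Thermogravimetric (TGA) mass-loss curve
#'
#' @param temperature Strictly increasing temperature grid, K.
#' @param relative_mass Sample mass relative to the initial mass,
#'   fractions in (0, 1\]; must start at 1.
#' @param heating_rate Metadata, K/min.
#' @return An object of class `tga_curve`.
#' @export
tga_curve <- function(temperature, relative_mass, heating_rate = 10) {
  if (length(temperature) != length(relative_mass))
    stop("temperature and relative_mass lengths differ")
  if (is.unsorted(temperature, strictly = TRUE))
    stop("temperature must be strictly increasing")
  if (any(relative_mass <= 0) || any(relative_mass > 1 + 1e-12))
    stop("relative_mass must lie in (0, 1]")
  if (abs(relative_mass[1] - 1) > 1e-9)
    stop("relative_mass must start at 1")
  structure(data.frame(temperature = temperature,
                       relative_mass = relative_mass),
            heating_rate = heating_rate,
            class = c("tga_curve", "data.frame"))
}

#' Residual moisture at reference temperatures
#'
#' Cumulative mass loss from the start of the TGA run, read at the
#' reference temperatures (linear interpolation between grid points):
#' `RM_T = (1 - relative_mass(T)) * 100` in wt%. The defaults 80, 110
#' and 180 degC separate unbound water, hydrate-bound water released by
#' dihydrate dehydration (above ~97 degC) and entrapped moisture
#' released above the glass transition.
#'
#' @param curve A [tga_curve()].
#' @param reference_temperatures K; all must lie inside the curve range.
#' @return An object of class `moisture_summary`: list with `rm` (wt%
#'   per reference), and for the standard three references `rm80`,
#'   `rm110`, `rm180`, `delta_rm110` (rm110 - rm80) and `delta_rm180`
#'   (rm180 - rm110).
#' @export
residual_moisture_at <- function(curve,
                                 reference_temperatures =
                                   c(80, 110, 180) + 273.15) {
  stopifnot(inherits(curve, "tga_curve"))
  tt <- curve$temperature
  if (any(reference_temperatures < tt[1]) ||
      any(reference_temperatures > tt[length(tt)]))
    stop("reference temperature outside the measured curve range")
  rm_t <- (1 - stats::approx(tt, curve$relative_mass,
                             xout = reference_temperatures)$y) * 100
  out <- list(rm = stats::setNames(rm_t,
                                   sprintf("%.0fK", reference_temperatures)))
  if (length(reference_temperatures) == 3 &&
      isTRUE(all.equal(reference_temperatures, c(80, 110, 180) + 273.15))) {
    out$rm80 <- rm_t[1]; out$rm110 <- rm_t[2]; out$rm180 <- rm_t[3]
    out$delta_rm110 <- rm_t[2] - rm_t[1]
    out$delta_rm180 <- rm_t[3] - rm_t[2]
  }
  structure(out, class = "moisture_summary")
}

#' Maximum crystalline dihydrate content from the 80-110 degC mass step
#'
#' Trehalose dihydrate releases its two crystal waters mostly above
#' 97 degC, so the mass loss between 80 and 110 degC bounds the
#' crystalline dihydrate content:
#' `content = delta_rm110 / w_hydrate_water` with
#' `w_hydrate_water = 2 M_water / M_dihydrate` (about 0.0952 using
#' 18.015 and 378.33 g/mol).
#'
#' @param delta_rm110 Mass loss between 80 and 110 degC, wt% (>= 0).
#' @param m_water,m_dihydrate Molar masses, g/mol.
#' @return Theoretical maximum crystalline dihydrate content, wt%.
#' @export
dihydrate_content <- function(delta_rm110, m_water = 18.015,
                              m_dihydrate = 378.33) {
  if (any(delta_rm110 < 0)) stop("delta_rm110 must be >= 0")
  w_hydrate_water <- 2 * m_water / m_dihydrate
  delta_rm110 / w_hydrate_water
}

#' Relative reduction between two residual-moisture levels
#'
#' `(rm_a - rm_b) / rm_a * 100`: the percent reduction from a baseline
#' condition a to condition b.
#'
#' @param rm_a Baseline residual moisture, wt% (> 0).
#' @param rm_b Comparison residual moisture, wt%.
#' @return Relative reduction in percent.
#' @export
rm_reduction <- function(rm_a, rm_b) {
  if (any(rm_a <= 0)) stop("baseline residual moisture must be positive")
  (rm_a - rm_b) / rm_a * 100
}

#' Fraction of unbound moisture removed by vacuum drying
#'
#' Compares the gravimetric mass loss during secondary vacuum drying
#' against the unbound residual moisture measured by TGA at 80 degC:
#' `vacuum_loss / rm80 * 100`. Values above 100% mean the vacuum step
#' removed more than the TGA-unbound moisture (kinetically hindered
#' desorption during TGA, or desolvation under vacuum); they are
#' flagged, not treated as errors.
#'
#' @param vacuum_loss Mass loss during vacuum drying, wt% (>= 0).
#' @param rm80 TGA residual moisture at 80 degC, wt% (> 0).
#' @return Removal percentage; attribute `exceeds_unbound` is TRUE
#'   where the value exceeds 100.
#' @export
vacuum_removal_fraction <- function(vacuum_loss, rm80) {
  if (any(rm80 <= 0)) stop("rm80 must be positive")
  if (any(vacuum_loss < 0)) stop("vacuum_loss must be >= 0")
  out <- vacuum_loss / rm80 * 100
  attr(out, "exceeds_unbound") <- out > 100
  out
}

#' Volume-weighted particle-size distribution sample
#'
#' @param size Bin-center particle sizes, m, strictly increasing
#'   (log-spaced grids are typical for laser diffraction).
#' @param volume_density Volume fraction per bin; non-negative, summing
#'   to 1 within 1e-9 (renormalized exactly).
#' @param stage De-agglomeration protocol stage: `"LD0"` (no
#'   ultrasound), `"LD1"` or `"LD2"` (2 x 30 s ultrasound).
#' @return An object of class `psd_sample`.
#' @export
psd_sample <- function(size, volume_density, stage = c("LD0", "LD1", "LD2")) {
  stage <- match.arg(stage)
  if (length(size) != length(volume_density))
    stop("size and volume_density lengths differ")
  if (length(size) < 1) stop("empty PSD")
  if (is.unsorted(size, strictly = TRUE))
    stop("size grid must be strictly increasing")
  if (any(volume_density < 0)) stop("volume densities must be >= 0")
  s <- sum(volume_density)
  if (abs(s - 1) > 1e-9)
    stop("volume densities must sum to 1 (within 1e-9)")
  structure(data.frame(size = size, volume_density = volume_density / s),
            stage = stage,
            class = c("psd_sample", "data.frame"))
}

#' Volume-weighted PSD quantiles (D10, D50, D90)
#'
#' Inverts the cumulative volume distribution by interpolation that is
#' linear in log-size (matching the log-spaced grids of laser
#' diffraction). Bin centers carry the cumulative value of their bin.
#'
#' @param psd A [psd_sample()].
#' @param probs Probabilities in (0, 1); default `c(0.1, 0.5, 0.9)`.
#' @return Named vector of sizes, m.
#' @export
psd_quantiles <- function(psd, probs = c(0.1, 0.5, 0.9)) {
  stopifnot(inherits(psd, "psd_sample"))
  if (any(probs <= 0) || any(probs >= 1))
    stop("probs must lie strictly in (0, 1)")
  cdf <- cumsum(psd$volume_density)
  if (nrow(psd) == 1)
    return(stats::setNames(rep(psd$size, length(probs)),
                           sprintf("D%.0f", 100 * probs)))
  lx <- log(psd$size)
  qs <- vapply(probs, function(p) {
    if (p <= cdf[1]) return(psd$size[1])
    i <- findInterval(p, cdf, rightmost.closed = TRUE)
    i <- min(i, length(cdf) - 1)
    w <- (p - cdf[i]) / (cdf[i + 1] - cdf[i])
    exp(lx[i] + w * (lx[i + 1] - lx[i]))
  }, 0)
  stats::setNames(qs, sprintf("D%.0f", 100 * probs))
}

#' Draw a size sample from a volume-weighted PSD
#'
#' The dip test needs a sample, not a histogram. Sizes are drawn by
#' volume-weighted resampling of bins with uniform jitter in log-size
#' within each bin, so repeated bin hits do not collapse into exact
#' ties.
#'
#' @param psd A [psd_sample()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of sizes (m), in log-uniform positions within
#'   their bins.
#' @export
psd_resample <- function(psd, n = 500, seed = 1) {
  stopifnot(inherits(psd, "psd_sample"))
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  lx <- log(psd$size)
  k <- length(lx)
  # bin edges: midpoints in log space, end bins mirrored
  mid <- (lx[-1] + lx[-k]) / 2
  lo <- c(2 * lx[1] - mid[1], mid)
  hi <- c(mid, 2 * lx[k] - mid[k - 1])
  bins <- sample.int(k, n, replace = TRUE, prob = psd$volume_density)
  exp(stats::runif(n, lo[bins], hi[bins]))
}

#' Compare PSDs before and after the de-agglomeration protocol
#'
#' Draws volume-weighted size samples from the LD0 (no ultrasound) and
#' LD2 (after ultrasound) distributions, runs the dip test on both, and
#' reports the quantile shifts. Breaking agglomerates moves volume from
#' a coarse agglomerate mode into the primary-particle mode, so the
#' probability of unimodality is expected to increase from LD0 to LD2.
#'
#' @param psd_ld0,psd_ld2 [psd_sample()] objects on the same size grid.
#' @param resample_n Sample size drawn from each PSD.
#' @param seed Integer seed.
#' @param bootstrap_reps Bootstrap replicates for each dip test.
#' @return A list with `ld0`, `ld2` (each a [unimodality_probability()]
#'   result), `quantile_shift` (LD2 - LD0 for D10/D50/D90, m), and
#'   `hdt_increased` (logical).
#' @export
deagglomeration_report <- function(psd_ld0, psd_ld2, resample_n = 500,
                                   seed = 1, bootstrap_reps = 2000) {
  stopifnot(inherits(psd_ld0, "psd_sample"), inherits(psd_ld2, "psd_sample"))
  if (nrow(psd_ld0) != nrow(psd_ld2) ||
      any(abs(psd_ld0$size - psd_ld2$size) >
          1e-12 * pmax(psd_ld0$size, psd_ld2$size)))
    stop("the two PSDs must share one size grid")
  s0 <- psd_resample(psd_ld0, resample_n, seed)
  s2 <- psd_resample(psd_ld2, resample_n, seed + 1)
  r0 <- unimodality_probability(log(s0), bootstrap_reps, seed + 2)
  r2 <- unimodality_probability(log(s2), bootstrap_reps, seed + 3)
  q0 <- psd_quantiles(psd_ld0)
  q2 <- psd_quantiles(psd_ld2)
  list(ld0 = r0, ld2 = r2,
       quantile_shift = q2 - q0,
       hdt_increased = r2$unimodality_probability >=
         r0$unimodality_probability)
}

#' Residual-moisture results of the reference spray-drying campaigns
#'
#' TG-MS residual moisture (wt% at 80, 110 and 180 degC), secondary
#' vacuum-drying mass loss and (for the sugar powders) the measured
#' glass-transition temperature for the published trehalose (SPT1-SPT6)
#' and glucagon (SPG1-SPG5) spray-drying experiments. SPG5 is the
#' glucagon-trehalose formulation; its 180 degC value is unavailable
#' because Maillard browning sets in above 170 degC.
#'
#' @return Data frame with columns `exp_id`, `system`, `rm80`, `rm110`,
#'   `rm180`, `vacuum_loss` (all wt%) and `tg_c` (degC, NA for
#'   glucagon).
#' @export
reference_moisture_table <- function() {
  data.frame(
    exp_id = c("SPT1", "SPT2", "SPT3", "SPT4", "SPT5", "SPT6",
               "SPG1", "SPG2", "SPG3", "SPG4", "SPG5"),
    system = c(rep("TRE", 6), rep("GLUC", 4), "GLUC-TRE"),
    rm80 = c(2.45, 3.81, 4.78, 3.57, 4.77, 3.80,
             3.99, 3.77, 3.78, 4.85, 4.38),
    rm110 = c(4.33, 4.10, 5.82, 3.87, 4.90, 3.99,
              4.27, 4.07, 4.19, 5.14, 7.16),
    rm180 = c(8.24, 4.13, 6.48, 3.90, 5.58, 4.49,
              7.81, 7.82, 8.08, 8.72, NA),
    vacuum_loss = c(6.34, 3.10, 4.70, 2.25, 4.28, 2.61,
                    4.15, 3.55, 3.42, 5.05, 5.83),
    tg_c = c(42.35, 60.26, 40.32, 65.12, 38.98, 57.16,
             NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE)
}
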