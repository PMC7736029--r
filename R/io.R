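# I/O boundaries: CSV readers for the instrument-facing formats
# (Celsius, percent, micrometers live here; everything internal is SI)
# and the versioned design-space report structure.

#' Read a droplet axis time series from CSV
#'
#' Expected columns: `time_s`, `major_um`, `minor_um`.
#'
#' @param path CSV file path.
#' @param solute_concentration Initial solute concentration, kg/m^3.
#' @return A [droplet_series()].
#' @export
read_droplet_csv <- function(path, solute_concentration) {
  x <- utils::read.csv(path)
  need <- c("time_s", "major_um", "minor_um")
  if (!all(need %in% names(x)))
    stop("droplet CSV needs columns: ", paste(need, collapse = ", "))
  droplet_series(x$time_s, x$major_um * 1e-6, x$minor_um * 1e-6,
                 solute_concentration)
}

#' Read a TGA curve from CSV
#'
#' Expected columns: `temperature_C`, `mass_pct` (percent of initial
#' mass).
#'
#' @param path CSV file path.
#' @param heating_rate K/min metadata.
#' @return A [tga_curve()].
#' @export
read_tga_csv <- function(path, heating_rate = 10) {
  x <- utils::read.csv(path)
  need <- c("temperature_C", "mass_pct")
  if (!all(need %in% names(x)))
    stop("TGA CSV needs columns: ", paste(need, collapse = ", "))
  tga_curve(x$temperature_C + 273.15, x$mass_pct / 100, heating_rate)
}

#' Read a volume-weighted PSD from CSV
#'
#' Expected columns: `size_um`, `volume_pct`; one file per
#' de-agglomeration stage.
#'
#' @param path CSV file path.
#' @param stage Protocol stage (`"LD0"`, `"LD1"`, `"LD2"`).
#' @return A [psd_sample()].
#' @export
read_psd_csv <- function(path, stage = "LD0") {
  x <- utils::read.csv(path)
  need <- c("size_um", "volume_pct")
  if (!all(need %in% names(x)))
    stop("PSD CSV needs columns: ", paste(need, collapse = ", "))
  psd_sample(x$size_um * 1e-6, x$volume_pct / sum(x$volume_pct),
             stage = stage)
}

#' Assemble a versioned design-space report
#'
#' Bundles station states, zone labels, the operation limit band and
#' yield accounting into one list ready for JSON serialization (e.g.
#' `jsonlite::write_json(report, path, auto_unbox = TRUE)`).
#'
#' @param stations A [station_states()] result.
#' @param limit_band Optional [operation_limit_band()] result.
#' @param yield Optional [process_yield()] result (fraction).
#' @return A list with `schema_version`, `stations`, `limit_band`,
#'   `yield`.
#' @export
design_space_report <- function(stations, limit_band = NULL, yield = NULL) {
  stopifnot(inherits(stations, "station_states"))
  list(schema_version = "1.0",
       stations = as.data.frame(stations),
       limit_band = if (!is.null(limit_band)) as.list(limit_band),
       yield = if (!is.null(yield)) as.numeric(yield))
}
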