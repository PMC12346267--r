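#' Read a YAML configuration file
#'
#' Thin wrapper over [yaml::read_yaml()]; the resulting list feeds
#' [ring_geometry()] (`config =`), [heating_schedule()] or
#' [build_tissue_model()] `properties`.
#'
#' @param path file path.
#' @export
load_config <- function(path) yaml::read_yaml(path)

#' Write an image to TIFF
#'
#' Stores the pixel values as 32-bit floating point TIFF. TIFF stores values
#' in [0, 1], so by default the image is min-max scaled on write; the
#' original range is returned (invisibly) and can be passed to
#' [read_image_tiff()] to restore the physical values.
#'
#' @param image a [pa_image()] or numeric matrix.
#' @param path output path.
#' @param normalize min-max scale into [0, 1] before writing; set to `FALSE`
#'   only for data already in [0, 1].
#' @return invisibly, the original `c(min, max)` range.
#' @export
write_image_tiff <- function(image, path, normalize = TRUE) {
  v <- image_values(image)
  rng <- range(v)
  if (normalize) {
    v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0
  } else if (rng[1] < 0 || rng[2] > 1)
    stop_pactherm("values outside [0, 1]; use normalize = TRUE")
  tiff::writeTIFF(v, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(rng)
}

#' @rdname write_image_tiff
#' @param range optional `c(min, max)` from [write_image_tiff()]; when given,
#'   the stored [0, 1] values are mapped back to that range.
#' @export
read_image_tiff <- function(path, range = NULL) {
  v <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(v)) == 3) v <- v[, , 1]
  if (!is.null(range)) v <- v * diff(range) + range[1]
  v
}

#' Save / load an RF frame series
#'
#' Native R serialization of the simulated acquisition container (frames,
#' timestamps, geometry, calibration, schedule).
#'
#' @param series an `rf_series` (see [simulate_thermometry_sequence()]).
#' @param path file path.
#' @export
write_rf_series <- function(series, path) {
  stopifnot(inherits(series, "rf_series"))
  saveRDS(series, path)
  invisible(path)
}

#' @rdname write_rf_series
#' @export
read_rf_series <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "rf_series")) stop_pactherm("file does not contain an rf_series")
  x
}

#' Serialize a thermal dose report to JSON
#'
#' @param report a [cem43t50()] dose report.
#' @param path output path.
#' @export
write_dose_report <- function(report, path) {
  stopifnot(inherits(report, "dose_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
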