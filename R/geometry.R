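#' Ring-array transducer geometry
#'
#' Describes a full-view circular ultrasound array: element positions on a
#' ring, center frequency and bandwidth of the elements, DAQ sampling rate and
#' the assumed speed of sound in the coupling medium. Defaults describe a
#' 512-element, 40-mm-radius, 5-MHz ring sampled at 40 MS/s.
#'
#' Units: lengths in mm, frequencies in MHz (sampling rate in MS/s, i.e.
#' samples per microsecond), speed of sound in mm/us, angles in radians.
#'
#' @param ring_radius ring radius in mm (> 0).
#' @param n_elements number of uniformly spaced elements.
#' @param center_frequency element center frequency, MHz.
#' @param fractional_bandwidth fractional (-6 dB) bandwidth of the element
#'   impulse response, relative to `center_frequency`.
#' @param sampling_rate DAQ sampling rate, MS/s. Must exceed twice the upper
#'   band edge `center_frequency * (1 + fractional_bandwidth / 2)`.
#' @param speed_of_sound assumed uniform speed of sound, mm/us.
#' @param config optional named list (e.g. from [yaml::read_yaml()]) whose
#'   entries override the defaults; explicit arguments take precedence over
#'   `config`.
#' @return An object of class `ring_geometry` with the above fields plus
#'   `element_angles` (strictly increasing, spacing `2*pi/n_elements`).
#' @examples
#' geo <- ring_geometry(n_elements = 64)
#' head(element_positions(geo))
#' @export
ring_geometry <- function(ring_radius = 40, n_elements = 512,
                          center_frequency = 5, fractional_bandwidth = 0.7,
                          sampling_rate = 40, speed_of_sound = 1.50,
                          config = NULL) {
  if (!is.null(config)) {
    stopifnot(is.list(config))
    defaults <- list(ring_radius = 40, n_elements = 512, center_frequency = 5,
                     fractional_bandwidth = 0.7, sampling_rate = 40,
                     speed_of_sound = 1.50)
    supplied <- as.list(match.call())[-1]
    supplied$config <- NULL
    vals <- utils::modifyList(defaults, config[names(config) %in% names(defaults)])
    vals <- utils::modifyList(vals, lapply(supplied, eval, parent.frame()))
    return(do.call(ring_geometry, vals))
  }
  if (!(ring_radius > 0)) stop_pactherm("ring_radius must be > 0")
  if (!(n_elements >= 1)) stop_pactherm("n_elements must be >= 1")
  if (!(center_frequency > 0) || !(sampling_rate > 0) || !(speed_of_sound > 0))
    stop_pactherm("frequencies and speed_of_sound must be > 0")
  band_edge <- center_frequency * (1 + fractional_bandwidth / 2)
  if (sampling_rate <= 2 * band_edge)
    stop_pactherm(sprintf(
      "Nyquist violation: sampling_rate %.3g MS/s must exceed twice the upper band edge %.3g MHz (center %.3g MHz, fractional bandwidth %.3g)",
      sampling_rate, band_edge, center_frequency, fractional_bandwidth))
  structure(list(
    ring_radius = ring_radius,
    n_elements = as.integer(n_elements),
    center_frequency = center_frequency,
    fractional_bandwidth = fractional_bandwidth,
    sampling_rate = sampling_rate,
    speed_of_sound = speed_of_sound,
    element_angles = 2 * pi * (seq_len(n_elements) - 1) / n_elements
  ), class = "ring_geometry")
}

#' Cartesian element positions of a ring array
#'
#' @param geometry a [ring_geometry()].
#' @return `n_elements x 2` matrix of (x, y) positions in mm, ring center at
#'   the origin.
#' @export
element_positions <- function(geometry) {
  stopifnot(inherits(geometry, "ring_geometry"))
  cbind(x = geometry$ring_radius * cos(geometry$element_angles),
        y = geometry$ring_radius * sin(geometry$element_angles))
}

#' @export
print.ring_geometry <- function(x, ...) {
  cat(sprintf(
    "Ring array: %d elements, radius %.1f mm, fc %.2f MHz (bw %.0f%%), %.0f MS/s, c = %.3f mm/us\n",
    x$n_elements, x$ring_radius, x$center_frequency,
    100 * x$fractional_bandwidth, x$sampling_rate, x$speed_of_sound))
  invisible(x)
}
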