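#' Element impulse response
#'
#' Constructs the receive impulse response used both by the forward simulator
#' and by the deconvolution stage: a Gaussian-modulated cosine at the array
#' center frequency whose Gaussian power spectrum has full width at half
#' maximum equal to `fractional_bandwidth * center_frequency`.
#'
#' @param geometry a [ring_geometry()].
#' @param n_sigma half-width of the sampled kernel in units of the envelope
#'   standard deviation.
#' @return object of class `impulse_response`: `kernel` (odd length),
#'   `sampling_rate` (MS/s) and `center` (index of time zero).
#' @export
eir_kernel <- function(geometry, n_sigma = 4) {
  stopifnot(inherits(geometry, "ring_geometry"))
  sigma <- pulse_sigma(geometry)
  fs <- geometry$sampling_rate
  W <- ceiling(n_sigma * sigma * fs) + 1L
  t <- (-W:W) / fs
  impulse_response(exp(-t^2 / (2 * sigma^2)) *
                     cos(2 * pi * geometry$center_frequency * t),
                   sampling_rate = fs, center = W + 1L)
}

#' @rdname eir_kernel
#' @param kernel numeric vector with nonzero energy.
#' @param sampling_rate sampling rate of the kernel, MS/s.
#' @param center 1-based index of the kernel sample at time zero.
#' @export
impulse_response <- function(kernel, sampling_rate, center = which.max(abs(kernel))) {
  kernel <- as.numeric(kernel)
  if (!any(kernel != 0)) stop_pactherm("impulse response kernel has zero energy")
  stopifnot(sampling_rate > 0, center >= 1, center <= length(kernel))
  structure(list(kernel = kernel, sampling_rate = sampling_rate,
                 center = as.integer(center)),
            class = "impulse_response")
}

# Envelope standard deviation (us) of the Gaussian-modulated cosine whose
# Gaussian power spectrum has FWHM = bw * fc.
pulse_sigma <- function(geometry) {
  sqrt(log(2)) / (pi * geometry$fractional_bandwidth * geometry$center_frequency)
}

# Analytic pulse evaluated at lag tau (us).
pulse_eval <- function(tau, geometry) {
  sigma <- pulse_sigma(geometry)
  exp(-tau^2 / (2 * sigma^2)) * cos(2 * pi * geometry$center_frequency * tau)
}

#' Per-element RF record container
#'
#' @param samples `n_elements x n_time_samples` matrix of acoustic pressure
#'   (arbitrary units), finite values only.
#' @param t0 time of the first sample relative to the laser pulse, us.
#' @param sampling_rate MS/s.
#' @param frame_time acquisition timestamp, s.
#' @param geometry the [ring_geometry()] that produced the record.
#' @return object of class `rf_frame`.
#' @export
rf_frame <- function(samples, t0, sampling_rate, frame_time = 0, geometry = NULL) {
  samples <- as.matrix(samples)
  if (!all(is.finite(samples))) stop_pactherm("RF samples must all be finite")
  structure(list(samples = samples, t0 = t0, sampling_rate = sampling_rate,
                 frame_time = frame_time, geometry = geometry),
            class = "rf_frame")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("RF frame: %d elements x %d samples @ %.0f MS/s, t0 = %.3g us, t = %.4g s\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate, x$t0, x$frame_time))
  invisible(x)
}

# Number of samples needed to cover direct arrivals from the whole phantom
# grid plus the pulse tail.
default_n_samples <- function(phantom_or_grid, geometry, pad_sigma = 5) {
  grid <- if (inherits(phantom_or_grid, "absorption_map")) phantom_or_grid$grid
          else phantom_or_grid
  tmax <- (geometry$ring_radius + grid_max_radius(grid)) / geometry$speed_of_sound
  as.integer(ceiling((tmax + pad_sigma * pulse_sigma(geometry)) * geometry$sampling_rate) + 2L)
}

#' Forward-project an absorption phantom to ring-array RF data
#'
#' Each nonzero phantom pixel acts as a point photoacoustic source: its
#' initial pressure is `p0 = Gamma0 * eta_th * Ae` with the Grueneisen
#' parameter `Gamma0` proportional to `T0 + c/b` (unit proportionality
#' constant), and it contributes to every element a band-limited pulse
#' delayed by distance / speed_of_sound and scaled by `p0 / distance`
#' (2D point sources, spherical spreading). Optionally adds i.i.d. Gaussian
#' noise whose standard deviation is expressed in units of the peak
#' noise-free amplitude of the frame (or of `noise_ref` when supplied, so a
#' frame series shares one absolute noise level).
#'
#' @param phantom an [make_phantom()] absorption map.
#' @param geometry a [ring_geometry()].
#' @param calib optional [grueneisen_calibration()]; when `NULL` the source
#'   amplitude is the absorption value itself.
#' @param noise_sd noise standard deviation relative to the peak noise-free
#'   signal (>= 0).
#' @param seed integer seed for the noise stream; identical seeds and inputs
#'   give bit-identical output.
#' @param n_samples record length; default covers all direct arrivals.
#' @param t0 time of first sample, us.
#' @param frame_time acquisition timestamp, s.
#' @param noise_ref absolute amplitude reference for the noise scale
#'   (internal use by the sequence simulator).
#' @return an [rf_frame()].
#' @export
forward_project <- function(phantom, geometry, calib = NULL, noise_sd = 0,
                            seed = NULL, n_samples = NULL, t0 = 0,
                            frame_time = 0, noise_ref = NULL) {
  stopifnot(inherits(phantom, "absorption_map"), inherits(geometry, "ring_geometry"))
  if (noise_sd < 0) stop_pactherm("noise_sd must be >= 0")
  if (grid_max_radius(phantom$grid) >= geometry$ring_radius)
    stop_pactherm("phantom grid extends outside the transducer ring")
  if (is.null(n_samples)) n_samples <- default_n_samples(phantom, geometry)
  samples <- project_sources(phantom$values, phantom$grid, geometry, calib,
                             n_samples, t0)
  if (noise_sd > 0) {
    ref <- noise_ref %||% max(abs(samples))
    noise <- with_seed(seed, rnorm(length(samples), sd = noise_sd * ref))
    samples <- samples + matrix(noise, nrow(samples), ncol(samples))
  }
  rf_frame(samples, t0 = t0, sampling_rate = geometry$sampling_rate,
           frame_time = frame_time, geometry = geometry)
}

# Noise-free projection of an arbitrary source map (matrix) on a grid.
project_sources <- function(values, grid, geometry, calib, n_samples, t0) {
  fs <- geometry$sampling_rate
  c0 <- geometry$speed_of_sound
  src <- which(values != 0)
  n_el <- geometry$n_elements
  out <- matrix(0, n_el, n_samples)
  if (length(src) == 0) return(out)
  gamma <- if (is.null(calib)) 1 else
    (calib$T0 + calib$c_over_b) * calib$eta_th
  co <- grid_coords(grid)
  sx <- co$xy[src, 1]; sy <- co$xy[src, 2]
  p0 <- gamma * values[src]
  ep <- element_positions(geometry)
  sigma <- pulse_sigma(geometry)
  W <- as.integer(ceiling(4 * sigma * fs) + 1L)
  offs <- -W:W
  for (e in seq_len(n_el)) {
    d <- sqrt((sx - ep[e, 1])^2 + (sy - ep[e, 2])^2)
    if (any(d < 1e-9))
      stop_pactherm("source pixel coincides with element ", e, " (zero distance)")
    delay <- d / c0
    amp <- p0 / d
    i0 <- as.integer(round((delay - t0) * fs)) + 1L
    idx <- outer(i0, offs, "+")
    tau <- t0 + (idx - 1) / fs - delay
    contrib <- amp * exp(-tau^2 / (2 * sigma^2)) *
      cos(2 * pi * geometry$center_frequency * tau)
    ok <- idx >= 1L & idx <= n_samples
    if (!all(ok)) { idx <- idx[ok]; contrib <- contrib[ok] }
    acc <- rowsum(as.vector(contrib), as.vector(idx))
    ii <- as.integer(rownames(acc))
    out[e, ii] <- out[e, ii] + acc[, 1]
  }
  out
}
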