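#' Time series of temperature maps
#'
#' @param times strictly increasing timestamps, minutes (relative to CW-laser
#'   on by convention).
#' @param delta `n_rows x n_cols x n_frames` array of temperature-rise maps,
#'   deg C (NA marks invalid pixels).
#' @param roi logical matrix, the tumor region of interest.
#' @param calibration optional [grueneisen_calibration()].
#' @param core_temperature deg C added to `delta` for absolute maps (body
#'   core 37 C in vivo, bath temperature for phantoms); NA if unknown.
#' @export
thermal_series <- function(times, delta, roi = NULL, calibration = NULL,
                           core_temperature = NA) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop_pactherm("times must be strictly increasing")
  if (length(dim(delta)) != 3 || dim(delta)[3] != length(times))
    stop_pactherm("delta must be an n_rows x n_cols x n_frames array matching times")
  if (!is.null(roi) && !identical(dim(roi), dim(delta)[1:2]))
    stop_pactherm("roi shape does not match maps")
  structure(list(times = times, delta = delta, roi = roi,
                 calibration = calibration, core_temperature = core_temperature),
            class = "thermal_series")
}

#' @export
print.thermal_series <- function(x, ...) {
  cat(sprintf("Thermal series: %d maps (%d x %d) over [%.3g, %.3g] min, core %.4g C\n",
              dim(x$delta)[3], dim(x$delta)[1], dim(x$delta)[2],
              min(x$times), max(x$times), x$core_temperature))
  invisible(x)
}

#' Relative PA amplitude change against a baseline window
#'
#' Forms the baseline map `p0` as the pixelwise mean amplitude over the
#' baseline frames (the first minute of the session with the CW laser off),
#' then returns `(frame - p0) / p0` per frame. Pixels whose baseline
#' amplitude falls below `floor_frac` of the median baseline amplitude (over
#' the ROI when given, otherwise over all positive-baseline pixels) are
#' flagged invalid (NA) — the ratio is meaningless where there is no signal.
#'
#' @param frames list of registered amplitude [pa_image()]s (or matrices), or
#'   a 3D array.
#' @param baseline_window integer indices of the baseline frames.
#' @param roi optional logical matrix used for the validity floor.
#' @param floor_frac validity floor as a fraction of the median baseline
#'   amplitude.
#' @return list with `rel` (3D array of dp/p0, NA where invalid), `p0`,
#'   `valid` (logical matrix).
#' @export
relative_change_series <- function(frames, baseline_window, roi = NULL,
                                   floor_frac = 0.05) {
  arr <- frames_to_array(frames)
  n_frames <- dim(arr)[3]
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) == 0 || any(baseline_window < 1) ||
      any(baseline_window > n_frames))
    stop_pactherm("baseline_window must be a nonempty set of frame indices")
  p0 <- apply(arr[, , baseline_window, drop = FALSE], c(1, 2), mean)
  ref <- if (!is.null(roi)) p0[roi] else p0[p0 > 0]
  if (length(ref) == 0 || all(!is.finite(ref)) || median(ref) <= 0)
    stop_pactherm("baseline contains no valid signal")
  valid <- p0 >= floor_frac * median(ref)
  if (!any(valid)) stop_pactherm("all pixels fall below the baseline validity floor")
  rel <- array(NA_real_, dim(arr))
  for (k in seq_len(n_frames)) {
    m <- (arr[, , k] - p0) / p0
    m[!valid] <- NA_real_
    rel[, , k] <- m
  }
  list(rel = rel, p0 = p0, valid = valid)
}

frames_to_array <- function(frames) {
  if (is.array(frames) && length(dim(frames)) == 3) return(frames)
  stopifnot(is.list(frames), length(frames) >= 1)
  mats <- lapply(frames, image_values)
  array(unlist(mats), c(dim(mats[[1]]), length(mats)))
}

#' Convert relative amplitude change to temperature maps
#'
#' Applies the Grueneisen thermometry relation `dT = a * dp/p0` with
#' `a = T0 + c/b` (see [thermal_coefficient()]); absolute maps are
#' `dT + core_temperature`.
#'
#' @param rel output of [relative_change_series()], or a 3D array of dp/p0.
#' @param calib a [grueneisen_calibration()].
#' @param core_temperature deg C; defaults to the calibration baseline `T0`.
#' @param times frame timestamps in minutes; defaults to frame index.
#' @param roi optional ROI mask carried into the series.
#' @return a [thermal_series()].
#' @export
temperature_series <- function(rel, calib, core_temperature = NULL,
                               times = NULL, roi = NULL) {
  stopifnot(inherits(calib, "grueneisen_calibration"))
  arr <- if (is.list(rel) && !is.null(rel$rel)) rel$rel else rel
  a <- thermal_coefficient(calib)
  if (!is.finite(a)) stop_pactherm("thermal coefficient is not finite")
  if (is.null(times)) times <- seq_len(dim(arr)[3]) - 1
  thermal_series(times, a * arr, roi = roi, calibration = calib,
                 core_temperature = core_temperature %||% calib$T0)
}

#' Per-interval ROI temperature metrics
#'
#' Bins the frames of a thermal series into consecutive time intervals and
#' pools all valid ROI pixels of all frames in each bin: `T_avg` is the pooled
#' mean and `T50` the pooled median (the temperature exceeded by half of the
#' tumor ROI), both in absolute deg C.
#'
#' @param series a [thermal_series()] with a nonempty ROI (or supply `roi`).
#' @param interval bin width, minutes.
#' @param roi optional mask overriding the one in `series`.
#' @return data.frame with one row per interval: `interval`, `t_start`,
#'   `t_avg`, `t50`, `n_frames`.
#' @export
roi_metrics <- function(series, interval = 1, roi = NULL) {
  stopifnot(inherits(series, "thermal_series"))
  roi <- roi %||% series$roi
  if (is.null(roi) || !any(roi)) stop_pactherm("ROI is empty")
  span <- diff(range(series$times))
  if (interval > span && length(series$times) > 1)
    stop_pactherm(sprintf("interval (%.3g min) longer than the series span (%.3g min)",
                          interval, span))
  core <- if (is.finite(series$core_temperature)) series$core_temperature else 0
  bin <- floor((series$times - series$times[1]) / interval)
  res <- lapply(sort(unique(bin)), function(b) {
    ks <- which(bin == b)
    pool <- as.vector(vapply(ks, function(k) series$delta[, , k][roi],
                             numeric(sum(roi)))) + core
    pool <- pool[is.finite(pool)]
    data.frame(interval = b + 1L, t_start = series$times[1] + b * interval,
               t_avg = mean(pool), t50 = median(pool), n_frames = length(ks))
  })
  do.call(rbind, res)
}

#' CEM43T50 thermal dose
#'
#' Cumulative equivalent minutes at 43 C computed from the per-interval
#' median ROI temperature: `CEM43T50 = sum_i t * R^(43 - T50_i)` with
#' `R = 0.5` for `T50_i >= 43` C and `R = 0.25` below (the standard CEM43
#' convention at the 43 C breakpoint).
#'
#' @param t50_series per-interval median ROI temperatures, deg C (absolute).
#' @param t reporting interval, minutes (> 0).
#' @param tavg_series optional matching per-interval mean temperatures,
#'   carried into the report.
#' @return object of class `dose_report` with fields `t`, `n`, `t50_series`,
#'   `tavg_series`, `R_above` (0.5), `R_below` (0.25) and `cem43t50`
#'   (equivalent minutes, >= 0).
#' @examples
#' cem43t50(rep(44, 10))$cem43t50   # 10 * 0.5^-1 = 20 equivalent minutes
#' @export
cem43t50 <- function(t50_series, t = 1, tavg_series = NULL) {
  if (!(t > 0)) stop_pactherm("reporting interval t must be > 0")
  t50_series <- as.numeric(t50_series)
  R <- ifelse(t50_series >= 43, 0.5, 0.25)
  dose <- sum(t * R^(43 - t50_series))
  structure(list(t = t, n = length(t50_series), t50_series = t50_series,
                 tavg_series = tavg_series, R_above = 0.5, R_below = 0.25,
                 cem43t50 = dose),
            class = "dose_report")
}

#' @export
print.dose_report <- function(x, ...) {
  cat(sprintf("CEM43T50 dose: %.4g equivalent min at 43 C (%d intervals of %.3g min, T50 %.1f-%.1f C)\n",
              x$cem43t50, x$n, x$t,
              min(x$t50_series), max(x$t50_series)))
  invisible(x)
}
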