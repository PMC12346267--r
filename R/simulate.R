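#' Photothermal heating schedule
#'
#' Timing and heating model of a treatment session: a baseline with the CW
#' laser off, a heating period, and a cool-down, imaged at a fixed frame rate.
#' Defaults follow the standard session layout (1 min baseline, 10 min
#' heating, 1 min cool-down) at a decimated 10 frames/min.
#'
#' The heating model describes the tumor temperature rise while the CW laser
#' is on, as one of:
#' \itemize{
#'   \item `list(type = "exponential", amp, rate, mask)` — exponential rise
#'     `amp * (1 - exp(-rate * t))` (deg C, min^-1) applied uniformly inside
#'     the named phantom mask; cool-down decays as `exp(-rate * t)`.
#'   \item `list(type = "uniform", amp, mask)` — constant `amp` during
#'     heating, zero outside the heating window.
#'   \item `list(type = "field", fun, mask)` — `fun(t)` returns a full
#'     temperature-rise map (deg C) for time `t` minutes after laser-on.
#' }
#'
#' @param baseline_duration,heating_duration,cooldown_duration minutes (>= 0).
#' @param frame_rate frames per minute (> 0).
#' @param heating_model see Details; default exponential rise with
#'   `amp = 15.865` deg C and `rate = 3.104` min^-1 in the `"tumor"` mask.
#' @return object of class `heating_schedule`.
#' @export
heating_schedule <- function(baseline_duration = 1, heating_duration = 10,
                             cooldown_duration = 1, frame_rate = 10,
                             heating_model = list(type = "exponential",
                                                  amp = 15.865, rate = 3.104,
                                                  mask = "tumor")) {
  if (any(c(baseline_duration, heating_duration, cooldown_duration) < 0))
    stop_pactherm("schedule durations must be >= 0")
  if (!(frame_rate > 0)) stop_pactherm("frame_rate must be > 0")
  structure(list(baseline_duration = baseline_duration,
                 heating_duration = heating_duration,
                 cooldown_duration = cooldown_duration,
                 frame_rate = frame_rate, heating_model = heating_model),
            class = "heating_schedule")
}

# Scalar temperature rise (deg C) of the heated region at session time t
# (minutes from session start), for mask-uniform heating models.
schedule_delta_t <- function(schedule, t) {
  hm <- schedule$heating_model
  bl <- schedule$baseline_duration; ht <- schedule$heating_duration
  vapply(t, function(ti) {
    if (ti < bl) return(0)
    tau <- ti - bl
    if (tau <= ht) {
      switch(hm$type,
             exponential = hm$amp * (1 - exp(-hm$rate * tau)),
             uniform = hm$amp,
             stop_pactherm("schedule_delta_t: unsupported heating model type ", hm$type))
    } else {
      tau2 <- tau - ht
      switch(hm$type,
             exponential = hm$amp * (1 - exp(-hm$rate * ht)) * exp(-hm$rate * tau2),
             uniform = 0)
    }
  }, numeric(1))
}

#' Simulate a PA thermometry acquisition with known ground truth
#'
#' Generates the full RF frame series of a heating session. Per frame, the
#' source amplitude of heated pixels scales as
#' `p(t)/p0 = 1 + dT(t) / (T0 + c/b)` — the exact forward counterpart of the
#' Grueneisen thermometry inversion — optional rigid inter-frame motion is
#' applied to the phantom before projection, and seeded Gaussian channel
#' noise is added with a fixed absolute level across the series (scaled to
#' the peak of the noise-free baseline frame).
#'
#' @param phantom a [make_phantom()] absorption map; must contain the mask
#'   named by the heating model.
#' @param schedule a [heating_schedule()].
#' @param calib a [grueneisen_calibration()].
#' @param geometry a [ring_geometry()].
#' @param motion_spec rigid jitter bounds: `list(max_rotation_deg, max_translation_mm)`;
#'   per-frame rotation and translation are drawn uniformly within them.
#'   Default none (fixed animal position).
#' @param noise_sd channel noise sd in units of the peak noise-free baseline
#'   amplitude.
#' @param seed integer; governs motion draws and noise.
#' @return list with `frames` (class `rf_series`: list of [rf_frame()],
#'   `times_min` from session start, geometry/calibration/schedule) and
#'   `truth` (a [thermal_series()] of ground-truth temperature-rise maps in
#'   the unmoved phantom frame, times in minutes relative to laser-on).
#' @export
simulate_thermometry_sequence <- function(phantom, schedule, calib, geometry,
                                          motion_spec = list(max_rotation_deg = 0,
                                                             max_translation_mm = 0),
                                          noise_sd = 0, seed = 1) {
  stopifnot(inherits(phantom, "absorption_map"),
            inherits(schedule, "heating_schedule"),
            inherits(calib, "grueneisen_calibration"),
            inherits(geometry, "ring_geometry"))
  hm <- schedule$heating_model
  mask <- phantom$masks[[hm$mask %||% "tumor"]]
  if (is.null(mask) && !identical(hm$type, "field"))
    stop_pactherm("phantom has no mask named '", hm$mask %||% "tumor", "'")
  total <- schedule$baseline_duration + schedule$heating_duration +
    schedule$cooldown_duration
  n_frames <- max(1L, as.integer(round(total * schedule$frame_rate)))
  times <- (seq_len(n_frames) - 1) / schedule$frame_rate
  a_coef <- thermal_coefficient(calib)
  n_samp <- default_n_samples(phantom, geometry)

  mr <- motion_spec$max_rotation_deg %||% 0
  mt <- motion_spec$max_translation_mm %||% 0
  moving <- (mr > 0 || mt > 0)
  uniform_model <- hm$type %in% c("exponential", "uniform")
  nr <- phantom$grid$n_rows; nc <- phantom$grid$n_cols

  with_seed(seed, {
    motion <- cbind(rot = runif(n_frames, -mr, mr),
                    dx = runif(n_frames, -mt, mt),
                    dy = runif(n_frames, -mt, mt))
    if (!moving) motion[] <- 0

    # temperature-rise maps (ground truth, unmoved frame)
    dT <- array(0, c(nr, nc, n_frames))
    if (uniform_model) {
      amp_t <- schedule_delta_t(schedule, times)
      for (k in seq_len(n_frames)) dT[, , k] <- amp_t[k] * mask
    } else {
      for (k in seq_len(n_frames)) {
        tk <- times[k] - schedule$baseline_duration
        dT[, , k] <- if (tk >= 0 && tk <= schedule$heating_duration) hm$fun(tk)
                     else matrix(0, nr, nc)
      }
    }
    if (any(calib$T0 + dT <= -calib$c_over_b))
      stop_pactherm("heating model drives the Grueneisen parameter nonpositive ",
                    "(temperature below -c/b)")

    frames <- vector("list", n_frames)
    noise_ref <- NULL
    if (!moving && uniform_model) {
      # rf_k = rf_background + (1 + dT_k / a) * rf_masked
      ph_rest <- phantom; ph_rest$values[mask] <- 0
      ph_mask <- phantom; ph_mask$values[!mask] <- 0
      rf_rest <- project_sources(ph_rest$values, phantom$grid, geometry, calib,
                                 n_samp, 0)
      rf_mask <- project_sources(ph_mask$values, phantom$grid, geometry, calib,
                                 n_samp, 0)
      noise_ref <- max(abs(rf_rest + rf_mask))
      for (k in seq_len(n_frames)) {
        s <- rf_rest + (1 + amp_t[k] / a_coef) * rf_mask
        if (noise_sd > 0)
          s <- s + matrix(rnorm(length(s), sd = noise_sd * noise_ref),
                          nrow(s), ncol(s))
        frames[[k]] <- rf_frame(s, t0 = 0, sampling_rate = geometry$sampling_rate,
                                frame_time = times[k] * 60, geometry = geometry)
      }
    } else {
      for (k in seq_len(n_frames)) {
        vals <- phantom$values * (1 + dT[, , k] / a_coef)
        if (moving)
          vals <- apply_rigid(vals, motion[k, 1],
                              motion[k, 2] / phantom$grid$pixel_size,
                              motion[k, 3] / phantom$grid$pixel_size)
        s <- project_sources(vals, phantom$grid, geometry, calib, n_samp, 0)
        if (is.null(noise_ref)) noise_ref <- max(abs(s))
        if (noise_sd > 0)
          s <- s + matrix(rnorm(length(s), sd = noise_sd * noise_ref),
                          nrow(s), ncol(s))
        frames[[k]] <- rf_frame(s, t0 = 0, sampling_rate = geometry$sampling_rate,
                                frame_time = times[k] * 60, geometry = geometry)
      }
    }

    truth <- thermal_series(times - schedule$baseline_duration, dT,
                            roi = if (is.null(mask)) NULL else mask,
                            calibration = calib, core_temperature = calib$T0)
    series <- structure(list(frames = frames, times_min = times,
                             geometry = geometry, calibration = calib,
                             schedule = schedule, motion = motion),
                        class = "rf_series")
    list(frames = series, truth = truth)
  })
}

#' @export
print.rf_series <- function(x, ...) {
  cat(sprintf("RF series: %d frames over %.3g min (%g frames/min), %d elements\n",
              length(x$frames), max(x$times_min), x$schedule$frame_rate,
              x$geometry$n_elements))
  invisible(x)
}
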