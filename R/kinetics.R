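#' Fit an exponential-rise heating curve
#'
#' Fits `T(t) = a * (1 - exp(-k t)) + b` to a heating trace by
#' Levenberg-Marquardt nonlinear least squares ([minpack.lm::nlsLM()]):
#' `a` is the heating amplitude (deg C), `k` the thermal rate constant
#' (min^-1) and `b` the baseline temperature. Starting values use the
#' standard heuristic (baseline = first sample, amplitude = last - first,
#' rate = inverse time to reach 63% of the amplitude), with up to
#' `n_restarts` jittered restarts if the first fit fails; the best solution
#' by residual sum of squares wins.
#'
#' A constant trace has no identifiable rate: the fit is flagged degenerate
#' with `amp = 0` and undefined `rate`/`r_squared`.
#'
#' @param times strictly increasing times, minutes (>= 4 points).
#' @param temps temperatures, deg C.
#' @param n_restarts maximum number of jittered restarts.
#' @return object of class `heating_fit` with fields `amp`, `rate`,
#'   `baseline`, `r_squared`, `degenerate`, `fitted`, `residuals`, `data`.
#' @examples
#' t <- seq(0, 0.5, by = 0.02)
#' fit <- fit_exponential_rise(t, 15.865 * (1 - exp(-3.104 * t)) + 0.73)
#' coef(fit)
#' @export
fit_exponential_rise <- function(times, temps, n_restarts = 5) {
  times <- as.numeric(times); temps <- as.numeric(temps)
  if (length(times) < 4) stop_pactherm("need at least 4 points")
  if (length(times) != length(temps)) stop_pactherm("times and temps lengths differ")
  if (any(diff(times) <= 0)) stop_pactherm("times must be strictly increasing")

  if (sd(temps) < 1e-12 * max(1, abs(mean(temps)))) {
    return(structure(list(amp = 0, rate = NA_real_, baseline = mean(temps),
                          r_squared = NA_real_, degenerate = TRUE,
                          fitted = temps, residuals = rep(0, length(temps)),
                          data = data.frame(times = times, temps = temps)),
                     class = "heating_fit"))
  }

  b0 <- temps[1]
  a0 <- temps[length(temps)] - temps[1]
  if (abs(a0) < 1e-12) a0 <- max(temps) - min(temps)
  t63 <- times[which(abs(temps - b0) >= 0.632 * abs(a0))[1]]
  if (is.na(t63) || t63 <= times[1]) t63 <- times[max(2, length(times) %/% 3)]
  k0 <- 1 / max(t63 - times[1], diff(range(times)) / 100)

  dat <- data.frame(t = times - times[1], y = temps)
  best <- NULL; best_ss <- Inf
  starts <- list(c(a = a0, k = k0, b = b0))
  for (r in seq_len(n_restarts))
    starts[[r + 1]] <- c(a = a0 * exp(runif(1, -0.7, 0.7)),
                         k = k0 * exp(runif(1, -1, 1)),
                         b = b0 + runif(1, -0.2, 0.2) * abs(a0))
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * (1 - exp(-k * t)) + b, data = dat,
                        start = as.list(s),
                        lower = c(a = -Inf, k = 1e-9, b = -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      ss <- sum(residuals(fit)^2)
      if (ss < best_ss) { best <- fit; best_ss <- ss }
      break  # restarts are a fallback for non-convergence only
    }
  }
  if (is.null(best))
    stop_pactherm("exponential-rise fit did not converge after ",
                  n_restarts, " restarts (best residual: ",
                  format(best_ss), ")")
  cf <- coef(best)
  sst <- sum((temps - mean(temps))^2)
  structure(list(amp = unname(cf["a"]), rate = unname(cf["k"]),
                 baseline = unname(cf["b"]),
                 r_squared = 1 - best_ss / sst, degenerate = FALSE,
                 fitted = as.numeric(fitted(best)),
                 residuals = as.numeric(residuals(best)),
                 data = data.frame(times = times, temps = temps)),
            class = "heating_fit")
}

#' @export
print.heating_fit <- function(x, ...) {
  if (x$degenerate)
    cat(sprintf("Heating fit: degenerate (constant trace, baseline %.4g C)\n", x$baseline))
  else
    cat(sprintf("Heating fit: amp %.4g C, rate %.4g min^-1, baseline %.4g C, R^2 = %.4g\n",
                x$amp, x$rate, x$baseline, x$r_squared))
  invisible(x)
}

#' @export
coef.heating_fit <- function(object, ...) {
  c(amp = object$amp, rate = object$rate, baseline = object$baseline)
}

#' @export
predict.heating_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$times else
    if (is.data.frame(newdata)) newdata$times else as.numeric(newdata)
  if (object$degenerate) return(rep(object$baseline, length(t)))
  object$amp * (1 - exp(-object$rate * (t - object$data$times[1]))) + object$baseline
}

#' @export
residuals.heating_fit <- function(object, ...) object$residuals

#' @export
summary.heating_fit <- function(object, ...) {
  print(object)
  if (!object$degenerate)
    cat(sprintf("  %d points, residual sd %.3g C\n",
                nrow(object$data), sd(object$residuals)))
  invisible(object)
}

#' Percent change between heating cycles
#'
#' Compares the fitted amplitude and rate constant of two heating cycles,
#' relative to the first cycle; positive values mean a decrease. Stable
#' photothermal agents show near-zero changes between the first and last
#' cycles.
#'
#' @param first,last [fit_exponential_rise()] fits (or any object with `amp`
#'   and `rate`).
#' @return list with `amp_change_pct` and `rate_change_pct`.
#' @export
cycle_change <- function(first, last) {
  if (first$amp == 0 || first$rate == 0 || !is.finite(first$rate))
    stop_pactherm("first cycle has zero (or undefined) amplitude or rate")
  list(amp_change_pct = 100 * (first$amp - last$amp) / first$amp,
       rate_change_pct = 100 * (first$rate - last$rate) / first$rate)
}

#' Photostability summary
#'
#' Expresses a PA-amplitude trace under cumulative laser exposure as percent
#' of its initial value.
#'
#' @param amplitudes numeric vector of amplitudes, or a data.frame whose
#'   second column holds them.
#' @return numeric vector, `100 * A / A[1]`.
#' @export
photostability_summary <- function(amplitudes) {
  a <- if (is.data.frame(amplitudes)) amplitudes[[2]] else as.numeric(amplitudes)
  if (length(a) == 0 || !(a[1] > 0)) stop_pactherm("initial amplitude must be > 0")
  100 * a / a[1]
}

#' Extinction spectrum table
#'
#' @param wavelengths strictly increasing, nm.
#' @param extinction nonnegative extinction values (arbitrary units).
#' @param label optional name.
#' @export
spectrum_table <- function(wavelengths, extinction, label = NULL) {
  wavelengths <- as.numeric(wavelengths); extinction <- as.numeric(extinction)
  if (any(diff(wavelengths) <= 0)) stop_pactherm("wavelengths must be strictly increasing")
  if (any(extinction < 0)) stop_pactherm("extinction must be >= 0")
  if (length(wavelengths) != length(extinction)) stop_pactherm("length mismatch")
  structure(list(wavelengths = wavelengths, extinction = extinction,
                 label = label), class = "spectrum_table")
}

#' Percent change in extinction at query wavelengths
#'
#' Linearly interpolates both spectra at each query wavelength and reports
#' `100 * (before - after) / before` — positive for a loss of extinction
#' (e.g. plasmonic peak degradation after laser exposure).
#'
#' @param before,after [spectrum_table()]s.
#' @param wavelengths query wavelengths, nm; must lie within both spectra.
#' @return named numeric vector of percent changes.
#' @export
extinction_change <- function(before, after, wavelengths) {
  stopifnot(inherits(before, "spectrum_table"), inherits(after, "spectrum_table"))
  interp <- function(s, w) {
    if (any(w < min(s$wavelengths) | w > max(s$wavelengths)))
      stop_pactherm("query wavelength outside spectrum range [",
                    min(s$wavelengths), ", ", max(s$wavelengths), "] nm")
    stats::approx(s$wavelengths, s$extinction, xout = w)$y
  }
  b <- interp(before, wavelengths); a <- interp(after, wavelengths)
  if (any(b == 0)) stop_pactherm("zero extinction in 'before' at a query wavelength")
  setNames(100 * (b - a) / b, paste0(wavelengths, "nm"))
}
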