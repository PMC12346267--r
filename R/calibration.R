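#' Grueneisen thermometry calibration
#'
#' The Grueneisen parameter of soft tissue and tissue-mimicking phantoms is,
#' over the hyperthermia range, linear in temperature: Gamma(T) = b*T + c.
#' Photoacoustic amplitude is proportional to Gamma, so a relative amplitude
#' change maps to a temperature change through the single ratio c/b and the
#' baseline temperature T0 (see [thermal_coefficient()]). Two standard
#' calibrations are provided: a water-bath phantom (T0 = 22 C, c/b = 2.75) and
#' soft tissue (T0 = 37 C, c/b = 13.14).
#'
#' @param T0 baseline temperature, deg C.
#' @param c_over_b ratio of the linear-fit constants c and b, deg C.
#' @param eta_th thermal conversion fraction in (0, 1]; the fraction of
#'   absorbed optical energy converted to heat.
#' @return object of class `grueneisen_calibration`.
#' @seealso [thermal_coefficient()]
#' @export
grueneisen_calibration <- function(T0, c_over_b, eta_th = 1.0) {
  if (!(T0 + c_over_b > 0))
    stop_pactherm("T0 + c_over_b must be > 0 (Gamma must be positive at baseline)")
  if (!(eta_th > 0 && eta_th <= 1))
    stop_pactherm("eta_th must lie in (0, 1]")
  structure(list(T0 = T0, c_over_b = c_over_b, eta_th = eta_th),
            class = "grueneisen_calibration")
}

#' @rdname grueneisen_calibration
#' @param which `"phantom"` or `"tissue"`.
#' @export
standard_calibration <- function(which = c("tissue", "phantom")) {
  switch(match.arg(which),
         phantom = grueneisen_calibration(T0 = 22, c_over_b = 2.75),
         tissue  = grueneisen_calibration(T0 = 37, c_over_b = 13.14))
}

#' Thermal conversion coefficient
#'
#' The coefficient `a` converting relative photoacoustic amplitude change to
#' temperature change, `dT = a * dp/p0`. With Gamma linear in temperature,
#' `a = T0 + c/b` (deg C): 24.75 C for the standard phantom calibration and
#' 50.14 C for soft tissue.
#'
#' @param calib a [grueneisen_calibration()].
#' @return coefficient `a` in deg C.
#' @export
thermal_coefficient <- function(calib) {
  stopifnot(inherits(calib, "grueneisen_calibration"))
  calib$T0 + calib$c_over_b
}

#' @export
print.grueneisen_calibration <- function(x, ...) {
  cat(sprintf("Grueneisen calibration: T0 = %.4g C, c/b = %.4g C (a = %.4g C), eta_th = %.3g\n",
              x$T0, x$c_over_b, thermal_coefficient(x), x$eta_th))
  invisible(x)
}
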