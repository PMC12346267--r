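#' Wiener deconvolution of the electrical impulse response
#'
#' Per-channel frequency-domain deconvolution
#' `X = Y * conj(H) / (|H|^2 + noise_reg * max|H|^2)`, recovering the receive
#' bandwidth (particularly the low-frequency content that carries the
#' slowly-varying thermal signal) from band-limited RF records.
#'
#' @param rf an [rf_frame()].
#' @param eir an [impulse_response()]; its `center` marks time zero so the
#'   deconvolution introduces no delay.
#' @param noise_reg relative Wiener noise floor (> 0).
#' @return an [rf_frame()] of the same dimensions.
#' @export
deconvolve_eir <- function(rf, eir, noise_reg = 1e-3) {
  stopifnot(inherits(rf, "rf_frame"), inherits(eir, "impulse_response"))
  if (!(noise_reg > 0)) stop_pactherm("noise_reg must be > 0")
  n_t <- ncol(rf$samples)
  k <- eir$kernel
  if (length(k) >= n_t) stop_pactherm("impulse response longer than RF record")
  h <- numeric(n_t)
  idx <- ((seq_along(k) - eir$center) %% n_t) + 1
  h[idx] <- h[idx] + k
  H <- fft(h)
  denom <- Mod(H)^2 + noise_reg * max(Mod(H)^2)
  S <- mvfft(t(rf$samples))
  out <- Re(mvfft(S * (Conj(H) / denom), inverse = TRUE)) / n_t
  rf_frame(t(out), t0 = rf$t0, sampling_rate = rf$sampling_rate,
           frame_time = rf$frame_time, geometry = rf$geometry)
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward-backward ([signal::filtfilt()]) per
#' channel; zero phase so arrival times are preserved, DC gain 1.
#'
#' @param rf an [rf_frame()].
#' @param cutoff cutoff frequency, MHz (default 0.5); must be below Nyquist.
#' @param order filter order.
#' @return an [rf_frame()].
#' @export
lowpass <- function(rf, cutoff = 0.5, order = 4) {
  stopifnot(inherits(rf, "rf_frame"))
  nyq <- rf$sampling_rate / 2
  if (!(cutoff > 0 && cutoff < nyq))
    stop_pactherm(sprintf("cutoff %.3g MHz must lie in (0, Nyquist = %.3g MHz)",
                          cutoff, nyq))
  w <- cutoff / nyq
  bf <- signal::butter(order, w, type = "low")
  # odd-reflection padding suppresses the zero-state edge transients of
  # filtfilt; the transient length scales with the inverse normalized cutoff
  n_pad <- min(ceiling(12 / w), ncol(rf$samples) - 1)
  filtered <- t(apply(rf$samples, 1, function(x) {
    n <- length(x)
    pre <- 2 * x[1] - x[(n_pad + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - n_pad)]
    y <- signal::filtfilt(bf, c(pre, x, post))
    y[(n_pad + 1):(n_pad + n)]
  }))
  rf_frame(filtered, t0 = rf$t0, sampling_rate = rf$sampling_rate,
           frame_time = rf$frame_time, geometry = rf$geometry)
}

# --- rigid resampling -------------------------------------------------------

# Forward rigid transform of an image: rotate by `rotation_deg` (CCW, about
# the image center) then translate by (dx, dy) pixels (x along columns, y
# along rows). Output sampled on the input grid by bilinear interpolation,
# zero outside.
apply_rigid <- function(values, rotation_deg, dx_px = 0, dy_px = 0) {
  values <- as.matrix(values)
  nr <- nrow(values); nc <- ncol(values)
  th <- rotation_deg * pi / 180
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  # inverse map: source = R^-1 (dest - center - d) + center
  jx <- rep(seq_len(nc), each = nr) - cx - dx_px
  iy <- rep(seq_len(nr), nc) - cy - dy_px
  sx <- cos(th) * jx + sin(th) * iy + cx
  sy <- -sin(th) * jx + cos(th) * iy + cy
  bilinear_sample(values, sy, sx, nr, nc)
}

# Undo an estimated (rotation, shift) in one bilinear resample:
# out(p) = values(R_theta (p - c + s) + c)
unregister <- function(values, rotation_deg, sx, sy) {
  nr <- nrow(values); nc <- ncol(values)
  th <- rotation_deg * pi / 180
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  jx <- rep(seq_len(nc), each = nr) - cx + sx
  iy <- rep(seq_len(nr), nc) - cy + sy
  qx <- cos(th) * jx - sin(th) * iy + cx
  qy <- sin(th) * jx + cos(th) * iy + cy
  bilinear_sample(values, qy, qx, nr, nc)
}

bilinear_sample <- function(values, si, sj, nr, nc) {
  i0 <- floor(si); j0 <- floor(sj)
  fi <- si - i0; fj <- sj - j0
  g <- function(i, j) {
    ok <- i >= 1 & i <= nr & j >= 1 & j <= nc
    v <- numeric(length(i))
    v[ok] <- values[cbind(i[ok], j[ok])]
    v
  }
  out <- (1 - fi) * (1 - fj) * g(i0, j0) + (1 - fi) * fj * g(i0, j0 + 1) +
    fi * (1 - fj) * g(i0 + 1, j0) + fi * fj * g(i0 + 1, j0 + 1)
  matrix(out, nr, nc)
}

# Separable Gaussian blur (reflected edges); sigma in pixels, 0 disables.
gaussian_smooth <- function(values, sigma) {
  if (sigma <= 0) return(values)
  w <- ceiling(3 * sigma)
  k <- exp(-((-w):w)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth1 <- function(m) {
    n <- nrow(m)
    idx <- c(pmin(pmax(1:(n + 2 * w) - w, 1), n))
    padded <- m[idx, , drop = FALSE]
    out <- apply(padded, 2, function(col) stats::filter(col, k, sides = 2))
    out[(w + 1):(w + n), , drop = FALSE]
  }
  t(smooth1(t(smooth1(values))))
}

# Zero-padded cross-correlation surface of two equal-size matrices (mean
# subtracted). Returns the surface (shift (0,0) at [1,1], negative shifts
# wrapped) and the normalization ||a|| * ||b||.
xcorr2 <- function(a, b) {
  nr <- nrow(a); nc <- ncol(a)
  pr <- nextn(2 * nr, 2); pc <- nextn(2 * nc, 2)
  pa <- matrix(0, pr, pc); pb <- matrix(0, pr, pc)
  a0 <- a - mean(a); b0 <- b - mean(b)
  pa[1:nr, 1:nc] <- a0; pb[1:nr, 1:nc] <- b0
  surf <- Re(fft(fft(pa) * Conj(fft(pb)), inverse = TRUE)) / (pr * pc)
  list(surface = surf, norm = sqrt(sum(a0^2)) * sqrt(sum(b0^2)),
       pr = pr, pc = pc)
}

# Peak of the cross-correlation surface with 3-point parabolic subpixel
# refinement; returns shift (dy, dx) of `a` relative to `b` (a(p) = b(p - s))
# and the normalized peak value.
xcorr_peak <- function(a, b, subpixel = TRUE) {
  xc <- xcorr2(a, b)
  surf <- xc$surface
  pk <- arrayInd(which.max(surf), dim(surf))
  refine <- function(vm, v0, vp) {
    den <- vm + vp - 2 * v0
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (vm - vp) / den))
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  i <- pk[1]; j <- pk[2]
  di <- dj <- 0
  if (subpixel) {
    di <- refine(surf[wrap(i - 1, xc$pr), j], surf[i, j], surf[wrap(i + 1, xc$pr), j])
    dj <- refine(surf[i, wrap(j - 1, xc$pc)], surf[i, j], surf[i, wrap(j + 1, xc$pc)])
  }
  # unwrap to signed shifts
  sy <- i - 1; if (sy > xc$pr / 2) sy <- sy - xc$pr
  sx <- j - 1; if (sx > xc$pc / 2) sx <- sx - xc$pc
  list(dy = sy + di, dx = sx + dj,
       value = surf[i, j] / max(xc$norm, .Machine$double.eps))
}

image_values <- function(x) if (inherits(x, "pa_image")) x$values else as.matrix(x)

#' Select the best-matching frame by cross-correlation
#'
#' Returns the candidate whose normalized 2D cross-correlation with the
#' reference has the highest peak — the motion-mitigating frame selection
#' used when several frames are acquired per position. Ties break to the
#' lowest index.
#'
#' @param candidates nonempty list of [pa_image()]s (or matrices), equal shapes.
#' @param reference a [pa_image()] or matrix of the same shape.
#' @param smooth_sigma Gaussian blur (pixels) applied before correlating,
#'   suppressing pixel noise; 0 disables.
#' @return integer index into `candidates`.
#' @export
select_frame <- function(candidates, reference, smooth_sigma = 1) {
  if (length(candidates) == 0) stop_pactherm("empty candidate list")
  ref <- gaussian_smooth(image_values(reference), smooth_sigma)
  scores <- vapply(candidates, function(cand) {
    v <- image_values(cand)
    if (!identical(dim(v), dim(ref))) stop_pactherm("candidate shape mismatch")
    xcorr_peak(gaussian_smooth(v, smooth_sigma), ref, subpixel = FALSE)$value
  }, numeric(1))
  which.max(scores)
}

#' Rigid transform description
#'
#' @param rotation degrees in (-180, 180].
#' @param translation length-2 numeric (dx, dy), mm.
#' @export
rigid_transform <- function(rotation, translation) {
  rotation <- ((rotation + 180) %% 360) - 180
  if (rotation == -180) rotation <- 180
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: rotation %.3f deg, translation (%.3f, %.3f) mm\n",
              x$rotation, x$translation[1], x$translation[2]))
  invisible(x)
}

#' Rigid registration by cross-correlation with least-squares refinement
#'
#' Estimates the rotation + translation mapping `fixed` onto `moving` and
#' resamples `moving` back onto `fixed`. A coarse stage gets into the basin
#' of attraction — rotation scan with golden-section refinement of the
#' normalized cross-correlation peak, subpixel translation from the
#' parabola-refined peak — followed by a joint Nelder-Mead minimization of
#' the sum of squared differences over (rotation, dx, dy), the
#' maximum-likelihood estimate under white noise.
#'
#' @param moving,fixed [pa_image()]s (or matrices) of the same shape.
#' @param max_rotation_deg rotation search half-range, degrees.
#' @param coarse_step_deg spacing of the coarse rotation scan.
#' @param smooth_sigma Gaussian blur (pixels) applied to the coarse-stage
#'   copies only, suppressing pixel noise; 0 disables.
#' @return list with `transform` (a [rigid_transform()]; translation in mm
#'   when the input carries a grid, otherwise pixels) and `registered`
#'   (`moving` resampled onto `fixed`, bilinear).
#' @export
register_rigid <- function(moving, fixed, max_rotation_deg = 10,
                           coarse_step_deg = 1, smooth_sigma = 1) {
  mv <- image_values(moving); fx <- image_values(fixed)
  if (!identical(dim(mv), dim(fx))) stop_pactherm("image shapes differ")
  if (sd(mv) == 0 || sd(fx) == 0)
    stop_pactherm("cannot register a flat (zero-variance) image")
  # coarse stage on lightly smoothed copies (suppresses pixel noise)
  mv_s <- gaussian_smooth(mv, smooth_sigma)
  fx_s <- gaussian_smooth(fx, smooth_sigma)
  score <- function(theta)
    xcorr_peak(apply_rigid(mv_s, -theta), fx_s, subpixel = FALSE)$value
  thetas <- seq(-max_rotation_deg, max_rotation_deg, by = coarse_step_deg)
  coarse <- vapply(thetas, score, numeric(1))
  t_best <- thetas[which.max(coarse)]
  lo <- max(-max_rotation_deg, t_best - coarse_step_deg)
  hi <- min(max_rotation_deg, t_best + coarse_step_deg)
  opt <- optimize(score, c(lo, hi), maximum = TRUE, tol = 1e-3)
  theta <- if (opt$objective >= max(coarse)) opt$maximum else t_best
  pk <- xcorr_peak(apply_rigid(mv_s, -theta), fx_s, subpixel = TRUE)
  # joint least-squares refinement on the raw images
  ssd <- function(p) sum((unregister(mv, p[1], p[2], p[3]) - fx)^2)
  ref <- stats::optim(c(theta, pk$dx, pk$dy), ssd, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10))
  theta <- ref$par[1]; s <- ref$par[2:3]
  registered <- unregister(mv, theta, s[1], s[2])
  # report the forward transform (fixed -> moving): d = R_theta %*% s
  th <- theta * pi / 180
  d <- c(cos(th) * s[1] - sin(th) * s[2],
         sin(th) * s[1] + cos(th) * s[2])
  px <- if (inherits(moving, "pa_image")) moving$grid$pixel_size else 1
  reg_img <- if (inherits(fixed, "pa_image"))
    pa_image(pmax(registered, if (fixed$polarity == "amplitude") 0 else -Inf),
             fixed$grid, fixed$polarity)
  else registered
  list(transform = rigid_transform(theta, d * px), registered = reg_img,
       peak_correlation = pk$value)
}
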