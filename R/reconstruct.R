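#' Reconstructed photoacoustic image
#'
#' @param values `n_rows x n_cols` matrix.
#' @param grid the [image_grid()] the image lives on.
#' @param polarity `"bipolar"` (raw delay-and-sum output) or `"amplitude"`
#'   (nonnegative, after [amplitude_image()]).
#' @export
pa_image <- function(values, grid, polarity = c("bipolar", "amplitude")) {
  polarity <- match.arg(polarity)
  values <- as.matrix(values)
  stopifnot(inherits(grid, "image_grid"),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  if (polarity == "amplitude" && any(values < 0))
    stop_pactherm("amplitude images must be nonnegative")
  structure(list(values = values, grid = grid, polarity = polarity),
            class = "pa_image")
}

#' @export
print.pa_image <- function(x, ...) {
  cat(sprintf("PA image (%s): %d x %d @ %.3g mm, range [%.3g, %.3g]\n",
              x$polarity, nrow(x$values), ncol(x$values), x$grid$pixel_size,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Precompute the sparse delay-and-sum projector
#'
#' Builds the sparse linear map from the flattened RF record (element-major,
#' time within element) to image pixels that implements delay-and-sum
#' reconstruction as a single matrix multiplication. For pixel x and element
#' e the delay `|x - e| / c` is mapped to a fractional sample index and
#' spread over the two bracketing samples by linear interpolation (or one
#' sample, nearest-neighbor). Pixel rows are normalized by the number of
#' contributing elements.
#'
#' Half-time truncation: with `half_time = TRUE`, only samples recorded
#' before `half_time_bound` (default `ring_radius / c`, the first half of a
#' record covering the ring transit) are used, so each pixel is reconstructed
#' from its near-side elements only. Direct arrivals from the field of view
#' reach the near side within this bound; later samples are dominated by
#' in-ring reflections and are discarded.
#'
#' @param geometry a [ring_geometry()].
#' @param grid an [image_grid()]; must lie strictly inside the ring.
#' @param n_samples length of the RF records the projector will be applied to.
#' @param t0 time of the first RF sample, us.
#' @param half_time logical; apply half-time truncation.
#' @param half_time_bound truncation time, us; default `ring_radius / c`.
#' @param interp `"linear"` or `"nearest"`.
#' @return object of class `sparse_projector`.
#' @export
build_projector <- function(geometry, grid, n_samples, t0 = 0,
                            half_time = TRUE, half_time_bound = NULL,
                            interp = c("linear", "nearest")) {
  stopifnot(inherits(geometry, "ring_geometry"), inherits(grid, "image_grid"))
  interp <- match.arg(interp)
  r_fov <- grid_max_radius(grid)
  if (r_fov >= geometry$ring_radius)
    stop_pactherm("reconstruction grid extends outside the transducer ring")
  c0 <- geometry$speed_of_sound; fs <- geometry$sampling_rate
  bound <- if (half_time) (half_time_bound %||% (geometry$ring_radius / c0)) else Inf
  n_px <- grid$n_rows * grid$n_cols
  xy <- grid_coords(grid)$xy
  ep <- element_positions(geometry)
  n_el <- geometry$n_elements
  n_samples <- as.integer(n_samples)

  ii <- jj <- xx <- vector("list", n_el)
  counts <- numeric(n_px)
  need_max <- 0
  for (e in seq_len(n_el)) {
    tau <- sqrt((xy[, 1] - ep[e, 1])^2 + (xy[, 2] - ep[e, 2])^2) / c0
    keep <- tau <= bound + 1e-9
    if (!any(keep)) next
    fi <- (tau[keep] - t0) * fs + 1
    px <- which(keep)
    if (interp == "linear") {
      i0 <- floor(fi); w <- fi - i0
      need_max <- max(need_max, max(i0) + 1)
      ii[[e]] <- c(px, px)
      jj[[e]] <- (e - 1) * n_samples + c(i0, i0 + 1)
      xx[[e]] <- c(1 - w, w)
    } else {
      i0 <- round(fi)
      need_max <- max(need_max, max(i0))
      ii[[e]] <- px
      jj[[e]] <- (e - 1) * n_samples + i0
      xx[[e]] <- rep(1, length(px))
    }
    counts[px] <- counts[px] + 1
  }
  if (need_max > n_samples)
    stop_pactherm(sprintf(
      "RF record too short: %d samples recorded but delays require %d (record must cover %.3g us)",
      n_samples, as.integer(need_max), t0 + (need_max - 1) / fs))
  if (any(counts == 0))
    stop_pactherm("some pixels receive no element contributions; relax half_time_bound")
  ii <- unlist(ii); jj <- unlist(jj); xx <- unlist(xx)
  xx <- xx / counts[ii]
  ok <- xx != 0
  weights <- Matrix::sparseMatrix(i = ii[ok], j = jj[ok], x = xx[ok],
                                  dims = c(n_px, n_el * n_samples))
  structure(list(weights = weights, geometry = geometry, grid = grid,
                 n_samples = n_samples, t0 = t0, half_time = half_time,
                 half_time_bound = bound, interp = interp,
                 element_counts = counts),
            class = "sparse_projector")
}

#' @export
print.sparse_projector <- function(x, ...) {
  cat(sprintf("Sparse DAS projector: %d x %d px <- %d el x %d samples, %s, half-time %s, %.3g%% nonzero\n",
              x$grid$n_rows, x$grid$n_cols, x$geometry$n_elements, x$n_samples,
              x$interp, if (x$half_time) sprintf("<= %.3g us", x$half_time_bound) else "off",
              100 * length(x$weights@x) / prod(dim(x$weights))))
  invisible(x)
}

#' Delay-and-sum reconstruction by sparse matrix multiplication
#'
#' @param rf an [rf_frame()] whose dimensions match the projector.
#' @param projector a [build_projector()] result.
#' @return a bipolar [pa_image()].
#' @export
das_reconstruct <- function(rf, projector) {
  stopifnot(inherits(rf, "rf_frame"), inherits(projector, "sparse_projector"))
  if (nrow(rf$samples) != projector$geometry$n_elements ||
      ncol(rf$samples) != projector$n_samples)
    stop_pactherm(sprintf(
      "RF shape (%d x %d) does not match projector (%d elements x %d samples)",
      nrow(rf$samples), ncol(rf$samples),
      projector$geometry$n_elements, projector$n_samples))
  v <- as.numeric(projector$weights %*% as.vector(t(rf$samples)))
  pa_image(matrix(v, projector$grid$n_rows, projector$grid$n_cols),
           projector$grid, "bipolar")
}

#' Naive loop delay-and-sum (reference implementation)
#'
#' Direct delay-index-sum over pixels and elements with the same delay,
#' interpolation, truncation and normalization rules as the sparse projector.
#' Serves as an independent oracle for [das_reconstruct()]; quadratic cost,
#' use on small cases only.
#'
#' @inheritParams build_projector
#' @param rf an [rf_frame()].
#' @return a bipolar [pa_image()].
#' @export
das_naive <- function(rf, geometry, grid, half_time = TRUE,
                      half_time_bound = NULL, interp = c("linear", "nearest")) {
  stopifnot(inherits(rf, "rf_frame"), inherits(geometry, "ring_geometry"),
            inherits(grid, "image_grid"))
  interp <- match.arg(interp)
  c0 <- geometry$speed_of_sound; fs <- geometry$sampling_rate
  bound <- if (half_time) (half_time_bound %||% (geometry$ring_radius / c0)) else Inf
  n_t <- ncol(rf$samples)
  co <- grid_coords(grid)
  out <- matrix(0, grid$n_rows, grid$n_cols)
  for (i in seq_len(grid$n_rows)) {
    for (j in seq_len(grid$n_cols)) {
      acc <- 0; n_contrib <- 0L
      for (e in seq_len(geometry$n_elements)) {
        dx <- co$x[j] - geometry$ring_radius * cos(geometry$element_angles[e])
        dy <- co$y[i] - geometry$ring_radius * sin(geometry$element_angles[e])
        tau <- sqrt(dx * dx + dy * dy) / c0
        if (tau > bound + 1e-9) next
        fi <- (tau - rf$t0) * fs + 1
        if (interp == "linear") {
          i0 <- floor(fi); w <- fi - i0
          if (i0 < 1 || i0 + 1 > n_t)
            stop_pactherm(sprintf("RF record too short: sample %d needed, %d recorded",
                                  as.integer(i0 + 1), n_t))
          acc <- acc + (1 - w) * rf$samples[e, i0] + w * rf$samples[e, i0 + 1]
        } else {
          i0 <- round(fi)
          if (i0 < 1 || i0 > n_t)
            stop_pactherm(sprintf("RF record too short: sample %d needed, %d recorded",
                                  as.integer(i0), n_t))
          acc <- acc + rf$samples[e, i0]
        }
        n_contrib <- n_contrib + 1L
      }
      out[i, j] <- if (n_contrib > 0) acc / n_contrib else 0
    }
  }
  pa_image(out, grid, "bipolar")
}

#' Absolute-value amplitude image
#'
#' @param image a bipolar [pa_image()].
#' @return a nonnegative amplitude [pa_image()].
#' @export
amplitude_image <- function(image) {
  stopifnot(inherits(image, "pa_image"))
  pa_image(abs(image$values), image$grid, "amplitude")
}

#' Mean image value over a region of interest
#'
#' @param image a [pa_image()].
#' @param mask logical matrix of the same shape; must select at least one pixel.
#' @return scalar mean over the masked pixels.
#' @export
roi_mean <- function(image, mask) {
  stopifnot(inherits(image, "pa_image"))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(image$values)))
    stop_pactherm("mask shape does not match image")
  if (!any(mask)) stop_pactherm("empty ROI mask")
  mean(image$values[mask])
}
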