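#' Build a digital absorption phantom
#'
#' Rasterizes a list of primitives (disks and axis-rotated ellipses) onto an
#' [image_grid()], producing a map of specific optical absorption (arbitrary
#' energy-density units) plus a named boolean mask per primitive. Overlapping
#' primitives add. The map is the spatial pattern of absorbed optical energy
#' that seeds the photoacoustic pressure rise.
#'
#' @param primitives list of primitive descriptions. Each is a list with
#'   `type` ("disk" or "ellipse"), `center` (x, y in mm), `amplitude` (>= 0),
#'   a `name` used for its mask, and either `radius` (disk, mm) or `radii`
#'   (ellipse semi-axes, mm) with optional `angle` (degrees, CCW).
#' @param grid an [image_grid()].
#' @param ring_radius radius of the surrounding transducer ring, mm; every
#'   primitive (and the grid) must lie strictly inside it.
#' @return An object of class `absorption_map`: `values` (n_rows x n_cols,
#'   all >= 0), `grid`, and `masks` (named list of logical matrices).
#' @examples
#' ph <- make_phantom(
#'   list(list(type = "disk", center = c(0, 0), radius = 2,
#'             amplitude = 1, name = "tumor")),
#'   image_grid(64, 64, 0.1))
#' sum(ph$masks$tumor) * 0.1^2   # ~ pi * 2^2
#' @export
make_phantom <- function(primitives, grid, ring_radius = 40) {
  stopifnot(inherits(grid, "image_grid"))
  if (grid_max_radius(grid) >= ring_radius)
    stop_pactherm("grid extends outside the transducer ring")
  values <- matrix(0, grid$n_rows, grid$n_cols)
  masks <- list()
  co <- grid_coords(grid)
  for (k in seq_along(primitives)) {
    p <- primitives[[k]]
    if (is.null(p$type)) stop_pactherm("primitive without a type")
    amp <- p$amplitude %||% 1
    if (amp < 0) stop_pactherm("primitive amplitude must be >= 0")
    ctr <- as.numeric(p$center)
    if (identical(p$type, "disk")) {
      radii <- rep(as.numeric(p$radius), 2); ang <- 0
    } else if (identical(p$type, "ellipse")) {
      radii <- as.numeric(p$radii); ang <- (p$angle %||% 0) * pi / 180
    } else stop_pactherm("unknown primitive type: ", p$type)
    if (any(radii <= 0)) stop_pactherm("primitive radii must be > 0")
    if (sqrt(sum(ctr^2)) + max(radii) >= ring_radius)
      stop_pactherm(sprintf("primitive %d extends outside the ring (radius %g mm)",
                            k, ring_radius))
    dx <- outer(rep(1, grid$n_rows), co$x - ctr[1])
    dy <- outer(co$y - ctr[2], rep(1, grid$n_cols))
    u <- cos(ang) * dx + sin(ang) * dy
    v <- -sin(ang) * dx + cos(ang) * dy
    inside <- (u / radii[1])^2 + (v / radii[2])^2 <= 1
    values <- values + amp * inside
    masks[[p$name %||% paste0("p", k)]] <- inside
  }
  structure(list(values = values, grid = grid, masks = masks,
                 ring_radius = ring_radius),
            class = "absorption_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.absorption_map <- function(x, ...) {
  cat(sprintf("Absorption map: %d x %d @ %.3g mm, %d primitive mask(s): %s\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$pixel_size,
              length(x$masks), paste(names(x$masks), collapse = ", ")))
  invisible(x)
}
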