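#' Pixel grid for phantoms and reconstructed images
#'
#' A regular 2D grid of square pixels in world coordinates (mm), ring center
#' at the origin. Pixels are addressed by (row, column); the world position of
#' pixel (i, j) centers is `origin + (j - 1, i - 1) * pixel_size`, with x along
#' columns and y along rows. By default the grid is centered on the origin.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param pixel_size pixel edge length, mm.
#' @param origin length-2 numeric, world (x, y) of the center of pixel (1, 1);
#'   `NULL` centers the grid on the ring axis.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(n_rows, n_cols, pixel_size, origin = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, pixel_size > 0)
  if (is.null(origin))
    origin <- c(-(n_cols - 1) / 2 * pixel_size, -(n_rows - 1) / 2 * pixel_size)
  stopifnot(length(origin) == 2)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_size = pixel_size, origin = as.numeric(origin)),
            class = "image_grid")
}

#' Pixel-center world coordinates
#'
#' @param grid an [image_grid()].
#' @return list with `x` (length `n_cols`), `y` (length `n_rows`) in mm, and
#'   `xy`, an `(n_rows*n_cols) x 2` matrix of all pixel centers in
#'   column-major (R matrix) order.
#' @export
grid_coords <- function(grid) {
  stopifnot(inherits(grid, "image_grid"))
  x <- grid$origin[1] + (seq_len(grid$n_cols) - 1) * grid$pixel_size
  y <- grid$origin[2] + (seq_len(grid$n_rows) - 1) * grid$pixel_size
  list(x = x, y = y,
       xy = cbind(x = rep(x, each = grid$n_rows), y = rep(y, grid$n_cols)))
}

# Largest pixel-center distance from the ring axis (the field-of-view radius).
grid_max_radius <- function(grid) {
  co <- grid_coords(grid)
  rx <- range(co$x); ry <- range(co$y)
  sqrt(max(rx^2) + max(ry^2))
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("Image grid: %d x %d pixels, %.3g mm/pixel, origin (%.3g, %.3g) mm\n",
              x$n_rows, x$n_cols, x$pixel_size, x$origin[1], x$origin[2]))
  invisible(x)
}
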