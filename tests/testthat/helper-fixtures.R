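# Shared fixture builders; everything is generated in code.

small_geometry <- function(n_elements = 16, ...) {
  ring_geometry(n_elements = n_elements, ...)
}

# phantom with a single centered disk named "tumor"
disk_phantom <- function(grid, radius = 2, amplitude = 1, center = c(0, 0),
                         ring_radius = 40) {
  make_phantom(list(list(type = "disk", center = center, radius = radius,
                         amplitude = amplitude, name = "tumor")),
               grid, ring_radius = ring_radius)
}

# near-point source (single pixel) at a world position; grid must be odd-sized
# and centered on the source for exact pixel alignment
point_phantom <- function(center = c(0, 0), n = 65, pixel_size = 0.1) {
  grd <- image_grid(n, n, pixel_size,
                    origin = c(center[1] - (n - 1) / 2 * pixel_size,
                               center[2] - (n - 1) / 2 * pixel_size))
  make_phantom(list(list(type = "disk", center = center,
                         radius = pixel_size / 4, amplitude = 1, name = "pt")),
               grd)
}

# smooth multi-blob image for registration / frame-selection tests; features
# spread across the frame so rotation has leverage
blob_image <- function(n = 96, n_blobs = 12, seed = 2) {
  set.seed(seed)
  img <- matrix(0, n, n)
  for (i in seq_len(n_blobs)) {
    cx <- runif(1, 0.15 * n, 0.85 * n); cy <- runif(1, 0.15 * n, 0.85 * n)
    s <- runif(1, 2, 6)
    img <- img + runif(1, 0.5, 1) *
      outer(seq_len(n), seq_len(n),
            function(a, b) exp(-((a - cy)^2 + (b - cx)^2) / (2 * s^2)))
  }
  img
}
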