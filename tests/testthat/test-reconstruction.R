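test_that("projector rows hold at most two samples per element", {
  geo <- ring_geometry(n_elements = 4, ring_radius = 10)
  grd <- image_grid(3, 3, 0.5)
  proj <- build_projector(geo, grd, n_samples = 400, half_time = FALSE)
  nnz_per_row <- tabulate(proj$weights@i + 1L, nbins = 9)
  expect_true(all(nnz_per_row <= 8))   # 2 per element x 4 elements
})

test_that("sparse projector equals the naive loop oracle", {
  geo <- small_geometry(16)
  grd <- image_grid(32, 32, 0.15)
  set.seed(7)
  n_t <- 1300
  rf <- rf_frame(matrix(rnorm(16 * n_t), 16, n_t), t0 = 0, sampling_rate = 40,
                 geometry = geo)
  for (ht in c(TRUE, FALSE)) {
    fast <- das_reconstruct(rf, build_projector(geo, grd, n_t, half_time = ht))
    slow <- das_naive(rf, geo, grd, half_time = ht)
    expect_lt(max(abs(fast$values - slow$values)) / max(abs(slow$values)), 1e-10)
  }
})

test_that("naive DAS is invariant to element ordering", {
  geo <- small_geometry(8)
  grd <- image_grid(12, 12, 0.2)
  ph <- disk_phantom(grd, radius = 0.8)
  rf <- forward_project(ph, geo)
  img <- das_naive(rf, geo, grd)
  set.seed(1)
  perm <- sample(8)
  geo_p <- geo; geo_p$element_angles <- geo$element_angles[perm]
  rf_p <- rf; rf_p$samples <- rf$samples[perm, ]
  img_p <- das_naive(rf_p, geo_p, grd)
  expect_equal(img_p$values, img$values, tolerance = 1e-12)
})

test_that("single-element backprojection is constant on circles about the element", {
  geo <- ring_geometry(n_elements = 1, ring_radius = 40)
  grd <- image_grid(31, 31, 0.2)
  set.seed(3)
  rf <- rf_frame(matrix(rnorm(1 * 1300), 1, 1300), 0, 40, geometry = geo)
  img <- das_naive(rf, geo, grd, half_time = FALSE)
  # pixels mirrored across the x-axis are equidistant from the element at (40, 0)
  expect_equal(img$values[1, ], img$values[31, ], tolerance = 1e-12)
})

test_that("zero RF reconstructs to a zero image; shape mismatches error", {
  geo <- small_geometry(8)
  grd <- image_grid(16, 16, 0.2)
  proj <- build_projector(geo, grd, 1300)
  img <- das_reconstruct(rf_frame(matrix(0, 8, 1300), 0, 40), proj)
  expect_true(all(img$values == 0))
  expect_error(das_reconstruct(rf_frame(matrix(0, 8, 1200), 0, 40), proj),
               "does not match")
})

test_that("too-short RF records are rejected naming the required length", {
  geo <- small_geometry(8)
  grd <- image_grid(16, 16, 0.2)
  err <- expect_error(build_projector(geo, grd, n_samples = 500), "too short")
  expect_match(conditionMessage(err), "500")
})

test_that("a point source is localized within one pixel at 0.15-mm pixels", {
  geo <- ring_geometry(n_elements = 64)
  for (ctr in list(c(0, 0), c(3.15, -2.1))) {
    n <- 41
    grd <- image_grid(n, n, 0.15, origin = c(ctr[1] - 20 * 0.15, ctr[2] - 20 * 0.15))
    ph <- make_phantom(list(list(type = "disk", center = ctr, radius = 0.03,
                                 amplitude = 1, name = "pt")), grd)
    rf <- forward_project(ph, geo)
    img <- das_reconstruct(rf, build_projector(geo, grd, ncol(rf$samples)))
    pk <- arrayInd(which.max(abs(img$values)), dim(img$values))
    expect_lte(max(abs(pk - c(21, 21))), 1)   # source sits at the center pixel
  }
})

test_that("half-time truncation removes a late synthetic echo", {
  geo <- small_geometry(32)
  grd <- image_grid(32, 32, 0.15)
  ph <- disk_phantom(grd, radius = 1)
  rf <- forward_project(ph, geo, n_samples = 1500)
  # synthetic reflection: arrives after ring_radius / c on every channel
  echo <- rf
  idx <- round((40 / 1.5 + 2) * 40)
  echo$samples[, idx:(idx + 3)] <- max(abs(rf$samples)) * 5
  on <- das_reconstruct(echo, build_projector(geo, grd, 1500, half_time = TRUE))
  off <- das_reconstruct(echo, build_projector(geo, grd, 1500, half_time = FALSE))
  clean <- das_reconstruct(rf, build_projector(geo, grd, 1500, half_time = TRUE))
  err_on <- max(abs(on$values - clean$values))
  err_off <- max(abs(off$values - clean$values))
  expect_lt(err_on, 1e-10 * max(abs(clean$values)))
  expect_gt(err_off, 0.5 * max(abs(clean$values)))
})

test_that("amplitude images and ROI means follow their definitions", {
  grd <- image_grid(4, 4, 0.1)
  img <- pa_image(matrix(-1, 4, 4), grd)
  expect_true(all(amplitude_image(img)$values == 1))
  img5 <- pa_image(matrix(5, 4, 4), grd)
  mask <- matrix(c(TRUE, rep(FALSE, 15)), 4, 4)
  expect_equal(roi_mean(img5, mask), 5)
  expect_error(roi_mean(img5, matrix(FALSE, 4, 4)), "empty")
  expect_error(roi_mean(img5, matrix(TRUE, 2, 2)), "shape")
})

test_that("ROI amplitude is linear in inclusion amplitude (dilution series)", {
  geo <- small_geometry(32)
  grd <- image_grid(48, 48, 0.1)
  proj <- NULL
  amps <- c(0.5, 1, 2, 4)
  means <- vapply(amps, function(a) {
    ph <- disk_phantom(grd, radius = 1.2, amplitude = a)
    rf <- forward_project(ph, geo)
    if (is.null(proj))
      proj <<- build_projector(geo, grd, ncol(rf$samples))
    roi_mean(amplitude_image(das_reconstruct(rf, proj)), ph$masks$tumor)
  }, numeric(1))
  expect_gt(cor(means, amps)^2, 0.99)
})
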