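test_that("the thermal coefficient equals T0 + c/b", {
  expect_equal(thermal_coefficient(standard_calibration("phantom")), 24.75)
  expect_equal(thermal_coefficient(standard_calibration("tissue")), 50.14)
  expect_equal(thermal_coefficient(grueneisen_calibration(30, 0)), 30)
  expect_error(grueneisen_calibration(-10, 5), "c_over_b")
  expect_error(grueneisen_calibration(22, 2.75, eta_th = 0), "eta_th")
})

test_that("relative change is zero at baseline and exact for scaled frames", {
  base <- matrix(runif(64, 0.5, 1), 8, 8)
  frames <- list(base, base, 1.1 * base)
  rel <- relative_change_series(frames, baseline_window = 1:2)
  expect_true(all(abs(rel$rel[, , 1]) < 1e-12, na.rm = TRUE))
  expect_equal(max(abs(rel$rel[, , 3] - 0.1), na.rm = TRUE), 0, tolerance = 1e-12)
})

test_that("pixels below the baseline validity floor are flagged invalid", {
  base <- matrix(1, 8, 8); base[1, 1] <- 0.001
  rel <- relative_change_series(list(base, base), 1)
  expect_true(is.na(rel$rel[1, 1, 2]))
  expect_false(anyNA(rel$rel[, , 2][-1]))
  expect_error(relative_change_series(list(matrix(0, 4, 4)), 1), "valid")
})

test_that("temperature conversion applies dT = a dp/p0 plus the core temperature", {
  tis <- standard_calibration("tissue")
  pha <- standard_calibration("phantom")
  rel <- array(0.1, c(2, 2, 1))
  expect_equal(temperature_series(rel, tis)$delta[1, 1, 1], 5.014)
  expect_equal(temperature_series(rel, pha)$delta[1, 1, 1], 2.475)
  ts0 <- temperature_series(array(0, c(2, 2, 1)), tis, core_temperature = 37)
  expect_true(all(ts0$delta + ts0$core_temperature == 37))
})

test_that("simulated sequences invert to the ground-truth temperature rise", {
  geo <- small_geometry(32)
  grd <- image_grid(48, 48, 0.1)
  ph <- disk_phantom(grd, radius = 1.5)
  cal <- standard_calibration("tissue")
  sch <- heating_schedule(baseline_duration = 1, heating_duration = 2,
                          cooldown_duration = 0, frame_rate = 1,
                          heating_model = list(type = "uniform", amp = 8,
                                               mask = "tumor"))
  sim <- simulate_thermometry_sequence(ph, sch, cal, geo, noise_sd = 0)
  proj <- build_projector(geo, grd, ncol(sim$frames$frames[[1]]$samples))
  imgs <- lapply(sim$frames$frames, function(f)
    amplitude_image(das_reconstruct(f, proj)))
  rel <- relative_change_series(imgs, baseline_window = 1, roi = ph$masks$tumor)
  hot <- rel$rel[, , 3][ph$masks$tumor]
  expect_lt(max(abs(hot - 8 / 50.14)) / (8 / 50.14), 0.01)
  ts <- temperature_series(rel, cal, core_temperature = 37,
                           times = sim$frames$times_min, roi = ph$masks$tumor)
  expect_equal(mean(ts$delta[, , 3][ph$masks$tumor], na.rm = TRUE), 8,
               tolerance = 0.01)
})

test_that("ROI metrics pool frames per interval with mean and median", {
  roi <- matrix(TRUE, 1, 3)
  maps <- array(rep(c(41, 43, 49), 4), c(1, 3, 4))
  ts <- thermal_series(times = c(0, 0.4, 1.0, 1.4), delta = maps, roi = roi,
                       core_temperature = 0)
  m <- roi_metrics(ts, interval = 1)
  expect_equal(nrow(m), 2)
  expect_equal(m$t50, c(43, 43))
  expect_equal(m$t_avg, rep((41 + 43 + 49) / 3, 2), tolerance = 1e-12)
  const <- thermal_series(0:3, array(45, c(2, 2, 4)), matrix(TRUE, 2, 2),
                          core_temperature = 0)
  mc <- roi_metrics(const, interval = 2)
  expect_true(all(mc$t_avg == 45) && all(mc$t50 == 45))
  expect_error(roi_metrics(const, interval = 10), "longer than")
})

test_that("T50 tracks ground-truth medians for a known heating field", {
  n <- 12
  roi <- matrix(TRUE, n, n)
  times <- seq(0, 4.5, by = 0.5)
  grad <- matrix(seq(0, 6, length.out = n * n), n, n)
  maps <- array(0, c(n, n, length(times)))
  for (k in seq_along(times)) maps[, , k] <- 37 + grad * (1 - exp(-times[k]))
  ts <- thermal_series(times, maps - 37, roi, core_temperature = 37)
  m <- roi_metrics(ts, interval = 1)
  truth <- vapply(split(seq_along(times), floor(times - times[1])), function(ks)
    median(as.vector(maps[, , ks])), numeric(1))
  expect_lt(max(abs(m$t50 - truth)), 0.2)
})

test_that("CEM43T50 matches closed forms and is monotone", {
  expect_equal(cem43t50(rep(43, 10))$cem43t50, 10)
  expect_equal(cem43t50(rep(44, 10))$cem43t50, 20)
  expect_equal(cem43t50(rep(41, 10))$cem43t50, 0.625)
  # nondecreasing in every T50_i, linear in t
  set.seed(8)
  t50 <- runif(10, 39, 47)
  base <- cem43t50(t50)$cem43t50
  for (i in c(1, 5, 10)) {
    up <- t50; up[i] <- up[i] + 0.5
    expect_gte(cem43t50(up)$cem43t50, base)
  }
  expect_equal(cem43t50(t50, t = 2)$cem43t50, 2 * base)
  expect_error(cem43t50(rep(43, 3), t = 0), "interval")
})
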