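test_that("the voxelized tumor volume matches the analytic ellipsoid volume", {
  m <- build_tissue_model("water", voxel_size = 0.25)
  vol <- sum(m$labels == 4L) * 0.25^3
  analytic <- 4 / 3 * pi * 3.5 * 4 * 2.5
  expect_lt(abs(vol - analytic) / analytic, 0.05)
  expect_equal(m$optical["tumor", "mua"], 1.46)
  expect_equal(m$optical["muscle", "mua"], 0.1)
  expect_equal(m$optical["skin", "mus"], 100)
})

test_that("coupling choice switches the medium, not the tissue stack", {
  w <- build_tissue_model("water", voxel_size = 0.5)
  a <- build_tissue_model("air", voxel_size = 0.5)
  # identical tissue labelling; only the coupling medium's properties change
  expect_identical(w$labels, a$labels)
  expect_equal(w$optical["coupling", "mua"], 0.02)
  expect_equal(a$optical["coupling", "mua"], 0)
  expect_equal(w$thermal["coupling", "k"], 0.60)
  expect_equal(a$thermal["coupling", "k"], 0.026)
  expect_equal(w$pin_temp[1], 35)
  expect_equal(a$pin_temp[1], 20)
  # probes sit in the labels they are named for
  expect_equal(w$labels[matrix(w$probes$skin_center, 1)], 2L)
  expect_equal(w$labels[matrix(w$probes$tumor_center, 1)], 4L)
  expect_equal(w$labels[matrix(w$probes$tumor_skin, 1)], 4L)
  expect_equal(w$labels[matrix(w$probes$tumor_muscle, 1)], 4L)
})

test_that("voxel sizes that do not divide the extent are rejected", {
  expect_error(build_tissue_model("water", voxel_size = 0.3), "divide")
})

test_that("a transparent medium lets every photon escape", {
  m <- build_tissue_model("air", voxel_size = 1,
                          properties = list(skin = list(mua = 0, mus = 0),
                                            muscle = list(mua = 0, mus = 0),
                                            tumor = list(mua = 0, mus = 0)))
  pm <- mc_absorbed_power(m, beam_spec(), n_photons = 1e4, seed = 3)
  expect_equal(pm$escaped_fraction, 1)
  expect_true(all(pm$q == 0))
})

test_that("Monte Carlo deposition conserves energy and is seed-reproducible", {
  m <- build_tissue_model("water", voxel_size = 1)
  pm <- mc_absorbed_power(m, beam_spec(), n_photons = 5e4, seed = 12)
  vox_cm3 <- (m$voxel_size / 10)^3
  balance <- sum(pm$q) * vox_cm3 + pm$escaped_fraction * pm$launched_power_W
  expect_lt(abs(balance - pm$launched_power_W) / pm$launched_power_W, 1e-6)
  expect_true(all(pm$q >= 0))
  pm2 <- mc_absorbed_power(m, beam_spec(), n_photons = 5e4, seed = 12)
  expect_identical(pm$q, pm2$q)
  pm3 <- mc_absorbed_power(m, beam_spec(), n_photons = 5e4, seed = 13)
  expect_false(identical(pm$q, pm3$q))
})

test_that("per-layer deposition is statistically stable across seeds", {
  m <- build_tissue_model("water", voxel_size = 1)
  per_layer <- function(seed) {
    pm <- mc_absorbed_power(m, beam_spec(), n_photons = 2e4, seed = seed)
    vapply(2:4, function(l) sum(pm$q[m$labels == l]), numeric(1))
  }
  runs <- vapply(1:10, per_layer, numeric(3))
  mu <- rowMeans(runs)
  sdv <- apply(runs, 1, sd)
  expect_true(all(abs(runs - mu) <= 3.5 * sdv + 1e-12))
  # relative spread is small for the dominant layers
  expect_lt(max(sdv / mu), 0.05)
})

test_that("a pure absorber reproduces the Beer-Lambert escape fraction", {
  mua <- 1  # cm^-1
  m <- build_tissue_model("water", voxel_size = 0.5,
                          properties = list(
                            coupling = list(mua = mua, mus = 0),
                            skin = list(mua = mua, mus = 0),
                            muscle = list(mua = mua, mus = 0),
                            tumor = list(mua = mua, mus = 0)))
  pm <- mc_absorbed_power(m, beam_spec(gaussian_radius = 0.5, iris_radius = 0.4),
                          n_photons = 1e5, seed = 5)
  expect_equal(pm$escaped_fraction, exp(-mua * 2), tolerance = 0.02)
})

test_that("zero source with uniform boundaries stays at the steady state", {
  m <- build_tissue_model("water", voxel_size = 1, isothermal_coupling = FALSE)
  m$pin_temp <- rep(37, 4)
  pm <- mc_absorbed_power(m, beam_spec(), n_photons = 100, seed = 1)
  pm$q[] <- 0
  r <- pennes_simulate(m, pm, duration = 1, dt = 0.5)
  expect_lt(max(abs(r$T_final - 37)), 1e-9)
})

test_that("heating is monotone toward a plateau under a constant source", {
  m <- build_tissue_model("water", voxel_size = 1)
  pm <- mc_absorbed_power(m, beam_spec(), n_photons = 5e4, seed = 2)
  r <- pennes_simulate(m, pm, duration = 5, dt = 0.5)
  tc <- r$traces[, "tumor_center"]
  expect_true(all(diff(tc) > -1e-9))
  expect_gt(tc[length(tc)], 37)
  # approaching plateau: late increments much smaller than early ones
  expect_lt(diff(tc)[length(tc) - 1], 0.1 * max(diff(tc)))
})

test_that("the steady 1D slab profile matches the parabolic closed form", {
  # wide flat slab, uniform source, no perfusion, all boundaries at 37 C:
  # the interior column satisfies T(z) = 37 + Q z (L - z) / (2 kappa)
  nx <- 81L; nz <- 9L
  dims <- c(nx, nx, nz)
  labels <- array(1L, dims)
  thermal <- matrix(c(1000, 4000, 0.5, 0), 1)  # rho, c, k, w
  Q <- rep(2e5, prod(dims))                    # W/m^3
  res <- pactherm:::.pennes_lod_cpp(
    as.integer(labels), as.integer(dims), 0.5, thermal,
    1050, 3617, 37, 37, 0L, Q, 1, 900L, 900L,
    as.integer((nx %/% 2) + nx * (nx %/% 2) + nx * nx * (0:(nz - 1))))
  Tz <- res$T_final[(nx %/% 2 + 1) + nx * (nx %/% 2) + nx * nx * (0:(nz - 1))]
  dx <- 0.5e-3
  L <- (nz - 1) * dx
  z <- (0:(nz - 1)) * dx
  analytic <- 37 + 2e5 * z * (L - z) / (2 * 0.5)
  expect_lt(max(abs(Tz - analytic)) / max(analytic - 37), 0.01)
})

test_that("halving the voxel size changes the tumor-center endpoint by < 5%", {
  # trilinear interpolation at the exact tumor-center point, so the
  # comparison is not confounded by the probe voxel sitting at different
  # physical depths on the two grids
  interp_T <- function(r, m, pt) {
    g <- c((pt[1] + m$extent / 2) / m$voxel_size + 0.5,
           (pt[2] + m$extent / 2) / m$voxel_size + 0.5,
           pt[3] / m$voxel_size + 0.5)
    i0 <- floor(g); f <- g - i0
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, f, 1 - f))
      acc <- acc + w * r$T_final[i0[1] + dx, i0[2] + dy, i0[3] + dz]
    }
    acc
  }
  temps <- vapply(c(0.25, 0.125), function(vx) {
    m <- build_tissue_model("water", voxel_size = vx)
    pm <- mc_absorbed_power(m, beam_spec(), n_photons = 2e5, seed = 21)
    r <- pennes_simulate(m, pm, duration = 2, dt = 1)
    interp_T(r, m, m$tumor_center)
  }, numeric(1))
  rise <- temps - 37
  expect_lt(abs(rise[2] - rise[1]) / rise[2], 0.05)
})

test_that("identical runs compare as identical; grid mismatches error", {
  m <- build_tissue_model("air", voxel_size = 1)
  pm <- mc_absorbed_power(m, beam_spec(), n_photons = 2e4, seed = 4)
  r <- pennes_simulate(m, pm, duration = 1, dt = 0.5)
  cmp <- compare_configurations(r, r)
  expect_equal(cmp$open_air$final, cmp$submerged$final)
  expect_identical(cmp$open_air$ordering, cmp$submerged$ordering)
  expect_equal(cmp$summary$max_depth_mm[1], cmp$summary$max_depth_mm[2])
  m2 <- build_tissue_model("air", voxel_size = 0.5)
  pm2 <- mc_absorbed_power(m2, beam_spec(), n_photons = 2e4, seed = 4)
  r2 <- pennes_simulate(m2, pm2, duration = 1, dt = 0.5)
  expect_error(compare_configurations(r, r2), "identical grids")
})
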