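test_that("deconvolving the kernel by itself yields a sharp impulse", {
  geo <- small_geometry(4)
  eir <- eir_kernel(geo)
  n_t <- 1024
  x <- numeric(n_t)
  at <- 500
  x[at + seq_along(eir$kernel) - eir$center] <- eir$kernel
  dec <- deconvolve_eir(rf_frame(rbind(x), 0, 40), eir, noise_reg = 1e-6)
  y <- abs(dec$samples[1, ])
  expect_equal(which.max(y), at)
  # mainlobe + ringing of the recovered band spans ~0.5 us; outside it the
  # response must be far below the impulse peak
  expect_gt(max(y) / max(y[-((at - 20):(at + 20))]), 100)
})

test_that("a delta kernel is the identity", {
  set.seed(4)
  x <- rnorm(512)
  eir <- impulse_response(c(0, 1, 0), sampling_rate = 40, center = 2)
  dec <- deconvolve_eir(rf_frame(rbind(x), 0, 40), eir, noise_reg = 1e-12)
  expect_equal(dec$samples[1, ], x, tolerance = 1e-10)
})

test_that("band-limited broadband sources round-trip through convolution + deconvolution", {
  geo <- small_geometry(4)
  eir <- eir_kernel(geo)
  set.seed(9)
  bp <- signal::butter(4, c(2, 8) / 20, type = "pass")
  src <- numeric(1024)
  src[300:700] <- signal::filtfilt(bp, rnorm(401))
  k <- eir$kernel
  conv <- stats::filter(c(numeric(64), src, numeric(64)), k, sides = 2)[65:1088]
  dec <- deconvolve_eir(rf_frame(rbind(conv), 0, 40), eir, noise_reg = 1e-4)
  expect_gt(cor(dec$samples[1, ], src), 0.99)
})

test_that("deconvolution and lowpass are linear operators", {
  geo <- small_geometry(4)
  eir <- eir_kernel(geo)
  set.seed(11)
  a <- matrix(rnorm(2 * 512), 2)
  b <- matrix(rnorm(2 * 512), 2)
  for (op in list(function(m) deconvolve_eir(rf_frame(m, 0, 40), eir)$samples,
                  function(m) lowpass(rf_frame(m, 0, 40))$samples)) {
    lhs <- op(a + 2 * b)
    rhs <- op(a) + 2 * op(b)
    expect_lt(max(abs(lhs - rhs)), 1e-10 * max(abs(lhs)))
  }
})

test_that("zero-energy kernels are rejected", {
  expect_error(impulse_response(numeric(8), 40), "zero energy")
})

test_that("the low-pass filter has unit DC gain and the specified rolloff", {
  const <- rf_frame(matrix(3, 1, 400), 0, 40)
  expect_equal(lowpass(const)$samples[1, ], rep(3, 400), tolerance = 1e-6)
  tt <- (0:1999) / 40
  tone5 <- sin(2 * pi * 5 * tt)
  out5 <- lowpass(rf_frame(rbind(tone5), 0, 40))$samples[1, ]
  expect_lt(sd(out5[500:1500]) / sd(tone5), 0.01)
  tone_low <- sin(2 * pi * 0.05 * tt)
  out_low <- lowpass(rf_frame(rbind(tone_low), 0, 40))$samples[1, ]
  expect_lt(abs(sd(out_low[500:1500]) / sd(tone_low[500:1500]) - 1), 0.01)
  expect_error(lowpass(rf_frame(matrix(0, 1, 100), 0, 40), cutoff = 25),
               "Nyquist")
})

test_that("frame selection picks the exact copy over shifted or noisy frames", {
  ref <- blob_image()
  shifted <- pactherm:::apply_rigid(ref, 0, 10, 0)
  set.seed(1)
  noise <- matrix(rnorm(length(ref)), nrow(ref))
  expect_equal(select_frame(list(shifted, ref, noise), ref), 2L)
  expect_equal(select_frame(list(ref), ref), 1L)
  expect_equal(select_frame(list(ref, ref), ref), 1L)   # tie -> lowest index
  expect_error(select_frame(list(), ref), "empty")
})

test_that("the least-jittered frame is selected under noise", {
  ref <- blob_image()
  pk <- max(ref)
  hits <- 0
  for (trial in 1:100) {
    set.seed(trial + 200)
    jit <- c(0.5, 2, 4, 6)
    cands <- lapply(jit, function(j) {
      ang <- runif(1, 0, 2 * pi)
      pactherm:::apply_rigid(ref, 0, j * cos(ang), j * sin(ang)) +
        matrix(rnorm(length(ref), sd = pk / 10), nrow(ref))
    })
    if (select_frame(cands, ref) == 1L) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("registering an image to itself returns the identity transform", {
  ref <- blob_image()
  r <- register_rigid(ref, ref, max_rotation_deg = 3)
  expect_lt(abs(r$transform$rotation), 0.1)
  expect_lt(max(abs(r$transform$translation)), 0.1)
})

test_that("known shifts and rotations are recovered within a quarter pixel/degree", {
  ref <- blob_image()
  shift <- register_rigid(pactherm:::apply_rigid(ref, 0, 3, -2), ref,
                          max_rotation_deg = 3)
  expect_lt(abs(shift$transform$rotation), 0.25)
  expect_lt(max(abs(shift$transform$translation - c(3, -2))), 0.25)
  rot <- register_rigid(pactherm:::apply_rigid(ref, 2), ref, max_rotation_deg = 5)
  expect_lt(abs(rot$transform$rotation - 2), 0.25)
  expect_lt(max(abs(rot$transform$translation)), 0.25)
  expect_error(register_rigid(matrix(1, 8, 8), matrix(1, 8, 8)), "flat")
})

test_that("random rigid transforms are recovered at SNR 20 (median errors < 0.25)", {
  ref <- blob_image()
  pk <- max(ref)
  terr <- rerr <- numeric(50)
  for (i in 1:50) {
    set.seed(i + 400)
    th <- runif(1, -5, 5)
    d <- runif(2, -5, 5) * sample(c(1, 0.3), 2, replace = TRUE)
    mv <- pactherm:::apply_rigid(ref, th, d[1], d[2]) +
      matrix(rnorm(length(ref), sd = pk / 20), nrow(ref))
    r <- register_rigid(mv, ref, max_rotation_deg = 6)
    rerr[i] <- abs(r$transform$rotation - th)
    terr[i] <- max(abs(r$transform$translation - d))
  }
  expect_lt(median(rerr), 0.25)
  expect_lt(median(terr), 0.25)
})
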