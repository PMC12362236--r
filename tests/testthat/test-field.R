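test_that("spot-count rule reproduces the printed field layouts", {
  counts <- function(L, s) nrow(make_spot_grid(field_config(L, s, 500, 8)))
  expect_equal(counts(100, 5), 441)
  expect_equal(counts(100, 3), 1089)
  expect_equal(counts(40, 5), 81)
})

test_that("scan order is serpentine starting bottom-left", {
  g <- make_spot_grid(field_config(10, 4, 100, 2))   # 3 x 3 spots
  expect_equal(g$x_mm, c(-4, 0, 4, 4, 0, -4, -4, 0, 4))
  expect_equal(g$y_mm, rep(c(-4, 0, 4), each = 3))
})

test_that("Gaussian kernel has the right peak, width and cutoff", {
  s <- 2.38
  expect_equal(spot_kernel_dose(0, s, phi = 2), 2)
  expect_equal(spot_kernel_dose(s, s, phi = 1), exp(-0.5))
  expect_equal(spot_kernel_dose(5 * s + 1e-9, s), 0)
  expect_gt(spot_kernel_dose(5 * s - 1e-9, s), 0)
})

test_that("calibration sets the regional mean dose to the nominal dose", {
  cfg <- field_config(100, 3, 500, 8)
  g <- calibrate_spot_weights(make_spot_grid(cfg), cfg)
  dm <- dose_map(g, cfg)
  expect_equal(mean(dm$dose_Gy), 8, tolerance = 1e-9)
  # doubling the nominal dose doubles weight and dwell
  cfg2 <- cfg; cfg2$dose_Gy <- 16
  g2 <- calibrate_spot_weights(make_spot_grid(cfg2), cfg2)
  expect_equal(attr(g2, "phi") / attr(g, "phi"), 2, tolerance = 1e-12)
  expect_equal(attr(g2, "dwell") / attr(g, "dwell"), 2, tolerance = 1e-12)
})

test_that("charge calibration reproduces the reference delivery timing", {
  cfg <- field_config(40, 5, 500, 8)
  g <- calibrate_spot_weights(make_spot_grid(cfg), cfg)
  # dwell of the 81-spot reference field: (222.4 - 80 x 1) / 81 ms
  expect_equal(attr(g, "dwell"), (0.2224 - 0.080) / 81, tolerance = 1e-9)
  expect_equal(field_delivery_time(g, cfg), 0.2224, tolerance = 1e-9)
  # beam-on time scales inversely with current, transitions fixed
  cfg1 <- field_config(40, 5, 1, 8)
  g1 <- calibrate_spot_weights(make_spot_grid(cfg1), cfg1)
  expect_equal(attr(g1, "dwell") / attr(g, "dwell"), 500, tolerance = 1e-9)
})

test_that("dose map has the field's four-fold symmetry", {
  cfg <- field_config(40, 5, 500, 8)
  g <- calibrate_spot_weights(make_spot_grid(cfg), cfg)
  dm <- dose_map(g, cfg)
  M <- matrix(dm$dose_Gy, nrow = length(unique(dm$x_mm)))
  expect_equal(M, M[nrow(M):1, ], tolerance = 1e-12)
  expect_equal(M, M[, ncol(M):1], tolerance = 1e-12)
  expect_equal(M, t(M), tolerance = 1e-12)
})

test_that("voxel waveforms conserve the voxel dose from the dose map", {
  cfg <- field_config(40, 5, 500, 8)
  g <- calibrate_spot_weights(make_spot_grid(cfg), cfg)
  dm <- dose_map(g, cfg)
  for (pt in list(c(0.5, 0.5), c(-10.5, 4.5), c(19.5, 19.5))) {
    wf <- voxel_waveform(pt[1], pt[2], g, cfg)
    want <- dm$dose_Gy[dm$x_mm == pt[1] & dm$y_mm == pt[2]]
    expect_lt(abs(total_dose(wf) - want), 1e-9)
  }
  expect_error(voxel_waveform(100, 0, g, cfg), "outside")
})

test_that("single-spot field gives a single-segment waveform", {
  cfg <- field_config(4, 4, 100, 2)   # one spot
  g <- calibrate_spot_weights(make_spot_grid(cfg), cfg, kappa = 1e-3)
  expect_equal(nrow(g), 1)
  wf <- voxel_waveform(0.5, 0.5, g, cfg)
  expect_equal(nrow(wf), 1)
  expect_equal(wf$rate * (wf$t_end - wf$t_start),
               spot_kernel_dose(sqrt(0.5), cfg$sigma_mm, attr(g, "phi")),
               tolerance = 1e-12)
})

test_that("tiny-field fixture is deterministic", {
  a <- generate_fixture("tiny-field", seed = 1)
  b <- generate_fixture("tiny-field", seed = 1)
  expect_identical(a$dose, b$dose)
})

test_that("near-zero dose field yields a proportionally tiny ROOH map", {
  cfg <- field_config(10, 5, 100, 1e-3)
  r <- simulate_field(cfg, stride = 5)
  expect_true(all(r$voxels$rooh_uM < 1e-3))
  expect_true(all(r$voxels$rooh_uM >= 0))
})
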