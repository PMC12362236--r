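test_that("average dose rate is dose over field time", {
  expect_equal(adr(8, 0.2224), 35.97, tolerance = 1e-3)
  expect_equal(adr(8, 1.1944), 6.698, tolerance = 1e-3)
  expect_equal(adr(0, 1), 0)
  expect_error(adr(8, 0), "zero")
})

test_that("dose-averaged dose rate weights rates by spot dose", {
  expect_equal(dadr(2, 1000), 1000)
  expect_equal(dadr(c(1, 1), c(1000, 500)), 750)
  # homogeneity: scaling all rates scales the result
  expect_equal(dadr(c(1, 3), 7 * c(1000, 500)), 7 * dadr(c(1, 3), c(1000, 500)))
  expect_error(dadr(c(1, 2), 1), "length")
  expect_error(dadr(c(0, 0), c(1, 1)), "zero total dose")
})

test_that("PBS dose rate spans the 1%-99% dose window", {
  # constant delivery: PBSDR equals the instantaneous rate
  wf <- constant_waveform(10, 100)
  expect_equal(pbsdr(wf), 100, tolerance = 1e-9)
  # two 5 Gy bursts separated by 1 s: the window spans the gap
  wf2 <- dose_waveform(c(0, 1.05), c(0.05, 1.10), c(100, 100))
  expect_equal(pbsdr(wf2), 9.8 / 1.098, tolerance = 1e-9)
  # a trailing pause changes ADR but not PBSDR
  expect_equal(pbsdr(wf2, D = total_dose(wf2)), pbsdr(wf2))
})

test_that("RVH is a survival curve over the voxel volume", {
  x <- c(1, 2, 3, 4)
  cv <- rvh(x)
  expect_equal(cv$volume_fraction, c(1, 0.75, 0.5, 0.25))
  expect_true(all(diff(cv$volume_fraction) <= 0))
  # constant map: all mass at one value
  cv2 <- rvh(rep(2.5, 10))
  expect_true(all(cv2$rooh_uM == 2.5))
  expect_error(rvh(numeric(0)), "empty")
})

test_that("ROOH[v] and the sparing difference behave like DVH statistics", {
  x <- 1:100
  expect_equal(rooh_at_volume(x, 50), median(x))
  conv <- c(1.4, 1.5, 1.6); uhdr <- c(1.3, 1.35, 1.4)
  expect_equal(delta_rooh(conv, uhdr), 1.5 - 1.35)
  expect_equal(delta_rooh(conv, conv), 0)
  expect_error(delta_rooh(conv, uhdr[1:2]), "mismatch")
})

test_that("iso-ROOH inversion finds the dose with equal mean response", {
  d <- c(2, 5, 8, 10, 15)
  conv <- dose_response(d, 0.2 * d^1.1)
  uhdr <- dose_response(d, 0.18 * d^1.1)
  iso <- iso_rooh_equivalent(conv, uhdr, 10)
  # closed form: 0.2 x^1.1 = 0.18 * 10^1.1 -> x = 10 * 0.9^(1/1.1)
  expect_equal(iso$conv_dose_Gy, 10 * 0.9^(1 / 1.1), tolerance = 1e-3)
  expect_equal(iso$dmf, 10 / iso$conv_dose_Gy)
  # identical curves give a unit dose-modifying factor
  iso2 <- iso_rooh_equivalent(conv, conv, 10)
  expect_equal(iso2$dmf, 1, tolerance = 1e-6)
  expect_error(iso_rooh_equivalent(conv, uhdr, 30), "outside")
  expect_error(dose_response(d, c(1, 2, 3, 3, 2)), "increasing")
})

test_that("threshold fraction handles the edge cases", {
  x <- c(1, 1.2, 1.4, 1.6)
  expect_equal(fraction_below(x, 1.3), 50)
  expect_equal(fraction_below(x, 0.5), 0)
  expect_equal(fraction_below(x, 2), 100)
  expect_error(fraction_below(numeric(0), 1), "empty")
})

test_that("DADR >= PBSDR >= ADR on paper-style PBS voxel traces", {
  # needs a field large enough that distant spots contribute ~nothing
  # (on a toy 3x3 field every spot contributes and PBSDR < ADR)
  cfg <- field_config(40, 5, 500, 8)
  g <- calibrate_spot_weights(make_spot_grid(cfg), cfg)
  ft <- field_delivery_time(g, cfg)
  for (pt in list(c(0.5, 0.5), c(-10.5, 14.5))) {
    wf <- voxel_waveform(pt[1], pt[2], g, cfg)
    D <- total_dose(wf)
    d_j <- wf$rate * (wf$t_end - wf$t_start)
    a <- adr(D, ft); p <- pbsdr(wf, D); dd <- dadr(d_j, wf$rate)
    expect_true(dd >= p - 1e-9 && p >= a - 1e-9)
  }
})
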