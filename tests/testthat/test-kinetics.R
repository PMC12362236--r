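test_that("zero-dose waveform produces no hydroperoxide", {
  net <- skin_network()
  wf <- dose_waveform(numeric(0), numeric(0), numeric(0))
  res <- simulate_kinetics(net, wf, proton_y)
  expect_equal(res$final_rooh_uM, 0)
  expect_equal(max(res$time), 150)
})

test_that("with reactions disabled the solution is the exact linear limit", {
  rx <- ros_reaction_table()[0, ]
  net <- build_network(ros_species(), rx)
  wf <- constant_waveform(8, 100)
  res <- simulate_kinetics(net, wf, proton_y)
  # G * rho_w * D for every primary species, in micromolar
  expect_equal(unname(res$final_uM["H2O2"]), 0.0698 * 8, tolerance = 1e-6)
  expect_equal(unname(res$final_uM["e"]), 0.260 * 8, tolerance = 1e-6)
  expect_equal(unname(res$final_uM["H2"]), 0.0504 * 8, tolerance = 1e-6)
  expect_equal(unname(res$final_uM["ROOH"]), 0)
})

test_that("quiescent initial state stays constant over the full window", {
  net <- skin_network()
  wf <- dose_waveform(numeric(0), numeric(0), numeric(0))
  res <- simulate_kinetics(net, wf, proton_y, dense = TRUE)
  y0 <- initial_state_of(net)
  for (nm in c("O2", "GSH"))
    expect_true(all(abs(res$conc[, nm] - y0[[nm]]) < 1e-12))
  expect_true(all(res$conc[, setdiff(colnames(res$conc), c("O2", "GSH"))
                  ] == 0))
})

test_that("adaptive solution matches a fixed-step implicit oracle", {
  # 10 ms single pulse at 800 Gy/s; backward Euler at dt = 1e-8 s
  net <- skin_network()
  flashros:::load_network_c(net, proton_y, 1)
  y0 <- unname(initial_state_of(net))
  oracle <- flashros:::be_solve_c(y0, 0.01, 1e-8, 800)
  wf <- dose_waveform(0, 0.01, 800)
  cfg <- kinetics_config(post_time = 0)
  res <- simulate_kinetics(net, wf, proton_y, cfg)
  adaptive <- unname(res$conc[nrow(res$conc), ])
  rel <- abs(adaptive - oracle) / pmax(abs(oracle), 1e-15)
  expect_true(all(rel < 1e-4))
})

test_that("final time honours the post-irradiation window", {
  net <- skin_network()
  wf <- constant_waveform(2, 100)
  res <- simulate_kinetics(net, wf, proton_y)
  expect_equal(max(res$time), 0.02 + 150)
  expect_equal(res$beam_off, 0.02)
})

test_that("results are robust to a 10x tighter relative tolerance", {
  net <- skin_network()
  wf <- constant_waveform(8, 100)
  r1 <- simulate_kinetics(net, wf, proton_y, kinetics_config(rtol = 1e-6))
  r2 <- simulate_kinetics(net, wf, proton_y, kinetics_config(rtol = 1e-7))
  expect_lt(abs(r1$final_rooh_uM - r2$final_rooh_uM) / r2$final_rooh_uM,
            0.001)
})

test_that("final ROOH is non-increasing as beam-on time shrinks 1000-fold", {
  net <- skin_network()
  rates <- c(0.5, 5, 50, 500)   # same 8 Gy, shrinking delivery time
  rooh <- vapply(rates, function(r) {
    simulate_kinetics(net, constant_waveform(8, r), proton_y)$final_rooh_uM
  }, numeric(1))
  expect_true(all(diff(rooh) <= 1e-9))
})

test_that("concentrations stay non-negative along the reported grid", {
  net <- skin_network()
  wf <- pulse_train_waveform(1, 1e-6, 10, 5)
  res <- simulate_kinetics(net, wf, proton_y, dense = TRUE)
  expect_true(all(res$conc >= 0))
  expect_gt(res$auc_roo_uMs, 0)
})

test_that("toy source-decay network matches its closed form", {
  fx <- generate_fixture("toy-network")
  rate <- 50
  wf <- constant_waveform(2, rate)   # 0.04 s on
  cfg <- kinetics_config(post_time = 0)
  res <- simulate_kinetics(fx$network, wf, primary_yields("proton"), cfg)
  g <- primary_yields("proton")[["e"]] * 1e-6
  k <- fx$k; tt <- 0.04
  expect_equal(unname(res$final_uM["e"]) * 1e-6,
               g * rate / k * (1 - exp(-k * tt)), tolerance = 1e-5)
})
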