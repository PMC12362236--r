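test_that("species set satisfies its invariants", {
  sp <- ros_species()
  expect_false(anyDuplicated(sp$name) > 0)
  expect_true(all(sp$conc >= 0))
  core <- c("e", "H", "OH", "H2", "H2O2", "O2m", "HO2m",
            "GSH", "GS", "R", "ROO", "ROOH")
  expect_true(all(core %in% sp$name[sp$role == "dynamic"]))
  pools <- c("H2O", "RH", "LH", "Hp", "OHm", "Fe2")
  expect_true(all(pools %in% sp$name[sp$role == "pool"]))
  expect_equal(sp$conc[sp$name == "GSH"], 410e-6)
  expect_equal(sp$conc[sp$name == "O2"], 10e-6)
  # oxygen can be pinned as a constant pool
  sp2 <- ros_species(o2_dynamic = FALSE)
  expect_equal(sp2$role[sp2$name == "O2"], "pool")
})

test_that("network construction validates its inputs", {
  sp <- ros_species()
  bad <- data.frame(id = "x", reactants = "e + NOPE", products = "H",
                    k = 1, order = 2, flag = "")
  expect_error(build_network(sp, bad), "unknown species")
  bad2 <- data.frame(id = "x", reactants = "e + H", products = "H2",
                     k = 1, order = 1, flag = "")
  expect_error(build_network(sp, bad2), "two dynamic reactants")
  bad3 <- data.frame(id = "x", reactants = "e", products = "",
                     k = -1, order = 1, flag = "")
  expect_error(build_network(sp, bad3), "negative rate constant")
})

test_that("first-order decay rows appear as linear loss terms", {
  net <- skin_network()
  state <- setNames(numeric(length(net$dyn)), net$dyn)
  state["R"] <- 1e-9   # dilute: self-recombination negligible
  d <- evaluate_rhs(net, state, rate = 0, proton_y)
  # alkyl radical: first-order natural decay at 300/s
  expect_equal(unname(d["R"]), -300 * 1e-9, tolerance = 1e-3)
  state[] <- 0; state["ROO"] <- 1e-9   # dilute: termination negligible
  d <- evaluate_rhs(net, state, rate = 0, proton_y)
  # both first-order peroxyl channels (conversion + propagation) drain ROO.
  expect_equal(unname(d["ROO"]), -(0.1092 + 20 * 2.04e-3) * 1e-9,
               tolerance = 1e-3)
  # and the first-order loss reappears as hydroperoxide
  expect_equal(unname(d["ROOH"]), (0.1092 + 20 * 2.04e-3) * 1e-9,
               tolerance = 1e-3)
})

test_that("radiolytic source term matches the primary yields", {
  # all rate constants zeroed: pure source at 1 Gy/s
  rx <- ros_reaction_table()
  rx$k[] <- 0
  net <- build_network(ros_species(), rx)
  state <- setNames(numeric(length(net$dyn)), net$dyn)
  d <- evaluate_rhs(net, state, rate = 1, proton_y)
  expect_equal(unname(d["H2O2"]), 0.0698e-6)
  expect_equal(unname(d["e"]), 0.260e-6)
  expect_equal(unname(d["OH"]), 0.270e-6)
  expect_true(all(d[setdiff(names(d), names(proton_y))] == 0))
})

test_that("quiescent system has zero derivative", {
  net <- skin_network()
  d <- evaluate_rhs(net, initial_state_of(net), rate = 0, proton_y)
  # initial state holds only O2 and GSH, which do not react with each other
  expect_true(all(d == 0))
})

test_that("rhs matches an independently assembled mass-action sum", {
  net <- skin_network()
  set.seed(42)
  for (i in 1:5) {
    state <- setNames(10^runif(length(net$dyn), -9, -6), net$dyn)
    rate <- runif(1, 0, 100)
    got <- evaluate_rhs(net, state, rate, proton_y)
    want <- brute_force_rhs(net, as.list(state), rate, proton_y)
    expect_equal(got, want[names(got)], tolerance = 1e-12)
  }
})

test_that("compiled rhs agrees with the R reference", {
  net <- skin_network()
  flashros:::load_network_c(net, proton_y, 1)
  set.seed(7)
  for (i in 1:5) {
    state <- 10^runif(length(net$dyn), -10, -5)
    rate <- runif(1, 0, 1e4)
    expect_equal(flashros:::eval_rhs_c(state, rate),
                 unname(evaluate_rhs(net, state, rate, proton_y)),
                 tolerance = 1e-14)
  }
})

test_that("empty reaction list leaves only the source term", {
  rx <- ros_reaction_table()[0, ]
  net <- build_network(ros_species(), rx)
  state <- setNames(rep(1e-6, length(net$dyn)), net$dyn)
  d <- evaluate_rhs(net, state, rate = 2, proton_y)
  expect_equal(unname(d["H2O2"]), 2 * 0.0698e-6)
  expect_equal(unname(d["ROOH"]), 0)
})
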