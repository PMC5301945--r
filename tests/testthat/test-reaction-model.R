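test_that("reparametrised Arrhenius rate constants behave correctly", {
  kin <- azi_kinetics()
  ## identity at the reference temperature
  expect_equal(rate_constant(kin, 0:3, 343.15), kin$k_ref)
  ## independently evaluated scalar value at 107 C for j = 0
  expect_equal(rate_constant(kin, 0, 380.15), 243.325227, tolerance = 1e-6)
  ## zero activation energy makes the constant temperature-independent
  kin0 <- azi_kinetics(E_a = rep(0, 4))
  expect_equal(rate_constant(kin0, 2, 400), kin0$k_ref[3])
  ## strictly increasing in T for positive activation energy
  expect_gt(rate_constant(kin, 3, 360), rate_constant(kin, 3, 350))
  expect_error(rate_constant(kin, 0, -5), "positive")
  expect_error(rate_constant(kin, 7, 300), "unknown reaction index")
})

test_that("van't Hoff equilibrium constants", {
  th <- azi_thermo(dG = c(j0 = 0, j1 = -5705, j2 = -1000))
  expect_equal(equilibrium_constant(th, 0, 298.15), 1)
  ## hand evaluation of exp(5705 / (R * 298.15))
  expect_equal(equilibrium_constant(th, 1, 298.15), 9.98787,
               tolerance = 1e-5)
  ## very positive dG drives K towards zero (reverse dominates)
  th2 <- azi_thermo(dG = c(j0 = 1e6))
  expect_lt(equilibrium_constant(th2, 0, 298.15), 1e-100)
  expect_error(equilibrium_constant(th, 3, 298.15), "not reversible")
})

test_that("rate laws are mass-action with a zero-order oxidant", {
  kin <- azi_kinetics(); th <- azi_thermo(); net <- azi_network()
  empty <- stats::setNames(numeric(8), azi_species())
  r0 <- reaction_rates(empty, 343.15, kin, th, net)
  expect_true(all(r0$species == 0) && all(r0$reaction == 0))
  ## doubling the oxidant concentration leaves every rate unchanged
  conc <- empty; conc[c("s1", "HOAc", "cat", "ox", "B")] <-
    c(0.1, 2, 0.01, 0.2, 0.001)
  ra <- reaction_rates(conc, 350, kin, th, net)
  conc["ox"] <- 0.4
  rb <- reaction_rates(conc, 350, kin, th, net)
  expect_identical(ra$reaction, rb$reaction)
  ## bimolecular step: k = 2 with both reactants at 1 mol/L gives 2
  kin2 <- azi_kinetics(k_ref = c(2, 1e-30, 1e-30, 1e-30))
  th_irrev <- azi_thermo(dG = c(j0 = -1e6, j1 = 0, j2 = 0, j3 = 0))
  conc2 <- empty; conc2[c("s1", "cat")] <- 1
  r2 <- reaction_rates(conc2, 343.15, kin2, th_irrev, net)
  expect_equal(unname(r2$reaction["j0"]), 2)
  expect_error(reaction_rates(conc - 1, 350, kin, th, net),
               "negative concentration")
})

test_that("zero-horizon simulation returns the initial state", {
  init <- initial_state(0.1, 20, 0.077, 2, T_K = 343.15)
  traj <- simulate_segment(init, azi_kinetics(), azi_thermo(),
                           azi_network(), horizon_s = 0)
  expect_equal(nrow(traj), 1L)
  expect_equal(unlist(traj[1, azi_species()]), init$conc,
               ignore_attr = TRUE)
})

test_that("a single first-order step decays exponentially", {
  ## reduce the network to B -> s2 at k = 0.1 /s; after 10 s the reactant
  ## should sit at exp(-1) of its start
  kin <- azi_kinetics(k_ref = c(1e-30, 1e-30, 1e-30, 0.1),
                      E_a = rep(0, 4))
  net <- azi_network(reversible = c(FALSE, FALSE, FALSE, FALSE))
  init <- mixture_state(c(B = 1), T_K = 343.15)
  traj <- simulate_segment(init, kin, azi_thermo(), net, horizon_s = 10)
  expect_equal(traj$B[nrow(traj)], exp(-1), tolerance = 1e-7)
  expect_equal(traj$s2[nrow(traj)], 1 - exp(-1), tolerance = 1e-7)
})

test_that("mass balances are conserved along default trajectories", {
  init <- initial_state(0.1, 46.1, 0.077, 2, T_K = 380.15)
  traj <- simulate_segment(init, azi_kinetics(), azi_thermo(),
                           azi_network(), horizon_s = 540)
  expect_lt(conservation_error(traj), 1e-8)
})

test_that("adaptive stiff solution matches a fine-step RK4 oracle", {
  net <- azi_network(); th <- azi_thermo()
  set.seed(11)
  for (draw in 1:3) {
    kin <- moderate_kinetics(k1_ref = stats::runif(1, 0.5, 10))
    kin$k_ref[c(1, 3, 4)] <- kin$k_ref[c(1, 3, 4)] *
      stats::runif(3, 0.5, 2)
    init <- initial_state(0.05, 10, 0.05, 2, T_K = 343.15)
    t_end <- 5
    traj <- simulate_segment(init, kin, th, net, horizon_s = t_end,
                             grid_s = c(0, t_end))
    oracle <- rk4_oracle(init$conc, 343.15, kin, th, net, t_end)
    expect_lt(max(abs(unlist(traj[2, azi_species()]) - oracle)), 1e-6)
  }
})

test_that("simulations at T_ref are independent of activation energies", {
  init <- initial_state(0.1, 20, 0.077, 2, T_K = 343.15)
  a <- simulate_segment(init, azi_kinetics(), azi_thermo(),
                        azi_network(), horizon_s = 600)
  kinE <- azi_kinetics(E_a = c(5e4, 1e5, 3e4, 2e5))
  b <- simulate_segment(init, kinE, azi_thermo(), azi_network(),
                        horizon_s = 600)
  expect_equal(a$s2, b$s2, tolerance = 1e-12)
})

test_that("non-oxidant trajectories are invariant to oxidant loading", {
  a <- initial_state(0.1, 20, 0.077, 2, T_K = 360)
  b <- initial_state(0.1, 20, 0.077, 0.5, T_K = 360)
  ta <- simulate_segment(a, azi_kinetics(), azi_thermo(), azi_network(),
                         horizon_s = 300)
  tb <- simulate_segment(b, azi_kinetics(), azi_thermo(), azi_network(),
                         horizon_s = 300)
  for (sp in setdiff(azi_species(), "ox"))
    expect_lt(max(abs(ta[[sp]] - tb[[sp]])), 1e-9)
})

test_that("model configuration round-trips through YAML", {
  path <- tempfile(fileext = ".yaml")
  write_model_config(path)
  cfg <- read_model_config(path)
  expect_equal(cfg$kinetics$k_ref, azi_kinetics()$k_ref)
  expect_equal(cfg$network$nu, azi_network()$nu)
  expect_equal(unname(cfg$thermo$dG["j2"]), unname(azi_thermo()$dG["j2"]))
  unlink(path)
})
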