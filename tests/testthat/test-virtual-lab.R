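test_that("noise-free virtual lab reproduces the process model exactly", {
  des <- experiment_design(80, c(5, 15, 30), 0.1, 20, 0.077, id = "nf")
  m <- run_virtual_experiment(des, azi_kinetics(), azi_thermo(),
                              azi_network(), noise = NULL, seed = 3)
  pred <- aziflow:::predict_c2(des, azi_kinetics(), azi_thermo(),
                               azi_network())
  expect_identical(m$c2_obs, pred)
  expect_equal(m$c1_0_obs, des$c1_0)
})

test_that("measurements are reproducible under a fixed seed", {
  des <- experiment_design(75, c(2, 8, 20, 40), 0.08, 15, 0.05, id = "d")
  a <- run_virtual_experiment(des, azi_kinetics(), azi_thermo(),
                              azi_network(), seed = 17)
  b <- run_virtual_experiment(des, azi_kinetics(), azi_thermo(),
                              azi_network(), seed = 17)
  expect_identical(a$c2_obs, b$c2_obs)
  expect_identical(a$c1_0_obs, b$c1_0_obs)
})

test_that("empirical noise matches the GC variance model", {
  ## 4000 replicate observations: the sd estimate has ~1 % sampling error
  des <- experiment_design(80, seq(2, 42, length.out = 10), 0.1, 20,
                           0.077, id = "mc")
  obs <- unlist(lapply(1:400, function(i)
    run_virtual_experiment(des, azi_kinetics(), azi_thermo(),
                           azi_network(), seed = 1000 + i)$c2_obs))
  truth <- rep(aziflow:::predict_c2(des, azi_kinetics(), azi_thermo(),
                                    azi_network()), 400)
  expect_equal(stats::sd(obs - truth), 5e-4, tolerance = 0.03)
  expect_lt(abs(mean(obs - truth)), 3e-5)    # unbiased
})

test_that("feasibility labels follow the rig constraints", {
  rule <- feasibility_rule(T_max_C = 110, c_ox_max = 0.3)
  ok <- experiment_design(100, c(5, 10), 0.1, 20, 0.077)
  hot <- experiment_design(115, c(5, 10), 0.1, 20, 0.077)
  thick <- experiment_design(100, c(5, 10), 0.18, 20, 0.077)  # ox 0.36 M
  expect_identical(assess_feasibility(ok, rule), 1L)
  expect_identical(assess_feasibility(hot, rule), -1L)
  expect_identical(assess_feasibility(thick, rule), -1L)
  m <- run_virtual_experiment(hot, azi_kinetics(), azi_thermo(),
                              azi_network(), rule = rule)
  expect_identical(m$feasible, -1L)
  expect_length(m$c2_obs, 0)
})

test_that("campaign totals mirror the published sample bookkeeping", {
  counts <- c(7, 6, 5, 11, 11, 11, 10, 10)
  designs <- lapply(seq_along(counts), function(i)
    experiment_design(70 + 2 * i, seq(1, 55, length.out = counts[i]),
                      0.1, 20, 0.077, id = paste0("e", i)))
  camp <- generate_campaign_dataset(designs, azi_kinetics(), azi_thermo(),
                                    azi_network(), seed = 5)
  expect_equal(camp$n_samples, 71)
  ## an infeasible design is labelled -1 and drops out of the total
  designs[[1]] <- experiment_design(120, seq(1, 55, length.out = 7),
                                    0.1, 20, 0.077, id = "hot")
  camp2 <- generate_campaign_dataset(designs, azi_kinetics(), azi_thermo(),
                                     azi_network(), seed = 5)
  expect_equal(camp2$n_samples, 64)
  expect_identical(camp2$experiments[[1]]$feasible, -1L)
  expect_error(generate_campaign_dataset(list(), azi_kinetics(),
                                         azi_thermo(), azi_network()),
               "non-empty")
})
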