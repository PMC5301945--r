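fim_design <- function(n = 5)
  experiment_design(70, seq(4, 40, length.out = n), 0.12, 10, 0.1,
                    id = "fim")

test_that("Fisher information has the closed-form scalar limit", {
  des <- experiment_design(70, c(10, 10.5, 11), 0.12, 10, 0.1, id = "s")
  noise <- variance_model()
  f <- fisher_information(des, "k3", azi_kinetics(), azi_thermo(),
                          azi_network(), noise)
  prof <- local_sensitivities(des, azi_kinetics(), azi_thermo(),
                              azi_network(), theta = "k3")
  expect_equal(unname(f$M[1, 1]),
               sum(prof$raw[, "k3"]^2) / noise$sigma_product^2,
               tolerance = 1e-8)
})

test_that("information scales inversely with the measurement variance", {
  des <- fim_design()
  f1 <- fisher_information(des, c("k0", "k3"), azi_kinetics(),
                           azi_thermo(), azi_network(),
                           variance_model(sigma_product = 5e-4))
  f2 <- fisher_information(des, c("k0", "k3"), azi_kinetics(),
                           azi_thermo(), azi_network(),
                           variance_model(sigma_product = 2.5e-4))
  expect_equal(f2$M, 4 * f1$M, tolerance = 1e-10)
})

test_that("FIM equals the brute-force outer-product sum and is additive", {
  des <- fim_design(6)
  noise <- variance_model()
  theta <- c("k0", "k2", "k3")
  f <- fisher_information(des, theta, azi_kinetics(), azi_thermo(),
                          azi_network(), noise)
  prof <- local_sensitivities(des, azi_kinetics(), azi_thermo(),
                              azi_network(), theta = theta)
  M <- matrix(0, 3, 3)
  for (k in seq_len(nrow(prof$raw)))
    M <- M + tcrossprod(prof$raw[k, ]) / noise$sigma_product^2
  expect_equal(unname(f$M), M, tolerance = 1e-8)
  ## additivity over disjoint sample subsets
  tt <- des$t_sample_min
  dA <- experiment_design(70, tt[1:3], 0.12, 10, 0.1, id = "A")
  dB <- experiment_design(70, tt[4:6], 0.12, 10, 0.1, id = "B")
  fA <- fisher_information(dA, theta, azi_kinetics(), azi_thermo(),
                           azi_network(), noise)
  fB <- fisher_information(dB, theta, azi_kinetics(), azi_thermo(),
                           azi_network(), noise)
  expect_equal(fA$M + fB$M, f$M, tolerance = 1e-6)
})

test_that("predicted t-tests use Student quantiles at n - p dof", {
  des <- experiment_design(70, c(5, 20, 45), 0.12, 10, 0.1, id = "t")
  f <- fisher_information(des, "k3", azi_kinetics(), azi_thermo(),
                          azi_network())
  tv <- predicted_t_values(f, aziflow:::theta_get(azi_kinetics()))
  expect_equal(attr(tv, "dof"), 2)
  expect_equal(tv$t_ref[1], 2.91998558, tolerance = 1e-6)
  ## a zero-valued parameter always fails the test
  th0 <- aziflow:::theta_get(azi_kinetics()); th0["k3"] <- 0
  expect_equal(predicted_t_values(f, th0)$t_value, 0)
})

test_that("D-optimal search beats the same decode space on a grid", {
  pr <- design_problem("k3", step = 1, n_samples = 4)
  res <- design_experiment(pr, n_starts = 4, maxit = 40, seed = 7)
  set.seed(99)
  grid_best <- max(apply(matrix(stats::rnorm(200 * 5, 0, 1.5), 200), 1,
                         function(z) {
    des <- try(aziflow:::decode_design(z, pr), silent = TRUE)
    if (inherits(des, "try-error")) return(-Inf)
    f <- fisher_information(des, "k3", pr$kin, pr$thermo, pr$net,
                            pr$noise)
    f$logdet
  }))
  expect_gte(res$logdet, grid_best - abs(grid_best) * 0.01)
})

test_that("designing for the unidentifiable j = 1 parameter fails", {
  pr <- design_problem("k1", step = 1, n_samples = 5)
  expect_error(design_experiment(pr, n_starts = 2, maxit = 20),
               "no feasible design")
})

test_that("designed experiments respect the rig feasibility rule", {
  pr <- design_problem(c("k0", "k3"), step = 1, n_samples = 6)
  res <- design_experiment(pr, n_starts = 3, maxit = 30, seed = 2)
  expect_identical(assess_feasibility(res$design), 1L)
  expect_lte(res$design$c1_0, 0.15)
})
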