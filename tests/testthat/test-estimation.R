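one_expt_campaign <- function(noise = NULL, seed = 1, target = "k3") {
  des <- experiment_design(70, c(2, 5, 10, 20, 35, 50), 0.1, 10, 0.077,
                           id = "e1")
  des$theta_target <- target
  generate_campaign_dataset(list(des), azi_kinetics(), azi_thermo(),
                            azi_network(), noise = noise, seed = seed)
}

test_that("the WLS objective is zero at truth and matches a naive loop", {
  camp <- one_expt_campaign()
  truth <- aziflow:::theta_get(azi_kinetics())
  expect_lt(wls_objective(truth["k3"], camp), 1e-6)
  ## independent double loop at perturbed parameters
  theta <- c(k3 = 0.12, k0 = 2.5)
  obj <- wls_objective(theta, camp)
  kin2 <- aziflow:::theta_set(azi_kinetics(), theta)
  acc <- 0
  for (m in camp$experiments) {
    pred <- aziflow:::predict_c2(m$design, kin2, azi_thermo(),
                                 azi_network(), rtol = 1e-10,
                                 atol = 1e-12)
    for (k in seq_along(pred))
      acc <- acc + ((m$c2_obs[k] - pred[k]) / 5e-4)^2
  }
  expect_equal(obj, acc, tolerance = 1e-10)
})

test_that("an observation off by exactly one sigma scores 1", {
  camp <- one_expt_campaign()
  camp$experiments[[1]]$c2_obs[3] <- camp$experiments[[1]]$c2_obs[3] + 5e-4
  truth <- aziflow:::theta_get(azi_kinetics())
  expect_equal(wls_objective(truth["k3"], camp), 1, tolerance = 1e-5)
})

test_that("single-parameter recovery from noise-free data is exact", {
  camp <- one_expt_campaign()
  kin_start <- azi_kinetics(); kin_start$k_ref[4] <- 0.3
  f <- fit_kinetics(camp, "k3", kin = kin_start)
  expect_true(f$converged)
  expect_equal(unname(f$theta_hat["k3"]), 0.140378, tolerance = 1e-3)
  expect_lt(f$objective, 1e-6)
})

test_that("warm-started joint fits never degrade the objective", {
  camp <- one_expt_campaign(noise = variance_model(), seed = 4)
  stage1 <- fit_kinetics(camp, "k3", kin = azi_kinetics())
  start_obj <- wls_objective(
    aziflow:::theta_get(stage1$kin, c("k3", "k0")), camp,
    kin = stage1$kin)
  joint <- fit_kinetics(camp, c("k3", "k0"), kin = stage1$kin)
  expect_lte(joint$objective, start_obj + 1e-8)
})

test_that("the j = 1 pair is practically unidentifiable", {
  camp <- one_expt_campaign(noise = variance_model(), seed = 9)
  f <- fit_kinetics(camp, "k1", kin = azi_kinetics())
  expect_gt(f$ci_half["k1"] / f$theta_hat["k1"], 10)
  expect_lt(f$t_value["k1"], 0.1)
})

test_that("kinfit methods expose the usual modelling surface", {
  camp <- one_expt_campaign(noise = variance_model(), seed = 2)
  f <- fit_kinetics(camp, c("k3", "k0"), kin = azi_kinetics())
  expect_s3_class(f, "kinfit")
  expect_named(coef(f), c("k3", "k0"))
  ci <- confint(f)
  expect_true(all(ci[, 2] >= ci[, 1]))
  expect_length(residuals(f), camp$n_samples)
  pred <- predict(f, camp$experiments[[1]]$design)
  expect_length(pred, 6)
  s <- summary(f)
  expect_s3_class(s, "summary.kinfit")
  expect_equal(nrow(s$table), 2)
  expect_output(print(f), "kinfit")
})
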