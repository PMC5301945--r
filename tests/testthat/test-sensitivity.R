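ref_design <- function() {
  experiment_design(82, c(1, 2, 5, 10, 20, 35, 50, 60), 0.1, 20, 0.077,
                    id = "screen")
}

test_that("raw sensitivities match an independent finite-difference loop", {
  des <- ref_design()
  kin <- azi_kinetics(); th <- azi_thermo(); net <- azi_network()
  prof <- local_sensitivities(des, kin, th, net,
                              theta = c("k3", "Ea3", "k0"))
  for (nm in c("k3", "Ea3", "k0")) {
    ## independently coded two-sided difference with a different step
    th0 <- aziflow:::theta_get(kin, nm)
    h <- 3e-5 * th0
    up <- aziflow:::predict_c2(des, aziflow:::theta_set(
      kin, stats::setNames(th0 + h, nm)), th, net)
    dn <- aziflow:::predict_c2(des, aziflow:::theta_set(
      kin, stats::setNames(th0 - h, nm)), th, net)
    oracle <- (up - dn) / (2 * h)
    scale <- max(abs(oracle))
    expect_lt(max(abs(prof$raw[, nm] - oracle)) / scale, 0.01)
  }
})

test_that("a step with zero net flux has a null sensitivity profile", {
  ## without acetic acid the protonation step never fires, so its rate
  ## constant cannot influence the output
  des <- experiment_design(82, c(5, 20, 45), 0.1, 0, 0.077, id = "noacid")
  prof <- local_sensitivities(des, azi_kinetics(), azi_thermo(),
                              azi_network(), theta = c("k1", "k3"))
  expect_lt(max(abs(prof$normalised[, "k1"])), 1e-10)
  expect_gt(max(abs(prof$normalised[, "k3"])), 1e-3)
})

test_that("estimability screen reproduces the j = 1 exclusion", {
  prof <- local_sensitivities(ref_design(), azi_kinetics(), azi_thermo(),
                              azi_network())
  est <- estimability_rank(prof)
  flagged <- est$parameter[!est$estimable]
  expect_setequal(flagged, c("k1", "Ea1"))
  ## threshold 0 admits everything; flags are monotone in the threshold
  expect_true(all(estimability_rank(prof, threshold = 0)$estimable))
  for (thr in c(1e-5, 1e-4, 1e-3, 1e-2)) {
    lo <- estimability_rank(prof, threshold = thr)
    hi <- estimability_rank(prof, threshold = thr * 10)
    lo <- lo[order(lo$parameter), ]; hi <- hi[order(hi$parameter), ]
    expect_true(all(hi$estimable <= lo$estimable))
  }
})

test_that("degenerate (productless) profiles are flagged", {
  kin_dead <- azi_kinetics(k_ref = rep(1e-30, 4))
  prof <- local_sensitivities(ref_design(), kin_dead, azi_thermo(),
                              azi_network(), theta = c("k0", "k3"))
  expect_true(prof$degenerate)
  est <- estimability_rank(prof)
  expect_false(any(est$estimable))
})

test_that("design-by-grouping follows shared peak windows", {
  mk_prof <- function(peaks) {
    nm <- names(peaks)
    structure(list(t_min = seq(1, 60),
                   normalised = matrix(1, 60, length(nm),
                                       dimnames = list(NULL, nm)),
                   peak_time = peaks,
                   peak_mag = stats::setNames(rep(1, length(nm)), nm),
                   degenerate = FALSE),
              class = "sensitivity_profiles")
  }
  ## all peaks coincident: one group per parameter type
  g1 <- group_parameters(mk_prof(c(k0 = 30, k2 = 30, k3 = 30,
                                   Ea0 = 10, Ea3 = 10)), window = 0.2)
  expect_length(g1, 2)
  expect_setequal(g1[[1]]$members, c("k0", "k2", "k3"))
  ## well-separated peaks become singletons
  g2 <- group_parameters(mk_prof(c(k0 = 5, k3 = 55)), window = 0.2)
  expect_length(g2, 2)
  ## zero window: everything is a singleton
  g3 <- group_parameters(mk_prof(c(k0 = 30, k2 = 30.5, k3 = 31)),
                         window = 0)
  expect_length(g3, 3)
})
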