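test_that("Latin hypercube designs are stratified and reproducible", {
  X <- lhs_design(N = 5, seed = 11)
  b <- aziflow:::bounds_matrix(design_space())
  for (k in seq_len(ncol(X))) {
    u <- (X[, k] - b[k, 1]) / (b[k, 2] - b[k, 1])
    expect_setequal(floor(u * 5), 0:4)   # one point per stratum
  }
  expect_identical(X, lhs_design(N = 5, seed = 11))
  ## N = 1 returns the mid-point of the space
  X1 <- lhs_design(N = 1, seed = 3)
  expect_equal(unname(X1[1, ]), unname((b[, 1] + b[, 2]) / 2))
  ## degenerate bounds are held constant with a warning
  bad <- design_space(); bad$R_cat <- c(0.05, 0.05)
  expect_warning(Xd <- lhs_design(bad, N = 4, seed = 2), "degenerate")
  expect_true(all(Xd[, "R_cat"] == 0.05))
})

test_that("candidate pools are uniform within bounds and seeded", {
  C <- candidate_set(n = 500, seed = 21)
  b <- aziflow:::bounds_matrix(design_space())
  for (k in seq_len(ncol(C)))
    expect_true(all(C[, k] >= b[k, 1] & C[, k] <= b[k, 2]))
  expect_identical(C, candidate_set(n = 500, seed = 21))
})

test_that("target checking implements both tolerance rules", {
  tg <- target_spec()
  expect_true(check_targets(list(yield_pct = 98.72, cost = 2108), tg))
  expect_true(check_targets(list(yield_pct = 100, cost = 1920), tg))
  expect_false(check_targets(list(yield_pct = 97.0, cost = 2108), tg))
  expect_false(check_targets(list(yield_pct = 100, cost = 2600), tg))
  expect_false(check_targets(list(yield_pct = NA, cost = 2108), tg))
})

moal_training <- function(n = 12, seed = 31) {
  X <- lhs_design(N = n, seed = seed)
  ev <- model_evaluator()
  rows <- apply(X, 1, ev, simplify = FALSE)
  list(X = X,
       Y = cbind(yield_pct = vapply(rows, function(r)
                   ifelse(r$feasible > 0, r$yield_pct, 0), numeric(1)),
                 cost = vapply(rows, function(r)
                   ifelse(r$feasible > 0, r$cost, 1e6), numeric(1))),
       feasible = vapply(rows, function(r) r$feasible, numeric(1)))
}

test_that("the proposal equals the exhaustive acquisition argmax", {
  tr <- moal_training()
  sur <- fit_surrogate(tr$X, tr$Y, tr$feasible)
  cl <- fit_feasibility_classifier(tr$X, tr$feasible)
  cands <- candidate_set(n = 300, seed = 41)
  prop <- propose_candidate(sur, cl, cands, X_evaluated = tr$X)
  ## independent scoring loop over all admitted candidates
  bands <- aziflow:::target_bands(target_spec())
  keep <- gpc_predict(cl, cands) >= 0.5
  py <- gp_predict(sur$yield, cands, include_noise = TRUE)
  pc <- gp_predict(sur$cost, cands, include_noise = TRUE)
  sc <- (pnorm((bands$yield[2] - py$mean) / py$sd) -
         pnorm((bands$yield[1] - py$mean) / py$sd)) *
        (pnorm((bands$cost[2] - pc$mean) / pc$sd) -
         pnorm((bands$cost[1] - pc$mean) / pc$sd))
  sc[!keep] <- -Inf
  if (max(sc) >= 1e-12) {
    expect_equal(unname(prop$x), unname(cands[which.max(sc), ]))
  } else {
    expect_true(prop$explore)
  }
  ## proposals never fall in the classifier-infeasible region
  expect_gte(gpc_predict(cl, matrix(prop$x, nrow = 1)), 0.5)
})

test_that("degenerate tolerances make every candidate tie at score one", {
  tr <- moal_training()
  sur <- fit_surrogate(tr$X, tr$Y, tr$feasible)
  cl <- fit_feasibility_classifier(tr$X, tr$feasible)
  cands <- candidate_set(n = 50, seed = 5)
  wide <- target_spec(tol_yield = 1e6, tol_cost = 1e6)
  prop <- propose_candidate(sur, cl, cands, targets = wide)
  admitted <- which(gpc_predict(cl, cands) >= 0.5)
  expect_equal(unname(prop$x), unname(cands[admitted[1], ]))
})

test_that("NSGA-II refinement never worsens the scalarised distance", {
  tr <- moal_training()
  sur <- fit_surrogate(tr$X, tr$Y, tr$feasible)
  x0 <- candidate_set(n = 1, seed = 6)[1, ]
  bands <- aziflow:::target_bands(target_spec())
  scal <- function(x) {
    X <- matrix(x, nrow = 1)
    sum(abs(c(gp_predict(sur$yield, X)$mean,
              gp_predict(sur$cost, X)$mean) -
            vapply(bands, mean, numeric(1))) /
        vapply(bands, function(b) (b[2] - b[1]) / 2, numeric(1)))
  }
  xr <- refine_with_ga(x0, sur, seed = 8)
  expect_lte(scal(xr), scal(x0) + 1e-9)
  ## zero generations: unchanged
  expect_identical(refine_with_ga(x0, sur, generations = 0), x0)
  ## refinement stays in the local neighbourhood box
  b <- aziflow:::bounds_matrix(design_space())
  expect_true(all(abs(xr - x0) <= 0.05 * (b[, 2] - b[, 1]) + 1e-12))
})

test_that("the closed loop converges immediately on a degenerate task", {
  tr <- moal_training(n = 6, seed = 13)
  ev <- function(x) list(yield_pct = 100, cost = 2108, feasible = 1L)
  r <- run_closed_loop(tr$X, tr$Y, tr$feasible, ev, max_iter = 5,
                       seed = 2, n_candidates = 200)
  expect_true(r$converged)
  expect_equal(r$iterations, 1)
})

test_that("the training set grows by one unique point per iteration", {
  tr <- moal_training(n = 6, seed = 14)
  ev <- function(x) list(yield_pct = 50, cost = 1e5, feasible = 1L)
  r <- run_closed_loop(tr$X, tr$Y, tr$feasible, ev, max_iter = 4,
                       seed = 3, n_candidates = 200)
  expect_false(r$converged)
  expect_equal(nrow(r$X_tr), 6 + 4)
  expect_equal(anyDuplicated(r$X_tr), 0)
  ## bit-reproducible under the same seed
  r2 <- run_closed_loop(tr$X, tr$Y, tr$feasible, ev, max_iter = 4,
                        seed = 3, n_candidates = 200)
  expect_identical(r$history, r2$history)
})

test_that("failed evaluations are folded back as infeasible points", {
  tr <- moal_training(n = 6, seed = 15)
  ev <- function(x) list(yield_pct = NA_real_, cost = NA_real_,
                         feasible = -1L)
  r <- run_closed_loop(tr$X, tr$Y, tr$feasible, ev, max_iter = 3,
                       seed = 4, n_candidates = 200)
  expect_false(r$converged)
  expect_true(all(r$history$feasible == -1))
  expect_equal(sum(r$feasible == -1), sum(tr$feasible == -1) + 3)
})
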