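#' Target specification for the self-optimisation
#'
#' The optimiser stops once both measured targets fall within tolerance:
#' yield within `tol_yield` percentage points of 100 %, and cost within a
#' relative fraction `tol_cost` of the cost target.
#'
#' @param yield Target yield, %.
#' @param cost Target specific cost, GBP h/kg.
#' @param tol_yield Yield tolerance, percentage points.
#' @param tol_cost Relative cost tolerance.
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(yield = 100, cost = 2108, tol_yield = 1.5,
                        tol_cost = 0.10) {
  if (tol_yield <= 0 || tol_cost <= 0) stop("tolerances must be positive")
  structure(list(yield = yield, cost = cost, tol_yield = tol_yield,
                 tol_cost = tol_cost),
            class = "target_spec")
}

#' Check objective values against the targets
#'
#' @param Y An `objective_values` object or named vector/list with
#'   `yield_pct` and `cost`.
#' @param targets A [target_spec()].
#' @return Logical: TRUE when both targets are attained within tolerance.
#' @export
check_targets <- function(Y, targets = target_spec()) {
  Y <- as.list(Y)
  y <- Y$yield_pct; cst <- Y$cost
  is.finite(y) && is.finite(cst) &&
    abs(y - targets$yield) <= targets$tol_yield &&
    abs(cst - targets$cost) / targets$cost <= targets$tol_cost
}

## Design-variable order used throughout the optimiser.
x_names <- function() c("T_C", "t_min", "c1_0", "R_acid", "R_cat")

bounds_matrix <- function(bounds = design_space()) {
  b <- do.call(rbind, bounds[x_names()])
  dimnames(b) <- list(x_names(), c("lower", "upper"))
  b
}

#' Latin hypercube design over the experiment space
#'
#' Stratified space-filling sample: in every dimension each of the N
#' equal-probability strata contains exactly one point.
#'
#' @param bounds Design-space bounds, see [design_space()].
#' @param N Number of points (N = 1 returns the mid-point).
#' @param seed Integer seed.
#' @return N x 5 matrix with columns `T_C, t_min, c1_0, R_acid, R_cat`.
#' @export
lhs_design <- function(bounds = design_space(), N = 5, seed = 1L) {
  b <- bounds_matrix(bounds)
  set.seed(seed)
  U <- if (N == 1) matrix(0.5, 1, nrow(b)) else lhs::randomLHS(N, nrow(b))
  X <- sweep(sweep(U, 2, b[, 2] - b[, 1], `*`), 2, b[, 1], `+`)
  degen <- b[, 2] <= b[, 1]
  if (any(degen)) {
    warning("degenerate bounds held constant: ",
            paste(rownames(b)[degen], collapse = ", "))
    for (k in which(degen)) X[, k] <- b[k, 1]
  }
  colnames(X) <- rownames(b)
  X
}

#' Uniform candidate pool over the design space
#'
#' The optimiser evaluates its surrogates on a fixed, seeded pool of
#' uniformly distributed candidate points (2000 by default).
#'
#' @param bounds Design-space bounds.
#' @param n Number of candidates.
#' @param seed Integer seed.
#' @return n x 5 matrix of candidate points.
#' @export
candidate_set <- function(bounds = design_space(), n = 2000, seed = 1L) {
  b <- bounds_matrix(bounds)
  set.seed(seed)
  X <- vapply(seq_len(nrow(b)), function(k)
    stats::runif(n, b[k, 1], b[k, 2]), numeric(n))
  X <- matrix(X, nrow = n, dimnames = list(NULL, rownames(b)))
  X
}

## Output transforms: cost is modelled on the log scale (it spans decades
## over the design space), yield on the natural scale.
y_transform <- function(Y) cbind(yield = Y[, 1], cost = log(pmax(Y[, 2], 1e-6)))

target_bands <- function(targets) {
  list(yield = c(targets$yield - targets$tol_yield,
                 targets$yield + targets$tol_yield),
       cost = log(pmax(c(targets$cost * (1 - targets$tol_cost),
                         targets$cost * (1 + targets$tol_cost)), 1e-9)))
}

#' Fit the per-target surrogates
#'
#' One Gaussian-process regression per target (yield; log cost), trained
#' on the feasible training points.
#'
#' @param X Training inputs (n x 5).
#' @param Y Training outputs: columns `yield_pct`, `cost`.
#' @param feasible Vector of +/-1 labels.
#' @param bounds Design-space bounds.
#' @return List of class `moal_surrogate` with one [gp_fit()] per target.
#' @export
fit_surrogate <- function(X, Y, feasible = rep(1, nrow(X)),
                          bounds = design_space()) {
  ok <- feasible > 0 & is.finite(Y[, 1]) & is.finite(Y[, 2]) & Y[, 2] > 0
  if (sum(ok) < 2) stop("need at least 2 feasible training points")
  b <- bounds_matrix(bounds)
  Yt <- y_transform(Y[ok, , drop = FALSE])
  structure(list(
    yield = gp_fit(X[ok, , drop = FALSE], Yt[, "yield"], bounds = b),
    cost = gp_fit(X[ok, , drop = FALSE], Yt[, "cost"], bounds = b)),
    class = "moal_surrogate")
}

#' Fit the feasibility classifier
#'
#' Binary Gaussian-process classification over the +/-1 feasibility
#' labels of the training set.
#'
#' @param X Training inputs.
#' @param feasible +/-1 labels.
#' @param bounds Design-space bounds.
#' @return A [gpc_fit()] object.
#' @export
fit_feasibility_classifier <- function(X, feasible,
                                       bounds = design_space()) {
  feasible[!is.finite(feasible)] <- -1
  gpc_fit(as.matrix(X), feasible, bounds = bounds_matrix(bounds))
}

## Acquisition score: joint probability, under the GP predictive
## distributions, that every target lands inside its tolerance band.
acquisition_scores <- function(surrogate, cands, bands) {
  py <- gp_predict(surrogate$yield, cands, include_noise = TRUE)
  pc <- gp_predict(surrogate$cost, cands, include_noise = TRUE)
  pband <- function(p, band) {
    s <- pmax(p$sd, 1e-9)
    stats::pnorm((band[2] - p$mean) / s) - stats::pnorm((band[1] - p$mean) / s)
  }
  list(score = pband(py, bands$yield) * pband(pc, bands$cost),
       var_total = py$sd^2 + pc$sd^2,
       pred = cbind(yield = py$mean, cost_log = pc$mean))
}

#' Propose the next experiment from the candidate pool
#'
#' Scores every classifier-feasible candidate by the joint probability of
#' attaining both targets under the surrogate predictive distributions
#' and returns the best (lowest index on ties).  When every feasible
#' candidate has negligible attainment probability the proposal falls
#' back to exploration (the feasible candidate with the largest total
#' predictive variance).  Candidates already evaluated are excluded so no
#' point is measured twice.
#'
#' @param surrogate A [fit_surrogate()] result.
#' @param classifier A [fit_feasibility_classifier()] result.
#' @param cands Candidate matrix from [candidate_set()].
#' @param targets A [target_spec()].
#' @param X_evaluated Matrix of already-evaluated inputs.
#' @return List with `x` (proposed point), `score`, `explore` flag.
#' @export
propose_candidate <- function(surrogate, classifier, cands,
                              targets = target_spec(),
                              X_evaluated = NULL) {
  p_feas <- gpc_predict(classifier, cands)
  keep <- p_feas >= 0.5
  if (!is.null(X_evaluated) && nrow(X_evaluated) > 0) {
    b <- surrogate$yield$bounds
    Cs <- scale01(cands, b[, 1], b[, 2])
    Es <- scale01(as.matrix(X_evaluated), b[, 1], b[, 2])
    dmin <- apply(Cs, 1, function(r) min(colSums((t(Es) - r)^2)))
    keep <- keep & dmin > 1e-12
  }
  if (!any(keep))
    stop("no feasible candidates: switch to exploration mode ",
         "(e.g. enlarge the candidate pool or relax the classifier)")
  acq <- acquisition_scores(surrogate, cands[keep, , drop = FALSE],
                            target_bands(targets))
  idx <- which(keep)
  explore <- max(acq$score) < 1e-12
  best <- if (explore) which.max(acq$var_total) else which.max(acq$score)
  list(x = cands[idx[best], ], score = acq$score[best], explore = explore,
       pred = acq$pred[best, ])
}

#' Refine a proposal with NSGA-II
#'
#' Perturbs the discrete-pool proposal by running NSGA-II on the two
#' surrogate objectives |prediction - target| (tolerance-normalised)
#' inside a +/-5 %-of-range neighbourhood box around the proposal
#' (clipped to the design space), with the population seeded around the
#' proposal.  Points the feasibility classifier rejects are penalised.
#' The returned point is never worse than the proposal in the scalarised
#' tolerance-normalised distance.
#'
#' @param x_star Proposed point (named vector).
#' @param surrogate A [fit_surrogate()] result.
#' @param bounds Design-space bounds.
#' @param targets A [target_spec()].
#' @param classifier Optional [fit_feasibility_classifier()] guard.
#' @param pop_size,generations NSGA-II settings (0 generations returns
#'   `x_star` unchanged).
#' @param seed Integer seed.
#' @return Refined point (named vector).
#' @export
refine_with_ga <- function(x_star, surrogate, bounds = design_space(),
                           targets = target_spec(), classifier = NULL,
                           pop_size = 40, generations = 20, seed = 1L) {
  if (generations == 0) return(x_star)
  b <- bounds_matrix(bounds)
  bands <- target_bands(targets)
  centres <- vapply(bands, mean, numeric(1))
  widths <- vapply(bands, function(x) (x[2] - x[1]) / 2, numeric(1))
  objfn <- function(x) {
    X <- matrix(x, nrow = 1)
    pen <- if (!is.null(classifier) && gpc_predict(classifier, X) < 0.5)
      1e3 else 0
    c(abs(gp_predict(surrogate$yield, X)$mean - centres["yield"]) / widths["yield"] + pen,
      abs(gp_predict(surrogate$cost, X)$mean - centres["cost"]) / widths["cost"] + pen)
  }
  span <- 0.05 * (b[, 2] - b[, 1])
  lower <- pmax(x_star - span, b[, 1])
  upper <- pmin(x_star + span, b[, 2])
  set.seed(seed)
  init <- t(replicate(pop_size, stats::runif(length(x_star), lower, upper)))
  init[1, ] <- x_star
  res <- nsga2(objfn, lower = lower, upper = upper,
               pop_size = pop_size, generations = generations,
               seed = seed, init = init)
  scal <- rowSums(res$F)
  best <- which.min(scal)
  if (scal[best] <= sum(objfn(x_star))) {
    out <- res$X[best, ]
    names(out) <- rownames(b)
    out
  } else x_star
}

#' Run the closed-loop target optimisation
#'
#' The multi-objective active-learning loop: fit surrogates and the
#' feasibility classifier on the training set, propose the best candidate
#' from the discrete pool, refine it with NSGA-II, evaluate it with the
#' supplied evaluator (process model or virtual laboratory), test the
#' measured outcome against the targets, and append the result to the
#' training set.  Stops on target attainment or after `max_iter`
#' iterations.  A failed evaluation is appended with feasibility label -1
#' and the loop continues.
#'
#' @param X_tr,Y_tr,feasible Initial training set: inputs (n x 5), outputs
#'   (columns `yield_pct`, `cost`) and +/-1 labels.
#' @param evaluator Function of a named design-variable vector returning a
#'   list with `yield_pct`, `cost`, `feasible`.
#' @param targets A [target_spec()].
#' @param bounds Design-space bounds.
#' @param max_iter Iteration cap.
#' @param seed Integer seed (controls the candidate pool and NSGA-II).
#' @param n_candidates Candidate-pool size.
#' @param refine Logical: apply NSGA-II refinement.
#' @return An object of class `moal`: `converged`, `X_opt`, `Y_opt`,
#'   `history` (one row per iteration), and the final training set.
#' @export
run_closed_loop <- function(X_tr, Y_tr, feasible, evaluator,
                            targets = target_spec(),
                            bounds = design_space(), max_iter = 50,
                            seed = 1L, n_candidates = 2000,
                            refine = TRUE) {
  stopifnot(max_iter >= 1, is.function(evaluator))
  X_tr <- as.matrix(X_tr); Y_tr <- as.matrix(Y_tr)
  cands <- candidate_set(bounds, n_candidates, seed)
  history <- NULL
  converged <- FALSE; X_opt <- NULL; Y_opt <- NULL
  for (it in seq_len(max_iter)) {
    surrogate <- fit_surrogate(X_tr, Y_tr, feasible, bounds)
    classifier <- fit_feasibility_classifier(X_tr, feasible, bounds)
    prop <- propose_candidate(surrogate, classifier, cands, targets,
                              X_evaluated = X_tr)
    x <- prop$x
    if (refine)
      x <- refine_with_ga(x, surrogate, bounds, targets,
                          classifier = classifier, seed = seed + it)
    out <- evaluator(x)
    feas_i <- if (is.null(out$feasible)) 1 else out$feasible
    y_i <- if (feas_i > 0) out$yield_pct else NA_real_
    c_i <- if (feas_i > 0) out$cost else NA_real_
    if (feas_i > 0 && (!is.finite(y_i) || !is.finite(c_i) || c_i <= 0))
      feas_i <- -1
    ok <- feas_i > 0 &&
      check_targets(list(yield_pct = y_i, cost = c_i), targets)
    history <- rbind(history, data.frame(
      iter = it, t(x), explore = prop$explore, score = prop$score,
      yield_pct = y_i, cost = c_i, feasible = feas_i, accepted = ok))
    X_tr <- rbind(X_tr, x)
    Y_tr <- rbind(Y_tr, c(if (is.na(y_i)) 0 else y_i,
                          if (is.na(c_i)) 1e6 else c_i))
    feasible <- c(feasible, feas_i)
    if (ok) {
      converged <- TRUE; X_opt <- x
      Y_opt <- list(yield_pct = y_i, cost = c_i)
      break
    }
  }
  structure(list(converged = converged, X_opt = X_opt, Y_opt = Y_opt,
                 iterations = if (is.null(history)) 0 else nrow(history),
                 history = history, X_tr = X_tr, Y_tr = Y_tr,
                 feasible = feasible, targets = targets, seed = seed),
            class = "moal")
}

#' @export
print.moal <- function(x, ...) {
  cat("<moal> closed-loop target optimisation:",
      if (x$converged) "CONVERGED" else "not converged",
      "after", x$iterations, "iterations\n")
  if (x$converged) {
    cat(sprintf("  X_opt: T %.1f C, t %.1f min, c1 %.3f M, R_acid %.1f, R_cat %.3f\n",
                x$X_opt["T_C"], x$X_opt["t_min"], x$X_opt["c1_0"],
                x$X_opt["R_acid"], x$X_opt["R_cat"]))
    cat(sprintf("  Y_opt: yield %.2f %%, cost %.0f GBP h/kg\n",
                x$Y_opt$yield_pct, x$Y_opt$cost))
  }
  invisible(x)
}

#' @export
plot.moal <- function(x, ...) {
  h <- x$history
  if (is.null(h)) return(invisible(x))
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$iter, h$yield_pct, xlab = "iteration",
                 ylab = "yield (%)", pch = 19,
                 col = ifelse(h$accepted, "forestgreen", "grey40"), ...)
  graphics::abline(h = x$targets$yield + c(-1, 1) * x$targets$tol_yield,
                   lty = 2)
  graphics::plot(h$iter, h$cost, xlab = "iteration",
                 ylab = "cost (GBP h/kg)", log = "y", pch = 19,
                 col = ifelse(h$accepted, "forestgreen", "grey40"), ...)
  graphics::abline(h = x$targets$cost * (1 + c(-1, 1) * x$targets$tol_cost),
                   lty = 2)
  invisible(x)
}

#' Write the optimisation history as CSV
#'
#' @param moal A `moal` object.
#' @param path Output file.
#' @export
write_moal_history <- function(moal, path) {
  utils::write.csv(moal$history, path, row.names = FALSE)
  invisible(path)
}

#' Snapshot the optimiser state as JSON
#'
#' Serialises the training set, labels, targets and seed so a run can be
#' resumed or audited.
#'
#' @param moal A `moal` object.
#' @param path Output JSON file.
#' @export
write_moal_state <- function(moal, path) {
  st <- list(converged = moal$converged, iterations = moal$iterations,
             seed = moal$seed,
             targets = unclass(moal$targets),
             X_tr = apply(moal$X_tr, 1, as.list, simplify = FALSE),
             Y_tr = apply(moal$Y_tr, 1, as.list, simplify = FALSE),
             feasible = moal$feasible,
             X_opt = if (is.null(moal$X_opt)) NULL else as.list(moal$X_opt))
  jsonlite::write_json(st, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
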