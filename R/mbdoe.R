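#' Fisher information of a design for a parameter subset
#'
#' FIM = sum_k s_k s_k' / sigma^2 over the design's sample times, where
#' s_k = d c2(t_k) / d theta is the raw output sensitivity and sigma the
#' constant GC product variance.  The D-criterion is the log-determinant.
#'
#' @param design An [experiment_design()].
#' @param theta Parameter names (subset of [theta_names()]).
#' @param kin,thermo,net Model components.
#' @param noise A [variance_model()].
#' @param rel_step Finite-difference step for the sensitivities.
#' @return An object of class `fim`: `theta`, `M`, `logdet`, `cov` (NULL
#'   when singular), `n_samples`, `sigma`.
#' @export
fisher_information <- function(design, theta, kin, thermo, net,
                               noise = variance_model(), rel_step = 1e-4) {
  prof <- local_sensitivities(design, kin, thermo, net, theta = theta,
                              rel_step = rel_step)
  S <- prof$raw
  M <- crossprod(S) / noise$sigma_product^2
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  singular <- any(ev <= 0) || min(ev) / max(ev) < 1e-12
  logdet <- if (singular) -Inf else sum(log(ev))
  cov <- if (singular) NULL else chol2inv(chol(M))
  if (!is.null(cov)) dimnames(cov) <- dimnames(M)
  structure(list(theta = theta, M = M, logdet = logdet, cov = cov,
                 n_samples = nrow(S), sigma = noise$sigma_product,
                 design = design),
            class = "fim")
}

#' Predicted t-values of a design
#'
#' Judges the expected precision of each target parameter: t_i =
#' theta_i / (q * sqrt([FIM^-1]_ii)) with q the two-tailed 95 % Student
#' quantile at dof = n_samples - |theta|; the design is deemed adequate
#' for parameter i when t_i exceeds the one-tailed 95 % reference quantile
#' t_ref at the same dof.
#'
#' @param fim A [fisher_information()] result.
#' @param theta_hat Named current parameter values.
#' @param alpha Significance level (default 0.05).
#' @return Data frame with `parameter`, `t_value`, `t_ref`, `pass`, and
#'   attribute `dof`.
#' @export
predicted_t_values <- function(fim, theta_hat, alpha = 0.05) {
  stopifnot(inherits(fim, "fim"))
  if (is.null(fim$cov)) stop("information matrix is singular")
  dof <- fim$n_samples - length(fim$theta)
  if (dof <= 0) stop("non-positive degrees of freedom: add samples")
  q <- stats::qt(1 - alpha / 2, dof)
  t_ref <- stats::qt(1 - alpha, dof)
  se <- sqrt(diag(fim$cov))
  tv <- abs(theta_hat[fim$theta]) / (q * se)
  out <- data.frame(parameter = fim$theta, t_value = unname(tv),
                    t_ref = t_ref, pass = unname(tv > t_ref),
                    row.names = NULL)
  attr(out, "dof") <- dof
  out
}

## Pairwise correlation measure from the predicted covariance.
max_pair_correlation <- function(cov) {
  if (is.null(cov) || nrow(cov) < 2) return(0)
  cr <- abs(stats::cov2cor(cov))
  diag(cr) <- 0
  max(cr)
}

#' D-optimal design problem
#'
#' Step-1 problems fix T = T_ref (eliminating the activation energies from
#' the model response) and target reference rate constants; step-2
#' problems free the temperature (T != T_ref) and target activation
#' energies with the rate constants held fixed.
#'
#' @param theta Target parameter names.
#' @param step 1 (isothermal at T_ref) or 2 (temperature free).
#' @param n_samples Number of GC samples (3..12).
#' @param kin,thermo,net,noise Model components and variance model.
#' @param bounds Design-space bounds, see [design_space()].
#' @param rule Rig [feasibility_rule()]; designed experiments must satisfy
#'   it (the oxidant limit caps the substrate concentration).
#' @param ox_equiv Oxidant equivalents fed with the substrate.
#' @return An object of class `design_problem`.
#' @export
design_problem <- function(theta, step, n_samples = 8,
                           kin = azi_kinetics(), thermo = azi_thermo(),
                           net = azi_network(), noise = variance_model(),
                           bounds = design_space(),
                           rule = feasibility_rule(), ox_equiv = 2) {
  stopifnot(step %in% 1:2)
  if (n_samples < 3 || n_samples > 12)
    stop("sample count must be within [3, 12]")
  if (step == 1 && any(startsWith(theta, "Ea")))
    stop("step-1 problems target reference rate constants only")
  bounds$c1_0[2] <- min(bounds$c1_0[2], rule$c_ox_max / ox_equiv)
  bounds$T_C[2] <- min(bounds$T_C[2], rule$T_max_C)
  structure(list(theta = theta, step = step, n_samples = n_samples,
                 kin = kin, thermo = thermo, net = net, noise = noise,
                 bounds = bounds, rule = rule, ox_equiv = ox_equiv),
            class = "design_problem")
}

## Decode an unconstrained optimiser vector into an experiment design.
## Sampling schedules are geometric (first time + spacing ratio), a
## two-parameter family that covers front-loaded through even schedules;
## times closer than the minimum spacing are merged.
decode_design <- function(z, problem, min_spacing_min = 0.5) {
  b <- problem$bounds
  sq <- function(z, lo, hi) lo + (hi - lo) * stats::plogis(z)
  c1 <- sq(z[1], b$c1_0[1], b$c1_0[2])
  Ra <- sq(z[2], b$R_acid[1], b$R_acid[2])
  Rc <- sq(z[3], b$R_cat[1], b$R_cat[2])
  i <- 4
  if (problem$step == 2) {
    T_C <- sq(z[i], b$T_C[1], b$T_C[2]); i <- i + 1
  } else T_C <- problem$kin$T_ref - 273.15
  t1 <- sq(z[i], b$t_min[1], b$t_min[2])
  rho <- 1.12 + 1.38 * stats::plogis(z[i + 1])  # spacing ratio in (1.12, 2.5)
  tt <- pmin(t1 * rho^(0:(problem$n_samples - 1)), b$t_min[2])
  tt <- tt[c(TRUE, diff(tt) >= min_spacing_min)]
  if (length(tt) < 3) stop("schedule collapsed below 3 samples")
  experiment_design(T_C = T_C, t_sample_min = tt, c1_0 = c1,
                    R_acid = Ra, R_cat = Rc,
                    ox_equiv = problem$ox_equiv,
                    id = paste0("design_", paste(problem$theta, collapse = "+")))
}

n_design_vars <- function(problem) if (problem$step == 2) 6L else 5L

#' D-optimal experiment design by multistart local search
#'
#' Maximises the log-determinant of the Fisher information over the
#' problem's free variables (composition, sampling schedule, and
#' temperature for step-2 problems) with a multistart Nelder-Mead search.
#'
#' @param problem A [design_problem()].
#' @param n_starts Number of random starts (>= 1).
#' @param maxit Nelder-Mead iterations per start.
#' @param seed Seed for the start points.
#' @param max_rel_se Practical-identifiability floor: designs whose
#'   predicted relative standard error exceeds this for any target
#'   parameter are infeasible.  The default rejects parameter subsets that
#'   no experiment can inform (e.g. the j = 1 pair); the campaign planner
#'   relaxes it and applies its own t-test selection instead.
#' @return List of class `doe_result` with the best `design`, its `fim`,
#'   the achieved `logdet` and the search log.
#' @export
design_experiment <- function(problem, n_starts = 8, maxit = 60,
                              seed = 1L, max_rel_se = 10) {
  stopifnot(inherits(problem, "design_problem"))
  d <- n_design_vars(problem)
  th <- theta_get(problem$kin, problem$theta)
  objective <- function(z) {
    des <- try(decode_design(z, problem), silent = TRUE)
    if (inherits(des, "try-error")) return(1e10)
    f <- try(fisher_information(des, problem$theta, problem$kin,
                                problem$thermo, problem$net, problem$noise),
             silent = TRUE)
    if (inherits(f, "try-error") || !is.finite(f$logdet) || is.null(f$cov))
      return(1e10)
    if (any(sqrt(diag(f$cov)) > max_rel_se * th)) return(1e10)
    -f$logdet
  }
  set.seed(seed)
  starts <- matrix(stats::rnorm(n_starts * d, 0, 1.2), nrow = n_starts)
  ## cheap random probe of the design space; the best probes join the
  ## multistart pool so the local search never loses to random baselines
  probes <- matrix(stats::rnorm(60 * d, 0, 1.5), nrow = 60)
  pv <- apply(probes, 1, objective)
  starts <- rbind(starts, probes[order(pv)[1:2], , drop = FALSE])
  best <- NULL
  log <- data.frame(start = integer(0), logdet = numeric(0))
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[s, ], objective, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    log <- rbind(log, data.frame(start = s, logdet = -fit$value))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  ## polish the incumbent with a restarted simplex
  if (!is.null(best) && best$value < 1e10) {
    fit <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit))
    if (fit$value < best$value) best <- fit
  }
  if (is.null(best) || best$value >= 1e10)
    stop("no feasible design: information matrix singular for {",
         paste(problem$theta, collapse = ", "), "}")
  design <- decode_design(best$par, problem)
  fim <- fisher_information(design, problem$theta, problem$kin,
                            problem$thermo, problem$net, problem$noise)
  structure(list(design = design, fim = fim, logdet = fim$logdet,
                 search_log = log, problem = problem),
            class = "doe_result")
}

#' Random feasible design of the same shape
#'
#' Baseline generator used to benchmark D-optimal designs: same sample
#' count, uniformly random composition and sample times within bounds.
#'
#' @param problem A [design_problem()].
#' @param seed Integer seed.
#' @return An [experiment_design()].
#' @export
random_design <- function(problem, seed = 1L) {
  set.seed(seed)
  b <- problem$bounds
  runifb <- function(r) stats::runif(1, r[1], r[2])
  T_C <- if (problem$step == 2) runifb(b$T_C) else problem$kin$T_ref - 273.15
  tt <- sort(stats::runif(problem$n_samples, b$t_min[1], b$t_min[2]))
  tt <- tt[c(TRUE, diff(tt) >= 0.5)]
  experiment_design(T_C = T_C, t_sample_min = tt, c1_0 = runifb(b$c1_0),
                    R_acid = runifb(b$R_acid), R_cat = runifb(b$R_cat),
                    id = paste0("random_", seed))
}

#' Plan the two-step design campaign
#'
#' Step 1 designs isothermal experiments at T_ref targeting reference rate
#' constants; step 2 designs temperature-varied experiments targeting
#' activation energies with rate constants fixed.  Within each step, all
#' combinations of single and grouped estimable parameters are designed
#' and screened: subsets whose predicted t-values all exceed the reference
#' t-value are kept, preferring larger subsets and breaking ties by the
#' smallest maximum pairwise correlation; when nothing passes, the best
#' singleton is retained.  Each selected problem is intended to be run
#' twice (design -> estimate, repeated) by [run_mbdoe_campaign()].
#'
#' @param groups Parameter groups from [group_parameters()].
#' @param kin,thermo,net,noise Model components and variance model.
#' @param bounds Design-space bounds.
#' @param n_samples Sample-count cap per experiment.
#' @param n_starts,maxit Search effort per design.
#' @param seed Integer seed.
#' @param max_subsets Cap on screened subsets per step.
#' @return List of class `campaign_plan`: selected `doe_result`s in order
#'   (step 1 then step 2), plus the screening table.
#' @export
plan_two_step_campaign <- function(groups, kin = azi_kinetics(),
                                   thermo = azi_thermo(),
                                   net = azi_network(),
                                   noise = variance_model(),
                                   bounds = design_space(),
                                   n_samples = 8, n_starts = 4, maxit = 40,
                                   seed = 1L, max_subsets = 8) {
  stopifnot(inherits(groups, "list"))
  members <- function(type)
    unique(unlist(lapply(groups, function(g)
      if (g$type == type) g$members else NULL)))
  ## candidate subsets: every singleton, every multi-parameter group and
  ## the full estimable set of the type (all combinations of single and
  ## grouped parameters, capped)
  subsets_of <- function(x, type) {
    if (length(x) == 0) return(list())
    gs <- Filter(function(g) g$type == type && length(g$members) > 1, groups)
    cand <- c(lapply(x, identity), lapply(gs, `[[`, "members"), list(x))
    cand <- unique(lapply(cand, sort))
    cand <- cand[order(-vapply(cand, length, integer(1)))]
    cand[seq_len(min(length(cand), max_subsets))]
  }
  plan <- list(); screen <- NULL
  theta_hat <- theta_get(kin)
  for (step in 1:2) {
    type <- if (step == 1) "k_ref" else "E_a"
    cands <- subsets_of(members(type), type)
    if (length(cands) == 0) next
    results <- list()
    for (i in seq_along(cands)) {
      sub <- cands[[i]]
      res <- try(design_experiment(
        design_problem(sub, step, n_samples, kin, thermo, net, noise,
                       bounds),
        n_starts = n_starts, maxit = maxit, seed = seed + i + 10 * step,
        max_rel_se = Inf),
        silent = TRUE)
      ok <- !inherits(res, "try-error")
      tv <- if (ok) try(predicted_t_values(res$fim, theta_hat),
                        silent = TRUE) else NULL
      pass <- ok && !inherits(tv, "try-error") && all(tv$pass)
      corr <- if (ok) max_pair_correlation(res$fim$cov) else NA
      screen <- rbind(screen, data.frame(
        step = step, subset = paste(sub, collapse = "+"),
        size = length(sub), pass = pass, max_corr = corr))
      if (ok) results[[paste(sub, collapse = "+")]] <-
        list(res = res, pass = pass, size = length(sub), corr = corr)
    }
    if (length(results) == 0) next
    passing <- Filter(function(r) r$pass, results)
    sizes <- vapply(results, `[[`, numeric(1), "size")
    corrs <- vapply(results, `[[`, numeric(1), "corr")
    if (length(passing) > 0) {
      keep <- passing[order(-vapply(passing, `[[`, numeric(1), "size"),
                            vapply(passing, `[[`, numeric(1), "corr"))]
      singles <- keep[vapply(keep, `[[`, numeric(1), "size") == 1]
      grouped <- keep[vapply(keep, `[[`, numeric(1), "size") > 1]
      sel <- c(singles, if (length(grouped) > 0) grouped[1])
    } else {
      ## nothing passes the t-test (typical under poor initial guesses):
      ## keep every singleton plus the least-correlated grouped design so
      ## the campaign still spans conditions for all target parameters
      singles <- results[sizes == 1]
      grouped <- results[sizes > 1]
      if (length(grouped) > 0)
        grouped <- grouped[order(corrs[sizes > 1])][1]
      sel <- c(singles, grouped)
    }
    for (r in sel) plan[[length(plan) + 1]] <- r$res
  }
  structure(list(designs = plan, screen = screen), class = "campaign_plan")
}

#' Serialise a campaign plan to JSON
#'
#' @param plan A `campaign_plan`.
#' @param path Output file.
#' @export
write_campaign_plan <- function(plan, path) {
  out <- lapply(plan$designs, function(r) {
    d <- r$design
    list(theta = r$problem$theta, step = r$problem$step,
         T_C = d$T_C, t_sample_min = d$t_sample_min, c1_0 = d$c1_0,
         R_acid = d$R_acid, R_cat = d$R_cat, logdet = r$logdet)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-design information diagnostics as CSV
#'
#' One row per target parameter: predicted standard error, relative
#' standard error and the design D-criterion.
#'
#' @param fim A [fisher_information()] result.
#' @param theta_hat Named current parameter values.
#' @param path Output file.
#' @export
write_fim_diagnostics <- function(fim, theta_hat, path) {
  se <- if (is.null(fim$cov)) rep(Inf, length(fim$theta))
        else sqrt(diag(fim$cov))
  df <- data.frame(parameter = fim$theta, predicted_se = se,
                   predicted_rel_se = se / theta_hat[fim$theta],
                   logdet_fim = fim$logdet,
                   n_samples = fim$n_samples)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
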