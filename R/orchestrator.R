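#' Simulate one designed experiment and report objectives
#'
#' Thin wrapper over the simulator for scripted use: validates the
#' operating point against the design-space bounds, simulates the
#' segment, and reports the trajectory together with yield and cost at
#' the final sample time.
#'
#' @param x Named operating point (`T_C`, `t_min`, `c1_0`, `R_acid`,
#'   `R_cat`).
#' @param kin,thermo,net Model components.
#' @param costmod A [cost_model()].
#' @param bounds Design-space bounds (NULL skips validation).
#' @param out_csv Optional path for the tidy trajectory CSV.
#' @return List with `trajectory`, `objectives`.
#' @export
simulate_experiment <- function(x, kin = azi_kinetics(),
                                thermo = azi_thermo(), net = azi_network(),
                                costmod = cost_model(),
                                bounds = design_space(), out_csv = NULL) {
  x <- as.list(x)
  if (!is.null(bounds)) {
    b <- bounds_matrix(bounds)
    for (nm in rownames(b)) {
      if (x[[nm]] < b[nm, 1] || x[[nm]] > b[nm, 2])
        stop(nm, " = ", x[[nm]], " outside design space [",
             b[nm, 1], ", ", b[nm, 2], "]")
    }
  }
  init <- initial_state(x$c1_0, x$R_acid, x$R_cat, 2, x$T_C + 273.15)
  traj <- simulate_segment(init, kin, thermo, net, horizon_s = x$t_min * 60)
  obj <- objective_values_from_c2(traj$s2[nrow(traj)], x, costmod)
  if (!is.null(out_csv)) write_trajectory(traj, out_csv)
  list(trajectory = traj, objectives = obj)
}

#' Run the full model-development campaign
#'
#' End-to-end model refinement: sensitivity screening and estimability
#' ranking on a reference design, design-by-grouping, two-step D-optimal
#' design of experiments (rate constants at T_ref, then activation
#' energies), virtual-lab data generation, and staged parameter
#' estimation.  Each step's design/estimate cycle is run twice to sharpen
#' poor initial guesses.
#'
#' @param kin_truth Ground-truth kinetics for the virtual laboratory.
#' @param kin_start Initial-guess kinetics for design and estimation.
#' @param thermo,net Thermodynamics and network (shared).
#' @param noise A [variance_model()] (`NULL` for noise-free data).
#' @param seed Integer seed.
#' @param n_samples Sample cap per designed experiment.
#' @param n_starts,maxit Design-search effort.
#' @param cycles Design/estimate repetitions per step.
#' @return List of class `mbdoe_campaign`: `plan`, `campaign` (data),
#'   `estimability`, `fit` (final joint `kinfit`).
#' @export
run_mbdoe_campaign <- function(kin_truth = azi_kinetics(),
                               kin_start = azi_kinetics(initial_guess = TRUE),
                               thermo = azi_thermo(), net = azi_network(),
                               noise = variance_model(), seed = 1L,
                               n_samples = 8, n_starts = 3, maxit = 30,
                               cycles = 2) {
  ## estimability screen on a representative temperature-varied design
  screen_design <- experiment_design(
    T_C = 82, t_sample_min = c(1, 2, 5, 10, 20, 35, 50, 60),
    c1_0 = 0.1, R_acid = 20, R_cat = 0.077, id = "screen")
  prof <- local_sensitivities(screen_design, kin_start, thermo, net)
  est <- estimability_rank(prof)
  estimable <- est$parameter[est$estimable]
  groups <- group_parameters(prof, estimable = estimable)

  kin_cur <- kin_start
  all_sets <- list()
  fit <- NULL
  noise_design <- if (is.null(noise)) variance_model() else noise
  for (cycle in seq_len(cycles)) {
    plan <- plan_two_step_campaign(groups, kin = kin_cur, thermo = thermo,
                                   net = net, noise = noise_design,
                                   n_samples = n_samples,
                                   n_starts = n_starts, maxit = maxit,
                                   seed = seed + cycle)
    designs <- lapply(seq_along(plan$designs), function(i) {
      r <- plan$designs[[i]]
      d <- r$design
      d$id <- sprintf("cycle%d_expt%d", cycle, i)
      d$theta_target <- r$problem$theta
      d
    })
    campaign <- generate_campaign_dataset(designs, kin_truth, thermo, net,
                                          noise = noise,
                                          seed = seed + 100L * cycle)
    all_sets <- c(all_sets, campaign$experiments)
    full <- structure(list(
      experiments = all_sets,
      n_samples = sum(vapply(all_sets, function(m) length(m$c2_obs),
                             numeric(1)))),
      class = "campaign_data")
    fit <- staged_estimation(full, kin = kin_cur, thermo = thermo,
                             net = net,
                             noise = if (is.null(noise)) variance_model()
                                     else noise,
                             multistart = if (cycle == cycles) 5L else 1L,
                             seed = seed + cycle,
                             stage1_order = est$parameter)
    if (isTRUE(fit$converged)) kin_cur <- fit$kin
  }
  structure(list(plan = plan, campaign = full, estimability = est,
                 groups = groups, fit = fit, profiles = prof),
            class = "mbdoe_campaign")
}

#' Run an optimisation campaign
#'
#' `mode = "insilico"`: train the active learner on the model-development
#' dataset and evaluate proposals on the calibrated process model;
#' successful conditions are re-evaluated through the noisy virtual lab
#' as validation.  `mode = "blackbox"`: train on a 5-point Latin
#' hypercube of virtual experiments and evaluate proposals directly on
#' the noisy virtual lab.
#'
#' @param mode `"insilico"` or `"blackbox"`.
#' @param kin,thermo,net Ground-truth model components.
#' @param costmod A [cost_model()].
#' @param targets A [target_spec()].
#' @param noise A [variance_model()].
#' @param seed Integer seed.
#' @param max_iter Iteration cap.
#' @param training Optional pre-built training list (`X`, `Y`,
#'   `feasible`), e.g. from [mbdoe_training_set()]; built on the fly when
#'   omitted.
#' @param n_lhs Training-set size for the black-box mode.
#' @return A `moal` object with an extra `validation` field in in-silico
#'   mode.
#' @export
run_optimisation <- function(mode = c("insilico", "blackbox"),
                             kin = azi_kinetics(), thermo = azi_thermo(),
                             net = azi_network(), costmod = cost_model(),
                             targets = target_spec(),
                             noise = variance_model(), seed = 1L,
                             max_iter = if (mode == "insilico") 200 else 15,
                             training = NULL, n_lhs = 5) {
  mode <- match.arg(mode)
  rule <- feasibility_rule()
  if (mode == "insilico") {
    if (is.null(training)) {
      camp <- run_mbdoe_campaign(kin_truth = kin, thermo = thermo,
                                 net = net, noise = noise, seed = seed)
      training <- mbdoe_training_set(camp$campaign, costmod)
    }
    evaluator <- model_evaluator(kin, thermo, net, costmod, rule)
  } else {
    if (is.null(training)) {
      Xl <- lhs_design(N = n_lhs, seed = seed)
      ev0 <- virtual_lab_evaluator(kin, thermo, net, noise, costmod, rule,
                                   seed = seed + 5000L)
      rows <- apply(Xl, 1, ev0, simplify = FALSE)
      training <- list(
        X = Xl,
        Y = cbind(yield_pct = vapply(rows, function(r)
                    ifelse(r$feasible > 0, r$yield_pct, 0), numeric(1)),
                  cost = vapply(rows, function(r)
                    ifelse(r$feasible > 0, r$cost, 1e6), numeric(1))),
        feasible = vapply(rows, function(r) r$feasible, numeric(1)))
    }
    evaluator <- virtual_lab_evaluator(kin, thermo, net, noise, costmod,
                                       rule, seed = seed + 9000L)
  }
  res <- run_closed_loop(training$X, training$Y, training$feasible,
                         evaluator, targets = targets,
                         max_iter = max_iter, seed = seed)
  if (mode == "insilico" && res$converged) {
    vev <- virtual_lab_evaluator(kin, thermo, net, noise, costmod, rule,
                                 seed = seed + 31L)
    res$validation <- vev(res$X_opt)
  }
  res
}

#' Write a reproducibility manifest
#'
#' Records seeds, package version and the model configuration digest so a
#' run can be reproduced bit-for-bit.
#'
#' @param path Output JSON file.
#' @param seed Seed(s) used.
#' @param extra Named list of additional entries.
#' @export
write_manifest <- function(path, seed, extra = list()) {
  info <- c(list(package = "aziflow",
                 version = as.character(utils::packageVersion("aziflow")),
                 r_version = R.version.string,
                 seed = seed, timestamp = format(Sys.time(), tz = "UTC")),
            extra)
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
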