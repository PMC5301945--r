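#' Process-model evaluator for the optimisation loop
#'
#' Wraps the calibrated kinetic model as a deterministic evaluator: the
#' proposed operating point is simulated, objectives computed, and the
#' rig feasibility rule applied (an infeasible point returns label -1
#' with no measurements, mimicking a failed experiment).
#'
#' @param kin,thermo,net Model components.
#' @param costmod A [cost_model()].
#' @param rule A [feasibility_rule()].
#' @param ox_equiv Oxidant equivalents.
#' @return Function of a named design vector, suitable for
#'   [run_closed_loop()].
#' @export
model_evaluator <- function(kin = azi_kinetics(), thermo = azi_thermo(),
                            net = azi_network(), costmod = cost_model(),
                            rule = feasibility_rule(), ox_equiv = 2) {
  function(x) {
    x <- as.list(x)
    des <- experiment_design(T_C = x$T_C, t_sample_min = x$t_min,
                             c1_0 = x$c1_0, R_acid = x$R_acid,
                             R_cat = x$R_cat, ox_equiv = ox_equiv)
    if (assess_feasibility(des, rule) < 0)
      return(list(yield_pct = NA_real_, cost = NA_real_, feasible = -1L))
    obj <- process_objectives(x, kin, thermo, net, costmod,
                              ox_equiv = ox_equiv)
    list(yield_pct = obj$yield_pct, cost = obj$cost, feasible = 1L)
  }
}

#' Virtual-laboratory evaluator for the optimisation loop
#'
#' Wraps the noisy virtual rig: the proposed point is run as a designed
#' flow experiment with a single GC sample at the reaction time, and the
#' objectives are computed from the *measured* product concentration and
#' substrate assay.  Each call consumes a fresh seed derived from the
#' base seed.
#'
#' @param kin,thermo,net Ground-truth model components.
#' @param noise A [variance_model()].
#' @param costmod A [cost_model()].
#' @param rule A [feasibility_rule()].
#' @param seed Base seed.
#' @param ox_equiv Oxidant equivalents.
#' @return Function of a named design vector for [run_closed_loop()].
#' @export
virtual_lab_evaluator <- function(kin = azi_kinetics(),
                                  thermo = azi_thermo(),
                                  net = azi_network(),
                                  noise = variance_model(),
                                  costmod = cost_model(),
                                  rule = feasibility_rule(), seed = 1L,
                                  ox_equiv = 2) {
  counter <- 0L
  function(x) {
    counter <<- counter + 1L
    x <- as.list(x)
    des <- experiment_design(T_C = x$T_C, t_sample_min = x$t_min,
                             c1_0 = x$c1_0, R_acid = x$R_acid,
                             R_cat = x$R_cat, ox_equiv = ox_equiv)
    m <- run_virtual_experiment(des, kin, thermo, net, noise = noise,
                                seed = seed + 7919L * counter, rule = rule)
    if (m$feasible < 0)
      return(list(yield_pct = NA_real_, cost = NA_real_, feasible = -1L))
    obj <- objective_values_from_c2(m$c2_obs[1],
                                    modifyList(x, list(c1_0 = m$c1_0_obs)),
                                    costmod, ox_equiv = ox_equiv)
    list(yield_pct = obj$yield_pct, cost = obj$cost, feasible = 1L)
  }
}

#' Build a surrogate training set from a measurement campaign
#'
#' Every GC sample of every feasible experiment becomes one training
#' point: inputs (T, sample time, composition), outputs (measured yield
#' and the specific cost evaluated at that reaction time).  Failed
#' experiments contribute one infeasible-labelled point.
#'
#' @param campaign A `campaign_data`.
#' @param costmod A [cost_model()].
#' @param ox_equiv Oxidant equivalents.
#' @return List with `X`, `Y`, `feasible` ready for [run_closed_loop()].
#' @export
mbdoe_training_set <- function(campaign, costmod = cost_model(),
                               ox_equiv = 2) {
  X <- NULL; Y <- NULL; feas <- integer(0)
  for (m in campaign$experiments) {
    d <- m$design
    if (m$feasible < 0) {
      X <- rbind(X, c(T_C = d$T_C, t_min = max(d$t_sample_min),
                      c1_0 = d$c1_0, R_acid = d$R_acid, R_cat = d$R_cat))
      Y <- rbind(Y, c(yield_pct = 0, cost = 1e6))
      feas <- c(feas, -1L)
      next
    }
    c1_obs <- if (is.finite(m$c1_0_obs)) m$c1_0_obs else d$c1_0
    for (k in seq_along(m$t_min)) {
      x <- list(T_C = d$T_C, t_min = m$t_min[k], c1_0 = c1_obs,
                R_acid = d$R_acid, R_cat = d$R_cat)
      obj <- objective_values_from_c2(m$c2_obs[k], x, costmod,
                                      ox_equiv = ox_equiv)
      X <- rbind(X, unlist(x))
      Y <- rbind(Y, c(yield_pct = obj$yield_pct, cost = obj$cost))
      feas <- c(feas, 1L)
    }
  }
  list(X = X, Y = Y, feasible = feas)
}
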