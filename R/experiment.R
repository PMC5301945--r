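#' Designed flow experiment
#'
#' A designed slug-flow experiment: reactor temperature, initial
#' composition expressed as substrate concentration plus acid and catalyst
#' ratios, and the GC sampling schedule.  User-facing units are degrees
#' Celsius and minutes; the simulator works in K and seconds.
#'
#' @param T_C Reaction temperature, degrees C.
#' @param t_sample_min Strictly increasing GC sample times, minutes.
#' @param c1_0 Initial substrate concentration, mol/L.
#' @param R_acid Acetic acid to substrate concentration ratio.
#' @param R_cat Catalyst to substrate concentration ratio.
#' @param ox_equiv Oxidant equivalents relative to substrate.
#' @param id Experiment label.
#' @return An object of class `experiment_design`.
#' @export
experiment_design <- function(T_C, t_sample_min, c1_0, R_acid, R_cat,
                              ox_equiv = 2, id = "expt") {
  if (any(diff(t_sample_min) <= 0) || any(t_sample_min <= 0))
    stop("sample times must be positive and strictly increasing (min)")
  if (c1_0 <= 0 || R_acid < 0 || R_cat <= 0 || ox_equiv < 0)
    stop("composition out of range")
  structure(list(T_C = T_C, t_sample_min = t_sample_min, c1_0 = c1_0,
                 R_acid = R_acid, R_cat = R_cat, ox_equiv = ox_equiv,
                 id = id),
            class = "experiment_design")
}

#' Design-space bounds of the flow rig
#'
#' Box bounds for the five experiment design variables
#' (T in C, reaction/sample time in min, substrate concentration in mol/L,
#' acid ratio, catalyst ratio), chosen to bracket every operating point
#' printed in the study.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
design_space <- function() {
  list(T_C = c(40, 110), t_min = c(1, 60), c1_0 = c(0.02, 0.2),
       R_acid = c(5, 60), R_cat = c(0.01, 0.15))
}

#' Constant-variance GC measurement model
#'
#' The GC analysis is modelled as unbiased Gaussian noise with constant
#' standard deviation: 0.0005 mol/L for the product and 0.0003 mol/L for
#' the pre-reaction substrate assay.  The reported instrument "accuracy
#' +/- x" is interpreted as one standard deviation; a uniform half-width
#' interpretation is selectable.
#'
#' @param sigma_product Product measurement sd, mol/L.
#' @param sigma_substrate Substrate measurement sd, mol/L.
#' @param family `"gaussian"` (default) or `"uniform"`.
#' @return An object of class `variance_model`.
#' @export
variance_model <- function(sigma_product = 5e-4, sigma_substrate = 3e-4,
                           family = c("gaussian", "uniform")) {
  family <- match.arg(family)
  if (sigma_product <= 0 || sigma_substrate <= 0)
    stop("measurement standard deviations must be positive")
  structure(list(sigma_product = sigma_product,
                 sigma_substrate = sigma_substrate, family = family),
            class = "variance_model")
}

#' Physical feasibility constraints of the rig
#'
#' An experiment fails (label -1) if the oxidant loading exceeds its
#' crystallisation limit or the temperature exceeds the catalyst
#' decomposition limit; optionally a random failure probability emulates
#' sporadic rig faults.
#'
#' @param T_max_C Maximum temperature, C.
#' @param c_ox_max Maximum oxidant concentration, mol/L.
#' @param p_random_failure Probability of a spurious failure (default 0).
#' @return An object of class `feasibility_rule`.
#' @export
feasibility_rule <- function(T_max_C = 110, c_ox_max = 0.3,
                             p_random_failure = 0) {
  structure(list(T_max_C = T_max_C, c_ox_max = c_ox_max,
                 p_random_failure = p_random_failure),
            class = "feasibility_rule")
}

#' Feasibility label of a design
#'
#' @param design An [experiment_design()].
#' @param rule A [feasibility_rule()].
#' @return `+1` if feasible, `-1` otherwise.
#' @export
assess_feasibility <- function(design, rule = feasibility_rule()) {
  c_ox <- design$ox_equiv * design$c1_0
  if (design$T_C > rule$T_max_C || c_ox > rule$c_ox_max) -1L else 1L
}

## Model-predicted product concentrations at the design's sample times.
predict_c2 <- function(design, kin, thermo, net, V_L = 2e-3,
                       rtol = 1e-8, atol = 1e-10) {
  t_s <- design$t_sample_min * 60
  init <- initial_state(design$c1_0, design$R_acid, design$R_cat,
                        design$ox_equiv, T_K = design$T_C + 273.15,
                        V_L = V_L)
  traj <- simulate_segment(init, kin, thermo, net,
                           horizon_s = max(t_s), grid_s = t_s,
                           rtol = rtol, atol = atol)
  traj$s2[match(t_s, traj$time_s)]
}

#' Run a virtual flow experiment
#'
#' Emulates the automated rig: simulates the designed slug through the
#' kinetic model and returns GC-like measurements — one noisy product
#' concentration per sample time and one noisy pre-reaction substrate
#' assay.  The noise is un-truncated Gaussian (negative observations are
#' possible near zero), keeping the error model unbiased.  Infeasible
#' designs return a failure label and no measurements.
#'
#' @param design An [experiment_design()].
#' @param kin,thermo,net Ground-truth model components.
#' @param noise A [variance_model()]; use sd 0 via `noise = NULL` for the
#'   noise-free limit.
#' @param seed Integer seed; fixed seed gives identical measurements.
#' @param rule A [feasibility_rule()].
#' @return An object of class `measurement_set` with fields `t_min`,
#'   `c2_obs`, `c1_0_obs`, `feasible`, `sigma` and `seed`.
#' @export
run_virtual_experiment <- function(design, kin, thermo, net,
                                   noise = variance_model(), seed = 1L,
                                   rule = feasibility_rule()) {
  feas <- assess_feasibility(design, rule)
  if (rule$p_random_failure > 0 && feas > 0) {
    set.seed(seed)
    if (stats::runif(1) < rule$p_random_failure) feas <- -1L
  }
  if (feas < 0) {
    return(structure(list(design = design, t_min = numeric(0),
                          c2_obs = numeric(0), c1_0_obs = NA_real_,
                          feasible = -1L, sigma = noise, seed = seed),
                     class = "measurement_set"))
  }
  c2 <- predict_c2(design, kin, thermo, net)
  sp <- if (is.null(noise)) 0 else noise$sigma_product
  ss <- if (is.null(noise)) 0 else noise$sigma_substrate
  set.seed(seed)
  if (!is.null(noise) && noise$family == "uniform") {
    c2_obs <- c2 + stats::runif(length(c2), -sp, sp)
    c1_obs <- design$c1_0 + stats::runif(1, -ss, ss)
  } else {
    c2_obs <- c2 + stats::rnorm(length(c2), 0, sp)
    c1_obs <- design$c1_0 + stats::rnorm(1, 0, ss)
  }
  structure(list(design = design, t_min = design$t_sample_min,
                 c2_obs = c2_obs, c2_true = c2, c1_0_obs = c1_obs,
                 feasible = 1L, sigma = noise, seed = seed),
            class = "measurement_set")
}

#' Run a campaign of virtual experiments
#'
#' One [run_virtual_experiment()] per design with per-experiment seeds
#' derived from `seed`.  Infeasible designs are labelled -1 and excluded
#' from the sample total.
#'
#' @param designs List of [experiment_design()] objects.
#' @param kin,thermo,net Ground-truth model components.
#' @param noise A [variance_model()] or `NULL` for noise-free data.
#' @param seed Integer campaign seed.
#' @param rule A [feasibility_rule()].
#' @return An object of class `campaign_data`: list of measurement sets
#'   plus `n_samples`, the total number of feasible samples.
#' @export
generate_campaign_dataset <- function(designs, kin, thermo, net,
                                      noise = variance_model(), seed = 1L,
                                      rule = feasibility_rule()) {
  if (length(designs) == 0) stop("design list must be non-empty")
  sets <- vector("list", length(designs))
  for (i in seq_along(designs)) {
    sets[[i]] <- run_virtual_experiment(designs[[i]], kin, thermo, net,
                                        noise = noise,
                                        seed = seed + 1000L * i, rule = rule)
  }
  n <- sum(vapply(sets, function(m) length(m$c2_obs), numeric(1)))
  structure(list(experiments = sets, n_samples = n, seed = seed),
            class = "campaign_data")
}

#' @export
print.measurement_set <- function(x, ...) {
  if (x$feasible < 0) {
    cat("<measurement_set> experiment", x$design$id, "FAILED (label -1)\n")
  } else {
    cat("<measurement_set>", x$design$id, ":", length(x$c2_obs),
        "product samples at", x$design$T_C, "C\n")
  }
  invisible(x)
}

#' @export
print.campaign_data <- function(x, ...) {
  cat("<campaign_data>", length(x$experiments), "experiments,",
      x$n_samples, "feasible samples\n")
  invisible(x)
}

#' Write a measurement set as CSV with a JSON sidecar
#'
#' The CSV holds columns `t_min` and `c2_obs_mol_per_L` plus one
#' pre-reaction substrate row; the sidecar records the design, seed and
#' measurement standard deviations for provenance.
#'
#' @param m A `measurement_set`.
#' @param path CSV path (the sidecar gets the extension `.json`).
#' @export
write_measurements <- function(m, path) {
  df <- data.frame(t_min = c(0, m$t_min),
                   species = c("s1", rep("s2", length(m$t_min))),
                   conc_obs_mol_per_L = c(m$c1_0_obs, m$c2_obs))
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(id = m$design$id, feasible = m$feasible, seed = m$seed,
               sigma_product = if (is.null(m$sigma)) 0 else m$sigma$sigma_product,
               sigma_substrate = if (is.null(m$sigma)) 0 else m$sigma$sigma_substrate,
               design = m$design[c("T_C", "t_sample_min", "c1_0",
                                   "R_acid", "R_cat", "ox_equiv")])
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
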