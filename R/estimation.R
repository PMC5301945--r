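## Weighted residual vector of a campaign under a parameter vector:
## (observed - model)/sigma over all feasible product samples.
campaign_residuals <- function(theta, campaign, kin, thermo, net, noise,
                               rtol = 1e-10, atol = 1e-12) {
  kin2 <- theta_set(kin, theta)
  res <- numeric(0)
  for (m in campaign$experiments) {
    if (m$feasible < 0) next
    pred <- try(suppressWarnings(
      predict_c2(m$design, kin2, thermo, net,
                 rtol = rtol, atol = atol)), silent = TRUE)
    if (inherits(pred, "try-error") || any(!is.finite(pred)))
      return(NULL)
    res <- c(res, (m$c2_obs - pred) / noise$sigma_product)
  }
  res
}

#' Weighted least-squares objective
#'
#' Sum over all feasible samples of (observed - model)^2 / sigma^2 with
#' the constant GC product variance.  Zero iff the model reproduces every
#' observation exactly.  A failed simulation returns a large penalty with
#' a warning rather than an error, so optimisers can recover.
#'
#' @param theta Named parameter values (subset of [theta_names()]).
#' @param campaign A `campaign_data` object.
#' @param kin,thermo,net Model components (parameters not in `theta` stay
#'   at their values in `kin`).
#' @param noise A [variance_model()].
#' @return Scalar objective value.
#' @export
wls_objective <- function(theta, campaign, kin = azi_kinetics(),
                          thermo = azi_thermo(), net = azi_network(),
                          noise = variance_model()) {
  if (length(campaign$experiments) == 0 || campaign$n_samples == 0)
    stop("campaign contains no data")
  r <- campaign_residuals(theta, campaign, kin, thermo, net, noise)
  if (is.null(r)) {
    warning("simulation failed at the requested parameters; penalised")
    return(1e12)
  }
  sum(r^2)
}

#' Fit kinetic parameters by weighted least squares
#'
#' Estimates a subset of the eight kinetic parameters from campaign data
#' by Levenberg-Marquardt minimisation of the weighted residuals in
#' log-parameter space (which enforces positivity), with optional
#' multistart jitter against local optima.  95 % confidence intervals and
#' t-values come from the Gauss-Newton curvature at the optimum.
#'
#' @param campaign A `campaign_data` object.
#' @param theta Names of the parameters to estimate.
#' @param start Named starting values (defaults to the values in `kin`).
#' @param kin,thermo,net Model components; parameters outside `theta`
#'   remain fixed at their `kin` values.
#' @param noise A [variance_model()].
#' @param multistart Number of starts (1 = no jitter); additional starts
#'   jitter log-uniformly within +/-30 % around the incumbent.
#' @param seed Seed for the jitter.
#' @param bounds_decades Log10 half-width of the parameter box.
#' @param maxiter Levenberg-Marquardt iteration cap.
#' @return An object of class `kinfit`.
#' @export
fit_kinetics <- function(campaign, theta, start = NULL,
                         kin = azi_kinetics(), thermo = azi_thermo(),
                         net = azi_network(), noise = variance_model(),
                         multistart = 1L, seed = 1L, bounds_decades = 6,
                         maxiter = 60) {
  stopifnot(all(theta %in% theta_names()))
  if (is.null(start)) start <- theta_get(kin, theta)
  start <- start[theta]
  if (any(start <= 0)) stop("starting values must be positive")
  lstart <- log(start)
  n_res <- sum(vapply(campaign$experiments, function(m)
    if (m$feasible > 0) length(m$c2_obs) else 0L, numeric(1)))
  resid_log <- function(lth) {
    r <- campaign_residuals(stats::setNames(exp(lth), theta), campaign,
                            kin, thermo, net, noise)
    ## smooth penalty on integrator failure, pulling back towards the
    ## start so the optimiser can recover from pathological parameters
    if (is.null(r)) rep(1e3 * (1 + sum(abs(lth - lstart)) / 10), n_res)
    else r
  }
  lower <- lstart - bounds_decades * log(10)
  upper <- lstart + bounds_decades * log(10)
  set.seed(seed)
  starts <- list(lstart)
  if (multistart > 1) {
    for (i in seq_len(multistart - 1)) {
      starts[[i + 1]] <- lstart +
        log(stats::runif(length(lstart), 0.7, 1.3))
    }
  }
  best <- NULL; best_obj <- Inf; best_dist <- Inf; n_fail <- 0
  for (s in starts) {
    fit <- try(minpack.lm::nls.lm(
      par = s, fn = resid_log, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                           ftol = 1e-12, ptol = 1e-10,
                                           epsfcn = 1e-8)),
      silent = TRUE)
    if (inherits(fit, "try-error")) { n_fail <- n_fail + 1; next }
    obj <- sum(fit$fvec^2)
    dist <- sqrt(sum((fit$par - lstart)^2))
    if (obj < best_obj - 1e-10 ||
        (abs(obj - best_obj) <= 1e-10 && dist < best_dist)) {
      best <- fit; best_obj <- obj; best_dist <- dist
    }
  }
  if (is.null(best))
    return(structure(list(converged = FALSE, theta = theta,
                          message = "all starts failed"),
                     class = "kinfit"))
  lhat <- best$par
  theta_hat <- stats::setNames(exp(lhat), theta)
  n <- length(best$fvec)
  p <- length(theta)
  dof <- max(n - p, 1)
  ## Gauss-Newton curvature in log space -> delta-method linear-scale CIs
  JtJ <- best$hessian
  ## eigen pseudo-inverse: directions the data do not constrain get an
  ## (effectively infinite) variance instead of a failed factorisation
  ev <- eigen((JtJ + t(JtJ)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 1e-16 * max(abs(ev$values), 1e-300))
  cov_log <- ev$vectors %*% (t(ev$vectors) / lam)
  se_log <- sqrt(pmax(diag(cov_log), 0))
  q <- stats::qt(0.975, dof)
  t_ref <- stats::qt(0.95, dof)
  se_lin <- theta_hat * se_log
  ci_half <- q * se_lin
  ## asymmetric log-scale Wald interval: the honest interval for a
  ## positivity-constrained parameter with a heavy-tailed estimate
  ci_lower <- theta_hat * exp(-q * se_log)
  ci_upper <- theta_hat * exp(q * se_log)
  t_value <- ifelse(se_lin > 0, theta_hat / (q * se_lin), Inf)
  structure(list(
    converged = best$info %in% 1:4, info = best$info,
    theta = theta, theta_hat = theta_hat, start = start,
    se = se_lin, ci_half = ci_half, ci_lower = ci_lower,
    ci_upper = ci_upper, t_value = t_value, t_ref = t_ref,
    dof = dof, objective = best_obj, cov_log = cov_log,
    n_obs = n, n_failed_starts = n_fail,
    kin = theta_set(kin, theta_hat), thermo = thermo, net = net,
    noise = noise, campaign = campaign),
    class = "kinfit")
}

#' Staged estimation over a designed campaign
#'
#' Mirrors the two-stage strategy of the study: each experiment first
#' refines only the parameters it was designed for (others fixed), then
#' all eight parameters — including the practically unidentifiable j = 1
#' pair — are estimated jointly from the full campaign with the stage-1
#' values as initial guesses and multistart jitter against local optima.
#'
#' @param campaign A `campaign_data`; experiments whose design carries a
#'   `theta_target` field get a stage-1 pass.
#' @param kin,thermo,net Model components holding the initial guesses.
#' @param noise A [variance_model()].
#' @param multistart Joint-stage starts (>= 5 jittered per the strategy).
#' @param seed Seed.
#' @param theta Parameters for the joint stage (default all eight).
#' @return A `kinfit` from the joint stage, with the stage-1 fits in
#'   field `stage1`.
#' @export
staged_estimation <- function(campaign, kin = azi_kinetics(initial_guess = TRUE),
                              thermo = azi_thermo(), net = azi_network(),
                              noise = variance_model(), multistart = 5L,
                              seed = 1L, theta = theta_names(),
                              stage1_order = NULL, bounds_decades = 3) {
  stage1 <- list()
  kin_cur <- kin
  idx <- seq_along(campaign$experiments)
  if (!is.null(stage1_order)) {
    ## refine strongly informative parameters first (continuation)
    pos <- vapply(campaign$experiments, function(m) {
      tt <- m$design$theta_target
      if (is.null(tt)) Inf else min(match(tt, stage1_order))
    }, numeric(1))
    idx <- idx[order(pos)]
  }
  for (i in idx) {
    m <- campaign$experiments[[i]]
    tt <- m$design$theta_target
    if (m$feasible < 0 || is.null(tt)) next
    sub <- structure(list(experiments = list(m),
                          n_samples = length(m$c2_obs)),
                     class = "campaign_data")
    f <- fit_kinetics(sub, theta = tt, kin = kin_cur, thermo = thermo,
                      net = net, noise = noise, multistart = 1L,
                      seed = seed + i, bounds_decades = bounds_decades)
    if (isTRUE(f$converged)) kin_cur <- f$kin
    stage1[[m$design$id]] <- f
  }
  joint <- fit_kinetics(campaign, theta = theta, kin = kin_cur,
                        thermo = thermo, net = net, noise = noise,
                        multistart = multistart, seed = seed,
                        bounds_decades = bounds_decades)
  joint$stage1 <- stage1
  joint
}

#' @export
print.kinfit <- function(x, ...) {
  if (!isTRUE(x$converged) && is.null(x$theta_hat)) {
    cat("<kinfit> FAILED:", x$message, "\n"); return(invisible(x))
  }
  cat("<kinfit> weighted least-squares fit of",
      length(x$theta), "kinetic parameters\n")
  cat("  objective:", format(x$objective, digits = 6),
      " obs:", x$n_obs, " converged:", x$converged, "\n")
  print(round(rbind(estimate = x$theta_hat, `ci95 half-width` = x$ci_half,
                    `t value` = x$t_value), 6))
  invisible(x)
}

#' @export
summary.kinfit <- function(object, ...) {
  df <- data.frame(parameter = object$theta,
                   initial_guess = unname(object$start),
                   estimate = unname(object$theta_hat),
                   ci95_half_width = unname(object$ci_half),
                   t_value = unname(object$t_value),
                   t_ref = object$t_ref, row.names = NULL)
  structure(list(table = df, objective = object$objective,
                 dof = object$dof, converged = object$converged),
            class = "summary.kinfit")
}

#' @export
print.summary.kinfit <- function(x, ...) {
  cat("Parameter estimates (weighted least squares, 95% CI):\n")
  print(x$table, digits = 5)
  cat("objective", format(x$objective, digits = 6), "on", x$dof,
      "degrees of freedom\n")
  invisible(x)
}

#' @export
coef.kinfit <- function(object, ...) object$theta_hat

#' @export
confint.kinfit <- function(object, parm, level = 0.95, ...) {
  ## log-scale Wald interval (parameters are positive by construction)
  se_log <- ifelse(object$theta_hat > 0,
                   object$se / object$theta_hat, Inf)
  q <- stats::qt(1 - (1 - level) / 2, object$dof)
  ci <- cbind(object$theta_hat * exp(-q * se_log),
              object$theta_hat * exp(q * se_log))
  colnames(ci) <- paste(c((1 - level) / 2, 1 - (1 - level) / 2) * 100, "%")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
predict.kinfit <- function(object, design, ...) {
  predict_c2(design, object$kin, object$thermo, object$net)
}

#' @export
residuals.kinfit <- function(object, ...) {
  campaign_residuals(object$theta_hat, object$campaign, object$kin,
                     object$thermo, object$net, object$noise)
}

#' @export
plot.kinfit <- function(x, ...) {
  obs <- unlist(lapply(x$campaign$experiments, function(m)
    if (m$feasible > 0) m$c2_obs else NULL))
  fit <- obs - residuals(x) * x$noise$sigma_product
  graphics::plot(fit, obs, xlab = "fitted c2 (mol/L)",
                 ylab = "observed c2 (mol/L)",
                 main = "kinfit: observed vs fitted", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Write a parameter-estimation report as CSV
#'
#' One row per parameter: initial guess, final value, units, 95 % CI
#' half-width, t-value and reference t-value.
#'
#' @param fit A `kinfit`.
#' @param path Output file.
#' @export
write_estimation_report <- function(fit, path) {
  units <- ifelse(startsWith(fit$theta, "Ea"), "J/mol",
                  ifelse(fit$theta == "k3", "1/s", "L/(mol s)"))
  df <- summary(fit)$table
  df$units <- units
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
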