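## The eight estimable kinetic parameters, by name.
theta_names <- function() c(paste0("k", 0:3), paste0("Ea", 0:3))

## Get/set named parameters on an azi_kinetics object.
theta_get <- function(kin, names = theta_names()) {
  all <- c(stats::setNames(kin$k_ref, paste0("k", 0:3)),
           stats::setNames(kin$E_a, paste0("Ea", 0:3)))
  all[names]
}

theta_set <- function(kin, theta) {
  for (nm in names(theta)) {
    j <- as.integer(sub("^(k|Ea)", "", nm)) + 1L
    if (startsWith(nm, "Ea")) kin$E_a[j] <- theta[[nm]]
    else kin$k_ref[j] <- theta[[nm]]
  }
  kin
}

#' Local dynamic sensitivity profiles
#'
#' Raw sensitivities d c2(t) / d theta of the measured output (product
#' concentration) with respect to each kinetic parameter, computed by
#' central finite differences with a relative step, and their normalised
#' form s~ = (d c2/d theta) * theta / max_t c2(t), which is dimensionless
#' and comparable across parameters.
#'
#' @param design An [experiment_design()] giving conditions and time grid.
#' @param kin,thermo,net Model components.
#' @param theta Parameter names to perturb (default all eight).
#' @param rel_step Relative finite-difference step.
#' @return An object of class `sensitivity_profiles`: list with `t_min`,
#'   matrices `raw` and `normalised` (time x parameter), `peak_time`,
#'   `peak_mag` (per parameter, of |normalised|), and `degenerate` flag
#'   (TRUE when no product forms).
#' @export
local_sensitivities <- function(design, kin, thermo, net,
                                theta = theta_names(), rel_step = 1e-4) {
  base <- predict_c2(design, kin, thermo, net)
  scale <- max(base)
  degenerate <- !is.finite(scale) || scale <= 1e-12
  raw <- matrix(0, nrow = length(base), ncol = length(theta),
                dimnames = list(NULL, theta))
  for (nm in theta) {
    th0 <- theta_get(kin, nm)
    h <- rel_step * abs(th0)
    if (h == 0) next
    up <- predict_c2(design, theta_set(kin, stats::setNames(th0 + h, nm)),
                     thermo, net)
    dn <- predict_c2(design, theta_set(kin, stats::setNames(th0 - h, nm)),
                     thermo, net)
    raw[, nm] <- (up - dn) / (2 * h)
  }
  normalised <- if (degenerate) raw * 0
    else sweep(raw, 2, theta_get(kin, theta), `*`) / scale
  pk <- apply(abs(normalised), 2, which.max)
  structure(list(t_min = design$t_sample_min, raw = raw,
                 normalised = normalised,
                 peak_time = stats::setNames(design$t_sample_min[pk],
                                             colnames(normalised)),
                 peak_mag = apply(abs(normalised), 2, max),
                 degenerate = degenerate, design = design),
            class = "sensitivity_profiles")
}

#' Estimability screen from sensitivity profiles
#'
#' Ranks parameters by the peak magnitude of their normalised sensitivity
#' and flags as non-estimable those whose peak falls below a relative
#' threshold of the largest peak.  Under the default model this reproduces
#' the finding that neither parameter of the off-cycle protonation step
#' (j = 1) can be estimated from product-concentration data.
#'
#' @param profiles A `sensitivity_profiles` object.
#' @param threshold Relative peak-magnitude threshold (see vignette for
#'   the calibration of the default).
#' @return Data frame with columns `parameter`, `peak_mag`, `peak_time`,
#'   `estimable`, ordered by decreasing peak magnitude.
#' @export
estimability_rank <- function(profiles, threshold = 3e-4) {
  stopifnot(inherits(profiles, "sensitivity_profiles"))
  pk <- profiles$peak_mag
  if (profiles$degenerate || all(pk == 0)) {
    return(data.frame(parameter = names(pk), peak_mag = pk,
                      peak_time = profiles$peak_time,
                      estimable = FALSE, row.names = NULL))
  }
  est <- pk >= threshold * max(pk)
  out <- data.frame(parameter = names(pk), peak_mag = unname(pk),
                    peak_time = unname(profiles$peak_time),
                    estimable = unname(est), row.names = NULL)
  out[order(-out$peak_mag), ]
}

#' Group parameters by shared sensitivity peak times
#'
#' Parameters of the same type (reference rate constants vs activation
#' energies) whose normalised sensitivity peaks fall within a common time
#' window are grouped for joint experiment design; parameters flagged
#' non-estimable are excluded.  Peaks are considered to share a window
#' when they lie within `window` times the sampling horizon of each other
#' (single-linkage).
#'
#' @param profiles A `sensitivity_profiles` object.
#' @param window Window width as a fraction of the horizon (0 gives all
#'   singletons).
#' @param estimable Optional character vector restricting the grouping.
#' @return List of `parameter_group`s: each a list with `members` and
#'   `type` (`"k_ref"` or `"E_a"`).
#' @export
group_parameters <- function(profiles, window = 0.2, estimable = NULL) {
  stopifnot(inherits(profiles, "sensitivity_profiles"))
  nm <- colnames(profiles$normalised)
  if (!is.null(estimable)) nm <- intersect(nm, estimable)
  horizon <- max(profiles$t_min)
  groups <- list()
  for (type in c("k_ref", "E_a")) {
    members <- nm[startsWith(nm, if (type == "k_ref") "k" else "Ea")]
    if (length(members) == 0) next
    pt <- profiles$peak_time[members]
    ord <- order(pt)
    cur <- members[ord[1]]
    for (i in seq_along(ord)[-1]) {
      if (pt[ord[i]] - pt[ord[i - 1]] <= window * horizon) {
        cur <- c(cur, members[ord[i]])
      } else {
        groups[[length(groups) + 1]] <-
          structure(list(members = cur, type = type),
                    class = "parameter_group")
        cur <- members[ord[i]]
      }
    }
    groups[[length(groups) + 1]] <-
      structure(list(members = cur, type = type), class = "parameter_group")
  }
  groups
}

#' Export sensitivity profiles as CSV
#'
#' @param profiles A `sensitivity_profiles` object.
#' @param path Output file.
#' @export
write_sensitivities <- function(profiles, path) {
  df <- data.frame(t_min = profiles$t_min, profiles$normalised,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
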