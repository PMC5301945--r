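#' Mixture state of a batch segment
#'
#' A reaction slug pumped through the coil behaves as an ideally mixed
#' batch reactor at its dispersion-free centre; its state is the vector of
#' molar concentrations plus temperature and segment volume.
#'
#' @param conc Named concentrations (mol/L) over [azi_species()]; missing
#'   species default to zero.
#' @param T_K Temperature, K.
#' @param V_L Segment volume, L.
#' @param t_s Elapsed reaction time, s.
#' @return An object of class `mixture_state`.
#' @export
mixture_state <- function(conc, T_K, V_L = 2e-3, t_s = 0) {
  full <- stats::setNames(numeric(8), azi_species())
  full[names(conc)] <- conc
  if (any(is.na(full)) || any(full < 0))
    stop("concentrations must be non-negative")
  if (T_K <= 0 || V_L <= 0) stop("temperature and volume must be positive")
  structure(list(conc = full, T_K = T_K, V_L = V_L, t_s = t_s,
                 moles = full * V_L),
            class = "mixture_state")
}

#' Initial mixture from a flow recipe
#'
#' Builds the segment's initial [mixture_state()] from the substrate
#' concentration, the acid and catalyst ratios and the oxidant
#' equivalents.
#'
#' @param c1_0 Substrate concentration, mol/L.
#' @param R_acid,R_cat Acid and catalyst to substrate ratios.
#' @param ox_equiv Oxidant equivalents.
#' @param T_K Temperature, K.
#' @param V_L Segment volume, L.
#' @return A [mixture_state()].
#' @export
initial_state <- function(c1_0, R_acid, R_cat, ox_equiv = 2, T_K,
                          V_L = 2e-3) {
  mixture_state(c(s1 = c1_0, HOAc = R_acid * c1_0, cat = R_cat * c1_0,
                  ox = ox_equiv * c1_0), T_K = T_K, V_L = V_L)
}

#' Simulate a batch reaction segment
#'
#' Integrates the isothermal mole balances dc_i/dt = sum_j nu_ij r_j of the
#' reaction network over a time horizon with a stiff-capable adaptive
#' solver (`deSolve::lsoda`, rtol 1e-8 / atol 1e-10).  Heat of reaction is
#' neglected (the lumped C-H activation is only slightly endothermic), so
#' temperature and volume are constant along the trajectory.
#'
#' @param initial A [mixture_state()] initial condition.
#' @param kin,thermo,net Model components.
#' @param horizon_s Integration horizon, s.
#' @param grid_s Optional time grid within `[0, horizon_s]` (s); defaults
#'   to 101 evenly spaced points.
#' @param rtol,atol Integrator tolerances.
#' @return A `segment_trajectory`: data frame with column `time_s` and one
#'   column per species (mol/L), plus attributes `T_K` and `V_L`.
#' @export
simulate_segment <- function(initial, kin, thermo, net,
                             horizon_s, grid_s = NULL,
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(initial, "mixture_state"))
  if (horizon_s < 0) stop("horizon must be non-negative")
  if (is.null(grid_s)) grid_s <- seq(0, horizon_s, length.out = 101)
  grid_s <- sort(unique(c(0, grid_s)))
  if (any(grid_s < 0) || any(grid_s > horizon_s + 1e-12))
    stop("time grid must lie within [0, horizon]")
  if (horizon_s == 0 || length(grid_s) == 1) {
    out <- data.frame(time_s = 0, t(initial$conc))
  } else {
    K <- eq_constants(thermo, net, initial$T_K)
    k <- rate_constant(kin, seq_len(ncol(net$nu)) - 1L, initial$T_K)
    parms <- c(nrow(net$nu), ncol(net$nu), k,
               ifelse(is.finite(K), 1 / K, 0),
               as.numeric(net$nu), as.numeric(net$orders),
               as.numeric(net$rev_orders))
    if (length(parms) > 512) stop("network too large for the compiled model")
    parms <- c(parms, numeric(512 - length(parms)))
    sol <- deSolve::lsoda(y = initial$conc, times = grid_s,
                          func = "azi_rhs", dllname = "aziflow",
                          initfunc = "azi_init", parms = parms,
                          rtol = rtol, atol = atol, maxsteps = 200000)
    if (attr(sol, "istate")[1] < 0)
      stop("stiff integration failed; retry with tighter tolerances ",
           "(e.g. rtol = ", rtol / 100, ")")
    out <- as.data.frame(sol)
    names(out) <- c("time_s", net$species)
  }
  structure(out, class = c("segment_trajectory", "data.frame"),
            T_K = initial$T_K, V_L = initial$V_L)
}

#' Conservation error of a trajectory
#'
#' The substrate-derived skeleton (s1 + s1HOAc + B + 2 A + s2) must be
#' constant along any trajectory; likewise total palladium
#' (cat + B + 2 A) and total acetate (HOAc + s1HOAc).  Returns the largest
#' relative drift of the three balances.
#'
#' @param traj A `segment_trajectory`.
#' @return Maximum relative conservation error (scalar).
#' @export
conservation_error <- function(traj) {
  bal <- list(
    skeleton = traj$s1 + traj$s1HOAc + traj$B + 2 * traj$A + traj$s2,
    palladium = traj$cat + traj$B + 2 * traj$A,
    acetate = traj$HOAc + traj$s1HOAc)
  err <- vapply(bal, function(b) {
    if (b[1] == 0) return(max(abs(b - b[1])))
    max(abs(b - b[1])) / abs(b[1])
  }, numeric(1))
  max(err)
}

#' Write a trajectory as tidy CSV
#'
#' Long format with columns `time_s`, `species`, `conc_mol_per_L`.
#'
#' @param traj A `segment_trajectory`.
#' @param path Output file.
#' @export
write_trajectory <- function(traj, path) {
  sp <- setdiff(names(traj), "time_s")
  long <- do.call(rbind, lapply(sp, function(s)
    data.frame(time_s = traj$time_s, species = s, conc_mol_per_L = traj[[s]])))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
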