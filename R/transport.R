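#' Fibrin gelation thresholds
#'
#' @param gel_threshold Fibrin concentration above which the network
#'   blocks flow (permeability 1 -> 0), nM. Default 450.
#' @param solid_threshold Fibrin concentration defining "solid" clot, the
#'   level used for the lagtime readout, nM. Default 3800 (half of the
#'   plasma fibrinogen concentration).
#' @return An object of class `gelation_params`.
#' @export
gelation_params <- function(gel_threshold = 450, solid_threshold = 3800) {
  if (!(gel_threshold > 0))
    stop("gel_threshold must be > 0", call. = FALSE)
  structure(list(gel_threshold = gel_threshold,
                 solid_threshold = solid_threshold),
            class = "gelation_params")
}

#' Time-integration policy
#'
#' @param cfl Advective CFL number (<= 1).
#' @param dt_max Maximum transport step, s.
#' @param rxn_tol Relative per-substep tolerance of the adaptive chemistry
#'   integrator.
#' @param flow_update_interval Minimum simulated time between flow
#'   re-solves after a permeability change, s (event-driven with
#'   coalescing; chemistry timescales are much longer than flow
#'   relaxation).
#' @param dt_output Output/recording cadence, s.
#' @param end_time_cap_min Run cap, minutes; a run that has not clotted by
#'   the cap is flagged `no_clot`.
#' @param coverage_threshold Activator coverage fraction defining the
#'   lagtime (default 0.5).
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(cfl = 0.9, dt_max = 0.25, rxn_tol = 1e-3,
                              flow_update_interval = 15, dt_output = 5,
                              end_time_cap_min = 150,
                              coverage_threshold = 0.5) {
  stopifnot(cfl > 0, cfl <= 1, dt_max > 0, rxn_tol > 0, dt_output > 0)
  structure(list(cfl = cfl, dt_max = dt_max, rxn_tol = rxn_tol,
                 flow_update_interval = flow_update_interval,
                 dt_output = dt_output,
                 end_time_cap_min = end_time_cap_min,
                 coverage_threshold = coverage_threshold),
            class = "integrator_config")
}

#' Initial simulation state
#'
#' Bulk species start at plasma composition everywhere; fibrin at zero;
#' surface species are confined to the activator boundary cells, where
#' their surface density is converted to an equivalent volumetric
#' concentration in the wall-adjacent cell (thin-layer discretization,
#' `c[nM] = sigma[nmol/mm^2] / dx[um] * 1e9`).
#'
#' @param domain A [domain_spec()].
#' @param scheme A `kinetic_scheme`.
#' @return An object of class `sim_state`: concentration matrix
#'   (`nx*ny` cells x species, x-fastest cell order), latched gel mask,
#'   inlet composition and the simulation clock.
#' @export
initialize_state <- function(domain, scheme) {
  comp <- compile_scheme(scheme)
  nc <- domain$nx * domain$ny
  conc <- matrix(rep(ifelse(comp$surface, 0, comp$plasma), each = nc),
                 nrow = nc, ncol = comp$ns,
                 dimnames = list(NULL, comp$names))
  act <- activator_cells(domain)   # wall row j=0 -> cell index == i
  if (length(act)) {
    sig <- comp$sigma0
    for (s in which(comp$surface & sig > 0)) {
      conc[act, s] <- sig[s] / domain$dx * 1e9
    }
  }
  st <- list(conc = conc, gel = integer(nc), time = 0,
             domain = domain, species = comp$names,
             inlet = ifelse(comp$surface, 0, comp$plasma),
             clip_mass = stats::setNames(numeric(comp$ns), comp$names))
  class(st) <- "sim_state"
  st
}

#' @exportS3Method base::print
print.sim_state <- function(x, ...) {
  cat("<sim_state> t = ", format(x$time, digits = 5), " s, ",
      x$domain$nx, "x", x$domain$ny, " cells, ",
      length(x$species), " species, ", sum(x$gel), " gel cells\n", sep = "")
  invisible(x)
}

#' Refresh inlet boundary composition
#'
#' The inlet (x = 0) carries a Dirichlet condition at plasma composition
#' for every bulk species (advective and diffusive); the outlet is
#' zero-gradient advective outflow and the walls are zero-flux. This
#' helper re-derives the inlet composition from a scheme (e.g. after a
#' factor-addition perturbation); [advance()] applies the conditions
#' during stepping.
#'
#' @param state A `sim_state`.
#' @param scheme A `kinetic_scheme`.
#' @return The state with its inlet composition updated.
#' @export
apply_boundary_conditions <- function(state, scheme) {
  comp <- compile_scheme(scheme)
  stopifnot(identical(comp$names, state$species))
  state$inlet <- ifelse(comp$surface, 0, comp$plasma)
  state
}

#' Refresh gel and solid-clot masks from the fibrin field
#'
#' Permeability is 0 where fibrin has ever reached the gel point and 1
#' elsewhere (the mask is latched: fibrinolysis is absent, so masks are
#' monotone non-decreasing in time).
#'
#' @param state A `sim_state`.
#' @param gel A [gelation_params()].
#' @return The state with `gel` updated and attributes `changed` (whether
#'   the permeability mask changed, i.e. a flow re-solve is due) and
#'   `solid` (the solid-clot mask) attached.
#' @export
update_gel <- function(state, gel) {
  fn <- state$conc[, "Fn"]
  new_gel <- as.integer(state$gel | (fn >= gel$gel_threshold))
  changed <- !identical(new_gel, state$gel)
  state$gel <- new_gel
  attr(state, "changed") <- changed
  attr(state, "solid") <- fn >= gel$solid_threshold
  state
}

#' Permeability field of a state
#' @param state A `sim_state`.
#' @return Integer vector over cells: 1 open, 0 gel.
#' @export
permeability <- function(state) 1L - state$gel

#' Advance the coupled fields
#'
#' One or more operator-split steps: upwind advection for convecting
#' species, explicit diffusion (unhindered by gel), adaptive per-cell
#' chemistry, and gel-mask latching. The step must respect the advective
#' CFL condition for the supplied flow (see [stable_dt()]).
#'
#' @param state A `sim_state`.
#' @param scheme A `kinetic_scheme` (or a pre-compiled scheme from the
#'   internal compiler, for repeated calls).
#' @param flow A `flow_state` (use [zero_flow()] for stagnant plasma).
#' @param dt Transport step, s.
#' @param nsteps Number of steps to take.
#' @param gel_params A [gelation_params()].
#' @param rxn_tol Chemistry tolerance (see [integrator_config()]).
#' @param closed Closed-box mode: no inflow/outflow through any boundary
#'   (used for conservation testing).
#' @return The advanced `sim_state`; attribute `mask_changed` reports
#'   whether any cell newly gelled.
#' @export
advance <- function(state, scheme, flow, dt, nsteps = 1L,
                    gel_params = gelation_params(), rxn_tol = 1e-3,
                    closed = FALSE) {
  comp <- if (inherits(scheme, "kinetic_scheme")) compile_scheme(scheme)
          else scheme
  dom <- state$domain
  conc <- state$conc + 0        # force a copy; kernel mutates in place
  gel <- state$gel + 0L
  clip <- state$clip_mass + 0
  fn_idx <- match("Fn", comp$names)
  res <- cpp_advance(conc, flow$u, flow$v, gel,
                     dom$nx, dom$ny, dom$dx,
                     comp$D, comp$convects, state$inlet, closed,
                     comp[c("rtype", "eidx", "sidx", "kf", "kr", "km",
                            "fptr", "fidx", "fpow", "bptr", "bidx", "bpow",
                            "nptr", "nidx", "ncoef")],
                     if (is.na(fn_idx)) -1L else fn_idx - 1L,
                     gel_params$gel_threshold,
                     dt, as.integer(nsteps), rxn_tol, clip)
  if (isTRUE(res$blowup))
    stop(sprintf("integration blow-up at cell %d, species %s",
                 res$bad_cell, comp$names[res$bad_species]), call. = FALSE)
  state$conc <- conc
  state$gel <- gel
  state$clip_mass <- stats::setNames(clip, comp$names)
  state$time <- state$time + dt * nsteps
  attr(state, "mask_changed") <- res$mask_changed
  state
}

#' Largest stable transport step for a flow state
#'
#' Minimum of the advective CFL bound, the explicit-diffusion stability
#' bound and `dt_max`.
#'
#' @param flow A `flow_state`.
#' @param scheme A `kinetic_scheme` or compiled scheme.
#' @param config An [integrator_config()].
#' @return Step size, s.
#' @export
stable_dt <- function(flow, scheme, config = integrator_config()) {
  comp <- if (inherits(scheme, "kinetic_scheme")) compile_scheme(scheme)
          else scheme
  dx <- flow$domain$dx
  umax <- max(abs(flow$u), abs(flow$v), 0)
  dt <- config$dt_max
  if (umax > 0) dt <- min(dt, config$cfl * dx / umax)
  dmax <- max(comp$D)
  if (dmax > 0) dt <- min(dt, 0.9 * dx^2 / (4 * dmax))
  dt
}

#' Solid-clot coverage of the activator
#'
#' Fraction of the activator length over which the fibrin concentration,
#' averaged over a fixed-height wall layer, is at or above the solid-clot
#' threshold (the lagtime readout). Averaging over a fixed physical band
#' rather than the wall-adjacent cell row keeps the readout comparable
#' across grid resolutions.
#'
#' @param state A `sim_state`.
#' @param gel A [gelation_params()].
#' @param band Wall-layer height over which fibrin is averaged, um
#'   (default 50; at least one cell row is always used).
#' @return Fraction in `[0, 1]`.
#' @export
activator_coverage <- function(state, gel, band = 50) {
  dom <- state$domain
  act <- activator_cells(dom)
  if (!length(act)) return(0)
  nrow_band <- max(1L, as.integer(floor(band / dom$dx + 1e-9)))
  nrow_band <- min(nrow_band, dom$ny)
  fn <- 0
  for (j in seq_len(nrow_band) - 1L) {
    fn <- fn + state$conc[act + j * dom$nx, "Fn"]
  }
  mean(fn / nrow_band >= gel$solid_threshold)
}
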