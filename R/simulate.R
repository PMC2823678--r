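#' A complete, reproducible experiment description
#'
#' Bundles everything one simulation needs: the kinetic scheme, an ordered
#' perturbation list, channel geometry, wall shear rate, gelation
#' thresholds and the integration policy.
#'
#' @param gamma_w Wall shear rate of the clean channel, 1/s.
#' @param scheme A `kinetic_scheme` (default: the packaged scheme).
#' @param perturbations Ordered list of perturbation edits (see
#'   [perturbations]); applied by [resolve_scenario()] before the run.
#' @param domain A [domain_spec()].
#' @param gel A [gelation_params()].
#' @param integrator An [integrator_config()].
#' @param id Scenario identifier (used in outputs and cache keys).
#' @param t_end_min Optional fixed run length, minutes; when set the run
#'   always continues to this time (used for kinetics readouts), otherwise
#'   it stops shortly after lagtime detection or at the cap.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(gamma_w, scheme = default_scheme(),
                            perturbations = list(),
                            domain = domain_spec(),
                            gel = gelation_params(),
                            integrator = integrator_config(),
                            id = "scenario", t_end_min = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"),
            inherits(domain, "domain_spec"),
            inherits(gel, "gelation_params"),
            inherits(integrator, "integrator_config"),
            is.numeric(gamma_w), length(gamma_w) == 1L, gamma_w >= 0)
  structure(list(gamma_w = gamma_w, scheme = scheme,
                 perturbations = perturbations, domain = domain,
                 gel = gel, integrator = integrator, id = id,
                 t_end_min = t_end_min),
            class = "scenario_config")
}

#' Resolve a scenario (apply its perturbations)
#'
#' @param scenario A [scenario_config()].
#' @return The scenario with all perturbations folded into its scheme,
#'   domain and thresholds, and its perturbation list emptied.
#' @export
resolve_scenario <- function(scenario) {
  out <- apply_perturbations(scenario, scenario$perturbations)
  out$perturbations <- list()
  out
}

#' Run one flow-coupled clotting simulation
#'
#' Initializes plasma in the channel, solves the clean-channel flow for
#' the requested wall shear rate, and advances the coupled
#' transport-chemistry system, re-solving the flow whenever the fibrin
#' gel mask grows (event-driven, coalesced over
#' `integrator$flow_update_interval` seconds). Records activator coverage
#' by solid clot, integral extrinsic tenase and remaining active TF at
#' the output cadence.
#'
#' @param scenario A [scenario_config()].
#' @param keep_state Return the final `sim_state` (default TRUE).
#' @param snapshot_times Optional numeric vector of times (min) at which
#'   to store full concentration-field snapshots.
#' @return A list of class `sim_result`: `trajectory` (data frame with
#'   `time_s`, `time_min`, `coverage`, `tenase_nmol_mm`,
#'   `tf_active_nmol_mm`, `n_gel`), `lagtime_min` (`NA` = no clot),
#'   `no_clot`, `status`, `n_flow_solves`, the resolved scenario and
#'   (optionally) the final state and snapshots.
#' @export
run_simulation <- function(scenario, keep_state = TRUE,
                           snapshot_times = NULL) {
  scn <- resolve_scenario(scenario)
  dom <- scn$domain; ic <- scn$integrator
  comp <- compile_scheme(scn$scheme)
  drv <- shear_to_drive(scn$gamma_w, dom)
  state <- initialize_state(dom, scn$scheme)
  flow <- solve_flow(dom, permeability(state), drv)
  n_solves <- 1L
  dt <- stable_dt(flow, comp, ic)
  cap_s <- (scn$t_end_min %||% ic$end_time_cap_min) * 60
  fixed_end <- !is.null(scn$t_end_min)
  t_last_solve <- 0
  pending_mask <- FALSE
  crossed_at <- NA_real_

  rec <- list()
  snaps <- list()
  record <- function(state) {
    cov <- activator_coverage(state, scn$gel)
    list(time_s = state$time, time_min = state$time / 60,
         coverage = cov,
         tenase_nmol_mm = integral_extrinsic_tenase(state),
         tf_active_nmol_mm = integral_active_tf(state),
         n_gel = sum(state$gel))
  }
  rec[[1]] <- record(state)
  status <- "ok"
  repeat {
    t_next <- min(state$time + ic$dt_output, cap_s)
    nsteps <- max(1L, as.integer(ceiling((t_next - state$time) / dt)))
    dt_eff <- (t_next - state$time) / nsteps
    state <- tryCatch(
      advance(state, comp, flow, dt_eff, nsteps, scn$gel, ic$rxn_tol),
      error = function(e) e)
    if (inherits(state, "error")) {
      status <- conditionMessage(state)
      state <- NULL
      break
    }
    if (isTRUE(attr(state, "mask_changed"))) pending_mask <- TRUE
    if (pending_mask &&
        state$time - t_last_solve >= ic$flow_update_interval &&
        scn$gamma_w > 0) {
      flow <- solve_flow(dom, permeability(state), drv)
      n_solves <- n_solves + 1L
      t_last_solve <- state$time
      pending_mask <- FALSE
      dt <- stable_dt(flow, comp, ic)
    }
    r <- record(state)
    rec[[length(rec) + 1L]] <- r
    if (!is.null(snapshot_times) &&
        any(abs(snapshot_times * 60 - state$time) < ic$dt_output / 2)) {
      snaps[[sprintf("t%.1fmin", state$time / 60)]] <- state$conc
    }
    if (is.na(crossed_at) && r$coverage >= ic$coverage_threshold)
      crossed_at <- state$time
    if (!fixed_end && !is.na(crossed_at) &&
        state$time >= crossed_at + ic$dt_output) break
    if (state$time >= cap_s) break
  }
  trajectory <- do.call(rbind, lapply(rec, as.data.frame))
  lt <- if (status == "ok") {
    lagtime(data.frame(time = trajectory$time_min,
                       coverage = trajectory$coverage),
            threshold = ic$coverage_threshold,
            cap = ic$end_time_cap_min)
  } else NA_real_
  out <- list(trajectory = trajectory,
              lagtime_min = lt,
              no_clot = is.na(lt),
              status = if (status == "ok") {
                if (is.na(lt) && !fixed_end) "no_clot" else "ok"
              } else paste("error:", status),
              n_flow_solves = n_solves,
              scenario = scn,
              final_state = if (keep_state) state else NULL,
              snapshots = if (length(snaps)) snaps else NULL)
  class(out) <- "sim_result"
  out
}

#' @exportS3Method base::print
print.sim_result <- function(x, ...) {
  cat("<sim_result> '", x$scenario$id, "' gamma_w = ", x$scenario$gamma_w,
      " /s: ", sep = "")
  if (x$no_clot) cat("no clot by ",
                     x$scenario$integrator$end_time_cap_min, " min cap\n",
                     sep = "")
  else cat("lagtime ", format(x$lagtime_min, digits = 4), " min\n", sep = "")
  invisible(x)
}

# cell-wise conversion factor: nM in a dx x dx cell -> nmol per mm depth
cell_to_nmol_mm <- function(domain) domain$dx * domain$dx * 1e-12

#' Integral extrinsic tenase along the activator
#'
#' Line integral of the TF.VIIa surface density over the activator patch,
#' per unit channel depth.
#'
#' @param state A `sim_state` carrying the `TF_VIIa` surface species.
#' @return Integral extrinsic tenase, nmol/mm.
#' @export
integral_extrinsic_tenase <- function(state) {
  act <- activator_cells(state$domain)
  if (!length(act) || !"TF_VIIa" %in% state$species) return(0)
  sum(state$conc[act, "TF_VIIa"]) * cell_to_nmol_mm(state$domain)
}

#' Remaining active (uninhibited) TF along the activator
#'
#' Total TF not yet locked in the quaternary complex: free TF plus TF.VII
#' plus TF.VIIa, per unit channel depth.
#'
#' @param state A `sim_state`.
#' @return Active TF, nmol/mm.
#' @export
integral_active_tf <- function(state) {
  act <- activator_cells(state$domain)
  pools <- intersect(c("TF", "TF_VII", "TF_VIIa"), state$species)
  if (!length(act) || !length(pools)) return(0)
  sum(state$conc[act, pools]) * cell_to_nmol_mm(state$domain)
}
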