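#' Named perturbation presets
#'
#' The perturbation vocabulary of the modular-decomposition experiments:
#' convection knockouts per factor class, feedback knockouts, factor and
#' inhibitor additions, and gelation-threshold variants.
#'
#' @return Named list; each element is a list of perturbation edits
#'   suitable for [scenario_config()].
#' @export
preset_perturbations <- function() {
  zym <- factor_group("zymogens")
  enz <- factor_group("enzymes")
  list(
    control = list(),
    gel_380 = list(pert_set_gel_threshold(380)),
    gel_760 = list(pert_set_gel_threshold(760)),
    solid_450 = list(pert_set_solid_threshold(450)),
    solid_7600 = list(pert_set_solid_threshold(7600)),
    activator_500 = list(pert_set_activator_length(500)),
    no_convection_zymogens = list(pert_set_convection(zym, FALSE)),
    no_convection_enzymes = list(pert_set_convection(enz, FALSE)),
    no_convection_enzymes_except_iia_xa =
      list(pert_set_convection(setdiff(enz, c("IIa", "Xa")), FALSE)),
    no_convection_iia_xa =
      list(pert_set_convection(c("IIa", "Xa"), FALSE)),
    no_xa_tfvii_activation = list(pert_zero_rate("xa_tfvii_activation")),
    no_iia_feedbacks = list(pert_zero_rate("iia_v_activation"),
                            pert_zero_rate("iia_vii_activation"),
                            pert_zero_rate("iia_viii_activation"),
                            pert_zero_rate("iia_xi_activation")),
    no_fibrinogen_cleavage = list(pert_zero_rate("fibrinogen_cleavage")),
    add_tfpi_5 = list(pert_add_conc("TFPI", 5)),
    add_at3_6800 = list(pert_add_conc("AT", 6800)),
    add_viia_10 = list(pert_add_conc("VIIa", 10))
  )
}

#' Build a scenario from a preset name
#'
#' @param preset Name from [preset_perturbations()].
#' @param gamma_w Wall shear rate, 1/s.
#' @param ... Passed to [scenario_config()].
#' @return A [scenario_config()].
#' @export
preset_scenario <- function(preset, gamma_w, ...) {
  pp <- preset_perturbations()
  if (!preset %in% names(pp))
    stop("unknown preset '", preset, "'; see preset_perturbations()",
         call. = FALSE)
  scenario_config(gamma_w, perturbations = pp[[preset]],
                  id = preset, ...)
}

scenario_hash <- function(scenario, gamma_w) {
  scn <- scenario
  scn$gamma_w <- gamma_w
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(resolve_scenario(scn), tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' Lagtime sweep over wall shear rates
#'
#' One simulation per shear; individual run failures are flagged and the
#' sweep continues. Completed points can be cached on disk, keyed by a
#' content hash of the fully resolved scenario (so editing any field of
#' the configuration invalidates the cache).
#'
#' @param scenario A [scenario_config()] (its `gamma_w` is ignored).
#' @param shears Wall shear rates, 1/s (sorted, non-empty).
#' @param cache_dir Optional directory for per-point caching; `NULL`
#'   disables caching.
#' @param verbose Print one line per completed point.
#' @return A [lagtime_curve()] with per-point run status in attribute
#'   `runs`.
#' @export
run_sweep <- function(scenario, shears, cache_dir = NULL, verbose = FALSE) {
  if (!length(shears)) stop("empty shear list", call. = FALSE)
  if (is.unsorted(shears, strictly = TRUE))
    stop("shears must be strictly increasing", call. = FALSE)
  lag <- numeric(length(shears)); status <- character(length(shears))
  for (k in seq_along(shears)) {
    key <- if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      file.path(cache_dir, paste0(scenario_hash(scenario, shears[k]), ".rds"))
    }
    if (!is.null(key) && file.exists(key)) {
      pt <- readRDS(key)
    } else {
      scn <- scenario; scn$gamma_w <- shears[k]
      res <- tryCatch(run_simulation(scn, keep_state = FALSE),
                      error = function(e) e)
      pt <- if (inherits(res, "error")) {
        list(lagtime = NA_real_,
             status = paste("error:", conditionMessage(res)))
      } else list(lagtime = res$lagtime_min, status = res$status)
      if (!is.null(key) && !startsWith(pt$status, "error"))
        saveRDS(pt, key, version = 2)
    }
    lag[k] <- pt$lagtime; status[k] <- pt$status
    if (verbose)
      message(sprintf("  gamma_w = %g /s: %s (%s)", shears[k],
                      if (is.na(pt$lagtime)) "no clot"
                      else sprintf("%.2f min", pt$lagtime), pt$status))
  }
  cv <- lagtime_curve(shears, lag, id = scenario$id)
  attr(cv, "runs") <- status
  cv
}

#' Flow-sensitivity table over perturbation presets
#'
#' For each preset: a perturbed lagtime sweep, the truncation interval
#' (cut at the first no-clot point of either curve), the flow-influence
#' coefficient against the control sweep and the sensitivity ratio of the
#' exponential fits over the same interval.
#'
#' @param presets Character vector of preset names (control is always run
#'   and reported first).
#' @param shears Shared shear grid, 1/s (default 0 to 28 by 4).
#' @param scenario Base scenario settings (scheme/domain/thresholds);
#'   default control configuration.
#' @param cache_dir,verbose Passed to [run_sweep()].
#' @return Data frame with columns `condition`, `R_range`, `interval`,
#'   `R_prime`; curves attached as attribute `curves`.
#' @export
run_table1 <- function(presets = c("no_convection_zymogens",
                                   "no_convection_enzymes"),
                       shears = seq(0, 28, by = 4),
                       scenario = scenario_config(0),
                       cache_dir = NULL, verbose = FALSE) {
  pp <- preset_perturbations()
  presets <- setdiff(presets, "control")
  ctrl_scn <- scenario; ctrl_scn$id <- "control"
  ctrl_scn$perturbations <- list()
  ctrl <- run_sweep(ctrl_scn, shears, cache_dir, verbose)
  ctrl_fin <- ctrl[!ctrl$no_clot, , drop = FALSE]
  rows <- list(data.frame(condition = "control", R_range = 1,
                          interval = paste0(min(ctrl_fin$gamma_w), "-",
                                            max(ctrl_fin$gamma_w)),
                          R_prime = 1))
  curves <- list(control = ctrl)
  for (p in presets) {
    scn <- scenario
    scn$perturbations <- pp[[p]]
    scn$id <- p
    cv <- run_sweep(scn, shears, cache_dir, verbose)
    curves[[p]] <- cv
    fi <- tryCatch(flow_influence(cv, ctrl, range(shears)),
                   error = function(e) NULL)
    Rp <- tryCatch({
      iv <- fi$interval
      sub <- function(x) x[x$gamma_w >= iv[1] & x$gamma_w <= iv[2], ,
                           drop = FALSE]
      sensitivity_ratio(fit_exponential(sub(cv)),
                        fit_exponential(sub(ctrl)))
    }, error = function(e) NA_real_)
    rows[[length(rows) + 1L]] <- data.frame(
      condition = p,
      R_range = if (is.null(fi)) NA_real_ else fi$R_range,
      interval = if (is.null(fi)) NA_character_
                 else paste0(fi$interval[1], "-", fi$interval[2]),
      R_prime = Rp)
  }
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  out
}

#' Lagtime versus activator size
#'
#' Sweeps the activator length at fixed wall shear rate and reports the
#' semi-reciprocal regression (lagtime against 1/length), whose linearity
#' diagnoses the hyperbolic dependence.
#'
#' @param lengths Activator lengths, um (each divisible by the grid
#'   spacing).
#' @param gamma_w Fixed wall shear rate, 1/s (default 17).
#' @param scenario Base scenario settings.
#' @param verbose Print progress.
#' @return Data frame `length_um`, `lagtime`, `no_clot`; attribute
#'   `semi_reciprocal` holds the `lm` fit of lagtime ~ 1/length over the
#'   clotting points (NULL if fewer than 2).
#' @export
run_activator_size_sweep <- function(lengths, gamma_w = 17,
                                     scenario = scenario_config(17),
                                     verbose = FALSE) {
  lag <- vapply(lengths, function(L) {
    scn <- scenario
    scn$gamma_w <- gamma_w
    scn$perturbations <- c(scenario$perturbations,
                           list(pert_set_activator_length(L)))
    scn$id <- paste0("activator_", L)
    res <- run_simulation(scn, keep_state = FALSE)
    if (verbose)
      message(sprintf("  L = %g um: %s", L,
                      if (res$no_clot) "no clot"
                      else sprintf("%.2f min", res$lagtime_min)))
    res$lagtime_min
  }, numeric(1))
  out <- data.frame(length_um = lengths, lagtime = lag, no_clot = is.na(lag))
  ok <- !is.na(lag)
  if (sum(ok) >= 2L)
    attr(out, "semi_reciprocal") <-
      stats::lm(lagtime ~ inv_length,
                data = data.frame(lagtime = lag[ok],
                                  inv_length = 1 / lengths[ok]))
  out
}

#' Integral tenase and TF-inhibition kinetics across flow conditions
#'
#' Runs the control scheme to a fixed end time at each shear (and
#' optionally the no-fibrinogen-cleavage variant, in which no clot can
#' form), recording the integral extrinsic tenase and remaining active TF
#' series suitable for overlay plots.
#'
#' @param shears Wall shear rates, 1/s (default `c(0, 7, 23)`).
#' @param t_end_min Run length, min.
#' @param include_no_cleavage Also run the fibrinogen-cleavage knockout at
#'   the highest shear.
#' @param scenario Base scenario settings.
#' @return Named list of `sim_result` objects.
#' @export
run_tenase_kinetics <- function(shears = c(0, 7, 23), t_end_min = 40,
                                include_no_cleavage = TRUE,
                                scenario = scenario_config(0)) {
  out <- list()
  for (g in shears) {
    scn <- scenario; scn$gamma_w <- g
    scn$t_end_min <- t_end_min
    scn$id <- sprintf("tenase_g%g", g)
    out[[scn$id]] <- run_simulation(scn, keep_state = FALSE)
  }
  if (include_no_cleavage) {
    scn <- scenario; scn$gamma_w <- max(shears)
    scn$t_end_min <- t_end_min
    scn$perturbations <- c(scenario$perturbations,
                           list(pert_zero_rate("fibrinogen_cleavage")))
    scn$id <- "tenase_no_cleavage"
    out[[scn$id]] <- run_simulation(scn, keep_state = FALSE)
  }
  out
}
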