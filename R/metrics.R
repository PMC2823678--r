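#' Clotting lagtime from a coverage series
#'
#' First crossing of the coverage threshold, linearly interpolated between
#' samples; `NA` (no clot) if the threshold is never crossed before the
#' cap.
#'
#' @param series Data frame with columns `time` (min, ordered) and
#'   `coverage` (fraction in `[0, 1]`).
#' @param threshold Coverage fraction defining the lagtime (default 0.5,
#'   i.e. half of the activator covered by solid clot).
#' @param cap Run cap, min.
#' @return Lagtime in minutes, or `NA_real_` for no clot.
#' @export
lagtime <- function(series, threshold = 0.5, cap = 150) {
  if (NROW(series) == 0L) stop("empty coverage series", call. = FALSE)
  t <- series$time; f <- series$coverage
  if (is.unsorted(t)) stop("series must be time-ordered", call. = FALSE)
  if (any(f < -1e-9 | f > 1 + 1e-9))
    stop("coverage fractions must lie in [0, 1]", call. = FALSE)
  hit <- which(f >= threshold)
  if (!length(hit)) return(NA_real_)
  k <- hit[1L]
  tl <- if (k == 1L) t[1L] else {
    t[k - 1L] + (threshold - f[k - 1L]) / (f[k] - f[k - 1L]) *
      (t[k] - t[k - 1L])
  }
  if (tl > cap) NA_real_ else tl
}

#' Lagtime-versus-shear curve
#'
#' @param gamma_w Wall shear rates, 1/s (strictly increasing).
#' @param lagtime_min Lagtimes, min (`NA` = no clot within the cap).
#' @param id Provenance: scenario id.
#' @return A data frame of class `lagtime_curve` with columns `gamma_w`,
#'   `lagtime` and `no_clot`.
#' @export
lagtime_curve <- function(gamma_w, lagtime_min, id = "scenario") {
  stopifnot(length(gamma_w) == length(lagtime_min))
  if (is.unsorted(gamma_w, strictly = TRUE))
    stop("gamma_w values must be strictly increasing", call. = FALSE)
  if (any(lagtime_min <= 0, na.rm = TRUE))
    stop("lagtimes must be positive", call. = FALSE)
  out <- data.frame(gamma_w = gamma_w, lagtime = lagtime_min,
                    no_clot = is.na(lagtime_min))
  attr(out, "id") <- id
  class(out) <- c("lagtime_curve", "data.frame")
  out
}

#' Exponential fit of a lagtime curve
#'
#' Nonlinear least squares for `y = y0 + A * exp(R * x)` with the
#' deterministic initial-guess rule: `y0` from the curve minimum, `A`
#' from the range, `R` from the log-slope of the last two points. Points
#' flagged `no_clot` are excluded (and their exclusion recorded). A flat
#' curve (range below `flat_tol`) is flagged `degenerate`: its exponent
#' is undefined, so downstream sensitivity ratios are not computable.
#'
#' @param curve A [lagtime_curve()] (or data frame with `gamma_w`,
#'   `lagtime`).
#' @param flat_tol Absolute lagtime range (min) below which the curve is
#'   considered flat. Default 0.1 min, the order of the grid-convergence
#'   error of short lagtimes.
#' @return An object of class `exponential_fit` with elements `y0`, `A`,
#'   `R`, `residual` (RMS), `degenerate`, `excluded` (shears dropped as
#'   no-clot).
#' @export
fit_exponential <- function(curve, flat_tol = 0.1) {
  x <- curve$gamma_w; y <- curve$lagtime
  excl <- x[is.na(y)]
  keep <- is.finite(y)
  x <- x[keep]; y <- y[keep]
  rng <- diff(range(y))
  if (rng < flat_tol) {
    return(structure(list(y0 = mean(y), A = 0, R = NA_real_,
                          residual = if (length(y) > 1L) stats::sd(y) else 0,
                          degenerate = TRUE, excluded = excl),
                     class = "exponential_fit"))
  }
  if (length(y) < 4L)
    stop("need at least 4 finite points to fit", call. = FALSE)
  n <- length(y)
  y0_0 <- min(y); A0 <- rng
  eps <- 1e-9 * max(rng, 1)
  R0 <- (log(max(y[n] - y0_0, eps)) - log(max(y[n - 1L] - y0_0, eps))) /
    (x[n] - x[n - 1L])
  if (!is.finite(R0) || R0 == 0) R0 <- 0.1
  fit <- minpack.lm::nlsLM(
    y ~ y0 + A * exp(R * x),
    start = list(y0 = y0_0, A = A0, R = R0),
    data = data.frame(x = x, y = y),
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- stats::coef(fit)
  structure(list(y0 = unname(cf["y0"]), A = unname(cf["A"]),
                 R = unname(cf["R"]),
                 residual = sqrt(mean(stats::resid(fit)^2)),
                 degenerate = FALSE, excluded = excl),
            class = "exponential_fit")
}

#' @exportS3Method base::print
print.exponential_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<exponential_fit> degenerate (flat curve), y0 =",
        format(x$y0, digits = 4), "\n")
  } else {
    cat(sprintf("<exponential_fit> y = %.4g + %.4g * exp(%.4g x), RMS %.3g\n",
                x$y0, x$A, x$R, x$residual))
  }
  invisible(x)
}

#' Comparative flow-influence coefficient
#'
#' Integral elevation of the perturbed lagtime curve over its own no-flow
#' value, relative to the same integral for the control, over the shear
#' interval `[i, j]` (trapezoidal rule on the shared shear grid). The
#' interval is auto-truncated at the first no-clot point of either curve.
#' Anchors: control against itself gives exactly 1; a perturbation whose
#' lagtime does not depend on shear gives 0.
#'
#' @param pert,ctrl [lagtime_curve()]s on a shared shear grid including
#'   `gamma_w = 0`.
#' @param interval Shear interval `c(i, j)`, 1/s.
#' @return List with `R_range`, the realised `interval`, and `truncated`.
#' @export
flow_influence <- function(pert, ctrl, interval = c(0, 28)) {
  g <- intersect(pert$gamma_w, ctrl$gamma_w)
  g <- sort(g[g >= interval[1] & g <= interval[2]])
  if (!(0 %in% pert$gamma_w) || !(0 %in% ctrl$gamma_w))
    stop("both curves must include gamma_w = 0", call. = FALSE)
  Lp <- pert$lagtime[match(g, pert$gamma_w)]
  Lc <- ctrl$lagtime[match(g, ctrl$gamma_w)]
  bad <- which(is.na(Lp) | is.na(Lc))
  truncated <- FALSE
  if (length(bad)) {
    if (bad[1L] <= 2L)
      stop("curves have no shared finite range over the interval",
           call. = FALSE)
    g <- g[seq_len(bad[1L] - 1L)]
    Lp <- Lp[seq_len(bad[1L] - 1L)]
    Lc <- Lc[seq_len(bad[1L] - 1L)]
    truncated <- TRUE
  }
  if (length(g) < 2L) stop("interval too short", call. = FALSE)
  Lp0 <- pert$lagtime[pert$gamma_w == 0]
  Lc0 <- ctrl$lagtime[ctrl$gamma_w == 0]
  trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                           utils::tail(y, -1)) / 2)
  den <- trapz(g, Lc - Lc0)
  if (den == 0) stop("control curve flat", call. = FALSE)
  list(R_range = trapz(g, Lp - Lp0) / den,
       interval = range(g), truncated = truncated)
}

#' Flow-sensitivity ratio of exponential fits
#'
#' Ratio of the fitted exponents, `R_pert / R_ctrl`: how much faster (or
#' slower) the perturbed lagtime grows per unit shear than the control.
#' Not computable (returns `NA`) when the perturbed fit is degenerate —
#' the flat-curve case.
#'
#' @param pert_fit,ctrl_fit [fit_exponential()] results.
#' @return `R_prime` (dimensionless), or `NA_real_` when not computable.
#' @export
sensitivity_ratio <- function(pert_fit, ctrl_fit) {
  if (ctrl_fit$degenerate)
    stop("control fit is degenerate", call. = FALSE)
  if (pert_fit$degenerate) return(NA_real_)
  pert_fit$R / ctrl_fit$R
}

#' TF-inhibition kinetics of a run
#'
#' Total uninhibited TF (free TF + TF.VII + TF.VIIa along the activator)
#' versus time, optionally normalized to the initial TF level.
#'
#' @param result A `sim_result` from [run_simulation()].
#' @param normalize Divide by the initial TF level.
#' @return Data frame with `time_min` and `tf_active` (nmol/mm, or
#'   fraction of initial when normalized).
#' @export
tf_inhibition_series <- function(result, normalize = FALSE) {
  tr <- result$trajectory
  out <- data.frame(time_min = tr$time_min, tf_active = tr$tf_active_nmol_mm)
  if (normalize) out$tf_active <- out$tf_active / out$tf_active[1L]
  out
}
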