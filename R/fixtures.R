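#' Analytic verification cases
#'
#' Self-contained closed-form references used to verify the numerical
#' components without external data. Each case bundles the configuration
#' fragment, the exact solution, an error norm and a tolerance that
#' accounts for the scheme's known truncation error. Cases are generated
#' at test time, never stored, so they cannot drift from the code.
#'
#' @name analytic_cases
NULL

analytic_case <- function(name, run, exact, tol, norm = "l2") {
  stopifnot(tol > 0)
  structure(list(name = name, run = run, exact = exact, tol = tol,
                 norm = norm), class = "analytic_case")
}

#' Evaluate an analytic case
#'
#' @param case An `analytic_case`.
#' @param ... Passed to the case's runner (e.g. resolution overrides).
#' @return List with `error`, `tol`, `pass`.
#' @export
run_analytic_case <- function(case, ...) {
  got <- case$run(...)
  want <- case$exact(got)
  err <- switch(case$norm,
                l2 = sqrt(sum((got$value - want)^2) / max(sum(want^2),
                                                          1e-300)),
                linf = max(abs(got$value - want)))
  list(name = case$name, error = err, tol = case$tol, pass = err <= case$tol)
}

#' Translated-Gaussian pure-advection case
#'
#' A Gaussian pulse advected by a uniform horizontal velocity; the exact
#' solution is the translated initial condition. The tolerance reflects
#' first-order upwind smearing over the travel distance.
#'
#' @param u Velocity, um/s (>= 0).
#' @param sigma0 Initial Gaussian width, um (>= 3 dx).
#' @param dx Grid spacing, um.
#' @param t_end Travel time, s.
#' @return An `analytic_case`; its runner returns the final field, the
#'   initial mass and the in-domain mass.
#' @export
make_advection_case <- function(u = 1000, sigma0 = 150, dx = 25,
                                t_end = 1) {
  stopifnot(u >= 0, sigma0 >= 3 * dx)
  nx <- 160L; ny <- 4L
  dom <- domain_spec(length_x = nx * dx, height_y = ny * dx,
                     activator_start = 0, activator_length = 0, dx = dx)
  x0 <- 0.25 * nx * dx
  scheme <- kinetic_scheme(
    list(species_spec("A", "zymogen", plasma_conc = 0,
                      diffusion_coeff = 0, convects = TRUE)),
    list())
  runner <- function() {
    st <- initialize_state(dom, scheme)
    xc <- (seq_len(dom$nx) - 0.5) * dx
    prof <- exp(-(xc - x0)^2 / (2 * sigma0^2))
    st$conc[, "A"] <- rep(prof, dom$ny)
    fl <- zero_flow(dom)
    fl$u[] <- u
    dt <- if (u > 0) 0.9 * dx / u else 0.1
    n <- max(1L, as.integer(ceiling(t_end / dt)))
    st2 <- advance(st, scheme, fl, t_end / n, n)
    list(value = st2$conc[seq_len(dom$nx), "A"], xc = xc, x0 = x0,
         mass0 = sum(prof) * dx, mass = sum(st2$conc[seq_len(dom$nx), "A"]) * dx,
         t = t_end, u = u, sigma0 = sigma0, dx = dx)
  }
  exact <- function(got) {
    exp(-(got$xc - got$x0 - got$u * got$t)^2 / (2 * got$sigma0^2))
  }
  # first-order upwind adds numerical diffusion D_num = u dx (1-CFL)/2;
  # the induced relative L2 error of this Gaussian is ~0.05 at CFL 0.9,
  # so 0.15 leaves margin without being vacuous
  analytic_case(sprintf("advection u=%g", u), runner, exact, 0.15)
}

#' Closed-form reaction cases
#'
#' Solvable kinetic motifs used to verify the chemistry sub-integrator:
#' first-order decay, reversible binding to its quadratic equilibrium,
#' and Michaelis-Menten in the substrate-excess (zero-order) limit.
#'
#' @param motif `"decay"`, `"binding"` or `"mm_excess"`.
#' @return An `analytic_case` whose runner integrates a single closed
#'   cell and returns the final composition.
#' @export
make_reaction_case <- function(motif = c("decay", "binding", "mm_excess")) {
  motif <- match.arg(motif)
  dom <- domain_spec(length_x = 50, height_y = 50, activator_start = 0,
                     activator_length = 0, dx = 50)
  run_box <- function(scheme, c0, t_end, dt = 0.05, tol = 1e-7) {
    st <- initialize_state(dom, scheme)
    st$conc[1, ] <- c0[st$species]
    n <- as.integer(ceiling(t_end / dt))
    st <- advance(st, scheme, zero_flow(dom), t_end / n, n,
                  rxn_tol = tol, closed = TRUE)
    st$conc[1, ]
  }
  if (motif == "decay") {
    k <- 0.1; a0 <- 1; t_end <- 10
    scheme <- kinetic_scheme(
      list(species_spec("A", plasma_conc = a0, diffusion_coeff = 0,
                        convects = FALSE),
           species_spec("B", plasma_conc = 0, diffusion_coeff = 0,
                        convects = FALSE)),
      list(reaction_spec("dec", c(A = 1), c(B = 1), "mass_action",
                         list(k = k))))
    runner <- function() list(value = run_box(scheme,
                                              c(A = a0, B = 0), t_end))
    exact <- function(got) c(A = a0 * exp(-k * t_end),
                             B = a0 * (1 - exp(-k * t_end)))
    return(analytic_case("first-order decay", runner, exact, 5e-7, "linf"))
  }
  if (motif == "binding") {
    kon <- 0.01; koff <- 0.05; tot <- 10; t_end <- 400
    scheme <- kinetic_scheme(
      list(species_spec("A", plasma_conc = tot, diffusion_coeff = 0,
                        convects = FALSE),
           species_spec("B", plasma_conc = tot, diffusion_coeff = 0,
                        convects = FALSE),
           species_spec("AB", plasma_conc = 0, diffusion_coeff = 0,
                        convects = FALSE)),
      list(reaction_spec("bind", c(A = 1, B = 1), c(AB = 1),
                         "reversible_binding",
                         list(k_on = kon, k_off = koff))))
    runner <- function() list(value = run_box(scheme,
      c(A = tot, B = tot, AB = 0), t_end, tol = 1e-8))
    exact <- function(got) {
      Kd <- koff / kon
      ab <- ((2 * tot + Kd) - sqrt((2 * tot + Kd)^2 - 4 * tot^2)) / 2
      c(A = tot - ab, B = tot - ab, AB = ab)
    }
    return(analytic_case("reversible binding equilibrium", runner, exact,
                         1e-8 * 10, "linf"))
  }
  # Michaelis-Menten, substrate excess: d[P]/dt ~ kcat*E (zero order)
  kcat <- 2; Km <- 5; E <- 1; S0 <- 50000; t_end <- 50
  scheme <- kinetic_scheme(
    list(species_spec("E", plasma_conc = E, diffusion_coeff = 0,
                      convects = FALSE),
         species_spec("S", plasma_conc = S0, diffusion_coeff = 0,
                      convects = FALSE),
         species_spec("P", plasma_conc = 0, diffusion_coeff = 0,
                      convects = FALSE)),
    list(reaction_spec("mm", c(E = 1, S = 1), c(E = 1, P = 1),
                       "michaelis_menten",
                       list(kcat = kcat, Km = Km, enzyme = "E",
                            substrate = "S"))))
  runner <- function() list(value = run_box(scheme,
    c(E = E, S = S0, P = 0), t_end))
  exact <- function(got) {
    p <- kcat * E * t_end       # zero-order limit, error O(Km/S0)
    c(E = E, S = S0 - p, P = p)
  }
  # the zero-order approximation itself errs by ~ p * Km / S0
  analytic_case("MM substrate excess", runner, exact,
                3 * kcat * E * t_end * (Km / S0), "linf")
}

#' Reference well-mixed trajectory (independent oracle)
#'
#' High-accuracy integration of a scheme under closed-box conditions
#' with `deSolve::lsoda` driven by [evaluate_rates()] — a codepath fully
#' independent of the spatial kernel's chemistry sub-integrator, so it
#' can serve as its oracle.
#'
#' @param scheme A `kinetic_scheme`.
#' @param t_end End time, s.
#' @param c0 Named initial concentrations (default: plasma composition
#'   plus surface species at their single-cell equivalent for `dx`).
#' @param times Output times (default 25 points).
#' @param dx Grid spacing used for the surface-density conversion, um.
#' @param rtol,atol Integration tolerances.
#' @return Data frame: `time` plus one column per species.
#' @export
make_zerod_oracle <- function(scheme, t_end, c0 = NULL, times = NULL,
                              dx = 50, rtol = 1e-10, atol = 1e-12) {
  comp <- compile_scheme(scheme)
  if (is.null(c0)) {
    c0 <- ifelse(comp$surface, comp$sigma0 / dx * 1e9, comp$plasma)
    names(c0) <- comp$names
  }
  if (is.null(times)) times <- seq(0, t_end, length.out = 25L)
  rhs <- function(t, y, parms) {
    list(evaluate_rates(pmax(y, 0), scheme))
  }
  out <- deSolve::lsoda(c0[comp$names], times, rhs, parms = NULL,
                        rtol = rtol, atol = atol)
  as.data.frame(out)
}

#' Synthetic coverage series with a known crossing time
#'
#' Piecewise-linear activator-coverage series that crosses 0.5 exactly at
#' the requested time; used to test the metrics layer without running
#' simulations.
#'
#' @param crossing_time Time of the 0.5 crossing, min (> 0).
#' @param t_max Series end, min.
#' @param n Number of samples.
#' @return Data frame with `time` and `coverage`.
#' @export
make_coverage_fixture <- function(crossing_time, t_max = 2 * crossing_time,
                                  n = 25L) {
  stopifnot(crossing_time > 0)
  t <- seq(0, t_max, length.out = n)
  cov <- pmin(1, 0.5 * t / crossing_time)
  data.frame(time = t, coverage = cov)
}
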