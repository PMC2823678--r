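# Small schemes and domains shared across tests; everything is built in
# code so fixtures cannot drift from the constructors.

tiny_ab_scheme <- function(k = 0.1) {
  kinetic_scheme(
    list(species_spec("A", plasma_conc = 1, diffusion_coeff = 0,
                      convects = FALSE),
         species_spec("B", plasma_conc = 0, diffusion_coeff = 0,
                      convects = FALSE)),
    list(reaction_spec("a_to_b", c(A = 1), c(B = 1), "mass_action",
                       list(k = k))),
    conservation_groups = list(AB = c("A", "B")))
}

single_cell_domain <- function(dx = 50) {
  domain_spec(length_x = dx, height_y = dx, activator_start = 0,
              activator_length = dx, dx = dx)
}

# default scheme with the calibrated constants, cached per session
cached_default_scheme <- local({
  sch <- NULL
  function() {
    if (is.null(sch)) sch <<- default_scheme()
    sch
  }
})

# naive per-reaction rate oracle, written independently of evaluate_rates
naive_net_rates <- function(conc, scheme) {
  out <- stats::setNames(numeric(length(scheme$species)),
                         species_names(scheme))
  for (r in scheme$reactions) {
    v <- switch(r$rate_law,
      mass_action = {
        x <- r$params$k
        for (s in names(r$reactants)) x <- x * conc[[s]]^r$reactants[[s]]
        x
      },
      michaelis_menten = {
        r$params$kcat * conc[[r$params$enzyme]] *
          conc[[r$params$substrate]] /
          (r$params$Km + conc[[r$params$substrate]])
      },
      reversible_binding = {
        f <- r$params$k_on
        for (s in names(r$reactants)) f <- f * conc[[s]]^r$reactants[[s]]
        f - r$params$k_off * conc[[names(r$products)]]
      })
    for (s in names(r$reactants)) out[s] <- out[s] - r$reactants[[s]] * v
    for (s in names(r$products)) out[s] <- out[s] + r$products[[s]] * v
  }
  out
}

# re-derive the activator wall-row cell indices (independent of the
# package's internal helper)
activator_cells_for_test <- function(domain) {
  i0 <- round(domain$activator_start / domain$dx)
  n <- round(domain$activator_length / domain$dx)
  (i0 + 1):(i0 + n)
}
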