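#' Declare a chemical species
#'
#' Builds the per-species record used by [kinetic_scheme()]: plasma
#' concentration (used both as the initial bulk value and as the inflow
#' composition), transport properties, and whether the species is confined
#' to the activator surface.
#'
#' @param name Species identifier (single string).
#' @param role One of `"zymogen"`, `"enzyme"`, `"cofactor"`, `"complex"`,
#'   `"inhibitor"`, `"fibrinogen"`, `"fibrin"`, `"surface-bound"`.
#' @param plasma_conc Plasma concentration, nM (inflow and initial bulk).
#' @param diffusion_coeff Diffusion coefficient, um^2/s.
#' @param convects Whether the convection term is active for this species.
#' @param surface_bound Confined to the activator patch (no transport).
#' @param surface_density Initial surface density, nmol/mm^2 (surface
#'   species only; usually nonzero only for TF).
#' @return An object of class `species_spec`.
#' @export
species_spec <- function(name, role = "zymogen", plasma_conc = 0,
                         diffusion_coeff = 50, convects = TRUE,
                         surface_bound = FALSE, surface_density = 0) {
  roles <- c("zymogen", "enzyme", "cofactor", "complex", "inhibitor",
             "fibrinogen", "fibrin", "surface-bound")
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  role <- match.arg(role, roles)
  if (surface_bound) {
    convects <- FALSE
    diffusion_coeff <- 0
  }
  sp <- list(name = name, role = role,
             plasma_conc = as.numeric(plasma_conc),
             diffusion_coeff = as.numeric(diffusion_coeff),
             convects = isTRUE(convects),
             surface_bound = isTRUE(surface_bound),
             surface_density = as.numeric(surface_density))
  class(sp) <- "species_spec"
  sp
}

#' Declare a reaction
#'
#' @param id Reaction identifier.
#' @param reactants,products Named integer vectors of stoichiometries,
#'   e.g. `c(TF_VII = 1, Xa = 1)`. Catalysts appear on both sides.
#' @param rate_law `"mass_action"`, `"michaelis_menten"` or
#'   `"reversible_binding"`.
#' @param params Named list of constants: `k` (mass action),
#'   `kcat`/`Km`/`enzyme`/`substrate` (Michaelis-Menten) or
#'   `k_on`/`k_off` (reversible binding). Units nM, s.
#' @param localization `"bulk"` or `"activator_surface"`.
#' @return An object of class `reaction_spec`.
#' @export
reaction_spec <- function(id, reactants, products, rate_law, params,
                          localization = "bulk") {
  rate_law <- match.arg(rate_law,
                        c("mass_action", "michaelis_menten",
                          "reversible_binding"))
  localization <- match.arg(localization, c("bulk", "activator_surface"))
  rx <- list(id = id,
             reactants = unlist(reactants), products = unlist(products),
             rate_law = rate_law, params = params,
             localization = localization)
  class(rx) <- "reaction_spec"
  rx
}

#' Assemble a kinetic scheme
#'
#' Validates species/reaction cross-references, non-negativity of all
#' constants, and the stoichiometric consistency of every conservation
#' group (each reaction must leave each group's summed protein core
#' unchanged in a closed system).
#'
#' @param species List of [species_spec()] objects.
#' @param reactions List of [reaction_spec()] objects.
#' @param conservation_groups Named list of character vectors of species
#'   names whose total is conserved in a closed system.
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(species, reactions, conservation_groups = list()) {
  sch <- list(species = species, reactions = reactions,
              conservation_groups = conservation_groups)
  class(sch) <- "kinetic_scheme"
  issues <- validate_scheme(sch)
  if (length(issues)) {
    stop("invalid kinetic scheme:\n", paste(issues, collapse = "\n"),
         call. = FALSE)
  }
  sch
}

#' @exportS3Method base::print
print.kinetic_scheme <- function(x, ...) {
  ns <- length(x$species)
  cat("<kinetic_scheme> ", ns, " species (",
      sum(vapply(x$species, function(s) s$surface_bound, logical(1))),
      " surface-bound), ", length(x$reactions), " reactions, ",
      length(x$conservation_groups), " conservation groups\n", sep = "")
  invisible(x)
}

#' Species names of a scheme
#' @param scheme A `kinetic_scheme`.
#' @return Character vector of species names, in scheme order.
#' @export
species_names <- function(scheme) {
  vapply(scheme$species, function(s) s$name, character(1))
}

#' Validate a kinetic scheme
#'
#' Machine-parsable validation: one issue per line, empty when valid.
#'
#' @param scheme A `kinetic_scheme` (or unclassed list with the same slots).
#' @return Character vector of issues (length 0 if the scheme is valid).
#' @export
validate_scheme <- function(scheme) {
  issues <- character(0)
  nm <- vapply(scheme$species, function(s) s$name, character(1))
  if (anyDuplicated(nm)) {
    issues <- c(issues, paste0("duplicate species name: ",
                               paste(unique(nm[duplicated(nm)]),
                                     collapse = ", ")))
  }
  for (s in scheme$species) {
    if (!is.finite(s$plasma_conc) || s$plasma_conc < 0)
      issues <- c(issues, paste0("species ", s$name,
                                 ": plasma_conc must be >= 0"))
    if (!is.finite(s$diffusion_coeff) || s$diffusion_coeff < 0)
      issues <- c(issues, paste0("species ", s$name,
                                 ": diffusion_coeff must be >= 0"))
    if (s$surface_bound && (s$convects || s$diffusion_coeff != 0))
      issues <- c(issues, paste0("species ", s$name,
                                 ": surface-bound species must not convect or diffuse"))
  }
  ids <- vapply(scheme$reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    issues <- c(issues, paste0("duplicate reaction id: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", ")))
  for (r in scheme$reactions) {
    part <- c(names(r$reactants), names(r$products))
    unknown <- setdiff(part, nm)
    if (length(unknown))
      issues <- c(issues, paste0("reaction ", r$id, ": unknown species ",
                                 paste(unknown, collapse = ", ")))
    st <- c(r$reactants, r$products)
    if (any(st != round(st)) || any(st < 0))
      issues <- c(issues, paste0("reaction ", r$id,
                                 ": stoichiometries must be non-negative integers"))
    want <- switch(r$rate_law,
                   mass_action = "k",
                   michaelis_menten = c("kcat", "Km"),
                   reversible_binding = c("k_on", "k_off"))
    miss <- setdiff(want, names(r$params))
    if (length(miss)) {
      issues <- c(issues, paste0("reaction ", r$id, ": missing constant ",
                                 paste(miss, collapse = ", ")))
      next
    }
    kk <- unlist(r$params[want])
    if (any(!is.finite(kk)) || any(kk < 0))
      issues <- c(issues, paste0("reaction ", r$id,
                                 ": rate constants must be finite and >= 0"))
    if (r$rate_law == "michaelis_menten") {
      if (!is.null(r$params$Km) && is.finite(r$params$Km) &&
          r$params$Km <= 0)
        issues <- c(issues, paste0("reaction ", r$id, ": Km must be > 0"))
      for (f in c("enzyme", "substrate")) {
        v <- r$params[[f]]
        if (is.null(v) || !v %in% nm)
          issues <- c(issues, paste0("reaction ", r$id, ": ", f,
                                     " must name a declared species"))
      }
    }
    if (r$rate_law == "reversible_binding" &&
        (length(r$reactants) != 2L || length(r$products) != 1L))
      issues <- c(issues, paste0("reaction ", r$id,
                                 ": reversible_binding needs A + B <-> AB form"))
  }
  # stoichiometric audit of the conservation groups
  if (!length(issues) && length(scheme$conservation_groups)) {
    S <- stoich_matrix(scheme)
    for (g in names(scheme$conservation_groups)) {
      members <- scheme$conservation_groups[[g]]
      unknown <- setdiff(members, nm)
      if (length(unknown)) {
        issues <- c(issues, paste0("conservation group ", g,
                                   ": unknown species ",
                                   paste(unknown, collapse = ", ")))
        next
      }
      drift <- colSums(S[members, , drop = FALSE])
      bad <- which(abs(drift) > 1e-12)
      if (length(bad))
        issues <- c(issues, paste0("conservation group ", g,
                                   ": violated by reaction ",
                                   paste(ids[bad], collapse = ", ")))
    }
  }
  issues
}

#' Net stoichiometry matrix (species x reactions)
#'
#' @param scheme A `kinetic_scheme`.
#' @return Numeric matrix, rows named by species, columns by reaction id.
#' @export
stoich_matrix <- function(scheme) {
  nm <- species_names(scheme)
  ids <- vapply(scheme$reactions, function(r) r$id, character(1))
  S <- matrix(0, length(nm), length(ids), dimnames = list(nm, ids))
  for (k in seq_along(scheme$reactions)) {
    r <- scheme$reactions[[k]]
    for (s in names(r$reactants)) S[s, k] <- S[s, k] - r$reactants[[s]]
    for (s in names(r$products))  S[s, k] <- S[s, k] + r$products[[s]]
  }
  S
}

#' Load a kinetic scheme from a YAML document
#'
#' The document has top-level keys `species`, `reactions` and (optionally)
#' `conservation_groups`; see the packaged default
#' (`system.file("extdata", "default_scheme.yaml", package = "coagflow")`)
#' for the expected layout. Units are fixed: nM, s, um, nmol/mm^2.
#'
#' @param path Path to a YAML file, or a YAML string.
#' @return A validated `kinetic_scheme`.
#' @export
load_scheme <- function(path) {
  doc <- if (length(path) == 1L && file.exists(path)) {
    yaml::read_yaml(path)
  } else {
    yaml::yaml.load(paste(path, collapse = "\n"))
  }
  for (key in c("species", "reactions")) {
    if (is.null(doc[[key]]))
      stop("scheme document is missing required key '", key, "'",
           call. = FALSE)
  }
  species <- lapply(doc$species, function(s) {
    species_spec(name = s$name,
                 role = s$role %||% "zymogen",
                 plasma_conc = s$plasma_conc %||% 0,
                 diffusion_coeff = s$diffusion_coeff %||%
                   (if (isTRUE(s$surface_bound)) 0 else 50),
                 convects = s$convects %||% !isTRUE(s$surface_bound),
                 surface_bound = s$surface_bound %||% FALSE,
                 surface_density = s$surface_density %||% 0)
  })
  reactions <- lapply(doc$reactions, function(r) {
    reaction_spec(id = r$id,
                  reactants = unlist(r$reactants),
                  products = unlist(r$products),
                  rate_law = r$rate_law,
                  params = r$params,
                  localization = r$localization %||% "bulk")
  })
  kinetic_scheme(species, reactions,
                 conservation_groups = doc$conservation_groups %||% list())
}

#' The packaged default coagulation scheme
#'
#' @return A validated `kinetic_scheme` (27 bulk + 4 surface species).
#' @export
default_scheme <- function() {
  load_scheme(system.file("extdata", "default_scheme.yaml",
                          package = "coagflow"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Net species production rates at a given composition
#'
#' Evaluates every rate law at the supplied (well-mixed) concentration
#' vector and assembles net production rates by stoichiometry. Mass action:
#' `k * prod(conc(reactants))`; Michaelis-Menten:
#' `kcat * E * S / (Km + S)`; reversible binding:
#' `k_on * A * B - k_off * AB`.
#'
#' @param conc Named numeric vector, nM, one entry per scheme species.
#' @param scheme A `kinetic_scheme`.
#' @return Named numeric vector of net production rates, nM/s.
#' @export
evaluate_rates <- function(conc, scheme) {
  nm <- species_names(scheme)
  if (is.null(names(conc))) {
    if (length(conc) != length(nm))
      stop("conc must have one entry per species", call. = FALSE)
    names(conc) <- nm
  }
  miss <- setdiff(nm, names(conc))
  if (length(miss))
    stop("conc is missing species: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(conc[nm])) || any(conc[nm] < 0))
    stop("negative or non-finite concentration (integrator bug signal)",
         call. = FALSE)
  rate <- vapply(scheme$reactions, function(r) reaction_rate(conc, r),
                 numeric(1))
  out <- as.numeric(stoich_matrix(scheme) %*% rate)
  names(out) <- nm
  out
}

reaction_rate <- function(conc, r) {
  switch(r$rate_law,
    mass_action = {
      v <- r$params$k
      for (s in names(r$reactants)) v <- v * conc[[s]]^r$reactants[[s]]
      v
    },
    michaelis_menten = {
      S <- conc[[r$params$substrate]]
      r$params$kcat * conc[[r$params$enzyme]] * S / (r$params$Km + S)
    },
    reversible_binding = {
      fwd <- r$params$k_on
      for (s in names(r$reactants)) fwd <- fwd * conc[[s]]^r$reactants[[s]]
      fwd - r$params$k_off * conc[[names(r$products)]]
    })
}

#' Conservation-group drift of a closed-system trajectory
#'
#' For a trajectory from a simulation with no inflow/outflow, reports the
#' maximum relative drift `|total(t) - total(0)| / total(0)` of each
#' conservation group.
#'
#' @param scheme A `kinetic_scheme` with conservation groups.
#' @param trajectory Matrix or data frame with one column per species
#'   (columns named by species; extra columns such as `time` are ignored).
#' @return Named numeric vector of max relative drifts, one per group.
#' @export
check_conservation <- function(scheme, trajectory) {
  trajectory <- as.matrix(as.data.frame(trajectory)[,
    intersect(colnames(as.data.frame(trajectory)), species_names(scheme)),
    drop = FALSE])
  if (nrow(trajectory) == 0L)
    stop("empty trajectory", call. = FALSE)
  vapply(scheme$conservation_groups, function(members) {
    tot <- rowSums(trajectory[, members, drop = FALSE])
    if (tot[1] == 0) return(max(abs(tot - tot[1])))
    max(abs(tot - tot[1]) / tot[1])
  }, numeric(1))
}

# ---- internal: compile a scheme into the flat arrays the C++ kernel uses ----
compile_scheme <- function(scheme) {
  nm <- species_names(scheme)
  ns <- length(nm)
  idx <- stats::setNames(seq_along(nm) - 1L, nm)  # 0-based
  nr <- length(scheme$reactions)
  rtype <- integer(nr); kf <- kr <- km <- numeric(nr)
  eidx <- sidx <- rep(-1L, nr)
  fptr <- bptr <- nptr <- integer(nr + 1L)
  fidx <- fpow <- bidx <- bpow <- integer(0)
  nidx <- integer(0); ncoef <- numeric(0)
  S <- stoich_matrix(scheme)
  for (k in seq_len(nr)) {
    r <- scheme$reactions[[k]]
    if (r$rate_law == "michaelis_menten") {
      rtype[k] <- 1L
      kf[k] <- r$params$kcat; km[k] <- r$params$Km
      eidx[k] <- idx[[r$params$enzyme]]
      sidx[k] <- idx[[r$params$substrate]]
    } else {
      rtype[k] <- 0L
      if (r$rate_law == "mass_action") {
        kf[k] <- r$params$k; kr[k] <- 0
      } else {
        kf[k] <- r$params$k_on; kr[k] <- r$params$k_off
      }
      fidx <- c(fidx, unname(idx[names(r$reactants)]))
      fpow <- c(fpow, as.integer(unname(r$reactants)))
      if (r$rate_law == "reversible_binding") {
        bidx <- c(bidx, unname(idx[names(r$products)]))
        bpow <- c(bpow, as.integer(unname(r$products)))
      }
    }
    nz <- which(S[, k] != 0)
    nidx <- c(nidx, nz - 1L)
    ncoef <- c(ncoef, unname(S[nz, k]))
    fptr[k + 1L] <- length(fidx)
    bptr[k + 1L] <- length(bidx)
    nptr[k + 1L] <- length(nidx)
  }
  list(ns = ns, nr = nr, names = nm,
       rtype = rtype, kf = kf, kr = kr, km = km,
       eidx = as.integer(eidx), sidx = as.integer(sidx),
       fptr = fptr, fidx = as.integer(fidx), fpow = as.integer(fpow),
       bptr = bptr, bidx = as.integer(bidx), bpow = as.integer(bpow),
       nptr = nptr, nidx = as.integer(nidx), ncoef = ncoef,
       D = vapply(scheme$species, function(s) s$diffusion_coeff, numeric(1)),
       convects = vapply(scheme$species, function(s) s$convects, logical(1)),
       surface = vapply(scheme$species, function(s) s$surface_bound, logical(1)),
       plasma = vapply(scheme$species, function(s) s$plasma_conc, numeric(1)),
       sigma0 = vapply(scheme$species, function(s) s$surface_density, numeric(1)))
}
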