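#' Perturbation edits
#'
#' Constructors for the edit vocabulary used by [apply_perturbations()]:
#' reaction knockouts, factor additions, per-species convection toggles and
#' scenario-geometry / gelation-threshold changes. Edits are applied in
#' order; the input object is never modified.
#'
#' @param reaction_id Reaction identifier to knock out (rate constants
#'   set to zero).
#' @param species Species name(s).
#' @param dconc Concentration increment, nM (applied to both the initial
#'   bulk value and the inflow composition).
#' @param on Logical: switch convection on or off for the named species.
#' @param length_um Activator patch length, um.
#' @param value_nM Threshold value, nM.
#' @return A `perturbation` object (a tagged list).
#' @name perturbations
NULL

pert <- function(type, ...) structure(list(type = type, ...),
                                      class = "perturbation")

#' @rdname perturbations
#' @export
pert_zero_rate <- function(reaction_id) pert("zero_rate", id = reaction_id)

#' @rdname perturbations
#' @export
pert_add_conc <- function(species, dconc) {
  pert("add_species_conc", species = species, dconc = dconc)
}

#' @rdname perturbations
#' @export
pert_set_convection <- function(species, on) {
  pert("set_convection", species = species, on = isTRUE(on))
}

#' @rdname perturbations
#' @export
pert_set_activator_length <- function(length_um) {
  pert("set_activator_length", length_um = length_um)
}

#' @rdname perturbations
#' @export
pert_set_gel_threshold <- function(value_nM) {
  pert("set_gel_threshold", value_nM = value_nM)
}

#' @rdname perturbations
#' @export
pert_set_solid_threshold <- function(value_nM) {
  pert("set_solid_threshold", value_nM = value_nM)
}

#' Apply an ordered list of perturbations
#'
#' Returns a new, revalidated object with the edits applied in order; the
#' input is unchanged. Scheme objects accept only scheme-level edits
#' (`zero_rate`, `add_species_conc`, `set_convection`); scenario objects
#' ([scenario_config()]) accept the full vocabulary.
#'
#' @param x A `kinetic_scheme` or `scenario_config`.
#' @param perturbations List of perturbation edits (see [perturbations]).
#' @return An object of the same class as `x`.
#' @export
apply_perturbations <- function(x, perturbations) {
  if (inherits(x, "scenario_config")) {
    for (p in perturbations) {
      stopifnot(inherits(p, "perturbation"))
      if (p$type == "set_activator_length") {
        x$domain$activator_length <- p$length_um
        x$domain <- do.call(domain_spec, x$domain[c(
          "length_x", "height_y", "activator_start", "activator_length",
          "dx")])
      } else if (p$type == "set_gel_threshold") {
        x$gel <- gelation_params(p$value_nM, x$gel$solid_threshold)
      } else if (p$type == "set_solid_threshold") {
        x$gel <- gelation_params(x$gel$gel_threshold, p$value_nM)
      } else {
        x$scheme <- apply_perturbations(x$scheme, list(p))
      }
    }
    return(x)
  }
  stopifnot(inherits(x, "kinetic_scheme"))
  nm <- species_names(x)
  ids <- vapply(x$reactions, function(r) r$id, character(1))
  for (p in perturbations) {
    stopifnot(inherits(p, "perturbation"))
    switch(p$type,
      zero_rate = {
        k <- match(p$id, ids)
        if (is.na(k))
          stop("zero_rate: no reaction with id '", p$id, "'", call. = FALSE)
        pk <- x$reactions[[k]]$params
        for (f in intersect(names(pk), c("k", "kcat", "k_on", "k_off")))
          pk[[f]] <- 0
        x$reactions[[k]]$params <- pk
      },
      add_species_conc = {
        k <- match(p$species, nm)
        if (is.na(k))
          stop("add_species_conc: unknown species '", p$species, "'",
               call. = FALSE)
        new_conc <- x$species[[k]]$plasma_conc + p$dconc
        if (new_conc < 0)
          stop("add_species_conc: resulting concentration of '", p$species,
               "' would be negative", call. = FALSE)
        x$species[[k]]$plasma_conc <- new_conc
      },
      set_convection = {
        k <- match(p$species, nm)
        if (anyNA(k))
          stop("set_convection: unknown species ",
               paste(p$species[is.na(k)], collapse = ", "), call. = FALSE)
        for (i in k) {
          if (x$species[[i]]$surface_bound && p$on)
            stop("set_convection: species '", x$species[[i]]$name,
                 "' is surface-bound", call. = FALSE)
          x$species[[i]]$convects <- p$on
        }
      },
      stop("perturbation '", p$type,
           "' does not apply to a bare kinetic scheme", call. = FALSE))
  }
  issues <- validate_scheme(x)
  if (length(issues))
    stop("perturbed scheme is invalid:\n", paste(issues, collapse = "\n"),
         call. = FALSE)
  x
}

#' Factor groups of the default scheme
#'
#' The zymogen and enzyme vocabularies used by the convection-toggle
#' experiments: zymogens are factors II, V, VII, VIII, IX, X, XI, PC and
#' fibrinogen; enzymes are IIa, Va, VIIa, VIIIa, IXa, Xa, XIa and APC.
#'
#' @param which `"zymogens"` or `"enzymes"`.
#' @return Character vector of species names.
#' @export
factor_group <- function(which = c("zymogens", "enzymes")) {
  switch(match.arg(which),
         zymogens = c("II", "V", "VII", "VIII", "IX", "X", "XI", "PC", "Fg"),
         enzymes  = c("IIa", "Va", "VIIa", "VIIIa", "IXa", "Xa", "XIa",
                      "APC"))
}
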