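test_that("the packaged scheme validates and carries the Xa feedback", {
  sch <- cached_default_scheme()
  expect_length(validate_scheme(sch), 0)
  # exactly one reaction produces TF_VIIa with Xa as catalyst, and it is
  # the only TF_VII -> TF_VIIa path besides direct VIIa binding
  feeds <- Filter(function(r) {
    "TF_VIIa" %in% names(r$products) && "Xa" %in% names(r$reactants) &&
      "Xa" %in% names(r$products)
  }, sch$reactions)
  expect_length(feeds, 1L)
  expect_identical(feeds[[1]]$id, "xa_tfvii_activation")
  from_tfvii <- Filter(function(r) {
    "TF_VII" %in% names(r$reactants) && "TF_VIIa" %in% names(r$products)
  }, sch$reactions)
  expect_identical(vapply(from_tfvii, function(r) r$id, character(1)),
                   "xa_tfvii_activation")
})

test_that("stoichiometric audit holds for every conservation group", {
  sch <- cached_default_scheme()
  S <- stoich_matrix(sch)
  for (g in names(sch$conservation_groups)) {
    drift <- colSums(S[sch$conservation_groups[[g]], , drop = FALSE])
    expect_true(all(abs(drift) < 1e-12), label = paste("group", g))
  }
})

test_that("unknown species and negative constants are rejected", {
  expect_error(load_scheme("
species:
  - {name: A}
reactions:
  - {id: bad, rate_law: mass_action, reactants: {A: 1},
     products: {FZz: 1}, params: {k: 0.1}}
"), "FZz")
  expect_error(kinetic_scheme(
    list(species_spec("A"), species_spec("B")),
    list(reaction_spec("r", c(A = 1), c(B = 1), "mass_action",
                       list(k = -1)))),
    ">= 0")
  rep <- validate_scheme(list(
    species = list(species_spec("A", plasma_conc = 2)),
    reactions = list(reaction_spec("r", c(A = 1), c(Qq = 1),
                                   "mass_action", list(k = 1))),
    conservation_groups = list()))
  expect_length(rep, 1L)
  expect_match(rep, "unknown species Qq")
})

test_that("a minimal two-species config loads", {
  sch <- load_scheme("
species:
  - {name: A, plasma_conc: 1}
  - {name: B}
reactions:
  - {id: dec, rate_law: mass_action, reactants: {A: 1}, products: {B: 1},
     params: {k: 0.1}}
")
  expect_length(sch$species, 2L)
  expect_length(sch$reactions, 1L)
  expect_equal(sch$reactions[[1]]$params$k, 0.1)
})

test_that("evaluate_rates matches the rate laws and the naive oracle", {
  # forced by the mass-action law: A+B -> C at k=1, [A]=[B]=1 gives 1 nM/s
  sch <- kinetic_scheme(
    list(species_spec("A", plasma_conc = 1), species_spec("B", plasma_conc = 1),
         species_spec("C")),
    list(reaction_spec("ab", c(A = 1, B = 1), c(C = 1), "mass_action",
                       list(k = 1))))
  r <- evaluate_rates(c(A = 1, B = 1, C = 0), sch)
  expect_equal(unname(r["C"]), 1)
  expect_equal(unname(r["A"]), -1)

  # all-zero composition: every rate law vanishes
  def <- cached_default_scheme()
  z <- stats::setNames(numeric(length(def$species)), species_names(def))
  expect_true(all(evaluate_rates(z, def) == 0))

  # a busy composition against an independently coded per-reaction loop
  set.seed(42)
  cc <- stats::setNames(runif(length(def$species), 0, 50),
                        species_names(def))
  got <- evaluate_rates(cc, def)
  want <- naive_net_rates(cc, def)
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(evaluate_rates(c(A = -1, B = 1, C = 0), sch), "negative")
})

test_that("perturbations apply in order, idempotently, out of place", {
  sch <- cached_default_scheme()
  p1 <- apply_perturbations(sch, list(pert_zero_rate("xa_tfvii_activation")))
  ids <- vapply(p1$reactions, function(r) r$id, character(1))
  expect_equal(p1$reactions[[match("xa_tfvii_activation", ids)]]$params$k, 0)
  # original untouched; double application equals single
  expect_gt(sch$reactions[[match("xa_tfvii_activation", ids)]]$params$k, 0)
  p2 <- apply_perturbations(p1, list(pert_zero_rate("xa_tfvii_activation")))
  expect_identical(p1, p2)

  # factor addition raises inflow/initial concentration
  pv <- apply_perturbations(sch, list(pert_add_conc("VIIa", 10)))
  k <- match("VIIa", species_names(sch))
  expect_equal(pv$species[[k]]$plasma_conc,
               sch$species[[k]]$plasma_conc + 10)

  # empty list is the identity
  expect_identical(apply_perturbations(sch, list()), sch)

  # convection toggles flip exactly the named species
  pe <- apply_perturbations(sch,
    list(pert_set_convection(factor_group("enzymes"), FALSE)))
  cv <- vapply(pe$species, function(s) s$convects, logical(1))
  names(cv) <- species_names(pe)
  expect_false(any(cv[factor_group("enzymes")]))
  expect_true(all(cv[c("II", "X", "Fg", "TFPI", "AT")]))

  expect_error(apply_perturbations(sch, list(pert_zero_rate("nope"))),
               "nope")
  expect_error(apply_perturbations(sch, list(pert_add_conc("TFPI", -99))),
               "negative")
})

test_that("check_conservation reports drift and rejects empty input", {
  sch <- tiny_ab_scheme()
  traj <- data.frame(time = 0:3, A = c(1, .8, .6, .5),
                     B = c(0, .2, .4, .5))
  expect_equal(unname(check_conservation(sch, traj)["AB"]), 0)
  bad <- traj; bad$B <- bad$B + c(0, 0, 0, 0.5)  # injected violation
  expect_gt(check_conservation(sch, bad)["AB"], 0.3)
  expect_error(check_conservation(sch, traj[0, ]), "empty")
})

test_that("validation report is one issue per line", {
  tmp <- tempfile()
  write_validation_report(cached_default_scheme(), tmp)
  expect_identical(readLines(tmp), "OK")
})
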