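# A miniature fast scenario: short channel, coarse grid, small activator.
mini_scenario <- function(gamma_w = 0, ...) {
  scenario_config(gamma_w,
                  domain = domain_spec(length_x = 1200, height_y = 400,
                                       activator_start = 200,
                                       activator_length = 400, dx = 100),
                  integrator = integrator_config(end_time_cap_min = 10,
                                                 dt_output = 5),
                  ...)
}

test_that("presets resolve and empty shear lists are rejected", {
  pp <- preset_perturbations()
  expect_true(all(c("control", "no_convection_enzymes", "add_viia_10",
                    "add_tfpi_5", "no_xa_tfvii_activation") %in% names(pp)))
  scn <- preset_scenario("no_convection_enzymes", 14)
  rs <- resolve_scenario(scn)
  cv <- vapply(rs$scheme$species, function(s) s$convects, logical(1))
  names(cv) <- species_names(rs$scheme)
  expect_false(any(cv[factor_group("enzymes")]))
  expect_error(run_sweep(mini_scenario(), numeric(0)), "empty")
  expect_error(preset_scenario("bogus", 0), "unknown preset")
})

test_that("scenario-level perturbations touch geometry and thresholds", {
  scn <- scenario_config(17, perturbations = list(
    pert_set_activator_length(500), pert_set_gel_threshold(760),
    pert_set_solid_threshold(7600)))
  rs <- resolve_scenario(scn)
  expect_equal(rs$domain$activator_length, 500)
  expect_equal(rs$gel$gel_threshold, 760)
  expect_equal(rs$gel$solid_threshold, 7600)
})

test_that("reruns are deterministic and the cache keys the full scenario", {
  scn <- mini_scenario(0, id = "mini")
  r1 <- run_simulation(scn, keep_state = FALSE)
  r2 <- run_simulation(scn, keep_state = FALSE)
  expect_identical(r1$trajectory, r2$trajectory)   # bit-identical rerun
  expect_false(r1$no_clot)

  cache <- file.path(tempdir(), "coagflow-test-cache")
  unlink(cache, recursive = TRUE)
  cv1 <- run_sweep(scn, c(0, 4), cache_dir = cache)
  n1 <- length(list.files(cache))
  expect_equal(n1, 2L)
  cv2 <- run_sweep(scn, c(0, 4), cache_dir = cache)  # served from cache
  expect_identical(cv1$lagtime, cv2$lagtime)
  expect_equal(length(list.files(cache)), n1)
  # any config edit invalidates the cached points
  scn2 <- scn
  scn2$gel <- gelation_params(gel_threshold = 500)
  run_sweep(scn2, c(0, 4), cache_dir = cache)
  expect_equal(length(list.files(cache)), 2L * n1)
  unlink(cache, recursive = TRUE)
})

test_that("activator-size sweep reports the semi-reciprocal regression", {
  out <- run_activator_size_sweep(c(400, 800), gamma_w = 0,
                                  scenario = mini_scenario(0))
  expect_equal(nrow(out), 2L)
  expect_true(all(!out$no_clot))
  # stagnant size-dependence is weak; the strong (hyperbolic) dependence
  # under flow is exercised in the acceptance suite
  expect_lte(out$lagtime[2], out$lagtime[1] + 0.5)
  fit <- attr(out, "semi_reciprocal")
  expect_s3_class(fit, "lm")
  one <- run_activator_size_sweep(800, gamma_w = 0,
                                  scenario = mini_scenario(0))
  expect_equal(nrow(one), 1L)
})

test_that("trajectory CSV and VTK exports round-trip", {
  scn <- mini_scenario(0)
  res <- run_simulation(scn, keep_state = TRUE)
  tmp <- tempfile(fileext = ".csv")
  write_trajectory_csv(res, tmp)
  back <- utils::read.csv(tmp)
  expect_equal(back$coverage, res$trajectory$coverage)
  vtk <- tempfile(fileext = ".vtk")
  write_vtk(res$final_state, vtk, species = "Fn")
  head <- readLines(vtk, n = 5)
  expect_match(head[4], "STRUCTURED_POINTS")
  fcsv <- tempfile(fileext = ".csv")
  write_field_csv(res$final_state, "Fn", fcsv)
  fb <- utils::read.csv(fcsv)
  expect_equal(nrow(fb), res$final_state$domain$nx *
                 res$final_state$domain$ny)
})
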