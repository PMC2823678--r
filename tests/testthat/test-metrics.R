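test_that("lagtime interpolates the first threshold crossing", {
  s <- data.frame(time = c(0, 2, 3), coverage = c(0, 0.4, 0.6))
  expect_equal(lagtime(s), 2.5)
  expect_true(is.na(lagtime(data.frame(time = 0:5,
                                       coverage = rep(0.49, 6)))))
  expect_error(lagtime(data.frame(time = numeric(), coverage = numeric())),
               "empty")
  expect_error(lagtime(data.frame(time = c(1, 0), coverage = c(0, 1))),
               "ordered")
  # crossing after the cap counts as no clot
  s2 <- make_coverage_fixture(crossing_time = 200)
  expect_true(is.na(lagtime(s2, cap = 150)))
  expect_equal(lagtime(make_coverage_fixture(2.5)), 2.5)
})

test_that("exponential fit recovers its generating parameters", {
  x <- seq(0, 28, by = 4)
  cv <- lagtime_curve(x, 1.54 + 2.86 * exp(0.129 * x))
  f <- fit_exponential(cv)
  expect_false(f$degenerate)
  expect_equal(f$y0, 1.54, tolerance = 1e-6)
  expect_equal(f$A, 2.86, tolerance = 1e-6)
  expect_equal(f$R, 0.129, tolerance = 1e-6)

  x8 <- seq(0, 21, by = 3)
  f2 <- fit_exponential(lagtime_curve(x8, 1 + exp(0.2 * x8)))
  expect_equal(c(f2$y0, f2$A, f2$R), c(1, 1, 0.2), tolerance = 1e-6)
})

test_that("flat curves are degenerate and no-clot points are excluded", {
  x <- seq(0, 28, by = 4)
  f <- fit_exponential(lagtime_curve(x, rep(2.5, length(x))))
  expect_true(f$degenerate)
  expect_true(is.na(f$R))
  y <- 1.54 + 2.86 * exp(0.129 * x)
  y[x > 20] <- NA               # capped runs
  f2 <- fit_exponential(lagtime_curve(x, y))
  expect_equal(f2$excluded, x[x > 20])
  expect_false(f2$degenerate)
})

test_that("exponential fit is scale-consistent", {
  x <- seq(0, 28, by = 4)
  y <- 2 + 3 * exp(0.1 * x)
  f1 <- fit_exponential(lagtime_curve(x, y))
  f2 <- fit_exponential(lagtime_curve(x, 5 * y))
  expect_equal(f2$y0, 5 * f1$y0, tolerance = 1e-6)
  expect_equal(f2$A, 5 * f1$A, tolerance = 1e-6)
  expect_equal(f2$R, f1$R, tolerance = 1e-6)
})

test_that("flow influence honours its normalization anchors", {
  x <- seq(0, 28, by = 4)
  ctrl <- lagtime_curve(x, 1.54 + 2.86 * exp(0.129 * x))
  # control against itself: exactly 1
  expect_identical(flow_influence(ctrl, ctrl)$R_range, 1)
  # flat perturbed curve: exactly 0
  flat <- lagtime_curve(x, rep(2.5, length(x)))
  expect_identical(flow_influence(flat, ctrl)$R_range, 0)
  # elevation exactly twice the control's: 2 (trapezoid-ratio oracle)
  twice <- lagtime_curve(x, ctrl$lagtime[1] + 2 * (ctrl$lagtime -
                                                     ctrl$lagtime[1]))
  expect_equal(flow_influence(twice, ctrl)$R_range, 2, tolerance = 1e-12)
  expect_error(flow_influence(ctrl, flat), "flat")
})

test_that("interval truncation stops at the first no-clot point", {
  x <- seq(0, 28, by = 4)
  ctrl <- lagtime_curve(x, 1.54 + 2.86 * exp(0.129 * x))
  y <- 1.54 + 5 * (ctrl$lagtime - 1.54)
  y[x > 12] <- NA
  pert <- lagtime_curve(x, y)
  fi <- flow_influence(pert, ctrl)
  expect_true(fi$truncated)
  expect_equal(fi$interval, c(0, 12))
  expect_equal(fi$R_range, 5, tolerance = 1e-12)
  # shrinking to a finite subinterval never yields NaN
  fi2 <- flow_influence(pert, ctrl, c(0, 8))
  expect_false(is.nan(fi2$R_range))
})

test_that("sensitivity ratio divides fitted exponents", {
  x <- seq(0, 28, by = 4)
  cf <- fit_exponential(lagtime_curve(x, 1 + 2 * exp(0.129 * x)))
  pf <- fit_exponential(lagtime_curve(x, 1 + 2 * exp(0.258 * x)))
  expect_equal(sensitivity_ratio(pf, cf), 2, tolerance = 1e-6)
  expect_equal(sensitivity_ratio(cf, cf), 1)
  flat <- fit_exponential(lagtime_curve(x, rep(2.5, length(x))))
  expect_true(is.na(sensitivity_ratio(flat, cf)))   # "-" entries
  expect_error(sensitivity_ratio(cf, flat), "degenerate")
})

test_that("integral tenase is the line integral of surface density", {
  dom <- domain_spec(length_x = 3000, height_y = 500,
                     activator_start = 1000, activator_length = 1000,
                     dx = 50)
  st <- initialize_state(dom, cached_default_scheme())
  expect_equal(integral_extrinsic_tenase(st), 0)
  # uniform density s over length L integrates to s*L:
  # equivalent volumetric 100 nM over 1000 um at dx = 50 um
  st$conc[activator_cells_for_test(dom), "TF_VIIa"] <- 100
  sigma <- 100 * 50 * 1e-9              # nmol/mm^2 per cell
  expect_equal(integral_extrinsic_tenase(st), sigma * 1)
  # initial active TF equals the configured surface density times length
  sig0 <- unname(st$conc[activator_cells_for_test(dom)[1], "TF"]) * 50 * 1e-9
  expect_equal(integral_active_tf(st), sig0 * 1 + sigma * 1)
})
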