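test_that("zero-variance coefficients make the MC estimate exact", {
  m <- intercept_model(log(0.1), 0)
  s <- toy_scenario()
  for (seed in c(1, 99, 2026)) {
    expect_equal(mc_percentile(m, s, n_draws = 500, seed = seed), 0.1,
                 tolerance = 1e-12)
  }
})

test_that("MC percentile is deterministic given the seed and monotone", {
  m <- intercept_model(log(0.05), 0.4)
  s <- toy_scenario()
  a <- mc_percentile(m, s, seed = 7)
  expect_identical(a, mc_percentile(m, s, seed = 7))
  expect_false(identical(a, mc_percentile(m, s, seed = 8)))
  # monotone in the requested percentile
  p <- vapply(c(50, 75, 90, 95, 99), function(q) {
    mc_percentile(m, s, percentile = q, seed = 7)
  }, numeric(1))
  expect_true(all(diff(p) > 0))
  # monotone in the coefficient mean
  m2 <- intercept_model(log(0.05) + 0.5, 0.4)
  expect_gt(mc_percentile(m2, s, seed = 7), a)
})

test_that("the default draw count is 1000 and small counts warn", {
  m <- intercept_model(log(0.05), 0.3)
  s <- toy_scenario()
  expect_identical(mc_percentile(m, s, seed = 3),
                   mc_percentile(m, s, n_draws = 1000, seed = 3))
  expect_warning(mc_percentile(m, s, n_draws = 50, seed = 3),
                 class = "silicarisk_warning")
})

test_that("large-draw MC approaches the analytic lognormal quantile", {
  mu <- log(0.08); s <- 0.35
  m <- intercept_model(mu, s)
  got <- mc_percentile(m, toy_scenario(), n_draws = 200000, seed = 12)
  expect_equal(got, exp(mu + 1.645 * s), tolerance = 0.01)
})

test_that("residual variability widens the estimate only when requested", {
  m <- intercept_model(log(0.05), 0, residual_log_sd = 0.8)
  s <- toy_scenario()
  without <- mc_percentile(m, s, seed = 4)
  with_res <- mc_percentile(m, s, seed = 4, include_residual = TRUE,
                            n_draws = 100000)
  expect_equal(without, 0.05, tolerance = 1e-12)
  expect_equal(with_res, exp(log(0.05) + 1.645 * 0.8), tolerance = 0.01)
})

test_that("separation factor reduces the estimate by 25%", {
  expect_equal(apply_separation_factor(0.100), 0.075)
  expect_equal(apply_separation_factor(0), 0)
  expect_equal(apply_separation_factor(apply_separation_factor(0.1)),
               0.1 * 0.5625) # double application would compound; assess() forbids it
  expect_error(apply_separation_factor(-0.1),
               class = "silicarisk_invalid_input")
})

test_that("duration discount halves estimates strictly below 4 h", {
  expect_equal(apply_duration_discount(0.10, 3.0), 0.05)
  expect_equal(apply_duration_discount(0.10, 5.0), 0.10)
  expect_equal(apply_duration_discount(0.10, 4.0), 0.10)
  expect_error(apply_duration_discount(0.10, 0),
               class = "silicarisk_invalid_input")
})

test_that("assess separates uncontrolled and controlled estimates coherently", {
  # toy model: wetting coefficient -ln(2) with zero variance
  m <- exposure_model(
    tibble::tibble(term = c("(Intercept)", "ctrl_wetting"),
                   estimate = c(log(0.1), -log(2)), se = c(0, 0)),
    control_terms = "wetting", db_version = "toy")
  s_none <- toy_scenario()
  est0 <- assess(m, s_none, seed = 5)
  expect_equal(est0$controlled_p95, est0$uncontrolled_p95)
  expect_false(est0$separation_applied)
  expect_false(est0$duration_discount_applied)

  s_wet <- toy_scenario(controls = "wetting")
  est <- assess(m, s_wet, seed = 5)
  expect_equal(est$controlled_p95, est$uncontrolled_p95 / 2, tolerance = 1e-12)
  expect_equal(est$uncontrolled_p95, 0.1, tolerance = 1e-12)

  s_sep <- toy_scenario(controls = c("wetting", "separation"))
  est2 <- assess(m, s_sep, seed = 5)
  expect_true(est2$separation_applied)
  expect_equal(est2$controlled_p95, 0.1 / 2 * 0.75, tolerance = 1e-12)

  s_short <- toy_scenario(controls = "wetting", task_duration_hours = 3)
  est3 <- assess(m, s_short, seed = 5)
  expect_true(est3$duration_discount_applied)
  expect_equal(est3$uncontrolled_p95, 0.1 * 0.5, tolerance = 1e-12)
  expect_equal(est3$controlled_p95, 0.1 / 2 * 0.5, tolerance = 1e-12)
})

test_that("assess compares to the OEL and never mutates its inputs", {
  m <- intercept_model(log(0.1), 0)
  s <- toy_scenario(controls = "separation")
  snapshot <- unserialize(serialize(s, NULL))
  est <- assess(m, s, oel = 0.025, seed = 2)
  expect_true(est$over_oel_uncontrolled)
  expect_true(est$over_oel_controlled)
  expect_true(est$respirator$required)
  expect_identical(s, snapshot) # what-if safety
  # under the OEL no respirator is required
  est2 <- assess(intercept_model(log(0.01), 0), toy_scenario(), seed = 2)
  expect_false(est2$over_oel_controlled)
  expect_false(est2$respirator$required)
  expect_identical(est2$over_oel_controlled, est2$controlled_p95 > est2$oel)
})

test_that("respirator recommendation walks the APF ladder", {
  none <- recommend_respirator(0.020, 0.025)
  expect_false(none$required)

  r8 <- recommend_respirator(0.200, 0.025)
  expect_true(r8$required)
  expect_equal(r8$hazard_ratio, 8)
  expect_equal(r8$minimum_apf, 10)

  r60 <- recommend_respirator(1.5, 0.025)
  expect_equal(r60$minimum_apf, 100)

  r400 <- recommend_respirator(10.0, 0.025)
  expect_equal(r400$hazard_ratio, 400)
  expect_equal(r400$minimum_apf, 1000) # supplied-air still covers 400

  esc <- recommend_respirator(30.0, 0.025) # ratio 1200 exceeds every APF
  expect_true(esc$escalate)
  expect_identical(esc$class_label, "reassess controls")
  expect_true(is.na(esc$minimum_apf))

  expect_error(recommend_respirator(0.1, 0),
               class = "silicarisk_invalid_input")
})

test_that("validation routine: empty input, small CSPs, exact GM identity", {
  m <- intercept_model(log(0.05), 0.1, residual_log_sd = 0.5)
  empty <- validate_against_measurements(m, new_measurement(0.05)[0, ])
  expect_equal(empty$n_csp, 0L)
  expect_equal(nrow(empty$by_csp), 0L)

  # intercept-only model fitted on a single CSP reproduces its GM exactly
  db <- generate_database(compact_spec(n = 60, seed = 31))
  db <- db[db$csp_id == db$csp_id[1], ]
  db$controls <- ""
  fit <- suppressWarnings(fit_exposure_model(
    db, terms = character(), controls = character(), duration = "none"))
  v <- validate_against_measurements(fit, db, seed = 1)
  expect_equal(v$by_csp$gm_ratio, 1, tolerance = 1e-12)

  # CSPs under the minimum size are excluded with a warning
  db2 <- db
  db2$csp_id[1:2] <- "CSP-RARE"
  expect_warning(
    v2 <- validate_against_measurements(fit, db2, seed = 1),
    "CSP-RARE")
  expect_equal(v2$n_csp, 1L)
  expect_identical(v2$excluded_csps, "CSP-RARE")
})
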