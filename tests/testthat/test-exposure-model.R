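two_group_db <- function() {
  # printed fixture: two sectors, three measurements each
  a <- c(0.02, 0.04, 0.08)
  b <- c(0.10, 0.20, 0.40)
  db <- do.call(rbind, lapply(seq_along(c(a, b)), function(i) {
    new_measurement(concentration = c(a, b)[i],
                    sector = rep(c("alpha", "beta"), each = 3)[i],
                    csp_id = "CSP-05")
  }))
  list(db = db, a = a, b = b)
}

test_that("two-group fit recovers the difference of group log-means", {
  fx <- two_group_db()
  m <- suppressWarnings(fit_exposure_model(
    fx$db, terms = "sector", controls = character(), duration = "none",
    min_cell = 3))
  expect_identical(m$reference_levels$sector, "alpha")
  expect_equal(m$coefficients$estimate[m$coefficients$term == "sector=beta"],
               mean(log(fx$b)) - mean(log(fx$a)), tolerance = 1e-12)
  expect_equal(m$coefficients$estimate[m$coefficients$term == "(Intercept)"],
               mean(log(fx$a)), tolerance = 1e-12)
})

test_that("fitted coefficients match a brute-force normal-equations solve", {
  db <- generate_database(compact_spec(n = 20, seed = 21))
  m <- suppressWarnings(fit_exposure_model(
    db, terms = "sector", controls = c("LEV", "wetting"),
    duration = "log", min_cell = 1))
  # independent oracle: solve X'X b = X'y directly
  X <- cbind(1,
             log(db$duration),
             as.numeric(db$sector == "industrial"),
             as.numeric(db$sector == "residential"),
             vapply(parse_controls(db$controls), function(s)
               as.numeric("LEV" %in% s), numeric(1)),
             vapply(parse_controls(db$controls), function(s)
               as.numeric("wetting" %in% s), numeric(1)))
  y <- log(db$concentration)
  b <- solve(crossprod(X), crossprod(X, y))
  got <- m$coefficients$estimate[match(
    c("(Intercept)", "log_duration", "sector=industrial",
      "sector=residential", "ctrl_LEV", "ctrl_wetting"),
    m$coefficients$term)]
  expect_equal(got, as.vector(b), tolerance = 1e-8)
  # oracle SEs: sigma^2 (X'X)^-1
  resid <- y - X %*% b
  s2 <- sum(resid^2) / (nrow(X) - ncol(X))
  se <- sqrt(diag(s2 * solve(crossprod(X))))
  got_se <- m$coefficients$se[match(
    c("(Intercept)", "log_duration", "sector=industrial",
      "sector=residential", "ctrl_LEV", "ctrl_wetting"),
    m$coefficients$term)]
  expect_equal(got_se, unname(se), tolerance = 1e-8)
  expect_equal(m$residual_log_sd, sqrt(s2), tolerance = 1e-8)
})

test_that("rescaling concentrations shifts only the intercept by ln(k)", {
  db <- generate_database(compact_spec(n = 300, seed = 22))
  m1 <- fit_compact(db)
  db2 <- db
  db2$concentration <- db2$concentration * 1000
  m2 <- fit_compact(db2)
  i1 <- m1$coefficients$term == "(Intercept)"
  expect_equal(m2$coefficients$estimate[i1] - m1$coefficients$estimate[i1],
               log(1000), tolerance = 1e-10)
  expect_equal(m2$coefficients$estimate[!i1], m1$coefficients$estimate[!i1],
               tolerance = 1e-10)
  expect_equal(m2$residual_log_sd, m1$residual_log_sd, tolerance = 1e-10)
})

test_that("row order does not affect the fit", {
  db <- generate_database(compact_spec(n = 300, seed = 23))
  m1 <- fit_compact(db)
  m2 <- fit_compact(db[sample(nrow(db)), ])
  expect_equal(m1$coefficients$estimate, m2$coefficients$estimate,
               tolerance = 1e-10)
  expect_equal(m1$coefficients$se, m2$coefficients$se, tolerance = 1e-10)
})

test_that("null data produce estimates within 3 SE almost always", {
  null_beta <- c("(Intercept)" = log(0.05))
  hits <- misses <- 0
  for (s in 1:20) {
    spec <- true_model_spec(
      n = 500, coefficients = null_beta, variables = compact_vars(),
      control_prevalence = c(LEV = 0.2, wetting = 0.3),
      residual_log_sd = 0.8, nondetect_fraction = 0, seed = 400 + s)
    m <- fit_compact(generate_database(spec))
    cf <- m$coefficients[m$coefficients$term != "(Intercept)", ]
    ok <- abs(cf$estimate) < 3 * cf$se
    hits <- hits + sum(ok); misses <- misses + sum(!ok)
  }
  expect_gte(hits / (hits + misses), 0.95)
})

test_that("sparse categorical levels raise a named error", {
  db <- generate_database(compact_spec(n = 200, seed = 24))
  db$sector[1] <- "offshore" # a single-observation level
  expect_error(fit_compact(db, min_cell = 5), "sector")
})

test_that("rank-deficient designs report the aliased terms", {
  db <- generate_database(compact_spec(n = 200, seed = 25))
  # make LEV and wetting perfectly collinear
  ctl <- parse_controls(db$controls)
  db$controls <- format_controls(lapply(ctl, function(s) {
    if ("LEV" %in% s) unique(c(s, "wetting")) else setdiff(s, "wetting")
  }))
  db$environment <- db$sector # duplicate a variable entirely
  expect_error(
    suppressWarnings(fit_exposure_model(
      db, terms = c("sector", "environment"), controls = c("LEV", "wetting"))),
    class = "silicarisk_rank_deficient")
})

test_that("scenario encoding is one-hot with reference levels at zero", {
  db <- generate_database(compact_spec(n = 300, seed = 26))
  m <- fit_compact(db)
  refs <- m$reference_levels
  base <- scenario(refs$csp_id, refs$sector, "new", refs$environment,
                   "british_columbia", sampling_duration = 100)
  v <- encode_scenario(base, m)
  expect_equal(unname(v["(Intercept)"]), 1)
  expect_equal(unname(v["log_duration"]), log(100))
  expect_equal(sum(v != 0), 2) # intercept and duration only

  one <- base; one$sector <- "industrial"
  v2 <- encode_scenario(one, m)
  expect_equal(unname(v2["sector=industrial"]), 1)
  expect_equal(sum(v2 != 0), 3)

  with_ctrl <- base; with_ctrl$controls <- c("LEV", "separation")
  v3 <- encode_scenario(with_ctrl, m)
  expect_equal(unname(v3["ctrl_LEV"]), 1)
  expect_equal(unname(v3["ctrl_wetting"]), 0)

  unseen <- base; unseen$csp_id <- "CSP-99"
  expect_error(encode_scenario(unseen, m), "csp_id",
               class = "silicarisk_unknown_level")
})

test_that("model JSON round-trips losslessly and checks its schema", {
  db <- generate_database(compact_spec(n = 300, seed = 27))
  m <- fit_compact(db, db_version = "db-2026-03")
  path <- withr::local_tempfile(fileext = ".json")
  serialize_model(m, path)
  back <- deserialize_model(path)
  expect_identical(back$coefficients$estimate, m$coefficients$estimate)
  expect_identical(back$coefficients$se, m$coefficients$se)
  expect_identical(back$residual_log_sd, m$residual_log_sd)
  expect_identical(back$reference_levels, m$reference_levels)
  expect_identical(back$db_version, "db-2026-03")
  expect_identical(back$term_catalog, m$term_catalog)

  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$residual_log_sd <- NULL
  tampered <- jsonlite::toJSON(doc, auto_unbox = TRUE)
  expect_error(deserialize_model(tampered), "residual_log_sd",
               class = "silicarisk_schema")

  doc2 <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc2$schema_version <- "9.9"
  expect_error(deserialize_model(jsonlite::toJSON(doc2, auto_unbox = TRUE)),
               class = "silicarisk_schema")
})

test_that("separation cannot be requested as a fitted term", {
  db <- generate_database(compact_spec(n = 100, seed = 28))
  expect_error(
    fit_exposure_model(db, terms = "sector",
                       controls = c("LEV", "separation")),
    "separation", class = "silicarisk_invalid_input")
})
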