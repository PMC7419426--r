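test_that("polymorph consolidation sums masses over air volume", {
  expect_equal(consolidate_polymorphs(0.010, 0.005, 0.5), 0.030)
  expect_equal(consolidate_polymorphs(0.010, NA, 1.0), 0.010)
  expect_equal(consolidate_polymorphs(0, 0, 2.0), 0.0)
  expect_error(consolidate_polymorphs(0.01, 0.005, 0),
               class = "silicarisk_invalid_input")
  expect_error(consolidate_polymorphs(-0.01, 0.005, 1),
               class = "silicarisk_invalid_input")
})

test_that("consolidation is symmetric in masses and scales as 1/volume", {
  set.seed(101)
  for (i in 1:25) {
    q <- runif(1, 0, 0.1); c <- runif(1, 0, 0.1)
    v <- runif(1, 0.1, 2); k <- runif(1, 0.5, 5)
    expect_equal(consolidate_polymorphs(q, c, v),
                 consolidate_polymorphs(c, q, v))
    expect_equal(consolidate_polymorphs(q, c, k * v),
                 consolidate_polymorphs(q, c, v) / k)
  }
})

test_that("non-detects are substituted with half the LOD, idempotently", {
  nd <- new_measurement(concentration = 0.02, nondetect_flag = TRUE, lod = 0.10)
  det <- new_measurement(concentration = 0.20)
  db <- rbind(nd, det)
  sub1 <- substitute_nondetect(db)
  expect_equal(sub1$concentration, c(0.05, 0.20))
  expect_identical(substitute_nondetect(sub1), sub1)

  bad <- new_measurement(concentration = 0.02, nondetect_flag = TRUE, lod = 0)
  expect_error(substitute_nondetect(bad), class = "silicarisk_invalid_input")
})

test_that("a fully conforming record passes all six QC criteria", {
  rec <- new_measurement(concentration = 0.05, method = "NIOSH 7602")
  res <- validate_record(rec)
  expect_true(res$passed)
  expect_length(res$failures, 0)
})

test_that("each QC criterion is detected independently and all are reported", {
  rec <- new_measurement(concentration = 0.05)
  area <- rec; area$sample_type <- "area"
  res <- validate_record(area)
  expect_false(res$passed)
  expect_identical(names(res$failures), "vi_personal")

  noflow <- rec; noflow$flow_rate <- NA_real_
  expect_identical(names(validate_record(noflow)$failures), "iii_params")

  multi <- rec
  multi$analyte <- "respirable_dust"
  multi$method <- "gravimetric only"
  multi$qaqc_confirmed <- FALSE
  multi$context_complete <- FALSE
  multi$sample_type <- "area"
  multi$flow_rate <- NA_real_
  res <- validate_record(multi)
  expect_setequal(names(res$failures), qc_criteria())
  expect_true(all(names(res$failures) %in% qc_criteria()))
})

test_that("the allowed-methods list is configurable", {
  rec <- new_measurement(concentration = 0.05, method = "MDHS 101/2")
  expect_false(validate_record(rec)$passed)
  expect_true(validate_record(rec, allowed_methods = "MDHS 101/2")$passed)
})

test_that("filter_database keeps exactly the passing records, idempotently", {
  fx <- generate_qc_fixtures(seed = 3)
  res <- filter_database(fx)
  expect_length(res$report, nrow(fx))
  expect_equal(nrow(res$passing), sum(is.na(fx$planted_failure)))
  # planted single-failure rows were rejected for exactly their criterion
  planted <- which(!is.na(fx$planted_failure))
  for (i in planted) {
    expect_identical(names(res$report[[i]]$failures), fx$planted_failure[i])
  }
  again <- filter_database(res$passing)
  expect_equal(again$passing, res$passing)

  empty <- filter_database(res$passing[0, ])
  expect_equal(nrow(empty$passing), 0)
  expect_length(empty$report, 0)
})

test_that("QC reports serialize to JSON with criterion identifiers", {
  fx <- generate_qc_fixtures(seed = 3)
  res <- filter_database(fx)
  path <- withr::local_tempfile(fileext = ".json")
  write_qc_report(res$report, path)
  parsed <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_length(parsed, nrow(fx))
  crits <- unlist(lapply(parsed, function(r) {
    vapply(r$failures, `[[`, character(1), "criterion")
  }))
  expect_setequal(unique(crits), qc_criteria())
})

test_that("the CSP registry has unique task/material/tool triples", {
  reg <- csp_registry()
  expect_true(nrow(reg) >= 24)
  expect_false(anyDuplicated(paste(reg$material, reg$task, reg$tool)) > 0)
  expect_false(anyDuplicated(reg$csp_id) > 0)
})

test_that("measurement CSV round-trips and converts microgram units", {
  db <- generate_database(compact_spec(n = 20, seed = 4,
                                       nondetect_fraction = 0.2))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(db, path)
  back <- read_measurements(path)
  expect_equal(back$concentration, db$concentration)
  expect_equal(back$controls, db$controls)
  expect_equal(back$nondetect_flag, db$nondetect_flag)

  raw <- utils::read.csv(path)
  raw$concentration_units <- "ug/m3"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, path2, row.names = FALSE, na = "")
  micro <- read_measurements(path2)
  expect_equal(micro$concentration, db$concentration / 1000)

  raw$concentration_units <- "ppm"
  utils::write.csv(raw, path2, row.names = FALSE, na = "")
  expect_error(read_measurements(path2), class = "silicarisk_schema")
})
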