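# Shared fixtures: compact ground-truth specs and hand-built toy models.

intercept_model <- function(mu, s, residual_log_sd = 0, db_version = "toy") {
  exposure_model(
    tibble::tibble(term = "(Intercept)", estimate = mu, se = s),
    residual_log_sd = residual_log_sd, db_version = db_version
  )
}

toy_scenario <- function(controls = character(), task_duration_hours = 8,
                         sampling_duration = 240) {
  scenario("CSP-05", "civil", "new", "outdoor", "british_columbia",
           sampling_duration = sampling_duration,
           task_duration_hours = task_duration_hours, controls = controls)
}

compact_vars <- function() {
  list(
    csp_id = stats::setNames(rep(1 / 6, 6), sprintf("CSP-%02d", 1:6)),
    sector = c(civil = 0.4, industrial = 0.3, residential = 0.3),
    environment = c(indoor = 0.5, outdoor = 0.5)
  )
}

compact_beta <- function() {
  c("(Intercept)" = log(0.05), "log_duration" = -0.15,
    stats::setNames(seq(-0.8, 1.2, length.out = 5),
                    sprintf("csp_id=CSP-%02d", 2:6)),
    "sector=industrial" = 0.3, "sector=residential" = 0.1,
    "environment=outdoor" = -0.4,
    "ctrl_LEV" = -0.7, "ctrl_wetting" = -0.5)
}

compact_spec <- function(n, seed, nondetect_fraction = 0,
                         residual_log_sd = 0.8) {
  true_model_spec(
    n = n, coefficients = compact_beta(), variables = compact_vars(),
    control_prevalence = c(LEV = 0.2, wetting = 0.3),
    residual_log_sd = residual_log_sd,
    nondetect_fraction = nondetect_fraction, seed = seed
  )
}

fit_compact <- function(db, ...) {
  suppressWarnings(fit_exposure_model(
    db, terms = c("csp_id", "sector", "environment"),
    controls = c("LEV", "wetting"), ...
  ))
}
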