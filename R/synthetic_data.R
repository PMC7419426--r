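# Synthetic exposure databases with known ground truth, so model fitting,
# prediction and the validation routine are testable without external data.

#' Default categorical level frequencies for generated databases
#'
#' Mirrors the structure of a construction RCS exposure database: the 25
#' bundled common silica processes (uniform), three sectors, three project
#' types, four work environments and two regions.
#'
#' @return Named list: variable -> named probability vector over levels.
#' @export
default_level_frequencies <- function() {
  csp <- csp_registry()$csp_id
  list(
    csp_id = stats::setNames(rep(1 / length(csp), length(csp)), csp),
    sector = c(civil = 1 / 3, industrial = 1 / 3, residential = 1 / 3),
    project_type = c(demolition = 1 / 3, new = 1 / 3, renovation = 1 / 3),
    environment = c(confined_space = 0.05, indoor = 0.40, outdoor = 0.50,
                    restricted_space = 0.05),
    region = c(alberta = 0.2, british_columbia = 0.8)
  )
}

#' Default true coefficients for generated databases
#'
#' Log-scale effects emulating a multiplicative exposure process: intercept
#' `ln(0.05)` mg/m^3, CSP effects spread over roughly a 12-fold range,
#' modest sector/project/environment/region effects, a mild negative
#' log-duration slope (longer samples average lower), and negative
#' engineering-control effects of 0.5-1.1 on the log scale (about 40-67%
#' exposure reduction).
#'
#' @return Named numeric vector over canonical term names
#'   (`"(Intercept)"`, `"log_duration"`, `"var=level"`, `"ctrl_<id>"`).
#' @export
default_true_coefficients <- function() {
  csp <- sort(csp_registry()$csp_id)
  csp_eff <- stats::setNames(
    round(seq(-1, 1.5, length.out = length(csp) - 1), 3),
    paste0("csp_id=", csp[-1]))
  c(
    "(Intercept)" = log(0.05),
    "log_duration" = -0.15,
    csp_eff,
    "sector=industrial" = 0.30, "sector=residential" = 0.10,
    "project_type=new" = -0.30, "project_type=renovation" = 0.20,
    "environment=indoor" = 0.50, "environment=outdoor" = -0.40,
    "environment=restricted_space" = 0.20,
    "region=british_columbia" = -0.10,
    "ctrl_LEV" = -0.70, "ctrl_LEV_integrated" = -1.10,
    "ctrl_wetting" = -0.50, "ctrl_waterspray_integrated" = -0.90
  )
}

#' Specify a ground-truth exposure-generating process
#'
#' The generator draws covariates from `variables`, control indicators from
#' `control_prevalence`, sampling durations uniformly from
#' `duration_range_min`, and concentrations from
#' `exp(X beta + Normal(0, residual_log_sd))`. Values below the limit of
#' detection are flagged as non-detects (half-LOD substitution is left to
#' [substitute_nondetect()]). When `nondetect_lod` is not given, the LOD is
#' set at the empirical `nondetect_fraction` quantile of the generated
#' concentrations (default 15% non-detects, typical of curated RCS data).
#'
#' @param n Number of measurements (>= 1).
#' @param coefficients Named true coefficients (log scale); see
#'   [default_true_coefficients()] for the naming convention.
#' @param variables Named list of level-frequency vectors (must each sum
#'   to 1); see [default_level_frequencies()].
#' @param control_prevalence Named prevalence per fitted control id.
#' @param residual_log_sd Residual log-SD (>= 0); default 0.8 (GSD ~ 2.2).
#' @param duration_range_min Uniform sampling-duration range, minutes.
#' @param nondetect_fraction Target non-detect share in (0, 1), or 0.
#' @param nondetect_lod Fixed LOD (mg/m^3) overriding `nondetect_fraction`.
#' @param seed Integer seed.
#' @return A `true_model_spec` object.
#' @export
true_model_spec <- function(n = 1000,
                            coefficients = default_true_coefficients(),
                            variables = default_level_frequencies(),
                            control_prevalence = c(
                              LEV = 0.15, LEV_integrated = 0.15,
                              wetting = 0.25, waterspray_integrated = 0.15),
                            residual_log_sd = 0.8,
                            duration_range_min = c(60, 480),
                            nondetect_fraction = 0.15,
                            nondetect_lod = NULL,
                            seed = 1L) {
  if (!is_number(n) || n < 1) sr_stop("`n` must be >= 1")
  if (length(coefficients) == 0L || is.null(names(coefficients))) {
    sr_stop("`coefficients` must be a non-empty named vector")
  }
  if (!is_number(residual_log_sd) || residual_log_sd < 0) {
    sr_stop("`residual_log_sd` must be >= 0")
  }
  for (var in names(variables)) {
    pr <- variables[[var]]
    if (is.null(names(pr)) || abs(sum(pr) - 1) > 1e-8 || any(pr < 0)) {
      sr_stop(sprintf("level frequencies for '%s' must be named and sum to 1",
                      var))
    }
  }
  known <- c("(Intercept)", "log_duration", "duration_min",
             unlist(lapply(names(variables), function(v) {
               paste0(v, "=", names(variables[[v]]))
             })),
             paste0("ctrl_", names(control_prevalence)))
  unknown <- setdiff(names(coefficients), known)
  if (length(unknown)) {
    sr_stop(sprintf("coefficient(s) reference unknown terms: %s",
                    paste(unknown, collapse = ", ")))
  }
  structure(list(
    n = as.integer(n), coefficients = coefficients, variables = variables,
    control_prevalence = control_prevalence,
    residual_log_sd = residual_log_sd,
    duration_range_min = duration_range_min,
    nondetect_fraction = nondetect_fraction,
    nondetect_lod = nondetect_lod, seed = as.integer(seed)
  ), class = "true_model_spec")
}

#' Generate a synthetic exposure database from a known truth
#'
#' @param spec A [true_model_spec()].
#' @return Measurement tibble (canonical schema) with `source = "synthetic"`
#'   and QC-passing metadata. Non-detect rows keep their true generated
#'   concentration alongside the flag and LOD; apply
#'   [substitute_nondetect()] before modelling.
#' @export
generate_database <- function(spec) {
  stopifnot(inherits(spec, "true_model_spec"))
  n <- spec$n
  beta <- spec$coefficients
  with_seed(spec$seed, {
    covs <- lapply(spec$variables, function(pr) {
      sample(names(pr), n, replace = TRUE, prob = pr)
    })
    ctrl_ind <- lapply(spec$control_prevalence, function(p) {
      stats::rbinom(n, 1, p)
    })
    duration <- stats::runif(n, spec$duration_range_min[1],
                             spec$duration_range_min[2])

    lp <- rep(unname(beta["(Intercept)"]) %|NA|% 0, n)
    if (!is.na(beta["log_duration"])) {
      lp <- lp + beta[["log_duration"]] * log(duration)
    }
    if (!is.na(beta["duration_min"])) {
      lp <- lp + beta[["duration_min"]] * duration
    }
    for (var in names(covs)) {
      eff <- beta[paste0(var, "=", covs[[var]])]
      eff[is.na(eff)] <- 0 # reference / unlisted levels
      lp <- lp + unname(eff)
    }
    for (ct in names(ctrl_ind)) {
      b <- beta[paste0("ctrl_", ct)]
      if (!is.na(b)) lp <- lp + unname(b) * ctrl_ind[[ct]]
    }
    conc <- exp(lp + stats::rnorm(n, 0, spec$residual_log_sd))

    lod <- spec$nondetect_lod
    if (is.null(lod) && spec$nondetect_fraction > 0) {
      lod <- stats::quantile(conc, spec$nondetect_fraction, names = FALSE)
    }
    nd <- if (is.null(lod)) rep(FALSE, n) else conc < lod

    controls <- format_controls(lapply(seq_len(n), function(i) {
      names(ctrl_ind)[vapply(ctrl_ind, function(z) z[i] == 1, logical(1))]
    }))
    methods <- sample(default_allowed_methods(), n, replace = TRUE)

    tibble::tibble(
      sample_id = sprintf("SYN-%06d", seq_len(n)),
      concentration = conc,
      nondetect_flag = nd,
      lod = if (is.null(lod)) NA_real_ else ifelse(nd, lod, NA_real_),
      quartz_mass = NA_real_, cristobalite_mass = NA_real_,
      air_volume = NA_real_,
      analyte = "RCS", method = methods,
      flow_rate = 2.5, duration = duration, sample_type = "personal",
      qaqc_confirmed = TRUE, context_complete = TRUE,
      csp_id = covs$csp_id %||% NA_character_,
      sector = covs$sector %||% NA_character_,
      project_type = covs$project_type %||% NA_character_,
      environment = covs$environment %||% NA_character_,
      region = covs$region %||% NA_character_,
      controls = controls,
      source = "synthetic", weight = 1
    )
  })
}

`%|NA|%` <- function(a, b) if (length(a) == 0L || is.na(a)) b else a

#' Derive a generating spec from a fitted model
#'
#' Builds a [true_model_spec()] whose true coefficients, residual log-SD,
#' duration term and categorical levels are taken from a fitted model, so
#' fresh data can be simulated from the model itself (e.g. for
#' self-consistency checks of [validate_against_measurements()]). Levels
#' are drawn uniformly within each variable unless `variables` overrides.
#'
#' @param model An [exposure_model()].
#' @param n,seed Generation size and seed.
#' @param variables Optional level-frequency override.
#' @param control_prevalence Prevalence per fitted control term.
#' @param nondetect_fraction Non-detect share; default 0 (no censoring).
#' @param duration_range_min Sampling-duration range, minutes.
#' @return A [true_model_spec()].
#' @export
spec_from_model <- function(model, n, seed = 1L, variables = NULL,
                            control_prevalence = NULL,
                            nondetect_fraction = 0,
                            duration_range_min = c(60, 480)) {
  stopifnot(inherits(model, "exposure_model"))
  if (is.null(variables)) {
    variables <- lapply(model$variables, function(levs) {
      stats::setNames(rep(1 / length(levs), length(levs)), levs)
    })
  }
  if (is.null(control_prevalence)) {
    control_prevalence <- stats::setNames(
      rep(0.2, length(model$control_terms)), model$control_terms)
  }
  true_model_spec(
    n = n,
    coefficients = stats::setNames(model$coefficients$estimate,
                                   model$coefficients$term),
    variables = variables,
    control_prevalence = control_prevalence,
    residual_log_sd = model$residual_log_sd,
    duration_range_min = duration_range_min,
    nondetect_fraction = nondetect_fraction,
    seed = seed
  )
}

#' Fixture records with planted QC failures
#'
#' Returns a labelled measurement set for exercising the QC filter: in the
#' default `"mixed"` variant, six records each fail exactly one of the six
#' criteria and four records pass; the `planted_failure` column (`NA` for
#' passing rows) makes expected counts exact.
#'
#' @param seed Integer seed for the concentrations.
#' @param variant `"mixed"` (default), `"all_pass"`, or `"all_fail"`.
#' @return Measurement tibble with an extra `planted_failure` column.
#' @export
generate_qc_fixtures <- function(seed = 1L, variant = c("mixed", "all_pass",
                                                        "all_fail")) {
  variant <- match.arg(variant)
  base <- function(conc, ...) {
    new_measurement(concentration = conc, csp_id = "CSP-05", sector = "civil",
                    project_type = "new", environment = "outdoor",
                    region = "british_columbia", source = "campaign", ...)
  }
  conc <- with_seed(seed, exp(stats::rnorm(10, log(0.05), 0.8)))
  fails <- list(
    i_analyte = base(conc[1], analyte = "respirable_dust"),
    ii_method = base(conc[2], method = "direct-reading photometer"),
    iii_params = base(conc[3], flow_rate = NA_real_),
    iv_qaqc = base(conc[4], qaqc_confirmed = FALSE),
    v_context = base(conc[5], context_complete = FALSE),
    vi_personal = base(conc[6], sample_type = "area")
  )
  passes <- lapply(conc[7:10], base)
  rows <- switch(variant,
    mixed = c(fails, passes),
    all_pass = passes,
    all_fail = fails
  )
  out <- do.call(rbind, rows)
  out$planted_failure <- switch(variant,
    mixed = c(names(fails), rep(NA_character_, length(passes))),
    all_pass = rep(NA_character_, length(passes)),
    all_fail = names(fails)
  )
  out
}
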