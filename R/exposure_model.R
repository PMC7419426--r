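# Multiplicative (log-linear) determinants-of-exposure model: scenario
# description, design encoding, OLS fit on log concentration, and a
# lossless JSON serialization used to version the deployed model.

MODEL_SCHEMA_VERSION <- "1.0"

#' Engineering-control identifiers
#'
#' The five controls the model recognises. The first four enter the
#' regression as indicator terms; `separation` (e.g. an enclosed cab) is
#' applied post hoc as a fixed reduction factor (see
#' [apply_separation_factor()]) because measurement data are too sparse to
#' estimate it.
#'
#' @return Character vector of control identifiers.
#' @export
control_ids <- function() {
  c("LEV", "LEV_integrated", "wetting", "waterspray_integrated", "separation")
}

#' Describe a work-task scenario
#'
#' A scenario is a single common silica process (CSP) with its categorical
#' determinants, durations, and the set of proposed controls.
#'
#' @param csp_id CSP identifier (see [csp_registry()]).
#' @param sector Industry sector (e.g. residential, industrial, civil).
#' @param project_type Project type (e.g. new, renovation, demolition).
#' @param environment Work environment (indoor, outdoor, restricted space,
#'   confined space).
#' @param region Geographic region.
#' @param sampling_duration Sampling duration entering the model, minutes.
#' @param task_duration_hours Expected task duration, hours; tasks under
#'   4 h receive a 50% discount on the final estimates.
#' @param controls Character vector, subset of [control_ids()].
#' @return A `silica_scenario` object.
#' @export
scenario <- function(csp_id, sector, project_type, environment, region,
                     sampling_duration = 240, task_duration_hours = 8,
                     controls = character()) {
  if (!is_number(sampling_duration) || sampling_duration <= 0) {
    sr_stop("`sampling_duration` must be positive (minutes)")
  }
  if (!is_number(task_duration_hours) || task_duration_hours <= 0) {
    sr_stop("`task_duration_hours` must be positive (hours)")
  }
  controls <- unique(as.character(controls))
  bad <- setdiff(controls, control_ids())
  if (length(bad)) {
    sr_stop(sprintf("unknown control identifier(s): %s (known: %s)",
                    paste(bad, collapse = ", "),
                    paste(control_ids(), collapse = ", ")))
  }
  structure(list(
    csp_id = as.character(csp_id), sector = as.character(sector),
    project_type = as.character(project_type),
    environment = as.character(environment), region = as.character(region),
    sampling_duration = as.numeric(sampling_duration),
    task_duration_hours = as.numeric(task_duration_hours),
    controls = controls
  ), class = "silica_scenario")
}

#' Construct an exposure model object from components
#'
#' Normally models come from [fit_exposure_model()]; this constructor
#' builds one directly (e.g. toy models in examples and tests, or a model
#' recovered from an external fit).
#'
#' @param coefficients Tibble/data frame with columns `term`, `estimate`
#'   (log mg/m^3 scale) and `se` (>= 0).
#' @param reference_levels Named list, one reference level per categorical
#'   variable (absent from `coefficients`).
#' @param variables Named list of all levels (reference first) per
#'   categorical variable.
#' @param control_terms Control identifiers fitted as indicator terms.
#' @param duration_term `"log"`, `"linear"` or `"none"`.
#' @param residual_log_sd Residual standard deviation on the log scale.
#' @param db_version Exposure-database version stamp carried into every
#'   estimate and ECP generated from this model.
#' @param fit_n Number of measurements the model was fitted on.
#' @return An `exposure_model` object.
#' @export
exposure_model <- function(coefficients, reference_levels = list(),
                           variables = list(), control_terms = character(),
                           duration_term = "none", residual_log_sd = 0,
                           db_version = "unversioned", fit_n = NA_integer_) {
  coefficients <- tibble::as_tibble(coefficients)
  if (!all(c("term", "estimate", "se") %in% names(coefficients))) {
    sr_stop("`coefficients` needs columns term, estimate, se", class = "schema")
  }
  if (any(coefficients$se < 0)) sr_stop("standard errors must be >= 0")
  if (!is_number(residual_log_sd) || residual_log_sd < 0) {
    sr_stop("`residual_log_sd` must be a non-negative number")
  }
  for (var in names(variables)) {
    ref <- reference_levels[[var]]
    if (is.null(ref) || !(ref %in% variables[[var]])) {
      sr_stop(sprintf("variable '%s' needs a reference level among its levels",
                      var), class = "schema")
    }
    if (paste0(var, "=", ref) %in% coefficients$term) {
      sr_stop(sprintf("reference level of '%s' must not carry a coefficient",
                      var), class = "schema")
    }
  }
  structure(list(
    schema_version = MODEL_SCHEMA_VERSION,
    db_version = as.character(db_version),
    coefficients = coefficients[, c("term", "estimate", "se")],
    reference_levels = reference_levels,
    variables = variables,
    control_terms = as.character(control_terms),
    duration_term = duration_term,
    residual_log_sd = as.numeric(residual_log_sd),
    fit_n = as.integer(fit_n),
    term_catalog = coefficients$term
  ), class = "exposure_model")
}

duration_column <- function(duration_term) {
  switch(duration_term, log = "log_duration", linear = "duration_min",
         none = NULL,
         sr_stop("`duration` must be one of log, linear, none"))
}

# Build the design matrix with canonical column names:
# "var=level" indicators (reference = alphabetically first level omitted),
# "ctrl_<id>" control indicators, and the duration column.
build_design <- function(records, terms, controls, duration_term,
                         variables = NULL, reference_levels = NULL) {
  n <- nrow(records)
  cols <- list()
  if (!is.null(dc <- duration_column(duration_term))) {
    if (any(is.na(records$duration) | records$duration <= 0)) {
      sr_stop("all records need a positive `duration` for the duration term")
    }
    cols[[dc]] <- if (duration_term == "log") log(records$duration)
                  else records$duration
  }
  for (var in terms) {
    x <- as.character(records[[var]])
    if (any(is.na(x))) {
      sr_stop(sprintf("variable '%s' has missing values", var))
    }
    levs <- if (is.null(variables)) sort(unique(x)) else variables[[var]]
    ref <- if (is.null(reference_levels)) levs[1] else reference_levels[[var]]
    for (lev in setdiff(levs, ref)) {
      cols[[paste0(var, "=", lev)]] <- as.numeric(x == lev)
    }
  }
  ctl <- parse_controls(records$controls)
  for (ct in controls) {
    cols[[paste0("ctrl_", ct)]] <-
      vapply(ctl, function(s) as.numeric(ct %in% s), numeric(1))
  }
  if (length(cols) == 0L) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

#' Fit the log-linear exposure model
#'
#' Ordinary least squares of `log(concentration)` on categorical determinant
#' indicators, engineering-control indicators and a duration term. Reference
#' levels are the alphabetically first level of each variable (configurable
#' via `reference_levels`). The fit is deterministic and invariant to row
#' order. Records should have passed QC and had non-detects substituted
#' (see [filter_database()], [substitute_nondetect()]).
#'
#' @param records Measurement tibble with positive concentrations.
#' @param terms Categorical determinant columns to include.
#' @param controls Control identifiers fitted as indicators; `separation` is
#'   not fittable (applied post hoc) and is rejected here.
#' @param duration `"log"` (default: log minutes), `"linear"`, or `"none"`.
#' @param db_version Database version stamp recorded in the model.
#' @param min_cell Minimum observations per categorical level (error below
#'   this, warning below 10).
#' @param reference_levels Optional named list overriding the default
#'   (alphabetically first) reference level per variable.
#' @param weights Use the records' `weight` column? Default `FALSE`
#'   (equal weight; de-aggregated pseudo-observations count like real ones).
#' @return An [exposure_model()] object.
#' @export
fit_exposure_model <- function(records,
                               terms = c("csp_id", "sector", "project_type",
                                         "environment", "region"),
                               controls = setdiff(control_ids(), "separation"),
                               duration = c("log", "linear", "none"),
                               db_version = "unversioned",
                               min_cell = 5,
                               reference_levels = NULL,
                               weights = FALSE) {
  duration <- match.arg(duration)
  records <- as_measurement_db(records)
  if ("separation" %in% controls) {
    sr_stop("`separation` cannot be fitted from data; it is applied post hoc")
  }
  if (any(is.na(records$concentration) | records$concentration <= 0)) {
    sr_stop(paste("all concentrations must be positive;",
                  "substitute non-detects with half the LOD first"))
  }

  variables <- list()
  refs <- list()
  kept_terms <- character()
  for (var in terms) {
    x <- as.character(records[[var]])
    if (any(is.na(x))) sr_stop(sprintf("variable '%s' has missing values", var))
    tab <- table(x)
    if (any(tab < min_cell)) {
      sr_stop(sprintf(
        "insufficient data for variable '%s': level(s) %s below %d observations",
        var, paste(names(tab)[tab < min_cell], collapse = ", "), min_cell))
    }
    if (any(tab < 10)) {
      sr_warn(sprintf("variable '%s' has level(s) with fewer than 10 observations: %s",
                      var, paste(names(tab)[tab < 10], collapse = ", ")))
    }
    levs <- sort(names(tab))
    ref <- reference_levels[[var]] %||% levs[1]
    if (!(ref %in% levs)) {
      sr_stop(sprintf("reference level '%s' not observed for '%s'", ref, var))
    }
    variables[[var]] <- c(ref, setdiff(levs, ref))
    refs[[var]] <- ref
    kept_terms <- c(kept_terms, var)
  }

  ctl <- parse_controls(records$controls)
  kept_controls <- character()
  for (ct in controls) {
    ind <- vapply(ctl, function(s) ct %in% s, logical(1))
    if (!any(ind) || all(ind)) {
      sr_warn(sprintf(
        "control '%s' is constant in the data and was dropped from the model", ct))
    } else {
      kept_controls <- c(kept_controls, ct)
    }
  }

  X <- build_design(records, kept_terms, kept_controls, duration,
                    variables, refs)
  y <- log(records$concentration)
  w <- if (isTRUE(weights)) records$weight else NULL

  fit <- if (ncol(X) > 0) stats::lm(y ~ X, weights = w)
         else stats::lm(y ~ 1, weights = w)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    aliased <- sub("^X", "", names(cf)[is.na(cf)])
    sr_stop(sprintf("rank-deficient design; aliased term(s): %s",
                    paste(aliased, collapse = ", ")), class = "rank_deficient")
  }
  sm <- summary(fit)
  est <- cf
  se <- sm$coefficients[, "Std. Error"]
  # lm() saw the design as a single matrix; restore the canonical names
  # (column order is preserved, aliasing was ruled out above)
  term_names <- c("(Intercept)", colnames(X))

  coefficients <- tibble::tibble(term = term_names,
                                 estimate = unname(est), se = unname(se))
  if (nrow(records) <= nrow(coefficients)) {
    sr_stop("more model terms than observations")
  }
  exposure_model(coefficients,
                 reference_levels = refs, variables = variables,
                 control_terms = kept_controls, duration_term = duration,
                 residual_log_sd = sm$sigma, db_version = db_version,
                 fit_n = nrow(records))
}

#' Encode a scenario against a model's term catalog
#'
#' Produces the design vector (intercept, duration term, one-hot categorical
#' indicators, fitted-control indicators) in the model's term order.
#' Reference levels contribute zero. An unseen category level raises an
#' explicit error naming the variable — never a silent coercion to the
#' reference.
#'
#' @param scen A [scenario()].
#' @param model An [exposure_model()].
#' @return Named numeric vector over the model's term catalog.
#' @export
encode_scenario <- function(scen, model) {
  stopifnot(inherits(scen, "silica_scenario"),
            inherits(model, "exposure_model"))
  v <- stats::setNames(numeric(length(model$term_catalog)), model$term_catalog)
  if ("(Intercept)" %in% names(v)) v["(Intercept)"] <- 1
  dc <- duration_column(model$duration_term)
  if (!is.null(dc)) {
    v[dc] <- if (model$duration_term == "log") log(scen$sampling_duration)
             else scen$sampling_duration
  }
  for (var in names(model$variables)) {
    val <- scen[[var]]
    if (is.null(val) || is.na(val) || !(val %in% model$variables[[var]])) {
      sr_stop(sprintf(
        "unknown level '%s' for variable '%s' (model knows: %s)",
        if (is.null(val) || is.na(val)) "missing" else val, var,
        paste(model$variables[[var]], collapse = ", ")),
        class = "unknown_level")
    }
    if (val != model$reference_levels[[var]]) {
      v[paste0(var, "=", val)] <- 1
    }
  }
  for (ct in model$control_terms) {
    if (ct %in% scen$controls) v[paste0("ctrl_", ct)] <- 1
  }
  v
}

#' Serialize and deserialize an exposure model
#'
#' The model document is JSON carrying the schema version, database version
#' stamp, term catalog, coefficient estimates and standard errors (written
#' at 17 significant digits so doubles round-trip exactly), reference
#' levels, and the residual log-SD.
#'
#' @param model An [exposure_model()].
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `serialize_model()`: `path` (invisibly) or a JSON string.
#' @export
serialize_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "exposure_model"))
  doc <- list(
    schema_version = model$schema_version,
    db_version = model$db_version,
    term_catalog = model$term_catalog,
    coefficients = lapply(seq_len(nrow(model$coefficients)), function(i) {
      list(term = model$coefficients$term[i],
           estimate = model$coefficients$estimate[i],
           se = model$coefficients$se[i])
    }),
    reference_levels = model$reference_levels,
    variables = model$variables,
    control_terms = model$control_terms,
    duration_term = model$duration_term,
    residual_log_sd = model$residual_log_sd,
    fit_n = model$fit_n
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           pretty = TRUE, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname serialize_model
#' @param document JSON string or path to a model JSON file.
#' @return `deserialize_model()`: the reconstructed [exposure_model()].
#' @export
deserialize_model <- function(document) {
  doc <- jsonlite::fromJSON(document, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE)
  required <- c("schema_version", "db_version", "coefficients",
                "reference_levels", "variables", "control_terms",
                "duration_term", "residual_log_sd")
  missing <- setdiff(required, names(doc))
  if (length(missing)) {
    sr_stop(sprintf("model document is missing field(s): %s",
                    paste(missing, collapse = ", ")), class = "schema")
  }
  if (!identical(doc$schema_version, MODEL_SCHEMA_VERSION)) {
    sr_stop(sprintf("incompatible model schema version '%s' (expected '%s')",
                    doc$schema_version, MODEL_SCHEMA_VERSION),
            class = "schema")
  }
  cf <- tibble::as_tibble(doc$coefficients)
  vars <- lapply(doc$variables, as.character)
  exposure_model(cf,
                 reference_levels = lapply(doc$reference_levels, as.character),
                 variables = vars,
                 control_terms = as.character(unlist(doc$control_terms)),
                 duration_term = doc$duration_term,
                 residual_log_sd = doc$residual_log_sd,
                 db_version = doc$db_version,
                 fit_n = doc$fit_n %||% NA_integer_)
}

#' @export
print.exposure_model <- function(x, ...) {
  cat(sprintf("<exposure_model> %d terms, fit_n = %s, db_version = %s\n",
              nrow(x$coefficients), x$fit_n, x$db_version))
  cat(sprintf("  residual log-SD = %.4f (GSD = %.2f)\n",
              x$residual_log_sd, exp(x$residual_log_sd)))
  invisible(x)
}
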