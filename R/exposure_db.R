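# Measurement database: schema, QC validation, polymorph consolidation,
# half-LOD substitution, and CSV/JSON input-output.

#' Canonical measurement schema
#'
#' Column names of the flat measurement table used throughout the package.
#' One row is one personal (or area) respirable crystalline silica (RCS)
#' sample together with its task covariates and QC metadata. Concentrations
#' are stored in mg/m^3; `controls` is a semicolon-separated set of control
#' identifiers (see [control_ids()]).
#'
#' @return Character vector of column names.
#' @export
measurement_columns <- function() {
  c(
    "sample_id", "concentration", "nondetect_flag", "lod",
    "quartz_mass", "cristobalite_mass", "air_volume",
    "analyte", "method", "flow_rate", "duration", "sample_type",
    "qaqc_confirmed", "context_complete",
    "csp_id", "sector", "project_type", "environment", "region",
    "controls", "source", "weight"
  )
}

#' Construct a single exposure measurement record
#'
#' Convenience constructor returning a one-row tibble in the canonical
#' schema (see [measurement_columns()]). Optional fields default to `NA`.
#'
#' @param concentration RCS concentration, mg/m^3 (non-negative).
#' @param nondetect_flag Was the sample below the limit of detection?
#' @param lod Limit of detection, mg/m^3 (required when `nondetect_flag`).
#' @param quartz_mass,cristobalite_mass Polymorph masses on the filter, mg.
#' @param air_volume Air volume sampled, m^3 (required with masses).
#' @param analyte One of `"RCS"`, `"quartz"`, `"cristobalite"`,
#'   `"respirable_dust"`, `"other"`.
#' @param method Analytical method label, e.g. `"NIOSH 7500"`.
#' @param flow_rate Sampling pump flow rate, L/min.
#' @param duration Sampling duration, minutes (> 0).
#' @param sample_type `"personal"` or `"area"`.
#' @param qaqc_confirmed Curator-asserted: original QA/QC adequate
#'   (calibration, field blanks, sample volume).
#' @param context_complete Curator-asserted: sufficient supplementary data
#'   to establish equivalence of operations.
#' @param csp_id Common silica process identifier (see [csp_registry()]).
#' @param sector,project_type,environment,region Categorical determinants.
#' @param controls Character vector of control identifiers in place
#'   (subset of [control_ids()]).
#' @param source Data provenance: `"literature"`, `"industry"`,
#'   `"government"`, `"campaign"`, `"deaggregated"` or `"synthetic"`.
#' @param weight Regression weight (default 1).
#' @param sample_id Optional identifier.
#' @return One-row tibble.
#' @export
new_measurement <- function(concentration,
                            nondetect_flag = FALSE,
                            lod = NA_real_,
                            quartz_mass = NA_real_,
                            cristobalite_mass = NA_real_,
                            air_volume = NA_real_,
                            analyte = "RCS",
                            method = "NIOSH 7500",
                            flow_rate = 2.5,
                            duration = 240,
                            sample_type = "personal",
                            qaqc_confirmed = TRUE,
                            context_complete = TRUE,
                            csp_id = NA_character_,
                            sector = NA_character_,
                            project_type = NA_character_,
                            environment = NA_character_,
                            region = NA_character_,
                            controls = character(),
                            source = "campaign",
                            weight = 1,
                            sample_id = NA_character_) {
  tibble::tibble(
    sample_id = as.character(sample_id),
    concentration = as.numeric(concentration),
    nondetect_flag = isTRUE(nondetect_flag),
    lod = as.numeric(lod),
    quartz_mass = as.numeric(quartz_mass),
    cristobalite_mass = as.numeric(cristobalite_mass),
    air_volume = as.numeric(air_volume),
    analyte = as.character(analyte),
    method = as.character(method),
    flow_rate = as.numeric(flow_rate),
    duration = as.numeric(duration),
    sample_type = as.character(sample_type),
    qaqc_confirmed = isTRUE(qaqc_confirmed),
    context_complete = isTRUE(context_complete),
    csp_id = as.character(csp_id),
    sector = as.character(sector),
    project_type = as.character(project_type),
    environment = as.character(environment),
    region = as.character(region),
    controls = format_controls(controls),
    source = as.character(source),
    weight = as.numeric(weight)
  )
}

#' @rdname new_measurement
#' @param records A data frame to coerce/complete to the canonical schema.
#' @export
as_measurement_db <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(measurement_columns(), names(records))
  for (col in missing) {
    records[[col]] <- switch(col,
      nondetect_flag = FALSE,
      qaqc_confirmed = FALSE,
      context_complete = FALSE,
      controls = "",
      source = NA_character_,
      weight = 1,
      analyte = , method = , sample_type = , sample_id = ,
      csp_id = , sector = , project_type = , environment = ,
      region = NA_character_,
      NA_real_
    )
  }
  records[, measurement_columns()]
}

#' Parse and format control-identifier sets
#'
#' Controls are stored in the flat table as a semicolon-separated string.
#'
#' @param x Character vector of encoded control sets.
#' @return `parse_controls()`: a list of character vectors;
#'   `format_controls()`: a character vector.
#' @export
parse_controls <- function(x) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(character())
    trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' @rdname parse_controls
#' @param controls Character vector (one set) or list of character vectors.
#' @export
format_controls <- function(controls) {
  if (!is.list(controls)) controls <- list(controls)
  vapply(controls, function(s) paste(s, collapse = ";"), character(1))
}

#' Standard analytical methods accepted at QC criterion (ii)
#'
#' Defaults to the standard RCS methods: NIOSH 7500 (including its 8 LPM
#' parallel-particle-impactor version), NIOSH 7602 and OSHA ID-142. The
#' list is configurable because other equivalent standard methods exist.
#'
#' @return Character vector of method labels.
#' @export
default_allowed_methods <- function() {
  c("NIOSH 7500", "NIOSH 7500-PPI-8LPM", "NIOSH 7602", "OSHA ID-142")
}

#' QC criterion identifiers
#'
#' The six validity criteria applied to each measurement: (i) the analyte is
#' respirable crystalline silica; (ii) a standard analytical method was
#' used; (iii) key sampling parameters (flow rate, duration) are reported;
#' (iv) original QA/QC was confirmed adequate; (v) sufficient supplementary
#' context to establish equivalence of operations; (vi) personal sampling.
#'
#' @return Character vector of the six criterion identifiers.
#' @export
qc_criteria <- function() {
  c("i_analyte", "ii_method", "iii_params", "iv_qaqc", "v_context",
    "vi_personal")
}

#' Consolidate quartz and cristobalite into an RCS concentration
#'
#' Polymorph filter masses are summed and divided by the total air volume
#' sampled; an absent mass is treated as zero.
#'
#' @param quartz_mass Quartz mass, mg (`NA` treated as 0).
#' @param cristobalite_mass Cristobalite mass, mg (`NA` treated as 0).
#' @param air_volume Air volume sampled, m^3 (> 0).
#' @return RCS concentration, mg/m^3. Vectorised.
#' @export
#' @examples
#' consolidate_polymorphs(0.010, 0.005, 0.5) # 0.030 mg/m^3
consolidate_polymorphs <- function(quartz_mass, cristobalite_mass, air_volume) {
  quartz_mass <- ifelse(is.na(quartz_mass), 0, as.numeric(quartz_mass))
  cristobalite_mass <- ifelse(is.na(cristobalite_mass), 0,
                              as.numeric(cristobalite_mass))
  air_volume <- as.numeric(air_volume)
  if (any(is.na(air_volume)) || any(air_volume <= 0)) {
    sr_stop("`air_volume` must be positive to consolidate polymorph masses")
  }
  if (any(quartz_mass < 0) || any(cristobalite_mass < 0)) {
    sr_stop("polymorph masses must be non-negative")
  }
  (quartz_mass + cristobalite_mass) / air_volume
}

#' Substitute half the LOD for non-detect measurements
#'
#' Rows flagged as non-detects get `concentration = lod / 2`; detected rows
#' are returned unchanged. Idempotent.
#'
#' @param records Measurement tibble (canonical schema).
#' @return The records with non-detects substituted.
#' @export
substitute_nondetect <- function(records) {
  records <- as_measurement_db(records)
  nd <- records$nondetect_flag %in% TRUE
  if (any(nd & (is.na(records$lod) | records$lod <= 0))) {
    sr_stop("non-detect records require a positive `lod`")
  }
  records$concentration[nd] <- records$lod[nd] / 2
  records
}

#' Validate one measurement against the six QC criteria
#'
#' All criteria are evaluated independently: every failure is reported, not
#' only the first. Validation never raises; malformed field values are
#' reported as failures of the relevant criterion.
#'
#' @param record One-row measurement tibble (or list coercible to one).
#' @param allowed_methods Accepted analytical methods (criterion ii).
#' @return A `qc_result`: list with `passed` (logical) and `failures`
#'   (named character vector, names are criterion identifiers).
#' @export
validate_record <- function(record, allowed_methods = default_allowed_methods()) {
  record <- as_measurement_db(record)
  if (nrow(record) != 1L) sr_stop("`record` must be a single measurement")
  failures <- character()

  analyte <- record$analyte
  if (is.na(analyte) || analyte != "RCS") {
    failures["i_analyte"] <- sprintf(
      "analyte must be respirable crystalline silica, got '%s' (respirable dust is excluded; quartz/cristobalite must be consolidated first)",
      if (is.na(analyte)) "missing" else analyte)
  }

  method <- record$method
  if (is.na(method) || !(trimws(method) %in% allowed_methods)) {
    failures["ii_method"] <- sprintf(
      "method '%s' is not a recognised standard method",
      if (is.na(method)) "missing" else method)
  }

  bad_flow <- is.na(record$flow_rate) || record$flow_rate <= 0
  bad_dur <- is.na(record$duration) || record$duration <= 0
  bad_conc <- is.na(record$concentration) || record$concentration < 0
  bad_lod <- isTRUE(record$nondetect_flag) &&
    (is.na(record$lod) || record$lod <= 0)
  if (bad_flow || bad_dur || bad_conc || bad_lod) {
    what <- c("flow rate"[bad_flow], "duration"[bad_dur],
              "concentration"[bad_conc], "LOD"[bad_lod])
    failures["iii_params"] <- sprintf(
      "key sampling parameters missing or malformed: %s",
      paste(what, collapse = ", "))
  }

  if (!isTRUE(record$qaqc_confirmed)) {
    failures["iv_qaqc"] <- "original QA/QC not confirmed adequate"
  }
  if (!isTRUE(record$context_complete)) {
    failures["v_context"] <-
      "insufficient supplementary data to establish equivalence of operations"
  }
  if (is.na(record$sample_type) || record$sample_type != "personal") {
    failures["vi_personal"] <- sprintf(
      "sample type must be personal, got '%s'",
      if (is.na(record$sample_type)) "missing" else record$sample_type)
  }

  structure(list(passed = length(failures) == 0L, failures = failures),
            class = "qc_result")
}

#' Filter a measurement database through QC validation
#'
#' @param records Measurement tibble.
#' @param allowed_methods Accepted analytical methods.
#' @return List with `passing` (the rows whose QC passed, original order)
#'   and `report` (list of `qc_result`, one per input row, input order).
#' @export
filter_database <- function(records, allowed_methods = default_allowed_methods()) {
  records <- as_measurement_db(records)
  if (nrow(records) == 0L) {
    return(list(passing = records, report = list()))
  }
  report <- lapply(seq_len(nrow(records)), function(i) {
    validate_record(records[i, ], allowed_methods)
  })
  passed <- vapply(report, `[[`, logical(1), "passed")
  list(passing = records[passed, ], report = report)
}

#' Write a QC report to JSON
#'
#' @param report List of `qc_result` as returned by [filter_database()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  out <- lapply(report, function(r) {
    list(passed = r$passed,
         failures = lapply(seq_along(r$failures), function(i) {
           list(criterion = names(r$failures)[i], reason = unname(r$failures[i]))
         }))
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Common silica process (CSP) registry
#'
#' A CSP combines a task (e.g. grinding) with a material (e.g. concrete)
#' and a tool (e.g. walk-behind saw). The registry ships as an editable CSV
#' resource seeded with the common construction processes; new CSPs can be
#' added by pointing `path` at an extended file.
#'
#' @param path Optional path to a registry CSV with columns
#'   `csp_id, material, task, tool, label`; defaults to the bundled registry.
#' @return Tibble of CSP descriptors.
#' @export
csp_registry <- function(path = NULL) {
  path <- path %||% system.file("extdata", "csp_registry.csv",
                                package = "silicarisk", mustWork = TRUE)
  reg <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("csp_id", "material", "task", "tool", "label")
  if (!all(needed %in% names(reg))) {
    sr_stop(sprintf("CSP registry must have columns: %s",
                    paste(needed, collapse = ", ")), class = "schema")
  }
  key <- paste(reg$material, reg$task, reg$tool, sep = "|")
  if (anyDuplicated(key)) {
    sr_stop("CSP registry has duplicated (material, task, tool) combinations",
            class = "schema")
  }
  if (anyDuplicated(reg$csp_id)) {
    sr_stop("CSP registry has duplicated csp_id values", class = "schema")
  }
  reg
}

#' Read and write the measurement CSV schema
#'
#' The flat file carries one row per measurement with an explicit
#' `concentration_units` column (`"mg/m3"` or `"ug/m3"`); microgram inputs
#' (concentration and LOD) are converted to mg/m^3 at parse time. Controls
#' are encoded as a semicolon-separated set.
#'
#' @param path CSV file path.
#' @return `read_measurements()`: measurement tibble in mg/m^3.
#' @export
read_measurements <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"concentration_units" %in% names(raw)) {
    sr_stop("measurement CSV requires an explicit `concentration_units` column",
            class = "schema")
  }
  units <- tolower(trimws(raw$concentration_units))
  scale <- ifelse(units %in% c("mg/m3", "mg/m^3"), 1,
           ifelse(units %in% c("ug/m3", "ug/m^3", "µg/m3", "µg/m^3"),
                  1e-3, NA_real_))
  if (any(is.na(scale))) {
    sr_stop(sprintf("unrecognised concentration units: %s",
                    paste(unique(units[is.na(scale)]), collapse = ", ")),
            class = "schema")
  }
  raw$concentration <- raw$concentration * scale
  if ("lod" %in% names(raw)) raw$lod <- raw$lod * scale
  raw$concentration_units <- NULL
  as_measurement_db(raw)
}

#' @rdname read_measurements
#' @param records Measurement tibble to write (mg/m^3).
#' @export
write_measurements <- function(records, path) {
  records <- as_measurement_db(records)
  out <- as.data.frame(records)
  out$concentration_units <- "mg/m3"
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
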