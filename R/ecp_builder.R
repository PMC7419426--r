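# Exposure control plan (ECP) assembly, a JSON-file archive with version
# stamps and soft deletion, and deterministic text/HTML rendering.

#' Company profile for the ECP title page
#'
#' @param company_name Company name (nonempty).
#' @param contact Contact person / details.
#' @param address Company address.
#' @param logo_path Optional path to a logo image (referenced, not embedded).
#' @return A named list of class `company_profile`.
#' @export
company_profile <- function(company_name, contact = "", address = "",
                            logo_path = NULL) {
  if (!is_string(company_name) || !nzchar(trimws(company_name))) {
    sr_stop("`company_name` must be a nonempty string")
  }
  structure(list(company_name = company_name, contact = contact,
                 address = address, logo_path = logo_path),
            class = "company_profile")
}

#' Assemble an exposure control plan document
#'
#' Combines company identifiers, job-level details, the task scenario, its
#' risk estimate and control details into a structured ECP. Administrative
#' controls are descriptive only — they are printed in the plan but never
#' alter exposure estimates. One scenario (a single common silica process)
#' per document; more complex jobs must be split into separate task-level
#' plans. The document is version-stamped with the exposure-database version
#' of the model that produced the estimate.
#'
#' @param profile A [company_profile()].
#' @param job Named list of job-level fields (e.g. `site_address`,
#'   `supervisor`, `start_date`).
#' @param scen The [scenario()] assessed.
#' @param estimate The `risk_estimate` from [assess()] for this scenario.
#' @param engineering_controls Character vector describing engineering
#'   controls in place.
#' @param administrative_controls Character vector (descriptive only).
#' @param ppe Character vector of personal protective equipment; a
#'   respirator line is added automatically when the estimate requires one.
#' @param created Timestamp string; injectable for reproducible output
#'   (default: current UTC time).
#' @return An `ecp_document`.
#' @export
build_ecp <- function(profile, job, scen, estimate,
                      engineering_controls = character(),
                      administrative_controls = character(),
                      ppe = character(), created = NULL) {
  stopifnot(inherits(profile, "company_profile"),
            inherits(estimate, "risk_estimate"))
  if (!inherits(scen, "silica_scenario")) {
    sr_stop("one scenario (a single common silica process) per ECP; split multi-task jobs into separate plans",
            class = "consistency")
  }
  if (!identical(scen$csp_id, estimate$csp_id)) {
    sr_stop(sprintf("scenario CSP '%s' does not match the estimate's CSP '%s'",
                    scen$csp_id, estimate$csp_id), class = "consistency")
  }
  if (isTRUE(estimate$respirator$required)) {
    ppe <- unique(c(ppe, sprintf(
      "Respirator: %s (minimum APF %s; hazard ratio %.2f)",
      estimate$respirator$class_label,
      format(estimate$respirator$minimum_apf),
      estimate$respirator$hazard_ratio)))
  }
  created <- created %||% format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  structure(list(
    ecp_id = NA_character_,
    profile = unclass(profile),
    job = as.list(job),
    scenario = unclass(scen),
    estimate = unclass(estimate),
    engineering_controls = as.character(engineering_controls),
    administrative_controls = as.character(administrative_controls),
    ppe = as.character(ppe),
    db_version = estimate$model_version,
    created = created,
    provenance = NULL,
    deleted = FALSE
  ), class = "ecp_document")
}

ecp_from_list <- function(doc) {
  doc$scenario <- structure(doc$scenario, class = "silica_scenario")
  doc$scenario$controls <- as.character(unlist(doc$scenario$controls))
  doc$estimate <- structure(doc$estimate, class = "risk_estimate")
  doc$estimate$applied_controls <-
    as.character(unlist(doc$estimate$applied_controls))
  doc$estimate$audit <- as.character(unlist(doc$estimate$audit))
  for (f in c("engineering_controls", "administrative_controls", "ppe")) {
    doc[[f]] <- as.character(unlist(doc[[f]]))
  }
  structure(doc, class = "ecp_document")
}

#' ECP archive: a directory of JSON documents with an index
#'
#' Desk-scale, auditable and diff-able: each stored plan is one JSON file
#' plus an entry in `index.json`. Stored plans can be recalled, copied
#' (with a provenance link), edited (a new version, keeping the estimate's
#' database version stamp) and soft-deleted (tombstoned, never removed).
#'
#' @param root Archive directory (created if missing).
#' @return An `ecp_archive` handle.
#' @export
ecp_archive <- function(root) {
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  idx_path <- file.path(root, "index.json")
  if (!file.exists(idx_path)) {
    jsonlite::write_json(list(next_id = 1L, entries = list()), idx_path,
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(root = root), class = "ecp_archive")
}

read_index <- function(archive) {
  jsonlite::fromJSON(file.path(archive$root, "index.json"),
                     simplifyVector = FALSE)
}

write_index <- function(archive, idx) {
  jsonlite::write_json(idx, file.path(archive$root, "index.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

index_entry <- function(idx, ecp_id) {
  hit <- Filter(function(e) identical(e$ecp_id, ecp_id), idx$entries)
  if (length(hit) == 0L) NULL else hit[[1]]
}

#' @rdname ecp_archive
#' @param archive An `ecp_archive`.
#' @param document An `ecp_document`.
#' @return `archive_store()`: the stored document, with its assigned
#'   `ecp_id`.
#' @export
archive_store <- function(archive, document) {
  stopifnot(inherits(archive, "ecp_archive"),
            inherits(document, "ecp_document"))
  idx <- read_index(archive)
  id <- sprintf("ECP-%06d", idx$next_id)
  idx$next_id <- idx$next_id + 1L
  document$ecp_id <- id
  plain <- unclass(document)
  plain$scenario <- unclass(plain$scenario)
  plain$estimate <- unclass(plain$estimate)
  jsonlite::write_json(plain,
                       file.path(archive$root, paste0(id, ".json")),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       null = "null")
  idx$entries <- c(idx$entries, list(list(
    ecp_id = id, created = document$created,
    csp_id = document$scenario$csp_id, db_version = document$db_version,
    provenance = document$provenance, deleted = FALSE)))
  write_index(archive, idx)
  document
}

#' @rdname ecp_archive
#' @param ecp_id Stored document identifier.
#' @return `archive_recall()`: the stored `ecp_document`.
#' @export
archive_recall <- function(archive, ecp_id) {
  idx <- read_index(archive)
  entry <- index_entry(idx, ecp_id)
  if (is.null(entry) || isTRUE(entry$deleted)) {
    sr_stop(sprintf("no ECP '%s' in archive", ecp_id), class = "not_found")
  }
  doc <- jsonlite::fromJSON(file.path(archive$root, paste0(ecp_id, ".json")),
                            simplifyVector = TRUE, simplifyDataFrame = FALSE)
  ecp_from_list(doc)
}

#' @rdname ecp_archive
#' @return `archive_copy()`: the new document (new id, provenance linking
#'   to the source id).
#' @export
archive_copy <- function(archive, ecp_id) {
  doc <- archive_recall(archive, ecp_id)
  doc$provenance <- ecp_id
  doc$ecp_id <- NA_character_
  archive_store(archive, doc)
}

#' @rdname ecp_archive
#' @param document_new Edited `ecp_document` replacing the stored content;
#'   its estimate's database version stamp is retained unchanged.
#' @return `archive_edit()`: the new version as stored.
#' @export
archive_edit <- function(archive, ecp_id, document_new) {
  old <- archive_recall(archive, ecp_id)
  stopifnot(inherits(document_new, "ecp_document"))
  if (!identical(document_new$db_version, old$db_version)) {
    sr_stop("an edit keeps the database version stamp of its estimate; refit and re-assess to change versions",
            class = "consistency")
  }
  document_new$provenance <- ecp_id
  document_new$ecp_id <- NA_character_
  archive_store(archive, document_new)
}

#' @rdname ecp_archive
#' @return `archive_delete()`: invisibly, the tombstoned id. Deletion is
#'   soft: the file is kept for auditability and the plan can no longer be
#'   recalled.
#' @export
archive_delete <- function(archive, ecp_id) {
  idx <- read_index(archive)
  entry <- index_entry(idx, ecp_id)
  if (is.null(entry)) {
    sr_stop(sprintf("no ECP '%s' in archive", ecp_id), class = "not_found")
  }
  idx$entries <- lapply(idx$entries, function(e) {
    if (identical(e$ecp_id, ecp_id)) e$deleted <- TRUE
    e
  })
  write_index(archive, idx)
  invisible(ecp_id)
}

fmt_conc <- function(x) sprintf("%.4g mg/m3", x)

ecp_sections <- function(doc) {
  est <- doc$estimate
  scen <- doc$scenario
  reg <- tryCatch(csp_registry(), error = function(e) NULL)
  csp_label <- scen$csp_id
  if (!is.null(reg) && scen$csp_id %in% reg$csp_id) {
    csp_label <- sprintf("%s (%s)", reg$label[reg$csp_id == scen$csp_id],
                         scen$csp_id)
  }
  if (isTRUE(est$respirator$required) && length(doc$ppe) == 0L) {
    sr_stop("render error: required section 'PPE' is empty while a respirator is required",
            class = "render")
  }
  list(
    "Title page" = c(
      sprintf("Exposure Control Plan: respirable crystalline silica"),
      sprintf("Company: %s", doc$profile$company_name),
      sprintf("Contact: %s", doc$profile$contact),
      sprintf("Address: %s", doc$profile$address),
      sprintf("Created: %s", doc$created),
      sprintf("Database version: %s", doc$db_version)
    ),
    "Job details" = c(
      vapply(names(doc$job), function(k) {
        sprintf("%s: %s", k, paste(format(doc$job[[k]]), collapse = " "))
      }, character(1)),
      sprintf("Task: %s", csp_label)
    ),
    "Risk assessment" = c(
      sprintf("Scenario: sector %s, project %s, environment %s, region %s",
              scen$sector, scen$project_type, scen$environment, scen$region),
      sprintf("Sampling duration: %g min; task duration: %g h",
              scen$sampling_duration, scen$task_duration_hours),
      sprintf("Uncontrolled 95th-percentile estimate: %s (%s the OEL of %s)",
              fmt_conc(est$uncontrolled_p95),
              if (est$over_oel_uncontrolled) "exceeds" else "within",
              fmt_conc(est$oel)),
      sprintf("Controlled 95th-percentile estimate: %s (%s the OEL of %s)",
              fmt_conc(est$controlled_p95),
              if (est$over_oel_controlled) "exceeds" else "within",
              fmt_conc(est$oel)),
      sprintf("Selected controls: %s",
              if (length(est$applied_controls)) {
                paste(est$applied_controls, collapse = ", ")
              } else "none"),
      sprintf("Separation-from-source factor applied: %s",
              est$separation_applied),
      sprintf("Short-duration discount applied: %s",
              est$duration_discount_applied),
      sprintf("Monte Carlo: %d draws, seed %d", est$n_draws, est$seed)
    ),
    "Engineering controls" = if (length(doc$engineering_controls)) {
      doc$engineering_controls
    } else "None specified",
    "Administrative controls" = c(
      if (length(doc$administrative_controls)) {
        doc$administrative_controls
      } else "None specified",
      "Administrative controls are listed for implementation but are not credited in the quantitative exposure estimates."
    ),
    "Personal protective equipment" = if (length(doc$ppe)) doc$ppe
                                      else "None required beyond site policy",
    "Worker protection in the vicinity" = paste(
      "Workers in the vicinity of the task who are not conducting it may",
      "also be exposed to respirable crystalline silica. The employer must",
      "restrict access to the work area, or extend equivalent controls and",
      "protection to those workers; this plan's estimates cover only the",
      "worker conducting the task."),
    "Version stamp" = sprintf(
      "Estimates generated with exposure database version %s.",
      doc$db_version)
  )
}

#' Render an ECP document to text or HTML
#'
#' Deterministic structured rendering: identical documents (including the
#' injected `created` timestamp) render byte-identically. A missing
#' required section — e.g. an empty PPE section while a respirator is
#' required — raises an error naming the section.
#'
#' @param document An `ecp_document`.
#' @param format `"text"` or `"html"`.
#' @param path Optional output file; if `NULL` the rendered string is
#'   returned.
#' @return The rendered document as a single string (invisibly when written
#'   to `path`).
#' @export
render_ecp <- function(document, format = c("text", "html"), path = NULL) {
  stopifnot(inherits(document, "ecp_document"))
  format <- match.arg(format)
  sections <- ecp_sections(document)
  out <- if (format == "text") {
    paste(vapply(names(sections), function(h) {
      paste0("== ", h, " ==\n", paste(sections[[h]], collapse = "\n"))
    }, character(1)), collapse = "\n\n")
  } else {
    body <- vapply(names(sections), function(h) {
      paste0("<section>\n<h2>", h, "</h2>\n",
             paste0("<p>", sections[[h]], "</p>", collapse = "\n"),
             "\n</section>")
    }, character(1))
    paste0("<!DOCTYPE html>\n<html>\n<head><meta charset=\"utf-8\">",
           "<title>Exposure Control Plan</title></head>\n<body>\n",
           paste(body, collapse = "\n"), "\n</body>\n</html>\n")
  }
  if (is.null(path)) return(out)
  writeLines(out, path, sep = "")
  invisible(out)
}
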