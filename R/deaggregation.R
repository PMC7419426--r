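# De-aggregation of published summary statistics into simulated discrete
# observations, so aggregate literature data can enter the modelling
# database alongside raw measurements.

#' Lognormal summary-statistic conversions
#'
#' Convert between arithmetic (AM, SD) and geometric (GM, GSD) summaries
#' under a lognormal assumption: `ln^2(GSD) = ln(1 + SD^2/AM^2)` and
#' `AM = GM * exp(ln^2(GSD) / 2)`.
#'
#' @param am,sd Arithmetic mean and standard deviation (mg/m^3).
#' @return Named list with `gm` and `gsd`.
#' @export
am_sd_to_gm_gsd <- function(am, sd) {
  if (any(am <= 0) || any(sd < 0)) {
    sr_stop("AM must be positive and SD non-negative")
  }
  ln2gsd <- log(1 + (sd / am)^2)
  list(gm = am * exp(-ln2gsd / 2), gsd = exp(sqrt(ln2gsd)))
}

#' @rdname am_sd_to_gm_gsd
#' @param gm,gsd Geometric mean (mg/m^3) and geometric standard deviation
#'   (unitless, >= 1).
#' @return Named list with `am` and `sd`.
#' @export
gm_gsd_to_am_sd <- function(gm, gsd) {
  if (any(gm <= 0) || any(gsd < 1)) {
    sr_stop("GM must be positive and GSD >= 1")
  }
  ln2 <- log(gsd)^2
  am <- gm * exp(ln2 / 2)
  list(am = am, sd = am * sqrt(exp(ln2) - 1))
}

#' De-aggregate a published summary statistic into discrete observations
#'
#' Draws `n` values from a lognormal with the record's geometric mean and
#' geometric standard deviation, then rescales affinely in log space so the
#' empirical GM and GSD (log-SD with the n-1 denominator) equal the targets
#' exactly. Arithmetic summaries (AM/SD) are first converted to GM/GSD under
#' a lognormal assumption. Deterministic given `seed`.
#'
#' @param n Number of observations the summary aggregates (>= 1).
#' @param center Central value, mg/m^3 (> 0).
#' @param center_kind `"GM"` or `"AM"`.
#' @param dispersion Dispersion value: GSD (unitless, >= 1) or SD (mg/m^3).
#' @param dispersion_kind `"GSD"` or `"SD"`.
#' @param covariates Named list of fields to stamp on the generated records
#'   (csp_id, sector, method, duration, ...); see [new_measurement()].
#' @param seed Integer seed.
#' @return Measurement tibble with `n` rows, `source = "deaggregated"`.
#' @export
#' @examples
#' obs <- deaggregate_summary(10, center = 0.05, dispersion = 2.0, seed = 42)
#' exp(mean(log(obs$concentration))) # 0.05
deaggregate_summary <- function(n, center, center_kind = c("GM", "AM"),
                                dispersion, dispersion_kind = c("GSD", "SD"),
                                covariates = list(), seed = 1L) {
  center_kind <- match.arg(center_kind)
  dispersion_kind <- match.arg(dispersion_kind)
  if (!is_number(n) || n < 1) sr_stop("`n` must be a count >= 1")
  n <- as.integer(n)
  if (!is_number(center) || center <= 0) sr_stop("`center` must be positive")
  if (!is_number(dispersion)) sr_stop("`dispersion` must be a number")

  if (center_kind == "AM" || dispersion_kind == "SD") {
    if (center_kind != "AM" || dispersion_kind != "SD") {
      sr_stop("AM must be paired with SD, and GM with GSD")
    }
    g <- am_sd_to_gm_gsd(center, dispersion)
    gm <- g$gm
    gsd <- g$gsd
  } else {
    if (dispersion < 1) sr_stop("GSD must be >= 1")
    gm <- center
    gsd <- dispersion
  }

  values <- if (n == 1L || gsd == 1) {
    rep(gm, n)
  } else {
    with_seed(seed, {
      z <- stats::rnorm(n)
      z <- (z - mean(z)) / stats::sd(z)
      exp(log(gm) + log(gsd) * z)
    })
  }

  rows <- lapply(values, function(v) {
    do.call(new_measurement,
            c(list(concentration = v, source = "deaggregated"), covariates))
  })
  do.call(rbind, rows)
}

#' Read summary-statistic records and de-aggregate them in bulk
#'
#' The CSV carries one published aggregate per row: columns `n`, `center`,
#' `center_kind`, `dispersion`, `dispersion_kind` plus any measurement
#' covariate columns (csp_id, sector, project_type, environment, region,
#' method, duration, controls, ...). Each row is expanded with
#' [deaggregate_summary()]; row `i` uses seed `seed + i - 1`.
#'
#' @param path Summary CSV path.
#' @return `read_summary_records()`: tibble of summary records.
#' @export
read_summary_records <- function(path) {
  raw <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  needed <- c("n", "center", "center_kind", "dispersion", "dispersion_kind")
  if (!all(needed %in% names(raw))) {
    sr_stop(sprintf("summary CSV must have columns: %s",
                    paste(needed, collapse = ", ")), class = "schema")
  }
  raw
}

#' @rdname read_summary_records
#' @param summaries Tibble of summary records (see `read_summary_records`).
#' @param seed Integer base seed.
#' @export
deaggregate_table <- function(summaries, seed = 1L) {
  cov_cols <- intersect(names(summaries), measurement_columns())
  cov_cols <- setdiff(cov_cols, "concentration")
  out <- lapply(seq_len(nrow(summaries)), function(i) {
    row <- summaries[i, ]
    covariates <- as.list(row[, cov_cols, drop = FALSE])
    covariates <- covariates[!vapply(covariates, is.na, logical(1))]
    deaggregate_summary(row$n, row$center, row$center_kind,
                        row$dispersion, row$dispersion_kind,
                        covariates = covariates, seed = seed + i - 1L)
  })
  do.call(rbind, out)
}
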