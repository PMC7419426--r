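# Monte Carlo exposure estimation, adjustment factors, OEL comparison,
# respirator recommendation and the model-vs-measured validation routine.

#' Monte Carlo upper-percentile exposure estimate
#'
#' For each draw, every model coefficient is sampled independently from a
#' normal distribution with the coefficient estimate as mean and its
#' standard error as standard deviation; the linear predictor for the
#' scenario is exponentiated back to mg/m^3 and the empirical percentile of
#' the draws is returned. This represents coefficient (parameter)
#' uncertainty; set `include_residual = TRUE` to additionally draw
#' within-scenario residual variability per sample.
#'
#' @param model An [exposure_model()].
#' @param scen A [scenario()].
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param percentile Upper percentile reported (default 95).
#' @param seed Integer seed; identical inputs give identical estimates.
#' @param include_residual Add a `Normal(0, residual_log_sd)` draw per
#'   sample (within-scenario variability). Default `FALSE`.
#' @return Exposure estimate, mg/m^3.
#' @export
#' @examples
#' m <- exposure_model(tibble::tibble(term = "(Intercept)",
#'                                    estimate = log(0.1), se = 0))
#' s <- scenario("CSP-05", "civil", "new", "outdoor", "bc")
#' mc_percentile(m, s) # exactly 0.1: zero-variance coefficients
mc_percentile <- function(model, scen, n_draws = 1000, percentile = 95,
                          seed = 1L, include_residual = FALSE) {
  if (!is_number(n_draws) || n_draws < 1) sr_stop("`n_draws` must be >= 1")
  n_draws <- as.integer(n_draws)
  if (n_draws < 100) {
    sr_warn(sprintf("n_draws = %d is below 100; percentile estimate will be unstable",
                    n_draws))
  }
  x <- encode_scenario(scen, model)
  est <- model$coefficients$estimate
  se <- model$coefficients$se
  p <- length(est)
  values <- with_seed(seed, {
    draws <- matrix(
      stats::rnorm(n_draws * p, mean = rep(est, each = n_draws),
                   sd = rep(se, each = n_draws)),
      nrow = n_draws, ncol = p)
    lp <- as.vector(draws %*% x)
    if (isTRUE(include_residual)) {
      lp <- lp + stats::rnorm(n_draws, 0, model$residual_log_sd)
    }
    exp(lp)
  })
  stats::quantile(values, percentile / 100, names = FALSE, type = 7)
}

#' Separation-from-source reduction factor
#'
#' Separation from the emission source (e.g. an enclosed cab) could not be
#' estimated from measurement data; a fixed 25% exposure reduction from
#' published literature is applied instead: the estimate is multiplied
#' by 0.75.
#'
#' @param estimate Exposure estimate, mg/m^3 (>= 0).
#' @param reduction Fractional reduction in (0, 1); default 0.25.
#' @return Reduced estimate, mg/m^3.
#' @export
apply_separation_factor <- function(estimate, reduction = 0.25) {
  if (any(!is.finite(estimate)) || any(estimate < 0)) {
    sr_stop("`estimate` must be non-negative")
  }
  if (!is_number(reduction) || reduction <= 0 || reduction >= 1) {
    sr_stop("`reduction` must be in (0, 1)")
  }
  estimate * (1 - reduction)
}

#' Short-task duration discount
#'
#' Final estimates are discounted by 50% when the stated task duration is
#' strictly under 4 hours (mirroring the OSHA short-duration allowance);
#' exactly 4.0 h is not discounted.
#'
#' @param estimate Exposure estimate, mg/m^3 (>= 0).
#' @param task_duration_hours Stated task duration, hours (> 0).
#' @param discount Multiplier applied below the threshold; default 0.5.
#' @param threshold_hours Strict threshold; default 4.
#' @return Possibly discounted estimate, mg/m^3.
#' @export
apply_duration_discount <- function(estimate, task_duration_hours,
                                    discount = 0.5, threshold_hours = 4) {
  if (any(!is.finite(estimate)) || any(estimate < 0)) {
    sr_stop("`estimate` must be non-negative")
  }
  if (!is_number(task_duration_hours) || task_duration_hours <= 0) {
    sr_stop("`task_duration_hours` must be positive")
  }
  if (task_duration_hours < threshold_hours) estimate * discount else estimate
}

#' Default assigned-protection-factor (APF) ladder
#'
#' Respirator classes ordered by increasing protection. Configurable; any
#' table with columns `class_label` and `apf` (ascending) can be supplied
#' to [recommend_respirator()].
#'
#' @return Tibble with columns `class_label`, `apf`.
#' @export
default_apf_table <- function() {
  tibble::tibble(
    class_label = c("half-facepiece air-purifying respirator",
                    "full-facepiece air-purifying respirator",
                    "powered air-purifying respirator (PAPR)",
                    "supplied-air respirator"),
    apf = c(10, 50, 100, 1000)
  )
}

#' Recommend respiratory protection for a residual over-exposure
#'
#' The required hazard ratio is `controlled_p95 / oel`. At or below 1 no
#' respirator is required; otherwise the smallest APF class with
#' `APF >= ratio` is recommended. If the ratio exceeds the largest APF in
#' the table, the recommendation escalates to reassessing controls.
#'
#' @param controlled_p95 Post-control 95th-percentile estimate, mg/m^3 (> 0).
#' @param oel Occupational exposure limit, mg/m^3 (> 0).
#' @param apf_table APF ladder; see [default_apf_table()].
#' @return List with `required`, `hazard_ratio`, `minimum_apf`,
#'   `class_label`, `escalate`.
#' @export
recommend_respirator <- function(controlled_p95, oel,
                                 apf_table = default_apf_table()) {
  if (!is_number(oel) || oel <= 0) sr_stop("`oel` must be positive")
  if (!is_number(controlled_p95) || controlled_p95 <= 0) {
    sr_stop("`controlled_p95` must be positive")
  }
  r <- controlled_p95 / oel
  if (r <= 1) {
    return(list(required = FALSE, hazard_ratio = r, minimum_apf = 1,
                class_label = "none required", escalate = FALSE))
  }
  apf_table <- apf_table[order(apf_table$apf), ]
  idx <- which(apf_table$apf >= r)
  if (length(idx) == 0L) {
    return(list(required = TRUE, hazard_ratio = r, minimum_apf = NA_real_,
                class_label = "reassess controls", escalate = TRUE))
  }
  list(required = TRUE, hazard_ratio = r,
       minimum_apf = apf_table$apf[idx[1]],
       class_label = apf_table$class_label[idx[1]], escalate = FALSE)
}

#' Assess a scenario: uncontrolled and controlled estimates vs an OEL
#'
#' Computes the Monte Carlo upper 95th-percentile exposure twice — once with
#' all controls stripped from the scenario and once with the selected
#' controls — applying the separation-from-source factor post hoc when
#' `separation` is selected, and the short-duration discount to both final
#' estimates. Both estimates are compared to the OEL and a respirator
#' recommendation is attached for any residual over-exposure. Inputs are
#' never mutated, so repeated calls with varied controls support "what-if"
#' iteration.
#'
#' @inheritParams mc_percentile
#' @param oel Occupational exposure limit, mg/m^3; default 0.025 (the BC /
#'   ACGIH TLV for respirable crystalline silica), configurable per
#'   jurisdiction.
#' @param apf_table APF ladder for respirator recommendation.
#' @param separation_reduction Separation-from-source fractional reduction.
#' @param discount,threshold_hours Short-duration discount parameters.
#' @return A `risk_estimate` list; see Details.
#' @details The returned object carries `uncontrolled_p95`, `controlled_p95`
#'   (mg/m^3, after adjustment factors), `applied_controls`,
#'   `separation_applied`, `duration_discount_applied`, `oel`,
#'   `over_oel_uncontrolled`, `over_oel_controlled`, `respirator`,
#'   `n_draws`, `seed`, `include_residual`, `model_version`, `csp_id` and a
#'   human-readable `audit` trail recording the canonical adjustment order
#'   (fitted control terms, then separation factor, then duration discount).
#' @export
assess <- function(model, scen, oel = 0.025, seed = 1L, n_draws = 1000,
                   include_residual = FALSE, apf_table = default_apf_table(),
                   separation_reduction = 0.25, discount = 0.5,
                   threshold_hours = 4) {
  stopifnot(inherits(scen, "silica_scenario"))
  if (!is_number(oel) || oel <= 0) sr_stop("`oel` must be positive")
  audit <- character()

  unc_scen <- scen
  unc_scen$controls <- character()
  u <- mc_percentile(model, unc_scen, n_draws, 95, seed, include_residual)
  c0 <- mc_percentile(model, scen, n_draws, 95, seed, include_residual)
  audit <- c(audit, sprintf(
    "MC p95, %d draws, seed %d: uncontrolled %.6g, with fitted control terms %.6g mg/m3",
    as.integer(n_draws), as.integer(seed), u, c0))

  separation_applied <- "separation" %in% scen$controls
  c1 <- c0
  if (separation_applied) {
    c1 <- apply_separation_factor(c0, separation_reduction)
    audit <- c(audit, sprintf(
      "separation-from-source factor: x%.2f -> %.6g mg/m3",
      1 - separation_reduction, c1))
  }

  discount_applied <- scen$task_duration_hours < threshold_hours
  u_final <- apply_duration_discount(u, scen$task_duration_hours,
                                     discount, threshold_hours)
  c_final <- apply_duration_discount(c1, scen$task_duration_hours,
                                     discount, threshold_hours)
  if (discount_applied) {
    audit <- c(audit, sprintf(
      "task duration %.2g h < %g h: x%.2f discount on final estimates",
      scen$task_duration_hours, threshold_hours, discount))
  }

  respirator <- recommend_respirator(c_final, oel, apf_table)
  structure(list(
    uncontrolled_p95 = u_final,
    controlled_p95 = c_final,
    applied_controls = scen$controls,
    separation_applied = separation_applied,
    duration_discount_applied = discount_applied,
    oel = oel,
    over_oel_uncontrolled = u_final > oel,
    over_oel_controlled = c_final > oel,
    respirator = respirator,
    n_draws = as.integer(n_draws),
    seed = as.integer(seed),
    include_residual = isTRUE(include_residual),
    model_version = model$db_version,
    csp_id = scen$csp_id,
    audit = audit
  ), class = "risk_estimate")
}

#' Write a risk estimate (with audit trail) to JSON
#'
#' @param estimate A `risk_estimate` from [assess()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_risk_estimate <- function(estimate, path) {
  jsonlite::write_json(unclass(estimate), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, null = "null")
  invisible(path)
}

#' @export
print.risk_estimate <- function(x, ...) {
  cat(sprintf("<risk_estimate> CSP %s (model %s)\n", x$csp_id, x$model_version))
  cat(sprintf("  uncontrolled p95: %.4g mg/m3 (%s OEL %.3g)\n",
              x$uncontrolled_p95,
              if (x$over_oel_uncontrolled) "OVER" else "under", x$oel))
  cat(sprintf("  controlled   p95: %.4g mg/m3 (%s OEL %.3g)\n",
              x$controlled_p95,
              if (x$over_oel_controlled) "OVER" else "under", x$oel))
  cat(sprintf("  respirator: %s\n", x$respirator$class_label))
  invisible(x)
}

#' Compare modelled estimates with measured data, per CSP
#'
#' For each common silica process with at least `min_n` measurements, the
#' modelled geometric mean (from the point-estimate linear predictor of each
#' record's covariates) and the modelled 95th percentile (Monte Carlo over
#' coefficient uncertainty, with residual variability included by default —
#' an empirical p95 of measurements reflects within-scenario variability)
#' are compared with the empirical GM and p95. CSPs with fewer than `min_n`
#' measurements are excluded with a warning.
#'
#' @param model An [exposure_model()].
#' @param records QC-passed, encodable measurement tibble.
#' @param n_draws Monte Carlo draws per CSP.
#' @param seed Integer seed.
#' @param min_n Minimum measurements per CSP (default 3).
#' @param include_residual Include residual variability in the modelled p95.
#' @return List of class `exposure_validation`: `by_csp` tibble (per-CSP
#'   empirical and modelled GM/p95, ratios, conservative flag),
#'   `mean_gm_ratio`, `mean_p95_ratio`, `conservative_fraction` (share of
#'   CSPs where modelled p95 >= empirical p95), `log_correlation` (Pearson
#'   correlation of log modelled vs log empirical GM), `n_csp`,
#'   `excluded_csps`.
#' @export
validate_against_measurements <- function(model, records, n_draws = 2000,
                                          seed = 1L, min_n = 3,
                                          include_residual = TRUE) {
  records <- as_measurement_db(records)
  empty <- list(
    by_csp = tibble::tibble(
      csp_id = character(), n = integer(),
      empirical_gm = numeric(), modeled_gm = numeric(), gm_ratio = numeric(),
      empirical_p95 = numeric(), modeled_p95 = numeric(),
      p95_ratio = numeric(), conservative = logical()),
    mean_gm_ratio = NA_real_, mean_p95_ratio = NA_real_,
    conservative_fraction = NA_real_, log_correlation = NA_real_,
    n_csp = 0L, excluded_csps = character())
  class(empty) <- "exposure_validation"
  if (nrow(records) == 0L) return(empty)

  groups <- split(records, records$csp_id)
  sizes <- vapply(groups, nrow, integer(1))
  excluded <- names(groups)[sizes < min_n]
  if (length(excluded)) {
    sr_warn(sprintf("CSP(s) with fewer than %d measurements excluded: %s",
                    min_n, paste(excluded, collapse = ", ")))
  }
  groups <- groups[sizes >= min_n]
  if (length(groups) == 0L) {
    empty$excluded_csps <- excluded
    return(empty)
  }

  est <- model$coefficients$estimate
  se <- model$coefficients$se
  p <- length(est)
  rows <- with_seed(seed, lapply(names(groups), function(id) {
    g <- groups[[id]]
    ctl <- parse_controls(g$controls)
    Xg <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      encode_scenario(
        scenario(g$csp_id[i], g$sector[i], g$project_type[i],
                 g$environment[i], g$region[i],
                 sampling_duration = g$duration[i],
                 controls = intersect(ctl[[i]], control_ids())),
        model)
    }))
    lp <- as.vector(Xg %*% est)
    draws <- matrix(stats::rnorm(n_draws * p, mean = rep(est, each = n_draws),
                                 sd = rep(se, each = n_draws)),
                    nrow = n_draws, ncol = p)
    sim_lp <- as.vector(draws %*% t(Xg)) # n_draws x n_records, pooled
    if (isTRUE(include_residual)) {
      sim_lp <- sim_lp + stats::rnorm(length(sim_lp), 0, model$residual_log_sd)
    }
    modeled_p95 <- stats::quantile(exp(sim_lp), 0.95, names = FALSE)
    emp_gm <- exp(mean(log(g$concentration)))
    emp_p95 <- stats::quantile(g$concentration, 0.95, names = FALSE)
    tibble::tibble(
      csp_id = id, n = nrow(g),
      empirical_gm = emp_gm, modeled_gm = exp(mean(lp)),
      gm_ratio = exp(mean(lp)) / emp_gm,
      empirical_p95 = emp_p95, modeled_p95 = modeled_p95,
      p95_ratio = modeled_p95 / emp_p95,
      conservative = modeled_p95 >= emp_p95)
  }))
  by_csp <- do.call(rbind, rows)
  out <- list(
    by_csp = by_csp,
    mean_gm_ratio = mean(by_csp$gm_ratio),
    mean_p95_ratio = mean(by_csp$p95_ratio),
    conservative_fraction = mean(by_csp$conservative),
    log_correlation = if (nrow(by_csp) >= 3) {
      stats::cor(log(by_csp$modeled_gm), log(by_csp$empirical_gm))
    } else NA_real_,
    n_csp = nrow(by_csp),
    excluded_csps = excluded
  )
  class(out) <- "exposure_validation"
  out
}
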