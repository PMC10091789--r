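#' Back-calculate a standard error and CI from an estimate and p-value
#'
#' For a two-sided normal test, `se = |estimate| / z(p/2)`; the Wald 95%
#' interval follows. Used to audit published confidence intervals when only
#' the point estimate and p-value are printed.
#'
#' @param estimate Non-zero point estimate.
#' @param p Two-sided p-value in (0, 1).
#' @return List with `se`, `ci_low`, `ci_high` (and `wide = TRUE` when the
#'   p-value is so close to 1 that the interval is effectively unbounded).
#' @export
ci_from_p <- function(estimate, p) {
  if (!is.numeric(p) || p <= 0 || p >= 1)
    stop_config("p must be strictly inside (0, 1)")
  if (estimate == 0) stop_config("estimate must be non-zero")
  z <- stats::qnorm(1 - p / 2)
  se <- abs(estimate) / z
  ci <- wald_ci(estimate, se)
  list(se = se, ci_low = ci[1], ci_high = ci[2], wide = z < 1e-3)
}

#' Avoidable-diagnosis count from a per-year GMTE
#'
#' Multiplies the per-year excess hazard in carriers by the carrier
#' patient-years accrued in the model; the CI endpoints are scaled by the
#' same linear map.
#'
#' @param gmte Per-year hazard difference (the GMTE).
#' @param patient_years Carrier patient-years (positive).
#' @param gmte_ci Optional length-2 CI for the GMTE.
#' @return List with `avoided` and (if a CI was given) `avoided_ci`.
#' @export
avoidable_count <- function(gmte, patient_years, gmte_ci = NULL) {
  if (!is.numeric(patient_years) || patient_years <= 0)
    stop_config("patient_years must be positive")
  out <- list(avoided = gmte * patient_years)
  if (!is.null(gmte_ci)) {
    stopifnot(length(gmte_ci) == 2L)
    out$avoided_ci <- sort(gmte_ci * patient_years)
  }
  out
}

#' Percent reduction in incidence among the treated
#'
#' @param avoided Avoidable-diagnosis count.
#' @param total_events Total diagnoses among treated patients (positive).
#' @param avoided_ci Optional CI for the avoided count.
#' @param digits Rounding (1 decimal place conventionally).
#' @return List with `percent` and optionally `percent_ci` (rounded), plus
#'   unrounded `percent_raw`.
#' @export
percent_reduction <- function(avoided, total_events, avoided_ci = NULL,
                              digits = 1L) {
  if (!is.numeric(total_events) || total_events <= 0)
    stop_config("total_events must be positive")
  raw <- 100 * avoided / total_events
  out <- list(percent = round(raw, digits), percent_raw = raw)
  if (!is.null(avoided_ci))
    out$percent_ci <- round(sort(100 * avoided_ci / total_events), digits)
  out
}

#' Translate a GMTE into population-impact quantities
#'
#' Combines [avoidable_count()] and [percent_reduction()]: how many
#' diagnoses would have been avoided had carriers experienced the
#' non-carrier treatment effect, and the corresponding percent reduction in
#' incidence among the treated. Accepts either a standard error or a
#' p-value (back-calculated via [ci_from_p()]) for the GMTE uncertainty.
#'
#' @param gmte Per-year hazard difference.
#' @param patient_years Carrier patient-years in the model.
#' @param total_events Total diagnoses among treated patients.
#' @param gmte_se Standard error of the GMTE (optional).
#' @param gmte_p Two-sided p-value of the GMTE (used if `gmte_se` missing).
#' @return Object of class `impact_estimate`.
#' @export
impact_estimate <- function(gmte, patient_years, total_events,
                            gmte_se = NULL, gmte_p = NULL) {
  if (is.null(gmte_se) && !is.null(gmte_p))
    gmte_se <- ci_from_p(gmte, gmte_p)$se
  gmte_ci <- if (!is.null(gmte_se)) wald_ci(gmte, gmte_se)
  ac <- avoidable_count(gmte, patient_years, gmte_ci)
  pr <- percent_reduction(ac$avoided, total_events, ac$avoided_ci)
  structure(list(gmte_per_year = gmte, gmte_se = gmte_se, gmte_ci = gmte_ci,
                 carrier_patient_years = patient_years,
                 total_events_treated = total_events,
                 avoided_count = ac$avoided,
                 avoided_ci = ac$avoided_ci,
                 percent_reduction = pr$percent,
                 percent_reduction_raw = pr$percent_raw,
                 percent_ci = pr$percent_ci),
            class = "impact_estimate")
}

#' Impact translation from a fitted TWIST suite
#'
#' Uses the suite's combined estimate, its carrier patient-years among the
#' treated and the treated event count.
#'
#' @param suite A `gmte_suite` from [run_twist()].
#' @return An `impact_estimate`.
#' @export
impact_from_twist <- function(suite) {
  stopifnot(inherits(suite, "gmte_suite"))
  impact_estimate(suite$combined$estimate,
                  suite$carrier_patient_years,
                  suite$treated_events,
                  gmte_se = suite$combined$se)
}

#' @export
print.impact_estimate <- function(x, ...) {
  cat(sprintf("GMTE %.5g per year over %.0f carrier patient-years\n",
              x$gmte_per_year, x$carrier_patient_years))
  if (!is.null(x$avoided_ci)) {
    cat(sprintf("Avoidable diagnoses: %.1f (~%d; 95%% CI %.0f to %.0f) of %d\n",
                x$avoided_count, round(x$avoided_count), x$avoided_ci[1],
                x$avoided_ci[2], x$total_events_treated))
    cat(sprintf("Incidence reduction among treated: %.1f%% (95%% CI %.1f to %.1f)\n",
                x$percent_reduction, x$percent_ci[1], x$percent_ci[2]))
  } else {
    cat(sprintf("Avoidable diagnoses: %.1f of %d (%.1f%%)\n",
                x$avoided_count, x$total_events_treated,
                x$percent_reduction))
  }
  invisible(x)
}
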