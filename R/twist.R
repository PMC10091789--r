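#' An estimate with its standard error
#'
#' Container for one TWIST component: per-year hazard difference, robust SE,
#' two-sided normal p-value and the Wald 95% interval
#' `estimate +/- 1.96*se`.
#'
#' @param label Estimator label (`GMTE1`, `GMTE0`, `RGMTE`, `MR`, `CAT`,
#'   `combined`).
#' @param estimate,se Point estimate and standard error (per year).
#' @return Object of class `gmte_estimate`.
#' @export
estimate_with_se <- function(label, estimate, se) {
  stopifnot(is.finite(estimate), is.finite(se), se > 0)
  ci <- wald_ci(estimate, se)
  structure(list(label = label, estimate = estimate, se = se,
                 p = z_p(estimate, se), ci_low = ci[1], ci_high = ci[2]),
            class = "gmte_estimate")
}

#' @export
print.gmte_estimate <- function(x, ...) {
  cat(sprintf("%-8s %+.5g /y  (se %.3g, 95%% CI %+.4g to %+.4g, p %.3g)\n",
              x$label, x$estimate, x$se, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' @export
as.data.frame.gmte_estimate <- function(x, ...) {
  data.frame(label = x$label, estimate = x$estimate, se = x$se, p = x$p,
             ci_low = x$ci_low, ci_high = x$ci_high,
             stringsAsFactors = FALSE)
}

estimates_df <- function(ests) {
  do.call(rbind, lapply(ests, as.data.frame))
}

## add the coded genotype contrast column `.g` for one variant
add_contrast <- function(rows, variant,
                         coding = c("dominant", "additive", "recessive")) {
  coding <- match.arg(coding)
  if (!variant %in% names(rows)) stop_config("variant column '", variant,
                                             "' not in table")
  rows$.g <- code_dosage(rows[[variant]], coding)
  if (stats::var(rows$.g, na.rm = TRUE) == 0)
    stop_config("variant ", variant, " is monomorphic under ", coding,
                " coding")
  rows
}

#' Stratum-specific GMTE estimates and their robust difference
#'
#' Fits the additive-hazards model separately in treated and untreated
#' subsets. `GMTE1` is the genotype coefficient among treated patients,
#' `GMTE0` among the untreated (a direct genotype effect, zero under the
#' exclusion restriction), and `RGMTE = GMTE1 - GMTE0` with variance
#' `var1 + var0` (independent subsets) is robust to direct genotype effects.
#'
#' @param rows Analysis table with both subsets.
#' @param variant Variant column name (rsid).
#' @param outcome Outcome label.
#' @param coding Genotype coding for the contrast.
#' @param covariates Adjustment columns (defaults to age, sex and any PCs
#'   present).
#' @return List with `GMTE1`, `GMTE0`, `RGMTE` (class `gmte_estimate`) and
#'   the underlying `fits`.
#' @export
gmte_components <- function(rows, variant, outcome, coding = "dominant",
                            covariates = default_covariates(rows)) {
  if (!any(rows$treated == 1L) || !any(rows$treated == 0L))
    stop("need both treated and untreated subsets")
  rows <- add_contrast(rows, variant, coding)
  f1 <- fit_additive_hazards(rows, outcome, c(".g", covariates), "treated")
  f0 <- fit_additive_hazards(rows, outcome, c(".g", covariates), "untreated")
  g1 <- estimate_with_se("GMTE1", f1$coefficients[[".g"]], f1$se[[".g"]])
  g0 <- estimate_with_se("GMTE0", f0$coefficients[[".g"]], f0$se[[".g"]])
  rg <- estimate_with_se("RGMTE", g1$estimate - g0$estimate,
                         sqrt(g1$se^2 + g0$se^2))
  list(GMTE1 = g1, GMTE0 = g0, RGMTE = rg,
       fits = list(treated = f1, untreated = f0))
}

#' Mendelian-randomization style GMTE estimate
#'
#' Full-sample genotype coefficient rescaled by the treated proportion.
#' Valid when the variant affects the outcome only through its interaction
#' with treatment (exclusion restriction) and genotype does not predict
#' treatment.
#'
#' @inheritParams gmte_components
#' @return A `gmte_estimate` labelled `MR` (attribute `p_treated` records
#'   the scaling proportion).
#' @export
mr_estimate <- function(rows, variant, outcome, coding = "dominant",
                        covariates = default_covariates(rows)) {
  pt <- mean(rows$treated == 1L)
  if (pt <= 0) stop("no treated patients: MR estimate undefined")
  if (pt >= 1) warning("all patients treated; MR reduces to GMTE1",
                       call. = FALSE)
  rows <- add_contrast(rows, variant, coding)
  f <- fit_additive_hazards(rows, outcome, c(".g", covariates), "all")
  est <- estimate_with_se("MR", f$coefficients[[".g"]] / pt,
                          f$se[[".g"]] / pt)
  attr(est, "p_treated") <- pt
  est
}

#' Corrected-as-treated (CAT) GMTE estimate
#'
#' Difference of adjusted treated-vs-untreated hazard contrasts between
#' carrier strata (a difference-in-differences). Unbiased only without
#' treatment-outcome confounding.
#'
#' @inheritParams gmte_components
#' @return A `gmte_estimate` labelled `CAT`.
#' @export
cat_estimate <- function(rows, variant, outcome, coding = "dominant",
                         covariates = default_covariates(rows)) {
  rows <- add_contrast(rows, variant, coding)
  carrier <- rows$.g > 0
  cells <- table(carrier, rows$treated)
  if (length(cells) < 4L || any(cells == 0L))
    stop("empty genotype-by-treatment cell: CAT estimate undefined")
  fc <- fit_additive_hazards(rows[carrier, , drop = FALSE], outcome,
                             c("treated", covariates), "all")
  fn <- fit_additive_hazards(rows[!carrier, , drop = FALSE], outcome,
                             c("treated", covariates), "all")
  estimate_with_se("CAT",
                   fc$coefficients[["treated"]] - fn$coefficients[["treated"]],
                   sqrt(fc$se[["treated"]]^2 + fn$se[["treated"]]^2))
}

default_covariates <- function(rows) {
  intersect(c("age_first_rx", "sex", grep("^pc\\d+$", names(rows),
                                          value = TRUE)), names(rows))
}

#' Pharmacogenetic assumption checks
#'
#' Tests the identification assumptions: (i) genotype does not predict
#' treatment (chi-square test of the genotype-by-treated table) and (ii)
#' genotype is not associated with measured covariates (per-covariate
#' regression on allele dosage). Constant covariates are skipped with a
#' note.
#'
#' @inheritParams gmte_components
#' @param alpha Significance level for the pass/fail flag.
#' @return `data.frame(check, statistic, p, pass, note)`.
#' @export
assumption_checks <- function(rows, variant,
                              covariates = default_covariates(rows),
                              alpha = 0.05) {
  g <- rows[[variant]]
  ok <- !is.na(g)
  res <- list()
  tab <- table(factor(g[ok]), rows$treated[ok])
  if (nrow(tab) >= 2L && ncol(tab) >= 2L) {
    ct <- suppressWarnings(stats::chisq.test(tab))
    res[[1]] <- data.frame(check = "genotype_vs_treatment",
                           statistic = unname(ct$statistic), p = ct$p.value,
                           pass = ct$p.value > alpha, note = "")
  } else {
    res[[1]] <- data.frame(check = "genotype_vs_treatment", statistic = NA,
                           p = NA, pass = NA,
                           note = "skipped: degenerate table")
  }
  for (cv in covariates) {
    x <- rows[[cv]][ok]
    if (length(unique(x[!is.na(x)])) < 2L) {
      res[[length(res) + 1]] <- data.frame(
        check = paste0("genotype_vs_", cv), statistic = NA, p = NA,
        pass = NA, note = "skipped: constant covariate")
      next
    }
    sm <- summary(stats::lm(x ~ g[ok]))$coefficients
    res[[length(res) + 1]] <- data.frame(
      check = paste0("genotype_vs_", cv), statistic = sm[2, "t value"],
      p = sm[2, "Pr(>|t|)"], pass = sm[2, "Pr(>|t|)"] > alpha, note = "")
  }
  do.call(rbind, res)
}

#' Inverse-variance-weighted combination with heterogeneity testing
#'
#' Cochran's Q on a candidate set of estimates; if the set is mutually
#' consistent (Q p-value above `alpha`) the estimates are combined with
#' inverse-variance weights (`variance = 1/sum(w)`). The selection rule
#' prefers the largest combinable set among the robust estimators
#' `{RGMTE, MR, CAT}`, then pairs in that order of robustness, falling back
#' to RGMTE alone. Pairwise Q statistics for every supplied pair are
#' reported for audit.
#'
#' @param estimates List of `gmte_estimate` objects (or a data.frame with
#'   `label`, `estimate`, `se`).
#' @param alpha Heterogeneity significance level.
#' @return List with `combined` (a `gmte_estimate`), `selection` (labels
#'   combined), `q_table` (pairwise and selected-set Q), and `note`.
#' @export
combine_ivw <- function(estimates, alpha = 0.05) {
  df <- if (is.data.frame(estimates)) estimates else estimates_df(estimates)
  stopifnot(all(c("label", "estimate", "se") %in% names(df)))
  if (anyDuplicated(df$label)) stop_config("duplicate estimate labels")
  rownames(df) <- df$label

  qstat <- function(labels) {
    e <- df[labels, "estimate"]; w <- 1 / df[labels, "se"]^2
    mu <- sum(w * e) / sum(w)
    Q <- sum(w * (e - mu)^2)
    k <- length(labels) - 1L
    c(Q = Q, df = k, p = stats::pchisq(Q, k, lower.tail = FALSE))
  }
  ivw <- function(labels) {
    w <- 1 / df[labels, "se"]^2
    estimate_with_se(paste0("combined(", paste(labels, collapse = "+"), ")"),
                     sum(w * df[labels, "estimate"]) / sum(w),
                     sqrt(1 / sum(w)))
  }

  pairs <- if (nrow(df) >= 2L) utils::combn(df$label, 2L, simplify = FALSE)
  else list()
  q_table <- do.call(rbind, lapply(pairs, function(pr) {
    q <- qstat(pr)
    data.frame(set = paste(pr, collapse = "+"), Q = q[["Q"]],
               df = q[["df"]], p = q[["p"]], stringsAsFactors = FALSE)
  }))

  if (nrow(df) == 1L) {
    return(list(combined = estimate_with_se(df$label[1], df$estimate[1],
                                            df$se[1]),
                selection = df$label[1], q_table = q_table,
                note = "single estimate: passthrough, nothing to combine"))
  }

  candidates <- list(c("RGMTE", "MR", "CAT"), c("RGMTE", "MR"),
                     c("RGMTE", "CAT"), c("MR", "CAT"))
  candidates <- Filter(function(s) all(s %in% df$label), candidates)
  note <- ""
  for (set in candidates) {
    q <- qstat(set)
    if (q[["p"]] > alpha) {
      q_table <- rbind(q_table, data.frame(
        set = paste0("[selected] ", paste(set, collapse = "+")),
        Q = q[["Q"]], df = q[["df"]], p = q[["p"]]))
      return(list(combined = ivw(set), selection = set, q_table = q_table,
                  note = note))
    }
  }
  ## heterogeneous: report the most robust single estimator
  fallback <- if ("RGMTE" %in% df$label) "RGMTE" else
    df$label[which.min(df$se)]
  list(combined = estimate_with_se(fallback, df[fallback, "estimate"],
                                   df[fallback, "se"]),
       selection = fallback, q_table = q_table,
       note = "heterogeneous estimates (Q p <= alpha): no combination; components reported separately")
}

#' Run the full TWIST analysis for one variant and outcome
#'
#' Computes the five genetically-moderated treatment effect estimators
#' (GMTE1, GMTE0, RGMTE, MR, CAT) on additive-hazards fits, runs the
#' assumption checks, tests heterogeneity, and selects/combines the mutually
#' consistent robust estimators. Records carrier patient-years among the
#' treated and the treated event count for downstream impact translation.
#'
#' @inheritParams gmte_components
#' @param estimators Which estimators to compute/combine (GMTE1, GMTE0 and
#'   RGMTE are always computed).
#' @param alpha Heterogeneity level for [combine_ivw()].
#' @return Object of class `gmte_suite`.
#' @export
run_twist <- function(rows, variant, outcome, coding = "dominant",
                      covariates = default_covariates(rows),
                      estimators = c("GMTE1", "GMTE0", "RGMTE", "MR", "CAT"),
                      alpha = 0.05) {
  comp <- gmte_components(rows, variant, outcome, coding, covariates)
  ests <- list(GMTE1 = comp$GMTE1, GMTE0 = comp$GMTE0, RGMTE = comp$RGMTE)
  notes <- character()
  if ("MR" %in% estimators)
    ests$MR <- mr_estimate(rows, variant, outcome, coding, covariates)
  if ("CAT" %in% estimators) {
    ests$CAT <- tryCatch(
      cat_estimate(rows, variant, outcome, coding, covariates),
      error = function(e) {
        notes <<- c(notes, paste("CAT unavailable:", conditionMessage(e)))
        NULL
      })
    if (is.null(ests$CAT)) ests$CAT <- NULL
  }
  checks <- assumption_checks(rows, variant, covariates)
  comb <- combine_ivw(ests[intersect(names(ests),
                                     c("RGMTE", "MR", "CAT"))], alpha)
  gmte0_null <- comp$GMTE0$p > 0.05
  if (!gmte0_null)
    notes <- c(notes, paste(
      "GMTE0 is non-null (p <= 0.05): direct genotype effect suspected;",
      "treat MR- and GMTE1-based conclusions with caution"))

  ## carrier patient-years and events among the treated (incident set)
  rows_c <- add_contrast(rows, variant, coding)
  pc <- paste0(outcome, "_prior")
  tr <- rows_c$treated == 1L & !is.na(rows_c$.g) &
    (if (pc %in% names(rows_c)) rows_c[[pc]] != 1L else TRUE)
  carrier_py <- sum(rows_c[[paste0(outcome, "_time")]][tr & rows_c$.g > 0],
                    na.rm = TRUE)
  treated_events <- sum(rows_c[[paste0(outcome, "_event")]][tr], na.rm = TRUE)

  structure(list(
    variant = variant, outcome = outcome, coding = coding,
    covariates = covariates,
    estimates = ests, estimates_table = estimates_df(ests),
    combined = comb$combined, selection = comb$selection,
    q_table = comb$q_table,
    assumption_checks = checks, gmte0_null = gmte0_null,
    carrier_patient_years = carrier_py,
    treated_events = treated_events,
    fits = comp$fits, notes = c(notes, if (nzchar(comb$note)) comb$note)),
    class = "gmte_suite")
}

#' @export
print.gmte_suite <- function(x, ...) {
  cat(sprintf("TWIST GMTE analysis: %s (%s coding) on outcome '%s'\n",
              x$variant, x$coding, x$outcome))
  cat(sprintf("  treated events %d, carrier patient-years %.0f\n",
              x$treated_events, x$carrier_patient_years))
  cat("\nEstimates (per-year hazard differences):\n")
  for (e in x$estimates) print(e)
  cat("\nHeterogeneity (Cochran Q):\n")
  if (!is.null(x$q_table) && nrow(x$q_table)) {
    qt <- x$q_table
    qt$Q <- round(qt$Q, 3); qt$p <- signif(qt$p, 3)
    print(qt, row.names = FALSE)
  }
  cat("\nSelected: ", paste(x$selection, collapse = "+"), "\n", sep = "")
  print(x$combined)
  cat(sprintf("\nGMTE0 null (no direct genotype effect in untreated): %s\n",
              if (isTRUE(x$gmte0_null)) "yes (p > 0.05)" else "NO"))
  cat("\nAssumption checks:\n")
  ac <- x$assumption_checks
  ac$statistic <- signif(ac$statistic, 3); ac$p <- signif(ac$p, 3)
  print(ac, row.names = FALSE)
  for (n in x$notes) cat("note: ", n, "\n", sep = "")
  invisible(x)
}
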