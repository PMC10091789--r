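#' Code genotype dosages into a contrast design
#'
#' @param dosage Integer minor-allele dosages (0/1/2, `NA` allowed).
#' @param model `"genotypic"` (het and hom-minor indicators against the
#'   common-homozygote reference), `"dominant"` (carrier indicator) or
#'   `"additive"` (dosage).
#' @param labels Optional genotype labels (length 3, e.g. `c("CC","CT","TT")`)
#'   used to name the contrasts.
#' @return Numeric matrix with one column per contrast, or `NULL` (with a
#'   warning) for a monomorphic variant.
#' @export
code_genotype <- function(dosage, model = c("genotypic", "dominant",
                                            "additive"),
                          labels = NULL) {
  model <- match.arg(model)
  if (length(unique(dosage[!is.na(dosage)])) < 2L) {
    warning("monomorphic variant: skipped", call. = FALSE)
    return(NULL)
  }
  lab <- labels %||% c("ref", "het", "hom")
  out <- switch(model,
    genotypic = cbind(stats::setNames(
      data.frame(as.numeric(dosage == 1L), as.numeric(dosage == 2L)),
      c(paste0(lab[2], "_vs_", lab[1]), paste0(lab[3], "_vs_", lab[1])))),
    dominant = stats::setNames(data.frame(as.numeric(dosage >= 1L)),
                               paste0("carrier_vs_", lab[1])),
    additive = stats::setNames(data.frame(as.numeric(dosage)),
                               "per_allele"))
  m <- as.matrix(out)
  ## drop empty contrast columns (e.g. no hom-minor present)
  m[, colSums(m, na.rm = TRUE) > 0 | model == "additive", drop = FALSE]
}

genotype_labels <- function(panel, variant) {
  i <- match(variant, panel$rsid)
  if (is.na(i)) return(NULL)
  ea <- panel$effect_allele[i]; oa <- panel$other_allele[i]
  c(paste0(oa, oa), paste0(oa, ea), paste0(ea, ea))
}

#' Cox proportional-hazards fit for one variant and outcome
#'
#' On-treatment association scan: treated patients without a prior diagnosis
#' of the outcome, Cox model with Efron tie handling, adjusted for age at
#' first prescription, sex and genetic principal components (the time axis
#' itself models length of treatment). Returns one row per genotype
#' contrast in the layout of a published association table.
#'
#' @param rows Analysis table.
#' @param variant Variant column name.
#' @param outcome Outcome label (`switch` uses the switching columns).
#' @param model Genotype coding model.
#' @param covariates Adjustment columns.
#' @param extra_covariates Additional adjustment columns (e.g.
#'   `co_antihypertensive` for the co-medication sensitivity analysis).
#' @param panel Optional variant panel for allele labels.
#' @param robust Use robust (sandwich) standard errors.
#' @return `data.frame` with columns `rsid, outcome, contrast, n_at_risk,
#'   n_events, hr, ci_low, ci_high, p, flagged`.
#' @export
fit_cox <- function(rows, variant, outcome, model = "genotypic",
                    covariates = default_covariates(rows),
                    extra_covariates = character(),
                    panel = NULL, robust = FALSE) {
  tc <- if (outcome == "switch") "switch_time" else paste0(outcome, "_time")
  ec <- if (outcome == "switch") "switch_event" else paste0(outcome, "_event")
  pc <- paste0(outcome, "_prior")
  keep <- rows$treated == 1L & !is.na(rows[[variant]]) &
    !is.na(rows[[tc]]) & !is.na(rows[[ec]])
  if (outcome != "switch" && pc %in% names(rows))
    keep <- keep & rows[[pc]] != 1L
  sub <- rows[keep, , drop = FALSE]
  labels <- if (!is.null(panel)) genotype_labels(panel, variant) else NULL
  design <- code_genotype(sub[[variant]], model, labels)
  if (is.null(design)) return(NULL)
  covs <- c(covariates, extra_covariates)
  covs <- covs[vapply(covs, function(cv)
    length(unique(sub[[cv]][!is.na(sub[[cv]])])) > 1L, logical(1))]
  dat <- data.frame(.time = sub[[tc]], .event = sub[[ec]], design,
                    sub[, covs, drop = FALSE], check.names = FALSE)
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]

  ## >=2 events per contrast level (partial-likelihood stability)
  contrasts <- colnames(design)
  ev_by <- vapply(contrasts, function(cn)
    sum(dat$.event[dat[[cn]] > 0]), numeric(1))
  if (sum(dat$.event) < 2L || any(ev_by < 2L)) {
    warning("fewer than 2 events in a contrast level for ", variant, "/",
            outcome, ": flagged", call. = FALSE)
    return(data.frame(rsid = variant, outcome = outcome,
                      contrast = contrasts, n_at_risk = nrow(dat),
                      n_events = ev_by, hr = NA, ci_low = NA, ci_high = NA,
                      p = NA, flagged = TRUE, row.names = NULL))
  }
  rhs <- paste(sprintf("`%s`", c(contrasts, covs)), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs))
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron", robust = robust),
    warning = function(w) {
      flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)
  co <- sm$coefficients[contrasts, , drop = FALSE]
  se_col <- if (robust) "robust se" else "se(coef)"
  if (any(abs(co[, "coef"]) > 15))
    stop("possible separation in variable ",
         contrasts[which.max(abs(co[, "coef"]))])
  ## group sizes: N and events for the non-reference genotype group
  grp_n <- vapply(contrasts, function(cn) sum(dat[[cn]] > 0), numeric(1))
  data.frame(rsid = variant, outcome = outcome, contrast = contrasts,
             n_at_risk = if (model == "additive") nrow(dat) else grp_n,
             n_events = ev_by,
             hr = exp(co[, "coef"]),
             ci_low = exp(co[, "coef"] - 1.96 * co[, se_col]),
             ci_high = exp(co[, "coef"] + 1.96 * co[, se_col]),
             p = co[, "Pr(>|z|)"], flagged = flagged, row.names = NULL)
}

#' Per-genotype event counts and percentages
#'
#' Tabulates, for one variant and outcome among treated incident-eligible
#' patients, the genotype-group size `N`, the number with a diagnosis `n`,
#' and `percent = 100 n / N` rounded to `digits` decimal places (2 for the
#' switching outcome, 1 otherwise, matching the conventional precision of
#' published association tables). Groups with `N = 0` are omitted.
#'
#' @inheritParams fit_cox
#' @param digits Rounding for the percentage column.
#' @return `data.frame(rsid, outcome, genotype, N, n, percent)`.
#' @export
count_events <- function(rows, variant, outcome, panel = NULL,
                         digits = if (outcome == "switch") 2L else 1L) {
  ec <- if (outcome == "switch") "switch_event" else paste0(outcome, "_event")
  pc <- paste0(outcome, "_prior")
  keep <- !is.na(rows[[variant]]) & !is.na(rows[[ec]])
  if ("treated" %in% names(rows)) keep <- keep & rows$treated == 1L
  if (outcome != "switch" && pc %in% names(rows))
    keep <- keep & rows[[pc]] != 1L
  sub <- rows[keep, , drop = FALSE]
  labels <- if (!is.null(panel)) genotype_labels(panel, variant) else
    c("0", "1", "2")
  g <- factor(sub[[variant]], levels = 0:2, labels = labels)
  N <- as.vector(table(g))
  n <- as.vector(tapply(sub[[ec]], g, sum, default = 0))
  out <- data.frame(rsid = variant, outcome = outcome, genotype = labels,
                    N = N, n = n,
                    percent = round(100 * n / N, digits),
                    stringsAsFactors = FALSE)
  out[out$N > 0L, , drop = FALSE]
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()], with the family size
#' `m` settable explicitly (the scan uses the panel of variants within one
#' outcome as the family).
#'
#' @param p P-values in \[0, 1\] (`NA` allowed, excluded from the family).
#' @param m Family size; defaults to the number of non-missing p-values.
#' @return Adjusted p-values, monotone and capped at 1.
#' @export
bh_adjust <- function(p, m = sum(!is.na(p))) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_config("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH", n = max(m, sum(!is.na(p))))
}

#' Per-variant, per-outcome Cox association scan
#'
#' Orchestrates [code_genotype()], [fit_cox()], [count_events()] and
#' [bh_adjust()] over the variant panel and outcome list, with the three
#' sensitivity configurations: co-medication adjustment, dCCB drug subset
#' (amlodipine-only vs other), and unrelated-only.
#'
#' @param rows Analysis table.
#' @param panel Variant panel.
#' @param outcomes Outcome labels (may include `"switch"`).
#' @param model Genotype coding model, or `NULL` to use each variant's
#'   panel-specified `inheritance_model`.
#' @param co_med_adjust Adjust for co-prescribed antihypertensives.
#' @param drug_subset `"all"`, `"amlodipine"` or `"other"`.
#' @param unrelated_only Restrict to `unrelated_flag == 1`.
#' @param covariates Adjustment columns.
#' @return `data.frame` of Cox results joined with genotype-group counts and
#'   a per-outcome BH-adjusted `fdr_p` column.
#' @export
scan_all <- function(rows, panel = default_variant_panel(),
                     outcomes = c(OUTCOME_LABELS, "switch"),
                     model = NULL, co_med_adjust = FALSE,
                     drug_subset = c("all", "amlodipine", "other"),
                     unrelated_only = FALSE,
                     covariates = default_covariates(rows)) {
  drug_subset <- match.arg(drug_subset)
  if (unrelated_only) rows <- rows[rows$unrelated_flag == 1L, , drop = FALSE]
  if (drug_subset != "all" && "amlodipine_only" %in% names(rows)) {
    keep <- rows$treated != 1L |
      (rows$amlodipine_only %in% (drug_subset == "amlodipine"))
    rows <- rows[keep, , drop = FALSE]
  }
  extra <- if (co_med_adjust) "co_antihypertensive" else character()
  if (co_med_adjust && "co_antihypertensive" %in% names(rows))
    rows$co_antihypertensive <- as.integer(rows$co_antihypertensive %in% TRUE)

  res <- list()
  for (oc in outcomes) {
    for (i in seq_len(nrow(panel))) {
      v <- panel$rsid[i]
      if (!v %in% names(rows)) next
      mod <- model %||% panel$inheritance_model[i]
      if (mod == "genotypic" &&
          sum(rows[[v]] == 2L, na.rm = TRUE) == 0L) mod <- "dominant"
      r <- suppressWarnings(
        fit_cox(rows, v, oc, model = mod, covariates = covariates,
                extra_covariates = extra, panel = panel))
      if (is.null(r)) next
      r$percent <- round(100 * r$n_events / r$n_at_risk, 1)
      res[[length(res) + 1]] <- r
    }
  }
  if (!length(res)) return(data.frame())
  out <- do.call(rbind, res)
  out$covariate_set <- paste(c(covariates, extra), collapse = "+")
  split_out <- split(out, out$outcome)
  out <- do.call(rbind, lapply(split_out, function(d) {
    d$fdr_p <- bh_adjust(d$p)
    d
  }))
  rownames(out) <- NULL
  out
}
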