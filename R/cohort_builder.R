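RECORD_SCHEMAS <- list(
  prescriptions = c("patient_id", "issue_date", "code_system", "code"),
  diagnoses     = c("patient_id", "event_date", "vocabulary", "code"),
  genotypes     = c("patient_id", "rsid", "dosage"),
  covariates    = c("patient_id", "sex", "yob")
)

#' Parse and validate a raw record table
#'
#' Reads one of the tab-delimited study inputs, enforces its schema, types
#' dates, and rejects malformed rows (unparseable dates, empty patient ids
#' and, for prescriptions, issue dates outside the GP data window).
#' Malformed rows are counted and reported; the run aborts if more than
#' `max_malformed` of rows are bad.
#'
#' @param path File path.
#' @param type One of `"prescriptions"`, `"diagnoses"`, `"genotypes"`,
#'   `"covariates"`.
#' @param gp_window Two dates bounding valid prescription issue dates.
#' @param max_malformed Maximum tolerated malformed-row fraction.
#' @return A typed `data.table`.
#' @export
parse_records <- function(path, type = names(RECORD_SCHEMAS),
                          gp_window = as.Date(c("1990-01-01", "2017-08-31")),
                          max_malformed = 0.01) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", colClasses = list(
    character = "patient_id"), na.strings = c("", "NA"))
  need <- RECORD_SCHEMAS[[type]]
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(dt) == 0L) {
    warning("empty ", type, " file: ", basename(path), call. = FALSE)
    return(dt)
  }
  bad <- is.na(dt$patient_id) | dt$patient_id == ""
  date_col <- switch(type, prescriptions = "issue_date",
                     diagnoses = "event_date", NULL)
  if (!is.null(date_col)) {
    d <- as.Date(as.character(dt[[date_col]]), format = "%Y-%m-%d")
    bad <- bad | is.na(d)
    if (type == "prescriptions")
      bad <- bad | (!is.na(d) & (d < gp_window[1] | d > gp_window[2]))
    data.table::set(dt, j = date_col, value = d)
  }
  if (type == "genotypes") bad <- bad | !dt$dosage %in% 0:2
  if (any(bad)) {
    frac <- mean(bad)
    if (frac > max_malformed)
      stop(sprintf("%.1f%% malformed rows in %s (limit %.1f%%)",
                   100 * frac, basename(path), 100 * max_malformed))
    warning(sprintf("%d malformed row(s) removed from %s", sum(bad),
                    basename(path)), call. = FALSE)
    dt <- dt[!bad]
  }
  dt[]
}

#' Attach drug classes to prescription records
#'
#' @param prescriptions Prescription records ([parse_records()]).
#' @param class_map Code-to-class lookup ([default_drug_classes()]).
#' @return The records with a `drug_class` column; unknown codes map to
#'   `"other"` (count reported via `message`).
#' @export
classify_prescriptions <- function(prescriptions,
                                   class_map = default_drug_classes()) {
  rx <- data.table::as.data.table(prescriptions)
  if ("drug_class" %in% names(rx)) return(rx)
  cm <- data.table::as.data.table(class_map)[, c("code_system", "code",
                                                 "drug_class")]
  rx <- cm[rx, on = c("code_system", "code")]
  n_unknown <- sum(is.na(rx$drug_class))
  if (n_unknown)
    message(n_unknown, " prescription(s) with unmapped codes -> class 'other'")
  rx[is.na(drug_class), drug_class := "other"]
  rx[]
}

#' Build dCCB exposure episodes
#'
#' One episode per patient with at least `min_prescriptions` dCCB
#' prescriptions: first and last dCCB issue dates, prescriptions per year,
#' the GP-prescribing censoring date (deduction date where available, else
#' the administrative end of prescribing data), a co-medication flag (any
#' non-dCCB antihypertensive issued within the episode window) and an
#' amlodipine-only flag.
#'
#' @param prescriptions Prescription records.
#' @param class_map Drug-class lookup.
#' @param deductions Optional `data.frame(patient_id, deduction_date)`.
#' @param gp_censor Administrative end of GP prescribing data.
#' @param min_prescriptions Minimum dCCB scripts to enter the cohort.
#' @return A `data.table` of exposure episodes.
#' @export
build_exposure <- function(prescriptions, class_map = default_drug_classes(),
                           deductions = NULL,
                           gp_censor = as.Date("2016-05-31"),
                           min_prescriptions = 1L) {
  rx <- classify_prescriptions(prescriptions, class_map)
  dccb <- rx[drug_class %in% DCCB_CLASSES]
  if (nrow(dccb) == 0L)
    return(data.table::data.table(
      patient_id = character(), first_rx_date = as.Date(character()),
      last_rx_date = as.Date(character()), censor_date = as.Date(character()),
      n_rx = integer(), prescriptions_per_year = numeric(),
      co_antihypertensive = logical(), amlodipine_only = logical()))
  ep <- dccb[, .(
    first_rx_date = min(issue_date),
    last_rx_date = max(issue_date),
    n_rx = .N,
    amlodipine_only = all(drug_class == "dccb_amlodipine")
  ), by = patient_id][n_rx >= min_prescriptions]
  ep[, prescriptions_per_year :=
       n_rx / pmax(years_between(first_rx_date, last_rx_date), 1 / DAYS_PER_YEAR)]
  ## co-prescribed antihypertensive inside [first_rx, last_rx]
  co <- rx[drug_class %in% ANTIHYPERTENSIVE_CLASSES,
           .(patient_id, issue_date)][ep, on = "patient_id", nomatch = NULL][
             issue_date >= first_rx_date & issue_date <= last_rx_date,
             unique(patient_id)]
  ep[, co_antihypertensive := patient_id %in% co]
  ep[, censor_date := gp_censor]
  if (!is.null(deductions)) {
    ded <- data.table::as.data.table(deductions)[!is.na(deduction_date)]
    ep[ded, on = "patient_id",
       censor_date := pmin(censor_date, as.Date(i.deduction_date))]
  }
  stopifnot(all(ep$first_rx_date <= ep$last_rx_date))
  data.table::setorder(ep, patient_id)[]
}

#' Ascertain one outcome per patient
#'
#' For each patient with an origin date (first dCCB prescription for treated
#' patients, study entry for untreated), flags a *prior* diagnosis (on or
#' before the origin), the first *incident* diagnosis (strictly after the
#' origin and on or before the effective censor date) and the follow-up time
#' in years to event or censoring. The effective censor date is the minimum
#' of the patient's censor date and the hospital-record `horizon`.
#'
#' @param cohort `data.frame(patient_id, origin_date, censor_date)`.
#' @param diagnoses Diagnosis records ([parse_records()]).
#' @param outcome One of `r paste(OUTCOME_LABELS, collapse=", ")`.
#' @param outcome_map Code-to-label lookup ([default_outcome_codes()]).
#' @param horizon Administrative horizon of the diagnosis source.
#' @return `data.table(patient_id, prior, event, time_years)`.
#' @export
ascertain_outcome <- function(cohort, diagnoses, outcome,
                              outcome_map = default_outcome_codes(),
                              horizon = as.Date("2020-09-30")) {
  if (!outcome %in% OUTCOME_LABELS)
    stop_config("parameter error: unknown outcome label '", outcome, "'")
  co <- data.table::as.data.table(cohort)[, .(patient_id, origin_date,
                                              censor_date)]
  om <- data.table::as.data.table(outcome_map)[outcome_label == outcome]
  dx <- data.table::as.data.table(diagnoses)
  dx <- om[, .(vocabulary, code)][dx, on = c("vocabulary", "code"),
                                  nomatch = NULL]
  co[, censor_eff := pmin(censor_date, horizon)]
  bad <- co$censor_eff <= co$origin_date
  if (any(bad)) {
    warning(sum(bad), " patient(s) with censor date on/before origin dropped",
            call. = FALSE)
    co <- co[!bad]
  }
  agg <- dx[co, on = "patient_id", nomatch = NULL][, .(
    prior = any(event_date <= origin_date),
    first_event = suppressWarnings(
      min(event_date[event_date > origin_date & event_date <= censor_eff]))
  ), by = patient_id]
  out <- agg[co, on = "patient_id"]
  out[is.na(prior), prior := FALSE]
  out[, event := !is.na(first_event) & is.finite(first_event)]
  out[, time_years := data.table::fifelse(
    event, years_between(origin_date, first_event),
    years_between(origin_date, censor_eff))]
  out[, .(patient_id, prior = as.integer(prior), event = as.integer(event),
          time_years)]
}

#' Detect switching from dCCB to an alternative antihypertensive
#'
#' A switch is the first issue of a non-dCCB antihypertensive after the
#' first dCCB prescription such that no further dCCB prescription occurs
#' within `gap_days` after that issue (co-therapy alongside continuing dCCB
#' is not a switch). Time is measured in years from the first dCCB
#' prescription; non-switchers are censored at the episode censor date.
#'
#' @param prescriptions Prescription records.
#' @param episodes Output of [build_exposure()].
#' @param class_map Drug-class lookup.
#' @param gap_days dCCB-free gap that qualifies an issue as a switch.
#' @return `data.table(patient_id, switch_event, switch_time)`.
#' @export
detect_switch <- function(prescriptions, episodes,
                          class_map = default_drug_classes(),
                          gap_days = 90) {
  rx <- classify_prescriptions(prescriptions, class_map)
  ep <- data.table::as.data.table(episodes)
  dccb <- rx[drug_class %in% DCCB_CLASSES, .(patient_id, issue_date)]
  cand <- rx[drug_class %in% ANTIHYPERTENSIVE_CLASSES,
             .(patient_id, issue_date)][
               ep[, .(patient_id, first_rx_date, censor_date)],
               on = "patient_id", nomatch = NULL][
                 issue_date > first_rx_date & issue_date <= censor_date]
  res <- ep[, .(patient_id, first_rx_date, censor_date)]
  res[, `:=`(switch_event = 0L,
             switch_time = years_between(first_rx_date, censor_date))]
  if (nrow(cand)) {
    data.table::setorder(cand, patient_id, issue_date)
    data.table::setorder(dccb, patient_id, issue_date)
    dccb_split <- split(as.numeric(dccb$issue_date), dccb$patient_id)
    hit <- cand[, {
      nd <- dccb_split[[patient_id[1]]]
      a <- as.numeric(issue_date)
      pos <- findInterval(a, nd) + 1L          # first dCCB strictly after a
      nxt <- c(nd, Inf)[pmin(pos, length(nd) + 1L)]
      ok <- nxt - a > gap_days
      if (any(ok)) .(switch_date = issue_date[which(ok)[1]]) else
        .(switch_date = as.Date(NA))
    }, by = patient_id][!is.na(switch_date)]
    res[hit, on = "patient_id",
        `:=`(switch_event = 1L,
             switch_time = years_between(first_rx_date, i.switch_date))]
  }
  res[, .(patient_id, switch_event, switch_time)]
}

#' Restrict to patients with heart disease before treatment
#'
#' Subsets analysis rows to patients whose prior-disease flag is set for any
#' of `labels` (MI/angina and heart failure by default), and adds a
#' composite endpoint, "first of any listed outcome", with
#' `composite_event`/`composite_time` columns (minimum of the component
#' event times; censored at the minimum component censor time otherwise).
#' Prior-disease patients are deliberately retained for the composite.
#'
#' @param rows Analysis table ([assemble_analysis_table()]).
#' @param labels Outcome labels defining "heart disease".
#' @return The subset with composite columns.
#' @export
subgroup_prior_disease <- function(rows, labels = c("chd", "hf")) {
  pri <- paste0(labels, "_prior")
  pri <- pri[pri %in% names(rows)]
  if (!length(pri)) stop_config("no prior-disease columns for labels given")
  keep <- rowSums(as.matrix(rows[, pri, drop = FALSE]) == 1L, na.rm = TRUE) > 0
  sub <- rows[keep, , drop = FALSE]
  evc <- paste0(labels, "_event")
  tmc <- paste0(labels, "_time")
  ev <- as.matrix(sub[, evc, drop = FALSE]) == 1L
  tm <- as.matrix(sub[, tmc, drop = FALSE])
  etime <- ifelse(ev, tm, Inf)
  has <- rowSums(ev, na.rm = TRUE) > 0
  sub$composite_event <- as.integer(has)
  sub$composite_time <- ifelse(has,
                               apply(etime, 1, min, na.rm = TRUE),
                               apply(tm, 1, min, na.rm = TRUE))
  sub
}

#' Drop listed patients (e.g. one of each related pair)
#'
#' @param rows Analysis table.
#' @param ids Patient ids to exclude.
#' @return `rows` without the listed patients.
#' @export
apply_exclusions <- function(rows, ids) {
  rows[!rows$patient_id %in% ids, , drop = FALSE]
}

#' Assemble the per-patient analysis table
#'
#' Joins exposure episodes, outcome ascertainment, switching, genotypes and
#' covariates into one row per patient. Treated rows time from the first
#' dCCB prescription; untreated comparators (never prescribed any dCCB) time
#' from study entry, taken as their first record date. Patients missing a
#' genotype stay in the table with `NA` dosage for that variant only (each
#' scan drops them variant-wise).
#'
#' @param prescriptions,diagnoses,genotypes,covariates Parsed record tables.
#' @param panel Variant panel ([default_variant_panel()]).
#' @param outcomes Outcome labels to ascertain.
#' @param class_map,outcome_map Lookup tables.
#' @param gp_censor End of GP prescribing data.
#' @param horizon Hospital-record horizon for outcome ascertainment.
#' @param gap_days Switch-definition gap.
#' @param min_prescriptions Minimum dCCB scripts for the treated cohort.
#' @param exclusions Optional patient ids marked related (`unrelated_flag`
#'   is set to 0 for them; use [apply_exclusions()] to drop).
#' @return A `data.frame`, one row per patient.
#' @export
assemble_analysis_table <- function(prescriptions, diagnoses, genotypes,
                                    covariates,
                                    panel = default_variant_panel(),
                                    outcomes = OUTCOME_LABELS,
                                    class_map = default_drug_classes(),
                                    outcome_map = default_outcome_codes(),
                                    gp_censor = as.Date("2016-05-31"),
                                    horizon = as.Date("2020-09-30"),
                                    gap_days = 90,
                                    min_prescriptions = 1L,
                                    exclusions = NULL) {
  cov <- data.table::as.data.table(covariates)
  if (anyDuplicated(cov$patient_id))
    stop("data error: duplicate patient_id in covariates")
  rx <- classify_prescriptions(prescriptions, class_map)
  deductions <- if ("deduction_date" %in% names(cov))
    cov[, .(patient_id, deduction_date = as.Date(deduction_date))] else NULL
  ep <- build_exposure(rx, class_map, deductions, gp_censor,
                       min_prescriptions)

  ## origins: treated from first dCCB script, untreated from first record
  first_rec <- rx[, .(entry_date = min(issue_date)), by = patient_id]
  base <- merge(cov[, .(patient_id)], first_rec, by = "patient_id")
  dropped <- nrow(cov) - nrow(base)
  if (dropped) message(dropped, " patient(s) without any record dropped")
  base <- merge(base, ep[, .(patient_id, first_rx_date, censor_date)],
                by = "patient_id", all.x = TRUE)
  base[, treated := as.integer(!is.na(first_rx_date))]
  base[, origin_date := data.table::fifelse(treated == 1L, first_rx_date,
                                            entry_date)]
  if (is.null(deductions)) {
    base[treated == 0L, censor_date := gp_censor]
  } else {
    base <- merge(base, deductions, by = "patient_id", all.x = TRUE)
    base[treated == 0L,
         censor_date := pmin(gp_censor, deduction_date, na.rm = TRUE)]
    base[, deduction_date := NULL]
  }

  out <- base[, .(patient_id, treated, origin_date, censor_date)]
  for (oc in outcomes) {
    asc <- ascertain_outcome(out, diagnoses, oc, outcome_map, horizon)
    data.table::setnames(asc, c("prior", "event", "time_years"),
                         paste0(oc, c("_prior", "_event", "_time")))
    out <- merge(out, asc, by = "patient_id", all.x = TRUE)
  }
  sw <- detect_switch(rx, ep, class_map, gap_days)
  out <- merge(out, sw, by = "patient_id", all.x = TRUE)
  out <- merge(out, ep[, .(patient_id, co_antihypertensive, amlodipine_only,
                           prescriptions_per_year)],
               by = "patient_id", all.x = TRUE)

  ## genotypes wide; missing dosage stays NA for that variant only
  gt <- data.table::as.data.table(genotypes)[rsid %in% panel$rsid]
  gtw <- data.table::dcast(gt, patient_id ~ rsid, value.var = "dosage")
  out <- merge(out, gtw, by = "patient_id", all.x = TRUE)

  cov_keep <- cov[, intersect(c("patient_id", "sex", "yob", "age_entry",
                                grep("^pc\\d+$", names(cov), value = TRUE)),
                              names(cov)), with = FALSE]
  out <- merge(out, cov_keep, by = "patient_id", all.x = TRUE)
  if ("age_entry" %in% names(out)) {
    out[, age_first_rx := age_entry]
    out[, age_entry := NULL]
  } else {
    out[, age_first_rx :=
          as.integer(format(origin_date, "%Y")) - yob + 0.5]
  }
  out[, unrelated_flag := as.integer(!patient_id %in% (exclusions %||%
                                                         character()))]
  data.table::setDF(out)
  out
}

#' Rebuild an analysis table from a synthetic study bundle
#'
#' Convenience wrapper: parses the bundle written by [write_study()] (using
#' its `config.yaml` for the censoring dates) and assembles the analysis
#' table. The hospital horizon is set to the bundle's administrative censor
#' so follow-up matches the generating process.
#'
#' @param bundle_dir Directory containing the bundle.
#' @param ... Passed to [assemble_analysis_table()].
#' @return A `data.frame` (see [assemble_analysis_table()]).
#' @export
build_cohort <- function(bundle_dir, ...) {
  cfg <- yaml::read_yaml(file.path(bundle_dir, "config.yaml"))
  rx <- parse_records(file.path(bundle_dir, "prescriptions.tsv"),
                      "prescriptions")
  dx <- parse_records(file.path(bundle_dir, "diagnoses.tsv"), "diagnoses")
  gt <- parse_records(file.path(bundle_dir, "genotypes.tsv"), "genotypes")
  cov <- parse_records(file.path(bundle_dir, "covariates.tsv"), "covariates")
  panel <- default_variant_panel()
  panel <- panel[panel$rsid %in% unique(gt$rsid), , drop = FALSE]
  if (!nrow(panel))
    panel <- data.frame(rsid = unique(gt$rsid), gene = NA, effect_allele = "A",
                        other_allele = "B", maf = NA,
                        inheritance_model = "dominant")
  assemble_analysis_table(
    rx, dx, gt, cov, panel = panel,
    outcomes = intersect(c(cfg$causal_outcome,
                           names(cfg$null_outcome_hazards)), OUTCOME_LABELS),
    gp_censor = as.Date(cfg$admin_censor),
    horizon = as.Date(cfg$admin_censor), ...)
}
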