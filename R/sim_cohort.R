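#' Generate genotypes in Hardy-Weinberg proportions
#'
#' Draws minor-allele counts 0/1/2 with genotype frequencies
#' \eqn{(1-q)^2, 2q(1-q), q^2} for minor-allele frequency \eqn{q}
#' (equivalently Binomial(2, q), the Hardy-Weinberg structure).
#'
#' @param n Number of individuals.
#' @param maf Minor-allele frequency in \[0, 1\] (monomorphic 0 allowed).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return Integer vector of minor-allele dosages.
#' @export
gen_genotypes <- function(n, maf, seed = NULL) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) || maf < 0 || maf > 1)
    stop_config("parameter error: maf must be a single value in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(n, 2L, maf)
}

## genotype dosage -> hazard-model coding
code_dosage <- function(dosage, inheritance) {
  switch(inheritance,
         dominant  = as.numeric(dosage >= 1L),
         additive  = as.numeric(dosage),
         recessive = as.numeric(dosage == 2L),
         stop_config("unknown inheritance model: ", inheritance))
}

#' Generate the synthetic population (genotypes, treatment, covariates)
#'
#' Treatment is Bernoulli(`p_treated`) independent of genotype unless
#' `treat_geno_or != 1` (assumption-violation mode, odds ratio per effect
#' allele of the causal variant) or a confounder is configured. Sex, age at
#' entry (truncated normal), entry date (uniform over the accrual window)
#' and `n_pcs` standard-normal principal components are attached.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` (the population part of the simulation truth) with
#'   one column per panel variant plus `patient_id`, `entry_date`,
#'   `age_first_rx`, `sex` (1 = female), `treated`, `u` (confounder) and
#'   `pc1..pcK`.
#' @export
gen_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(config$n_patients)
  geno <- vapply(config$variant_mafs, function(q) gen_genotypes(n, q),
                 integer(n))
  colnames(geno) <- names(config$variant_mafs)
  g_causal <- geno[, config$causal_variant]

  u <- if (config$confounder$prevalence > 0)
    stats::rbinom(n, 1L, config$confounder$prevalence) else integer(n)
  if (config$treat_geno_or != 1 || config$confounder$treat_or != 1) {
    eta <- stats::qlogis(config$p_treated) +
      log(config$treat_geno_or) * g_causal +
      log(config$confounder$treat_or) * u
    treated <- stats::rbinom(n, 1L, stats::plogis(eta))
  } else {
    treated <- stats::rbinom(n, 1L, config$p_treated)
  }

  entry_offset <- floor(stats::runif(
    n, 0, as.numeric(config$last_entry - config$study_start) + 1))
  pcs <- matrix(stats::rnorm(n * config$n_pcs), n,
                dimnames = list(NULL, paste0("pc", seq_len(config$n_pcs))))
  pop <- data.frame(
    patient_id = sprintf("P%07d", seq_len(n)),
    entry_date = config$study_start + entry_offset,
    age_first_rx = rtruncnorm(n, config$first_rx_age_mean,
                              config$first_rx_age_sd,
                              config$first_rx_age_range[1],
                              config$first_rx_age_range[2]),
    sex = stats::rbinom(n, 1L, config$p_female),
    treated = treated,
    u = u,
    stringsAsFactors = FALSE)
  cbind(pop, pcs, as.data.frame(geno))
}

#' Generate event and censoring times under the additive-hazards model
#'
#' Each individual's hazard is
#' `h0 + beta_treat*T + beta_geno*G + beta_interact*G*T (+ confounder)`,
#' with G coded per `config$inheritance`. Event times are
#' Exponential(hazard); the observed time is the minimum of the event time,
#' GP-deduction dropout (Exponential(`dropout_rate`)) and the administrative
#' horizon implied by the entry date. Negative hazards are an error, never
#' silently truncated.
#'
#' @param pop Output of [gen_population()].
#' @param config The same [sim_config()].
#' @return `pop` with columns `hazard`, `event_time` (latent),
#'   `dropout_time` (latent), `admin_years`, `time` (observed, years),
#'   `event` (indicator) and `dropped` (deduction observed first).
#' @export
gen_event_times <- function(pop, config) {
  stopifnot(inherits(config, "sim_config"))
  g <- code_dosage(pop[[config$causal_variant]], config$inheritance)
  h <- config$baseline_hazard + config$beta_treat * pop$treated +
    config$beta_geno * g + config$beta_interact * g * pop$treated +
    config$confounder$hazard * pop$u
  if (any(h < 0)) {
    i <- which(h < 0)[1]
    stop_config(sprintf(
      "negative hazard %.3g/y for subgroup [%s, G=%g]: adjust coefficients",
      h[i], if (pop$treated[i] == 1) "treated" else "untreated", g[i]))
  }
  n <- nrow(pop)
  pop$hazard <- h
  pop$event_time <- stats::rexp(n) / h                       # h = 0 -> Inf
  pop$dropout_time <- if (config$dropout_rate > 0)
    stats::rexp(n) / config$dropout_rate else rep(Inf, n)
  pop$admin_years <- years_between(pop$entry_date, config$admin_censor)
  cens <- pmin(pop$dropout_time, pop$admin_years)
  pop$time <- pmin(pop$event_time, cens)
  pop$event <- as.integer(pop$event_time <= cens)
  pop$dropped <- as.integer(pop$event == 0L & pop$dropout_time < pop$admin_years)
  pop
}

#' Simulate the full ground truth in one call
#'
#' Seeds the RNG from `config$rng_seed`, then runs [gen_population()] and
#' [gen_event_times()]. Identical configurations give identical output.
#'
#' @param config A [sim_config()].
#' @return The truth `data.frame` with the configuration attached as
#'   attribute `"config"`.
#' @export
simulate_truth <- function(config) {
  set.seed(config$rng_seed)
  truth <- gen_event_times(gen_population(config), config)
  attr(truth, "config") <- config
  truth
}

#' Convert simulation truth to an analysis table
#'
#' Fast in-memory path from [simulate_truth()] to the per-patient analysis
#' rows consumed by the scan and TWIST stages, bypassing file round-trips.
#' Equivalent (to day resolution) to writing the record bundle with
#' [write_study()] and rebuilding it with [build_cohort()]; the equivalence
#' is exercised in the test suite.
#'
#' @param truth Output of [simulate_truth()].
#' @param config Configuration; defaults to the one attached to `truth`.
#' @return A `data.frame` with genotype dosages, covariates and
#'   `<outcome>_prior/_event/_time` columns for the causal outcome.
#' @export
as_analysis_table <- function(truth, config = attr(truth, "config")) {
  stopifnot(inherits(config, "sim_config"))
  out <- truth[, c("patient_id", "treated", "age_first_rx", "sex",
                   grep("^pc\\d+$", names(truth), value = TRUE),
                   names(config$variant_mafs)), drop = FALSE]
  oc <- config$causal_outcome
  out[[paste0(oc, "_prior")]] <- 0L
  out[[paste0(oc, "_event")]] <- truth$event
  out[[paste0(oc, "_time")]] <- truth$time
  out$unrelated_flag <- 1L
  out
}

## sample outcome-label -> icd10 code (first mapped code per label)
icd10_for <- function(label, outcome_map) {
  codes <- outcome_map$code[outcome_map$vocabulary == "icd10" &
                              outcome_map$outcome_label == label]
  if (!length(codes)) stop_config("no icd10 code mapped for label ", label)
  codes[1]
}

#' Write the synthetic study bundle
#'
#' Expands the simulation truth into the raw record tables the cohort
#' builder consumes: `prescriptions.tsv` (repeat dCCB scripts at the
#' configured intensity, co-medication issued on dCCB prescription days,
#' switch initiations, and a registration-marking script for untreated
#' patients), `diagnoses.tsv` (ICD-10 coded events for the causal outcome,
#' genotype-independent events for the other outcomes, and optional
#' pre-treatment diagnoses), `genotypes.tsv` (long format),
#' `covariates.tsv` (sex, yob, age at entry, PCs, deduction date) plus
#' `truth.tsv` and a `config.yaml` snapshot. Re-running with the same
#' configuration reproduces the files byte for byte.
#'
#' @param truth Output of [simulate_truth()].
#' @param out_dir Output directory (created if needed).
#' @param config Configuration; defaults to the attribute on `truth`.
#' @return Invisibly, a named list of file paths.
#' @export
write_study <- function(truth, out_dir, config = attr(truth, "config")) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create directory ", out_dir)
  ## independent deterministic stream for the record-level dressing
  set.seed((config$rng_seed + 999983L) %% .Machine$integer.max)
  outcome_map <- default_outcome_codes()
  n <- nrow(truth)
  treated_idx <- which(truth$treated == 1L)
  nt <- length(treated_idx)

  ## ---- treated prescription episodes -----------------------------------
  cmin <- years_between(config$last_entry, config$admin_censor)
  cmax <- years_between(config$study_start, config$admin_censor)
  ## episodes are truncated by deduction dropout, switching and the admin
  ## horizon; calibrate the latent scale so the *observed* mean hits target
  mu <- calibrate_episode_mean(config$episode_years_mean,
                               config$dropout_rate + config$switch_rate,
                               cmin, cmax)
  gp_horizon <- pmin(truth$admin_years[treated_idx],
                     truth$dropout_time[treated_idx])
  ep_latent <- stats::rexp(nt) * mu
  ep <- pmin(pmax(ep_latent, 0.08), gp_horizon)
  ## switching: a qualifying alternative-antihypertensive initiation
  s_latent <- if (config$switch_rate > 0)
    stats::rexp(nt) / config$switch_rate else rep(Inf, nt)
  switch_delay <- stats::runif(nt, 7, 30) / DAYS_PER_YEAR
  switched <- s_latent < ep & (s_latent + switch_delay) < gp_horizon
  ep[switched] <- s_latent[switched]
  switch_time <- ifelse(switched, s_latent + switch_delay, NA_real_)

  rate <- pmin(pmax(stats::rnorm(nt, config$rx_per_year_mean,
                                 config$rx_per_year_sd), 1), 25)
  ## enough scripts that consecutive gaps (with +/-20% jitter) stay < 90 days,
  ## so continuing therapy is never mistaken for a switch
  k <- pmax(2L, ceiling(rate * ep), ceiling(ep * DAYS_PER_YEAR / 60) + 1L)
  amlo <- stats::rbinom(nt, 1L, config$p_amlodipine) == 1L
  dccb_code <- ifelse(amlo, "0206020A0",
                      sample(c("0206020R0", "0206020F0", "0206020L0"), nt,
                             replace = TRUE))
  comed <- stats::rbinom(nt, 1L, config$p_comedication) == 1L
  comed_code <- sample(c("0205051R0", "0204000E0", "0202010B0"), nt,
                       replace = TRUE)
  alt_code <- sample(c("0205051L0", "0205052N0", "0204000H0", "0202010F0"),
                     nt, replace = TRUE)

  rx_list <- vector("list", nt)
  entry_t <- truth$entry_date[treated_idx]
  for (j in seq_len(nt)) {
    kk <- k[j]
    pts <- seq(0, ep[j], length.out = kk)
    if (kk > 2L) {
      sp <- ep[j] / (kk - 1L)
      mid <- 2:(kk - 1L)
      pts[mid] <- pts[mid] + stats::runif(kk - 2L, -0.2, 0.2) * sp
    }
    days <- sort(unique(round(pts * DAYS_PER_YEAR)))
    dates <- entry_t[j] + days
    codes <- rep(dccb_code[j], length(dates))
    if (comed[j]) {
      pool <- head(dates, -1L)       # co-issue on dCCB days, never the last
      cd <- pool[sample.int(length(pool), min(2L, length(pool)))]
      dates <- c(dates, cd)
      codes <- c(codes, rep(comed_code[j], length(cd)))
    }
    if (switched[j]) {
      sd0 <- entry_t[j] + round(switch_time[j] * DAYS_PER_YEAR)
      alt_dates <- sd0 + c(0, 40, 80)
      alt_dates <- alt_dates[years_between(entry_t[j], alt_dates) <= gp_horizon[j]]
      dates <- c(dates, alt_dates)
      codes <- c(codes, rep(alt_code[j], length(alt_dates)))
    }
    rx_list[[j]] <- data.table::data.table(
      patient_id = truth$patient_id[treated_idx[j]],
      issue_date = dates, code = codes)
  }
  rx <- data.table::rbindlist(rx_list)

  ## untreated: a single registration-marking (non-antihypertensive) script
  unt <- truth$patient_id[truth$treated == 0L]
  if (length(unt)) {
    rx <- data.table::rbindlist(list(rx, data.table::data.table(
      patient_id = unt,
      issue_date = truth$entry_date[truth$treated == 0L],
      code = "0407010H0")))
  }
  rx[, code_system := "bnf"]
  data.table::setorder(rx, patient_id, issue_date, code)
  data.table::setcolorder(rx, c("patient_id", "issue_date", "code_system",
                                "code"))

  ## ---- diagnoses --------------------------------------------------------
  dx_list <- list()
  ev <- truth$event == 1L
  if (any(ev)) {
    dx_list$causal <- data.table::data.table(
      patient_id = truth$patient_id[ev],
      event_date = truth$entry_date[ev] + round(truth$time[ev] * DAYS_PER_YEAR),
      vocabulary = "icd10",
      code = icd10_for(config$causal_outcome, outcome_map))
  }
  other <- config$null_outcome_hazards
  other <- other[setdiff(names(other), config$causal_outcome)]
  for (lab in names(other)) {
    t_o <- stats::rexp(n) / other[[lab]]
    obs <- t_o < pmin(truth$dropout_time, truth$admin_years)
    if (any(obs)) {
      dx_list[[lab]] <- data.table::data.table(
        patient_id = truth$patient_id[obs],
        event_date = truth$entry_date[obs] + round(t_o[obs] * DAYS_PER_YEAR),
        vocabulary = "icd10",
        code = icd10_for(lab, outcome_map))
    }
  }
  pri <- config$prior_prevalence
  for (lab in names(pri)[pri > 0]) {
    has <- stats::rbinom(n, 1L, pri[[lab]]) == 1L
    if (any(has)) {
      dx_list[[paste0("prior_", lab)]] <- data.table::data.table(
        patient_id = truth$patient_id[has],
        event_date = truth$entry_date[has] -
          round(stats::runif(sum(has), 0.5, 10) * DAYS_PER_YEAR),
        vocabulary = "icd10",
        code = icd10_for(lab, outcome_map))
    }
  }
  dx <- data.table::rbindlist(dx_list)
  if (nrow(dx)) data.table::setorder(dx, patient_id, event_date, code)

  ## ---- genotypes (long), covariates, truth, config ----------------------
  rsids <- names(config$variant_mafs)
  gt <- data.table::data.table(
    patient_id = rep(truth$patient_id, length(rsids)),
    rsid = rep(rsids, each = n),
    dosage = as.integer(unlist(truth[rsids], use.names = FALSE)))
  data.table::setorder(gt, patient_id, rsid)

  pcs <- grep("^pc\\d+$", names(truth), value = TRUE)
  cov <- data.table::as.data.table(
    truth[, c("patient_id", "sex", "age_first_rx", pcs)])
  cov[, yob := as.integer(format(truth$entry_date, "%Y")) -
        as.integer(floor(truth$age_first_rx))]
  cov[, age_entry := round(truth$age_first_rx, 4)]
  cov[, deduction_date := data.table::fifelse(
    truth$dropout_time < truth$admin_years,
    truth$entry_date + round(truth$dropout_time * DAYS_PER_YEAR),
    as.Date(NA))]
  cov[, age_first_rx := NULL]
  data.table::setcolorder(cov, c("patient_id", "sex", "yob", "age_entry",
                                 "deduction_date", pcs))

  tr <- data.table::as.data.table(truth)
  tr[, switch_event := 0L]
  tr[, switch_time_years := NA_real_]
  tr[treated == 1L, `:=`(switch_event = as.integer(switched),
                         switch_time_years = switch_time)]
  tr[, entry_date := as.character(entry_date)]

  paths <- list(
    prescriptions = file.path(out_dir, "prescriptions.tsv"),
    diagnoses     = file.path(out_dir, "diagnoses.tsv"),
    genotypes     = file.path(out_dir, "genotypes.tsv"),
    covariates    = file.path(out_dir, "covariates.tsv"),
    truth         = file.path(out_dir, "truth.tsv"),
    config        = file.path(out_dir, "config.yaml"))
  data.table::fwrite(rx, paths$prescriptions, sep = "\t")
  data.table::fwrite(dx, paths$diagnoses, sep = "\t")
  data.table::fwrite(gt, paths$genotypes, sep = "\t")
  data.table::fwrite(cov, paths$covariates, sep = "\t")
  data.table::fwrite(tr, paths$truth, sep = "\t")
  cfg_out <- lapply(unclass(config), function(x) {
    if (inherits(x, "Date")) return(as.character(x))
    if (is.numeric(x) && !is.null(names(x))) return(as.list(x))  # yaml map
    x
  })
  yaml::write_yaml(cfg_out, paths$config)
  invisible(paths)
}

#' Simulate and write a study bundle in one call
#'
#' @inheritParams write_study
#' @param config A [sim_config()].
#' @return Invisibly, a list with the truth `data.frame` and the file paths.
#' @export
simulate_study <- function(config, out_dir) {
  truth <- simulate_truth(config)
  paths <- write_study(truth, out_dir, config)
  invisible(list(truth = truth, paths = paths))
}
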