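#' Run the full analysis pipeline from a configuration
#'
#' One reproducible run: optionally simulate a study bundle, build the
#' analysis table, run the Cox association scan, run TWIST for the
#' configured variant/outcome pairs, translate combined GMTEs into impact
#' estimates, and write every result plus a structured log and a verbatim
#' configuration snapshot into one output directory. All randomness flows
#' from `config$seed`; re-running a config reproduces deterministic outputs.
#'
#' @param config A named list or path to a YAML file with elements:
#'   `out_dir`; either `simulate` (a list of [sim_config()] overrides) or
#'   `input_dir` (an existing bundle); optional `outcomes`, `model`,
#'   `twist` (list of lists with `variant`, `outcome`, `coding`),
#'   `co_med_adjust`, `drug_subset`, `unrelated_only`, `seed`.
#' @return Invisibly, a list with the analysis table, scan table, TWIST
#'   suites, impact estimates and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop_config("config error: out_dir required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(fmt, ...) {
    line <- sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"), ...)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed %||% 1L
  yaml::write_yaml(config, file.path(out_dir, "run_config.yaml"))

  bundle_dir <- config$input_dir
  if (!is.null(config$simulate)) {
    bundle_dir <- file.path(out_dir, "bundle")
    stage("simulate", {
      sim_args <- config$simulate
      sim_args$rng_seed <- seed
      cfg <- do.call(sim_config, sim_args)
      simulate_study(cfg, bundle_dir)
      logf("simulate: wrote bundle (%d patients, seed %d)",
           cfg$n_patients, seed)
    })
  }
  if (is.null(bundle_dir)) stop_config("config error: need simulate or input_dir")

  tab <- stage("build", {
    t <- build_cohort(bundle_dir)
    logf("build: %d analysis rows (%d treated)", nrow(t), sum(t$treated))
    t
  })
  data.table::fwrite(tab, file.path(out_dir, "analysis_table.tsv"),
                     sep = "\t")

  panel <- default_variant_panel()
  panel <- panel[panel$rsid %in% names(tab), , drop = FALSE]
  outcomes <- config$outcomes %||%
    intersect(c(OUTCOME_LABELS, "switch"),
              c(sub("_event$", "", grep("_event$", names(tab), value = TRUE))))
  scan <- stage("scan", {
    s <- scan_all(tab, panel = panel, outcomes = outcomes,
                  model = config$model,
                  co_med_adjust = isTRUE(config$co_med_adjust),
                  drug_subset = config$drug_subset %||% "all",
                  unrelated_only = isTRUE(config$unrelated_only))
    logf("scan: %d result rows over %d variants x %d outcomes",
         nrow(s), nrow(panel), length(outcomes))
    s
  })
  data.table::fwrite(scan, file.path(out_dir, "scan_results.tsv"), sep = "\t")

  twist_specs <- config$twist %||% list()
  suites <- list()
  impacts <- list()
  for (ts in twist_specs) {
    key <- paste0(ts$variant, "_", ts$outcome)
    suites[[key]] <- stage(paste0("twist:", key), {
      s <- run_twist(tab, ts$variant, ts$outcome,
                     coding = ts$coding %||% "dominant")
      logf("twist %s: combined %s = %.5g /y (p %.3g)", key,
           paste(s$selection, collapse = "+"), s$combined$estimate,
           s$combined$p)
      s
    })
    data.table::fwrite(suites[[key]]$estimates_table,
                       file.path(out_dir, paste0("twist_", key, ".tsv")),
                       sep = "\t")
    if (suites[[key]]$treated_events > 0)
      impacts[[key]] <- impact_from_twist(suites[[key]])
  }
  if (length(impacts)) {
    imp_df <- do.call(rbind, lapply(names(impacts), function(k) {
      x <- impacts[[k]]
      data.frame(analysis = k, gmte_per_year = x$gmte_per_year,
                 carrier_patient_years = x$carrier_patient_years,
                 treated_events = x$total_events_treated,
                 avoided = x$avoided_count,
                 avoided_low = x$avoided_ci[1], avoided_high = x$avoided_ci[2],
                 percent_reduction = x$percent_reduction,
                 percent_low = x$percent_ci[1], percent_high = x$percent_ci[2])
    }))
    data.table::fwrite(imp_df, file.path(out_dir, "impact.tsv"), sep = "\t")
  }

  report_path <- file.path(out_dir, "report.txt")
  stage("report", {
    con <- file(report_path, "w")
    on.exit(close(con))
    sink(con); on.exit(sink(), add = TRUE, after = FALSE)
    cat("pgxtwist pipeline report\n========================\n\n")
    cat("Seed:", seed, "  rows:", nrow(tab), " treated:", sum(tab$treated),
        "\n\n")
    for (t in report_tables(scan, panel)) {
      print(t, row.names = FALSE); cat("\n")
    }
    for (key in names(suites)) {
      cat("\n---- TWIST ", key, " ----\n", sep = "")
      print(suites[[key]])
      if (!is.null(impacts[[key]])) print(impacts[[key]])
    }
    logf("report: written to %s", report_path)
  })
  invisible(list(table = tab, scan = scan, twist = suites, impact = impacts,
                 out_dir = out_dir,
                 paths = list(analysis_table = file.path(out_dir, "analysis_table.tsv"),
                              scan = file.path(out_dir, "scan_results.tsv"),
                              report = report_path, log = log_path)))
}

#' Format scan results as per-outcome association tables
#'
#' Emits one table per outcome in the layout
#' `Outcome | Gene | Allele | N | n | % | HR | 95% CI | P | FDR P`.
#'
#' @param scan Output of [scan_all()].
#' @param panel Variant panel (for gene names).
#' @return Named list of `data.frame`s, one per outcome (header-only when
#'   the scan is empty).
#' @export
report_tables <- function(scan, panel = default_variant_panel()) {
  cols <- c("outcome", "gene", "rsid", "contrast", "N", "n", "percent",
            "hr", "ci_low", "ci_high", "p", "fdr_p")
  if (is.null(scan) || !nrow(scan)) {
    empty <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
    return(list(empty = empty))
  }
  s <- merge(scan, panel[, c("rsid", "gene")], by = "rsid", all.x = TRUE)
  s$N <- s$n_at_risk; s$n <- s$n_events
  s$hr <- round(s$hr, 2); s$ci_low <- round(s$ci_low, 2)
  s$ci_high <- round(s$ci_high, 2)
  s$p <- signif(s$p, 2); s$fdr_p <- signif(s$fdr_p, 2)
  lapply(split(s[, cols], s$outcome), function(d)
    d[order(d$gene, d$rsid, d$contrast), , drop = FALSE])
}
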