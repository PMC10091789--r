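#' Default 23-variant pharmacogenetic panel
#'
#' Candidate variants reported to modify dihydropyridine calcium-channel
#' blocker (dCCB) response or adverse-event risk, one row per variant with
#' gene, effect (minor) allele, other allele, minor-allele frequency and the
#' default inheritance coding. The five variants with the strongest clinical
#' signals (in *RYR3*, *CYP3A5*, *NUMA1*, *APCDD1* and *ADRA1A*) carry
#' frequencies consistent with the published genotype-group sizes; the
#' remaining entries are illustrative defaults in the common-variant range
#' (MAF 3-50%). Edit or replace the shipped table for a different panel.
#'
#' @return A `data.frame` with columns `rsid`, `gene`, `effect_allele`,
#'   `other_allele`, `maf`, `inheritance_model`.
#' @export
default_variant_panel <- function() {
  read_panel_file(system.file("extdata", "variant_panel.tsv",
                              package = "pgxtwist", mustWork = TRUE))
}

#' Read a variant panel file
#'
#' @param path Tab-delimited file with the columns of
#'   [default_variant_panel()].
#' @return A validated `data.frame`.
#' @export
read_panel_file <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("rsid", "gene", "effect_allele", "other_allele", "maf",
            "inheritance_model")
  miss <- setdiff(need, names(p))
  if (length(miss)) stop_config("variant panel missing column(s): ",
                                paste(miss, collapse = ", "))
  if (any(p$effect_allele == p$other_allele))
    stop_config("variant panel: effect and other allele must differ")
  if (any(p$maf < 0 | p$maf > 0.5))
    stop_config("variant panel: maf must be in [0, 0.5]")
  if (anyDuplicated(p$rsid)) stop_config("variant panel: duplicated rsid")
  p
}

#' Default drug-class map (prescription code to antihypertensive class)
#'
#' Flat lookup from `(code_system, code)` to a drug class:
#' `dccb_amlodipine`, `dccb_other`, `ace`, `arb`, `beta_blocker`,
#' `alpha_blocker`, `diuretic`, `vasodilator` or `other`. Codes not in the
#' map fall through to `other` (counted and reported by the cohort builder).
#' The shipped map covers the codes emitted by the synthetic generator plus
#' common BNF stems; extend it for real extracts.
#'
#' @return A `data.frame` with columns `code_system`, `code`, `drug_name`,
#'   `drug_class`.
#' @export
default_drug_classes <- function() {
  utils::read.delim(system.file("extdata", "drug_classes.tsv",
                                package = "pgxtwist", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

#' Default diagnosis-code map (ICD-10/ICD-9/Read to outcome label)
#'
#' Maps coded diagnosis records to the studied outcome labels `hf`, `chd`,
#' `ckd`, `stroke`, `oedema`. One input row maps to at most one label.
#' The shipped lists are illustrative defaults (full cohort-specific code
#' lists are not public); replace the table for production use.
#'
#' @return A `data.frame` with columns `vocabulary`, `code`, `outcome_label`.
#' @export
default_outcome_codes <- function() {
  utils::read.delim(system.file("extdata", "outcome_codes.tsv",
                                package = "pgxtwist", mustWork = TRUE),
                    stringsAsFactors = FALSE)
}

default_panel_mafs <- function() {
  panel <- default_variant_panel()
  stats::setNames(panel$maf, panel$rsid)
}

## classes counted as antihypertensive co-medication (everything but dCCB)
ANTIHYPERTENSIVE_CLASSES <- c("ace", "arb", "beta_blocker", "alpha_blocker",
                              "diuretic", "vasodilator")
DCCB_CLASSES <- c("dccb_amlodipine", "dccb_other")
OUTCOME_LABELS <- c("chd", "hf", "ckd", "stroke", "oedema")
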