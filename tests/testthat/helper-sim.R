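## small, fast configurations used across test files

## moderate effects + moderate n: quick but informative recovery checks
small_cfg <- function(seed = 1L, ...) {
  defaults <- list(n_patients = 4000L, p_treated = 0.35,
                   variant_mafs = c(rs877087 = 0.46, rs776746 = 0.066),
                   baseline_hazard = 0.01, beta_treat = 0.01, beta_geno = 0,
                   beta_interact = 0.005, rng_seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

## all effect coefficients zero: the null generator
null_cfg <- function(seed = 1L, ...) {
  defaults <- list(n_patients = 4000L, p_treated = 0.35,
                   variant_mafs = c(rs877087 = 0.3),
                   baseline_hazard = 0.02, beta_treat = 0, beta_geno = 0,
                   beta_interact = 0, rng_seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

quiet_build <- function(dir, ...) {
  suppressWarnings(suppressMessages(build_cohort(dir, ...)))
}

## tiny hand-built prescription table (classified BNF codes)
rx_row <- function(id, date, code) {
  data.frame(patient_id = id, issue_date = as.Date(date),
             code_system = "bnf", code = code, stringsAsFactors = FALSE)
}
AMLO <- "0206020A0"; NIFE <- "0206020R0"; ACE <- "0205051R0"
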