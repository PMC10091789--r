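test_that("RGMTE is exactly GMTE1 minus GMTE0 with summed variances", {
  cfg <- small_cfg(seed = 4)
  tab <- as_analysis_table(simulate_truth(cfg))
  comp <- gmte_components(tab, "rs877087", "hf",
                          covariates = c("age_first_rx", "sex"))
  expect_identical(comp$RGMTE$estimate,
                   comp$GMTE1$estimate - comp$GMTE0$estimate)
  expect_identical(comp$RGMTE$se, sqrt(comp$GMTE1$se^2 + comp$GMTE0$se^2))
  ## Wald interval invariant: ci = estimate +/- 1.96 se
  expect_equal(comp$GMTE1$ci_low, comp$GMTE1$estimate - 1.96 * comp$GMTE1$se)
  ## beta_geno = 0 -> GMTE0 is null
  expect_gt(comp$GMTE0$p, 0.05)
})

test_that("IVW combination matches hand-computed algebra", {
  ## equal pair: (v, s/sqrt(2))
  e <- list(estimate_with_se("RGMTE", 0.4, 0.1),
            estimate_with_se("MR", 0.4, 0.1))
  cb <- combine_ivw(e)
  expect_equal(cb$combined$estimate, 0.4)
  expect_equal(cb$combined$se, 0.1 / sqrt(2))

  ## worked example: (0.5, 0.1) + (0.9, 0.2)
  e2 <- list(estimate_with_se("RGMTE", 0.5, 0.1),
             estimate_with_se("MR", 0.9, 0.2))
  cb2 <- combine_ivw(e2)
  expect_equal(cb2$combined$estimate, 0.58)
  expect_equal(cb2$combined$se, 0.0894, tolerance = 1e-3)
  qrow <- cb2$q_table[cb2$q_table$set == "RGMTE+MR", ]
  expect_equal(qrow$Q, 3.2)
  expect_equal(qrow$df, 1)
  expect_equal(qrow$p, 0.0736, tolerance = 1e-2)
  expect_equal(cb2$selection, c("RGMTE", "MR"))  # combinable at alpha=.05
  ## combined variance below each component variance
  expect_lt(cb2$combined$se, min(0.1, 0.2))

  ## strongly heterogeneous pair: no combination, robust fallback
  e3 <- list(estimate_with_se("RGMTE", 0.0, 0.1),
             estimate_with_se("MR", 1.0, 0.1))
  cb3 <- combine_ivw(e3)
  expect_equal(cb3$selection, "RGMTE")
  expect_match(cb3$note, "heterogeneous")

  ## single estimate: passthrough with note
  cb4 <- combine_ivw(list(estimate_with_se("RGMTE", 0.2, 0.05)))
  expect_match(cb4$note, "passthrough")
  expect_equal(cb4$combined$estimate, 0.2)
})

test_that("MR estimate is the rescaled full-sample coefficient", {
  cfg <- small_cfg(seed = 6)
  tab <- as_analysis_table(simulate_truth(cfg))
  mr <- mr_estimate(tab, "rs877087", "hf", covariates = c("sex"))
  pt <- mean(tab$treated)
  tab$.g <- as.numeric(tab$rs877087 >= 1)
  full <- fit_additive_hazards(tab, "hf", c(".g", "sex"), "all")
  expect_equal(mr$estimate, full$coefficients[[".g"]] / pt)
  expect_equal(mr$se, full$se[[".g"]] / pt)

  ## hand division on the documented magnitudes
  expect_equal(0.0001 / 0.145, 0.00069, tolerance = 0.01)

  ## proportion treated = 1: MR degenerates to the treated-only coefficient
  tab1 <- tab[tab$treated == 1L, ]
  expect_warning(mr1 <- mr_estimate(tab1, "rs877087", "hf",
                                    covariates = c("sex")),
                 "all patients treated")
  f1 <- fit_additive_hazards(tab1, "hf", c(".g", "sex"), "treated")
  expect_equal(mr1$estimate, f1$coefficients[[".g"]])
})

test_that("CAT recovers the interaction without confounding and is biased with it", {
  ## no confounding: CAT ~ beta_interact
  ests <- lapply(301:305, function(s) {
    cfg <- small_cfg(seed = s, n_patients = 12000L)
    tab <- as_analysis_table(simulate_truth(cfg))
    list(cat = cat_estimate(tab, "rs877087", "hf", covariates = "sex"),
         rg = gmte_components(tab, "rs877087", "hf",
                              covariates = "sex")$RGMTE)
  })
  cat_mean <- mean(vapply(ests, function(e) e$cat$estimate, numeric(1)))
  expect_equal(cat_mean, 0.005, tolerance = 0.3)

  ## confounded treatment assignment: the per-stratum as-treated treatment
  ## coefficients are clearly biased; in a purely additive model with a
  ## genotype-independent confounder that bias is *common* to both strata,
  ## so the CAT difference sheds it and both CAT and RGMTE stay near truth.
  cfgc <- small_cfg(seed = 99, n_patients = 20000L,
                    confounder = list(prevalence = 0.3, hazard = 0.02,
                                      treat_or = 3))
  tabc <- as_analysis_table(simulate_truth(cfgc))
  tabc$.g <- as.numeric(tabc$rs877087 >= 1)
  f_c <- fit_additive_hazards(tabc[tabc$.g > 0, ], "hf", c("treated", "sex"))
  f_n <- fit_additive_hazards(tabc[tabc$.g == 0, ], "hf", c("treated", "sex"))
  truth_c <- 0.01 + 0.005   # beta_treat + beta_interact in carriers
  truth_n <- 0.01
  expect_gt(f_c$coefficients[["treated"]] - truth_c,
            2 * f_c$se[["treated"]])
  expect_gt(f_n$coefficients[["treated"]] - truth_n,
            2 * f_n$se[["treated"]])
  catc <- cat_estimate(tabc, "rs877087", "hf", covariates = "sex")
  rgc <- gmte_components(tabc, "rs877087", "hf", covariates = "sex")$RGMTE
  expect_lt(abs(catc$estimate - 0.005), 3 * catc$se)
  expect_lt(abs(rgc$estimate - 0.005), 3 * rgc$se)
})

test_that("assumption checks pass on the default generator and catch violations", {
  pass <- vapply(1:10, function(s) {
    tab <- as_analysis_table(simulate_truth(null_cfg(seed = s)))
    ac <- assumption_checks(tab, "rs877087",
                            covariates = c("age_first_rx", "sex", "pc1"))
    all(ac$pass[!is.na(ac$pass)])
  }, logical(1))
  expect_gte(mean(pass), 0.7)   # each seed runs several 5%-level tests

  treatment_ok <- vapply(1:10, function(s) {
    tab <- as_analysis_table(simulate_truth(null_cfg(seed = s)))
    ac <- assumption_checks(tab, "rs877087", covariates = character())
    ac$pass[ac$check == "genotype_vs_treatment"]
  }, logical(1))
  expect_gte(mean(treatment_ok), 0.9)

  ## constant covariate is skipped with a note
  tab <- as_analysis_table(simulate_truth(null_cfg(seed = 3)))
  tab$const <- 1
  ac <- assumption_checks(tab, "rs877087", covariates = "const")
  expect_match(ac$note[ac$check == "genotype_vs_const"], "constant")
})

test_that("run_twist recovers the generating GMTE and flags exclusion violations", {
  suites <- lapply(1:6, function(s) {
    tab <- as_analysis_table(simulate_truth(small_cfg(seed = 100 + s)))
    run_twist(tab, "rs877087", "hf", covariates = c("age_first_rx", "sex"),
              estimators = c("GMTE1", "GMTE0", "RGMTE", "MR"))
  })
  est <- vapply(suites, function(x) x$combined$estimate, numeric(1))
  mcse <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.005), 3 * mcse + 0.0005)
  ## GMTE0 null in most seeds (5%-level test per seed)
  expect_gte(mean(vapply(suites, function(x) x$gmte0_null, logical(1))),
             5 / 6)

  ## direct genotype effect (beta_geno > 0): GMTE0 non-null, MR flagged
  cfg_g <- small_cfg(seed = 7, beta_geno = 0.004, n_patients = 20000L)
  tab_g <- as_analysis_table(simulate_truth(cfg_g))
  tw_g <- run_twist(tab_g, "rs877087", "hf",
                    covariates = c("age_first_rx", "sex"),
                    estimators = c("GMTE1", "GMTE0", "RGMTE", "MR"))
  expect_false(tw_g$gmte0_null)
  expect_true(any(grepl("caution", tw_g$notes)))

  ## report carries the pieces impact translation needs
  s1 <- suites[[1]]
  expect_gt(s1$carrier_patient_years, 0)
  expect_gt(s1$treated_events, 0)
  out <- capture.output(print(s1))
  expect_true(any(grepl("Assumption checks", out)))
})
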