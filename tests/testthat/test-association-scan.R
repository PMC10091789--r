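test_that("code_genotype produces the documented contrast designs", {
  d <- c(0L, 1L, 2L)
  gen <- code_genotype(d, "genotypic")
  expect_equal(unname(gen), cbind(c(0, 1, 0), c(0, 0, 1)))
  dom <- code_genotype(d, "dominant")
  expect_equal(unname(drop(dom)), c(0, 1, 1))    # dosage 2 -> carrier
  add <- code_genotype(d, "additive")
  expect_equal(unname(drop(add)), c(0, 1, 2))
  expect_warning(expect_null(code_genotype(rep(0L, 10), "dominant")),
                 "monomorphic")
  ## additive mean dosage ~ 2q on an HWE sample
  g <- gen_genotypes(20000, 0.2, seed = 3)
  expect_equal(mean(code_genotype(g, "additive")), 0.4, tolerance = 0.03)
})

test_that("count_events reproduces printed percentages from N and n", {
  ## build rows from printed (N, n) pairs and recount
  fake_rows <- function(N, n, dosage, outcome) {
    do.call(rbind, lapply(seq_along(N), function(i) {
      df <- data.frame(dosage = dosage[i],
                       ev = c(rep(1L, n[i]), rep(0L, N[i] - n[i])))
      names(df)[1] <- "rsid_x"
      names(df)[2] <- paste0(outcome, "_event")
      df
    }))
  }
  sw <- fake_rows(c(29126, 4135, 156), c(2608, 376, 25), 0:2, "switch")
  names(sw)[2] <- "switch_event"
  cts <- count_events(sw, "rsid_x", "switch")
  expect_equal(cts$percent[cts$genotype == "2"], 16.03)  # 25/156, 2 dp

  ckd <- fake_rows(c(25177, 3545, 140), c(1757, 239, 18), 0:2, "ckd")
  cts2 <- count_events(ckd, "rsid_x", "ckd")
  expect_equal(cts2$percent, c(7.0, 6.7, 12.9))          # 1 dp

  ## n = 0 -> 0%; N = 0 group omitted
  z <- fake_rows(c(100, 50), c(0, 5), 0:1, "hf")
  cz <- count_events(z, "rsid_x", "hf")
  expect_equal(cz$percent[cz$genotype == "0"], 0)
  expect_false("2" %in% cz$genotype)
})

test_that("bh_adjust is the step-up procedure and is order-invariant", {
  expect_equal(bh_adjust(0.02, m = 1), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.2, 0.013, 0.9, 0.04)
  perm <- sample(seq_along(p))
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fit_cox recovers a known multiplicative hazard ratio", {
  ## proportional-hazards generator, true HR 1.5
  logs <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 5000
    g <- rbinom(n, 1, 0.4)
    t_ev <- rexp(n) / (0.03 * 1.5^g)
    rows <- data.frame(patient_id = as.character(1:n), treated = 1L,
                       gvar = g, hf_time = pmin(t_ev, 10),
                       hf_event = as.integer(t_ev <= 10), hf_prior = 0L,
                       age_first_rx = rnorm(n, 61, 8),
                       sex = rbinom(n, 1, 0.46))
    r <- fit_cox(rows, "gvar", "hf", model = "dominant",
                 covariates = c("age_first_rx", "sex"))
    log(r$hr)
  }, numeric(1))
  expect_equal(mean(logs), log(1.5), tolerance = 0.05)
})

test_that("null genotype CI covers 1.0 at the nominal rate", {
  covered <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    n <- 1500
    g <- rbinom(n, 2, 0.3)
    t_ev <- rexp(n) / 0.05
    rows <- data.frame(patient_id = as.character(1:n), treated = 1L,
                       gvar = g, hf_time = pmin(t_ev, 8),
                       hf_event = as.integer(t_ev <= 8), hf_prior = 0L)
    r <- fit_cox(rows, "gvar", "hf", model = "dominant",
                 covariates = character())
    r$ci_low <= 1 && r$ci_high >= 1
  }, logical(1))
  expect_gte(mean(covered), 0.85)
})

test_that("scan_all orchestrates the grid with BH correction and options", {
  cfg <- small_cfg(seed = 31)
  d <- withr::local_tempdir()
  simulate_study(cfg, d)
  tab <- quiet_build(d)
  panel <- default_variant_panel()
  panel <- panel[panel$rsid %in% c("rs877087", "rs776746"), ]

  scan <- suppressWarnings(
    scan_all(tab, panel, outcomes = c("hf", "chd", "switch")))
  expect_true(all(c("rsid", "outcome", "hr", "p", "fdr_p") %in% names(scan)))
  expect_true(all(scan$fdr_p >= scan$p - 1e-12, na.rm = TRUE))
  expect_true(all(scan$fdr_p <= 1, na.rm = TRUE))
  expect_true(all(scan$ci_low <= scan$hr & scan$hr <= scan$ci_high,
                  na.rm = TRUE))
  expect_true(all(scan$n_events <= scan$n_at_risk, na.rm = TRUE))

  ## drug subset reduces the at-risk denominator
  scan_am <- suppressWarnings(
    scan_all(tab, panel, outcomes = "hf", drug_subset = "amlodipine"))
  full_n <- max(scan$n_at_risk[scan$outcome == "hf"])
  expect_lt(max(scan_am$n_at_risk), full_n)

  ## sensitivity options leave a null-confounding fixture nearly unchanged
  scan_co <- suppressWarnings(
    scan_all(tab, panel, outcomes = "hf", co_med_adjust = TRUE))
  base_hf <- scan[scan$outcome == "hf" & scan$rsid == "rs877087", ]
  co_hf <- scan_co[scan_co$rsid == "rs877087", ]
  m <- merge(base_hf, co_hf, by = "contrast")
  se_log <- (log(m$ci_high.x) - log(m$ci_low.x)) / (2 * 1.96)
  expect_true(all(abs(log(m$hr.x) - log(m$hr.y)) < se_log))
})
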