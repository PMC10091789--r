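test_that("parse_records enforces schema, window and malformed-row limits", {
  d <- withr::local_tempdir()
  f <- file.path(d, "rx.tsv")

  ## empty file with header -> empty stream plus warning
  writeLines("patient_id\tissue_date\tcode_system\tcode", f)
  expect_warning(out <- parse_records(f, "prescriptions"), "empty")
  expect_equal(nrow(out), 0L)

  ## date outside the GP window is rejected
  write.table(rbind(rx_row("A", "2010-01-01", AMLO),
                    rx_row("B", "2020-01-01", AMLO)),
              f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_warning(out <- parse_records(f, "prescriptions", max_malformed = 0.6),
                 "malformed")
  expect_identical(out$patient_id, "A")

  ## > 1% malformed aborts
  big <- data.frame(patient_id = c(paste0("P", 1:99), "X", "Y"),
                    issue_date = c(rep("2010-01-01", 99), "not-a-date",
                                   "2019-01-01"),
                    code_system = "bnf", code = AMLO)
  write.table(big, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(parse_records(f, "prescriptions"), "malformed")

  ## missing column is a schema error
  writeLines("patient_id\tcode", f)
  expect_error(parse_records(f, "prescriptions"), "schema error")
})

test_that("build_exposure derives episode window, co-medication and drug flags", {
  rx <- rbind(rx_row("A", "2010-01-01", AMLO),
              rx_row("A", "2010-02-01", AMLO),
              rx_row("A", "2010-03-01", AMLO),
              rx_row("B", "2011-01-01", AMLO),
              rx_row("B", "2011-06-01", ACE),   # co-therapy inside window
              rx_row("B", "2012-01-01", NIFE))
  ep <- build_exposure(rx)
  a <- ep[ep$patient_id == "A", ]
  expect_equal(a$first_rx_date, as.Date("2010-01-01"))
  expect_equal(a$last_rx_date, as.Date("2010-03-01"))
  expect_false(a$co_antihypertensive)
  expect_true(a$amlodipine_only)
  b <- ep[ep$patient_id == "B", ]
  expect_true(b$co_antihypertensive)
  expect_false(b$amlodipine_only)
  expect_true(all(ep$first_rx_date <= ep$last_rx_date &
                    ep$last_rx_date <= ep$censor_date))

  ## cohort entry rule: minimum number of dCCB scripts
  ep2 <- build_exposure(rx, min_prescriptions = 3L)
  expect_identical(ep2$patient_id, "A")
})

test_that("ascertain_outcome separates prior from incident diagnoses", {
  cohort <- data.frame(patient_id = c("A", "B", "C"),
                       origin_date = as.Date("2010-01-01"),
                       censor_date = as.Date("2015-01-01"))
  dx <- data.frame(patient_id = c("A", "B"),
                   event_date = as.Date(c("2009-12-02", "2012-01-01")),
                   vocabulary = "icd10", code = "I50.0",
                   stringsAsFactors = FALSE)
  out <- ascertain_outcome(cohort, dx, "hf")
  out <- out[order(out$patient_id), ]
  expect_equal(out$prior, c(1L, 0L, 0L))     # 30 days before first rx
  expect_equal(out$event, c(0L, 1L, 0L))
  expect_equal(out$time_years[out$patient_id == "B"], 2, tolerance = 0.01)
  ## censored patient gets time to censor date
  expect_equal(out$time_years[out$patient_id == "C"], 5, tolerance = 0.01)
  expect_error(ascertain_outcome(cohort, dx, "gout"), "parameter error")
})

test_that("detect_switch distinguishes switching from co-therapy", {
  ep <- build_exposure(rbind(rx_row("A", "2010-01-01", AMLO),
                             rx_row("A", "2010-06-01", AMLO),
                             rx_row("B", "2010-01-01", AMLO),
                             rx_row("B", "2010-09-15", AMLO),
                             rx_row("B", "2010-10-20", AMLO)))
  ## A: dCCB Jan-Jun, ACE from Sep, no later dCCB -> switch at Sep
  rxA <- rbind(rx_row("A", "2010-01-01", AMLO), rx_row("A", "2010-06-01", AMLO),
               rx_row("A", "2010-09-01", ACE),
               ## B: ACE alongside continuing dCCB -> co-therapy, not switch
               rx_row("B", "2010-01-01", AMLO), rx_row("B", "2010-09-15", AMLO),
               rx_row("B", "2010-09-20", ACE), rx_row("B", "2010-10-20", AMLO))
  sw <- detect_switch(rxA, ep)
  swA <- sw[sw$patient_id == "A", ]
  expect_equal(swA$switch_event, 1L)
  expect_equal(swA$switch_time,
               as.numeric(as.Date("2010-09-01") - as.Date("2010-01-01")) / 365.25)
  expect_equal(sw$switch_event[sw$patient_id == "B"], 0L)
})

test_that("synthetic bundle round-trips through the cohort builder exactly", {
  cfg <- small_cfg(seed = 42)
  d <- withr::local_tempdir()
  res <- simulate_study(cfg, d)
  truth <- res$truth
  tab <- quiet_build(d)
  expect_equal(nrow(tab), nrow(truth))

  m <- merge(truth[, c("patient_id", "treated", "event", "time",
                       "entry_date")],
             tab[, c("patient_id", "treated", "hf_event", "hf_time")],
             by = "patient_id")
  expect_identical(m$treated.x, m$treated.y)        # treated flags exact
  expect_identical(m$event, m$hf_event)             # event flags exact
  expect_lt(max(abs(m$time - m$hf_time)) * 365.25, 1.5)  # day resolution

  ## first-prescription dates equal truth entry dates
  rx <- suppressWarnings(parse_records(file.path(d, "prescriptions.tsv"),
                                       "prescriptions"))
  ep <- suppressMessages(build_exposure(rx))
  m2 <- merge(ep, truth[truth$treated == 1L, c("patient_id", "entry_date")],
              by = "patient_id")
  expect_equal(nrow(m2), sum(truth$treated))
  expect_identical(m2$first_rx_date, m2$entry_date)

  ## switching flags match the generator truth and its configured hazard
  tt <- utils::read.delim(file.path(d, "truth.tsv"))
  msw <- merge(tt[tt$treated == 1, c("patient_id", "switch_event")],
               tab[, c("patient_id", "switch_event")], by = "patient_id")
  expect_identical(as.integer(msw$switch_event.x),
                   as.integer(msw$switch_event.y))
  p_obs <- mean(msw$switch_event.y)
  expect_lt(abs(p_obs - mean(tt$switch_event[tt$treated == 1])),
            3 * sqrt(p_obs * (1 - p_obs) / nrow(msw)) + 1e-9)

  ## no event after censoring, positive times, genotype group sizes add up
  expect_true(all(tab$hf_time > 0))
  g_n <- table(tab$rs877087)
  expect_equal(sum(g_n), sum(!is.na(tab$rs877087)))

  ## observed episode length near the configured 5.9-year mean
  yrs <- as.numeric(ep$last_rx_date - ep$first_rx_date) / 365.25
  expect_equal(mean(yrs), 5.9, tolerance = 0.10)
})

test_that("subgroup and exclusion helpers behave as counting oracles predict", {
  cfg <- small_cfg(seed = 8, prior_prevalence = c(chd = 0.10, hf = 0.02))
  d <- withr::local_tempdir()
  simulate_study(cfg, d)
  tab <- quiet_build(d)

  sub <- subgroup_prior_disease(tab, labels = c("chd", "hf"))
  frac <- nrow(sub) / nrow(tab)
  expect_equal(frac, 1 - (1 - 0.10) * (1 - 0.02), tolerance = 0.15)
  ## composite event time = min of component event times
  both <- sub[sub$chd_event == 1 & sub$hf_event == 1, ]
  if (nrow(both))
    expect_equal(both$composite_time, pmin(both$chd_time, both$hf_time))
  expect_true(all(sub$composite_event %in% 0:1))

  ## no prior disease -> empty subset
  cfg0 <- small_cfg(seed = 9)
  d0 <- withr::local_tempdir()
  simulate_study(cfg0, d0)
  tab0 <- quiet_build(d0)
  expect_equal(nrow(subgroup_prior_disease(tab0)), 0L)

  ## exclusion list reduces rows by its length
  ids <- tab$patient_id[1:25]
  expect_equal(nrow(apply_exclusions(tab, ids)), nrow(tab) - 25L)

  ## missing genotype drops the patient for that variant only
  tab$rs877087[1] <- NA
  cts <- count_events(tab, "rs877087", "hf")
  expect_equal(sum(cts$N),
               sum(!is.na(tab$rs877087) & tab$treated == 1 &
                     tab$hf_prior != 1))

  ## duplicate patient ids are a data error
  cov <- utils::read.delim(file.path(d, "covariates.tsv"))
  rx <- suppressWarnings(parse_records(file.path(d, "prescriptions.tsv"),
                                       "prescriptions"))
  dx <- suppressWarnings(parse_records(file.path(d, "diagnoses.tsv"),
                                       "diagnoses"))
  gt <- suppressWarnings(parse_records(file.path(d, "genotypes.tsv"),
                                       "genotypes"))
  expect_error(assemble_analysis_table(rx, dx, gt, rbind(cov, cov[1, ])),
               "duplicate patient_id")
})
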