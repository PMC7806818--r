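# Cohort selection: index date, era assignment, follow-up, ASCT, and the
# inclusion/exclusion rules with their audit log.

dx_row <- function(date, icd9, position = "primary", setting = "outpatient",
                   pid = "p1") {
  data.frame(patient_id = pid, claim_date = as.Date(date), icd9 = icd9,
             position = position, setting = setting, stringsAsFactors = FALSE)
}

test_that("index date is the earliest qualifying myeloma claim", {
  dx <- rbind(dx_row("2013-04-02", "203.00"), dx_row("2013-01-15", "203.01"))
  expect_equal(find_index_date(dx), as.Date("2013-01-15"))
  expect_true(is.na(find_index_date(dx_row("2013-01-01", "250.00"))))
  # claim position does not gate the index
  dx <- rbind(dx_row("2010-06-01", "203", "secondary"),
              dx_row("2010-05-20", "203.0", "primary"))
  expect_equal(find_index_date(dx), as.Date("2010-05-20"))
  # 203.1x (plasma cell leukemia) never sets the index
  expect_true(is.na(find_index_date(dx_row("2010-01-01", "203.1"))))
})

test_that("era boundary is 2012-06-01 inclusive for the post period", {
  expect_equal(assign_period(as.Date("2012-05-31")), "pre_bortezomib")
  expect_equal(assign_period(as.Date("2012-06-01")), "post_bortezomib")
  expect_equal(assign_period(as.Date("2007-01-01")), "pre_bortezomib")
  expect_error(assign_period(as.Date("2006-12-31")), "window")
  expect_error(assign_period(as.Date("2016-01-01")), "window")
})

test_that("follow-up ends at the earliest of death, dis-enrollment, censor", {
  f <- compute_followup(as.Date("2015-01-01"), as.Date("2016-01-01"), as.Date(NA))
  expect_equal(f$followup_years, 365 / 365.25)
  expect_true(f$died)
  f <- compute_followup(as.Date("2015-01-01"), as.Date(NA), as.Date("2019-06-01"))
  expect_equal(f$followup_end, as.Date("2017-12-31"))
  expect_false(f$died)
  f <- compute_followup(as.Date("2017-12-31"), as.Date(NA), as.Date(NA))
  expect_equal(f$followup_years, 0)
  f <- compute_followup(as.Date("2015-01-01"), as.Date(NA), as.Date("2016-03-01"))
  expect_equal(f$followup_end, as.Date("2016-03-01"))
  expect_error(compute_followup(as.Date("2015-01-01"), as.Date("2014-12-31"),
                                as.Date(NA)),
               "death before index")
})

test_that("ASCT flag uses the first on-or-after-index transplant", {
  pr <- function(...) {
    d <- as.Date(c(...))
    data.frame(patient_id = rep("p1", length(d)), procedure_date = d,
               procedure = rep("ASCT", length(d)), stringsAsFactors = FALSE)
  }
  idx <- as.Date("2013-01-01")
  expect_false(flag_asct(idx, pr())$asct)
  a <- flag_asct(idx, pr("2013-10-28"))
  expect_true(a$asct)
  expect_equal(a$asct_date, idx + 300)
  # pre-index procedures are ignored
  expect_false(flag_asct(idx, pr("2012-12-01"))$asct)
  expect_equal(flag_asct(idx, pr("2012-12-01", "2014-01-01"))$asct_date,
               as.Date("2014-01-01"))
})

make_bundle <- function(patients, diagnoses, dispensings = NULL,
                        procedures = NULL, deaths = NULL) {
  empty_rx <- data.frame(patient_id = character(0),
                         dispense_date = as.Date(character(0)),
                         drug = character(0), days_supply = integer(0),
                         setting = character(0), stringsAsFactors = FALSE)
  empty_pr <- data.frame(patient_id = character(0),
                         procedure_date = as.Date(character(0)),
                         procedure = character(0), stringsAsFactors = FALSE)
  empty_de <- data.frame(patient_id = character(0),
                         death_date = as.Date(character(0)),
                         stringsAsFactors = FALSE)
  claims_bundle(patients, diagnoses, dispensings %||% empty_rx,
                procedures %||% empty_pr, deaths %||% empty_de)
}

pat_row <- function(pid, birth = "1950-01-01", enroll = "2005-01-01",
                    end = NA) {
  data.frame(patient_id = pid, birth_date = as.Date(birth), sex = "male",
             enroll_start = as.Date(enroll), enroll_end = as.Date(end),
             stringsAsFactors = FALSE)
}

rx_row <- function(pid, date, drug = "thalidomide") {
  data.frame(patient_id = pid, dispense_date = as.Date(date), drug = drug,
             days_supply = 28L, setting = "outpatient", stringsAsFactors = FALSE)
}

test_that("selection rules exclude with the documented reasons", {
  # 2 months of lookback instead of 12
  b <- make_bundle(pat_row("p1", enroll = "2014-01-01"),
                   rbind(dx_row("2014-03-01", "203.00"),
                         dx_row("2014-04-01", "203.00")),
                   rx_row("p1", "2014-03-05"))
  sel <- apply_selection(b)
  expect_equal(nrow(sel$cohort), 0)
  expect_equal(sel$exclusions$rule[sel$exclusions$primary],
               "insufficient_lookback")

  # plasma-cell leukemia code 40 days after the first myeloma claim
  b <- make_bundle(pat_row("p2"),
                   rbind(dx_row("2013-05-01", "203.0", pid = "p2"),
                         dx_row("2013-06-10", "203.1", pid = "p2"),
                         dx_row("2013-07-01", "203.00", pid = "p2")),
                   rx_row("p2", "2013-05-02"))
  sel <- apply_selection(b)
  expect_equal(sel$exclusions$rule[sel$exclusions$primary],
               "plasma_cell_leukemia_within_2mo")

  # same code outside the 61-day window does not exclude
  b <- make_bundle(pat_row("p3"),
                   rbind(dx_row("2013-05-01", "203.0", pid = "p3"),
                         dx_row("2013-08-01", "203.1", pid = "p3"),
                         dx_row("2013-07-01", "203.00", pid = "p3")),
                   rx_row("p3", "2013-05-02"))
  expect_equal(nrow(apply_selection(b)$cohort), 1)

  # prior primary cancer before index
  b <- make_bundle(pat_row("p4"),
                   rbind(dx_row("2012-01-01", "162.9", pid = "p4"),
                         dx_row("2013-05-01", "203.00", pid = "p4"),
                         dx_row("2013-06-01", "203.00", pid = "p4")),
                   rx_row("p4", "2013-05-02"))
  sel <- apply_selection(b)
  expect_equal(sel$exclusions$rule[sel$exclusions$primary], "prior_cancer")

  # untreated and no further myeloma visit: both rules logged, first primary
  b <- make_bundle(pat_row("p5"), dx_row("2013-05-01", "203.00", pid = "p5"))
  sel <- apply_selection(b)
  expect_setequal(sel$exclusions$rule,
                  c("no_mm_visit_after_index", "untreated"))
  expect_equal(sel$exclusions$rule[sel$exclusions$primary],
               "no_mm_visit_after_index")
})

test_that("planted violations are excluded with matching rules, others kept", {
  plants <- c(insufficient_lookback = 2, age_under_18 = 2, prior_cancer = 2,
              plasma_cell_leukemia_within_2mo = 2,
              no_mm_visit_after_index = 1, untreated = 1)
  sim <- simulate_bundle(sim_config(n_patients = 100, seed = 3,
                                    planted_violations = plants))
  sel <- apply_selection(sim$bundle)
  truth <- sim$truth$patients
  planted <- truth[!is.na(truth$planted_rule), ]
  expect_equal(nrow(sel$cohort), 90)
  prim <- sel$exclusions[sel$exclusions$primary, ]
  expect_equal(nrow(prim), 10)
  expect_equal(prim$rule[match(planted$patient_id, prim$patient_id)],
               planted$planted_rule)
})

test_that("selection partitions the input and is order-independent", {
  sim <- simulate_bundle(sim_config(n_patients = 80, seed = 9,
                                    planted_violations = c(untreated = 4)))
  sel <- apply_selection(sim$bundle)
  expect_equal(nrow(sel$cohort) + length(unique(sel$exclusions$patient_id)),
               nrow(sim$bundle$patients))
  shuffled <- sim$bundle
  set.seed(1)
  for (tab in c("patients", "diagnoses", "dispensings"))
    shuffled[[tab]] <- shuffled[[tab]][sample(nrow(shuffled[[tab]])), ]
  sel2 <- apply_selection(shuffled)
  o1 <- sel$cohort[order(sel$cohort$patient_id), ]
  o2 <- sel2$cohort[order(sel2$cohort$patient_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("relaxing the lookback requirement never shrinks the cohort", {
  sim <- simulate_bundle(sim_config(
    n_patients = 60, seed = 13,
    planted_violations = c(insufficient_lookback = 5)))
  strict <- apply_selection(sim$bundle, cohort_config(lookback_months = 12))
  lax <- apply_selection(sim$bundle, cohort_config(lookback_months = 0))
  expect_true(all(strict$cohort$patient_id %in% lax$cohort$patient_id))
  expect_equal(nrow(lax$cohort), nrow(strict$cohort) + 5)
})
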