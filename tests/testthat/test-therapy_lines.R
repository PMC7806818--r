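# Line-of-therapy construction: coverage, gap rule, addition rule,
# classification, naming; oracle equivalence on randomized histories.

rx <- function(dates, drug, supply = 30, pid = "p1") {
  data.frame(patient_id = pid, dispense_date = as.Date(dates), drug = drug,
             days_supply = as.integer(supply), setting = "outpatient",
             stringsAsFactors = FALSE)
}

idx <- as.Date("2013-01-01")
far <- as.Date("2020-12-31")

test_that("coverage intervals merge overlapping and adjacent dispensings", {
  ci <- coverage_intervals(rx("2013-01-01", "thalidomide"))
  expect_equal(ci$start, as.Date("2013-01-01"))
  expect_equal(ci$end, as.Date("2013-01-30"))
  ci <- coverage_intervals(rx(c("2013-01-01", "2013-01-31"), "thalidomide"))
  expect_equal(nrow(ci), 1)
  expect_equal(ci$end, as.Date("2013-03-01"))
  ci <- coverage_intervals(rx(c("2013-01-01", "2013-03-02"), "thalidomide"))
  expect_equal(nrow(ci), 2)
  # different drugs are not merged
  ci <- coverage_intervals(rbind(rx("2013-01-01", "thalidomide"),
                                 rx("2013-01-15", "bortezomib")))
  expect_equal(nrow(ci), 2)
})

test_that("a sustained gap ends the line; the next dispensing opens a new one", {
  # thalidomide monthly x6, 90 days of silence, then bortezomib
  d <- rbind(rx(idx + seq(0, by = 28, length.out = 6), "thalidomide", 28),
             rx(idx + 5 * 28 + 28 + 90, "bortezomib", 28))
  lines <- build_lines(d, idx, data_end = far)
  expect_equal(nrow(lines), 2)
  expect_equal(lines$drugs, c("thalidomide", "bortezomib"))
  expect_equal(lines$end_reason[1], "gap")
  expect_equal(lines$end_date[1], idx + 5 * 28 + 27)
  expect_equal(lines$start_date[2], idx + 5 * 28 + 28 + 90)
})

test_that("a drug added within 90 days joins the line", {
  d <- rbind(rx(idx + seq(0, by = 28, length.out = 7), "bortezomib", 28),
             rx(idx + 45, "thalidomide", 28),
             rx(idx + 73, "thalidomide", 28))
  lines <- build_lines(d, idx, data_end = far)
  expect_equal(nrow(lines), 1)
  expect_equal(lines$drugs, "bortezomib|thalidomide")
  expect_equal(lines$regimen_class, "NA")
})

test_that("a new drug after day 90 opens a new line the day it is dispensed", {
  d <- rbind(rx(idx + seq(0, by = 28, length.out = 7), "bortezomib", 28),
             rx(idx + 120, "lenalidomide", 28))
  lines <- build_lines(d, idx, data_end = far)
  expect_equal(nrow(lines), 2)
  expect_equal(lines$end_reason[1], "new_drug_after_90d")
  expect_equal(lines$end_date[1], idx + 119)
  expect_equal(lines$start_date[2], idx + 120)
  # bortezomib dispensed on/after the switch joins the new line
  d2 <- rbind(d, rx(idx + 120, "bortezomib", 28))
  lines2 <- build_lines(d2, idx, data_end = far)
  expect_equal(lines2$drugs[2], "bortezomib|lenalidomide")
  expect_equal(lines2$drugs[1], "bortezomib")
})

test_that("boundary days: 90 joins, 91 opens; 59-day gap holds, 60 ends", {
  base <- rx(idx, "bortezomib", 120)
  joins <- build_lines(rbind(base, rx(idx + 90, "thalidomide", 30)), idx,
                       data_end = far)
  expect_equal(nrow(joins), 1)
  expect_equal(joins$drugs, "bortezomib|thalidomide")
  opens <- build_lines(rbind(base, rx(idx + 91, "thalidomide", 30)), idx,
                       data_end = far)
  expect_equal(nrow(opens), 2)
  expect_equal(opens$end_reason[1], "new_drug_after_90d")

  # 30-day supply ending day 29; resume on day 89 -> 59 uncovered days
  holds <- build_lines(rx(c(idx, idx + 89), "bortezomib", 30), idx,
                       data_end = far)
  expect_equal(nrow(holds), 1)
  ends <- build_lines(rx(c(idx, idx + 90), "bortezomib", 30), idx,
                      data_end = far)
  expect_equal(nrow(ends), 2)
  expect_equal(ends$end_reason[1], "gap")
})

test_that("death and end of data close the final line", {
  d <- rx(idx, "melphalan", 30)
  lines <- build_lines(d, idx, death_date = idx + 10, data_end = far)
  expect_equal(lines$end_reason, "death")
  expect_equal(lines$end_date, idx + 10)
  # death during the post-coverage gap still attributes to the line
  lines <- build_lines(d, idx, death_date = idx + 45, data_end = far)
  expect_equal(lines$end_reason, "death")
  expect_equal(lines$end_date, idx + 29)
  # death after the gap completes: the line ended by gap
  lines <- build_lines(d, idx, death_date = idx + 200, data_end = far)
  expect_equal(lines$end_reason, "gap")
  # data end within coverage
  lines <- build_lines(d, idx, data_end = idx + 15)
  expect_equal(lines$end_reason, "data_end")
  expect_equal(lines$end_date, idx + 15)
  expect_error(build_lines(rx(idx - 1, "melphalan"), idx, data_end = far),
               "before index")
})

test_that("duplicated dispensings change no line boundaries", {
  set.seed(101)
  for (rep in 1:30) {
    d <- random_dispensings()
    base <- build_lines(d, as.Date("2010-01-01"), data_end = far)
    dup <- rbind(d, d[sample(nrow(d), 1), ])
    expect_equal(build_lines(dup, as.Date("2010-01-01"), data_end = far), base)
  }
})

test_that("with infinite gap and addition window every patient has one line", {
  set.seed(55)
  p <- lot_params(gap_days = 1e9, addition_window_days = 1e9)
  for (rep in 1:30) {
    d <- random_dispensings()
    lines <- build_lines(d, as.Date("2010-01-01"), data_end = far, params = p)
    expect_equal(nrow(lines), 1)
    expect_setequal(strsplit(lines$drugs, "|", fixed = TRUE)[[1]],
                    unique(d$drug))
  }
})

test_that("build_lines matches the day-scan oracle on random histories", {
  set.seed(2024)
  index <- as.Date("2010-01-01")
  for (rep in 1:200) {
    d <- random_dispensings()
    death <- if (runif(1) < 0.3)
      index + sample.int(900, 1) else as.Date(NA)
    if (!is.na(death) && death < min(d$dispense_date)) death <- as.Date(NA)
    dend <- index + sample(300:1500, 1)
    d <- d[d$dispense_date <= dend, , drop = FALSE]
    if (nrow(d) == 0) next
    lines <- build_lines(d, index, death, dend)
    oracle <- lot_oracle(d, index, death, dend)
    expect_lines_match_oracle(lines, oracle, info = paste("case", rep))
  }
})

test_that("every dispensing is attributed to exactly one line", {
  set.seed(77)
  for (rep in 1:50) {
    d <- random_dispensings()
    lines <- build_lines(d, as.Date("2010-01-01"), data_end = far)
    n_attr <- 0
    for (k in seq_len(nrow(lines))) {
      upper <- if (k < nrow(lines)) lines$start_date[k + 1] - 1 else far
      n_attr <- n_attr + sum(d$dispense_date >= lines$start_date[k] &
                               d$dispense_date <= upper)
    }
    expect_equal(n_attr, nrow(d))
    expect_true(all(diff(as.numeric(lines$start_date)) > 0))
  }
})

test_that("line classes follow the four-way taxonomy", {
  expect_equal(classify_line(c("bortezomib", "thalidomide", "dexamethasone")),
               "NA")
  expect_equal(classify_line(c("melphalan", "thalidomide")), "CCNA")
  expect_equal(classify_line("dexamethasone"), "SA")
  expect_equal(classify_line(c("melphalan", "prednisolone")), "CA")
  expect_equal(classify_line("lenalidomide"), "NA")
  expect_error(classify_line(character(0)), "empty")
})

test_that("named regimens follow the taxonomy precedence", {
  expect_equal(name_regimen(c("bortezomib", "thalidomide")),
               "Bortezomib + Thalidomide")
  expect_equal(name_regimen(c("bortezomib", "thalidomide", "dexamethasone")),
               "Bortezomib + Thalidomide")
  expect_equal(name_regimen(c("bortezomib", "thalidomide", "cyclophosphamide")),
               "Bortezomib + Thalidomide + chemo")
  expect_equal(name_regimen(c("melphalan", "bortezomib", "thalidomide")),
               "Melphalan + bortezomib + thalidomide")
  expect_equal(name_regimen(c("melphalan", "thalidomide")),
               "Melphalan + thalidomide")
  expect_equal(name_regimen(c("melphalan", "bortezomib")),
               "Melphalan + bortezomib")
  expect_equal(name_regimen(c("melphalan", "prednisolone")), "Melphalan-based")
  expect_equal(name_regimen("thalidomide"), "Thalidomide-based")
  expect_equal(name_regimen(c("thalidomide", "cyclophosphamide")),
               "Thalidomide-based + chemo")
  expect_equal(name_regimen("bortezomib"), "Bortezomib-based")
  expect_equal(name_regimen(c("cyclophosphamide", "vincristine")),
               "Two-chemo combination")
  expect_equal(name_regimen(c("cyclophosphamide", "vincristine", "etoposide")),
               "Three-chemo combination")
  expect_equal(name_regimen("cyclophosphamide"), "Cyclophosphamide-based")
  expect_equal(name_regimen("etoposide"), "Other mono chemo")
  expect_equal(name_regimen(c("dexamethasone", "prednisolone")), "Steroid")
  expect_equal(name_regimen("lenalidomide"), "Lenalidomide-based")
})
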