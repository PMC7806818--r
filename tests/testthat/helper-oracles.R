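# Independent oracles: a literal day-by-day line-of-therapy walker and a
# brute-force Charlson enumerator. Both apply the rules as written, one
# calendar day / one table row at a time, with no shared code with the
# package implementations.

# Day-scan line-of-therapy oracle. Walks every calendar day, tracking the
# set of covered days of the current line; applies, in order per day:
# dispensing events (regimen-switch rule), death, the gap counter, end of
# data.
lot_oracle <- function(disp, index_date, death_date = NA, data_end,
                       gap_days = 60, window_days = 90) {
  death_date <- as.Date(death_date)
  data_end <- as.Date(data_end)
  limit <- min(c(data_end, death_date), na.rm = TRUE)
  disp <- disp[disp$dispense_date <= limit, , drop = FALSE]
  disp <- disp[!duplicated(disp[, c("dispense_date", "drug", "days_supply")]), ,
               drop = FALSE]
  out <- list()
  if (nrow(disp) == 0) return(out)

  cur <- NULL
  streak <- 0
  close_line <- function(end, reason) {
    out[[length(out) + 1]] <<- list(start = cur$start, end = end,
                                    drugs = sort(unique(cur$drugs)),
                                    reason = reason)
    cur <<- NULL
    streak <<- 0
  }
  open_line <- function(day, todays) {
    cur <<- list(start = day, drugs = todays$drug, covered = integer(0))
    for (r in seq_len(nrow(todays)))
      cur$covered <<- union(cur$covered,
                            as.integer(todays$dispense_date[r]) +
                              seq_len(todays$days_supply[r]) - 1L)
    streak <<- 0
  }

  day <- min(disp$dispense_date)
  while (day <= limit) {
    todays <- disp[disp$dispense_date == day, , drop = FALSE]
    if (nrow(todays) > 0) {
      if (is.null(cur)) {
        open_line(day, todays)
      } else if (any(!todays$drug %in% cur$drugs) &&
                 as.integer(day - cur$start) > window_days) {
        close_line(day - 1, "new_drug_after_90d")
        open_line(day, todays)
      } else {
        cur$drugs <- union(cur$drugs, todays$drug)
        for (r in seq_len(nrow(todays)))
          cur$covered <- union(cur$covered,
                               as.integer(todays$dispense_date[r]) +
                                 seq_len(todays$days_supply[r]) - 1L)
        streak <- 0
      }
    }
    if (!is.na(death_date) && day == death_date) {
      if (!is.null(cur))
        close_line(as.Date(min(max(cur$covered), as.integer(day)),
                           origin = "1970-01-01"), "death")
      return(out)
    }
    if (!is.null(cur)) {
      if (as.integer(day) %in% cur$covered) streak <- 0 else streak <- streak + 1
      if (streak >= gap_days)
        close_line(as.Date(max(cur$covered), origin = "1970-01-01"), "gap")
    }
    if (day == data_end) {
      if (!is.null(cur))
        close_line(as.Date(min(max(cur$covered), as.integer(day)),
                           origin = "1970-01-01"), "data_end")
      return(out)
    }
    day <- day + 1
  }
  out
}

# compare oracle output with build_lines() output
expect_lines_match_oracle <- function(lines, oracle, info = NULL) {
  expect_equal(nrow(lines), length(oracle), info = info)
  for (k in seq_along(oracle)) {
    expect_equal(lines$start_date[k], oracle[[k]]$start, info = info)
    expect_equal(lines$end_date[k], oracle[[k]]$end, info = info)
    expect_equal(strsplit(lines$drugs[k], "|", fixed = TRUE)[[1]],
                 oracle[[k]]$drugs, info = info)
    expect_equal(lines$end_reason[k], oracle[[k]]$reason, info = info)
  }
}

# random small dispensing history: <= max_disp dispensings of <= max_drugs
# drugs, consecutive dispensings separated by 1-200 days
random_dispensings <- function(max_disp = 10, max_drugs = 3,
                               index = as.Date("2010-01-01")) {
  n <- sample.int(max_disp, 1)
  drugs <- sample(c("bortezomib", "thalidomide", "lenalidomide", "melphalan",
                    "cyclophosphamide", "dexamethasone"),
                  sample.int(max_drugs, 1))
  gaps <- sample.int(200, n, replace = TRUE)
  dates <- index + cumsum(c(sample.int(14, 1) - 1, gaps[-1]))
  data.frame(patient_id = "px",
             dispense_date = dates,
             drug = sample(drugs, n, replace = TRUE),
             days_supply = sample.int(90, n, replace = TRUE),
             setting = "outpatient",
             stringsAsFactors = FALSE)
}

# Brute-force Charlson enumerator over the shipped weight table: literal
# triple loop claims x conditions x prefixes, then hierarchy, then sum.
cci_oracle <- function(diagnoses, index_date, window_days = 365,
                       map = deyo_map(), include_malignancy = FALSE) {
  present <- character(0)
  for (i in seq_len(nrow(diagnoses))) {
    d <- diagnoses$claim_date[i]
    if (!(d < index_date && d >= index_date - window_days)) next
    code <- diagnoses$icd9[i]
    for (j in seq_len(nrow(map))) {
      for (p in strsplit(map$icd9_prefixes[j], "|", fixed = TRUE)[[1]]) {
        hit <- if (grepl(".", p, fixed = TRUE)) startsWith(code, p)
               else sub("\\..*$", "", code) == p
        if (hit) present <- union(present, map$condition[j])
      }
    }
  }
  if (!include_malignancy)
    present <- setdiff(present, c("malignancy", "metastatic_solid_tumor"))
  total <- 0
  for (g in present) {
    superseded <- FALSE
    for (h in present)
      if (map$supersedes[map$condition == h] == g) superseded <- TRUE
    if (!superseded) total <- total + map$weight[map$condition == g]
  }
  total
}

# random pre-index claim profile drawing codes that hit many Deyo groups,
# near-miss codes, and irrelevant ones
random_cci_profile <- function(index = as.Date("2012-07-01")) {
  codes <- c("410.1", "412", "428.0", "443.9", "785.4", "433.1", "290.0",
             "493.2", "506.4", "714.0", "725", "531.3", "571.2", "571.5",
             "572.3", "456.0", "250.00", "250.31", "250.51", "250.70",
             "342.9", "344.1", "582", "583.4", "585.9", "586", "588.1",
             "162.9", "203.00", "196.1", "199.0", "042",
             # near misses and noise
             "571.1", "250.81", "443.1", "506.1", "583.8", "199.2",
             "285.9", "486", "805.2", "V43.4", "710.2")
  n <- sample.int(8, 1)
  data.frame(patient_id = "px",
             claim_date = index - sample.int(500, n, replace = TRUE),
             icd9 = sample(codes, n, replace = TRUE),
             position = sample(c("primary", "secondary"), n, replace = TRUE),
             setting = sample(c("outpatient", "inpatient"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}
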