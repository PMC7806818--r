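# Line-of-therapy construction from dispensing claims.
#
# A line ends at the earliest of:
#   (a) a gap of >= gap_days with no drug coverage from any drug in the
#       line (end date = last covered day);
#   (b) the day before a dispensing of a drug outside the line's set more
#       than addition_window_days after line start (that dispensing opens
#       the next line);
#   (c) death; (d) end of data.
# A drug first dispensed within addition_window_days of line start joins
# the line; re-dispensing an in-line drug never opens a line.

#' Line-of-therapy parameters
#'
#' @param gap_days uncovered days that end a line (default 60: a 59-day
#'   coverage gap keeps the line alive, a 60-day gap ends it).
#' @param addition_window_days window after line start during which a new
#'   drug is an addition to the line (default 90; day 90 itself joins the
#'   line, day 91 opens a new one).
#' @param gap_basis `"coverage"` measures the gap in days without drug
#'   coverage (dispense date + days supply); `"dispense_date"` measures it
#'   between consecutive dispense dates, for sensitivity analysis.
#' @return list of class `lot_params`.
#' @export
lot_params <- function(gap_days = 60, addition_window_days = 90,
                       gap_basis = c("coverage", "dispense_date")) {
  gap_basis <- match.arg(gap_basis)
  if (gap_days < 1 || addition_window_days < 1)
    stopf("gap_days and addition_window_days must be positive")
  structure(list(gap_days = gap_days,
                 addition_window_days = addition_window_days,
                 gap_basis = gap_basis), class = "lot_params")
}

#' Per-drug coverage intervals
#'
#' Each dispensing covers `[dispense_date, dispense_date + days_supply - 1]`;
#' overlapping or adjacent intervals of the same drug are merged.
#'
#' @param dispensings dispensing claims of one patient.
#' @return data.frame `drug`, `start`, `end`, sorted by drug then start.
#' @export
coverage_intervals <- function(dispensings) {
  out <- lapply(split(dispensings, dispensings$drug), function(d) {
    d <- d[order(d$dispense_date), , drop = FALSE]
    s <- d$dispense_date
    e <- d$dispense_date + d$days_supply - 1
    ms <- s[1]; me <- e[1]
    starts <- as.Date(character(0)); ends <- as.Date(character(0))
    for (i in seq_along(s)[-1]) {
      if (s[i] <= me + 1) {
        me <- max(me, e[i])
      } else {
        starts <- c(starts, ms); ends <- c(ends, me)
        ms <- s[i]; me <- e[i]
      }
    }
    data.frame(drug = d$drug[1], start = c(starts, ms), end = c(ends, me),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(drug = character(0), start = as.Date(character(0)),
                      end = as.Date(character(0)), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Build ordered lines of therapy for one patient
#'
#' @param dispensings dispensing claims of one patient, all on/after the
#'   index date; duplicated rows are tolerated (they change nothing).
#' @param index_date myeloma index date.
#' @param death_date death date or `NA`.
#' @param data_end end of the patient's data (follow-up end).
#' @param params a [lot_params()].
#' @param dictionary drug dictionary, used for classification.
#' @return data.frame with one row per line: `line_number`, `start_date`,
#'   `end_date`, `drugs` (pipe-delimited, sorted), `end_reason`
#'   (`gap`, `new_drug_after_90d`, `death`, `data_end`), `regimen_class`,
#'   `named_regimen`.
#' @export
build_lines <- function(dispensings, index_date, death_date = NA,
                        data_end, params = lot_params(),
                        dictionary = mm_drug_dictionary()) {
  death_date <- as.Date(death_date)
  data_end <- as.Date(data_end)
  if (nrow(dispensings) > 0 && any(dispensings$dispense_date < index_date))
    stopf("dispensing before index date")
  limit <- min_date(death_date, data_end)
  disp <- dispensings[dispensings$dispense_date <= limit, , drop = FALSE]
  disp <- disp[order(disp$dispense_date, disp$drug), , drop = FALSE]
  # duplicated rows are idempotent by construction; drop exact duplicates
  disp <- disp[!duplicated(disp[, c("dispense_date", "drug", "days_supply")]), ,
               drop = FALSE]

  lines <- list()
  n <- nrow(disp)
  i <- 1
  while (i <= n) {
    start <- disp$dispense_date[i]
    drugs <- character(0)
    last_cov <- start - 1   # last day covered by any drug of the line
    last_disp <- start      # last dispense date seen in the line
    end_date <- as.Date(NA); reason <- NA_character_
    j <- i
    while (j <= n) {
      t <- disp$dispense_date[j]
      k <- j
      while (k <= n && disp$dispense_date[k] == t) k <- k + 1
      grp <- j:(k - 1)   # all dispensings of day t are one event
      gap_anchor <- if (params$gap_basis == "coverage") last_cov else last_disp
      if (length(drugs) > 0 &&
          days_between(gap_anchor, t) - 1 >= params$gap_days) {
        reason <- "gap"; end_date <- min_date(last_cov, limit); break
      }
      if (length(drugs) > 0 && any(!(disp$drug[grp] %in% drugs)) &&
          days_between(start, t) > params$addition_window_days) {
        reason <- "new_drug_after_90d"; end_date <- min_date(t - 1, limit); break
      }
      drugs <- union(drugs, disp$drug[grp])
      cov_end <- max(t + disp$days_supply[grp] - 1)
      if (cov_end > last_cov) last_cov <- cov_end
      if (t > last_disp) last_disp <- t
      j <- k
    }
    if (is.na(reason)) {
      # no further dispensings: earliest of gap completion, death, data end
      gap_anchor <- if (params$gap_basis == "coverage") last_cov else last_disp
      gap_time <- gap_anchor + params$gap_days
      death_time <- if (is.na(death_date)) as.Date("9999-12-31") else death_date
      if (death_time <= min(gap_time, data_end)) {
        reason <- "death"; end_date <- min_date(last_cov, death_date)
      } else if (gap_time <= data_end) {
        reason <- "gap"; end_date <- min_date(last_cov, data_end)
      } else {
        reason <- "data_end"; end_date <- min_date(last_cov, data_end)
      }
    }
    drugs <- sort(drugs)
    lines[[length(lines) + 1]] <- data.frame(
      line_number = length(lines) + 1L,
      start_date = start, end_date = end_date,
      drugs = paste(drugs, collapse = "|"),
      end_reason = reason,
      regimen_class = classify_line(drugs, dictionary),
      named_regimen = name_regimen(drugs, dictionary),
      stringsAsFactors = FALSE)
    i <- j
  }
  out <- do.call(rbind, lines)
  if (is.null(out))
    out <- data.frame(line_number = integer(0),
                      start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      drugs = character(0), end_reason = character(0),
                      regimen_class = character(0),
                      named_regimen = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify a line of therapy
#'
#' Four first-line classes: `NA` (novel agents without chemotherapy),
#' `CCNA` (chemotherapy combined with novel agents), `CA` (chemotherapy
#' without novel agents), `SA` (steroids alone). Steroid co-medication
#' never changes the class of a line containing chemotherapy or novel
#' agents.
#'
#' @param drugs character vector of canonical drug names (or a line row's
#'   pipe-delimited `drugs` string).
#' @param dictionary drug dictionary.
#' @return one of `"NA"`, `"CCNA"`, `"CA"`, `"SA"`.
#' @export
classify_line <- function(drugs, dictionary = mm_drug_dictionary()) {
  drugs <- drug_vector(drugs)
  if (length(drugs) == 0) stopf("empty drug set")
  cats <- categorize_drug(drugs, dictionary)
  has_novel <- any(cats == "novel_agent")
  has_chemo <- any(cats == "chemotherapy")
  if (has_novel && has_chemo) "CCNA"
  else if (has_novel) "NA"
  else if (has_chemo) "CA"
  else "SA"
}

drug_vector <- function(drugs) {
  if (length(drugs) == 1 && grepl("|", drugs, fixed = TRUE))
    drugs <- strsplit(drugs, "|", fixed = TRUE)[[1]]
  unique(drugs[nzchar(drugs)])
}

#' Name the regimen of a line
#'
#' Maps the line's drug set to the named-regimen taxonomy used in
#' first-line treatment tables, first matching rule wins. Steroids never
#' affect the label. Lenalidomide-only novel lines (typical of later
#' lines) get `"Lenalidomide-based"` labels.
#'
#' @param drugs drug names (vector or pipe-delimited string).
#' @param dictionary drug dictionary.
#' @return a regimen label; `"Other"` if nothing matches.
#' @export
name_regimen <- function(drugs, dictionary = mm_drug_dictionary()) {
  drugs <- drug_vector(drugs)
  if (length(drugs) == 0) stopf("empty drug set")
  cats <- categorize_drug(drugs, dictionary)
  chemo <- drugs[cats == "chemotherapy"]
  novel <- drugs[cats == "novel_agent"]
  has <- function(x) x %in% drugs
  other_chemo <- setdiff(chemo, "melphalan")

  if (has("bortezomib") && has("thalidomide")) {
    if (has("melphalan")) return("Melphalan + bortezomib + thalidomide")
    if (length(chemo) > 0) return("Bortezomib + Thalidomide + chemo")
    return("Bortezomib + Thalidomide")
  }
  if (has("melphalan") && has("thalidomide")) return("Melphalan + thalidomide")
  if (has("melphalan") && has("bortezomib")) return("Melphalan + bortezomib")
  if (has("thalidomide"))
    return(if (length(chemo) > 0) "Thalidomide-based + chemo" else "Thalidomide-based")
  if (has("bortezomib"))
    return(if (length(chemo) > 0) "Bortezomib-based + chemo" else "Bortezomib-based")
  if (has("lenalidomide"))
    return(if (length(chemo) > 0) "Lenalidomide-based + chemo" else "Lenalidomide-based")
  if (length(chemo) == 1) {
    if (has("melphalan")) return("Melphalan-based")
    if (has("cyclophosphamide")) return("Cyclophosphamide-based")
    return("Other mono chemo")
  }
  if (length(chemo) == 2) return("Two-chemo combination")
  if (length(chemo) >= 3) return("Three-chemo combination")
  if (all(categorize_drug(drugs, dictionary) == "steroid")) return("Steroid")
  "Other"
}

#' Build lines for every cohort member
#'
#' @param bundle a `claims_bundle`.
#' @param cohort cohort table from [apply_selection()].
#' @param params a [lot_params()].
#' @param dictionary drug dictionary.
#' @return data.frame of lines with a leading `patient_id` column.
#' @export
cohort_lines <- function(bundle, cohort, params = lot_params(),
                         dictionary = mm_drug_dictionary()) {
  rx_by <- split(bundle$dispensings, bundle$dispensings$patient_id)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    rx <- rx_by[[cohort$patient_id[i]]]
    if (is.null(rx)) return(NULL)
    rx <- rx[rx$dispense_date >= cohort$index_date[i], , drop = FALSE]
    ln <- build_lines(rx, cohort$index_date[i],
                      cohort$death_date[i], cohort$followup_end[i],
                      params, dictionary)
    if (nrow(ln) == 0) return(NULL)
    cbind(patient_id = cohort$patient_id[i], ln, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- cbind(patient_id = character(0),
                 build_lines(bundle$dispensings[0, ], as.Date("2000-01-01"),
                             NA, as.Date("2000-01-02")))
  rownames(out) <- NULL
  out
}
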