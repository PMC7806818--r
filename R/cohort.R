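# Cohort selection: inclusion/exclusion rules, index date, treatment era,
# ASCT status and follow-up window.

MM_STUDY_START <- as.Date("2007-01-01")
MM_STUDY_END   <- as.Date("2015-12-31")
MM_CENSOR_DATE <- as.Date("2017-12-31")
MM_PERIOD_BOUNDARY <- as.Date("2012-06-01")

# Exclusion rules in the order used to pick the primary reason.
EXCLUSION_RULES <- c("no_mm_diagnosis", "index_out_of_window", "age_under_18",
                     "insufficient_lookback", "prior_cancer",
                     "plasma_cell_leukemia_within_2mo",
                     "no_mm_visit_after_index", "untreated")

#' Cohort selection configuration
#'
#' @param censor_date administrative end of follow-up.
#' @param period_boundary first day of the post-bortezomib era.
#' @param lookback_months required continuous enrollment before index.
#' @param pcl_window_days window after the first myeloma claim in which a
#'   plasma-cell-leukemia / other-immunoproliferative code (203.1x, 203.8x)
#'   triggers exclusion ("within 2 months", operationalized as 61 days).
#' @param prior_cancer_min_claims number of pre-index claims with a non-MM
#'   primary-cancer code (ICD-9 140-208, excluding 203.0x) needed to
#'   exclude; 1 is the conservative default.
#' @param study_start,study_end index-date eligibility window.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(censor_date = MM_CENSOR_DATE,
                          period_boundary = MM_PERIOD_BOUNDARY,
                          lookback_months = 12,
                          pcl_window_days = 61,
                          prior_cancer_min_claims = 1,
                          study_start = MM_STUDY_START,
                          study_end = MM_STUDY_END) {
  censor_date <- as.Date(censor_date)
  if (censor_date < as.Date(study_start)) stopf("censor date before study start")
  structure(list(censor_date = censor_date,
                 period_boundary = as.Date(period_boundary),
                 lookback_months = lookback_months,
                 pcl_window_days = pcl_window_days,
                 prior_cancer_min_claims = prior_cancer_min_claims,
                 study_start = as.Date(study_start),
                 study_end = as.Date(study_end)),
            class = "cohort_config")
}

is_mm_code <- function(code) {
  code == "203" | code == "203.0" | startsWith(code, "203.0")
}

is_pcl_code <- function(code) {
  startsWith(code, "203.1") | startsWith(code, "203.8")
}

is_cancer_code <- function(code) {
  root <- suppressWarnings(as.integer(icd9_root(code)))
  !is.na(root) & root >= 140 & root <= 208 & !is_mm_code(code)
}

#' Find the myeloma index date
#'
#' The index date is the earliest claim — any position, any setting — coded
#' 203, 203.0 or 203.0x.
#'
#' @param diagnoses diagnosis claims of a single patient.
#' @return a `Date`, or `NA` if the patient has no myeloma claim.
#' @export
find_index_date <- function(diagnoses) {
  hits <- diagnoses$claim_date[is_mm_code(diagnoses$icd9)]
  if (length(hits) == 0) return(as.Date(NA))
  min(hits)
}

#' Assign the bortezomib-era period
#'
#' @param index_date index date(s) within the study window.
#' @param config a [cohort_config()].
#' @return `"pre_bortezomib"` for diagnoses before the boundary date,
#'   `"post_bortezomib"` from the boundary (2012-06-01) on.
#' @export
assign_period <- function(index_date, config = cohort_config()) {
  index_date <- as.Date(index_date)
  if (any(is.na(index_date)) ||
      any(index_date < config$study_start | index_date > config$study_end))
    stopf("index date outside study window")
  ifelse(index_date >= config$period_boundary, "post_bortezomib", "pre_bortezomib")
}

#' Compute the follow-up window
#'
#' Follow-up runs from index to the earliest of death, dis-enrollment and
#' the administrative censor date.
#'
#' @param index_date index date.
#' @param death_date death date or `NA`.
#' @param enroll_end enrollment end or `NA` (open).
#' @param config a [cohort_config()].
#' @return list with `followup_end` (Date), `followup_years`, `died`.
#' @export
compute_followup <- function(index_date, death_date, enroll_end,
                             config = cohort_config()) {
  if (!is.na(death_date) && death_date < index_date)
    stopf("death before index date (corrupt data)")
  end <- min_date(death_date, enroll_end, config$censor_date)
  died <- !is.na(death_date) && death_date <= end
  list(followup_end = end,
       followup_years = days_between(index_date, end) / DAYS_PER_YEAR,
       died = died)
}

#' Flag autologous stem-cell transplantation
#'
#' @param index_date index date.
#' @param procedures procedure claims of the patient.
#' @return list with `asct` (logical) and `asct_date` (first ASCT on/after
#'   index, else `NA`); pre-index procedures are ignored.
#' @export
flag_asct <- function(index_date, procedures) {
  d <- procedures$procedure_date[procedures$procedure == "ASCT" &
                                   procedures$procedure_date >= index_date]
  if (length(d) == 0) list(asct = FALSE, asct_date = as.Date(NA))
  else list(asct = TRUE, asct_date = min(d))
}

#' Apply the cohort inclusion and exclusion rules
#'
#' Retains patients newly diagnosed in the study window, aged >= 18 at
#' index, continuously enrolled for the lookback period, with a further
#' myeloma visit after index and at least one myeloma-drug dispensing
#' on/after index; excludes prior non-myeloma primary cancer and early
#' plasma-cell-leukemia / other-immunoproliferative codes. Every excluded
#' patient is logged with all triggered rules; the first rule in the
#' documented order is flagged as primary.
#'
#' @param bundle a `claims_bundle`.
#' @param config a [cohort_config()].
#' @param dictionary drug dictionary.
#' @return list with `cohort` (one row per member) and `exclusions`
#'   (`patient_id`, `rule`, `detail`, `primary`).
#' @export
apply_selection <- function(bundle, config = cohort_config(),
                            dictionary = mm_drug_dictionary()) {
  stopifnot(inherits(bundle, "claims_bundle"))
  pats <- bundle$patients
  dx_by <- split(bundle$diagnoses, bundle$diagnoses$patient_id)
  rx_by <- split(bundle$dispensings, bundle$dispensings$patient_id)
  pr_by <- split(bundle$procedures, bundle$procedures$patient_id)
  death_idx <- match(pats$patient_id, bundle$deaths$patient_id)
  lookback_days <- round(config$lookback_months * DAYS_PER_MONTH)

  members <- vector("list", nrow(pats))
  excl <- list()
  for (i in seq_len(nrow(pats))) {
    pid <- pats$patient_id[i]
    dx <- dx_by[[pid]]
    if (is.null(dx)) dx <- bundle$diagnoses[0, ]
    rx <- rx_by[[pid]]
    if (is.null(rx)) rx <- bundle$dispensings[0, ]
    death_date <- if (is.na(death_idx[i])) as.Date(NA) else
      bundle$deaths$death_date[death_idx[i]]

    rules <- character(0); details <- character(0)
    fail <- function(rule, detail) {
      rules <<- c(rules, rule); details <<- c(details, detail)
    }

    index <- find_index_date(dx)
    if (is.na(index)) {
      fail("no_mm_diagnosis", "no qualifying 203/203.0x claim")
    } else {
      if (index < config$study_start || index > config$study_end)
        fail("index_out_of_window", sprintf("index %s", format(index)))
      age <- floor(days_between(pats$birth_date[i], index) / DAYS_PER_YEAR)
      if (age < 18) fail("age_under_18", sprintf("age %d at index", age))
      if (is.na(pats$enroll_start[i]) ||
          pats$enroll_start[i] > index - lookback_days)
        fail("insufficient_lookback",
             sprintf("enrolled from %s", format(pats$enroll_start[i])))
      pre <- dx[dx$claim_date < index, , drop = FALSE]
      n_cancer <- sum(is_cancer_code(pre$icd9))
      if (n_cancer >= config$prior_cancer_min_claims)
        fail("prior_cancer", sprintf("%d pre-index cancer claim(s)", n_cancer))
      pcl <- dx$icd9[is_pcl_code(dx$icd9) &
                       dx$claim_date >= index &
                       dx$claim_date <= index + config$pcl_window_days]
      if (length(pcl) > 0)
        fail("plasma_cell_leukemia_within_2mo",
             sprintf("code %s within %d days", pcl[1], config$pcl_window_days))
      if (!any(is_mm_code(dx$icd9) & dx$claim_date > index))
        fail("no_mm_visit_after_index", "no further MM claim after index")
      if (!any(rx$dispense_date >= index))
        fail("untreated", "no MM-drug dispensing on/after index")
    }

    if (length(rules) > 0) {
      ord <- order(match(rules, EXCLUSION_RULES))
      excl[[length(excl) + 1]] <- data.frame(
        patient_id = pid, rule = rules[ord], detail = details[ord],
        primary = seq_along(rules) == 1, stringsAsFactors = FALSE)
      next
    }

    pr <- pr_by[[pid]]
    if (is.null(pr)) pr <- bundle$procedures[0, ]
    fu <- compute_followup(index, death_date, pats$enroll_end[i], config)
    as <- flag_asct(index, pr)
    members[[i]] <- data.frame(
      patient_id = pid, index_date = index,
      age_at_dx = floor(days_between(pats$birth_date[i], index) / DAYS_PER_YEAR),
      sex = pats$sex[i],
      period = assign_period(index, config),
      treated = TRUE, asct = as$asct, asct_date = as$asct_date,
      followup_end = fu$followup_end, followup_years = fu$followup_years,
      died = fu$died, death_date = death_date,
      stringsAsFactors = FALSE)
  }

  cohort <- do.call(rbind, members[!vapply(members, is.null, logical(1))])
  if (is.null(cohort)) {
    cohort <- data.frame(patient_id = character(0), index_date = as.Date(character(0)),
                         age_at_dx = integer(0), sex = character(0),
                         period = character(0), treated = logical(0),
                         asct = logical(0), asct_date = as.Date(character(0)),
                         followup_end = as.Date(character(0)),
                         followup_years = numeric(0), died = logical(0),
                         death_date = as.Date(character(0)),
                         stringsAsFactors = FALSE)
  }
  rownames(cohort) <- NULL
  exclusions <- if (length(excl) > 0) do.call(rbind, excl) else
    data.frame(patient_id = character(0), rule = character(0),
               detail = character(0), primary = logical(0),
               stringsAsFactors = FALSE)
  rownames(exclusions) <- NULL
  list(cohort = cohort, exclusions = exclusions)
}
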