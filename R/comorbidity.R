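# Charlson/Deyo comorbidity index and the four myeloma-associated
# comorbidity flags, assessed over the 12 months before the index date.

MM_COMORBIDITY_CODES <- list(
  anemia   = c("281", "283", "284", "285", "776"),
  renal    = "586",
  pneumonia = "486",
  fracture = as.character(800:829)
)

# condition groups matched by each claim code (character vector of group names)
match_deyo_conditions <- function(code, map) {
  hit <- vapply(seq_len(nrow(map)), function(i) {
    any(vapply(strsplit(map$icd9_prefixes[i], "|", fixed = TRUE)[[1]],
               function(p) icd9_matches(code, p), logical(1)))
  }, logical(1))
  map$condition[hit]
}

#' Charlson comorbidity index (Deyo ICD-9-CM adaptation)
#'
#' Sums the Deyo weights over the distinct condition groups matched by any
#' diagnosis claim in the pre-index window. Each group counts once;
#' hierarchy rules silence a mild condition when its severe counterpart is
#' present (diabetes with complications over diabetes, moderate/severe over
#' mild liver disease, metastatic disease over other malignancy). The
#' malignancy and metastatic groups are excluded by default: every patient
#' in a myeloma cohort carries a 200-208 code, which would add a constant.
#'
#' @param diagnoses diagnosis claims of one patient.
#' @param index_date index date; the window is
#'   `[index - window_days, index)`.
#' @param window_days assessment window length in days.
#' @param map Deyo map from [deyo_map()].
#' @param include_malignancy logical; if `TRUE` the malignancy and
#'   metastatic groups contribute to the score.
#' @return nonnegative integer score.
#' @examples
#' dx <- data.frame(patient_id = "p", claim_date = as.Date("2013-06-01"),
#'                  icd9 = "250.00", position = "primary",
#'                  setting = "outpatient")
#' compute_cci(dx, as.Date("2014-01-01"))  # 1
#' @export
compute_cci <- function(diagnoses, index_date, window_days = 365,
                        map = deyo_map(), include_malignancy = FALSE) {
  win <- diagnoses[diagnoses$claim_date < index_date &
                     diagnoses$claim_date >= index_date - window_days, ,
                   drop = FALSE]
  if (nrow(win) == 0) return(0L)
  groups <- unique(unlist(lapply(unique(win$icd9), match_deyo_conditions, map = map)))
  if (!include_malignancy)
    groups <- setdiff(groups, c("malignancy", "metastatic_solid_tumor"))
  # hierarchy: drop any group superseded by a present severe group
  superseded <- map$supersedes[match(groups, map$condition)]
  groups <- setdiff(groups, superseded[superseded != ""])
  sum(map$weight[match(groups, map$condition)])
}

#' Band a CCI score as in standard cohort tables
#'
#' @param cci integer score(s).
#' @return factor with levels `"0"`, `"1"`, `"2"`, `"3+"`.
#' @export
cci_band <- function(cci) {
  cut(cci, breaks = c(-Inf, 0, 1, 2, Inf), labels = c("0", "1", "2", "3+"))
}

#' Flag the four myeloma-associated comorbidities
#'
#' A condition is flagged when the window holds at least three outpatient
#' visit claims (distinct claim dates) or at least one inpatient claim with
#' a primary or secondary diagnosis of: anemia (281, 283, 284, 285, 776),
#' renal injury/failure (586), pneumonia (486) or bone fracture (800-829).
#'
#' @param diagnoses diagnosis claims of one patient.
#' @param index_date index date; window is `[index - window_days, index]`
#'   (through the index date, i.e. "at diagnosis").
#' @param window_days assessment window length in days.
#' @return named logical vector `anemia`, `renal`, `pneumonia`, `fracture`.
#' @export
flag_mm_comorbidities <- function(diagnoses, index_date, window_days = 365) {
  win <- diagnoses[diagnoses$claim_date <= index_date &
                     diagnoses$claim_date >= index_date - window_days, ,
                   drop = FALSE]
  vapply(MM_COMORBIDITY_CODES, function(prefixes) {
    hit <- vapply(win$icd9, function(code)
      any(vapply(prefixes, function(p) icd9_matches(code, p), logical(1))),
      logical(1))
    if (!any(hit)) return(FALSE)
    sub <- win[hit, , drop = FALSE]
    inpt <- sum(sub$setting == "inpatient")
    outpt_visits <- length(unique(sub$claim_date[sub$setting == "outpatient"]))
    inpt >= 1 || outpt_visits >= 3
  }, logical(1))
}

#' Comorbidity profiles for a whole cohort
#'
#' @param bundle a `claims_bundle`.
#' @param cohort cohort table from [apply_selection()].
#' @param window_days assessment window in days.
#' @param map Deyo map.
#' @param include_malignancy see [compute_cci()].
#' @return data.frame: `patient_id`, `cci`, `cci_band`, `anemia`, `renal`,
#'   `pneumonia`, `fracture`.
#' @export
comorbidity_profiles <- function(bundle, cohort, window_days = 365,
                                 map = deyo_map(), include_malignancy = FALSE) {
  dx_by <- split(bundle$diagnoses, bundle$diagnoses$patient_id)
  empty <- bundle$diagnoses[0, ]
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    dx <- dx_by[[cohort$patient_id[i]]]
    if (is.null(dx)) dx <- empty
    cci <- compute_cci(dx, cohort$index_date[i], window_days, map,
                       include_malignancy)
    flags <- flag_mm_comorbidities(dx, cohort$index_date[i], window_days)
    data.frame(patient_id = cohort$patient_id[i], cci = cci,
               cci_band = as.character(cci_band(cci)),
               anemia = flags[["anemia"]], renal = flags[["renal"]],
               pneumonia = flags[["pneumonia"]], fracture = flags[["fracture"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(patient_id = character(0), cci = integer(0),
                      cci_band = character(0), anemia = logical(0),
                      renal = logical(0), pneumonia = logical(0),
                      fracture = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
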