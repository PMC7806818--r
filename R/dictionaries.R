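#' Myeloma drug dictionary
#'
#' Canonical lowercase drug names mapped to treatment categories. The
#' chemotherapy and novel-agent lists follow the reimbursement-code
#' definitions used for myeloma claims in Taiwan; steroids are not
#' enumerated by any coding standard, so dexamethasone and prednisolone are
#' included by default and further substances can be appended.
#'
#' @param extra_steroids optional character vector of additional steroid
#'   names to include (lowercased).
#' @return a data.frame with columns `drug` and `category`
#'   (one of `"chemotherapy"`, `"novel_agent"`, `"steroid"`).
#' @examples
#' dict <- mm_drug_dictionary()
#' subset(dict, category == "novel_agent")
#' @export
mm_drug_dictionary <- function(extra_steroids = character(0)) {
  chemo <- c("cyclophosphamide", "melphalan", "bendamustine", "vincristine",
             "etoposide", "liposomal doxorubicin", "cisplatin")
  novel <- c("bortezomib", "thalidomide", "lenalidomide")
  steroid <- unique(c("dexamethasone", "prednisolone", tolower(extra_steroids)))
  overlap <- intersect(steroid, c(chemo, novel))
  if (length(overlap) > 0)
    stopf("steroid list overlaps other categories: %s", paste(overlap, collapse = ", "))
  data.frame(
    drug = c(chemo, novel, steroid),
    category = c(rep("chemotherapy", length(chemo)),
                 rep("novel_agent", length(novel)),
                 rep("steroid", length(steroid))),
    stringsAsFactors = FALSE
  )
}

#' Categorize a drug
#'
#' @param drug character vector of canonical drug names.
#' @param dictionary a drug dictionary as returned by [mm_drug_dictionary()].
#' @return character vector of categories.
#' @examples
#' categorize_drug("bortezomib")    # "novel_agent"
#' categorize_drug("melphalan")     # "chemotherapy"
#' @export
categorize_drug <- function(drug, dictionary = mm_drug_dictionary()) {
  drug <- tolower(trimws(drug))
  idx <- match(drug, dictionary$drug)
  if (anyNA(idx)) {
    stopf("unknown drug: %s", paste(unique(drug[is.na(idx)]), collapse = ", "))
  }
  dictionary$category[idx]
}

#' Deyo adaptation of the Charlson comorbidity map for ICD-9-CM
#'
#' Seventeen condition groups, each with its ICD-9-CM code prefixes and
#' Charlson weight, following the Deyo (1992) administrative-data
#' adaptation. Shipped as a plain-text table under `extdata` so the code
#' sets can be audited or amended without code changes; this function loads
#' and validates it.
#'
#' A `supersedes` column encodes the hierarchy rules: a severe condition
#' (e.g. diabetes with complications) silences its mild counterpart when
#' both are coded.
#'
#' @param path optional path to an alternative map file with columns
#'   `condition`, `icd9_prefixes` (pipe-delimited), `weight`, `supersedes`.
#' @return data.frame with those four columns; `weight` integer.
#' @export
deyo_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "deyo_icd9.csv", package = "mmpathways")
  }
  map <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("condition", "icd9_prefixes", "weight", "supersedes")
  if (!all(need %in% names(map))) stopf("Deyo map must have columns: %s", paste(need, collapse = ", "))
  map$weight <- as.integer(map$weight)
  if (!all(map$weight %in% c(1L, 2L, 3L, 6L))) stopf("Deyo weights must be in {1,2,3,6}")
  if (anyDuplicated(map$condition)) stopf("duplicate Deyo condition groups")
  bad <- setdiff(setdiff(map$supersedes, ""), map$condition)
  if (length(bad) > 0) stopf("supersedes refers to unknown condition: %s", paste(bad, collapse = ", "))
  map
}
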