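# CSV readers/writers for the five flat claims tables, with row-level
# validation. Malformed rows are never silently dropped: every rejected row
# is reported with its table, row number and reason.

CLAIMS_SCHEMAS <- list(
  patients    = c("patient_id", "birth_date", "sex", "enroll_start", "enroll_end"),
  diagnoses   = c("patient_id", "claim_date", "icd9", "position", "setting"),
  dispensings = c("patient_id", "dispense_date", "drug", "days_supply", "setting"),
  procedures  = c("patient_id", "procedure_date", "procedure"),
  deaths      = c("patient_id", "death_date")
)

empty_rejects <- function() {
  data.frame(table = character(0), row = integer(0),
             patient_id = character(0), reason = character(0),
             stringsAsFactors = FALSE)
}

add_reject <- function(rejects, table, rows, patient_id, reason) {
  if (length(rows) == 0) return(rejects)
  rbind(rejects, data.frame(table = table, row = rows,
                            patient_id = patient_id, reason = reason,
                            stringsAsFactors = FALSE))
}

#' Assemble a claims bundle from typed tables
#'
#' Light constructor used by the simulator and by [read_claims_bundle()];
#' checks column names only.
#'
#' @param patients,diagnoses,dispensings,procedures,deaths data.frames with
#'   the documented schemas (dates as `Date`, `days_supply` integer).
#' @param rejects optional reject report.
#' @return an object of class `claims_bundle`.
#' @export
claims_bundle <- function(patients, diagnoses, dispensings, procedures, deaths,
                          rejects = empty_rejects()) {
  tabs <- list(patients = patients, diagnoses = diagnoses,
               dispensings = dispensings, procedures = procedures,
               deaths = deaths)
  for (nm in names(tabs)) {
    missing <- setdiff(CLAIMS_SCHEMAS[[nm]], names(tabs[[nm]]))
    if (length(missing) > 0)
      stopf("table '%s' lacks columns: %s", nm, paste(missing, collapse = ", "))
  }
  structure(c(tabs, list(rejects = rejects)), class = "claims_bundle")
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("Claims bundle\n")
  for (nm in names(CLAIMS_SCHEMAS))
    cat(sprintf("  %-12s %6d rows\n", nm, nrow(x[[nm]])))
  cat(sprintf("  %-12s %6d rows\n", "rejects", nrow(x$rejects)))
  invisible(x)
}

#' Read the five claims tables
#'
#' Reads `patients.csv`, `diagnoses.csv`, `dispensings.csv`,
#' `procedures.csv` and `deaths.csv`, parses every field, and collects any
#' row violating a schema invariant (unparseable date, unknown drug,
#' `days_supply < 1`, ...) into the bundle's reject report rather than
#' dropping it silently.
#'
#' @param paths either a directory containing the five files under their
#'   standard names, or a named character vector/list with elements
#'   `patients`, `diagnoses`, `dispensings`, `procedures`, `deaths`.
#' @param dictionary drug dictionary used to validate dispensed drugs.
#' @return a `claims_bundle`; component `rejects` holds the reject report
#'   (`table`, `row`, `patient_id`, `reason`).
#' @export
read_claims_bundle <- function(paths, dictionary = mm_drug_dictionary()) {
  if (is.character(paths) && length(paths) == 1 && dir.exists(paths)) {
    paths <- file.path(paths, paste0(names(CLAIMS_SCHEMAS), ".csv"))
    names(paths) <- names(CLAIMS_SCHEMAS)
  }
  paths <- as.list(paths)
  missing <- setdiff(names(CLAIMS_SCHEMAS), names(paths))
  if (length(missing) > 0)
    stopf("missing table paths: %s", paste(missing, collapse = ", "))
  absent <- unlist(paths[!file.exists(unlist(paths))])
  if (length(absent) > 0)
    stopf("claims file not found: %s", paste(absent, collapse = ", "))

  raw <- lapply(names(CLAIMS_SCHEMAS), function(nm) {
    x <- utils::read.csv(paths[[nm]], stringsAsFactors = FALSE,
                         colClasses = "character")
    missing <- setdiff(CLAIMS_SCHEMAS[[nm]], names(x))
    if (length(missing) > 0)
      stopf("file '%s' lacks columns: %s", paths[[nm]],
            paste(missing, collapse = ", "))
    x[, CLAIMS_SCHEMAS[[nm]], drop = FALSE]
  })
  names(raw) <- names(CLAIMS_SCHEMAS)

  rejects <- empty_rejects()
  keep_valid <- function(tab, nm, bad, reason) {
    new_bad <- bad & !tab$.rejected
    rejects <<- add_reject(rejects, nm, tab$.row[new_bad],
                           tab$patient_id[new_bad], reason)
    tab$.rejected[new_bad] <- TRUE
    tab
  }
  prep <- function(tab) {
    tab$.row <- seq_len(nrow(tab))
    tab$.rejected <- rep(FALSE, nrow(tab))
    tab
  }
  date_col <- function(tab, nm, col) {
    d <- parse_iso_date(tab[[col]])
    open_ok <- col == "enroll_end"  # open enrollment allowed
    bad <- is.na(d) & !(open_ok & (is.na(tab[[col]]) | trimws(tab[[col]]) == ""))
    tab <- keep_valid(tab, nm, bad, sprintf("unparseable date in %s", col))
    tab[[col]] <- d
    tab
  }
  enum_col <- function(tab, nm, col, allowed) {
    tab[[col]] <- tolower(trimws(tab[[col]]))
    keep_valid(tab, nm, !(tab[[col]] %in% allowed), sprintf("invalid %s", col))
  }

  pa <- prep(raw$patients)
  pa <- keep_valid(pa, "patients", is.na(pa$patient_id) | pa$patient_id == "",
                   "missing patient_id")
  pa <- date_col(pa, "patients", "birth_date")
  pa <- date_col(pa, "patients", "enroll_start")
  pa <- date_col(pa, "patients", "enroll_end")
  pa <- enum_col(pa, "patients", "sex", c("male", "female"))
  pa <- keep_valid(pa, "patients",
                   !is.na(pa$enroll_end) & !is.na(pa$enroll_start) &
                     pa$enroll_end < pa$enroll_start,
                   "enroll_start after enroll_end")
  pa <- keep_valid(pa, "patients",
                   !is.na(pa$birth_date) & !is.na(pa$enroll_start) &
                     pa$birth_date > pa$enroll_start,
                   "birth_date after enroll_start")

  dx <- prep(raw$diagnoses)
  dx <- date_col(dx, "diagnoses", "claim_date")
  dx$icd9 <- toupper(trimws(dx$icd9))
  dx <- keep_valid(dx, "diagnoses", !is_valid_icd9(dx$icd9), "invalid icd9 code")
  dx <- enum_col(dx, "diagnoses", "position", c("primary", "secondary"))
  dx <- enum_col(dx, "diagnoses", "setting", c("outpatient", "inpatient"))

  rx <- prep(raw$dispensings)
  rx <- date_col(rx, "dispensings", "dispense_date")
  rx$drug <- tolower(trimws(rx$drug))
  rx <- keep_valid(rx, "dispensings", !(rx$drug %in% dictionary$drug),
                   "unknown drug")
  ds <- suppressWarnings(as.integer(rx$days_supply))
  rx <- keep_valid(rx, "dispensings", is.na(ds), "unparseable days_supply")
  rx <- keep_valid(rx, "dispensings", !is.na(ds) & ds < 1, "days_supply < 1")
  rx$days_supply <- ds
  rx <- enum_col(rx, "dispensings", "setting", c("outpatient", "inpatient"))

  pr <- prep(raw$procedures)
  pr <- date_col(pr, "procedures", "procedure_date")
  pr <- enum_col(pr, "procedures", "procedure", c("asct", "other"))
  pr$procedure <- toupper(pr$procedure)
  pr$procedure[pr$procedure == "OTHER"] <- "other"

  de <- prep(raw$deaths)
  de <- date_col(de, "deaths", "death_date")
  de <- keep_valid(de, "deaths", duplicated(de$patient_id) & !de$.rejected,
                   "duplicate death record")

  strip <- function(tab, nm) {
    out <- tab[!tab$.rejected, CLAIMS_SCHEMAS[[nm]], drop = FALSE]
    rownames(out) <- NULL
    out
  }
  claims_bundle(strip(pa, "patients"), strip(dx, "diagnoses"),
                strip(rx, "dispensings"), strip(pr, "procedures"),
                strip(de, "deaths"), rejects = rejects)
}

#' Write a claims bundle to a directory
#'
#' Emits the five CSV tables with ISO-8601 dates; a round trip through
#' [read_claims_bundle()] reproduces the records exactly.
#'
#' @param bundle a `claims_bundle`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_claims_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "claims_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(CLAIMS_SCHEMAS)) {
    tab <- bundle[[nm]]
    for (col in names(tab)) if (inherits(tab[[col]], "Date"))
      tab[[col]] <- format(tab[[col]], "%Y-%m-%d")
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tab, p, row.names = FALSE, quote = TRUE, na = "")
    paths <- c(paths, p)
  }
  invisible(paths)
}
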