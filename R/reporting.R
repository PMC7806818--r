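# Paper-shaped summary tables with small-cell privacy suppression.

AGE_BANDS <- c("18-29", "30-39", "40-49", "50-59", "60-69", "70-79", ">=80")

age_band <- function(age) {
  cut(age, breaks = c(-Inf, 29, 39, 49, 59, 69, 79, Inf), labels = AGE_BANDS)
}

new_summary_table <- function(display, count, n) {
  structure(list(display = display, count = count, n = n,
                 suppressed = matrix(FALSE, nrow(display), ncol(display),
                                     dimnames = dimnames(display)),
                 mask = NULL),
            class = "summary_table")
}

fmt_n_pct <- function(k, n) {
  pct <- if (n > 0) 100 * k / n else 0
  sprintf("%d (%.1f)", k, pct)
}

#' Demographics and clinical characteristics table
#'
#' One column per transplant-status x first-line-class stratum; rows for
#' sex, age (mean/SD and bands), follow-up duration, myeloma-associated
#' comorbidities and the Charlson index. Apply
#' [suppress_small_counts()] before rendering for release.
#'
#' @param cohort cohort table.
#' @param comorbidity table from [comorbidity_profiles()].
#' @param lines line table from [cohort_lines()].
#' @param period restrict to one era (`"pre_bortezomib"` /
#'   `"post_bortezomib"`) or `NULL` for all patients.
#' @return a `summary_table`.
#' @export
demographics_table <- function(cohort, comorbidity, lines, period = NULL) {
  if (!is.null(period)) cohort <- cohort[cohort$period == period, , drop = FALSE]
  l1 <- lines[lines$line_number == 1, , drop = FALSE]
  cohort$first_line_class <- l1$regimen_class[match(cohort$patient_id,
                                                    l1$patient_id)]
  cm <- comorbidity[match(cohort$patient_id, comorbidity$patient_id), ,
                    drop = FALSE]

  cols <- list()
  for (a in c(TRUE, FALSE)) for (cl in c("NA", "CCNA", "CA", "SA")) {
    idx <- which(cohort$asct == a & !is.na(cohort$first_line_class) &
                   cohort$first_line_class == cl)
    cols[[sprintf("%s/%s", if (a) "ASCT" else "noASCT", cl)]] <- idx
  }
  # empty strata are kept as n = 0 columns
  row_names <- c("N", "Male", "Female", "Age mean (SD)", AGE_BANDS,
                 "Follow-up mean (SD)", "Follow-up median (range)",
                 "Follow-up Q1, Q3",
                 "Renal impairment", "Anemia", "Bone fracture", "Pneumonia",
                 "Mean CCI (SD)", "CCI = 0", "CCI = 1", "CCI = 2", "CCI >= 3")
  display <- matrix("", length(row_names), length(cols),
                    dimnames = list(row_names, names(cols)))
  count <- matrix(NA_real_, length(row_names), length(cols),
                  dimnames = list(row_names, names(cols)))
  n_col <- integer(length(cols))

  for (j in seq_along(cols)) {
    idx <- cols[[j]]
    n <- length(idx)
    n_col[j] <- n
    co <- cohort[idx, , drop = FALSE]
    cmj <- cm[idx, , drop = FALSE]
    put_count <- function(row, k) {
      display[row, j] <<- fmt_n_pct(k, n)
      count[row, j] <<- k
    }
    display["N", j] <- as.character(n); count["N", j] <- n
    put_count("Male", sum(co$sex == "male"))
    put_count("Female", sum(co$sex == "female"))
    if (n > 0) {
      display["Age mean (SD)", j] <- sprintf("%.1f (%.1f)", mean(co$age_at_dx),
                                             stats::sd(co$age_at_dx))
      bands <- table(age_band(co$age_at_dx))
      for (b in AGE_BANDS) put_count(b, as.integer(bands[[b]]))
      fy <- co$followup_years
      display["Follow-up mean (SD)", j] <- sprintf("%.2f (%.2f)", mean(fy),
                                                   stats::sd(fy))
      display["Follow-up median (range)", j] <-
        sprintf("%.2f (%.2f-%.2f)", stats::median(fy), min(fy), max(fy))
      q <- stats::quantile(fy, c(0.25, 0.75), names = FALSE)
      display["Follow-up Q1, Q3", j] <- sprintf("%.2f, %.2f", q[1], q[2])
      put_count("Renal impairment", sum(cmj$renal))
      put_count("Anemia", sum(cmj$anemia))
      put_count("Bone fracture", sum(cmj$fracture))
      put_count("Pneumonia", sum(cmj$pneumonia))
      display["Mean CCI (SD)", j] <- sprintf("%.1f (%.1f)", mean(cmj$cci),
                                             stats::sd(cmj$cci))
      cb <- table(factor(cmj$cci_band, levels = c("0", "1", "2", "3+")))
      put_count("CCI = 0", as.integer(cb[["0"]]))
      put_count("CCI = 1", as.integer(cb[["1"]]))
      put_count("CCI = 2", as.integer(cb[["2"]]))
      put_count("CCI >= 3", as.integer(cb[["3+"]]))
    }
  }
  new_summary_table(display, count, stats::setNames(n_col, names(cols)))
}

#' First-line regimen table
#'
#' Counts (and within-column percentages) of named first-line regimens by
#' stratum.
#'
#' @param lines line table.
#' @param cohort cohort table.
#' @param by stratum columns of the cohort (default transplant status and
#'   era).
#' @return a `summary_table`.
#' @export
regimen_table <- function(lines, cohort, by = c("asct", "period")) {
  l1 <- lines[lines$line_number == 1, , drop = FALSE]
  idx <- match(l1$patient_id, cohort$patient_id)
  key <- do.call(paste, c(unname(cohort[idx, by, drop = FALSE]), list(sep = "/")))
  regimens <- sort(unique(l1$named_regimen))
  kcols <- sort(unique(key))
  display <- matrix("", length(regimens) + 1, length(kcols),
                    dimnames = list(c("N", regimens), kcols))
  count <- matrix(NA_real_, nrow(display), ncol(display),
                  dimnames = dimnames(display))
  n_col <- integer(length(kcols))
  for (j in seq_along(kcols)) {
    sub <- l1$named_regimen[key == kcols[j]]
    n <- length(sub); n_col[j] <- n
    display["N", j] <- as.character(n); count["N", j] <- n
    for (r in regimens) {
      k <- sum(sub == r)
      display[r, j] <- fmt_n_pct(k, n)
      count[r, j] <- k
    }
  }
  new_summary_table(display, count, stats::setNames(n_col, kcols))
}

#' Suppress small cells for privacy
#'
#' Masks every count-typed cell with a non-zero count below the threshold
#' (and its percentage); zeros and counts at or above the threshold are
#' untouched. This is the standard small-cell release rule for claims
#' data.
#'
#' @param table a `summary_table`.
#' @param threshold minimum releasable non-zero count (default 3: counts 1
#'   and 2 are masked).
#' @param mask the token rendered in place of a masked cell.
#' @return the table with masked `display` cells and the `suppressed`
#'   matrix set.
#' @export
suppress_small_counts <- function(table, threshold = 3, mask = "<3") {
  stopifnot(inherits(table, "summary_table"))
  hit <- !is.na(table$count) & table$count > 0 & table$count < threshold
  table$display[hit] <- mask
  table$suppressed <- hit
  table$mask <- mask
  table
}

#' @export
print.summary_table <- function(x, ...) {
  print(as.data.frame(x), right = TRUE)
  if (any(x$suppressed))
    cat(sprintf("Cells rendered '%s' hold non-zero counts below the release threshold.\n",
                x$mask %||% "<3"))
  invisible(x)
}

#' @export
as.data.frame.summary_table <- function(x, ...) {
  as.data.frame(x$display, stringsAsFactors = FALSE)
}

#' Write a summary table as CSV
#'
#' @param table a `summary_table`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_summary_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = TRUE)
  invisible(path)
}
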