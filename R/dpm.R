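# Disease-progression model: per-patient journeys through treatment lines
# and the empirical Markov model over them.
#
# States: L1, L2, L3 (line-indexed; lines beyond the third fold into L3),
# DEATH, CONTINUE (still on the current line at study end). DEATH and
# CONTINUE are absorbing. Transition probabilities are maximum-likelihood
# multinomial estimates: p(dest | src) = transitions(src -> dest) /
# occupancy(src).

JOURNEY_STATES <- c("L1", "L2", "L3", "DEATH", "CONTINUE")
MAX_REPORTED_LINE <- 3L

#' Build the state path of one patient
#'
#' @param lines the patient's therapy lines (ordered), as from
#'   [build_lines()].
#' @param death_date death date or `NA`.
#' @param followup_end end of follow-up.
#' @return list with `states` (character path starting at `"L1"` and ending
#'   in `"DEATH"` or `"CONTINUE"`) and `dates` (state entry dates; the
#'   terminal date is the death date or follow-up end).
#' @export
build_journey <- function(lines, death_date = NA, followup_end) {
  if (nrow(lines) == 0) stopf("patient has no therapy lines")
  death_date <- as.Date(death_date)
  if (!is.na(death_date) && death_date < lines$start_date[1])
    stopf("death before first-line start")
  died <- !is.na(death_date) && death_date <= followup_end
  depth <- min(nrow(lines), MAX_REPORTED_LINE)
  states <- paste0("L", seq_len(depth))
  dates <- lines$start_date[seq_len(depth)]
  if (died) {
    states <- c(states, "DEATH"); dates <- c(dates, death_date)
  } else {
    states <- c(states, "CONTINUE"); dates <- c(dates, followup_end)
  }
  list(states = states, dates = dates)
}

#' Build journeys for a whole cohort
#'
#' @param lines line table from [cohort_lines()].
#' @param cohort cohort table; only patients with at least one line get a
#'   journey (cohort selection requires treatment, so normally all).
#' @return data.frame of class `patient_journeys`: `patient_id`, stratum
#'   keys (`period`, `asct`, `first_line_class`), `path` (states joined by
#'   `">"`), `n_lines`, entry dates `d1`..`d3`, and `end_date`.
#' @export
cohort_journeys <- function(lines, cohort) {
  by <- split(lines, lines$patient_id)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    ln <- by[[cohort$patient_id[i]]]
    if (is.null(ln)) return(NULL)
    ln <- ln[order(ln$line_number), , drop = FALSE]
    j <- build_journey(ln, cohort$death_date[i], cohort$followup_end[i])
    ds <- rep(as.Date(NA), MAX_REPORTED_LINE)
    k <- min(nrow(ln), MAX_REPORTED_LINE)
    ds[seq_len(k)] <- ln$start_date[seq_len(k)]
    data.frame(patient_id = cohort$patient_id[i],
               period = cohort$period[i], asct = cohort$asct[i],
               first_line_class = ln$regimen_class[1],
               path = paste(j$states, collapse = ">"),
               n_lines = nrow(ln),
               d1 = ds[1], d2 = ds[2], d3 = ds[3],
               end_date = j$dates[length(j$dates)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(patient_id = character(0), period = character(0),
                      asct = logical(0), first_line_class = character(0),
                      path = character(0), n_lines = integer(0),
                      d1 = as.Date(character(0)), d2 = as.Date(character(0)),
                      d3 = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("patient_journeys", "data.frame")
  out
}

journey_pairs <- function(paths) {
  st <- strsplit(paths, ">", fixed = TRUE)
  data.frame(
    id = rep(seq_along(st), vapply(st, length, integer(1)) - 1),
    from = unlist(lapply(st, function(s) s[-length(s)])),
    to = unlist(lapply(st, function(s) s[-1])),
    stringsAsFactors = FALSE)
}

stratum_key <- function(journeys, strata) {
  if (length(strata) == 0) rep("all", nrow(journeys))
  else do.call(paste, c(unname(journeys[strata]), list(sep = "/")))
}

#' Estimate the Markov disease-progression model
#'
#' Maximum-likelihood multinomial estimation of the transition
#' probabilities between journey states, optionally stratified (by default
#' by era, transplant status and first-line class). Returns a classed fit
#' with `print`, `summary`, `coef`, `simulate` and `plot` methods.
#'
#' @param journeys a `patient_journeys` table from [cohort_journeys()].
#' @param strata character vector of journey columns to stratify on; use
#'   `character(0)` for a pooled model.
#' @return an object of class `mm_dpm` with components `transitions`
#'   (stratum, `from`, `to`, `count`, `n_at_risk`, `probability`),
#'   `durations` (inter-line gaps in months, see
#'   [summarize_durations()]), `strata`, `n` (journeys used).
#' @export
estimate_transitions <- function(journeys,
                                 strata = c("period", "asct",
                                            "first_line_class")) {
  if (nrow(journeys) == 0) {
    warning("no journeys: empty transition table")
    return(structure(list(
      transitions = data.frame(stratum = character(0), from = character(0),
                               to = character(0), count = integer(0),
                               n_at_risk = integer(0),
                               probability = numeric(0),
                               stringsAsFactors = FALSE),
      durations = summarize_durations(journeys, strata),
      strata = strata, n = 0L), class = "mm_dpm"))
  }
  key <- stratum_key(journeys, strata)
  pieces <- lapply(split(seq_len(nrow(journeys)), key), function(idx) {
    pairs <- journey_pairs(journeys$path[idx])
    cnt <- as.data.frame(table(from = pairs$from, to = pairs$to),
                         stringsAsFactors = FALSE)
    cnt <- cnt[cnt$Freq > 0, , drop = FALSE]
    occ <- tapply(pairs$id, pairs$from, function(x) length(x))
    cnt$n_at_risk <- as.integer(occ[cnt$from])
    data.frame(from = cnt$from, to = cnt$to, count = as.integer(cnt$Freq),
               n_at_risk = cnt$n_at_risk,
               probability = cnt$Freq / cnt$n_at_risk,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, Map(function(k, d) cbind(stratum = k, d,
                                                 stringsAsFactors = FALSE),
                            names(pieces), pieces))
  ord <- order(tab$stratum, match(tab$from, JOURNEY_STATES),
               match(tab$to, JOURNEY_STATES))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(transitions = tab,
                 durations = summarize_durations(journeys, strata),
                 strata = strata, n = nrow(journeys)),
            class = "mm_dpm")
}

#' Summaries of inter-line durations
#'
#' Months (days / 30.4375) between commencement of consecutive lines,
#' summarized per stratum and transition.
#'
#' @param journeys a `patient_journeys` table.
#' @param strata stratum columns, as in [estimate_transitions()].
#' @return data.frame: stratum, `transition`, `n`, `mean`, `median`, `q1`,
#'   `q3`, `min`, `max` (months).
#' @export
summarize_durations <- function(journeys,
                                strata = c("period", "asct",
                                           "first_line_class")) {
  empty <- data.frame(stratum = character(0), transition = character(0),
                      n = integer(0), mean = numeric(0), median = numeric(0),
                      q1 = numeric(0), q3 = numeric(0), min = numeric(0),
                      max = numeric(0), stringsAsFactors = FALSE)
  if (nrow(journeys) == 0) return(empty)
  key <- stratum_key(journeys, strata)
  gaps <- list(`L1>L2` = days_between(journeys$d1, journeys$d2) / DAYS_PER_MONTH,
               `L2>L3` = days_between(journeys$d2, journeys$d3) / DAYS_PER_MONTH)
  rows <- list()
  for (k in sort(unique(key))) {
    for (tr in names(gaps)) {
      g <- gaps[[tr]][key == k]
      g <- g[!is.na(g)]
      if (length(g) == 0) next
      q <- stats::quantile(g, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        stratum = k, transition = tr, n = length(g), mean = mean(g),
        median = q[2], q1 = q[1], q3 = q[3], min = min(g), max = max(g),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.mm_dpm <- function(x, digits = 3, ...) {
  cat(sprintf("Markov disease-progression model (%d journeys", x$n))
  if (length(x$strata) > 0)
    cat(", stratified by ", paste(x$strata, collapse = " x "), sep = "")
  cat(")\n")
  for (s in unique(x$transitions$stratum)) {
    cat("\nstratum:", s, "\n")
    print(coef_matrix(x, s), digits = digits)
  }
  invisible(x)
}

coef_matrix <- function(x, stratum) {
  tab <- x$transitions[x$transitions$stratum == stratum, , drop = FALSE]
  src <- intersect(JOURNEY_STATES, unique(tab$from))
  dst <- intersect(JOURNEY_STATES, unique(tab$to))
  m <- matrix(0, length(src), length(dst), dimnames = list(src, dst))
  for (i in seq_len(nrow(tab))) m[tab$from[i], tab$to[i]] <- tab$probability[i]
  m
}

#' @export
coef.mm_dpm <- function(object, ...) {
  sapply(unique(object$transitions$stratum), function(s) coef_matrix(object, s),
         simplify = FALSE)
}

#' @export
summary.mm_dpm <- function(object, ...) {
  structure(list(fit = object), class = "summary.mm_dpm")
}

#' @export
print.summary.mm_dpm <- function(x, ...) {
  print(x$fit)
  if (nrow(x$fit$durations) > 0) {
    cat("\nInter-line durations (months):\n")
    d <- x$fit$durations
    d[c("mean", "median", "q1", "q3", "min", "max")] <-
      lapply(d[c("mean", "median", "q1", "q3", "min", "max")], round, 1)
    print(d, row.names = FALSE)
  }
  invisible(x)
}

#' Simulate journeys from a fitted disease-progression model
#'
#' Draws state paths from the fitted multinomial transition probabilities.
#'
#' @param object an `mm_dpm` fit.
#' @param nsim number of journeys per stratum.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return data.frame `stratum`, `path`.
#' @export
simulate.mm_dpm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(unique(object$transitions$stratum), function(s) {
    m <- coef_matrix(object, s)
    paths <- vapply(seq_len(nsim), function(i) {
      st <- "L1"; path <- st
      while (st %in% rownames(m)) {
        st <- sample(colnames(m), 1, prob = m[st, ])
        path <- c(path, st)
        if (st %in% c("DEATH", "CONTINUE")) break
      }
      paste(path, collapse = ">")
    }, character(1))
    data.frame(stratum = s, path = paths, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
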