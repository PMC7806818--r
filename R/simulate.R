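# Synthetic administrative-claims generator with serialized ground truth.
#
# Every patient is generated from their own RNG stream derived from
# (seed, patient index), so changing n_patients never perturbs earlier
# patients. The generator draws a treatment journey from a ground-truth
# Markov matrix, then realizes it as dated dispensings whose cadence keeps
# within-line coverage continuous and makes every inter-line boundary
# unambiguous (75-day treatment gaps, regimen switches after day 90), so
# the pipeline can recover the truth exactly.

SIM_STRATA <- c("pre_asct", "pre_noasct", "post_asct", "post_noasct")

sim_stratum <- function(period, asct) {
  paste0(ifelse(period == "pre_bortezomib", "pre", "post"),
         ifelse(asct, "_asct", "_noasct"))
}

#' Simulation configuration with study-calibrated defaults
#'
#' Defaults reflect the published cohort structure: the era split and ASCT
#' rates (246/2230 pre, 280/1862 post), age means/SDs per era and
#' transplant status, first-line class mixes (e.g. post-era non-ASCT NA
#' 0.546, CCNA 0.295, CA 0.028, SA 0.132), branch probabilities out of each
#' line echoing the published progression figures, and lognormal inter-line
#' sojourns (median 11.6 months line 1 to 2, 6.8 months line 2 to 3).
#'
#' @param n_patients number of patients.
#' @param seed integer seed; every patient stream derives from it.
#' @param p_post probability of diagnosis in the post-bortezomib era.
#' @param index_window optional `c(start, end)` dates overriding the era
#'   windows for index dates (era is then derived from the drawn date).
#' @param asct_prob named vector, ASCT probability per era.
#' @param age named list per stratum (`pre_asct`, `pre_noasct`,
#'   `post_asct`, `post_noasct`) of `c(mean, sd)` years.
#' @param male_prob named vector per stratum.
#' @param class_mix named list per stratum of first-line class
#'   probabilities `c(NA=, CCNA=, CA=, SA=)`, each summing to 1.
#' @param transition_matrix named list per stratum of 3x3 matrices (rows
#'   `L1`..`L3`, columns `next`, `death`, `continue`), rows summing to 1
#'   and `L3 -> next` zero.
#' @param sojourn_median_months lognormal medians for the line-1-to-2 and
#'   line-2-to-3 start-to-start sojourns.
#' @param sojourn_sdlog lognormal sigma of the sojourns.
#' @param death_median_months,death_sdlog lognormal of time from line start
#'   to death for journeys ending at that line.
#' @param min_sojourn_days,min_death_days lower clamps keeping every drawn
#'   interval realizable by the dispensing schedule.
#' @param cadence_days,supply_days dispensing cadence and days supply
#'   (equal by default: continuous within-line coverage).
#' @param gap_plant_days length of the planted between-line treatment gap
#'   (75: comfortably beyond the 60-day rule, so round trips are exact).
#' @param new_drug_prob probability that a line transition is realized as a
#'   late regimen switch (rule b) instead of a treatment gap.
#' @param comorb_probs probabilities of planting each myeloma comorbidity
#'   claim pattern and an extra Charlson condition.
#' @param planted_violations named integer vector: how many patients to
#'   corrupt per exclusion rule (disjoint; applied to the first patients).
#' @param censor_date administrative censor date.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 100, seed = 20070101,
                       p_post = 1862 / 4092,
                       index_window = NULL,
                       asct_prob = c(pre_bortezomib = 246 / 2230,
                                     post_bortezomib = 280 / 1862),
                       age = list(pre_asct = c(53.9, 7.2),
                                  pre_noasct = c(69.4, 11.6),
                                  post_asct = c(57.0, 7.7),
                                  post_noasct = c(69.6, 11.5)),
                       male_prob = c(pre_asct = 0.585, pre_noasct = 0.573,
                                     post_asct = 0.525, post_noasct = 0.535),
                       class_mix = list(
                         pre_asct = c("NA" = 0.41, CCNA = 0.19, CA = 0.24, SA = 0.16),
                         pre_noasct = c("NA" = 0.18, CCNA = 0.28, CA = 0.30, SA = 0.24),
                         post_asct = c("NA" = 0.761, CCNA = 0.225, CA = 0.007, SA = 0.007),
                         post_noasct = c("NA" = 863, CCNA = 466, CA = 44, SA = 209) / 1582),
                       transition_matrix = list(
                         pre_asct = rbind(L1 = c(0.55, 0.12, 0.33),
                                          L2 = c(0.45, 0.22, 0.33),
                                          L3 = c(0, 0.45, 0.55)),
                         pre_noasct = rbind(L1 = c(0.45, 0.45, 0.10),
                                            L2 = c(0.38, 0.45, 0.17),
                                            L3 = c(0, 0.65, 0.35)),
                         post_asct = rbind(L1 = c(0.587, 0.033, 0.380),
                                           L2 = c(0.424, 0.152, 0.424),
                                           L3 = c(0, 0.35, 0.65)),
                         post_noasct = rbind(L1 = c(0.519, 0.330, 0.151),
                                             L2 = c(0.40, 0.35, 0.25),
                                             L3 = c(0, 0.50, 0.50))),
                       sojourn_median_months = c(L1 = 11.6, L2 = 6.8),
                       sojourn_sdlog = 0.5,
                       death_median_months = c(L1 = 8, L2 = 6, L3 = 5),
                       death_sdlog = 0.6,
                       min_sojourn_days = 105, min_death_days = 35,
                       cadence_days = 28, supply_days = 28,
                       gap_plant_days = 75,
                       new_drug_prob = 0.3,
                       comorb_probs = c(anemia = 0.38, renal = 0.20,
                                        pneumonia = 0.15, fracture = 0.17,
                                        charlson_extra = 0.35),
                       planted_violations = integer(0),
                       censor_date = MM_CENSOR_DATE) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_patients < 1) stopf("n_patients must be >= 1")
  for (s in SIM_STRATA) {
    mix <- cfg$class_mix[[s]]
    if (abs(sum(mix) - 1) > 1e-6)
      stopf("class mix for %s sums to %.4f, not 1", s, sum(mix))
    tm <- cfg$transition_matrix[[s]]
    if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-6))
      stopf("transition matrix for %s has rows not summing to 1", s)
    if (tm[3, 1] != 0) stopf("L3 cannot transition to a next line (%s)", s)
  }
  if (any(cfg$asct_prob < 0 | cfg$asct_prob > 1) || cfg$p_post < 0 || cfg$p_post > 1)
    stopf("probabilities must lie in [0, 1]")
  if (cfg$gap_plant_days < 60)
    stopf("gap_plant_days %d would not trigger the 60-day line-end rule",
          cfg$gap_plant_days)
  if (cfg$min_sojourn_days <= 90)
    stopf("min_sojourn_days must exceed the 90-day addition window")
  if (cfg$min_sojourn_days < cfg$gap_plant_days + cfg$supply_days + 1)
    stopf(paste("infeasible config: min_sojourn_days %d leaves no room for",
                "a dispensing before the %d-day planted gap"),
          cfg$min_sojourn_days, cfg$gap_plant_days)
  if (cfg$min_death_days <= cfg$supply_days)
    stopf("min_death_days must exceed the days supply")
  if (sum(cfg$planted_violations) > cfg$n_patients)
    stopf("more planted violations than patients")
  bad <- setdiff(names(cfg$planted_violations),
                 setdiff(EXCLUSION_RULES, c("no_mm_diagnosis",
                                            "index_out_of_window")))
  if (length(bad) > 0)
    stopf("unknown plant rule(s): %s", paste(bad, collapse = ", "))
  invisible(cfg)
}

# first-line and later-line regimens per class/era; steroid co-medication
# never changes the class
sim_regimen <- function(class, period, line_number, prev_drugs) {
  post <- period == "post_bortezomib"
  if (line_number == 1) {
    drugs <- switch(class,
      "NA" = if (post) {
        if (stats::runif(1) < 0.8) c("bortezomib", "thalidomide") else "bortezomib"
      } else "thalidomide",
      CCNA = if (post) c("bortezomib", "thalidomide", "cyclophosphamide")
             else c("melphalan", "thalidomide"),
      CA = if (stats::runif(1) < 0.6) "melphalan"
           else c("cyclophosphamide", "vincristine"),
      SA = "dexamethasone")
    if (class %in% c("NA", "CCNA") && stats::runif(1) < 0.5)
      drugs <- c(drugs, "dexamethasone")
    return(drugs)
  }
  pool <- c("lenalidomide", "cyclophosphamide", "bortezomib", "melphalan",
            "etoposide")
  avail <- setdiff(pool, prev_drugs)
  main <- sample(avail, 1)
  if (stats::runif(1) < 0.3) c(main, "dexamethasone") else main
}

rand_date <- function(from, to) {
  from + sample.int(as.integer(to - from) + 1L, 1L) - 1L
}

#' Simulate a claims bundle with known ground truth
#'
#' @param config a [sim_config()].
#' @return list with `bundle` (a `claims_bundle`) and `truth` (class
#'   `simulation_truth`): per-patient realized journey, line starts,
#'   regimen labels, transition mechanisms and planted exclusion rule,
#'   plus the generating configuration.
#' @export
simulate_bundle <- function(config = sim_config()) {
  validate_sim_config(config)
  censor <- as.Date(config$censor_date)
  plants <- rep(names(config$planted_violations), config$planted_violations)

  acc <- list(pat = list(), dx = list(), rx = list(), pr = list(), de = list(),
              truth = list())
  for (i in seq_len(config$n_patients)) {
    set.seed((config$seed %% 1000003L) * 2011L + i * 7L)
    pid <- sprintf("P%05d%04X", i, sample.int(65536L, 1L) - 1L)

    # demographics and era
    if (!is.null(config$index_window)) {
      index <- rand_date(as.Date(config$index_window[1]),
                         as.Date(config$index_window[2]))
      period <- assign_period(index)
    } else {
      period <- if (stats::runif(1) < config$p_post) "post_bortezomib"
                else "pre_bortezomib"
      index <- if (period == "pre_bortezomib")
        rand_date(MM_STUDY_START, MM_PERIOD_BOUNDARY - 1)
      else rand_date(MM_PERIOD_BOUNDARY, MM_STUDY_END)
    }
    asct <- stats::runif(1) < config$asct_prob[[period]]
    stratum <- sim_stratum(period, asct)
    age <- round(stats::rnorm(1, config$age[[stratum]][1],
                              config$age[[stratum]][2]))
    age <- min(max(age, 20), 95)
    birth <- index - (ceiling(age * DAYS_PER_YEAR) + sample.int(300L, 1L))
    sex <- if (stats::runif(1) < config$male_prob[[stratum]]) "male" else "female"
    enroll_start <- index - 365L - sample.int(1970L, 1L) - 29L

    dx_date <- index; dx_code <- "203.00"
    dx_pos <- "primary"; dx_set <- "outpatient"
    # confirmatory myeloma visit after index
    dx_date <- c(dx_date, index + 14)
    dx_code <- c(dx_code, "203.00"); dx_pos <- c(dx_pos, "primary")
    dx_set <- c(dx_set, "outpatient")

    # comorbidity claims in the pre-index year
    cp <- config$comorb_probs
    if (stats::runif(1) < cp[["anemia"]]) {
      dx_date <- c(dx_date, index - c(30, 75, 120))
      dx_code <- c(dx_code, rep("285.9", 3))
      dx_pos <- c(dx_pos, rep("secondary", 3))
      dx_set <- c(dx_set, rep("outpatient", 3))
    }
    if (stats::runif(1) < cp[["renal"]]) {
      dx_date <- c(dx_date, index - 90); dx_code <- c(dx_code, "586")
      dx_pos <- c(dx_pos, "primary"); dx_set <- c(dx_set, "inpatient")
    }
    if (stats::runif(1) < cp[["pneumonia"]]) {
      dx_date <- c(dx_date, index - 45); dx_code <- c(dx_code, "486")
      dx_pos <- c(dx_pos, "primary"); dx_set <- c(dx_set, "inpatient")
    }
    if (stats::runif(1) < cp[["fracture"]]) {
      dx_date <- c(dx_date, index - 160); dx_code <- c(dx_code, "805.2")
      dx_pos <- c(dx_pos, "primary"); dx_set <- c(dx_set, "inpatient")
    }
    if (stats::runif(1) < cp[["charlson_extra"]]) {
      dx_date <- c(dx_date, index - 100)
      dx_code <- c(dx_code, sample(c("250.00", "428.0", "496", "585.9",
                                     "571.2"), 1))
      dx_pos <- c(dx_pos, "secondary"); dx_set <- c(dx_set, "outpatient")
    }

    # journey from the ground-truth Markov matrix
    fl_class <- sample(names(config$class_mix[[stratum]]), 1,
                       prob = config$class_mix[[stratum]])
    tm <- config$transition_matrix[[stratum]]
    line_starts <- index + sample.int(15L, 1L) - 1L
    states <- "L1"; mechanisms <- character(0)
    death_date <- as.Date(NA)
    repeat {
      k <- length(line_starts)
      dest <- sample(c("next", "death", "continue"), 1, prob = tm[min(k, 3), ])
      if (dest == "next" && k < 3) {
        med <- config$sojourn_median_months[[min(k, 2)]] * DAYS_PER_MONTH
        gap <- max(config$min_sojourn_days,
                   round(stats::rlnorm(1, log(med), config$sojourn_sdlog)))
        nxt <- line_starts[k] + gap
        mech <- if (stats::runif(1) < config$new_drug_prob) "new_drug" else "gap"
        if (nxt > censor) { states <- c(states, "CONTINUE"); break }
        line_starts <- c(line_starts, nxt)
        mechanisms <- c(mechanisms, mech)
        states <- c(states, paste0("L", k + 1))
      } else if (dest == "death") {
        med <- config$death_median_months[[min(k, 3)]] * DAYS_PER_MONTH
        dd <- line_starts[k] +
          max(config$min_death_days,
              round(stats::rlnorm(1, log(med), config$death_sdlog)))
        if (dd > censor) { states <- c(states, "CONTINUE"); break }
        death_date <- dd
        states <- c(states, "DEATH")
        break
      } else {
        states <- c(states, "CONTINUE")
        break
      }
    }

    # realize each line as dispensings
    n_lines <- length(line_starts)
    drug_sets <- vector("list", n_lines)
    rx_date <- as.Date(character(0)); rx_drug <- character(0)
    rx_supply <- integer(0)
    for (k in seq_len(n_lines)) {
      drug_sets[[k]] <- sim_regimen(fl_class, period, k,
                                    if (k > 1) drug_sets[[k - 1]] else character(0))
      treat_end <- if (k < n_lines) {
        if (mechanisms[k] == "gap") line_starts[k + 1] - config$gap_plant_days - 1
        else line_starts[k + 1] - 1
      } else if (!is.na(death_date)) death_date
      else censor
      treat_end <- min(treat_end, censor)
      dates <- seq(line_starts[k], treat_end, by = config$cadence_days)
      supplies <- pmin(config$supply_days,
                       as.integer(treat_end - dates) + 1L)
      for (g in drug_sets[[k]]) {
        rx_date <- c(rx_date, dates)
        rx_drug <- c(rx_drug, rep(g, length(dates)))
        rx_supply <- c(rx_supply, supplies)
      }
    }

    pr_date <- as.Date(character(0)); pr_code <- character(0)
    if (asct) {
      ad <- index + max(60L, round(stats::rlnorm(1, log(0.9 * DAYS_PER_YEAR), 0.5)))
      ad <- min(ad, min_date(death_date - 1, censor))
      if (ad > index) { pr_date <- ad; pr_code <- "ASCT" }
    }

    planted <- if (i <= length(plants)) plants[i] else NA_character_
    if (!is.na(planted)) {
      if (planted == "insufficient_lookback") enroll_start <- index - 60L
      if (planted == "age_under_18") {
        birth <- index - round(10 * DAYS_PER_YEAR)
        enroll_start <- max(enroll_start, birth + 30L)  # keep record coherent
      }
      if (planted == "prior_cancer") {
        dx_date <- c(dx_date, index - 200)
        dx_code <- c(dx_code, "162.9")
        dx_pos <- c(dx_pos, "primary"); dx_set <- c(dx_set, "outpatient")
      }
      if (planted == "plasma_cell_leukemia_within_2mo") {
        dx_date <- c(dx_date, index + 30)
        dx_code <- c(dx_code, "203.10")
        dx_pos <- c(dx_pos, "secondary"); dx_set <- c(dx_set, "outpatient")
      }
      if (planted == "no_mm_visit_after_index") {
        keep <- !(is_mm_code(dx_code) & dx_date > index)
        dx_date <- dx_date[keep]; dx_code <- dx_code[keep]
        dx_pos <- dx_pos[keep]; dx_set <- dx_set[keep]
      }
      if (planted == "untreated") {
        rx_date <- as.Date(character(0)); rx_drug <- character(0)
        rx_supply <- integer(0)
      }
    }

    acc$pat[[i]] <- list(pid = pid, birth = birth, sex = sex,
                         es = enroll_start)
    acc$dx[[i]] <- list(pid = rep(pid, length(dx_date)), date = dx_date,
                        code = dx_code, pos = dx_pos, set = dx_set)
    acc$rx[[i]] <- list(pid = rep(pid, length(rx_date)), date = rx_date,
                        drug = rx_drug, supply = rx_supply)
    acc$pr[[i]] <- list(pid = rep(pid, length(pr_date)), date = pr_date,
                        code = pr_code)
    if (!is.na(death_date))
      acc$de[[i]] <- list(pid = pid, date = death_date)
    acc$truth[[i]] <- list(
      pid = pid, period = period, asct = asct, fl_class = fl_class,
      path = paste(states, collapse = ">"),
      index = index,
      line_starts = paste(format(line_starts), collapse = "|"),
      mechanisms = paste(mechanisms, collapse = "|"),
      regimens = paste(vapply(drug_sets, function(d)
        paste(sort(d), collapse = "+"), character(1)), collapse = "|"),
      death = death_date, planted = planted)
  }

  cat_dates <- function(lst) as.Date(unlist(lapply(lst, as.character)),
                                     origin = "1970-01-01")
  patients <- data.frame(
    patient_id = vapply(acc$pat, `[[`, character(1), "pid"),
    birth_date = cat_dates(lapply(acc$pat, `[[`, "birth")),
    sex = vapply(acc$pat, `[[`, character(1), "sex"),
    enroll_start = cat_dates(lapply(acc$pat, `[[`, "es")),
    enroll_end = as.Date(rep(NA, config$n_patients)),
    stringsAsFactors = FALSE)
  diagnoses <- data.frame(
    patient_id = unlist(lapply(acc$dx, `[[`, "pid")),
    claim_date = cat_dates(lapply(acc$dx, `[[`, "date")),
    icd9 = unlist(lapply(acc$dx, `[[`, "code")),
    position = unlist(lapply(acc$dx, `[[`, "pos")),
    setting = unlist(lapply(acc$dx, `[[`, "set")),
    stringsAsFactors = FALSE)
  dispensings <- data.frame(
    patient_id = unlist(lapply(acc$rx, `[[`, "pid")),
    dispense_date = cat_dates(lapply(acc$rx, `[[`, "date")),
    drug = unlist(lapply(acc$rx, `[[`, "drug")),
    days_supply = as.integer(unlist(lapply(acc$rx, `[[`, "supply"))),
    setting = rep("outpatient", length(unlist(lapply(acc$rx, `[[`, "pid")))),
    stringsAsFactors = FALSE)
  procedures <- data.frame(
    patient_id = unlist(lapply(acc$pr, `[[`, "pid")),
    procedure_date = cat_dates(lapply(acc$pr, `[[`, "date")),
    procedure = unlist(lapply(acc$pr, `[[`, "code")),
    stringsAsFactors = FALSE)
  if (nrow(procedures) == 0)
    procedures <- data.frame(patient_id = character(0),
                             procedure_date = as.Date(character(0)),
                             procedure = character(0), stringsAsFactors = FALSE)
  de <- acc$de[!vapply(acc$de, is.null, logical(1))]
  deaths <- data.frame(
    patient_id = vapply(de, `[[`, character(1), "pid"),
    death_date = cat_dates(lapply(de, `[[`, "date")),
    stringsAsFactors = FALSE)
  if (nrow(deaths) == 0)
    deaths <- data.frame(patient_id = character(0),
                         death_date = as.Date(character(0)),
                         stringsAsFactors = FALSE)

  truth_df <- data.frame(
    patient_id = vapply(acc$truth, `[[`, character(1), "pid"),
    period = vapply(acc$truth, `[[`, character(1), "period"),
    asct = vapply(acc$truth, `[[`, logical(1), "asct"),
    first_line_class = vapply(acc$truth, `[[`, character(1), "fl_class"),
    path = vapply(acc$truth, `[[`, character(1), "path"),
    index_date = cat_dates(lapply(acc$truth, `[[`, "index")),
    line_starts = vapply(acc$truth, `[[`, character(1), "line_starts"),
    mechanisms = vapply(acc$truth, `[[`, character(1), "mechanisms"),
    regimens = vapply(acc$truth, `[[`, character(1), "regimens"),
    death_date = cat_dates(lapply(acc$truth, `[[`, "death")),
    planted_rule = vapply(acc$truth, `[[`, character(1), "planted"),
    stringsAsFactors = FALSE)

  list(bundle = claims_bundle(patients, diagnoses, dispensings, procedures,
                              deaths),
       truth = structure(list(patients = truth_df,
                              transition_matrix = config$transition_matrix,
                              config = config),
                         class = "simulation_truth"))
}

#' Write simulation ground truth as JSON
#'
#' @param truth a `simulation_truth`.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_simulation_truth <- function(truth, path) {
  tm <- lapply(truth$transition_matrix, function(m) {
    colnames(m) <- c("next", "death", "continue"); as.data.frame(m)
  })
  jsonlite::write_json(list(patients = truth$patients,
                            transition_matrix = tm),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
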