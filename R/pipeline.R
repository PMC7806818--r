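# End-to-end orchestration: claims -> cohort -> comorbidity -> lines ->
# disease-progression model -> reports, with every artifact written as
# CSV/JSON and a deterministic run log.

#' Run the full treatment-pathway pipeline
#'
#' Executes every stage and writes the artifacts to `out_dir`:
#' `cohort.csv`, `exclusions.csv`, `comorbidity.csv`, `lines.csv`,
#' `transitions.csv`, `durations.csv`, `sankey.json` (pooled) and
#' `sankey_<stratum>.json`, `table1_*.csv`, `table2.csv`, `rejects.csv`,
#' `run.log`, plus `truth.json` when simulating. Identical inputs and
#' configuration give identical artifacts.
#'
#' @param out_dir output directory (created if needed).
#' @param input directory (or named paths) with the five claims CSVs;
#'   ignored when `simulate` is given.
#' @param simulate `NULL`, or a [sim_config()] to generate the input
#'   bundle instead of reading one.
#' @param config a [cohort_config()].
#' @param params a [lot_params()].
#' @param strata stratification of the progression model.
#' @param suppress_threshold small-cell release threshold for tables.
#' @return invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(out_dir, input = NULL, simulate = NULL,
                         config = cohort_config(), params = lot_params(),
                         strata = c("period", "asct"),
                         suppress_threshold = 3) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  wcsv <- function(df, name) {
    for (col in names(df)) if (inherits(df[[col]], "Date"))
      df[[col]] <- format(df[[col]], "%Y-%m-%d")
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE, na = "")
  }

  truth <- NULL
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "sim_config"))
    sim <- stage("simulate", simulate_bundle(simulate))
    bundle <- sim$bundle
    truth <- sim$truth
    write_simulation_truth(truth, file.path(out_dir, "truth.json"))
    say("simulated %d patients (seed %d)", simulate$n_patients, simulate$seed)
  } else {
    bundle <- stage("read_claims", read_claims_bundle(input))
    say("read claims bundle: %d patients, %d rejects",
        nrow(bundle$patients), nrow(bundle$rejects))
  }
  wcsv(bundle$rejects, "rejects.csv")

  sel <- stage("cohort", apply_selection(bundle, config))
  say("cohort: %d members, %d excluded", nrow(sel$cohort),
      length(unique(sel$exclusions$patient_id)))
  wcsv(sel$cohort, "cohort.csv")
  wcsv(sel$exclusions, "exclusions.csv")

  comorb <- stage("comorbidity", comorbidity_profiles(bundle, sel$cohort))
  wcsv(comorb, "comorbidity.csv")

  lines <- stage("therapy_lines", cohort_lines(bundle, sel$cohort, params))
  say("lines: %d lines across %d treated patients", nrow(lines),
      length(unique(lines$patient_id)))
  wcsv(lines, "lines.csv")

  journeys <- stage("journeys", cohort_journeys(lines, sel$cohort))
  dpm <- stage("dpm", estimate_transitions(journeys, strata))
  wcsv(dpm$transitions, "transitions.csv")
  wcsv(dpm$durations, "durations.csv")
  if (nrow(dpm$transitions) > 0) {
    pooled <- to_sankey(dpm)
    check_flow_conservation(pooled)
    write_sankey_json(pooled, file.path(out_dir, "sankey.json"))
    for (s in unique(dpm$transitions$stratum)) {
      g <- to_sankey(dpm, s)
      check_flow_conservation(g)
      write_sankey_json(g, file.path(out_dir, sprintf(
        "sankey_%s.json", gsub("[^A-Za-z0-9_]+", "_", s))))
    }
  }

  tables <- list()
  for (p in unique(sel$cohort$period)) {
    t1 <- stage("reporting", suppress_small_counts(
      demographics_table(sel$cohort, comorb, lines, period = p),
      threshold = suppress_threshold))
    tables[[paste0("table1_", p)]] <- t1
    write_summary_table(t1, file.path(out_dir, sprintf("table1_%s.csv", p)))
  }
  if (nrow(lines) > 0) {
    t2 <- stage("reporting", suppress_small_counts(
      regimen_table(lines, sel$cohort), threshold = suppress_threshold))
    tables$table2 <- t2
    write_summary_table(t2, file.path(out_dir, "table2.csv"))
  }

  cfg_json <- file.path(out_dir, "config.json")
  jsonlite::write_json(list(cohort = unclass(config), lot = unclass(params),
                            strata = strata,
                            suppress_threshold = suppress_threshold,
                            seed = if (!is.null(simulate)) simulate$seed),
                       cfg_json, auto_unbox = TRUE, force = TRUE, digits = NA)
  say("config hash: %s", unname(tools::md5sum(cfg_json)))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(bundle = bundle, truth = truth, cohort = sel$cohort,
                 exclusions = sel$exclusions, comorbidity = comorb,
                 lines = lines, journeys = journeys, dpm = dpm,
                 tables = tables, out_dir = out_dir))
}
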