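#' Configuration for a full pipeline run
#'
#' Bundles every stage's options. The effective configuration is serialized
#' as JSON next to the outputs so a run is reproducible from its artifact
#' directory alone.
#'
#' @param out_dir artifact directory.
#' @param seed global seed; per-stage seeds derive from it via
#'   [derive_seed()].
#' @param sim a [sim_config()] for the synthetic extract; its `seed` is
#'   overwritten by the derived simulate-stage seed. Set to `NULL` to use
#'   an existing extract in `extract_dir`.
#' @param extract_dir directory with extract CSVs when `sim` is `NULL`.
#' @param rules_dir dictionary directory for [default_rules()].
#' @param policy multi-note resolution policy for [classify_table()].
#' @param window study window.
#' @param age_cut,provider_age_cut dichotomization cuts (`NULL` = observed
#'   mean).
#' @param wcorr GEE working correlation.
#' @param bivariate_vars cohort columns for the descriptive comparison.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            seed = 1L,
                            sim = sim_config(seed = 1L),
                            extract_dir = NULL,
                            rules_dir = system.file("extdata", "rules",
                                                    package = "alcodoc"),
                            policy = "most-recent",
                            window = c("2015-01-01", "2018-01-01"),
                            age_cut = NULL,
                            provider_age_cut = NULL,
                            wcorr = "exchangeable",
                            bivariate_vars = c("male", "urban",
                                               "hypertension", "depression",
                                               "diabetes", "osteoarthritis",
                                               "age_years",
                                               "visits_per_year_median")) {
  if (is.null(sim) && is.null(extract_dir)) {
    stop_config("either sim or extract_dir must be given")
  }
  if (!dir.exists(rules_dir)) {
    stop_config("rules directory does not exist: ", rules_dir)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 extract_dir = extract_dir, rules_dir = rules_dir,
                 policy = policy, window = as.character(window),
                 age_cut = age_cut, provider_age_cut = provider_age_cut,
                 wcorr = wcorr, bivariate_vars = bivariate_vars),
            class = "pipeline_config")
}

#' Run the full pipeline: simulate, classify, build cohort, analyze
#'
#' Executes the stages in order, writing each stage's output before the
#' next starts: the extract CSVs, `classified.csv`, `cohort.csv`,
#' `results.csv`/`report.txt`, plus `run_config.json` and a `run.log` with
#' per-stage row counts. On error a `FAILED` marker naming the stage is
#' left in the artifact directory and the error is re-thrown.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the artifact `dir`, the `cohort`, the
#'   `prevalence` table and the two `models`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop_config("config must be a pipeline_config")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  failed <- file.path(config$out_dir, "FAILED")
  if (file.exists(failed)) unlink(failed)
  logf <- file.path(config$out_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), ...)
    cat(line, "\n", file = logf, append = TRUE, sep = "")
    message(line)
  }
  stage <- "config"
  result <- tryCatch({
    rules <- default_rules(config$rules_dir)

    stage <- "simulate"
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- derive_seed(config$seed, "simulate")
      extract <- simulate_extract(sim)
      write_extract(extract, file.path(config$out_dir, "extract"))
      say("simulate: ", nrow(extract$patients), " patients, ",
          nrow(extract$encounters), " encounters, ",
          nrow(extract$riskfactor), " risk-factor notes")
    } else {
      extract <- read_extract(config$extract_dir)
      say("loaded extract from ", config$extract_dir)
    }

    stage <- "classify"
    classified <- classify_table(extract$riskfactor, rules,
                                 policy = config$policy)
    data.table::fwrite(classified,
                       file.path(config$out_dir, "classified.csv"))
    say("classify: ", nrow(classified), " patients labelled")

    stage <- "cohort"
    cohort <- build_cohort(extract, classified, rules = rules,
                           window = config$window,
                           age_cut = config$age_cut,
                           provider_age_cut = config$provider_age_cut)
    data.table::fwrite(as.data.frame(cohort),
                       file.path(config$out_dir, "cohort.csv"))
    say("cohort: ", nrow(cohort), " eligible patients; ",
        sum(cohort$documented), " documented (",
        sum(!is.na(cohort$category) & cohort$category != "UNKNOWN"),
        " classified + ",
        sum(cohort$category == "UNKNOWN", na.rm = TRUE), " unknown)")

    stage <- "analyze"
    prev <- prevalence_table(cohort)
    bivs <- lapply(config$bivariate_vars, function(v)
      bivariate_compare(cohort, v))
    doc_model <- fit_documentation_model(cohort, corstr = config$wcorr)
    risk_model <- fit_risk_model(cohort, corstr = config$wcorr)
    say("analyze: documentation model n=", doc_model$n_used,
        ", risk model n=", risk_model$n_used)

    stage <- "report"
    write_report(prev, bivs, list(doc_model, risk_model), config$out_dir)
    say("report: results.csv + report.txt written")

    cfg_json <- config
    cfg_json$sim <- if (is.null(config$sim)) NULL else
      unclass(config$sim)
    jsonlite::write_json(unclass(cfg_json),
                         file.path(config$out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    list(dir = config$out_dir, cohort = cohort, prevalence = prev,
         bivariates = bivs, models = list(documentation = doc_model,
                                          risk = risk_model))
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)), failed)
    stop(e)
  })
  invisible(result)
}

#' Validate an extract directory
#'
#' Schema, foreign-key, date-format and flag checks over the five extract
#' tables (plus `truth.csv` when present).
#'
#' @param dir extract directory.
#' @return object of class `alcodoc_validation`: data frame of violations
#'   (`table`, `check`, `n`, `detail`); zero rows means a clean extract.
#' @export
validate_extract <- function(dir) {
  if (!dir.exists(dir)) stop_data("no such directory: ", dir)
  v <- list()
  flag <- function(table, check, n, detail = "") {
    if (n > 0) v[[length(v) + 1]] <<- data.frame(
      table = table, check = check, n = as.integer(n), detail = detail,
      stringsAsFactors = FALSE)
  }
  need <- list(
    patients = c("patient_id", "provider_id", "sex", "birth_date",
                 "cma_population"),
    providers = c("provider_id", "sex", "birth_date", "provider_type"),
    encounters = c("encounter_id", "patient_id", "provider_id", "date"),
    conditions = c("patient_id"),
    riskfactor = c("patient_id", "date", "text"))
  tabs <- list()
  for (nm in names(need)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      flag(nm, "missing_file", 1, path)
      next
    }
    tabs[[nm]] <- as.data.frame(data.table::fread(path))
    missing <- setdiff(need[[nm]], names(tabs[[nm]]))
    flag(nm, "missing_columns", length(missing),
         paste(missing, collapse = ","))
  }
  ok <- function(nm, cols) !is.null(tabs[[nm]]) &&
    all(cols %in% names(tabs[[nm]]))
  chk_date <- function(nm, col) {
    if (!ok(nm, col)) return()
    d <- suppressWarnings(as.Date(as.character(tabs[[nm]][[col]]),
                                  format = "%Y-%m-%d"))
    flag(nm, paste0("bad_date:", col), sum(is.na(d)))
  }
  chk_date("patients", "birth_date")
  chk_date("providers", "birth_date")
  chk_date("encounters", "date")
  chk_date("riskfactor", "date")
  if (ok("patients", "patient_id")) {
    flag("patients", "duplicate_patient_id",
         sum(duplicated(tabs$patients$patient_id)))
  }
  fk <- function(child, col, parent, pcol) {
    if (!ok(child, col) || !ok(parent, pcol)) return()
    flag(child, paste0("fk:", col),
         sum(!tabs[[child]][[col]] %in% tabs[[parent]][[pcol]]))
  }
  fk("patients", "provider_id", "providers", "provider_id")
  fk("encounters", "patient_id", "patients", "patient_id")
  fk("encounters", "provider_id", "providers", "provider_id")
  fk("conditions", "patient_id", "patients", "patient_id")
  fk("riskfactor", "patient_id", "patients", "patient_id")
  if (!is.null(tabs$conditions)) {
    for (col in setdiff(names(tabs$conditions), "patient_id")) {
      flag("conditions", paste0("non_binary:", col),
           sum(!tabs$conditions[[col]] %in% c(0, 1, NA)))
    }
  }
  if (ok("riskfactor", "text")) {
    flag("riskfactor", "empty_text",
         sum(!nzchar(trimws(as.character(tabs$riskfactor$text)))))
  }
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) {
    truth <- as.data.frame(data.table::fread(tp))
    if (all(c("documented", "rendered_text") %in% names(truth))) {
      doc <- as.logical(truth$documented)
      txt <- nzchar(as.character(truth$rendered_text))
      flag("truth", "documented_without_text", sum(doc & !txt))
      flag("truth", "text_without_documented", sum(!doc & txt))
    }
  }
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(table = character(0), check = character(0),
               n = integer(0), detail = character(0),
               stringsAsFactors = FALSE)
  structure(out, class = c("alcodoc_validation", "data.frame"))
}

#' @export
print.alcodoc_validation <- function(x, ...) {
  if (nrow(x) == 0) {
    cat("extract OK: 0 violations\n")
  } else {
    cat(nrow(x), "violation type(s):\n")
    print.data.frame(x)
  }
  invisible(x)
}
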