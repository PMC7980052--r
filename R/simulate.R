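#' Configuration for the synthetic EMR generator
#'
#' Returns a validated configuration object. Defaults are calibrated once to
#' the published marginals of a large Canadian primary-care cohort: 40.6% of
#' adult patients with any alcohol documentation; a documented-category mix
#' with 4.9% unclassifiable entries; covariate effects on documentation and
#' on heightened risk (heavy or past use) set to the published adjusted odds
#' ratios. Intercepts are calibrated numerically at simulation time so the
#' realized marginals equal `p_document_base` and the mix regardless of the
#' effect maps.
#'
#' @param n_patients,n_providers cohort and cluster counts.
#' @param seed integer seed; mandatory, drives every draw.
#' @param p_document_base marginal probability of any alcohol documentation.
#' @param doc_logit_effects named numeric: log-odds increments on
#'   documentation for `male`, `age_over_mean`, `rural`, `high_visits`,
#'   `depression`, `diabetes`, `hypertension`, `osteoarthritis`,
#'   `provider_male`, `provider_age_over_mean`.
#' @param category_mix named probability vector over
#'   `NONE, LIGHT, MODERATE, HEAVY, PAST, UNKNOWN`, conditional on
#'   documentation; must sum to 1.
#' @param risk_logit_effects named numeric: log-odds increments on
#'   heightened risk (HEAVY or PAST vs NONE/LIGHT/MODERATE) for `male`,
#'   `age_per_year` (continuous, centered at `age_mean`), `rural`,
#'   `high_visits`, `depression`, `diabetes`, `hypertension`,
#'   `osteoarthritis`.
#' @param date_window half-open `[start, end)` ISO-8601 study window.
#' @param visit_rate mean encounters per patient-year.
#' @param visit_size negative-binomial size (dispersion) for yearly visit
#'   counts; the default reproduces a visit SD near 5.8 at mean 4.9.
#' @param comorbidity_prevalences named condition probabilities.
#' @param text_noise_rate probability a rendered note is garbled into an
#'   unclassifiable variant (truth label retained). Default 0: ambiguity is
#'   already represented by the UNKNOWN share of `category_mix`.
#' @param p_male,p_urban,age_mean,age_sd patient demographics.
#' @param provider_p_female,provider_age_mean,provider_age_sd,provider_p_fp
#'   provider demographics.
#' @param urban_missing_rate probability the CMA-population field is missing.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 10000,
                       n_providers = 50,
                       seed = 1L,
                       p_document_base = 0.406,
                       doc_logit_effects = c(
                         male = log(1.09), age_over_mean = log(1.26),
                         rural = 0, high_visits = log(1.11),
                         depression = log(1.11), diabetes = log(0.95),
                         hypertension = log(1.07), osteoarthritis = log(1.01),
                         provider_male = log(0.90),
                         provider_age_over_mean = log(1.09)),
                       category_mix = c(
                         NONE = 57712, LIGHT = 117779, MODERATE = 82178,
                         HEAVY = 8088, PAST = 4519, UNKNOWN = 13992) / 284268,
                       risk_logit_effects = c(
                         male = log(3.27), age_per_year = log(1.01),
                         rural = log(1.35), high_visits = log(1.23),
                         depression = log(2.01), diabetes = log(0.83),
                         hypertension = log(1.24), osteoarthritis = log(1.04)),
                       date_window = c("2015-01-01", "2018-01-01"),
                       visit_rate = 4.9,
                       visit_size = 0.84,
                       comorbidity_prevalences = c(
                         depression = 0.18444, diabetes = 0.11067,
                         hypertension = 0.23822, osteoarthritis = 0.13702,
                         copd = 0.03935, dementia = 0.01670,
                         epilepsy = 0.01214, parkinsons = 0.00351),
                       text_noise_rate = 0,
                       p_male = 0.429,
                       p_urban = 0.845,
                       age_mean = 50.7,
                       age_sd = 17.6,
                       provider_p_female = 0.50,
                       provider_age_mean = 49.6,
                       provider_age_sd = 11.1,
                       provider_p_fp = 0.994,
                       urban_missing_rate = 0) {
  cfg <- list(n_patients = as.integer(n_patients),
              n_providers = as.integer(n_providers),
              seed = as.integer(seed),
              p_document_base = p_document_base,
              doc_logit_effects = doc_logit_effects,
              category_mix = category_mix,
              risk_logit_effects = risk_logit_effects,
              date_window = as.character(date_window),
              visit_rate = visit_rate,
              visit_size = visit_size,
              comorbidity_prevalences = comorbidity_prevalences,
              text_noise_rate = text_noise_rate,
              p_male = p_male, p_urban = p_urban,
              age_mean = age_mean, age_sd = age_sd,
              provider_p_female = provider_p_female,
              provider_age_mean = provider_age_mean,
              provider_age_sd = provider_age_sd,
              provider_p_fp = provider_p_fp,
              urban_missing_rate = urban_missing_rate)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' @noRd
validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_document_base, cfg$text_noise_rate, cfg$p_male,
             cfg$p_urban, cfg$provider_p_female, cfg$provider_p_fp,
             cfg$urban_missing_rate, cfg$comorbidity_prevalences,
             cfg$category_mix)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop_config("all probabilities must lie in [0, 1]")
  }
  if (abs(sum(cfg$category_mix) - 1) > 1e-12) {
    stop_config("category_mix must sum to 1 (got ",
                format(sum(cfg$category_mix), digits = 15), ")")
  }
  if (!setequal(names(cfg$category_mix), alcohol_categories())) {
    stop_config("category_mix must be named over the six categories")
  }
  if (is.na(cfg$n_providers) || cfg$n_providers < 1) {
    stop_config("n_providers must be >= 1")
  }
  if (is.na(cfg$n_patients) || cfg$n_patients < 0) {
    stop_config("n_patients must be >= 0")
  }
  if (is.na(cfg$seed)) stop_config("seed is mandatory")
  win <- as.Date(cfg$date_window)
  if (any(is.na(win)) || length(win) != 2 || win[1] >= win[2]) {
    stop_config("date_window must be two ISO dates, start < end")
  }
  invisible(cfg)
}

#' Read a generator configuration from a JSON file
#'
#' The file holds flat key/value pairs plus nested effect maps, one entry
#' per [sim_config()] argument; omitted fields take the documented
#' defaults. `seed` is mandatory.
#'
#' @param path JSON file path.
#' @return a validated `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_config("no such config file: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- setdiff(names(formals(sim_config)), "...")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop_config("unknown config fields: ",
                               paste(bad, collapse = ", "))
  if (!"seed" %in% names(raw)) stop_config("seed is mandatory")
  maps <- c("doc_logit_effects", "risk_logit_effects", "category_mix",
            "comorbidity_prevalences")
  for (m in intersect(maps, names(raw))) raw[[m]] <- unlist(raw[[m]])
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_patients, "patients,", x$n_providers,
      "providers, seed", x$seed, "\n")
  cat("  P(documented) =", x$p_document_base,
      "| window", x$date_window[1], "to", x$date_window[2], "\n")
  cat("  category mix:",
      paste(sprintf("%s %.3f", names(x$category_mix), x$category_mix),
            collapse = ", "), "\n")
  invisible(x)
}

# note templates; every clean template must round-trip through the
# classifier (enforced by test suite, not assumed)
#' @noRd
.tmpl_none <- c("non-drinker", "denies alcohol", "never drinks",
                "no etoh use", "does not drink alcohol", "denies etoh")
#' @noRd
.tmpl_past <- c("past drinker", "recovering alcoholic",
                "attends alcoholics anonymous",
                "recovered alcoholic, sober since 2010",
                "quit drinking", "past heavy use")
#' @noRd
.tmpl_unknown <- c("father was an alcoholic", "family history of alcoholism",
                   "social drinker", "drinks socially",
                   "occasional etoh use", "alcohol discussed")
#' @noRd
.tmpl_noise <- c("etoh", "alcohol use", "see notes", "discussed", "+",
                 "drinks sometimes")

# quantity templates as sprintf patterns taking an integer drinks/week
#' @noRd
render_quantity <- function(q, style) {
  out <- character(length(q))
  out[style == 1] <- sprintf("%d drinks per week", q[style == 1])
  out[style == 2] <- sprintf("%d drinks/week", q[style == 2])
  out[style == 3] <- sprintf("etoh %d/wk", q[style == 3])
  out[style == 4] <- sprintf("%d beers a week", q[style == 4])
  s5 <- style == 5  # range with midpoint q, stays inside the band
  out[s5] <- sprintf("%d-%d drinks per week", q[s5] - 1, q[s5] + 1)
  s6 <- style == 6  # daily form, only offered when q is a multiple of 7
  out[s6] <- sprintf("%d drinks per day", q[s6] %/% 7)
  s7 <- style == 7  # number word
  out[s7] <- sprintf("%s drinks a week", names(word_numbers)[q[s7]])
  out
}

#' Render a free-text note for a known alcohol category
#'
#' Produces template text that the default classifier maps back to the
#' input category (the round-trip property the test suite enforces).
#' Consumption bands require a weekly quantity inside the band; PAST and
#' UNKNOWN take no quantity; NONE accepts 0 or no quantity.
#'
#' @param category character vector of labels from [alcohol_categories()].
#' @param quantity_per_week numeric vector, `NA` where absent; band
#'   categories require a value inside their band (light (0,3),
#'   moderate \[3,15\], heavy (15, Inf)).
#' @return character vector of rendered notes. Uses the current RNG stream.
#' @examples
#' set.seed(1)
#' render_note("PAST")
#' render_note("MODERATE", 6)
#' @export
render_note <- function(category, quantity_per_week = NA_real_) {
  n <- length(category)
  q <- rep_len(as.numeric(quantity_per_week), n)
  if (!all(category %in% alcohol_categories())) {
    stop_config("unknown category label")
  }
  band <- category %in% c("LIGHT", "MODERATE", "HEAVY")
  if (any(band & (is.na(q) | q < 0))) {
    stop_config("band categories require a non-negative quantity_per_week")
  }
  expect <- band_label(q)
  if (any(band & expect != category)) {
    stop_config("quantity_per_week inconsistent with category band")
  }
  out <- character(n)
  pick <- function(mask, pool) {
    if (any(mask)) out[mask] <<- sample(pool, sum(mask), replace = TRUE)
    out
  }
  out <- pick(category == "NONE", .tmpl_none)
  out <- pick(category == "PAST", .tmpl_past)
  out <- pick(category == "UNKNOWN", .tmpl_unknown)
  if (any(band)) {
    qi <- as.integer(round(q[band]))
    # snap any non-integer quantity back inside its band after rounding
    qi <- pmax(qi, 1L)
    qi[category[band] == "MODERATE"] <- pmin(pmax(qi[category[band] ==
                                                       "MODERATE"], 3L), 15L)
    qi[category[band] == "LIGHT"] <- pmin(qi[category[band] == "LIGHT"], 2L)
    qi[category[band] == "HEAVY"] <- pmax(qi[category[band] == "HEAVY"], 16L)
    style <- sample.int(5, sum(band), replace = TRUE)
    # style 5 (range) needs q-1 >= 1 to stay in LIGHT; style 6 daily; 7 words
    style[style == 5 & qi <= 1] <- 1L
    up6 <- style == 4 & qi %% 7L == 0L & qi > 0L
    style[up6] <- 6L
    up7 <- style == 2 & qi <= 20L
    style[up7] <- 7L
    out[band] <- render_quantity(qi, style)
  }
  out
}

#' @noRd
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

# solve the intercept so the realized marginal equals the target
#' @noRd
calibrate_intercept <- function(eta, target) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  stats::uniroot(f, c(-40, 40), tol = 1e-12)$root
}

#' @noRd
iso_dates_of_year <- function(year) {
  format(seq(as.Date(sprintf("%d-01-01", year)),
             as.Date(sprintf("%d-12-31", year)), by = "day"), "%Y-%m-%d")
}

#' Simulate a multi-table EMR extract with known ground truth
#'
#' Draws independent patient and provider covariates, overdispersed yearly
#' visit counts, a logistic documentation indicator (intercept calibrated so
#' the marginal equals `p_document_base`), a covariate-tilted category for
#' documented patients, and a rendered free-text note per documented
#' patient. Clustering arises from shared provider-level covariates; given
#' the covariates, outcomes are independent across patients.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `alcodoc_extract`: a list of data frames
#'   `patients`, `providers`, `encounters`, `conditions`, `riskfactor`,
#'   `truth`, plus the `config` used.
#' @export
simulate_extract <- function(config) {
  validate_sim_config(config)
  if (config$n_patients == 0) stop_data("empty extract: n_patients is 0")
  set.seed(config$seed)
  n <- config$n_patients
  k <- config$n_providers
  win <- as.Date(config$date_window)
  years <- as.integer(format(win[1], "%Y")):(as.integer(format(win[2] - 1,
                                                               "%Y")))
  ny <- length(years)

  ## providers -------------------------------------------------------------
  prov_male <- stats::rbinom(k, 1, 1 - config$provider_p_female)
  prov_age <- rtrunc_norm(k, config$provider_age_mean,
                          config$provider_age_sd, 25, 80)
  prov_fp <- stats::rbinom(k, 1, config$provider_p_fp)
  prov_birth <- win[2] - 1 - round(prov_age * 365.25)
  providers <- data.frame(
    provider_id = seq_len(k),
    sex = ifelse(prov_male == 1, "M", "F"),
    birth_date = format(prov_birth, "%Y-%m-%d"),
    provider_type = ifelse(prov_fp == 1, "FP", "NP"),
    stringsAsFactors = FALSE)

  ## patients --------------------------------------------------------------
  provider_id <- sample(rep_len(seq_len(k), n))
  male <- stats::rbinom(n, 1, config$p_male)
  age <- rtrunc_norm(n, config$age_mean, config$age_sd, 18, 105)
  urban <- stats::rbinom(n, 1, config$p_urban)
  cma_pop <- integer(n)
  cma_pop[urban == 1] <- sample(c(150000L, 500000L, 1200000L, 2500000L),
                                sum(urban == 1), replace = TRUE)
  cma_pop[urban == 0] <- sample(c(5000L, 20000L, 80000L, 99999L),
                                sum(urban == 0), replace = TRUE)
  if (config$urban_missing_rate > 0) {
    cma_pop[stats::runif(n) < config$urban_missing_rate] <- NA_integer_
  }

  ## encounters: NB yearly counts, at least one encounter overall ----------
  counts <- matrix(stats::rnbinom(n * ny, mu = config$visit_rate,
                                  size = config$visit_size),
                   nrow = n, ncol = ny)
  none <- which(rowSums(counts) == 0)
  if (length(none)) {
    counts[cbind(none, sample.int(ny, length(none), replace = TRUE))] <- 1L
  }
  date_pool <- lapply(years, iso_dates_of_year)
  date_pool_int <- lapply(years, function(y)
    as.integer(seq(as.Date(sprintf("%d-01-01", y)),
                   as.Date(sprintf("%d-12-31", y)), by = "day")))
  per_year <- vector("list", ny)
  for (j in seq_len(ny)) {
    cj <- counts[, j]
    pid_j <- rep.int(seq_len(n), cj)
    doy_j <- sample.int(length(date_pool[[j]]), sum(cj), replace = TRUE)
    per_year[[j]] <- list(pid = pid_j, date = date_pool[[j]][doy_j],
                          dint = date_pool_int[[j]][doy_j])
  }
  enc_pid <- unlist(lapply(per_year, `[[`, "pid"), use.names = FALSE)
  enc_date <- unlist(lapply(per_year, `[[`, "date"), use.names = FALSE)
  encounters <- data.frame(
    encounter_id = seq_along(enc_pid),
    patient_id = enc_pid,
    provider_id = provider_id[enc_pid],
    date = enc_date,
    stringsAsFactors = FALSE)

  # anchor birth dates at the last in-window encounter so derived age
  # equals the drawn age
  enc_int <- unlist(lapply(per_year, `[[`, "dint"), use.names = FALSE)
  agg <- data.table::data.table(pid = enc_pid, d = enc_int)
  agg <- agg[, list(last = max(d)), keyby = "pid"]
  last_enc <- agg$last[match(seq_len(n), agg$pid)]
  birth <- as.Date(last_enc - round(age * 365.25), origin = "1970-01-01")
  patients <- data.frame(
    patient_id = seq_len(n),
    provider_id = provider_id,
    sex = ifelse(male == 1, "M", "F"),
    birth_date = format(birth, "%Y-%m-%d"),
    cma_population = cma_pop,
    stringsAsFactors = FALSE)

  ## conditions ------------------------------------------------------------
  prev <- config$comorbidity_prevalences
  conditions <- data.frame(patient_id = seq_len(n))
  for (cond in names(prev)) {
    conditions[[cond]] <- stats::rbinom(n, 1, prev[[cond]])
  }

  ## documentation model ----------------------------------------------------
  med_visits <- if (ny == 3) {
    counts[, 1] + counts[, 2] + counts[, 3] -
      pmax(counts[, 1], counts[, 2], counts[, 3]) -
      pmin(counts[, 1], counts[, 2], counts[, 3])
  } else {
    apply(counts, 1, stats::median)
  }
  high_visits <- as.integer(med_visits > 3)
  x_doc <- cbind(male = male,
                 age_over_mean = as.integer(age > config$age_mean),
                 rural = 1L - urban,
                 high_visits = high_visits,
                 depression = conditions$depression %||% 0L,
                 diabetes = conditions$diabetes %||% 0L,
                 hypertension = conditions$hypertension %||% 0L,
                 osteoarthritis = conditions$osteoarthritis %||% 0L,
                 provider_male = prov_male[provider_id],
                 provider_age_over_mean =
                   as.integer(prov_age[provider_id] >
                                config$provider_age_mean))
  eff <- config$doc_logit_effects
  bad <- setdiff(names(eff), colnames(x_doc))
  if (length(bad)) stop_config("unknown doc_logit_effects: ",
                               paste(bad, collapse = ", "))
  eta_doc <- as.vector(x_doc[, names(eff), drop = FALSE] %*% eff)
  b0 <- calibrate_intercept(eta_doc, config$p_document_base)
  documented <- if (is.infinite(b0)) {
    rep(b0 > 0, n)
  } else {
    stats::runif(n) < stats::plogis(b0 + eta_doc)
  }

  ## category model, conditional on documentation --------------------------
  mix <- config$category_mix[alcohol_categories()]
  category <- rep(NA_character_, n)
  doc_idx <- which(documented)
  if (length(doc_idx)) {
    is_unknown <- stats::runif(length(doc_idx)) < mix[["UNKNOWN"]]
    category[doc_idx[is_unknown]] <- "UNKNOWN"
    cls <- doc_idx[!is_unknown]
    if (length(cls)) {
      p_cls <- mix[c("NONE", "LIGHT", "MODERATE", "HEAVY", "PAST")] /
        (1 - mix[["UNKNOWN"]])
      p_risk <- p_cls[["HEAVY"]] + p_cls[["PAST"]]
      x_risk <- cbind(male = male[cls],
                      age_per_year = age[cls] - config$age_mean,
                      rural = 1L - urban[cls],
                      high_visits = high_visits[cls],
                      depression = conditions$depression[cls],
                      diabetes = conditions$diabetes[cls],
                      hypertension = conditions$hypertension[cls],
                      osteoarthritis = conditions$osteoarthritis[cls])
      reff <- config$risk_logit_effects
      badr <- setdiff(names(reff), colnames(x_risk))
      if (length(badr)) stop_config("unknown risk_logit_effects: ",
                                    paste(badr, collapse = ", "))
      eta_r <- as.vector(x_risk[, names(reff), drop = FALSE] %*% reff)
      a0 <- calibrate_intercept(eta_r, p_risk)
      risk <- if (is.infinite(a0)) rep(a0 > 0, length(cls)) else
        stats::runif(length(cls)) < stats::plogis(a0 + eta_r)
      hi <- cls[risk]
      lo <- cls[!risk]
      category[hi] <- sample(c("HEAVY", "PAST"), length(hi), replace = TRUE,
                             prob = p_cls[c("HEAVY", "PAST")])
      category[lo] <- sample(c("NONE", "LIGHT", "MODERATE"), length(lo),
                             replace = TRUE,
                             prob = p_cls[c("NONE", "LIGHT", "MODERATE")])
    }
  }

  ## render notes -----------------------------------------------------------
  qty <- rep(NA_real_, n)
  qty[which(category == "LIGHT")] <-
    sample(1:2, sum(category == "LIGHT", na.rm = TRUE), replace = TRUE)
  qty[which(category == "MODERATE")] <-
    sample(3:15, sum(category == "MODERATE", na.rm = TRUE), replace = TRUE)
  qty[which(category == "HEAVY")] <-
    sample(16:40, sum(category == "HEAVY", na.rm = TRUE), replace = TRUE)
  qty[which(category == "NONE")] <- 0
  text <- rep("", n)
  if (length(doc_idx)) {
    text[doc_idx] <- render_note(category[doc_idx], qty[doc_idx])
    if (config$text_noise_rate > 0) {
      garble <- doc_idx[stats::runif(length(doc_idx)) <
                          config$text_noise_rate]
      text[garble] <- sample(.tmpl_noise, length(garble), replace = TRUE)
    }
  }
  all_days <- unlist(date_pool, use.names = FALSE)
  rf_date <- sample(all_days, length(doc_idx), replace = TRUE)
  riskfactor <- data.frame(patient_id = doc_idx,
                           date = rf_date,
                           text = text[doc_idx],
                           stringsAsFactors = FALSE)

  truth <- data.frame(patient_id = seq_len(n),
                      documented = documented,
                      true_category = ifelse(documented, category, ""),
                      rendered_text = text,
                      stringsAsFactors = FALSE)

  structure(list(patients = patients, providers = providers,
                 encounters = encounters, conditions = conditions,
                 riskfactor = riskfactor, truth = truth, config = config),
            class = "alcodoc_extract")
}

#' @export
print.alcodoc_extract <- function(x, ...) {
  cat("<alcodoc_extract>\n")
  for (nm in c("patients", "providers", "encounters", "conditions",
               "riskfactor", "truth")) {
    cat(sprintf("  %-11s %9d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Write an extract to a directory of CSV files
#'
#' Emits the six fixed-name RFC-4180 CSV tables (`patients.csv`,
#' `providers.csv`, `encounters.csv`, `conditions.csv`, `riskfactor.csv`,
#' `truth.csv`).
#'
#' @param extract an `alcodoc_extract`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_extract <- function(extract, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("patients", "providers", "encounters", "conditions",
               "riskfactor", "truth")) {
    data.table::fwrite(extract[[nm]], file.path(dir, paste0(nm, ".csv")),
                       quote = "auto", na = "")
  }
  invisible(dir)
}

#' Read an extract directory written by [write_extract()]
#'
#' @param dir directory holding the extract CSVs; `truth.csv` is optional.
#' @return an `alcodoc_extract` (without a `config`).
#' @export
read_extract <- function(dir) {
  tabs <- list()
  for (nm in c("patients", "providers", "encounters", "conditions",
               "riskfactor")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(path)) stop_data("missing extract file: ", path)
    tabs[[nm]] <- as.data.frame(data.table::fread(path,
                                                  colClasses = NULL))
  }
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) tabs$truth <- as.data.frame(data.table::fread(tp))
  if ("text" %in% names(tabs$riskfactor)) {
    tabs$riskfactor$text <- as.character(tabs$riskfactor$text)
  }
  structure(tabs, class = "alcodoc_extract")
}
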