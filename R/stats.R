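#' Prevalence of alcohol-consumption categories among documented patients
#'
#' Tabulates the five classified categories (percent of the classified
#' total, rounded half-up to one decimal), the unclassified count, the
#' documentation rate, and the heightened-risk share (heavy plus past over
#' classified).
#'
#' @param cohort an `alcodoc_cohort` (needs `documented` and `category`).
#' @return object of class `prevalence_table`.
#' @export
prevalence_table <- function(cohort) {
  cats <- c("NONE", "LIGHT", "MODERATE", "HEAVY", "PAST")
  counts <- vapply(cats, function(k)
    sum(cohort$category == k, na.rm = TRUE), integer(1))
  unclassified <- sum(cohort$category == "UNKNOWN", na.rm = TRUE)
  classified_total <- sum(counts)
  if (classified_total == 0) stop_data("no classified patients")
  documented_total <- sum(cohort$documented)
  cohort_total <- nrow(cohort)
  structure(list(
    counts = counts,
    percents = round_half_up(100 * counts / classified_total, 1),
    classified_total = classified_total,
    unclassified_count = unclassified,
    documented_total = documented_total,
    cohort_total = cohort_total,
    documentation_rate = round_half_up(100 * documented_total /
                                         cohort_total, 1),
    heightened_risk_percent = round_half_up(
      100 * (counts[["HEAVY"]] + counts[["PAST"]]) / classified_total, 1)),
    class = "prevalence_table")
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat("Documented alcohol use:", x$documented_total, "of", x$cohort_total,
      sprintf("patients (%.1f%%)\n", x$documentation_rate))
  lab <- c(NONE = "Non-drinker", LIGHT = "Light", MODERATE = "Moderate",
           HEAVY = "Heavy", PAST = "Past")
  for (k in names(x$counts)) {
    cat(sprintf("  %-12s %5.1f%% (%s)\n", lab[[k]], x$percents[[k]],
                format(x$counts[[k]], big.mark = ",")))
  }
  cat("  Classified total:", format(x$classified_total, big.mark = ","),
      "| unclassified:", format(x$unclassified_count, big.mark = ","), "\n")
  cat(sprintf("  Heightened risk (heavy or past): %.1f%%\n",
              x$heightened_risk_percent))
  invisible(x)
}

#' Compare a covariate between documented and undocumented patients
#'
#' Boolean covariates get a chi-square test without continuity correction
#' (switching to Fisher's exact test when a cell is empty, flagged in the
#' result); numeric covariates get a Welch two-sample t-test. Group
#' summaries (proportion or mean with 95% CI) mirror a descriptive-table
#' layout.
#'
#' @param cohort an `alcodoc_cohort`.
#' @param variable name of a cohort column.
#' @return object of class `alcodoc_bivariate`.
#' @export
bivariate_compare <- function(cohort, variable) {
  if (!variable %in% names(cohort)) stop_data("no such column: ", variable)
  x <- cohort[[variable]]
  grp <- cohort$documented
  keep <- !is.na(x) & !is.na(grp)
  x <- x[keep]
  grp <- grp[keep]
  zq <- stats::qnorm(0.975)
  if (is_bool_col(x)) {
    x <- as.logical(x)
    tab <- table(factor(grp, c(FALSE, TRUE)), factor(x, c(FALSE, TRUE)))
    exact <- any(tab == 0)
    ht <- if (exact) stats::fisher.test(tab) else
      stats::chisq.test(tab, correct = FALSE)
    smry <- lapply(c(FALSE, TRUE), function(gv) {
      n <- sum(grp == gv)
      k <- sum(x[grp == gv])
      p <- k / n
      se <- sqrt(p * (1 - p) / n)
      list(n = k, denom = n, estimate = p,
           ci = c(max(0, p - zq * se), min(1, p + zq * se)))
    })
    statistic <- if (exact) NA_real_ else unname(ht$statistic)
    type <- if (exact) "fisher" else "chisq"
  } else {
    ht <- stats::t.test(x[grp], x[!grp])
    smry <- lapply(c(FALSE, TRUE), function(gv) {
      xs <- x[grp == gv]
      m <- mean(xs)
      se <- stats::sd(xs) / sqrt(length(xs))
      list(n = length(xs), denom = length(xs), estimate = m, sd = stats::sd(xs),
           ci = c(m - zq * se, m + zq * se))
    })
    statistic <- unname(ht$statistic)
    type <- "t"
  }
  structure(list(variable = variable, type = type, statistic = statistic,
                 p = ht$p.value,
                 undocumented = smry[[1]], documented = smry[[2]]),
            class = "alcodoc_bivariate")
}

#' @export
print.alcodoc_bivariate <- function(x, ...) {
  fmt <- function(s) {
    if (!is.null(s$sd)) {
      sprintf("%.1f ((%.1f) %.2f-%.2f)", s$estimate, s$sd, s$ci[1], s$ci[2])
    } else {
      sprintf("%s (%.1f, %.3f-%.3f)", format(s$n, big.mark = ","),
              100 * s$estimate, s$ci[1], s$ci[2])
    }
  }
  cat(sprintf("%s  [%s test]\n", x$variable, x$type))
  cat("  no record:  ", fmt(x$undocumented), "\n")
  cat("  with record:", fmt(x$documented), "\n")
  cat("  p =", format.pval(x$p, digits = 3), "\n")
  invisible(x)
}

#' Crude odds ratio with Woolf confidence interval
#'
#' For the 2x2 table `(a, b; c, d)` the odds ratio is `ad/bc` with
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))` as its CI. A zero
#' cell triggers the Haldane-Anscombe correction (0.5 added to every cell),
#' flagged in the result.
#'
#' @param a,b,c,d non-negative cell counts: `a`,`b` the exposed/unexposed
#'   with the outcome, `c`,`d` without.
#' @param conf_level confidence level, default 0.95.
#' @return list with `or`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' crude_odds_ratio(10, 5, 2, 4)$or  # 4
#' @export
crude_odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop_data("cell counts must be non-negative")
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / cells))
  list(or = or, ci_low = exp(log(or) - zq * se),
       ci_high = exp(log(or) + zq * se), corrected = corrected)
}

# shared machinery for the two published models
#' @noRd
fit_clustered_model <- function(cohort, outcome, terms, corstr, unadjusted,
                                outcome_name) {
  dat <- as.data.frame(cohort)[, c(outcome, terms, "provider_id")]
  names(dat)[1] <- ".y"
  dat <- dat[!is.na(dat$.y), , drop = FALSE]
  if (nrow(dat) == 0) stop_model("no usable rows for ", outcome_name)
  dat$.y <- as.numeric(dat$.y)
  for (tm in terms) {
    if (is.logical(dat[[tm]])) dat[[tm]] <- as.numeric(dat[[tm]])
  }
  full <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fit <- gee_logit(full, dat, id = "provider_id", corstr = corstr)
  adj <- tidy_gee(fit)
  adj <- adj[adj$term != "(Intercept)", , drop = FALSE]
  res <- data.frame(term = adj$term,
                    adjusted_or = adj$or, adjusted_ci_low = adj$ci_low,
                    adjusted_ci_high = adj$ci_high, p = adj$p,
                    stringsAsFactors = FALSE)
  if (unadjusted) {
    un <- lapply(terms, function(tm) {
      f1 <- stats::as.formula(paste(".y ~", tm))
      t1 <- tidy_gee(gee_logit(f1, dat, id = "provider_id",
                               corstr = corstr))
      t1[t1$term != "(Intercept)", c("term", "or", "ci_low", "ci_high")]
    })
    un <- do.call(rbind, un)
    m <- match(res$term, un$term)
    res$unadjusted_or <- un$or[m]
    res$unadjusted_ci_low <- un$ci_low[m]
    res$unadjusted_ci_high <- un$ci_high[m]
  }
  structure(list(outcome = outcome_name, terms = res,
                 n_used = fit$n_used, n_dropped = fit$n_dropped,
                 n_clusters = fit$n_clusters,
                 working_correlation = fit$corstr, alpha = fit$alpha,
                 fit = fit),
            class = "alcodoc_model")
}

#' Provider-clustered model of alcohol documentation
#'
#' Marginal logistic model (GEE, robust standard errors, clustered by
#' provider) of whether a patient has any alcohol documentation, with the
#' published term list: patient sex, dichotomized age, rural residency,
#' the visit split, depression, diabetes, hypertension, the
#' arthritis/bone-condition flag, provider sex and dichotomized provider
#' age. Unadjusted odds ratios come from single-term clustered fits.
#'
#' @param cohort an `alcodoc_cohort`.
#' @param corstr working correlation for the GEE.
#' @param unadjusted also fit per-term single-covariate models (default
#'   `TRUE`; disable in tight simulation loops).
#' @return object of class `alcodoc_model`: `terms` data frame with
#'   adjusted (and unadjusted) odds ratios, 95% CIs and p-values, plus
#'   `n_used`, `n_clusters`, `working_correlation` and the raw `fit`.
#' @export
fit_documentation_model <- function(cohort,
                                    corstr = c("exchangeable",
                                               "independence"),
                                    unadjusted = TRUE) {
  corstr <- match.arg(corstr)
  cohort <- as.data.frame(cohort)
  cohort$rural <- !cohort$urban
  terms <- c("male", "age_over_mean", "rural", "high_visits", "depression",
             "diabetes", "hypertension", "osteoarthritis", "provider_male",
             "provider_age_over_mean")
  missing <- setdiff(terms, names(cohort))
  if (length(missing)) stop_data("cohort lacks model terms: ",
                                 paste(missing, collapse = ", "))
  fit_clustered_model(cohort, "documented", terms, corstr, unadjusted,
                      "alcohol documentation (yes vs no)")
}

#' Provider-clustered model of heightened alcohol-related risk
#'
#' Restricted to classified patients (the unclassifiable bucket is out of
#' the denominator), models heavy-or-past drinking with patient terms only;
#' age enters continuously per year.
#'
#' @inheritParams fit_documentation_model
#' @return an `alcodoc_model`.
#' @export
fit_risk_model <- function(cohort,
                           corstr = c("exchangeable", "independence"),
                           unadjusted = TRUE) {
  corstr <- match.arg(corstr)
  cohort <- as.data.frame(cohort)
  cohort$rural <- !cohort$urban
  terms <- c("male", "age_years", "rural", "high_visits", "depression",
             "diabetes", "hypertension", "osteoarthritis")
  missing <- setdiff(terms, names(cohort))
  if (length(missing)) stop_data("cohort lacks model terms: ",
                                 paste(missing, collapse = ", "))
  fit_clustered_model(cohort, "heightened_risk", terms, corstr, unadjusted,
                      "heightened alcohol-related risk (heavy or past)")
}

#' @export
print.alcodoc_model <- function(x, ...) {
  cat("Outcome:", x$outcome, "\n")
  cat("  n =", format(x$n_used, big.mark = ","), "in", x$n_clusters,
      "provider clusters;", x$working_correlation,
      "working correlation\n")
  t <- x$terms
  has_un <- "unadjusted_or" %in% names(t)
  for (i in seq_len(nrow(t))) {
    un <- if (has_un) sprintf("%.2f (%.2f-%.2f)  ", t$unadjusted_or[i],
                              t$unadjusted_ci_low[i],
                              t$unadjusted_ci_high[i]) else ""
    cat(sprintf("  %-24s %s%.2f (%.2f-%.2f)  p=%s\n", t$term[i], un,
                t$adjusted_or[i], t$adjusted_ci_low[i],
                t$adjusted_ci_high[i],
                format.pval(t$p[i], digits = 2, eps = 1e-4)))
  }
  invisible(x)
}

#' Write machine- and human-readable result tables
#'
#' Emits `results.csv` (schema: section, term, estimate, ci_low, ci_high,
#' p, n) and `report.txt` with prevalence, bivariate and model sections in
#' a published-table layout. Percents are rounded half-up to one decimal,
#' odds ratios to two.
#'
#' @param prevalence a `prevalence_table`.
#' @param bivariates list of `alcodoc_bivariate` results (may be empty).
#' @param models list of `alcodoc_model` fits (may be empty).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
write_report <- function(prevalence, bivariates = list(), models = list(),
                         out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add <- function(section, term, estimate, ci_low = NA, ci_high = NA,
                  p = NA, n = NA) {
    rows[[length(rows) + 1]] <<- data.frame(
      section = section, term = term, estimate = estimate,
      ci_low = ci_low, ci_high = ci_high, p = p, n = n,
      stringsAsFactors = FALSE)
  }
  for (k in names(prevalence$counts)) {
    add("prevalence", k, prevalence$percents[[k]],
        n = prevalence$counts[[k]])
  }
  add("prevalence", "UNCLASSIFIED", NA, n = prevalence$unclassified_count)
  add("prevalence", "documentation_rate", prevalence$documentation_rate,
      n = prevalence$cohort_total)
  add("prevalence", "heightened_risk_share",
      prevalence$heightened_risk_percent, n = prevalence$classified_total)
  for (bv in bivariates) {
    add(paste0("bivariate:", bv$variable), "documented",
        bv$documented$estimate, bv$documented$ci[1], bv$documented$ci[2],
        bv$p, bv$documented$denom)
    add(paste0("bivariate:", bv$variable), "undocumented",
        bv$undocumented$estimate, bv$undocumented$ci[1],
        bv$undocumented$ci[2], bv$p, bv$undocumented$denom)
  }
  for (md in models) {
    sec <- paste0("model:", md$outcome)
    t <- md$terms
    for (i in seq_len(nrow(t))) {
      add(sec, t$term[i], round_half_up(t$adjusted_or[i], 2),
          round_half_up(t$adjusted_ci_low[i], 2),
          round_half_up(t$adjusted_ci_high[i], 2), t$p[i], md$n_used)
      if ("unadjusted_or" %in% names(t)) {
        add(sec, paste0(t$term[i], ":unadjusted"),
            round_half_up(t$unadjusted_or[i], 2),
            round_half_up(t$unadjusted_ci_low[i], 2),
            round_half_up(t$unadjusted_ci_high[i], 2), NA, md$n_used)
      }
    }
  }
  results <- do.call(rbind, rows)
  csv_path <- file.path(out_dir, "results.csv")
  data.table::fwrite(results, csv_path)

  txt_path <- file.path(out_dir, "report.txt")
  con <- file(txt_path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("Alcohol documentation analysis")
  wl(strrep("=", 60))
  wl("")
  wl("Category prevalence among documented patients")
  out <- utils::capture.output(print(prevalence))
  writeLines(out, con)
  for (bv in bivariates) {
    wl("")
    writeLines(utils::capture.output(print(bv)), con)
  }
  for (md in models) {
    wl("")
    writeLines(utils::capture.output(print(md)), con)
  }
  wl("")
  wl("No multiple-testing correction applied.")
  invisible(c(csv_path, txt_path))
}
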