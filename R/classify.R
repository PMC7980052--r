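#' Normalize free text prior to rule matching
#'
#' Lowercases, maps typographic quotes/dashes to ASCII, collapses runs of
#' whitespace, trims, and strips trailing sentence punctuation. Idempotent:
#' `normalize_text(normalize_text(x)) == normalize_text(x)`.
#'
#' @param raw character vector (may contain `NA` or empty strings).
#' @return normalized character vector of the same length.
#' @examples
#' normalize_text("  Social   Drinker. ")  # "social drinker"
#' @export
normalize_text <- function(raw) {
  x <- as.character(raw)
  x[is.na(x)] <- ""
  x <- gsub("[‘’]", "'", x)
  x <- gsub("[“”]", "\"", x)
  x <- gsub("[–—]", "-", x)
  x <- tolower(x)
  x <- gsub("\\s+", " ", x)
  x <- trimws(x)
  x <- sub("[[:space:].!?]+$", "", x)
  x
}

# number words up to twenty mapped to digits for the quantity grammar
#' @noRd
word_numbers <- c(one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
                  seven = 7, eight = 8, nine = 9, ten = 10, eleven = 11,
                  twelve = 12, thirteen = 13, fourteen = 14, fifteen = 15,
                  sixteen = 16, seventeen = 17, eighteen = 18, nineteen = 19,
                  twenty = 20)

#' @noRd
sub_word_numbers <- function(x) {
  hit <- grepl(paste0("\\b(?:", paste(names(word_numbers), collapse = "|"),
                      ")\\b"), x, perl = TRUE)
  if (any(hit)) {
    y <- x[hit]
    for (w in names(word_numbers)) {
      y <- gsub(paste0("\\b", w, "\\b"), word_numbers[[w]], y, perl = TRUE)
    }
    x[hit] <- y
  }
  x
}

# quantity grammar: <number>[-<number>] [unit] (per|a|/) (week|day|month)
#' @noRd
.qty_num <- "\\d+(?:\\.\\d+)?"
#' @noRd
.qty_unit <- paste0(
  "(?:\\s*(?:standard\\s+)?",
  "(?:drinks?|beers?|glass(?:es)?|bottles?|units?|shots?|etoh))?"
)
#' @noRd
.qty_period <- paste0(
  "(?:\\s*(?:per|each|a|an)\\s+(?:week|wk|day|month|mo)\\b",
  "|\\s*/\\s*(?:week|wk|w|day|d|month|mo)\\b",
  "|\\s+(?:weekly|daily|monthly)\\b)"
)
#' @noRd
.qty_single <- paste0("(", .qty_num, ")", .qty_unit, .qty_period)
#' @noRd
.qty_range <- paste0("(", .qty_num, ")\\s*(?:-|to\\s)\\s*(", .qty_num, ")",
                     .qty_unit, .qty_period)

# weekly-equivalent multiplier read off a matched snippet
#' @noRd
period_factor <- function(snippet) {
  f <- rep(1, length(snippet))
  f[grepl("\\b(?:day|daily|d)\\b", snippet, perl = TRUE)] <- 7
  f[grepl("\\b(?:month|mo|monthly)\\b", snippet, perl = TRUE)] <- 7 / 30
  f
}

# vectorized quantity extraction on normalized text; returns the
# weekly-equivalent value and the matched snippet ("" when absent)
#' @noRd
extract_quantity_full <- function(text) {
  s <- sub_word_numbers(text)
  value <- rep(NA_real_, length(s))
  snip <- character(length(s))

  take <- function(pattern, resolve) {
    open <- is.na(value)
    if (!any(open)) return(invisible())
    m <- regexpr(pattern, s[open], perl = TRUE)
    hit <- m > 0
    if (any(hit)) {
      mm <- substring(s[open][hit], m[hit],
                      m[hit] + attr(m, "match.length")[hit] - 1)
      idx <- which(open)[hit]
      value[idx] <<- resolve(mm) * period_factor(mm)
      snip[idx] <<- mm
    }
  }

  take(.qty_range, function(mm) {
    nums <- regmatches(mm, gregexpr(.qty_num, mm, perl = TRUE))
    vapply(nums, function(v) mean(as.numeric(v[1:2])), numeric(1))
  })
  take(.qty_single, function(mm) {
    as.numeric(regmatches(mm, regexpr(.qty_num, mm, perl = TRUE)))
  })
  list(value = value, match = snip)
}

#' Extract a weekly-equivalent drink quantity from normalized text
#'
#' Parses `<number> [unit] per <period>` constructs, including ranges
#' (resolved to their midpoint), `/wk`-style shorthand, number words up to
#' twenty, and `weekly`/`daily`/`monthly` adverbs. Daily quantities are
#' multiplied by 7, monthly divided by 30/7. Unparseable text yields `NA`.
#'
#' @param text character vector of normalized text (see [normalize_text()]).
#' @param rules a rule set (reserved for grammar extensions; unused fields
#'   are ignored).
#' @return numeric vector of drinks per week, `NA` where absent.
#' @examples
#' extract_quantity(c("2 drinks per week", "4 drinks a day", "drinks socially"))
#' @export
extract_quantity <- function(text, rules = default_rules()) {
  extract_quantity_full(normalize_text(text))$value
}

# band thresholds; heavy cut drops to 10/wk for females under the
# sex-specific guideline option
#' @noRd
band_label <- function(qty, heavy_cut = 15) {
  lab <- rep(NA_character_, length(qty))
  ok <- !is.na(qty)
  lab[ok & qty == 0] <- "NONE"
  lab[ok & qty > 0 & qty < 3] <- "LIGHT"
  lab[ok & qty >= 3 & qty <= heavy_cut] <- "MODERATE"
  lab[ok & qty > heavy_cut] <- "HEAVY"
  lab
}

# vectorized core: one row per note
#' @noRd
classify_notes <- function(raw, rules, sex = NULL) {
  n <- length(raw)
  norm <- normalize_text(raw)
  past_re <- phrase_regex(rules$past_keywords)
  none_re <- phrase_regex(rules$none_keywords)
  unk_re <- phrase_regex(rules$unknown_markers)

  match_snip <- function(re, txt) {
    m <- regexpr(re, txt, perl = TRUE)
    out <- character(length(txt))
    hit <- m > 0
    out[hit] <- substring(txt[hit], m[hit],
                          m[hit] + attr(m, "match.length")[hit] - 1)
    out
  }
  past_ev <- match_snip(past_re, norm)
  none_ev <- match_snip(none_re, norm)
  unk_ev <- match_snip(unk_re, norm)

  # sentence-window negation: a quantity sharing a sentence with a denial
  # phrase is voided ("denies etoh. wife: 10/wk" keeps the quantity)
  sents <- strsplit(norm, "\\s*[.;]\\s*", perl = TRUE)
  len <- lengths(sents)
  flat <- unlist(sents, use.names = FALSE)
  note_id <- rep.int(seq_len(n), len)
  q <- extract_quantity_full(flat)
  denied <- grepl(none_re, flat, perl = TRUE)
  q$value[denied] <- NA_real_

  qty <- rep(NA_real_, n)
  qsnip <- character(n)
  ok <- !is.na(q$value)
  # first parseable, non-voided quantity in reading order wins
  keep <- which(ok)[!duplicated(note_id[ok])]
  qty[note_id[keep]] <- q$value[keep]
  qsnip[note_id[keep]] <- q$match[keep]

  heavy_cut <- rep(15, n)
  if (rules$sex_specific_bands && !is.null(sex)) {
    heavy_cut[toupper(substr(as.character(sex), 1, 1)) == "F"] <- 10
  }

  label <- rep("UNKNOWN", n)
  bl <- band_label(qty, heavy_cut)
  label[!is.na(bl)] <- bl[!is.na(bl)]
  label[is.na(qty) & nzchar(none_ev)] <- "NONE"
  label[nzchar(past_ev)] <- "PAST"

  evidence <- character(n)
  add_ev <- function(ev, tag, snips) {
    hit <- nzchar(snips)
    piece <- paste0(tag, ":", snips[hit])
    ev[hit] <- ifelse(nzchar(ev[hit]), paste(ev[hit], piece, sep = "; "),
                      piece)
    ev
  }
  evidence <- add_ev(evidence, "past", past_ev)
  evidence <- add_ev(evidence, "qty", qsnip)
  evidence <- add_ev(evidence, "none", none_ev)
  evidence[label == "UNKNOWN"] <- add_ev(character(sum(label == "UNKNOWN")),
                                         "marker",
                                         unk_ev[label == "UNKNOWN"])

  data.frame(label = label, drinks_per_week = qty, evidence = evidence,
             stringsAsFactors = FALSE)
}

#' Classify a single free-text alcohol note
#'
#' Applies the deterministic rule system: phrases indicating past use
#' dominate; otherwise a parsed weekly quantity is banded as light
#' (<3 drinks/week), moderate (3-15) or heavy (>15); otherwise a denial
#' phrase gives non-drinker; anything else (family history, unquantified
#' mentions, empty text) is unknown.
#'
#' @param raw a single free-text entry.
#' @param rules a rule set from [default_rules()].
#' @param sex optional patient sex ("M"/"F"); only consulted when the rule
#'   set enables sex-specific bands.
#' @return an object of class `alcohol_category`: list with `label`,
#'   `drinks_per_week` (`NA` when no quantity parsed), and `evidence`
#'   (character vector of fired rules, empty only for UNKNOWN).
#' @examples
#' classify_note("recovering, attends Alcoholics Anonymous")$label  # PAST
#' classify_note("3 drinks a week")$label                           # MODERATE
#' classify_note("father was an alcoholic")$label                   # UNKNOWN
#' @export
classify_note <- function(raw, rules = default_rules(), sex = NULL) {
  stopifnot(length(raw) == 1)
  row <- classify_notes(raw, rules, sex)
  ev <- strsplit(row$evidence, "; ", fixed = TRUE)[[1]]
  structure(list(label = row$label,
                 drinks_per_week = row$drinks_per_week,
                 evidence = ev),
            class = "alcohol_category")
}

#' @export
print.alcohol_category <- function(x, ...) {
  cat("<alcohol_category>", x$label)
  if (!is.na(x$drinks_per_week)) {
    cat(sprintf(" (%.1f drinks/week)", x$drinks_per_week))
  }
  cat("\n")
  if (length(x$evidence)) cat("  evidence:", paste(x$evidence, collapse = "; "),
                              "\n")
  invisible(x)
}

#' Classify a risk-factor table, one resolved label per patient
#'
#' Classifies every note, then resolves patients with multiple notes to a
#' single category. Under the default `most-recent` policy the note with the
#' latest date wins; exact date ties (and tables without a date column) fall
#' back to the heavier-risk label. The `heaviest` policy takes the
#' heaviest-risk label outright.
#'
#' @param riskfactor data frame with columns `patient_id`, `text`, and
#'   optionally `date` (ISO-8601).
#' @param rules a rule set from [default_rules()].
#' @param policy `"most-recent"` (default) or `"heaviest"`.
#' @param sex optional data frame `patient_id`,`sex` for sex-specific bands.
#' @return data frame with one row per patient present in `riskfactor`:
#'   `patient_id`, `label`, `drinks_per_week`, `evidence`.
#' @export
classify_table <- function(riskfactor, rules = default_rules(),
                           policy = c("most-recent", "heaviest"),
                           sex = NULL) {
  policy <- match.arg(policy)
  need <- c("patient_id", "text")
  if (!all(need %in% names(riskfactor))) {
    stop_data("riskfactor table must have columns: ",
              paste(need, collapse = ", "))
  }
  if (nrow(riskfactor) == 0) {
    return(data.frame(patient_id = riskfactor$patient_id[0],
                      label = character(0), drinks_per_week = numeric(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  }
  sex_vec <- NULL
  if (!is.null(sex) && rules$sex_specific_bands) {
    sex_vec <- sex$sex[match(riskfactor$patient_id, sex$patient_id)]
  }
  cls <- classify_notes(riskfactor$text, rules, sex_vec)
  date <- if ("date" %in% names(riskfactor)) {
    parse_iso_date(riskfactor$date)
  } else {
    rep(0L, nrow(riskfactor))
  }
  sev <- category_severity(cls$label)
  key <- if (policy == "most-recent") {
    order(riskfactor$patient_id, date, sev)
  } else {
    order(riskfactor$patient_id, sev)
  }
  # after ordering, the last row per patient is the resolved note
  pid <- riskfactor$patient_id[key]
  last <- !duplicated(pid, fromLast = TRUE)
  take <- key[last]
  data.frame(patient_id = riskfactor$patient_id[take],
             label = cls$label[take],
             drinks_per_week = cls$drinks_per_week[take],
             evidence = cls$evidence[take],
             stringsAsFactors = FALSE)
}
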