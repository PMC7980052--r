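#' Round half away from zero at a fixed number of decimals
#'
#' Published clinical tables round 0.5 up (43.65 -> 43.7), unlike base
#' [round()], which rounds half to even. Used everywhere a percent or odds
#' ratio is formatted for a table.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(43.577)   # 43.6
#' round_half_up(2.5, 0)   # 3
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic per-stage seed fan-out: one global seed drives every stage,
# so a stage can be rerun in isolation with the same stream it saw in the
# pipeline. Offsets are fixed and documented; result kept below 2^31.
#' Derive a per-stage seed from a global seed
#'
#' @param seed global integer seed.
#' @param stage stage name, one of "simulate", "classify", "cohort",
#'   "analyze", "report".
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 1L, classify = 2L, cohort = 3L, analyze = 4L,
               report = 5L)
  if (!stage %in% names(offsets)) {
    stop("unknown stage: ", stage, call. = FALSE)
  }
  as.integer((as.numeric(seed) * 48271 + offsets[[stage]]) %% 2147483647)
}

#' @noRd
stop_config <- function(...) {
  stop(structure(class = c("alcodoc_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
stop_data <- function(...) {
  stop(structure(class = c("alcodoc_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
stop_model <- function(...) {
  stop(structure(class = c("alcodoc_model_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @noRd
is_bool_col <- function(x) is.logical(x) || all(x %in% c(0, 1, NA))

# fast vectorized ISO-8601 date parser (days since 1970-01-01, integer).
# as.Date() costs seconds per million rows; encounter tables run to
# millions. `validate` adds a strict-format check so malformed entries
# come back NA instead of being misread.
#' @noRd
parse_iso_date <- function(x, validate = FALSE) {
  x <- as.character(x)
  suppressWarnings({
    y <- as.integer(substr(x, 1, 4))
    m <- as.integer(substr(x, 6, 7))
    d <- as.integer(substr(x, 9, 10))
  })
  bad <- is.na(y) | is.na(m) | is.na(d) | m < 1L | m > 12L | d < 1L |
    d > 31L | nchar(x) != 10L
  if (validate) bad <- bad | !grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(bad)) {
    y[bad] <- 2000L
    m[bad] <- 1L
    d[bad] <- 1L
  }
  yy <- y - (m <= 2L)
  era <- (yy - ifelse(yy < 0L, 399L, 0L)) %/% 400L
  yoe <- yy - era * 400L
  doy <- (153L * (m + ifelse(m > 2L, -3L, 9L)) + 2L) %/% 5L + d - 1L
  doe <- yoe * 365L + yoe %/% 4L - yoe %/% 100L + doy
  out <- era * 146097L + doe - 719468L
  out[bad] <- NA_integer_
  out
}

#' Alcohol category labels
#'
#' The six labels used throughout: the three guideline consumption bands,
#' non-drinkers, past drinkers, and the unclassified bucket.
#' @return character vector of the six labels in canonical order.
#' @export
alcohol_categories <- function() {
  c("NONE", "LIGHT", "MODERATE", "HEAVY", "PAST", "UNKNOWN")
}

# severity used only to break exact date ties between notes; heightened-risk
# labels outrank consumption bands, UNKNOWN ranks lowest
#' @noRd
category_severity <- function(label) {
  rank <- c(UNKNOWN = 0, NONE = 1, LIGHT = 2, MODERATE = 3, HEAVY = 4,
            PAST = 5)
  rank[label]
}
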