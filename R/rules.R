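#' Rule set for alcohol free-text classification
#'
#' A rule set bundles the phrase dictionaries and the quantity grammar the
#' classifier uses. Dictionaries are plain-text files, one phrase per line,
#' `#` starting a comment, so a site-specific keyword list can be dropped in
#' without touching code.
#'
#' @param dir directory containing `past.txt`, `none.txt`, `unknown.txt`.
#'   Defaults to the dictionaries shipped with the package.
#' @param sex_specific_bands logical; if `TRUE`, the heavy threshold is 15
#'   drinks/week for males and 10 for females (the Canadian low-risk
#'   guideline limits) instead of the sex-agnostic 15. Off by default: the
#'   published category bands are sex-agnostic.
#' @return an object of class `alcodoc_rules`.
#' @examples
#' r <- default_rules()
#' length(r$past_keywords) >= 4
#' @export
default_rules <- function(dir = system.file("extdata", "rules",
                                            package = "alcodoc"),
                          sex_specific_bands = FALSE) {
  read_dict <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop_config("missing dictionary file: ", path)
    x <- readLines(path, encoding = "UTF-8", warn = FALSE)
    x <- sub("#.*$", "", x)
    x <- trimws(tolower(x))
    x <- x[nzchar(x)]
    if (any(!nzchar(x))) stop_config("empty phrase in ", f)
    x
  }
  rules <- list(
    past_keywords = read_dict("past.txt"),
    none_keywords = read_dict("none.txt"),
    unknown_markers = read_dict("unknown.txt"),
    sex_specific_bands = isTRUE(sex_specific_bands),
    precedence = c("PAST", "QUANTITY", "NONE", "UNKNOWN")
  )
  required <- c("alcoholics anonymous", "recovering", "recovered", "past")
  missing <- setdiff(required, rules$past_keywords)
  if (length(missing)) {
    stop_config("past.txt must contain the core phrases: ",
                paste(missing, collapse = ", "))
  }
  structure(rules, class = "alcodoc_rules")
}

#' @export
print.alcodoc_rules <- function(x, ...) {
  cat("<alcodoc_rules>\n")
  cat("  past keywords:   ", length(x$past_keywords), "\n")
  cat("  denial keywords: ", length(x$none_keywords), "\n")
  cat("  unknown markers: ", length(x$unknown_markers), "\n")
  cat("  bands: light (0,3), moderate [3,15], heavy (15,Inf)",
      if (x$sex_specific_bands) "[sex-specific heavy threshold]" else "",
      "\n")
  invisible(x)
}

# one alternation regex per dictionary, word-bounded; phrases may hold
# regex metacharacters ("ex-drinker"), so escape them first
#' @noRd
phrase_regex <- function(phrases) {
  esc <- gsub("([.\\\\|()\\[\\]{}^$*+?-])", "\\\\\\1", phrases, perl = TRUE)
  paste0("\\b(?:", paste(esc, collapse = "|"), ")\\b")
}
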