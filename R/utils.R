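# Shared helpers: rounding, name normalization, ISO-8601 durations, errors.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all reported percentages so that
#' e.g. 26.95 prints as 27.0. `base::round()` rounds half to even, which
#' would silently change reported one-decimal frequencies.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.25, 0.35), 1) # 0.3 0.4
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Normalize a disease name for exact-match grounding
#'
#' Case-folds, applies Unicode compatibility normalization (NFKC, so en-dash
#' and typographic quotes collapse), replaces punctuation and symbol
#' characters with spaces, collapses whitespace, and drops a leading or
#' trailing article "the". Idempotent: `normalize_name(normalize_name(x))`
#' equals `normalize_name(x)`.
#'
#' @param s character vector of raw names.
#' @return character vector of normalized keys.
#' @export
#' @examples
#' normalize_name("Loeys–Dietz Syndrome") # "loeys dietz syndrome"
normalize_name <- function(s) {
  out <- stringi::stri_trans_nfkc(s)
  out <- stringi::stri_trans_tolower(out)
  out <- stringi::stri_replace_all_regex(out, "[\\p{P}\\p{S}]", " ")
  out <- stringi::stri_replace_all_regex(out, "\\s+", " ")
  out <- stringi::stri_trim_both(out)
  out <- stringi::stri_replace_all_regex(out, "^the\\s+|\\s+the$", "")
  stringi::stri_trim_both(out)
}

# ---- ISO-8601 durations (date components only; ages never need H/M/S) ----

iso8601_regex <- "^P(?:(\\d+)Y)?(?:(\\d+)M)?(?:(\\d+)W)?(?:(\\d+)D)?$"

#' Parse an ISO-8601 duration used as an age
#'
#' Accepts the date components of an ISO-8601 duration (`P14Y2M`, `P6M`,
#' `P3W`, `P10D`). Components are non-negative by construction of the
#' grammar; at least one component must be present.
#'
#' @param x a single duration string.
#' @return named list with integer `years`, `months`, `weeks`, `days`.
#' @export
parse_iso8601_duration <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- stringr::str_match(x, iso8601_regex)
  if (is.na(m[1, 1]) || x == "P") {
    abort_pdx("invalid ISO-8601 duration: {x}", class = "pdx_schema_error",
              x = x)
  }
  comp <- suppressWarnings(as.integer(m[1, 2:5]))
  comp[is.na(comp)] <- 0L
  if (all(m[1, 2:5] %in% NA)) {
    abort_pdx("ISO-8601 duration has no components: {x}",
              class = "pdx_schema_error", x = x)
  }
  list(years = comp[1], months = comp[2], weeks = comp[3], days = comp[4])
}

is_iso8601_duration <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x) &&
    grepl(iso8601_regex, x) && x != "P" &&
    grepl("[0-9]", x)
}

# classed condition helper; message supports glue-style interpolation
abort_pdx <- function(msg, class, ..., call = rlang::caller_env()) {
  rlang::abort(glue_msg(msg, ..., .env = call), class = c(class, "pdx_error"))
}

glue_msg <- function(msg, ..., .env) {
  dots <- list(...)
  for (nm in names(dots)) assign(nm, dots[[nm]], envir = environment())
  as.character(stringr::str_glue(msg))
}

# deterministic sub-seed derived from a master seed and a string tag;
# stays below 2^31 so it is always a valid R integer seed
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
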