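# Prompt templates: one YAML file per language under inst/extdata/templates.
# A template is constant text (task header, genetic-disease statement, an
# example output block that is ALWAYS English, and a directive to answer in
# English) plus phrase patterns with named placeholders for the variable
# parts: sex/age sentence, onset sentences, observed/excluded feature lists,
# and list connectors.

template_required_keys <- c(
  "language", "header", "example_output", "answer_directive",
  "sex_age", "sex_age_no_age",
  "sex_male", "sex_female", "sex_other", "sex_unknown",
  "age_years", "age_months", "age_days",
  "disease_onset", "feature_onset",
  "observed", "excluded", "list_sep", "list_final")

template_placeholders <- c("sex", "age", "n", "label", "labels")

#' Load prompt templates
#'
#' Reads one YAML template per language. With no arguments, loads the nine
#' shipped study-language templates (en, zh, cs, nl, de, it, ja, es, tr).
#'
#' @param dir directory of `<language>.yaml` files.
#' @param languages which languages to load; default all files in `dir`.
#' @return a named `prompt_templates` list (one entry per language).
#' @export
load_templates <- function(dir = system.file("extdata", "templates",
                                             package = "polyglotdx"),
                           languages = NULL) {
  files <- sort(list.files(dir, pattern = "\\.yaml$", full.names = TRUE))
  langs <- sub("\\.yaml$", "", basename(files))
  if (!is.null(languages)) {
    missing <- setdiff(languages, langs)
    if (length(missing)) {
      abort_pdx("no template file for language(s): {m}",
                class = "pdx_no_template_error",
                m = paste(missing, collapse = ", "))
    }
    files <- files[langs %in% languages]
    langs <- langs[langs %in% languages]
  }
  out <- purrr::map(files, yaml::read_yaml)
  names(out) <- langs
  structure(out, class = "prompt_templates")
}

#' @export
print.prompt_templates <- function(x, ...) {
  cat(sprintf("<prompt_templates: %s>\n", paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Validate a template set
#'
#' Report-only structural check of every language template: all required
#' keys present and non-empty, the English example-output block present and
#' shaped like a numbered list, the answer-in-English directive present, and
#' no undeclared `{placeholder}` tokens anywhere. Returns a tibble of
#' violations; zero rows means the set is valid.
#'
#' @param templates a [load_templates()] result.
#' @return tibble with columns `language`, `check`, `detail`.
#' @export
validate_templates <- function(templates) {
  one <- function(lang, t) {
    v <- list()
    add <- function(check, detail) {
      v[[length(v) + 1L]] <<- tibble(language = lang, check = check,
                                     detail = detail)
    }
    missing <- setdiff(template_required_keys, names(t))
    for (k in missing) add("missing key", k)
    present <- intersect(setdiff(template_required_keys,
                                 c("list_sep", "list_final")), names(t))
    for (k in present) {
      if (!nzchar(trimws(t[[k]] %||% ""))) add("empty key", k)
    }
    if (!is.null(t$example_output) &&
        !grepl("^\\s*1[.)]", t$example_output)) {
      add("malformed example output", "does not start with a numbered item")
    }
    if (is.null(t$answer_directive) || !nzchar(trimws(t$answer_directive %||% ""))) {
      add("missing answer-language directive", "answer_directive")
    }
    for (k in intersect(names(t), template_required_keys)) {
      toks <- stringr::str_match_all(t[[k]] %||% "", "\\{([^}]*)\\}")[[1]][, 2]
      for (tok in setdiff(toks, template_placeholders)) {
        add("undeclared placeholder", sprintf("%s: {%s}", k, tok))
      }
    }
    bind_rows(v)
  }
  out <- purrr::imap(unclass(templates), ~ one(.y, .x)) %>% bind_rows()
  if (!nrow(out)) {
    out <- tibble(language = character(), check = character(),
                  detail = character())
  }
  out
}

# fill {name} placeholders in a template string
fill_template <- function(pattern, values) {
  for (nm in names(values)) {
    pattern <- gsub(paste0("{", nm, "}"), values[[nm]], pattern, fixed = TRUE)
  }
  pattern
}
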