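# Deterministic rendering of a case vignette into a narrative diagnostic
# prompt. A prompt is: constant header (task + genetic-disease statement +
# English example output + answer-in-English directive), then the sex/age
# sentence, an optional disease-onset sentence, the observed-features
# sentence, and (only when present) the excluded-features sentence.
# The ground-truth diagnosis is never rendered.

render_age_phrase <- function(age, t) {
  d <- parse_iso8601_duration(age)
  if (d$years >= 1L) {
    fill_template(t$age_years, list(n = d$years))
  } else if (d$months >= 1L) {
    fill_template(t$age_months, list(n = d$months))
  } else {
    fill_template(t$age_days, list(n = d$weeks * 7L + d$days))
  }
}

#' Render the sex/age sentence of a prompt
#'
#' Age granularity follows clinical phrasing: whole years when at least one
#' year old, months when under a year, days when under a month. An unknown
#' sex renders the template's neutral noun; an absent age uses the
#' template's age-free variant.
#'
#' @param subj a [subject()].
#' @param language language code.
#' @param templates a [load_templates()] result.
#' @return a single sentence.
#' @export
render_age_sex <- function(subj, language, templates) {
  t <- get_template(templates, language)
  sex_noun <- t[[paste0("sex_", tolower(subj$sex))]]
  if (is.null(subj$age)) {
    fill_template(t$sex_age_no_age, list(sex = sex_noun))
  } else {
    fill_template(t$sex_age, list(sex = sex_noun,
                                  age = render_age_phrase(subj$age, t)))
  }
}

get_template <- function(templates, language) {
  t <- templates[[language]]
  if (is.null(t)) {
    abort_pdx("no template registered for language {language}",
              class = "pdx_no_template_error", language = language)
  }
  t
}

join_labels <- function(labels, t) {
  n <- length(labels)
  if (n == 1L) return(labels)
  paste0(paste(labels[-n], collapse = t$list_sep), t$list_final, labels[n])
}

render_onset_value <- function(onset, language, lexicon, t) {
  if (grepl("^P", onset)) {
    render_age_phrase(onset, t)
  } else {
    # onset-class CURIE: use its translated label when the lexicon has one
    tryCatch(translate_term(onset, language, lexicon),
             pdx_missing_translation_error = function(e) onset)
  }
}

#' Build a diagnostic prompt for one case in one language
#'
#' Pure function of its inputs: the same (vignette, language, lexicon,
#' templates) always yields a byte-identical prompt. Every feature label is
#' translated through the lexicon and appears exactly once; excluded
#' features render in their own negated sentence, elided when the case has
#' none. The diagnosis label and id are guaranteed absent from the output
#' (checked defensively, error class `pdx_leak_error`).
#'
#' @param v a [case_vignette()].
#' @param language language code with a registered template.
#' @param lexicon a [load_lexicon()] result covering the vignette's terms.
#' @param templates a [load_templates()] result.
#' @return a `prompt_text`: list with `case_id`, `language`, `text`.
#' @export
build_prompt <- function(v, language, lexicon, templates) {
  t <- get_template(templates, language)

  label_for <- function(term_id, onset) {
    lab <- translate_term(term_id, language, lexicon)
    if (!is.na(onset)) {
      fill_template(t$feature_onset,
                    list(label = lab,
                         age = render_onset_value(onset, language, lexicon, t)))
    } else {
      lab
    }
  }

  obs <- v$features[!v$features$excluded, ]
  exc <- v$features[v$features$excluded, ]
  obs_labels <- purrr::map2_chr(obs$term_id, obs$onset, label_for)

  parts <- c(
    trimws(t$header),
    trimws(t$example_output),
    trimws(t$answer_directive),
    "",
    render_age_sex(v$subject, language, templates))
  if (!is.null(v$disease_onset)) {
    parts <- c(parts,
               fill_template(t$disease_onset,
                             list(age = render_onset_value(
                               v$disease_onset, language, lexicon, t))))
  }
  parts <- c(parts,
             fill_template(t$observed, list(labels = join_labels(obs_labels, t))))
  if (nrow(exc)) {
    exc_labels <- purrr::map2_chr(exc$term_id, exc$onset, label_for)
    parts <- c(parts,
               fill_template(t$excluded,
                             list(labels = join_labels(exc_labels, t))))
  }
  text <- paste(parts, collapse = "\n")

  for (leak in c(v$diagnosis$label, v$diagnosis$disease_id)) {
    if (nzchar(leak) && grepl(leak, text, fixed = TRUE)) {
      abort_pdx("diagnosis leaked into prompt for case {id}",
                class = "pdx_leak_error", id = v$id)
    }
  }
  structure(list(case_id = v$id, language = language, text = text),
            class = "prompt_text")
}

#' @export
print.prompt_text <- function(x, ...) {
  cat(sprintf("<prompt_text %s [%s]>\n%s\n", x$case_id, x$language, x$text))
  invisible(x)
}

#' Build prompts for a whole cohort across languages
#'
#' @param vignettes list of [case_vignette()] objects.
#' @param languages language codes.
#' @inheritParams build_prompt
#' @return tibble with columns `case_id`, `language`, `text`.
#' @export
build_prompts <- function(vignettes, languages, lexicon, templates) {
  tidyr::expand_grid(v = vignettes, language = languages) %>%
    mutate(p = purrr::map2(.data$v, .data$language,
                           ~ build_prompt(.x, .y, lexicon, templates)),
           case_id = purrr::map_chr(.data$p, "case_id"),
           text = purrr::map_chr(.data$p, "text")) %>%
    select("case_id", "language", "text")
}
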