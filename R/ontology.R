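# Ontology services: the multilingual phenotype lexicon and the disease
# graph with genetic-subtype equivalence. These are the two ontology facts
# the benchmark depends on: (1) does a case have translations of all its HPO
# terms in all study languages, and (2) which disease ids count as the same
# clinical diagnosis.

#' The nine study languages (ISO-639-1 codes)
#'
#' English plus the eight translation languages: Chinese, Czech, Dutch,
#' German, Italian, Japanese, Spanish, Turkish.
#' @export
study_languages <- c("en", "zh", "cs", "nl", "de", "it", "ja", "es", "tr")

#' Load a multilingual term-label lexicon from TSV
#'
#' Expects UTF-8 TSV with a header row and exactly three columns:
#' `term_id`, `language`, `label`. Multiple labels per (term, language)
#' accumulate; exact duplicate rows are dropped, so ingestion is idempotent.
#'
#' @param tsv either a path to a `.tsv` file or the TSV text itself.
#' @return a `multilingual_lexicon`: a tibble with columns `term_id`,
#'   `language`, `label` and a `"languages"` attribute.
#' @export
load_lexicon <- function(tsv) {
  if (length(tsv) == 1L && !grepl("[\t\n]", tsv) && file.exists(tsv)) {
    tsv <- readr::read_file(tsv)
  }
  if (!validUTF8(tsv)) {
    abort_pdx("lexicon TSV is not valid UTF-8", class = "pdx_encoding_error")
  }
  tab <- readr::read_tsv(I(tsv), col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(tab) != 3L) {
    abort_pdx("lexicon TSV must have 3 columns (term_id, language, label), got {n}",
              class = "pdx_format_error", n = ncol(tab))
  }
  names(tab) <- c("term_id", "language", "label")
  tab <- distinct(tab)
  as_lexicon(tab)
}

as_lexicon <- function(tab) {
  structure(as_tibble(tab),
            languages = sort(unique(tab$language)),
            class = c("multilingual_lexicon", class(tibble())))
}

#' Translate one term into one language
#'
#' Returns the first label recorded for the (term, language) pair. A missing
#' translation raises a `pdx_missing_translation_error`; the cohort filter
#' catches this condition, it is not fatal to a pipeline run.
#'
#' @param term_id HPO CURIE.
#' @param language ISO-639-1 code present in the lexicon.
#' @param lexicon a [load_lexicon()] result.
#' @return a single translated label.
#' @export
translate_term <- function(term_id, language, lexicon) {
  hits <- lexicon$label[lexicon$term_id == term_id &
                          lexicon$language == language]
  if (!length(hits)) {
    abort_pdx("no {language} translation for {term_id}",
              class = "pdx_missing_translation_error",
              language = language, term_id = term_id)
  }
  hits[[1]]
}

#' Does a case have translations of every term in every language?
#'
#' The cohort filter: a vignette is retained only if every feature term —
#' observed AND excluded — has a lexicon entry in all requested languages.
#' The benchmark restricts its corpus to such fully translated cases so each
#' case is prompted identically across languages.
#'
#' @param v a [case_vignette()].
#' @param lexicon a [load_lexicon()] result.
#' @param languages languages required; defaults to every language in the
#'   lexicon (the nine study languages for the shipped generators).
#' @return `TRUE` or `FALSE`.
#' @export
has_full_translation <- function(v, lexicon,
                                 languages = attr(lexicon, "languages")) {
  need <- unique(v$features$term_id)
  have <- lexicon %>%
    filter(.data$term_id %in% need, .data$language %in% languages) %>%
    distinct(.data$term_id, .data$language)
  nrow(have) == length(need) * length(languages)
}

# ---- Disease graph ----------------------------------------------------

#' Construct a Mondo-like disease graph
#'
#' Diseases carry a primary label and synonyms; genetic subtypes link to
#' their clinical-disease group head by a single-level `subtype_links`
#' relation (subtype -> head). That relation generates the diagnostic
#' equivalence classes used for scoring: a clinical disease and all of its
#' genetic subtypes count as the same diagnosis.
#'
#' @param terms tibble with columns `id` (CURIE), `label`; optional list
#'   column `parents`.
#' @param synonyms tibble with columns `id`, `synonym`, `scope`
#'   (`"EXACT"` or `"RELATED"`); may be empty.
#' @param subtype_links tibble with columns `subtype`, `head`; may be empty.
#' @return a `disease_graph`.
#' @export
disease_graph <- function(terms, synonyms = NULL, subtype_links = NULL) {
  terms <- as_tibble(terms)
  stopifnot(all(c("id", "label") %in% names(terms)))
  if (anyDuplicated(terms$id)) {
    abort_pdx("duplicate disease ids in graph", class = "pdx_schema_error")
  }
  if (any(!nzchar(terms$label))) {
    abort_pdx("empty disease label", class = "pdx_schema_error")
  }
  if (is.null(synonyms)) {
    synonyms <- tibble(id = character(), synonym = character(),
                       scope = character())
  }
  if (is.null(subtype_links) || !nrow(as_tibble(subtype_links))) {
    subtype_links <- tibble(subtype = character(), head = character())
  }
  subtype_links <- as_tibble(subtype_links)
  endpoints <- c(subtype_links$subtype, subtype_links$head)
  if (!all(endpoints %in% terms$id)) {
    abort_pdx("subtype link endpoint not in graph terms",
              class = "pdx_schema_error")
  }
  if (any(subtype_links$subtype == subtype_links$head) ||
      any(subtype_links$head %in% subtype_links$subtype)) {
    # single-level relation: a head is never itself a subtype, so no chains
    # or cycles can exist
    abort_pdx("subtype links must be single-level (head of one link cannot be subtype of another)",
              class = "pdx_schema_error")
  }
  if (anyDuplicated(subtype_links$subtype)) {
    abort_pdx("a subtype may link to only one group head",
              class = "pdx_schema_error")
  }
  structure(list(terms = terms, synonyms = as_tibble(synonyms),
                 subtype_links = subtype_links),
            class = "disease_graph")
}

#' @export
print.disease_graph <- function(x, ...) {
  cat(sprintf("<disease_graph: %d diseases, %d synonyms, %d subtype links>\n",
              nrow(x$terms), nrow(x$synonyms), nrow(x$subtype_links)))
  invisible(x)
}

#' Read / write a disease graph as JSON
#'
#' The on-disk format has three arrays: `terms` (`id`, `label`), `synonyms`
#' (`id`, `synonym`, `scope`), and `subtype_links` (`subtype`, `head`).
#'
#' @param path JSON file path.
#' @return [read_disease_graph()] a `disease_graph`;
#'   [write_disease_graph()] the path, invisibly.
#' @export
read_disease_graph <- function(path) {
  x <- jsonlite::fromJSON(path)
  disease_graph(terms = as_tibble(x$terms),
                synonyms = if (length(x$synonyms)) as_tibble(x$synonyms),
                subtype_links = if (length(x$subtype_links)) as_tibble(x$subtype_links))
}

#' @rdname read_disease_graph
#' @param graph a `disease_graph`.
#' @export
write_disease_graph <- function(graph, path) {
  jsonlite::write_json(
    list(terms = graph$terms, synonyms = graph$synonyms,
         subtype_links = graph$subtype_links),
    path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Diagnostic equivalence class of a disease
#'
#' Returns the set of disease ids regarded as the same diagnosis for
#' scoring: the clinical group head together with all of its genetic
#' subtypes. For an id with no subtype relations the class is the singleton
#' `{id}`. Membership is symmetric: `b %in% equivalence_class(a)` iff
#' `a %in% equivalence_class(b)`.
#'
#' @param disease_id CURIE present in the graph.
#' @param graph a [disease_graph()].
#' @return character vector of CURIEs (always contains `disease_id`).
#' @export
equivalence_class <- function(disease_id, graph) {
  if (!disease_id %in% graph$terms$id) {
    abort_pdx("unknown disease id: {id}", class = "pdx_unknown_disease_error",
              id = disease_id)
  }
  links <- graph$subtype_links
  head_id <- if (disease_id %in% links$subtype) {
    links$head[match(disease_id, links$subtype)]
  } else {
    disease_id
  }
  sort(unique(c(head_id, links$subtype[links$head == head_id])))
}
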