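# Automatic evaluation of free-text differentials: extract the ranked
# candidate list, ground each candidate to a disease id by exact match on
# normalized labels/synonyms, and score against the truth with genetic
# subtypes of a clinical disease counting as equivalent.

list_item_regex <- "^\\s*(?:[-*•]|\\(?\\d+\\s*[.):\\-]?)\\s+(.+?)\\s*$"

#' Parse a free-text LLM response into a ranked differential
#'
#' Extracts an ordered candidate list from numbered (`1.`, `1)`, `1 -`) or
#' bulleted lines. Rank markers, parenthetical annotations (typically gene
#' names) and trailing punctuation are stripped. Ranks are assigned
#' contiguously from 1 in order of appearance, with no cap — the Top-10 cap
#' is a reporting convention applied at aggregation, not at parse time. A
#' text with no extractable list (e.g. a refusal) yields a zero-row tibble,
#' the No Diagnosis value.
#'
#' @param raw_text the response text.
#' @return tibble with columns `rank`, `raw`; zero rows means No Diagnosis.
#' @export
parse_response <- function(raw_text) {
  lines <- stringr::str_split_1(raw_text %||% "", "\\r?\\n")
  m <- stringr::str_match(lines, list_item_regex)[, 2]
  cands <- m[!is.na(m)]
  cands <- stringr::str_remove_all(cands, "\\s*\\([^()]*\\)")
  cands <- stringr::str_remove(cands, "[[:punct:]\\s]+$")
  cands <- cands[nzchar(trimws(cands))]
  tibble(rank = seq_along(cands), raw = cands)
}

#' Build a grounding index over a disease graph
#'
#' Maps normalized name -> disease id for every primary label and synonym.
#' A primary-label match always wins over a synonym match; a normalized
#' synonym shared by more than one disease is marked ambiguous and can never
#' ground (determinism over recall).
#'
#' @param graph a [disease_graph()].
#' @param synonym_scope `"all"` to index EXACT and RELATED synonyms,
#'   `"exact"` to restrict to EXACT.
#' @return tibble with columns `key`, `id`, `source`, `ambiguous`.
#' @export
grounding_index <- function(graph, synonym_scope = c("all", "exact")) {
  synonym_scope <- match.arg(synonym_scope)
  labels <- tibble(key = normalize_name(graph$terms$label),
                   id = graph$terms$id, source = "label")
  syns <- graph$synonyms
  if (synonym_scope == "exact") syns <- filter(syns, .data$scope == "EXACT")
  syns <- tibble(key = normalize_name(syns$synonym), id = syns$id,
                 source = "synonym")
  syns <- syns %>%
    filter(!.data$key %in% labels$key) %>%  # labels take precedence
    distinct(.data$key, .data$id, .keep_all = TRUE) %>%
    group_by(.data$key) %>%
    mutate(ambiguous = dplyr::n_distinct(.data$id) > 1) %>%
    ungroup()
  labels$ambiguous <- labels$key %in% labels$key[duplicated(labels$key)]
  bind_rows(labels, syns)
}

#' Ground one candidate name to a disease id
#'
#' Exact match after [normalize_name()]; no fuzzy matching. Returns the
#' disease CURIE, or `NA` (a grounding failure) when the name is unknown or
#' ambiguous.
#'
#' @param candidate raw candidate string.
#' @param graph a [disease_graph()], or a prebuilt [grounding_index()].
#' @return a CURIE or `NA_character_`.
#' @export
ground <- function(candidate, graph) {
  index <- if (inherits(graph, "disease_graph")) grounding_index(graph) else graph
  key <- normalize_name(candidate)
  hits <- index[index$key == key, ]
  if (!nrow(hits)) return(NA_character_)
  hits <- hits[hits$source == if ("label" %in% hits$source) "label" else "synonym", ]
  if (any(hits$ambiguous) || dplyr::n_distinct(hits$id) > 1) {
    return(NA_character_)
  }
  hits$id[[1]]
}

#' Ground every candidate of a parsed differential
#'
#' @param differential tibble from [parse_response()].
#' @inheritParams ground
#' @return the differential with a `grounding` column (`NA` = failure).
#' @export
ground_differential <- function(differential, graph) {
  index <- if (inherits(graph, "disease_graph")) grounding_index(graph) else graph
  differential %>%
    mutate(grounding = purrr::map_chr(.data$raw, ground, graph = index))
}

#' Score one grounded differential against the ground truth
#'
#' The outcome is `RANKED(k)` for the smallest rank whose grounded id lies
#' in the truth's diagnostic [equivalence_class()] (so any genetic subtype
#' of the true clinical disease counts), `NOT_RANKED` when no candidate
#' matches, and `NO_DIAGNOSIS` for an empty differential. Grounding failures
#' never match.
#'
#' @param grounded tibble from [ground_differential()] (zero rows = No
#'   Diagnosis).
#' @param truth true disease CURIE, present in the graph.
#' @param graph a [disease_graph()].
#' @return one-row tibble: `outcome` (`"ranked"`, `"not_ranked"`,
#'   `"no_diagnosis"`), `rank`, `n_candidates`, `n_grounding_failures`.
#' @export
score_case <- function(grounded, truth, graph) {
  eq <- equivalence_class(truth, graph)
  if (!nrow(grounded)) {
    return(tibble(outcome = "no_diagnosis", rank = NA_integer_,
                  n_candidates = 0L, n_grounding_failures = 0L))
  }
  hit <- which(grounded$grounding %in% eq)
  tibble(
    outcome = if (length(hit)) "ranked" else "not_ranked",
    rank = if (length(hit)) as.integer(grounded$rank[min(hit)]) else NA_integer_,
    n_candidates = nrow(grounded),
    n_grounding_failures = sum(is.na(grounded$grounding)))
}

#' Parse, ground and score a table of responses
#'
#' The full evaluation stage for a benchmark run.
#'
#' @param responses tibble from [query_all()] (`case_id`, `language`,
#'   `raw_text`).
#' @param truths named character vector: case_id -> true disease id.
#' @param graph a [disease_graph()].
#' @return a `case_results` tibble: `case_id`, `language`, `outcome`,
#'   `rank`, `n_candidates`, `n_grounding_failures`.
#' @export
score_responses <- function(responses, truths, graph) {
  index <- grounding_index(graph)
  out <- purrr::pmap(
    responses %>% select("case_id", "language", "raw_text"),
    function(case_id, language, raw_text) {
      scored <- parse_response(raw_text) %>%
        ground_differential(index) %>%
        score_case(truths[[case_id]], graph)
      mutate(scored, case_id = case_id, language = language,
             .before = 1)
    }) %>% bind_rows()
  class(out) <- c("case_results", class(out))
  out
}

#' Item-level grounding failure rate per language
#'
#' Total grounding failures divided by total candidate items (duplicated
#' candidate strings count per occurrence). Languages with zero candidates
#' report rate 0.
#'
#' @param results a [score_responses()] table.
#' @return tibble with `language`, `n_items`, `n_failures`, `failure_rate`.
#' @export
grounding_failure_rate <- function(results) {
  results %>%
    group_by(.data$language) %>%
    summarise(n_items = sum(.data$n_candidates),
              n_failures = sum(.data$n_grounding_failures),
              .groups = "drop") %>%
    mutate(failure_rate = ifelse(.data$n_items > 0,
                                 .data$n_failures / .data$n_items, 0))
}
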