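# Backend contract for querying a text-generation model, plus two offline
# backends: a recorded backend that replays response files, and a seeded
# mock backend that plants outcomes (correct diagnosis at rank k, not
# ranked, refusal) with known probabilities so downstream scoring can be
# verified by parameter recovery.

#' Backend configuration
#'
#' Mirrors the study conditions: default parameters, unit temperature, no
#' token limit.
#'
#' @param model_name backend model identifier.
#' @param temperature sampling temperature, must be non-negative.
#' @param max_tokens optional token cap (`NULL` = unlimited).
#' @return an `llm_config`.
#' @export
llm_config <- function(model_name = "mock", temperature = 1,
                       max_tokens = NULL) {
  stopifnot(is.numeric(temperature), temperature >= 0)
  structure(list(model_name = model_name, temperature = temperature,
                 max_tokens = max_tokens), class = "llm_config")
}

#' Outcome specification for the mock backend
#'
#' Gives the probability of each plantable outcome for one case: the correct
#' diagnosis at rank k (k = 1..10), a differential that omits it, or a
#' refusal. Probabilities must sum to 1 (tolerance 1e-9). `synonym_rate` is
#' the chance the planted correct answer uses a synonym (possibly of a
#' genetic subtype) rather than a primary label; `ungroundable_rate` is the
#' per-item chance a distractor is an ungroundable free-text string.
#'
#' @param p_ranked numeric vector of rank probabilities; element k is
#'   P(correct at rank k). Length 1..10.
#' @param p_not_ranked P(correct diagnosis absent from the list).
#' @param p_refusal P(no parseable differential returned).
#' @param synonym_rate,ungroundable_rate rates in `[0, 1]`.
#' @return a `mock_spec`.
#' @export
mock_spec <- function(p_ranked, p_not_ranked = 0, p_refusal = 0,
                      synonym_rate = 0.3, ungroundable_rate = 0.04) {
  stopifnot(length(p_ranked) >= 1, length(p_ranked) <= 10,
            all(p_ranked >= 0), p_not_ranked >= 0, p_refusal >= 0,
            synonym_rate >= 0, synonym_rate <= 1,
            ungroundable_rate >= 0, ungroundable_rate <= 1)
  total <- sum(p_ranked) + p_not_ranked + p_refusal
  if (abs(total - 1) > 1e-9) {
    abort_pdx("mock outcome probabilities must sum to 1, got {t}",
              class = "pdx_spec_error", t = format(total, digits = 12))
  }
  structure(list(p_ranked = as.numeric(p_ranked),
                 p_not_ranked = p_not_ranked, p_refusal = p_refusal,
                 synonym_rate = synonym_rate,
                 ungroundable_rate = ungroundable_rate),
            class = "mock_spec")
}

refusal_bank <- list(
  en = "I'm sorry but based on the information provided, I cannot return a confident diagnosis",
  zh = "很抱歉，根据所提供的信息，我无法给出明确的诊断。",
  cs = "Je mi líto, ale na základě poskytnutých informací nemohu stanovit spolehlivou diagnózu.",
  nl = "Het spijt me, maar op basis van de verstrekte informatie kan ik geen betrouwbare diagnose geven.",
  de = "Es tut mir leid, aber auf Grundlage der bereitgestellten Informationen kann ich keine sichere Diagnose stellen.",
  it = "Mi dispiace, ma sulla base delle informazioni fornite non posso formulare una diagnosi certa.",
  ja = "申し訳ありませんが、提供された情報からは確実な診断をお伝えできません。",
  es = "Lo siento, pero con la información proporcionada no puedo ofrecer un diagnóstico fiable.",
  tr = "Üzgünüm, ancak sağlanan bilgilere dayanarak güvenilir bir tanı veremiyorum.")

# largest-remainder integer allocation of n among probabilities
alloc_counts <- function(probs, n) {
  raw <- probs * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

outcome_names <- function(spec) {
  c(paste0("rank", seq_along(spec$p_ranked)), "not_ranked", "refusal")
}

sample_outcomes <- function(spec, n, mode) {
  probs <- c(spec$p_ranked, spec$p_not_ranked, spec$p_refusal)
  labs <- outcome_names(spec)
  if (mode == "exact") {
    rep(labs, alloc_counts(probs, n))
  } else {
    sample(labs, n, replace = TRUE, prob = probs)
  }
}

# one realized response text for a planted outcome
realize_response <- function(outcome, truth, language, graph, spec,
                             name_pool) {
  if (outcome == "refusal") {
    return(list(text = refusal_bank[[language]] %||% refusal_bank$en,
                rank = NA_integer_, used_synonym = NA,
                n_candidates = 0L, n_ungroundable = 0L))
  }
  rank <- if (outcome == "not_ranked") NA_integer_ else {
    as.integer(sub("^rank", "", outcome))
  }
  eq <- equivalence_class(truth, graph)
  n_cand <- sample(8:12, 1)
  if (!is.na(rank)) n_cand <- max(n_cand, rank)

  pool <- name_pool[!name_pool$id %in% eq, ]
  idx <- sample(nrow(pool), min(n_cand, nrow(pool)))
  names_out <- pool$name[idx]
  n_cand <- length(names_out)
  ungroundable <- stats::runif(n_cand) < spec$ungroundable_rate
  if (any(ungroundable)) {
    names_out[ungroundable] <- sprintf(
      "unrecognized condition %s",
      paste0("X", sample(1e6, sum(ungroundable))))
  }
  used_synonym <- NA
  if (!is.na(rank)) {
    member <- if (length(eq) > 1L) sample(eq, 1) else eq
    syns <- graph$synonyms$synonym[graph$synonyms$id == member]
    used_synonym <- length(syns) > 0 && stats::runif(1) < spec$synonym_rate
    truth_name <- if (used_synonym) sample(rep(syns, 2), 1) else {
      graph$terms$label[match(member, graph$terms$id)]
    }
    names_out[rank] <- truth_name
    ungroundable[rank] <- FALSE
  }
  list(text = paste(sprintf("%d. %s", seq_len(n_cand), names_out),
                    collapse = "\n"),
       rank = rank, used_synonym = used_synonym,
       n_candidates = n_cand, n_ungroundable = sum(ungroundable))
}

#' Build a deterministic mock LLM backend
#'
#' Plants an outcome for every (case, language) pair according to a
#' [mock_spec()] (optionally per-language) and realizes it as a numbered
#' differential list, with the correct disease — primary label or synonym,
#' possibly of a genetic subtype — at the planted rank among distractor
#' disease names drawn outside the truth's equivalence class, or as a
#' refusal sentence. Fully deterministic under `seed`.
#'
#' In `"exact"` mode outcomes are allocated to cases by largest-remainder
#' counts (aggregations are then exactly the spec, up to integer rounding);
#' `"sample"` mode draws each case independently, for stochastic tests.
#'
#' @param spec a [mock_spec()], or a named list of them keyed by language.
#' @param graph the [disease_graph()] providing names and equivalence.
#' @param truths named character vector: case_id -> true disease id.
#' @param languages language codes to cover.
#' @param seed integer seed.
#' @param mode `"exact"` or `"sample"`.
#' @return a `mock_backend`; its `$ledger` tibble records every planted
#'   outcome (case, language, outcome, rank, synonym use, ungroundable
#'   items) for ledger-faithfulness checks.
#' @export
make_mock_backend <- function(spec, graph, truths, languages = "en",
                              seed = 1L, mode = c("exact", "sample")) {
  mode <- match.arg(mode)
  specs <- if (inherits(spec, "mock_spec")) {
    stats::setNames(rep(list(spec), length(languages)), languages)
  } else {
    missing <- setdiff(languages, names(spec))
    if (length(missing)) {
      abort_pdx("no mock spec for language(s): {m}", class = "pdx_spec_error",
                m = paste(missing, collapse = ", "))
    }
    spec
  }
  name_pool <- bind_rows(
    tibble(id = graph$terms$id, name = graph$terms$label),
    tibble(id = graph$synonyms$id, name = graph$synonyms$synonym))

  rows <- withr::with_seed(seed, {
    purrr::map(languages, function(lang) {
      sp <- specs[[lang]]
      outs <- sample_outcomes(sp, length(truths), mode)
      purrr::map2(names(truths), outs, function(cid, o) {
        r <- realize_response(o, truths[[cid]], lang, graph, sp, name_pool)
        tibble(case_id = cid, language = lang, raw_text = r$text,
               outcome = ifelse(grepl("^rank", o), "ranked", o),
               rank = r$rank, used_synonym = r$used_synonym,
               n_candidates = r$n_candidates,
               n_ungroundable = r$n_ungroundable)
      }) %>% bind_rows()
    }) %>% bind_rows()
  })

  structure(list(tag = "MOCK",
                 responses = rows %>% select("case_id", "language", "raw_text"),
                 ledger = rows %>% select(-"raw_text")),
            class = c("mock_backend", "llm_backend"))
}

#' Build a recorded-response backend
#'
#' Replays responses stored as `responses/<language>/<case_id>.txt`. A
#' missing or empty file yields an empty response, which downstream scoring
#' treats as a refusal (No Diagnosis).
#'
#' @param dir root directory of recorded responses.
#' @return a `recorded_backend`.
#' @export
recorded_backend <- function(dir) {
  if (!dir.exists(dir)) {
    abort_pdx("recorded-response directory {dir} does not exist",
              class = "pdx_backend_unavailable_error", dir = dir)
  }
  structure(list(tag = "RECORDED", dir = dir),
            class = c("recorded_backend", "llm_backend"))
}

#' Query a backend with one prompt
#'
#' Exactly one response per prompt; a backend that cannot serve the prompt
#' raises `pdx_backend_unavailable_error` rather than returning a silent
#' empty success.
#'
#' @param prompt a `prompt_text` from [build_prompt()].
#' @param config an [llm_config()] (recorded/mock backends ignore it).
#' @param backend a backend object.
#' @return one-row tibble: `case_id`, `language`, `raw_text`, `backend`.
#' @export
query <- function(prompt, config = llm_config(), backend) {
  UseMethod("query", backend)
}

#' @export
query.mock_backend <- function(prompt, config = llm_config(), backend) {
  hit <- backend$responses %>%
    filter(.data$case_id == prompt$case_id,
           .data$language == prompt$language)
  if (!nrow(hit)) {
    abort_pdx("mock backend has no planted response for {id} [{lang}]",
              class = "pdx_backend_unavailable_error",
              id = prompt$case_id, lang = prompt$language)
  }
  tibble(case_id = prompt$case_id, language = prompt$language,
         raw_text = hit$raw_text[[1]], backend = "MOCK")
}

#' @export
query.recorded_backend <- function(prompt, config = llm_config(), backend) {
  f <- file.path(backend$dir, prompt$language,
                 paste0(prompt$case_id, ".txt"))
  raw <- if (file.exists(f)) readr::read_file(f) else ""
  tibble(case_id = prompt$case_id, language = prompt$language,
         raw_text = raw, backend = "RECORDED")
}

#' Query a backend with a prompt table
#'
#' @param prompts tibble from [build_prompts()].
#' @inheritParams query
#' @return tibble of responses, one row per prompt.
#' @export
query_all <- function(prompts, config = llm_config(), backend) {
  purrr::pmap(prompts, function(case_id, language, text, ...) {
    query(structure(list(case_id = case_id, language = language,
                         text = text), class = "prompt_text"),
          config, backend)
  }) %>% bind_rows()
}
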