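# End-to-end driver: cohort filter -> prompts -> backend -> scoring ->
# per-language summaries, frequency table, cross-language comparison, and
# (optionally) a written report directory with a run manifest.

#' Run the full benchmark pipeline
#'
#' Chains every stage: restricts the cohort to fully translated cases (the
#' corpus filter), renders prompts in each language, queries the backend,
#' parses/grounds/scores the responses, aggregates per-language counts and
#' frequencies, and runs the cross-language Kruskal-Wallis comparison. With
#' `out_dir` set, writes `prompts/<lang>/<case>.txt`,
#' `responses/<lang>/<case>.txt`, `results.jsonl`, `summary_counts.tsv`,
#' `summary_freq.tsv`, `comparison.json` and `manifest.json`. Two runs with
#' identical inputs and seed produce byte-identical tables.
#'
#' @param vignettes list of [case_vignette()] objects.
#' @param lexicon a [load_lexicon()] result.
#' @param graph a [disease_graph()].
#' @param templates a [load_templates()] result.
#' @param backend a backend object, or `NULL` to build a mock backend from
#'   `mock` over the filtered cohort.
#' @param mock a [mock_spec()] or per-language list (see
#'   [generate_mock_spec()]); used only when `backend` is `NULL`.
#' @param languages language codes to benchmark.
#' @param seed seed for the mock backend.
#' @param mock_mode `"exact"` or `"sample"` outcome planting.
#' @param out_dir optional report directory.
#' @return a `pipeline_run` list: `prompts`, `responses`, `results`,
#'   `summary`, `grounding`, `comparison`, `excluded_cases`, `manifest`.
#' @export
run_pipeline <- function(vignettes, lexicon, graph,
                         templates = load_templates(),
                         backend = NULL, mock = NULL,
                         languages = study_languages, seed = 1L,
                         mock_mode = c("exact", "sample"),
                         out_dir = NULL) {
  mock_mode <- match.arg(mock_mode)
  keep <- purrr::map_lgl(vignettes, has_full_translation, lexicon = lexicon,
                         languages = languages)
  excluded_cases <- purrr::map_chr(vignettes[!keep], "id")
  vignettes <- vignettes[keep]
  if (!length(vignettes)) {
    abort_pdx("no fully translated cases left after the cohort filter",
              class = "pdx_empty_cohort_error")
  }
  truths <- cohort_truths(vignettes)

  prompts <- build_prompts(vignettes, languages, lexicon, templates)
  if (is.null(backend)) {
    if (is.null(mock)) {
      mock <- mock_spec(p_ranked = c(0.2, 0.05, 0.03, rep(0.01, 7)),
                        p_not_ranked = 0.6, p_refusal = 0.05)
    }
    backend <- make_mock_backend(mock, graph, truths, languages,
                                 seed = seed, mode = mock_mode)
  }
  responses <- query_all(prompts, backend = backend)
  results <- score_responses(responses, truths, graph)
  summary <- aggregate_results(results)
  grounding <- grounding_failure_rate(results)
  comparison <- if (length(languages) >= 2) {
    kruskal_wallis(rank_scores(results))
  }

  manifest <- list(
    package = "polyglotdx",
    version = as.character(utils::packageVersion("polyglotdx")),
    seed = seed,
    languages = languages,
    n_cases = length(vignettes),
    n_excluded_cases = length(excluded_cases),
    backend = if (inherits(backend, "mock_backend")) "MOCK" else
      backend$tag %||% "UNKNOWN",
    mock_mode = mock_mode,
    rank_score_convention = "ranked=k, not_ranked=11, no_diagnosis excluded",
    config_hash = rlang::hash(list(names(truths), languages, seed, mock_mode)))

  run <- structure(
    list(prompts = prompts, responses = responses, results = results,
         summary = summary, grounding = grounding, comparison = comparison,
         excluded_cases = excluded_cases, manifest = manifest),
    class = "pipeline_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run: %d cases x %d languages, backend %s>\n",
              x$manifest$n_cases, length(x$manifest$languages),
              x$manifest$backend))
  print(x$summary)
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Write a pipeline run to a report directory
#'
#' @param run a `pipeline_run`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("prompts", "responses")) {
    tab <- run[[sub]]
    text_col <- if (sub == "prompts") "text" else "raw_text"
    for (lang in unique(tab$language)) {
      d <- file.path(out_dir, sub, lang)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      rows <- tab[tab$language == lang, ]
      purrr::walk2(rows$case_id, rows[[text_col]],
                   ~ readr::write_file(paste0(.y, "\n"),
                                       file.path(d, paste0(.x, ".txt"))))
    }
  }
  jsonl <- purrr::pmap_chr(run$results, function(...) {
    jsonlite::toJSON(list(...), auto_unbox = TRUE, na = "null")
  })
  readr::write_lines(jsonl, file.path(out_dir, "results.jsonl"))

  counts <- as_tibble(run$summary) %>%
    select("language", "top1", "top3", "top10", "not_ranked",
           "no_diagnosis") %>%
    rename(`Language` = "language", `Top-1` = "top1", `Top-3` = "top3",
           `Top-10` = "top10", `Not Ranked` = "not_ranked",
           `No Diagnosis` = "no_diagnosis")
  readr::write_tsv(counts, file.path(out_dir, "summary_counts.tsv"))

  freq <- as_tibble(run$summary) %>%
    select("language", "freq_top1", "freq_top3", "freq_top10") %>%
    rename(`Language` = "language", `Top-1 (%)` = "freq_top1",
           `Top-3 (%)` = "freq_top3", `Top-10 (%)` = "freq_top10")
  readr::write_tsv(freq, file.path(out_dir, "summary_freq.tsv"))

  if (!is.null(run$comparison)) {
    jsonlite::write_json(tidy(run$comparison),
                         file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
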