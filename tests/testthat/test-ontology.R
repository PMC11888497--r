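test_that("lexicon TSV ingestion accumulates and deduplicates", {
  tsv <- paste(
    "term_id\tlanguage\tlabel",
    "HP:0000001\ten\tSeizure",
    "HP:0000001\tde\tKrampfanfall",
    "HP:0000001\tja\tてんかん発作",
    sep = "\n")
  lex <- load_lexicon(tsv)
  expect_equal(nrow(lex), 3L)
  expect_setequal(attr(lex, "languages"), c("en", "de", "ja"))

  # duplicate row is idempotent
  lex2 <- load_lexicon(paste(tsv, "HP:0000001\tde\tKrampfanfall", sep = "\n"))
  expect_equal(nrow(lex2), nrow(lex))

  # wrong column count
  expect_error(load_lexicon("a\tb\nx\ty"), class = "pdx_format_error")
})

test_that("distinct (term, language) keys match an independent count", {
  lex <- tiny_lexicon(n_terms = 100)
  # independent count over the raw table with base R
  keys <- unique(paste(lex$term_id, lex$language))
  expect_length(keys, 100L * 9L)
})

test_that("translate_term returns the first label and signals missing entries", {
  lex <- load_lexicon(paste(
    "term_id\tlanguage\tlabel",
    "HP:0000001\ten\tSeizure",
    "HP:0000001\ten\tEpileptic seizure",
    sep = "\n"))
  expect_equal(translate_term("HP:0000001", "en", lex), "Seizure")
  expect_error(translate_term("HP:0000001", "tr", lex),
               class = "pdx_missing_translation_error")
})

test_that("full-translation filter requires every term in every language", {
  lex <- tiny_lexicon(n_terms = 5)
  v <- read_vignette(minimal_vignette_json())
  v$features$term_id <- "HP:0000001"
  expect_true(has_full_translation(v, lex))

  # drop only the Czech entry of one term -> filtered out
  lex_cs <- dplyr::filter(tibble::as_tibble(lex),
                          !(term_id == "HP:0000001" & language == "cs"))
  attr(lex_cs, "languages") <- attr(lex, "languages")
  expect_false(has_full_translation(v, lex_cs,
                                    languages = study_languages))

  # monotone: removing a language from the requirement never flips TRUE->FALSE
  for (drop in study_languages) {
    reduced <- setdiff(study_languages, drop)
    expect_true(has_full_translation(v, lex, languages = reduced))
  }
})

test_that("cohort filter retains exactly the ledger's fully translated cases", {
  w <- small_world(seed = 3, n_cases = 40,
                   translation_completeness_rate = 0.8)
  keep <- purrr::map_lgl(w$cohort$vignettes, has_full_translation,
                         lexicon = w$onto$lexicon,
                         languages = study_languages)
  expect_equal(unname(keep), w$cohort$ledger$fully_translated)
  expect_true(any(!keep))  # incompleteness rate 0.2 must bite somewhere
})

test_that("equivalence class rolls up a clinical disease and its six subtypes", {
  g <- toy_graph()
  eq <- equivalence_class("MONDO:0000001", g)
  expect_length(eq, 7L)
  # any subtype yields the same class
  expect_equal(equivalence_class("MONDO:0000004", g), eq)
  # subtype-free disease is a singleton
  expect_equal(equivalence_class("MONDO:0000008", g), "MONDO:0000008")
  expect_error(equivalence_class("MONDO:9999999", g),
               class = "pdx_unknown_disease_error")
})

test_that("equivalence class matches brute-force closure on random subtype forests", {
  withr::with_seed(101, {
    for (rep in 1:100) {
      n_heads <- sample(2:6, 1)
      terms <- list()
      links <- list()
      next_id <- 1L
      for (h in seq_len(n_heads)) {
        head_id <- sprintf("MONDO:%07d", next_id); next_id <- next_id + 1L
        terms[[length(terms) + 1L]] <- tibble::tibble(
          id = head_id, label = paste("disease", head_id))
        for (s in seq_len(sample(0:6, 1))) {
          sub_id <- sprintf("MONDO:%07d", next_id); next_id <- next_id + 1L
          terms[[length(terms) + 1L]] <- tibble::tibble(
            id = sub_id, label = paste("disease", sub_id))
          links[[length(links) + 1L]] <- tibble::tibble(subtype = sub_id,
                                                        head = head_id)
        }
      }
      terms <- dplyr::bind_rows(terms)
      links <- dplyr::bind_rows(
        c(links, list(tibble::tibble(subtype = character(),
                                     head = character()))))
      g <- disease_graph(terms, subtype_links = links)
      for (id in sample(terms$id, min(5, nrow(terms)))) {
        expect_equal(equivalence_class(id, g), oracle_equivalence(id, links))
      }
    }
  })
})

test_that("equivalence membership is symmetric and reflexive", {
  g <- toy_graph()
  ids <- g$terms$id
  for (a in ids) {
    eq_a <- equivalence_class(a, g)
    expect_true(a %in% eq_a)
    for (b in eq_a) expect_true(a %in% equivalence_class(b, g))
  }
})

test_that("disease graph JSON round-trips and rejects broken link structures", {
  g <- toy_graph()
  path <- withr::local_tempfile(fileext = ".json")
  write_disease_graph(g, path)
  g2 <- read_disease_graph(path)
  expect_equal(g2$terms, g$terms)
  expect_equal(g2$subtype_links, g$subtype_links)

  expect_error(
    disease_graph(g$terms,
                  subtype_links = tibble::tibble(subtype = "MONDO:0000001",
                                                 head = "MONDO:9999999")),
    class = "pdx_schema_error")
  # chained links (head is itself a subtype) are rejected
  expect_error(
    disease_graph(g$terms,
                  subtype_links = tibble::tibble(
                    subtype = c("MONDO:0000002", "MONDO:0000001"),
                    head = c("MONDO:0000001", "MONDO:0000008"))),
    class = "pdx_schema_error")
})
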