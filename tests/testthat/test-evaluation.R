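test_that("numbered, bulleted and decorated lists parse in order", {
  p <- parse_response("1. Marfan syndrome\n2. Homocystinuria")
  expect_equal(p$raw, c("Marfan syndrome", "Homocystinuria"))
  expect_equal(p$rank, 1:2)

  styles <- c("1) Marfan syndrome\n2) Homocystinuria",
              "1 - Marfan syndrome\n2 - Homocystinuria",
              "- Marfan syndrome\n- Homocystinuria",
              "(1) Marfan syndrome\n(2) Homocystinuria")
  for (s in styles) {
    expect_equal(parse_response(s)$raw,
                 c("Marfan syndrome", "Homocystinuria"), info = s)
  }

  # gene annotations and trailing punctuation are stripped
  p <- parse_response("1. Marfan syndrome (FBN1),\n2. Loeys-Dietz syndrome (TGFBR1).")
  expect_equal(p$raw, c("Marfan syndrome", "Loeys-Dietz syndrome"))

  # long lists are not truncated at 10
  long <- paste(sprintf("%d. Disease %s", 1:12, letters[1:12]),
                collapse = "\n")
  expect_equal(parse_response(long)$rank, 1:12)
})

test_that("refusals and unstructured text yield No Diagnosis", {
  refusal <- "I'm sorry but based on the information provided, I cannot return a confident diagnosis"
  expect_equal(nrow(parse_response(refusal)), 0L)
  expect_equal(nrow(parse_response("")), 0L)
  expect_equal(nrow(parse_response("The patient likely has a syndrome.")), 0L)
})

test_that("name normalization folds case, unicode dashes and punctuation", {
  expect_equal(normalize_name("Loeys–Dietz Syndrome"),
               "loeys dietz syndrome")
  expect_equal(normalize_name("MARFAN SYNDROME,"), "marfan syndrome")
  expect_equal(normalize_name("The Stickler syndrome"), "stickler syndrome")
})

test_that("normalization is idempotent across generated synonym strings", {
  w <- small_world(seed = 21, n_cases = 5)
  strings <- c(w$onto$graph$terms$label, w$onto$graph$synonyms$synonym,
               w$onto$lexicon$label)
  strings <- withr::with_seed(1, sample(strings, min(1000, length(strings))))
  once <- normalize_name(strings)
  expect_identical(normalize_name(once), once)
})

test_that("grounding prefers labels, resolves unique synonyms, fails ambiguity", {
  g <- toy_graph()
  expect_equal(ground("Marfan syndrome", g), "MONDO:0000008")
  expect_equal(ground("marfan's syndrome.", g), "MONDO:0000008")
  expect_equal(ground("LDS1", g), "MONDO:0000002")
  expect_true(is.na(ground("completely made-up disease", g)))
  # synonym attached to two diseases is a failure, not an arbitrary pick
  expect_true(is.na(ground("shared synonym", g)))

  # linear-scan oracle over the synonym table for unique synonyms
  for (i in seq_len(nrow(g$synonyms))) {
    s <- g$synonyms$synonym[i]
    hits <- unique(g$synonyms$id[normalize_name(g$synonyms$synonym) ==
                                   normalize_name(s)])
    expected <- if (length(hits) == 1) hits else NA_character_
    expect_equal(ground(s, g), expected, info = s)
  }

  # EXACT-only scope drops RELATED synonyms
  idx_exact <- grounding_index(g, synonym_scope = "exact")
  expect_true(is.na(ground("shared synonym", idx_exact)))
  expect_equal(ground("LDS1", idx_exact), "MONDO:0000002")
})

test_that("scoring takes the smallest matching rank with subtype equivalence", {
  g <- toy_graph()
  gd <- ground_differential(
    parse_response("1. Homocystinuria\n2. Loeys-Dietz syndrome type 3\n3. Loeys-Dietz syndrome"),
    g)
  res <- score_case(gd, "MONDO:0000001", g)
  expect_equal(res$outcome, "ranked")
  expect_equal(res$rank, 2L)

  # truth replaced by any member of its class gives the same result
  for (truth in equivalence_class("MONDO:0000001", g)) {
    expect_equal(score_case(gd, truth, g), res)
  }

  all_wrong <- ground_differential(
    parse_response("1. Homocystinuria\n2. made-up disease"), g)
  expect_equal(score_case(all_wrong, "MONDO:0000008", g)$outcome,
               "not_ranked")
  expect_equal(score_case(all_wrong, "MONDO:0000008", g)$n_grounding_failures,
               1L)

  nd <- score_case(ground_differential(parse_response(""), g),
                   "MONDO:0000008", g)
  expect_equal(nd$outcome, "no_diagnosis")
  expect_equal(nd$n_candidates, 0L)
  expect_error(score_case(all_wrong, "MONDO:9999999", g),
               class = "pdx_unknown_disease_error")
})

test_that("permuting candidates that both fail to ground never changes the outcome", {
  g <- toy_graph()
  a <- ground_differential(
    parse_response("1. junk one\n2. junk two\n3. Marfan syndrome"), g)
  b <- ground_differential(
    parse_response("1. junk two\n2. junk one\n3. Marfan syndrome"), g)
  expect_equal(score_case(a, "MONDO:0000008", g),
               score_case(b, "MONDO:0000008", g))
})

test_that("ranked outcomes are monotone under list truncation", {
  g <- toy_graph()
  lines <- c("1. Homocystinuria", "2. junk", "3. Marfan syndrome",
             "4. Stickler syndrome")
  k <- 3L
  for (len in seq_along(lines)) {
    gd <- ground_differential(
      parse_response(paste(lines[seq_len(len)], collapse = "\n")), g)
    res <- score_case(gd, "MONDO:0000008", g)
    if (len >= k) {
      expect_equal(res$outcome, "ranked"); expect_equal(res$rank, k)
    } else {
      expect_equal(res$outcome, "not_ranked")
    }
  }
})

test_that("grounding failure rate is item-level per language", {
  results <- tibble::tibble(
    case_id = sprintf("c%d", 1:10), language = "en",
    outcome = "not_ranked", rank = NA_integer_,
    n_candidates = 10L,
    n_grounding_failures = c(5L, rep(0L, 9)))
  gfr <- grounding_failure_rate(results)
  expect_equal(gfr$failure_rate, 0.05)

  empty <- dplyr::mutate(results, n_candidates = 0L,
                         n_grounding_failures = 0L)
  expect_equal(grounding_failure_rate(empty)$failure_rate, 0)
})

test_that("planted ungroundable rate is recovered at the item level", {
  w <- small_world(seed = 17, n_cases = 1000)
  truths <- cohort_truths(w$cohort$vignettes)
  spec <- mock_spec(p_ranked = 0.2, p_not_ranked = 0.8,
                    ungroundable_rate = 0.04)
  b <- make_mock_backend(spec, w$onto$graph, truths, languages = "en",
                         seed = 23, mode = "sample")
  results <- score_responses(b$responses, truths, w$onto$graph)
  gfr <- grounding_failure_rate(results)
  # planted items are Bernoulli(0.04) per distractor slot
  n_items <- gfr$n_items
  se <- sqrt(0.04 * 0.96 / n_items)
  expect_lt(abs(gfr$failure_rate - 0.04), 3 * se)
})
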