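# Shared fixtures (built in code) and independent oracles.

# -- toy disease graph: one clinical disease with six genetic subtypes,
#    one subtype-free disease, and synonym edge cases ------------------

toy_graph <- function() {
  terms <- tibble::tibble(
    id = c("MONDO:0000001", sprintf("MONDO:000000%d", 2:7),
           "MONDO:0000008", "MONDO:0000009", "MONDO:0000010"),
    label = c("Loeys-Dietz syndrome",
              paste("Loeys-Dietz syndrome type", 1:6),
              "Marfan syndrome", "Homocystinuria", "Stickler syndrome"))
  synonyms <- tibble::tibble(
    id = c("MONDO:0000008", "MONDO:0000002", "MONDO:0000009",
           "MONDO:0000010"),
    synonym = c("Marfan's syndrome", "LDS1", "shared synonym",
                "shared synonym"),
    scope = c("EXACT", "EXACT", "RELATED", "RELATED"))
  subtype_links <- tibble::tibble(
    subtype = sprintf("MONDO:000000%d", 2:7),
    head = "MONDO:0000001")
  disease_graph(terms, synonyms, subtype_links)
}

# -- minimal vignette JSON (one observed feature) ----------------------

minimal_vignette_json <- function() {
  '{
    "id": "case_min",
    "subject": {"id": "s1", "sex": "MALE",
                "timeAtLastEncounter": {"age": {"iso8601duration": "P14Y2M"}}},
    "phenotypicFeatures": [{"type": {"id": "HP:0001250"}}],
    "diseases": [{"term": {"id": "MONDO:0000008", "label": "Marfan syndrome"}}]
  }'
}

# a 14-feature vignette (11 observed, 3 excluded) as JSON text
fixture_vignette_json_14 <- function() {
  feats <- lapply(1:14, function(i) {
    f <- list(type = list(id = sprintf("HP:%07d", i)))
    if (i > 11) f$excluded <- TRUE
    f
  })
  jsonlite::toJSON(list(
    id = "case_14",
    subject = list(id = "s14", sex = "FEMALE",
                   timeAtLastEncounter = list(age = list(iso8601duration = "P3Y"))),
    phenotypicFeatures = feats,
    diseases = list(list(term = list(id = "MONDO:0000010",
                                     label = "Stickler syndrome")))),
    auto_unbox = TRUE)
}

# tiny lexicon covering terms HP:0000001..n in the given languages
tiny_lexicon <- function(n_terms = 5, languages = study_languages) {
  rows <- expand.grid(term_id = sprintf("HP:%07d", seq_len(n_terms)),
                      language = languages, stringsAsFactors = FALSE)
  rows$label <- paste0(rows$language, " label for ", rows$term_id)
  header <- "term_id\tlanguage\tlabel"
  body <- paste(rows$term_id, rows$language, rows$label, sep = "\t")
  load_lexicon(paste(c(header, body), collapse = "\n"))
}

# small synthetic world shared by heavier tests
small_world <- function(seed = 7, n_cases = 20, ...) {
  spec <- generator_spec(seed = seed, n_diseases = 15,
                         n_phenotype_terms = 80, n_cases = n_cases, ...)
  onto <- generate_ontology(spec)
  coh <- generate_cohort(spec, onto)
  list(spec = spec, onto = onto, cohort = coh)
}

# -- independent oracles -----------------------------------------------

# brute-force closure over the raw edge list: follow the subtype link up
# once, then collect everything that links down to the same head
oracle_equivalence <- function(id, links) {
  head <- id
  for (j in seq_len(nrow(links))) {
    if (links$subtype[j] == id) head <- links$head[j]
  }
  members <- head
  for (j in seq_len(nrow(links))) {
    if (links$head[j] == head) members <- c(members, links$subtype[j])
  }
  sort(unique(members))
}

# tie-corrected Kruskal-Wallis H from the pooled-rank formula, with the
# chi-squared p-value; independent of stats::kruskal.test
oracle_kruskal <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * (mean(ri) - (N + 1) / 2)^2))
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  list(H = H, p = stats::pchisq(H, length(groups) - 1, lower.tail = FALSE))
}
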