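# Seeded synthetic generators for every fixture the pipeline consumes:
# a Mondo-like disease graph with genetic subtypes and synonyms, an
# HPO-like phenotype vocabulary with multilingual labels, and case cohorts
# with the statistical shape of the study corpus (about 14 phenotype terms
# per case, observed and excluded features, diseases with 0-6 subtypes).
# Phenotype-to-disease plausibility is deliberately not modeled: the
# machinery under test is parsing/grounding/scoring, not clinical content.

#' Specification for the synthetic generators
#'
#' Defaults emulate the benchmark corpus shape at desk scale: a mean of 14
#' phenotype terms per case with roughly a fifth of features excluded,
#' diseases carrying 0-6 genetic subtypes (the documented subtype range),
#' one to four synonyms per disease, and the nine study languages.
#'
#' @param seed master seed; every generated artifact is a pure function of
#'   the spec including this seed.
#' @param n_diseases number of clinical (group-head) diseases.
#' @param subtype_counts integer values the per-disease subtype count is
#'   drawn uniformly from.
#' @param n_phenotype_terms size of the phenotype vocabulary.
#' @param languages language codes for the lexicon.
#' @param n_cases cohort size.
#' @param terms_per_case_mean mean features per case (1 + Poisson(mean-1)),
#'   or give `terms_per_case` to fix exact values.
#' @param terms_per_case optional integer vector sampled uniformly instead
#'   of the Poisson draw (a single value fixes the count).
#' @param excluded_fraction per-feature probability of being an excluded
#'   (ruled-out) feature; the first feature of a case is always observed.
#' @param translation_completeness_rate per-term probability that all
#'   non-English translations exist.
#' @param synonyms_per_disease integer values the per-disease synonym count
#'   is drawn uniformly from.
#' @return a `generator_spec`.
#' @export
generator_spec <- function(seed = 42L, n_diseases = 40L,
                           subtype_counts = 0:6,
                           n_phenotype_terms = 300L,
                           languages = study_languages,
                           n_cases = 50L,
                           terms_per_case_mean = 14,
                           terms_per_case = NULL,
                           excluded_fraction = 0.2,
                           translation_completeness_rate = 1,
                           synonyms_per_disease = 1:4) {
  stopifnot(n_diseases >= 1, n_phenotype_terms >= 1, n_cases >= 1,
            all(subtype_counts >= 0), terms_per_case_mean >= 1,
            excluded_fraction >= 0, excluded_fraction < 1,
            translation_completeness_rate >= 0,
            translation_completeness_rate <= 1,
            all(synonyms_per_disease >= 0), "en" %in% languages)
  structure(as.list(environment()), class = "generator_spec")
}

syllables <- c("vel", "kar", "mon", "tir", "sab", "lun", "pre", "dov",
               "qui", "zan", "fel", "gor", "hax", "ilb", "jus", "kle",
               "nor", "ost", "pam", "rud", "sil", "tov", "urm", "wex")

# unique capitalized pseudowords, deterministic under the active RNG state
pseudowords <- function(n, n_syll = 3L) {
  out <- character(0)
  while (length(out) < n) {
    w <- replicate(n - length(out),
                   paste(sample(syllables, n_syll, replace = TRUE),
                         collapse = ""))
    out <- unique(c(out, w))
  }
  stringr::str_to_title(out[seq_len(n)])
}

# per-language "anomaly of X" phrasing for synthetic phenotype labels
anomaly_phrase <- c(
  en = "Anomaly of %s", zh = "%s异常", cs = "Anomálie %s",
  nl = "Anomalie van %s", de = "Anomalie der %s", it = "Anomalia di %s",
  ja = "%s異常", es = "Anomalía de %s", tr = "%s anomalisi")

synonym_patterns <- c("%s disease", "familial %s disorder",
                      "hereditary %s anomaly", "%s deficiency")

#' Generate a synthetic disease graph, phenotype vocabulary and lexicon
#'
#' Clinical diseases receive a uniformly drawn number of genetic subtypes
#' (ids linked to the head through the subtype relation) and a small set of
#' EXACT/RELATED synonyms built from the disease's base name. Phenotype
#' terms get an English label always and non-English labels at the spec's
#' completeness rate (an incomplete term is missing at least one language).
#' Deterministic under the spec seed.
#'
#' @param spec a [generator_spec()].
#' @return list with `graph` (a [disease_graph()]), `phenotype_terms`
#'   (tibble `term_id`, `label`, `complete`), and `lexicon`.
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  withr::with_seed(derive_seed(spec$seed, "ontology"), {
    base <- pseudowords(spec$n_diseases)
    n_sub <- sample(rep(spec$subtype_counts, 2), spec$n_diseases,
                    replace = TRUE)
    next_id <- 1L
    mondo <- function(k) sprintf("MONDO:%07d", k)

    terms <- list(); links <- list(); syns <- list()
    for (i in seq_len(spec$n_diseases)) {
      head_id <- mondo(next_id); next_id <- next_id + 1L
      head_label <- paste(base[i], "syndrome")
      terms[[length(terms) + 1L]] <- tibble(id = head_id, label = head_label)
      fam <- head_id
      if (n_sub[i] > 0) {
        for (k in seq_len(n_sub[i])) {
          sub_id <- mondo(next_id); next_id <- next_id + 1L
          terms[[length(terms) + 1L]] <-
            tibble(id = sub_id, label = paste(head_label, "type", k))
          links[[length(links) + 1L]] <- tibble(subtype = sub_id,
                                                head = head_id)
          fam <- c(fam, sub_id)
        }
      }
      n_syn <- sample(rep(spec$synonyms_per_disease, 2), 1)
      if (n_syn > 0) {
        pats <- sample(rep(synonym_patterns, 2), n_syn)
        owner <- sample(rep(fam, 2), n_syn, replace = TRUE)
        suffix <- ifelse(duplicated(pats), " variant", "")
        syns[[length(syns) + 1L]] <- tibble(
          id = owner,
          synonym = paste0(sprintf(pats, base[i]), suffix),
          scope = sample(c("EXACT", "RELATED"), n_syn, replace = TRUE,
                         prob = c(0.7, 0.3)))
      }
    }
    graph <- disease_graph(bind_rows(terms), bind_rows(syns),
                           bind_rows(links))

    pheno_words <- pseudowords(spec$n_phenotype_terms, 2L)
    pheno <- tibble(
      term_id = sprintf("HP:%07d", seq_len(spec$n_phenotype_terms)),
      label = sprintf(anomaly_phrase[["en"]], tolower(pheno_words)),
      complete = stats::runif(spec$n_phenotype_terms) <
        spec$translation_completeness_rate)

    non_en <- setdiff(spec$languages, "en")
    lex <- purrr::pmap(pheno, function(term_id, label, complete) {
      langs <- if (complete || !length(non_en)) non_en else {
        keep <- sample(length(non_en) - 1L, 1L)
        sample(non_en, keep)
      }
      word <- tolower(stringr::str_match(label, "of (\\w+)$")[, 2])
      tibble(term_id = term_id,
             language = c("en", langs),
             label = c(label,
                       sprintf(anomaly_phrase[c("en", langs)][-1], word)))
    }) %>% bind_rows()

    list(graph = graph, phenotype_terms = pheno, lexicon = as_lexicon(lex))
  })
}

#' Generate a synthetic case cohort
#'
#' Per-case feature counts are 1 + Poisson(mean - 1) draws (or uniform over
#' `terms_per_case` when given), features are sampled without replacement
#' from the vocabulary, each non-leading feature is excluded with the
#' spec's fraction, and each case is assigned one true disease uniformly
#' from the graph (heads and subtypes alike). The ledger records, per case,
#' the truth and whether all its terms are fully translated.
#'
#' @param spec a [generator_spec()].
#' @param ontology a [generate_ontology()] result.
#' @return list with `vignettes` (list of [case_vignette()]) and `ledger`
#'   (tibble `case_id`, `disease_id`, `n_features`, `fully_translated`).
#' @export
generate_cohort <- function(spec, ontology) {
  stopifnot(inherits(spec, "generator_spec"))
  withr::with_seed(derive_seed(spec$seed, "cohort"), {
    graph <- ontology$graph
    pheno <- ontology$phenotype_terms
    sexes <- c("MALE", "FEMALE", "OTHER", "UNKNOWN")

    out <- purrr::map(seq_len(spec$n_cases), function(i) {
      n_feat <- if (!is.null(spec$terms_per_case)) {
        sample(rep(spec$terms_per_case, 2), 1)
      } else {
        1L + stats::rpois(1, spec$terms_per_case_mean - 1)
      }
      n_feat <- min(max(n_feat, 1L), nrow(pheno))
      rows <- pheno[sample(nrow(pheno), n_feat), ]
      excluded <- stats::runif(n_feat) < spec$excluded_fraction
      excluded[1] <- FALSE
      onset <- ifelse(stats::runif(n_feat) < 0.1,
                      sprintf("P%dY", sample(0:15, n_feat, replace = TRUE) + 1L),
                      NA_character_)
      years <- sample(0:60, 1)
      age <- if (years == 0) sprintf("P%dM", sample(1:11, 1)) else {
        sprintf("P%dY", years)
      }
      truth_idx <- sample(nrow(graph$terms), 1)
      v <- case_vignette(
        id = sprintf("case_%04d", i),
        subject = subject(sprintf("subject_%04d", i),
                          sex = sample(sexes, 1,
                                       prob = c(0.48, 0.48, 0.02, 0.02)),
                          age = age),
        features = tibble(term_id = rows$term_id, excluded = excluded,
                          onset = onset),
        diagnosis = list(disease_id = graph$terms$id[truth_idx],
                         label = graph$terms$label[truth_idx]),
        disease_onset = if (stats::runif(1) < 0.3 && years > 0) {
          sprintf("P%dY", sample(seq_len(years), 1))
        })
      list(v = v,
           ledger = tibble(case_id = v$id,
                           disease_id = v$diagnosis$disease_id,
                           n_features = n_feat,
                           fully_translated = all(rows$complete)))
    })
    list(vignettes = purrr::map(out, "v"),
         ledger = purrr::map(out, "ledger") %>% bind_rows())
  })
}

#' Build (per-language) mock outcome specifications
#'
#' Convenience wrapper turning a base outcome-probability block into a
#' per-language [mock_spec()] set, with optional per-language overrides so
#' each language can plant its own distribution.
#'
#' @param outcome_probabilities list of [mock_spec()] arguments
#'   (`p_ranked`, `p_not_ranked`, `p_refusal`, optionally `synonym_rate`,
#'   `ungroundable_rate`).
#' @param languages languages to cover.
#' @param per_language_overrides named list (by language) of argument lists
#'   replacing the base block for that language.
#' @return named list of `mock_spec` objects, one per language.
#' @export
generate_mock_spec <- function(outcome_probabilities,
                               languages = study_languages,
                               per_language_overrides = NULL) {
  build <- function(args) do.call(mock_spec, args)
  base <- build(outcome_probabilities)
  out <- stats::setNames(rep(list(base), length(languages)), languages)
  for (lang in names(per_language_overrides %||% list())) {
    if (!lang %in% languages) {
      abort_pdx("override for unknown language {lang}",
                class = "pdx_spec_error", lang = lang)
    }
    out[[lang]] <- build(per_language_overrides[[lang]])
  }
  out
}

#' Extract case_id -> truth disease mapping from a cohort
#'
#' @param vignettes list of [case_vignette()] objects.
#' @return named character vector.
#' @export
cohort_truths <- function(vignettes) {
  stats::setNames(purrr::map_chr(vignettes, ~ .x$diagnosis$disease_id),
                  purrr::map_chr(vignettes, "id"))
}
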