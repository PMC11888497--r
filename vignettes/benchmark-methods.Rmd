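---
title: "Benchmarking multilingual LLM differential diagnosis: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking multilingual LLM differential diagnosis: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyglotdx)
```

## The problem and the evaluation model

Rare-disease patients often wait years for a diagnosis, and large language
models are being assessed as differential-diagnosis aids. Because most
medical text — and most LLM training data — is English, a central question
is whether an LLM's diagnostic performance in other languages matches its
English performance. Answering that requires a pipeline that (a) renders
the *same* structured patient into an equivalent narrative prompt in each
language, (b) evaluates the model's free-text answer automatically and
identically across languages, and (c) aggregates and compares outcomes
with standard statistics. `polyglotdx` implements that pipeline end to end
and makes every stage testable offline.

The unit of analysis is a **case vignette**: a strict subset of the GA4GH
Phenopacket Schema holding a subject (sex, age as an ISO-8601 duration),
an ordered list of observed and excluded HPO phenotype terms with optional
onsets, and the ground-truth disease, which is carried for scoring but
never rendered into a prompt.

For each case and language the model's reply is classified into one of
three outcomes:

* **Ranked(k)** — the correct diagnosis appears at rank *k* of the parsed
  differential, where *correct* means the grounded disease id lies in the
  truth's *diagnostic equivalence class*: a clinical disease together with
  all of its genetic subtypes. A reply of "Loeys-Dietz syndrome type 2"
  counts for a truth of "Loeys-Dietz syndrome" and vice versa.
* **Not Ranked** — a parseable differential that never hits the class
  (grounding failures never match).
* **No Diagnosis** — no parseable ranked list (typically a refusal).

Per language the pipeline reports cumulative counts Top-1, Top-3, Top-10
and the two residual columns. Two arithmetic identities are enforced at
construction time and re-checked by the test suite:

* conservation: Top-10 + Not Ranked + No Diagnosis = number of cases
  (a correct hit beyond rank 10 is counted as Not Ranked for reporting);
* frequency definition: Top-N% = 100 × Top-N / (n − No Diagnosis),
  rounded half-up to one decimal. The denominator excludes refusals, so a
  language where the model refuses often is not additionally penalised on
  the frequency scale.

Cross-language comparison uses the Kruskal-Wallis H test on per-case
ordinal scores (tie-corrected, chi-squared p with groups − 1 degrees of
freedom, delegated to `stats::kruskal.test()`).

## Pipeline stages and their contracts

1. **`read_vignette()` / `read_cohort()`** parse the phenopacket-subset
   JSON. Unknown fields warn and are ignored; cohort order is
   lexicographic by filename so runs never depend on filesystem
   enumeration; per-file failures are collected, not fatal.
2. **`load_lexicon()` / `has_full_translation()`** hold per-language HPO
   labels and implement the cohort filter: a case enters the benchmark
   only if *every* feature term (observed and excluded) has a translation
   in every study language, so all languages see the same cases.
3. **`build_prompt()`** renders the narrative prompt from per-language
   YAML templates: a constant header (task statement, the statement that
   the condition is genetic, an example output block that is always
   English, and a directive to answer in English), then sex/age sentence,
   optional disease-onset sentence, observed-features sentence, and an
   excluded-features sentence elided when the case has none. The function
   is pure — identical inputs give byte-identical prompts — and refuses to
   emit a prompt containing the diagnosis label or id.
4. **`query()`** talks to a backend behind a single contract; mock and
   recorded backends ship with the package. Scoring depends only on the
   response text, never on which backend produced it.
5. **`parse_response()` → `ground()` → `score_case()`** extract the
   ranked list (numbered or bulleted; rank markers, parenthetical gene
   annotations and trailing punctuation stripped; no truncation at parse
   time), ground each candidate by exact match on normalized English
   labels and synonyms, and score against the truth's equivalence class.
6. **`aggregate_results()` / `kruskal_wallis()` / `run_pipeline()`**
   produce the per-language summary tibble, the omnibus comparison, and a
   written report directory (prompt and response files, JSON-lines
   results, TSV summary tables, a manifest recording seed, versions and
   the rank-score convention).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `temperature` (`llm_config`) | 1 | evaluation under the backend's default sampling regime, no token cap |
| `terms_per_case_mean` | 14 | corpus-shaped cohorts: ~14 HPO terms per case |
| `excluded_fraction` | 0.2 | roughly 3 excluded features per 14-term case, matching the observed/excluded mix the prompts must exercise |
| `subtype_counts` | 0–6 uniform | spans subtype-free diseases up to the six-subtype clinical groups that motivate equivalence rollup |
| `synonym_rate` (mock) | 0.3 | planted correct answers regularly arrive as synonyms, exercising the synonym index |
| `ungroundable_rate` (mock) | 0.04 | item-level grounding-failure rate in the middle of the 2–6% range reported for real runs |
| `unranked_score` (`rank_scores`) | 11 | one beyond the Top-10 reporting cap |

Age rendering granularity is years when ≥ 1 year, months when < 1 year,
days when < 1 month — natural clinical phrasing; the schema keeps the raw
ISO-8601 string so no information is lost upstream of rendering.

## What the synthetic generators emulate — and what they do not

`generate_ontology()` and `generate_cohort()` produce a Mondo-like disease
graph (labels, synonyms with EXACT/RELATED scope, single-level
subtype-to-head links), an HPO-like vocabulary with per-language labels
present at a configurable completeness rate, and corpus-shaped cohorts.
`make_mock_backend()` plants outcomes with known probabilities and
realizes them as numbered lists whose distractors are drawn *outside* the
truth's equivalence class, so a planted "Not Ranked" can never score as an
accidental subtype hit; refusal sentences come from a small multilingual
bank. Planting is exact (largest-remainder allocation) by default, for
bitwise-checkable aggregation, with a sampling mode for stochastic tests.

The generators deliberately do **not** model phenotype–disease
co-occurrence (prompt plausibility is irrelevant to the machinery under
test), linguistic variation of model replies beyond list/refusal/
ungroundable structure, or deep ontology hierarchy beyond the one-level
subtype relation. Passing tests therefore demonstrate that the plumbing —
filtering, templating, parsing, grounding, equivalence scoring,
aggregation, statistics — is correct and deterministic; they say nothing
about how any real model performs on real cases.

## Numerical and design choices

* **Rounding** is half-up to one decimal for all reported percentages
  (`round_half_up()`); banker's rounding would alter printed frequencies.
* **Normalization** (`normalize_name()`): NFKC, case-fold, punctuation and
  symbols to spaces, whitespace collapse, leading/trailing "the" dropped.
  Idempotent by construction and property-tested.
* **Grounding is exact-match only.** Fuzzy matching would change failure
  statistics in unverifiable ways. A normalized synonym shared by two
  diseases is a grounding failure, not an arbitrary pick; primary labels
  always beat synonyms. Both EXACT and RELATED synonyms are indexed by
  default (`synonym_scope = "exact"` restricts). The index is built from
  English names only, because replies are requested in English;
  non-English candidate strings simply fail to ground.
* **Duplicated candidate names** within one differential count per
  occurrence in the item-level grounding-failure rate.
* **Onset precedence**: a disease-level onset renders as its own sentence;
  feature-level onsets render inline after the feature label. Excluded
  features render as a single negated sentence listing their labels.
* **Kruskal-Wallis sample construction**: Ranked(k) → k, Not Ranked → 11,
  No Diagnosis excluded by default (optionally scored at 12 via
  `rank_scores()`); the convention is written into the run manifest so any
  comparison is reproducible. With every observation tied the
  tie-correction formula is 0/0; the package returns H = 0, p = 1 by
  convention.
* **All-refusal degenerate input**: counts aggregate to (0, 0, 0, 0, n);
  the frequency is undefined and `topn_frequency()` raises a classed
  error rather than returning 0/0.

## Problem sizes used by the shipped tests

The test suite and acceptance script run entirely on synthetic fixtures:
toy graphs of ~10 diseases for unit tests; cohorts of 20–60 cases for
pipeline tests; 5000 cases for distribution-shape checks; mock runs of
2000 and 4967 cases for parameter recovery (the latter matching the
reference corpus size, checked within three binomial standard errors);
and 100-instance sweeps for the oracle-equivalence properties. A full
nine-language, 50-case pipeline run — 450 prompts, responses and scored
results — is executed twice to verify byte-identical reports and a
complete absence of diagnosis leakage in prompts.

## Known limitations

* Template wording is this package's own concise phrasing per language;
  the testable contract is structure (header, genetic-disease statement,
  English example block, English-answer directive, observed/excluded
  sections), not any particular clinical register. Grammatical agreement
  beyond what the templates encode (declension, classifiers) is out of
  scope.
* The live-API backend is intentionally out of scope; the contract
  (`query()`) is the extension point, and recorded responses replay real
  runs offline.
* Reference per-language counts ship as a fixture to validate reporting
  arithmetic; the package cannot (and does not try to) re-derive them
  without the original corpus and model access.
* The cross-language H statistic depends on the unranked-case convention;
  with only printed summary tables one cannot reconstruct the per-case
  sample behind a published H value, which is why the package reports its
  convention in every manifest.
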