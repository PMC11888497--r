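# Per-language aggregation (benchmark-table counts and frequency style),
# the cross-language Kruskal-Wallis comparison, and tidy/plot methods.

#' Construct a per-language summary from outcome counts
#'
#' Validates the summary invariants: cumulative counts are monotone
#' (top1 <= top3 <= top10) and Top-10 + Not Ranked + No Diagnosis equals the
#' case total. Frequencies are recomputed from the counts (never stored
#' independently) as 100 * topN / (n_total - no_diagnosis) — the denominator
#' excludes refusals — rounded half-up to one decimal.
#'
#' @param language language code or name.
#' @param top1,top3,top10 cumulative correct-diagnosis counts.
#' @param not_ranked cases whose differential omitted the correct diagnosis.
#' @param no_diagnosis cases with no parseable differential.
#' @return a `language_summary` tibble, one row per language.
#' @export
language_summary <- function(language, top1, top3, top10, not_ranked,
                             no_diagnosis) {
  if (any(top1 > top3) || any(top3 > top10)) {
    abort_pdx("cumulative counts must satisfy top1 <= top3 <= top10",
              class = "pdx_schema_error")
  }
  n_total <- top10 + not_ranked + no_diagnosis
  denom <- n_total - no_diagnosis
  freq <- function(k) ifelse(denom > 0, round_half_up(100 * k / denom, 1),
                             NA_real_)
  out <- tibble(language = language, n_total = as.integer(n_total),
                top1 = as.integer(top1), top3 = as.integer(top3),
                top10 = as.integer(top10),
                not_ranked = as.integer(not_ranked),
                no_diagnosis = as.integer(no_diagnosis),
                freq_top1 = freq(top1), freq_top3 = freq(top3),
                freq_top10 = freq(top10))
  class(out) <- c("language_summary", class(tibble()))
  out
}

#' Aggregate case results into per-language summaries
#'
#' Counts correct diagnoses at Top-1/Top-3/Top-10 per language. A case
#' ranked beyond 10 counts in "Not Ranked", so the reported row always
#' satisfies Top-10 + Not Ranked + No Diagnosis = n cases.
#'
#' @param results a [score_responses()] table.
#' @return a `language_summary` tibble, one row per language.
#' @export
aggregate_results <- function(results) {
  if (!nrow(results)) {
    abort_pdx("no case results to aggregate", class = "pdx_empty_input_error")
  }
  counts <- results %>%
    group_by(.data$language) %>%
    summarise(
      top1 = sum(.data$outcome == "ranked" & .data$rank <= 1, na.rm = TRUE),
      top3 = sum(.data$outcome == "ranked" & .data$rank <= 3, na.rm = TRUE),
      top10 = sum(.data$outcome == "ranked" & .data$rank <= 10, na.rm = TRUE),
      not_ranked = sum(.data$outcome == "not_ranked" |
                         (.data$outcome == "ranked" & .data$rank > 10)),
      no_diagnosis = sum(.data$outcome == "no_diagnosis"),
      .groups = "drop")
  language_summary(counts$language, counts$top1, counts$top3, counts$top10,
                   counts$not_ranked, counts$no_diagnosis)
}

#' Top-N frequency of a summary row
#'
#' 100 * topN / (n_total - no_diagnosis), rounded half-up to one decimal —
#' the denominator excludes No Diagnosis cases.
#'
#' @param summary a [language_summary()] tibble.
#' @param n one of 1, 3, 10.
#' @return numeric vector of percentages, one per summary row.
#' @export
topn_frequency <- function(summary, n) {
  if (!n %in% c(1, 3, 10)) {
    abort_pdx("n must be 1, 3 or 10", class = "pdx_spec_error")
  }
  denom <- summary$n_total - summary$no_diagnosis
  if (any(denom <= 0)) {
    abort_pdx("all cases are No Diagnosis; frequency undefined",
              class = "pdx_degenerate_error")
  }
  round_half_up(100 * summary[[paste0("top", n)]] / denom, 1)
}

#' Reference per-language outcome counts
#'
#' The printed per-language result table of a published nine-language
#' GPT-4o rare-disease benchmark over 4967 phenopacket-derived cases,
#' shipped as a plain-TSV fixture. Used to verify the reporting arithmetic
#' (frequencies and row-sum conservation) against known values.
#'
#' @return a `language_summary` tibble with nine rows.
#' @export
benchmark_counts <- function() {
  tab <- readr::read_tsv(
    system.file("extdata", "benchmark_counts.tsv", package = "polyglotdx"),
    col_types = "ciiiii", progress = FALSE)
  language_summary(tab$language, tab$top1, tab$top3, tab$top10,
                   tab$not_ranked, tab$no_diagnosis)
}

# ---- Cross-language comparison ---------------------------------------

#' Per-case ordinal scores for the cross-language rank comparison
#'
#' Converts outcomes to an ordinal score per case: a ranked case scores its
#' rank k, a Not Ranked case scores `unranked_score` (default 11, one
#' beyond the Top-10 reporting cap), and No Diagnosis cases are excluded by
#' default (alternatively scored at `no_diagnosis_score`). The construction
#' used is an analysis choice and should be reported with results.
#'
#' @param results a [score_responses()] table.
#' @param unranked_score score for Not Ranked cases.
#' @param no_diagnosis `"exclude"` (default) or `"score"`.
#' @param no_diagnosis_score score used when `no_diagnosis = "score"`.
#' @return tibble with columns `language`, `score`.
#' @export
rank_scores <- function(results, unranked_score = 11,
                        no_diagnosis = c("exclude", "score"),
                        no_diagnosis_score = 12) {
  no_diagnosis <- match.arg(no_diagnosis)
  out <- results
  if (no_diagnosis == "exclude") {
    out <- filter(out, .data$outcome != "no_diagnosis")
  }
  out %>%
    mutate(score = dplyr::case_when(
      .data$outcome == "ranked" ~ as.numeric(.data$rank),
      .data$outcome == "not_ranked" ~ as.numeric(unranked_score),
      TRUE ~ as.numeric(no_diagnosis_score))) %>%
    select("language", "score")
}

#' Kruskal-Wallis comparison of rank scores across languages
#'
#' Omnibus nonparametric test for distributional differences of per-case
#' ordinal scores among languages: tie-corrected H statistic, p-value from
#' the chi-squared approximation with (groups - 1) degrees of freedom
#' (delegated to [stats::kruskal.test()]).
#'
#' @param scores tibble with columns `language` (or `group`) and `score`,
#'   e.g. from [rank_scores()]; or a named list of numeric vectors.
#' @return a `rank_comparison` object with `H`, `df`, `p_value`, `groups`.
#' @export
kruskal_wallis <- function(scores) {
  if (is.list(scores) && !is.data.frame(scores)) {
    scores <- purrr::imap(scores, ~ tibble(language = .y, score = .x)) %>%
      bind_rows()
  }
  if ("group" %in% names(scores) && !"language" %in% names(scores)) {
    scores <- rename(scores, language = "group")
  }
  groups <- count(scores, .data$language, name = "n")
  if (nrow(groups) < 2 || any(groups$n == 0)) {
    abort_pdx("need at least two non-empty groups",
              class = "pdx_insufficient_groups_error")
  }
  if (dplyr::n_distinct(scores$score) == 1) {
    # every observation tied: no between-group variation, H is 0 by
    # convention (the tie-corrected formula is 0/0 here)
    return(structure(list(H = 0, df = nrow(groups) - 1L, p_value = 1,
                          groups = groups), class = "rank_comparison"))
  }
  kt <- stats::kruskal.test(score ~ factor(language), data = scores)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p_value = kt$p.value, groups = groups),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis rank comparison: H = %.3f, df = %d, p = %.4g (%d groups)\n",
              x$H, as.integer(x$df), x$p_value, nrow(x$groups)))
  invisible(x)
}

#' @describeIn kruskal_wallis one-row tibble with `statistic`, `df`,
#'   `p.value`, `n_groups`, `n_total`.
#' @param x a `rank_comparison`.
#' @param ... unused.
#' @method tidy rank_comparison
#' @export
tidy.rank_comparison <- function(x, ...) {
  tibble(statistic = x$H, df = x$df, p.value = x$p_value,
         n_groups = nrow(x$groups), n_total = sum(x$groups$n),
         method = "Kruskal-Wallis rank sum test")
}

#' @method glance rank_comparison
#' @export
glance.rank_comparison <- function(x, ...) tidy(x)

# ---- Tidiers and plots for summaries ---------------------------------

#' Long-format view of per-language summaries
#'
#' @param x a `language_summary` tibble.
#' @param ... unused.
#' @return tibble with `language`, `top_n`, `count`, `frequency`.
#' @method tidy language_summary
#' @export
tidy.language_summary <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x)[c("language", "top1", "top3", "top10")],
                      -"language", names_to = "top_n", values_to = "count") %>%
    mutate(top_n = factor(.data$top_n, levels = c("top1", "top3", "top10"),
                          labels = c("Top-1", "Top-3", "Top-10")),
           frequency = round_half_up(
             100 * .data$count /
               (x$n_total - x$no_diagnosis)[match(.data$language, x$language)],
             1))
}

#' Plot per-language Top-N frequencies
#'
#' Grouped bar chart of Top-1/Top-3/Top-10 frequencies (denominator
#' excluding No Diagnosis cases) by language.
#'
#' @param object a `language_summary` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot language_summary
#' @export
autoplot.language_summary <- function(object, ...) {
  dat <- tidy.language_summary(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$language, y = .data$frequency,
                                    fill = .data$top_n)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::labs(x = NULL, y = "Correct diagnoses (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
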