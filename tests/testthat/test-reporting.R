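test_that("reference table frequencies reproduce the published percentages", {
  tab <- benchmark_counts()
  expect_equal(nrow(tab), 9L)

  eng <- tab[tab$language == "English", ]
  expect_equal(topn_frequency(eng, 1), 19.8)
  expect_equal(topn_frequency(eng, 3), 27.0)
  expect_equal(topn_frequency(eng, 10), 31.1)

  other <- tab[tab$language != "English", ]
  expect_equal(range(topn_frequency(other, 1)), c(16.9, 20.5))
  expect_equal(range(topn_frequency(other, 3)), c(25.3, 27.7))
  expect_equal(range(topn_frequency(other, 10)), c(28.5, 31.8))

  # which languages sit at the extremes
  expect_equal(other$language[which.min(topn_frequency(other, 1))],
               "Japanese")
  expect_equal(other$language[which.max(topn_frequency(other, 1))], "Dutch")
  expect_equal(other$language[which.max(topn_frequency(other, 10))],
               "Spanish")
})

test_that("row-sum conservation holds for every reference row", {
  tab <- benchmark_counts()
  expect_true(all(tab$top10 + tab$not_ranked + tab$no_diagnosis == 4967L))
  expect_true(all(tab$n_total == 4967L))
  expect_true(all(tab$top1 <= tab$top3 & tab$top3 <= tab$top10))
})

test_that("the frequency denominator excludes No Diagnosis cases", {
  # switching the denominator to the full total moves English Top-1 only
  # in the second decimal: 985/4966 vs 985/4967
  with_excl <- 100 * 985 / (4967 - 1)
  with_total <- 100 * 985 / 4967
  expect_equal(round_half_up(with_excl, 1), 19.8)
  expect_equal(round_half_up(with_total, 1), 19.8)
  expect_gt(abs(with_excl - with_total), 0.001)
  expect_lt(abs(with_excl - with_total), 0.01)
})

test_that("aggregation counts cumulative ranks and guards degenerate input", {
  results <- tibble::tibble(
    case_id = sprintf("c%d", 1:10), language = "en",
    outcome = c(rep("ranked", 6), rep("not_ranked", 2),
                rep("no_diagnosis", 2)),
    rank = c(1L, 1L, 2L, 3L, 9L, 12L, NA, NA, NA, NA),
    n_candidates = c(rep(12L, 6), 5L, 5L, 0L, 0L),
    n_grounding_failures = 0L)
  s <- aggregate_results(results)
  expect_equal(s$top1, 2L)
  expect_equal(s$top3, 4L)
  expect_equal(s$top10, 5L)       # rank 12 does not count at Top-10
  expect_equal(s$not_ranked, 3L)  # ...and lands in Not Ranked instead
  expect_equal(s$no_diagnosis, 2L)
  expect_equal(s$n_total, 10L)
  expect_equal(s$top10 + s$not_ranked + s$no_diagnosis, s$n_total)

  all_nd <- dplyr::mutate(results, outcome = "no_diagnosis",
                          rank = NA_integer_)
  s_nd <- aggregate_results(all_nd)
  expect_equal(c(s_nd$top1, s_nd$top3, s_nd$top10, s_nd$not_ranked,
                 s_nd$no_diagnosis), c(0L, 0L, 0L, 0L, 10L))
  expect_error(topn_frequency(s_nd, 1), class = "pdx_degenerate_error")
  expect_error(aggregate_results(results[0, ]),
               class = "pdx_empty_input_error")
})

test_that("kruskal_wallis matches the rank-sum oracle", {
  # frozen hand-computed value: {1,2,3} vs {4,5,6}, no ties ->
  # H = 12/(6*7) * (3*(2-3.5)^2 + 3*(5-3.5)^2) = 27/7
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-12)

  # identical constant groups: no between-group variation
  expect_warning(
    kw0 <- kruskal_wallis(list(a = rep(2, 3), b = rep(2, 3))),
    regexp = NA)
  expect_equal(kw0$H, 0)

  # random small instances (total n <= 8), with ties, against the oracle
  withr::with_seed(77, {
    for (rep in 1:200) {
      k <- sample(2:3, 1)
      sizes <- sample(1:3, k, replace = TRUE)
      while (sum(sizes) > 8) sizes <- sample(1:3, k, replace = TRUE)
      groups <- lapply(sizes, function(n) sample(1:4, n, replace = TRUE))
      if (length(unique(unlist(groups))) == 1) next  # all tied: H undefined 0/0
      names(groups) <- paste0("g", seq_len(k))
      kw <- kruskal_wallis(groups)
      oracle <- oracle_kruskal(groups)
      expect_equal(kw$H, oracle$H, tolerance = 1e-10)
      expect_equal(kw$p_value, oracle$p, tolerance = 1e-10)
      expect_equal(kw$df, k - 1L)
    }
  })

  expect_error(kruskal_wallis(list(a = 1:3)),
               class = "pdx_insufficient_groups_error")
})

test_that("kruskal_wallis holds its nominal type-I error on null ordinal data", {
  withr::with_seed(123, {
    p <- replicate(100, {
      groups <- lapply(1:9, function(i) sample(c(1:10, 11), 40,
                                               replace = TRUE,
                                               prob = c(rep(0.03, 10), 0.7)))
      names(groups) <- paste0("lang", 1:9)
      kruskal_wallis(groups)$p_value
    })
  })
  expect_lt(mean(p < 0.05), 0.12)
})

test_that("rank scores follow the documented convention", {
  results <- tibble::tibble(
    case_id = c("a", "b", "c"), language = "en",
    outcome = c("ranked", "not_ranked", "no_diagnosis"),
    rank = c(4L, NA, NA), n_candidates = c(10L, 10L, 0L),
    n_grounding_failures = 0L)
  expect_equal(rank_scores(results)$score, c(4, 11))
  expect_equal(rank_scores(results, no_diagnosis = "score")$score,
               c(4, 11, 12))
})

test_that("tidiers and autoplot expose the summary and comparison", {
  tab <- benchmark_counts()
  long <- tidy(tab)
  expect_equal(nrow(long), 27L)
  expect_equal(long$frequency[long$language == "English" &
                                long$top_n == "Top-1"], 19.8)
  p <- autoplot(tab)
  expect_s3_class(p, "ggplot")

  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  td <- tidy(kw)
  expect_equal(td$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(glance(kw)$n_total, 6L)
})
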