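test_that("make_contaminated_set keeps exactly floor(fraction * n) term genes", {
  term <- sprintf("T%02d", 1:10)
  pool <- c(term, sprintf("P%02d", 1:50))
  mix <- make_contaminated_set(term, pool, 0.5, seed = 1, origin_term = "X:1")
  expect_length(mix$genes, 10)
  expect_identical(length(intersect(mix$genes, term)), 5L)
  expect_identical(mix$condition, "mix5050")
  expect_false(anyDuplicated(mix$genes) > 0)

  # odd size: floor rule -> 6 term + 7 background
  term13 <- sprintf("T%02d", 1:13)
  pool13 <- c(term13, sprintf("P%02d", 1:50))
  mix13 <- make_contaminated_set(term13, pool13, 0.5, seed = 2)
  expect_length(mix13$genes, 13)
  expect_identical(length(intersect(mix13$genes, term13)), 6L)

  # fraction 0: fully random from the whole pool, size preserved
  rnd <- make_contaminated_set(sprintf("T%02d", 1:8), pool, 0, seed = 3)
  expect_length(rnd$genes, 8)
  expect_identical(rnd$condition, "random")

  # fraction 1: the real set, unsampled
  real <- make_contaminated_set(term, pool, 1, seed = 4)
  expect_setequal(real$genes, term)
  expect_identical(real$condition, "real")

  expect_error(
    make_contaminated_set(term, c(term, "onlyone"), 0.5, seed = 5),
    class = "gslm_argument_error"
  )
  expect_error(
    make_contaminated_set(term, c(term, "onlyone"), 0.5, seed = 5),
    "short by"
  )
})

test_that("contamination composition is exact over many seeded draws", {
  term <- sprintf("T%02d", 1:11)
  pool <- c(term, sprintf("P%03d", 1:200))
  for (seed in 1:300) {
    mix <- make_contaminated_set(term, pool, 0.5, seed = seed)
    expect_identical(length(intersect(mix$genes, term)), 5L)   # floor(11/2)
    expect_identical(length(setdiff(mix$genes, term)), 6L)
    expect_length(mix$genes, 11)
  }
  # seeded reproducibility
  expect_identical(make_contaminated_set(term, pool, 0.5, seed = 12)$genes,
                   make_contaminated_set(term, pool, 0.5, seed = 12)$genes)
})

test_that("bin_confidence partitions [0, 1] per the published bins", {
  expect_identical(bin_confidence(0.85), "medium")
  expect_identical(bin_confidence(0.96), "high")
  expect_identical(bin_confidence(0.0), "not_assigned")
  expect_identical(bin_confidence(0.005), "low")  # below 0.01 still low
  expect_identical(bin_confidence(0.80), "medium")
  expect_identical(bin_confidence(0.87), "high")
  expect_identical(bin_confidence(1.0), "high")
  expect_error(bin_confidence(1.2), class = "gslm_argument_error")
  expect_error(bin_confidence(-0.1), class = "gslm_argument_error")
})

test_that("benchmark sets conserve size and reproduce under the same seed", {
  toy <- make_toy_ontology(n_terms = 12, seed = 9)
  ont <- toy$ontology
  terms <- filter_and_sample_terms(ont, 3, 100, n = 5, seed = 1)
  s1 <- benchmark_sets(ont, terms, seed = 42)
  s2 <- benchmark_sets(ont, terms, seed = 42)
  for (id in terms) {
    n <- length(aggregate_genes(ont, id))
    for (cond in c("real", "mix5050", "random")) {
      expect_length(s1[[id]][[cond]]$genes, n)
      expect_identical(s1[[id]][[cond]]$genes, s2[[id]][[cond]]$genes)
    }
  }
  s3 <- benchmark_sets(ont, terms, seed = 43)
  expect_false(identical(s1[[terms[1]]]$mix5050$genes,
                         s3[[terms[1]]]$mix5050$genes))
})

test_that("run_benchmark reproduces the forced contingency table", {
  toy <- make_toy_ontology(n_terms = 12, seed = 9)
  ont <- toy$ontology
  terms <- filter_and_sample_terms(ont, 3, 100, n = 10, seed = 1)
  expect_length(terms, 10)
  sets <- benchmark_sets(ont, terms, seed = 42)
  script <- list()
  for (id in terms) {
    script <- script_response(script, sets[[id]]$real$genes,
                              name = "Real process", confidence = 0.9)
    script <- script_response(script, sets[[id]]$mix5050$genes,
                              name = "Half process", confidence = 0.5)
    # random sets fall through to the zero-confidence sentinel default
  }
  res <- run_benchmark(ont, terms, scripted_llm(script), seed = 42)
  expected <- matrix(
    c(10L, 0L, 0L, 0L,
      0L, 0L, 10L, 0L,
      0L, 0L, 0L, 10L),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("real", "mix5050", "random"),
                    c("high", "medium", "low", "not_assigned"))
  )
  expect_identical(res$table, expected)
  expect_identical(unname(rowSums(res$table)), rep(10, 3))
  expect_identical(res$failures, 0L)

  # zero terms -> empty table
  empty <- run_benchmark(ont, character(), scripted_llm(), seed = 42)
  expect_identical(sum(empty$table), 0L)

  # bit-reproducible end to end
  res2 <- run_benchmark(ont, terms, scripted_llm(script), seed = 42)
  expect_identical(res$records, res2$records)
})

test_that("parse failures are excluded from the table with a warning", {
  toy <- make_toy_ontology(n_terms = 12, seed = 9)
  ont <- toy$ontology
  terms <- filter_and_sample_terms(ont, 3, 100, n = 2, seed = 1)
  broken <- llm_backend("broken", function(prompt, ...) "no header at all")
  expect_warning(
    res <- run_benchmark(ont, terms, broken, seed = 42),
    "excluded"
  )
  expect_identical(res$failures, 6L)
  expect_identical(sum(res$table), 0L)
})

test_that("compare_distributions: chi-squared on contingencies", {
  res <- compare_distributions(c(10, 0), c(0, 10))
  expect_identical(res$statistic, 20)
  expect_identical(res$df, 1L)
  expect_identical(compare_distributions(c(5, 5), c(5, 5))$statistic, 0)

  # agrees with the stock test (no continuity correction)
  withr::with_seed(17, {
    for (i in 1:10) {
      a <- sample(0:20, 4)
      b <- sample(1:20, 4)
      keep <- (a + b) > 0
      if (sum(keep) < 2) next
      ours <- compare_distributions(a, b)
      stock <- suppressWarnings(
        stats::chisq.test(rbind(a[keep], b[keep]), correct = FALSE)
      )
      expect_equal(ours$statistic, unname(stock$statistic))
      expect_equal(ours$p_value, stock$p.value)
    }
  })

  # zero-marginal columns are dropped before d.f. computation
  res3 <- compare_distributions(c(10, 0, 3), c(2, 0, 8))
  expect_identical(res3$df, 1L)
  expect_error(compare_distributions(c(10, 0), c(5, 0)),
               class = "gslm_argument_error")
})

test_that("compare_distributions: Mann-Whitney U on score lists", {
  res <- compare_distributions(c(1, 2, 3), c(4, 5, 6),
                               method = "mannwhitney")
  expect_identical(res$statistic, 0)
  expect_lte(res$p_value, 1)
  sym <- compare_distributions(c(4, 5, 6), c(1, 2, 3),
                               method = "mannwhitney")
  expect_identical(sym$statistic, 9)  # n1 * n2 - U
})
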