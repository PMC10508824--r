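# Scripted fixtures for the five-step citation loop.
para_good <- "SNX6 and SNX12 mediate retromer-dependent endosomal sorting of cargo."
para_nogenes <- "These proteins participate in many cellular activities."
para_many_kw <- "LYST regulates lysosomal trafficking, size, morphology and sorting."

citation_backend <- function() {
  # support-verdict keys (titles) come first: judge prompts embed both the
  # title and the paragraph, and first match wins
  scripted_text_llm(c(
    setNames("supported: yes | basis: abstract", "Retromer in sorting"),
    setNames("supported: no | basis: none", "Unrelated cardiology paper"),
    setNames("supported: yes | basis: title", "SNX6 and SNX12 in traffic"),
    setNames("supported: no | basis: none", "Another miss"),
    setNames("supported: no | basis: none", "Background review"),
    setNames("genes: SNX6, SNX12 | keywords: endosomal sorting; retromer",
             para_good),
    setNames("unknown", para_nogenes),
    setNames(paste("genes: LYST | keywords: lysosomal trafficking;",
                   "organelle size; morphology; sorting; autophagy"),
             para_many_kw)
  ))
}

citation_records <- function() {
  data.frame(
    pmid = sprintf("100%d", 1:5),
    title = c("Retromer in sorting", "Unrelated cardiology paper",
              "SNX6 and SNX12 in traffic", "Another miss",
              "Background review"),
    abstract = c(
      "SNX6 binds retromer.",                       # 1 gene
      "Hearts and valves.",                         # 0 genes
      "SNX6 and SNX12 act in endosomal sorting.",   # 2 genes
      "Nothing relevant but mentions SNX6 anyway.", # 1 gene
      "General sorting review."                     # 0 genes
    )
  )
}

test_that("extract_keywords parses replies, truncates, and returns unknown", {
  backend <- citation_backend()
  kx <- extract_keywords(backend, para_good)
  expect_s3_class(kx, "KeywordExtraction")
  expect_identical(kx$gene_symbols, c("SNX6", "SNX12"))
  expect_identical(kx$function_keywords, c("endosomal sorting", "retromer"))

  expect_true(is_unknown(extract_keywords(backend, para_nogenes)))

  expect_warning(
    kx5 <- extract_keywords(backend, para_many_kw),
    "first 3"
  )
  expect_length(kx5$function_keywords, 3)
  expect_identical(kx5$function_keywords[1], "lysosomal trafficking")

  # keywords without genes is unknown, not an error
  kw_only <- scripted_text_llm(character(),
                               default = "genes: | keywords: sorting")
  expect_true(is_unknown(extract_keywords(kw_only, "some paragraph")))

  # structurally unparsable replies are parse errors, distinct from unknown
  garbled <- scripted_text_llm(character(), default = "whatever text")
  expect_error(extract_keywords(garbled, "some paragraph"),
               class = "gslm_parse_error")
})

test_that("build_query assembles the gene-AND-keyword expression", {
  kx <- structure(
    list(gene_symbols = "SNX6", function_keywords = "retromer"),
    class = "KeywordExtraction"
  )
  expect_identical(
    build_query(kx),
    '(SNX6[Title/Abstract]) AND ("retromer"[Title/Abstract])'
  )
  kx2 <- structure(
    list(gene_symbols = c("SNX6", "SNX12"),
         function_keywords = c("endosomal sorting", "retromer")),
    class = "KeywordExtraction"
  )
  q <- build_query(kx2)
  expect_identical(
    q,
    paste0('(SNX6[Title/Abstract] OR SNX12[Title/Abstract]) AND ',
           '("endosomal sorting"[Title/Abstract] OR "retromer"[Title/Abstract])')
  )
  expect_identical(lengths(regmatches(q, gregexpr(" AND ", q))), 1L)

  kx3 <- structure(
    list(gene_symbols = "A", function_keywords = 'say "hi"'),
    class = "KeywordExtraction"
  )
  expect_warning(q3 <- build_query(kx3), "quotes")
  expect_identical(q3, '(A[Title/Abstract]) AND ("say hi"[Title/Abstract])')
})

test_that("rank_publications orders by gene coverage then relevance", {
  recs <- citation_records()
  recs$relevance_rank <- seq_len(nrow(recs))
  ranked <- rank_publications(recs, c("SNX6", "SNX12"), top_k = 3)
  expect_identical(nrow(ranked), 3L)
  # 2-gene abstract first, then the 1-gene abstracts in relevance order
  expect_identical(ranked$pmid, c("1003", "1001", "1004"))
  expect_identical(ranked$gene_mention_count, c(2L, 1L, 1L))
  # permutation-then-truncation: a subset of the input, no duplicates
  expect_true(all(ranked$pmid %in% recs$pmid))
  expect_false(anyDuplicated(ranked$pmid) > 0)
  # word boundaries: SNX1 must not match SNX12
  one <- data.frame(pmid = "1", title = "t", abstract = "SNX12 only here",
                    relevance_rank = 1L)
  expect_identical(rank_publications(one, "SNX1")$gene_mention_count, 0L)
})

test_that("judge_support parses verdicts and never fabricates them", {
  backend <- citation_backend()
  yes <- judge_support(
    backend,
    list(pmid = "1001", title = "Retromer in sorting", abstract = "x"),
    para_good
  )
  expect_true(yes$supported)
  expect_identical(yes$basis, "abstract")

  no <- judge_support(
    backend,
    list(pmid = "1002", title = "Unrelated cardiology paper", abstract = "x"),
    para_good
  )
  expect_false(no$supported)
  expect_identical(no$basis, "none")

  title_only <- judge_support(
    backend,
    list(pmid = "1003", title = "SNX6 and SNX12 in traffic", abstract = ""),
    para_good
  )
  expect_true(title_only$supported)
  expect_identical(title_only$basis, "title")

  inconsistent <- scripted_text_llm(character(),
                                    default = "supported: yes | basis: none")
  expect_error(
    judge_support(inconsistent, list(pmid = "1", title = "t", abstract = ""),
                  "p"),
    class = "gslm_parse_error"
  )
})

test_that("cite_paragraph composes the five steps end to end", {
  backend <- citation_backend()
  pubmed <- canned_pubmed(citation_records())

  cites <- cite_paragraph(backend, pubmed, para_good)
  # top 3 by gene mentions: 1003, 1001, 1004; verdicts keep 1003 and 1001
  expect_length(cites, 2)
  expect_setequal(vapply(cites, `[[`, "", "pmid"), c("1001", "1003"))

  # paragraph with no genes -> unknown sentinel
  expect_true(is_unknown(cite_paragraph(backend, pubmed, para_nogenes)))

  # empty search result -> empty citation list, not an error
  empty_pm <- canned_pubmed()
  expect_length(cite_paragraph(backend, empty_pm, para_good), 0)

  # deterministic across reruns
  again <- cite_paragraph(backend, pubmed, para_good)
  expect_identical(cites, again)
})

test_that("cite_essay isolates per-paragraph failures", {
  backend <- scripted_text_llm(c(
    setNames("supported: yes | basis: both", "Retromer in sorting"),
    setNames("genes: SNX6 | keywords: sorting", "good paragraph"),
    setNames("total garbage", "bad paragraph")
  ))
  pubmed <- canned_pubmed(citation_records()[1, ])
  ann <- structure(
    list(name = "x", confidence = 0.9,
         paragraphs = c("good paragraph SNX6", "bad paragraph"),
         raw_response = "", model_id = "m"),
    class = "LLMAnnotation"
  )
  out <- cite_essay(backend, pubmed, ann)
  expect_length(out, 2)
  expect_length(out[[1]], 1)
  expect_identical(out[[1]][[1]]$pmid, "1001")
  expect_s3_class(out[[2]], "condition")  # failure isolated, essay completed
})
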