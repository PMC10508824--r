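test_that("parse_obo reads terms, edges, obsolete flags and namespace filters", {
  obo <- paste(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: parent", "namespace: biological_process", "",
    "[Term]", "id: GO:2", "name: child", "namespace: biological_process",
    "is_a: GO:1 ! parent", "",
    sep = "\n"
  )
  ont <- parse_obo(text = obo)
  expect_length(ont$terms, 2)
  expect_identical(ont$terms[["GO:2"]]$parents, "GO:1")
  expect_identical(ont$children[["GO:1"]], "GO:2")

  # obsolete: retained, flagged, no parents, excluded from sampling pools
  obo_obs <- paste(
    obo,
    "[Term]", "id: GO:3", "name: gone", "namespace: biological_process",
    "is_a: GO:1", "is_obsolete: true", "",
    sep = "\n"
  )
  ont2 <- attach_annotations(
    parse_obo(text = obo_obs),
    data.frame(term_id = c("GO:1", "GO:2", "GO:3"),
               gene = c("a", "b", "c"))
  )
  expect_true(ont2$terms[["GO:3"]]$obsolete)
  expect_length(ont2$terms[["GO:3"]]$parents, 0)
  expect_false("GO:3" %in% filter_and_sample_terms(ont2, 1, 10, n = 10))

  # 5-term mix of BP and MF, filtered to BP: hand count is 3
  obo_mix <- paste(
    "format-version: 1.2", "",
    "[Term]", "id: M:1", "name: bp one", "namespace: biological_process", "",
    "[Term]", "id: M:2", "name: bp two", "namespace: biological_process",
    "is_a: M:1", "",
    "[Term]", "id: M:3", "name: mf one", "namespace: molecular_function", "",
    "[Term]", "id: M:4", "name: bp three", "namespace: biological_process",
    "is_a: M:3", "",
    "[Term]", "id: M:5", "name: mf two", "namespace: molecular_function", "",
    sep = "\n"
  )
  bp <- parse_obo(text = obo_mix, namespace = "biological_process")
  expect_setequal(names(bp$terms), c("M:1", "M:2", "M:4"))
  # M:4's parent was filtered out with its branch
  expect_length(bp$terms[["M:4"]]$parents, 0)
})

test_that("parse_obo rejects malformed stanzas and cyclic graphs", {
  bad <- paste(
    "[Term]", "id: GO:1", "name: ok", "this line has no separator", "",
    sep = "\n"
  )
  expect_error(parse_obo(text = bad), class = "gslm_parse_error")
  expect_error(parse_obo(text = bad), "line 4")

  cyc <- paste(
    "[Term]", "id: GO:1", "name: a", "namespace: biological_process",
    "is_a: GO:2", "",
    "[Term]", "id: GO:2", "name: b", "namespace: biological_process",
    "is_a: GO:1", "",
    sep = "\n"
  )
  expect_error(parse_obo(text = cyc), class = "gslm_structure_error")
})

test_that("parse_obo follows part_of relationships by default, switchable", {
  obo <- paste(
    "[Term]", "id: GO:1", "name: whole", "namespace: biological_process", "",
    "[Term]", "id: GO:2", "name: part", "namespace: biological_process",
    "relationship: part_of GO:1 ! whole", "",
    "[Term]", "id: GO:3", "name: reg", "namespace: biological_process",
    "relationship: regulates GO:1", "",
    sep = "\n"
  )
  ont <- parse_obo(text = obo)
  expect_identical(ont$terms[["GO:2"]]$parents, "GO:1")
  expect_length(ont$terms[["GO:3"]]$parents, 0)  # regulates ignored
  ont_isa <- parse_obo(text = obo, relations = character())
  expect_length(ont_isa$terms[["GO:2"]]$parents, 0)
})

test_that("aggregate_genes unions direct annotations over descendants", {
  ont <- diamond_ontology()
  # single edge: parent {b from child}
  expect_identical(aggregate_genes(ont, "T:2"), c("b", "c"))
  # leaf: unchanged
  expect_identical(aggregate_genes(ont, "T:4"), "c")
  # diamond: grandchild's gene counted once at the top
  agg <- aggregate_genes(ont, "T:1")
  expect_identical(agg, oracle_aggregate(ont, "T:1"))
  expect_identical(sum(agg == "c"), 1L)
  expect_error(aggregate_genes(ont, "T:99"), class = "gslm_lookup_error")
})

test_that("aggregation matches the brute-force closure oracle on random DAGs", {
  for (seed in 1:5) {
    toy <- make_toy_ontology(
      n_terms = sample(5:30, 1), depth = sample(2:4, 1),
      genes_per_term = c(1L, 4L), seed = seed, agg_range = c(1L, 1000L)
    )
    ont <- toy$ontology
    for (id in names(ont$terms)) {
      expect_identical(aggregate_genes(ont, id), oracle_aggregate(ont, id))
    }
    # monotonicity along every edge
    for (tm in ont$terms) {
      for (p in tm$parents) {
        expect_true(all(
          aggregate_genes(ont, tm$term_id) %in% aggregate_genes(ont, p)
        ))
      }
    }
  }
})

test_that("filter_and_sample_terms respects inclusive bounds, seeds and exhaustion", {
  ont <- sized_ontology(c(2, 3, 100, 101))
  eligible <- filter_and_sample_terms(ont, 3, 100, n = 10)
  expect_setequal(eligible, c("S:2", "S:3"))
  expect_setequal(filter_and_sample_terms(ont, 3, 100, n = 2, seed = 99),
                  c("S:2", "S:3"))
  expect_identical(
    filter_and_sample_terms(ont, 2, 101, n = 1, seed = 42),
    filter_and_sample_terms(ont, 2, 101, n = 1, seed = 42)
  )
})

test_that("every eligible term is eventually sampled across seeds", {
  ont <- sized_ontology(rep(5, 10))
  hits <- unique(unlist(lapply(1:200, function(s) {
    filter_and_sample_terms(ont, 3, 100, n = 1, seed = s)
  })))
  expect_setequal(hits, names(ont$terms))
})

test_that("is_ancestor is proper transitive ancestry", {
  ont <- diamond_ontology()
  expect_true(is_ancestor(ont, "T:2", "T:4"))      # direct parent
  expect_false(is_ancestor(ont, "T:4", "T:4"))     # not its own ancestor
  expect_true(is_ancestor(ont, "T:1", "T:4"))      # grandparent, two paths
  expect_false(is_ancestor(ont, "T:4", "T:1"))     # direction matters
  expect_error(is_ancestor(ont, "T:9", "T:1"), class = "gslm_lookup_error")
  for (a in names(ont$terms)) {
    for (q in names(ont$terms)) {
      expect_identical(is_ancestor(ont, a, q), oracle_is_ancestor(ont, a, q))
    }
  }
})

test_that("read_annotations handles GAF and TSV, with evidence filtering", {
  gaf <- tempfile(fileext = ".gaf")
  writeLines(c(
    "!gaf-version: 2.2",
    paste("UniProt", "P1", "TP53", "", "GO:1", "PMID:1", "IDA",
          "", "P", "", "", "protein", "taxon:9606", "2023", "UniProt",
          sep = "\t"),
    paste("UniProt", "P2", "MDM2", "", "GO:1", "PMID:2", "IEA",
          "", "P", "", "", "protein", "taxon:9606", "2023", "UniProt",
          sep = "\t")
  ), gaf)
  df <- read_annotations(gaf, format = "gaf")
  expect_setequal(df$gene, c("TP53", "MDM2"))
  df_ida <- read_annotations(gaf, format = "gaf", evidence = "IDA")
  expect_identical(df_ida$gene, "TP53")

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("GO:1\tTP53", "GO:2\tBRCA1"), tsv)
  df2 <- read_annotations(tsv, format = "tsv")
  expect_identical(df2$term_id, c("GO:1", "GO:2"))

  ont <- sized_ontology(c(3, 3))
  expect_warning(
    attach_annotations(ont, data.frame(term_id = "NOPE:1", gene = "g")),
    "unknown terms"
  )
})
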