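# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's own traversal/counting code paths.

# A diamond DAG: C is reachable from GP via two paths (A and B).
diamond_ontology <- function() {
  obo <- paste(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: T:1",
    "name: grandparent",
    "namespace: biological_process",
    "",
    "[Term]",
    "id: T:2",
    "name: left child",
    "namespace: biological_process",
    "is_a: T:1",
    "",
    "[Term]",
    "id: T:3",
    "name: right child",
    "namespace: biological_process",
    "is_a: T:1",
    "",
    "[Term]",
    "id: T:4",
    "name: grandchild",
    "namespace: biological_process",
    "is_a: T:2",
    "is_a: T:3",
    "",
    sep = "\n"
  )
  ont <- parse_obo(text = obo)
  attach_annotations(ont, data.frame(
    term_id = c("T:1", "T:2", "T:3", "T:4"),
    gene = c("a", "b", "x", "c")
  ))
}

# Ontology with isolated terms whose aggregated sizes are exactly `sizes`.
sized_ontology <- function(sizes) {
  ids <- sprintf("S:%d", seq_along(sizes))
  stanzas <- vapply(ids, function(id) {
    paste("[Term]", paste0("id: ", id), paste0("name: term ", id),
          "namespace: biological_process", "", sep = "\n")
  }, "")
  ont <- parse_obo(text = paste(c("format-version: 1.2", "", stanzas),
                                collapse = "\n"))
  ann <- do.call(rbind, lapply(seq_along(sizes), function(i) {
    data.frame(term_id = ids[i],
               gene = sprintf("g%d_%d", i, seq_len(sizes[i])))
  }))
  attach_annotations(ont, ann)
}

# Independent reachability oracle: boolean matrix transitive closure over
# parent->child edges, then union of direct annotations.
oracle_aggregate <- function(ont, term_id) {
  ids <- names(ont$terms)
  n <- length(ids)
  M <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (tm in ont$terms) {
    for (p in tm$parents) M[p, tm$term_id] <- TRUE
  }
  R <- M | diag(n) > 0
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  reach <- ids[R[term_id, ]]
  sort(unique(unlist(ont$direct_annotations[reach], use.names = FALSE)))
}

# Independent ancestor oracle from the same closure matrix.
oracle_is_ancestor <- function(ont, candidate, query) {
  ids <- names(ont$terms)
  n <- length(ids)
  M <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (tm in ont$terms) {
    for (p in tm$parents) M[tm$term_id, p] <- TRUE  # child -> parent
  }
  R <- M
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R[query, candidate]
}

# Exhaustive hypergeometric upper tail from combinatorics only.
oracle_hypergeom <- function(overlap, term_size, query_size, universe) {
  ks <- seq(overlap, min(term_size, query_size))
  sum(choose(term_size, ks) * choose(universe - term_size, query_size - ks)) /
    choose(universe, query_size)
}

# Sort-based percentile oracle (unlike the counting implementation): the
# actual value takes the deepest position among its ties in the descending
# concatenated list, so tied background values do not count as "less
# similar".
oracle_percentile <- function(actual, background) {
  s <- sort(c(actual, background), decreasing = TRUE)
  pos <- max(which(s == actual))
  100 * (length(s) - pos) / length(background)
}

expect_same_ontology <- function(a, b) {
  expect_setequal(names(a$terms), names(b$terms))
  for (id in names(a$terms)) {
    expect_identical(a$terms[[id]]$name, b$terms[[id]]$name)
    expect_identical(a$terms[[id]]$namespace, b$terms[[id]]$namespace)
    expect_setequal(a$terms[[id]]$parents, b$terms[[id]]$parents)
    expect_identical(a$terms[[id]]$obsolete, b$terms[[id]]$obsolete)
  }
  expect_setequal(names(a$direct_annotations), names(b$direct_annotations))
  for (id in names(a$direct_annotations)) {
    expect_setequal(a$direct_annotations[[id]], b$direct_annotations[[id]])
  }
}

# Script a toy ontology so the backend echoes each term's curated name at a
# given confidence.
echo_script <- function(ont, term_ids, confidence = 0.95) {
  script <- list()
  for (id in term_ids) {
    script <- script_response(
      script, aggregate_genes(ont, id),
      name = term_name(ont, id), confidence = confidence
    )
  }
  script
}
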