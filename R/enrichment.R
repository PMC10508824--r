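# Native functional-enrichment baseline: one-sided hypergeometric
# over-representation test per term, Benjamini-Hochberg correction across
# tested terms, Jaccard index as effect size, and the annotation decision
# (adjusted p <= alpha and best JI >= min_ji).

#' Upper-tail hypergeometric p-value
#'
#' `P(X >= overlap)` for the overlap between a query of `query_size` genes and
#' a term of `term_size` genes drawn from a universe of `universe` genes.
#'
#' @param overlap observed overlap count.
#' @param term_size number of universe genes annotated to the term.
#' @param query_size number of query genes in the universe.
#' @param universe universe size.
#' @return p-value in `(0, 1]`; `overlap = 0` gives exactly 1.
#' @export
hypergeometric_pvalue <- function(overlap, term_size, query_size, universe) {
  if (term_size > universe || query_size > universe ||
      overlap > min(term_size, query_size) || overlap < 0 ||
      overlap < term_size + query_size - universe) {
    gslm_stop("impossible hypergeometric configuration", "gslm_argument_error")
  }
  stats::phyper(overlap - 1, term_size, universe - term_size, query_size,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Native implementation of the standard FDR step-up procedure: sorted
#' p-values are scaled by `m / rank` and a running minimum from the largest
#' rank downward enforces monotonicity; results are capped at 1 and returned
#' in input order.
#'
#' @param p_values numeric vector with all values in `(0, 1]`.
#' @return adjusted p-values, order-aligned with the input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    gslm_stop("p-values must lie in (0, 1]", "gslm_argument_error")
  }
  m <- length(p_values)
  o <- order(p_values)
  ranked <- p_values[o] * m / seq_len(m)
  adjusted <- rev(cummin(rev(ranked)))
  adjusted <- pmin(adjusted, 1)
  out <- numeric(m)
  out[o] <- adjusted
  out
}

#' Jaccard index between two gene sets
#'
#' @param a,b [GeneSet][gene_set]s or character vectors; both non-empty.
#' @return `|A intersect B| / |A union B|`.
#' @export
jaccard <- function(a, b) {
  a <- unique(as_genes(a))
  b <- unique(as_genes(b))
  stopifnot(length(a) > 0, length(b) > 0)
  length(intersect(a, b)) / length(union(a, b))
}

#' Enrich a query gene set against a term library and decide annotation
#'
#' The query is restricted to the universe (default: the union of all library
#' genes) before testing. Every library term sharing at least one gene with
#' the query is tested with [hypergeometric_pvalue()]; BH correction runs
#' across all tested terms. Among significant terms (adjusted p <= `alpha`)
#' the best is the one with the largest Jaccard index (ties broken by smaller
#' adjusted p, then lexicographic term id) and the query is `annotated` when
#' that best JI is at least `min_ji`.
#'
#' @param query a [GeneSet][gene_set] or character vector.
#' @param library named list, term id -> gene vector (e.g.
#'   [ontology_library()] or a parsed GMT).
#' @param universe background gene vector; default is the library union.
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param min_ji minimum Jaccard index for annotation (default 0.1).
#' @return list with `results` (data.frame ordered by adjusted p then term
#'   id), `annotated` (logical), `best` (one-row data.frame or `NULL`).
#' @export
enrich_and_decide <- function(query, library, universe = NULL,
                              alpha = 0.05, min_ji = 0.1) {
  stopifnot(length(library) > 0, !is.null(names(library)))
  query_genes <- unique(as_genes(query))
  if (is.null(universe)) {
    universe <- unique(unlist(library, use.names = FALSE))
  } else {
    universe <- unique(as_genes(universe))
  }
  query_genes <- intersect(query_genes, universe)
  if (!length(query_genes)) {
    gslm_stop("query has no genes in the universe", "gslm_argument_error")
  }
  lib <- lapply(library, function(g) intersect(unique(g), universe))
  overlaps <- vapply(lib, function(g) length(intersect(g, query_genes)), 0L)
  tested <- names(lib)[overlaps > 0 & lengths(lib) > 0]
  if (!length(tested)) {
    return(list(
      results = empty_enrichment(), annotated = FALSE, best = NULL
    ))
  }
  n_universe <- length(universe)
  rows <- lapply(tested, function(id) {
    ts <- length(lib[[id]])
    ov <- overlaps[[id]]
    data.frame(
      term_id = id,
      p_value = hypergeometric_pvalue(ov, ts, length(query_genes), n_universe),
      overlap = ov,
      term_size = ts,
      query_size = length(query_genes),
      jaccard = ov / (ts + length(query_genes) - ov)
    )
  })
  res <- do.call(rbind, rows)
  res$adjusted_p <- benjamini_hochberg(res$p_value)
  res <- res[order(res$adjusted_p, res$p_value, res$term_id), ]
  res <- res[, c("term_id", "p_value", "adjusted_p", "overlap",
                 "term_size", "query_size", "jaccard")]
  rownames(res) <- NULL
  sig <- res[res$adjusted_p <= alpha, , drop = FALSE]
  best <- NULL
  if (nrow(sig)) {
    sig <- sig[order(-sig$jaccard, sig$adjusted_p, sig$term_id), ]
    best <- sig[1, , drop = FALSE]
    rownames(best) <- NULL
  }
  list(
    results = res,
    annotated = !is.null(best) && best$jaccard >= min_ji,
    best = best
  )
}

empty_enrichment <- function() {
  data.frame(
    term_id = character(), p_value = numeric(), adjusted_p = numeric(),
    overlap = integer(), term_size = integer(), query_size = integer(),
    jaccard = numeric()
  )
}
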