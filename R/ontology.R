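#' Ontology container
#'
#' An `Ontology` holds the term DAG parsed from an OBO file plus direct
#' gene annotations. Terms are stored as a named list of records
#' (`term_id`, `name`, `namespace`, `parents`, `obsolete`); `children` is the
#' reverse adjacency used for descendant traversal; `direct_annotations` maps
#' term ids to character vectors of gene symbols.
#'
#' @param terms named list of term records.
#' @param direct_annotations named list, term id -> character vector of genes.
#' @return an object of class `Ontology`.
#' @keywords internal
new_ontology <- function(terms, direct_annotations = list()) {
  children <- list()
  for (tm in terms) {
    for (p in tm$parents) {
      children[[p]] <- c(children[[p]], tm$term_id)
    }
  }
  structure(
    list(
      terms = terms,
      children = children,
      direct_annotations = direct_annotations
    ),
    class = "Ontology"
  )
}

#' @export
print.Ontology <- function(x, ...) {
  ns <- table(vapply(x$terms, `[[`, "", "namespace"))
  obs <- sum(vapply(x$terms, `[[`, FALSE, "obsolete"))
  cat(sprintf(
    "<Ontology> %d terms (%d obsolete), %d annotated, namespaces: %s\n",
    length(x$terms), obs, length(x$direct_annotations),
    paste(sprintf("%s=%d", names(ns), ns), collapse = ", ")
  ))
  invisible(x)
}

term_ids <- function(ont) names(ont$terms)

term_exists <- function(ont, term_id) term_id %in% names(ont$terms)

assert_term <- function(ont, term_id) {
  if (!term_exists(ont, term_id)) {
    gslm_stop(sprintf("unknown term id '%s'", term_id), "gslm_lookup_error")
  }
}

#' Parse an OBO 1.2/1.4 ontology file
#'
#' Reads `[Term]` stanzas, keeping `is_a` and (by default) `part_of`
#' relationship edges as parent links. Obsolete terms are retained with
#' `obsolete = TRUE` but stripped of parents; they are excluded from sampling
#' pools and calibration corpora downstream. Edges pointing at terms dropped
#' by the namespace filter (or otherwise unknown) are discarded.
#'
#' @param file path to an OBO file.
#' @param text OBO document as a single string or character vector of lines
#'   (alternative to `file`).
#' @param namespace optional branch filter, e.g. `"biological_process"`.
#' @param relations relationship types treated as parent edges in addition to
#'   `is_a`. Default follows standard GO practice (`part_of`).
#' @return an [Ontology][new_ontology] with empty annotations; see
#'   [attach_annotations()].
#' @export
parse_obo <- function(file = NULL, text = NULL, namespace = NULL,
                      relations = "part_of") {
  if (is.null(text)) {
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  terms <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur, terms) {
    if (is.null(cur) || is.null(cur$term_id)) return(terms)
    if (cur$obsolete) cur$parents <- character()
    cur$parents <- unique(cur$parents)
    terms[[cur$term_id]] <- cur
    terms
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "!")) next
    if (startsWith(ln, "[")) {
      terms <- flush(cur, terms)
      cur <- NULL
      in_term <- identical(ln, "[Term]")
      if (in_term) {
        cur <- list(
          term_id = NULL, name = NA_character_,
          namespace = NA_character_, parents = character(),
          obsolete = FALSE
        )
      }
      next
    }
    if (!in_term) next
    colon <- regexpr(":", ln, fixed = TRUE)
    if (colon < 0) {
      gslm_stop(
        sprintf("malformed OBO stanza line %d: '%s'", i, ln),
        "gslm_parse_error"
      )
    }
    key <- substr(ln, 1, colon - 1)
    val <- trimws(substr(ln, colon + 1, nchar(ln)))
    # strip trailing "! name" comments
    val <- trimws(sub("\\s!\\s.*$", "", val))
    if (key == "id") {
      cur$term_id <- val
    } else if (key == "name") {
      cur$name <- val
    } else if (key == "namespace") {
      cur$namespace <- val
    } else if (key == "is_a") {
      cur$parents <- c(cur$parents, val)
    } else if (key == "relationship") {
      parts <- strsplit(val, "[[:space:]]+")[[1]]
      if (length(parts) >= 2 && parts[1] %in% relations) {
        cur$parents <- c(cur$parents, parts[2])
      }
    } else if (key == "is_obsolete") {
      cur$obsolete <- identical(tolower(val), "true")
    }
  }
  terms <- flush(cur, terms)
  if (!is.null(namespace)) {
    keep <- vapply(
      terms,
      function(tm) identical(tm$namespace, namespace), FALSE
    )
    terms <- terms[keep]
  }
  # drop edges into unknown/filtered terms
  known <- names(terms)
  terms <- lapply(terms, function(tm) {
    tm$parents <- tm$parents[tm$parents %in% known]
    tm
  })
  ont <- new_ontology(terms)
  check_acyclic(ont)
  ont
}

# Kahn topological sort over child->parent edges; cycles are a structural
# error because descendant aggregation would not terminate meaningfully.
check_acyclic <- function(ont) {
  indeg <- vapply(ont$terms, function(tm) length(tm$parents), 0L)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    id <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in ont$children[[id]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ont$terms)) {
    gslm_stop("ontology parent graph contains a cycle", "gslm_structure_error")
  }
  invisible(ont)
}

#' Read term-gene annotations
#'
#' Supports GAF 2.1/2.2 (tab-separated, `!` comment lines, column 3 = gene
#' symbol, column 5 = term id, column 7 = evidence code) and a two-column
#' TSV fallback (`term_id<TAB>gene_symbol`).
#'
#' @param file path to the annotation file.
#' @param format `"gaf"` or `"tsv"`.
#' @param evidence optional character vector of GAF evidence codes to keep
#'   (default keeps everything; the reference pipeline applied no filter).
#' @return data.frame with columns `term_id`, `gene`.
#' @export
read_annotations <- function(file, format = c("gaf", "tsv"), evidence = NULL) {
  format <- match.arg(format)
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (!length(lines)) {
    return(data.frame(term_id = character(), gene = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "gaf") {
    bad <- which(lengths(fields) < 7)
    if (length(bad)) {
      gslm_stop(
        sprintf("GAF line %d has fewer than 7 columns", bad[1]),
        "gslm_format_error"
      )
    }
    df <- data.frame(
      term_id = vapply(fields, `[[`, "", 5),
      gene = vapply(fields, `[[`, "", 3),
      evidence = vapply(fields, `[[`, "", 7)
    )
    if (!is.null(evidence)) df <- df[df$evidence %in% evidence, , drop = FALSE]
    df$evidence <- NULL
  } else {
    bad <- which(lengths(fields) < 2)
    if (length(bad)) {
      gslm_stop(
        sprintf("annotation TSV line %d has fewer than 2 columns", bad[1]),
        "gslm_format_error"
      )
    }
    df <- data.frame(
      term_id = vapply(fields, `[[`, "", 1),
      gene = vapply(fields, `[[`, "", 2)
    )
  }
  df$gene <- trimws(df$gene)
  df <- df[nzchar(df$gene) & nzchar(df$term_id), , drop = FALSE]
  unique(df)
}

#' Attach direct annotations to an ontology
#'
#' @param ont an [Ontology][new_ontology].
#' @param annotations data.frame with columns `term_id`, `gene` (as returned
#'   by [read_annotations()]). Rows whose term id is not in the ontology are
#'   dropped with a warning.
#' @return the ontology with `direct_annotations` populated.
#' @export
attach_annotations <- function(ont, annotations) {
  stopifnot(inherits(ont, "Ontology"))
  known <- annotations$term_id %in% names(ont$terms)
  if (any(!known)) {
    gslm_warn(sprintf(
      "%d annotation rows reference unknown terms and were dropped",
      sum(!known)
    ))
    annotations <- annotations[known, , drop = FALSE]
  }
  ann <- split(annotations$gene, annotations$term_id)
  ont$direct_annotations <- lapply(
    ann,
    function(g) sort(clean_genes(g, warn_dups = FALSE))
  )
  ont
}

# All descendants of a term (excluding itself), via the children map.
descendants <- function(ont, term_id) {
  out <- character()
  queue <- ont$children[[term_id]] %||% character()
  while (length(queue)) {
    id <- queue[[1]]
    queue <- queue[-1]
    if (id %in% out) next
    out <- c(out, id)
    queue <- c(queue, ont$children[[id]] %||% character())
  }
  out
}

#' Aggregate the effective gene set of a term
#'
#' A term's gene set is the union of its direct annotations with those of all
#' its ontological descendants (is_a plus whichever relations were kept at
#' parse time), deduplicated and sorted for deterministic serialization.
#'
#' @param ont an [Ontology][new_ontology] with annotations attached.
#' @param term_id term curie.
#' @return sorted character vector of gene symbols.
#' @export
aggregate_genes <- function(ont, term_id) {
  assert_term(ont, term_id)
  ids <- c(term_id, descendants(ont, term_id))
  sort(unique(unlist(ont$direct_annotations[ids], use.names = FALSE)))
}

#' Filter terms by aggregated size and sample
#'
#' Eligible terms are non-obsolete and have an aggregated gene-set size within
#' `[min_size, max_size]` (inclusive). A uniform sample without replacement of
#' `n` term ids is drawn reproducibly under `seed`; if fewer terms are
#' eligible than `n`, all eligible terms are returned.
#'
#' @param ont an [Ontology][new_ontology].
#' @param min_size,max_size inclusive aggregated-size bounds (defaults 3 and
#'   100, the band used for term selection).
#' @param n number of terms to sample.
#' @param seed integer RNG seed.
#' @return character vector of term ids.
#' @export
filter_and_sample_terms <- function(ont, min_size = 3L, max_size = 100L,
                                    n, seed = 42L) {
  stopifnot(min_size <= max_size, n >= 0)
  pool <- sort(names(ont$terms))
  pool <- pool[!vapply(ont$terms[pool], `[[`, FALSE, "obsolete")]
  sizes <- vapply(pool, function(id) length(aggregate_genes(ont, id)), 0L)
  eligible <- pool[sizes >= min_size & sizes <= max_size]
  if (length(eligible) <= n) {
    return(eligible)
  }
  withr::with_seed(seed, sample(eligible, n))
}

#' Test proper ancestry between two terms
#'
#' @param ont an [Ontology][new_ontology].
#' @param candidate,query term curies.
#' @return `TRUE` iff `candidate` is reachable from `query` via parent edges.
#'   A term is not its own ancestor.
#' @export
is_ancestor <- function(ont, candidate, query) {
  assert_term(ont, candidate)
  assert_term(ont, query)
  seen <- character()
  queue <- ont$terms[[query]]$parents
  while (length(queue)) {
    id <- queue[[1]]
    queue <- queue[-1]
    if (id == candidate) return(TRUE)
    if (id %in% seen) next
    seen <- c(seen, id)
    queue <- c(queue, ont$terms[[id]]$parents)
  }
  FALSE
}

#' Term name lookup
#' @param ont an [Ontology][new_ontology].
#' @param term_id term curie.
#' @return the term's name string.
#' @export
term_name <- function(ont, term_id) {
  assert_term(ont, term_id)
  ont$terms[[term_id]]$name
}

#' Pool of all annotated genes
#'
#' Union of every direct annotation in the ontology; the background pool from
#' which contaminated and random benchmark sets draw genes.
#'
#' @param ont an [Ontology][new_ontology].
#' @return sorted character vector of gene symbols.
#' @export
annotation_pool <- function(ont) {
  sort(unique(unlist(ont$direct_annotations, use.names = FALSE)))
}

#' Build an enrichment library from an ontology
#'
#' @param ont an [Ontology][new_ontology].
#' @param term_ids terms to include (default: all non-obsolete terms with at
#'   least one aggregated gene).
#' @return named list, term id -> aggregated gene vector.
#' @export
ontology_library <- function(ont, term_ids = NULL) {
  if (is.null(term_ids)) {
    term_ids <- sort(names(ont$terms))
    term_ids <- term_ids[!vapply(ont$terms[term_ids], `[[`, FALSE, "obsolete")]
  }
  lib <- lapply(term_ids, function(id) aggregate_genes(ont, id))
  names(lib) <- term_ids
  lib[lengths(lib) > 0]
}
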