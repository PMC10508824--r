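# Deterministic test scaffolding: seeded toy ontologies that round-trip
# through OBO/TSV files, and scripted LLM backends keyed on gene-list
# fingerprints so end-to-end runs are reproducible with zero network access.

#' Generate a toy ontology
#'
#' Builds a seeded random DAG of `n_terms` terms over `depth` levels (every
#' non-root term has one or two parents in the previous level), assigns each
#' term a direct gene set drawn from a shared pool, and verifies that every
#' term's aggregated size falls within `agg_range`. Optionally writes a
#' loadable OBO file and annotation TSV whose re-parse equals the in-memory
#' object.
#'
#' @param n_terms number of terms (>= 1).
#' @param depth number of DAG levels.
#' @param genes_per_term length-2 range of direct genes per term.
#' @param seed integer seed; the construction is bit-reproducible.
#' @param agg_range acceptable aggregated-size band (default 3-100);
#'   violation is an error (infeasible constraints).
#' @param dir if non-NULL, writes `toy.obo` and `toy_annotations.tsv` there.
#' @param namespace branch label given to every term.
#' @return list with `ontology`, `obo` (path or NULL), `annotations`
#'   (path or NULL).
#' @export
make_toy_ontology <- function(n_terms = 12L, depth = 3L,
                              genes_per_term = c(3L, 10L), seed = 7L,
                              agg_range = c(3L, 100L), dir = NULL,
                              namespace = "biological_process") {
  stopifnot(n_terms >= 1, depth >= 1, length(genes_per_term) == 2)
  ids <- sprintf("TOY:%07d", seq_len(n_terms))
  # a gene pool much larger than any term's draw, so the annotated-gene
  # background dwarfs individual aggregates (as in a real branch) and the
  # contamination benchmark always has contaminants to draw from
  pool <- sprintf("GENE%05d",
                  seq_len(max(500L, 20L * n_terms * genes_per_term[2])))
  ont <- withr::with_seed(seed, {
    # terms spread evenly over levels and partitioned into disjoint root
    # "families": parents are drawn within the family's previous level, so
    # every root's subtree (and hence every aggregate) stays a small
    # fraction of the annotation pool — mirroring a real branch, where the
    # background of all annotated genes dwarfs any size-banded term
    levels <- sort(rep_len(seq_len(depth), n_terms))
    n_roots <- sum(levels == 1L)
    family <- integer(n_terms)
    family[levels == 1L] <- seq_len(n_roots)
    family[levels > 1L] <- rep_len(seq_len(n_roots), n_terms - n_roots)
    terms <- list()
    for (i in seq_len(n_terms)) {
      parents <- character()
      if (levels[i] > 1L) {
        prev <- which(family == family[i] & levels == levels[i] - 1L)
        if (!length(prev)) {
          prev <- which(family == family[i] & levels < levels[i])
        }
        candidates <- ids[prev]
        n_par <- min(length(candidates), sample(1:2, 1))
        parents <- sample(candidates, n_par)
      }
      terms[[ids[i]]] <- list(
        term_id = ids[i],
        name = paste("toy process", paste0("alpha", i), paste0("beta", i)),
        namespace = namespace,
        parents = sort(parents),
        obsolete = FALSE
      )
    }
    ann <- lapply(seq_len(n_terms), function(i) {
      sort(sample(pool, sample(genes_per_term[1]:genes_per_term[2], 1)))
    })
    names(ann) <- ids
    o <- new_ontology(terms, ann)
    o
  })
  sizes <- vapply(ids, function(id) length(aggregate_genes(ont, id)), 0L)
  if (any(sizes < agg_range[1] | sizes > agg_range[2])) {
    gslm_stop(
      sprintf(
        "infeasible size constraints: aggregated sizes span %d-%d, band is %d-%d",
        min(sizes), max(sizes), agg_range[1], agg_range[2]
      ),
      "gslm_argument_error"
    )
  }
  obo_path <- NULL
  ann_path <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    obo_path <- file.path(dir, "toy.obo")
    ann_path <- file.path(dir, "toy_annotations.tsv")
    write_obo(ont, obo_path)
    write_annotations_tsv(ont, ann_path)
  }
  list(ontology = ont, obo = obo_path, annotations = ann_path)
}

#' Serialize an ontology to OBO
#'
#' All parent links are written as `is_a` edges (the in-memory model merges
#' the relation types kept at parse time into one parent list).
#'
#' @param ont an [Ontology][new_ontology].
#' @param path output path.
#' @export
write_obo <- function(ont, path) {
  lines <- c("format-version: 1.2", "")
  for (id in sort(names(ont$terms))) {
    tm <- ont$terms[[id]]
    lines <- c(
      lines, "[Term]",
      paste0("id: ", tm$term_id),
      paste0("name: ", tm$name),
      paste0("namespace: ", tm$namespace),
      if (tm$obsolete) "is_obsolete: true",
      paste0("is_a: ", sort(tm$parents)),
      ""
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Serialize direct annotations to a two-column TSV
#'
#' @param ont an [Ontology][new_ontology].
#' @param path output path.
#' @export
write_annotations_tsv <- function(ont, path) {
  lines <- unlist(lapply(sort(names(ont$direct_annotations)), function(id) {
    paste(id, sort(ont$direct_annotations[[id]]), sep = "\t")
  }))
  writeLines(lines %||% character(), path)
  invisible(path)
}

#' Scripted LLM backend keyed on gene-list fingerprints
#'
#' The backend extracts the gene list from the terminal `Proteins:` line of
#' the prompt, fingerprints it with [gene_fingerprint()], and returns the
#' scripted response for that fingerprint. Unknown fingerprints yield the
#' zero-confidence refusal sentinel, so tests can probe unscripted sets.
#' Fingerprinting the gene list rather than the whole prompt means editing
#' the prompt template does not invalidate a script.
#'
#' @param script named character vector or list mapping fingerprints to
#'   response texts (see [script_response()]).
#' @param default response for unknown fingerprints.
#' @param model_id backend identifier.
#' @return an [llm_backend()] with a `$calls` environment counting backend
#'   invocations (for cache tests).
#' @export
scripted_llm <- function(script = character(),
                         default = paste0("Process: ", unrelated_sentinel,
                                          " (0.00)"),
                         model_id = "scripted") {
  script <- as.list(script)
  calls <- new.env(parent = emptyenv())
  calls$n <- 0L
  backend <- llm_backend(model_id, function(prompt, temperature, seed,
                                            max_tokens) {
    calls$n <- calls$n + 1L
    lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
    protein_lines <- grep("^Proteins:", lines, value = TRUE)
    if (!length(protein_lines)) {
      gslm_stop("scripted backend: no 'Proteins:' line in prompt",
                "gslm_backend_error")
    }
    listed <- sub("^Proteins:\\s*", "", protein_lines[length(protein_lines)])
    genes <- trimws(strsplit(listed, ",", fixed = TRUE)[[1]])
    fp <- gene_fingerprint(genes)
    script[[fp]] %||% default
  })
  backend$calls <- calls
  backend
}

#' Add a scripted response for a gene set
#'
#' @param script existing script (named list/vector).
#' @param genes gene symbols the response is for.
#' @param response response text, or use `name`/`confidence` to format a
#'   standard header.
#' @param name,confidence convenience: builds
#'   `"Process: <name> (<confidence>)"` when `response` is missing.
#' @return the updated script.
#' @export
script_response <- function(script, genes, response = NULL, name = NULL,
                            confidence = NULL) {
  if (is.null(response)) {
    response <- sprintf("Process: %s (%s)", name,
                        formatC(confidence, format = "f", digits = 2))
  }
  script[[gene_fingerprint(genes)]] <- response
  script
}

#' Scripted text backend keyed on prompt substrings
#'
#' Returns the response whose key (a literal substring, e.g. the paragraph a
#' prompt embeds) occurs in the prompt; first match in key order wins. Used
#' to script the keyword-extraction and support-judgment calls of the
#' citation module.
#'
#' @param responses named character vector: substring -> reply.
#' @param default reply when no key matches (error if NULL).
#' @param model_id backend identifier.
#' @return an [llm_backend()].
#' @export
scripted_text_llm <- function(responses, default = NULL,
                              model_id = "scripted-text") {
  llm_backend(model_id, function(prompt, temperature, seed, max_tokens) {
    for (key in names(responses)) {
      if (grepl(key, prompt, fixed = TRUE)) return(responses[[key]])
    }
    if (is.null(default)) {
      gslm_stop("scripted text backend: no key matches the prompt",
                "gslm_backend_error")
    }
    default
  })
}
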