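# Embedding backends implement:
#   backend$id           : string identifying the embedder
#   backend$embed(texts) -> numeric matrix, one row per input text
# The same text must always map to the same vector and all vectors share one
# fixed dimension. A biomedical sentence encoder (e.g. SapBERT) plugs in here
# for real runs; tests use the deterministic hash-bag mock.

#' Construct an embedding backend
#'
#' @param id string identifying the embedder.
#' @param embed function mapping a character vector to a numeric matrix with
#'   one row per text.
#' @return object of class `embedding_backend`.
#' @export
embedding_backend <- function(id, embed) {
  stopifnot(is.character(id), is.function(embed))
  structure(list(id = id, embed = embed), class = "embedding_backend")
}

#' Hash-bag mock embedder
#'
#' Deterministic test double for a sentence encoder: texts are lowercased,
#' split on non-alphanumerics, and each token increments a hashed bucket of a
#' fixed-dimension bag vector. Identical strings therefore embed identically
#' (cosine exactly 1) and strings with disjoint tokens are orthogonal up to
#' hash collisions (negligible at `dim = 512` and test vocabulary sizes).
#'
#' @param dim vector dimension.
#' @return an [embedding_backend()].
#' @export
hash_embedder <- function(dim = 512L) {
  dim <- as.integer(dim)
  stopifnot(dim > 0)
  embedding_backend(sprintf("hash-bag-%d", dim), function(texts) {
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(texts)) {
      tokens <- strsplit(tolower(texts[i]), "[^a-z0-9]+")[[1]]
      tokens <- tokens[nzchar(tokens)]
      for (tok in tokens) {
        # low-order digest digits: the rolling hash is near-sequential for
        # strings differing only in their final character, so the high-order
        # digits would alias such tokens into one bucket
        bucket <- (strtoi(substr(gslm_digest(tok), 10, 16), 16L) %% dim) + 1L
        out[i, bucket] <- out[i, bucket] + 1
      }
    }
    out
  })
}

#' Fixed-vector mock embedder
#'
#' Maps an explicit table of texts to explicit vectors; unknown texts are an
#' error. Used to test cosine arithmetic against closed-form values.
#'
#' @param vectors named list of equal-length numeric vectors.
#' @return an [embedding_backend()].
#' @export
fixed_embedder <- function(vectors) {
  stopifnot(length(unique(lengths(vectors))) == 1)
  embedding_backend("fixed", function(texts) {
    missing <- setdiff(texts, names(vectors))
    if (length(missing)) {
      gslm_stop(
        sprintf("fixed embedder has no vector for: %s",
                paste(missing, collapse = ", ")),
        "gslm_lookup_error"
      )
    }
    do.call(rbind, vectors[texts])
  })
}

#' Disk-memoised wrapper around an embedding backend
#'
#' Caches one JSON vector per text, keyed by embedder id + text digest, so a
#' branch-wide name corpus is embedded once per model.
#'
#' @param backend an [embedding_backend()].
#' @param dir cache directory.
#' @return an [embedding_backend()] with the same id.
#' @export
cached_embedder <- function(backend, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  embedding_backend(backend$id, function(texts) {
    paths <- file.path(
      dir, paste0(gslm_digest(backend$id), "-",
                  vapply(texts, gslm_digest, ""), ".json")
    )
    have <- file.exists(paths)
    rows <- vector("list", length(texts))
    for (i in which(have)) {
      rows[[i]] <- tryCatch(
        as.numeric(unlist(jsonlite::read_json(paths[i]))),
        error = function(e) NULL
      )
    }
    todo <- which(vapply(rows, is.null, FALSE))
    if (length(todo)) {
      fresh <- backend$embed(texts[todo])
      for (j in seq_along(todo)) {
        rows[[todo[j]]] <- fresh[j, ]
        jsonlite::write_json(fresh[j, ], paths[todo[j]], digits = NA)
      }
    }
    do.call(rbind, rows)
  })
}

cosine <- function(a, b) {
  if (identical(a, b)) {
    if (sum(a * a) == 0) {
      gslm_stop("zero-norm embedding vector", "gslm_numeric_error")
    }
    return(1.0)
  }
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) {
    gslm_stop("zero-norm embedding vector", "gslm_numeric_error")
  }
  sum(a * b) / (na * nb)
}

#' Semantic similarity between two names
#'
#' Cosine similarity of the two embedding vectors. Symmetric; identical
#' strings score exactly 1.
#'
#' @param backend an [embedding_backend()].
#' @param a,b non-empty name strings.
#' @return similarity in `[-1, 1]` (non-negative for bag embeddings).
#' @export
name_similarity <- function(backend, a, b) {
  stopifnot(nzchar(a), nzchar(b))
  emb <- backend$embed(c(a, b))
  cosine(emb[1, ], emb[2, ])
}

#' Percentile rank of a similarity against a background
#'
#' The percentage of background values strictly less than the actual value:
#' `100 * #\{b < actual\} / length(background)`. Ties do not count toward the
#' percentile.
#'
#' @param actual observed similarity.
#' @param background non-empty numeric vector of background similarities.
#' @return percentile in `[0, 100]`.
#' @export
percentile_rank <- function(actual, background) {
  stopifnot(length(background) > 0)
  100 * sum(background < actual) / length(background)
}

#' Calibrate a proposed name against a branch's name corpus
#'
#' Embeds the proposed name and every non-obsolete term name in the target
#' term's branch. The similarity to the target's own name is the actual
#' score; similarities to every *other* name form the background for
#' [percentile_rank()]; the best-matching corpus term (target included in the
#' pool) is recorded for the generalization check.
#'
#' @param backend an [embedding_backend()].
#' @param llm_name the LLM-proposed name.
#' @param target_term curie of the term whose gene set was analysed.
#' @param ont an [Ontology][new_ontology].
#' @return object of class `CalibratedSimilarity` with fields `llm_name`,
#'   `target_term`, `target_name`, `score`, `percentile`, `best_match_term`,
#'   `best_match_name`, `best_match_score`, `category` (`NA` until
#'   [classify_naming()]).
#' @export
calibrate <- function(backend, llm_name, target_term, ont) {
  assert_term(ont, target_term)
  branch <- ont$terms[[target_term]]$namespace
  ids <- sort(names(ont$terms))
  keep <- vapply(ont$terms[ids], function(tm) {
    identical(tm$namespace, branch) && !tm$obsolete
  }, FALSE)
  ids <- ids[keep]
  if (length(ids) < 2) {
    gslm_stop(
      sprintf("branch '%s' has no background corpus beyond the target",
              branch),
      "gslm_structure_error"
    )
  }
  corpus_names <- vapply(ont$terms[ids], `[[`, "", "name")
  emb <- backend$embed(c(llm_name, corpus_names))
  q <- emb[1, ]
  sims <- vapply(seq_along(ids), function(i) cosine(q, emb[i + 1, ]), 0)
  target_idx <- match(target_term, ids)
  score <- sims[target_idx]
  background <- sims[-target_idx]
  best_idx <- which.max(sims)
  structure(
    list(
      llm_name = llm_name,
      target_term = target_term,
      target_name = corpus_names[target_idx],
      score = score,
      percentile = percentile_rank(score, background),
      best_match_term = ids[best_idx],
      best_match_name = corpus_names[best_idx],
      best_match_score = sims[best_idx],
      category = NA_character_
    ),
    class = "CalibratedSimilarity"
  )
}

#' @export
print.CalibratedSimilarity <- function(x, ...) {
  cat(sprintf(
    "<CalibratedSimilarity> '%s' vs %s ('%s'): score %.3f, percentile %.1f, best match %s\n",
    x$llm_name, x$target_term, x$target_name, x$score, x$percentile,
    x$best_match_term
  ))
  invisible(x)
}

naming_categories <- c("recovered", "generalized", "other", "not_named")

#' Classify a naming outcome
#'
#' * `not_named` — the annotation carried confidence 0 (refusal sentinel);
#' * `recovered` — percentile at or above the threshold (default 95th);
#' * `generalized` — otherwise, the best-matching corpus name belongs to a
#'   proper ancestor of the target term;
#' * `other` — everything else.
#'
#' @param result a [calibrate()]d similarity.
#' @param annotation the `LLMAnnotation` that proposed the name.
#' @param ont the [Ontology][new_ontology] used for calibration.
#' @param threshold percentile threshold for recovery (default 95).
#' @return the `result` with `category` filled in.
#' @export
classify_naming <- function(result, annotation, ont, threshold = 95) {
  stopifnot(inherits(result, "CalibratedSimilarity"))
  result$category <- if (annotation$confidence == 0) {
    "not_named"
  } else if (result$percentile >= threshold) {
    "recovered"
  } else if (is_ancestor(ont, result$best_match_term, result$target_term)) {
    "generalized"
  } else {
    "other"
  }
  result
}
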