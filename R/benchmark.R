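# Confidence benchmark: probe the LLM's self-confidence with three gene-set
# conditions per term — "real" (the term's full aggregated set), "mix5050"
# (half term genes, half background contaminants) and "random" (all genes
# drawn from the annotation-wide background pool) — then bin the reported
# confidence scores and compare the condition-wise distributions.

benchmark_conditions <- c("real", "mix5050", "random")
confidence_bins <- c("high", "medium", "low", "not_assigned")

#' Build a contaminated benchmark gene set
#'
#' Keeps `floor(fraction * n)` genes sampled from the origin term's gene set
#' and fills the remaining `n - floor(fraction * n)` slots with contaminants
#' sampled from `pool` excluding the term's genes, so the stated
#' contamination fraction is exact. `fraction = 1` returns the full term set
#' ("real"); `fraction = 0` samples all `n` genes from the full pool (term
#' genes may re-enter by chance — the "random" condition).
#'
#' @param term_genes the origin term's aggregated gene vector.
#' @param pool background pool of all annotated genes.
#' @param fraction fraction of genes kept from the term (default 0.5).
#' @param seed integer RNG seed.
#' @param origin_term optional curie recorded on the result.
#' @return object of class `BenchmarkSet` with fields `origin_term`,
#'   `condition`, `genes`, `seed`.
#' @export
make_contaminated_set <- function(term_genes, pool, fraction = 0.5, seed,
                                  origin_term = NA_character_) {
  term_genes <- unique(as_genes(term_genes))
  pool <- unique(as_genes(pool))
  stopifnot(fraction >= 0, fraction <= 1, length(term_genes) > 0)
  n <- length(term_genes)
  condition <- if (fraction >= 1) {
    "real"
  } else if (fraction == 0) {
    "random"
  } else {
    "mix5050"
  }
  if (condition == "real") {
    genes <- term_genes
  } else if (condition == "random") {
    if (length(pool) < n) {
      gslm_stop(
        sprintf("pool of %d genes cannot supply %d random genes",
                length(pool), n),
        "gslm_argument_error"
      )
    }
    genes <- withr::with_seed(seed, sample(pool, n))
  } else {
    n_keep <- floor(fraction * n)
    n_contam <- n - n_keep
    contam_pool <- setdiff(pool, term_genes)
    if (length(contam_pool) < n_contam) {
      gslm_stop(
        sprintf(
          "contaminant pool has %d genes but %d are needed (short by %d)",
          length(contam_pool), n_contam, n_contam - length(contam_pool)
        ),
        "gslm_argument_error"
      )
    }
    genes <- withr::with_seed(seed, {
      c(sample(term_genes, n_keep), sample(contam_pool, n_contam))
    })
  }
  structure(
    list(
      origin_term = origin_term,
      condition = condition,
      genes = genes,
      seed = as.integer(seed)
    ),
    class = "BenchmarkSet"
  )
}

#' Bin a confidence score
#'
#' Partition of `[0, 1]`: `not_assigned` = \{0\}; `low` = (0, 0.80);
#' `medium` = [0.80, 0.87); `high` = [0.87, 1.00]. Vectorised.
#'
#' @param score numeric confidence score(s) in `[0, 1]`.
#' @return character vector of bin labels.
#' @export
bin_confidence <- function(score) {
  if (any(is.na(score)) || any(score < 0) || any(score > 1)) {
    gslm_stop("confidence scores must lie in [0, 1]", "gslm_argument_error")
  }
  ifelse(score == 0, "not_assigned",
    ifelse(score < 0.80, "low",
      ifelse(score < 0.87, "medium", "high")
    )
  )
}

#' Generate the three benchmark conditions for each term
#'
#' Seeds are derived as `seed + 3 * (term position - 1) + offset` with offsets
#' 0/1/2 for real/mix5050/random, so compositions are reproducible per term
#' and independent of the other terms.
#'
#' @param ont an annotated [Ontology][new_ontology].
#' @param term_ids terms to benchmark.
#' @param seed integer base seed.
#' @param fraction contamination fraction for the mixed condition.
#' @return named list (by term) of lists with elements `real`, `mix5050`,
#'   `random`, each a `BenchmarkSet`.
#' @export
benchmark_sets <- function(ont, term_ids, seed = 42L, fraction = 0.5) {
  pool <- annotation_pool(ont)
  out <- lapply(seq_along(term_ids), function(i) {
    id <- term_ids[[i]]
    genes <- aggregate_genes(ont, id)
    base <- seed + 3L * (i - 1L)
    list(
      real = make_contaminated_set(genes, pool, 1, base, id),
      mix5050 = make_contaminated_set(genes, pool, fraction, base + 1L, id),
      random = make_contaminated_set(genes, pool, 0, base + 2L, id)
    )
  })
  names(out) <- term_ids
  out
}

#' Run the confidence benchmark
#'
#' For each term, generates the real / mix5050 / random sets, queries the
#' backend, parses the response and bins the confidence. Backend or parse
#' failures are recorded and excluded from the contingency table with a
#' logged count.
#'
#' @param ont an annotated [Ontology][new_ontology].
#' @param term_ids terms to benchmark.
#' @param backend an [llm_backend()].
#' @param cfg a [prompt_config()].
#' @param cache optional [llm_cache()].
#' @param embedder optional [embedding_backend()]; when supplied, each record
#'   gains the semantic similarity of the proposed name to the origin term's
#'   curated name.
#' @param seed integer base seed for set generation.
#' @param fraction contamination fraction for the mixed condition.
#' @return list with `table` (condition x bin count matrix; row sums equal
#'   the number of successfully processed terms per condition), `records`
#'   (per-set data.frame) and `failures` (count).
#' @export
run_benchmark <- function(ont, term_ids, backend, cfg = prompt_config(),
                          cache = NULL, embedder = NULL, seed = 42L,
                          fraction = 0.5) {
  tab <- matrix(
    0L, nrow = 3, ncol = 4,
    dimnames = list(benchmark_conditions, confidence_bins)
  )
  sets <- benchmark_sets(ont, term_ids, seed, fraction)
  records <- list()
  failures <- 0L
  for (id in names(sets)) {
    for (cond in benchmark_conditions) {
      bset <- sets[[id]][[cond]]
      ann <- tryCatch(
        annotate_gene_set(backend, bset$genes, cfg, cache),
        error = function(e) e
      )
      if (inherits(ann, "error")) {
        failures <- failures + 1L
        next
      }
      bin <- bin_confidence(ann$confidence)
      tab[cond, bin] <- tab[cond, bin] + 1L
      rec <- data.frame(
        term = id, condition = cond, seed = bset$seed,
        name = ann$name, confidence = ann$confidence, bin = bin
      )
      if (!is.null(embedder)) {
        rec$similarity_to_origin <- if (ann$confidence == 0) {
          NA_real_
        } else {
          name_similarity(embedder, ann$name, term_name(ont, id))
        }
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  if (failures > 0) {
    gslm_warn(sprintf("%d benchmark queries failed and were excluded",
                      failures))
  }
  list(
    table = tab,
    records = if (length(records)) do.call(rbind, records) else NULL,
    failures = failures
  )
}

#' Compare two confidence distributions
#'
#' `method = "chisq"`: chi-squared test of homogeneity on the 2 x k
#' contingency formed by two bin-count vectors; columns with zero marginal
#' total are dropped before computing `(k - 1)` degrees of freedom; no
#' continuity correction. `method = "mannwhitney"`: two-sided Mann-Whitney U
#' on two raw score vectors.
#'
#' @param a,b bin-count vectors (chisq) or score vectors (mannwhitney).
#' @param method `"chisq"` or `"mannwhitney"`.
#' @return list with `statistic`, `p_value`, `df` (chisq only), `method`.
#' @export
compare_distributions <- function(a, b, method = c("chisq", "mannwhitney")) {
  method <- match.arg(method)
  if (method == "chisq") {
    tab <- rbind(a, b)
    if (any(tab < 0) || any(rowSums(tab) == 0)) {
      gslm_stop("each table needs non-negative counts and a positive total",
                "gslm_argument_error")
    }
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2) {
      gslm_stop("degenerate table: fewer than two populated bins",
                "gslm_argument_error")
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    statistic <- sum((tab - expected)^2 / expected)
    df <- as.integer((nrow(tab) - 1) * (ncol(tab) - 1))
    list(
      statistic = statistic,
      p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
      df = df,
      method = "chisq"
    )
  } else {
    stopifnot(length(a) > 0, length(b) > 0)
    wt <- stats::wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                             correct = FALSE)
    list(
      statistic = unname(wt$statistic),
      p_value = wt$p.value,
      method = "mannwhitney"
    )
  }
}
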