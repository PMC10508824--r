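# Five-step citation module for analysis essays:
#   1. LLM extracts gene symbols + up to three function keywords per paragraph
#      (paragraphs lacking either are skipped, returning the unknown sentinel)
#   2. assemble a PubMed query: (genes OR'd) AND (keywords OR'd)
#   3. search PubMed, sorted by relevance
#   4. re-rank by the number of distinct query genes mentioned in the abstract
#   5. LLM judges whether each top publication's title/abstract supports the
#      paragraph; only supported publications are returned as citations.
#
# PubMed clients implement: client$search(query, retmax) -> data.frame with
# columns pmid, title, abstract, relevance_rank. A canned client backs tests.

#' The unknown sentinel for skipped paragraphs
#' @return object of class `gslm_unknown`.
#' @export
unknown_sentinel <- function() structure(list(), class = "gslm_unknown")

#' @rdname unknown_sentinel
#' @param x object to test.
#' @export
is_unknown <- function(x) inherits(x, "gslm_unknown")

default_keyword_prompt <- paste(
  "Extract two types of keywords from the analysis paragraph below:",
  "(1) gene symbols explicitly mentioned in the paragraph and",
  "(2) up to three keywords associated with gene functions or biological processes, ordered by their importance.",
  "Reply on a single line in exactly this format:",
  "genes: <symbol1>, <symbol2> | keywords: <keyword1>; <keyword2>; <keyword3>",
  "If the paragraph does not contain at least one gene symbol and one functional keyword, reply exactly: unknown",
  "Here is an example paragraph:",
  "SNX6 and SNX12 are sorting nexins acting in retromer-dependent endosomal sorting.",
  "The example reply is:",
  "genes: SNX6, SNX12 | keywords: endosomal sorting; retromer",
  "Here is the analysis paragraph:",
  "{paragraph}",
  sep = "\n"
)

default_support_prompt <- paste(
  "You are assessing literature support for a statement from a gene set analysis.",
  "Publication title: {title}",
  "Publication abstract: {abstract}",
  "Analysis paragraph: {paragraph}",
  "Do the title and abstract provide evidence for one or more statements of fact in the paragraph?",
  "Reply on a single line in exactly this format:",
  "supported: <yes|no> | basis: <title|abstract|both|none>",
  sep = "\n"
)

#' Extract gene symbols and function keywords from a paragraph
#'
#' Prompts the backend and parses its structured reply. A reply of `unknown`,
#' or one lacking either a gene symbol or a keyword, yields the
#' [unknown_sentinel()] (the paragraph is skipped downstream). More than
#' three keywords are truncated to the three most important with a warning.
#' A structurally unparsable reply is a parse error, distinct from unknown.
#'
#' @param backend an [llm_backend()].
#' @param paragraph non-empty paragraph text.
#' @param cfg a [prompt_config()] (decoding parameters only).
#' @param cache optional [llm_cache()].
#' @param template prompt template with a `{paragraph}` slot.
#' @return list with `gene_symbols`, `function_keywords` (class
#'   `KeywordExtraction`), or the unknown sentinel.
#' @export
extract_keywords <- function(backend, paragraph, cfg = prompt_config(),
                             cache = NULL,
                             template = default_keyword_prompt) {
  stopifnot(nzchar(paragraph))
  prompt <- sub("{paragraph}", paragraph, template, fixed = TRUE)
  reply <- query_llm(backend, prompt, cfg, cache)
  parse_keyword_reply(reply)
}

parse_keyword_reply <- function(reply) {
  line <- trimws(reply)
  if (identical(tolower(line), "unknown")) return(unknown_sentinel())
  if (!grepl("genes:", line, fixed = TRUE) ||
      !grepl("keywords:", line, fixed = TRUE)) {
    gslm_stop(
      paste0("unparsable keyword-extraction reply: ", substr(line, 1, 120)),
      "gslm_parse_error"
    )
  }
  genes_part <- sub("^.*genes:", "", line)
  genes_part <- sub("\\|.*$", "", genes_part)
  kw_part <- sub("^.*keywords:", "", line)
  genes <- trimws(strsplit(genes_part, ",", fixed = TRUE)[[1]])
  genes <- genes[nzchar(genes)]
  keywords <- trimws(strsplit(kw_part, ";", fixed = TRUE)[[1]])
  keywords <- keywords[nzchar(keywords)]
  if (!length(genes) || !length(keywords)) return(unknown_sentinel())
  if (length(keywords) > 3) {
    gslm_warn("more than 3 function keywords returned; keeping the first 3")
    keywords <- keywords[1:3]
  }
  structure(
    list(gene_symbols = genes, function_keywords = keywords),
    class = "KeywordExtraction"
  )
}

#' Assemble a PubMed query expression
#'
#' `(g1[Title/Abstract] OR ...) AND ("k1"[Title/Abstract] OR ...)`: a match
#' requires at least one gene symbol and at least one function keyword in the
#' title or abstract. Keywords are quoted as phrases; embedded double quotes
#' are stripped with a warning.
#'
#' @param extraction a valid `KeywordExtraction`.
#' @return the query expression string.
#' @export
build_query <- function(extraction) {
  stopifnot(inherits(extraction, "KeywordExtraction"))
  genes <- extraction$gene_symbols
  keywords <- extraction$function_keywords
  if (any(grepl('"', keywords, fixed = TRUE))) {
    gslm_warn("double quotes stripped from function keywords")
    keywords <- gsub('"', "", keywords, fixed = TRUE)
  }
  gene_clause <- paste(
    sprintf("%s[Title/Abstract]", genes), collapse = " OR "
  )
  kw_clause <- paste(
    sprintf('"%s"[Title/Abstract]', keywords), collapse = " OR "
  )
  sprintf("(%s) AND (%s)", gene_clause, kw_clause)
}

#' Re-rank publications by gene coverage
#'
#' Counts the distinct query genes mentioned in each abstract
#' (case-insensitive, word boundaries), sorts by descending mention count
#' with relevance rank as a stable tie-break, and keeps the top `top_k`.
#'
#' @param records data.frame with columns `pmid`, `title`, `abstract`,
#'   `relevance_rank`.
#' @param genes query gene symbols.
#' @param top_k number of publications to keep (default 3).
#' @return re-ranked subset of `records` with a `gene_mention_count` column.
#' @export
rank_publications <- function(records, genes, top_k = 3L) {
  if (!nrow(records)) return(records)
  counts <- vapply(records$abstract, function(ab) {
    sum(vapply(genes, function(g) {
      grepl(paste0("\\b", escape_regex(g), "\\b"), ab, ignore.case = TRUE)
    }, FALSE))
  }, 0L, USE.NAMES = FALSE)
  records$gene_mention_count <- counts
  ord <- order(-counts, records$relevance_rank)
  utils::head(records[ord, , drop = FALSE], top_k)
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

#' Judge whether a publication supports a paragraph
#'
#' Prompts the backend with the publication title, abstract and the analysis
#' paragraph, and parses its structured yes/no verdict. Verdicts are never
#' fabricated: an unparsable or internally inconsistent reply (supported but
#' basis "none") is a parse error.
#'
#' @param backend an [llm_backend()].
#' @param record one-row data.frame (or list) with `pmid`, `title`,
#'   `abstract`.
#' @param paragraph the analysis paragraph.
#' @param cfg a [prompt_config()].
#' @param cache optional [llm_cache()].
#' @param template prompt template with `{title}`, `{abstract}`,
#'   `{paragraph}` slots.
#' @return list with `pmid`, `supported`, `basis` (class `CitationVerdict`).
#' @export
judge_support <- function(backend, record, paragraph, cfg = prompt_config(),
                          cache = NULL, template = default_support_prompt) {
  stopifnot(nzchar(record$title))
  prompt <- sub("{title}", record$title, template, fixed = TRUE)
  prompt <- sub("{abstract}", record$abstract %||% "", prompt, fixed = TRUE)
  prompt <- sub("{paragraph}", paragraph, prompt, fixed = TRUE)
  reply <- trimws(query_llm(backend, prompt, cfg, cache))
  m <- regmatches(reply, regexec(
    "supported:[[:space:]]*(yes|no)[[:space:]]*\\|[[:space:]]*basis:[[:space:]]*(title|abstract|both|none)",
    tolower(reply)
  ))[[1]]
  if (length(m) != 3) {
    gslm_stop(
      paste0("unparsable support verdict: ", substr(reply, 1, 120)),
      "gslm_parse_error"
    )
  }
  supported <- identical(m[2], "yes")
  basis <- m[3]
  if (supported && basis == "none") {
    gslm_stop("inconsistent verdict: supported with basis 'none'",
              "gslm_parse_error")
  }
  if (!supported) basis <- "none"
  structure(
    list(pmid = record$pmid, supported = supported, basis = basis),
    class = "CitationVerdict"
  )
}

#' Canned PubMed client
#'
#' Test double for the E-utilities client: `search()` returns a fixed record
#' table (optionally keyed by exact query string), truncated to `retmax` and
#' carrying 1-based relevance ranks.
#'
#' @param records default data.frame with columns `pmid`, `title`,
#'   `abstract`.
#' @param by_query optional named list mapping query strings to record
#'   data.frames.
#' @return object of class `pubmed_client`.
#' @export
canned_pubmed <- function(records = NULL, by_query = NULL) {
  empty <- data.frame(
    pmid = character(), title = character(), abstract = character(),
    relevance_rank = integer()
  )
  structure(list(
    search = function(query, retmax = 20L) {
      out <- if (!is.null(by_query) && query %in% names(by_query)) {
        by_query[[query]]
      } else {
        records
      }
      if (is.null(out) || !nrow(out)) return(empty)
      out <- utils::head(out, retmax)
      out$relevance_rank <- seq_len(nrow(out))
      out
    }
  ), class = "pubmed_client")
}

#' Live PubMed E-utilities client
#'
#' esearch (relevance-sorted JSON) + efetch (XML) via the `curl` binary.
#' Requires network access and the `xml2` package; results are cached on disk
#' by query digest and requests are rate-limited. Tests use [canned_pubmed()]
#' instead.
#'
#' @param cache_dir optional directory for cached search results.
#' @param delay seconds to sleep before each request (NCBI politeness).
#' @return object of class `pubmed_client`.
#' @export
entrez_pubmed <- function(cache_dir = NULL, delay = 0.4) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    gslm_stop("the live PubMed client requires the xml2 package",
              "gslm_config_error")
  }
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"
  fetch <- function(url) {
    Sys.sleep(delay)
    out <- suppressWarnings(
      system2("curl", c("-sS", "--fail", shQuote(url)),
              stdout = TRUE, stderr = TRUE)
    )
    if ((attr(out, "status") %||% 0L) != 0L) {
      gslm_stop(paste("PubMed request failed:", paste(out, collapse = " ")),
                "gslm_backend_error")
    }
    paste(out, collapse = "\n")
  }
  structure(list(
    search = function(query, retmax = 20L) {
      cache_path <- NULL
      if (!is.null(cache_dir)) {
        dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
        cache_path <- file.path(
          cache_dir, paste0(gslm_digest(c(query, retmax)), ".json")
        )
        if (file.exists(cache_path)) {
          cached <- jsonlite::read_json(cache_path, simplifyVector = TRUE)
          return(as.data.frame(cached))
        }
      }
      es <- jsonlite::fromJSON(fetch(sprintf(
        "%s/esearch.fcgi?db=pubmed&retmode=json&sort=relevance&retmax=%d&term=%s",
        base, retmax, utils::URLencode(query, reserved = TRUE)
      )))
      ids <- es$esearchresult$idlist
      if (!length(ids)) {
        return(data.frame(
          pmid = character(), title = character(), abstract = character(),
          relevance_rank = integer()
        ))
      }
      doc <- xml2::read_xml(fetch(sprintf(
        "%s/efetch.fcgi?db=pubmed&retmode=xml&id=%s",
        base, paste(ids, collapse = ",")
      )))
      arts <- xml2::xml_find_all(doc, ".//PubmedArticle")
      recs <- data.frame(
        pmid = vapply(arts, function(a) {
          xml2::xml_text(xml2::xml_find_first(a, ".//PMID"))
        }, ""),
        title = vapply(arts, function(a) {
          xml2::xml_text(xml2::xml_find_first(a, ".//ArticleTitle"))
        }, ""),
        abstract = vapply(arts, function(a) {
          paste(xml2::xml_text(
            xml2::xml_find_all(a, ".//Abstract/AbstractText")
          ), collapse = " ")
        }, "")
      )
      # efetch does not preserve esearch order; restore relevance order
      recs <- recs[match(ids, recs$pmid), , drop = FALSE]
      recs <- recs[!is.na(recs$pmid), , drop = FALSE]
      recs$relevance_rank <- seq_len(nrow(recs))
      if (!is.null(cache_path)) {
        jsonlite::write_json(recs, cache_path, dataframe = "columns")
      }
      recs
    }
  ), class = "pubmed_client")
}

#' Attach citations to one analysis paragraph
#'
#' Composes the five steps in order. Paragraphs yielding no valid keyword
#' extraction return the [unknown_sentinel()]; an empty search result yields
#' an empty citation list (not an error); only verdict-supported publications
#' among the re-ranked top `top_k` are returned.
#'
#' @param backend an [llm_backend()].
#' @param pubmed a `pubmed_client` ([canned_pubmed()] or [entrez_pubmed()]).
#' @param paragraph the analysis paragraph.
#' @param cfg a [prompt_config()].
#' @param cache optional [llm_cache()].
#' @param top_k publications judged per paragraph (default 3).
#' @param retmax search results requested (default 20).
#' @return list of supported records (each with `pmid`, `title`, `basis`),
#'   possibly empty, or the unknown sentinel.
#' @export
cite_paragraph <- function(backend, pubmed, paragraph, cfg = prompt_config(),
                           cache = NULL, top_k = 3L, retmax = 20L) {
  extraction <- extract_keywords(backend, paragraph, cfg, cache)
  if (is_unknown(extraction)) return(unknown_sentinel())
  query <- build_query(extraction)
  records <- pubmed$search(query, retmax)
  if (!nrow(records)) return(list())
  top <- rank_publications(records, extraction$gene_symbols, top_k)
  out <- list()
  for (i in seq_len(nrow(top))) {
    rec <- top[i, , drop = FALSE]
    verdict <- judge_support(backend, rec, paragraph, cfg, cache)
    if (verdict$supported) {
      out[[length(out) + 1L]] <- list(
        pmid = rec$pmid, title = rec$title, basis = verdict$basis,
        gene_mention_count = rec$gene_mention_count
      )
    }
  }
  out
}

#' Attach citations to every paragraph of an annotation
#'
#' Per-paragraph failures are isolated: an error in one paragraph is recorded
#' as a failure entry and does not abort the essay.
#'
#' @param backend an [llm_backend()].
#' @param pubmed a `pubmed_client`.
#' @param annotation an `LLMAnnotation`.
#' @param ... passed to [cite_paragraph()].
#' @return list (one element per paragraph) of citation lists, unknown
#'   sentinels, or condition objects for failed paragraphs.
#' @export
cite_essay <- function(backend, pubmed, annotation, ...) {
  lapply(annotation$paragraphs, function(p) {
    tryCatch(cite_paragraph(backend, pubmed, p, ...), error = function(e) e)
  })
}
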