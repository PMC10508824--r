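#' @keywords internal
"_PACKAGE"

# Classed conditions so callers can distinguish parse errors, lookup errors,
# backend failures etc. from plain stops.
gslm_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "gslm_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

gslm_warn <- function(msg) warning(msg, call. = FALSE)

#' Deterministic text digest
#'
#' Pure-R rolling hash (two independent djb2-style words) used for LLM cache
#' keys, scripted-backend fingerprints and embedding-cache filenames. It is an
#' indexing key, not a cryptographic hash.
#'
#' @param x character vector; elements are joined with a separator before
#'   hashing, so `gslm_digest(c("a","b"))` differs from `gslm_digest("ab")`.
#' @return a 16-hex-digit string.
#' @export
gslm_digest <- function(x) {
  x <- paste(enc2utf8(as.character(x)), collapse = "\x1f")
  v <- utf8ToInt(x)
  h1 <- 5381
  h2 <- 52711
  # 33 * 2^32 and 31 * 2^32 stay far below 2^53, so double arithmetic is exact
  for (ch in v) {
    h1 <- (h1 * 33 + ch) %% 4294967296
    h2 <- (h2 * 31 + ch + 7) %% 4294967296
  }
  # values exceed .Machine$integer.max, so emit hex from 16-bit halves
  sprintf(
    "%04x%04x%04x%04x",
    as.integer(h1 %/% 65536), as.integer(h1 %% 65536),
    as.integer(h2 %/% 65536), as.integer(h2 %% 65536)
  )
}

#' Fingerprint of a gene list
#'
#' Digest of the sorted, comma-joined gene symbols. Scripted LLM backends key
#' their canned responses on this fingerprint rather than on the full prompt,
#' so editing the prompt template does not invalidate a test script.
#'
#' @param genes character vector of gene symbols.
#' @return a 16-hex-digit string.
#' @export
gene_fingerprint <- function(genes) {
  gslm_digest(paste(sort(unique(as.character(genes))), collapse = ","))
}

# Clean a vector of gene symbols: character, trimmed, non-empty,
# whitespace-free, deduplicated with optional warning.
clean_genes <- function(genes, context = "gene set", warn_dups = TRUE) {
  genes <- trimws(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (any(grepl("[[:space:]]", genes))) {
    gslm_stop(
      sprintf("%s contains gene symbols with internal whitespace", context),
      "gslm_format_error"
    )
  }
  if (anyDuplicated(genes)) {
    if (warn_dups) {
      gslm_warn(sprintf("duplicate gene symbols collapsed in %s", context))
    }
    genes <- unique(genes)
  }
  genes
}

`%||%` <- function(a, b) if (is.null(a)) b else a
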