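#' Construct a gene set
#'
#' @param set_id identifier, unique within a collection.
#' @param genes character vector of gene symbols; duplicates are collapsed
#'   with a warning, symbols must be non-empty and whitespace-free.
#' @param label free-text source description.
#' @return object of class `GeneSet`.
#' @export
gene_set <- function(set_id, genes, label = "") {
  stopifnot(is.character(set_id), length(set_id) == 1, nzchar(set_id))
  genes <- clean_genes(genes, context = sprintf("gene set '%s'", set_id))
  if (!length(genes)) {
    gslm_stop(
      sprintf("gene set '%s' is empty", set_id),
      "gslm_format_error"
    )
  }
  structure(
    list(set_id = set_id, label = label, genes = genes),
    class = "GeneSet"
  )
}

#' @export
print.GeneSet <- function(x, ...) {
  cat(sprintf(
    "<GeneSet> %s (%d genes): %s%s\n",
    x$set_id, length(x$genes),
    paste(utils::head(x$genes, 6), collapse = ", "),
    if (length(x$genes) > 6) ", ..." else ""
  ))
  invisible(x)
}

#' @export
length.GeneSet <- function(x) length(x$genes)

as_genes <- function(x) {
  if (inherits(x, "GeneSet")) x$genes else as.character(x)
}

#' Read a GMT gene-set file
#'
#' One set per tab-separated line: name, description, then gene symbols.
#'
#' @param file path to a GMT file.
#' @param text GMT content as a string (alternative to `file`).
#' @return list of [GeneSet][gene_set] objects in file order.
#' @export
read_gmt <- function(file = NULL, text = NULL) {
  lines <- if (is.null(text)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(text, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(lines)]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      gslm_stop(
        sprintf("GMT line %d has fewer than 3 fields", i),
        "gslm_format_error"
      )
    }
    out[[i]] <- gene_set(fields[1], fields[-(1:2)], label = fields[2])
  }
  out
}

#' Write gene sets to a GMT file
#'
#' Round-trips with [read_gmt()]. Gene symbols containing tabs or newlines
#' would corrupt the format and are rejected.
#'
#' @param sets list of [GeneSet][gene_set] objects.
#' @param file output path.
#' @export
write_gmt <- function(sets, file) {
  lines <- vapply(sets, function(s) {
    stopifnot(inherits(s, "GeneSet"))
    if (!length(s$genes)) {
      gslm_stop(
        sprintf("refusing to write empty gene set '%s'", s$set_id),
        "gslm_format_error"
      )
    }
    if (any(grepl("[\t\n]", c(s$set_id, s$label, s$genes)))) {
      gslm_stop(
        sprintf("gene set '%s' contains tab/newline characters", s$set_id),
        "gslm_format_error"
      )
    }
    paste(c(s$set_id, s$label, s$genes), collapse = "\t")
  }, "")
  writeLines(lines, file)
  invisible(file)
}

#' Filter gene sets by size
#'
#' Inclusive bounds; the band for both curated-term and 'omics
#' set selection. Input order is preserved and the operation is idempotent.
#'
#' @param sets list of [GeneSet][gene_set] objects.
#' @param min_size,max_size inclusive size bounds.
#' @return the surviving subset, in input order.
#' @export
filter_by_size <- function(sets, min_size = 3L, max_size = 100L) {
  stopifnot(min_size <= max_size)
  sets[vapply(
    sets,
    function(s) length(s$genes) >= min_size && length(s$genes) <= max_size,
    FALSE
  )]
}

#' Read a plain gene list (one symbol per line)
#'
#' @param file path; lines are trimmed, blanks and `#` comments skipped.
#' @param set_id identifier for the resulting set (default: file base name).
#' @return a [GeneSet][gene_set].
#' @export
read_gene_list <- function(file, set_id = NULL) {
  lines <- trimws(readLines(file, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  gene_set(set_id %||% tools::file_path_sans_ext(basename(file)), lines)
}

#' Threshold a gene score table into a gene set
#'
#' Converts a two-column TSV (`gene<TAB>score`) into a gene set by absolute
#' score threshold — the extraction used for differential-expression
#' signatures (z-score cutoff 2 by default). Absolute-value semantics keep
#' both up- and down-regulated genes; set `absolute = FALSE` for a signed
#' (score >= threshold) cut.
#'
#' @param file path to the score TSV (no header).
#' @param threshold numeric cutoff (default 2).
#' @param set_id identifier for the resulting set.
#' @param absolute use `|score| >= threshold` (default) or a signed cut.
#' @return a [GeneSet][gene_set].
#' @export
read_score_table <- function(file, threshold = 2, set_id = NULL,
                             absolute = TRUE) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2)
  if (length(bad)) {
    gslm_stop(
      sprintf("score table line %d has fewer than 2 columns", bad[1]),
      "gslm_format_error"
    )
  }
  genes <- vapply(fields, `[[`, "", 1)
  scores <- as.numeric(vapply(fields, `[[`, "", 2))
  keep <- if (absolute) abs(scores) >= threshold else scores >= threshold
  gene_set(
    set_id %||% tools::file_path_sans_ext(basename(file)),
    genes[keep]
  )
}
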