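# The engineered prompt: seven ordered sections whose concatenation, with the
# gene list substituted into the terminal slot, is the full LLM query. The
# defaults reproduce the published gene-set analysis prompt, including the
# one-shot pancreatic example and the zero-confidence "System of unrelated
# proteins" sentinel.

default_system_content <- paste0(
  "You are an efficient and insightful assistant to a molecular biologist"
)

default_task_instructions <- paste(
  "Write a critical analysis of the biological processes performed by this system of interacting proteins.",
  "Base your analysis on prior knowledge available in your training data.",
  "After completing your analysis, propose a brief and detailed name for the most prominent biological process performed by the system.",
  sep = "\n"
)

default_confidence_instructions <- paste(
  "After completing your analysis, please also assign a confidence score to the process name you selected.",
  "This score should follow the name in parentheses and range from 0.00 to 1.00. A score of 0.00 indicates the",
  "lowest confidence, while 1.00 reflects the highest confidence. This score helps gauge how accurately the chosen",
  "name represents the functions and activities within the system of interacting proteins. When determining your",
  "score, consider the proportion of genes in the protein system that participate in the identified biological process.",
  "For instance, if you select \"Ribosome biogenesis\" as the process name but only a few genes in the system",
  "contribute to this process, the score should be lower compared to a scenario where a majority of the genes are involved in \"Ribosome biogenesis\".",
  sep = "\n"
)

default_format_instructions <- paste0(
  "Put your chosen name at the top of the analysis as 'Process: <name>'."
)

default_analytical_approach <- paste(
  "Be concise, do not use unnecessary words.",
  "Be factual, do not editorialize.",
  "Be specific, avoid overly general statements such as 'the proteins are involved in various cellular processes'.",
  "Avoid listing facts about individual proteins. Instead, try to group proteins with similar functions and discuss their",
  "interplay, synergistic or antagonistic effects and functional integration within the system.",
  "Also avoid choosing generic process names such as 'Cellular Signaling and Regulation'.",
  "If you cannot identify a prominent biological process for the proteins in the system, I want you to communicate this in you analysis and name the process: \"System of unrelated proteins\". Provide a score of 0.00 for a \"System of unrelated proteins\".",
  sep = "\n"
)

default_one_shot_example <- paste(
  "To help you in your work, I am providing an example system of interacting proteins and the corresponding example analysis output.",
  "The example system of interacting proteins is: PDX1, SLC2A2, NKX6\u20131, GLP1, GCG.",
  "The example analysis output is:",
  "Process: Pancreatic development and glucose homeostasis (0.96)",
  "1. PDX1 is a homeodomain transcription factor involved in the specification of the early pancreatic epithelium and its subsequent differentiation.",
  "It activates the transcription of several genes including insulin, somatostatin, glucokinase and glucose transporter type 2.",
  "It is essential for maintenance of the normal hormone-producing phenotype in the pancreatic beta-cell.",
  "In pancreatic acinar cells, it forms a complex with PBX1b and MEIS2b and mediates the activation of the ELA1 enhancer.",
  "2. NKX6\u20131 is also a transcription factor involved in the development of pancreatic beta-cells during the secondary transition.",
  "Together with NKX2\u20132 and IRX3, controls the generation of motor neurons in the neural tube and belongs to the neural progenitor",
  "factors induced by Sonic Hedgehog (SHH) signals.",
  "3. GCG and GLP1, respectively glucagon and glucagon-like peptide 1, are involved in glucose metabolism and homeostasis.",
  "GCG raises blood glucose levels by promoting gluconeogenesis and is the counter regulatory hormone of Insulin.",
  "GLP1 is a potent stimulator of Glucose-Induced Insulin Secretion (GSIS). Plays roles in gastric motility and suppresses blood glucagon levels.",
  "Promotes growth of the intestinal epithelium and pancreatic islet mass both by islet neogenesis and islet cell proliferation.",
  "4. SLC2A2, also known as GLUT2, is a facilitative hexose transporter. In hepatocytes, it mediates bi-directional transport of glucose across the plasma membranes,",
  "while in the pancreatic beta-cell, it is the main transporter responsible for glucose uptake and part of the cell's glucose-sensing mechanism.",
  "It is involved in glucose transport in the small intestine and kidney too.",
  "To summarize, the genes in this set are involved in the specification, differentiation, growth and functionality of the pancreas, with a particular emphasis on the pancreatic beta-cell. Particularly, the architecture of the pancreatic",
  "islet ensures proper glucose sensing and homeostasis via a number of different hormones and receptors that can elicit both synergistic and antagonistic effects in the pancreas itself and other peripheral tissues.",
  sep = "\n"
)

default_input_template <- "Here are the interacting proteins:\nProteins: {protein list}"

#' Prompt configuration
#'
#' Holds the seven prompt sections plus the decoding parameters sent to the
#' backend. Defaults reproduce the published settings: temperature 0.0,
#' seed 42, at most 1,000 response tokens.
#'
#' @param system_content,task_instructions,confidence_instructions,format_instructions,analytical_approach,one_shot_example,input_template
#'   the seven prompt sections, concatenated in this order by
#'   [build_prompt()]. All must be non-empty.
#' @param temperature sampling temperature in `[0, 2]`.
#' @param seed integer decoding seed passed to backends that support one.
#' @param max_tokens response token cap.
#' @return object of class `PromptConfig`.
#' @export
prompt_config <- function(system_content = default_system_content,
                          task_instructions = default_task_instructions,
                          confidence_instructions = default_confidence_instructions,
                          format_instructions = default_format_instructions,
                          analytical_approach = default_analytical_approach,
                          one_shot_example = default_one_shot_example,
                          input_template = default_input_template,
                          temperature = 0.0, seed = 42L, max_tokens = 1000L) {
  sections <- list(
    system_content = system_content,
    task_instructions = task_instructions,
    confidence_instructions = confidence_instructions,
    format_instructions = format_instructions,
    analytical_approach = analytical_approach,
    one_shot_example = one_shot_example,
    input_template = input_template
  )
  for (nm in names(sections)) {
    if (!is.character(sections[[nm]]) || length(sections[[nm]]) != 1 ||
        !nzchar(sections[[nm]])) {
      gslm_stop(sprintf("prompt section '%s' must be non-empty", nm),
                "gslm_config_error")
    }
  }
  stopifnot(temperature >= 0, temperature <= 2, max_tokens >= 1)
  structure(
    c(sections, list(
      temperature = temperature,
      seed = as.integer(seed),
      max_tokens = as.integer(max_tokens)
    )),
    class = "PromptConfig"
  )
}

#' Build the full prompt for a gene set
#'
#' Concatenates the seven sections and substitutes the comma-space separated
#' gene symbols into the `{protein list}` slot. Byte-stable for fixed inputs.
#'
#' @param cfg a [prompt_config()].
#' @param genes a [GeneSet][gene_set] or character vector of gene symbols.
#' @return the prompt text.
#' @export
build_prompt <- function(cfg = prompt_config(), genes) {
  stopifnot(inherits(cfg, "PromptConfig"))
  genes <- as_genes(genes)
  if (!length(genes)) {
    gslm_stop("cannot build a prompt for an empty gene set",
              "gslm_format_error")
  }
  body <- paste(
    cfg$system_content, cfg$task_instructions, cfg$confidence_instructions,
    cfg$format_instructions, cfg$analytical_approach, cfg$one_shot_example,
    cfg$input_template,
    sep = "\n"
  )
  sub("{protein list}", paste(genes, collapse = ", "), body, fixed = TRUE)
}

#' The refusal sentinel name
#'
#' Gene sets the model cannot coherently name are assigned this name together
#' with a confidence of 0.00.
#' @export
unrelated_sentinel <- "System of unrelated proteins"

# Header pattern: optional leading whitespace/markdown bolding, "Process:",
# the name, then a parenthesized decimal score at end of line.
process_header_pattern <- paste0(
  "^[[:space:]]*(?:\\*\\*|__)?[[:space:]]*",
  "Process:[[:space:]]*(.*?)[[:space:]]*",
  "\\(([0-9]*\\.?[0-9]+)\\)[[:space:]]*(?:\\*\\*|__)?[[:space:]]*$"
)

#' Parse an LLM response into a structured annotation
#'
#' Finds the first line of the form `Process: <name> (<score>)` (markdown
#' bolding and leading whitespace tolerated), strips the prefix and score,
#' clamps the confidence into `[0, 1]` (with a warning when out of range) and
#' splits the remaining text into paragraphs on blank lines.
#'
#' @param raw the raw response text.
#' @param model_id backend identifier recorded on the annotation.
#' @return object of class `LLMAnnotation` with fields `name`, `confidence`,
#'   `paragraphs`, `raw_response`, `model_id`.
#' @export
parse_response <- function(raw, model_id = NA_character_) {
  stopifnot(is.character(raw), length(raw) == 1)
  lines <- strsplit(raw, "\n", fixed = TRUE)[[1]]
  m <- regmatches(lines, regexec(process_header_pattern, lines, perl = TRUE))
  hit <- which(lengths(m) == 3L)
  if (!length(hit)) {
    gslm_stop(
      paste0("no 'Process: <name> (<score>)' header found in response:\n",
             substr(raw, 1, 200)),
      "gslm_parse_error"
    )
  }
  hit <- hit[1]
  name <- m[[hit]][2]
  confidence <- suppressWarnings(as.numeric(m[[hit]][3]))
  if (is.na(confidence)) {
    gslm_stop("unparsable confidence score in response header",
              "gslm_parse_error")
  }
  if (confidence < 0 || confidence > 1) {
    gslm_warn(sprintf(
      "confidence %.3f outside [0, 1]; clamped", confidence
    ))
    confidence <- min(max(confidence, 0), 1)
  }
  body <- paste(lines[-hit], collapse = "\n")
  paragraphs <- strsplit(body, "\n[[:space:]]*\n+")[[1]]
  paragraphs <- trimws(paragraphs)
  paragraphs <- paragraphs[nzchar(paragraphs)]
  structure(
    list(
      name = name,
      confidence = confidence,
      paragraphs = paragraphs,
      raw_response = raw,
      model_id = model_id
    ),
    class = "LLMAnnotation"
  )
}

#' @export
print.LLMAnnotation <- function(x, ...) {
  cat(sprintf(
    "<LLMAnnotation> %s (%.2f), %d paragraph(s)\n",
    x$name, x$confidence, length(x$paragraphs)
  ))
  invisible(x)
}

#' Render an annotation back to response text
#'
#' Inverse of [parse_response()] for annotations whose confidence has at most
#' two decimal places: `parse_response(render_annotation(x))` recovers the
#' name and confidence exactly.
#'
#' @param ann an `LLMAnnotation`.
#' @return response-formatted text.
#' @export
render_annotation <- function(ann) {
  stopifnot(inherits(ann, "LLMAnnotation"))
  paste0(
    "Process: ", ann$name, " (",
    formatC(ann$confidence, format = "f", digits = 2), ")\n\n",
    paste(ann$paragraphs, collapse = "\n\n")
  )
}

#' Is an annotation a refusal?
#'
#' @param ann an `LLMAnnotation`.
#' @return `TRUE` iff the confidence is 0 (the sentinel contract).
#' @export
is_refusal <- function(ann) {
  isTRUE(ann$confidence == 0) || identical(ann$name, unrelated_sentinel)
}
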