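# LLM backends implement a single contract:
#   backend$model_id   : string identifying the model
#   backend$complete(prompt, temperature, seed, max_tokens) -> response text
# Everything above the contract (prompt construction, caching, retries,
# parsing) is backend-agnostic, so scripted test backends and live API
# backends are interchangeable.

#' Construct an LLM backend from a completion function
#'
#' @param model_id string identifying the model.
#' @param complete function `(prompt, temperature, seed, max_tokens)`
#'   returning the response text.
#' @return object of class `llm_backend`.
#' @export
llm_backend <- function(model_id, complete) {
  stopifnot(is.character(model_id), is.function(complete))
  structure(list(model_id = model_id, complete = complete),
            class = "llm_backend")
}

#' @export
print.llm_backend <- function(x, ...) {
  cat(sprintf("<llm_backend> %s\n", x$model_id))
  invisible(x)
}

#' On-disk response cache
#'
#' One JSON record per response, keyed by a digest of
#' `(model_id, prompt, temperature, seed, max_tokens)`. Because responses at
#' temperature 0 can still vary between calls, the cached first response is
#' the unit of reproducibility for a run.
#'
#' @param dir cache directory (created if missing).
#' @return object of class `llm_cache`.
#' @export
llm_cache <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  structure(list(dir = dir), class = "llm_cache")
}

cache_key <- function(model_id, prompt, temperature, seed, max_tokens) {
  gslm_digest(c(
    model_id, prompt,
    format(temperature, digits = 15), format(seed), format(max_tokens)
  ))
}

cache_get <- function(cache, key) {
  path <- file.path(cache$dir, paste0(key, ".json"))
  if (!file.exists(path)) return(NULL)
  rec <- tryCatch(jsonlite::read_json(path), error = function(e) NULL)
  if (is.null(rec) || !is.character(rec$response %||% NULL)) {
    gslm_warn(sprintf("corrupt cache record %s; bypassing cache", basename(path)))
    return(NULL)
  }
  rec$response
}

cache_put <- function(cache, key, model_id, response) {
  path <- file.path(cache$dir, paste0(key, ".json"))
  jsonlite::write_json(
    list(key = key, model_id = model_id, response = response),
    path, auto_unbox = TRUE
  )
  invisible(path)
}

#' Query an LLM backend with caching and bounded retries
#'
#' A cache hit short-circuits the backend; on a miss the response is stored
#' verbatim. Transient backend failures are retried up to `max_retries`
#' times before a `gslm_backend_error` is raised.
#'
#' @param backend an [llm_backend()].
#' @param prompt prompt text (see [build_prompt()]).
#' @param cfg a [prompt_config()] supplying temperature/seed/max_tokens.
#' @param cache an [llm_cache()] or `NULL` to disable caching.
#' @param max_retries total attempts allowed per query.
#' @param retry_delay seconds slept between attempts.
#' @return the response text.
#' @export
query_llm <- function(backend, prompt, cfg = prompt_config(), cache = NULL,
                      max_retries = 3L, retry_delay = 0) {
  stopifnot(inherits(backend, "llm_backend"))
  key <- cache_key(backend$model_id, prompt, cfg$temperature, cfg$seed,
                   cfg$max_tokens)
  if (!is.null(cache)) {
    hit <- cache_get(cache, key)
    if (!is.null(hit)) return(hit)
  }
  last_err <- NULL
  for (attempt in seq_len(max_retries)) {
    response <- tryCatch(
      backend$complete(prompt, cfg$temperature, cfg$seed, cfg$max_tokens),
      error = function(e) {
        last_err <<- e
        NULL
      }
    )
    if (!is.null(response)) {
      if (!is.null(cache)) cache_put(cache, key, backend$model_id, response)
      return(response)
    }
    if (attempt < max_retries && retry_delay > 0) Sys.sleep(retry_delay)
  }
  gslm_stop(
    sprintf("backend '%s' failed after %d attempts: %s",
            backend$model_id, max_retries, conditionMessage(last_err)),
    "gslm_backend_error"
  )
}

#' Annotate a gene set end to end
#'
#' Builds the prompt, queries the backend (through the cache, if given) and
#' parses the response.
#'
#' @inheritParams query_llm
#' @param genes a [GeneSet][gene_set] or character vector.
#' @return an `LLMAnnotation` (see [parse_response()]).
#' @export
annotate_gene_set <- function(backend, genes, cfg = prompt_config(),
                              cache = NULL) {
  prompt <- build_prompt(cfg, genes)
  raw <- query_llm(backend, prompt, cfg, cache)
  parse_response(raw, model_id = backend$model_id)
}

#' Live OpenAI-compatible chat backend
#'
#' Thin adapter around the chat-completions HTTP API via the `curl` binary.
#' Requires network access and an API key; never used by the test suite,
#' which runs exclusively on [scripted_llm()] fixtures.
#'
#' @param model model identifier, e.g. `"gpt-4-1106-preview"`.
#' @param api_key API key (default: `OPENAI_API_KEY` environment variable).
#' @param base_url API root.
#' @return an [llm_backend()].
#' @export
openai_backend <- function(model = "gpt-4-1106-preview",
                           api_key = Sys.getenv("OPENAI_API_KEY"),
                           base_url = "https://api.openai.com/v1") {
  if (!nzchar(api_key)) {
    gslm_stop("no API key configured (set OPENAI_API_KEY)",
              "gslm_config_error")
  }
  llm_backend(model, function(prompt, temperature, seed, max_tokens) {
    body <- jsonlite::toJSON(list(
      model = model,
      temperature = temperature,
      seed = seed,
      max_tokens = max_tokens,
      messages = list(list(role = "user", content = prompt))
    ), auto_unbox = TRUE)
    body_file <- tempfile(fileext = ".json")
    on.exit(unlink(body_file))
    writeLines(body, body_file)
    out <- suppressWarnings(system2(
      "curl",
      c("-sS", "--fail", "-X", "POST",
        "-H", "Content-Type: application/json",
        "-H", shQuote(paste0("Authorization: Bearer ", api_key)),
        "-d", paste0("@", body_file),
        shQuote(paste0(base_url, "/chat/completions"))),
      stdout = TRUE, stderr = TRUE
    ))
    status <- attr(out, "status") %||% 0L
    if (status != 0L) {
      gslm_stop(paste("API request failed:", paste(out, collapse = " ")),
                "gslm_backend_error")
    }
    parsed <- jsonlite::fromJSON(paste(out, collapse = "\n"),
                                 simplifyVector = FALSE)
    parsed$choices[[1]]$message$content
  })
}
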