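# Pluggable language-model backend contract.
#
# A backend is a list with fields `id` (string) and `handler`
# (function(request) -> raw response text).  Every pipeline stage talks to
# backends exclusively through backend_request()/complete(), so any model —
# a hosted API adapter, a local model, or the deterministic oracle used for
# testing — can be plugged in without touching the stages.  The request
# carries a structured `meta` list (patient/trial identifiers and side)
# alongside the rendered prompt; rule-driven backends may use it, text-only
# backends ignore it.

#' Construct a backend request
#'
#' @param purpose One of `"keywords"`, `"matching"`, `"aggregation"` —
#'   fixed per call site.
#' @param prompt Rendered prompt text.
#' @param temperature Decoding temperature; the pipeline default is 0 for
#'   deterministic outputs.
#' @param meta Structured request metadata (IDs) for rule-driven backends.
#' @return A `backend_request` object.
#' @export
backend_request <- function(purpose, prompt, temperature = 0, meta = list()) {
  purpose <- match.arg(purpose, c("keywords", "matching", "aggregation"))
  if (!.is_string(prompt) || !nzchar(prompt)) .stopf("prompt must be a non-empty string")
  if (!is.numeric(temperature) || temperature < 0) .stopf("temperature must be >= 0")
  structure(
    list(purpose = purpose, prompt = prompt, temperature = temperature, meta = meta),
    class = "backend_request"
  )
}

#' Create a backend from a handler function
#'
#' @param id Backend identifier, recorded in response provenance.
#' @param handler `function(request)` returning raw response text.
#' @return A `trialmatchr_backend` object.
#' @export
make_backend <- function(id, handler) {
  if (!.is_string(id) || !nzchar(id)) .stopf("backend id must be a non-empty string")
  if (!is.function(handler)) .stopf("handler must be a function")
  structure(list(id = id, handler = handler), class = "trialmatchr_backend")
}

#' Complete a request against a backend
#'
#' @param backend A `trialmatchr_backend` (see [make_backend()],
#'   [cached_backend()], [oracle_backend()]).
#' @param request A [backend_request()].
#' @param retries Number of additional attempts after a retryable transport
#'   failure.
#' @return A `backend_response`: list with `raw_text`, `backend_id`,
#'   `cache_hit`.
#' @export
complete <- function(backend, request, retries = 3L) {
  if (!inherits(backend, "trialmatchr_backend")) .stopf("not a trialmatchr backend")
  if (!inherits(request, "backend_request")) .stopf("not a backend_request")
  last <- NULL
  for (attempt in seq_len(retries + 1L)) {
    res <- tryCatch(backend$handler(request), trialmatchr_transport_error = function(e) e)
    if (!inherits(res, "condition")) {
      if (!.is_string(res) || !nzchar(res)) {
        .stopf("backend %s returned an empty response", backend$id)
      }
      hit <- isTRUE(attr(res, "cache_hit"))
      return(structure(
        list(raw_text = as.character(res), backend_id = backend$id, cache_hit = hit),
        class = "backend_response"
      ))
    }
    last <- res
  }
  .stopf(
    "backend %s failed after %d attempts: %s", backend$id, retries + 1L,
    conditionMessage(last)
  )
}

# Cache key: exact concatenation of backend id, purpose, decoding
# parameters and the full prompt.  Using the full request text (rather
# than a digest) makes collisions impossible.
.cache_key <- function(backend_id, request) {
  paste(backend_id, request$purpose, format(request$temperature), request$prompt,
        sep = "\x1f")
}

#' Wrap a backend with a response cache
#'
#' Responses are memoized in memory and, when `cache_dir` is given,
#' persisted to an append-only JSONL file (`cache.jsonl`) that is reloaded
#' on construction, so warm-cache runs are byte-reproducible and make no
#' backend calls.
#'
#' @param backend Backend to wrap.
#' @param cache_dir Optional directory for the persistent cache file.
#' @return A caching `trialmatchr_backend` with the same id.
#' @export
cached_backend <- function(backend, cache_dir = NULL) {
  store <- new.env(parent = emptyenv())
  cache_file <- NULL
  if (!is.null(cache_dir)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    cache_file <- file.path(cache_dir, "cache.jsonl")
    if (file.exists(cache_file)) {
      for (line in readLines(cache_file, encoding = "UTF-8", warn = FALSE)) {
        if (!nzchar(trimws(line))) next
        rec <- jsonlite::fromJSON(line, simplifyVector = TRUE)
        assign(rec$key, rec$response, envir = store)
      }
    }
  }
  handler <- function(request) {
    key <- .cache_key(backend$id, request)
    if (exists(key, envir = store, inherits = FALSE)) {
      res <- get(key, envir = store, inherits = FALSE)
      attr(res, "cache_hit") <- TRUE
      return(res)
    }
    res <- backend$handler(request)
    assign(key, res, envir = store)
    if (!is.null(cache_file)) {
      line <- jsonlite::toJSON(list(key = key, response = res), auto_unbox = TRUE)
      cat(line, "\n", sep = "", file = cache_file, append = TRUE)
    }
    res
  }
  make_backend(backend$id, handler)
}

#' Deterministic scripted backend for tests
#'
#' Answers each request by calling `fn(request)`; a convenience wrapper
#' around [make_backend()] that gives the backend a stable id.
#'
#' @param fn `function(request)` returning raw text.
#' @param id Backend identifier.
#' @return A `trialmatchr_backend`.
#' @export
mock_backend <- function(fn, id = "mock") make_backend(id, fn)
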