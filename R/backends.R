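# Inference-backend contract. A backend classifies query items (questions
# or hypotheses built by build_queries()) into verdicts; classification must
# be deterministic: the same query always yields the same verdict. The
# published transformer checkpoints (roberta-base-boolq, t5-base-finetuned-
# boolq, t5-large NLI) conform to this contract but require an external
# model runtime; offline work and tests use the mock backends below.

#' Classify queries with an inference backend
#'
#' @param backend A backend object (see [backend_mock()],
#'   [backend_gold_echo()], [resolve_backend()]).
#' @param queries A query tibble from [build_queries()].
#' @return `queries` with added `verdict` (character) and `score` (numeric,
#'   `NA` when the backend exposes none) columns.
#' @export
classify <- function(backend, queries) UseMethod("classify")

#' @export
classify.default <- function(backend, queries) {
  abort("Not a relation-extraction backend; see resolve_backend()",
        class = "biodivrelex_config_error")
}

default_negative <- function(mode) ifelse(mode == "nli", "neutral", "No")
default_positive <- function(mode) ifelse(mode == "nli", "entailment", "Yes")

#' Mock inference backend
#'
#' Deterministic stand-in for a hosted model, driven by an explicit lookup
#' table from query text to verdict and/or a keyword heuristic. With
#' `heuristic = TRUE` (default when no lookup entry matches), a query is
#' answered positively iff every whitespace word of the filled entity slots
#' appears in the context sentence — a crude containment check that makes
#' offline end-to-end runs behave plausibly. Unmatched queries otherwise
#' get the negative verdict for their mode.
#'
#' @param lookup Named character vector or list mapping `query_text` to a
#'   verdict, or a path to a JSON object file of the same shape.
#' @param heuristic Use the word-containment heuristic for queries absent
#'   from the lookup.
#' @return A backend object usable with [classify()].
#' @export
#' @examples
#' b <- backend_mock(lookup = c("Is there oak savanna in Luzon?" = "Yes"))
backend_mock <- function(lookup = NULL, heuristic = TRUE) {
  if (is.character(lookup) && length(lookup) == 1 && file.exists(lookup)) {
    lookup <- unlist(jsonlite::fromJSON(lookup, simplifyVector = TRUE))
  }
  lookup <- if (is.null(lookup)) character() else unlist(as.list(lookup))
  structure(list(lookup = lookup, heuristic = isTRUE(heuristic)),
            class = c("relex_backend_mock", "relex_backend"))
}

#' @export
classify.relex_backend_mock <- function(backend, queries) {
  verdict <- purrr::map_chr(seq_len(nrow(queries)), function(i) {
    q <- queries$query_text[i]
    if (q %in% names(backend$lookup)) return(unname(backend$lookup[[q]]))
    if (backend$heuristic) {
      words <- setdiff(strsplit(q, "[[:space:]]+")[[1]],
                       c("Is", "there", "in", "Did", "event", "happen", "on",
                         "The", "was", "happened", "on."))
      words <- gsub("[?.]$", "", words)
      ctx <- strsplit(queries$context_text[i], "[[:space:]]+")[[1]]
      if (all(words %in% ctx)) return(default_positive(queries$mode[i]))
    }
    default_negative(queries$mode[i])
  })
  queries$verdict <- verdict
  queries$score <- NA_real_
  queries
}

#' Gold-echo backend
#'
#' Answers each query from supplied gold labels: positive iff every
#' candidate pair the query covers is gold-positive. Used to test pipeline
#' plumbing end to end (a perfect inference model).
#'
#' @param gold An instance tibble with 0/1 `label`s.
#' @return A backend object usable with [classify()].
#' @export
backend_gold_echo <- function(gold) {
  stopifnot(all(gold$label %in% c(0L, 1L)))
  structure(list(gold = setNames(gold$label, instance_key(gold))),
            class = c("relex_backend_gold", "relex_backend"))
}

#' @export
classify.relex_backend_gold <- function(backend, queries) {
  verdict <- purrr::map_chr(seq_len(nrow(queries)), function(i) {
    keys <- queries$covered[[i]]
    labels <- backend$gold[keys]
    if (anyNA(labels)) {
      abort("Gold-echo backend: query covers pairs absent from the gold set",
            class = "biodivrelex_alignment_error")
    }
    if (all(labels == 1L)) default_positive(queries$mode[i]) else default_negative(queries$mode[i])
  })
  queries$verdict <- verdict
  queries$score <- NA_real_
  queries
}

#' Resolve a backend by configuration name
#'
#' `"mock"` and `"gold-echo"` are built in and run offline. The names of the
#' three published transformer checkpoints (`"roberta-boolq"`, `"t5-boolq"`,
#' `"t5-nli"`) are recognized but require an external model runtime that
#' this package does not bundle; requesting one raises an actionable error
#' suggesting [backend_mock()].
#'
#' @param name Backend name.
#' @param ... Passed to the backend constructor (`lookup`/`heuristic` for
#'   mock, `gold` for gold-echo).
#' @return A backend object.
#' @export
resolve_backend <- function(name, ...) {
  switch(name,
    "mock" = backend_mock(...),
    "gold-echo" = backend_gold_echo(...),
    "roberta-boolq" = ,
    "t5-boolq" = ,
    "t5-nli" = abort(sprintf(
      paste0("Backend '%s' requires an external transformer runtime that is ",
             "not bundled with this package. Use backend_mock() (backend ",
             "name 'mock') for offline runs, or adapt classify() to your ",
             "model server."), name),
      class = "biodivrelex_backend_unavailable"),
    abort(sprintf("Unknown backend '%s'", name),
          class = "biodivrelex_config_error")
  )
}
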