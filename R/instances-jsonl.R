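# Relation-instance exchange format: one JSON object per line with keys
# sent_id, text, tokens, relation_type, source{type,start,end,text},
# target{type,start,end,text}, label (0/1/null), predicted_by (optional),
# doc_id (optional extra). Spans on disk are 0-based half-open so files are
# interoperable with other implementations; in-memory tibbles use 1-based
# inclusive token ranges.

instance_cols <- function() {
  c("doc_id", "sent_id", "text", "relation_type",
    "source_type", "source_start", "source_end", "source_text",
    "target_type", "target_start", "target_end", "target_text",
    "label", "predicted_by")
}

empty_instances <- function() {
  tibble::tibble(
    doc_id = character(), sent_id = character(), text = character(),
    relation_type = character(),
    source_type = character(), source_start = integer(),
    source_end = integer(), source_text = character(),
    target_type = character(), target_start = integer(),
    target_end = integer(), target_text = character(),
    label = integer(), predicted_by = character()
  )
}

instance_key <- function(instances) {
  paste(instances$doc_id, instances$sent_id, instances$relation_type,
        instances$source_start, instances$source_end,
        instances$target_start, instances$target_end, sep = "\r")
}

#' Read relation instances from JSONL
#'
#' @param path Path to a JSONL file, or a character vector of JSON lines.
#' @return An instance tibble (one row per candidate pair) with a `label`
#'   column where `NA` means unlabeled.
#' @export
read_instances_jsonl <- function(path) {
  lines <- if (length(path) > 1 || grepl("\n", path, fixed = TRUE) ||
               startsWith(trimws(path), "{")) {
    unlist(strsplit(path, "\n", fixed = TRUE))
  } else {
    readLines(path, encoding = "UTF-8", warn = FALSE)
  }
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_instances())

  required <- c("sent_id", "text", "tokens", "relation_type", "source", "target", "label")
  rows <- purrr::imap(lines, function(line, i) {
    obj <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    missing <- setdiff(required, names(obj))
    if (length(missing)) {
      abort(sprintf("Line %d: missing key(s) %s", i,
                    paste(sQuote(missing), collapse = ", ")),
            class = "biodivrelex_schema_error")
    }
    for (side in c("source", "target")) {
      miss <- setdiff(c("type", "start", "end", "text"), names(obj[[side]]))
      if (length(miss)) {
        abort(sprintf("Line %d: %s is missing key(s) %s", i, side,
                      paste(sQuote(miss), collapse = ", ")),
              class = "biodivrelex_schema_error")
      }
    }
    tibble::tibble(
      doc_id = as.character(obj$doc_id %||% "doc1"),
      sent_id = as.character(obj$sent_id),
      text = obj$text,
      relation_type = obj$relation_type,
      source_type = obj$source$type,
      source_start = as.integer(obj$source$start) + 1L,
      source_end = as.integer(obj$source$end),
      source_text = obj$source$text,
      target_type = obj$target$type,
      target_start = as.integer(obj$target$start) + 1L,
      target_end = as.integer(obj$target$end),
      target_text = obj$target$text,
      label = if (is.null(obj$label)) NA_integer_ else as.integer(obj$label),
      predicted_by = as.character(obj$predicted_by %||% NA_character_)
    )
  })
  bind_rows(rows)
}

#' Write relation instances to JSONL
#'
#' `read_instances_jsonl(write_instances_jsonl(x))` is the identity on the
#' instance table.
#'
#' @param instances An instance tibble.
#' @param path Optional output path; when `NULL` the JSONL text is returned.
#' @return `path` invisibly, or the JSONL text when `path` is `NULL`.
#' @export
write_instances_jsonl <- function(instances, path = NULL) {
  lines <- purrr::map_chr(seq_len(max(nrow(instances), 0)), function(i) {
    r <- instances[i, ]
    obj <- list(
      doc_id = r$doc_id,
      sent_id = r$sent_id,
      text = r$text,
      tokens = strsplit(r$text, " ", fixed = TRUE)[[1]],
      relation_type = r$relation_type,
      source = list(type = r$source_type, start = r$source_start - 1L,
                    end = r$source_end, text = r$source_text),
      target = list(type = r$target_type, start = r$target_start - 1L,
                    end = r$target_end, text = r$target_text),
      label = r$label  # NA serialized as JSON null (unlabeled)
    )
    if (!is.na(r$predicted_by)) obj$predicted_by <- r$predicted_by
    jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null")
  })
  text <- paste(lines, collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, useBytes = TRUE)
  invisible(path)
}
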