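# Core domain types: entity/relation vocabularies, the annotated-corpus
# container, and validators shared by every other module.

#' Biodiversity entity types
#'
#' The four named-entity types the relation extractor works over. Serialized
#' names are the corpus labels used in `biodiv=` BIO tags and in JSONL files.
#'
#' @return A character vector of the four entity type names.
#' @export
#' @examples
#' entity_types()
entity_types <- function() {
  c("Habitat", "GeographicLocation", "ReproductiveCondition", "TemporalExpression")
}

#' Relation type registry
#'
#' The two binary relation types. `has_time` links a reproductive-condition
#' mention (source) to a temporal expression (target); `has_location` links a
#' habitat mention (source) to a geographic location (target). Directionality
#' is always source to target.
#'
#' @return A tibble with columns `relation_type`, `source_type`, `target_type`.
#' @export
#' @examples
#' relation_types()
relation_types <- function() {
  tibble::tibble(
    relation_type = c("has_time", "has_location"),
    source_type   = c("ReproductiveCondition", "Habitat"),
    target_type   = c("TemporalExpression", "GeographicLocation")
  )
}

relation_info <- function(relation_type) {
  rt <- relation_types()
  row <- rt[rt$relation_type == relation_type, ]
  if (nrow(row) != 1) {
    abort(sprintf(
      "Unknown relation type '%s'; expected one of: %s",
      relation_type, paste(rt$relation_type, collapse = ", ")
    ), class = "biodivrelex_config_error")
  }
  as.list(row)
}

token_cols <- function() {
  c("doc_id", "sent_id", "token_id", "form", "upos", "head", "deprel")
}

mention_cols <- function() {
  c("doc_id", "sent_id", "entity_type", "start", "end", "text")
}

#' Construct an annotated corpus
#'
#' Bundles a token table and a mention table into a validated corpus object,
#' the unit all extraction functions operate on. Token ids are 1-based and
#' contiguous within a sentence (matching CoNLL-U IDs); `head` uses the
#' CoNLL-U convention (0 = syntactic root, `NA` = unparsed). Mention spans are
#' inclusive token ranges `start..end` and may not overlap within a sentence.
#'
#' @param tokens A data frame with columns `doc_id`, `sent_id`, `token_id`,
#'   `form`, and optionally `upos`, `head`, `deprel` (plus any extra CoNLL-U
#'   carry-through columns such as `lemma`, `xpos`, `feats`, `deps`, `misc`).
#' @param mentions A data frame with columns `doc_id`, `sent_id`,
#'   `entity_type`, `start`, `end`, and optionally `text` (filled from the
#'   tokens when missing).
#' @return An object of class `biodiv_corpus`: a list with tibbles `$tokens`
#'   and `$mentions`.
#' @export
#' @examples
#' toks <- tibble::tibble(
#'   doc_id = "d1", sent_id = "s1", token_id = 1:3,
#'   form = c("flowering", "in", "March")
#' )
#' men <- tibble::tibble(
#'   doc_id = "d1", sent_id = "s1",
#'   entity_type = c("ReproductiveCondition", "TemporalExpression"),
#'   start = c(1L, 3L), end = c(1L, 3L)
#' )
#' biodiv_corpus(toks, men)
biodiv_corpus <- function(tokens, mentions = NULL) {
  tokens <- as_tibble(tokens)
  for (col in c("upos", "deprel")) {
    if (!col %in% names(tokens)) tokens[[col]] <- NA_character_
  }
  if (!"head" %in% names(tokens)) tokens$head <- NA_integer_
  tokens$token_id <- as.integer(tokens$token_id)
  tokens$head <- as.integer(tokens$head)
  tokens$sent_id <- as.character(tokens$sent_id)
  tokens$doc_id <- as.character(tokens$doc_id)

  if (is.null(mentions) || nrow(as_tibble(mentions)) == 0) {
    mentions <- tibble::tibble(
      doc_id = character(), sent_id = character(), entity_type = character(),
      start = integer(), end = integer(), text = character()
    )
  }
  mentions <- as_tibble(mentions)
  mentions$start <- as.integer(mentions$start)
  mentions$end <- as.integer(mentions$end)
  mentions$sent_id <- as.character(mentions$sent_id)
  mentions$doc_id <- as.character(mentions$doc_id)
  if (!"text" %in% names(mentions)) {
    mentions$text <- mention_text(tokens, mentions)
  } else if (anyNA(mentions$text)) {
    idx <- is.na(mentions$text)
    mentions$text[idx] <- mention_text(tokens, mentions[idx, ])
  }

  x <- structure(list(tokens = tokens, mentions = mentions),
                 class = "biodiv_corpus")
  validate_corpus(x)
  x
}

mention_text <- function(tokens, mentions) {
  if (nrow(mentions) == 0) return(character())
  purrr::pmap_chr(
    mentions[, c("doc_id", "sent_id", "start", "end")],
    function(doc_id, sent_id, start, end) {
      forms <- tokens$form[tokens$doc_id == doc_id &
                             tokens$sent_id == sent_id &
                             tokens$token_id >= start &
                             tokens$token_id <= end]
      paste(forms, collapse = " ")
    }
  )
}

validate_corpus <- function(x) {
  tokens <- x$tokens
  mentions <- x$mentions
  missing_tok <- setdiff(c("doc_id", "sent_id", "token_id", "form"), names(tokens))
  if (length(missing_tok)) {
    abort(paste0("tokens is missing column(s): ", paste(missing_tok, collapse = ", ")),
          class = "biodivrelex_invalid_annotation")
  }

  by_sent <- split(tokens$token_id, paste(tokens$doc_id, tokens$sent_id, sep = "\r"))
  for (key in names(by_sent)) {
    ids <- by_sent[[key]]
    if (!identical(sort(ids), seq_along(ids))) {
      abort(sprintf("Token ids in sentence '%s' are not contiguous 1..n",
                    sub("\r", "/", key)),
            class = "biodivrelex_invalid_annotation")
    }
  }
  bad_head <- !is.na(tokens$head) & (tokens$head == tokens$token_id | tokens$head < 0)
  if (any(bad_head)) {
    abort("A token's head may not be itself or negative",
          class = "biodivrelex_invalid_annotation")
  }

  if (nrow(mentions) > 0) {
    unknown <- setdiff(unique(mentions$entity_type), entity_types())
    if (length(unknown)) {
      abort(paste0("Unknown entity type(s): ", paste(unknown, collapse = ", ")),
            class = "biodivrelex_invalid_annotation")
    }
    n_tok <- tokens %>%
      group_by(.data$doc_id, .data$sent_id) %>%
      summarise(n_tokens = max(.data$token_id), .groups = "drop")
    m <- left_join(mentions, n_tok, by = c("doc_id", "sent_id"))
    if (anyNA(m$n_tokens)) {
      abort("Mention refers to a sentence absent from the token table",
            class = "biodivrelex_invalid_annotation")
    }
    bad_span <- m$start < 1 | m$end < m$start | m$end > m$n_tokens
    if (any(bad_span)) {
      abort("Mention span out of bounds (need 1 <= start <= end <= sentence length)",
            class = "biodivrelex_invalid_annotation")
    }
    overlap <- mentions %>%
      group_by(.data$doc_id, .data$sent_id) %>%
      arrange(.data$start, .by_group = TRUE) %>%
      summarise(bad = any(diff_overlap(.data$start, .data$end)), .groups = "drop")
    if (any(overlap$bad)) {
      abort("Mentions within a sentence must not overlap token-wise",
            class = "biodivrelex_invalid_annotation")
    }
  }
  invisible(x)
}

diff_overlap <- function(start, end) {
  if (length(start) < 2) return(FALSE)
  start[-1] <= end[-length(end)]
}

#' @export
print.biodiv_corpus <- function(x, ...) {
  n_sent <- nrow(distinct(x$tokens, .data$doc_id, .data$sent_id))
  cat(sprintf(
    "<biodiv_corpus> %d document(s), %d sentence(s), %d token(s), %d mention(s)\n",
    length(unique(x$tokens$doc_id)), n_sent, nrow(x$tokens), nrow(x$mentions)
  ))
  if (nrow(x$mentions)) {
    tab <- table(x$mentions$entity_type)
    cat("  mentions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Sentence surface text
#'
#' Space-joins token forms per sentence. Original inter-token spacing is not
#' stored, so this is the canonical reconstruction used in templates and
#' JSONL output.
#'
#' @param corpus A [biodiv_corpus()].
#' @return A tibble with columns `doc_id`, `sent_id`, `text`, `n_tokens`.
#' @export
sentence_text <- function(corpus) {
  corpus$tokens %>%
    group_by(.data$doc_id, .data$sent_id) %>%
    summarise(text = paste(.data$form, collapse = " "),
              n_tokens = max(.data$token_id), .groups = "drop")
}

sentence_keys <- function(tokens) {
  paste(tokens$doc_id, tokens$sent_id, sep = "\r")
}
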