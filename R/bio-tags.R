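# BIO (Beginning / Inside / Outside) tag codec for entity mentions.
# Tags look like "B-Habitat", "I-TemporalExpression", "O"; the tag vocabulary
# is fixed by entity_types().

#' Encode mentions as per-token BIO tags
#'
#' Each token outside every mention gets `"O"`; the first token of a mention
#' of type X gets `"B-X"` and subsequent tokens `"I-X"`. Mentions must be
#' non-overlapping (enforced by [biodiv_corpus()]).
#'
#' @param corpus A [biodiv_corpus()].
#' @return The token table with an added `bio` column.
#' @export
#' @examples
#' fx <- paper_fixture()
#' encode_bio_tags(fx$corpus)
encode_bio_tags <- function(corpus) {
  tokens <- corpus$tokens
  tokens$bio <- "O"
  if (nrow(corpus$mentions)) {
    key_tok <- sentence_keys(tokens)
    for (i in seq_len(nrow(corpus$mentions))) {
      m <- corpus$mentions[i, ]
      idx <- which(key_tok == paste(m$doc_id, m$sent_id, sep = "\r") &
                     tokens$token_id >= m$start & tokens$token_id <= m$end)
      idx <- idx[order(tokens$token_id[idx])]
      tokens$bio[idx] <- c(paste0("B-", m$entity_type),
                           rep(paste0("I-", m$entity_type), length(idx) - 1L))
    }
  }
  tokens
}

#' Decode per-token BIO tags into mention spans
#'
#' Inverse of [encode_bio_tags()]. An `I-X` tag not preceded by a `B-X`/`I-X`
#' of the same type starts a new mention (orphan-I promotion), so noisy
#' annotations are ingested rather than rejected; on well-formed input the
#' round trip `decode(encode(x))` reproduces the mentions exactly.
#'
#' @param tagged_tokens A token table carrying a `bio` column (as produced by
#'   [encode_bio_tags()] or the CoNLL-U reader).
#' @return A mention tibble (`doc_id`, `sent_id`, `entity_type`, `start`,
#'   `end`, `text`).
#' @export
decode_bio_tags <- function(tagged_tokens) {
  stopifnot("bio" %in% names(tagged_tokens))
  bad <- !grepl("^(O|[BI]-.+)$", tagged_tokens$bio)
  if (any(bad)) {
    abort(sprintf("Unknown BIO tag '%s'", tagged_tokens$bio[which(bad)[1]]),
          class = "biodivrelex_parse_error")
  }
  unknown_type <- setdiff(
    unique(sub("^[BI]-", "", tagged_tokens$bio[tagged_tokens$bio != "O"])),
    entity_types()
  )
  if (length(unknown_type)) {
    abort(paste0("BIO tag names unknown entity type: ",
                 paste(unknown_type, collapse = ", ")),
          class = "biodivrelex_parse_error")
  }

  out <- tagged_tokens %>%
    group_by(.data$doc_id, .data$sent_id) %>%
    arrange(.data$token_id, .by_group = TRUE) %>%
    summarise(spans = list(decode_bio_sentence(.data$bio, .data$token_id, .data$form)),
              .groups = "drop") %>%
    tidyr::unnest("spans")
  out[, mention_cols()]
}

decode_bio_sentence <- function(bio, token_id, form) {
  starts <- integer(); ends <- integer(); types <- character(); texts <- character()
  cur_type <- NULL; cur_start <- NA_integer_; cur_end <- NA_integer_; cur_forms <- character()
  flush <- function() {
    if (!is.null(cur_type)) {
      starts <<- c(starts, cur_start); ends <<- c(ends, cur_end)
      types <<- c(types, cur_type); texts <<- c(texts, paste(cur_forms, collapse = " "))
    }
  }
  for (i in seq_along(bio)) {
    tag <- bio[i]
    if (tag == "O") {
      flush(); cur_type <- NULL
    } else {
      marker <- substr(tag, 1, 1)
      type <- substr(tag, 3, nchar(tag))
      continues <- marker == "I" && !is.null(cur_type) && identical(cur_type, type)
      if (continues) {
        cur_end <- token_id[i]; cur_forms <- c(cur_forms, form[i])
      } else {
        flush()  # B-, or orphan/type-switching I- promoted to a new mention
        cur_type <- type; cur_start <- token_id[i]; cur_end <- token_id[i]
        cur_forms <- form[i]
      }
    }
  }
  flush()
  tibble::tibble(entity_type = types, start = starts, end = ends, text = texts)
}
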