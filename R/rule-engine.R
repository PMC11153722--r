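# Token-type encoding and regular-expression relation rules.
#
# A sentence is mapped, per relation type, to one character per token over
# the alphabet {S, T, d, o}: S = token inside a source-typed mention,
# T = token inside a target-typed mention, d = "," or ";" (enumeration
# delimiter), o = everything else. Entity membership takes precedence over
# delimiter status, so a comma inside a coordinate-style location mention
# encodes as T, not d. Because each token is exactly one character, mention
# token spans are also character spans of the encoded string.

RULE_PATTERNS <- c(
  forward  = "[S]+(o)?(To|Td|T)+",
  backward = "(?<!S)(To|Td|T)*T(o)?[S]+"
)

#' Encode sentences as token-type strings
#'
#' @param corpus A [biodiv_corpus()].
#' @param relation_type `"has_time"` or `"has_location"` (decides which
#'   entity types count as source and target; mentions of the two
#'   non-participating types encode as `o`).
#' @return A tibble with one row per sentence: `doc_id`, `sent_id`,
#'   `relation_type`, `type_string`.
#' @export
#' @examples
#' fx <- paper_fixture()
#' encode_token_types(fx$corpus, "has_time")
encode_token_types <- function(corpus, relation_type) {
  info <- relation_info(relation_type)
  tokens <- corpus$tokens
  chars <- rep("o", nrow(tokens))
  chars[tokens$form %in% c(",", ";")] <- "d"
  key_tok <- sentence_keys(tokens)
  men <- corpus$mentions
  for (i in seq_len(nrow(men))) {
    sym <- if (men$entity_type[i] == info$source_type) "S"
           else if (men$entity_type[i] == info$target_type) "T"
           else next
    idx <- key_tok == paste(men$doc_id[i], men$sent_id[i], sep = "\r") &
      tokens$token_id >= men$start[i] & tokens$token_id <= men$end[i]
    chars[idx] <- sym
  }
  tokens %>%
    mutate(.char = chars) %>%
    group_by(.data$doc_id, .data$sent_id) %>%
    arrange(.data$token_id, .by_group = TRUE) %>%
    summarise(type_string = paste(.data$.char, collapse = ""), .groups = "drop") %>%
    mutate(relation_type = relation_type) %>%
    select("doc_id", "sent_id", "relation_type", "type_string")
}

#' Match the two relation rules against a token-type string
#'
#' Scans with each rule independently using the regex engine's standard
#' left-to-right, non-overlapping, greedy semantics. Rule `forward`
#' (`[S]+(o)?(To|Td|T)+`) captures a source run followed (after at most one
#' other token) by a delimited run of targets; rule `backward`
#' (`(?<!S)(To|Td|T)*T(o)?[S]+`) captures targets preceding a source.
#'
#' @param type_string A single string over the alphabet `S`, `T`, `d`, `o`.
#' @return A tibble with columns `rule`, `start`, `end` (1-based inclusive
#'   character/token positions of each match).
#' @export
regex_rule_matches <- function(type_string) {
  stopifnot(length(type_string) == 1)
  out <- purrr::imap(RULE_PATTERNS, function(pat, nm) {
    m <- gregexpr(pat, type_string, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)
    tibble::tibble(rule = nm, start = as.integer(m),
                   end = as.integer(m) + attr(m, "match.length") - 1L)
  })
  found <- bind_rows(out)
  if (nrow(found) == 0) {
    tibble::tibble(rule = character(), start = integer(), end = integer())
  } else {
    found
  }
}

#' Apply the regex relation rules to a corpus
#'
#' For every rule match, each source mention and each target mention whose
#' token span lies entirely inside the matched span are paired and labeled
#' related. The union over both rules is returned, deduplicated. A mention
#' only partially covered by a match is not paired.
#'
#' @param corpus A [biodiv_corpus()].
#' @param relation_type `"has_time"` or `"has_location"`.
#' @return An instance tibble of rule-positive pairs, `label = 1`,
#'   `predicted_by = "rule"`.
#' @export
apply_regex_rules <- function(corpus, relation_type) {
  info <- relation_info(relation_type)
  tts <- encode_token_types(corpus, relation_type)
  candidates <- generate_candidates(corpus, relation_type)
  if (nrow(candidates) == 0) return(candidates)

  key_cand <- paste(candidates$doc_id, candidates$sent_id, sep = "\r")
  hits <- purrr::map(seq_len(nrow(tts)), function(i) {
    matches <- regex_rule_matches(tts$type_string[i])
    if (nrow(matches) == 0) return(NULL)
    cand <- candidates[key_cand == paste(tts$doc_id[i], tts$sent_id[i], sep = "\r"), ]
    covered <- purrr::map(seq_len(nrow(matches)), function(j) {
      cand[cand$source_start >= matches$start[j] & cand$source_end <= matches$end[j] &
             cand$target_start >= matches$start[j] & cand$target_end <= matches$end[j], ]
    })
    bind_rows(covered)
  })
  out <- bind_rows(hits)
  if (nrow(out) == 0) return(candidates[0, ])
  out %>%
    distinct() %>%
    mutate(label = 1L, predicted_by = "rule") %>%
    arrange(.data$doc_id, .data$sent_id, .data$source_start, .data$target_start)
}

#' Detect compound entities
#'
#' A compound entity is a run of two or more same-type mentions with at most
#' one token between consecutive members (e.g. temporal expressions joined
#' by "and"). The sentence is collapsed to an entity-granular string — `E`
#' per mention of the requested type, `t` per other token — and maximal
#' matches of `(Et|E){2,}` become compounds. `joined_text` concatenates the
#' member texts and the single intervening tokens with spaces.
#'
#' @param corpus A [biodiv_corpus()].
#' @param entity_type One of [entity_types()].
#' @return A tibble with one row per compound: `doc_id`, `sent_id`,
#'   `entity_type`, `compound_id`, `n_members`, `member_starts`,
#'   `member_ends` (list columns of token indices), `joined_text`.
#' @export
#' @examples
#' fx <- paper_fixture()
#' detect_compound_entities(fx$corpus, "TemporalExpression")
detect_compound_entities <- function(corpus, entity_type) {
  entity_type <- match.arg(entity_type, entity_types())
  tokens <- corpus$tokens
  men <- corpus$mentions %>% filter(.data$entity_type == !!entity_type)
  keys <- unique(sentence_keys(tokens))
  key_tok <- sentence_keys(tokens)
  key_men <- paste(men$doc_id, men$sent_id, sep = "\r")

  rows <- purrr::map(keys, function(key) {
    sent <- tokens[key_tok == key, ]
    sent <- sent[order(sent$token_id), ]
    sm <- men[key_men == key, ]
    sm <- sm[order(sm$start), ]
    if (nrow(sm) < 2) return(NULL)

    # entity-granular units: one 'E' per mention (span collapsed), one 't'
    # per token outside those mentions
    unit_sym <- character(); unit_ref <- list()
    i <- 1L
    while (i <= nrow(sent)) {
      mi <- which(sm$start == sent$token_id[i])
      if (length(mi) == 1) {
        unit_sym <- c(unit_sym, "E"); unit_ref <- c(unit_ref, list(sm[mi, ]))
        i <- i + (sm$end[mi] - sm$start[mi] + 1L)
      } else {
        unit_sym <- c(unit_sym, "t"); unit_ref <- c(unit_ref, list(sent$form[i]))
        i <- i + 1L
      }
    }
    ent_string <- paste(unit_sym, collapse = "")
    m <- gregexpr("(Et|E){2,}", ent_string, perl = TRUE)[[1]]
    if (m[1] == -1) return(NULL)

    purrr::map(seq_along(m), function(j) {
      span <- seq.int(m[j], m[j] + attr(m, "match.length")[j] - 1L)
      while (unit_sym[span[length(span)]] == "t") span <- span[-length(span)]
      members <- purrr::keep(unit_ref[span], is.data.frame)
      parts <- purrr::map_chr(unit_ref[span], function(u) {
        if (is.data.frame(u)) u$text else u
      })
      mem <- bind_rows(members)
      tibble::tibble(
        doc_id = sent$doc_id[1], sent_id = sent$sent_id[1],
        entity_type = entity_type,
        n_members = nrow(mem),
        member_starts = list(mem$start), member_ends = list(mem$end),
        joined_text = paste(parts, collapse = " ")
      )
    }) %>% bind_rows()
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      doc_id = character(), sent_id = character(), entity_type = character(),
      compound_id = integer(), n_members = integer(),
      member_starts = list(), member_ends = list(), joined_text = character()
    ))
  }
  out %>%
    group_by(.data$doc_id, .data$sent_id) %>%
    mutate(compound_id = row_number()) %>%
    ungroup() %>%
    select("doc_id", "sent_id", "entity_type", "compound_id", "n_members",
           "member_starts", "member_ends", "joined_text")
}
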