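# Zero-shot relation classification via boolean-QA questions or NLI
# hypotheses. Entity surface text is inserted into the templates verbatim —
# no grammatical normalization — because the inference models are expected
# to be robust to slightly awkward phrasings ("Did fruit event happen on
# August 1963?").

#' Fill the boolean-QA question template
#'
#' `has_location` pairs become "Is there <habitat> in <geographic
#' location>?"; `has_time` pairs become "Did <reproductive condition> event
#' happen on <temporal expression>?". Vectorized over entity texts.
#'
#' @param source_text,target_text Entity surface strings (a compound
#'   entity's `joined_text` may be used as the target).
#' @param relation_type `"has_time"` or `"has_location"`.
#' @return Character vector of questions.
#' @export
#' @examples
#' make_question("lowland dipterocarp forest", "Bukit Sai", "has_location")
#' make_question("fruit", "August 1963", "has_time")
make_question <- function(source_text, target_text, relation_type) {
  fill_template(source_text, target_text, relation_type,
                loc = "Is there %s in %s?", time = "Did %s event happen on %s?")
}

fill_template <- function(source_text, target_text, relation_type, loc, time) {
  stopifnot(all(nzchar(source_text)), all(nzchar(target_text)))
  n <- max(length(source_text), length(target_text), length(relation_type), 0L)
  if (n == 0) return(character())
  src <- rep_len(source_text, n)
  tgt <- rep_len(target_text, n)
  is_loc <- rep_len(relation_type, n) == "has_location"
  out <- character(n)
  out[is_loc] <- sprintf(loc, src[is_loc], tgt[is_loc])
  out[!is_loc] <- sprintf(time, src[!is_loc], tgt[!is_loc])
  out
}

#' Fill the NLI hypothesis template
#'
#' `has_location` pairs become "The <habitat> was in <geographic
#' location>."; `has_time` pairs become "The <reproductive condition> event
#' happened on <temporal expression>.". Vectorized over entity texts.
#'
#' @inheritParams make_question
#' @return Character vector of hypotheses.
#' @export
#' @examples
#' make_hypothesis("lowland dipterocarp forest", "Bukit Sai", "has_location")
make_hypothesis <- function(source_text, target_text, relation_type) {
  fill_template(source_text, target_text, relation_type,
                loc = "The %s was in %s.", time = "The %s event happened on %s.")
}

#' Build backend queries for candidate instances
#'
#' Every instance yields exactly one query unless absorbed into a compound
#' query: with `compounds` supplied, all instances sharing a sentence and a
#' source whose targets are members of one compound are covered by a single
#' query whose target slot holds the compound's `joined_text` (one model
#' call deciding several pairs); remaining instances get singleton queries.
#' The sentence text is the passage (boolean QA) or premise (NLI).
#'
#' @param instances An instance tibble.
#' @param mode `"nli"` or `"boolqa"`.
#' @param compounds Optional output of [detect_compound_entities()] for the
#'   relation's target type.
#' @return A query tibble: `query_id`, `doc_id`, `sent_id`, `mode`,
#'   `relation_type`, `context_text`, `query_text`, and `covered` (list
#'   column of instance keys the query decides).
#' @export
build_queries <- function(instances, mode = c("nli", "boolqa"), compounds = NULL) {
  mode <- match.arg(mode)
  template <- if (mode == "nli") make_hypothesis else make_question
  if (nrow(instances) == 0) {
    return(tibble::tibble(query_id = integer(), doc_id = character(),
                          sent_id = character(), mode = character(),
                          relation_type = character(), context_text = character(),
                          query_text = character(), covered = list()))
  }

  inst <- mutate(instances, .key = instance_key(instances), .compound = NA_integer_)
  comp_rows <- NULL
  if (!is.null(compounds) && nrow(compounds) > 0) {
    for (ci in seq_len(nrow(compounds))) {
      cp <- compounds[ci, ]
      member <- inst$doc_id == cp$doc_id & inst$sent_id == cp$sent_id &
        inst$target_start %in% cp$member_starts[[1]] & is.na(inst$.compound)
      if (!any(member)) next
      # one compound query per distinct source in the sentence
      for (src in unique(inst$source_start[member])) {
        sel <- member & inst$source_start == src
        inst$.compound[sel] <- ci * 10000L + as.integer(src)
        first <- which(sel)[1]
        comp_rows <- bind_rows(comp_rows, tibble::tibble(
          doc_id = cp$doc_id, sent_id = cp$sent_id, mode = mode,
          relation_type = inst$relation_type[first],
          context_text = inst$text[first],
          query_text = template(inst$source_text[first], cp$joined_text,
                                inst$relation_type[first]),
          covered = list(inst$.key[sel])
        ))
      }
    }
  }
  single <- inst[is.na(inst$.compound), ]
  single_rows <- tibble::tibble(
    doc_id = single$doc_id, sent_id = single$sent_id, mode = mode,
    relation_type = single$relation_type,
    context_text = single$text,
    query_text = template(single$source_text, single$target_text,
                          single$relation_type),
    covered = purrr::map(single$.key, identity)
  )
  out <- bind_rows(comp_rows, single_rows)
  out$query_id <- seq_len(nrow(out))
  select(out, "query_id", "doc_id", "sent_id", "mode", "relation_type",
         "context_text", "query_text", "covered")
}

#' Map a backend verdict to a binary relation label
#'
#' `Yes` (boolean QA) and `entailment` (NLI) mean the relation holds;
#' `No`, `neutral` and `contradiction` mean it does not.
#'
#' @param verdict Character vector of verdicts (case-insensitive).
#' @return Integer vector of 0/1 labels.
#' @export
#' @examples
#' verdict_to_label(c("Yes", "No", "entailment", "neutral", "contradiction"))
verdict_to_label <- function(verdict) {
  v <- tolower(verdict)
  ok <- v %in% c("yes", "no", "entailment", "neutral", "contradiction")
  if (!all(ok)) {
    abort(sprintf("Unknown verdict '%s'", verdict[which(!ok)[1]]),
          class = "biodivrelex_contract_error")
  }
  as.integer(v %in% c("yes", "entailment"))
}
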