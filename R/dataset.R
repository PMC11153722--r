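# Candidate-pair construction and dataset splitting. A candidate is every
# (source-typed mention, target-typed mention) pair co-occurring in a
# sentence; the extractors then decide the binary label for each pair.

#' Generate candidate relation instances
#'
#' For each sentence, returns the full cross product of source-typed and
#' target-typed mentions for the requested relation type(s), ordered by
#' `(source_start, target_start)`, with `label = NA` (unlabeled).
#' A sentence with one habitat mention and two geographic-location mentions
#' therefore yields two `has_location` candidates.
#'
#' @param corpus A [biodiv_corpus()].
#' @param relation_type `"has_time"`, `"has_location"`, or both (default).
#' @return An instance tibble (see [read_instances_jsonl()] for the schema).
#' @export
#' @examples
#' fx <- paper_fixture()
#' generate_candidates(fx$corpus, "has_location")
generate_candidates <- function(corpus,
                                relation_type = c("has_time", "has_location")) {
  relation_type <- match.arg(relation_type, several.ok = TRUE)
  txt <- sentence_text(corpus)
  men <- corpus$mentions
  out <- purrr::map(relation_type, function(rt) {
    info <- relation_info(rt)
    src <- men %>%
      filter(.data$entity_type == info$source_type) %>%
      rename(source_type = "entity_type", source_start = "start",
             source_end = "end", source_text = "text")
    tgt <- men %>%
      filter(.data$entity_type == info$target_type) %>%
      rename(target_type = "entity_type", target_start = "start",
             target_end = "end", target_text = "text")
    inner_join(src, tgt, by = c("doc_id", "sent_id"),
               relationship = "many-to-many") %>%
      mutate(relation_type = rt, label = NA_integer_,
             predicted_by = NA_character_)
  })
  bind_rows(out) %>%
    left_join(txt[, c("doc_id", "sent_id", "text")], by = c("doc_id", "sent_id")) %>%
    arrange(.data$doc_id, .data$sent_id, .data$relation_type,
            .data$source_start, .data$target_start) %>%
    select(all_of(instance_cols()))
}

#' Split instances into train / dev / test
#'
#' Deterministic seeded random partition. Split sizes are `round(n * f)` for
#' all but the last fraction, with the remainder assigned to the last split;
#' the same seed always reproduces the same membership. Splitting by
#' sentence (all instances of a sentence kept together) is available to
#' guard against leakage, but the default unit is the instance.
#'
#' @param instances An instance tibble.
#' @param fractions Named or unnamed numeric vector summing to 1; defaults
#'   to the conventional 70/10/20.
#' @param seed Integer seed.
#' @param unit `"instance"` (default) or `"sentence"`.
#' @return The instance tibble with an added `split` column
#'   (`"train"`/`"dev"`/`"test"`, or `split1..k` for other fraction counts).
#' @export
split_instances <- function(instances,
                            fractions = c(train = 0.7, dev = 0.1, test = 0.2),
                            seed = 1L,
                            unit = c("instance", "sentence")) {
  unit <- match.arg(unit)
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("Split fractions must sum to 1", class = "biodivrelex_config_error")
  }
  names(fractions) <- names(fractions) %||%
    if (length(fractions) == 3) c("train", "dev", "test") else paste0("split", seq_along(fractions))

  assign_splits <- function(n) {
    sizes <- round(n * fractions)
    sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
    if (any(sizes < 0)) {
      abort("Fractions produce a negative split size", class = "biodivrelex_config_error")
    }
    perm <- withr::with_seed(seed, sample.int(n))
    lab <- rep(names(fractions), times = sizes)
    lab[order(perm)]  # element i gets the label of its permuted position
  }

  if (unit == "instance") {
    instances$split <- assign_splits(nrow(instances))
  } else {
    keys <- unique(paste(instances$doc_id, instances$sent_id, sep = "\r"))
    lab <- setNames(assign_splits(length(keys)), keys)
    instances$split <- unname(lab[paste(instances$doc_id, instances$sent_id, sep = "\r")])
  }
  instances
}

#' Co-occurrence baseline
#'
#' Labels every candidate pair as related (`1`). Since every intra-sentence
#' pair is predicted positive, recall is always 100% and the Matthews
#' correlation is 0 (no negatives are ever predicted).
#'
#' @param instances An instance tibble.
#' @return The tibble with `label = 1` and `predicted_by = "baseline"`.
#' @export
cooccurrence_baseline <- function(instances) {
  mutate(instances,
         label = rep(1L, dplyr::n()),
         predicted_by = rep("baseline", dplyr::n()))
}
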