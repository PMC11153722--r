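# Dependency-distance relation matching. The sentence's head links form an
# undirected graph (one edge per non-root head attachment); the distance
# between two mentions is the minimum shortest-path length over all token
# pairs drawn from the two spans. Pairs in fragmented parses with no
# connecting path get distance Inf and are never predicted related.

sentence_graph <- function(sent_tokens) {
  n <- nrow(sent_tokens)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  has_edge <- !is.na(sent_tokens$head) & sent_tokens$head > 0
  if (any(has_edge)) {
    g <- igraph::add_edges(g, rbind(sent_tokens$token_id[has_edge],
                                    sent_tokens$head[has_edge]))
  }
  g
}

#' Dependency distances for candidate pairs
#'
#' Adds a `distance` column to an instance table: the number of edges on the
#' shortest undirected path between the source and target mentions
#' (minimum over their token pairs), or `Inf` when no path exists.
#'
#' @param instances An instance tibble (e.g. from [generate_candidates()]).
#' @param corpus The [biodiv_corpus()] the instances came from; all tokens of
#'   the involved sentences must carry head annotations.
#' @return `instances` with a numeric `distance` column.
#' @export
dependency_distances <- function(instances, corpus) {
  if (nrow(instances) == 0) {
    instances$distance <- numeric(0)
    return(instances)
  }
  tokens <- corpus$tokens
  key_tok <- sentence_keys(tokens)
  keys <- unique(paste(instances$doc_id, instances$sent_id, sep = "\r"))

  dists <- setNames(vector("list", length(keys)), keys)
  for (key in keys) {
    sent <- tokens[key_tok == key, ]
    sent <- sent[order(sent$token_id), ]
    if (anyNA(sent$head)) {
      abort(sprintf(
        "Sentence '%s' has tokens without head annotations; run a dependency parser (or use the synthetic generator with parse_emission = TRUE) before computing dependency distances",
        sub("\r", "/", key)
      ), class = "biodivrelex_missing_parse")
    }
    dists[[key]] <- igraph::distances(sentence_graph(sent))
  }

  key_inst <- paste(instances$doc_id, instances$sent_id, sep = "\r")
  instances$distance <- purrr::map_dbl(seq_len(nrow(instances)), function(i) {
    d <- dists[[key_inst[i]]]
    min(d[instances$source_start[i]:instances$source_end[i],
          instances$target_start[i]:instances$target_end[i]])
  })
  instances
}

#' Predict relations by dependency-distance threshold
#'
#' Labels a pair related iff its dependency distance is at most `n`. The
#' default `n = 4` is the development-set choice that maximized F1 for the
#' has_location relation; as `n` grows toward the sentence size the
#' predictions converge to the co-occurrence baseline.
#'
#' @param instances An instance tibble.
#' @param corpus The source [biodiv_corpus()].
#' @param n Maximum dependency distance (>= 1) for a positive prediction.
#' @return The instances with `label` 0/1 and `predicted_by = "rule"`.
#'   Unreachable pairs are labeled 0 with a warning summary.
#' @export
predict_by_distance <- function(instances, corpus, n = 4L) {
  stopifnot(n >= 1)
  scored <- dependency_distances(instances, corpus)
  n_unreach <- sum(is.infinite(scored$distance))
  if (n_unreach > 0) {
    warn(sprintf("%d pair(s) had no dependency path and were labeled 0", n_unreach))
  }
  scored %>%
    mutate(label = as.integer(.data$distance <= n),
           predicted_by = "rule") %>%
    select(-"distance")
}

#' Sweep the dependency-distance threshold
#'
#' Evaluates [predict_by_distance()] for every threshold in `n_range`
#' against gold labels, typically on a development set. Recall (and the
#' predicted-positive count) is non-decreasing in `n` because the prediction
#' sets are nested.
#'
#' @param instances Candidate instances (labels ignored).
#' @param gold Instances with gold 0/1 labels over the same candidate keys.
#' @param corpus The source [biodiv_corpus()].
#' @param n_range Integer thresholds to evaluate (default 1:8).
#' @return A `relex_sweep` tibble with columns `n`, `tp`, `fp`, `fn`, `tn`,
#'   `precision`, `recall`, `f1`, `mcc`.
#' @export
sweep_distance_threshold <- function(instances, gold, corpus, n_range = 1:8) {
  scored <- dependency_distances(instances, corpus)
  rows <- purrr::map(sort(n_range), function(n) {
    pred <- scored %>%
      mutate(label = as.integer(.data$distance <= n)) %>%
      select(-"distance")
    cc <- confusion_counts(pred, gold)
    tibble::tibble(n = n, tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
                   precision = prf1(cc)[["precision"]],
                   recall = prf1(cc)[["recall"]],
                   f1 = prf1(cc)[["f1"]],
                   mcc = mcc(cc))
  })
  structure(bind_rows(rows), class = c("relex_sweep", "tbl_df", "tbl", "data.frame"))
}

#' @export
autoplot.relex_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(long$n)) +
    ggplot2::labs(x = "maximum dependency distance n", y = NULL,
                  colour = NULL,
                  title = "Dependency-distance threshold sweep") +
    ggplot2::theme_minimal()
}
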