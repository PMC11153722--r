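tiny_parsed <- function() {
  # flowering <- occurred(root) -> March, with "in" under March
  toks <- tibble::tibble(
    doc_id = "d", sent_id = "s", token_id = 1:4,
    form = c("flowering", "occurred", "in", "March"),
    head = c(2L, 0L, 4L, 2L)
  )
  men <- tibble::tibble(
    doc_id = "d", sent_id = "s",
    entity_type = c("ReproductiveCondition", "TemporalExpression"),
    start = c(1L, 4L), end = c(1L, 4L)
  )
  biodiv_corpus(toks, men)
}

test_that("dependency distance is the shortest undirected path between spans", {
  corpus <- tiny_parsed()
  cand <- generate_candidates(corpus, "has_time")
  d <- dependency_distances(cand, corpus)
  expect_equal(d$distance, 2)

  # a mention adjacent to its own governor is one edge away
  adj <- cand
  adj$target_start <- 2L; adj$target_end <- 2L
  expect_equal(dependency_distances(adj, corpus)$distance, 1)

  # identical spans are at distance zero
  self <- cand
  self$target_start <- 1L; self$target_end <- 1L
  expect_equal(dependency_distances(self, corpus)$distance, 0)
})

test_that("distances are symmetric and match Floyd-Warshall on random trees", {
  set.seed(77)
  for (trial in 1:40) {
    n <- sample(4:10, 1)
    heads <- random_tree_heads(n)
    toks <- random_span_corpus(n, heads)
    spans <- sort(sample(n, 2))
    men <- tibble::tibble(doc_id = "t", sent_id = "s1",
                          entity_type = c("ReproductiveCondition", "TemporalExpression"),
                          start = spans, end = pmin(spans + sample(0:1, 2, TRUE), n))
    men$end[1] <- min(men$end[1], men$start[2] - 1L)  # keep non-overlapping
    corpus <- biodiv_corpus(toks, men)
    cand <- generate_candidates(corpus, "has_time")
    got <- dependency_distances(cand, corpus)$distance

    fw <- floyd_warshall_distances(heads)
    want <- min(fw[men$start[1]:men$end[1], men$start[2]:men$end[2]])
    expect_equal(got, want)

    flipped <- cand
    flipped[, c("source_start", "source_end", "target_start", "target_end")] <-
      cand[, c("target_start", "target_end", "source_start", "source_end")]
    expect_equal(dependency_distances(flipped, corpus)$distance, got)
  }
})

test_that("missing heads raise an informative error; fragments are unreachable", {
  corpus <- tiny_parsed()
  corpus$tokens$head[3] <- NA_integer_
  cand <- generate_candidates(corpus, "has_time")
  expect_error(dependency_distances(cand, corpus),
               regexp = "parser", class = "biodivrelex_missing_parse")

  frag <- tiny_parsed()
  frag$tokens$head <- c(2L, 0L, 4L, 0L)  # two roots, disconnected halves
  cand <- generate_candidates(frag, "has_time")
  expect_equal(dependency_distances(cand, frag)$distance, Inf)
  expect_warning(pred <- predict_by_distance(cand, frag, n = 8),
                 regexp = "no dependency path")
  expect_equal(pred$label, 0L)
})

test_that("threshold predictions use n inclusively and converge to co-occurrence", {
  corpus <- tiny_parsed()
  cand <- generate_candidates(corpus, "has_time")
  expect_equal(predict_by_distance(cand, corpus, n = 4)$label, 1L)
  expect_equal(predict_by_distance(cand, corpus, n = 2)$label, 1L)
  expect_equal(predict_by_distance(cand, corpus, n = 1)$label, 0L)

  gen <- generate_corpus(generator_config(seed = 8, n_sentences = 40))
  gold <- gen$gold[gen$gold$relation_type == "has_time", ]
  cand <- gold
  n_tokens_max <- max(gen$corpus$tokens$token_id)
  wide <- predict_by_distance(cand, gen$corpus, n = n_tokens_max)
  base <- cooccurrence_baseline(cand)
  expect_equal(wide$label, base$label)
})

test_that("recall and predicted positives are monotone in the sweep threshold", {
  gen <- generate_corpus(generator_config(seed = 19, n_sentences = 60))
  gold <- gen$gold[gen$gold$relation_type == "has_time", ]
  sw <- sweep_distance_threshold(gold, gold, gen$corpus, n_range = 1:8)
  expect_equal(nrow(sw), 8)
  expect_true(all(diff(sw$recall) >= 0))
  expect_true(all(diff(sw$tp + sw$fp) >= 0))
})

test_that("the sweep recovers a planted distance threshold", {
  for (planted in 2:4) {
    cfg <- generator_config(seed = 100 + planted, n_sentences = 120,
                            planted_distance = planted)
    gen <- generate_corpus(cfg)
    gold <- gen$gold
    sw <- sweep_distance_threshold(gold, gold, gen$corpus, n_range = 1:8)
    expect_equal(sw$n[which.max(sw$f1)], planted)
    expect_equal(max(sw$f1), 1.0)
  }
})
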