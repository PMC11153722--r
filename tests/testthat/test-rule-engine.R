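test_that("token-type encoding maps entity membership, delimiters and others", {
  corpus <- enumeration_sentence()
  expect_equal(encode_token_types(corpus, "has_time")$type_string, "SoToTdSoT")
  # no habitat/location mentions: everything is other except the comma
  expect_equal(encode_token_types(corpus, "has_location")$type_string, "ooooodooo")
})

test_that("entity membership beats delimiter status for commas inside mentions", {
  fx <- paper_fixture()
  enc <- encode_token_types(fx$corpus, "has_location")
  dong <- enc$type_string[enc$sent_id == "dongmakhai"]
  # the comma inside the coordinate mention (token 12) encodes as T; the
  # free-standing comma (token 14) stays d
  expect_equal(substr(dong, 12, 12), "T")
  expect_equal(substr(dong, 14, 14), "d")
})

test_that("regex rules pair each source with its delimited targets only", {
  corpus <- enumeration_sentence()
  pairs <- apply_regex_rules(corpus, "has_time")
  got <- paste(pairs$source_text, pairs$target_text)
  expect_setequal(got, c("flowering March", "flowering April", "fruiting May"))
  expect_true(all(pairs$label == 1L))
  expect_true(all(pairs$predicted_by == "rule"))

  expect_equal(nrow(regex_rule_matches("oToTd")), 0)  # no source, no match
})

test_that("a source separated from its target by two other tokens is not rule-matched", {
  fx <- paper_fixture()
  pairs <- apply_regex_rules(fx$corpus, "has_time")
  # "setting fruit only in 1968" encodes SooT: left for the backend
  expect_false(any(pairs$source_text == "fruit"))
  expect_setequal(pairs$target_text[pairs$source_text == "flowered"],
                  c("July - August 1963", "May - June 1968"))
})

test_that("rule matching and pair extraction agree with the grammar oracle", {
  set.seed(20251001)
  for (i in 1:1000) {
    len <- sample(1:12, 1)
    s <- paste(sample(c("S", "T", "d", "o"), len, replace = TRUE,
                      prob = c(0.3, 0.3, 0.15, 0.25)), collapse = "")
    got <- regex_rule_matches(s)
    want <- oracle_rule_matches(s)
    expect_equal(as.data.frame(got[order(got$rule, got$start), ]),
                 want[order(want$rule, want$start), ],
                 ignore_attr = TRUE, label = paste("matches for", s))

    corpus <- corpus_from_type_string(s)
    pairs <- apply_regex_rules(corpus, "has_time")
    got_pairs <- unique(paste(pairs$source_start, pairs$target_start))
    want_df <- oracle_char_pairs(s)
    want_pairs <- unique(paste(want_df$s, want_df$t))
    expect_setequal(got_pairs, want_pairs)
  }
})

test_that("compound detection groups same-type runs separated by one token", {
  fx <- paper_fixture()
  comp <- detect_compound_entities(fx$corpus, "TemporalExpression")
  expect_equal(nrow(comp), 1)
  expect_equal(comp$n_members, 2)
  expect_equal(comp$joined_text, "July - August 1963 and May - June 1968")

  # a single mention can never form a compound
  single <- biodiv_corpus(
    tibble::tibble(doc_id = "d", sent_id = "s", token_id = 1:2,
                   form = c("in", "March")),
    tibble::tibble(doc_id = "d", sent_id = "s",
                   entity_type = "TemporalExpression", start = 2L, end = 2L)
  )
  expect_equal(nrow(detect_compound_entities(single, "TemporalExpression")), 0)

  # two tokens between members break the run
  far <- biodiv_corpus(
    tibble::tibble(doc_id = "d", sent_id = "s", token_id = 1:4,
                   form = c("March", "and", "also", "April")),
    tibble::tibble(doc_id = "d", sent_id = "s",
                   entity_type = rep("TemporalExpression", 2),
                   start = c(1L, 4L), end = c(1L, 4L))
  )
  expect_equal(nrow(detect_compound_entities(far, "TemporalExpression")), 0)
})

test_that("compound members never overlap and number at least two", {
  gen <- generate_corpus(generator_config(seed = 31, n_sentences = 60))
  for (etype in c("TemporalExpression", "GeographicLocation")) {
    comp <- detect_compound_entities(gen$corpus, etype)
    if (nrow(comp) == 0) next
    expect_true(all(comp$n_members >= 2))
    for (i in seq_len(nrow(comp))) {
      starts <- comp$member_starts[[i]]
      ends <- comp$member_ends[[i]]
      expect_true(all(diff(starts) > 0))
      expect_true(all(ends[-length(ends)] < starts[-1]))
    }
  }
})

test_that("rules attain perfect precision on rule-matchable synthetic structure", {
  cfg <- generator_config(
    seed = 17, n_sentences = 60,
    structure_weights = c(adjacent_pair = 0.5, enumeration = 0.5,
                          compound_run = 0, reversed_order = 0,
                          distractor_only = 0)
  )
  gen <- generate_corpus(cfg)
  for (rt in c("has_time", "has_location")) {
    gold <- gen$gold[gen$gold$relation_type == rt, ]
    if (nrow(gold) == 0) next
    pred <- run_method(gen$corpus, "regex", rt)
    ev <- evaluate_relations(pred, gold)
    expect_equal(ev$precision, 1.0)
    expect_equal(ev$recall, 1.0)
  }
})
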