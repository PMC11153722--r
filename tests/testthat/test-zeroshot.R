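test_that("question and hypothesis templates reproduce the published strings", {
  expect_identical(
    make_question("lowland dipterocarp forest", "Bukit Sai", "has_location"),
    "Is there lowland dipterocarp forest in Bukit Sai?"
  )
  expect_identical(
    make_question("fruit", "August 1963", "has_time"),
    "Did fruit event happen on August 1963?"
  )
  expect_identical(
    make_hypothesis("lowland dipterocarp forest", "Bukit Sai", "has_location"),
    "The lowland dipterocarp forest was in Bukit Sai."
  )
  expect_identical(
    make_hypothesis("fruit", "August 1963", "has_time"),
    "The fruit event happened on August 1963."
  )
})

test_that("every candidate is covered by exactly one query", {
  gen <- generate_corpus(generator_config(seed = 6, n_sentences = 40))
  cand <- gen$gold[gen$gold$relation_type == "has_time", ]
  for (use_comp in c(FALSE, TRUE)) {
    comp <- if (use_comp) {
      detect_compound_entities(gen$corpus, "TemporalExpression")
    }
    q <- build_queries(cand, mode = "nli", compounds = comp)
    covered <- unlist(q$covered)
    expect_equal(sort(covered), sort(unique(covered)))
    expect_equal(length(covered), nrow(cand))
  }
})

test_that("a compound target yields one query deciding several pairs", {
  fx <- paper_fixture()
  cand <- generate_candidates(fx$corpus, "has_time")
  flowered <- cand[cand$sent_id == "flowered" & cand$source_text == "flowered", ]
  comp <- detect_compound_entities(fx$corpus, "TemporalExpression")
  q <- build_queries(flowered, mode = "nli", compounds = comp)
  compound_q <- q[lengths(q$covered) > 1, ]
  expect_equal(nrow(compound_q), 1)
  expect_identical(
    compound_q$query_text,
    "The flowered event happened on July - August 1963 and May - June 1968."
  )
  expect_equal(lengths(compound_q$covered), 2)
  # the bare final 1968 is outside the compound and keeps its own query
  expect_equal(nrow(q), 2)
})

test_that("verdicts map to labels by entailment/yes only", {
  expect_equal(
    verdict_to_label(c("Yes", "No", "entailment", "neutral", "contradiction")),
    c(1L, 0L, 1L, 0L, 0L)
  )
  expect_error(verdict_to_label("maybe"), class = "biodivrelex_contract_error")
})

test_that("mock backend obeys its lookup table and is deterministic", {
  q <- tibble::tibble(
    query_id = 1:2, doc_id = "d", sent_id = "s", mode = "boolqa",
    relation_type = "has_location",
    context_text = c("oak savanna covers Luzon .", "nothing here ."),
    query_text = c("Is there oak savanna in Luzon?", "Is there forest in Mars?"),
    covered = list("k1", "k2")
  )
  be <- backend_mock(lookup = c("Is there forest in Mars?" = "No"),
                     heuristic = FALSE)
  out1 <- classify(be, q)
  out2 <- classify(be, q)
  expect_identical(out1$verdict, out2$verdict)
  expect_equal(out1$verdict, c("No", "No"))  # no lookup hit -> negative default

  heur <- classify(backend_mock(), q)
  expect_equal(heur$verdict[1], "Yes")  # all entity words occur in context
})

test_that("gold-echo backend answers from covered pair labels", {
  fx <- paper_fixture()
  cand <- generate_candidates(fx$corpus, "has_time")
  q <- build_queries(cand, mode = "nli")
  be <- backend_gold_echo(fx$gold)
  out <- classify(be, q)
  labels <- verdict_to_label(out$verdict)
  key <- unlist(out$covered)
  gold_key <- setNames(fx$gold$label,
                       paste(fx$gold$doc_id, fx$gold$sent_id, fx$gold$relation_type,
                             fx$gold$source_start, fx$gold$source_end,
                             fx$gold$target_start, fx$gold$target_end, sep = "\r"))
  expect_equal(unname(rep(labels, lengths(out$covered))), unname(gold_key[key]))
})

test_that("backend resolution errors are actionable", {
  expect_s3_class(resolve_backend("mock"), "relex_backend")
  expect_error(resolve_backend("t5-nli"),
               regexp = "backend_mock",
               class = "biodivrelex_backend_unavailable")
  expect_error(resolve_backend("nonsense"),
               class = "biodivrelex_config_error")
})
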