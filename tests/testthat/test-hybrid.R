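test_that("hybrid labels rule matches first and defers the rest to the backend", {
  # flowering in March and April , fruiting in May  ("SoToTdSoT"):
  # 2 sources x 3 targets = 6 candidates; rules decide 3, backend gets 3
  corpus <- enumeration_sentence()
  cand <- generate_candidates(corpus, "has_time")
  expect_equal(nrow(cand), 6)
  gold <- dplyr::mutate(cand, label = dplyr::if_else(
    paste(source_text, target_text) %in%
      c("flowering March", "flowering April", "fruiting May"), 1L, 0L))
  out <- run_hybrid(corpus, "has_time", backend_gold_echo(gold),
                    use_compound = FALSE)
  stats <- attr(out, "stats")
  expect_equal(stats$candidates, 6)
  expect_equal(stats$rule_positives, 3)
  expect_equal(stats$backend_queries, 3)
  expect_equal(sort(unique(out$predicted_by)), c("backend", "rule"))
  expect_equal(evaluate_relations(out, gold)$f1, 1.0)
})

test_that("with no rule matches the backend receives every candidate", {
  fx <- paper_fixture()
  cand <- generate_candidates(fx$corpus, "has_location")
  bukitsai_gold <- fx$gold[fx$gold$relation_type == "has_location", ]
  out <- run_hybrid(fx$corpus, "has_location", backend_gold_echo(bukitsai_gold),
                    use_compound = FALSE)
  by_sent <- table(out$sent_id, out$predicted_by)
  expect_equal(unname(by_sent["bukitsai", "backend"]), 2)  # rules silent there
  expect_equal(unname(by_sent["dongmakhai", "rule"]), 2)
})

test_that("hybrid output covers every candidate exactly once and supersets rule positives", {
  gen <- generate_corpus(generator_config(seed = 23, n_sentences = 80))
  for (rt in c("has_time", "has_location")) {
    cand <- generate_candidates(gen$corpus, rt)
    gold <- gen$gold[gen$gold$relation_type == rt, ]
    out <- run_hybrid(gen$corpus, rt, backend_gold_echo(gold))
    expect_equal(nrow(out), nrow(cand))
    key <- paste(out$sent_id, out$source_start, out$target_start)
    expect_false(any(duplicated(key)))

    regex_only <- run_method(gen$corpus, "regex", rt)
    rk <- paste(regex_only$sent_id, regex_only$source_start, regex_only$target_start)
    expect_true(all(rk[regex_only$label == 1] %in% key[out$label == 1]))
  }
})

test_that("compound grouping strictly reduces backend calls when compounds exist", {
  gen <- generate_corpus(generator_config(
    seed = 41, n_sentences = 60,
    structure_weights = c(adjacent_pair = 0.2, enumeration = 0.2,
                          compound_run = 0.4, reversed_order = 0.1,
                          distractor_only = 0.1)
  ))
  gold <- gen$gold[gen$gold$relation_type == "has_time", ]
  be <- backend_gold_echo(gold)
  plain <- attr(run_hybrid(gen$corpus, "has_time", be, use_compound = FALSE), "stats")
  comp <- attr(run_hybrid(gen$corpus, "has_time", be, use_compound = TRUE), "stats")
  expect_lte(plain$backend_queries, plain$candidates)
  expect_gt(comp$compound_groups, 0)
  expect_lt(comp$backend_queries, plain$backend_queries)
})

test_that("a gold-echoing backend makes the hybrid reproduce gold exactly", {
  gen <- generate_corpus(generator_config(seed = 57, n_sentences = 100))
  for (rt in c("has_time", "has_location")) {
    gold <- gen$gold[gen$gold$relation_type == rt, ]
    if (nrow(gold) == 0) next
    out <- run_hybrid(gen$corpus, rt, backend_gold_echo(gold), use_compound = TRUE)
    ev <- evaluate_relations(out, gold)
    expect_equal(ev$f1, 1.0)
    expect_equal(ev$mcc, 1.0)
  }
})

test_that("a nondeterministic backend is rejected as a contract violation", {
  flaky <- structure(list(state = new.env()), class = c("flaky_backend", "relex_backend"))
  flaky$state$flip <- FALSE
  registerS3method("classify", "flaky_backend", function(backend, queries) {
    backend$state$flip <- !backend$state$flip
    queries$verdict <- if (backend$state$flip) "entailment" else "neutral"
    queries$score <- NA_real_
    queries
  }, envir = asNamespace("biodivrelex"))
  fx <- paper_fixture()
  expect_error(run_hybrid(fx$corpus, "has_location", flaky),
               class = "biodivrelex_contract_error")
})

test_that("run_method dispatches the seven comparable extractors", {
  fx <- paper_fixture()
  gold_time <- fx$gold[fx$gold$relation_type == "has_time", ]
  be <- backend_gold_echo(fx$gold)

  co <- run_method(fx$corpus, "cooccurrence", "has_time")
  expect_true(all(co$label == 1L))

  rx <- run_method(fx$corpus, "regex", "has_time")
  expect_equal(sum(rx$label), 2)          # standalone: non-matches are 0
  expect_true(all(rx$label %in% 0:1))

  dd <- run_method(fx$corpus, "distance", "has_time", distance_n = 1L)
  expect_equal(sum(dd$label), 1)          # only flowered ~ July-August 1963

  nli <- run_method(fx$corpus, "nli", "has_time", backend = be)
  expect_true(all(nli$predicted_by == "backend"))

  hc <- run_method(fx$corpus, "hybrid_compound", "has_time", backend = be)
  expect_true(all(rx$label[rx$label == 1] <= 1) &&
                all(paste(rx$sent_id, rx$source_start, rx$target_start)[rx$label == 1] %in%
                      paste(hc$sent_id, hc$source_start, hc$target_start)[hc$label == 1]))

  expect_error(run_method(fx$corpus, "magic", "has_time"),
               class = "biodivrelex_config_error")
  expect_error(run_method(fx$corpus, "nli", "has_time"),
               regexp = "backend", class = "biodivrelex_config_error")
})
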