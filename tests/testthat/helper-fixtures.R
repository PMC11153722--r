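# The enumeration sentence used across rule and hybrid tests: two
# reproductive events, three months, a comma delimiter; its has_time
# token-type encoding is "SoToTdSoT".
enumeration_sentence <- function() {
  toks <- tibble::tibble(
    doc_id = "d", sent_id = "s",
    token_id = 1:9,
    form = c("flowering", "in", "March", "and", "April", ",", "fruiting", "in", "May")
  )
  men <- tibble::tibble(
    doc_id = "d", sent_id = "s",
    entity_type = c("ReproductiveCondition", "TemporalExpression",
                    "TemporalExpression", "ReproductiveCondition",
                    "TemporalExpression"),
    start = c(1L, 3L, 5L, 7L, 9L), end = c(1L, 3L, 5L, 7L, 9L)
  )
  biodiv_corpus(toks, men)
}
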