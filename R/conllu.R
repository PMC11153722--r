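# CoNLL-U I/O with the biodiv FEATS extension. Entity annotations travel as
# a `biodiv=<BIO-tag>` feature in the FEATS (6th) column so files stay valid
# for standard CoNLL-U tooling. Multiword-token ranges (ID "1-2") and empty
# nodes (ID "1.1") are carried through verbatim but ignored for entities and
# dependencies.

CONLLU_COLS <- c("id", "form", "lemma", "upos", "xpos", "feats",
                 "head", "deprel", "deps", "misc")

#' Read a CoNLL-U file with biodiv entity annotations
#'
#' Parses 10-column CoNLL-U. Sentence boundaries are blank lines; `# sent_id`
#' and `# newdoc id` comments set identifiers (falling back to running
#' numbers). A `biodiv=<BIO-tag>` entry in FEATS marks entity membership;
#' tokens without one are outside every mention. BIO tags are decoded into
#' mention spans via [decode_bio_tags()].
#'
#' @param path Path to a CoNLL-U file, or a character vector of lines
#'   (anything containing a newline or of length > 1 is treated as content).
#' @return A [biodiv_corpus()]. Carry-through columns `lemma`, `xpos`,
#'   `feats` (minus the biodiv entry), `deps`, `misc` are kept so that
#'   [write_conllu_biodiv()] round-trips.
#' @export
read_conllu_biodiv <- function(path) {
  lines <- if (length(path) > 1 || grepl("\n", path, fixed = TRUE)) {
    unlist(strsplit(path, "\n", fixed = TRUE))
  } else {
    readLines(path, encoding = "UTF-8", warn = FALSE)
  }

  doc_id <- "doc1"; sent_no <- 0L; sent_id <- NULL
  rows <- list(); pending <- FALSE
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (line == "") { pending <- FALSE; sent_id <- NULL; next }
    if (startsWith(line, "#")) {
      if (grepl("^# *newdoc id *=", line)) {
        doc_id <- trimws(sub("^# *newdoc id *=", "", line))
      } else if (grepl("^# *sent_id *=", line)) {
        sent_id <- trimws(sub("^# *sent_id *=", "", line))
      }
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 10) {
      abort(sprintf("Line %d: expected 10 tab-separated columns, found %d",
                    ln, length(fields)),
            class = "biodivrelex_parse_error")
    }
    if (!pending) {
      sent_no <- sent_no + 1L
      if (is.null(sent_id)) sent_id <- as.character(sent_no)
      pending <- TRUE
    }
    rows[[length(rows) + 1L]] <-
      c(list(doc_id = doc_id, sent_id = sent_id, line = ln), setNames(as.list(fields), CONLLU_COLS))
  }
  raw <- bind_rows(rows)
  if (nrow(raw) == 0) {
    return(biodiv_corpus(tibble::tibble(
      doc_id = character(), sent_id = character(), token_id = integer(),
      form = character()
    )))
  }

  word <- raw[grepl("^[0-9]+$", raw$id), ]
  biodiv <- extract_biodiv_feat(word$feats, word$line)
  tokens <- tibble::tibble(
    doc_id = word$doc_id, sent_id = word$sent_id,
    token_id = as.integer(word$id), form = word$form,
    upos = na_if_underscore(word$upos),
    head = as.integer(ifelse(word$head == "_", NA, word$head)),
    deprel = na_if_underscore(word$deprel),
    lemma = word$lemma, xpos = word$xpos,
    feats = biodiv$rest, deps = word$deps, misc = word$misc,
    bio = biodiv$tag
  )
  mentions <- decode_bio_tags(tokens)
  tokens$bio <- NULL
  biodiv_corpus(tokens, mentions)
}

na_if_underscore <- function(x) ifelse(x == "_", NA_character_, x)

extract_biodiv_feat <- function(feats, line_no) {
  parts <- strsplit(feats, "|", fixed = TRUE)
  tag <- character(length(feats)); rest <- character(length(feats))
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    is_bd <- startsWith(p, "biodiv=")
    if (sum(is_bd) > 1) {
      abort(sprintf("Line %d: multiple biodiv features", line_no[i]),
            class = "biodivrelex_parse_error")
    }
    if (any(is_bd)) {
      val <- sub("^biodiv=", "", p[is_bd])
      if (!grepl("^(O|[BI]-.+)$", val)) {
        abort(sprintf("Line %d: 'biodiv=%s' is not a valid BIO tag", line_no[i], val),
              class = "biodivrelex_parse_error")
      }
      tag[i] <- val
    } else {
      tag[i] <- "O"
    }
    keep <- p[!is_bd & p != "_"]
    rest[i] <- if (length(keep)) paste(keep, collapse = "|") else "_"
  }
  list(tag = tag, rest = rest)
}

#' Write a corpus as CoNLL-U with biodiv entity annotations
#'
#' Inverse of [read_conllu_biodiv()]: BIO tags are re-encoded from the
#' mention table and appended to FEATS as `biodiv=<tag>` (joined with `|`
#' onto any existing features; `_` when there are none and the token is
#' outside all mentions). ID, FORM, HEAD, DEPREL and biodiv content
#' round-trip exactly.
#'
#' @param corpus A [biodiv_corpus()].
#' @param path Optional output path; when `NULL` the CoNLL-U text is
#'   returned as a single string.
#' @return `path` invisibly when writing to a file, otherwise the text.
#' @export
write_conllu_biodiv <- function(corpus, path = NULL) {
  tokens <- encode_bio_tags(corpus)
  for (col in c("lemma", "xpos", "feats", "deps", "misc")) {
    if (!col %in% names(tokens)) tokens[[col]] <- "_"
  }
  out <- character()
  keys <- unique(sentence_keys(tokens))
  last_doc <- NULL
  for (key in keys) {
    sent <- tokens[sentence_keys(tokens) == key, ]
    sent <- sent[order(sent$token_id), ]
    feats <- ifelse(
      sent$bio == "O", sent$feats,
      ifelse(sent$feats == "_", paste0("biodiv=", sent$bio),
             paste0(sent$feats, "|biodiv=", sent$bio))
    )
    lines <- paste(
      sent$token_id, sent$form, sent$lemma,
      ifelse(is.na(sent$upos), "_", sent$upos), sent$xpos, feats,
      ifelse(is.na(sent$head), "_", sent$head),
      ifelse(is.na(sent$deprel), "_", sent$deprel),
      sent$deps, sent$misc,
      sep = "\t"
    )
    header <- character()
    if (!identical(last_doc, sent$doc_id[1])) {
      header <- sprintf("# newdoc id = %s", sent$doc_id[1])
      last_doc <- sent$doc_id[1]
    }
    out <- c(out, header, sprintf("# sent_id = %s", sent$sent_id[1]), lines, "")
  }
  text <- paste(out, collapse = "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, useBytes = TRUE)
  invisible(path)
}
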