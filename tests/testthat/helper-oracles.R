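# Independent oracles, written without regexes or igraph so they cannot
# share a defect with the implementation paths they check.

# -- rule grammar recognizers (full-string match, character-by-character) --

# decompose ch[i..n] into >= 1 units of To / Td / T, consuming it exactly
units_exact <- function(ch, i, n) {
  if (i > n || ch[i] != "T") return(FALSE)
  for (len in c(2L, 1L)) {
    j <- i + len - 1L
    if (j > n) next
    if (len == 2L && !(ch[i + 1L] %in% c("o", "d"))) next
    if (j == n || units_exact(ch, j + 1L, n)) return(TRUE)
  }
  FALSE
}

# decompose ch[i..j] into >= 0 units of To / Td / T
units_star <- function(ch, i, j) {
  if (i > j) return(TRUE)
  units_exact(ch, i, j)
}

# source run, optional other, then delimited target run
full_match_forward <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  for (a in seq_len(n)) {
    if (ch[a] != "S") break
    for (b in 0:1) {
      k <- a + b
      if (b == 1 && (k > n || ch[k] != "o")) next
      if (k < n && units_exact(ch, k + 1L, n)) return(TRUE)
    }
  }
  FALSE
}

# target run, then a source run optionally preceded by one other token
full_match_backward <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  for (p in seq_len(n)) {          # position of the mandatory T
    if (ch[p] != "T") next
    if (!units_star(ch, 1L, p - 1L)) next
    for (b in 0:1) {
      k <- p + b
      if (b == 1 && (k > n || ch[k] != "o")) next
      if (k < n && all(ch[(k + 1L):n] == "S")) return(TRUE)
    }
  }
  FALSE
}

# left-to-right non-overlapping scan taking the longest full match at each
# start; the backward rule may not start right after an S (lookbehind)
oracle_rule_matches <- function(type_string) {
  ch <- strsplit(type_string, "")[[1]]
  n <- length(ch)
  out <- list()
  for (rule in c("forward", "backward")) {
    matcher <- if (rule == "forward") full_match_forward else full_match_backward
    pos <- 1L
    while (pos <= n) {
      if (rule == "backward" && pos > 1L && ch[pos - 1L] == "S") {
        pos <- pos + 1L
        next
      }
      best <- 0L
      for (end in n:pos) {
        if (matcher(substr(type_string, pos, end))) { best <- end; break }
      }
      if (best > 0L) {
        out[[length(out) + 1L]] <- data.frame(rule = rule, start = pos, end = best)
        pos <- best + 1L
      } else {
        pos <- pos + 1L
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(rule = character(), start = integer(), end = integer())
}

# pairs from oracle matches: every (S position, T position) fully inside a
# match span (single-char mentions)
oracle_char_pairs <- function(type_string) {
  ch <- strsplit(type_string, "")[[1]]
  m <- oracle_rule_matches(type_string)
  pairs <- unique(do.call(rbind, lapply(seq_len(nrow(m)), function(j) {
    span <- seq.int(m$start[j], m$end[j])
    s_pos <- span[ch[span] == "S"]
    t_pos <- span[ch[span] == "T"]
    if (!length(s_pos) || !length(t_pos)) return(NULL)
    expand.grid(s = s_pos, t = t_pos)
  })))
  if (is.null(pairs)) data.frame(s = integer(), t = integer()) else pairs
}

# build a corpus whose token-type encoding is exactly `type_string`, with
# each S and T character its own single-token mention
corpus_from_type_string <- function(type_string, relation_type = "has_time") {
  ch <- strsplit(type_string, "")[[1]]
  info <- as.list(relation_types()[relation_types()$relation_type == relation_type, ])
  forms <- c(S = "flowering", T = "March", d = ",", o = "x")[ch]
  tokens <- tibble::tibble(doc_id = "t", sent_id = "s1",
                           token_id = seq_along(ch), form = unname(forms))
  idx <- which(ch %in% c("S", "T"))
  mentions <- tibble::tibble(
    doc_id = "t", sent_id = "s1",
    entity_type = ifelse(ch[idx] == "S", info$source_type, info$target_type),
    start = idx, end = idx
  )
  biodiv_corpus(tokens, mentions)
}

# -- all-pairs shortest paths by Floyd-Warshall over the head links --

floyd_warshall_distances <- function(head) {
  n <- length(head)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (i in seq_len(n)) {
    if (!is.na(head[i]) && head[i] > 0) d[i, head[i]] <- d[head[i], i] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# random dependency tree: token i attaches to an earlier token (or root)
random_tree_heads <- function(n) {
  vapply(seq_len(n), function(i) {
    if (i == 1) 0L else sample.int(i - 1L, 1L)
  }, integer(1))
}

random_span_corpus <- function(n_tokens, heads) {
  tibble::tibble(doc_id = "t", sent_id = "s1", token_id = seq_len(n_tokens),
                 form = paste0("w", seq_len(n_tokens)), head = heads)
}
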