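---
title: "Methods: unsupervised relation extraction for biodiversity text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised relation extraction for biodiversity text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodivrelex)
```

## The task and its assumptions

The package decides, for entity pairs co-occurring in a sentence, whether a
binary relation holds: `has_time` from a reproductive-condition mention to
a temporal expression, and `has_location` from a habitat mention to a
geographic location. Three assumptions are load-bearing:

* **Entities are given.** Named-entity recognition happens upstream; input
  corpora arrive with mentions already marked (as `biodiv=` BIO tags in
  CoNLL-U FEATS, or as spans in JSONL). Mentions are whole-token,
  contiguous, and non-overlapping within a sentence; nested or
  discontinuous mentions are rejected at construction.
* **Relations are intra-sentence.** Candidates are the cross product of
  source-typed and target-typed mentions within one sentence; nothing
  crosses sentence boundaries.
* **No training.** Every component is either hand-written (rules) or a
  zero-shot use of a model trained for another task (boolean QA, NLI).
  Labeled data is needed only to *evaluate*.

## The extractors

**Token-type rules.** Per relation type, a sentence becomes one character
per token: `S` inside a source mention, `T` inside a target mention, `d`
for a bare `,`/`;`, `o` otherwise. Entity membership wins over delimiter
status — the comma inside a coordinate mention such as
`18deg20'03"N , 102deg30'5"E` is `T`, because token typing is defined by
entity membership first and coordinates legitimately contain commas. Two
patterns are scanned independently with ordinary left-to-right,
non-overlapping, greedy regex semantics:

* `[S]+(o)?(To|Td|T)+` — a source run, at most one intervening token, then
  a delimited target run;
* `(?<!S)(To|Td|T)*T(o)?[S]+` — the mirror image, targets first.

Every source and target mention whose span lies *entirely* inside a match
is paired; a partially covered mention was not matched in any defensible
sense. The union over both rules is returned, deduplicated. The engine
dialect (greedy non-overlapping scan, union across rules) is pinned down by
a property test: on random type strings the matcher must agree with a
brute-force recognizer that takes the longest grammar-accepted substring at
each leftmost start.

**Dependency distance.** Head links define an undirected graph; the
distance between two mentions is the minimum shortest-path length over all
token pairs drawn from the two spans. Undirected traversal is deliberate —
counting edges "along the path" regardless of direction — since a
directed-only reading would leave most pairs unreachable. Min-over-pairs is
the span anchor because it is symmetric and tolerant of attachment errors
inside a mention. Punctuation participates as parsed; no pruning. A pair
with no path (fragmented parse) gets distance `Inf`, is never predicted
related, and is counted in a warning. A pair is predicted related iff its
distance is at most `n`.

**Zero-shot templating.** Each undecided pair is rendered with one of four
fixed templates (question or hypothesis per relation type), inserting
entity surface text verbatim — no inflection repair, since inference models
are expected to tolerate slightly ungrammatical fills. A backend maps each
query to `Yes`/`No` or `entailment`/`neutral`/`contradiction`; only
`Yes`/`entailment` means related. Backends must be deterministic; the
pipeline classifies each batch twice and raises a contract violation if
verdicts differ. Probabilistic boolean-QA backends should decide by argmax
(equivalently a 0.5 threshold when a single probability is exposed): the
method's outputs are class decisions, not calibrated scores.

**Compound entities and the hybrid.** Runs of two or more same-type
mentions separated by at most one token — matched by `(Et|E){2,}` over an
entity-granular string (`E` per mention, `t` per other token) — form a
compound whose `joined_text` concatenates members and single separators.
The two-step hybrid labels regex matches first, then queries the backend
once per (source, compound) plus once per uncovered pair; a compound
query's verdict propagates uniformly to every pair it covers. Uniform
propagation is a documented choice, not an inference: when a compound mixes
a true and a false member the whole group inherits one verdict, which is
the price of the reduced query count. Rule positives are never overridden.
Step 2 can only add positives, so hybrid positives always contain
standalone-rule positives.

## Tunable parameters

| Parameter | Where | Default | Why |
|---|---|---|---|
| `n` (max dependency distance) | `predict_by_distance()` | 4 | development-set choice for has_location; sweep 1–8 and pick by F1 for new corpora |
| `use_compound` | `run_hybrid()` | `TRUE` | enables query grouping; disable to score each pair independently |
| `mode` | `run_hybrid()`, `build_queries()` | `"nli"` | the NLI formulation is the most precise backend family in our comparisons |
| split fractions | `split_instances()` | 0.7/0.1/0.2 | conventional train/dev/test protocol |
| compound scope | `detect_compound_entities()` | targets | grouping is applied to target entities; sources are left singular (the enumerated side in this literature is overwhelmingly the target: date and place lists) |

Sizes are `round(n * f)` with the remainder assigned to the last split —
deterministic and documented, at the cost of a possible one-off on the test
split. The split unit defaults to the instance; a sentence-level unit is
available against leakage when candidates from one sentence should not
straddle splits.

## The synthetic generator

Real gold corpora for this task are small and not freely redistributable,
so the package ships a seeded generator (`generate_corpus()`) whose
sentences are drawn from five structure templates: rule-matchable
source–target adjacency, delimiter-separated enumerations, compound target
runs placed *out of reach* of the rules (two tokens after the source),
target-before-source order, and distractor co-occurrences with gold label
0. Defaults: 100 sentences, a 77/23 has_time/has_location mix mirroring
the imbalance of instances in dipterocarp phenology literature, structure
weights (0.30, 0.20, 0.15, 0.15, 0.20), vocabularies drawn as small closed
lists from that literature's typical habitats, toponyms, reproductive
terms and temporal expressions. Each sentence carries one source mention
and one to five targets; the single-source simplification keeps planted
dependency distances exact (a second source anchored elsewhere would
perturb min-over-pairs distances).

With `parse_emission = TRUE` the generator emits head links by a simple
scheme — sentence-final punctuation as root, mention-initial tokens as
anchors, other span tokens attached to their anchor — and *plants*
distances: each related pair is connected through a chain of spare tokens
of length drawn from `1..planted_distance` (default 3), each unrelated pair
at exactly `planted_distance + 1`. Only path lengths matter downstream, so
no claim of syntactic realism is made. The planting makes two things
testable: a threshold sweep on gold labels recovers `planted_distance`
uniquely, and the distance extractor at the recovered threshold is perfect
on generated data (which real parses will never be).

What the generator does **not** emulate — hence what passing tests do not
show about real data: OCR noise and tokenization errors, genuine parse
ambiguity, entity mentions the NER layer missed or hallucinated, relations
whose evidence is semantic rather than positional, and the long tail of
sentence structures outside the five templates. Metrics on synthetic
corpora characterize the *machinery* (coverage, precision of the rules on
rule-shaped text, query bookkeeping), not expected field performance.

## Numerical and representational choices

* **Indices.** Token ids are 1-based and contiguous per sentence, matching
  CoNLL-U IDs and R convention; mention spans are inclusive `start..end`.
  The JSONL exchange format instead stores 0-based half-open spans so files
  interoperate with implementations in 0-based languages; conversion
  happens only at that boundary.
* **BIO ingestion.** An `I-X` without a preceding `B-X`/`I-X` of the same
  type starts a new mention (orphan-I promotion): tolerant of noisy
  annotations, while the encode/decode round-trip property is asserted on
  well-formed input.
* **CoNLL-U dialect.** Entity annotations are stored as a `biodiv=` entry
  in FEATS (joined with `|` to existing features, `_` when empty), keeping
  files valid for standard tooling. Multiword-token ranges and empty nodes
  are ignored for entities and distances.
* **Metrics conventions.** P, R, F1 and MCC all return 0.0 on a zero
  denominator. This is what makes the all-positive co-occurrence baseline
  score recall 100% with MCC exactly 0 — the degenerate denominator factor
  (`tn + fn = 0`) is mapped to 0, not NaN. Reports print percentages with
  two decimals. Annotator agreement is binary F1 with the annotators in
  either order (P and R swap; F1 is invariant), micro-averaged over
  whatever relation types the aligned tables contain.
* **Determinism.** All sampling (generator, splits) is wrapped in
  `withr::with_seed`; the same seed gives byte-identical CoNLL-U and JSONL
  output. Backends must be pure functions of the query.
* **Degenerate inputs.** Empty corpora, sentences without candidate pairs,
  and empty instance tables flow through every function as empty tibbles
  with the right columns rather than errors; missing heads raise a
  dedicated condition telling the caller to parse first.

## Problem sizes used in the shipped checks

The test suite exercises 1,000 random type strings (length ≤ 12) against
the rule-grammar oracle, 50 random trees (≤ 10 tokens) against a
Floyd–Warshall oracle, 100 generator seeds for invariant fuzzing, and
corpora of 40–200 sentences for the behavioral properties; the
reproduction script generates 300 sentences. These sizes give exact or
near-exhaustive coverage of the discrete structures involved while keeping
a full run comfortably interactive.

## Known limitations

* The three published transformer checkpoints are not bundled; the
  `classify()` contract plus the mock and gold-echo backends stand in.
  Wiring a real model server means implementing one S3 method.
* Surface text is reconstructed by space-joining tokens; original spacing
  is not stored. Templates and JSONL tokens inherit this.
* A compound query covering pairs of mixed gold truth propagates one
  verdict to all of them (see above).
* The co-occurrence candidate model caps recall of every extractor at
  whatever fraction of true relations is intra-sentence.
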