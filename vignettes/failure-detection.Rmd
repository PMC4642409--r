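---
title: "Auditing concept-mapper output on community text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing concept-mapper output on community text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maplint)
```

## The method

Concept mappers built for clinical and scholarly prose misfire on
patient-generated community text in systematic, recognizable ways.
`maplint` treats each mapper assertion — one record per mapped term
occurrence, carrying a character span, the matched text, a CUI, a concept
name, semantic types and the mapper's phrase index — as the unit of
analysis, keeping only the mapper's top-ranked concept per term, and runs
twelve independent detectors over (text, tokens, mapping records,
dictionaries). Each detector is a pure function of its declared inputs;
causes are not mutually exclusive, and one mapping may be flagged several
times.

The three failure types and their operating assumptions:

**Boundary failures.** The mapper's own segmentation (every mapped term a
separate record) is compared against an independent phrase chunker. Two
mappings form a candidate pair when they are adjacent in token order
within one sentence — only whitespace or punctuation tokens between them;
an intervening unmapped word token breaks adjacency (the method restricts
itself to adjacent paired mappings, so longer split n-grams are
undercounted by design). A pair is a failure when both members sit inside
one chunk, taking the deepest (shortest) chunk when a parser returns a
nested structure, because shorter phrases carry the more coherent
meaning. Membership of the combined, space-joined surface in a known-term
lexicon is recorded (`combined_in_lexicon`) but not required — a split
phrase whose combination is missing from the vocabulary is still a split
phrase, and such combinations are themselves useful signals of vocabulary
gaps.

**Missed terms.** Both causes use one differential contract: substitute,
re-map with the injected mapper, and count the mappings over the
substituted region that the original region lacked. Substituting one
occurrence at a time attributes each failure to a span of the original
text, which the corpus-level "difference in total mappings" view cannot
do; when substitutions do not overlap, the per-occurrence gains sum
exactly to the corpus-level delta (asserted in the tests). Community
acronyms are mined with a Schwartz–Hearst-style rule adapted to forum
writing: candidates are fully capitalized words (a trailing lowercase
letter is tolerated for plurals), definitions come from the parenthetical
patterns `long form (SF)` and `SF (long form)`, every character of the
short form must appear in order in the long form with matching first
characters, and the long form may span at most `min(|SF|+5, 2|SF|)`
words. Definitions are community property: once defined anywhere in a
community they apply to all of its posts. When one short form accumulates
conflicting definitions (a real phenomenon: *BC* as *breast cancer* or
*blood count*), the most recent definition at or before the post in
corpus order wins, and posts preceding every definition use the earliest
— temporal locality being the least surprising deterministic rule.
A correction that yields a *wrong* new mapping still counts as a detected
missed term: the original surface was missed either way.

**Word-sense ambiguity.** Nine predicates, mostly dictionary- or
regex-based, described in the README. Two deserve notes. The
mismapped-verb detector assumes verbs may legitimately map only to the 34
semantic types of the ontology's Event tree; any verb-tagged mapping
whose types all fall under Entity is flagged. This knowingly over-flags
verbs like *wait* whose concepts sit in "Functional Concept" (an
Entity-tree type) — the documented false-positive profile of the method —
and the bundled tree table follows the method's own Entity placement of
"Disease or Syndrome". The inconsistency detector assumes members use a
term consistently and the mapper is right the majority of the time: for
any case-folded surface with at least `min_occurrences` (default 2 — a
surface seen once cannot be inconsistent) mappings and two or more
distinct CUIs, every non-majority mapping is flagged, with the majority
CUI as evidence. Ties break to the lexicographically smallest CUI and are
marked as ties; the majority always survives, so a consistently *wrong*
mapping (e.g. a verb *go* always mapped to a gene) is a known blind spot.

**Accounting.** Two counting conventions are both legitimate and both
exposed: *failure events* (boundary = pairs; a phrase split into three
concepts is two events) drive the per-cause summary table, with ambiguity
deduplicated so one mapping occurrence counts once however many causes
flagged it; *affected mappings* (a boundary pair implicates both
constituents; the worked example's "12 mappings + 1 missed term = 13")
drive the overall affected set. Percentages are per-cause counts over the
unique-failure total, half-up at two decimals, so ambiguity rows may sum
past 100% while the unique rows sum to it exactly.

**Evaluation.** The sampler draws a fixed number of detected cases per
cause plus a shared pool of undetected mappings, without replacement,
keyed by stable case identifiers and shuffled with an explicit seed — a
pure function of its inputs, so the draw survives row permutation.
Negatives are drawn uniformly over undetected mappings corpus-wide.
Verdicts come back from human judges as CSV; the tool only computes the
confusion matrix and reports precision, recall, accuracy and F1 as
percentages at two decimals (raw ratios retained internally so display
rounding never accumulates).

## Pluggable contracts and bundled defaults

Four external services enter as function contracts:

| contract | signature | bundled default |
|---|---|---|
| tagger  | `text -> tokens` | closed-class word lists + suffix heuristics |
| chunker | `tokens -> chunks` | regex-over-POS noun-phrase chunker |
| speller | `token -> correction or NULL` | edit-distance ≤ 2 lexicon lookup |
| mapper  | `text -> mapping records` | table-driven mock mapper |

The defaults are deterministic and deliberately small: the tagger is only
required to be correct on the vocabulary of the bundled fixtures
(contractions split on the apostrophe into two tokens — *I'd* is a
personal pronoun plus a modal — which the multi-POS detector depends on);
the chunker emits flat noun-phrase runs (optional determiner, adjectives,
then nouns/numbers), a stand-in for a constituency parser; the speller
corrects only lower-case alphabetic tokens of length ≥ 4 to the nearest
lexicon entry within Levenshtein distance 2, ties broken alphabetically,
leaving capitalized tokens to external suggestion services. Production
analyses should inject real services; every contract is validated at the
boundary (token spans must tile the non-whitespace characters exactly).

Offsets are 0-based, half-open, in code points throughout; the fielded
MMI reader converts its `start/length` positional pairs to this
convention on read and verifies each record by slicing the post text.
Sentence segmentation splits after `. ! ?` runs followed by whitespace
and a capital or digit — simple, deterministic, reproducible.

## Dictionaries

The detectors depend on seven resources, bundled as small plain-text
fixtures under `inst/extdata/lexicons/`: ~240 first names (including the
documented trouble-makers Meg, Rebecca, Don, Candy, Sunday, Faith, Hope),
20 community handles, ~50 Internet-slang terms (the medical acronyms AML,
CMF and RX are excluded at load, as the method prescribes), ~100
cancer-gene symbols (matched case-insensitively: community text
lowercases gene names), a ~300-word spell lexicon, a known multi-word
term list, and a semantic-type tree table with exactly 34 Event-tree
types. These are deterministic stand-ins for the large licensed or
proprietary dictionaries a production deployment would supply; dictionary
coverage directly bounds detector behaviour (a richer name dictionary
raises recall and lowers precision of the names detector).

## The synthetic generator

`generate_corpus()` emulates a cancer-community corpus: posts are
assembled from benign clinical sentence templates, and each of the twelve
phenomena is injected per post with a configured probability (defaults:
pronoun *I* 0.15, inconsistent mapping 0.12, splitting/nomenclature/
misspelling/contraction/slang/name/verb 0.10, colloquial/number/email
0.08 — ordered to mirror the relative prevalence of the failure causes in
community text, where narrative "I" dominates). Acronyms are defined
parenthetically at their first injection and reused bare afterwards;
misspellings come from a fixed table (*docotor*, *byopsi*,
*methastasis*) so the bundled speller reliably recovers them; the
inconsistent surface (*blood test*) receives the minority concept
("Blood test device", C0994779) on every third corpus-wide occurrence,
giving an exact 2:1 majority for "Hematologic Tests" (C0018941). The
mock mapper is a transparent dictionary scanner (longest match at word
boundaries), so ground truth is exact by construction; placeholder CUIs
live in the reserved range C9900001–C9909999.

Because injection and detection share vocabularies by construction,
dictionary/regex/rule detectors achieve 100% recall on the generator's
ground truth, and the inconsistency detector flags exactly the injected
minority mappings — the tests assert both. This validates the *plumbing*,
not the field performance: real community text has vocabulary the bundled
dictionaries lack, misspellings beyond distance 2, taggers and parsers
with their own error profiles, and mappers whose inconsistency is not a
clean 2:1 schedule. Passing tests therefore show the detectors implement
their predicates exactly; they do not predict precision on real data,
which is what the manual-judgment harness is for.

## Numerical and design choices

* Percentages and metrics round half-up at 2 decimals
  (`floor(100x + 0.5)/100`), matching conventional report formatting;
  base `round()`'s round-half-even is deliberately not used.
* Majority ties in the inconsistency detector break to the smallest CUI;
  `min_occurrences = 2` by default.
* A pair of adjacent mappings may be separated by punctuation but not by
  any unmapped word token (configurable only by injecting a different
  adjacency notion via the chunker/tokens; documented as an open choice).
* Mappings with unknown semantic types are skipped by the verb detector
  with a warning rather than guessed.
* Multi-token mappings use the first verb-tagged token in the span for
  the verb test.
* The time regex accepts `h[:mm] am/pm`; digit-group strings (`3/4`,
  `11/07`) always qualify as number expressions, while bare 1–2 digit
  runs qualify only adjacent to month names or age keywords — the
  description "a string of numbers" is under-constrained, and this
  bounds false positives while covering every documented example.
  "Quantitative Concept" mappings are excluded by default (an accepted
  undercount); `include_quantitative = TRUE` reverses the exclusion.
* The worked-example fixture's twelfth mapping (*I'm*) is a
  reconstruction — the example fixes the count at twelve without
  printing every concept — and *Hi* carries its gene-concept reading
  ("ABCC8 gene"), the reading the battery can detect.
* Degenerate inputs: empty corpora round-trip as empty; an all-negative
  prediction set makes precision an explicit error rather than NaN; a
  zero mapping total makes the failure rate an error.

## Problem sizes

The test suite runs the full battery on corpora of 40–60 synthetic posts
(roughly 150–300 mappings), the detector-versus-oracle equivalence over
100 seeded corpora of ≤ 200 mappings each, and ground-truth recovery on
two 60-post corpora — sizes chosen so the whole suite completes in about
a minute and a half on one core while every code path and cause is
exercised many times over.

## Known limitations

* Boundary detection recombines exactly two mappings; split n-grams of
  three or more concepts are counted pairwise, underestimating phrase
  splits.
* Missed terms whose expansion the mapper *still* cannot map are
  invisible to the differential contract.
* The inconsistency detector cannot see consistently wrong mappings, and
  trusts the majority even where the majority is wrong.
* The bundled tagger/chunker/speller are fixture-scale; their error
  profiles on arbitrary text are not characterized. Inject real services
  for production audits.
* Name/slang/gene matching is whole-surface and case-insensitive, which
  reproduces the method's documented false positives (*Hope*, *Sunday*
  as common nouns) by design.
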