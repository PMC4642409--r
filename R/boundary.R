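# Boundary-failure detection: single coherent phrases that the mapper split
# into multiple concepts, found by comparing the mapper's own phrase
# segmentation (every mapped term is its own record) against an independent
# phrase chunker. A pair of adjacently mapped terms sitting inside one
# chunk is a split-phrase event, whether or not the combined surface is a
# known concept term; membership of the combination in the known-term
# lexicon is recorded alongside.

#' Bundled fallback phrase chunker
#'
#' A regex-over-POS noun-phrase chunker standing in for a full constituency
#' parser: each maximal run of optional determiner, adjectives, then
#' nouns/proper nouns/numbers becomes one chunk (depth 1). Output is laminar
#' by construction (chunks are disjoint). Callers may inject a real parser
#' through the `chunker` argument of [detect_boundary_failures()]; a parser
#' may return nested chunks with larger `depth` meaning shorter/inner
#' phrase.
#'
#' @param tokens a token tibble for one or more sentences
#'   (see [tokenize_and_tag()]).
#' @return a tibble of chunks: `start`, `end` (character offsets),
#'   `sentence_index`, `depth`.
#' @export
default_chunker <- function(tokens) {
  out <- list()
  np_tag <- function(tag) tag %in% c("NN", "NNS", "NNP", "NNPS", "CD")
  pre_tag <- function(tag) tag %in% c("DT", "JJ", "JJR", "JJS", "PRP$")
  for (si in unique(tokens$sentence_index)) {
    sent <- tokens[tokens$sentence_index == si, , drop = FALSE]
    i <- 1L
    while (i <= nrow(sent)) {
      if (pre_tag(sent$pos_tag[i]) || np_tag(sent$pos_tag[i])) {
        j <- i
        while (j <= nrow(sent) &&
               (pre_tag(sent$pos_tag[j]) || np_tag(sent$pos_tag[j]))) {
          j <- j + 1L
        }
        # require at least one head noun/number in the run
        run <- sent[i:(j - 1L), , drop = FALSE]
        heads <- which(vapply(run$pos_tag, np_tag, logical(1)))
        if (length(heads) > 0) {
          out[[length(out) + 1L]] <- tibble::tibble(
            start = run$start[1], end = run$end[nrow(run)],
            sentence_index = si, depth = 1L)
        }
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(start = integer(), end = integer(),
                          sentence_index = integer(), depth = integer()))
  }
  do.call(rbind, out)
}

#' Find adjacently mapped term pairs
#'
#' Collects ordered pairs of mapping records that are adjacent in token
#' order within one sentence: only whitespace or punctuation tokens may lie
#' between them — if any unmapped word token (a token containing a letter or
#' digit) intervenes, the pair is not adjacent. Because the mapper emits one
#' record per mapped term, any two distinct adjacent records represent
#' terms the mapper treated as separate.
#'
#' @param mappings mapping records for one post, in any order.
#' @param tokens the post's token tibble.
#' @return a tibble of pair indices into the (start-ordered) `mappings`:
#'   `left_row`, `right_row`.
#' @export
find_adjacent_pairs <- function(mappings, tokens) {
  out <- tibble::tibble(left_row = integer(), right_row = integer())
  if (nrow(mappings) < 2) return(out)
  mappings <- mappings[order(mappings$start, mappings$end), , drop = FALSE]
  is_word <- grepl("[A-Za-z0-9]", tokens$surface)
  sent_of_span <- function(s, e) {
    covered <- tokens$sentence_index[spans_overlap(tokens$start, tokens$end, s, e)]
    if (length(covered) == 0) NA_integer_ else covered[1]
  }
  pairs <- list()
  for (i in seq_len(nrow(mappings) - 1L)) {
    j <- i + 1L
    if (mappings$end[i] > mappings$start[j]) next  # overlapping records
    si <- sent_of_span(mappings$start[i], mappings$end[i])
    sj <- sent_of_span(mappings$start[j], mappings$end[j])
    if (is.na(si) || is.na(sj) || si != sj) next
    gap_words <- is_word &
      tokens$start >= mappings$end[i] & tokens$end <= mappings$start[j]
    if (any(gap_words)) next
    pairs[[length(pairs) + 1L]] <- tibble::tibble(left_row = i, right_row = j)
  }
  if (length(pairs) > 0) out <- do.call(rbind, pairs)
  attr(out, "mappings_sorted") <- mappings
  out
}

#' Detect boundary (split-phrase) failures
#'
#' A pair of adjacently mapped terms becomes a failure when both members lie
#' inside one phrase chunk — using the deepest (shortest) chunk containing
#' both. The combined surface (the two matched texts case-folded and joined
#' with one space) is looked up in the known-term lexicon; pairs whose
#' combination is absent are still failures, flagged
#' `combined_in_lexicon = FALSE`, since they too are split phrases (and may
#' point at vocabulary gaps).
#'
#' @param post_id the post identifier (for the emitted records).
#' @param mappings mapping records for the post.
#' @param tokens the post's token tibble.
#' @param term_lexicon a `maplint_lexicon` of known multi-word concept terms.
#' @param chunker a chunker contract (default [default_chunker()]).
#' @return a failure tibble (cause `splitting_phrase`), one row per pair,
#'   spanning from the left term's start to the right term's end.
#' @export
detect_boundary_failures <- function(post_id, mappings, tokens, term_lexicon,
                                     chunker = default_chunker) {
  pairs <- find_adjacent_pairs(mappings, tokens)
  if (nrow(pairs) == 0) return(empty_failures())
  sorted <- attr(pairs, "mappings_sorted")
  chunks <- chunker(tokens)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    left <- sorted[pairs$left_row[k], ]
    right <- sorted[pairs$right_row[k], ]
    containing <- chunks[chunks$start <= left$start & chunks$end >= right$end, ,
                         drop = FALSE]
    if (nrow(containing) == 0) next
    chunk <- containing[which.max(containing$depth), ]  # shortest phrase
    combined <- paste(casefold_term(left$matched_text),
                      casefold_term(right$matched_text))
    in_lex <- lexicon_contains(term_lexicon, combined)
    rows[[length(rows) + 1L]] <- new_failures(
      post_id = post_id, cause = "splitting_phrase",
      start = left$start, end = right$end,
      surface = paste(left$matched_text, right$matched_text),
      evidence = sprintf("chunk [%d,%d) depth %d; combined %s %s known-term lexicon",
                         chunk$start, chunk$end, chunk$depth,
                         dQuote(combined), if (in_lex) "in" else "not in"),
      left_start = left$start, left_end = left$end,
      right_start = right$start, right_end = right$end,
      combined_in_lexicon = in_lex
    )
  }
  bind_failures(rows)
}
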