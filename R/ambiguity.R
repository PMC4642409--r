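# The nine word-sense-ambiguity detectors.
#
# Each detector is a pure function of its declared inputs (mapping records
# plus tokens, raw text or a dictionary) and may be run in any order; one
# mapping can be flagged by several causes (the causes are not mutually
# exclusive — deduplication happens downstream).

#' @rdname detect_slang
#' @export
detect_multi_pos <- function(mappings, tokens) {
  rows <- integer()
  ev <- character()
  for (i in seq_len(nrow(mappings))) {
    toks <- tokens_in_span(tokens, mappings$start[i], mappings$end[i])
    if (nrow(toks) >= 2 && length(unique(toks$pos_tag)) >= 2) {
      rows <- c(rows, i)
      ev <- c(ev, paste0("POS tags: ", paste(toks$pos_tag, collapse = "+")))
    }
  }
  ambiguity_failures(mappings, rows, "multi_pos_contraction", ev)
}

#' @rdname detect_slang
#' @export
detect_colloquial_gene <- function(mappings, gene_lexicon) {
  is_gene <- vapply(mappings$semantic_types, function(st) {
    "Gene or Genome" %in% st
  }, logical(1))
  rows <- which(is_gene & !lexicon_contains(gene_lexicon, mappings$matched_text))
  ambiguity_failures(
    mappings, rows, "colloquial_gene",
    sprintf("%s mapped to Gene or Genome but absent from %s dictionary",
            dQuote(mappings$matched_text[rows]), gene_lexicon$name))
}

MONTH_PATTERN <- "(?:jan(?:uary)?|feb(?:ruary)?|mar(?:ch)?|apr(?:il)?|may|jun[e]?|jul[y]?|aug(?:ust)?|sep(?:t(?:ember)?)?|oct(?:ober)?|nov(?:ember)?|dec(?:ember)?)"

# spans (0-based half-open) matched by a perl regex
regex_spans <- function(text, pattern, ignore_case = FALSE) {
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = ignore_case)[[1]]
  if (m[1] == -1) return(tibble::tibble(start = integer(), end = integer()))
  tibble::tibble(start = m - 1L, end = m - 1L + attr(m, "match.length"))
}

# digit-run spans inside the matches of `pattern`
digit_spans_within <- function(text, pattern) {
  outer <- regex_spans(text, pattern, ignore_case = TRUE)
  if (nrow(outer) == 0) return(outer)
  out <- lapply(seq_len(nrow(outer)), function(k) {
    seg <- slice_text(text, outer$start[k], outer$end[k])
    d <- regex_spans(seg, "[0-9]+[^[:space:]]*[0-9]+|[0-9]+")
    d$start <- d$start + outer$start[k]
    d$end <- d$end + outer$start[k]
    d
  })
  do.call(rbind, out)
}

# character spans of problematic date/time/number expressions:
#  - times: digits, optional :minutes, then am/pm
#  - digit strings: >= 2 digit groups joined by single non-alphanumeric chars
#  - bare 1-2 digit runs only in date/age position (next to a month name or
#    an age keyword); unanchored bare runs are left alone to bound false
#    positives
number_spans <- function(text) {
  rbind(
    regex_spans(text, "(?<![0-9])[0-9]{1,2}(:[0-9]{2})?[ ]?[ap]m(?![A-Za-z])",
                ignore_case = TRUE),
    regex_spans(text, "[0-9]+(?:[^[:alnum:][:space:]][0-9]+)+"),
    digit_spans_within(text, paste0("\\b", MONTH_PATTERN, "\\.?[ ][0-9]{1,2}\\b")),
    digit_spans_within(text, paste0("\\b[0-9]{1,2}(?:st|nd|rd|th)?[ ](?:of[ ])?",
                                    MONTH_PATTERN, "\\b")),
    digit_spans_within(text, "\\bage[ds]?[ ][0-9]{1,3}\\b"),
    digit_spans_within(text, "\\b[0-9]{1,3}[ ]years?[ ]old\\b")
  )
}

NUMBER_SEMTYPES <- c(
  "Amino Acid, Peptide, or Protein", "Finding", "Gene or Genome",
  "Intellectual Product", "Medical Device", "Research Activity"
)

#' @rdname detect_slang
#' @param text the post's raw text (for the regex-based detectors).
#' @param include_quantitative also flag mappings carrying the
#'   "Quantitative Concept" semantic type (default `FALSE`: such mappings
#'   are excluded, accepting an undercount).
#' @export
detect_numbers <- function(mappings, text, include_quantitative = FALSE) {
  spans <- number_spans(text)
  if (nrow(spans) == 0) return(empty_failures())
  allowed <- NUMBER_SEMTYPES
  if (include_quantitative) allowed <- c(allowed, "Quantitative Concept")
  rows <- integer(); ev <- character()
  for (i in seq_len(nrow(mappings))) {
    hit <- which(spans_overlap(spans$start, spans$end,
                               mappings$start[i], mappings$end[i]))
    if (length(hit) == 0) next
    st <- mappings$semantic_types[[i]]
    if (!any(st %in% allowed)) next
    if (!include_quantitative && "Quantitative Concept" %in% st) next
    rows <- c(rows, i)
    ev <- c(ev, sprintf("date/time expression %s",
                        dQuote(slice_text(text, spans$start[hit[1]],
                                          spans$end[hit[1]]))))
  }
  ambiguity_failures(mappings, rows, "number", ev)
}

EMAIL_PATTERN <- "[A-Za-z0-9._%+-]+@[A-Za-z0-9-]+(?:\\.[A-Za-z0-9-]+)*\\.[A-Za-z]{2,6}"
URL_PATTERN <- "(?:https?://[^[:space:]]+|\\b[A-Za-z0-9-]+(?:\\.[A-Za-z0-9-]+)*\\.(?:com|org|net|edu|gov|info|io|co|uk|ca|au)(?:/[^[:space:]]*)?)"

#' @rdname detect_slang
#' @export
detect_email_url <- function(mappings, text) {
  spans <- rbind(regex_spans(text, EMAIL_PATTERN, ignore_case = TRUE),
                 regex_spans(text, URL_PATTERN, ignore_case = TRUE))
  if (nrow(spans) == 0) return(empty_failures())
  rows <- integer(); ev <- character()
  for (i in seq_len(nrow(mappings))) {
    hit <- which(spans_overlap(spans$start, spans$end,
                               mappings$start[i], mappings$end[i]))
    if (length(hit) == 0) next
    rows <- c(rows, i)
    ev <- c(ev, sprintf("inside email/URL %s",
                        dQuote(slice_text(text, spans$start[hit[1]],
                                          spans$end[hit[1]]))))
  }
  ambiguity_failures(mappings, rows, "email_url", ev)
}

#' Dictionary, regex and POS ambiguity detectors
#'
#' Each detector flags mapping records for one cause of word-sense
#' ambiguity:
#'
#' * `detect_multi_pos()`: a single mapped term whose span covers two or
#'   more tokens bearing two or more distinct POS tags — the signature of a
#'   contraction such as "I'd" mapped to a concept.
#' * `detect_colloquial_gene()`: colloquial language mistaken for genes — a
#'   mapping with the "Gene or Genome" semantic type whose surface is not
#'   in the cancer-gene dictionary.
#' * `detect_numbers()`: dates, times and other numbers not indicating
#'   disease status, mapped to semantic types where numbers make no sense
#'   ("Quantitative Concept" mappings are excluded by default).
#' * `detect_email_url()`: mappings overlapping an email address or URL.
#' * `detect_slang()`: surfaces in the Internet-slang/SMS list (medical
#'   acronyms such as AML, CMF and RX must have been excluded at load).
#' * `detect_names()`: surfaces in the combined first-name + community
#'   handle list. Popular names used as common nouns ("Hope", "Sunday")
#'   are flagged too, by design — this reproduces the method's documented
#'   false-positive profile.
#' * `detect_pronoun_I()`: the narrative pronoun "I" (tagged pronoun, or
#'   foreign word — a known tagger failure mode that is included) mapped to
#'   "Blood group antibody I" or "Iodides".
#' * `detect_mismapped_verbs()`: verb-tagged terms mapped only to
#'   Entity-tree semantic types, where verbs are not expected (Event-tree
#'   types are exempt; unknown types skip the mapping with a warning).
#'
#' @param mappings a mapping-record tibble for one post (corpus-wide for
#'   dictionary detectors is also fine).
#' @param tokens the post's token tibble (POS-tagged).
#' @param gene_lexicon,slang_lexicon,name_lexicon,handles `maplint_lexicon`
#'   dictionaries.
#' @param semtype_table the semantic-type tree table.
#' @return a failure tibble (possibly empty).
#' @export
detect_slang <- function(mappings, slang_lexicon) {
  rows <- which(lexicon_contains(slang_lexicon, mappings$matched_text))
  ambiguity_failures(
    mappings, rows, "internet_slang",
    sprintf("%s in %s dictionary", dQuote(mappings$matched_text[rows]),
            slang_lexicon$name))
}

#' @rdname detect_slang
#' @export
detect_names <- function(mappings, name_lexicon, handles = NULL) {
  combined <- name_lexicon$entries
  if (!is.null(handles)) combined <- union(combined, handles$entries)
  rows <- which(squash_ws(casefold_term(mappings$matched_text)) %in% combined)
  ambiguity_failures(
    mappings, rows, "name",
    sprintf("%s in combined first-name/handle list",
            dQuote(mappings$matched_text[rows])))
}

PRONOUN_I_CONCEPTS <- c("Blood group antibody I", "Iodides")

#' @rdname detect_slang
#' @export
detect_pronoun_I <- function(mappings, tokens) {
  rows <- integer(); ev <- character()
  for (i in seq_len(nrow(mappings))) {
    if (mappings$matched_text[i] != "I") next
    if (!mappings$concept_name[i] %in% PRONOUN_I_CONCEPTS) next
    toks <- tokens_in_span(tokens, mappings$start[i], mappings$end[i])
    if (!any(toks$pos_tag %in% c("PRP", "FW"))) next
    rows <- c(rows, i)
    ev <- c(ev, sprintf("pronoun \"I\" (tag %s) mapped to %s",
                        toks$pos_tag[1], dQuote(mappings$concept_name[i])))
  }
  ambiguity_failures(mappings, rows, "pronoun_I", ev)
}

#' @rdname detect_slang
#' @export
detect_mismapped_verbs <- function(mappings, tokens, semtype_table) {
  rows <- integer(); ev <- character()
  for (i in seq_len(nrow(mappings))) {
    toks <- tokens_in_span(tokens, mappings$start[i], mappings$end[i])
    verb <- which(grepl("^VB", toks$pos_tag))
    if (length(verb) == 0) next
    trees <- classify_semantic_type(semtype_table, mappings$semantic_types[[i]])
    if (any(trees == "unknown")) {
      warning("unknown semantic type for mapping ",
              dQuote(mappings$matched_text[i]), " (",
              paste(mappings$semantic_types[[i]][trees == "unknown"],
                    collapse = ", "), "); skipped", call. = FALSE)
      next
    }
    if (any(trees == "Event")) next
    rows <- c(rows, i)
    ev <- c(ev, sprintf("verb (%s) mapped to Entity-tree type(s): %s",
                        toks$pos_tag[verb[1]],
                        paste(mappings$semantic_types[[i]], collapse = ", ")))
  }
  ambiguity_failures(mappings, rows, "mismapped_verb", ev)
}

#' Term/CUI frequency table
#'
#' Counts, corpus-wide, how often each case-folded surface form was mapped
#' to each CUI. This is the evidence base for the inconsistent-mapping
#' detector: a surface mapped to several CUIs was interpreted
#' inconsistently by the mapper's word-sense disambiguation.
#'
#' @param mappings corpus-wide mapping records.
#' @return a tibble: `surface`, `cui`, `n`; per-surface counts sum to the
#'   surface's total occurrence count among mappings.
#' @export
build_cui_frequency_table <- function(mappings) {
  if (nrow(mappings) == 0) {
    return(tibble::tibble(surface = character(), cui = character(),
                          n = integer()))
  }
  surface <- squash_ws(casefold_term(mappings$matched_text))
  agg <- stats::aggregate(list(n = rep(1L, nrow(mappings))),
                          by = list(surface = surface, cui = mappings$cui),
                          FUN = sum)
  out <- tibble::as_tibble(agg[order(agg$surface, agg$cui), ])
  out$n <- as.integer(out$n)
  out
}

#' Detect inconsistent mappings
#'
#' Assumes community members use a term consistently and that the mapper
#' picks the right concept the majority of the time: for every surface form
#' with at least `min_occurrences` mappings and at least two distinct CUIs,
#' each mapping to a non-majority CUI is flagged. Majority ties break to the
#' lexicographically smallest CUI (recorded as a tie in the evidence), so
#' the result is deterministic and the majority always survives unflagged.
#' A surface always mapped to one CUI is never flagged — consistently wrong
#' mappings are a documented blind spot of this detector.
#'
#' @param mappings corpus-wide mapping records.
#' @param table optional precomputed [build_cui_frequency_table()] output
#'   for the same corpus.
#' @param min_occurrences minimum number of occurrences of a surface before
#'   inconsistency is assessed (default 2).
#' @return a failure tibble; evidence carries the majority CUI.
#' @export
detect_inconsistent <- function(mappings, table = NULL, min_occurrences = 2) {
  if (is.null(table)) table <- build_cui_frequency_table(mappings)
  if (nrow(table) == 0) return(empty_failures())
  rows <- integer(); ev <- character()
  surface_all <- squash_ws(casefold_term(mappings$matched_text))
  for (s in unique(table$surface)) {
    sub <- table[table$surface == s, , drop = FALSE]
    if (sum(sub$n) < min_occurrences || nrow(sub) < 2) next
    top <- sub$cui[sub$n == max(sub$n)]
    majority <- sort(top)[1]
    tie <- length(top) > 1
    flag <- which(surface_all == s & mappings$cui != majority)
    rows <- c(rows, flag)
    ev <- c(ev, rep(sprintf("majority CUI %s (%d/%d)%s", majority,
                            max(sub$n), sum(sub$n),
                            if (tie) ", tie broken lexicographically" else ""),
                    length(flag)))
  }
  ambiguity_failures(mappings, rows, "inconsistent_mapping", ev)
}
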