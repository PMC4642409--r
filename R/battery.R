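# The full detector battery over a corpus.

#' Run the failure-detection battery
#'
#' Runs the selected detectors over a corpus of posts and their mapping
#' records and returns one failure tibble. Per-post detectors (boundary,
#' numbers, email/URL, multi-POS, pronoun "I", mismapped verbs) tokenize
#' each post once with the supplied tagger; dictionary detectors run
#' corpus-wide; the inconsistency detector builds its term/CUI frequency
#' table from the whole corpus. The two missed-term detectors need a mapper
#' contract for differential re-mapping and are skipped (with a message)
#' when `mapper` is `NULL`.
#'
#' @param posts a post tibble.
#' @param mappings mapping records for those posts.
#' @param lexicons a lexicon set as from [default_lexicons()].
#' @param detectors causes to run; default all 12 (see [FAILURE_CAUSES]).
#' @param mapper optional mapper contract (`text -> mapping records`) for
#'   the missed-term detectors.
#' @param speller speller contract; default built from `lexicons$spell`.
#' @param abbrev_table optional precomputed [extract_abbreviations()] table;
#'   default: mined from `posts`.
#' @param tagger,chunker tagger and chunker contracts.
#' @param min_occurrences threshold for the inconsistency detector.
#' @param include_quantitative passed to [detect_numbers()].
#' @return a failure tibble (all causes mixed; see
#'   [deduplicate_failures()]).
#' @export
detect_failures <- function(posts, mappings,
                            lexicons = default_lexicons(),
                            detectors = names(FAILURE_CAUSES),
                            mapper = NULL, speller = NULL,
                            abbrev_table = NULL,
                            tagger = default_tagger,
                            chunker = default_chunker,
                            min_occurrences = 2,
                            include_quantitative = FALSE) {
  bad <- setdiff(detectors, names(FAILURE_CAUSES))
  if (length(bad) > 0) {
    stop("unknown detector(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- list()
  want <- function(d) d %in% detectors

  # corpus-wide dictionary detectors
  if (want("colloquial_gene")) {
    out$gene <- detect_colloquial_gene(mappings, lexicons$genes)
  }
  if (want("internet_slang")) out$slang <- detect_slang(mappings, lexicons$slang)
  if (want("name")) {
    out$name <- detect_names(mappings, lexicons$first_names, lexicons$handles)
  }
  if (want("inconsistent_mapping")) {
    out$inc <- detect_inconsistent(mappings, min_occurrences = min_occurrences)
  }

  need_missed <- any(c("community_nomenclature", "misspelling") %in% detectors)
  if (need_missed && is.null(mapper)) {
    message("no mapper supplied; skipping missed-term detectors")
    need_missed <- FALSE
  }
  if (need_missed && want("community_nomenclature") && is.null(abbrev_table)) {
    abbrev_table <- extract_abbreviations(posts)
  }
  if (need_missed && want("misspelling") && is.null(speller)) {
    speller <- default_speller(lexicons$spell)
  }

  # per-post detectors
  for (i in seq_len(nrow(posts))) {
    pid <- posts$post_id[i]
    text <- posts$text[i]
    pm <- mappings[mappings$post_id == pid, , drop = FALSE]
    toks <- tokenize_and_tag(text, tagger)
    key <- paste0("post", i)
    if (nrow(pm) > 0) {
      if (want("splitting_phrase")) {
        out[[paste0(key, "b")]] <- detect_boundary_failures(
          pid, pm, toks, lexicons$terms, chunker)
      }
      if (want("multi_pos_contraction")) {
        out[[paste0(key, "mp")]] <- detect_multi_pos(pm, toks)
      }
      if (want("number")) {
        out[[paste0(key, "n")]] <- detect_numbers(pm, text,
                                                  include_quantitative)
      }
      if (want("email_url")) {
        out[[paste0(key, "e")]] <- detect_email_url(pm, text)
      }
      if (want("pronoun_I")) {
        out[[paste0(key, "p")]] <- detect_pronoun_I(pm, toks)
      }
      if (want("mismapped_verb")) {
        out[[paste0(key, "v")]] <- detect_mismapped_verbs(pm, toks,
                                                          lexicons$semtypes)
      }
    }
    if (need_missed) {
      post_row <- posts[i, ]
      if (want("community_nomenclature")) {
        out[[paste0(key, "cn")]] <- expand_and_remap(post_row, abbrev_table,
                                                     mapper, posts)
      }
      if (want("misspelling")) {
        out[[paste0(key, "ms")]] <- spellcheck_and_remap(post_row, speller,
                                                         mapper)
      }
    }
  }
  bind_failures(out)
}
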