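# Unified failure records.
#
# Every detector emits rows of one tibble schema so that downstream
# accounting (deduplication, affected-mapping sets, sampling) can treat the
# twelve causes uniformly. Boundary failures are pair-level events and carry
# both constituent mapping spans; ambiguity failures reference one mapping;
# missed-term failures reference a span of the original (uncorrected) text.

#' The twelve failure causes
#'
#' Three failure types and their causes: boundary failures
#' (`splitting_phrase`), missed-term failures (`community_nomenclature`,
#' `misspelling`), and the nine word-sense-ambiguity causes.
#'
#' @format a named character vector mapping cause to failure type.
#' @export
FAILURE_CAUSES <- c(
  splitting_phrase = "boundary",
  community_nomenclature = "missed_term",
  misspelling = "missed_term",
  multi_pos_contraction = "ambiguity",
  colloquial_gene = "ambiguity",
  number = "ambiguity",
  email_url = "ambiguity",
  internet_slang = "ambiguity",
  name = "ambiguity",
  pronoun_I = "ambiguity",
  mismapped_verb = "ambiguity",
  inconsistent_mapping = "ambiguity"
)

new_failures <- function(post_id = character(0), cause = character(0),
                         start = integer(0), end = integer(0),
                         surface = character(0), cui = NA_character_,
                         concept_name = NA_character_,
                         evidence = character(0),
                         left_start = NA_integer_, left_end = NA_integer_,
                         right_start = NA_integer_, right_end = NA_integer_,
                         combined_in_lexicon = NA,
                         replacement = NA_character_,
                         new_mapping_count = NA_integer_) {
  n <- length(post_id)
  stopifnot(all(cause %in% names(FAILURE_CAUSES)) || n == 0)
  tibble::tibble(
    post_id = as.character(post_id),
    type = if (n) unname(FAILURE_CAUSES[cause]) else character(0),
    cause = as.character(cause),
    start = as.integer(start),
    end = as.integer(end),
    surface = as.character(surface),
    cui = rep_len(as.character(cui), n),
    concept_name = rep_len(as.character(concept_name), n),
    evidence = as.character(evidence),
    left_start = rep_len(as.integer(left_start), n),
    left_end = rep_len(as.integer(left_end), n),
    right_start = rep_len(as.integer(right_start), n),
    right_end = rep_len(as.integer(right_end), n),
    combined_in_lexicon = rep_len(as.logical(combined_in_lexicon), n),
    replacement = rep_len(as.character(replacement), n),
    new_mapping_count = rep_len(as.integer(new_mapping_count), n)
  )
}

empty_failures <- function() new_failures()

# rbind a list of failure tibbles, tolerating empties
bind_failures <- function(lst) {
  lst <- Filter(function(x) !is.null(x) && nrow(x) > 0, lst)
  if (length(lst) == 0) return(empty_failures())
  do.call(rbind, lst)
}

# ambiguity failure rows from mapping-record rows
ambiguity_failures <- function(mappings, rows, cause, evidence) {
  if (length(rows) == 0) return(empty_failures())
  m <- mappings[rows, , drop = FALSE]
  new_failures(
    post_id = m$post_id, cause = cause, start = m$start, end = m$end,
    surface = m$matched_text, cui = m$cui, concept_name = m$concept_name,
    evidence = evidence
  )
}
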