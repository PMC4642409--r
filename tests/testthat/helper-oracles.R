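# Brute-force oracle implementations of the detector predicates, kept
# deliberately naive (explicit loops, no shared helpers with the package
# internals beyond the published contracts), plus small fixture builders.

slice0 <- function(text, start, end) substr(text, start + 1, end)

fixture_lexicons <- local({
  lex <- NULL
  function() {
    if (is.null(lex)) lex <<- default_lexicons()
    lex
  }
})

# a one-post corpus from raw text plus a list of (surface, cui, concept,
# types) mapping specs located by n-th occurrence
make_post <- function(text, post_id = "p1", community_id = "c1") {
  tibble::tibble(community_id = community_id, post_id = post_id,
                 author_handle = "h1", text = text,
                 timestamp = NA_character_)
}

make_mappings <- function(text, specs, post_id = "p1") {
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    occurrence <- if (is.null(s$occurrence)) 1L else s$occurrence
    m <- gregexpr(paste0("(?<![A-Za-z0-9])",
                         gsub("([\\W])", "\\\\\\1", s$surface, perl = TRUE),
                         "(?![A-Za-z0-9])"), text, perl = TRUE)[[1]]
    stopifnot(m[1] != -1, length(m) >= occurrence)
    start <- m[occurrence] - 1L
    end <- start + attr(m, "match.length")[occurrence]
    tibble::tibble(post_id = post_id, phrase_index = i, start = start,
                   end = end, matched_text = s$surface,
                   cui = s$cui, concept_name = s$concept,
                   semantic_types = list(s$types), score = 1000)
  })
  do.call(rbind, rows)
}

## ---- oracle predicates ----------------------------------------------------

overlap0 <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1

tokens_over <- function(tokens, s, e) {
  keep <- logical(nrow(tokens))
  for (t in seq_len(nrow(tokens))) {
    keep[t] <- overlap0(tokens$start[t], tokens$end[t], s, e)
  }
  tokens[keep, , drop = FALSE]
}

oracle_multi_pos <- function(mappings, tokens) {
  hit <- integer()
  for (i in seq_len(nrow(mappings))) {
    tk <- tokens_over(tokens, mappings$start[i], mappings$end[i])
    if (nrow(tk) >= 2 && length(unique(tk$pos_tag)) >= 2) hit <- c(hit, i)
  }
  hit
}

oracle_colloquial_gene <- function(mappings, genes) {
  hit <- integer()
  for (i in seq_len(nrow(mappings))) {
    if ("Gene or Genome" %in% mappings$semantic_types[[i]] &&
        !(tolower(mappings$matched_text[i]) %in% genes$entries)) {
      hit <- c(hit, i)
    }
  }
  hit
}

oracle_slang <- function(mappings, slang) {
  which(tolower(trimws(mappings$matched_text)) %in% slang$entries)
}

oracle_names <- function(mappings, first_names, handles) {
  pool <- c(first_names$entries, handles$entries)
  which(tolower(trimws(mappings$matched_text)) %in% pool)
}

oracle_pronoun_I <- function(mappings, tokens) {
  hit <- integer()
  for (i in seq_len(nrow(mappings))) {
    if (mappings$matched_text[i] != "I") next
    if (!mappings$concept_name[i] %in%
        c("Blood group antibody I", "Iodides")) next
    tk <- tokens_over(tokens, mappings$start[i], mappings$end[i])
    if (any(tk$pos_tag %in% c("PRP", "FW"))) hit <- c(hit, i)
  }
  hit
}

oracle_mismapped_verbs <- function(mappings, tokens, semtypes) {
  tree_of <- function(st) {
    j <- match(tolower(st), tolower(semtypes$type_name))
    ifelse(is.na(j), "unknown", semtypes$tree[j])
  }
  hit <- integer()
  for (i in seq_len(nrow(mappings))) {
    tk <- tokens_over(tokens, mappings$start[i], mappings$end[i])
    if (!any(substr(tk$pos_tag, 1, 2) == "VB")) next
    trees <- vapply(mappings$semantic_types[[i]], tree_of, character(1))
    if (any(trees == "unknown")) next
    if (all(trees == "Entity")) hit <- c(hit, i)
  }
  hit
}

# whitespace-delimited words of `text` with their 0-based spans
ws_words <- function(text) {
  m <- gregexpr("[^[:space:]]+", text)[[1]]
  if (m[1] == -1) {
    return(data.frame(word = character(), start = integer(),
                      end = integer()))
  }
  data.frame(word = regmatches(text, list(m))[[1]], start = m - 1L,
             end = m - 1L + attr(m, "match.length"))
}

MONTHS <- c("january", "february", "march", "april", "may", "june", "july",
            "august", "september", "october", "november", "december")

oracle_numbers <- function(mappings, text) {
  allowed <- c("Amino Acid, Peptide, or Protein", "Finding",
               "Gene or Genome", "Intellectual Product", "Medical Device",
               "Research Activity")
  w <- ws_words(text)
  bare <- gsub("[[:punct:]]+$", "", tolower(w$word))
  is_time <- grepl("^[0-9]{1,2}(:[0-9]{2})?[ap]m$", bare)
  is_numstr <- grepl("^[0-9]+([^0-9A-Za-z][0-9]+)+$", bare)
  is_bare_digits <- grepl("^[0-9]{1,2}$", bare)
  n <- nrow(w)
  neighbour_month_or_age <- vapply(seq_len(n), function(k) {
    near <- c(if (k > 1) bare[k - 1], if (k < n) bare[k + 1])
    any(substr(near, 1, 3) %in% substr(MONTHS, 1, 3)) ||
      any(near %in% c("age", "aged"))
  }, logical(1))
  numy <- is_time | is_numstr | (is_bare_digits & neighbour_month_or_age)
  hit <- integer()
  for (i in seq_len(nrow(mappings))) {
    over <- FALSE
    for (k in which(numy)) {
      if (overlap0(w$start[k], w$end[k],
                   mappings$start[i], mappings$end[i])) over <- TRUE
    }
    if (!over) next
    st <- mappings$semantic_types[[i]]
    if (any(st %in% allowed) && !("Quantitative Concept" %in% st)) {
      hit <- c(hit, i)
    }
  }
  hit
}

oracle_email_url <- function(mappings, text) {
  w <- ws_words(text)
  addressy <- vapply(w$word, function(x) {
    has_at <- grepl("@", x, fixed = TRUE)
    domainish <- grepl("\\.[A-Za-z.]{2,6}(/|$|[[:punct:]]*$)", x)
    httpish <- grepl("^https?://", x, ignore.case = TRUE)
    (has_at && domainish) || httpish || (domainish && grepl("\\w\\.\\w", x))
  }, logical(1))
  hit <- integer()
  for (i in seq_len(nrow(mappings))) {
    for (k in which(addressy)) {
      if (overlap0(w$start[k], w$end[k],
                   mappings$start[i], mappings$end[i])) {
        hit <- c(hit, i)
        break
      }
    }
  }
  hit
}

oracle_inconsistent <- function(mappings, min_occurrences = 2) {
  surf <- tolower(trimws(gsub("[[:space:]]+", " ", mappings$matched_text)))
  hit <- integer()
  for (s in unique(surf)) {
    idx <- which(surf == s)
    if (length(idx) < min_occurrences) next
    tab <- table(mappings$cui[idx])
    if (length(tab) < 2) next
    majority <- sort(names(tab)[tab == max(tab)])[1]
    hit <- c(hit, idx[mappings$cui[idx] != majority])
  }
  sort(hit)
}

# all-pairs boundary oracle: every ordered mapping pair that is adjacent
# (same sentence, no unmapped word token between) and sits inside one chunk
oracle_boundary_pairs <- function(mappings, tokens, chunks) {
  mappings <- mappings[order(mappings$start, mappings$end), , drop = FALSE]
  n <- nrow(mappings)
  found <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (mappings$end[i] > mappings$start[j]) next
      # j must be the next mapping after i
      between_maps <- any(mappings$start > mappings$start[i] &
                            mappings$start < mappings$start[j] &
                            seq_len(n) != i & seq_len(n) != j)
      if (between_maps) next
      ti <- tokens_over(tokens, mappings$start[i], mappings$end[i])
      tj <- tokens_over(tokens, mappings$start[j], mappings$end[j])
      if (nrow(ti) == 0 || nrow(tj) == 0) next
      if (ti$sentence_index[1] != tj$sentence_index[1]) next
      gap_word <- FALSE
      for (t in seq_len(nrow(tokens))) {
        if (tokens$start[t] >= mappings$end[i] &&
            tokens$end[t] <= mappings$start[j] &&
            grepl("[A-Za-z0-9]", tokens$surface[t])) gap_word <- TRUE
      }
      if (gap_word) next
      inside <- FALSE
      for (c in seq_len(nrow(chunks))) {
        if (chunks$start[c] <= mappings$start[i] &&
            chunks$end[c] >= mappings$end[j]) inside <- TRUE
      }
      if (inside) {
        found[[length(found) + 1L]] <- c(mappings$start[i], mappings$end[j])
      }
    }
  }
  found
}

# span-set comparison helper: detector output vs oracle row indices
expect_same_flags <- function(failures, mappings, oracle_rows) {
  got <- sort(paste(failures$start, failures$end))
  want <- sort(paste(mappings$start[oracle_rows], mappings$end[oracle_rows]))
  expect_identical(got, want)
}
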