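# Missed-term failure detection.
#
# Two causes: community-specific nomenclature (abbreviations/acronyms the
# community coined, mined with a Schwartz–Hearst-style parenthetical rule
# and expanded before re-mapping) and misspellings (corrected by a speller
# contract before re-mapping). Both use the same differential contract: a
# substitution is a failure when re-mapping the modified text yields at
# least one mapping over the substituted region that the original region
# did not have. One occurrence is substituted at a time, so every failure
# is attributed to the span of the original text that triggered it.

SF_CORE_PATTERN <- "^[A-Z][A-Z0-9]*[A-Z]$"

# candidate short form: fully capitalized word, the last character may be
# lowercase (pluralization); returns the capitalized core or NA
sf_core <- function(word) {
  core <- sub("(?<=[A-Z])[a-z]$", "", word, perl = TRUE)
  if (grepl(SF_CORE_PATTERN, core)) core else NA_character_
}

# do the characters of `sf` occur in `long` in order (case-insensitive),
# with the first character of sf starting the first word of long?
chars_in_order <- function(sf, long) {
  sfc <- strsplit(tolower(sf), "")[[1]]
  lfc <- strsplit(tolower(long), "")[[1]]
  if (length(lfc) == 0 || sfc[1] != lfc[1]) return(FALSE)
  pos <- 0L
  for (ch in sfc) {
    hits <- which(lfc == ch)
    hits <- hits[hits > pos]
    if (length(hits) == 0) return(FALSE)
    pos <- hits[1]
  }
  TRUE
}

max_longform_words <- function(sf) min(nchar(sf) + 5L, nchar(sf) * 2L)

# shortest trailing run of `words` that satisfies the character rule
shortest_valid_suffix <- function(sf, words) {
  limit <- min(length(words), max_longform_words(sf))
  if (limit == 0) return(NULL)
  for (k in seq_len(limit)) {
    cand <- words[(length(words) - k + 1L):length(words)]
    if (chars_in_order(sf, paste(cand, collapse = " "))) return(cand)
  }
  NULL
}

#' Extract community abbreviations and acronyms
#'
#' Mines short-form/long-form pairs from post text with a rule-based
#' algorithm in the Schwartz–Hearst family, adapted to community writing:
#' candidates are fully capitalized words (the last character may be
#' lowercase, for plurals); a definition is accepted for the parenthetical
#' patterns `long form (SF)` or `SF (long form)` when every character of
#' the short form appears in the long form in order (case-insensitive,
#' first characters matching) and the long form spans at most
#' `min(|SF| + 5, |SF| * 2)` words. Entries are stored per community so the
#' expansion step can apply them to other posts of the same community even
#' where no definition is present.
#'
#' @param posts a post tibble.
#' @param community_id optional: restrict to one community.
#' @param allow,deny optional character vectors of short forms acting as a
#'   manual-verification filter (keep only `allow` if given; always drop
#'   `deny`).
#' @return a tibble: `short_form`, `long_form` (case-folded), `community_id`,
#'   `defining_post_id`.
#' @export
extract_abbreviations <- function(posts, community_id = NULL,
                                  allow = NULL, deny = character()) {
  if (!is.null(community_id)) {
    posts <- posts[posts$community_id %in% community_id, , drop = FALSE]
  }
  entries <- list()
  add <- function(sf, lf, cid, pid) {
    entries[[length(entries) + 1L]] <<- tibble::tibble(
      short_form = sf, long_form = squash_ws(casefold_term(lf)),
      community_id = cid, defining_post_id = pid)
  }
  for (i in seq_len(nrow(posts))) {
    text <- posts$text[i]
    m <- gregexpr("\\(([^()]*)\\)", text, perl = TRUE)[[1]]
    if (m[1] == -1) next
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      inner <- substr(text, m[k] + 1L, m[k] + lens[k] - 2L)
      before <- substr(text, 1, m[k] - 1L)
      # stop the candidate long form at a sentence boundary
      before <- sub(".*[.!?]", "", before)
      before_words <- strsplit(trimws(before), "[[:space:]]+")[[1]]
      before_words <- before_words[nzchar(before_words)]
      inner_trim <- trimws(inner)
      # pattern: long form (SF)
      core <- if (grepl("^[[:alnum:]]+$", inner_trim)) sf_core(inner_trim) else NA
      if (!is.na(core)) {
        lf <- shortest_valid_suffix(core, before_words)
        if (!is.null(lf)) {
          add(core, paste(lf, collapse = " "),
              posts$community_id[i], posts$post_id[i])
          next
        }
      }
      # pattern: SF (long form)
      if (length(before_words) > 0) {
        prev <- before_words[length(before_words)]
        core2 <- if (grepl("^[[:alnum:]]+$", prev)) sf_core(prev) else NA
        inner_words <- strsplit(inner_trim, "[[:space:]]+")[[1]]
        if (!is.na(core2) &&
            length(inner_words) <= max_longform_words(core2) &&
            chars_in_order(core2, inner_trim)) {
          add(core2, inner_trim, posts$community_id[i], posts$post_id[i])
        }
      }
    }
  }
  out <- if (length(entries) == 0) {
    tibble::tibble(short_form = character(), long_form = character(),
                   community_id = character(), defining_post_id = character())
  } else {
    unique(do.call(rbind, entries))
  }
  if (!is.null(allow)) out <- out[out$short_form %in% allow, , drop = FALSE]
  out[!out$short_form %in% deny, , drop = FALSE]
}

# whole-token occurrences of a literal surface (0-based half-open spans)
token_occurrences <- function(text, surface) {
  pat <- paste0("(?<![A-Za-z0-9])", gsub("([\\W])", "\\\\\\1", surface, perl = TRUE),
                "(?![A-Za-z0-9])")
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  tibble::tibble(start = m - 1L, end = m - 1L + attr(m, "match.length"))
}

# differential re-mapping for one substitution: how many mappings over the
# substituted region are new relative to the original region?
substitution_gain <- function(text, start, end, replacement, mapper,
                              orig_mappings = NULL) {
  if (is.null(orig_mappings)) orig_mappings <- mapper(text)
  modified <- paste0(substr(text, 1, start), replacement,
                     substr(text, end + 1L, nchar(text)))
  new_mappings <- mapper(modified)
  region_end <- start + nchar(replacement)
  in_new <- spans_overlap(new_mappings$start, new_mappings$end, start, region_end)
  in_old <- spans_overlap(orig_mappings$start, orig_mappings$end, start, end)
  gained <- setdiff(new_mappings$cui[in_new], orig_mappings$cui[in_old])
  length(gained)
}

# applicable long form for one short form at one post position, honouring
# temporal locality: the most recent definition at or before the post,
# else the earliest definition in the community
resolve_long_form <- function(entries, post_position, positions) {
  if (nrow(entries) == 1) return(entries$long_form[1])
  def_pos <- positions[entries$defining_post_id]
  def_pos[is.na(def_pos)] <- Inf
  before <- which(def_pos <= post_position)
  if (length(before) > 0) {
    entries$long_form[before[which.max(def_pos[before])]]
  } else {
    entries$long_form[which.min(def_pos)]
  }
}

#' Expand community abbreviations and re-map
#'
#' For each whole-token occurrence of a known short form in the post,
#' substitutes the community's long form, re-runs the mapper, and emits one
#' missed-term failure (cause `community_nomenclature`) per occurrence whose
#' substituted region yields at least one mapping absent from the original
#' region. Failures are reported at original-text spans. When one short form
#' has conflicting definitions within a community, the most recent
#' definition at or before the post (in corpus order) wins; posts preceding
#' every definition use the earliest.
#'
#' @param post a one-row post tibble (or a list with `post_id`,
#'   `community_id`, `text`).
#' @param table an abbreviation table from [extract_abbreviations()].
#' @param mapper a mapper contract: `text -> mapping records`.
#' @param posts optional full corpus, used only to order posts for the
#'   conflicting-definition rule.
#' @return a failure tibble.
#' @export
expand_and_remap <- function(post, table, mapper, posts = NULL) {
  table <- table[table$community_id == post$community_id, , drop = FALSE]
  if (nrow(table) == 0) return(empty_failures())
  positions <- if (is.null(posts)) {
    stats::setNames(seq_along(unique(table$defining_post_id)),
                    unique(table$defining_post_id))
  } else {
    stats::setNames(seq_len(nrow(posts)), posts$post_id)
  }
  post_position <- positions[post$post_id]
  if (is.na(post_position)) post_position <- Inf
  text <- post$text
  orig <- tryCatch(mapper(text), error = function(e) {
    stop("mapper failed on post ", post$post_id, ": ", conditionMessage(e),
         call. = FALSE)
  })
  rows <- list()
  for (sf in unique(table$short_form)) {
    lf <- resolve_long_form(table[table$short_form == sf, , drop = FALSE],
                            post_position, positions)
    occ <- token_occurrences(text, sf)
    for (k in seq_len(nrow(occ))) {
      gain <- tryCatch(
        substitution_gain(text, occ$start[k], occ$end[k], lf, mapper, orig),
        error = function(e) {
          stop("mapper failed on post ", post$post_id, ": ",
               conditionMessage(e), call. = FALSE)
        })
      if (gain >= 1) {
        rows[[length(rows) + 1L]] <- new_failures(
          post_id = post$post_id, cause = "community_nomenclature",
          start = occ$start[k], end = occ$end[k], surface = sf,
          evidence = sprintf("expanded to %s; %d new mapping(s)",
                             dQuote(lf), gain),
          replacement = lf, new_mapping_count = gain)
      }
    }
  }
  bind_failures(rows)
}

#' Bundled fallback speller
#'
#' Builds a speller contract from a word lexicon: a lower-case alphabetic
#' token of at least four characters that is not in the lexicon is corrected
#' to the nearest lexicon entry within Levenshtein distance 2 (ties broken
#' alphabetically); everything else, including in-lexicon tokens, gets no
#' correction. Production analyses inject an external suggestion service
#' through the `speller` argument of [spellcheck_and_remap()].
#'
#' @param lexicon a `maplint_lexicon` of correctly spelled words.
#' @param max_distance maximum edit distance considered (default 2).
#' @return a function `token -> corrected string or NULL`.
#' @export
default_speller <- function(lexicon, max_distance = 2) {
  entries <- lexicon$entries
  function(token) {
    if (!grepl("^[a-z]+$", token) || nchar(token) < 4) return(NULL)
    if (token %in% entries) return(NULL)
    d <- utils::adist(token, entries)[1, ]
    dmin <- min(d)
    if (dmin > max_distance) return(NULL)
    sort(entries[d == dmin])[1]
  }
}

#' Correct misspellings and re-map
#'
#' Applies the speller to every word token of the post; for each corrected
#' token, substitutes the correction, re-runs the mapper, and emits one
#' missed-term failure (cause `misspelling`) per occurrence whose
#' substituted region yields at least one new mapping — even if that new
#' mapping is itself wrong, since the original term was still missed. A
#' speller error on a token skips the token with a warning.
#'
#' @param post a one-row post tibble.
#' @param speller a speller contract: `token -> corrected string or NULL`.
#' @param mapper a mapper contract.
#' @return a failure tibble, at original-text spans.
#' @export
spellcheck_and_remap <- function(post, speller, mapper) {
  text <- post$text
  toks <- tokenize_raw(text)
  toks <- toks[grepl("^[A-Za-z]+$", toks$surface), , drop = FALSE]
  orig <- tryCatch(mapper(text), error = function(e) {
    stop("mapper failed on post ", post$post_id, ": ", conditionMessage(e),
         call. = FALSE)
  })
  rows <- list()
  for (k in seq_len(nrow(toks))) {
    corrected <- tryCatch(speller(toks$surface[k]), error = function(e) {
      warning("speller failed on token ", dQuote(toks$surface[k]),
              " (post ", post$post_id, "): ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(corrected) || identical(corrected, toks$surface[k])) next
    gain <- substitution_gain(text, toks$start[k], toks$end[k], corrected,
                              mapper, orig)
    if (gain >= 1) {
      rows[[length(rows) + 1L]] <- new_failures(
        post_id = post$post_id, cause = "misspelling",
        start = toks$start[k], end = toks$end[k], surface = toks$surface[k],
        evidence = sprintf("corrected to %s; %d new mapping(s)",
                           dQuote(corrected), gain),
        replacement = corrected, new_mapping_count = gain)
    }
  }
  bind_failures(rows)
}

#' Write / read an abbreviation table
#'
#' TSV serialization (`short_form`, `long_form`, `community_id`,
#' `defining_post_id`).
#'
#' @param table an abbreviation tibble.
#' @param path file path.
#' @return `path` (write) or the tibble (read).
#' @export
write_abbreviations <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_abbreviations
#' @export
read_abbreviations <- function(path) {
  tibble::as_tibble(utils::read.delim(path, colClasses = "character",
                                      fileEncoding = "UTF-8"))
}
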