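# Post/mapping I/O, tokenization and POS tagging.
#
# Offsets everywhere are 0-based, half-open, in Unicode code points.
# External mapper output (the MMI dialect) is converted to this convention
# at the boundary on read.

POST_COLUMNS <- c("community_id", "post_id", "author_handle", "text")

MAPPING_COLUMNS <- c(
  "post_id", "phrase_index", "start", "end", "matched_text",
  "cui", "concept_name", "semantic_types", "score"
)

new_posts <- function(community_id = character(), post_id = character(),
                      author_handle = character(), text = character(),
                      timestamp = character()) {
  tibble::tibble(
    community_id = as.character(community_id),
    post_id = as.character(post_id),
    author_handle = as.character(author_handle),
    text = as.character(text),
    timestamp = as.character(timestamp)
  )
}

validate_posts <- function(posts) {
  dup <- posts$post_id[duplicated(posts$post_id)]
  if (length(dup) > 0) {
    stop("duplicate post_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  blank <- which(trimws(posts$text) == "")
  if (length(blank) > 0) {
    stop("empty text for post_id: ",
         paste(posts$post_id[blank], collapse = ", "), call. = FALSE)
  }
  posts
}

#' Read community posts
#'
#' Reads a corpus of online-community posts from JSONL (one object per line,
#' keys `community_id`, `post_id`, `author_handle`, `text`, optional
#' `timestamp`) or CSV with the identical header. Text is preserved verbatim;
#' no normalization is applied on read.
#'
#' @param source path to the input file.
#' @param format_dialect `"jsonl"` or `"csv"`.
#' @return a tibble with one row per post. `post_id` values are checked for
#'   uniqueness and texts must be non-empty after whitespace stripping.
#' @export
read_posts <- function(source, format_dialect = c("jsonl", "csv")) {
  format_dialect <- match.arg(format_dialect)
  if (!file.exists(source)) stop("no such file: ", source, call. = FALSE)
  if (format_dialect == "jsonl") {
    lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(new_posts())
    rows <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) abort_record(i, "malformed JSON"))
      missing <- setdiff(POST_COLUMNS, names(rec))
      if (length(missing) > 0) {
        abort_record(i, paste0("missing field(s): ",
                               paste(missing, collapse = ", ")))
      }
      new_posts(rec$community_id, rec$post_id, rec$author_handle, rec$text,
                if (is.null(rec$timestamp)) NA_character_ else rec$timestamp)
    })
    posts <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(source, colClasses = "character",
                          fileEncoding = "UTF-8")
    if (nrow(df) == 0) return(new_posts())
    missing <- setdiff(POST_COLUMNS, names(df))
    if (length(missing) > 0) {
      stop("missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    posts <- new_posts(df$community_id, df$post_id, df$author_handle, df$text,
                       if ("timestamp" %in% names(df)) df$timestamp
                       else NA_character_)
  }
  validate_posts(posts)
}

#' Write community posts
#'
#' Inverse of [read_posts()]: emits JSONL or CSV that round-trips exactly.
#'
#' @param posts a post tibble as returned by [read_posts()].
#' @param path output file path.
#' @param format_dialect `"jsonl"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_posts <- function(posts, path, format_dialect = c("jsonl", "csv")) {
  format_dialect <- match.arg(format_dialect)
  if (format_dialect == "jsonl") {
    lines <- vapply(seq_len(nrow(posts)), function(i) {
      rec <- as.list(posts[i, ])
      if (is.na(rec$timestamp)) rec$timestamp <- NULL
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  } else {
    utils::write.csv(posts, path, row.names = FALSE, fileEncoding = "UTF-8",
                     na = "")
  }
  invisible(path)
}

new_mapping_records <- function(post_id = character(),
                                phrase_index = integer(),
                                start = integer(), end = integer(),
                                matched_text = character(),
                                cui = character(),
                                concept_name = character(),
                                semantic_types = list(),
                                score = numeric()) {
  tibble::tibble(
    post_id = as.character(post_id),
    phrase_index = as.integer(phrase_index),
    start = as.integer(start),
    end = as.integer(end),
    matched_text = as.character(matched_text),
    cui = as.character(cui),
    concept_name = as.character(concept_name),
    semantic_types = as.list(semantic_types),
    score = as.numeric(score)
  )
}

#' Validate mapping records against their posts
#'
#' Checks CUI syntax (`C` + 7 digits), that each span lies within its post's
#' text, that the matched text equals the covered slice up to case and
#' whitespace normalization, and that each record's semantic-type list is
#' non-empty.
#'
#' @param records a mapping-record tibble.
#' @param posts the post corpus the records refer to.
#' @return `records`, invisibly rearranged not at all; errors on violation.
#' @export
validate_mapping_records <- function(records, posts) {
  bad_cui <- !grepl("^C[0-9]{7}$", records$cui)
  if (any(bad_cui)) {
    abort_record(which(bad_cui)[1],
                 paste0("invalid CUI syntax: ", records$cui[bad_cui][1]))
  }
  if (any(lengths(records$semantic_types) == 0)) {
    abort_record(which(lengths(records$semantic_types) == 0)[1],
                 "empty semantic_types")
  }
  text_of <- stats::setNames(posts$text, posts$post_id)
  for (i in seq_len(nrow(records))) {
    pid <- records$post_id[i]
    if (!pid %in% names(text_of)) {
      abort_record(i, paste0("unknown post_id: ", pid))
    }
    txt <- text_of[[pid]]
    s <- records$start[i]; e <- records$end[i]
    if (is.na(s) || is.na(e) || s < 0 || e <= s || e > nchar(txt)) {
      stop(sprintf("alignment error: post %s span [%s,%s) outside text of length %d",
                   pid, s, e, nchar(txt)), call. = FALSE)
    }
    slice <- slice_text(txt, s, e)
    if (squash_ws(casefold_term(slice)) !=
        squash_ws(casefold_term(records$matched_text[i]))) {
      stop(sprintf(
        "alignment error: post %s span [%d,%d) reads %s but record says %s",
        pid, s, e, dQuote(slice), dQuote(records$matched_text[i])),
        call. = FALSE)
    }
  }
  invisible(records)
}

parse_semtypes <- function(x) {
  if (is.list(x)) return(lapply(x, as.character))
  lapply(strsplit(as.character(x), "|", fixed = TRUE), trimws)
}

#' Read concept-mapping records
#'
#' Reads one record per mapped term from the interchange TSV (columns
#' `post_id`, `phrase_index`, `start`, `end`, `matched_text`, `cui`,
#' `concept_name`, `semantic_types` pipe-separated, `score`), its JSONL
#' mirror, or fielded MMI mapper output
#' (`post_id|MMI|score|concept_name|CUI|[semtypes]|trigger|positional`),
#' where positional info is a `start/length` pair (0-based start), with
#' multiple occurrences separated by `;`.
#'
#' Records are validated against the supplied posts: spans must lie within
#' the post text and the matched text must equal the covered slice up to
#' case/whitespace normalization. The mapper is assumed to have been run
#' keeping only its top-ranked concept, so there is exactly one record per
#' mapped term occurrence.
#'
#' @param source path to the input file.
#' @param posts the post corpus (for span validation, and for recovering
#'   matched text in the MMI dialect).
#' @param dialect `"tsv"`, `"jsonl"` or `"mmi"`.
#' @return a mapping-record tibble; `semantic_types` is a list column.
#' @export
read_mapping_records <- function(source, posts,
                                 dialect = c("tsv", "jsonl", "mmi")) {
  dialect <- match.arg(dialect)
  if (!file.exists(source)) stop("no such file: ", source, call. = FALSE)
  if (dialect == "tsv") {
    df <- utils::read.delim(source, colClasses = "character",
                            fileEncoding = "UTF-8", check.names = FALSE)
    if (nrow(df) == 0) return(new_mapping_records())
    missing <- setdiff(MAPPING_COLUMNS, names(df))
    if (length(missing) > 0) {
      stop("missing column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    records <- new_mapping_records(
      df$post_id, as.integer(df$phrase_index), as.integer(df$start),
      as.integer(df$end), df$matched_text, df$cui, df$concept_name,
      parse_semtypes(df$semantic_types), as.numeric(df$score))
  } else if (dialect == "jsonl") {
    lines <- readLines(source, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(new_mapping_records())
    rows <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e) abort_record(i, "malformed JSON"))
      missing <- setdiff(MAPPING_COLUMNS, names(rec))
      if (length(missing) > 0) {
        abort_record(i, paste0("missing field(s): ",
                               paste(missing, collapse = ", ")))
      }
      new_mapping_records(rec$post_id, rec$phrase_index, rec$start, rec$end,
                          rec$matched_text, rec$cui, rec$concept_name,
                          list(as.character(rec$semantic_types)), rec$score)
    })
    records <- do.call(rbind, rows)
  } else {
    records <- read_mmi_lines(readLines(source, encoding = "UTF-8",
                                        warn = FALSE), posts)
  }
  validate_mapping_records(records, posts)
  records
}

# Parse fielded MMI lines. Positional info is start/length with a 0-based
# start; phrase_index is assigned sequentially within each post in reading
# order (MMI does not carry the mapper's phrase segmentation id).
read_mmi_lines <- function(lines, posts) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(new_mapping_records())
  text_of <- stats::setNames(posts$text, posts$post_id)
  out <- list()
  counters <- new.env(parent = emptyenv())
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "|", fixed = TRUE)[[1]]
    if (length(f) < 8 || f[2] != "MMI") {
      abort_record(i, "not a fielded MMI line (expected 8 pipe-separated fields with MMI tag)")
    }
    pid <- f[1]
    if (!pid %in% names(text_of)) abort_record(i, paste0("unknown post_id: ", pid))
    semtypes <- trimws(strsplit(gsub("^\\[|\\]$", "", f[6]), ",")[[1]])
    for (pos in strsplit(f[8], ";", fixed = TRUE)[[1]]) {
      m <- regmatches(pos, regexec("^([0-9]+)/([0-9]+)$", pos))[[1]]
      if (length(m) == 0) abort_record(i, paste0("bad positional info: ", pos))
      start <- as.integer(m[2])
      end <- start + as.integer(m[3])
      idx <- (if (exists(pid, envir = counters)) get(pid, envir = counters)
              else 0L) + 1L
      assign(pid, idx, envir = counters)
      out[[length(out) + 1L]] <- new_mapping_records(
        pid, idx, start, end,
        slice_text(text_of[[pid]], start, end),
        f[5], f[4], list(semtypes), as.numeric(f[3]))
    }
  }
  do.call(rbind, out)
}

#' Write concept-mapping records
#'
#' Emits the interchange TSV or JSONL; both round-trip through
#' [read_mapping_records()] exactly.
#'
#' @param records a mapping-record tibble.
#' @param path output file path.
#' @param dialect `"tsv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_mapping_records <- function(records, path, dialect = c("tsv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    df <- records
    df$semantic_types <- vapply(records$semantic_types, paste,
                                character(1), collapse = "|")
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    lines <- vapply(seq_len(nrow(records)), function(i) {
      rec <- as.list(records[i, ])
      rec$semantic_types <- rec$semantic_types[[1]]
      jsonlite::toJSON(rec, auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## Tokenization and POS tagging

# sentence spans: break after runs of .!? followed by whitespace + an
# upper-case letter, digit or opening quote, or at end of text;
# exclamation/question runs collapse into one boundary
sentence_spans <- function(text) {
  n <- nchar(text)
  if (n == 0) return(tibble::tibble(start = integer(), end = integer()))
  breaks <- integer()
  mm <- gregexpr("[.!?]+", text)[[1]]
  if (mm[1] != -1) {
    lens <- attr(mm, "match.length")
    for (k in seq_along(mm)) {
      after <- mm[k] + lens[k]           # 1-based index of char after the run
      rest <- substr(text, after, n)
      if (after > n || grepl("^[[:space:]]+[\"'(]?[A-Z0-9]", rest)) {
        breaks <- c(breaks, after - 1L)  # 0-based end offset of the sentence
      }
    }
  }
  starts <- c(0L, breaks)
  ends <- c(breaks, n)
  keep <- starts < ends
  spans <- tibble::tibble(start = starts[keep], end = ends[keep])
  # drop spans that are pure whitespace
  spans[vapply(seq_len(nrow(spans)), function(i) {
    nzchar(trimws(slice_text(text, spans$start[i], spans$end[i])))
  }, logical(1)), ]
}

TOKEN_PATTERN <- "['’][A-Za-z]+|[A-Za-z0-9]+|[^[:space:]]"

# raw tokens with spans and sentence indices (no tags yet)
tokenize_raw <- function(text) {
  sents <- sentence_spans(text)
  out <- list()
  for (si in seq_len(nrow(sents))) {
    seg <- slice_text(text, sents$start[si], sents$end[si])
    m <- gregexpr(TOKEN_PATTERN, seg, perl = TRUE)[[1]]
    if (m[1] == -1) next
    lens <- attr(m, "match.length")
    out[[si]] <- tibble::tibble(
      surface = regmatches(seg, list(m))[[1]],
      start = sents$start[si] + m - 1L,
      end = sents$start[si] + m - 1L + lens,
      sentence_index = si - 1L
    )
  }
  if (length(out) == 0) {
    return(tibble::tibble(surface = character(), start = integer(),
                          end = integer(), sentence_index = integer()))
  }
  do.call(rbind, out)
}

# closed-class word lists for the fallback tagger
TAG_LEXICON <- local({
  lex <- c(
    stats::setNames(rep("PRP", 12),
      c("i", "you", "he", "she", "it", "we", "they", "me", "him", "her",
        "us", "them")),
    stats::setNames(rep("PRP$", 6),
      c("my", "your", "his", "its", "our", "their")),
    stats::setNames(rep("MD", 9),
      c("will", "would", "can", "could", "may", "might", "must", "shall",
        "should")),
    stats::setNames(rep("DT", 11),
      c("the", "a", "an", "this", "that", "these", "those", "some", "any",
        "each", "every")),
    stats::setNames(rep("IN", 25),
      c("of", "in", "on", "at", "by", "for", "with", "about", "against",
        "between", "into", "through", "during", "before", "after", "from",
        "under", "over", "since", "without", "within", "along", "across",
        "upon", "near")),
    stats::setNames(rep("CC", 6),
      c("and", "but", "or", "nor", "so", "yet")),
    stats::setNames(rep("UH", 9),
      c("hi", "hello", "hey", "oh", "ah", "wow", "lol", "omg", "xoxo")),
    stats::setNames(rep("RB", 16),
      c("not", "very", "too", "also", "just", "really", "still", "again",
        "often", "never", "always", "soon", "now", "then", "here", "there")),
    stats::setNames(rep("VBD", 27),
      c("was", "were", "had", "did", "said", "saw", "went", "got", "told",
        "took", "gave", "came", "found", "thought", "knew", "felt", "made",
        "lost", "left", "kept", "began", "met", "sent", "heard", "held",
        "meant", "ran")),
    stats::setNames(rep("VBZ", 4), c("is", "has", "does", "says")),
    stats::setNames(rep("VBP", 46),
      c("am", "are", "be", "have", "do", "go", "get", "say", "see", "know",
        "think", "want", "wish", "feel", "need", "take", "give", "come",
        "find", "tell", "make", "wait", "snap", "bow", "sign", "help",
        "keep", "let", "put", "seem", "try", "love", "pray", "thank",
        "miss", "send", "stay", "start", "stop", "talk", "turn", "use",
        "work", "call", "ask", "live")),
    stats::setNames(rep("JJ", 24),
      c("good", "great", "bad", "new", "old", "big", "small", "triple",
        "double", "negative", "positive", "aggressive", "inoperable",
        "last", "next", "many", "few", "several", "early", "late", "first",
        "second", "third", "internal")),
    c(to = "TO", no = "DT", off = "RP", up = "RP", down = "RP",
      out = "RP", what = "WP", who = "WP", which = "WDT", when = "WRB",
      where = "WRB", how = "WRB", why = "WRB")
  )
  lex
})

CONTRACTION_TAGS <- c(
  "'d" = "MD", "'ll" = "MD", "'m" = "VBP", "'re" = "VBP", "'ve" = "VBP",
  "'s" = "VBZ", "'t" = "RB"
)

tag_one <- function(surface, sentence_initial) {
  low <- tolower(surface)
  low_ascii <- chartr("’", "'", low)
  if (low_ascii %in% names(CONTRACTION_TAGS)) {
    return(unname(CONTRACTION_TAGS[[low_ascii]]))
  }
  if (grepl("^['’]", surface)) return("POS")
  if (grepl("^[.!?]+$", surface)) return(".")
  if (surface == ",") return(",")
  if (surface == "(") return("(")
  if (surface == ")") return(")")
  if (grepl("^[^A-Za-z0-9]+$", surface)) return("SYM")
  if (grepl("^[0-9]", surface)) return("CD")
  if (low %in% names(TAG_LEXICON)) return(unname(TAG_LEXICON[[low]]))
  if (grepl("[a-z]", surface) && grepl("^[A-Z]", surface) &&
      !sentence_initial) {
    return("NNP")
  }
  if (grepl("ing$", low) && nchar(low) > 4) return("VBG")
  if (grepl("ed$", low) && nchar(low) > 3) return("VBD")
  if (grepl("ly$", low) && nchar(low) > 3) return("RB")
  if (grepl("(ous|ful|ive|ish|able|ible)$", low)) return("JJ")
  if (grepl("[^su]s$", low) && nchar(low) > 3) return("NNS")
  "NN"
}

#' Bundled fallback POS tagger
#'
#' A deterministic rule-based tagger: sentence segmentation, apostrophe-split
#' contractions, closed-class word lists, and suffix heuristics. It satisfies
#' the tagger contract (every non-whitespace character covered by exactly one
#' token) and is tuned to be correct on the vocabulary of the bundled
#' fixtures; production analyses should inject a full statistical tagger
#' through the `tagger` argument of [tokenize_and_tag()].
#'
#' @param text a single string.
#' @return a token tibble: `surface`, `start`, `end` (0-based half-open code
#'   point offsets), `pos_tag` (Penn-Treebank-style), `sentence_index`.
#' @export
default_tagger <- function(text) {
  toks <- tokenize_raw(text)
  if (nrow(toks) == 0) {
    toks$pos_tag <- character()
    return(toks[, c("surface", "start", "end", "pos_tag", "sentence_index")])
  }
  first_of_sentence <- !duplicated(toks$sentence_index)
  toks$pos_tag <- vapply(seq_len(nrow(toks)), function(i) {
    tag_one(toks$surface[i], first_of_sentence[i])
  }, character(1))
  toks[, c("surface", "start", "end", "pos_tag", "sentence_index")]
}

#' Tokenize and POS-tag text
#'
#' Runs the supplied tagger (default: the bundled rule-based
#' [default_tagger()]) and checks the token contract: spans in bounds,
#' non-overlapping, ordered, and covering every non-whitespace character.
#' Contractions are split on the apostrophe into two tokens, each with its
#' own tag (e.g. a personal-pronoun token plus a modal token for "I'd").
#'
#' @param text a single string (may be empty).
#' @param tagger a function `text -> token tibble` honouring the contract.
#' @return a token tibble (see [default_tagger()]).
#' @export
tokenize_and_tag <- function(text, tagger = default_tagger) {
  toks <- tagger(text)
  if (nrow(toks) == 0) return(toks)
  stopifnot(all(toks$start >= 0), all(toks$end <= nchar(text)),
            all(toks$start < toks$end))
  o <- order(toks$start)
  toks <- toks[o, ]
  if (any(toks$start[-1] < toks$end[-nrow(toks)])) {
    stop("tagger contract violation: overlapping tokens", call. = FALSE)
  }
  covered <- unlist(lapply(seq_len(nrow(toks)), function(i) {
    seq(toks$start[i] + 1L, toks$end[i])
  }))
  chars <- strsplit(text, "")[[1]]
  nonspace <- which(!grepl("[[:space:]]", chars))
  if (!setequal(covered, nonspace)) {
    stop("tagger contract violation: tokens must cover every non-whitespace character exactly once",
         call. = FALSE)
  }
  toks
}

# tokens (rows of a token tibble) overlapping a mapping span
tokens_in_span <- function(tokens, start, end) {
  tokens[spans_overlap(tokens$start, tokens$end, start, end), , drop = FALSE]
}
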