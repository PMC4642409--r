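# Dictionary resources the detectors depend on.
#
# All lexicons are one-entry-per-line UTF-8 files; entries are case-folded
# and whitespace-normalized on load, so membership tests are
# case-insensitive. The semantic-type table is a two-column TSV
# (type_name, tree) partitioning types into the Event and Entity trees of
# the concept ontology's semantic network; the Event partition holds
# exactly 34 types.

#' Load a dictionary lexicon
#'
#' Reads a one-entry-per-line file, case-folds and trims entries, collapses
#' duplicates and removes `exclusions` (matched after case-folding). Used
#' for the first-name, community-handle, Internet-slang, cancer-gene,
#' spell-check and known-term dictionaries. An empty result is a
#' configuration error: a detector with an empty dictionary is meaningless.
#'
#' @param path path to the lexicon file.
#' @param name short label used in evidence strings.
#' @param exclusions entries to drop (e.g. medical acronyms that must be
#'   removed from an Internet-slang list such as AML, CMF and RX).
#' @return an object of class `maplint_lexicon` with fields `name`,
#'   `entries` (case-folded, sorted) and `source`.
#' @export
load_lexicon <- function(path, name, exclusions = character()) {
  if (!file.exists(path)) {
    stop("lexicon file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  entries <- unique(squash_ws(casefold_term(raw)))
  entries <- setdiff(entries[nzchar(entries)],
                     squash_ws(casefold_term(exclusions)))
  if (length(entries) == 0) {
    stop("lexicon ", dQuote(name), " is empty after exclusions (", path, ")",
         call. = FALSE)
  }
  structure(list(name = name, entries = sort(entries), source = path),
            class = "maplint_lexicon")
}

#' Build a lexicon from a character vector
#'
#' Convenience constructor used by tests and the synthetic generator;
#' applies the same case-folding and whitespace normalization as
#' [load_lexicon()].
#'
#' @param entries character vector of terms.
#' @param name short label.
#' @return a `maplint_lexicon`.
#' @export
as_lexicon <- function(entries, name = "adhoc") {
  entries <- unique(squash_ws(casefold_term(entries)))
  entries <- entries[nzchar(entries)]
  if (length(entries) == 0) stop("empty lexicon", call. = FALSE)
  structure(list(name = name, entries = sort(entries), source = NA_character_),
            class = "maplint_lexicon")
}

#' @export
print.maplint_lexicon <- function(x, ...) {
  cat(sprintf("<lexicon %s: %d entries>\n", x$name, length(x$entries)))
  invisible(x)
}

#' Case-insensitive lexicon membership
#'
#' @param lexicon a `maplint_lexicon`.
#' @param terms character vector of probes; probes are case-folded and
#'   whitespace-normalized before lookup.
#' @return logical vector.
#' @export
lexicon_contains <- function(lexicon, terms) {
  squash_ws(casefold_term(terms)) %in% lexicon$entries
}

#' Load the semantic-type tree table
#'
#' Reads a two-column TSV (`type_name`, `tree`) assigning every semantic
#' type to the Event or Entity tree. The loaded table must contain exactly
#' 34 Event-tree types and no type may appear twice.
#'
#' @param path path to the TSV; defaults to the bundled table.
#' @return a tibble with columns `type_name` and `tree`.
#' @export
load_semantic_type_table <- function(path = bundled_lexicon_path("semantic_types.tsv")) {
  df <- utils::read.delim(path, colClasses = "character",
                          fileEncoding = "UTF-8")
  if (!all(c("type_name", "tree") %in% names(df))) {
    stop("semantic-type table needs columns type_name and tree", call. = FALSE)
  }
  df$type_name <- trimws(df$type_name)
  df$tree <- trimws(df$tree)
  if (anyDuplicated(casefold_term(df$type_name))) {
    stop("semantic type listed twice: ",
         df$type_name[duplicated(casefold_term(df$type_name))][1],
         call. = FALSE)
  }
  if (!all(df$tree %in% c("Event", "Entity"))) {
    stop("tree must be Event or Entity", call. = FALSE)
  }
  if (sum(df$tree == "Event") != 34) {
    stop("the Event partition must contain exactly 34 semantic types, found ",
         sum(df$tree == "Event"), call. = FALSE)
  }
  tibble::as_tibble(df[, c("type_name", "tree")])
}

#' Classify a semantic type into the Event or Entity tree
#'
#' Total and deterministic: known types return their tree, anything else
#' returns `"unknown"` (never an error). Lookup is case-insensitive.
#'
#' @param table a semantic-type table from [load_semantic_type_table()].
#' @param semantic_type character vector of type names.
#' @return character vector over `c("Event", "Entity", "unknown")`.
#' @export
classify_semantic_type <- function(table, semantic_type) {
  idx <- match(casefold_term(semantic_type), casefold_term(table$type_name))
  out <- table$tree[idx]
  out[is.na(out)] <- "unknown"
  out
}

#' Path to a bundled lexicon fixture
#'
#' @param name file name under the package's `extdata/lexicons` directory.
#' @return absolute path.
#' @export
bundled_lexicon_path <- function(name) {
  p <- system.file("extdata", "lexicons", name, package = "maplint",
                   mustWork = FALSE)
  if (p == "") stop("no bundled lexicon called ", name, call. = FALSE)
  p
}

#' Load the full bundled lexicon set
#'
#' Loads the fixture dictionaries shipped with the package: first names,
#' community handles, Internet slang/SMS shorthand (with the medical
#' acronyms AML, CMF and RX excluded), cancer gene symbols, a spell-check
#' word list, a known multi-word term lexicon, and the semantic-type tree
#' table. These are deliberately small, deterministic stand-ins for the
#' large external dictionaries a production deployment would plug in.
#'
#' @return a named list: `first_names`, `handles`, `slang`, `genes`,
#'   `spell`, `terms` (each a `maplint_lexicon`) and `semtypes` (a tibble).
#' @export
default_lexicons <- function() {
  list(
    first_names = load_lexicon(bundled_lexicon_path("first_names.txt"),
                               "first_names"),
    handles = load_lexicon(bundled_lexicon_path("handles.txt"), "handles"),
    slang = load_lexicon(bundled_lexicon_path("slang.txt"), "slang",
                         exclusions = c("AML", "CMF", "RX")),
    genes = load_lexicon(bundled_lexicon_path("cancer_genes.txt"), "genes"),
    spell = load_lexicon(bundled_lexicon_path("spell_lexicon.txt"), "spell"),
    terms = load_lexicon(bundled_lexicon_path("known_terms.txt"), "terms"),
    semtypes = load_semantic_type_table()
  )
}
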