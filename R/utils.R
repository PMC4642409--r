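# Internal helpers shared across modules.
#
# All character offsets in this package are 0-based, half-open, counted in
# Unicode code points: a span [start, end) covers substr(text, start + 1, end).

#' Slice a string by a 0-based half-open span
#'
#' @param text a single string.
#' @param start,end integer offsets, 0-based, half-open.
#' @return the covered substring.
#' @keywords internal
#' @noRd
slice_text <- function(text, start, end) {
  substr(text, start + 1L, end)
}

# case-fold: the package-wide normalization for dictionary probes
casefold_term <- function(x) tolower(trimws(x))

# collapse internal whitespace runs to single spaces (for multi-word terms)
squash_ws <- function(x) gsub("[[:space:]]+", " ", trimws(x))

# round half-up to `digits` decimals (base round() is round-half-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# do spans [s1,e1) and [s2,e2) overlap?
spans_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & s2 < e1
}

# run code with a private RNG state seeded from `seed`, restoring the caller's
# stream afterwards; keeps sampling reproducible without clobbering the session
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# stop() with a consistent error prefix naming the offending record
abort_record <- function(line, msg) {
  stop(sprintf("record %s: %s", line, msg), call. = FALSE)
}

empty_tibble <- function(proto) {
  proto[0, , drop = FALSE]
}
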