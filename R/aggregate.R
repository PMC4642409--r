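# Unique-failure accounting and summary reports.
#
# Two counting conventions are first-class:
#  * failure events: boundary failures count pair-level, missed terms and
#    ambiguity failures occurrence-level; within the ambiguity type one
#    mapping occurrence counts once toward the unique total no matter how
#    many causes flagged it (this is the convention of the per-cause
#    summary table);
#  * affected mappings: a boundary pair implicates both constituent
#    mappings, an ambiguity failure its one mapping, a missed term its
#    span; the result is a set (the convention of the worked example's
#    "12 mappings + 1 missed term = 13 failures" count).

#' Deduplicate failure records
#'
#' Collapses ambiguity failures so that one mapping occurrence counts once
#' toward the unique ambiguity total regardless of how many causes flagged
#' it; all flagging causes are retained in the collapsed record's `causes`
#' field. Boundary failures stay pair-level events and missed-term failures
#' occurrence-level (their triggers are disjoint by construction).
#'
#' @param failures a failure tibble (any mix of causes, any order).
#' @return a list: `unique_failures` (ambiguity rows collapsed, with a
#'   `causes` comma-separated field), `cause_counts` (named vector over the
#'   12 causes, pre-deduplication), `unique_ambiguity_count`,
#'   `unique_total`.
#' @export
deduplicate_failures <- function(failures) {
  cause_counts <- vapply(names(FAILURE_CAUSES), function(cz) {
    sum(failures$cause == cz)
  }, integer(1))
  amb <- failures[failures$type == "ambiguity", , drop = FALSE]
  other <- failures[failures$type != "ambiguity", , drop = FALSE]
  if (nrow(amb) > 0) {
    key <- paste(amb$post_id, amb$start, amb$end, sep = "\r")
    ord <- order(key, amb$cause)
    amb <- amb[ord, , drop = FALSE]
    key <- key[ord]
    causes <- vapply(split(amb$cause, key), function(cs) {
      paste(sort(unique(cs)), collapse = ",")
    }, character(1))
    keep <- !duplicated(key)
    amb <- amb[keep, , drop = FALSE]
    amb$causes <- unname(causes[key[keep]])
  } else {
    amb$causes <- character(0)
  }
  other$causes <- other$cause
  ord2 <- order(other$post_id, other$start, other$end, other$cause)
  other <- other[ord2, , drop = FALSE]
  unique_failures <- rbind(other, amb)
  unique_failures <- unique_failures[order(unique_failures$post_id,
                                           unique_failures$start,
                                           unique_failures$end,
                                           unique_failures$cause), ,
                                     drop = FALSE]
  list(
    unique_failures = unique_failures,
    cause_counts = cause_counts,
    unique_ambiguity_count = nrow(amb),
    unique_total = nrow(other) + nrow(amb)
  )
}

#' Affected mappings and missed-term spans
#'
#' The set of `(post_id, start, end)` spans implicated by the unique
#' failures: boundary failures contribute both constituent mapping spans,
#' ambiguity failures their mapping span, missed-term failures their span
#' of unrecognized original text. Being a set, a mapping flagged by several
#' causes appears once.
#'
#' @param unique_failures the `unique_failures` element of
#'   [deduplicate_failures()] (a raw failure tibble also works).
#' @return a tibble: `post_id`, `start`, `end`, `kind`
#'   (`mapping` or `missed_term`).
#' @export
affected_mappings <- function(unique_failures) {
  f <- unique_failures
  pieces <- list()
  b <- f[f$type == "boundary", , drop = FALSE]
  if (nrow(b) > 0) {
    pieces$bl <- tibble::tibble(post_id = b$post_id, start = b$left_start,
                                end = b$left_end, kind = "mapping")
    pieces$br <- tibble::tibble(post_id = b$post_id, start = b$right_start,
                                end = b$right_end, kind = "mapping")
  }
  a <- f[f$type == "ambiguity", , drop = FALSE]
  if (nrow(a) > 0) {
    pieces$a <- tibble::tibble(post_id = a$post_id, start = a$start,
                               end = a$end, kind = "mapping")
  }
  m <- f[f$type == "missed_term", , drop = FALSE]
  if (nrow(m) > 0) {
    pieces$m <- tibble::tibble(post_id = m$post_id, start = m$start,
                               end = m$end, kind = "missed_term")
  }
  if (length(pieces) == 0) {
    return(tibble::tibble(post_id = character(), start = integer(),
                          end = integer(), kind = character()))
  }
  out <- unique(do.call(rbind, pieces))
  out[order(out$post_id, out$start, out$end), , drop = FALSE]
}

#' Summarize failures
#'
#' Builds the per-cause summary: counts for all 12 causes (ambiguity causes
#' pre-deduplication, so their percentages can exceed 100% in sum), the
#' unique ambiguity and overall totals, per-cause percentages of the unique
#' total (half-up, 2 decimals), and failure rates over the corpus's total
#' mapping count: `failure_rate` uses the unique-failure total (pair-level
#' boundary counting) and `affected_rate` the affected-mapping set.
#'
#' @param failures a failure tibble, or the list from
#'   [deduplicate_failures()].
#' @param total_mappings total number of mapper records in the corpus.
#' @return an object of class `failure_summary`.
#' @export
summarize_failures <- function(failures, total_mappings) {
  if (!is.numeric(total_mappings) || total_mappings <= 0) {
    stop("failure rate undefined: total_mappings must be positive",
         call. = FALSE)
  }
  dd <- if (is.list(failures) && !is.data.frame(failures)) failures
        else deduplicate_failures(failures)
  pct <- round_half_up(100 * dd$cause_counts / dd$unique_total, 2)
  pct[!is.finite(pct)] <- NA_real_
  affected <- affected_mappings(dd$unique_failures)
  structure(list(
    cause_counts = dd$cause_counts,
    cause_percent = pct,
    unique_ambiguity_count = dd$unique_ambiguity_count,
    unique_ambiguity_percent =
      round_half_up(100 * dd$unique_ambiguity_count / dd$unique_total, 2),
    unique_total = dd$unique_total,
    total_mappings = as.integer(total_mappings),
    failure_rate = round_half_up(100 * dd$unique_total / total_mappings, 2),
    affected_count = nrow(affected),
    affected_rate = round_half_up(100 * nrow(affected) / total_mappings, 2)
  ), class = "failure_summary")
}

#' Summary from pre-aggregated counts
#'
#' Builds a `failure_summary` directly from per-cause counts, the unique
#' ambiguity total and the corpus mapping total — for re-deriving the
#' percentage columns of an already-aggregated failure report (e.g. a
#' published counts table) without the underlying failure records.
#'
#' @param cause_counts named integer vector over the 12 causes.
#' @param unique_ambiguity_count deduplicated ambiguity total.
#' @param total_mappings corpus mapping total.
#' @return a `failure_summary` (without affected-mapping figures, which
#'   need the records: `affected_count`/`affected_rate` are `NA`).
#' @export
summary_from_counts <- function(cause_counts, unique_ambiguity_count,
                                total_mappings) {
  stopifnot(setequal(names(cause_counts), names(FAILURE_CAUSES)),
            total_mappings > 0)
  cause_counts <- cause_counts[names(FAILURE_CAUSES)]
  non_amb <- names(FAILURE_CAUSES)[FAILURE_CAUSES != "ambiguity"]
  unique_total <- sum(cause_counts[non_amb]) + unique_ambiguity_count
  structure(list(
    cause_counts = cause_counts,
    cause_percent = round_half_up(100 * cause_counts / unique_total, 2),
    unique_ambiguity_count = unique_ambiguity_count,
    unique_ambiguity_percent =
      round_half_up(100 * unique_ambiguity_count / unique_total, 2),
    unique_total = unique_total,
    total_mappings = as.integer(total_mappings),
    failure_rate = round_half_up(100 * unique_total / total_mappings, 2),
    affected_count = NA_integer_,
    affected_rate = NA_real_
  ), class = "failure_summary")
}

#' @export
print.failure_summary <- function(x, ...) {
  cat("Concept-mapping failure summary\n")
  cat(sprintf("  total mappings analysed: %d\n", x$total_mappings))
  cat(sprintf("  unique failures: %d (%.2f%% of mappings)\n",
              x$unique_total, x$failure_rate))
  df <- summary_table(x)
  cat(paste0("  ", format(df$cause, width = 24), " ",
             format(df$count, width = 8), " ",
             format(sprintf("%.2f", df$percent), width = 7), "\n"), sep = "")
  invisible(x)
}

#' Summary as a table
#'
#' One row per cause (count and percentage of the unique-failure total),
#' plus the unique ambiguity and overall totals; mirrors the layout of a
#' per-cause failure report and is the payload for [write_summary_tsv()].
#'
#' @param summary a `failure_summary`.
#' @return a tibble: `type`, `cause`, `count`, `percent`.
#' @export
summary_table <- function(summary) {
  causes <- names(FAILURE_CAUSES)
  tibble::tibble(
    type = c(unname(FAILURE_CAUSES[causes]), "ambiguity", "all"),
    cause = c(causes, "unique_ambiguity_total", "unique_total"),
    count = c(unname(summary$cause_counts), summary$unique_ambiguity_count,
              summary$unique_total),
    percent = c(unname(summary$cause_percent),
                summary$unique_ambiguity_percent, 100)
  )
}

#' Write the summary table as TSV
#'
#' @param summary a `failure_summary`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(summary, path) {
  utils::write.table(summary_table(summary), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write unique failures as JSONL
#'
#' One JSON object per unique failure: `post_id`, `span`, `type`, `causes`,
#' `cui`, `evidence`.
#'
#' @param unique_failures the collapsed failure tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_failures_jsonl <- function(unique_failures, path) {
  lines <- vapply(seq_len(nrow(unique_failures)), function(i) {
    f <- unique_failures[i, ]
    jsonlite::toJSON(list(
      post_id = f$post_id, start = f$start, end = f$end, type = f$type,
      causes = strsplit(f$causes, ",")[[1]],
      cui = if (is.na(f$cui)) NULL else f$cui,
      evidence = f$evidence), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
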