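# Performance-evaluation harness: stratified sampling of detected and
# undetected mappings for blind manual judgment, and confusion-matrix
# metrics over the returned verdicts. The tool draws and shuffles the
# cases and computes the metrics; the verdicts themselves are human
# judgments supplied as a CSV.

case_key <- function(post_id, start, end) {
  paste(post_id, start, end, sep = ":")
}

#' Stratified evaluation sample
#'
#' Draws `n_per_cause` detected cases from each failure cause (the
#' positives) and `n_negative` cases uniformly from the mappings the
#' battery did not flag (the negatives), all without replacement, then
#' shuffles the combined set into a blind display order. Selection is keyed
#' by stable case identifiers and performed with an explicit seed, so the
#' sample is a pure function of `(failures, all_mappings, seed)`:
#' permuting the input rows does not change the selected set.
#'
#' @param failures a failure tibble (the battery output).
#' @param all_mappings every mapping record of the corpus.
#' @param n_per_cause positives per cause (causes present in `failures`;
#'   a cause with fewer detected cases than `n_per_cause` is an error
#'   naming the cause and the available count).
#' @param n_negative number of undetected mappings to draw.
#' @param seed integer seed.
#' @param causes which causes to sample (default: all 12).
#' @return an `evaluation_sample` tibble: `case_id`, `post_id`, `start`,
#'   `end`, `predicted` (`"positive"`/`"negative"`), `cause` (`NA` for
#'   negatives), `display_order`; rows are returned in display order.
#' @export
stratified_sample <- function(failures, all_mappings, n_per_cause,
                              n_negative, seed,
                              causes = names(FAILURE_CAUSES)) {
  affected <- affected_mappings(failures)
  undetected <- all_mappings[!case_key(all_mappings$post_id,
                                       all_mappings$start,
                                       all_mappings$end) %in%
                               case_key(affected$post_id, affected$start,
                                        affected$end), , drop = FALSE]
  if (nrow(undetected) < n_negative) {
    stop(sprintf("only %d undetected mappings available, need %d",
                 nrow(undetected), n_negative), call. = FALSE)
  }
  pick <- function(keys, n) {
    keys <- sort(unique(keys))
    if (n == 0) return(character(0))
    keys[sample.int(length(keys), n)]
  }
  with_seed(seed, {
    pos <- list()
    for (cz in sort(causes)) {
      cf <- failures[failures$cause == cz, , drop = FALSE]
      cf <- cf[!duplicated(case_key(cf$post_id, cf$start, cf$end)), ,
               drop = FALSE]
      if (nrow(cf) < n_per_cause) {
        stop(sprintf("cause %s has only %d detected case(s), need %d",
                     cz, nrow(cf), n_per_cause), call. = FALSE)
      }
      keys <- case_key(cf$post_id, cf$start, cf$end)
      sel <- pick(keys, n_per_cause)
      cf <- cf[match(sel, keys), , drop = FALSE]
      if (nrow(cf) > 0) {
        pos[[cz]] <- tibble::tibble(
          case_id = paste0("pos:", cz, ":", sel),
          post_id = cf$post_id, start = cf$start, end = cf$end,
          predicted = "positive", cause = cz)
      }
    }
    neg_keys <- case_key(undetected$post_id, undetected$start,
                         undetected$end)
    seln <- pick(neg_keys, n_negative)
    und <- undetected[match(seln, neg_keys), , drop = FALSE]
    neg <- tibble::tibble(
      case_id = paste0("neg:", seln),
      post_id = und$post_id, start = und$start, end = und$end,
      predicted = "negative", cause = NA_character_)
    cases <- do.call(rbind, c(pos, list(neg)))
    cases$display_order <- sample.int(nrow(cases))
    cases <- cases[order(cases$display_order), , drop = FALSE]
    class(cases) <- c("evaluation_sample", class(cases))
    cases
  })
}

#' Single-component evaluation sample
#'
#' Combines one cause's positives with a shared, previously drawn negative
#' pool (so every component is judged against the same negatives), then
#' shuffles.
#'
#' @param failures a failure tibble.
#' @param shared_negatives the negative rows of a previous
#'   [stratified_sample()] (rows with `predicted == "negative"`).
#' @param cause the single cause to sample.
#' @param n_per_cause number of positives.
#' @param seed integer seed.
#' @return an `evaluation_sample` tibble of
#'   `n_per_cause + nrow(shared_negatives)` cases.
#' @export
component_sample <- function(failures, shared_negatives, cause, n_per_cause,
                             seed) {
  pos <- stratified_sample(failures,
                           all_mappings = shared_negatives[0, c("post_id",
                                                                "start",
                                                                "end")],
                           n_per_cause = n_per_cause, n_negative = 0,
                           seed = seed, causes = cause)
  neg <- shared_negatives[, c("case_id", "post_id", "start", "end",
                              "predicted", "cause")]
  cases <- rbind(pos[, c("case_id", "post_id", "start", "end", "predicted",
                         "cause")], neg)
  with_seed(seed + 1L, {
    cases$display_order <- sample.int(nrow(cases))
  })
  cases <- cases[order(cases$display_order), , drop = FALSE]
  class(cases) <- c("evaluation_sample", class(cases))
  cases
}

#' Export an evaluation sample for blind judgment
#'
#' Writes the cases in display order; by default the predicted labels and
#' causes are omitted so judges assess mappings blind.
#'
#' @param sample an `evaluation_sample`.
#' @param path output CSV path.
#' @param blind drop `predicted`/`cause` columns (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_sample_csv <- function(sample, path, blind = TRUE) {
  df <- as.data.frame(sample)
  if (blind) df <- df[, c("case_id", "post_id", "start", "end",
                          "display_order")]
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read manual verdicts
#'
#' A CSV of `case_id, verdict` with verdicts `positive` (the mapping is
#' truly a failure) or `negative`.
#'
#' @param path CSV path.
#' @return a tibble.
#' @export
read_labels_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (!all(c("case_id", "verdict") %in% names(df))) {
    stop("labels file needs columns case_id and verdict", call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Confusion-matrix metrics
#'
#' Joins manual verdicts to the tool's predictions on the same case set and
#' derives precision, recall, accuracy and F1, reported as percentages
#' rounded half-up to 2 decimals (raw ratios are retained in the returned
#' object). A metric whose denominator is zero is an error naming the
#' metric.
#'
#' @param labels verdict tibble (`case_id`, `verdict`) — the manual truth.
#' @param predictions an `evaluation_sample`, or any tibble with `case_id`
#'   and `predicted`.
#' @return a `confusion_matrix`: `tp`, `fp`, `fn`, `tn` plus `precision`,
#'   `recall`, `accuracy`, `f1` (percent, 2 decimals) and the raw ratios.
#' @export
compute_metrics <- function(labels, predictions) {
  if (nrow(labels) == 0) stop("empty case set", call. = FALSE)
  if (!setequal(labels$case_id, predictions$case_id) ||
      nrow(labels) != nrow(predictions)) {
    stop("labels and predictions must cover the same case set",
         call. = FALSE)
  }
  truth <- labels$verdict[match(predictions$case_id, labels$case_id)]
  stopifnot(all(truth %in% c("positive", "negative")),
            all(predictions$predicted %in% c("positive", "negative")))
  tp <- sum(predictions$predicted == "positive" & truth == "positive")
  fp <- sum(predictions$predicted == "positive" & truth == "negative")
  fn <- sum(predictions$predicted == "negative" & truth == "positive")
  tn <- sum(predictions$predicted == "negative" & truth == "negative")
  confusion_matrix(tp, fp, fn, tn)
}

#' @rdname compute_metrics
#' @param tp,fp,fn,tn confusion-matrix counts.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(counts >= 0))
  need <- function(den, metric) {
    if (den == 0) {
      stop("metric undefined (zero denominator): ", metric, call. = FALSE)
    }
    den
  }
  precision <- tp / need(tp + fp, "precision")
  recall <- tp / need(tp + fn, "recall")
  accuracy <- (tp + tn) / need(tp + fp + fn + tn, "accuracy")
  f1 <- if (precision + recall == 0) {
    stop("metric undefined (zero denominator): f1", call. = FALSE)
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = round_half_up(100 * precision, 2),
    recall = round_half_up(100 * recall, 2),
    accuracy = round_half_up(100 * accuracy, 2),
    f1 = round_half_up(100 * f1, 2),
    raw = c(precision = precision, recall = recall, accuracy = accuracy,
            f1 = f1)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("Confusion matrix: TP=%d FP=%d FN=%d TN=%d\n",
              x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("  precision %.2f%%  recall %.2f%%  accuracy %.2f%%  F1 %.2f%%\n",
              x$precision, x$recall, x$accuracy, x$f1))
  invisible(x)
}
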