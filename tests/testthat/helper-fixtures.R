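# shared sampling fixture: fabricated detected failures (n per cause) and
# an undetected mapping pool, for exercising the evaluation sampler
sampling_fixture <- function(n_per_cause = 8, n_undetected = 40) {
  causes <- names(FAILURE_CAUSES)
  failures <- do.call(rbind, lapply(causes, function(cz) {
    n <- n_per_cause
    maplint:::new_failures(
      post_id = sprintf("p%02d", seq_len(n)), cause = rep(cz, n),
      start = seq_len(n) * 10L + match(cz, causes) * 1000L,
      end = seq_len(n) * 10L + match(cz, causes) * 1000L + 4L,
      surface = rep(cz, n), evidence = rep("synthetic", n),
      left_start = 0L, left_end = 1L, right_start = 2L, right_end = 3L)
  }))
  mappings <- tibble::tibble(
    post_id = sprintf("q%02d", seq_len(n_undetected)),
    phrase_index = seq_len(n_undetected),
    start = seq_len(n_undetected) * 7L,
    end = seq_len(n_undetected) * 7L + 3L,
    matched_text = "x", cui = "C0000001", concept_name = "X",
    semantic_types = replicate(n_undetected, "Finding", simplify = FALSE),
    score = 1)
  list(failures = failures, mappings = mappings)
}
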