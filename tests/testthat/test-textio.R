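test_that("posts round-trip through JSONL and CSV", {
  posts <- tibble::tibble(
    community_id = c("c1", "c1"), post_id = c("p1", "p2"),
    author_handle = c("ann", "bee"),
    text = c("My mother finished chemotherapy last week.",
             "Treatment starts next month."),
    timestamp = c("2012-05-01T10:00:00Z", NA))
  for (dialect in c("jsonl", "csv")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_posts(posts, path, dialect)
    back <- read_posts(path, dialect)
    expect_equal(as.data.frame(back)[, c("community_id", "post_id", "text")],
                 as.data.frame(posts)[, c("community_id", "post_id", "text")])
    expect_identical(back$text, posts$text)
  }
})

test_that("malformed post streams are rejected with context", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines('{"community_id":"c1","post_id":"p1","text":"hello there"}',
             path)
  expect_error(read_posts(path, "jsonl"), "author_handle")

  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("community_id,post_id,author_handle,text,timestamp",
               "c1,p1,ann,some text,",
               "c1,p1,bee,other text,"), csv)
  expect_error(read_posts(csv, "csv"), "duplicate post_id")
})

test_that("an empty stream yields an empty corpus without error", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), path)
  posts <- read_posts(path, "jsonl")
  expect_equal(nrow(posts), 0)
})

test_that("mapping records round-trip and validate spans", {
  text <- "My friend was just diagnosed with Stage IV cancer"
  posts <- make_post(text)
  start <- regexpr("Stage", text)[1] - 1L
  records <- tibble::tibble(
    post_id = "p1", phrase_index = 1L, start = start, end = start + 5L,
    matched_text = "stage", cui = "C1306673", concept_name = "Stage",
    semantic_types = list("Qualitative Concept"), score = 861)
  for (dialect in c("tsv", "jsonl")) {
    path <- withr::local_tempfile(fileext = paste0(".", dialect))
    write_mapping_records(records, path, dialect)
    back <- read_mapping_records(path, posts, dialect)
    expect_equal(back$cui, "C1306673")
    expect_equal(back$semantic_types[[1]], "Qualitative Concept")
    expect_equal(back$start, start)
    expect_equal(back$end, start + 5L)
  }
})

test_that("span and CUI violations are alignment/format errors", {
  posts <- make_post("short text here")
  rec <- tibble::tibble(
    post_id = "p1", phrase_index = 1L, start = 0L, end = 500L,
    matched_text = "short", cui = "C0000001", concept_name = "X",
    semantic_types = list("Finding"), score = 1)
  expect_error(validate_mapping_records(rec, posts), "alignment error")
  rec$end <- 5L
  rec$cui <- "Q123"
  expect_error(validate_mapping_records(rec, posts), "CUI")
  rec$cui <- "C0000001"
  rec$matched_text <- "wrong"
  expect_error(validate_mapping_records(rec, posts), "alignment error")
})

test_that("MMI positional info converts to half-open offsets that slice back", {
  # a post whose 0-based offsets 117..124 spell the trigger word
  prefix <- strrep("the scan showed no change today ", 4)  # 128 chars
  text <- paste0(substr(prefix, 1, 117), "melanoma and more")
  posts <- make_post(text)
  expect_equal(substr(text, 118, 125), "melanoma")
  path <- withr::local_tempfile(fileext = ".mmi")
  writeLines("p1|MMI|1000|Melanoma|C9900016|[Neoplastic Process]|melanoma|117/8",
             path)
  rec <- read_mapping_records(path, posts, "mmi")
  expect_equal(rec$start, 117L)
  expect_equal(rec$end, 125L)
  expect_equal(substr(text, rec$start + 1, rec$end), "melanoma")
  expect_equal(rec$matched_text, "melanoma")
})

test_that("contractions split into tokens with distinct tags", {
  toks <- tokenize_and_tag("I'd")
  expect_equal(nrow(toks), 2)
  expect_equal(toks$surface, c("I", "'d"))
  expect_equal(toks$pos_tag, c("PRP", "MD"))

  expect_equal(nrow(tokenize_and_tag("")), 0)

  toks2 <- tokenize_and_tag("my docotor said so")
  expect_equal(toks2$pos_tag[toks2$surface == "said"], "VBD")
})

test_that("tokens cover every non-whitespace character exactly once", {
  texts <- c(
    "Hi Meg, I wish my docotor would haven't said I'd have chemo brain.",
    "It's 12PM and I'm signing off! LOL Don",
    "Email me at janedoe@example.net anytime.",
    "Stage 3 Esophageal cancer (EC) - EC counts smoking.",
    "  odd   spacing\tand\nnewlines  ")
  for (text in texts) {
    toks <- tokenize_and_tag(text)
    covered <- unlist(mapply(function(s, e) seq(s + 1, e),
                             toks$start, toks$end, SIMPLIFY = FALSE))
    chars <- strsplit(text, "")[[1]]
    expect_setequal(covered, which(!grepl("[[:space:]]", chars)))
    # reconstruction: surfaces at their spans reproduce the input
    for (i in seq_len(nrow(toks))) {
      expect_identical(substr(text, toks$start[i] + 1, toks$end[i]),
                       toks$surface[i])
    }
  }
})

test_that("sentence segmentation splits on terminators before capitals", {
  toks <- tokenize_and_tag(
    "The biopsy came back clean. It's 12PM and I'm done! LOL Don")
  expect_equal(length(unique(toks$sentence_index)), 3)
  expect_equal(toks$sentence_index[toks$surface == "biopsy"], 0L)
  expect_equal(toks$sentence_index[toks$surface == "12PM"], 1L)
  expect_equal(toks$sentence_index[toks$surface == "Don"], 2L)
})
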