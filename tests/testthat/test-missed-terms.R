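test_that("parenthetical definitions are mined with the character-order rule", {
  posts <- make_post(paste(
    "My mother was diagnosed with Stage 3 Esophageal cancer (EC) earlier",
    "this year - EC also counts smoking and alcohol as two major",
    "aggravating factors and is an aggressive cancer"))
  tab <- extract_abbreviations(posts)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$short_form, "EC")
  expect_equal(tab$long_form, "esophageal cancer")
  expect_equal(tab$defining_post_id, "p1")

  # reversed pattern: SF (long form)
  posts2 <- make_post("Call LLS (Leukemia and Lymphoma Society) for help.")
  tab2 <- extract_abbreviations(posts2)
  expect_equal(tab2$short_form, "LLS")
  expect_equal(tab2$long_form, "leukemia and lymphoma society")
})

test_that("candidates must be capitalized and definitions must exist", {
  # lowercase parenthetical is not a candidate
  expect_equal(nrow(extract_abbreviations(
    make_post("she was diagnosed with esophageal cancer (ec) last year"))), 0)
  # a bare acronym with no definition anywhere yields no entry
  expect_equal(nrow(extract_abbreviations(
    make_post("LLS helped my family a lot this year"))), 0)
  # character-order violation: letters not in order in the long form
  expect_equal(nrow(extract_abbreviations(
    make_post("we visited the cancer support group (EC) on Tuesday"))), 0)
  # plural short form keeps its capitalized core
  tabp <- extract_abbreviations(
    make_post("She joined two esophageal cancers (ECs) discussion boards."))
  expect_equal(tabp$short_form, "EC")
})

test_that("expansion re-mapping emits one failure per newly mapped occurrence", {
  mapper <- make_mock_mapper()
  table <- tibble::tibble(short_form = "EC", long_form = "esophageal cancer",
                          community_id = "c1", defining_post_id = "p0")
  post <- make_post("The EC has not spread. EC worries me. We discussed EC today.",
                    post_id = "p5")
  f <- expand_and_remap(post, table, mapper)
  expect_equal(nrow(f), 3)
  expect_equal(unique(f$cause), "community_nomenclature")
  expect_equal(f$new_mapping_count, rep(1L, 3))
  expect_equal(f$surface, rep("EC", 3))
  # spans point at the original text
  for (i in 1:3) {
    expect_equal(slice0(post$text, f$start[i], f$end[i]), "EC")
  }

  # differential accounting: replacing all occurrences at once changes the
  # corpus mapping total by the sum of per-occurrence gains
  expanded <- gsub("\\bEC\\b", "esophageal cancer", post$text)
  delta <- nrow(mapper(expanded)) - nrow(mapper(post$text))
  expect_equal(delta, sum(f$new_mapping_count))

  # no occurrences, no failures
  expect_equal(nrow(expand_and_remap(make_post("Nothing to expand here."),
                                     table, mapper)), 0)
  # table from another community does not apply
  post_other <- make_post("The EC has not spread.", community_id = "c9")
  expect_equal(nrow(expand_and_remap(post_other, table, mapper)), 0)
})

test_that("conflicting definitions resolve by temporal locality", {
  rows <- function(lf, pid) {
    tibble::tibble(short_form = "BC", long_form = lf, community_id = "c1",
                   defining_post_id = pid)
  }
  table <- rbind(rows("breast cancer", "p1"), rows("blood count", "p3"))
  concept <- function(surface, cui) {
    tibble::tibble(surface = surface, cui = cui, concept_name = surface,
                   semantic_types = list("Finding"), case_sensitive = FALSE)
  }
  mapper <- make_mock_mapper(rbind(concept("breast cancer", "C9905011"),
                                   concept("blood count", "C9905012")))
  posts <- do.call(rbind, lapply(1:4, function(i) {
    make_post(c("My BC (breast cancer) news.", "The BC is back.",
                "New BC (blood count) today.", "The BC is back.")[i],
              post_id = paste0("p", i))
  }))
  # post 2 precedes the second definition: earlier definition applies
  f2 <- expand_and_remap(posts[2, ], table, mapper, posts)
  expect_match(f2$replacement, "breast cancer")
  # post 4 follows both: most recent definition applies
  f4 <- expand_and_remap(posts[4, ], table, mapper, posts)
  expect_match(f4$replacement, "blood count")
})

test_that("abbreviation extraction is idempotent and order-independent", {
  posts <- rbind(
    make_post("Stage 3 Esophageal cancer (EC) was the diagnosis.",
              post_id = "a"),
    make_post("Call LLS (Leukemia and Lymphoma Society) for help.",
              post_id = "b"),
    make_post("Nothing defined here at all.", post_id = "c"))
  tab1 <- extract_abbreviations(posts)
  tab2 <- extract_abbreviations(posts[c(3, 1, 2), ])
  key <- function(t) sort(paste(t$short_form, t$long_form))
  expect_identical(key(tab1), key(tab2))
  expect_identical(key(extract_abbreviations(posts)), key(tab1))
})

test_that("spell-correction re-mapping flags only corrections that map anew", {
  lex <- fixture_lexicons()
  mapper <- make_mock_mapper()
  speller <- default_speller(lex$spell)

  post <- make_post("my docotor said so")
  f <- spellcheck_and_remap(post, speller, mapper)
  expect_equal(nrow(f), 1)
  expect_equal(f$cause, "misspelling")
  expect_equal(f$surface, "docotor")
  expect_equal(f$replacement, "doctor")
  expect_equal(slice0(post$text, f$start, f$end), "docotor")

  # a fully correctly spelled post yields nothing
  clean <- make_post("Her doctor explained the results clearly.")
  expect_equal(nrow(spellcheck_and_remap(clean, speller, mapper)), 0)

  # a bad correction that maps to nothing new is not a failure
  bad_speller <- function(token) {
    if (token == "Donesaub") "dinosaur" else NULL
  }
  post2 <- make_post("They started Donesaub last month.")
  expect_equal(nrow(spellcheck_and_remap(post2, bad_speller, mapper)), 0)
})

test_that("the default speller ignores in-lexicon, short and non-lowercase tokens", {
  speller <- default_speller(fixture_lexicons()$spell)
  expect_null(speller("doctor"))    # in lexicon
  expect_null(speller("of"))        # too short
  expect_null(speller("Donesaub"))  # capitalized: left to external services
  expect_null(speller("zzzzqqq"))   # nothing within distance 2
  expect_equal(speller("byopsi"), "biopsy")
  expect_equal(speller("methastasis"), "metastasis")
})
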