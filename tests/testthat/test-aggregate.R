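# a small failure set with known overlap structure: one mapping ("OMG")
# flagged by two ambiguity causes, one boundary pair, one missed term
overlap_fixture <- function() {
  text <- "OMG she has chemo brain and a docotor"
  m <- make_mappings(text, list(
    list(surface = "OMG", cui = "C9900028", concept = "OMG gene",
         types = "Gene or Genome"),
    list(surface = "chemo", cui = "C9900017", concept = "Chemotherapy Regimen",
         types = "Therapeutic or Preventive Procedure"),
    list(surface = "brain", cui = "C9900018", concept = "Brain",
         types = "Body Part, Organ, or Organ Component")))
  lex <- fixture_lexicons()
  toks <- tokenize_and_tag(text)
  f <- rbind(
    detect_slang(m, lex$slang),
    detect_colloquial_gene(m, lex$genes),
    detect_boundary_failures("p1", m, toks, lex$terms),
    spellcheck_and_remap(make_post(text), default_speller(lex$spell),
                         make_mock_mapper()))
  list(text = text, mappings = m, failures = f)
}

test_that("one mapping flagged by two causes counts once among unique failures", {
  fx <- overlap_fixture()
  dd <- deduplicate_failures(fx$failures)
  expect_equal(dd$cause_counts[["internet_slang"]], 1L)
  expect_equal(dd$cause_counts[["colloquial_gene"]], 1L)
  expect_equal(dd$unique_ambiguity_count, 1L)
  # both causes are retained on the collapsed record
  omg <- dd$unique_failures[dd$unique_failures$type == "ambiguity", ]
  expect_equal(omg$causes, "colloquial_gene,internet_slang")
  # boundary pair + missed term + one unique ambiguity
  expect_equal(dd$unique_total, 3L)
  # set-union oracle over (post, span) for the ambiguity type
  amb <- fx$failures[fx$failures$type == "ambiguity", ]
  expect_equal(dd$unique_ambiguity_count,
               length(unique(paste(amb$post_id, amb$start, amb$end))))
})

test_that("disjoint failures make the unique total the plain sum", {
  fx <- overlap_fixture()
  f <- fx$failures[fx$failures$cause != "internet_slang", ]
  dd <- deduplicate_failures(f)
  expect_equal(dd$unique_total, sum(dd$cause_counts))
})

test_that("affected mappings follow the per-mapping counting convention", {
  fx <- overlap_fixture()
  dd <- deduplicate_failures(fx$failures)
  am <- affected_mappings(dd$unique_failures)
  # boundary pair contributes 2 mappings; OMG once despite 2 causes;
  # the missed term contributes its span
  expect_equal(nrow(am), 4)
  expect_equal(sum(am$kind == "missed_term"), 1)
})

test_that("summaries are invariant under input permutation", {
  fx <- overlap_fixture()
  f <- fx$failures
  s1 <- summarize_failures(f, total_mappings = nrow(fx$mappings))
  set.seed(9)
  for (r in 1:5) {
    s2 <- summarize_failures(f[sample.int(nrow(f)), ],
                             total_mappings = nrow(fx$mappings))
    expect_equal(s1$cause_counts, s2$cause_counts)
    expect_equal(s1$unique_total, s2$unique_total)
    expect_equal(s1$affected_count, s2$affected_count)
  }
})

test_that("percentages recompute from counts at two decimals, half-up", {
  counts <- c(
    splitting_phrase = 29965, community_nomenclature = 1167,
    misspelling = 2375, multi_pos_contraction = 416,
    colloquial_gene = 4162, number = 143, email_url = 1448,
    internet_slang = 3442, name = 10061, pronoun_I = 61119,
    mismapped_verb = 51193, inconsistent_mapping = 29308)
  s <- summary_from_counts(counts, unique_ambiguity_count = 154904,
                           total_mappings = 383572)
  expect_equal(s$unique_total, 188411)
  expect_equal(s$cause_percent[["splitting_phrase"]], 15.90)
  expect_equal(s$cause_percent[["community_nomenclature"]], 0.62)
  expect_equal(s$cause_percent[["misspelling"]], 1.26)
  expect_equal(s$cause_percent[["multi_pos_contraction"]], 0.22)
  expect_equal(s$cause_percent[["colloquial_gene"]], 2.21)
  expect_equal(s$cause_percent[["number"]], 0.08)
  expect_equal(s$cause_percent[["email_url"]], 0.77)
  expect_equal(s$cause_percent[["internet_slang"]], 1.83)
  expect_equal(s$cause_percent[["name"]], 5.34)
  expect_equal(s$cause_percent[["pronoun_I"]], 32.44)
  expect_equal(s$cause_percent[["mismapped_verb"]], 27.17)
  expect_equal(s$cause_percent[["inconsistent_mapping"]], 15.56)
  expect_equal(s$unique_ambiguity_percent, 82.22)
  expect_equal(s$failure_rate, 49.12)
  # unique rows account for everything exactly once
  non_amb <- counts[c("splitting_phrase", "community_nomenclature",
                      "misspelling")]
  expect_equal(sum(non_amb) + 154904, s$unique_total)
  # per-cause ambiguity counts exceed the deduplicated total (overlap)
  expect_gte(sum(counts) - sum(non_amb), 154904)
})

test_that("degenerate summaries behave: one failure is 100%, zero mappings error", {
  lex <- fixture_lexicons()
  text <- "LOL to all"
  m <- make_mappings(text, list(
    list(surface = "LOL", cui = "C9900026", concept = "LOX1 gene",
         types = "Gene or Genome")))
  f <- detect_slang(m, lex$slang)
  s <- summarize_failures(f, total_mappings = 1)
  expect_equal(s$cause_percent[["internet_slang"]], 100)
  expect_equal(s$failure_rate, 100)
  expect_error(summarize_failures(f, total_mappings = 0), "undefined")
})
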