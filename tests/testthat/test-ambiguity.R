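test_that("multi-POS detection flags contractions spanning distinct tags", {
  text <- "I'd have said I'm fine."
  specs <- list(
    list(surface = "I'd", cui = "C9900022", concept = "Incision and drainage",
         types = "Therapeutic or Preventive Procedure"),
    list(surface = "I'm", cui = "C9900023", concept = "Intramuscular Injection",
         types = "Therapeutic or Preventive Procedure"),
    list(surface = "said", cui = "C9900033",
         concept = "Simian Acquired Immunodeficiency Syndrome",
         types = "Disease or Syndrome"))
  m <- make_mappings(text, specs)
  toks <- tokenize_and_tag(text)
  f <- detect_multi_pos(m, toks)
  expect_setequal(f$surface, c("I'd", "I'm"))
  expect_match(f$evidence[f$surface == "I'd"], "PRP\\+MD")
  # single-token mappings are never flagged
  expect_false("said" %in% f$surface)
})

test_that("gene-type mappings outside the gene dictionary are colloquial failures", {
  lex <- fixture_lexicons()
  m <- rbind(
    make_mappings("hi everyone", list(
      list(surface = "hi", cui = "C9900024", concept = "ABCC8 gene",
           types = "Gene or Genome"))),
    make_mappings("we wish you well", list(
      list(surface = "wish", cui = "C9900025", concept = "WISH gene",
           types = "Gene or Genome"))),
    make_mappings("BRCA1 carriers meet", list(
      list(surface = "BRCA1", cui = "C9905021", concept = "BRCA1 gene",
           types = "Gene or Genome"))))
  f <- detect_colloquial_gene(m, lex$genes)
  expect_setequal(f$surface, c("hi", "wish"))
})

test_that("times and digit strings flag non-quantitative semantic types only", {
  text <- "I got there at 4:12pm and chemo was on 3/4 when she was aged 5."
  specs <- list(
    list(surface = "12pm", cui = "C9900035",
         concept = "Maxillary left first premolar mesial prosthesis",
         types = "Medical Device"),
    list(surface = "3/4", cui = "C0442757", concept = "Distance vision 3/4",
         types = "Finding"),
    list(surface = "5", cui = "C9905031", concept = "5",
         types = "Quantitative Concept"))
  m <- make_mappings(text, specs)
  f <- detect_numbers(m, text)
  expect_setequal(f$surface, c("12pm", "3/4"))
  # the exclusion is a documented choice, reversible by configuration
  f2 <- detect_numbers(m, text, include_quantitative = TRUE)
  expect_true("5" %in% f2$surface)
})

test_that("mappings inside email addresses and URLs are flagged", {
  text <- "Write janedoe@example.net or visit http://www.example.org/en/guide soon."
  specs <- list(
    list(surface = "net", cui = "C9900036", concept = "SPINK5 gene",
         types = "Gene or Genome"),
    list(surface = "en", cui = "C9900037", concept = "NT5E gene",
         types = "Gene or Genome"),
    list(surface = "soon", cui = "C9905041", concept = "Soon",
         types = "Temporal Concept"))
  m <- make_mappings(text, specs)
  f <- detect_email_url(m, text)
  expect_setequal(f$surface, c("net", "en"))
})

test_that("slang matching uses the exclusion-filtered dictionary", {
  lex <- fixture_lexicons()
  text <- "LOL she wrote XO and then AML results came"
  specs <- list(
    list(surface = "LOL", cui = "C9900026", concept = "LOX1 gene",
         types = "Gene or Genome"),
    list(surface = "XO", cui = "C9900027", concept = "XDH gene",
         types = "Gene or Genome"),
    list(surface = "AML", cui = "C9905051", concept = "Acute Myeloid Leukemia",
         types = "Neoplastic Process"))
  m <- make_mappings(text, specs)
  f <- detect_slang(m, lex$slang)
  expect_setequal(f$surface, c("LOL", "XO"))
  expect_false("AML" %in% f$surface)
})

test_that("name matching covers first names and handles, including noun uses", {
  lex <- fixture_lexicons()
  text <- "Meg and Don said hope is all we have, signed survivorgirl"
  specs <- list(
    list(surface = "Meg", cui = "C9900029", concept = "Megestrol",
         types = "Pharmacologic Substance"),
    list(surface = "Don", cui = "C9900030", concept = "Diazooxonorleucine",
         types = "Pharmacologic Substance"),
    list(surface = "hope", cui = "C9905061", concept = "Hope",
         types = "Mental Process"),
    list(surface = "signed", cui = "C9905062", concept = "Signed",
         types = "Finding"),
    list(surface = "survivorgirl", cui = "C9905063", concept = "Survivor",
         types = "Population Group"))
  m <- make_mappings(text, specs)
  f <- detect_names(m, lex$first_names, lex$handles)
  # "hope" as a common noun is a known, deliberate false positive
  expect_setequal(f$surface, c("Meg", "Don", "hope", "survivorgirl"))
})

test_that("narrative pronoun I flags only the two concepts, PRP or FW tags", {
  text <- "I said I would go"
  m <- rbind(
    make_mappings(text, list(
      list(surface = "I", cui = "C9900021", concept = "Iodides",
           types = "Inorganic Chemical"))),
    make_mappings(text, list(
      list(surface = "I", cui = "C9905071", concept = "Blood group antibody I",
           types = "Immunologic Factor", occurrence = 2L))),
    make_mappings(text, list(
      list(surface = "said", cui = "C9900033",
           concept = "Simian Acquired Immunodeficiency Syndrome",
           types = "Disease or Syndrome"))))
  toks <- tokenize_and_tag(text)
  f <- detect_pronoun_I(m, toks)
  expect_equal(nrow(f), 2)
  expect_setequal(f$concept_name,
                  c("Iodides", "Blood group antibody I"))

  # foreign-word tagging still counts; other concepts never do
  fw_tagger <- function(text) {
    toks <- default_tagger(text)
    toks$pos_tag[toks$surface == "I"] <- "FW"
    toks
  }
  f_fw <- detect_pronoun_I(m, tokenize_and_tag(text, fw_tagger))
  expect_equal(nrow(f_fw), 2)

  m_other <- make_mappings(text, list(
    list(surface = "I", cui = "C9905072", concept = "Iodine-131",
         types = "Inorganic Chemical")))
  expect_equal(nrow(detect_pronoun_I(m_other, toks)), 0)
})

test_that("verb mappings are flagged only for pure Entity-tree types", {
  lex <- fixture_lexicons()
  text <- "She said we wait and then go to the gym"
  specs <- list(
    list(surface = "said", cui = "C9900033",
         concept = "Simian Acquired Immunodeficiency Syndrome",
         types = "Disease or Syndrome"),
    list(surface = "wait", cui = "C9905081", concept = "Wait",
         types = "Functional Concept"),
    list(surface = "go", cui = "C9905082", concept = "Going",
         types = "Daily or Recreational Activity"))
  m <- make_mappings(text, specs)
  toks <- tokenize_and_tag(text)
  f <- detect_mismapped_verbs(m, toks, lex$semtypes)
  # "wait" (Functional Concept, Entity) is the documented false positive
  expect_setequal(f$surface, c("said", "wait"))
  # Event-tree types are exempt
  expect_false("go" %in% f$surface)

  # unknown semantic type: mapping skipped with a warning
  m_unknown <- make_mappings(text, list(
    list(surface = "said", cui = "C9905083", concept = "X",
         types = "Totally Unknown Type")))
  expect_warning(f_u <- detect_mismapped_verbs(m_unknown, toks, lex$semtypes),
                 "unknown semantic type")
  expect_equal(nrow(f_u), 0)
})

test_that("the CUI frequency table counts exactly and sums per surface", {
  text <- paste(rep("the blood test came back", 3), collapse = ". ")
  m <- rbind(
    make_mappings(text, list(
      list(surface = "blood test", cui = "C0018941",
           concept = "Hematologic Tests", types = "Laboratory Procedure"))),
    make_mappings(text, list(
      list(surface = "blood test", cui = "C0018941",
           concept = "Hematologic Tests", types = "Laboratory Procedure",
           occurrence = 2L))),
    make_mappings(text, list(
      list(surface = "blood test", cui = "C0994779",
           concept = "Blood test device", types = "Medical Device",
           occurrence = 3L))))
  tab <- build_cui_frequency_table(m)
  expect_equal(tab$n[tab$cui == "C0018941"], 2L)
  expect_equal(tab$n[tab$cui == "C0994779"], 1L)
  expect_equal(sum(tab$n), nrow(m))
  expect_equal(nrow(build_cui_frequency_table(m[0, ])), 0)
})

test_that("inconsistency flags minority mappings, never the majority", {
  text <- paste(rep("the blood test came back", 3), collapse = ". ")
  m <- rbind(
    make_mappings(text, list(
      list(surface = "blood test", cui = "C0018941",
           concept = "Hematologic Tests", types = "Laboratory Procedure"))),
    make_mappings(text, list(
      list(surface = "blood test", cui = "C0018941",
           concept = "Hematologic Tests", types = "Laboratory Procedure",
           occurrence = 2L))),
    make_mappings(text, list(
      list(surface = "blood test", cui = "C0994779",
           concept = "Blood test device", types = "Medical Device",
           occurrence = 3L))))
  f <- detect_inconsistent(m)
  expect_equal(nrow(f), 1)
  expect_equal(f$cui, "C0994779")
  expect_match(f$evidence, "C0018941")

  # a consistently (even if wrongly) mapped surface is never flagged
  m_const <- m
  m_const$cui <- "C0018941"
  expect_equal(nrow(detect_inconsistent(m_const)), 0)

  # 50/50 tie: deterministic lexicographic majority, same output both orders
  m_tie <- m[c(1, 3), ]
  f_a <- detect_inconsistent(m_tie)
  f_b <- detect_inconsistent(m_tie[2:1, ])
  expect_equal(nrow(f_a), 1)
  expect_equal(f_a$cui, "C0994779")  # C0018941 < C0994779 wins the tie
  expect_match(f_a$evidence, "tie")
  expect_setequal(paste(f_a$start, f_a$cui), paste(f_b$start, f_b$cui))
})

test_that("detectors are pure and order-independent, causes non-exclusive", {
  lex <- fixture_lexicons()
  text <- "OMG the results came"
  m <- make_mappings(text, list(
    list(surface = "OMG", cui = "C9900028", concept = "OMG gene",
         types = "Gene or Genome")))
  f1 <- detect_slang(m, lex$slang)
  f2 <- detect_colloquial_gene(m, lex$genes)
  expect_equal(nrow(f1), 1)
  expect_equal(nrow(f2), 1)
  # same mapping flagged under two causes
  expect_equal(f1$start, f2$start)
  expect_false(identical(f1$cause, f2$cause))
  # re-running yields identical output
  expect_identical(detect_slang(m, lex$slang), f1)
})
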