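# Synthetic community corpora with injected failure phenomena, a
# table-driven mock mapper, paired mapping records and ground-truth labels.
#
# The mock mapper is a transparent dictionary scanner, not a model: ground
# truth must be exact. Concepts whose real identifiers are not part of the
# bundled knowledge use placeholder CUIs in the reserved range
# C9900001-C9909999 so fixtures can never be mistaken for genuine
# vocabulary identifiers; identifiers that are part of the bundled
# knowledge (e.g. the blood-test pair C0018941/C0994779) are used verbatim.

#' Mock concept table
#'
#' The surface-to-concept dictionary behind [make_mock_mapper()]: benign
#' clinical vocabulary mapped to sensible concepts plus the classic
#' mismapping patterns (colloquialisms and slang to gene concepts, first
#' names to drugs, the pronoun "I" to Iodides, past-tense verbs to
#' disease/device concepts, times to a prosthesis concept, email/URL
#' fragments to genes).
#'
#' @return a tibble: `surface`, `cui`, `concept_name`, `semantic_types`
#'   (list column), `case_sensitive`.
#' @export
mock_concept_table <- function() {
  row <- function(surface, cui, concept, types, cs = NA) {
    if (is.na(cs)) cs <- grepl("[A-Z]", surface)
    tibble::tibble(surface = surface, cui = cui, concept_name = concept,
                   semantic_types = list(types), case_sensitive = cs)
  }
  do.call(rbind, list(
    # benign vocabulary
    row("chemotherapy", "C9900001", "Chemotherapy",
        "Therapeutic or Preventive Procedure"),
    row("tamoxifen", "C9900002", "Tamoxifen", "Pharmacologic Substance"),
    row("clinic", "C9900003", "Outpatient Clinic",
        "Health Care Related Organization"),
    row("scan", "C9900004", "Radionuclide Imaging", "Diagnostic Procedure"),
    row("biopsy", "C9900005", "Biopsy", "Diagnostic Procedure"),
    row("infusion", "C9900006", "Infusion Procedure",
        "Therapeutic or Preventive Procedure"),
    row("hospital", "C9900007", "Hospital",
        "Health Care Related Organization"),
    row("doctor", "C9900008", "Physician",
        "Professional or Occupational Group"),
    row("surgeon", "C9900009", "Surgeon",
        "Professional or Occupational Group"),
    row("oncologist", "C9900010", "Oncologist",
        "Professional or Occupational Group"),
    row("steroids", "C9900011", "Steroid Preparation",
        "Pharmacologic Substance"),
    row("treatment", "C9900012", "Therapeutic Aspects",
        "Functional Concept"),
    row("esophageal cancer", "C9900013", "Esophageal Carcinoma",
        "Neoplastic Process"),
    row("prostate cancer", "C9900014", "Prostate Carcinoma",
        "Neoplastic Process"),
    row("metastasis", "C9900015", "Metastasis", "Neoplastic Process"),
    row("melanoma", "C9900016", "Melanoma", "Neoplastic Process"),
    # split-phrase constituents
    row("chemo", "C9900017", "Chemotherapy Regimen",
        "Therapeutic or Preventive Procedure"),
    row("brain", "C9900018", "Brain",
        "Body Part, Organ, or Organ Component"),
    row("double", "C9900019", "Double Value Type", "Intellectual Product"),
    row("mastectomy", "C9900020", "Mastectomy",
        "Therapeutic or Preventive Procedure"),
    row("stage", "C1306673", "Stage", "Qualitative Concept"),
    # ambiguity patterns
    row("I", "C9900021", "Iodides", "Inorganic Chemical"),
    row("I'd", "C9900022", "Incision and drainage",
        "Therapeutic or Preventive Procedure"),
    row("I'm", "C9900023", "Intramuscular Injection",
        "Therapeutic or Preventive Procedure"),
    row("hi", "C9900024", "ABCC8 gene", "Gene or Genome"),
    row("wish", "C9900025", "WISH gene", "Gene or Genome"),
    row("LOL", "C9900026", "LOX1 gene", "Gene or Genome"),
    row("XO", "C9900027", "XDH gene", "Gene or Genome"),
    row("OMG", "C9900028", "OMG gene", "Gene or Genome"),
    row("Meg", "C9900029", "Megestrol", "Pharmacologic Substance"),
    row("Don", "C9900030", "Diazooxonorleucine", "Pharmacologic Substance"),
    row("Rebecca", "C9900031", "Becatecarin", "Pharmacologic Substance"),
    row("Candy", "C9900032", "Candy dosage form",
        "Biomedical or Dental Material"),
    row("said", "C9900033", "Simian Acquired Immunodeficiency Syndrome",
        "Disease or Syndrome"),
    row("saw", "C9900034", "Saw device", "Medical Device"),
    row("12pm", "C9900035", "Maxillary left first premolar mesial prosthesis",
        "Medical Device", cs = FALSE),
    row("3/4", "C0442757", "Distance vision 3/4", "Finding", cs = FALSE),
    row("net", "C9900036", "SPINK5 gene", "Gene or Genome"),
    row("en", "C9900037", "NT5E gene", "Gene or Genome"),
    row("blood test", "C0018941", "Hematologic Tests", "Laboratory Procedure")
  ))
}

#' Build a table-driven mock mapper
#'
#' Returns a mapper contract (`text -> mapping records`) that scans the
#' text for dictionary surfaces at word boundaries (longest match wins on
#' overlap; surfaces containing an upper-case letter match case-sensitively,
#' the rest case-insensitively) and emits one top-ranked record per match,
#' with sequential phrase indices — every mapped term is its own phrase,
#' mirroring a mapper that parses terms separately.
#'
#' @param table a concept table as from [mock_concept_table()].
#' @return a function `text -> mapping-record tibble` (with empty
#'   `post_id`; callers fill it in).
#' @export
make_mock_mapper <- function(table = mock_concept_table()) {
  force(table)
  function(text) {
    hits <- list()
    for (i in seq_len(nrow(table))) {
      pat <- paste0("(?<![A-Za-z0-9])",
                    gsub("([\\W])", "\\\\\\1", table$surface[i], perl = TRUE),
                    "(?![A-Za-z0-9])")
      m <- gregexpr(pat, text, perl = TRUE,
                    ignore.case = !table$case_sensitive[i])[[1]]
      if (m[1] == -1) next
      lens <- attr(m, "match.length")
      hits[[length(hits) + 1L]] <- tibble::tibble(
        start = m - 1L, end = m - 1L + lens, row = i)
    }
    if (length(hits) == 0) return(new_mapping_records())
    h <- do.call(rbind, hits)
    h <- h[order(h$start, -h$end), , drop = FALSE]
    keep <- logical(nrow(h))
    last_end <- -1L
    for (k in seq_len(nrow(h))) {
      if (h$start[k] >= last_end) {
        keep[k] <- TRUE
        last_end <- h$end[k]
      }
    }
    h <- h[keep, , drop = FALSE]
    new_mapping_records(
      post_id = rep("", nrow(h)),
      phrase_index = seq_len(nrow(h)),
      start = h$start, end = h$end,
      matched_text = vapply(seq_len(nrow(h)), function(k) {
        slice_text(text, h$start[k], h$end[k])
      }, character(1)),
      cui = table$cui[h$row],
      concept_name = table$concept_name[h$row],
      semantic_types = table$semantic_types[h$row],
      score = rep(1000, nrow(h))
    )
  }
}

BENIGN_SENTENCES <- c(
  "My mother finished chemotherapy last week.",
  "The oncologist recommended tamoxifen for five years.",
  "We visited the clinic again this morning.",
  "Her latest scan showed no change.",
  "The nurses were kind during every infusion.",
  "Everyone has been so supportive this week.",
  "Treatment starts next month at the hospital.",
  "Her doctor explained the results clearly.",
  "The biopsy came back clean on Tuesday.",
  "She rested most of the afternoon."
)

# one snippet per injection: sentence plus the phenomenon surface whose
# first whole-token occurrence in the sentence is the ground-truth span
SNIPPETS <- list(
  splitting_phrase = list(
    list(text = "My friend has chemo brain after treatment.",
         surface = "chemo brain"),
    list(text = "She had a double mastectomy in the spring.",
         surface = "double mastectomy")
  ),
  community_nomenclature = list(
    define = list(
      text = "My mother was diagnosed with esophageal cancer (EC) earlier this year.",
      surface = "EC"),
    reuse = list(text = "The EC has not spread so far.", surface = "EC")
  ),
  misspelling = list(
    list(text = "My docotor changed the dose again.", surface = "docotor"),
    list(text = "The byopsi results were not clear.", surface = "byopsi"),
    list(text = "They found no methastasis this time.",
         surface = "methastasis")
  ),
  multi_pos_contraction = list(
    list(text = "I'd rather skip the steroids.", surface = "I'd"),
    list(text = "I'm hoping for good news.", surface = "I'm")
  ),
  colloquial_gene = list(
    list(text = "Hi everyone, sending love and strength.", surface = "Hi"),
    list(text = "We wish you all the best.", surface = "wish")
  ),
  number = list(
    list(text = "See you at 12pm tomorrow.", surface = "12pm"),
    list(text = "Chemo was on 3/4 this year.", surface = "3/4")
  ),
  email_url = list(
    list(text = "You can email me at janedoe@example.net anytime.",
         surface = "net"),
    list(text = "More details at http://www.example.org/en/guide online.",
         surface = "en")
  ),
  internet_slang = list(
    list(text = "That news made me LOL so hard.", surface = "LOL"),
    list(text = "Hugs and XO to everyone.", surface = "XO")
  ),
  name = list(
    list(text = "Thanks for the advice, Meg.", surface = "Meg"),
    list(text = "Don will see the surgeon on Monday.", surface = "Don")
  ),
  pronoun_I = list(
    list(text = "I had chemotherapy yesterday.", surface = "I"),
    list(text = "I slept well last night.", surface = "I")
  ),
  mismapped_verb = list(
    list(text = "She said the scans looked fine.", surface = "said"),
    list(text = "We saw the surgeon last Friday.", surface = "saw")
  ),
  inconsistent_mapping = list(
    list(text = "Her blood test results came back today.",
         surface = "blood test")
  )
)

#' Simulation configuration
#'
#' Study conditions for the synthetic generator: corpus size, per-cause
#' injection rates (the probability that a given post receives one
#' instance of that cause), the benign-sentence count range per post, and
#' the seed. The inconsistently mapped surface ("blood test") follows a
#' 2:1 majority schedule: every third occurrence corpus-wide receives the
#' minority concept.
#'
#' @param n_posts number of posts (>= 1).
#' @param rates named vector/list of injection probabilities in `[0, 1]`,
#'   one per cause; defaults as below.
#' @param benign_range min/max benign sentences per post.
#' @param community_id community label for all posts.
#' @param seed integer seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_posts = 40,
                              rates = NULL,
                              benign_range = c(2, 4),
                              community_id = "community-1",
                              seed = 1) {
  defaults <- c(
    splitting_phrase = 0.10, community_nomenclature = 0.10,
    misspelling = 0.10, multi_pos_contraction = 0.10,
    colloquial_gene = 0.08, number = 0.08, email_url = 0.08,
    internet_slang = 0.10, name = 0.10, pronoun_I = 0.15,
    mismapped_verb = 0.10, inconsistent_mapping = 0.12
  )
  if (!is.null(rates)) {
    rates <- unlist(rates)
    bad <- setdiff(names(rates), names(defaults))
    if (length(bad) > 0) stop("unknown cause(s): ", paste(bad, collapse = ", "),
                              call. = FALSE)
    defaults[names(rates)] <- rates
  }
  stopifnot(n_posts >= 1, all(defaults >= 0), all(defaults <= 1),
            length(benign_range) == 2, benign_range[1] >= 1)
  structure(list(n_posts = as.integer(n_posts), rates = defaults,
                 benign_range = as.integer(benign_range),
                 community_id = community_id, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a synthetic community corpus
#'
#' Builds posts from benign sentence templates with seeded injections of
#' the twelve failure phenomena (split phrases, community acronyms defined
#' parenthetically in early posts and reused bare later, fixed
#' misspellings of clinical terms, contractions, colloquialisms and slang
#' colliding with gene concepts, times/dates, emails/URLs, first names,
#' narrative "I", verbs colliding with Entity-tree concepts, and an
#' inconsistently mapped surface on a 2:1 majority schedule), then runs
#' the mock mapper over every post and emits the paired mapping records
#' and exact ground-truth labels. Reproducible: the same config (including
#' seed) yields byte-identical output.
#'
#' @param config a [simulation_config()].
#' @return a list: `posts`, `mappings`, `truth` (tibble: `post_id`,
#'   `start`, `end`, `type`, `cause`, `phenomenon`), `mapper` (the mock
#'   mapper used).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  mapper <- make_mock_mapper()
  with_seed(config$seed, {
    posts <- list()
    truth <- list()
    abbrev_defined <- FALSE
    for (p in seq_len(config$n_posts)) {
      pid <- sprintf("post-%03d", p)
      n_benign <- sample(seq(config$benign_range[1], config$benign_range[2]), 1)
      sentences <- sample(BENIGN_SENTENCES, n_benign, replace = TRUE)
      phenomena <- list()  # sentence text -> phenomenon, added below
      for (cause in names(config$rates)) {
        if (stats::runif(1) >= config$rates[[cause]]) next
        snippet <- if (cause == "community_nomenclature") {
          if (abbrev_defined) SNIPPETS[[cause]]$reuse
          else { abbrev_defined <- TRUE; SNIPPETS[[cause]]$define }
        } else {
          variants <- SNIPPETS[[cause]]
          variants[[sample.int(length(variants), 1)]]
        }
        phenomena[[length(phenomena) + 1L]] <-
          c(snippet, list(cause = cause))
      }
      all_sent <- c(as.list(sentences),
                    lapply(phenomena, function(ph) ph$text))
      kind <- c(rep(0L, length(sentences)), seq_along(phenomena))
      ord <- sample.int(length(all_sent))
      all_sent <- all_sent[ord]
      kind <- kind[ord]
      offsets <- cumsum(c(0L, vapply(all_sent, nchar, integer(1)) + 1L))
      text <- paste(unlist(all_sent), collapse = " ")
      for (k in seq_along(all_sent)) {
        if (kind[k] == 0L) next
        ph <- phenomena[[kind[k]]]
        if (ph$cause == "inconsistent_mapping") next  # labelled after mapping
        occ <- token_occurrences(ph$text, ph$surface)
        truth[[length(truth) + 1L]] <- tibble::tibble(
          post_id = pid,
          start = offsets[k] + occ$start[1],
          end = offsets[k] + occ$end[1],
          type = unname(FAILURE_CAUSES[ph$cause]),
          cause = ph$cause,
          phenomenon = ph$surface)
      }
      posts[[p]] <- new_posts(config$community_id, pid,
                              sprintf("member%02d", 1 + (p %% 7)), text,
                              NA_character_)
    }
    posts <- do.call(rbind, posts)

    mappings <- list()
    for (p in seq_len(nrow(posts))) {
      m <- mapper(posts$text[p])
      m$post_id <- rep(posts$post_id[p], nrow(m))
      mappings[[p]] <- m
    }
    mappings <- do.call(rbind, mappings)

    # inconsistency schedule: every 3rd corpus-wide occurrence of the
    # inconsistent surface gets the minority concept and a truth label
    inc <- which(casefold_term(mappings$matched_text) == "blood test")
    minority <- inc[seq_along(inc) %% 3 == 0]
    if (length(minority) > 0) {
      mappings$cui[minority] <- "C0994779"
      mappings$concept_name[minority] <- "Blood test device"
      mappings$semantic_types[minority] <- list("Medical Device")
      truth[[length(truth) + 1L]] <- tibble::tibble(
        post_id = mappings$post_id[minority],
        start = mappings$start[minority],
        end = mappings$end[minority],
        type = "ambiguity", cause = "inconsistent_mapping",
        phenomenon = "blood test")
    }
    truth <- if (length(truth) == 0) {
      tibble::tibble(post_id = character(), start = integer(),
                     end = integer(), type = character(),
                     cause = character(), phenomenon = character())
    } else {
      do.call(rbind, truth)
    }
    truth <- truth[order(truth$post_id, truth$start, truth$cause), ,
                   drop = FALSE]
    list(posts = posts, mappings = mappings, truth = truth, mapper = mapper)
  })
}

#' The worked-example fixture
#'
#' A single post — "Hi Meg, I wish my docotor would haven't said I'd have
#' chemo brain. It's 12PM and I'm signing off! LOL Don" — with the twelve
#' top-ranked mapping records a concept mapper produces on it, every one
#' incorrect, plus the overlooked misspelling "docotor". The expected
#' labels give, for each span, the causes the battery should report; the
#' concept for "I'm" is a fixture-defined reconstruction (the worked
#' example fixes the mapping count at twelve without printing every
#' concept), and "Hi" carries its gene-concept reading.
#'
#' @return a list: `post` (one-row post tibble), `mappings` (12 records),
#'   `expected` (tibble: `surface`, `start`, `end`, `causes`).
#' @export
figure1_fixture <- function() {
  text <- paste0("Hi Meg, I wish my docotor would haven't said I'd have ",
                 "chemo brain. It's 12PM and I'm signing off! LOL Don")
  post <- new_posts("community-1", "fig1", "member01", text, NA_character_)
  tab <- mock_concept_table()
  span_of <- function(surface, occurrence = 1L) {
    occ <- token_occurrences(text, surface)
    c(occ$start[occurrence], occ$end[occurrence])
  }
  rec <- function(idx, find, key = find, occurrence = 1L) {
    sp <- span_of(find, occurrence)
    r <- tab[tab$surface == key, ]
    stopifnot(nrow(r) == 1, !is.na(sp[1]))
    new_mapping_records("fig1", idx, sp[1], sp[2], find, r$cui,
                        r$concept_name, r$semantic_types, 1000)
  }
  mappings <- rbind(
    rec(1L, "Hi", "hi"), rec(2L, "Meg"), rec(3L, "I"), rec(4L, "wish"),
    rec(5L, "said"), rec(6L, "I'd"), rec(7L, "chemo"), rec(8L, "brain"),
    rec(9L, "12PM", "12pm"), rec(10L, "I'm"), rec(11L, "LOL"),
    rec(12L, "Don"))
  mappings$matched_text <- vapply(seq_len(nrow(mappings)), function(i) {
    slice_text(text, mappings$start[i], mappings$end[i])
  }, character(1))
  expected <- tibble::tibble(
    surface = c("Hi", "Meg", "I", "wish", "docotor", "said", "I'd",
                "chemo brain", "12PM", "I'm", "LOL", "Don"),
    causes = c("colloquial_gene", "name", "pronoun_I",
               "colloquial_gene,mismapped_verb", "misspelling",
               "mismapped_verb", "multi_pos_contraction",
               "splitting_phrase", "number", "multi_pos_contraction",
               "colloquial_gene,internet_slang", "name"))
  sp <- t(vapply(seq_len(nrow(expected)), function(i) {
    span_of(expected$surface[i])
  }, integer(2)))
  expected$start <- sp[, 1]
  expected$end <- sp[, 2]
  list(post = post, mappings = mappings,
       expected = expected[, c("surface", "start", "end", "causes")])
}
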