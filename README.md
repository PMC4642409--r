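# maplint

Automated failure detection for biomedical concept mapping of online
health-community text.

## The problem

Biomedical concept mappers such as MetaMap link free text to concepts in
the UMLS Metathesaurus (each concept a CUI, `C` + 7 digits, carrying
semantic types from the Semantic Network). These tools were built for
clinical notes and journal articles; run over patient-generated posts from
online cancer communities they fail in characteristic ways, and the
standard remedy — manual annotation of a gold corpus — is too expensive to
repeat every time the tool, the vocabulary or the community changes.

`maplint` implements a low-cost, fully automated audit battery over a
mapper's output. It targets three failure types with twelve causes:

* **Boundary failures** (`splitting_phrase`) — a single coherent phrase
  split into multiple concepts (e.g. *chemo brain* → "Chemotherapy" +
  "Brain"). Detected by collecting adjacently mapped terms the mapper
  treated as separate phrases and testing, with an independent phrase
  chunker, whether both lie in the same (shortest) phrase.
* **Missed-term failures** — relevant terms left unmapped:
  `community_nomenclature` (acronyms coined in the community, mined with a
  Schwartz–Hearst-style parenthetical rule, expanded, then re-mapped) and
  `misspelling` (spell-corrected, then re-mapped). Both use a differential
  contract: a substitution is a failure iff re-mapping yields a mapping
  over the substituted region that the original did not have.
* **Word-sense-ambiguity failures** — a term mapped to the wrong concept:
  `multi_pos_contraction` (one mapped term bearing ≥ 2 POS tags, e.g.
  *I'd* → "Incision and drainage"), `colloquial_gene` ("Gene or Genome"
  mappings absent from a cancer-gene dictionary, e.g. *LOL* → LOX1 gene),
  `number` (times/dates mapped to non-quantitative types, e.g. *12pm* →
  a prosthesis concept), `email_url`, `internet_slang`, `name` (first
  names and community handles, e.g. *Meg* → megestrol), `pronoun_I`
  (narrative *I* → "Iodides"/"Blood group antibody I"), `mismapped_verb`
  (verbs mapped only to Entity-tree semantic types), and
  `inconsistent_mapping` (a surface mapped to a non-majority CUI, from a
  corpus-wide term/CUI frequency table).

Failures are aggregated with unique-failure accounting (one mapping
occurrence counts once no matter how many ambiguity causes flag it;
boundary events are pair-level), and a stratified-sampling harness draws
detected/undetected cases for blind manual judgment, scoring the verdicts
as precision, recall, accuracy and F1 = 2PR/(P+R).

External services (POS tagger, constituency parser, spelling suggester,
the mapper itself) enter through plain function contracts with
deterministic bundled defaults, so the battery runs offline and tests are
reproducible. A synthetic corpus generator injects all twelve phenomena
with exact ground-truth labels.

## Worked example

The bundled fixture is the sentence *"Hi Meg, I wish my docotor would
haven't said I'd have chemo brain. It's 12PM and I'm signing off! LOL
Don"* with the twelve top-ranked mapping records a concept mapper emits on
it — every one incorrect — plus the overlooked misspelling *docotor*:

```r
library(maplint)
fx  <- figure1_fixture()
f   <- detect_failures(fx$post, fx$mappings, default_lexicons(),
                       mapper = make_mock_mapper())
dd  <- deduplicate_failures(f)
am  <- affected_mappings(dd$unique_failures)
nrow(fx$mappings)              # 12  mapping records, all wrong
nrow(am)                       # 13  unique failures (12 mappings + 1 missed term)
table(f$cause)
#>        colloquial_gene        internet_slang        mismapped_verb
#>                      3                     1                     2
#>            misspelling multi_pos_contraction                  name
#>                      1                     2                     2
#>                 number             pronoun_I      splitting_phrase
#>                      1                     1                     1
```

Fourteen cause-level detections collapse to 13 unique failures: *wish* is
flagged twice (a gene-type mapping **and** an Entity-tree verb) and *LOL*
twice (slang **and** gene-type), while the *chemo*/*brain* boundary pair
contributes both constituent mappings to the affected set.

Confusion-matrix metrics from manual verdicts:

```r
confusion_matrix(tp = 498, fp = 102, fn = 40, tn = 560)
#> Confusion matrix: TP=498 FP=102 FN=40 TN=560
#>   precision 83.00%  recall 92.57%  accuracy 88.17%  F1 87.52%
```

A shell front end wraps the same functions:

```sh
exec/maplint simulate --out-dir sim --n-posts 40 --seed 1
exec/maplint summarize --posts sim/posts.jsonl --mappings sim/mappings.tsv
```

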