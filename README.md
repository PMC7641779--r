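# pgxkit

Pharmacogenomics (PGx) is the study of how genetic variants shape drug
efficacy and toxicity. The operational knowledge clinicians need — *which
drug treats which disease in the presence of which mutation, at what dose,
adjusted how when an adverse reaction occurs or the patient belongs to a
special population* — sits in drug labels as prose. `pgxkit` is an R
toolkit for turning that prose into a typed, validated pharmacogenomics
knowledge graph, aimed at text-mining and knowledge-base researchers
working with drug-label corpora.

The package implements the full stack around a typed entity/relation
model:

* **schema** — entities `(EID*, TERM*, Source, SemanticType*)` and
  relations `(RID*, Relationship*, Domain*, Range*, Definition,
  TreeNumber*)` over six semantic types (Drug, Gene, Disease,
  AdverseReaction, Population, DrugUse); a 26-relation registry (14
  first-level + 12 second-level, dotted tree numbers) loaded from an
  editable YAML config, with structural validation of entities and
  triples.
* **corpus** — sectioned label documents, character-offset span
  annotations over 8 mention labels, strict spans ↔ BIO conversion,
  seeded train/test splitting with round-half-up sizing, corpus
  statistics, and exact-match inter-annotator agreement
  `F = 2|matches|/(|A|+|B|)`.
* **ner** — a from-scratch linear-chain conditional random field:
  discrete feature templates, exact forward–backward and Viterbi
  inference in log space, deterministic L2-penalized L-BFGS training
  (emission weights *and* transition matrix learned), entity-level
  micro/per-label precision, recall and F1, and a dense-emission encoder
  seam where a pretrained contextual encoder can plug in.
* **normalize** — an auditable synonym table mapping label phrasings
  ("in combination with", "with *** mutation") to registry relations,
  with longest-match scanning and bounded wildcard capture.
* **kgraph** — a validated triple store with relationship-group counts,
  the risk-factor queries `Dr = F(C, G)` (drugs from disease and
  mutated gene) and `Ds = F(Dr, G, A, P)` (dosage from drug,
  conditioned independently on adverse reaction and population), and
  TSV / N-Triples / JSON export.
* **ingest** — parsers for SPL label XML, DrugBank-style drug records
  (with CAS checksum validation), and RxNorm RRF files (dose-form
  concepts and relations), all tolerant of schema drift.
* **synthdata** — a seeded generator of synthetic drug labels with a
  gold ledger of spans and relation expressions, so every stage is
  testable with no downloads.

## Worked example

```r
library(pgxkit)

build_default_registry()
#> <pgx_registry: 6 semantic types, 26 relations (14 first-level, 12 second-level)>

# Normalize relation expressions in label prose
tab <- load_default_rules()
normalize_expression(
  "TAFINLARB is indicated in combination with trametinib for the treatment of melanoma with BRAF V600E mutation",
  tab)
#>   start end                  surface    normalized    capture
#> 1    23  42      in combination with synergized_by       <NA>
#> 2    54  74     for the treatment of        treats       <NA>
#> 3    84 108 with BRAF V600E mutation have_mutation BRAF V600E
```

The matcher found three relation expressions, each reported with its
0-based half-open character offsets, the registry relation it normalizes
to, and (for the wildcard rule) the captured gene variant.

```r
# The melanoma demonstration store: 4846 validated triples in 9 groups
store <- melanoma_case_store()
group_counts(store)$total
#> [1] 4846

# Which drugs both treat melanoma and are linked to BRAF?
query_drugs(store, disease = "dm:melanoma", gene = "dm:BRAF")
#> [1] "db:dabrafenib"  "db:encorafenib" "db:vemurafenib"

# Trametinib dosage, conditioned on a fever adverse reaction:
# contextual instructions outrank the default ("2 mg orally once daily")
head(query_dosage(store, "db:trametinib", adverse_reaction = "dm:fever"), 2)
#>                 drug_use                   term          context condition
#> 1 rx:du_stop_permanently       stop permanently adverse_reaction  dm:fever
#> 2           syn:adj_0001 adjusted instruction 1 adverse_reaction  dm:fever
```

Training and evaluating the CRF tagger on synthetic labels:

```r
gen <- generate_corpus(generator_config(n_documents = 60, seed = 7))
model <- train_crf(docs_to_sequences(gen$docs[1:50], gen$ledger$spans))
test_ids <- vapply(gen$docs[51:60], `[[`, "", "doc_id")
gold <- gen$ledger$spans[gen$ledger$spans$doc_id %in% test_ids, ]
pred <- do.call(rbind, lapply(gen$docs[51:60],
                              function(d) tag_document(model, d)))
evaluate_ner(gold, pred)
#> <pgx_eval (entity-level exact span+label match)>
#>   micro P/R/F1: 100.00 / 100.00 / 100.00
```

Perfect held-out scores are expected here: templated synthetic text is
near-separable, so this exercises the learning machinery end to end rather
than estimating real-label accuracy (see the methods vignette,
`vignettes/pgx-knowledge-model.Rmd`).

A thin command-line wrapper over the same functions is installed at
`inst/exec/pgxkit.R` (`gen-synth`, `train-ner`, `eval-ner`, `tag`,
`export-melanoma`).

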