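---
title: "A pharmacogenomics knowledge model for drug labels: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A pharmacogenomics knowledge model for drug labels: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgxkit)
```

## The problem

Regulator-approved drug labels are the most reliable public record of how a
drug should be used: indications, dosage and administration, behaviour in
specific populations, warnings, and adverse reactions. For precision
medication the useful content is relational — *this drug treats that
disease when this gene carries that mutation, at this dose, unless this
adverse reaction occurs*. `pgxkit` turns such label content into a typed,
validated knowledge graph and provides every supporting layer needed to do
that reproducibly: a schema, an annotation corpus model, a sequence tagger
for entity mentions, a normalizer for relation phrasing, a triple store
with the clinically motivated queries, and a synthetic label generator so
the whole pipeline is testable offline.

## The knowledge model

Entities are records `(EID*, TERM*, Source, SemanticType*)` (starred fields
required). Six semantic types are modelled — Drug, Gene, Disease,
AdverseReaction, Population, DrugUse — each with a fixed attribute
inventory (e.g. Drug carries DrugName, Description, ChemicalFormula,
MolecularWeight, DrugApprovalStatus, CAS, UNII, PharmacologyIndication;
Gene carries GeneName and Mutation). At presentation level Population and
DrugUse are often grouped as a single "precise medication" category, giving
a five-type view; we keep them separate because their attribute sets and
annotation behaviour differ, and we document the five-type view as a
grouping rather than a structural fact.

Relations are records `(RID*, Relationship*, Domain*, Range*, Definition,
TreeNumber*)`. The registry ships 26 relations arranged in a two-level
taxonomy: 14 first-level and 12 second-level. Tree numbers are dotted codes
(`R01`, `R01.01`); the level is the dot count plus one. The source
inventory publishes nine relation names (treats, synergized_by,
antagonized_by, have_dosage, have_mutation, is_biomarker_efficacy_of,
is_biomarker_prognosis_of, has_dose_form, dose_form_of) but not the full
26-relation list; the remainder is reconstructed from the nine relationship
groups observed in the melanoma case (drug–drug, drug–adverse reaction,
drug–dosage, adverse reaction–dosage, drug–disease, drug–gene,
drug–population, gene–mutation, gene–disease) plus the RxNorm-style
ingredient/brand link. Reconstructed relations are flagged
`reconstructed: true` in the registry config so curators can see exactly
which definitions are placeholders. The whole registry lives in one
editable YAML file; `write_registry()`/`load_registry()` round-trip it, and
loading re-checks closure (every domain/range names a registered type,
inverse pairs mirror each other).

Validation is structural only — domain/range typing, attribute inventory
membership, required fields. There is deliberately no OWL-style reasoning:
violations are returned as readable reports, never inferred away.

Two modelling choices deserve mention. Gene variants (BRAF V600E) are both
an attribute of a Gene entity *and* representable as Gene-typed entities in
their own right, because the melanoma data contains gene–mutation triples
with the variant in object position; `have_mutation` therefore has domain
Gene and range Gene. And dosage context is encoded purely as triples: an
adverse reaction selects an adjusted instruction via
`(AdverseReaction, adjusts_dosage-family, DrugUse)` joined through the
drug's `has_adverse_reaction` link, and population-specific dosage via
`(Drug, has_population_dosage, DrugUse)`. This keeps the risk-factor
queries — drugs from disease and gene; dosage from drug conditioned
independently on adverse reaction and population — answerable by direct
triple traversal.

## Corpus layer

Annotations are character-offset spans: 0-based, half-open, local to one of
the five label sections ("Indications and Usage", "Dosage and
Administration", "Use in Specific Populations", "Warnings and Precautions",
"Adverse Reactions"), with one of 8 mention labels (Drug, Gene, Disease,
Body_Part, Daily_Dose, Dose_Form, Frequency, Adverse_Reaction) and an
annotator id. Sections are annotated independently, which is why offsets
are per-section rather than per-document.

Tagging uses plain BIO, the minimal scheme that a per-token tagger output
requires. Conversion from spans to tags is strict: a span that cuts
through a token is an error, not a silent snap, because misaligned offsets
are annotation bugs that must surface. The inverse conversion repairs
invalid `I-` openings to `B-` (the conventional repair) and reports how
many it fixed. Round-tripping spans → BIO → spans is the identity for
aligned, non-overlapping spans, and the suite property-tests that on
random layouts.

Train/test splitting rounds the train size half-up, so 190 documents at
fraction 0.9 give exactly 171/19; assignment is a pure function of the
seed. Inter-annotator agreement is the exact-match F score
`F = 2|matches| / (|A| + |B|)`, symmetric in the two annotators; two empty
sets are defined to agree perfectly (with a message, since that case is
almost always a pipeline bug). Double annotation with senior adjudication
is represented as data — the `annotator` column — not as workflow code.

## The tagger

The named-entity layer is a linear-chain conditional random field with
discrete feature templates, implemented in full: exact forward–backward in
log space, exact Viterbi decoding, and penalized maximum-likelihood
training where both emission weights and the transition matrix are
learned. The architecture that motivated it pairs a pretrained transformer
encoder with exactly such a CRF output layer; the pretrained encoder needs
external weights and is out of scope here, so the package exposes the seam
instead: every inference function accepts a dense `N × L` emission matrix
in place of a token sequence, which is precisely what a learned encoder
would supply. A `lookup_encoder()` exercises that path in the tests. The
feature-based CRF is itself the classical strong baseline for this task.

Feature templates per position: lowercased token, word shape
(`BRAF → AAAA`, `V600E → A999A`), prefixes/suffixes to length 3, an
is-digit flag, each emitted for the focus token and all neighbours within
a window (default radius 2; boundary positions contribute `<BOS>`/`<EOS>`
markers). Templates are deliberately deterministic strings so the model
file can be flat diffable text.

Numerical choices:

* All inference is in log space with max-shifted log-sum-exp; the
  partition function, marginals, and Viterbi are exact, and the test suite
  checks them against brute-force enumeration over all `L^N` paths on
  random small instances (to 1e-8), plus the analytic gradient against
  central finite differences (to 1e-5 relative).
* Training minimizes the L2-penalized negative log-likelihood
  (`sum(w^2)/(2*sigma^2)`, default `sigma = 10`) with batch L-BFGS from
  zero initialization. A batch deterministic optimizer was chosen over a
  stochastic mini-batch schedule deliberately: at this corpus scale
  determinism and a clean descent contract are worth more than fidelity to
  a schedule that belongs to the out-of-scope encoder stage. Training twice
  yields bit-identical weights.
* Viterbi ties break toward the lexicographically smallest label-index
  sequence; `"O"` is the first label, so the zero model decodes everything
  as outside. Tie behaviour is part of the tested contract.

Evaluation is entity-level exact span+label matching (the CoNLL
convention), matched one-to-one, with micro-averaged precision/recall/F1
pooled over labels and per-label metrics alongside; percentages are
rounded half-up to two decimals. Whether published figures for this task
are token-level or entity-level is generally ambiguous; entity-level is
the standard for drug-label NER, and the report object states its
granularity. The metric arithmetic itself guarantees that equal micro
precision and recall force the same micro-F1, which the suite pins at the
85.12 operating point.

## Expression normalization

Relation extraction from free text is out of scope (the source workflow
performed it manually); what the package automates is the normalization of
already-extracted surface expressions. The matcher is a literal,
case-insensitive, whitespace-normalized scanner with a single wildcard
operator `***` capturing a maximal non-empty token run (bounded, default 6
tokens). It is deliberately not a regex engine: the rule table
(`surface<TAB>normalized`) is meant to be curated and audited by
non-programmers. The scan is longest-match-first at each position;
earlier-starting matches win and the scan resumes after them, so output is
deterministic and non-overlapping. The shipped table covers the published
expression inventory (treatment, combination, avoidance, dosage, and
mutation phrasings); it is explicitly extensible because the published
table is labelled as examples, not an exhaustive inventory.

## Triple store and the melanoma case

The store validates every triple on insertion and silently deduplicates
exact repeats. Group counting keys triples by the (domain, range) type
pair of their relation — the relationship groups of the model — and its
total provably equals the store size. Export formats: TSV (re-importable,
byte-identical round-trip), W3C N-Triples with IRIs minted
deterministically from eids/rids under a configurable base, and grouped
JSON.

`melanoma_case_store()` rebuilds the demonstration case: seven drugs
(binimetinib, cobimetinib, dabrafenib, encorafenib, nivolumab, trametinib,
vemurafenib), BRAF with V600E/V600K, curated target links (the three BRAF
inhibitors target BRAF; the MEK inhibitors MAP2K1; nivolumab PDCD1),
trametinib's default dosage ("2 mg orally once daily") and its
adverse-reaction adjustments (fever or interstitial lung disease select
permanent discontinuation). Each relationship group is then filled to its
published size (4713 drug–drug, 41 drug–adverse reaction, 30 drug–dosage,
24 adverse reaction–dosage, 22 drug–disease, 7 drug–gene, 4
drug–population, 2 gene–mutation, 3 gene–disease; total 4846) with
auxiliary entities whose `syn:` id prefix marks them as synthetic — the
published data set lists the group sizes but not the individual triples,
so everything beyond the curated core is a stand-in that preserves the
arithmetic, not the content.

## Ingest

Three source dialects are read, all tested on synthetic fixtures: SPL XML
(sections found by normalized title match — the additive fallback of
LOINC-code matching would sit behind the same interface), DrugBank-style
drug records (the eight Drug attributes; CAS numbers are checksum-checked
and flagged rather than dropped), and RxNorm RRF pipe-delimited files
(concepts plus relations filtered to `has_dose_form`/`dose_form_of`). The
RRF parser never aborts on a malformed line: it reports the line number
and continues, because release files in the wild contain glitches and a
one-line failure must not cost the batch. Which source field maps to the
PharmacologyIndication attribute is not specified anywhere authoritative;
we map the record's indication text and document that as an assumption.
UTF-8 is mandated throughout.

## Synthetic data: what it does and does not show

The generator emulates the statistical *shape* of annotated drug labels:
five sections per document, sentences drawn from section-appropriate
templates whose slots are filled from per-label vocabularies, relation
expressions embedded verbatim from the normalization table's surface
inventory, and entity-free distractor sentences at a configurable rate
(default 0.3 per section). The default vocabulary is seeded with the
melanoma cast (the seven drugs, BRAF V600E/V600K, "2 mg orally once
daily") plus invented fillers with obviously synthetic names, so
integration fixtures read like the real case without copying any corpus.
Every emission is recorded in a gold ledger with exact offsets, and the
generator's own tally is cross-checked against `corpus_stats()`.

Sizes and rates were fixed once, before any evaluation, at what a small
annotated label corpus realistically looks like: 1–3 template sentences
per section, a 0.3 distractor rate, and the 50-train/10-test integration
scale used by the learning checks (with the curve measured at 10/25/50
training documents over 3 seeds).

Because templated text is near-separable, a feature CRF reaches very high
held-out F1 on it (the suite requires ≥ 95% micro-F1 at 50 training
documents and a non-decreasing curve in training size). That is a
*correctness* check of the learning machinery — features, gradient,
optimizer, decoder, evaluator — not a performance claim about real drug
labels, whose vocabulary openness, boundary ambiguity, and annotation
noise the generator does not attempt to model. `corrupt()` exists
precisely to reintroduce one real-world property (annotator disagreement)
with a known edit ledger, so the agreement measure can be validated
against a computable expectation.

## Degenerate inputs and tie-breaks, collected

* Empty sequence: partition function and decoding error; empty corpus:
  splitting errors; single-tag corpus: training errors (degenerate task).
* Two empty annotation sets: agreement defined as 1.0, with a message.
* Invalid `I-` openings: repaired to `B-`, counted, reported.
* Duplicate triples: ignored with a message; invalid triples: batch
  aborts with the validation report.
* Viterbi ties: lexicographic smallest label-index path.
* Percent rounding: half-up at two decimals, applied at the report edge
  only — internal arithmetic is unrounded.

## Known limitations

* No transformer encoder is trained or shipped; the encoder seam is typed
  and tested but the headline accuracy of encoder-based taggers on real
  corpora is out of reach (and out of scope) here.
* Relation *extraction* from free text is not attempted; the normalizer
  assumes expressions have been located.
* The 17 reconstructed relation definitions are placeholders pending a
  curated inventory; they are flagged in the config.
* The generator's realism is template realism; results on it bound
  nothing about real-label performance.
* Validation is structural; no inference (e.g. inverse completion) is
  performed, only inverse-consistency checking of the registry itself.

## Problem sizes used by the checks

The test suite and the acceptance script run entirely on synthetic data at
desk scale: enumeration oracles at `N ≤ 4, L ≤ 3` (200 instances),
round-trip properties at 1000 random layouts, learning checks at 60
generated documents per seed, and the full 4846-triple melanoma store.
These sizes were chosen as the smallest at which each property is
meaningfully exercised.
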