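# Seeded generator of synthetic drug labels with gold entity spans and
# gold relation expressions. Documents carry the five label sections;
# mentions are drawn from per-label vocabularies seeded with the melanoma
# cast plus clearly synthetic fillers; relation expressions are embedded
# verbatim from the normalization table's surface inventory, so every
# stage of the pipeline (ingest -> NER -> normalize -> kgraph) can be
# exercised without downloads.

default_vocab <- function() {
  list(
    Drug = c("binimetinib", "cobimetinib", "dabrafenib", "encorafenib",
             "nivolumab", "trametinib", "vemurafenib",
             # synthetic fillers
             "sorafexinib", "lumentinib", "pazertinib", "velgrafenib"),
    Gene = c("BRAF V600E", "BRAF V600K", "NRAS Q61K", "KIT D816V",
             "EGFR L858R", "MTOR S2215Y"),
    Disease = c("melanoma", "metastatic melanoma", "colorectal cancer",
                "thyroid carcinoma", "non-small cell lung cancer"),
    Body_Part = c("skin", "liver", "lungs", "brain", "lymph nodes"),
    Daily_Dose = c("2 mg", "45 mg", "240 mg", "960 mg", "0.5 mg"),
    Dose_Form = c("tablet", "capsule", "oral solution", "injection"),
    Frequency = c("once daily", "twice daily", "every 12 hours",
                  "once weekly"),
    Adverse_Reaction = c("fever", "rash", "nausea", "diarrhea", "fatigue",
                         "vomiting", "interstitial lung disease"))
}

# Sentence templates: text with {SLOT} placeholders plus the normalized
# relations whose surface expressions the template embeds verbatim.
# Slot -> label: DRUG/DRUG2 -> Drug, GENE -> Gene, DISEASE -> Disease,
# DOSE -> Daily_Dose, FORM -> Dose_Form, FREQ -> Frequency,
# AR/AR2/AR3 -> Adverse_Reaction, BODY -> Body_Part.
default_templates <- function() {
  list(
    "Indications and Usage" = list(
      list(text = "{DRUG} is indicated for the treatment of {DISEASE} with {GENE} mutation.",
           relations = c("treats", "have_mutation")),
      list(text = "{DRUG} is indicated in combination with {DRUG2} for the treatment of {DISEASE}.",
           relations = c("synergized_by", "treats")),
      list(text = "{DRUG} is indicated as monotherapy of {DISEASE}.",
           relations = "treats"),
      list(text = "{DRUG} is indicated for the prevention of {DISEASE} and for relief of the signs and symptoms of {DISEASE2}.",
           relations = c("treats", "treats"))),
    "Dosage and Administration" = list(
      list(text = "The recommended dosage of {DRUG} is {DOSE} orally {FREQ}.",
           relations = "have_dosage"),
      list(text = "Administer {DRUG} as one {FORM} of {DOSE} {FREQ}.",
           relations = character()),
      list(text = "Do not exceed total daily doses of {DOSE}.",
           relations = "have_dosage")),
    "Use in Specific Populations" = list(
      list(text = "The safety of {DRUG} in pediatric patients with {DISEASE} has not been established.",
           relations = character()),
      list(text = "Avoid concomitant use of {DRUG2} during treatment with {DRUG}.",
           relations = "antagonized_by"),
      list(text = "Patients who may be homozygous for {GENE} should receive {DRUG} with caution.",
           relations = "have_mutation")),
    "Warnings and Precautions" = list(
      list(text = "Permanently discontinue {DRUG} in patients who develop {AR}.",
           relations = character()),
      list(text = "The presence of {GENE} mutation may require monitoring of the {BODY}.",
           relations = "have_mutation"),
      list(text = "Avoid concurrent administration of {DRUG2} with {DRUG}.",
           relations = "antagonized_by")),
    "Adverse Reactions" = list(
      list(text = "The most common adverse reactions were {AR}, {AR2}, and {AR3}.",
           relations = character()),
      list(text = "{AR} affecting the {BODY} was reported in patients receiving {DRUG}.",
           relations = character())))
}

distractor_sentences <- function() {
  c("Store at room temperature away from moisture.",
    "Advise patients to read the approved patient labeling.",
    "The safety profile was consistent across clinical studies.",
    "No new safety signals were identified during postmarketing surveillance.",
    "Refer to the full prescribing information for further details.")
}

slot_label <- function(slot) {
  switch(sub("[0-9]+$", "", slot),
         DRUG = "Drug", GENE = "Gene", DISEASE = "Disease",
         DOSE = "Daily_Dose", FORM = "Dose_Form", FREQ = "Frequency",
         AR = "Adverse_Reaction", BODY = "Body_Part",
         stop("unknown template slot: ", slot))
}

#' Generator configuration
#'
#' @param n_documents Number of synthetic labels to generate.
#' @param seed Integer seed; the whole generation is a deterministic
#'   function of it.
#' @param vocab Per-label term lists; defaults cover every entity label.
#' @param templates Per-section sentence templates with entity and
#'   relation-expression slots.
#' @param noise Distractor-sentence rate in `[0, 1]`: expected proportion
#'   of entity-free sentences appended per section.
#' @param sentences_per_section Range (min, max) of template sentences per
#'   section.
#' @return A list of class `pgx_generator_config`.
#' @export
generator_config <- function(n_documents = 10L, seed = 1L,
                             vocab = default_vocab(),
                             templates = default_templates(),
                             noise = 0.3, sentences_per_section = c(1L, 3L)) {
  labs <- pgx_entity_labels()
  missing <- labs[!vapply(labs, function(l) length(vocab[[l]]) > 0L, NA)]
  if (length(missing))
    stop("vocabulary empty for label(s): ", paste(missing, collapse = ", "))
  if (is.na(noise) || noise < 0 || noise > 1) stop("noise must be in [0, 1]")
  if (n_documents < 1L) stop("n_documents must be >= 1")
  structure(list(n_documents = as.integer(n_documents),
                 seed = as.integer(seed), vocab = vocab,
                 templates = templates, noise = noise,
                 sentences_per_section = as.integer(sentences_per_section)),
            class = "pgx_generator_config")
}

# Render one template: sample slot fillers, assemble text, record spans
# (offsets local to the sentence) and relation instances.
render_template <- function(tpl, vocab) {
  parts <- regmatches(tpl$text,
                      gregexpr("\\{[A-Z0-9]+\\}|[^{}]+", tpl$text))[[1L]]
  text <- ""
  spans <- data.frame(start = integer(), end = integer(), label = character(),
                      surface = character())
  used <- list()
  for (p in parts) {
    if (grepl("^\\{[A-Z0-9]+\\}$", p)) {
      slot <- gsub("[{}]", "", p)
      lab <- slot_label(slot)
      pool <- setdiff(vocab[[lab]], unlist(used[lab]))
      if (!length(pool)) pool <- vocab[[lab]]
      term <- pool[sample.int(length(pool), 1L)]
      used[[lab]] <- c(used[[lab]], term)
      spans <- rbind(spans, data.frame(start = nchar(text),
                                       end = nchar(text) + nchar(term),
                                       label = lab, surface = term))
      text <- paste0(text, term)
    } else {
      text <- paste0(text, p)
    }
  }
  list(text = text, spans = spans, relations = tpl$relations)
}

#' Generate a synthetic annotated corpus
#'
#' Deterministically (given the seed) generates `n_documents` labels, each
#' with the five label sections, recording every emitted entity mention
#' with exact character offsets and every embedded relation expression in
#' a gold ledger. Distractor sentences contain no gold entities.
#'
#' @param config A [generator_config()].
#' @return List with `docs` (list of `pgx_document`) and `ledger`:
#'   `spans` (a [span_annotations()] table, annotator `"gold"`),
#'   `relations` (doc_id, section_index, normalized, expression_text),
#'   `entity_counts` (per-label emission tally).
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "pgx_generator_config"))
  with_seed(config$seed, {
    docs <- vector("list", config$n_documents)
    all_spans <- list()
    all_rels <- list()
    secs <- pgx_label_sections()
    for (d in seq_len(config$n_documents)) {
      doc_id <- sprintf("synlabel-%03d", d)
      sec_text <- character(length(secs))
      for (si in seq_along(secs)) {
        pool <- config$templates[[secs[si]]]
        rng <- config$sentences_per_section
        n_sent <- sample(rng[1L]:rng[2L], 1L)
        pick <- sample.int(length(pool), min(n_sent, length(pool)))
        text <- ""
        for (ti in pick) {
          r <- render_template(pool[[ti]], config$vocab)
          off <- nchar(text) + if (nzchar(text)) 1L else 0L
          text <- if (nzchar(text)) paste(text, r$text) else r$text
          if (nrow(r$spans))
            all_spans[[length(all_spans) + 1L]] <- data.frame(
              doc_id = doc_id, section_index = si,
              start = r$spans$start + off, end = r$spans$end + off,
              label = r$spans$label, annotator = "gold",
              surface = r$spans$surface)
          for (rel in r$relations)
            all_rels[[length(all_rels) + 1L]] <- data.frame(
              doc_id = doc_id, section_index = si, normalized = rel,
              sentence = r$text)
        }
        if (stats::runif(1L) < config$noise) {
          ds <- distractor_sentences()
          text <- paste(text, ds[sample.int(length(ds), 1L)])
        }
        sec_text[si] <- text
      }
      docs[[d]] <- document(doc_id, setNames(sec_text, secs))
    }
    spans <- if (length(all_spans)) do.call(rbind, all_spans)
             else data.frame()
    spans <- span_annotations(spans$doc_id, spans$section_index, spans$start,
                              spans$end, spans$label, spans$annotator,
                              spans$surface)
    rels <- if (length(all_rels)) do.call(rbind, all_rels)
            else data.frame(doc_id = character(), section_index = integer(),
                            normalized = character(), sentence = character())
    counts <- table(factor(spans$label, levels = pgx_entity_labels()))
    list(docs = docs,
         ledger = list(spans = spans, relations = rels,
                       entity_counts = setNames(as.integer(counts),
                                                names(counts))))
  })
}

#' Emit a document as SPL-dialect XML
#'
#' Round-trips through [parse_spl()]: `parse_spl(emit_spl(doc))` reproduces
#' the document's sections and text. Special characters are XML-escaped.
#'
#' @param doc A `pgx_document`.
#' @return XML text (single string).
#' @export
emit_spl <- function(doc) {
  root <- xml2::xml_new_root("document")
  xml2::xml_add_child(root, "id", root = doc$doc_id)
  body <- xml2::xml_add_child(xml2::xml_add_child(root, "component"),
                              "structuredBody")
  for (i in seq_len(nrow(doc$sections))) {
    comp <- xml2::xml_add_child(body, "component")
    sec <- xml2::xml_add_child(comp, "section")
    xml2::xml_add_child(sec, "title", doc$sections$name[i])
    xml2::xml_add_child(sec, "text", doc$sections$text[i])
  }
  as.character(root)
}

#' Perturb gold annotations with a known edit ledger
#'
#' Deterministically drops, shifts, or relabels a fraction of spans,
#' simulating a second annotator, and returns the expected agreement F
#' score against the original set computed from the edit ledger alone:
#' every edited span stops matching exactly, dropped spans shrink the
#' second set, so `F = 2 * (n - n_edits) / (n + n - n_drops)`.
#'
#' @param spans Gold [span_annotations()].
#' @param rate Fraction of spans to perturb, in `[0, 1]`.
#' @param seed Integer seed.
#' @param ops Edit operations to draw from: subset of `"drop"`, `"shift"`,
#'   `"relabel"`.
#' @param annotator Annotator id for the perturbed set.
#' @return List: `spans` (perturbed table), `expected_f`, `edits` (data
#'   frame of row index and operation).
#' @export
corrupt <- function(spans, rate, seed = 1L,
                    ops = c("drop", "shift", "relabel"), annotator = "B") {
  stopifnot(rate >= 0, rate <= 1)
  ops <- match.arg(ops, several.ok = TRUE)
  n <- nrow(spans)
  n_edit <- round(rate * n)
  with_seed(seed, {
    idx <- if (n_edit > 0L) sample.int(n, n_edit) else integer()
    op <- if (n_edit > 0L) sample(ops, n_edit, replace = TRUE) else character()
    out <- spans
    drop_rows <- integer()
    for (k in seq_along(idx)) {
      i <- idx[k]
      if (op[k] == "shift" && out$end[i] - out$start[i] < 2L)
        op[k] <- if ("relabel" %in% ops) "relabel" else "drop"
      if (op[k] == "drop") {
        drop_rows <- c(drop_rows, i)
      } else if (op[k] == "shift") {
        out$start[i] <- out$start[i] + 1L
        out$surface[i] <- NA_character_
      } else {
        out$label[i] <- sample(setdiff(pgx_entity_labels(), out$label[i]), 1L)
      }
    }
    if (length(drop_rows)) out <- out[-drop_rows, , drop = FALSE]
    out$annotator <- rep_len(annotator, nrow(out))
    rownames(out) <- NULL
    n_drop <- length(drop_rows)
    expected_f <- if (n + (n - n_drop) == 0L) 1.0
                  else 2 * (n - n_edit) / (n + (n - n_drop))
    list(spans = out, expected_f = expected_f,
         edits = data.frame(row = idx, op = op))
  })
}

#' Write a synthetic corpus release to disk
#'
#' Generates a corpus and writes SPL XML files, CoNLL gold, standoff
#' spans, relation gold TSV, and a JSON manifest — the file bundle the
#' command-line `gen-synth` entry point produces.
#'
#' @param dir Output directory (created if needed).
#' @param n Number of documents.
#' @param seed Integer seed.
#' @return The manifest as a list, invisibly.
#' @export
gen_synth_files <- function(dir, n = 50L, seed = 7L) {
  cfg <- generator_config(n_documents = n, seed = seed)
  gen <- generate_corpus(cfg)
  dir.create(file.path(dir, "spl"), recursive = TRUE, showWarnings = FALSE)
  for (d in gen$docs)
    writeLines(emit_spl(d), file.path(dir, "spl", paste0(d$doc_id, ".xml")))
  write_conll(gen$docs, gen$ledger$spans, file.path(dir, "gold.conll"))
  write_standoff(gen$ledger$spans, file.path(dir, "gold_spans.tsv"))
  utils::write.table(gen$ledger$relations, file.path(dir, "gold_relations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(n_documents = n, seed = seed,
                   entity_counts = as.list(gen$ledger$entity_counts),
                   files = c("spl/", "gold.conll", "gold_spans.tsv",
                             "gold_relations.tsv"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
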