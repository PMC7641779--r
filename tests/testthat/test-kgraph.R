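small_store <- function() {
  s <- triple_store(test_registry())
  add_entities(s, list(
    entity("db:trametinib", "trametinib", "Drug"),
    entity("db:dabrafenib", "dabrafenib", "Drug"),
    entity("dm:melanoma", "melanoma", "Disease"),
    entity("dm:BRAF", "BRAF", "Gene"),
    entity("rx:du1", "2 mg orally once daily", "DrugUse"),
    entity("dm:fever", "fever", "AdverseReaction")))
}

test_that("add_triple validates, deduplicates and counts", {
  s <- small_store()
  s <- add_triple(s, "db:trametinib", "treats", "dm:melanoma")
  expect_equal(nrow(s$triples), 1L)
  expect_message(
    s <- add_triple(s, "db:trametinib", "treats", "dm:melanoma"),
    "duplicate")
  expect_equal(nrow(s$triples), 1L)
  expect_error(add_triple(s, "dm:BRAF", "treats", "dm:melanoma"),
               "domain violation")
  expect_error(add_triple(s, "db:trametinib", "treats", "db:unknown"),
               "unknown object")
  expect_error(add_triple(s, "db:trametinib", "no_rel", "dm:melanoma"),
               "unregistered")
})

test_that("stored triples re-validate after any sequence of adds", {
  s <- small_store()
  s <- add_triples(s, data.frame(
    subject = c("db:trametinib", "db:trametinib", "db:trametinib"),
    rid = c("treats", "have_dosage", "synergized_by"),
    object = c("dm:melanoma", "rx:du1", "db:dabrafenib")))
  for (i in seq_len(nrow(s$triples)))
    expect_length(validate_triple(s$entities[[s$triples$subject[i]]],
                                  s$triples$rid[i],
                                  s$entities[[s$triples$object[i]]],
                                  s$registry), 0L)
})

test_that("group_counts totals always equal the store size", {
  empty <- triple_store(test_registry())
  g0 <- group_counts(empty)
  expect_equal(g0$total, 0L)
  expect_equal(nrow(g0$counts), 0L)
  s <- small_store()
  s <- add_triples(s, data.frame(
    subject = "db:trametinib",
    rid = c("treats", "have_dosage", "synergized_by", "has_adverse_reaction"),
    object = c("dm:melanoma", "rx:du1", "db:dabrafenib", "dm:fever")))
  g <- group_counts(s)
  expect_equal(g$total, nrow(s$triples))
  expect_equal(sum(g$counts$count), g$total)
  # k same-group triples form one group of k
  s2 <- small_store()
  s2 <- add_triples(s2, data.frame(
    subject = c("db:trametinib", "db:dabrafenib"), rid = "treats",
    object = "dm:melanoma"))
  g2 <- group_counts(s2)
  expect_equal(g2$counts$count, 2L)
})

test_that("melanoma store reproduces the case breakdown", {
  s <- melanoma_case_store()
  g <- group_counts(s)
  expect_equal(g$total, 4846L)
  got <- setNames(g$counts$count,
                  paste(g$counts$subject_type, g$counts$object_type, sep = "-"))
  expect_equal(got[["Drug-Drug"]], 4713L)
  expect_equal(got[["Drug-AdverseReaction"]], 41L)
  expect_equal(got[["Drug-DrugUse"]], 30L)
  expect_equal(got[["AdverseReaction-DrugUse"]], 24L)
  expect_equal(got[["Drug-Disease"]], 22L)
  expect_equal(got[["Drug-Gene"]], 7L)
  expect_equal(got[["Drug-Population"]], 4L)
  expect_equal(got[["Gene-Gene"]], 2L)
  expect_equal(got[["Gene-Disease"]], 3L)
})

test_that("query_drugs filters by disease and gene and matches a full scan", {
  s <- melanoma_case_store(c(drug_drug = 20L))
  hits <- query_drugs(s, disease = "dm:melanoma", gene = "dm:BRAF")
  # independent naive scan over the triple list
  tr <- s$triples
  rels <- registry_relations(s$registry)
  dd <- rels$rid[rels$domain == "Drug" & rels$range == "Disease"]
  dg <- rels$rid[rels$domain == "Drug" & rels$range == "Gene"]
  gd <- rels$rid[rels$domain == "Gene" & rels$range == "Drug"]
  by_dis <- unique(tr$subject[tr$rid %in% dd & tr$object == "dm:melanoma"])
  by_gene <- unique(c(tr$subject[tr$rid %in% dg & tr$object == "dm:BRAF"],
                      tr$object[tr$rid %in% gd & tr$subject == "dm:BRAF"]))
  expect_equal(hits, sort(intersect(by_dis, by_gene)))
  expect_equal(hits, c("db:dabrafenib", "db:encorafenib", "db:vemurafenib"))
  # disease alone: all seven case drugs treat melanoma
  expect_length(query_drugs(s, disease = "dm:melanoma"), 7L)
  expect_error(query_drugs(s), "at least one")
  expect_error(query_drugs(s, disease = "dm:nope"), "unknown")
  # no treats triple -> empty
  s2 <- small_store()
  expect_length(query_drugs(s2, disease = "dm:melanoma"), 0L)
})

test_that("query_dosage returns defaults and contextual overrides", {
  s <- melanoma_case_store(c(drug_drug = 10L, drug_adverse_reaction = 2L,
                             adverse_reaction_dosage = 2L, drug_dosage = 1L,
                             drug_population = 2L))
  d <- query_dosage(s, "db:trametinib")
  expect_true("2 mg orally once daily" %in%
                d$term[d$context == "default"])
  d2 <- query_dosage(s, "db:trametinib", adverse_reaction = "dm:fever")
  expect_true("stop permanently" %in% d2$term)
  # contextual rows outrank (precede) the default
  expect_lt(min(which(d2$context == "adverse_reaction")),
            min(which(d2$context == "default")))
  expect_error(query_dosage(s, NULL), "required")
  # drug with no dosage triple -> empty
  s2 <- small_store()
  s2 <- add_triple(s2, "db:trametinib", "treats", "dm:melanoma")
  expect_equal(nrow(query_dosage(s2, "db:dabrafenib")), 0L)
})

test_that("exports follow their grammars and TSV round-trips bytewise", {
  s <- small_store()
  empty_tsv <- export_store(s, "tsv")
  expect_equal(empty_tsv, "subject\trelationship\tobject\tdoc_id\tsection\n")
  s <- add_triples(s, data.frame(
    subject = "db:trametinib",
    rid = c("treats", "have_dosage", "synergized_by"),
    object = c("dm:melanoma", "rx:du1", "db:dabrafenib"),
    doc_id = "doc1", section = "Indications and Usage"))
  nt <- export_store(s, "ntriples")
  lines <- strsplit(nt, "\n")[[1L]]
  expect_length(lines, 3L)
  expect_true(all(grepl("^<[^>]+> <[^>]+> <[^>]+> \\.$", lines)))
  tsv <- export_store(s, "tsv")
  s2 <- triple_store(test_registry())
  s2$entities <- s$entities
  s2 <- import_triples_tsv(s2, tsv)
  expect_identical(export_store(s2, "tsv"), tsv)
  js <- jsonlite::fromJSON(export_store(s, "json"), simplifyVector = FALSE)
  expect_equal(js$total, 3L)
  expect_equal(sum(vapply(js$groups, `[[`, 0L, "count")), 3L)
  expect_error(export_store(s, "xml"))
})
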