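test_that("parse_spl extracts the five target sections in label order", {
  doc <- parse_spl(spl_fixture())
  expect_s3_class(doc, "pgx_document")
  expect_equal(doc$doc_id, "fix-001")
  expect_equal(doc$sections$name, pgx_label_sections())
  expect_equal(doc$sections$text, paste("Text of", pgx_label_sections()))
})

test_that("parse_spl reports missing sections and rejects non-XML", {
  four <- setdiff(pgx_label_sections(), "Warnings and Precautions")
  expect_message(doc <- parse_spl(spl_fixture(sections = four)),
                 "Warnings and Precautions")
  expect_equal(nrow(doc$sections), 4L)
  expect_error(parse_spl("this is { not xml"), "")
  # section titles match case-insensitively with collapsed whitespace
  xml <- gsub("Indications and Usage", "INDICATIONS  AND USAGE",
              spl_fixture())
  doc2 <- parse_spl(xml)
  expect_true("Indications and Usage" %in% doc2$sections$name)
})

test_that("parse_drugbank extracts the drug attribute fields", {
  rec <- parse_drugbank(drugbank_fixture())
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$name, c("trametinib", "aspirin"))
  expect_equal(rec$molecular_weight, c(615.39, 180.16))
  expect_equal(rec$approval_status, c("approved", "approved"))
  expect_equal(rec$cas, c("871700-17-3", "50-78-2"))
  expect_true(all(rec$cas_ok))
  # missing UNII stays NA without error
  expect_true(is.na(rec$unii[2L]))
})

test_that("CAS checksum validation flags corrupt numbers but keeps records", {
  expect_true(cas_valid("50-78-2"))
  expect_false(cas_valid("50-78-3"))
  expect_false(cas_valid("not-a-cas"))
  expect_true(is.na(cas_valid(NA_character_)))
  bad <- sub("50-78-2", "50-78-9", drugbank_fixture())
  expect_message(rec <- parse_drugbank(bad), "invalid CAS")
  expect_equal(nrow(rec), 2L)
  expect_false(rec$cas_ok[2L])
})

test_that("parse_rxnorm_rrf filters dose-form relations and survives bad lines", {
  conso <- c(rrf_conso_line("100", "trametinib"),
             rrf_conso_line("101", "dabrafenib"),
             rrf_conso_line("200", "oral tablet", tty = "DF"),
             rrf_conso_line("201", "capsule", tty = "DF"),
             rrf_conso_line("300", "trametinib 2 mg oral tablet",
                            tty = "SCD"))
  rel <- c(rrf_rel_line("300", "200", "has_dose_form"),
           rrf_rel_line("200", "300", "dose_form_of"),
           rrf_rel_line("100", "101", "interacts_with"))
  out <- parse_rxnorm_rrf(conso, rel)
  expect_equal(nrow(out$concepts), 5L)
  expect_equal(nrow(out$dose_form_relations), 2L)
  expect_setequal(out$dose_form_relations$relation_name,
                  c("has_dose_form", "dose_form_of"))
  empty <- parse_rxnorm_rrf(character(), character())
  expect_equal(nrow(empty$concepts), 0L)
  expect_equal(nrow(empty$dose_form_relations), 0L)
  # one malformed line among many: parsed rest, reported with line number
  expect_message(out2 <- parse_rxnorm_rrf(c(conso, "bad|line"), rel),
                 "malformed")
  expect_equal(nrow(out2$concepts), 5L)
  expect_match(out2$errors, "line 6", all = FALSE)
})

test_that("ingested records become valid registry entities", {
  reg <- test_registry()
  rec <- parse_drugbank(drugbank_fixture())
  ents <- records_to_entities(rec, reg)
  expect_length(ents, 2L)
  for (e in ents) {
    expect_length(validate_entity(e, reg), 0L)
    expect_equal(e$source, "DrugBank")
    expect_equal(e$semantic_type, "Drug")
  }
  expect_equal(ents[[1L]]$attributes[["DrugName"]], "trametinib")
  expect_length(records_to_entities(rec[0, ], reg), 0L)

  conso <- c(rrf_conso_line("300", "trametinib 2 mg oral tablet",
                            tty = "SCD"),
             rrf_conso_line("200", "oral tablet", tty = "DF"))
  rel <- rrf_rel_line("300", "200", "has_dose_form")
  rx <- rxnorm_to_entities(parse_rxnorm_rrf(conso, rel), reg)
  types <- vapply(rx$entities, `[[`, "", "semantic_type")
  expect_setequal(types, c("Drug", "DrugUse"))
  # relation endpoints become a loadable triple candidate
  s <- add_entities(triple_store(reg), rx$entities)
  s <- add_triples(s, rx$triples)
  expect_equal(nrow(s$triples), 1L)
  expect_equal(s$triples$rid, "R05")
})

test_that("SPL parse -> emit -> parse is stable", {
  doc <- parse_spl(spl_fixture())
  doc2 <- parse_spl(emit_spl(doc))
  expect_equal(doc2$sections, doc$sections)
  expect_equal(doc2$doc_id, doc$doc_id)
})
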