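test_that("tokenize splits punctuation and keeps offsets exact", {
  expect_equal(nrow(tokenize("")), 0L)
  tk <- tokenize("2 mg orally once daily")
  expect_equal(tk$token, c("2", "mg", "orally", "once", "daily"))
  expect_equal(tk$start, c(0L, 2L, 5L, 12L, 17L))
  expect_equal(tk$end, c(1L, 4L, 11L, 16L, 22L))
  tk2 <- tokenize("BRAF V600E mutation.")
  expect_equal(tk2$token, c("BRAF", "V600E", "mutation", "."))
})

test_that("tokenize loses no non-separator characters (property)", {
  withr::local_seed(11)
  for (i in 1:50) {
    text <- random_span_layout()$text
    tk <- tokenize(text)
    expect_equal(substring(text, tk$start + 1L, tk$end), tk$token)
    chars <- function(x) sort(strsplit(paste(x, collapse = ""), "")[[1L]])
    expect_equal(chars(tk$token), chars(gsub("\\s", "", text)))
  }
})

test_that("spans_to_bio follows the B/I/O rule", {
  tk <- tokenize("2 mg orally once daily")
  expect_equal(spans_to_bio(tk, NULL), rep("O", 5L))
  spans <- data.frame(start = c(0L, 12L), end = c(4L, 22L),
                      label = c("Daily_Dose", "Frequency"))
  expect_equal(spans_to_bio(tk, spans),
               c("B-Daily_Dose", "I-Daily_Dose", "O", "B-Frequency",
                 "I-Frequency"))
  # adjacent same-label spans: second opens with B-
  tk2 <- tokenize("fever rash")
  adj <- data.frame(start = c(0L, 6L), end = c(5L, 10L),
                    label = "Adverse_Reaction")
  expect_equal(spans_to_bio(tk2, adj),
               c("B-Adverse_Reaction", "B-Adverse_Reaction"))
  # mid-token boundary is a hard error naming the span
  expect_error(
    spans_to_bio(tk, data.frame(start = 0L, end = 3L, label = "Daily_Dose")),
    "align")
})

test_that("bio_to_spans inverts spans_to_bio and repairs invalid openings", {
  tk <- tokenize("trametinib tablets .")
  sp <- bio_to_spans(tk, c("B-Drug", "I-Drug", "O"))
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$start, 0L)
  expect_equal(sp$end, 18L)
  expect_equal(sp$label, "Drug")
  expect_equal(nrow(bio_to_spans(tk, rep("O", 3L))), 0L)
  tk2 <- tokenize("the BRAF")
  expect_message(sp2 <- bio_to_spans(tk2, c("O", "I-Gene")), "repaired")
  expect_equal(sp2$label, "Gene")
  expect_equal(sp2$start, 4L)
})

test_that("spans -> BIO -> spans is the identity on random layouts", {
  withr::local_seed(23)
  for (i in 1:100) {
    lay <- random_span_layout()
    tags <- spans_to_bio(lay$tokens, lay$spans)
    back <- bio_to_spans(lay$tokens, tags, quiet = TRUE)
    sp <- lay$spans[order(lay$spans$start), , drop = FALSE]
    rownames(sp) <- NULL
    expect_equal(back[, c("start", "end", "label")], sp)
  }
})

test_that("split_corpus applies round-half-up and is seed-deterministic", {
  docs <- as.list(seq_len(190))
  sp <- split_corpus(docs, 0.9, seed = 3)
  expect_length(sp$train, 171L)
  expect_length(sp$test, 19L)
  sp10 <- split_corpus(as.list(1:10), 0.9, seed = 1)
  expect_length(sp10$train, 9L)
  expect_length(sp10$test, 1L)
  expect_identical(split_corpus(docs, 0.9, seed = 42),
                   split_corpus(docs, 0.9, seed = 42))
  expect_error(split_corpus(list(), 0.9, 1), "empty")
  # partition property across sizes and fractions
  for (f in c(0.5, 0.8, 0.9)) for (n in c(1:10, 97L, 250L, 500L)) {
    s <- split_corpus(as.list(seq_len(n)), f, seed = 5)
    expect_length(s$train, floor(f * n + 0.5))
    expect_setequal(c(unlist(s$train), unlist(s$test)), seq_len(n))
  }
})

test_that("corpus_stats tallies mentions, unigrams and bigrams", {
  empty <- corpus_stats(list(), span_annotations())
  expect_true(all(empty$entity_counts == 0L))
  expect_equal(empty$n_unique_unigrams, 0L)
  d <- document("d1", c("Indications and Usage" =
                          "trametinib treats melanoma. trametinib works."))
  sp <- span_annotations(rep("d1", 3L), 1L, c(0L, 28L, 18L),
                         c(10L, 38L, 26L), c("Drug", "Drug", "Disease"),
                         surface = c("trametinib", "trametinib", "melanoma"))
  st <- corpus_stats(list(d), sp)
  expect_equal(unname(st$entity_counts[c("Drug", "Disease", "Gene")]),
               c(2L, 1L, 0L))
  expect_equal(unname(st$entity_unique_terms["Drug"]), 1L)
  expect_equal(st$n_docs, 1L)
  expect_gt(st$n_unique_bigrams, 0L)
})

test_that("agreement F is the matched-pair harmonic measure", {
  a <- span_annotations(rep("d1", 4L), 1L, c(0L, 10L, 20L, 30L),
                        c(5L, 15L, 25L, 35L), "Drug", "A")
  expect_equal(agreement_f(a, a), 1.0)
  b <- a
  b$annotator <- "B"
  b$start[4L] <- 31L  # one disagreement
  expect_equal(agreement_f(a, b), 2 * 3 / (4 + 4))
  expect_equal(agreement_f(a, b), agreement_f(b, a))
  disj <- a
  disj$label <- "Gene"
  expect_equal(agreement_f(a, disj), 0.0)
  expect_message(f <- agreement_f(span_annotations(), span_annotations()),
                 "empty")
  expect_equal(f, 1.0)
})

test_that("agreement F is symmetric on random perturbed pairs (property)", {
  gen <- generate_corpus(generator_config(n_documents = 2, seed = 9))
  for (s in 1:5) {
    pert <- corrupt(gen$ledger$spans, rate = 0.3, seed = s)
    expect_equal(agreement_f(gen$ledger$spans, pert$spans),
                 agreement_f(pert$spans, gen$ledger$spans))
  }
})

test_that("CoNLL and standoff files round-trip", {
  gen <- generate_corpus(generator_config(n_documents = 2, seed = 4))
  path <- withr::local_tempfile(fileext = ".conll")
  write_conll(gen$docs, gen$ledger$spans, path)
  seqs <- read_conll(path)
  expect_equal(length(seqs), 2L * 5L)
  orig <- docs_to_sequences(gen$docs, gen$ledger$spans)
  expect_equal(lapply(seqs, `[[`, "tokens"), lapply(orig, `[[`, "tokens"))
  expect_equal(lapply(seqs, `[[`, "tags"), lapply(orig, `[[`, "tags"))

  spath <- withr::local_tempfile(fileext = ".tsv")
  write_standoff(gen$ledger$spans, spath)
  back <- read_standoff(spath)
  expect_equal(as.data.frame(back), as.data.frame(gen$ledger$spans))
})

test_that("validate_spans catches out-of-range and overlapping spans", {
  d <- document("d1", c("Adverse Reactions" = "fever and rash"))
  ok <- span_annotations("d1", 1L, 0L, 5L, "Adverse_Reaction")
  expect_length(validate_spans(ok, list(d)), 0L)
  bad <- span_annotations("d1", 1L, c(0L, 3L), c(5L, 8L), "Adverse_Reaction")
  expect_match(validate_spans(bad, list(d)), "overlapping", all = FALSE)
  oob <- span_annotations("d1", 1L, 10L, 99L, "Adverse_Reaction")
  expect_match(validate_spans(oob, list(d)), "outside", all = FALSE)
})
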