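test_that("feature templates cover token identity, shape and boundaries", {
  f <- extract_features(c("BRAF", "V600E"), 1L, window = 1L)
  expect_true("[+0]w=braf" %in% f)
  expect_true("[+0]shape=AAAA" %in% f)
  expect_true("[-1]<BOS>" %in% f)
  expect_true("[+1]shape=A999A" %in% f)
  f2 <- extract_features(c("2", "mg"), 1L, window = 0L)
  expect_true("[+0]isdigit" %in% f2)
  f3 <- extract_features("x", 1L, window = 2L)
  expect_equal(sum(grepl("<EOS>", f3)), 2L)
})

test_that("log partition has the closed form at zero weights", {
  reg_labels <- c("O", "B-Drug", "I-Drug")
  m <- structure(list(labels = reg_labels, features = "f", window = 0L,
                      w_em = matrix(0, 1, 3), w_tr = matrix(0, 3, 3)),
                 class = "pgx_crf")
  E <- matrix(0, 2, 3)
  expect_equal(crf_log_partition(m, E), log(9))
  for (N in 1:4) {
    expect_equal(crf_log_partition(m, matrix(0, N, 3)), N * log(3))
    # uniform model: any tag sequence has likelihood L^-N
    tags <- sample(reg_labels, N, replace = TRUE)
    expect_equal(sequence_log_likelihood(m, matrix(0, N, 3), tags),
                 -N * log(3))
  }
})

test_that("exact inference agrees with exhaustive enumeration", {
  withr::local_seed(101)
  for (i in 1:60) {
    inst <- random_crf_instance()
    oracle <- brute_force_crf(inst$E, inst$W)
    expect_equal(pgxkit:::crf_log_partition_cpp(inst$E, inst$W), oracle$logZ,
                 tolerance = 1e-10)
    # probabilities over all paths sum to one
    expect_equal(sum(exp(oracle$scores - oracle$logZ)), 1, tolerance = 1e-8)
    v <- pgxkit:::crf_viterbi_cpp(inst$E, inst$W)
    expect_equal(v$score, oracle$best_score, tolerance = 1e-10)
    expect_equal(as.integer(v$path), as.integer(oracle$best_path))
  }
})

test_that("Viterbi breaks ties lexicographically", {
  # all-zero scores: every path ties; smallest label index everywhere wins
  E <- matrix(0, 3, 3); W <- matrix(0, 3, 3)
  expect_equal(as.integer(pgxkit:::crf_viterbi_cpp(E, W)$path), c(1L, 1L, 1L))
  # a dominant emission forces the decoded label at that position
  E2 <- matrix(0, 3, 3); E2[2, 3] <- 10
  expect_equal(as.integer(pgxkit:::crf_viterbi_cpp(E2, W)$path)[2], 3L)
})

test_that("analytic gradient matches central finite differences", {
  withr::local_seed(7)
  L <- 3L; F_ <- 5L; Ntot <- 7L
  X <- Matrix::sparseMatrix(i = sample(Ntot, 12L, replace = TRUE),
                            j = sample(F_, 12L, replace = TRUE), x = 1,
                            dims = c(Ntot, F_))
  fz <- list(X = X, ranges = cbind(from = c(1L, 4L), to = c(3L, 7L)),
             y = sample(L, Ntot, replace = TRUE),
             feature_names = paste0("f", 1:F_))
  par <- stats::rnorm(F_ * L + L * L) * 0.5
  res <- pgxkit:::crf_obj_grad(par, fz, L, l2_sigma = 2)
  h <- 1e-6
  fd <- vapply(seq_along(par), function(k) {
    up <- par; up[k] <- up[k] + h
    dn <- par; dn[k] <- dn[k] - h
    (pgxkit:::crf_obj_grad(up, fz, L, 2)$objective -
       pgxkit:::crf_obj_grad(dn, fz, L, 2)$objective) / (2 * h)
  }, 0)
  expect_lt(max(abs(res$gradient - fd)) / max(1, max(abs(fd))), 1e-5)
})

test_that("single-feature logistic toy has the closed-form gradient", {
  # one token, one always-on feature, two labels: the emission gradient for
  # (feature, label j) is p_j - 1{y = j}
  L <- 2L
  fz <- list(X = Matrix::sparseMatrix(i = 1L, j = 1L, x = 1,
                                      dims = c(1L, 1L)),
             ranges = cbind(from = 1L, to = 1L), y = 1L,
             feature_names = "bias")
  par <- c(0.7, -0.3, rep(0, 4L))  # w_em then w_tr
  p <- exp(par[1:2]) / sum(exp(par[1:2]))
  g <- pgxkit:::crf_obj_grad(par, fz, L, l2_sigma = 1e6)$gradient
  expect_equal(g[1:2], p - c(1, 0), tolerance = 1e-9)
})

test_that("a feature firing only for gold tags raises gold likelihood", {
  m <- structure(list(labels = c("O", "B-Drug"), features = c("a", "b"),
                      window = 0L, w_em = matrix(0, 2, 2),
                      w_tr = matrix(0, 2, 2)), class = "pgx_crf")
  E0 <- matrix(0, 2, 2)
  ll0 <- sequence_log_likelihood(m, E0, c("B-Drug", "O"))
  E1 <- E0; E1[1, 2] <- 1  # boost the gold label at position 1
  ll1 <- sequence_log_likelihood(m, E1, c("B-Drug", "O"))
  expect_gt(ll1, ll0)
  expect_lte(ll1, 0)
})

test_that("training is deterministic, descends, and rejects degeneracy", {
  gen <- generate_corpus(generator_config(n_documents = 8, seed = 5))
  seqs <- docs_to_sequences(gen$docs, gen$ledger$spans)
  cfg <- train_config(max_iterations = 40L)
  m1 <- train_crf(seqs, cfg)
  m2 <- train_crf(seqs, cfg)
  expect_identical(m1$w_em, m2$w_em)
  expect_identical(m1$w_tr, m2$w_tr)
  expect_lte(m1$fit$final_objective, m1$fit$initial_objective)
  allO <- lapply(seqs, function(s) list(tokens = s$tokens,
                                        tags = rep("O", length(s$tokens))))
  expect_error(train_crf(allO, cfg), "single tag")
  expect_error(train_crf(list(), cfg), "empty")
})

test_that("trained model tags held-out synthetic text accurately", {
  gen <- generate_corpus(generator_config(n_documents = 14, seed = 21))
  docs <- gen$docs
  train <- docs[1:10]; test <- docs[11:14]
  m <- train_crf(docs_to_sequences(train, gen$ledger$spans),
                 train_config(max_iterations = 80L))
  test_ids <- vapply(test, `[[`, "", "doc_id")
  gold <- gen$ledger$spans[gen$ledger$spans$doc_id %in% test_ids, ]
  pred <- do.call(rbind, lapply(test, function(d) tag_document(m, d)))
  ev <- evaluate_ner(gold, pred)
  expect_gt(ev$micro["f1"], 80)
})

test_that("model text format round-trips and decodes identically", {
  gen <- generate_corpus(generator_config(n_documents = 5, seed = 3))
  m <- train_crf(docs_to_sequences(gen$docs, gen$ledger$spans),
                 train_config(max_iterations = 30L))
  path <- withr::local_tempfile(fileext = ".crf")
  write_crf(m, path)
  m2 <- read_crf(path)
  expect_equal(m2$w_em, m$w_em)
  expect_equal(m2$labels, m$labels)
  toks <- c("trametinib", "is", "indicated")
  expect_identical(viterbi_decode(m2, toks)$tags,
                   viterbi_decode(m, toks)$tags)
})

test_that("entity-level evaluation pools counts and rounds to 2 decimals", {
  gold <- span_annotations(rep("d", 4L), 1L, c(0L, 10L, 20L, 30L),
                           c(5L, 15L, 25L, 35L),
                           c("Drug", "Gene", "Drug", "Disease"))
  expect_equal(unname(evaluate_ner(gold, gold)$micro),
               c(100, 100, 100))
  pred <- gold
  pred$label[4L] <- "Gene"  # one label error: 3 of 4 exact matches
  ev <- evaluate_ner(gold, pred)
  expect_equal(unname(ev$micro), c(75, 75, 75))
  expect_equal(unname(ev$counts), c(3L, 1L, 1L))
  # micro F1 is the harmonic mean of micro P and R; P = R forces F1 = P
  expect_equal(unname(micro_metrics(8512, 1488, 1488)),
               c(85.12, 85.12, 85.12))
})

test_that("a lookup encoder drives the dense-emission path end to end", {
  labels <- c("O", "B-Drug")
  tab <- matrix(c(0, 5), 1, 2, dimnames = list("trametinib", NULL))
  m <- structure(list(labels = labels, features = character(), window = 0L,
                      w_em = matrix(0, 0, 2), w_tr = matrix(0, 2, 2)),
                 class = "pgx_crf")
  enc <- lookup_encoder(tab, labels)
  E <- enc(c("give", "trametinib", "now"))
  out <- viterbi_decode(m, E)
  expect_equal(out$tags, c("O", "B-Drug", "O"))
  expect_lt(sequence_log_likelihood(m, E, out$tags), 0)
})
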