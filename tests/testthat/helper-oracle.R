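# Independent brute-force oracle for linear-chain CRF inference: exhaustive
# enumeration over all L^N tag paths. Deliberately shares no code with the
# package's forward-backward / Viterbi implementation.

brute_force_crf <- function(E, W) {
  N <- nrow(E); L <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(L)), N)))
  scores <- apply(paths, 1L, function(y) {
    s <- sum(E[cbind(seq_len(N), y)])
    if (N > 1L) s <- s + sum(W[cbind(y[-N], y[-1L])])
    s
  })
  # lexicographically smallest argmax path
  best <- which(scores == max(scores))
  lex <- best[do.call(order, as.data.frame(paths[best, , drop = FALSE]))][1L]
  list(logZ = log(sum(exp(scores))), scores = scores, paths = paths,
       best_score = max(scores), best_path = paths[lex, ])
}

random_crf_instance <- function(N = NULL, L = NULL) {
  if (is.null(N)) N <- sample(1:4, 1L)
  if (is.null(L)) L <- sample(2:3, 1L)
  list(E = matrix(stats::rnorm(N * L), N, L),
       W = matrix(stats::rnorm(L * L), L, L))
}

# Random boundary-aligned, non-overlapping span layout over a random token
# sequence; returns the text, its tokens, and the spans.
random_span_layout <- function(max_tokens = 12L) {
  words <- c("trametinib", "BRAF", "V600E", "melanoma", "fever", "2", "mg",
             "daily", "tablet", "rash", "skin", "dose", "orally", ".")
  n <- sample(seq_len(max_tokens), 1L)
  text <- paste(sample(words, n, replace = TRUE), collapse = " ")
  tk <- tokenize(text)
  nt <- nrow(tk)
  spans <- data.frame(start = integer(), end = integer(), label = character())
  i <- 1L
  while (i <= nt) {
    if (stats::runif(1L) < 0.4) {
      len <- sample(seq_len(min(3L, nt - i + 1L)), 1L)
      spans <- rbind(spans, data.frame(
        start = tk$start[i], end = tk$end[i + len - 1L],
        label = sample(pgx_entity_labels(), 1L)))
      i <- i + len
    } else i <- i + 1L
  }
  list(text = text, tokens = tk, spans = spans)
}

# Shared small fixtures ------------------------------------------------

test_registry <- local({
  reg <- NULL
  function() {
    if (is.null(reg)) reg <<- build_default_registry()
    reg
  }
})

spl_fixture <- function(sections = pgx_label_sections(),
                        doc_id = "fix-001") {
  texts <- paste("Text of", sections)
  emit_spl(document(doc_id, stats::setNames(texts, sections)))
}

drugbank_fixture <- function() {
  paste0(
    "<drugbank>",
    "<drug><name>trametinib</name>",
    "<description>A MEK inhibitor.</description>",
    "<chemical-formula>C26H23FIN5O4</chemical-formula>",
    "<average-molecular-weight>615.39</average-molecular-weight>",
    "<groups><group>approved</group></groups>",
    "<cas-number>871700-17-3</cas-number>",
    "<unii>33E86K87QN</unii>",
    "<indication>Treatment of melanoma.</indication></drug>",
    "<drug><name>aspirin</name>",
    "<description>An NSAID.</description>",
    "<chemical-formula>C9H8O4</chemical-formula>",
    "<average-molecular-weight>180.16</average-molecular-weight>",
    "<groups><group>approved</group></groups>",
    "<cas-number>50-78-2</cas-number>",
    "<indication>Analgesic.</indication></drug>",
    "</drugbank>")
}

rrf_conso_line <- function(rxcui, str, tty = "IN", sab = "RXNORM") {
  f <- rep("", 18L)
  f[1] <- rxcui; f[2] <- "ENG"; f[12] <- sab; f[13] <- tty; f[15] <- str
  paste0(paste(f, collapse = "|"), "|")
}

rrf_rel_line <- function(cui1, cui2, rela) {
  f <- rep("", 16L)
  f[1] <- cui1; f[3] <- "CUI"; f[4] <- "RO"; f[5] <- cui2; f[7] <- "CUI"
  f[8] <- rela
  paste0(paste(f, collapse = "|"), "|")
}
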