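# Drug-label documents, span annotations, BIO conversion, splits, corpus
# statistics and inter-annotator agreement.

#' Entity label inventory and drug-label section vocabulary
#'
#' `pgx_entity_labels()` returns the 8 mention-level annotation labels;
#' `pgx_label_sections()` returns the five drug-label sections the corpus
#' layer annotates.
#'
#' @return Character vector.
#' @export
pgx_entity_labels <- function() {
  c("Drug", "Gene", "Disease", "Body_Part", "Daily_Dose", "Dose_Form",
    "Frequency", "Adverse_Reaction")
}

#' @rdname pgx_entity_labels
#' @export
pgx_label_sections <- function() {
  c("Indications and Usage", "Dosage and Administration",
    "Use in Specific Populations", "Warnings and Precautions",
    "Adverse Reactions")
}

#' Sectioned drug-label document
#'
#' @param doc_id Document identifier, unique within a corpus.
#' @param sections Named character vector or list: names are section names
#'   (see [pgx_label_sections()]), values the section text.
#' @return An object of class `pgx_document` with a `sections` data frame
#'   (`name`, `text`), preserving section order.
#' @export
document <- function(doc_id, sections) {
  nm <- names(sections)
  if (is.null(nm) || any(!nzchar(nm))) stop("section names must be non-empty")
  structure(list(doc_id = as.character(doc_id),
                 sections = data.frame(name = nm,
                                       text = as.character(unlist(sections)),
                                       row.names = NULL)),
            class = "pgx_document")
}

#' @export
print.pgx_document <- function(x, ...) {
  cat(sprintf("<pgx_document %s: %d section(s), %d chars>\n", x$doc_id,
              nrow(x$sections), sum(nchar(x$sections$text))))
  invisible(x)
}

#' Construct a span-annotation table
#'
#' Spans are character-offset annotations: 0-based, half-open offsets into
#' the text of one section (sections are annotated independently). Each row
#' carries the document, section index, offsets, one of the 8 entity labels,
#' and the annotator id.
#'
#' @param doc_id,section_index,start,end,label Parallel vectors.
#' @param annotator Annotator identifier (recycled).
#' @param surface Optional surface strings (recycled, may be `NA`).
#' @return A data frame of class `pgx_spans`.
#' @export
span_annotations <- function(doc_id = character(), section_index = integer(),
                             start = integer(), end = integer(),
                             label = character(), annotator = "gold",
                             surface = NA_character_) {
  n <- max(length(doc_id), length(start))
  df <- data.frame(doc_id = rep_len(as.character(doc_id), n),
                   section_index = rep_len(as.integer(section_index), n),
                   start = rep_len(as.integer(start), n),
                   end = rep_len(as.integer(end), n),
                   label = rep_len(as.character(label), n),
                   annotator = rep_len(as.character(annotator), n),
                   surface = rep_len(as.character(surface), n),
                   row.names = NULL)
  class(df) <- c("pgx_spans", "data.frame")
  df
}

#' Check span invariants against their documents
#'
#' Verifies offsets lie inside the section text, labels come from the
#' 8-label inventory, and spans from one annotator on one section do not
#' overlap.
#'
#' @param spans A [span_annotations()] table.
#' @param docs List of `pgx_document` (may be named by doc_id).
#' @return Character vector of violation messages (empty when valid).
#' @export
validate_spans <- function(spans, docs) {
  v <- character()
  ids <- vapply(docs, `[[`, "", "doc_id")
  bad <- setdiff(unique(spans$label), pgx_entity_labels())
  if (length(bad)) v <- c(v, paste("unknown label(s):", paste(bad, collapse = ", ")))
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, ]
    d <- docs[[match(s$doc_id, ids)]]
    if (is.null(d)) { v <- c(v, paste("unknown doc", s$doc_id)); next }
    n <- nchar(d$sections$text[s$section_index])
    if (is.na(n) || s$start < 0L || s$start >= s$end || s$end > n)
      v <- c(v, sprintf("span %d: offsets [%d,%d) outside section (len %d)",
                        i, s$start, s$end, n))
  }
  key <- interaction(spans$doc_id, spans$section_index, spans$annotator,
                     drop = TRUE)
  for (k in levels(key)) {
    g <- spans[key == k, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1L && any(g$start[-1L] < g$end[-nrow(g)]))
      v <- c(v, paste("overlapping spans within", k))
  }
  v
}

#' Tokenize section text with character offsets
#'
#' Whitespace-delimited tokenization that splits punctuation from words:
#' alphanumeric runs (allowing internal hyphens, slashes, apostrophes and
#' periods, so `"V600E"`, `"0.5"` and `"first-line"` stay whole) and single
#' punctuation marks are separate tokens. Numeric-unit pairs (`"2 mg"`)
#' remain two tokens. Offsets are 0-based, half-open, and each token equals
#' its source slice, so no characters are lost.
#'
#' @param text A single string.
#' @return A data frame of class `pgx_tokens` with columns `token`, `start`,
#'   `end`.
#' @examples
#' tokenize("2 mg orally once daily")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- data.frame(token = character(), start = integer(), end = integer())
  class(empty) <- c("pgx_tokens", "data.frame")
  if (is.na(text) || !nzchar(text)) return(empty)
  pat <- "[A-Za-z0-9]+(?:[.\\-'/][A-Za-z0-9]+)*|[^\\sA-Za-z0-9]"
  m <- gregexpr(pat, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  out <- data.frame(token = substring(text, start + 1L, end),
                    start = start, end = end, row.names = NULL)
  class(out) <- c("pgx_tokens", "data.frame")
  out
}

#' Convert character spans to a BIO tag sequence
#'
#' The first token of each span is tagged `B-<label>`, subsequent tokens
#' `I-<label>`, everything else `O`. Adjacent same-label spans are kept
#' distinct because the second opens with `B-`. Spans must start and end
#' exactly on token boundaries; a span cutting through a token raises an
#' error (annotation bugs must surface, not be snapped silently).
#'
#' @param tokens A [tokenize()] table for one section.
#' @param spans Span rows for that section (only `start`, `end`, `label`
#'   are used); must be non-overlapping.
#' @return Character vector of BIO tags, one per token.
#' @export
spans_to_bio <- function(tokens, spans) {
  tags <- rep("O", nrow(tokens))
  if (is.null(spans) || nrow(spans) == 0L) return(tags)
  spans <- spans[order(spans$start), , drop = FALSE]
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, ]
    first <- which(tokens$start == s$start)
    last <- which(tokens$end == s$end)
    if (length(first) != 1L || length(last) != 1L || last < first)
      stop(sprintf(
        "span [%d,%d) '%s' does not align to token boundaries", s$start,
        s$end, s$label))
    if (any(tags[first:last] != "O"))
      stop(sprintf("span [%d,%d) overlaps a previous span", s$start, s$end))
    tags[first] <- paste0("B-", s$label)
    if (last > first) tags[(first + 1L):last] <- paste0("I-", s$label)
  }
  tags
}

#' Recover character spans from a BIO tag sequence
#'
#' Inverse of [spans_to_bio()]: round-trips exactly on valid input. Invalid
#' openings (`I-` after `O` or after a different label) are repaired to `B-`
#' in the conventional way and reported via a message.
#'
#' @param tokens A [tokenize()] table.
#' @param tags BIO tag vector, one per token.
#' @param quiet Suppress the repair message.
#' @return Data frame with columns `start`, `end`, `label`, `surface`.
#' @export
bio_to_spans <- function(tokens, tags, quiet = FALSE) {
  stopifnot(length(tags) == nrow(tokens))
  n_fix <- 0L
  prev <- "O"
  for (i in seq_along(tags)) {
    t <- tags[i]
    if (startsWith(t, "I-")) {
      lab <- substring(t, 3L)
      ok <- (startsWith(prev, "B-") || startsWith(prev, "I-")) &&
        substring(prev, 3L) == lab
      if (!ok) {
        tags[i] <- paste0("B-", lab)
        n_fix <- n_fix + 1L
      }
    }
    prev <- tags[i]
  }
  if (n_fix > 0L && !quiet)
    message("bio_to_spans: repaired ", n_fix, " invalid I- opening(s) to B-")
  starts <- which(startsWith(tags, "B-"))
  out <- data.frame(start = integer(), end = integer(), label = character(),
                    surface = character())
  for (i in starts) {
    lab <- substring(tags[i], 3L)
    j <- i
    while (j < length(tags) && tags[j + 1L] == paste0("I-", lab)) j <- j + 1L
    out <- rbind(out, data.frame(start = tokens$start[i], end = tokens$end[j],
                                 label = lab, surface = NA_character_))
  }
  out
}

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Split a corpus into train and test sets
#'
#' Random assignment, deterministic in `seed`. The train size is
#' `round-half-up(train_fraction * n)`, so 190 documents at fraction 0.9
#' give exactly 171 train / 19 test.
#'
#' @param docs List of documents (or any list-like corpus).
#' @param train_fraction Proportion in (0, 1).
#' @param seed Integer seed.
#' @return List with elements `train` and `test`, a disjoint partition of
#'   `docs`.
#' @export
split_corpus <- function(docs, train_fraction = 0.9, seed = 1L) {
  n <- length(docs)
  if (n == 0L) stop("cannot split an empty corpus")
  stopifnot(train_fraction > 0, train_fraction < 1)
  n_train <- as.integer(floor(train_fraction * n + 0.5))
  idx <- with_seed(seed, sample.int(n, n_train))
  list(train = docs[sort(idx)], test = docs[setdiff(seq_len(n), idx)])
}

#' Corpus statistics
#'
#' Entity counts per label (both mention counts and unique case-folded
#' surface terms), unique unigram and bigram counts over the case-folded
#' tokenized text, and document count.
#'
#' @param docs List of `pgx_document`.
#' @param spans A [span_annotations()] table over those documents.
#' @return A list of class `pgx_corpus_stats`: `n_docs`, `entity_counts`,
#'   `entity_unique_terms`, `n_unique_unigrams`, `n_unique_bigrams`.
#' @export
corpus_stats <- function(docs, spans = NULL) {
  labs <- pgx_entity_labels()
  cnt <- setNames(integer(length(labs)), labs)
  uniq <- setNames(integer(length(labs)), labs)
  if (!is.null(spans) && nrow(spans)) {
    tab <- table(factor(spans$label, levels = labs))
    cnt[names(tab)] <- as.integer(tab)
    sf <- tolower(ifelse(is.na(spans$surface), "", spans$surface))
    for (l in labs)
      uniq[l] <- length(unique(sf[spans$label == l & nzchar(sf)]))
  }
  uni <- character(0); bi <- character(0)
  for (d in docs) for (txt in d$sections$text) {
    tk <- tolower(tokenize(txt)$token)
    uni <- c(uni, tk)
    if (length(tk) > 1L) bi <- c(bi, paste(tk[-length(tk)], tk[-1L]))
  }
  structure(list(n_docs = length(docs), entity_counts = cnt,
                 entity_unique_terms = uniq,
                 n_unique_unigrams = length(unique(uni)),
                 n_unique_bigrams = length(unique(bi))),
            class = "pgx_corpus_stats")
}

#' @export
print.pgx_corpus_stats <- function(x, ...) {
  cat(sprintf("<pgx_corpus_stats: %d docs, %d mentions, %d unigrams, %d bigrams>\n",
              x$n_docs, sum(x$entity_counts), x$n_unique_unigrams,
              x$n_unique_bigrams))
  print(x$entity_counts)
  invisible(x)
}

#' Inter-annotator agreement F score
#'
#' Agreement between two annotators' span sets, treating one as reference:
#' `F = 2 * |exact matches| / (|a| + |b|)` where a match requires identical
#' (doc, section, start, end, label). The measure is symmetric in the two
#' sets. Two empty sets agree perfectly (F = 1, reported via a message).
#'
#' @param a,b Span tables from two annotators over the same documents.
#' @return F score in `[0, 1]`.
#' @export
agreement_f <- function(a, b) {
  na <- if (is.null(a)) 0L else nrow(a)
  nb <- if (is.null(b)) 0L else nrow(b)
  if (na + nb == 0L) {
    message("agreement_f: both annotation sets empty; agreement defined as 1")
    return(1.0)
  }
  key <- function(x) paste(x$doc_id, x$section_index, x$start, x$end, x$label,
                           sep = "\r")
  ka <- key(a); kb <- key(b)
  # one-to-one matching on exact keys (duplicates matched up to multiplicity)
  ta <- table(ka)
  tb <- table(kb)[names(ta)]
  tb[is.na(tb)] <- 0L
  matches <- sum(pmin(as.integer(ta), as.integer(tb)))
  2 * matches / (na + nb)
}

#' Write and read CoNLL-style token/tag files
#'
#' One token per line as `token<TAB>tag`, a blank line between sequences,
#' and a `-DOCSTART- <doc_id>` line opening each document. Each section of
#' a document is one sequence.
#'
#' @param docs List of `pgx_document`.
#' @param spans Gold spans for those documents (one annotator).
#' @param path Output file.
#' @return `write_conll()`: `path` invisibly. `read_conll()`: a list of
#'   sequences, each `list(doc_id, section_index, tokens, tags)`.
#' @export
write_conll <- function(docs, spans, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (d in docs) {
    writeLines(paste("-DOCSTART-", d$doc_id), con)
    for (si in seq_len(nrow(d$sections))) {
      tk <- tokenize(d$sections$text[si])
      sp <- spans[spans$doc_id == d$doc_id & spans$section_index == si, ,
                  drop = FALSE]
      tags <- spans_to_bio(tk, sp)
      if (nrow(tk)) writeLines(paste(tk$token, tags, sep = "\t"), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

#' @rdname write_conll
#' @export
read_conll <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  out <- list()
  doc_id <- NA_character_
  tok <- character(); tag <- character()
  flush <- function() {
    if (length(tok))
      out[[length(out) + 1L]] <<- list(doc_id = doc_id, section_index = NA_integer_,
                                       tokens = tok, tags = tag)
    tok <<- character(); tag <<- character()
  }
  for (ln in lines) {
    if (startsWith(ln, "-DOCSTART-")) {
      flush()
      doc_id <- sub("^-DOCSTART-\\s*", "", ln)
    } else if (!nzchar(ln)) {
      flush()
    } else {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      tok <- c(tok, parts[1L]); tag <- c(tag, parts[2L])
    }
  }
  flush()
  # renumber section indices per document in order of appearance
  ids <- vapply(out, `[[`, "", "doc_id")
  for (d in unique(ids)) {
    w <- which(ids == d)
    for (k in seq_along(w)) out[[w[k]]]$section_index <- k
  }
  out
}

#' Write and read standoff span files
#'
#' Tab-separated columns: doc_id, section_index, start, end, label,
#' annotator, surface.
#'
#' @param spans A [span_annotations()] table.
#' @param path File path.
#' @return `write_standoff()`: `path` invisibly. `read_standoff()`: a
#'   `pgx_spans` table.
#' @export
write_standoff <- function(spans, path) {
  utils::write.table(spans, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_standoff
#' @export
read_standoff <- function(path) {
  df <- utils::read.delim(path, sep = "\t", quote = "", encoding = "UTF-8",
                          colClasses = c("character", "integer", "integer",
                                         "integer", "character", "character",
                                         "character"))
  span_annotations(df$doc_id, df$section_index, df$start, df$end, df$label,
                   df$annotator, df$surface)
}
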