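# Feature-based linear-chain CRF tagger: discrete feature templates,
# exact inference (forward-backward, Viterbi) over emission + transition
# log-scores, penalized maximum-likelihood training, and entity-level
# evaluation. Dense emission matrices are accepted everywhere a token
# sequence is, which is the plug-in point for learned encoders.

#' Training configuration for the CRF
#'
#' @param l2_sigma Gaussian prior scale; the penalty added to the negative
#'   log-likelihood is `sum(w^2) / (2 * l2_sigma^2)`. Must be positive.
#' @param max_iterations Iteration cap for the batch quasi-Newton optimizer.
#' @param tolerance Relative objective-change convergence threshold.
#' @param seed Integer seed recorded with the run. Training is deterministic
#'   (zero initialization, batch optimizer), so the seed does not alter the
#'   result; it is kept so stochastic extensions preserve the interface.
#' @return A list of class `pgx_train_config`.
#' @export
train_config <- function(l2_sigma = 10, max_iterations = 150L,
                         tolerance = 1e-7, seed = 1L) {
  stopifnot(l2_sigma > 0, max_iterations >= 1)
  structure(list(l2_sigma = l2_sigma,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, seed = as.integer(seed)),
            class = "pgx_train_config")
}

#' Discrete feature templates for one token position
#'
#' Deterministic feature strings for position `i` of a token sequence:
#' lowercased token, word shape (uppercase -> `A`, lowercase -> `a`,
#' digit -> `9`), prefixes and suffixes to length 3, and an is-digit flag —
#' each emitted for the focus token and for every neighbor within the
#' window, tagged with its relative offset. Positions beyond the sequence
#' boundary contribute `<BOS>`/`<EOS>` markers instead.
#'
#' @param tokens Character vector of surface tokens.
#' @param i Position (1-based).
#' @param window Context radius in tokens (non-negative).
#' @return Character vector of feature strings.
#' @examples
#' extract_features(c("BRAF", "V600E"), 1, window = 1)
#' @export
extract_features <- function(tokens, i, window = 2L) {
  stopifnot(window >= 0L, i >= 1L, i <= length(tokens))
  out <- character()
  for (o in (-window):window) {
    j <- i + o
    pre <- sprintf("[%+d]", o)
    if (j < 1L) { out <- c(out, paste0(pre, "<BOS>")); next }
    if (j > length(tokens)) { out <- c(out, paste0(pre, "<EOS>")); next }
    out <- c(out, paste0(pre, token_templates(tokens[j])))
  }
  out
}

token_templates <- function(tok) {
  lo <- tolower(tok)
  shape <- gsub("[0-9]", "9", gsub("[a-z]", "a", gsub("[A-Z]", "A", tok)))
  n <- nchar(lo)
  f <- c(paste0("w=", lo), paste0("shape=", shape))
  for (k in 1:3) if (n >= k)
    f <- c(f, paste0("pre", k, "=", substr(lo, 1L, k)),
           paste0("suf", k, "=", substr(lo, n - k + 1L, n)))
  if (grepl("^[0-9]+([./][0-9]+)?$", tok)) f <- c(f, "isdigit")
  f
}

# The full BIO tag set over the entity label inventory; "O" first so that
# the all-zero model decodes to "O" under the lexicographic tie-break.
bio_tagset <- function(extra = character()) {
  labs <- pgx_entity_labels()
  base <- c("O", as.vector(rbind(paste0("B-", labs), paste0("I-", labs))))
  c(base, setdiff(extra, base))
}

# Featurize a list of sequences (list(tokens=chr, tags=chr|NULL)) into one
# stacked sparse design matrix plus per-sequence row ranges.
featurize <- function(seqs, window, feature_names = NULL, labels = NULL) {
  feats <- vector("list", length(seqs))
  for (s in seq_along(seqs)) {
    tk <- seqs[[s]]$tokens
    feats[[s]] <- lapply(seq_along(tk), extract_features, tokens = tk,
                         window = window)
  }
  lens <- vapply(feats, length, 0L)
  if (sum(lens) == 0L) stop("no tokens to featurize")
  all_feats <- unlist(feats, recursive = TRUE, use.names = FALSE)
  per_pos <- unlist(lapply(feats, vapply, length, 0L), use.names = FALSE)
  if (is.null(feature_names)) feature_names <- sort(unique(all_feats))
  col <- match(all_feats, feature_names)           # NA = unseen at predict
  row <- rep.int(seq_len(sum(lens)), per_pos)
  keep <- !is.na(col)
  X <- Matrix::sparseMatrix(i = row[keep], j = col[keep], x = 1,
                            dims = c(sum(lens), length(feature_names)))
  ends <- cumsum(lens)
  ranges <- cbind(from = c(1L, head(ends, -1L) + 1L), to = ends)
  y <- NULL
  if (!is.null(labels) && !is.null(seqs[[1L]]$tags)) {
    tags <- unlist(lapply(seqs, `[[`, "tags"), use.names = FALSE)
    y <- match(tags, labels)
    if (anyNA(y)) stop("tag outside the model label set: ",
                       paste(unique(tags[is.na(y)]), collapse = ", "))
  }
  list(X = X, ranges = ranges, y = y, feature_names = feature_names)
}

pack_weights <- function(w_em, w_tr) c(as.numeric(w_em), as.numeric(w_tr))
unpack_weights <- function(par, F_, L) {
  list(w_em = matrix(par[seq_len(F_ * L)], F_, L),
       w_tr = matrix(par[F_ * L + seq_len(L * L)], L, L))
}

# Penalized negative log-likelihood and its gradient over a featurized
# corpus. Gradient = model-expected feature counts - empirical counts
# + L2 term, assembled from per-sequence forward-backward marginals.
crf_obj_grad <- function(par, fz, L, l2_sigma) {
  F_ <- length(fz$feature_names)
  w <- unpack_weights(par, F_, L)
  E_all <- as.matrix(fz$X %*% w$w_em)
  Ntot <- nrow(E_all)
  P_all <- matrix(0, Ntot, L)
  trans_exp <- matrix(0, L, L)
  nll <- 0
  for (s in seq_len(nrow(fz$ranges))) {
    rows <- fz$ranges[s, "from"]:fz$ranges[s, "to"]
    Es <- E_all[rows, , drop = FALSE]
    mg <- crf_marginals_cpp(Es, w$w_tr)
    P_all[rows, ] <- mg$node
    trans_exp <- trans_exp + mg$trans
    ys <- fz$y[rows]
    gold <- sum(Es[cbind(seq_along(rows), ys)])
    if (length(ys) > 1L)
      gold <- gold + sum(w$w_tr[cbind(ys[-length(ys)], ys[-1L])])
    nll <- nll + mg$logZ - gold
  }
  Y <- Matrix::sparseMatrix(i = seq_len(Ntot), j = fz$y, x = 1,
                            dims = c(Ntot, L))
  grad_em <- as.matrix(Matrix::crossprod(fz$X, P_all - Y)) + w$w_em / l2_sigma^2
  emp_tr <- matrix(0, L, L)
  for (s in seq_len(nrow(fz$ranges))) {
    ys <- fz$y[fz$ranges[s, "from"]:fz$ranges[s, "to"]]
    if (length(ys) > 1L) {
      ij <- cbind(ys[-length(ys)], ys[-1L])
      for (r in seq_len(nrow(ij)))
        emp_tr[ij[r, 1L], ij[r, 2L]] <- emp_tr[ij[r, 1L], ij[r, 2L]] + 1
    }
  }
  grad_tr <- trans_exp - emp_tr + w$w_tr / l2_sigma^2
  list(objective = nll + sum(par^2) / (2 * l2_sigma^2),
       gradient = pack_weights(grad_em, grad_tr))
}

#' Gradient of the penalized CRF objective
#'
#' Returns the gradient of the L2-penalized negative log-likelihood at the
#' model's current weights over a batch of gold-tagged sequences: expected
#' feature counts under the model minus empirical counts, plus the L2 term.
#' Primarily exposed for optimizer plumbing and finite-difference checks.
#'
#' @param model A `pgx_crf` model.
#' @param sequences List of `list(tokens, tags)` gold sequences.
#' @param config A [train_config()].
#' @return Numeric gradient vector of length `length(features) * L + L^2`.
#' @export
crf_gradient <- function(model, sequences, config = train_config()) {
  if (length(sequences) == 0L) stop("empty batch")
  fz <- featurize(sequences, model$window, model$features, model$labels)
  crf_obj_grad(pack_weights(model$w_em, model$w_tr), fz,
               length(model$labels), config$l2_sigma)$gradient
}

#' Train a linear-chain CRF tagger
#'
#' Batch penalized maximum-likelihood training of emission and transition
#' weights (the transition matrix is learned, not templated) with a
#' quasi-Newton optimizer (L-BFGS-B) from zero initialization, which makes
#' the run fully deterministic. The penalized objective is non-increasing
#' across accepted iterations; optimization stops on the relative tolerance
#' or the iteration cap.
#'
#' @param sequences Training data: a list of `list(tokens = <character>,
#'   tags = <BIO character>)`, e.g. from [read_conll()] or
#'   [docs_to_sequences()].
#' @param config A [train_config()].
#' @param window Feature context radius (see [extract_features()]).
#' @return A model of class `pgx_crf`: `labels`, `features`, `window`,
#'   `w_em` (features x labels), `w_tr` (labels x labels), plus optimizer
#'   diagnostics in `$fit`.
#' @export
train_crf <- function(sequences, config = train_config(), window = 2L) {
  if (length(sequences) == 0L) stop("empty training corpus")
  tags <- unlist(lapply(sequences, `[[`, "tags"), use.names = FALSE)
  if (length(unique(tags)) < 2L)
    stop("degenerate task: training corpus contains a single tag")
  labels <- bio_tagset(extra = unique(tags))
  fz <- featurize(sequences, window, labels = labels)
  L <- length(labels)
  F_ <- length(fz$feature_names)
  par0 <- numeric(F_ * L + L * L)
  cache <- new.env(parent = emptyenv())
  eval_at <- function(p) {
    if (!identical(cache$par, p))  {
      cache$res <- crf_obj_grad(p, fz, L, config$l2_sigma)
      cache$par <- p
    }
    cache$res
  }
  obj0 <- eval_at(par0)$objective
  fit <- stats::optim(par0, fn = function(p) eval_at(p)$objective,
                      gr = function(p) eval_at(p)$gradient,
                      method = "L-BFGS-B",
                      control = list(maxit = config$max_iterations,
                                     factr = config$tolerance /
                                       .Machine$double.eps))
  if (fit$value > obj0 + 1e-8)
    stop("optimizer failed the descent contract")
  w <- unpack_weights(fit$par, F_, L)
  structure(list(labels = labels, features = fz$feature_names,
                 window = as.integer(window), w_em = w$w_em, w_tr = w$w_tr,
                 config = config,
                 fit = list(initial_objective = obj0,
                            final_objective = fit$value,
                            convergence = fit$convergence,
                            n_evals = fit$counts)),
            class = "pgx_crf")
}

#' @export
print.pgx_crf <- function(x, ...) {
  cat(sprintf("<pgx_crf: %d labels, %d features, window %d, objective %.3f>\n",
              length(x$labels), length(x$features), x$window,
              x$fit$final_objective))
  invisible(x)
}

# Resolve the (emission matrix, labels) pair for model + input, accepting
# either a token sequence (featurized emissions) or a dense emission matrix
# from an external encoder.
resolve_emissions <- function(model, seq) {
  if (is.matrix(seq)) {
    if (ncol(seq) != length(model$labels))
      stop("emission matrix must have one column per label")
    return(seq)
  }
  tokens <- if (is.data.frame(seq)) seq$token else as.character(seq)
  if (length(tokens) == 0L) stop("empty sequence")
  fz <- featurize(list(list(tokens = tokens)), model$window, model$features)
  as.matrix(fz$X %*% model$w_em)
}

#' Log-partition function of a sequence
#'
#' The log of the sum of `exp(path score)` over all `L^N` tag sequences,
#' computed exactly by the forward recursion in log space.
#'
#' @param model A `pgx_crf` model.
#' @param seq Token character vector, [tokenize()] table, or a dense
#'   `N x L` emission score matrix (the encoder plug-in path).
#' @return Scalar log Z.
#' @export
crf_log_partition <- function(model, seq) {
  crf_log_partition_cpp(resolve_emissions(model, seq), model$w_tr)
}

#' Conditional log-likelihood of a tag sequence
#'
#' `score(tags) - log Z`; always non-positive.
#'
#' @inheritParams crf_log_partition
#' @param tags BIO tag vector, one per token.
#' @return Scalar log-probability.
#' @export
sequence_log_likelihood <- function(model, seq, tags) {
  E <- resolve_emissions(model, seq)
  y <- match(tags, model$labels)
  if (anyNA(y)) stop("tag outside the model label set: ",
                     paste(unique(tags[is.na(y)]), collapse = ", "))
  if (length(y) != nrow(E)) stop("one tag per token required")
  sc <- sum(E[cbind(seq_len(nrow(E)), y)])
  if (length(y) > 1L) sc <- sc + sum(model$w_tr[cbind(y[-length(y)], y[-1L])])
  sc - crf_log_partition_cpp(E, model$w_tr)
}

#' Viterbi decoding
#'
#' Returns the tag sequence attaining the maximum path score; ties are
#' broken toward the lexicographically smallest label-index sequence, so
#' the all-zero model decodes every token as the first label (`"O"`).
#'
#' @inheritParams crf_log_partition
#' @return `list(tags = <character>, score = <numeric>)`.
#' @export
viterbi_decode <- function(model, seq) {
  E <- resolve_emissions(model, seq)
  v <- crf_viterbi_cpp(E, model$w_tr)
  list(tags = model$labels[v$path], score = v$score)
}

#' Tag a document and return predicted entity spans
#'
#' Tokenizes each section, decodes it with the model, and converts the BIO
#' output back to character spans.
#'
#' @param model A `pgx_crf` model.
#' @param doc A `pgx_document`.
#' @param annotator Annotator id recorded on the predicted spans.
#' @return A [span_annotations()] table.
#' @export
tag_document <- function(model, doc, annotator = "crf") {
  out <- span_annotations()
  for (si in seq_len(nrow(doc$sections))) {
    tk <- tokenize(doc$sections$text[si])
    if (nrow(tk) == 0L) next
    tags <- viterbi_decode(model, tk$token)$tags
    sp <- bio_to_spans(tk, tags, quiet = TRUE)
    if (nrow(sp))
      out <- rbind(out, span_annotations(
        doc$doc_id, si, sp$start, sp$end, sp$label, annotator,
        substring(doc$sections$text[si], sp$start + 1L, sp$end)))
  }
  out
}

#' Convert annotated documents to tagged training sequences
#'
#' Each section becomes one sequence of tokens with gold BIO tags derived
#' from the span annotations.
#'
#' @param docs List of `pgx_document`.
#' @param spans Gold [span_annotations()] (one annotator).
#' @return List of `list(doc_id, section_index, tokens, tags)`.
#' @export
docs_to_sequences <- function(docs, spans) {
  out <- list()
  for (d in docs) for (si in seq_len(nrow(d$sections))) {
    tk <- tokenize(d$sections$text[si])
    if (nrow(tk) == 0L) next
    sp <- spans[spans$doc_id == d$doc_id & spans$section_index == si, ,
                drop = FALSE]
    out[[length(out) + 1L]] <- list(doc_id = d$doc_id, section_index = si,
                                    tokens = tk$token,
                                    tags = spans_to_bio(tk, sp))
  }
  out
}

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

prf <- function(tp, fp, fn) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = round_half_up(p), recall = round_half_up(r),
    f1 = round_half_up(f))
}

#' Entity-level NER evaluation
#'
#' Exact-match, entity-level evaluation (CoNLL convention): a predicted
#' span is a true positive iff a gold span with identical (doc, section,
#' start, end, label) exists, matched one-to-one. Micro-averaged
#' precision/recall/F1 pool TP/FP/FN over all labels; per-label metrics use
#' that label's counts. Percentages are rounded half-up to 2 decimals; each
#' F1 is the harmonic mean of its (unrounded) precision and recall, so
#' micro-P = micro-R forces micro-F1 to the same value.
#'
#' @param gold,pred Span tables over the same documents.
#' @return A list of class `pgx_eval`: `per_label` data frame (label, tp,
#'   fp, fn, precision, recall, f1), `micro` named vector, `counts` totals.
#' @export
evaluate_ner <- function(gold, pred) {
  labs <- union(pgx_entity_labels(), union(gold$label, pred$label))
  key <- function(x) paste(x$doc_id, x$section_index, x$start, x$end, x$label,
                           sep = "\r")
  per <- data.frame(label = labs, tp = 0L, fp = 0L, fn = 0L,
                    precision = 0, recall = 0, f1 = 0)
  for (i in seq_along(labs)) {
    g <- gold[gold$label == labs[i], , drop = FALSE]
    p <- pred[pred$label == labs[i], , drop = FALSE]
    tg <- table(key(g)); tp_ <- table(key(p))
    common <- intersect(names(tg), names(tp_))
    tp <- sum(pmin(as.integer(tg[common]), as.integer(tp_[common])))
    per$tp[i] <- tp
    per$fp[i] <- nrow(p) - tp
    per$fn[i] <- nrow(g) - tp
    per[i, c("precision", "recall", "f1")] <- prf(tp, per$fp[i], per$fn[i])
  }
  micro <- prf(sum(per$tp), sum(per$fp), sum(per$fn))
  structure(list(per_label = per, micro = micro,
                 counts = c(tp = sum(per$tp), fp = sum(per$fp),
                            fn = sum(per$fn)),
                 granularity = "entity-level exact span+label match"),
            class = "pgx_eval")
}

#' Micro metrics from pooled counts
#'
#' Computes micro-averaged precision/recall/F1 directly from pooled
#' TP/FP/FN counts (the metric arithmetic used by [evaluate_ner()]).
#'
#' @param tp,fp,fn Pooled counts.
#' @return Named vector `precision`, `recall`, `f1` in percent (2 decimals).
#' @export
micro_metrics <- function(tp, fp, fn) prf(tp, fp, fn)

#' @export
print.pgx_eval <- function(x, ...) {
  cat(sprintf("<pgx_eval (%s)>\n  micro P/R/F1: %.2f / %.2f / %.2f\n",
              x$granularity, x$micro["precision"], x$micro["recall"],
              x$micro["f1"]))
  shown <- x$per_label[x$per_label$tp + x$per_label$fp + x$per_label$fn > 0, ]
  if (nrow(shown)) print(shown, row.names = FALSE)
  invisible(x)
}

#' Build a lookup encoder
#'
#' A minimal dense-emission encoder for the CRF's encoder interface: maps
#' each token to a fixed per-label score row via a lookup table (unknown
#' tokens score zero). Stands where a learned contextual encoder would plug
#' in.
#'
#' @param table Numeric matrix with one row per known token (rownames are
#'   the tokens) and one column per label.
#' @param labels The model's label vector (column order of `table`).
#' @return A function `tokens -> N x L` emission matrix.
#' @export
lookup_encoder <- function(table, labels) {
  stopifnot(ncol(table) == length(labels), !is.null(rownames(table)))
  function(tokens) {
    E <- matrix(0, length(tokens), length(labels))
    hit <- match(tokens, rownames(table))
    E[!is.na(hit), ] <- table[hit[!is.na(hit)], , drop = FALSE]
    E
  }
}

#' Write and read a CRF model as versioned flat text
#'
#' A binary-free, diffable model format: header, label list, feature list,
#' and weights as decimal text.
#'
#' @param model A `pgx_crf`.
#' @param path File path.
#' @return `write_crf()`: `path` invisibly; `read_crf()`: a `pgx_crf`.
#' @export
write_crf <- function(model, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("pgxkit-crf 1",
               paste("window", model$window),
               paste("labels", length(model$labels))), con)
  writeLines(model$labels, con)
  writeLines(paste("features", length(model$features)), con)
  writeLines(model$features, con)
  writeLines("weights", con)
  writeLines(sprintf("%.17g", c(model$w_em, model$w_tr)), con)
  invisible(path)
}

#' @rdname write_crf
#' @export
read_crf <- function(path) {
  ln <- readLines(path, encoding = "UTF-8")
  if (ln[1L] != "pgxkit-crf 1") stop("not a pgxkit-crf version 1 file")
  window <- as.integer(sub("^window ", "", ln[2L]))
  L <- as.integer(sub("^labels ", "", ln[3L]))
  labels <- ln[3L + seq_len(L)]
  i <- 4L + L
  F_ <- as.integer(sub("^features ", "", ln[i]))
  features <- ln[i + seq_len(F_)]
  stopifnot(ln[i + F_ + 1L] == "weights")
  w <- as.numeric(ln[(i + F_ + 2L):length(ln)])
  stopifnot(length(w) == F_ * L + L * L)
  u <- unpack_weights(w, F_, L)
  structure(list(labels = labels, features = features, window = window,
                 w_em = u$w_em, w_tr = u$w_tr, config = NULL,
                 fit = list(final_objective = NA_real_)),
            class = "pgx_crf")
}
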