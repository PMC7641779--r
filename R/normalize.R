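# Normalization of relation surface expressions: maps the phrasing drug
# labels use ("in combination with", "with *** mutation") to registered
# relation names via an auditable literal synonym table. Matching is
# case-insensitive, whitespace-normalized, literal except for a single
# wildcard operator "***" that captures a bounded, maximal, non-empty token
# run (e.g. a gene + variant). Deliberately not regex: curator rules stay
# readable and reviewable.

#' Load the default relation-expression synonym table
#'
#' Reads the shipped tab-separated rule file (`surface<TAB>normalized`,
#' `#` comments) covering the published expression inventory: treatment
#' phrasings map to `treats`, combination phrasings to `synergized_by`,
#' avoidance phrasings to `antagonized_by`, dosage phrasings to
#' `have_dosage`, and mutation phrasings (with a wildcard for the variant)
#' to `have_mutation`. Every normalized name is checked against the
#' registry.
#'
#' @param path Rule file path; defaults to the shipped table.
#' @param registry A `pgx_registry` used to resolve normalized names.
#' @param max_wildcard_tokens Upper bound on the token run a `***` slot may
#'   capture.
#' @return A data frame of class `pgx_synonyms` with columns `surface`,
#'   `normalized`.
#' @export
load_default_rules <- function(path = NULL, registry = build_default_registry(),
                               max_wildcard_tokens = 6L) {
  if (is.null(path))
    path <- system.file("extdata", "relation_expressions.tsv",
                        package = "pgxkit", mustWork = TRUE)
  ln <- readLines(path, encoding = "UTF-8")
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  parts <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("rule file lines must be surface<TAB>normalized")
  tab <- data.frame(surface = trimws(vapply(parts, `[[`, "", 1L)),
                    normalized = trimws(vapply(parts, `[[`, "", 2L)),
                    row.names = NULL)
  synonym_table(tab, registry, max_wildcard_tokens)
}

#' Construct a synonym table
#'
#' @param rules Data frame with columns `surface`, `normalized`.
#' @param registry Registry used to resolve normalized relation names; pass
#'   `NULL` to skip resolution (not recommended).
#' @param max_wildcard_tokens Wildcard capture bound.
#' @return A `pgx_synonyms` data frame.
#' @export
synonym_table <- function(rules, registry = build_default_registry(),
                          max_wildcard_tokens = 6L) {
  key <- normalize_surface(rules$surface)
  if (anyDuplicated(key))
    stop("duplicate surface form(s): ",
         paste(unique(rules$surface[duplicated(key)]), collapse = ", "))
  if (any(!nzchar(key))) stop("empty surface form")
  if (!is.null(registry)) {
    bad <- unique(rules$normalized[!vapply(rules$normalized, function(n)
      !is.null(find_relation(registry, n)), NA)])
    if (length(bad))
      stop("normalized name(s) not in registry: ", paste(bad, collapse = ", "))
  }
  out <- data.frame(surface = as.character(rules$surface),
                    normalized = as.character(rules$normalized),
                    row.names = NULL)
  attr(out, "max_wildcard_tokens") <- as.integer(max_wildcard_tokens)
  class(out) <- c("pgx_synonyms", "data.frame")
  out
}

normalize_surface <- function(x) tolower(gsub("\\s+", " ", trimws(x)))

#' Add a synonym rule
#'
#' @param table A `pgx_synonyms` table.
#' @param surface New surface expression.
#' @param normalized Registered relation name it normalizes to.
#' @param registry Registry for name resolution.
#' @return The updated table.
#' @export
add_synonym <- function(table, surface, normalized,
                        registry = build_default_registry()) {
  if (normalize_surface(surface) %in% normalize_surface(table$surface))
    stop("duplicate surface form: '", surface, "'")
  if (is.null(find_relation(registry, normalized)))
    stop("unknown normalized relation: '", normalized, "'")
  out <- rbind(as.data.frame(table),
               data.frame(surface = surface, normalized = normalized))
  synonym_table(out, registry = NULL,
                attr(table, "max_wildcard_tokens") %||% 6L)
}

# Try to match one rule pattern starting at token position pos.
# Returns list(len = tokens consumed, capture = character or NA) or NULL.
match_pattern_at <- function(toks, pos, pat, max_wild) {
  n <- length(toks)
  match_rest <- function(ti, pi) {
    if (pi > length(pat)) return(list(end = ti - 1L, capture = NULL))
    if (pat[pi] == "***") {
      # maximal non-empty capture within the bound
      for (k in rev(seq_len(max_wild))) {
        if (ti + k - 1L > n) next
        res <- match_rest(ti + k, pi + 1L)
        if (!is.null(res)) {
          res$capture <- c(list(c(ti, ti + k - 1L)), res$capture)
          return(res)
        }
      }
      return(NULL)
    }
    if (ti > n || toks[ti] != pat[pi]) return(NULL)
    match_rest(ti + 1L, pi + 1L)
  }
  res <- match_rest(pos, 1L)
  if (is.null(res)) return(NULL)
  list(len = res$end - pos + 1L, capture = res$capture)
}

#' Normalize relation expressions in text
#'
#' Scans a phrase or sentence for rule-table surface expressions. Matching
#' is case-insensitive over whitespace-normalized tokens; at each position
#' the longest matching rule wins; matches never overlap (the
#' earlier-starting match wins and the scan resumes after it). A `***`
#' wildcard slot captures a maximal non-empty token run, bounded by the
#' table's capture limit.
#'
#' @param text Input string.
#' @param table A `pgx_synonyms` table.
#' @return Data frame with one row per match: `start`, `end` (0-based,
#'   half-open character offsets), `surface` (matched slice), `normalized`,
#'   `capture` (wildcard text or `NA`).
#' @examples
#' tab <- load_default_rules()
#' normalize_expression("patients with BRAF V600E mutation", tab)
#' @export
normalize_expression <- function(text, table) {
  out <- data.frame(start = integer(), end = integer(), surface = character(),
                    normalized = character(), capture = character())
  if (is.na(text) || !nzchar(text)) return(out)
  tk <- tokenize(text)
  toks <- tolower(tk$token)
  pats <- strsplit(normalize_surface(table$surface), " ", fixed = TRUE)
  max_wild <- attr(table, "max_wildcard_tokens") %||% 6L
  pos <- 1L
  while (pos <= length(toks)) {
    best <- NULL
    for (r in seq_along(pats)) {
      m <- match_pattern_at(toks, pos, pats[[r]], max_wild)
      if (!is.null(m) && (is.null(best) || m$len > best$len)) {
        best <- m
        best$rule <- r
      }
    }
    if (is.null(best)) { pos <- pos + 1L; next }
    last <- pos + best$len - 1L
    cap <- NA_character_
    if (length(best$capture)) {
      cr <- best$capture[[1L]]
      cap <- substring(text, tk$start[cr[1L]] + 1L, tk$end[cr[2L]])
    }
    out <- rbind(out, data.frame(
      start = tk$start[pos], end = tk$end[last],
      surface = substring(text, tk$start[pos] + 1L, tk$end[last]),
      normalized = table$normalized[best$rule], capture = cap))
    pos <- last + 1L
  }
  out
}

#' Look up a single surface expression
#'
#' Exact (whitespace/case-normalized) lookup of one expression in the
#' table; wildcard slots match per [normalize_expression()].
#'
#' @param surface Expression to resolve.
#' @param table A `pgx_synonyms` table.
#' @return The normalized relation name, or `NA_character_` if no rule
#'   covers the whole expression.
#' @export
lookup_expression <- function(surface, table) {
  m <- normalize_expression(surface, table)
  tk <- tokenize(surface)
  if (nrow(m) == 1L && m$start[1L] == tk$start[1L] &&
      m$end[1L] == tk$end[nrow(tk)])
    m$normalized[1L]
  else NA_character_
}
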