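# Triple store over the knowledge-model registry: validated insertion,
# relationship-group counting, the risk-factor queries (drugs from disease
# and gene; dosage from drug conditioned on adverse reaction or
# population), and export/import.

#' Create an empty triple store
#'
#' A store holds an entity collection, a triple table, and the registry the
#' triples are validated against. Every stored triple passes
#' [validate_triple()]; exact duplicates are ignored.
#'
#' @param registry A `pgx_registry`.
#' @return An object of class `pgx_store`.
#' @export
triple_store <- function(registry = build_default_registry()) {
  structure(list(entities = list(),
                 triples = data.frame(subject = character(),
                                      rid = character(),
                                      object = character(),
                                      doc_id = character(),
                                      section = character()),
                 registry = registry),
            class = "pgx_store")
}

#' @export
print.pgx_store <- function(x, ...) {
  cat(sprintf("<pgx_store: %d entities, %d triples>\n", length(x$entities),
              nrow(x$triples)))
  invisible(x)
}

#' Add entities to a store
#'
#' Entities are validated against the store's registry; duplicate eids are
#' rejected.
#'
#' @param store A `pgx_store`.
#' @param entities A `pgx_entity` or list of them.
#' @return The updated store.
#' @export
add_entities <- function(store, entities) {
  if (inherits(entities, "pgx_entity")) entities <- list(entities)
  for (e in entities) {
    v <- validate_entity(e, store$registry)
    if (length(v)) stop("invalid entity '", e$eid, "': ",
                        paste(v, collapse = "; "))
    if (e$eid %in% names(store$entities))
      stop("duplicate eid: '", e$eid, "'")
    store$entities[[e$eid]] <- e
  }
  store
}

entity_type_of <- function(store, eids) {
  idx <- match(eids, names(store$entities))
  vapply(idx, function(i) if (is.na(i)) NA_character_
         else store$entities[[i]]$semantic_type, "")
}

#' Add triples to a store
#'
#' Validates each (subject, relation, object) triple against the registry
#' (domain/range and entity resolution) and appends the valid ones. Exact
#' duplicates — already stored or repeated in the batch — are ignored with
#' a message. Any validation failure aborts the whole batch with a report.
#'
#' @param store A `pgx_store`.
#' @param triples Data frame with columns `subject`, `rid` (rid or
#'   relationship name), `object`, and optional `doc_id`, `section`
#'   provenance columns.
#' @return The updated store.
#' @export
add_triples <- function(store, triples) {
  if (nrow(triples) == 0L) return(store)
  if (is.null(triples$doc_id)) triples$doc_id <- NA_character_
  if (is.null(triples$section)) triples$section <- NA_character_
  # resolve relationship names to rids
  rel_names <- vapply(store$registry$relations, `[[`, "", "relationship")
  by_name <- match(triples$rid, rel_names)
  triples$rid <- ifelse(triples$rid %in% names(store$registry$relations),
                        triples$rid,
                        names(store$registry$relations)[by_name])
  report <- character()
  if (anyNA(triples$rid))
    report <- c(report, "unregistered relation(s) in batch")
  st <- entity_type_of(store, triples$subject)
  ot <- entity_type_of(store, triples$object)
  if (anyNA(st))
    report <- c(report, paste("unknown subject entity:",
                              paste(unique(triples$subject[is.na(st)]), collapse = ", ")))
  if (anyNA(ot))
    report <- c(report, paste("unknown object entity:",
                              paste(unique(triples$object[is.na(ot)]), collapse = ", ")))
  if (!length(report)) {
    dom <- vapply(store$registry$relations[triples$rid], `[[`, "", "domain")
    rng <- vapply(store$registry$relations[triples$rid], `[[`, "", "range")
    bad <- which(st != dom | ot != rng | triples$subject == triples$object)
    for (i in head(bad, 20L))
      report <- c(report, paste(collapse = "; ", validate_triple(
        store$entities[[triples$subject[i]]], triples$rid[i],
        store$entities[[triples$object[i]]], store$registry)))
  }
  if (length(report))
    stop("invalid triple batch:\n  ", paste(report, collapse = "\n  "))
  key <- function(df) paste(df$subject, df$rid, df$object, sep = "\r")
  new <- !duplicated(key(triples)) & !(key(triples) %in% key(store$triples))
  if (any(!new))
    message("add_triples: ignored ", sum(!new), " duplicate triple(s)")
  store$triples <- rbind(store$triples,
                         triples[new, c("subject", "rid", "object", "doc_id",
                                        "section")])
  rownames(store$triples) <- NULL
  store
}

#' @rdname add_triples
#' @param subject,rid,object,doc_id,section Fields of a single triple.
#' @export
add_triple <- function(store, subject, rid, object, doc_id = NA_character_,
                       section = NA_character_) {
  add_triples(store, data.frame(subject = subject, rid = rid, object = object,
                                doc_id = doc_id, section = section))
}

#' Count triples by relationship group
#'
#' Groups triples by the ordered (domain, range) semantic-type pair of
#' their relation — the relationship groups of the model (drug–drug,
#' drug–adverse reaction, drug–dosage, ...). The total always equals the
#' store size.
#'
#' @param store A `pgx_store`.
#' @return A list of class `pgx_group_counts`: `counts` data frame
#'   (`subject_type`, `object_type`, `count`, descending), `total`.
#' @export
group_counts <- function(store) {
  if (nrow(store$triples) == 0L) {
    return(structure(list(counts = data.frame(subject_type = character(),
                                              object_type = character(),
                                              count = integer()),
                          total = 0L), class = "pgx_group_counts"))
  }
  dom <- vapply(store$registry$relations[store$triples$rid], `[[`, "", "domain")
  rng <- vapply(store$registry$relations[store$triples$rid], `[[`, "", "range")
  tab <- as.data.frame(table(subject_type = dom, object_type = rng),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, ]
  tab <- tab[order(-tab$Freq, tab$subject_type, tab$object_type), ]
  structure(list(counts = data.frame(subject_type = tab$subject_type,
                                     object_type = tab$object_type,
                                     count = as.integer(tab$Freq),
                                     row.names = NULL),
                 total = nrow(store$triples)),
            class = "pgx_group_counts")
}

#' @export
print.pgx_group_counts <- function(x, ...) {
  cat(sprintf("<pgx_group_counts: %d triples in %d group(s)>\n", x$total,
              nrow(x$counts)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

relations_between <- function(store, domain, range) {
  keep <- vapply(store$registry$relations, function(r)
    r$domain == domain && r$range == range, NA)
  names(store$registry$relations)[keep]
}

require_entity <- function(store, eid, what) {
  if (!eid %in% names(store$entities))
    stop("unknown ", what, " entity: '", eid, "'")
  invisible(eid)
}

#' Query drugs by disease and/or gene context
#'
#' The drug-selection query of the model: drugs indicated for the disease
#' (a Drug-to-Disease triple such as `treats`) and/or linked to the mutated
#' gene (any Drug-to-Gene or Gene-to-Drug relation, e.g. target or
#' biomarker links). When both are given, both conditions must hold.
#' Results are sorted by eid for determinism.
#'
#' @param store A `pgx_store`.
#' @param disease,gene Entity ids; at least one must be given.
#' @param treats_only If `TRUE`, the disease condition uses only the
#'   `treats` relation rather than all Drug-to-Disease relations.
#' @return Character vector of Drug entity ids.
#' @export
query_drugs <- function(store, disease = NULL, gene = NULL,
                        treats_only = FALSE) {
  if (is.null(disease) && is.null(gene))
    stop("at least one of disease or gene must be given")
  tr <- store$triples
  cand <- NULL
  if (!is.null(disease)) {
    require_entity(store, disease, "disease")
    rels <- if (treats_only) find_relation(store$registry, "treats")$rid
            else relations_between(store, "Drug", "Disease")
    cand <- unique(tr$subject[tr$rid %in% rels & tr$object == disease])
  }
  if (!is.null(gene)) {
    require_entity(store, gene, "gene")
    d2g <- relations_between(store, "Drug", "Gene")
    g2d <- relations_between(store, "Gene", "Drug")
    linked <- unique(c(tr$subject[tr$rid %in% d2g & tr$object == gene],
                       tr$object[tr$rid %in% g2d & tr$subject == gene]))
    cand <- if (is.null(cand)) linked else intersect(cand, linked)
  }
  cand <- cand[entity_type_of(store, cand) == "Drug"]
  sort(cand)
}

#' Query dosage for a drug, optionally conditioned on context
#'
#' The dosage-selection query: the default dosage instructions of a drug
#' are its Drug-to-DrugUse triples (`have_dosage`, `has_routine_dosage`).
#' Risk factors act independently and override the default: an adverse
#' reaction selects adjusted instructions through the drug's
#' `has_adverse_reaction` link and the reaction's `adjusts_dosage`-family
#' triples; a population selects the drug's `has_population_dosage`
#' instructions (restricted to the population's term when the DrugUse
#' entity records an `ApplicablePopulation` attribute). Contextual rows
#' outrank (precede) default rows.
#'
#' @param store A `pgx_store`.
#' @param drug Drug entity id (required).
#' @param adverse_reaction,population Optional context entity ids.
#' @return Data frame: `drug_use` (eid), `term` (instruction text),
#'   `context` (`"adverse_reaction"`, `"population"` or `"default"`),
#'   `condition` (the context eid or `NA`).
#' @export
query_dosage <- function(store, drug, adverse_reaction = NULL,
                         population = NULL) {
  if (missing(drug) || is.null(drug)) stop("drug is required")
  require_entity(store, drug, "drug")
  tr <- store$triples
  rows <- function(du, context, condition) data.frame(
    drug_use = du,
    term = vapply(store$entities[du], `[[`, "", "term"),
    context = context, condition = condition, row.names = NULL)
  out <- rows(character(), character(), character())
  if (!is.null(adverse_reaction)) {
    require_entity(store, adverse_reaction, "adverse reaction")
    has_ar <- any(tr$rid %in% relations_between(store, "Drug", "AdverseReaction") &
                    tr$subject == drug & tr$object == adverse_reaction)
    if (has_ar) {
      adj <- relations_between(store, "AdverseReaction", "DrugUse")
      du <- unique(tr$object[tr$rid %in% adj & tr$subject == adverse_reaction])
      if (length(du)) out <- rbind(out, rows(sort(du), "adverse_reaction",
                                             adverse_reaction))
    }
  }
  if (!is.null(population)) {
    require_entity(store, population, "population")
    pd <- find_relation(store$registry, "has_population_dosage")$rid
    du <- unique(tr$object[tr$rid == pd & tr$subject == drug])
    pop_term <- store$entities[[population]]$term
    keep <- vapply(du, function(id) {
      ap <- store$entities[[id]]$attributes["ApplicablePopulation"]
      is.na(ap) || identical(unname(ap), pop_term)
    }, NA)
    du <- du[keep]
    if (length(du)) out <- rbind(out, rows(sort(du), "population", population))
  }
  def <- c(find_relation(store$registry, "have_dosage")$rid,
           find_relation(store$registry, "has_routine_dosage")$rid)
  du <- unique(tr$object[tr$rid %in% def & tr$subject == drug])
  if (length(du)) out <- rbind(out, rows(sort(du), "default", NA_character_))
  out
}

#' Export a triple store
#'
#' Three serializations: `"tsv"` (subject, relationship, object, doc_id,
#' section; header line; re-importable via [import_triples_tsv()] with
#' byte-identical re-export), `"ntriples"` (W3C N-Triples with IRIs minted
#' deterministically from eids/rids under `base`), and `"json"` (triples
#' grouped by relationship group, mirroring a downloadable data-set
#' layout).
#'
#' @param store A `pgx_store`.
#' @param format One of `"tsv"`, `"ntriples"`, `"json"`.
#' @param base IRI base prefix for N-Triples minting.
#' @return A single character scalar (the serialized payload).
#' @export
export_store <- function(store, format = c("tsv", "ntriples", "json"),
                         base = "http://example.org/pgx/") {
  format <- match.arg(format)
  tr <- store$triples
  if (format == "tsv") {
    rel <- vapply(store$registry$relations[tr$rid], `[[`, "", "relationship")
    if (nrow(tr) == 0L) rel <- character()
    lines <- c(paste("subject", "relationship", "object", "doc_id", "section",
                     sep = "\t"),
               if (nrow(tr)) paste(tr$subject, rel, tr$object,
                                   ifelse(is.na(tr$doc_id), "", tr$doc_id),
                                   ifelse(is.na(tr$section), "", tr$section),
                                   sep = "\t"))
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  if (format == "ntriples") {
    if (nrow(tr) == 0L) return("")
    iri <- function(kind, id) paste0("<", base, kind, "/", id, ">")
    return(paste0(paste(iri("entity", tr$subject), iri("relation", tr$rid),
                        iri("entity", tr$object), ".\n", sep = " "),
                  collapse = ""))
  }
  gc_ <- group_counts(store)
  dom <- vapply(store$registry$relations[tr$rid], `[[`, "", "domain")
  rng <- vapply(store$registry$relations[tr$rid], `[[`, "", "range")
  rel <- vapply(store$registry$relations[tr$rid], `[[`, "", "relationship")
  groups <- lapply(seq_len(nrow(gc_$counts)), function(i) {
    g <- gc_$counts[i, ]
    sel <- which(dom == g$subject_type & rng == g$object_type)
    list(group = paste0(g$subject_type, "-", g$object_type),
         count = g$count,
         triples = lapply(sel, function(k)
           list(subject = tr$subject[k], relationship = rel[k],
                object = tr$object[k])))
  })
  as.character(jsonlite::toJSON(list(total = gc_$total, groups = groups),
                                auto_unbox = TRUE, pretty = TRUE))
}

#' Import triples from TSV into a store
#'
#' Inverse of the TSV export: entities must already be registered in the
#' store.
#'
#' @param store A `pgx_store` holding the entities.
#' @param text TSV payload as produced by `export_store(format = "tsv")`.
#' @return The updated store.
#' @export
import_triples_tsv <- function(store, text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(store)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(k) vapply(parts, function(p) if (length(p) >= k) p[k] else "", "")
  df <- data.frame(subject = get(1L), rid = get(2L), object = get(3L),
                   doc_id = get(4L), section = get(5L))
  df$doc_id[!nzchar(df$doc_id)] <- NA_character_
  df$section[!nzchar(df$section)] <- NA_character_
  add_triples(store, df)
}
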