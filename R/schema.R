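#' @useDynLib pgxkit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim runif setNames
#' @importFrom utils head read.delim
NULL

#' Semantic-type definition
#'
#' A semantic type names one of the knowledge model's entity categories
#' (Drug, Gene, Disease, AdverseReaction, Population, DrugUse) and fixes the
#' inventory of attributes an entity of that type may carry.
#'
#' @param name Type name (unique within a registry).
#' @param attributes Character vector of permitted attribute names, no
#'   duplicates.
#' @return An object of class `pgx_semantic_type`.
#' @export
semantic_type <- function(name, attributes = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  attributes <- as.character(attributes)
  if (anyDuplicated(attributes))
    stop("duplicate attribute names for semantic type '", name, "'")
  structure(list(name = name, attributes = attributes),
            class = "pgx_semantic_type")
}

#' Typed entity record
#'
#' An entity is the model's atomic node: a unique identifier, a required
#' preferred term, an optional provenance source, a semantic type, and a set
#' of typed attributes. Identifier and term are required; validation against
#' a registry is performed by [validate_entity()], not at construction.
#'
#' @param eid Entity identifier (conventionally source-prefixed, e.g.
#'   `"db:trametinib"`, `"syn:d001"`).
#' @param term Preferred surface term.
#' @param semantic_type Name of a semantic type.
#' @param source Provenance label such as `"DrugBank"`, `"RxNorm"`, or a
#'   corpus id. Optional.
#' @param attributes Named character vector or named list of attribute
#'   values.
#' @return An object of class `pgx_entity`.
#' @export
entity <- function(eid, term, semantic_type, source = NA_character_,
                   attributes = character()) {
  attributes <- unlist(attributes)
  if (is.null(attributes)) attributes <- character()
  structure(list(eid = as.character(eid), term = as.character(term),
                 source = as.character(source),
                 semantic_type = as.character(semantic_type),
                 attributes = attributes),
            class = "pgx_entity")
}

#' @export
print.pgx_entity <- function(x, ...) {
  cat(sprintf("<pgx_entity %s: \"%s\" [%s]%s>\n", x$eid, x$term,
              x$semantic_type,
              if (length(x$attributes)) paste0(", ", length(x$attributes),
                                               " attribute(s)") else ""))
  invisible(x)
}

#' Relation definition
#'
#' A relation-registry record: identifier, relation name, the semantic types
#' permitted as subject (domain) and object (range), an optional free-text
#' definition, and a hierarchical tree number placing the relation at the
#' first or second level of the relation taxonomy.
#'
#' @param rid Relation identifier.
#' @param relationship Relation name, e.g. `"treats"`.
#' @param domain,range Semantic-type names constraining subject and object.
#' @param definition Free-text definition (optional).
#' @param tree_number Dotted hierarchy code, e.g. `"R01"` (first level) or
#'   `"R01.01"` (second level).
#' @param reconstructed Logical flag: `TRUE` marks relations completed from
#'   the relationship-group inventory rather than a published definition.
#' @param inverse_of Optional relationship name this relation inverts.
#' @return An object of class `pgx_relation_def`.
#' @export
relation_def <- function(rid, relationship, domain, range, definition = "",
                         tree_number = rid, reconstructed = FALSE,
                         inverse_of = NA_character_) {
  req <- c(rid = rid, relationship = relationship, domain = domain,
           range = range, tree_number = tree_number)
  bad <- names(req)[!nzchar(as.character(req)) | is.na(req)]
  if (length(bad))
    stop("relation_def: required field(s) empty: ", paste(bad, collapse = ", "))
  relation_level(tree_number)  # validates the code grammar
  structure(list(rid = as.character(rid),
                 relationship = as.character(relationship),
                 domain = as.character(domain), range = as.character(range),
                 definition = as.character(definition),
                 tree_number = as.character(tree_number),
                 reconstructed = isTRUE(reconstructed),
                 inverse_of = as.character(inverse_of)),
            class = "pgx_relation_def")
}

#' Hierarchy level of a relation tree number
#'
#' Tree numbers are dotted codes: a code with no separator is first-level
#' (`"R03"` -> 1), one separator is second-level (`"R03.01"` -> 2). The
#' taxonomy has exactly two levels; deeper codes are rejected.
#'
#' @param tree_number Code string.
#' @return Integer level, 1 or 2.
#' @export
relation_level <- function(tree_number) {
  if (length(tree_number) != 1L || is.na(tree_number) ||
      !grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)?$", tree_number))
    stop("malformed tree number: '", tree_number,
         "' (expected CODE or CODE.CODE)")
  if (grepl("\\.", tree_number)) 2L else 1L
}

#' Build a knowledge-model registry from a config file
#'
#' Reads the single human-editable YAML config that defines semantic types,
#' their attribute inventories, and the relation registry with tree numbers.
#' The shipped default mirrors the model's published inventory: 6 semantic
#' types and 26 relations (14 first-level, 12 second-level), of which the
#' unpublished remainder is flagged `reconstructed`.
#'
#' @param path Path to a registry YAML file; defaults to the shipped config.
#' @return An object of class `pgx_registry` with elements `semantic_types`
#'   (named list of [semantic_type()]) and `relations` (named-by-rid list of
#'   [relation_def()]).
#' @examples
#' reg <- build_default_registry()
#' length(reg$relations)
#' @export
load_registry <- function(path) {
  cfg <- yaml::read_yaml(path)
  sts <- lapply(cfg$semantic_types, function(s)
    semantic_type(s$name, unlist(s$attributes)))
  names(sts) <- vapply(sts, `[[`, "", "name")
  if (anyDuplicated(names(sts)))
    stop("duplicate semantic type names in registry config")
  rels <- lapply(cfg$relations, function(r)
    relation_def(r$rid, r$relationship, r$domain, r$range,
                 definition = r$definition %||% "",
                 tree_number = r$tree_number %||% r$rid,
                 reconstructed = isTRUE(r$reconstructed),
                 inverse_of = r$inverse_of %||% NA_character_))
  names(rels) <- vapply(rels, `[[`, "", "rid")
  if (anyDuplicated(names(rels))) stop("duplicate rids in registry config")
  reg <- structure(list(semantic_types = sts, relations = rels,
                        version = cfg$version %||% 1L),
                   class = "pgx_registry")
  issues <- check_registry(reg)
  if (length(issues)) stop("inconsistent registry config:\n  ",
                           paste(issues, collapse = "\n  "))
  reg
}

#' @rdname load_registry
#' @export
build_default_registry <- function() {
  load_registry(system.file("extdata", "registry.yaml", package = "pgxkit",
                            mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Structural self-consistency: domain/range closure, inverse mirroring.
check_registry <- function(reg) {
  issues <- character()
  st <- names(reg$semantic_types)
  for (r in reg$relations) {
    if (!r$domain %in% st)
      issues <- c(issues, sprintf("relation %s: unregistered domain '%s'",
                                  r$rid, r$domain))
    if (!r$range %in% st)
      issues <- c(issues, sprintf("relation %s: unregistered range '%s'",
                                  r$rid, r$range))
    if (!is.na(r$inverse_of)) {
      inv <- find_relation(reg, r$inverse_of)
      if (is.null(inv))
        issues <- c(issues, sprintf("relation %s: inverse '%s' not registered",
                                    r$rid, r$inverse_of))
      else if (inv$domain != r$range || inv$range != r$domain)
        issues <- c(issues, sprintf(
          "relation %s: inverse pair with %s does not mirror domain/range",
          r$rid, inv$rid))
    }
  }
  rn <- vapply(reg$relations, `[[`, "", "relationship")
  if (anyDuplicated(rn))
    issues <- c(issues, paste("duplicate relationship names:",
                              paste(unique(rn[duplicated(rn)]), collapse = ", ")))
  issues
}

#' @export
print.pgx_registry <- function(x, ...) {
  lv <- vapply(x$relations, function(r) relation_level(r$tree_number), 0L)
  cat(sprintf(paste0("<pgx_registry: %d semantic types, %d relations ",
                     "(%d first-level, %d second-level)>\n"),
              length(x$semantic_types), length(x$relations),
              sum(lv == 1L), sum(lv == 2L)))
  invisible(x)
}

#' Look up a relation by rid or relationship name
#'
#' @param reg A `pgx_registry`.
#' @param key A rid (e.g. `"R01"`) or relationship name (e.g. `"treats"`).
#' @return The matching `pgx_relation_def`, or `NULL` if absent.
#' @export
find_relation <- function(reg, key) {
  if (key %in% names(reg$relations)) return(reg$relations[[key]])
  for (r in reg$relations) if (r$relationship == key) return(r)
  NULL
}

#' Summarize a registry's relations as a data frame
#'
#' @param reg A `pgx_registry`.
#' @return A data frame with one row per relation: rid, relationship, domain,
#'   range, tree_number, level, reconstructed.
#' @export
registry_relations <- function(reg) {
  data.frame(
    rid = vapply(reg$relations, `[[`, "", "rid"),
    relationship = vapply(reg$relations, `[[`, "", "relationship"),
    domain = vapply(reg$relations, `[[`, "", "domain"),
    range = vapply(reg$relations, `[[`, "", "range"),
    tree_number = vapply(reg$relations, `[[`, "", "tree_number"),
    level = vapply(reg$relations, function(r) relation_level(r$tree_number), 0L),
    reconstructed = vapply(reg$relations, `[[`, NA, "reconstructed"),
    row.names = NULL)
}

#' Serialize a registry back to its YAML config format
#'
#' `write_registry()` followed by [load_registry()] reproduces the registry
#' (round-trip identity), so curator edits and programmatic edits share one
#' format.
#'
#' @param reg A `pgx_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(reg, path) {
  cfg <- list(
    version = reg$version,
    semantic_types = lapply(unname(reg$semantic_types), function(s)
      list(name = s$name, attributes = as.list(s$attributes))),
    relations = lapply(unname(reg$relations), function(r) {
      out <- list(rid = r$rid, relationship = r$relationship,
                  domain = r$domain, range = r$range,
                  definition = r$definition, tree_number = r$tree_number)
      if (r$reconstructed) out$reconstructed <- TRUE
      if (!is.na(r$inverse_of)) out$inverse_of <- r$inverse_of
      out
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Validate an entity against a registry
#'
#' Checks the structural invariants of the entity model: non-empty
#' identifier and term (both required), a registered semantic type, and
#' attribute keys restricted to the type's attribute inventory. Violations
#' are reported, not thrown.
#'
#' @param e A [entity()].
#' @param reg A `pgx_registry`.
#' @return Character vector of violation messages; empty means valid.
#' @examples
#' reg <- build_default_registry()
#' e <- entity("db:DB08911", "trametinib", "Drug",
#'             attributes = c(DrugName = "trametinib"))
#' validate_entity(e, reg)  # character(0)
#' @export
validate_entity <- function(e, reg) {
  v <- character()
  if (is.na(e$eid) || !nzchar(e$eid))
    v <- c(v, "EID is required and must be non-empty")
  if (is.na(e$term) || !nzchar(e$term))
    v <- c(v, "TERM is required and must be non-empty")
  st <- reg$semantic_types[[e$semantic_type]]
  if (is.null(st)) {
    v <- c(v, sprintf("semantic type '%s' is not registered", e$semantic_type))
  } else if (length(e$attributes)) {
    bad <- setdiff(names(e$attributes), st$attributes)
    for (a in bad)
      v <- c(v, sprintf("attribute '%s' is not in the %s attribute set", a,
                        st$name))
  }
  v
}

#' Validate a (subject, relation, object) triple against a registry
#'
#' A triple is valid when its relation is registered, the subject entity's
#' semantic type equals the relation's domain, and the object entity's type
#' equals the relation's range. Subject and object are assumed individually
#' valid (see [validate_entity()]).
#'
#' @param subject,object `pgx_entity` objects.
#' @param rid Relation id or relationship name.
#' @param reg A `pgx_registry`.
#' @return Character vector of violation messages; empty means valid.
#' @export
validate_triple <- function(subject, rid, object, reg) {
  rel <- find_relation(reg, rid)
  if (is.null(rel)) return(sprintf("unregistered relation '%s'", rid))
  v <- character()
  if (subject$semantic_type != rel$domain)
    v <- c(v, sprintf("domain violation: %s subject '%s' for relation %s (domain %s)",
                      subject$semantic_type, subject$eid, rel$relationship,
                      rel$domain))
  if (object$semantic_type != rel$range)
    v <- c(v, sprintf("range violation: %s object '%s' for relation %s (range %s)",
                      object$semantic_type, object$eid, rel$relationship,
                      rel$range))
  if (identical(subject$eid, object$eid))
    v <- c(v, sprintf("reflexive triple: subject and object are both '%s'",
                      subject$eid))
  v
}
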