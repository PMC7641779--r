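# Readers for the three source dialects: structured product label (SPL)
# XML for sectioned label text, DrugBank-style drug records for drug
# attributes, and RxNorm RRF pipe-delimited files for dose-form concepts
# and relations. Parsers target the minimal field subset the knowledge
# model consumes and ignore unknown elements, so schema drift in the
# sources does not break them.

spl_section_lookup <- function(title) {
  hit <- match(tolower(gsub("\\s+", " ", trimws(title))),
               tolower(pgx_label_sections()))
  if (is.na(hit)) NA_character_ else pgx_label_sections()[hit]
}

#' Parse a structured product label (SPL) XML document
#'
#' Extracts the document id and the five target label sections, identified
#' by normalized case-insensitive title match ("Indications and Usage",
#' "Dosage and Administration", "Use in Specific Populations", "Warnings
#' and Precautions", "Adverse Reactions"). Sections with other titles are
#' ignored; missing target sections are reported via a message. Section
#' text is whitespace-normalized.
#'
#' @param xml_text SPL XML as a string, or a file path.
#' @return A `pgx_document`.
#' @export
parse_spl <- function(xml_text) {
  doc <- xml2::read_xml(xml_text)  # malformed XML -> parse error w/ location
  xml2::xml_ns_strip(doc)
  id_node <- xml2::xml_find_first(doc, ".//id")
  doc_id <- if (inherits(id_node, "xml_missing")) "unknown"
            else xml2::xml_attr(id_node, "root")
  secs <- xml2::xml_find_all(doc, ".//section")
  names_out <- character(); text_out <- character()
  for (s in secs) {
    title <- xml2::xml_text(xml2::xml_find_first(s, "./title"))
    canon <- spl_section_lookup(title)
    if (is.na(canon)) next
    txt <- xml2::xml_text(xml2::xml_find_first(s, "./text"))
    names_out <- c(names_out, canon)
    text_out <- c(text_out, gsub("\\s+", " ", trimws(txt)))
  }
  missing <- setdiff(pgx_label_sections(), names_out)
  if (length(missing))
    message("parse_spl(", doc_id, "): missing section(s): ",
            paste(missing, collapse = "; "))
  if (!length(names_out))
    stop("no recognizable label sections in document '", doc_id, "'")
  document(doc_id, setNames(text_out, names_out))
}

#' Validate a CAS registry number
#'
#' Format `d{2,7}-d{2}-d` with the standard check digit: the sum of each
#' digit times its 1-based position from the right (excluding the check
#' digit), modulo 10.
#'
#' @param cas Character vector of candidate CAS numbers.
#' @return Logical vector (`NA` in, `NA` out).
#' @export
cas_valid <- function(cas) {
  vapply(cas, function(x) {
    if (is.na(x) || !nzchar(x)) return(NA)
    if (!grepl("^[0-9]{2,7}-[0-9]{2}-[0-9]$", x)) return(FALSE)
    d <- as.integer(strsplit(gsub("-", "", x), "")[[1L]])
    n <- length(d)
    body <- d[-n]
    sum(body * rev(seq_along(body))) %% 10L == d[n]
  }, NA, USE.NAMES = FALSE)
}

#' Parse DrugBank-style drug records
#'
#' One record per `<drug>` element; absent fields are left empty (`NA`),
#' molecular weight is parsed as a decimal, approval status is taken from
#' the record's group memberships, and the pharmacology indication from
#' the record's indication text. CAS numbers failing the checksum are kept
#' but flagged.
#'
#' @param xml_text DrugBank-dialect XML string or file path.
#' @return A data frame of class `pgx_drug_records`: `name`, `description`,
#'   `chemical_formula`, `molecular_weight`, `approval_status`, `cas`,
#'   `unii`, `pharmacology_indication`, `cas_ok`.
#' @export
parse_drugbank <- function(xml_text) {
  doc <- xml2::read_xml(xml_text)
  xml2::xml_ns_strip(doc)
  drugs <- xml2::xml_find_all(doc, ".//drug")
  field <- function(node, xpath) {
    v <- xml2::xml_text(xml2::xml_find_first(node, xpath))
    if (is.na(v) || !nzchar(trimws(v))) NA_character_ else trimws(v)
  }
  rows <- lapply(drugs, function(d) {
    groups <- xml2::xml_text(xml2::xml_find_all(d, ".//groups/group"))
    data.frame(
      name = field(d, "./name"),
      description = field(d, "./description"),
      chemical_formula = field(d, "./chemical-formula"),
      molecular_weight = suppressWarnings(
        as.numeric(field(d, "./average-molecular-weight"))),
      approval_status = if (length(groups)) paste(groups, collapse = ",")
                        else NA_character_,
      cas = field(d, "./cas-number"),
      unii = field(d, "./unii"),
      pharmacology_indication = field(d, "./indication"))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(name = character())
  if (nrow(out) && any(is.na(out$name) | !nzchar(out$name)))
    stop("drug record with empty name")
  out$cas_ok <- cas_valid(out$cas)
  if (any(out$cas_ok %in% FALSE))
    message("parse_drugbank: ", sum(out$cas_ok %in% FALSE),
            " record(s) with invalid CAS checksum (kept, flagged)")
  class(out) <- c("pgx_drug_records", "data.frame")
  out
}

parse_rrf_lines <- function(lines, n_fields, what) {
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "|", fixed = TRUE)
  ok <- lengths(parts) == n_fields
  errors <- character()
  if (any(!ok))
    errors <- sprintf("%s line %d: expected %d fields, got %d", what,
                      which(!ok), n_fields, lengths(parts)[!ok])
  list(parts = parts[ok], errors = errors)
}

#' Parse RxNorm RRF concept and relation files
#'
#' Pipe-delimited per the RRF convention: concept lines (RXNCONSO layout,
#' 18 fields) keyed by concept id with name, term type and source; relation
#' lines (RXNREL layout, 16 fields) filtered to the dose-form pair
#' `has_dose_form` / `dose_form_of`. A line with the wrong field count is
#' reported with its line number and skipped; parsing continues.
#'
#' @param conso_lines Character vector of RXNCONSO-style lines.
#' @param rel_lines Character vector of RXNREL-style lines.
#' @return List: `concepts` (data frame `rxcui`, `name`, `tty`, `sab`),
#'   `dose_form_relations` (data frame `source_concept_id`,
#'   `target_concept_id`, `relation_name`), `errors` (character).
#' @export
parse_rxnorm_rrf <- function(conso_lines, rel_lines) {
  co <- parse_rrf_lines(conso_lines, 18L, "RXNCONSO")
  re <- parse_rrf_lines(rel_lines, 16L, "RXNREL")
  errors <- c(co$errors, re$errors)
  if (length(errors)) message("parse_rxnorm_rrf: ", length(errors),
                              " malformed line(s) skipped")
  concepts <- data.frame(
    rxcui = vapply(co$parts, `[[`, "", 1L),
    name = vapply(co$parts, `[[`, "", 15L),
    tty = vapply(co$parts, `[[`, "", 13L),
    sab = vapply(co$parts, `[[`, "", 12L))
  rela <- vapply(re$parts, `[[`, "", 8L)
  keep <- rela %in% c("has_dose_form", "dose_form_of")
  rels <- data.frame(
    source_concept_id = vapply(re$parts, `[[`, "", 1L)[keep],
    target_concept_id = vapply(re$parts, `[[`, "", 5L)[keep],
    relation_name = rela[keep])
  list(concepts = concepts, dose_form_relations = rels, errors = errors)
}

slug <- function(x) gsub("[^a-z0-9]+", "_", tolower(x))

#' Convert parsed source records to knowledge-model entities
#'
#' `records_to_entities()` turns DrugBank-style records into Drug entities
#' (source `"DrugBank"`, eids `db:<slug>`) carrying the drug attribute set.
#' `rxnorm_to_entities()` turns dose-form concepts into DrugUse entities
#' (source `"RxNorm"`, eids `rx:<rxcui>`), ingredient concepts into Drug
#' entities, and dose-form relations into triple candidates. All produced
#' entities pass [validate_entity()].
#'
#' @param records A `pgx_drug_records` frame from [parse_drugbank()].
#' @param registry A `pgx_registry`.
#' @return `records_to_entities()`: list of `pgx_entity`.
#' @export
records_to_entities <- function(records, registry = build_default_registry()) {
  out <- lapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    vals <- c(DrugName = r$name, Description = r$description,
              ChemicalFormula = r$chemical_formula,
              MolecularWeight = if (is.na(r$molecular_weight)) NA_character_
                                else format(r$molecular_weight),
              DrugApprovalStatus = r$approval_status, CAS = r$cas,
              UNII = r$unii, PharmacologyIndication = r$pharmacology_indication)
    entity(paste0("db:", slug(r$name)), r$name, "Drug", source = "DrugBank",
           attributes = vals[!is.na(vals)])
  })
  for (e in out) {
    v <- validate_entity(e, registry)
    if (length(v)) stop("ingested entity failed validation: ",
                        paste(v, collapse = "; "))
  }
  out
}

#' @rdname records_to_entities
#' @param parsed Output of [parse_rxnorm_rrf()].
#' @return `rxnorm_to_entities()`: list with `entities` (DrugUse entities
#'   for dose-form concepts, Drug entities for ingredient concepts) and
#'   `triples` (candidate rows for [add_triples()]).
#' @export
rxnorm_to_entities <- function(parsed, registry = build_default_registry()) {
  con <- parsed$concepts
  rel <- parsed$dose_form_relations
  df_ids <- unique(c(
    rel$target_concept_id[rel$relation_name == "has_dose_form"],
    rel$source_concept_id[rel$relation_name == "dose_form_of"]))
  ents <- lapply(seq_len(nrow(con)), function(i) {
    c_ <- con[i, ]
    if (c_$rxcui %in% df_ids || c_$tty == "DF")
      entity(paste0("rx:", c_$rxcui), c_$name, "DrugUse", source = "RxNorm",
             attributes = c(DoseForm = c_$name))
    else
      entity(paste0("rx:", c_$rxcui), c_$name, "Drug", source = "RxNorm",
             attributes = c(DrugName = c_$name))
  })
  for (e in ents) {
    v <- validate_entity(e, registry)
    if (length(v)) stop("ingested entity failed validation: ",
                        paste(v, collapse = "; "))
  }
  triples <- data.frame(subject = paste0("rx:", rel$source_concept_id),
                        rid = rel$relation_name,
                        object = paste0("rx:", rel$target_concept_id))
  list(entities = ents, triples = triples)
}
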