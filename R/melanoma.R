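# Demonstration store for BRAF-mutant melanoma: the seven drugs and the
# curated core links (targets, dosage, adverse-reaction adjustments), with
# each relationship group filled to a requested size by clearly synthetic
# auxiliary entities ("syn:" prefix). The default group sizes reproduce
# the melanoma case breakdown (total 4846).

melanoma_drugs <- function() c("binimetinib", "cobimetinib", "dabrafenib",
                               "encorafenib", "nivolumab", "trametinib",
                               "vemurafenib")

#' Default melanoma relationship-group sizes
#'
#' The nine relationship-group sizes of the melanoma case (drug–drug 4713,
#' drug–adverse reaction 41, drug–dosage 30, adverse reaction–dosage 24,
#' drug–disease 22, drug–gene 7, drug–population 4, gene–mutation 2,
#' gene–disease 3; total 4846).
#'
#' @return Named integer vector.
#' @export
melanoma_group_sizes <- function() {
  c(drug_drug = 4713L, drug_adverse_reaction = 41L, drug_dosage = 30L,
    adverse_reaction_dosage = 24L, drug_disease = 22L, drug_gene = 7L,
    drug_population = 4L, gene_mutation = 2L, gene_disease = 3L)
}

#' Build the melanoma demonstration store
#'
#' Constructs a validated triple store for BRAF-mutant melanoma: the seven
#' case drugs, the BRAF gene with its V600E/V600K variants, curated target
#' and biomarker links (the three BRAF inhibitors target BRAF; the MEK
#' inhibitors target MAP2K1; nivolumab targets PDCD1), trametinib's default
#' dosage ("2 mg orally once daily") and its adverse-reaction adjustments
#' (fever or interstitial lung disease select permanent discontinuation),
#' then fills each relationship group to the requested size with synthetic
#' `syn:`-prefixed auxiliary entities so group arithmetic can be exercised
#' at full scale.
#'
#' @param group_sizes Named vector as in [melanoma_group_sizes()]. Pass a
#'   smaller set (e.g. all core sizes) for a lighter store.
#' @param registry The registry to validate against.
#' @return A `pgx_store`.
#' @examples
#' s <- melanoma_case_store(melanoma_group_sizes())
#' group_counts(s)$total  # 4846
#' @export
melanoma_case_store <- function(group_sizes = melanoma_group_sizes(),
                                registry = build_default_registry()) {
  gs <- melanoma_group_sizes()
  gs[names(group_sizes)] <- group_sizes
  store <- triple_store(registry)
  drugs <- paste0("db:", melanoma_drugs())
  ents <- c(
    lapply(melanoma_drugs(), function(d)
      entity(paste0("db:", d), d, "Drug", source = "DrugBank",
             attributes = c(DrugName = d, DrugApprovalStatus = "approved"))),
    list(
      entity("dm:melanoma", "melanoma", "Disease", source = "DailyMed",
             attributes = c(DiseaseName = "melanoma", Position = "skin")),
      entity("dm:BRAF", "BRAF", "Gene", source = "DailyMed",
             attributes = c(GeneName = "BRAF")),
      entity("dm:BRAF_V600E", "BRAF V600E", "Gene", source = "DailyMed",
             attributes = c(GeneName = "BRAF", Mutation = "V600E")),
      entity("dm:BRAF_V600K", "BRAF V600K", "Gene", source = "DailyMed",
             attributes = c(GeneName = "BRAF", Mutation = "V600K")),
      entity("dm:MAP2K1", "MAP2K1", "Gene", source = "DailyMed",
             attributes = c(GeneName = "MAP2K1")),
      entity("dm:PDCD1", "PDCD1", "Gene", source = "DailyMed",
             attributes = c(GeneName = "PDCD1")),
      entity("dm:fever", "fever", "AdverseReaction", source = "DailyMed"),
      entity("dm:ild", "interstitial lung disease", "AdverseReaction",
             source = "DailyMed"),
      entity("rx:du_trametinib_default", "2 mg orally once daily", "DrugUse",
             source = "RxNorm",
             attributes = c(DailyDose = "2 mg", Frequency = "once daily")),
      entity("rx:du_stop_permanently", "stop permanently", "DrugUse",
             source = "RxNorm"),
      entity("dm:pregnancy", "pregnancy", "Population", source = "DailyMed",
             attributes = c(ApplicablePopulation = "pregnancy")),
      entity("dm:pediatric", "pediatric", "Population", source = "DailyMed",
             attributes = c(PediatricUsePopulation = "pediatric"))))
  store <- add_entities(store, ents)

  tri <- function(s, r, o) data.frame(subject = s, rid = r, object = o)
  core <- rbind(
    tri(drugs, "treats", "dm:melanoma"),
    tri(c("db:dabrafenib", "db:encorafenib", "db:vemurafenib"), "targets_gene",
        "dm:BRAF"),
    tri(c("db:binimetinib", "db:cobimetinib", "db:trametinib"), "targets_gene",
        "dm:MAP2K1"),
    tri("db:nivolumab", "targets_gene", "dm:PDCD1"),
    tri("dm:BRAF", "have_mutation", c("dm:BRAF_V600E", "dm:BRAF_V600K")),
    tri("dm:BRAF", "causes", "dm:melanoma"),
    tri(c("dm:BRAF_V600E", "dm:BRAF_V600K"), "causes", "dm:melanoma"),
    tri("db:trametinib", "have_dosage", "rx:du_trametinib_default"),
    tri("db:trametinib", "has_adverse_reaction", c("dm:fever", "dm:ild")),
    tri(c("dm:fever", "dm:ild"), "discontinues_drug",
        "rx:du_stop_permanently"),
    tri("db:trametinib", "has_population_use", "dm:pregnancy"),
    tri("db:trametinib", "contraindicated_in", "dm:pediatric"))
  store <- add_triples(store, core)

  # fill each group to its target with synthetic auxiliary entities
  mint <- function(n, prefix, type, term_prefix) {
    if (n <= 0L) return(character())
    ids <- sprintf("syn:%s%04d", prefix, seq_len(n))
    lapply(seq_len(n), function(i)
      entity(ids[i], paste(term_prefix, i), type, source = "synthetic"))
  }
  fill <- function(store, pair_key, subjects, rel, prefix, type, term_prefix) {
    have <- group_counts(store)$counts
    gmap <- list(drug_drug = c("Drug", "Drug"),
                 drug_adverse_reaction = c("Drug", "AdverseReaction"),
                 drug_dosage = c("Drug", "DrugUse"),
                 adverse_reaction_dosage = c("AdverseReaction", "DrugUse"),
                 drug_disease = c("Drug", "Disease"),
                 drug_population = c("Drug", "Population"))
    pr <- gmap[[pair_key]]
    cur <- have$count[have$subject_type == pr[1L] & have$object_type == pr[2L]]
    need <- gs[[pair_key]] - (if (length(cur)) cur else 0L)
    if (need <= 0L) return(store)
    n_obj <- ceiling(need / length(subjects))
    objs <- mint(n_obj, prefix, type, term_prefix)
    store <- add_entities(store, objs)
    oid <- vapply(objs, `[[`, "", "eid")
    k <- seq_len(need)
    df <- data.frame(subject = subjects[(k - 1L) %% length(subjects) + 1L],
                     rid = rel,
                     object = oid[(k - 1L) %/% length(subjects) + 1L])
    add_triples(store, df)
  }
  store <- fill(store, "drug_drug", drugs, "interacts_with", "ddi_", "Drug",
                "co-reported drug")
  store <- fill(store, "drug_adverse_reaction", drugs, "has_adverse_reaction",
                "ar_", "AdverseReaction", "adverse reaction")
  store <- fill(store, "drug_dosage", drugs, "have_dosage", "du_", "DrugUse",
                "dosage instruction")
  store <- fill(store, "adverse_reaction_dosage", c("dm:fever", "dm:ild"),
                "adjusts_dosage", "adj_", "DrugUse", "adjusted instruction")
  store <- fill(store, "drug_disease", drugs, "prevents", "dis_", "Disease",
                "related neoplasm")
  store <- fill(store, "drug_population", drugs, "has_population_use", "pop_",
                "Population", "population")
  store
}
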