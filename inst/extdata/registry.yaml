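# Default pharmacogenomics knowledge-model registry.
# Semantic types carry their attribute inventories; relations carry
# domain/range constraints and a dotted tree number (no dot = first level,
# one dot = second level). Relations without a published definition are
# flagged reconstructed: true and carry placeholder definitions; curators
# can re-key tree numbers or extend the set here without code changes.
version: 1
semantic_types:
  - name: Drug
    attributes: [DrugName, Description, ChemicalFormula, MolecularWeight,
                 DrugApprovalStatus, CAS, UNII, PharmacologyIndication]
  - name: Gene
    attributes: [GeneName, Mutation]
  - name: Disease
    attributes: [DiseaseName, Position]
  - name: AdverseReaction
    attributes: []
  - name: Population
    attributes: [PediatricUsePopulation, ApplicablePopulation, Gender, Age, Race]
  - name: DrugUse
    attributes: [DailyDose, DoseForm, Frequency, TakeTimeFor, TakeWithMeal]
relations:
  # -- first level ------------------------------------------------------
  - rid: R01
    relationship: treats
    domain: Drug
    range: Disease
    definition: The drug is indicated for the disease.
    tree_number: R01
  - rid: R02
    relationship: interacts_with
    domain: Drug
    range: Drug
    definition: The two drugs have a clinically relevant interaction.
    tree_number: R02
    reconstructed: true
  - rid: R03
    relationship: have_dosage
    domain: Drug
    range: DrugUse
    definition: The drug has the stated dosage instruction.
    tree_number: R03
  - rid: R04
    relationship: has_adverse_reaction
    domain: Drug
    range: AdverseReaction
    definition: The drug can cause the adverse reaction.
    tree_number: R04
    reconstructed: true
  - rid: R05
    relationship: has_dose_form
    domain: Drug
    range: DrugUse
    definition: The drug product is supplied in the dose form.
    tree_number: R05
  - rid: R06
    relationship: dose_form_of
    domain: DrugUse
    range: Drug
    definition: The dose form belongs to the drug product.
    tree_number: R06
    inverse_of: has_dose_form
  - rid: R07
    relationship: have_mutation
    domain: Gene
    range: Gene
    definition: The gene carries the stated mutation (variant as entity).
    tree_number: R07
  - rid: R08
    relationship: causes
    domain: Gene
    range: Disease
    definition: Mutation of the gene causes or drives the disease.
    tree_number: R08
    reconstructed: true
  - rid: R09
    relationship: is_biomarker_of
    domain: Gene
    range: Drug
    definition: The gene is a pharmacogenomic biomarker for the drug.
    tree_number: R09
    reconstructed: true
  - rid: R10
    relationship: has_population_use
    domain: Drug
    range: Population
    definition: The drug has use guidance for the specific population.
    tree_number: R10
    reconstructed: true
  - rid: R11
    relationship: targets_gene
    domain: Drug
    range: Gene
    definition: The drug targets the gene product.
    tree_number: R11
    reconstructed: true
  - rid: R12
    relationship: adjusts_dosage
    domain: AdverseReaction
    range: DrugUse
    definition: Occurrence of the adverse reaction selects the adjusted dosage.
    tree_number: R12
    reconstructed: true
  - rid: R13
    relationship: has_symptom
    domain: Disease
    range: AdverseReaction
    definition: The disease presents with the sign or symptom.
    tree_number: R13
    reconstructed: true
  - rid: R14
    relationship: has_brand
    domain: Drug
    range: Drug
    definition: The ingredient is marketed under the brand product.
    tree_number: R14
    reconstructed: true
  # -- second level -----------------------------------------------------
  - rid: R01.01
    relationship: prevents
    domain: Drug
    range: Disease
    definition: The drug is indicated for prevention of the disease.
    tree_number: R01.01
    reconstructed: true
  - rid: R01.02
    relationship: relieves_symptoms_of
    domain: Drug
    range: Disease
    definition: The drug relieves signs and symptoms of the disease.
    tree_number: R01.02
    reconstructed: true
  - rid: R02.01
    relationship: synergized_by
    domain: Drug
    range: Drug
    definition: The drug is used in combination with the other drug.
    tree_number: R02.01
  - rid: R02.02
    relationship: antagonized_by
    domain: Drug
    range: Drug
    definition: Concurrent administration with the other drug is to be avoided.
    tree_number: R02.02
  - rid: R03.01
    relationship: has_routine_dosage
    domain: Drug
    range: DrugUse
    definition: The drug has the stated routine (recommended) dosage.
    tree_number: R03.01
    reconstructed: true
  - rid: R03.02
    relationship: has_population_dosage
    domain: Drug
    range: DrugUse
    definition: The drug has a dosage specific to a patient population.
    tree_number: R03.02
    reconstructed: true
  - rid: R09.01
    relationship: is_biomarker_efficacy_of
    domain: Gene
    range: Drug
    definition: The gene is a biomarker of efficacy for the drug.
    tree_number: R09.01
  - rid: R09.02
    relationship: is_biomarker_prognosis_of
    domain: Gene
    range: Drug
    definition: The gene is a biomarker of prognosis under the drug.
    tree_number: R09.02
  - rid: R10.01
    relationship: contraindicated_in
    domain: Drug
    range: Population
    definition: The drug is contraindicated in the population.
    tree_number: R10.01
    reconstructed: true
  - rid: R11.01
    relationship: inhibits
    domain: Drug
    range: Gene
    definition: The drug inhibits the gene product.
    tree_number: R11.01
    reconstructed: true
  - rid: R12.01
    relationship: reduces_dosage
    domain: AdverseReaction
    range: DrugUse
    definition: The adverse reaction selects a reduced dosage.
    tree_number: R12.01
    reconstructed: true
  - rid: R12.02
    relationship: discontinues_drug
    domain: AdverseReaction
    range: DrugUse
    definition: The adverse reaction requires stopping the drug.
    tree_number: R12.02
    reconstructed: true
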