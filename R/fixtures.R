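# Packaged Parkinson's disease fixture: the 25-drug indication set with
# PubChem CIDs and LINCS-membership flags, and the five Parkinson indication
# concept terms plus distractor diseases.  ATC codes are standard WHO codes
# for these drugs; the OMOP-style concept identifiers are synthetic
# placeholders (the real identifiers live in the upstream indication
# database and are not needed by the query logic).

#' Packaged Parkinson's disease drug-set fixture
#'
#' Builds a small knowledge graph around the curated Parkinson's disease
#' drug set: 25 drugs indicated for Parkinson-related concepts, all carrying
#' nervous-system (ATC "N") codes, of which 22 are LINCS perturbagens; the 5
#' Parkinson indication concepts plus 6 distractor diseases; signature stubs
#' (one per LINCS drug, single cell line) so that LINCS membership is
#' derivable from DRUG_SIGNATURE degree; and two decoy drugs — one indicated
#' for Parkinsonism but without a nervous-system ATC code, one nervous-system
#' drug indicated only for a distractor concept — so the ATC and concept
#' filters both have work to do.
#'
#' @return List with elements `kg` (the `kgap_graph`) and `query` (the
#'   [disease_query()] `"Parkinson"` with ATC prefix `"N"`).
#' @examples
#' fx <- table4_fixture()
#' ds <- select_drug_set(fx$kg, fx$query)
#' nrow(ds$drugs)
#' @export
table4_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "kgap",
                                 mustWork = TRUE)
  dr <- .read_tsv(ext("pd_drugs.tsv"))
  cc <- .read_tsv(ext("pd_concepts.tsv"))

  drugs <- data.frame(
    drug_id = paste0("DC", dr$struct_id),
    name = dr$name,
    pubchem_cid = as.integer(dr$pubchem_cid),
    atc_codes = dr$atc_codes,
    in_lincs = dr$in_lincs == "TRUE",
    stringsAsFactors = FALSE
  )
  # decoys: indicated for a matched concept but not ATC-N; ATC-N but
  # indicated only for a distractor concept
  decoys <- data.frame(
    drug_id = c("DCdecoy1", "DCdecoy2"),
    name = c("domperidone", "donepezil"),
    pubchem_cid = c(3151L, 3152L),
    atc_codes = c("A03FA03", "N06DA02"),
    in_lincs = c(TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  drugs <- rbind(drugs, decoys)

  concepts <- data.frame(concept_id = cc$concept_id, name = cc$name,
                         stringsAsFactors = FALSE)
  pd_concepts <- cc$concept_id[cc$is_query == "TRUE"]
  alz <- cc$concept_id[cc$name == "Alzheimer's disease"]

  indication <- rbind(
    data.frame(drug_id = paste0("DC", dr$struct_id),
               concept_id = pd_concepts[1], stringsAsFactors = FALSE),
    data.frame(drug_id = c("DC2105", "DC2429", "DCdecoy1"),
               concept_id = pd_concepts[2], stringsAsFactors = FALSE),
    data.frame(drug_id = c("DCdecoy2", "DC2392"),
               concept_id = alz, stringsAsFactors = FALSE)
  )

  lincs_drugs <- drugs$drug_id[drugs$in_lincs]
  signatures <- data.frame(
    signature_id = paste0("SIG_", lincs_drugs),
    cell_id = "HA1E",
    stringsAsFactors = FALSE
  )
  drug_signature <- data.frame(
    drug_id = lincs_drugs,
    signature_id = paste0("SIG_", lincs_drugs),
    stringsAsFactors = FALSE
  )
  cells <- data.frame(cell_id = "HA1E", name = "kidney epithelial cell line",
                      stringsAsFactors = FALSE)

  kg <- kgap_graph(
    drugs = drugs, genes = NULL, signatures = signatures, cells = cells,
    concepts = concepts, drug_signature = drug_signature,
    signature_gene = NULL, indication = indication
  )
  list(kg = kg, query = disease_query("Parkinson", atc_prefix = "N"))
}
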