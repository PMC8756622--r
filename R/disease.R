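# Disease query -> drug set.  A disease is specified by a case-insensitive
# substring matched against indication concept names, optionally restricted
# by an ATC code prefix on the drugs (level-1 letter "N" = nervous system).

#' Construct a disease query
#'
#' @param name_substring nonempty string matched case-insensitively against
#'   indication concept names (e.g. `"Parkinson"`).
#' @param atc_prefix optional ATC code prefix; a drug passes if any of its
#'   ATC codes starts with it (e.g. `"N"` for nervous-system drugs).  Drugs
#'   with no ATC codes fail an ATC-restricted query.
#' @param require_in_lincs if `TRUE`, restrict the drug set to drugs present
#'   in LINCS (those with at least one DRUG_SIGNATURE edge).
#' @return An object of class `kgap_disease_query`.
#' @export
disease_query <- function(name_substring, atc_prefix = NULL,
                          require_in_lincs = FALSE) {
  if (!is.character(name_substring) || length(name_substring) != 1L ||
      !nzchar(name_substring)) {
    stop("name_substring must be a nonempty string", call. = FALSE)
  }
  structure(
    list(name_substring = name_substring,
         atc_prefix = atc_prefix,
         require_in_lincs = isTRUE(require_in_lincs)),
    class = "kgap_disease_query"
  )
}

#' Match disease concepts by name substring
#'
#' Returns every Concept node whose name contains the substring,
#' case-insensitively, ordered by concept key for determinism.  An empty
#' result is valid.
#'
#' @param kg a `kgap_graph`.
#' @param name_substring substring to match (case-insensitive, literal).
#' @return Data frame of matching concept rows, ordered by `concept_id`.
#' @export
match_concepts <- function(kg, name_substring) {
  stopifnot(inherits(kg, "kgap_graph"))
  cc <- kg$nodes$concept
  hit <- grepl(tolower(name_substring), tolower(cc$name), fixed = TRUE)
  out <- cc[hit, , drop = FALSE]
  out <- out[order(out$concept_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the drug set representing a disease
#'
#' Implements the indication-based disease representation: every drug with an
#' INDICATION edge to a concept matched by the query's name substring, kept
#' if (when an ATC prefix is set) at least one of its ATC codes starts with
#' that prefix, and ordered alphabetically by drug name.  The subset present
#' in LINCS (nonzero DRUG_SIGNATURE degree) is reported alongside.
#'
#' @param kg a `kgap_graph`.
#' @param query a [disease_query()], or a string taken as the name substring.
#' @return An object of class `kgap_drug_set`: list with `matched_concepts`
#'   (concept keys), `drugs` (data frame of drug rows, alphabetical by name),
#'   and `drugs_in_lincs` (character vector of drug keys).
#' @examples
#' fx <- table4_fixture()
#' ds <- select_drug_set(fx$kg, fx$query)
#' nrow(ds$drugs)              # 25 drugs indicated for Parkinson's, ATC "N"
#' length(ds$drugs_in_lincs)   # 22 of them are LINCS perturbagens
#' @export
select_drug_set <- function(kg, query) {
  stopifnot(inherits(kg, "kgap_graph"))
  if (is.character(query)) query <- disease_query(query)
  stopifnot(inherits(query, "kgap_disease_query"))

  concepts <- match_concepts(kg, query$name_substring)
  ind <- kg$edges$indication
  drug_ids <- unique(ind$drug_id[ind$concept_id %in% concepts$concept_id])
  drugs <- kg$nodes$drug[kg$nodes$drug$drug_id %in% drug_ids, , drop = FALSE]

  if (!is.null(query$atc_prefix) && nzchar(query$atc_prefix)) {
    keep <- vapply(strsplit(drugs$atc_codes, "|", fixed = TRUE),
                   function(codes) any(startsWith(codes, query$atc_prefix)),
                   logical(1))
    drugs <- drugs[keep, , drop = FALSE]
  }
  if (query$require_in_lincs) {
    drugs <- drugs[drugs$in_lincs, , drop = FALSE]
  }
  drugs <- drugs[order(drugs$name, drugs$drug_id), , drop = FALSE]
  rownames(drugs) <- NULL
  structure(
    list(matched_concepts = concepts$concept_id,
         drugs = drugs,
         drugs_in_lincs = drugs$drug_id[drugs$in_lincs]),
    class = "kgap_drug_set"
  )
}

#' @export
print.kgap_drug_set <- function(x, ...) {
  cat(sprintf("<kgap_drug_set> %d drugs (%d in LINCS), %d matched concepts\n",
              nrow(x$drugs), length(x$drugs_in_lincs),
              length(x$matched_concepts)))
  if (nrow(x$drugs)) {
    print(utils::head(x$drugs[, intersect(c("name", "drug_id", "pubchem_cid",
                                            "in_lincs"), names(x$drugs))],
                      10))
    if (nrow(x$drugs) > 10) cat("  ...\n")
  }
  invisible(x)
}

.drug_ids <- function(drug_set) {
  if (inherits(drug_set, "kgap_drug_set")) return(drug_set$drugs$drug_id)
  as.character(drug_set)
}
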