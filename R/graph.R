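# Core property-graph container: five node types (Drug, Gene, Signature,
# Cell, Concept) and three explicit edge tables (DRUG_SIGNATURE,
# SIGNATURE_GENE, INDICATION).  The CELL_SIGNATURE relationship is carried by
# the cell_id column of the signature table, since every signature belongs to
# exactly one cell line.

.NODE_TYPES <- c("drug", "gene", "signature", "cell", "concept")
.EDGE_TYPES <- c("drug_signature", "signature_gene", "indication")

.NODE_KEYS <- c(
  drug = "drug_id", gene = "gene_id", signature = "signature_id",
  cell = "cell_id", concept = "concept_id"
)

.NODE_REQUIRED <- list(
  drug      = c("drug_id", "name"),
  gene      = c("gene_id", "symbol"),
  signature = c("signature_id", "cell_id"),
  cell      = c("cell_id"),
  concept   = c("concept_id", "name")
)

.EDGE_REQUIRED <- list(
  drug_signature = c("drug_id", "signature_id"),
  signature_gene = c("signature_id", "gene_id", "z"),
  indication     = c("drug_id", "concept_id")
)

.TDL_LEVELS <- c("Tclin", "Tchem", "Tbio", "Tdark")

.empty_node <- function(type) {
  cols <- switch(type,
    drug = c("drug_id", "name", "pubchem_cid", "atc_codes", "in_lincs"),
    gene = c("gene_id", "symbol", "tdl", "family"),
    signature = c("signature_id", "cell_id"),
    cell = c("cell_id", "name"),
    concept = c("concept_id", "name")
  )
  df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(cols)), cols),
    stringsAsFactors = FALSE
  )
  if (type == "drug") {
    df$pubchem_cid <- integer(0)
    df$in_lincs <- logical(0)
  }
  df
}

.empty_edge <- function(type) {
  cols <- .EDGE_REQUIRED[[type]]
  df <- as.data.frame(
    stats::setNames(rep(list(character(0)), length(cols)), cols),
    stringsAsFactors = FALSE
  )
  if (type == "signature_gene") df$z <- numeric(0)
  df
}

.first_n <- function(x, n = 5L) {
  x <- unique(x)
  extra <- if (length(x) > n) sprintf(" (and %d more)", length(x) - n) else ""
  paste0(paste(utils::head(x, n), collapse = ", "), extra)
}

#' Construct a knowledge graph from node and edge tables
#'
#' Assembles a `kgap_graph` from in-memory data frames and checks every schema
#' invariant: unique node keys, referential integrity of all edges (including
#' the signature-to-cell link), finite numeric z-scores, at most one edge per
#' endpoint pair, valid Target Development Level values, and agreement of a
#' supplied `in_lincs` flag with the drug's DRUG_SIGNATURE degree.  When the
#' flag is absent it is derived from that degree.
#'
#' @param drugs data frame with columns `drug_id`, `name` and optionally
#'   `pubchem_cid` (integer), `atc_codes` (codes separated by `|`, may be
#'   empty) and `in_lincs` (logical).
#' @param genes data frame with `gene_id`, `symbol` and optionally `tdl`
#'   (one of Tclin/Tchem/Tbio/Tdark) and `family`.
#' @param signatures data frame with `signature_id` and `cell_id`; the
#'   `cell_id` column is the CELL_SIGNATURE relationship.
#' @param cells data frame with `cell_id` and optionally `name`.
#' @param concepts data frame with `concept_id` (OMOP-style disease concept
#'   key) and `name`; other identifier columns are kept as properties.
#' @param drug_signature edge data frame with `drug_id`, `signature_id`.
#' @param signature_gene edge data frame with `signature_id`, `gene_id` and
#'   the differential-expression z-score column `z`.
#' @param indication edge data frame with `drug_id`, `concept_id`.
#' @param dedup if `TRUE`, duplicate edges keep the first occurrence instead
#'   of failing.
#' @return An object of class `kgap_graph`: a list with elements `nodes`
#'   (named list of node data frames) and `edges` (named list of edge data
#'   frames).
#' @seealso [load_graph()] to read the same structure from TSV files.
#' @examples
#' kg <- kgap_graph(
#'   drugs = data.frame(drug_id = "d1", name = "levodopa"),
#'   genes = data.frame(gene_id = "g1", symbol = "SYNGR3"),
#'   signatures = data.frame(signature_id = "s1", cell_id = "c1"),
#'   cells = data.frame(cell_id = "c1"),
#'   concepts = data.frame(concept_id = "omop1", name = "Parkinson's disease"),
#'   drug_signature = data.frame(drug_id = "d1", signature_id = "s1"),
#'   signature_gene = data.frame(signature_id = "s1", gene_id = "g1", z = 4.2),
#'   indication = data.frame(drug_id = "d1", concept_id = "omop1")
#' )
#' meta_graph(kg)
#' @export
kgap_graph <- function(drugs = NULL, genes = NULL, signatures = NULL,
                       cells = NULL, concepts = NULL,
                       drug_signature = NULL, signature_gene = NULL,
                       indication = NULL, dedup = FALSE) {
  nodes <- list(drug = drugs, gene = genes, signature = signatures,
                cell = cells, concept = concepts)
  edges <- list(drug_signature = drug_signature,
                signature_gene = signature_gene,
                indication = indication)
  for (t in .NODE_TYPES) {
    if (is.null(nodes[[t]])) nodes[[t]] <- .empty_node(t)
    nodes[[t]] <- .check_node_table(nodes[[t]], t)
  }
  for (t in .EDGE_TYPES) {
    if (is.null(edges[[t]])) edges[[t]] <- .empty_edge(t)
    edges[[t]] <- .check_edge_table(edges[[t]], t, dedup = dedup)
  }
  kg <- structure(list(nodes = nodes, edges = edges), class = "kgap_graph")
  validate_graph(kg)
}

.check_node_table <- function(df, type, file = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- .NODE_REQUIRED[[type]]
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in %s nodes%s: missing required column(s) %s",
                 type, if (is.null(file)) "" else paste0(" [", file, "]"),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  key <- .NODE_KEYS[[type]]
  df[[key]] <- as.character(df[[key]])
  if (anyDuplicated(df[[key]])) {
    stop(sprintf("integrity error: duplicate %s key(s): %s", type,
                 .first_n(df[[key]][duplicated(df[[key]])])), call. = FALSE)
  }
  if (type == "drug") {
    if (is.null(df$pubchem_cid)) df$pubchem_cid <- NA_integer_
    df$pubchem_cid <- suppressWarnings(as.integer(df$pubchem_cid))
    if (is.null(df$atc_codes)) df$atc_codes <- ""
    df$atc_codes <- as.character(df$atc_codes)
    df$atc_codes[is.na(df$atc_codes)] <- ""
    if (!is.null(df$in_lincs) && !is.logical(df$in_lincs)) {
      df$in_lincs <- toupper(as.character(df$in_lincs)) %in% c("TRUE", "T", "1")
    }
  }
  if (type == "gene" && !is.null(df$tdl)) {
    df$tdl <- as.character(df$tdl)
    df$tdl[df$tdl %in% c("", "NA")] <- NA_character_
    bad <- !is.na(df$tdl) & !(df$tdl %in% .TDL_LEVELS)
    if (any(bad)) {
      stop(sprintf("validation error: unknown TDL value(s): %s",
                   .first_n(df$tdl[bad])), call. = FALSE)
    }
  }
  if (type == "signature") df$cell_id <- as.character(df$cell_id)
  rownames(df) <- NULL
  df
}

.check_edge_table <- function(df, type, dedup = FALSE, file = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  req <- .EDGE_REQUIRED[[type]]
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in %s edges%s: missing required column(s) %s",
                 type, if (is.null(file)) "" else paste0(" [", file, "]"),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in setdiff(req, "z")) df[[col]] <- as.character(df[[col]])
  if (type == "signature_gene") {
    if (is.character(df$z)) {
      z <- suppressWarnings(as.numeric(df$z))
      bad <- is.na(z) & !is.na(df$z)
      if (any(bad)) {
        stop(sprintf("parse error: non-numeric z value(s) in signature_gene: %s",
                     .first_n(df$z[bad])), call. = FALSE)
      }
      df$z <- z
    }
    if (!all(is.finite(df$z))) {
      stop("parse error: z values in signature_gene must be finite",
           call. = FALSE)
    }
  }
  pair <- do.call(paste, c(df[setdiff(req, "z")], sep = "\r"))
  if (anyDuplicated(pair)) {
    if (dedup) {
      df <- df[!duplicated(pair), , drop = FALSE]
    } else {
      dup <- df[duplicated(pair), setdiff(req, "z"), drop = FALSE]
      stop(sprintf("integrity error: duplicate %s edge(s): %s", type,
                   .first_n(do.call(paste, c(dup, sep = "/")))),
           call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

#' Validate all invariants of a knowledge graph
#'
#' Re-checks referential integrity of every edge against the node tables,
#' derives or verifies the per-drug `in_lincs` flag, and returns the graph
#' (invisibly usable in pipelines).  Called by [kgap_graph()] and
#' [load_graph()]; useful after manual mutation of the tables.
#'
#' @param kg a `kgap_graph`.
#' @param max_report maximum number of offending identifiers to list in an
#'   error message.
#' @return `kg`, with `in_lincs` filled in, if every invariant holds;
#'   otherwise an error describing the first offenders.
#' @export
validate_graph <- function(kg, max_report = 5L) {
  stopifnot(inherits(kg, "kgap_graph"))
  n <- kg$nodes
  e <- kg$edges
  .ref <- function(ids, keys, edge, col) {
    bad <- setdiff(ids, keys)
    if (length(bad)) {
      stop(sprintf("integrity error: %s edge references unknown %s: %s",
                   edge, col, .first_n(bad, max_report)), call. = FALSE)
    }
  }
  .ref(n$signature$cell_id, n$cell$cell_id, "CELL_SIGNATURE", "cell_id")
  .ref(e$drug_signature$drug_id, n$drug$drug_id, "DRUG_SIGNATURE", "drug_id")
  .ref(e$drug_signature$signature_id, n$signature$signature_id,
       "DRUG_SIGNATURE", "signature_id")
  .ref(e$signature_gene$signature_id, n$signature$signature_id,
       "SIGNATURE_GENE", "signature_id")
  .ref(e$signature_gene$gene_id, n$gene$gene_id, "SIGNATURE_GENE", "gene_id")
  .ref(e$indication$drug_id, n$drug$drug_id, "INDICATION", "drug_id")
  .ref(e$indication$concept_id, n$concept$concept_id, "INDICATION",
       "concept_id")

  derived <- n$drug$drug_id %in% e$drug_signature$drug_id
  if (is.null(n$drug$in_lincs) || all(is.na(n$drug$in_lincs))) {
    kg$nodes$drug$in_lincs <- derived
  } else {
    supplied <- n$drug$in_lincs
    kg$nodes$drug$in_lincs[is.na(supplied)] <- derived[is.na(supplied)]
    mism <- !is.na(supplied) & supplied != derived
    if (any(mism)) {
      stop(sprintf(
        "integrity error: in_lincs flag disagrees with DRUG_SIGNATURE degree for: %s",
        .first_n(n$drug$drug_id[mism], max_report)), call. = FALSE)
    }
  }
  kg
}

#' @export
print.kgap_graph <- function(x, ...) {
  cat("<kgap_graph>\n")
  mg <- meta_graph(x)
  if (nrow(mg$nodes)) {
    cat("  nodes:\n")
    for (i in seq_len(nrow(mg$nodes))) {
      cat(sprintf("    %-10s %d\n", mg$nodes$node_type[i], mg$nodes$count[i]))
    }
  } else cat("  (empty)\n")
  if (nrow(mg$edges)) {
    cat("  relationships:\n")
    for (i in seq_len(nrow(mg$edges))) {
      cat(sprintf("    (%s)-[%s]->(%s) %d\n", mg$edges$source_type[i],
                  mg$edges$edge_type[i], mg$edges$target_type[i],
                  mg$edges$count[i]))
    }
  }
  invisible(x)
}

#' Report the meta-graph (schema-level node and relationship counts)
#'
#' The analogue of an introspective schema query on a property-graph
#' database: one row per nonempty node type with its count, and one row per
#' nonempty relationship pattern `(source)-[edge]->(target)` with its count.
#' CELL_SIGNATURE is counted from the signatures that name a cell.
#'
#' @param kg a `kgap_graph`.
#' @return A list with data frames `nodes` (`node_type`, `count`) and `edges`
#'   (`source_type`, `edge_type`, `target_type`, `count`), restricted to
#'   nonempty collections.
#' @export
meta_graph <- function(kg) {
  stopifnot(inherits(kg, "kgap_graph"))
  node_counts <- vapply(kg$nodes, nrow, integer(1))
  label <- c(drug = "Drug", gene = "Gene", signature = "Signature",
             cell = "Cell", concept = "Concept")
  nodes <- data.frame(
    node_type = unname(label[names(node_counts)]),
    count = unname(node_counts),
    stringsAsFactors = FALSE
  )
  nodes <- nodes[nodes$count > 0, , drop = FALSE]

  cs <- sum(!is.na(kg$nodes$signature$cell_id) &
              nzchar(kg$nodes$signature$cell_id))
  edges <- data.frame(
    source_type = c("Signature", "Cell", "Drug", "Drug"),
    edge_type = c("SIGNATURE_GENE", "CELL_SIGNATURE", "DRUG_SIGNATURE",
                  "INDICATION"),
    target_type = c("Gene", "Signature", "Signature", "Concept"),
    count = c(nrow(kg$edges$signature_gene), cs,
              nrow(kg$edges$drug_signature), nrow(kg$edges$indication)),
    stringsAsFactors = FALSE
  )
  edges <- edges[edges$count > 0, , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  list(nodes = nodes, edges = edges)
}
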