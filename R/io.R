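# TSV I/O.  Dialect: UTF-8, tab separator, single header row, no quoting
# (tabs may not occur inside values).  Keys are compared case-sensitively.

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE,
                    na.strings = character(0), comment.char = "",
                    fileEncoding = "UTF-8")
}

.write_tsv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    v <- out[[col]]
    if (is.logical(v)) {
      out[[col]] <- ifelse(is.na(v), "", ifelse(v, "TRUE", "FALSE"))
    } else if (is.double(v)) {
      out[[col]] <- sprintf("%.17g", v)  # round-trips IEEE doubles exactly
    } else {
      v <- as.character(v)
      v[is.na(v)] <- ""
      out[[col]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

.default_files <- function(dir) {
  list(
    nodes = list(
      drug = file.path(dir, "drug.tsv"),
      gene = file.path(dir, "gene.tsv"),
      signature = file.path(dir, "signature.tsv"),
      cell = file.path(dir, "cell.tsv"),
      concept = file.path(dir, "concept.tsv")
    ),
    edges = list(
      drug_signature = file.path(dir, "drug_signature.tsv"),
      signature_gene = file.path(dir, "signature_gene.tsv"),
      indication = file.path(dir, "indication.tsv")
    )
  )
}

#' Load a knowledge graph from tab-separated node and edge files
#'
#' Reads the five node tables and three edge tables, coerces typed columns
#' (`z` numeric, `pubchem_cid` integer, `in_lincs` logical), and validates
#' every schema invariant via [kgap_graph()].  A missing required column is a
#' schema error; an edge naming an unknown node is an integrity error that
#' reports the first offending identifiers; a non-numeric z is a parse error.
#' Unknown extra columns are preserved as opaque properties.
#'
#' @param node_files named list of paths (`drug`, `gene`, `signature`,
#'   `cell`, `concept`); entries may be omitted for empty collections.
#' @param edge_files named list of paths (`drug_signature`, `signature_gene`,
#'   `indication`); entries may be omitted.
#' @param dir convenience: a directory containing files under the default
#'   names `drug.tsv`, `gene.tsv`, ... as written by [export_graph()].  Used
#'   when `node_files`/`edge_files` are not given; files absent from the
#'   directory load as empty collections.
#' @param dedup keep the first occurrence of duplicate edges instead of
#'   failing.
#' @return A validated `kgap_graph`.
#' @export
load_graph <- function(node_files = NULL, edge_files = NULL, dir = NULL,
                       dedup = FALSE) {
  if (!is.null(dir)) {
    d <- .default_files(dir)
    if (is.null(node_files)) {
      node_files <- Filter(file.exists, d$nodes)
    }
    if (is.null(edge_files)) {
      edge_files <- Filter(file.exists, d$edges)
    }
  }
  node_files <- node_files %||% list()
  edge_files <- edge_files %||% list()
  bad <- setdiff(names(node_files), .NODE_TYPES)
  if (length(bad)) stop("unknown node type(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  bad <- setdiff(names(edge_files), .EDGE_TYPES)
  if (length(bad)) stop("unknown edge type(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  nodes <- lapply(node_files, .read_tsv)
  edges <- lapply(edge_files, .read_tsv)
  kgap_graph(
    drugs = nodes$drug, genes = nodes$gene, signatures = nodes$signature,
    cells = nodes$cell, concepts = nodes$concept,
    drug_signature = edges$drug_signature,
    signature_gene = edges$signature_gene,
    indication = edges$indication,
    dedup = dedup
  )
}

#' Export a knowledge graph to tab-separated node and edge files
#'
#' Writes one TSV per node and edge collection under the default file names
#' understood by [load_graph()].  z-scores are written with 17 significant
#' digits so that `load_graph(dir = export_graph(kg, dir))` reproduces the
#' graph exactly, key for key and z for z.
#'
#' @param kg a `kgap_graph`.
#' @param dir output directory; created if needed.
#' @return `dir`, invisibly.
#' @export
export_graph <- function(kg, dir) {
  stopifnot(inherits(kg, "kgap_graph"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory: ", dir, call. = FALSE)
  }
  d <- .default_files(dir)
  for (t in .NODE_TYPES) .write_tsv(kg$nodes[[t]], d$nodes[[t]])
  for (t in .EDGE_TYPES) .write_tsv(kg$edges[[t]], d$edges[[t]])
  invisible(dir)
}

#' Generate a Cypher script recreating the graph in a Neo4j instance
#'
#' Emits `CREATE` statements for every node and relationship.  Generation
#' only -- no server interaction; intended for loading the same graph into an
#' external property-graph database for browsing.
#'
#' @param kg a `kgap_graph`.
#' @param path optional file to write to.
#' @return Character vector of Cypher statements (invisibly when `path` is
#'   given).
#' @export
cypher_script <- function(kg, path = NULL) {
  stopifnot(inherits(kg, "kgap_graph"))
  esc <- function(x) gsub("'", "\\\\'", as.character(x))
  out <- character(0)
  node_label <- c(drug = "Drug", gene = "Gene", signature = "Signature",
                  cell = "Cell", concept = "Concept")
  for (t in .NODE_TYPES) {
    df <- kg$nodes[[t]]
    key <- .NODE_KEYS[[t]]
    for (i in seq_len(nrow(df))) {
      props <- vapply(names(df), function(col) {
        v <- df[[col]][i]
        if (is.na(v) || identical(v, "")) return(NA_character_)
        if (is.numeric(v)) sprintf("%s: %s", col, format(v, digits = 17))
        else if (is.logical(v)) sprintf("%s: %s", col, tolower(v))
        else sprintf("%s: '%s'", col, esc(v))
      }, character(1))
      props <- props[!is.na(props)]
      out <- c(out, sprintf("CREATE (:%s {%s});", node_label[[t]],
                            paste(props, collapse = ", ")))
    }
  }
  rel <- function(df, from_lab, from_key, rel_type, to_lab, to_key, props) {
    vapply(seq_len(nrow(df)), function(i) {
      p <- if (length(props)) {
        sprintf(" {%s}", paste(sprintf("%s: %s", props,
                                       format(df[[props]][i], digits = 17)),
                               collapse = ", "))
      } else ""
      sprintf(
        "MATCH (a:%s {%s: '%s'}), (b:%s {%s: '%s'}) CREATE (a)-[:%s%s]->(b);",
        from_lab, from_key, esc(df[[from_key]][i]),
        to_lab, to_key, esc(df[[to_key]][i]), rel_type, p)
    }, character(1))
  }
  sig <- kg$nodes$signature
  sig_cell <- sig[!is.na(sig$cell_id) & nzchar(sig$cell_id), , drop = FALSE]
  out <- c(
    out,
    rel(sig_cell, "Cell", "cell_id", "CELL_SIGNATURE", "Signature",
        "signature_id", character(0)),
    rel(kg$edges$drug_signature, "Drug", "drug_id", "DRUG_SIGNATURE",
        "Signature", "signature_id", character(0)),
    rel(kg$edges$signature_gene, "Signature", "signature_id",
        "SIGNATURE_GENE", "Gene", "gene_id", "z"),
    rel(kg$edges$indication, "Drug", "drug_id", "INDICATION", "Concept",
        "concept_id", character(0))
  )
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
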