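# Evidence-path enumeration and Stouffer aggregation -- the KGAP score.
#
# One evidence path is a (drug, signature, gene) traversal whose
# signature-gene z-score passes |z| > threshold (strict).  Per-gene paths
# are combined with Stouffer's weighted-z function
#   Z = sum(w_i * Z_i) / sqrt(sum(w_i^2)),
# all weights one by default.  Two modes:
#   Z ("Z-weighted"): Z_i = |z_i| (or signed z_i), so score = sum|z|/sqrt(k);
#   D ("D-weighted"): Z_i = 1, so score = sqrt(k) -- rank order equals the
#   per-gene evidence-path count (signature degree).

#' Enumerate Drug--Signature--Gene evidence paths above a z threshold
#'
#' Returns exactly the set of traversals `(d, s, g, z)` with a
#' DRUG_SIGNATURE edge `(d, s)`, a SIGNATURE_GENE edge `(s, g, z)`, `d` in
#' the query drug set, and `|z|` strictly greater than the threshold.  Each
#' distinct (drug, signature) pair contributes one path per qualifying gene:
#' signatures are independent experiments, so no per-drug or per-cell
#' deduplication is applied.
#'
#' @param kg a `kgap_graph`.
#' @param drug_set a `kgap_drug_set` from [select_drug_set()] or a character
#'   vector of drug keys; must be nonempty.
#' @param z_threshold nonnegative threshold on `|z|` (default 3, the
#'   strong-evidence cutoff for Level-5-style z-scores).
#' @return Data frame with columns `drug_id`, `signature_id`, `gene_id`, `z`,
#'   ordered by (drug_id, signature_id, gene_id).
#' @export
enumerate_paths <- function(kg, drug_set, z_threshold = 3) {
  stopifnot(inherits(kg, "kgap_graph"))
  ids <- .drug_ids(drug_set)
  if (length(ids) == 0L) {
    stop("usage error: drug_set must be nonempty", call. = FALSE)
  }
  if (!is.numeric(z_threshold) || length(z_threshold) != 1L ||
      is.na(z_threshold) || z_threshold < 0) {
    stop("z_threshold must be a single nonnegative number", call. = FALSE)
  }
  unknown <- setdiff(ids, kg$nodes$drug$drug_id)
  if (length(unknown)) {
    stop("integrity error: drug_set contains unknown drug(s): ",
         .first_n(unknown), call. = FALSE)
  }
  ds <- kg$edges$drug_signature
  ds <- ds[ds$drug_id %in% ids, c("drug_id", "signature_id"), drop = FALSE]
  sg <- kg$edges$signature_gene
  sg <- sg[abs(sg$z) > z_threshold, c("signature_id", "gene_id", "z"),
           drop = FALSE]
  paths <- merge(ds, sg, by = "signature_id", sort = FALSE)
  paths <- paths[, c("drug_id", "signature_id", "gene_id", "z"), drop = FALSE]
  paths <- paths[order(paths$drug_id, paths$signature_id, paths$gene_id), ,
                 drop = FALSE]
  rownames(paths) <- NULL
  paths
}

#' Stouffer's weighted z-score aggregation
#'
#' Computes `sum(w * z) / sqrt(sum(w^2))`.  With unit weights this is
#' `sum(z) / sqrt(k)` for `k` values: confidence grows with the square root
#' of the number of confirming observations.  Used here as an evidence
#' aggregate, not as a test statistic.
#'
#' @param z numeric vector of z-scores (nonempty, finite).
#' @param weights numeric vector of weights, same length; default all one.
#' @return The aggregated z, a single number.
#' @examples
#' stouffer_aggregate(2.5)               # identity for k = 1
#' stouffer_aggregate(c(3, 3, 3, 3))     # 4 * 3 / sqrt(4) = 6
#' @export
stouffer_aggregate <- function(z, weights = rep(1, length(z))) {
  if (length(z) == 0L) {
    stop("usage error: z must be nonempty", call. = FALSE)
  }
  if (length(weights) != length(z)) {
    stop("usage error: weights must match z in length", call. = FALSE)
  }
  if (!all(is.finite(z)) || !all(is.finite(weights))) {
    stop("usage error: z and weights must be finite", call. = FALSE)
  }
  denom <- sum(weights^2)
  if (denom <= 0) {
    stop("usage error: weights must not be all zero", call. = FALSE)
  }
  sum(weights * z) / sqrt(denom)
}

#' Scoring parameters for the gene ranking
#'
#' @param z_threshold nonnegative `|z|` cutoff for evidence paths (default 3).
#' @param mode `"Z"` (z-magnitude weighted) or `"D"` (degree-only; every path
#'   contributes 1, so the score is `sqrt(path count)`).
#' @param use_absolute_z in mode Z, aggregate `|z|` (default) rather than
#'   signed z.  Magnitudes are the default because a path is evidence of
#'   perturbation regardless of direction, and signed values from opposing
#'   signatures would cancel.
#' @return An object of class `kgap_score_params`.
#' @export
score_params <- function(z_threshold = 3, mode = c("Z", "D"),
                         use_absolute_z = TRUE) {
  mode <- match.arg(mode)
  if (!is.numeric(z_threshold) || length(z_threshold) != 1L ||
      is.na(z_threshold) || z_threshold < 0) {
    stop("z_threshold must be a single nonnegative number", call. = FALSE)
  }
  structure(
    list(z_threshold = z_threshold, mode = mode,
         use_absolute_z = isTRUE(use_absolute_z)),
    class = "kgap_score_params"
  )
}

#' Aggregate evidence paths into ranked per-gene scores
#'
#' Groups paths by gene and applies [stouffer_aggregate()] with unit weights:
#' mode `"Z"` aggregates the path z-magnitudes (or signed z when
#' `use_absolute_z = FALSE`), giving `sum|z| / sqrt(k)`; mode `"D"` sets
#' every contribution to 1, giving `sqrt(k)` so that ranking equals ranking
#' by evidence-path count.  Output is sorted by score descending with ties
#' broken by gene key, and ranks are 1..n in that order.
#'
#' @param paths data frame from [enumerate_paths()].
#' @param params a [score_params()] object (its `z_threshold` is not
#'   re-applied; thresholding happens at enumeration).
#' @return Data frame with columns `gene_id`, `k` (path count), `score`,
#'   `rank`.  Empty paths give an empty result.
#' @export
score_genes <- function(paths, params = score_params()) {
  stopifnot(inherits(params, "kgap_score_params"))
  if (is.null(paths) || nrow(paths) == 0L) {
    return(data.frame(gene_id = character(0), k = integer(0),
                      score = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  contrib <- switch(params$mode,
    Z = if (params$use_absolute_z) abs(paths$z) else paths$z,
    D = rep(1, nrow(paths))
  )
  sums <- tapply(contrib, paths$gene_id, sum)
  k <- as.integer(table(paths$gene_id)[names(sums)])
  out <- data.frame(
    gene_id = names(sums),
    k = k,
    score = as.numeric(sums) / sqrt(k),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Full disease-to-gene scoring pipeline
#'
#' Convenience wrapper: enumerate evidence paths for a drug set and rank
#' genes, returning the hitlist annotated with gene symbols (and TDL when
#' present on the graph's gene nodes).
#'
#' @param kg a `kgap_graph`.
#' @param drug_set drug set or character vector of drug keys.
#' @param params a [score_params()].
#' @return Ranked hitlist data frame (`gene_id`, `symbol`, `k`, `score`,
#'   `rank`, and `tdl` if available).
#' @export
kgap_score <- function(kg, drug_set, params = score_params()) {
  paths <- enumerate_paths(kg, drug_set, params$z_threshold)
  hits <- score_genes(paths, params)
  genes <- kg$nodes$gene
  cols <- intersect(c("symbol", "tdl"), names(genes))
  hits <- cbind(hits,
                genes[match(hits$gene_id, genes$gene_id), cols, drop = FALSE])
  hits <- hits[, c("gene_id", cols, "k", "score", "rank"), drop = FALSE]
  rownames(hits) <- NULL
  hits
}
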