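# Illumination-oriented post-ranking: TDL annotation, TIN-X-style
# non-dominated-solution ranks over (novelty, importance), and surfacing of
# top understudied (Tdark) candidates.

#' Non-dominated-solution ranks over novelty and importance
#'
#' Successive Pareto-front peeling, maximizing both coordinates.  Rank 1 is
#' the set of points relative to which none are superior in both dimensions;
#' rank 2 is the front of the remainder, and so on until every point is
#' ranked.  "Superior" means strictly greater in *both* coordinates: a point
#' equal in one coordinate does not dominate.  Ranks are therefore invariant
#' to input order and to strictly increasing transforms of either axis
#' (log-scaling for display never changes ranks).
#'
#' @param points data frame with columns `novelty` and `importance`, both
#'   finite and strictly positive (bibliometric rarity and disease--gene
#'   co-occurrence strength).
#' @return `points` with an integer `nds_rank` column appended (input row
#'   order preserved).
#' @examples
#' nds_rank(data.frame(novelty = c(1, 2, 0.5), importance = c(2, 1, 0.5)))
#' @export
nds_rank <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("novelty", "importance") %in% names(points)))
  if (nrow(points) == 0L) {
    stop("usage error: points must be nonempty", call. = FALSE)
  }
  nov <- as.numeric(points$novelty)
  imp <- as.numeric(points$importance)
  if (!all(is.finite(nov)) || !all(is.finite(imp)) ||
      any(nov <= 0) || any(imp <= 0)) {
    stop("validation error: novelty and importance must be finite and > 0",
         call. = FALSE)
  }
  n <- length(nov)
  rank_out <- integer(n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    idx <- remaining[order(-nov[remaining], -imp[remaining])]
    # sweep in decreasing novelty; a point is dominated iff some point with
    # strictly greater novelty also has strictly greater importance
    best_imp <- -Inf           # max importance over strictly-greater novelty
    group_max <- -Inf          # max importance within the current novelty tie
    prev_nov <- NA_real_
    front <- logical(length(idx))
    for (j in seq_along(idx)) {
      i <- idx[j]
      if (!isTRUE(nov[i] == prev_nov)) {
        best_imp <- max(best_imp, group_max)
        group_max <- -Inf
        prev_nov <- nov[i]
      }
      front[j] <- !(best_imp > imp[i])
      group_max <- max(group_max, imp[i])
    }
    front_idx <- idx[front]
    rank_out[front_idx] <- r
    remaining <- setdiff(remaining, front_idx)
  }
  points$nds_rank <- rank_out
  points
}

#' Annotate a hitlist with Target Development Levels
#'
#' Joins a gene-to-TDL table onto the hitlist without disturbing its order.
#' Genes absent from the table are annotated `"unknown"`.
#'
#' @param gene_scores ranked hitlist data frame with a `gene_id` column.
#' @param tdl_table data frame with columns `gene_id` and `tdl`, each TDL one
#'   of Tclin, Tchem, Tbio, Tdark.  May be empty.
#' @return `gene_scores` with a `tdl` column (existing `tdl` is replaced).
#' @export
annotate_tdl <- function(gene_scores, tdl_table) {
  stopifnot(is.data.frame(gene_scores), "gene_id" %in% names(gene_scores))
  if (is.null(tdl_table) || nrow(tdl_table) == 0L) {
    gene_scores$tdl <- rep("unknown", nrow(gene_scores))
    return(gene_scores)
  }
  stopifnot(all(c("gene_id", "tdl") %in% names(tdl_table)))
  tdl <- as.character(tdl_table$tdl)
  bad <- !(tdl %in% .TDL_LEVELS)
  if (any(bad)) {
    stop("validation error: malformed TDL value(s): ", .first_n(tdl[bad]),
         call. = FALSE)
  }
  idx <- match(gene_scores$gene_id, as.character(tdl_table$gene_id))
  gene_scores$tdl <- ifelse(is.na(idx), "unknown", tdl[idx])
  gene_scores
}

#' Top understudied (Tdark) genes of a hitlist
#'
#' Filters the annotated hitlist to TDL `"Tdark"` and truncates to the `n`
#' highest-ranked, preserving hitlist order -- the route by which an
#' understudied candidate like a top-ranked dark synaptic gene is surfaced.
#'
#' @param annotated hitlist with a `tdl` column ([annotate_tdl()] output).
#' @param n maximum number of genes to return.
#' @return The filtered, truncated subsequence of the hitlist.
#' @export
top_dark <- function(annotated, n = 10L) {
  stopifnot(is.data.frame(annotated), "tdl" %in% names(annotated))
  dark <- annotated[annotated$tdl == "Tdark", , drop = FALSE]
  out <- utils::head(dark, n)
  rownames(out) <- NULL
  out
}
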