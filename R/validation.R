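# ROC/AUC validation of gene rankings against known-target sets.
#
# The AUC here measures enrichment of known targets among highly scored
# genes (equivalently the normalized Mann-Whitney U statistic with ties
# counting one half); it is not a classifier metric.

#' Define a validation gene set
#'
#' @param name label for the set (e.g. `"all-targets"`, `"moa-targets"`).
#' @param positives nonempty character vector of gene keys treated as known
#'   targets.
#' @return An object of class `kgap_validation_set`.
#' @export
validation_set <- function(name, positives) {
  positives <- unique(as.character(positives))
  if (length(positives) == 0L) {
    stop("usage error: positives must be nonempty", call. = FALSE)
  }
  structure(list(name = name, positives = positives),
            class = "kgap_validation_set")
}

#' Label a score vector against a validation set
#'
#' Every gene of the universe receives its hitlist score (0 when absent from
#' the hitlist: no surviving evidence path is itself information) and a
#' binary label marking membership in the positive set.
#'
#' @param gene_scores hitlist data frame with `gene_id` and `score` columns
#'   ([score_genes()] / [kgap_score()] output).
#' @param vset a [validation_set()] or character vector of positive gene keys.
#' @param universe character vector of gene keys to evaluate over (typically
#'   all Gene nodes of the graph); must contain at least one positive.
#' @return Data frame with columns `gene_id`, `score`, `label` (1 = known
#'   target), one row per universe gene.
#' @export
label_scores <- function(gene_scores, vset, universe) {
  if (inherits(vset, "kgap_validation_set")) vset <- vset$positives
  vset <- unique(as.character(vset))
  universe <- unique(as.character(universe))
  if (!any(vset %in% universe)) {
    stop("usage error: no positives present in the universe", call. = FALSE)
  }
  idx <- match(universe, gene_scores$gene_id)
  score <- ifelse(is.na(idx), 0, gene_scores$score[idx])
  data.frame(
    gene_id = universe,
    score = score,
    label = as.integer(universe %in% vset),
    stringsAsFactors = FALSE
  )
}

#' ROC curve and AUC of a labeled score vector
#'
#' Sweeps the score threshold from high to low with tied scores grouped (one
#' ROC vertex per distinct score), yielding a curve from (0,0) to (1,1).  The
#' trapezoidal area equals the Mann-Whitney U statistic normalized by
#' `n_pos * n_neg`, with tied positive/negative pairs contributing one half.
#'
#' @param labeled data frame with `score` and `label` columns, both classes
#'   present ([label_scores()] output).
#' @param mode,set_name optional labels carried into the result.
#' @return An object of class `kgap_validation_result`: list with `mode`,
#'   `set_name`, `n_pos`, `n_neg`, `roc_points` (data frame `fpr`, `tpr`)
#'   and `auc`.
#' @export
roc_auc <- function(labeled, mode = NA_character_, set_name = NA_character_) {
  stopifnot(all(c("score", "label") %in% names(labeled)))
  lab <- as.integer(labeled$label)
  n_pos <- sum(lab == 1L)
  n_neg <- sum(lab == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("usage error: both classes must be present", call. = FALSE)
  }
  o <- order(labeled$score, decreasing = TRUE)
  s <- labeled$score[o]
  l <- lab[o]
  last <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- cumsum(l)[last]
  fp <- cumsum(1L - l)[last]
  roc <- data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  structure(
    list(mode = mode, set_name = set_name, n_pos = n_pos, n_neg = n_neg,
         roc_points = roc, auc = auc),
    class = "kgap_validation_result"
  )
}

#' @export
print.kgap_validation_result <- function(x, ...) {
  cat(sprintf("<kgap_validation_result> mode=%s set=%s  n_pos=%d n_neg=%d  AUC=%.4f\n",
              x$mode, x$set_name, x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Run the full validation grid (mode x validation set)
#'
#' For every combination of scoring parameters and validation set, scores
#' the genes, labels them over the chosen universe, and computes ROC/AUC --
#' the degree-weighted / z-weighted by all-targets / MoA-targets four-panel
#' analysis when given two of each.
#'
#' @param kg a `kgap_graph`.
#' @param drug_set drug set or character vector of drug keys.
#' @param vsets list of [validation_set()] objects.
#' @param params_list list of [score_params()]; default the D and Z modes at
#'   `z_threshold = 3`.
#' @param universe `"genes"` (default) evaluates over all Gene nodes with
#'   non-hits scored 0; `"hits"` restricts to scored genes only.
#' @return A list of `kgap_validation_result`, one per (mode, set), plus a
#'   `summary` attribute data frame (`mode`, `set_name`, `n_pos`, `n_neg`,
#'   `auc`).
#' @export
run_validation <- function(kg, drug_set, vsets,
                           params_list = list(score_params(mode = "D"),
                                              score_params(mode = "Z")),
                           universe = c("genes", "hits")) {
  universe <- match.arg(universe)
  if (inherits(vsets, "kgap_validation_set")) vsets <- list(vsets)
  results <- list()
  for (params in params_list) {
    hits <- kgap_score(kg, drug_set, params)
    univ <- if (universe == "genes") kg$nodes$gene$gene_id else hits$gene_id
    for (vset in vsets) {
      res <- roc_auc(label_scores(hits, vset, univ),
                     mode = params$mode, set_name = vset$name)
      results[[paste(params$mode, vset$name, sep = ".")]] <- res
    }
  }
  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(mode = r$mode, set_name = r$set_name, n_pos = r$n_pos,
               n_neg = r$n_neg, auc = r$auc, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  attr(results, "summary") <- summary
  results
}
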