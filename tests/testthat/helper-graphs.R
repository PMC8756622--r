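# Shared fixtures and independent oracles.

# 2 drugs / 3 signatures / 4 genes / 1 cell / 1 concept toy graph
toy_kg <- function(z = c(4.2, -3.5, 1.0, 2.2), in_lincs = NULL) {
  drugs <- data.frame(
    drug_id = c("d1", "d2"),
    name = c("alpha", "beta"),
    atc_codes = c("N04BA01", "A03FA03"),
    stringsAsFactors = FALSE
  )
  if (!is.null(in_lincs)) drugs$in_lincs <- in_lincs
  kgap_graph(
    drugs = drugs,
    genes = data.frame(gene_id = paste0("g", 1:4),
                       symbol = paste0("GENE", 1:4)),
    signatures = data.frame(signature_id = paste0("s", 1:3), cell_id = "c1"),
    cells = data.frame(cell_id = "c1"),
    concepts = data.frame(concept_id = "omop1", name = "toy disease"),
    drug_signature = data.frame(drug_id = c("d1", "d1", "d2"),
                                signature_id = c("s1", "s2", "s3")),
    signature_gene = data.frame(
      signature_id = c("s1", "s1", "s2", "s3"),
      gene_id = c("g1", "g2", "g3", "g4"),
      z = z
    ),
    indication = data.frame(drug_id = c("d1", "d2"), concept_id = "omop1")
  )
}

# exhaustive triple-loop evidence-path oracle, independent of the merge-based
# implementation
brute_force_paths <- function(kg, drug_ids, z_threshold) {
  out <- list()
  ds <- kg$edges$drug_signature
  sg <- kg$edges$signature_gene
  for (d in drug_ids) {
    for (i in seq_len(nrow(ds))) {
      if (ds$drug_id[i] != d) next
      s <- ds$signature_id[i]
      for (j in seq_len(nrow(sg))) {
        if (sg$signature_id[j] == s && abs(sg$z[j]) > z_threshold) {
          out[[length(out) + 1L]] <- data.frame(
            drug_id = d, signature_id = s, gene_id = sg$gene_id[j],
            z = sg$z[j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(drug_id = character(0), signature_id = character(0),
                      gene_id = character(0), z = numeric(0)))
  }
  out <- do.call(rbind, out)
  out <- out[order(out$drug_id, out$signature_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# O(n^2) pairwise Mann-Whitney AUC oracle (ties count one half)
pairwise_auc <- function(score, label) {
  pos <- score[label == 1]
  neg <- score[label == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# O(n^2) repeated Pareto-front peeling oracle for nds ranks
peel_fronts <- function(nov, imp) {
  n <- length(nov)
  rank_out <- integer(n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining)) {
    r <- r + 1L
    dominated <- vapply(remaining, function(i) {
      any(nov[remaining] > nov[i] & imp[remaining] > imp[i])
    }, logical(1))
    front <- remaining[!dominated]
    rank_out[front] <- r
    remaining <- setdiff(remaining, front)
  }
  rank_out
}

# per-gene groupby + direct formula evaluation, independent of score_genes
brute_force_scores <- function(paths, mode, use_absolute_z = TRUE) {
  genes <- sort(unique(paths$gene_id))
  rows <- lapply(genes, function(g) {
    z <- paths$z[paths$gene_id == g]
    contrib <- if (mode == "Z") {
      if (use_absolute_z) abs(z) else z
    } else rep(1, length(z))
    data.frame(gene_id = g, k = length(z),
               score = sum(contrib) / sqrt(length(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
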