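# Synthetic knowledge-graph generator.
#
# Emulates, at desk scale, a LINCS-style tripartite Drug--Signature--Gene
# graph with Cell and Concept satellites: background signature-gene z-scores
# are standard-normal-like noise (Level-5-style normalized z-scores), and a
# planted signal raises |z| on edges linking the query drugs' signatures to a
# designated set of true target genes.  The generator fixes the study
# conditions under which the scoring and validation machinery is exercised;
# it makes no attempt to match real LINCS degree distributions, cell panels
# or compound coverage.

#' Parameters for the synthetic knowledge-graph generator
#'
#' Defaults are sized for sub-second generation while leaving the |z| > 3
#' evidence filter meaningfully sparse on the background: 20 drugs of which
#' 5 are query drugs, 10 signatures per drug over 5 cell lines, 500 genes of
#' which 10 are planted true targets, signature-gene edge density 0.2,
#' standard-normal background noise, and a planted mean |z| of 4.
#'
#' @param n_drugs total number of Drug nodes.
#' @param n_query_drugs number of drugs linked by INDICATION to the query
#'   concept (the disease-representing drug set); at most `n_drugs`.
#' @param n_signatures_per_drug signatures per drug (each drug-signature pair
#'   is one perturbation experiment).
#' @param n_cells number of Cell nodes; each signature is assigned one.
#' @param n_genes number of Gene nodes.
#' @param n_true_targets number of planted true-target genes; at most
#'   `n_genes`.
#' @param effect_mu mean |z| boost on edges between query-drug signatures and
#'   true-target genes; 0 plants no signal.
#' @param noise_sd spread of the zero-centered background z distribution
#'   (default 1, standard normal).
#' @param edge_density fraction of (signature, gene) pairs receiving a
#'   SIGNATURE_GENE edge, in (0, 1].
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return An object of class `kgap_synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 20L, n_query_drugs = 5L,
                           n_signatures_per_drug = 10L, n_cells = 5L,
                           n_genes = 500L, n_true_targets = 10L,
                           effect_mu = 4, noise_sd = 1, edge_density = 0.2,
                           seed = 1L) {
  spec <- list(
    n_drugs = as.integer(n_drugs),
    n_query_drugs = as.integer(n_query_drugs),
    n_signatures_per_drug = as.integer(n_signatures_per_drug),
    n_cells = as.integer(n_cells),
    n_genes = as.integer(n_genes),
    n_true_targets = as.integer(n_true_targets),
    effect_mu = as.numeric(effect_mu),
    noise_sd = as.numeric(noise_sd),
    edge_density = as.numeric(edge_density),
    seed = as.integer(seed)
  )
  counts <- spec[c("n_drugs", "n_query_drugs", "n_signatures_per_drug",
                   "n_cells", "n_genes", "n_true_targets")]
  if (any(vapply(counts, function(x) is.na(x) || x < 1L, logical(1)))) {
    stop("validation error: all counts must be positive integers",
         call. = FALSE)
  }
  if (spec$n_query_drugs > spec$n_drugs) {
    stop("validation error: n_query_drugs must not exceed n_drugs",
         call. = FALSE)
  }
  if (spec$n_true_targets > spec$n_genes) {
    stop("validation error: n_true_targets must not exceed n_genes",
         call. = FALSE)
  }
  if (is.na(spec$effect_mu) || spec$effect_mu < 0) {
    stop("validation error: effect_mu must be >= 0", call. = FALSE)
  }
  if (is.na(spec$noise_sd) || spec$noise_sd <= 0) {
    stop("validation error: noise_sd must be > 0", call. = FALSE)
  }
  if (is.na(spec$edge_density) || spec$edge_density <= 0 ||
      spec$edge_density > 1) {
    stop("validation error: edge_density must be in (0, 1]", call. = FALSE)
  }
  structure(spec, class = "kgap_synthetic_spec")
}

#' Generate a synthetic knowledge graph with planted drug-to-gene signal
#'
#' Builds a schema-complete `kgap_graph`: drugs (the first `n_query_drugs`
#' carry nervous-system-style ATC codes and INDICATION edges to a single
#' query concept), signatures with cell assignments, genes, and
#' SIGNATURE_GENE edges sampled at `edge_density`.  Background edge z-scores
#' are drawn from `N(0, noise_sd)`; edges joining a query-drug signature to a
#' true-target gene are drawn with magnitude centered at `effect_mu` and
#' random sign (so that absolute-z and signed-z aggregation can disagree).
#' The output is deterministic given `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return List with elements `kg` (the `kgap_graph`) and `truth` (list of
#'   `query_drug_ids`, `true_target_gene_ids`, `query_concept_id`).
#' @examples
#' sim <- generate_graph(synthetic_spec(seed = 42))
#' meta_graph(sim$kg)
#' @export
generate_graph <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "kgap_synthetic_spec"))
  set.seed(spec$seed)

  drug_ids <- sprintf("D%04d", seq_len(spec$n_drugs))
  query_drugs <- drug_ids[seq_len(spec$n_query_drugs)]
  gene_ids <- sprintf("G%05d", seq_len(spec$n_genes))
  true_targets <- sort(sample(gene_ids, spec$n_true_targets))
  cell_ids <- sprintf("C%02d", seq_len(spec$n_cells))

  n_sig <- spec$n_drugs * spec$n_signatures_per_drug
  sig_ids <- sprintf("S%05d", seq_len(n_sig))
  sig_drug <- rep(drug_ids, each = spec$n_signatures_per_drug)
  sig_cell <- sample(cell_ids, n_sig, replace = TRUE)

  drugs <- data.frame(
    drug_id = drug_ids,
    name = paste0("compound-", tolower(drug_ids)),
    pubchem_cid = 100000L + seq_len(spec$n_drugs),
    atc_codes = ifelse(drug_ids %in% query_drugs, "N04BX99", "A01AA99"),
    stringsAsFactors = FALSE
  )
  genes <- data.frame(
    gene_id = gene_ids,
    symbol = paste0("SYN", seq_len(spec$n_genes)),
    stringsAsFactors = FALSE
  )
  signatures <- data.frame(signature_id = sig_ids, cell_id = sig_cell,
                           stringsAsFactors = FALSE)
  cells <- data.frame(cell_id = cell_ids,
                      name = paste0("cellline-", tolower(cell_ids)),
                      stringsAsFactors = FALSE)
  concept_id <- "OMOP:900001"
  concepts <- data.frame(concept_id = concept_id,
                         name = "synthetic query disease",
                         stringsAsFactors = FALSE)

  drug_signature <- data.frame(drug_id = sig_drug, signature_id = sig_ids,
                               stringsAsFactors = FALSE)
  indication <- data.frame(drug_id = query_drugs, concept_id = concept_id,
                           stringsAsFactors = FALSE)

  # sample (signature, gene) pairs at edge_density, row-major by signature
  keep <- which(stats::runif(n_sig * spec$n_genes) < spec$edge_density)
  sig_idx <- ((keep - 1L) %/% spec$n_genes) + 1L
  gene_idx <- ((keep - 1L) %% spec$n_genes) + 1L
  z <- stats::rnorm(length(keep), mean = 0, sd = spec$noise_sd)
  planted <- (sig_drug[sig_idx] %in% query_drugs) &
    (gene_ids[gene_idx] %in% true_targets)
  n_planted <- sum(planted)
  if (n_planted > 0 && spec$effect_mu > 0) {
    sign <- sample(c(-1, 1), n_planted, replace = TRUE)
    z[planted] <- sign * stats::rnorm(n_planted, mean = spec$effect_mu,
                                      sd = spec$noise_sd)
  }
  signature_gene <- data.frame(
    signature_id = sig_ids[sig_idx],
    gene_id = gene_ids[gene_idx],
    z = z,
    stringsAsFactors = FALSE
  )

  kg <- kgap_graph(
    drugs = drugs, genes = genes, signatures = signatures, cells = cells,
    concepts = concepts, drug_signature = drug_signature,
    signature_gene = signature_gene, indication = indication
  )
  list(
    kg = kg,
    truth = list(query_drug_ids = query_drugs,
                 true_target_gene_ids = true_targets,
                 query_concept_id = concept_id)
  )
}
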