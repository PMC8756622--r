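# kgap — knowledge-graph evidence-path aggregation for drug target illumination

`kgap` is an R implementation of the KGAP approach to drug target discovery:
represent a disease by its set of approved drugs, follow each drug through
LINCS-style differential-expression signatures to the genes those signatures
perturb, and aggregate the resulting evidence paths into a per-gene score
that ranks candidate targets.  It is aimed at computational drug-discovery
and chemogenomics researchers who want the full path-scoring, validation and
prioritization machinery in a self-contained, testable library — including a
synthetic knowledge-graph generator, so every step runs without any external
database.

## The model

The knowledge graph has five node types — Drug, Signature, Gene, Cell,
Concept — and four relationships:

```
(Drug)-[INDICATION]->(Concept)          approved indications (disease terms)
(Drug)-[DRUG_SIGNATURE]->(Signature)    which experiment used which drug
(Cell)-[CELL_SIGNATURE]->(Signature)    the cell line of the experiment
(Signature)-[SIGNATURE_GENE {z}]->(Gene)  per-gene differential-expression z
```

A disease query is a case-insensitive substring over Concept names plus an
optional ATC-code restriction on the drugs (level-1 `"N"` = nervous system).
Every traversal `(d)-(s)-(g)` with `d` in the resulting drug set and
`|z| > 3` (strict) is one **evidence path**.  Per gene, the `k` path
contributions `Z_1..Z_k` are combined with Stouffer's weighted-z function,
all weights one:

```
score(g) = ( Σ_i w_i Z_i ) / sqrt( Σ_i w_i² )
```

- **Z-weighted mode**: `Z_i = |z_i|`, so `score = Σ|z| / √k`;
- **D-weighted mode** (degree-only): `Z_i = 1`, so `score = √k`, ranking
  genes by their evidence-path count.

Rankings are validated as *enrichment* of a known-target gene set: the score
vector over all genes (non-hits scored 0) is swept into a ROC curve whose
trapezoidal area equals the tie-aware normalized Mann–Whitney statistic.
For illumination, hitlists are annotated with Target Development Levels
(Tclin/Tchem/Tbio/Tdark) and with TIN-X-style non-dominated-solution ranks
(`nds_rank`): successive Pareto fronts maximizing bibliometric novelty and
importance.

## Worked example

The packaged Parkinson's disease fixture reproduces the curated drug-set
query — 5 matched indication concepts, 25 drugs, 22 of them LINCS
perturbagens:

```r
library(kgap)
fx <- table4_fixture()
select_drug_set(fx$kg, fx$query)
#> <kgap_drug_set> 25 drugs (22 in LINCS), 5 matched concepts
#>             name drug_id pubchem_cid in_lincs
#> 1     amantadine   DC144        2130     TRUE
#> 2    apomorphine   DC228        6005     TRUE
#> ...
#> 6     dexetimide   DC831       30843    FALSE
```

Scoring and validation run end-to-end on a synthetic graph with planted
drug→gene signal (20 drugs, 5 of them query drugs, 200 signatures, 500
genes, 10 true targets, mean planted |z| = 4):

```r
sim  <- generate_graph(synthetic_spec(seed = 42))
hits <- kgap_score(sim$kg, sim$truth$query_drug_ids, score_params(mode = "Z"))
head(hits, 3)
#>   gene_id symbol  k    score rank
#> 1  G00146 SYN146 13 15.23215    1
#> 2  G00500 SYN500 11 13.82978    2
#> 3  G00049  SYN49  9 13.29562    3

lab <- label_scores(hits, sim$truth$true_target_gene_ids,
                    sim$kg$nodes$gene$gene_id)
roc_auc(lab, mode = "Z", set_name = "planted-targets")
#> <kgap_validation_result> mode=Z set=planted-targets  n_pos=10 n_neg=490  AUC=1.0000
```

Here all ten planted targets occupy the top ten ranks: `score = Σ|z|/√k`
rewards genes hit repeatedly and strongly by the query drugs' signatures,
and the AUC of 1.0 says every planted target outranks every background
gene.  `annotate_tdl()`, `nds_rank()` and `top_dark()` then post-rank such a
hitlist for understudied candidates.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/kgap.R simulate --out graph/ --effect-mu 4 --seed 17
Rscript inst/cli/kgap.R score --graph graph/ --drug-set graph/truth_query_drugs.tsv --mode Z
```

## Scale: what this package does and does not reproduce

The full-scale KGAP analysis runs on a graph built from LINCS L1000 Level 5
signatures joined with DrugCentral and TCRD — 45,623,637 SIGNATURE_GENE
edges, 591,676 signatures, 12,329 genes — where the Parkinson query yields a
641-gene hitlist with validation ROC AUC between 0.64 and 0.74 against
DrugCentral target sets, and the top-ranked Tdark gene is SYNGR3.  Those
numbers are properties of the external database snapshots; this package does
not download or rebuild them.  They are documented here for context and
replaced, for testing, by exact oracles on the desk-scale primitives and by
planted-signal recovery on the synthetic generator.  The packaged fixture's
OMOP-style concept identifiers are synthetic placeholders; drug names,
PubChem CIDs, LINCS flags and ATC codes are the real curated values.

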