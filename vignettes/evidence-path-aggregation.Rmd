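---
title: "Evidence-path aggregation: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence-path aggregation: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kgap)
```

## The procedure

`kgap` turns a disease into a ranked gene list in four steps.

1. **Disease → drug set.** A disease is represented by the approved drugs
   indicated for it: every Concept node whose name contains the query
   substring (case-insensitively) contributes its incoming INDICATION
   edges, and the resulting drugs are optionally restricted to those with
   an ATC code under a given prefix.  The premise is that an approved
   indication is high-confidence, regulator-vetted knowledge, so the drug
   set is a trustworthy entry point into the graph.

2. **Drug set → evidence paths.** Each drug's perturbation signatures carry
   per-gene differential-expression z-scores (LINCS L1000 Level 5 style:
   maximally processed, normalized moderated z-scores).  Every traversal
   `(drug)-(signature)-(gene)` with `|z|` strictly above the threshold is
   one evidence path.  Each (drug, signature) pair contributes
   independently — signatures are separate experiments, and replicate-level
   aggregation already happened upstream in Level-5 processing — so no
   per-drug or per-cell-line deduplication is applied.

3. **Paths → per-gene score.** The `k` paths of a gene are combined with
   Stouffer's weighted-z function, `Z = Σ w_i Z_i / sqrt(Σ w_i²)`, all
   weights one.  The function is used as an evidence aggregate, not a test
   statistic: no p-value is attached.  Two modes bracket the plausible
   weightings: D-weighted sets every contribution to 1 (score `√k`, rank
   order = path-count order, a pure degree measure), and Z-weighted uses
   the z magnitudes (score `Σ|z|/√k`), so a gene gains from being hit both
   often and strongly.

4. **Validation and prioritization.** The score vector is assessed as
   enrichment of known targets (ROC/AUC), and hitlists are post-ranked by
   Target Development Level and by non-dominated-solution ranks over
   bibliometric novelty and importance, surfacing understudied (Tdark)
   candidates.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `z_threshold` | 3 | strict `abs(z)` cutoff defining an evidence path.  Unitless (z-scores).  At 3, a standard-normal background passes ~0.27% of edges, so paths are rare unless signal is present. |
| `mode` | `"Z"` | `"Z"` aggregates z magnitudes; `"D"` counts paths. |
| `use_absolute_z` | `TRUE` | Magnitudes enter the aggregate by default: a strong perturbation is evidence of target engagement regardless of direction, and signed values from signatures perturbing the same gene in opposite directions would cancel.  `FALSE` switches to signed aggregation for sensitivity analysis. |
| `atc_prefix` | none | restricts the drug set by therapeutic class; drugs with no ATC codes fail a restricted query, because the restriction exists precisely to focus the etiology. |
| `universe` | all genes | validation universe.  Genes without surviving paths score 0 — absence of strong evidence is itself information — and the alternative `"hits"` universe restricts to scored genes. |

Choices made where the underlying definitions were genuinely open:

- **Signed vs. absolute z in Z mode.**  Thresholding is on `|z|` in any
  case; aggregation defaults to `|z|` (rationale above), with the signed
  variant exposed as an option rather than hidden.
- **"D-weighted" semantics.**  Degree weighting is implemented inside the
  same Stouffer framework by setting every contribution to 1, giving
  `√k`.  This preserves the degree-based rank order exactly while keeping
  both modes instances of one formula.
- **Strict threshold.**  `|z| > 3`, not `≥`: an edge exactly at the
  threshold is not a path.  The boundary is tested explicitly.
- **Tie-breaking.**  Equal scores rank by lexicographic gene key, so output
  is byte-identical across runs and input orderings.
- **Pareto dominance ties.**  In `nds_rank`, "superior" means strictly
  greater in *both* coordinates; a point equal in one coordinate does not
  dominate.  This is the conservative convention: it never demotes a point
  on the strength of a coordinate tie.  Ranks are invariant to monotone
  axis transforms, so log-scaled display never changes them.
- **ATC filter applies to drugs,** not to indications: the restriction is a
  property of the therapeutic class of the drug.

## Numerical and degenerate-input behaviour

- `stouffer_aggregate` rejects empty input and all-zero weight vectors; it
  is exactly scale-equivariant (`c·Z` in, `c·score` out).
- `roc_auc` groups tied scores into single ROC vertices; the trapezoidal
  area then equals the Mann–Whitney U statistic normalized by
  `n_pos · n_neg` with ties counting one half.  Single-class input is a
  usage error rather than a silent 0.5.
- An empty path set scores to an empty hitlist, not an error; an empty drug
  set *is* an error, since it means the disease query failed.
- Graph loading is fail-fast: unknown endpoint keys, duplicate edges,
  non-numeric or non-finite z, and malformed TDL values all abort with the
  first offending identifiers listed.  Duplicate edges can instead keep the
  first occurrence under `dedup = TRUE`.
- TSV export writes doubles with 17 significant digits, so export → load
  round-trips reproduce every z bit-for-bit.

## What the synthetic generator emulates — and what it does not

`generate_graph()` emulates the structural skeleton of a LINCS-style
build: a tripartite Drug–Signature–Gene graph with Cell and Concept
satellites, background signature–gene z-scores drawn from `N(0, noise_sd)`
(default standard normal, making the `|z| > 3` filter meaningfully sparse),
and a planted signal: edges joining query-drug signatures to designated
true-target genes get magnitude centered at `effect_mu` with random sign.
The random sign deliberately exercises the absolute-z default against
cancellation.  The defaults — 20 drugs (5 query), 10 signatures per drug, 5
cells, 500 genes, 10 true targets, edge density 0.2 — generate in well
under a second and give the validation suite a few thousand candidate
edges per run.

The generator does **not** emulate: real LINCS degree distributions (the
real graph is far sparser per signature and vastly larger), the cell-line
panel, correlated signatures of the same drug, compound-specific polypharm
effects, or any biology of which genes respond together.  Passing the
planted-recovery tests therefore shows that the *machinery* — path
enumeration, aggregation, labeling, ROC — correctly recovers signal it is
pointed at; it says nothing about the biological validity of rankings on
real data, and the published full-scale enrichment figures are not
reproducible at this scale (see the README's scale section).

## Problem sizes used by the test suite

Oracle comparisons run on graphs of at most ~10³ signature–gene edges
(exhaustive triple-loop enumeration), 200-point ROC inputs against an
O(n²) pairwise oracle, and 500-point non-dominated-rank inputs against
repeated front peeling.  Planted-recovery statistics use the generator
defaults over 20 fixed seeds for the null (mean AUC ≈ 0.5) and single
fixed seeds for the effect-size sweep (AUC monotone over effect 0/2/4,
≥ 0.9 at effect 4).  These sizes were chosen so a full run is a
coffee-sip, not a coffee-break, while keeping every comparison exact or
Monte-Carlo-tight.

## Known limitations

- The two scoring modes bracket, but cannot settle, the exact weighting an
  external graph-database implementation might use; both are exposed and
  validated against their own definitions.
- Bibliometric novelty/importance values are consumed as inputs; the text
  mining that produces them is upstream and out of scope, so `nds_rank`
  agreement with any published rank depends entirely on the input corpus.
- The indication model is flat: no ontology expansion beyond substring
  matching, no SNOMED→OMOP mapping.  A query term must appear verbatim
  (case-insensitively) in the concept name.
- `in_lincs` is defined as nonzero DRUG_SIGNATURE degree; a drug present in
  the source assay but filtered of all its signatures would count as absent.
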