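---
title: "Methods: screening, ranking and kinetics calculations in mkfop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, ranking and kinetics calculations in mkfop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mkfop)
```

# Scope

mkfop implements the computational stages of a megakaryocyte (MK)
forward-programming study: prioritizing a transcription-factor (TF)
cocktail from a source-versus-target expression contrast plus a
protein-interaction network, validating programmed-cell identity with a
whole-transcriptome comparison stack, and quantifying platelet output and
kinetics. Everything runs on synthetic data with planted ground truth;
real data in the same formats (tab-separated expression matrices with
sibling detection p-value files, two-column edge lists, GMT gene sets,
`time_h,count` survival CSVs) can be substituted at any entry point.

# The screening and ranking model

The screen computes, per gene, the log2 differential between the target
(MK) and source (pluripotent) group means. Genes qualify as candidates
when they are annotated as DNA-binding, detected in at least one target
sample (detection p ≤ 0.01), and upregulated by at least `min_log2fc`
(default 1 — the lower bound of the exclusion rule below, the only
fold-change threshold the screening stage uses). Curation then removes
histone-coding genes — abundant, strongly differential, but not lineage
TFs — and appends knowledge-based additions, which are accepted without
annotation because they enter on prior evidence, not screen statistics.

Ranking uses three criteria per candidate: the number of distinct
candidate interaction partners (internal degree), the number of distinct
chromatin-modifier partners (modifier degree; the modifier list —
acetyltransferases, deacetylases, DNA methyltransferases — is
caller-supplied), and the log2 differential. Before ranking, the exclusion
rule flags candidates with log2fc < 1 (reason `low_fc`) or with
1 ≤ log2fc < 2 and zero total degree (reason `low_fc_no_interactions`).
Both thresholds are parameters (`fc_hard`, `fc_soft`). "No reported
interactions" is read as internal degree + modifier degree = 0; flagged
records are never dropped, so the audit trail from screen to shortlist is
preserved in the ranked table.

No single published combination formula exists for the three criteria, so
the package uses the least-assumptive aggregator: competition ranking
(ties share the smallest ordinal; the next ordinal is skipped) per
criterion, each descending, summed with equal weight; the final order is
ascending rank sum, ties broken by higher log2fc and then gene id. The
ordering is therefore a documented design choice, deterministic and
invariant under input permutation, and is verified in the tests against a
naive double-loop oracle for small inputs. Symbol matching throughout is
exact and case-sensitive; aliasing is the caller's responsibility.

# The transcriptome comparison stack

*Filtering.* A probe is informative when its detection p ≤ 0.01 in at
least one sample; probes failing this in all samples are removed, and the
surviving probes form the universe for enrichment testing.

*Normalization.* Between-sample quantile normalization (via limma); after
it every sample carries the identical sorted value multiset. This is a
rank-based between-array normalization chosen because it is fully
specifiable; a robust-spline fit would require reproducing a specific
package's internals without changing what downstream stages consume.

*Differential expression.* Per-gene Welch two-sample t-tests on log2
intensities with Benjamini–Hochberg adjustment across all tested genes;
significance requires both |log2fc| ≥ 1 (2-fold) and FDR ≤ 0.05. Welch
was chosen over a moderated (empirical-Bayes) t because it makes the
fewest assumptions and its calibration can be verified by simulation: over
200 all-null simulations the empirical FDR stays below 7.5% (5% nominal
plus Monte-Carlo margin), and planted 2-fold effects at array-like noise
are recovered with ≥ 96% power (both checks are in the test suite).
Degenerate genes with zero variance in both groups and equal means get
p = 1. An optional known-batch mean-centering can be applied upstream by
the caller; latent-factor batch correction is out of scope.

*Clustering and ordination.* Samples are clustered by UPGMA (average
linkage) on d = 1 − Pearson correlation; merge heights are non-decreasing
on such metrics and match a naive O(n³) oracle in the tests. Ordination is
classical metric MDS (principal coordinates) of the samples; components
whose eigenvalue falls below 10⁻⁸ of the largest are dropped as numerical
noise, which keeps coordinate columns centered to machine precision and
pairwise distances exactly recoverable for embeddable configurations.

*Enrichment.* Over-representation uses the upper-tail hypergeometric
probability P(X ≥ k) with the informative-probe universe as sampling
frame and BH adjustment across terms. The running-sum enrichment score
orders genes by decreasing score; hits increment by |score|^p (normalized
to total 1 over hits, p = 1 by default), misses decrement by
1/(N − |S|); ES is the maximum deviation from zero. Because realistic
group sizes here can be as small as two samples, NES and FDR come from
gene-set-label permutation rather than phenotype permutation: NES divides
ES by the mean |ES| of same-sign permutations and the FDR is the same-sign
permutation tail probability. Ties in the ranking keep input order.

# Yield and kinetics calculations

All assay arithmetic is implemented exactly as defined: 2^−ΔCt relative
expression against a housekeeping reference; bead-based absolute counts;
platelets per MK sown; aggregation, delta-aggregation (unclamped —
negative deltas are informative) and adhesion percentages; thrombus
incorporation density per 100 µm²; and yield projection
total_platelets = input_cells × mk_per_input × platelets_per_mk with
whole transfusion units counted conservatively by floor at 2.4 × 10¹¹
platelets per unit (the unit size is a parameter since published unit
definitions vary).

Platelet survival is modelled as a single exponential relative to the
30-min post-transfusion equilibrium point: least squares of log2(count) on
time over the points at or after the equilibrium index, half-life =
−1/slope. Points before equilibrium are excluded because early samples
reflect distribution and recovery, not clearance. Multi-compartment
("multiple-hit") survival models are deliberately out of scope; on series
that decay exponentially the two approaches give the same trend estimate,
and the simpler model is fully specified by the data format. A
non-negative slope raises an error rather than returning a negative
half-life.

# What the synthetic data emulate

`gen_expression` draws per-gene baselines N(8, 1.5²) on the log2 scale
with independent Gaussian replicate noise (sd 0.3, a typical array
residual), 4 replicates per condition, 2000 genes of which 150 are
DNA-binding. Ten planted factors get +3 log2 units in the target — the
scale of a silent TF switching on — and twelve decoys get +1.5, enough to
pass the screening floor but within the exclusion band, so ranking is
exercised by candidates that genuinely compete. Ten histone genes and a
10% undetected-probe fraction exercise curation and filtering. The planted
network truth connects each planted factor to 3 neighbouring planted
factors and 2 modifiers; `gen_network` adds Erdős–Rényi background edges
(p = 0.005 over all node pairs, sampled by pair-index unranking so the
full pair list is never materialized). A scale-free background was
deliberately omitted: degree-count scoring needs a controlled null, not a
realistic topology. Count noise is multiplicative log-normal, the minimal
positive-support noise model under which log-linear fitting is unbiased in
the median. Seeds are explicit arguments everywhere; identical arguments
give bit-identical output, and the generator's own statistical calibration
(null differences centred at zero over 100 seeds) is property-tested.

These simulations establish that the pipeline recovers what it plants
under its stated noise model. They do not establish performance on real
arrays — probe-level artefacts, correlated noise, batch structure and
annotation error are not simulated — so passing tests validate the
computations, not biological discovery power.

# Problem sizes and numerical choices

The default test and acceptance workloads use 2000-gene screens across 40
seeds, 200 null simulations of 1000 genes, 1000-permutation GSEA, and 200
survival series per half-life value — sizes chosen so the full suite
completes in well under a minute per stage while leaving Monte-Carlo
margins comfortably wide. Oracle comparisons run at the sizes where
exhaustive enumeration is exact (hypergeometric N ≤ 12, UPGMA ≤ 8 leaves,
rankings ≤ 6 candidates, PCoA ≤ 10 points). Tolerances: 10⁻¹² for exact
arithmetic identities, 10⁻⁸–10⁻¹⁰ where eigendecompositions or
accumulated floating-point sums are involved.

# Known limitations

- The rank-sum aggregator is a design choice; any published shortlist
  produced by a different (unpublished) combination rule will not be
  reproduced exactly.
- Welch t with BH is calibrated but less powerful than moderated-t at
  very small n; with 2 samples per group the fold-change gate dominates.
- Gene-label permutation GSEA tests a different null than phenotype
  permutation; its FDR is conservative for correlated gene sets.
- Probe-to-gene collapsing for specific array platforms is not provided;
  real-data mode expects pre-collapsed input.
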