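---
title: "Screening osteogenic differentiation candidate genes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening osteogenic differentiation candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoscreen)
```

# The screening problem

Bone marrow-derived mesenchymal stem cells (BMSCs) can be driven toward
osteoblasts in culture; the genes that regulate this osteogenic
differentiation are candidate targets for bone-regeneration therapeutics.
`osteoscreen` implements a desk-scale screening pipeline for such
regulators from merged, multi-dataset log2 expression time courses: a
control group (day 0) against osteogenically induced samples labeled by
stage (day 1, 3, 7, ...), typically pooled from several array platforms
("batches").

The pipeline combines five evidence lines per gene:

1. **Differential expression** between control and induced samples,
   using an empirical-Bayes moderated t with asymmetric log fold-change
   gates.
2. **Association with osteoblast pathway activity**, where activity is a
   per-sample ssGSEA enrichment score of curated "osteoblast" gene sets.
3. **Co-expression hubness**: a frequency consensus over degree hubs of
   correlation-threshold networks (thresholds swept from 0.6 to 0.9),
   with up- and down-regulated genes analyzed in separate networks.
4. **PPI hubness**: degree ranking in the protein-protein interaction
   subgraph induced on the differentially expressed genes.
5. **Novelty**: genes that are themselves members of the osteoblast
   pathway gene sets, or that appear on a user-supplied
   previously-studied list, are excluded from candidacy with a recorded
   reason.

The ranked output is a per-gene evidence vector plus an additive score;
the intended headline behaviour is that a true, so-far-unannotated
regulator survives the novelty filter and ranks first.

# Statistical components

## Batch integration

`combat_adjust()` is the parametric empirical-Bayes location/scale
model: per gene, data are standardized under a linear model with batch
indicators and (by default) the control/induced group as a protected
covariate; per-batch location and scale effects are shrunk toward
batch-level normal and inverse-gamma priors by iterative EB estimation
(convergence when the relative parameter change drops below `1e-4`, at
most 100 iterations, batches processed in first-appearance order), then
removed. The group covariate matters: without it, the induction signal
of a batch whose samples skew late-stage would be absorbed into that
batch's location effect. The implementation reproduces the reference
parametric `sva::ComBat` output to numerical precision, which the test
suite asserts.

Two properties of this estimator are worth knowing. First, it is
deliberately *not* aggressive on batches that look clean: when the
between-batch spread of a gene's location estimates is comparable to
sampling noise, shrinkage retains much of the observed (noise-driven)
batch offset rather than forcing batch means to coincide. Second, it is
only approximately idempotent: re-adjusting adjusted data re-estimates
the shrunken scale factors and can still move individual values
noticeably. Exact idempotence would require dropping the EB shrinkage
(plain per-batch standardization), which is not the standard formulation
and not what this package implements.

## Moderated differential expression

`moderated_de()` fits the classic two-group model: log fold change is
the difference of group means on the log2 matrix; the pooled residual
variance gets a scaled inverse-chi-square prior whose hyperparameters
`(d0, s0^2)` are estimated by moment matching on the log variances
(with a Newton inverse-trigamma solve); the moderated t uses the
posterior variance and `d0 + d_g` degrees of freedom. With shrinkage
disabled the statistic reduces exactly to the pooled-variance two-sample
t, which is the limit the suite checks at `1e-10`. Underdispersed log
variances (an infeasible moment system) fall back to full shrinkage
(`d0 = Inf`) with a warning.

DEG classification uses BH-adjusted p < 0.05 with asymmetric gates:
logFC > 1 for upregulation and logFC < -0.8 for downregulation. The
asymmetry is deliberate — in osteogenic induction data a symmetric -1
gate yields very few downregulated genes — and both gates are exposed
as arguments. For the secondary high-vs-low regulator comparison (median
split on the candidate gene's expression, ties to "low"), no fold-change
gate is applied, only BH < 0.05.

## Pathway activity and association

`ssgsea_scores()` ranks genes within each sample (average ranks on
ties; walk order breaks remaining ties by gene symbol so scores are
deterministic) and integrates the difference between the rank-weighted
in-set CDF (`rank^alpha`, `alpha = 0.25`) and the unweighted out-of-set
ECDF — the running-sum total, not its supremum. Scores are normalized
by the matrix-wide range so they remain comparable across samples. One
caveat the suite documents: with `alpha > 0` the score of a *random*
set has a systematic positive offset (about a tenth of the score range),
because early list positions carry the largest weights; the offset is
common to all sets and harmless for the relative comparisons the
pipeline makes, and it vanishes at `alpha = 0`. Sets with fewer than
`min_overlap = 3` members in the matrix are dropped, as is the
degenerate set that contains every gene.

Gene-pathway association is plain Pearson correlation with the exact
t-transform p-value on `n - 2` df and BH correction applied jointly over
the whole gene-by-pathway table (the correction scope is a package
decision; a raw-p flag is available). Constant vectors are reported as
`r = 0, p = 1` with a warning rather than NA, so downstream counting
stays total.

## Networks and hubs

Co-expression networks connect genes with `|r|` at or above each
threshold in `{0.6, 0.7, 0.8, 0.9}` (absolute correlation by default —
within a single regulation direction the sign carries little extra
information; a signed mode exists). Per network, hubs are the `top_k =
5` largest degrees with ties at the k-th degree included and isolated
nodes never hubs; the consensus rule asks for a hub call in at least
half the thresholds. Neither the per-network hub rule nor the consensus
cutoff is canonical in the literature, so both are arguments and the
report always carries the per-threshold indicators for auditing. PPI
hubs are the `top_k = 9` largest degrees in the DEG-induced subgraph,
mirroring the scale of the nine-hub PPI analyses this pipeline is
patterned on.

## Enrichment

`hypergeometric_ora()` is the upper-tail hypergeometric test against a
finite universe with BH correction over the tested terms.
`preranked_gsea()` is the weighted Kolmogorov-Smirnov running sum
(weight `|stat|^1`, signed maximum deviation) with a gene-label
permutation null — the only null available to a pre-ranked list — and
`p = (1 + #{|ES_perm| >= |ES|}) / (nperm + 1)`, bit-reproducible under a
seed. No normalized enrichment score is computed; the permutation p with
BH correction is the decision statistic.

## Relative quantification

`fold_change_ddct()` implements 2^-ddCt from group-mean dCt values
(target minus housekeeping Ct), with per-replicate fold changes and
their SD emitted for mean-plus-minus-SD reporting. Swapping groups
inverts the fold exactly; shifting all Ct values cancels.

# The synthetic study generator

Because the pipeline's real inputs are merged public array datasets,
testing needs data with known truth. `simulate_timecourse()` emulates a
four-batch osteogenic induction cohort: five stages (day 0 = control,
days 1/3/7/14 induced), three samples per batch and stage — 60 samples,
12 controls versus 48 induced, the same shape and scale as the merged
multi-accession cohorts this design targets.

Generator choices, made once as study conditions:

* **Baselines and noise.** Baseline expression is Uniform(6, 12) log2
  units (planted up-DEGs start in the lower, down-DEGs in the upper half
  of that range, so induced profiles stay inside the plausible dynamic
  range). Gene-wise noise variance follows a scaled inverse chi-square
  law around `0.5^2` with 8 prior df — the microarray variance model
  that the moderated-t machinery itself assumes, which also makes the
  null raw p exactly calibrated for the type-I checks.
* **Planted DEGs.** 40 up and 30 down genes shift by 3 log2 units; half
  respond fully at day 1 and hold ("early"), half ramp linearly to day
  14. Averaged over the induced stages a ramp gene then shows ~1.3
  units, comfortably past the +1/-0.8 gates; sensitivity and empirical
  FDR of the gates are measured by the acceptance checks, not assumed.
* **Pathway modules.** Eight disjoint 15-gene modules respond to a
  latent activity `day / (day + 0.25)` (zero in controls, essentially
  switched on by day 1) with per-sample Gaussian jitter (sd 0.15);
  members add `0.6 x activity` log2 units. The last module is a
  "development" module with the sign flipped — differentiation and
  development activity move oppositely. Module categories mirror the
  five-way osteoblast annotation (differentiation, proliferation,
  transcription factor, signaling, development).
* **The regulator.** One up-DEG follows the deterministic stage
  activity with low residual noise (0.4 x the prior scale). That makes
  it strongly correlated with its module's ssGSEA score, strongly
  co-expressed with the early DEGs, and — by construction of the PPI
  fixture, where it touches every other DEG — the maximal-degree PPI
  node.
* **Competitor hubs and the novelty filter.** A handful of planted
  low-noise co-expression hub genes and eight designated high-degree
  PPI genes act as competitors with strong evidence. They are emitted
  as members of the osteoblast gene sets (the regulator never is), so
  the novelty filter excludes them — the generator reproduces the
  situation where strong hub genes are already pathway-annotated or
  previously studied and the interesting candidate is the one that is
  not.
* **Batch effects.** Additive per-gene shifts (sd 1 log2 unit, centered
  per gene across batches so batch structure does not move a gene's
  grand mean) and inverse-gamma multiplicative scale effects (shape 5,
  mean 1), applied after the biology.
* **Determinism.** One seed drives everything through fixed
  per-component substreams; the same configuration reproduces the same
  study bit for bit.

What the generator does *not* emulate: count noise (it is an
array-style Gaussian model, not RNA-seq), probe-level structure (probe
collapsing is tested on hand-built tables), correlated gene-gene
background beyond the planted modules, missing values, and any real
biological annotation. Passing tests therefore demonstrate the
statistical machinery and its integration, not performance on any real
dataset.

# Numerical and tie-breaking conventions

* BH adjustment: step-up with cumulative minimum, capped at 1, input
  order preserved.
* Median split: ties go to "low"; a degenerate all-equal split is an
  error.
* Fold-change ranking: descending logFC, ties by ascending raw p, then
  gene symbol — the ranking is always a strict permutation.
* Candidate ranking: descending additive score, ties by positive
  association count, then symbol.
* Hub calling: ties at the k-th degree are included; isolated nodes are
  never hubs; an all-isolated network yields an empty hub set with a
  warning.
* Edge lists: undirected, lexicographically ordered pairs, duplicate
  edges keep the maximum weight, self-loops dropped with a warning.
* ssGSEA and GSEA walk order: decreasing statistic, ties by gene symbol.
* ComBat EB iteration: relative-change tolerance `1e-4`, 100-iteration
  cap.

# Problem sizes used by the checks

The shipped suite and the acceptance script work at deliberately modest
scale: 1000-gene, 60-sample studies; 20-seed sweeps for recovery
properties; 50-seed sweeps for type-I control; 200 replicates at 199
permutations for GSEA null calibration; 10-gene instances for the
brute-force running-sum oracles; all hypergeometric configurations up to
a 15-gene universe for the ORA oracle. These sizes give the property
checks stable pass/fail behaviour while keeping a full run in the
minutes range.

# Known limitations

* The EB batch adjustment is not idempotent and by design leaves part
  of noise-driven batch offsets in place (see above); downstream
  inference happens on the adjusted matrix, as is standard.
* The weighted ssGSEA score of a random set is positively offset;
  cross-set comparisons are unaffected, absolute score values should
  not be over-interpreted.
* The additive evidence score is a determinized stand-in for what is in
  practice a narrative integration step; the full evidence vector is
  always emitted so any other rule can be applied.
* "Previously studied" status is user-supplied; the package makes no
  attempt to infer novelty from the literature.
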