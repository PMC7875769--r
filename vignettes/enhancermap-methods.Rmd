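---
title: "Methods: enhancer activity, modules, GWAS enrichment and QC"
author: "enhancermap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enhancer activity, modules, GWAS enrichment and QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the methods it implements: the
models and rules, the parameters that matter, the synthetic compendium that
backs the test suite, and the numerical and design choices made where the
procedure admitted more than one reading.

# The analysis chain

## Active enhancers

The atomic regulatory element is a DHS interval on a declared genome
(0-based, half-open). Element *d* is an **active enhancer** in biosample
*s* iff

1. *d* overlaps (by at least 1 bp) a segment labelled with one of the
   enhancer states `E7, E8, E9, E10, E11, E15` of the 18-state chromatin
   model in the segmentation of *s*, and
2. the mean H3K27ac −log₁₀ *P* over the window *d* extended by 100 bp on
   each side exceeds 2.

The mean in (2) is weighted by the base-pair overlap of each fixed-width
signal bin with the window — the natural continuous reading, since the
averaging weight is otherwise unspecified. `binarization_cutoff()` maps the
observed-scale cutoff of 2 onto another signal distribution via
inverse-ECDF (type-1) quantile matching, which is exact under monotone
rescaling.

Elements active under both enhancer- and promoter-state gates are
classified by a **strict** majority rule: enhancer iff more than 75 % of
active occurrences (per-biosample active calls, not per-state calls) carry
enhancer annotation, promoter symmetrically, dyadic otherwise. Exactly
75 % is dyadic.

## Enhancer modules

Modules are found by k-centroids on the binary activity matrix under the
Jaccard distance `d(x, c) = 1 − |x ∧ c| / |x ∨ c|`; two empty sets have
distance 0. Choices a Lloyd-style alternation needs pinned down:

* **Centroids.** Updated as within-module column means (interpretable as
  activity frequencies, matching the 25 % inclusion rule used downstream)
  and binarized at ≥ 0.5 for distance evaluation. A real-valued Jaccard
  extension (`1 − Σ min / Σ max`) is available behind
  `binary_centroids = FALSE`, since whether the original procedure used
  binary or real centroids is not determinable from its description.
* **Initialization.** Greedy farthest-point: a seeded random first
  centroid, then the element maximizing the minimal distance to the chosen
  set (ties to the lowest row index).
* **Restarts.** Lloyd iterations find local optima; `nstart = 5` seeded
  restarts are run and the lowest final mean-distance objective wins (ties
  to the earliest restart). One restart occasionally merges two planted
  modules and splits another on the reference compendium; five make
  recovery stable without noticeable cost at desk scale.
* **Ties and empties.** Assignment ties break to the lowest module index;
  an emptied module is re-seeded with the globally worst-fit element.
  Convergence is assignment stability or an objective change below
  `tol = 1e-6`, capped at `max_iter = 100`.

Diagonalization orders columns for display: columns with a value above
0.25 in more than half the rows first (the broadly active block, ordered
by name), the rest by argmax row, ties lexicographic. Metadata enrichment
tests each module's included biosamples (centre > 0.25) against each
metadata label by the upper-tail hypergeometric; entries with
−log₁₀ *p* > 2 are flagged for reporting.

## Enhancer–gene links

Candidates pair every enhancer with every gene whose TSS lies within 1 Mb
of the enhancer midpoint (inclusive; a TSS at 1,000,001 bp is out). The
feature vector is the per-mark Pearson correlation between gene expression
and enhancer signal across shared biosamples, plus the absolute TSS
distance. Undefined correlations (constant vectors) are recorded as 0 with
a flag rather than dropped. Negatives pair each positive's enhancer with a
uniformly random gene from a different chromosome; the **distance feature
of a negative reuses its paired positive's distance**, so the classifier
cannot separate the classes on distance alone (resampling from the
positive distance distribution is available as an alternative). The
classifier is 500 gradient-boosted trees of depth 4 at learning rate 0.05
(binary logistic objective, single thread, seeded); these hyperparameters
are conventional defaults, exposed as arguments. Probabilities are the
model's logistic outputs without recalibration; links are kept iff
probability strictly exceeds 5/7. Evaluation follows the standard
protocol: thresholded methods are scored on their kept set; score-only
baselines contribute each enhancer's single best-scoring gene; empty call
sets report precision 0 with an `undefined_precision` flag.

## GWAS pruning and enrichment

Pruning: HLA associations (chr6:29,691,116–33,054,976, inclusive; applied
only to positions on `chr6`) are removed first; within each study
(trait + PubMed id) associations are ranked by increasing p-value and a
SNP is kept iff it is more than 5,000 bp from every previously kept SNP on
its chromosome; studies with sample size below 10,000 or fewer than 10
kept SNPs are dropped. Sample size is taken per study (the study's
maximum), matching catalog conventions where it is a study-level field.

Overlap: a SNP (1-based) hits an enhancer iff it lies within 2,500 bp of
the enhancer midpoint, inclusive; midpoints of 0-based half-open intervals
are converted to 1-based coordinates before the comparison.

Flat enrichment: for each (annotation set, study) pair, the upper-tail
hypergeometric p-value of the 2×2 table of unique-SNP counts. A SNP shared
by several studies counts once in the catalog background (K, N) and once
per study in the study counts (k, n). All pairs of one call form a single
BH family, and significance is `p_BH ≤ α`.

Empirical FDR: the study labels are permuted **globally across all
associations** (positions fixed), breaking genotype–phenotype links while
preserving the positional architecture; the estimate is the mean number of
significant pairs over 100 shuffles divided by the real count. The
significance rule is the caller's: BH at α, or nominal p-values
(`adjust = "none"`) — under a global null BH typically yields zero
significant pairs in both numerator and denominator, so nominal
significance is the informative choice for calibration studies. Zero real
significant pairs yield `NA` with a warning.

The biosample tree is complete-linkage agglomeration on
1 − Jaccard(sample enhancer sets). The merge loop is written out rather
than delegated to `hclust()` because the tie-break is part of the
contract: among equally distant pairs, the pair whose smallest original
sample index is smallest merges first. Each node's **consensus** set is
the intersection of its leaves' enhancer sets (computed bottom-up, hence a
superset of its parent's); the **tested** set is consensus minus parent
consensus (the root tests its full consensus). Both the differential and
the full-consensus test are implemented (`tested = "consensus"`) because
the two available descriptions of the procedure differ; the differential
reading is the default since it makes ancestor–descendant tests disjoint
and matches the "differential enhancers between the node and its parent"
framing. Empty tested sets are skipped and recorded.

Rarefaction: greedy set cover over studies — at each step the set
significantly enriched for the most uncovered studies is added (ties by
set id); when no significant (set, uncovered study) pair remains, the pair
with maximal −log₁₀ *p* is used.

## Trait partitioning

Node tissue labels require a strict >50 % leaf majority (a 50/50 node is
"multiple"). The tissue × trait matrix sums −log₁₀ *p* over each tissue's
BH-significant nodes. Classification counts enriched tissues per trait:
one = unifactorial, two or more = multifactorial, at least
`poly_threshold` (default 10, configurable because the printed definition
of "polyfactorial" in the source material is internally inconsistent) =
polyfactorial. Binarization for classification and similarity uses BH
significance at the run's α, not a fixed −log₁₀ *p* cut.

The fixed-marginal permutation null holds the focal tissue's node rows
fixed and rewires the remaining block by checkerboard swaps: two random
1-entries spanning a 2×2 checkerboard are exchanged, preserving all row
and column sums. Each permutation sample applies 10 × (number of ones)
swaps after an equal burn-in; the attempt budget is 200 per requested swap.
The sampler is the standard degree-preserving chain; the marginal
constraint is stated by the method, the chain is this package's choice.
Row/column sums are asserted unchanged at every sample. When the matrix
admits **no** checkerboard, the conditional null given the marginals is a
point mass at the observed matrix, so every overlap p-value is 1 (with a
warning) — e.g. the all-ones matrix.

Networks: trait profiles are column-normalized; edges connect pairs at
cosine distance ≤ 0.25, coloured by the tissue maximizing the elementwise
product. The genetic-overlap network bins SNPs into 10-kb windows from
each chromosome start and links studies at Jaccard ≥ 1 % (the stricter 5 %
main-text variant is an argument). Force-directed layouts are
presentation-only, seeded, and excluded from correctness guarantees.

`nearest_expressed_gene()` filters genes to group-mean expression
≥ 2 log₂ FPKM **before** the nearest-TSS search; equidistant genes resolve
to the lower coordinate. `coassociation()` splits a focal trait's loci
into those co-locating with another trait's loci inside a node's enhancers
(both within 2.5 kb of the same enhancer midpoint) and the rest, and
applies a one-tailed Mann–Whitney test on locus significances. The exact
two-sample construction behind the original display is not fully
specified; this reading is isolated in that one function.

## Track QC and swap detection

`qc_metrics()` computes the four standard imputation-QC quantities:
genome-wide Pearson correlation, observed and imputed peak recoveries
(the top-1 %/top-5 % convention; ties in the top-x % sets break by genomic
order), and the AUC with which imputed signal ranks the top-1 % observed
bins. Low-quality tracks are flagged at the elbow of the ranked
correlations: the first rank where the drop exceeds 5 % of the previous
value, **including** the elbow point and everything below it.

The swap detectors compare each observed track with the imputed
compendium through top-10 average correlations. The flag rule — residuals
of a per-mark linear model beyond 3 SD — is implemented as **externally
studentized residuals with deterministic iterative peeling** (remove the
worst >3-SD point, refit on the clean remainder, score every point against
the clean fit). At compendium scale (thousands of tracks per regression)
this is numerically indistinguishable from dividing raw residuals by their
SD; at desk scale it is what keeps the rule meaningful: a single swapped
track is a high-leverage point that drags an OLS line through itself, and
co-occurring planted anomalies mask each other through the inflated
residual SD.

* **Sample swaps** regress the own-sample imputed correlation on the
  top-10 same-mark average, per mark, and flag the one-sided *deficit*
  tail (score < −3): an exchanged sample label lowers the own-sample
  correlation below what the track's mark-level similarity predicts.
* **Antibody swaps** evaluate each track only against its *maximal*
  cross-mark average (the candidate true mark) and require the compound
  signature: cross-mark excess > 3 SD in the per-mark-pair regression
  **and** a same-mark average more than 3 SD below its mark's cloud. The
  regression covariate is the mean cross-mark average over the remaining
  marks, which absorbs per-sample "connectivity" (a well-connected sample
  lifts all its cross-mark averages together; a swap lifts exactly one).
  The same-mark average is deliberately kept out of the regression design:
  its collapse under a swap would be an extreme-leverage x that anchors
  the fit.
* **Secondary reactivities** apply the same cross-mark machinery to delta
  tracks — observed minus quantile-rescaled imputed, clipped at zero
  (excess observed signal is what a secondary antibody produces; observed
  tracks are systematically the more intense) — without the same-mark
  deficit condition, since a clean delta legitimately resembles nothing.

Degenerate inputs are handled explicitly: all-constant tracks make the
correlation an error (not NaN); residual SDs below 1e−12 emit a warning
and no flags; all-zero delta tracks are skipped with a warning; marks with
fewer than 10 imputed tracks fall back to all available, with a warning.

# The synthetic compendium

The generator emulates the *inputs* of the chain with planted ground
truth, one RNG stream per artifact class (layout, signal, states,
expression, catalog, swaps) derived from the master seed by fixed offsets,
so resizing one artifact class never perturbs another. Identical configs
yield byte-identical emitted files.

* **Genome and elements.** Chromosomes `chrS1…chrSk` (synthetic names, so
  the HLA filter — keyed to `chr6` — never fires accidentally) in 200-bp
  bins, the analysis resolution at which all downstream rules operate.
  Elements occupy single bins placed on a 4-bin lattice, guaranteeing
  ≥3-bin spacing so ±100-bp flanks never collide.
* **Modules and activity.** Tissue-specific modules are assigned to groups
  round-robin; a configurable fraction of modules is broadly active
  (≥77 % of groups). An enhancer of a module is active in a biosample of
  the module's groups with probability 0.9, elsewhere with leak
  probability 0.02.
* **Signal.** Active elements carry a plateau of `2 + Gamma(2, 1.5)` over
  the element bin and both flanks (so the ±100-bp weighted mean equals the
  plateau and exceeds 2 by construction); background is
  `Exponential(mean 0.5)`. The distributional shapes are stand-ins —
  unimodal, strictly separating the cutoff of 2 in expectation with
  realistic tail overlap — and are not claims about real imputed tracks.
* **Genes and links.** Each gene's TSS bin carries promoter state;
  expression is a weighted sum (`U(0.5, 1.5)` weights) of the mean
  H3K27ac signal of its linked enhancers (preferentially one module,
  within 1 Mb) plus `N(0, 0.5)` noise.
* **GWAS catalog.** Each trait is one study with log-uniform p-values in
  [1e−30, 5e−8] and sample size ≥ 10,000; a planted fraction of its lead
  SNPs lands within 2.5 kb of midpoints of enhancers of the trait's
  tissue-group modules (module-level ground truth, not leak-contaminated
  per-sample calls); the rest are uniform.
* **QC compendium.** Observed/imputed track pairs are additive mixtures of
  a mark archetype (weight 0.55), a tissue-group profile (0.25) and a
  biosample-private profile (0.2), all Gamma over bins, plus Gaussian
  noise (SD 0.08 observed, half that imputed). The weights make the
  own-sample observed/imputed correlation clearly exceed any cross-sample
  correlation — the separation the detectors rely on. `plant_swaps()`
  exchanges track contents pairwise (same-mark across samples, or
  same-sample across marks) and spreads sample-swap pairs across distinct
  marks when possible: two equal outliers among the ~40 tracks of one
  regression would cap the attainable studentized score near √(n/k),
  independent of effect size.

**What the generator does not emulate** — and hence what green tests do
not show about real data: read-level noise and mappability, genuine LD
between SNPs (planted SNPs are placed directly in enhancers), realistic
chromatin-state transition structure (states exist only at element bins),
inter-mark biology (QC marks are independent archetypes), population
structure in GWAS, or the intensity distributions of real imputed tracks.
The suite demonstrates correctness of the rules and recoverability of
planted structure, not biological performance.

# Study designs used by the tests and the acceptance script

All sizes below are the package's reference desk-scale designs.

* **Reference compendium** (`synth_config()` defaults): 3 × 2 Mb
  chromosomes, 5 tissue groups × 8 biosamples, 6 modules × 200 enhancers
  (one broad), activity 0.9 / leak 0.02, 60 genes × 2 links, 10 traits ×
  30 lead SNPs at planted fraction 0.8. Module recovery is evaluated here
  with k = 6.
* **Trait-partitioning power**: 6 groups × 5 biosamples, 6 specific
  modules, no broad module — planted SNPs then live only in
  group-specific enhancers, so "the top-ranked node lies in the planted
  tissue's subtree" is a well-posed recovery question (a broad module
  would legitimately pull top nodes to multi-group clades).
* **Null calibration**: 4 × 6 Mb chromosomes, 10 groups × 1 biosample, 10
  disjoint modules × 2,000 enhancers, 15 traits × 600 lead SNPs, planted
  fraction 0. This design was chosen by a power analysis of hypergeometric
  discreteness: (i) ~40-kb SNP spacing keeps the 5-kb greedy pruning from
  imposing a hard-core point process, which would make real traits
  underdispersed (conservative) relative to trait-shuffled catalogs and
  bias the empirical FDR upward; (ii) per-set SNP capture
  probabilities ~0.35 with 600 draws keep the largest hypergeometric point
  masses near 0.03, so the discrete-conservative ECDF gap stays well below
  the KS 1 % critical value and the nominal rejection rate inside
  0.05 ± 0.02; (iii) one biosample per group with disjoint modules makes
  p-values across sets nearly independent, as the KS test assumes. The
  empirical-FDR bound is evaluated pooled across seeds (total shuffled
  significant / total real significant): per-seed ratios with ~5
  significant pairs in the denominator are dominated by Poisson noise.
* **Link recovery**: 250 genes × 2 links (500 planted links), features
  from H3K27ac correlation plus distance, 70/30 split by gene, evaluated
  on held-out positives and their paired negatives — the universe the
  paired-negative protocol defines. Scoring all window candidates instead
  would conflate module-mate correlation with link truth.
* **Swap detection**: 40 samples × 5 marks (200 tracks), 2 planted sample
  swaps + 2 antibody swaps.

# Determinism and the manifest

Every stochastic step derives its seed from one master seed by fixed
offsets; `run_pipeline()` run twice from one configuration produces
byte-identical outputs and manifest. The manifest records, per stage,
inputs, outputs, an md5 parameter hash and the seed; wall-clock timings go
to a side log rather than the manifest precisely so the manifest can be
byte-reproducible. Warnings raised by stages (skipped nodes, undefined
FDRs, degenerate inputs) surface in the stage records.

# Known limitations

* The k-centroids and tree procedures are exact implementations of the
  stated rules, but the rules themselves (binary vs real centroids;
  differential vs consensus tested sets) admit two readings each; both are
  implemented, defaults documented above.
* The classifier uses the five marks listed by the source description of
  the linking procedure; a sixth mark can be supplied, but the default
  synthetic compendium generates H3K27ac only.
* The Mann–Whitney co-association construction is a best-effort reading,
  isolated in one function.
* The checkerboard chain is run with a fixed swap budget, not a proven
  mixing time; for the matrix sizes used here the permutation-matrix
  structure of the test fixtures mixes far faster than the budget.
* Hypergeometric enrichment treats SNPs as exchangeable draws; real LD
  violates this, and the synthetic catalogs do not model LD, so
  calibration results transfer to real catalogs only after LD pruning of
  the kind the 5-kb greedy step approximates.
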