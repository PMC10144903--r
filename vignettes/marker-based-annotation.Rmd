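---
title: "Marker-based scoring, annotation and integration: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-based scoring, annotation and integration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markerscore)
```

## The problem

Single-cell RNA-seq datasets of the same tissue produced by different labs
disagree in two ways that block joint analysis: technical batch effects
separate the datasets in expression space, and each group annotates cell
types with its own names and resolution. Model-based integration methods
resolve this by fitting large models; `markerscore` instead relies on a
model-free observation: ranked cell-type marker genes are approximately
invariant across studies, so a representation built *only* from marker
expression both removes most batch signal and is directly interpretable.

The workflow has three computational stages:

1. **Marker identification.** From an annotated reference, one-vs-rest
   differential expression is run per cell type with an ensemble of tests,
   and the per-test rankings are merged into a single ranked marker list
   per type.
2. **Score-matrix construction.** Each dataset's cells × genes matrix is
   converted to a cells × cell-types *score matrix*: the weighted sum of
   each type's marker expression. This is the integrated representation.
3. **Consensus label transfer.** Cells are labeled by their argmax score,
   over-clustered many times on the score matrix, each clustering votes a
   label per cluster, and the per-cell majority across clusterings is the
   final call. A certainty score flags cells that match no reference type.

## Stage 1: the marker ensemble

No single DE test ranks markers reliably for all datasets, so an ensemble
is used. Three tests are built in — a tie-corrected one-sided Wilcoxon
rank-sum (exact null for small untied groups, normal approximation
otherwise), a one-sided Welch t, and a pure log2 fold-change ranking —
with Benjamini–Hochberg adjustment within each (cell type, test). Two
aggregation schemes merge the per-test rankings:

* **Top-k + robust rank aggregation** (default). Each test contributes its
  top 20 genes. For a gene with normalized ranks $r_{(1)} \le \dots \le
  r_{(m)}$ across the $m$ tests (absent = 1), the score is
  $\rho = \min_k P(\mathrm{Beta}(k,\, m-k+1) \le r_{(k)})$ — the most
  surprising of its order statistics under the null that ranks are
  uniform. Ranking uses raw $\rho$; a Bonferroni-corrected value (× m, the
  number of order statistics minimized over) is reported for reference.
* **Significant-only + Lancaster combination.** Only genes significant
  after adjustment contribute; their p-values are combined through
  chi-square quantile transforms with per-test weights (all weights 2 by
  default, which makes the combination exactly Fisher's method). The
  fold-change ranking carries no p-values, so under this scheme it cannot
  vote; the default uniform weight keeps the two p-bearing tests equal
  until users supply their own weights.

Per type, the top `n_markers` aggregated genes (default 20) form the
ranked marker list. The default depth follows the per-test compilation
depth; it is exposed because the right depth depends on how distinct the
reference's types are.

## Marker weights

Within a type's ranked list of $N$ markers, rank 1 contributes 100% of
its expression to the score and rank $N$ contributes 50%; intermediate
ranks $i \ge 2$ get weight $1 - (i/N)/2$. The printed formula alone gives
$1 - 1/(2N)$ at $i = 1$, which contradicts the stated 100% endpoint, so
the top rank is pinned to weight 1 and the discount applies to the rest —
the only reading that reproduces both endpoints exactly. Two alternative
schemes (Rank Order Centroid rescaled to the same [0.5, 1] envelope, and
a linear ratio scheme) are available as options; all three agree at the
endpoints. Weighting matters only when types share markers (subtypes);
with fully exclusive markers it rescales columns without changing the
argmax.

## Stage 2: score variants

With log-normalized expression $v$ (counts scaled to 10,000 per cell,
then $\ln(1+x)$), the **raw score** of cell $c$ for type $t$ is
$\sum_g w_{g,t}\, v_{c,g}$ over $t$'s markers present in the data. The
**thresholded TF-IDF variant** (the default, after Pliner et al.'s
scoring idea) first suppresses each marker's values below its
expression percentile across all cells (default 0.25, linear
interpolation between order statistics) and scales the survivors by
$\mathrm{idf} = \ln(1 + n/(1+n_{\mathrm{expr}}))$, up-weighting
selectively expressed markers; then the weighted sum is taken as before.
The TF-IDF form itself is a design choice (the idea is "suppress, then
re-weight by selectivity"); it is isolated behind the `variant` argument
so it can be swapped.

Markers absent from a query's gene set are dropped *without*
renormalizing the remaining weights — renormalization would silently
inflate the scores of poorly covered types — and the per-type fraction of
weight mass found is attached to the result (`coverage`). Gene matching
is case-sensitive and exact: silent case-folding hides species mix-ups.

Percentile thresholds are computed per dataset on whatever matrix is
being scored. When reference and query are scored separately (the normal
workflow), each uses its own thresholds; scoring a concatenated matrix is
the way to share thresholds, and is what a user should do when the query
is tiny.

## Stage 3: consensus transfer and certainty

The per-cell argmax label is noisy exactly where scores are close, so it
is reconciled with structure: a cosine kNN graph on score rows is
over-clustered with Louvain at resolutions 3, 5, 7 crossed with
neighborhood sizes 5, 10, 15 (nine runs; seeds derived as
`seed + 1000 * run`), each cluster takes the modal argmax label of its
members ("unassigned" votes only if unanimous; modal ties go to the type
with the higher within-cluster mean score, then lexicographic), and each
cell's final label is the majority across the nine runs (ties: the cell's
own score, then lexicographic). Majority vote is this package's committed
reading of "consensus"; the nine labelings are returned so other
reconciliations can be applied. Louvain (not Leiden) is the default to
match the method's description.

For large data the cells are split into contiguous index chunks and each
chunk is annotated independently — no cross-chunk graph, which is what
makes the parallel contract exact: one chunk is bit-identical to the
unchunked path, and chunking only perturbs results through graph
truncation at chunk boundaries. Callers who fear index-correlated
structure should shuffle cells first.

**Certainty.** With reference centroids $\mu_1, \dots, \mu_K$ (mean score
vector per reference label, Euclidean distances in score space — the
method's own representation), a query cell's certainty is
$C = 1 - D_\mathrm{1st}/D_{N\mathrm{th}}$, the complement of the ratio of
nearest to farthest centroid distance. Cells of a type the reference has
never seen sit far from *all* centroids at comparable distances, so
$C \to 0$; cells on a centroid have $C \to 1$ (a cell coinciding with all
centroids is defined as $C = 1$). Labels with $C$ below a threshold
(default 0.55, the middle of the useful 0.5–0.6 band) become
"unassigned".

## Evaluation metrics

Accuracy and macro F1 (unweighted mean of per-class F1 over classes
present in the truth; undefined F1 counts as 0) measure annotation.
Representation quality uses the rescaled silhouette $(1+S)/2$ under
Euclidean distance on the representation, and batch-mixing entropy: the
representation is embedded to 2-D with UMAP (cosine metric, 15 neighbors,
min_dist 0.1, seeded), regions are the 100 nearest embedded neighbors of
500 sampled cells, and the mean Shannon entropy of batch proportions per
region is reported, both raw and divided by $\ln(\text{batches})$. The
entropy is the conventional $-\sum x \ln x$ (the sign making "higher =
better mixed" true); the region construction is a design choice made for
determinism and scalability, since "region" admits many definitions. ARI
and NMI (natural logs, geometric-mean normalization; one-class edge cases
defined as 1 for identical partitions, else 0) compare labelings when
naming conventions differ. Aggregates: integration = 0.7·silhouette +
0.3·batch entropy, annotation = 0.7·macro F1 + 0.3·accuracy, overall =
their mean — weighting biological structure over mixing, and balanced
over raw accuracy.

## The synthetic test bench

Every claim above is exercised on seeded synthetic data, because the
atlas-scale datasets the method targets are not reproducible at desk
scale. The generator draws gene-wise negative-binomial counts
(mean–shape parameterization, variance $\mu + \mu^2/\theta$) with:
per-gene log-normal baseline means; a per-cell log-normal library-size
factor; a per-(batch, gene) log-normal factor of SD `batch_sigma` giving
multiplicative batch effects; and disjoint planted marker blocks whose
mean is multiplied by `marker_fold` in their own type. Hierarchy mode
adds subtypes that inherit the parent's markers and plant their own
exclusive markers at fold $\sqrt{\texttt{marker\_fold}}$ — markers of a
finer type are real but weaker, mirroring atlas high/low annotation
levels.

The benchmark conditions are 6 types × 3 batches × 100 cells per type
per batch (300 per type, 1800 total), 2000 genes, 15 markers per type at
fold 4, `batch_sigma` 0.5. The free noise knobs are set so the fixture
is a *clean* benchmark in which the planted structure is recoverable by
construction: baseline log-mean −0.5 and log-SD 1 (per-gene mean ≈ 1
count/cell — the per-gene depth of a well-sequenced droplet run, here
over a 2000-gene panel), library-size log-SD 0.3, and $\theta = 5$
(moderate overdispersion). At substantially shallower depth or stronger
overdispersion the types stop being separable in score space and every
downstream number degrades smoothly — a property of the data, not of the
implementation; the package makes no claim about that regime.

What the generator deliberately omits: doublets, ambient RNA,
batch-specific cell-type composition, zero inflation beyond the NB, and
correlated gene modules. Passing tests therefore show the machinery is
correct under the stated generative model, not that annotation will reach
the same numbers on real tissue.

## Numerical and degenerate-input choices

* Percentiles use type-7 linear interpolation (R's default), recorded so
  results are bit-reproducible.
* DE ranks break ties by gene index; RRA ties break by mean normalized
  rank then gene index; all consensus tie-breaks are documented above and
  end in lexicographic order, so every path is deterministic given the
  seed.
* A gene identical in both DE groups has statistic 0 and one-sided
  p = 0.5; a zero-variance Welch comparison with equal means likewise.
* All-zero score rows are "unassigned" at the argmax stage; all-zero
  marker columns pass through the TF-IDF transform as zeros.
* Matrix Market orientation is auto-detected from barcode/feature counts;
  a square matrix requires an explicit orientation flag.
* Counts with zero-total cells are rejected at normalization (the
  quantity count/total is undefined), naming the cells.

## Problem sizes used in the test suite

The shipped tests run the full benchmark fixture (1800 cells × 2000
genes) once and cache it; property suites use small exhaustive or random
configurations (rank lists over universes ≤ 5 against a
numerical-integration oracle, 100 random labelings against contingency
oracles). The complete suite runs in well under two minutes on one core.

## Known limitations

* Annotation quality is bounded by reference quality; types absent from
  the reference can only ever be "unassigned", never discovered.
* The chunked path's labels depend (mildly) on the chunk partition; exact
  reproducibility requires fixing `n_chunks` along with the seed.
* Batch-mixing entropy inherits UMAP's seed sensitivity; compare values
  only at a fixed seed.
* The score matrix has as many dimensions as reference cell types; with
  very few types the over-clustering graph can be rank-deficient and
  Louvain's resolution loses leverage.
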