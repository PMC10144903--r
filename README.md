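# markerscore

Model-free standardization, annotation and integration of single-cell
RNA-seq data through marker-weighted cell-type score matrices.

Single-cell datasets of the same tissue from different labs are separated
by batch effects and annotated with incompatible cell-type names and
resolutions. Model-based integration tools resolve this by training large
models; `markerscore` instead exploits the fact that ranked cell-type
marker genes are approximately invariant across studies. It converts each
dataset's cells × genes expression matrix into a cells × cell-types
**score matrix** — for cell *c* and type *t* with *N* ranked markers,

> score(c, t) = Σᵢ wᵢ · v(c, gᵢ),  w₁ = 1, wᵢ = 1 − (i/N)·(1/2) for i ≥ 2,

where *v* is log-normalized expression (scale factor 10,000), optionally
percentile-thresholded and TF-IDF-scaled first (the default "pliner"
variant, threshold 0.25). The top-ranked marker contributes 100% of its
expression, the last 50%. This low-dimensional representation removes
most batch signal while staying directly interpretable, and is the basis
for:

* **marker identification** from an annotated reference via an ensemble
  of one-vs-rest DE tests (Wilcoxon, Welch t, log2 fold change), merged
  by robust rank aggregation of each test's top 20 genes
  (ρ = minₖ P(Beta(k, m−k+1) ≤ r₍ₖ₎)) or by Lancaster/Fisher combination
  of significant p-values;
* **consensus label transfer**: per-cell argmax labels reconciled with
  Louvain over-clustering on a cosine kNN graph at resolutions 3/5/7 ×
  neighborhood sizes 5/10/15, majority-voted across the nine runs, with
  contiguous-chunk parallel execution for large data;
* **unseen-type detection** via the certainty score
  C = 1 − D₁ₛₜ/D_Nth (nearest over farthest reference-centroid distance;
  cells below the 0.55 default threshold become "unassigned");
* **evaluation**: accuracy, macro F1, rescaled silhouette (1+S)/2,
  UMAP-region batch-mixing entropy, ARI, NMI, and the weighted aggregates
  0.7·silhouette + 0.3·entropy and 0.7·macro F1 + 0.3·accuracy;
* a **seeded multi-batch simulator** (negative-binomial counts, planted
  exclusive markers, log-normal batch effects, optional two-level
  hierarchy) so the whole workflow is testable without external atlases.

## Worked example

Simulate the standard benchmark (6 types × 3 batches × 100 cells each,
2000 genes, 15 markers/type at fold 4, batch sigma 0.5), split it into
reference and query, and run the full workflow:

```r
library(markerscore)

sim <- simulate_multibatch(SimulationConfig(seed = 7))
sp  <- split_reference_query(sim$data, fraction = 0.5, seed = 7)
ref <- log_normalize(sp$reference)
qry <- log_normalize(sp$query)

markers <- identify_markers(ref, scheme = "rra_top20", n_markers = 15)
wm      <- weigh_markers(markers)
ref_scores <- score_cells(ref, wm, variant = "pliner")
qry_scores <- score_cells(qry, wm, variant = "pliner")

ann  <- consensus_annotate(qry_scores, ConsensusConfig(seed = 7))
cert <- compute_certainty(qry_scores, ref_scores, sp$reference$label)
ann$certainty <- cert$certainty
ann  <- apply_unassigned(ann, 0.55)

report <- aggregate_scores(MetricsReport(
  acc        = overall_accuracy(ann$label, qry$label),
  macro_f1   = macro_f1(ann$label, qry$label),
  s_celltype = celltype_silhouette(qry_scores$scores, qry$label),
  s_batch    = batch_entropy_mixing(qry_scores$scores, qry$batch, seed = 7)))
print(report)
```

```
MetricsReport:
  acc           0.9033
  macro_f1      0.9486
  s_celltype    0.7255
  s_batch       0.9855
  s_integration 0.8035
  s_annotation  0.9350
  s_overall     0.8692
```

Reading the numbers: the 900 query cells are annotated with macro F1 0.95
against the planted truth (accuracy is lower only because 86 low-certainty
cells were conservatively left "unassigned"); in score space the six types
stay separated (rescaled silhouette 0.73 > 0.5, the no-structure point)
while the three batches are almost perfectly mixed (normalized entropy
0.99, where 1 means every local neighborhood holds all batches in equal
proportion). Skipping `apply_unassigned` — sensible when the reference is
known to cover every query type — raises accuracy to 0.99.

## Command line

The same workflow is scriptable via the installed `exec/markerscore`
Rscript:

```sh
markerscore simulate --seed 3 --out sim/
markerscore markers  --ref sim/ --labels sim/metadata.tsv --out markers.csv
markerscore score    --data sim/ --markers markers.csv --variant pliner --out scores.csv
markerscore annotate --scores scores.csv --chunks 4 --seed 3 --out annot.tsv
markerscore evaluate --pred annot.tsv --truth sim/metadata.tsv \
                     --representation scores.csv --out report.json
markerscore run      --config run.yaml        # all stages from a YAML config
```

Logs go to stderr, data to files; any stage failure exits non-zero with a
one-line cause.

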