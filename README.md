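# stgraft

Transfer cell-type annotations from an annotated scRNA-seq reference onto
single-cell-resolution spatial transcriptomics data.

Spatial platforms (Stereo-seq cellbins, STARmap, CosMx SMI, Slide-seq)
resolve where cells sit but measure fewer genes, more noisily, than
scRNA-seq — so cell types cannot be called well from the spatial counts
alone. stgraft bridges the two modalities in three stages:

1. **Batch harmonization.** A conditional negative-binomial variational
   autoencoder is trained jointly on the gene-aligned reference matrix *SI*
   and spatial matrix *TI* with the modality as a covariate, yielding
   embeddings *SSI* and *TTI* (n × 30) in one shared latent space.
2. **Teacher.** An xgboost classifier (softmax multi-class objective,
   probabilistic form, DART tree-dropout) trained on (*SSI*, labels) emits a
   row-stochastic teacher distribution *D* over the C cell types for every
   spatial cell.
3. **Graph annotator.** A k-nearest-neighbour spatial graph with Gaussian
   kernel weights `W(u,v) = exp(-d(u,v)² / 2θ²)` (k = 30) feeds a dual
   autoencoder: a fully connected AE compresses *TTI* to *X* (MSE loss
   `L_AE`), a two-layer graph encoder produces a spatial embedding *S*, and
   the fusion `Z = X + S` drives both an inner-product adjacency decoder
   `A' = σ(Z Zᵀ)` (binary cross-entropy `L_GAE`) and a linear-softmax
   student `P = softmax(Z W + b)` distilled against the frozen teacher,
   `L_SSL = -(1/(n·c)) Σ D log P`. Training minimizes
   `w_dae·L_AE + w_gae·L_GAE + w_cls·L_SSL` (defaults 1, 1, 20); the
   student's argmax is the final, spatially coherent label per cell.

The package also ships the pseudo spatial-transcriptomics simulators used
for benchmarking (hierarchical rows and 100 × 100 blocks with dispersed
background cells, sampled with replacement from a reference) and the
evaluation metrics (accuracy, support-weighted F1, confusion matrices,
expression-profile Spearman correlation, neighbour-label agreement), so the
entire pipeline is testable without any download.

## Worked example

Simulate an annotated reference (5 × 1,000 cells, 500 genes, four types
with 25 signature genes at 4-fold change plus a flat background type) and a
hierarchical pseudo-tissue (4,000 typed cells in four rows + 400 dispersed
background cells), then transfer labels end to end:

```r
library(stgraft)

ref <- make_synthetic_reference(synthetic_reference_spec(seed = 12))
st  <- make_pseudo_st(ref, pseudo_layout("hierarchical"), seed = 13)
res <- run_pipeline(ref, st, pipeline_config(seed = 1))
res$report
#> <evaluation_report> n = 4400, accuracy = 0.9900, weighted F1 = 0.9898
#> per-class F1:
#> background      type1      type2      type3      type4
#>     0.9420     0.9940     0.9916     0.9960     0.9965
```

The accuracy is the fraction of the 4,400 spatial cells whose predicted
type equals the simulation's ground truth; the weighted F1 averages
per-class F1 with ground-truth support weights. Background cells — which
have no signature genes and no spatial region of their own — are the hard
class: graph smoothing absorbs a few of them into the surrounding region,
while the four structured types are recovered almost perfectly and the
final labels are spatially more coherent than the teacher's:

```r
accuracy_score(st$labels, res$teacher_labels)
#> [1] 0.9984091
neighbor_agreement(res$labels, res$graph)        # spatial coherence
#> [1] 0.7937665
neighbor_agreement(res$teacher_labels, res$graph)
#> [1] 0.7798011
plot_spatial_labels(st, res$labels)              # predicted tissue map
```

Real datasets enter through plain-text dataset directories
(`counts.mtx`/`counts.csv` + `genes.tsv` + `cells.tsv` with `x`, `y` and a
label column); see `?read_expression_dataset`. A thin command-line wrapper
lives at `inst/scripts/stgraft.R`:

```sh
Rscript inst/scripts/stgraft.R simulate --layout hierarchical --seed 0 \
    --out-ref ref_dir --out-st st_dir
Rscript inst/scripts/stgraft.R run --ref ref_dir --st st_dir --out out
```

## Documentation

The methods vignette
(`vignettes/annotation-transfer-methods.Rmd`) describes the model, its
assumptions, every tunable parameter with its default and rationale, what
the simulators do and do not emulate, numerical edge cases, and known
limitations.
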