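# mmihcl

Integration of two **unpaired** single-cell modalities that share only a
handful of weakly correlated *linked features* — e.g. a small protein
panel against genome-wide RNA, or ATAC regions against gene expression,
measured on different cells. The package produces an explicit cell-to-cell
matching between the modalities and a joint embedding, and is aimed at
computational biologists who need cross-modality label transfer, feature
prediction, or a co-embedding when no paired multi-omic assay exists.

## Method at a glance

With matrices $X \in \mathbb R^{n_x \times p_x}$,
$Y \in \mathbb R^{n_y \times p_y}$ and $p_\text{link}$ linked feature
pairs (linkage ratio
$\rho = \min(p_\text{link}/p_x,\, p_\text{link}/p_y)$; $\rho < 10\%$ is
the weak-linkage regime):

1. **Adaptive kNN graphs.** Per modality, a weighted cell graph on PCA
   scores whose per-cell neighbour count $k_i$ is chosen by a closed-form
   threshold on the cell's top-$k$ weight distribution
   ($w_{ij} > 1 - (\bar w_i - 1 - \delta)^2$), then symmetric GCN
   normalization $\bar A = D^{-1/2}(A+I)D^{-1/2}$.
2. **Hypergraph-contrastive encoder** $H(E, \bar A)$: per layer, a local
   GCN branch $\bar A E^{(l-1)}$ and a global branch
   $H(H^\top E^{(l-1)})$ through a learned soft incidence
   $H = E^{(0)}W$ onto $K$ virtual hyperedges, aligned by an InfoNCE
   loss with temperature $\tau$ and trained with weight decay
   $\lambda\lVert W\rVert^2$; branch and layer outputs are summed.
3. **Matching.** Correlation distances $d_{ij} = \mathrm{clip}(1 -
   \mathrm{PCC}, 0, 1)$ between encoded linked-feature rows; *p-best*
   rectangular linear assignment (solve, forbid selected pairs, re-solve)
   gives a many-to-many matching, filtered at matching degree
   $\alpha$.
4. **Iterated CCA.** $T$ rounds of: CCA joint embedding conditioned on
   the current matching → hypergraph re-encoding → re-matching; then a
   final 1-to-$N$ assignment and joint embeddings $X^*, Y^*$.

An integration scorecard (ACC, FOSCTTM, NMI, ARI, silhouette widths,
graph connectivity) nests into
$S_\text{overall} = 0.6\,S_\text{bio} + 0.4\,S_\text{batch}$.
See `vignettes/mmihcl-methods.Rmd` for the full model, parameter table
and design rationale.

## Worked example

Simulate two linked modalities with known ground truth, integrate, and
score the result:

```r
library(mmihcl)

spec <- synthetic_spec(n_types = 3, proportions = c(0.5, 0.3, 0.2),
                       nx = 300, ny = 300, px = 120, py = 120,
                       p_link = 40, linkage_strength = 0.9,
                       noise_sd = 0.3, seed = 42)
sim <- generate_multimodal(spec)
sim$linkage
#> <feature_linkage> 40 pairs, rho = 0.3333 (strong linkage)

fit <- mmihcl(sim$x, sim$y, config = mmihcl_config(seed = 42))
fit
#> <mmihcl> 300 x-cells ~ 300 y-cells, 40 linked features (rho = 0.333, strong)
#>   3 refinement iteration(s); final matching: 300 pairs (N = 1), mean degree 0.196
#>   joint embeddings: 300 x 20 and 300 x 20

matching_accuracy(fit$matching, sim$x$cell_type_labels,
                  sim$y$cell_type_labels)
#> [1] 1

report <- evaluate_integration(fit$x_embedding, fit$y_embedding,
                               sim$x$cell_type_labels,
                               sim$y$cell_type_labels,
                               matching = fit$matching,
                               true_pairs = sim$true_pairs, seed = 42)
report
#> <mmihcl_metrics>
#>   ACC      1.0000   FOSCTTM 0.2743 (paired: TRUE)
#>   NMI      0.9792   ARI     0.9900   ASW_label 0.5347
#>   GC       1.0000   ASW_batch 0.9905
#>   S_bio    0.8459   S_batch 0.9952   S_overall 0.9057
```

Read the numbers as follows: every matched cell pair shares a cell type
(`ACC = 1`), and community structure in the joint embedding reproduces
the planted types almost exactly (`NMI = 0.98`, `ARI = 0.99`); the two
modalities are thoroughly mixed within types (`ASW_batch`, `GC` near 1).
`FOSCTTM = 0.27` says that on this deliberately small fixture about a
quarter of the other modality sits closer than a cell's true partner —
alignment is sharp at the cell-type level and coarser at the
individual-cell level; on the larger reference fixture
(`reference_fixtures()$easy_strong`, 600 cells per side) the median
FOSCTTM over five seeds drops below 0.1. Cross-modality feature
prediction for the x-cells is then one call,
`predict(fit, reference = sim$y)`.

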