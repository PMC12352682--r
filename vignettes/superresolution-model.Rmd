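---
title: "Doubling the resolution of spot-based spatial transcriptomics: model and evaluation protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doubling the resolution of spot-based spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resolvST)
```

## The problem

Sequencing-based spatial transcriptomics measures whole-transcriptome
expression at capture spots arranged on a lattice: a square grid with
roughly 100 µm spacing on classic ST arrays, or a staggered honeycomb with
55 µm spacing on Visium arrays (where array row and column always share
parity). Most of the tissue surface lies between spots, so downstream
analyses — domain segmentation, trajectory inference, marker visualization —
work on a heavily subsampled picture of the section. `resolvST` predicts
expression at the unmeasured half-step lattice positions, doubling the grid
resolution per gene.

Each gene's spatial expression is treated as a single-channel grayscale
image on the lattice (genes form the batch axis of a `G × 1 × H × W`
tensor; non-tissue cells carry a binary mask). The model outputs four
*sub-pixel channels* per input cell — the values at offsets (0,0), (0,1),
(1,0), (1,1) of the corresponding 2×2 block of the doubled grid — which
interleave into a `2H × 2W` map. This is the standard sub-pixel
convolution trick from image super-resolution, transplanted to expression
grids.

## Architecture

Three components process the grid in sequence, each compensating for a
blind spot of the others:

1. **Convolutional front-end.** Two stacked 3×3 convolutions
   (same-padding, ReLU) extract local co-expression texture. Functionally
   related genes co-vary over short ranges; small receptive fields model
   that directly.
2. **Vision transformer.** The feature map is cut into non-overlapping
   `p × p` patches (`p = 2` by default), each linearly embedded into a
   `D`-dimensional token (`D = 128`). Because self-attention is
   permutation-invariant, a sinusoidal absolute positional encoding
   `PE(pos, 2i) = sin(pos / 10000^{2i/D})`,
   `PE(pos, 2i+1) = cos(pos / 10000^{2i/D})` is added to the tokens.
   Multi-head self-attention (4 heads) then mixes information across the
   whole section, capturing long-range co-expression that convolutions
   cannot see.
3. **Graph module.** Attention has no built-in notion of physical
   adjacency, so each transformer block also aggregates over a fixed
   spatial graph: patches are nodes at their (row, col) patch indices,
   edge weights are a Gaussian kernel of the Euclidean distance,
   `A_ij = exp(-d_ij² / 2σ²)`, only each node's `k = 4` nearest
   neighbours are kept (the four lattice neighbours), and rows are
   normalized as `Ã_ij = A_ij M_ij / (Σ_j A_ij M_ij + ε)`. The graph
   depends on geometry alone; it is built once per input shape and is not
   learned.

Each block composes the three sub-layers with pre-norm residuals:

```
z <- z + MHSA(LN(z))
z <- z + Proj(Ã · LN(z))      # graph aggregation, projected back to D
z <- z + MLP(LN(z))
```

A final linear head maps every token to `4p²` values, which un-flatten to
the four sub-pixel channels over that patch ("inverse patch
reconstruction").

### Design choices that the architecture description leaves open

* **Sub-layer order.** The graph step sits between attention and the MLP
  with its own residual; ablation flags (`use_gnn`, `use_pos_encoding`)
  allow removing either ingredient for sensitivity checks.
* **Self-loops.** A patch is *not* its own neighbour by default: the
  distance-0 kernel weight of 1 would dominate the row normalization and
  wash out neighbour signal. `gnn_include_self = TRUE` reverses this.
* **kNN ties.** Integer lattices make equidistant neighbours the rule,
  not the exception; ties break toward the smaller row-major index, which
  keeps graphs, and therefore fits, bit-reproducible.
* **CNN width.** Both convolution layers default to 32 channels; the
  patch embedding accepts any channel count, so the second layer is not
  forced back to one channel.
* **MLP width.** Hidden size is `2D`. Chosen for CPU tractability; the
  usual `4D` is available through `mlp_ratio`.
* **σ and ε.** `σ = 1` patch-index unit puts the four lattice neighbours
  at kernel weight `exp(-1/2)` before normalization; `ε = 1e-8` merely
  guards the division.

## Self-supervised training and the evaluation protocol

No high-resolution ground truth exists, so training pairs are
manufactured geometrically from the section itself:

* **Square dialect:** retain spots at even rows *and* even columns (step
  2 in both axes).
* **Visium dialect:** the honeycomb occupies equal-parity positions;
  retaining the (even, even) spots keeps an evenly spread sample whose
  halved indices tile a full rectangular grid. (The even-odd rule is the
  only parity rule whose retained set preserves the section's geometric
  coverage; other parities can be composed manually from the grid
  operations if wanted.)

All remaining tissue positions are *masked*: their expression is removed
from the input and they double as the held-out test set. The model maps
the low-resolution grid to a 2× output that overlays the original grid
position-for-position (retained spot `(2i, 2j)` → low-res cell `(i, j)` →
output position `(2i, 2j)`), and is trained to reconstruct the *entire*
original grid under the masked loss below. At inference the
full-resolution grid goes in and a 2× enhanced grid comes out, with the
tissue mask upsampled nearest-neighbour and everything outside the
original boundary excluded from scoring. Training and evaluation happen
on the same section (transductive use); nothing transfers across tissues.

### Masked multi-channel loss

With `Y` the `2H × 2W` target, `M` its tissue mask, and `Ŷ` the
four-channel prediction, the loss is

$$L = \frac{1}{4N}\sum_{k=0}^{3}\sum_{i,j} M^{(k)}_{i,j}
      \left(\hat Y^{(k)}_{i,j} - Y^{(k)}_{i,j}\right)^2,
\qquad N = \sum_{k,i,j} M^{(k)}_{i,j},$$

where `M^(k)[i,j] = M[2i + ⌊k/2⌋, 2j + (k mod 2)]` subsamples the mask
into the channels. Note that the `1/(4N)` prefactor divides by 4 even
though `N` already counts all four channels; the package implements this
printed form verbatim (`loss_norm = "paper_form"`) and offers the plain
per-valid-pixel mean (`loss_norm = "per_pixel"`), which differs by an
exact factor 4 and is absorbed by the learning rate.

Optimization is full-batch Adam (`lr = 1e-3`, no scheduler, no early
stopping, no augmentation) for a fixed number of epochs — 500 by default,
matching the reference protocol for real sections; the synthetic cases in
the tests converge far sooner. Initialization is truncated-normal
(sd 0.02) with zeroed biases, fully seeded: two fits with the same seed
are bit-identical, which the test suite asserts end-to-end.

### Normalization

How raw counts should be transformed before entering the network is a
modelling choice the protocol itself does not fix. The package default —
applied by `superres()` and exposed as `normalize_expression()` —
is `log1p` followed by per-gene min-max scaling to `[0, 1]`, which puts
every gene on the loss's natural scale regardless of expression level.
The per-gene parameters are stored so `predict(fit, scale = "original")`
can invert the transform. Gene-wise Pearson evaluation is unaffected by
any per-gene monotone-affine rescaling of the log values.

## Baselines and metrics

Four classical interpolators impute the masked positions per gene from
the retained grid: nearest-neighbour (ties to the smaller row-major
index), bilinear, bicubic (separable Catmull-Rom, `a = -0.5`, linear
border extrapolation so linear fields stay exact up to the hull edge),
and NEDI — new edge-directed interpolation in its canonical 2× form,
estimating per-position interpolation weights by ridge-regularized local
least squares on the low-resolution covariance, with bilinear fallback at
borders and ill-conditioned windows. Targets outside the retained convex
hull fall back to nearest-neighbour and are flagged.

Accuracy is summarized by the gene-wise Pearson correlation between
predicted and true expression across evaluated spots, reported per gene
with the median as the headline statistic; zero-variance genes are
excluded from the median and counted separately. Spatial-domain quality
uses the silhouette coefficient and the Davies–Bouldin index with
Euclidean distances (the conventional choice; the definitions do not fix
the metric). Which embedding feeds the cluster metrics is likewise open;
the package clusters principal components of the super-resolved
expression by k-means (`cluster_metrics()`), and both metric functions
accept any embedding matrix.

## What the synthetic generator does and does not cover

`simulate_spots()` emulates the *structure* of spot data — both lattice
dialects, smooth per-gene fields (oriented linear gradients, Gaussian
bumps, Voronoi-domain constants), Gaussian or Poisson count noise, and a
disk tissue mask that exercises the masking path of the loss. Noise-free
gradient fields are exactly linear, giving the bilinear baseline a known
zero-error case; domain-constant genes give cluster metrics a known
near-perfect case.

It makes no attempt to match real tissue count distributions:
no gene–gene correlation structure beyond the shared domains, no
dropout/zero inflation, no spatial platform artefacts. Passing tests
therefore demonstrate that the machinery is correct and that the model
learns genuine spatial structure — not that it attains any particular
accuracy on real sections, which depends on data depth, normalization and
training length.

## Numerical choices and problem sizes

Degenerate inputs are handled explicitly: down-sampling refuses grids
smaller than 2×2 and empty masks; an all-zero loss mask is a guarded
division; a single-patch grid skips the graph step (no neighbours exist);
odd grid dimensions are zero-padded to patch multiples and cropped back
after reconstruction, with ⌈H/2⌉×⌈W/2⌉ low-resolution grids. Layer norm
uses eps 1e-5; Adam uses (0.9, 0.999, 1e-8).

The bundled checks run at desk scale, chosen so the whole suite finishes
in minutes on one CPU core: the end-to-end learning check trains 300
epochs on a 24 × 24 section with 16 smooth-field genes (gradients and
Gaussian bumps, Gaussian noise sd 0.05) and must halve its initial loss
and match or beat the nearest-neighbour baseline's median PCC at the
held-out positions; the determinism check repeats a full
simulate→train→enhance→evaluate cycle at 16 × 16. The acceptance script
reruns the 24 × 24 benchmark plus a 20 × 20 domain-structured clustering
benchmark and reports exactly what it computes. Real Visium sections
(thousands of spots) train in tens of minutes on a CPU at the default
configuration; reducing `embed_dim` or `n_blocks` trades accuracy for
time smoothly.

## Known limitations

* Only the 2× scale factor is implemented — the sub-pixel contract is
  fixed at four channels.
* Genes are processed as independent images; cross-gene parameters are
  shared but there is no explicit gene–gene modelling.
* The transductive protocol trains one model per section; there is no
  pretraining or transfer.
* Histology images, pixel-space coordinates, UMAP/trajectory analyses and
  comparisons against learned external imputation methods are out of
  scope.
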