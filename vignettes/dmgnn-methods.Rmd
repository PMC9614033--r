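---
title: "DM-GNN: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DM-GNN: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`dmgnn` classifies two cohorts of individual brain connectomes with a
multi-modality graph neural network built on corresponding cortical
landmarks (the DICCCOL system: 358 cortical points whose fiber-bundle
shape signatures are consistent across individuals), and ranks landmarks
as candidate biomarkers by their learned attention scores. This vignette
is the package's own account of the method: the model, its assumptions,
the tunable parameters, the synthetic data it is validated on, and the
numerical choices made where the design was genuinely open.

## Pipeline overview

For every subject the pipeline builds one graph:

* **Nodes** are the 358 corresponding landmarks (configurable count).
* **Node features** are rows of the subject's functional similarity
  matrix $F \in \mathbb{R}^{N \times N}$ (Pearson correlation between
  landmark time series), sparsified by a group-difference mask.
* **Edges** are thresholded tractography fiber counts: $E_{ij} = 1$ iff
  more than $t_s$ fibers pass within a capture radius of both landmarks
  $i$ and $j$; the diagonal of $E$ is fixed at 1.

A three-layer graph convolutional network with self-attention graph
pooling (SAGPool) and a mean/max readout produces a two-class score and,
as a by-product, a per-landmark attention score $Z$ used for biomarker
ranking.

## Landmark correspondence via trace-maps

A landmark's fiber bundle is every tractography streamline with at least
one point within `radius` (default 2 mm) of the landmark. The bundle's
shape is summarized by the **trace-map**: each fiber is resampled to 31
equidistant points and split into three parts of exactly one third of its
arc length; each part contributes the unit chord from its first to its
last point; each chord increments the bin of the equal-area sphere
partition region containing it. With 122 regions this yields a 122-bin
histogram whose mass is exactly $3 \times$ the bundle size — a testable
conservation law, which is why bins are raw counts (Pearson correlation,
the only consumer, is scale-invariant anyway).

Resampling to $3m + 1$ points (not $3m$) makes the three parts share
boundary points, so "three equal parts" is exact rather than
approximate for unevenly sampled polylines.

The 122-region partition is a deterministic zonal equal-area
construction: two polar caps plus collars cut into equal-longitude
sectors, with collar boundaries placed at colatitudes derived from
cumulative region counts so that every region's area is exactly
$4\pi/122$. Being pure arithmetic, it is identical across platforms and
needs no shipped lookup table.

Landmark prediction on a new subject starts from per-landmark initial
vertices (on real data these come from a surface registration, which is
out of scope and consumed as an input; synthetic cohorts supply them
directly). Candidates are all mesh vertices within five rings of the
initial vertex (the initial vertex itself included). Each candidate is
scored by the mean Pearson correlation between its bundle trace-map and
the ten template trace-maps for that landmark; the best-scoring candidate
wins, with exact ties broken by the lowest vertex index. Mean rather than
maximum over templates keeps the score symmetric in the templates and
deterministic. Candidates with constant (typically empty) trace-maps are
excluded; if all candidates are degenerate the error names the landmark.

## Graph construction

**Functional features.** $F_{ij}$ is the Pearson correlation of the
landmark time series (the reference acquisition length is 2,300 volumes).
For each matrix entry, a two-sample t-test compares its values across
group-A versus group-B *training* subjects; entries with $p < f_s$
(default 0.05) are retained, all others set to 0. This mask is the only
sparsification of $F$ — the threshold named $f_s$ plays both the role of
the significance level and of the sparsity control, because no second
magnitude cutoff exists in the design. The mask is computed per
cross-validation fold from that fold's training subjects only and then
applied to training *and* test subjects of the fold; tests verify the
mask is bit-identical under permutation of test-subject labels (no
leakage). Entries constant across all training subjects (e.g. the unit
diagonal) have an undefined t statistic and are defined as not
significant, hence masked to 0. The Welch (unequal-variance) test is the
default, with the pooled-variance Student test behind `var_equal = TRUE`;
the choice is not dictated by the protocol and Welch is the more robust
default. No multiple-testing correction is applied, by design.

**Structural edges.** $S_{ij}$ counts fibers incident (within `radius`)
to both landmarks; $E_{ij} = \mathbf{1}[S_{ij} > t_s]$ off the diagonal
and $E_{ii} = 1$. Neither $f_s$ nor $t_s$ has a canonical numeric value
in the protocol, so both are required configuration with defaults
$f_s = 0.05$ and $t_s = 0$ (any shared fiber makes an edge), and both are
echoed into every run's provenance record.

## The model

**Graph convolution.** With $\Lambda_{ii} = \sum_j E_{ij} + 1$,

$$\tilde{E} = \Lambda^{-1/2} (E + I) \Lambda^{-1/2}, \qquad
  f_h = \sigma(\tilde{E}\, f_{in}\, W).$$

The formula is implemented literally: since a valid $E$ already has unit
diagonal, $E + I$ gives every node a self-loop weight of 2. The
conventional single-self-loop normalization is available as
`strict_gcn = TRUE`. Either way $\tilde{E}$ is symmetric and non-negative
with spectral radius exactly 1 on a connected graph — an invariant the
tests check against a dense eigensolver. The activation $\sigma$ is the
rectifier. Three layers (input $\to$ 64, 64 $\to$ 64, 64 $\to$ 64) with
row-wise layer normalization between consecutive layers; the per-layer
outputs are concatenated into $f_c \in \mathbb{R}^{N \times 192}$.

**Self-attention pooling.**

$$Z = \tanh(\tilde{E}\, f_c\, W_s), \qquad
  \text{index} = \mathrm{top}(Z, \lfloor kN \rfloor)$$

with $k = 0.2$. The score activation is not named in the protocol; tanh
is the default of the SAGPool architecture this module follows. The floor
convention for $\lfloor kN \rfloor$ is fixed by the published
top-30% biomarker count ($\lfloor 0.3 \times 358 \rfloor = 107$), and the
same rounding is applied to $k$ ($\lfloor 0.2 \times 358 \rfloor = 71$
retained nodes). Retained features are multiplied by their attention
scores (standard SAGPool gating); the equations alone do not state the
multiplication, so `gate = FALSE` disables it. Exact score ties resolve
to the lower node index. Note that scores computed through BLAS matrix
products are rarely bit-equal, so the tie rule matters mainly for
degenerate inputs.

**Readout and head.** The graph feature is the concatenation of the
column-wise mean and column-wise maximum of the retained features
(length 384), followed by a rectified fully connected layer of width 64
and a linear layer to 2 class scores; the predicted class is the argmax,
ties resolving to the first class. The head's hidden width is not in the
protocol; 64 matches the convolution width. Training minimizes softmax
cross-entropy (the loss is likewise unstated; cross-entropy is the
standard choice for a two-way softmax head).

**Optimization.** Adam (learning rate $3 \times 10^{-4}$, weight decay
0.002 added to gradients, $\beta = (0.9, 0.999)$), full batch, exactly
800 epochs, no early stopping; the final-epoch model is the fold model.
All graphs of a batch are stacked as one disjoint-union graph (a
block-diagonal sparse adjacency), which is numerically identical to
per-subject processing and keeps the training loop in BLAS. Weights are
initialized with a fixed-seed scaled-uniform (Glorot) scheme; every seed
is recorded in the provenance file. Backpropagation is implemented
analytically and is verified against central finite differences (relative
error $< 10^{-4}$ per coordinate) and against a straight-line
reference forward pass in the test suite.

## Evaluation protocol

Stratified 5-fold cross-validation (both groups split evenly across
folds, a 4:1 train:test ratio), subject order shuffled by a seed. With
86 balanced subjects the test folds have sizes 18/17/17/17/17. Reported
metrics: per-fold accuracy, sensitivity and specificity with group A
("preterm-like") as the positive class — stated explicitly because SEN
and SPE swap under relabeling — plus their mean and standard deviation,
and a single ROC-AUC over the pooled test scores of all folds, computed
by the rank-statistic (Mann–Whitney) formulation with midrank ties. The
ROC input is the softmax probability of the positive class.

## Biomarker analysis

Attention scores $Z$ are min–max normalized to $[0, 1]$ per subject
(z-scoring is available by flag; min–max is the default reading of
"normalize the score", and a constant vector maps to zeros). Group-level
importance is the per-landmark mean of normalized scores over group A,
group B, and all subjects; the top 30% ($\lfloor 0.3 N \rfloor$
landmarks) of each form the group biomarker sets, and overlaps between
sets are reported. Each subject's attention comes, by default, from the
model of the fold in which that subject was a *test* subject (one model
per subject, no information from models trained on that subject);
`attention_from = "train"` switches to training-fold models instead —
the protocol's wording ("when training") is ambiguous and both readings
are provided.

Region-level summaries consume a plain mapping table (subject, landmark,
region label) — performing an actual atlas surface registration is out of
scope. Two aggregation schemes are provided: *registration priority*
(each subject's own top set mapped through its own labels, proportions
averaged over subjects) and *average priority* (one top set from the
group-mean scores, mapped per subject, then averaged). They agree exactly
when all subjects share one selection and one labeling, which the tests
verify. Proportions are over the biomarker count per subject, so each
subject's distribution sums to 1 including any explicit "unmapped" share.
Functional-partition participation works the same way per developmental
time point, with partitions absent at a time point reported as
not-applicable rather than 0.

## The synthetic cohort generator

The generator exists so every stage is testable without restricted
neuroimaging data; it emulates the *interfaces* of a real cohort (meshes,
fibers, landmark time series, labels), not its biophysics — no
hemodynamic model, no diffusion simulation, no registration.

* **Surface**: a subdivided icosahedron sphere (12, 42, 162, 642, ...
  vertices; radius 50 mm), the smallest subdivision holding the requested
  landmark count; landmarks are evenly spaced vertices. The closed,
  near-uniform mesh makes ring neighborhoods and recovery tests exact.
* **Time series**: a latent-factor model. A cohort-level loading matrix
  $\Lambda \in \mathbb{R}^{N \times 10}$ (standard normal entries) is
  perturbed per subject with loading noise (`subject_sd = 0.3`) — without
  it, between-subject variance of correlation entries would be limited to
  finite-length sampling noise and the t-test mask would be degenerate.
  Node signals are $\Lambda_s\, s(t) + \varepsilon$, with unit-variance
  latent components and white noise (`noise_sd = 1`). The pipeline only
  consumes Pearson correlations, so any model with controllable pairwise
  correlation suffices; this is the simplest such model.
* **Planted functional effect**: group B gains one extra latent component
  loaded only by the `effect_nodes`, with loading `functional_effect`.
  This confines the planted correlation shift to effect-node *pairs*
  (mixed pairs change only at second order through the variance), which
  is what makes "did the pipeline recover the planted nodes?" a
  well-posed question. With the default scales, `functional_effect = 2`
  shifts effect-pair correlations by roughly $+0.3$ — a strong,
  clearly-separable group difference; 1 is a moderate one.
* **Fibers**: jittered arcs (0.5 mm Gaussian jitter) between each
  landmark and its 3 nearest landmarks, with Poisson bundle sizes (mean
  4), plus three short local fibers through every landmark so no
  trace-map is empty. On effect-node pairs, group B's bundle mean is
  shifted by `structural_effect`.
* **Templates**: ten perturbed copies of the first subject's per-landmark
  trace-maps (relative Gaussian bin noise, default 0.1); zero
  perturbation reproduces the reference exactly.

Everything is deterministic given the seed, and identical cohorts are
byte-identical on disk.

What passing recovery tests on this generator shows: the masks, model,
training loop, attention ranking and metrics do what they claim on data
whose ground truth is known. What it does not show: performance on real
infant cohorts, where correlation structure is non-stationary, fiber
counts are registration- and tracking-dependent, and group differences
are far subtler than the planted ones.

## Problem sizes and numerical choices

The test suite and the acceptance script run the full protocol at reduced
problem sizes chosen to exercise every code path at desk scale: the
recovery experiment uses 20 + 20 subjects, 100 landmarks with a strong
planted effect on 30, the full 2,300 timepoints, 5 folds, and 200 epochs
(training on these cohorts converges well before 200 epochs; the package
default remains 800). The landmark-prediction check runs at the full 358
landmarks. Tolerances: layer-norm epsilon $10^{-5}$; spectral-radius
checks at $10^{-10}$; forward-pass reference agreement at $10^{-8}$.
Degenerate inputs fail loudly with the offending landmark, subject or
field named: zero-variance time series, all-constant candidate
trace-maps, empty pooled graphs, single-class AUC.

Landmark indices are 1-based everywhere, in memory and in files, matching
R convention.

## Known limitations

* Attention-based biomarker recovery is statistical, not exact: gradient
  flows only through the $\lfloor kN \rfloor$ selected nodes, so the
  learned attention partially reflects its own initialization, and
  planted-node enrichment is strongest in the biomarker set of the group
  that carries the planted component (group A's signals contain no
  information about which nodes were planted when the effect is
  B-specific).
* The packaged surface-registration step is a pass-through: initial
  vertices and region tables are inputs.
* Training is CPU, dense-BLAS based; it is sized for hundreds of
  landmarks and tens of subjects, not for voxel-level graphs.
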