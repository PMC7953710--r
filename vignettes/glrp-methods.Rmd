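---
title: "Graph-CNN classification and GLRP explanations: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-CNN classification and GLRP explanations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(glrpnet)
```

## The task and the model

`glrpnet` classifies *graph signals*: each sample assigns one non-negative
value (for example a min-shifted gene expression measurement) to every
vertex of a fixed undirected weighted graph (for example a protein–protein
interaction network restricted to its main connected component — graph
convolutions require a connected operand).  The classifier is a spectral
graph convolutional network; the package's purpose is not only to train it
but to *explain* every single prediction as a relevance score per vertex,
and to condense those scores into a sample-specific molecular subnetwork.

### Spectral convolution

The combinatorial Laplacian `L = D − A` is symmetric positive
semidefinite; its eigendecomposition defines the graph Fourier transform,
and filtering a signal means reweighting its graph-frequency components.
To keep filters local and avoid the eigendecomposition, the filter is a
degree-(K−1) polynomial in the rescaled Laplacian
`L̃ = L/λ_max − I` (spectrum inside [−1, 1]), evaluated with the Chebyshev
recurrence `x̄_k = 2L̃x̄_{k−1} − x̄_{k−2}` — exactly K−1 sparse
matrix–vector products per filter.  A `K`-term filter sees a (K−1)-hop
neighbourhood; the default architecture uses `K = 8` (a 7-hop reach, which
on a small-world molecular network covers most of the graph) and 16–32
filters per layer.

`λ_max` is estimated by power iteration (relative tolerance 1e-10, capped
at 1000 iterations).  We do *not* apply a safety margin on top of the
estimate: the estimation error is orders of magnitude below the 1e-6 band
we assert on the rescaled spectrum, and an inflated `λ_max` would make the
simple closed-form cases (a single edge has `λ_max = 2` exactly) fail
their documented values.  Edgeless graphs (`λ_max < 1e-12`) are rejected
rather than divided by.

### Pooling

Max pooling of size 2 requires pairing vertices.  Levels of greedy
heavy-edge matching (score `w_uv(1/d_u + 1/d_v)`, seeded visiting order,
ties toward the smaller vertex index) build a coarsening hierarchy;
unmatched vertices become singletons.  A permutation with inserted
edgeless *fake* vertices makes every coarse vertex a contiguous fine pair,
so pooling is a 1-D pairwise max.  Fake vertices carry zero signal and are
explicitly masked to zero after every convolution (bias included), so they
can never win a max against a real non-negative activation and they receive
zero relevance.  One consequence of our graph container (zero diagonal) is
that intra-cluster weights are dropped when building coarse graphs rather
than kept as self-loops; this only affects the coarse Laplacians' fine
structure, not the pairing.

### Training

Softmax cross-entropy over two output neurons, minimized by momentum SGD
(defaults: learning rate 0.01, momentum 0.9, decay 0.95 per epoch, 100
epochs, batch 64, global gradient-norm clipping at 5 — all config-driven).
Clipping matters: conv-coefficient gradient norms grow with the vertex
count, so on larger graphs the first unclipped momentum steps overshoot,
kill the ReLU chain and pin training at log 2.  Gradients are derived by hand,
including the adjoint of the Chebyshev recurrence, and are verified against
central finite differences in the test suite.  Training is deterministic
given a seed (initialisation, coarsening order and batch shuffling all
draw from the seeded RNG).

**Initialisation.**  Weights are truncated normal (resampled beyond 2σ)
with fan-in scaling, σ = √(2/fan_in) (He).  A fixed σ = 0.1 — common in
older graph-CNN code — puts the 8192-wide flattened dense layer at
pre-activation sd ≈ 9; the first SGD updates then explode and kill most
conv-layer ReLU units, pinning training at log 2 on some seeds.  Fan-in
scaling keeps activations and gradients at unit scale; a fixed σ remains
available (`chebnet_hyperparams(init_sd = )`).  Biases are initialised at
0.01, *not* 0: with strictly
non-negative inputs, a filter whose coefficient combination happens to be
negative produces negative pre-activations at every vertex, and with a
zero bias such a ReLU channel is dead at initialisation with exactly zero
gradient — with few filters a whole network can be born dead (we observed
training pinned at log 2 with all conv pre-activations negative).  A small
positive bias keeps near-zero channels trainable and is negligible
elsewhere; note the z⁺ relevance rule excludes biases regardless.

## GLRP

Relevance starts at the **pre-softmax logit** of the explained output
neuron (by default the predicted one).  Propagating through softmax is
undefined for the z⁺ rule, and the logit preserves the argmax, which is
what the explanation is about; a non-positive explained logit triggers a
warning (the relevance map is then ~0 or sign-flipped and should not be
interpreted).  The z⁺ rule

`R_i = Σ_j a_i w⁺_ij / (Σ_i a_i w⁺_ij + ε) R_j`, `ε = 1e-10`

is applied at every dense layer, at every graph-convolutional layer, and
at the input layer too — legitimate because all activations in the ReLU
chain, and the inputs themselves, are non-negative.  For a conv layer the
channel-`j` filter is materialized as the dense matrix
`Ŵ_j = [L̄_0 … L̄_{K−1}] θ_{·,j}` (the `L̄_k` are the Chebyshev matrix
polynomials of `L̃`, computed once per layer and reused across channels and
samples) and treated as a fully connected weight matrix; per-channel input
relevances are summed.  These matrices are dense — `m × (m·F_in)` per
channel — so materialization is lazy, per channel, and guarded by a
memory budget (default 4 GiB).  Max-pool relevance is winner-take-all to
the forward argmax (ties to the lower index), conserving relevance
exactly.

**Conservation.**  Biases are excluded from the rule as written, so with
all biases zero the total relevance equals the explained logit to ~1e-10
relative (asserted at 1e-6).  With biases, relevance is *absorbed* at
neurons whose positive-weighted input sum is ~0 (for example neurons active
purely through their bias): the per-layer relevance totals are reported by
`conservation_report()` — the leak is always non-negative — and are never
redistributed.

## Synthetic worlds and what a green test establishes

The generators state the world the tests live in; their defaults are fixed
once and not revisited:

* `make_scale_free_graph()` — preferential attachment (2 edges per new
  vertex), unit weights.  The degree tail follows a power law whose
  Hill/Clauset MLE exponent lands in the high-2s, emulating the
  connectivity regime of protein interaction networks (reported exponent
  around 2.7).
* `plant_class_signals()` — baseline `|N(μ0 = 2, σ = 1)|` per vertex
  (folded normal, honouring the non-negative-input contract of the z⁺
  input rule); class 1 adds `δ = 2` on a BFS-grown connected module
  (default 50 of 2000 vertices).  `δ/σ = 2` per vertex makes the *summed*
  signal essentially noise-free (z ≈ 2√50), so a held-out AUC near 1 is
  expected, and the informative measurement is where the relevance lands.
* `make_grid_patterns()` — horizontal vs vertical full-length bars
  (thickness 2, amplitude 1) at uniform random positions on an 8-NN
  unit-weight pixel grid, plus `|N(0, 0.1)|` background noise: a
  clean-background regime comparable to digit images, standing in for the
  usual image sanity check.
* `make_pathways()` — one "causal" gene set overlapping the planted module
  by a stated fraction, the rest uniform draws.

These worlds emulate localized, additive class signal with i.i.d. noise.
They do **not** emulate microarray noise structure, gene–gene correlation
beyond the planted module, batch effects, or class imbalance — so a green
test establishes the correctness and localization behaviour of the
machinery, not clinical performance.

One behaviour worth knowing: explanations are class-specific.  In the
planted-module world the module drives the class-1 logit, so class-1
samples' subnetworks hit the causal pathway hard, while class-0
explanations legitimately concentrate elsewhere (whatever evidence raises
the class-0 logit).  The end-to-end test asserts causal-pathway dominance
for class-1 samples only.

## Numerical and design decisions

* **Quantile normalization** uses the mean order-statistic reference with
  exact tie-averaging; a fit/apply split (`quantile_reference()` /
  `quantile_normalize(X, reference)`) lets held-out samples be normalized
  onto the training reference, since normalizing all samples jointly leaks
  test information — both uses are supported, the joint fit being the
  default for a single cohort.
* **Duplicate gene columns** collapse to the column with the highest mean,
  mirroring the common probe-collapsing rule.
* **Expression terciles** (LOW/NORMAL/HIGH) use type-7 linear-interpolation
  quantiles at 25%/75% over the whole cohort by default.
* **Fisher test** is one-sided ("greater"): the question is enrichment,
  not depletion.  Adjustment is Benjamini–Hochberg by default
  (Bonferroni available); the adjustment family is per query set by
  default, switchable to one global family.
* **ΔP** is the symmetric-difference fraction of matched pathway genes,
  explicitly undefined (NA, skipped with a count) when neither subnetwork
  touches the pathway.
* **Top-k selection** breaks relevance ties by vertex name; `k = 140` is a
  visualization-driven default, not methodological.
* **Pooling placement**: one pool after each convolution layer (the
  default architecture helper), since the alternative reading — a single
  pooling stage — is supported by just omitting pool layers from the spec.
* **Epsilon** is 1e-10 (the stabilizer is occasionally printed ambiguously
  as "1^-10" in the literature; we read it as 1e-10), configurable.

## Known limitations

* Dense `Ŵ_j` materialization makes GLRP memory- and compute-heavy on
  large graphs (quadratic in m per channel); the memory guard fails fast
  rather than thrash.
* No batch normalization (no accepted LRP rule for it on graph-CNNs), no
  LRP variants (αβ, flat, γ), no relevant-walk explanations.
* Training is plain momentum SGD in base R: adequate at the desk scales
  used here, not engineered for 10^5-vertex graphs.
* The z⁺ rule explains *positive evidence* for the selected class only;
  misclassified samples can be explained from the true class via
  `class_selection = "specified"`, but the interpretation caveats above
  apply.
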