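---
title: "Dimensionality-reduction-based multimodal data fusion with fusedr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dimensionality-reduction-based multimodal data fusion with fusedr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fusedr)
```

## The problem

Biomedical studies increasingly collect several *modalities* per subject —
imaging-derived feature tables, proteomic panels, histomorphometry,
spectroscopy — that differ wildly in dimensionality and scale. A classifier
built on any one modality uses only part of the available signal; naive
concatenation of feature tables lets high-dimensional or noisy modalities
swamp informative low-dimensional ones. fusedr implements a generalized
workflow for *knowledge-representation-then-fusion*: each modality is first
transformed into a common space where scale and dimensionality differences
disappear, and the transformed representations are then combined into a
single fused result $\hat{\mathcal R}$ on which one predictor is built.

The workflow has four stages, each of which is an exchangeable module:

1. **Representation** — per modality: classifier decision scores
   $h_m(c_i) \in [0,1]$, kernel similarity matrices $K_m$, or
   low-dimensional embeddings $y_m$ obtained by eigendecomposition.
2. **Resampling** (optional) — $n$ "weak" representations per modality by
   perturbing samples (bootstrap), features (feature bagging), or a
   representation parameter, giving $nM$ representations in total.
3. **Fusion** — direct combination (concatenation, means, probabilistic
   AND), co-association matrix fusion, or structural (Procrustes) fusion.
4. **Weighting** — either unweighted combination (element-wise median as a
   robust estimator) or weights learned from training labels on a simplex
   grid.

## The central eigenproblems

Pairwise structure in a representation is captured by an $N \times N$
co-association matrix $W$ (affinities, distances, or kernel values). An
embedding $y$ that preserves this structure solves the generalized
eigenproblem

$$W y = \lambda D y, \qquad D_{ii} = \sum_j W_{ij}, \qquad y^\top D y = 1 .$$

Fusion happens by combining several co-association matrices
$\hat W = \xi_t[W_t]$ (element-wise median or weighted sum) before a single
decomposition. For kernel representations the same problem is kernelized:
with $\hat K = \sum_t \alpha_t K_t$,

$$\hat K \hat W \hat K^\top R = \Lambda\,(\hat K \hat D \hat K^\top + \varepsilon I)\, R,$$

and the fused embedding is $Y = \hat K^\top R$. With $\hat K = I$ and
$\varepsilon = 0$ this reduces exactly to the plain co-association problem —
the test suite asserts the reduction to $10^{-10}$ on random instances,
using two independent solver code paths.

### Numerical choices

* **Solver.** The plain problem is solved on the symmetrized form
  $S = D^{-1/2} W D^{-1/2}$; the kernelized problem through a Cholesky
  factor of the right-hand matrix. Both routes use dense symmetric `eigen`.
* **The trivial solution.** $\lambda = 1$ with constant $y$ always solves
  the plain problem and carries no information. We remove it by *deflating*
  the known constant direction to eigenvalue $-2$ (plain problem) or by
  projecting the direction $u_0$ with $\hat K R^{-1} u_0 \approx
  \mathbf 1$ out of the whitened operator (kernelized problem). Deflation
  — rather than "drop the top eigenpair" — keeps the behavior correct when
  $\lambda = 1$ is degenerate: for a disconnected graph the
  component-separating eigenvector also has $\lambda = 1$ and must be
  retained.
* **Ridge.** Kernel Gram products are typically rank-deficient, so the
  right-hand side gets $\varepsilon = 10^{-6}\,\mathrm{tr}(\hat K \hat D
  \hat K^\top)/N$ by default; `ridge = 0` raises a categorized error when
  the Cholesky fails.
* **Sign and order.** Columns are eigenvalue-descending; each eigenvector's
  largest-magnitude entry is made positive so results are reproducible.
  Eigenvalue ties keep solver output order; we document rather than break
  this instability.
* **Bandwidths.** Gaussian kernels and affinities default to the median
  pairwise Euclidean distance ("median heuristic"), which adapts to each
  modality's scale.
* **Distances to affinities.** Median-combined *distance* co-association
  matrices are bridged to the affinity needed by the eigenproblem via
  $\exp(-\hat W^2 / 2\sigma^2)$ with $\sigma$ the median off-diagonal
  distance.

## The four preset strategies

| preset | resampling | representation | weighting | fusion |
|---|---|---|---|---|
| `DFS-DD` | — | decisions | unweighted | direct, probabilistic AND |
| `DFS-EC` | feature bagging | PCA | unweighted | co-association, median |
| `DFS-KC` | — | Gaussian kernels | weighted, semi-supervised | multi-kernel embedding |
| `DFS-ES` | — | LLE | unweighted | structural (Procrustes, mean) |

Defaults the presets had to fix where the method family leaves them open:

* **`DFS-EC`**: $n = 25$ feature-bagged replicates per modality with subset
  size $\lceil P/2 \rceil$ (drawn with replacement); distances in PCA score
  space as the co-association quantifier.
* **`DFS-DD`**: the AND is the probability product
  $\hat h = \prod_m h_m$; a hard conjunction of thresholded decisions is
  available as the `binary_and` rule.
* **Embedding dimensionality**: $d = 5$ package-wide. `DFS-KC` uses
  $d = 2$: the label-tilted co-association concentrates class contrast in
  the leading eigenvectors, and trailing eigenvectors only hand the
  bagged-tree classifier noise to overfit.
* **LLE neighborhood**: $k = 10$, standard (unmodified) LLE with
  regularized local Gram matrices.

### The semi-supervised co-association matrix of DFS-KC

All entries of $\hat W$ live on one *affinity scale*: the base matrix is
the weighted mean of diagonal-normalized kernels. Training labels then
modulate the labeled block — same-class pairs scaled by $(1 + \gamma)$,
cross-class pairs by $(1 - \gamma)$, with supervision strength
$\gamma = 0.25$ by default. Two design points deserve emphasis:

* A *label-only* supervised block (affinity 1 within class, 0 across,
  kernel similarities only for unlabeled pairs) looks natural but fails
  structurally: labeled samples then separate at a scale the
  kernel-smoothed coordinates of unlabeled samples cannot reach, so a
  classifier trained on training rows of the embedding faces test rows
  collapsed near the origin. Keeping supervision multiplicative on the
  affinity scale keeps training and test geometry commensurate. This is
  why $\gamma$ is moderate: at $\gamma \to 1$ (cross-class affinities
  erased) the same scale pathology reappears.
* **Weight learning** scores each candidate $\alpha$ on an embedding built
  from the candidate's *unsupervised* kernel geometry ($\gamma = 0$),
  evaluated by the Fisher criterion (between- over within-class scatter)
  against training labels. Scoring the label-tilted embedding instead is
  blind: supervision separates the training classes for *any* kernel,
  including pure noise, so the objective would not discriminate. With the
  unsupervised geometry a noise kernel shows essentially zero class
  scatter and is weighted away. The preset searches a coarse simplex grid
  (step 0.25): with two or three modalities and a scatter objective
  estimated from a few hundred samples, a finer grid mostly fits objective
  noise.

### Transduction and label hygiene

Co-association and kernel fusion operate on all-$N$ matrices, so fused
representations are computed *transductively* over training and test
samples together. Supervision is restricted by construction: inside
cross-validation, every pipeline stage receives a label vector with the
current test fold masked to `NA`, so decisions are cross-fit within the
training fold, weights are learned on training labels only, and the
semi-supervised block covers training pairs only. `run_strategy(...,
poison_test_labels = TRUE)` scrambles test labels before they enter the
pipeline; the test suite asserts the output is bit-identical, which holds
only if no stage can read test labels.

## Evaluation harness

The classifier is an ensemble of 100 bagged decision trees, each grown on a
bootstrap sample of the training rows and a random 66% subset of the
features, scored by the fraction of trees voting class 1. Robustness is
estimated by randomized three-fold cross-validation with *per-patient*
(group) segregation, repeated 25 times; each repeat pools all out-of-fold
scores into a single AUC (pooling is lower-variance than fold-averaging and
leaves one number per repeat). Strategies are compared on their 25-AUC
vectors by the Kruskal–Wallis rank test, followed by Dunn's pairwise
z-tests with Bonferroni adjustment — the canonical rank-based post hoc.

## The synthetic generator

`generate_multimodal()` draws Gaussian class-conditional data: labels
Bernoulli(balance); each modality $m$ carries $S_m$ signal features with
class-mean gap $d_m$ (in noise-sd units) plus pure-noise features, globally
scaled per modality to emulate scale heterogeneity. The closed-form AUC of
one signal feature, $\Phi(d/\sqrt 2)$, and of a modality's optimal score,
$\Phi(\sqrt{S_m}\, d_m/\sqrt 2)$, give exact calibration targets; the test
suite checks empirical AUCs against them to ±0.03. Three structures cover
the interesting regimes: `complementary` (independent signal per modality,
joint Bayes AUC exceeds each marginal), `redundant` (one shared latent
signal), and `one_noisy` (all signal confined to the first modality).
`make_fixture()` provides shape-matched stand-ins for three cohort regimes
(77×(327+146), 40×(189+650), 3000×(58+6) with 36 patient groups); their
effect sizes are package choices, since only shapes and qualitative
behavior of the real cohorts are public.

What the generator does *not* emulate: feature correlation structure within
a modality, heavy tails, batch effects, nonlinear class boundaries, or
missing modalities. Passing tests therefore demonstrate correctness of the
machinery and qualitative behavior (fusion gain on complementary signal,
weighting's robustness to a noise modality, null calibration), not
performance claims about any clinical dataset.

## Problem sizes used by the checks

The property checks run at deliberately compact sizes: eigensolver and
reduction contracts on 20×20 / 15×15 random affinities; generator
calibration at $N = 2000$; fusion-benefit and noise-robustness experiments
at $N = 300$, $P = (50, 50)$, $S = (5, 5)$, $d_m = 1$ with 25×3-fold
grouped cross-validation; null calibration at $N = 120$ with permuted
labels. These sizes keep the full suite reproducible on a laptop while
leaving the stochastic margins (e.g. fusion benefit ≥ 0.03 AUC) clearly
resolvable.

## Known limitations

* Embeddings are transductive; there is no out-of-sample (Nyström)
  extension, so new samples require re-embedding.
* Two classes only; no multi-class or multi-task support.
* Samples missing a modality are dropped (inner join on sample IDs), not
  imputed.
* CCA-based fusion is intentionally absent from the strategy set.
* `learn_modality_weights(objective = "train_auc")` cross-fits the bagged
  ensemble per candidate and is markedly slower than the default Fisher
  objective; it is provided for completeness.
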