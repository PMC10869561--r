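---
title: "Multi-view latent feature learning for microbe-disease association prediction"
author: "latentMDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view latent feature learning for microbe-disease association prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentMDA)
```

## The problem

Curated catalogues of microbe-disease associations (MDAs) record which
microbial taxa have been observed, in the literature, to be altered in or
causally tied to a disease. These catalogues are small and extremely
sparse — on the order of a few hundred validated links over hundreds of
microbes and a few dozen diseases, a density around 4% — and each curated
link is a positive-only observation: an absent entry means *unvalidated*,
not *absent*. The prediction task is bipartite link ranking: given the
binary adjacency matrix $A \in \{0,1\}^{m \times n}$ (rows microbes,
columns diseases), score every unvalidated pair so that true but
not-yet-curated associations rank highly.

latentMDA implements a multi-view latent feature learning approach to this
task: each side of the bipartite graph (microbes, diseases) is a *view*,
each view carries two feature modalities, and both views are factorized
into a common latent interaction matrix under graph regularization and a
row-sparsity penalty, with the two views' predictions fused by averaging.

## Similarity: Gaussian interaction profile kernels

The only side information used is the association matrix itself. The
*interaction profile* $IP(m_i)$ of microbe $i$ is row $i$ of $A$; disease
profiles are columns. The Gaussian interaction profile (GIP) kernel
similarity between two microbes is

$$S_M(i,j) = \exp\left(-\gamma_m \, \lVert IP(m_i) - IP(m_j)\rVert^2\right),
\qquad
\gamma_m = \gamma'_m \Big/ \left(\tfrac{1}{m}\sum_{i=1}^m \lVert IP(m_i)\rVert^2\right),$$

i.e. a Gaussian kernel whose bandwidth is the scaling constant
$\gamma'_m$ (default 1) divided by the mean squared profile norm, so that
the kernel scale adapts to the catalogue's density. $S_D$ over diseases is
defined the same way on columns. The bandwidth is always computed from the
**original binary** matrix: the completion step below manufactures
nonzero entries, and letting those feed back into the bandwidth would make
the similarity depend on its own output. Profiles are binary, so squared
norms are exact integer counts before exponentiation.

Entities with all-zero profiles get no special casing — their kernel row
is determined by the other profiles' norms — because the completion step
is the designated remedy for empty profiles.

## Completion: weighted K nearest known neighbors (WKNKN)

Positive-only sparsity means most zeros are unobserved rather than
negative. WKNKN replaces each zero with an interaction-likelihood score
borrowed from *known* neighbors — entities with at least one curated
association. For a microbe $q$, let $m_1, \dots, m_K$ be the up-to-$K$
known microbes nearest to $q$ by GIP similarity, in decreasing order
(ties broken by ascending index for determinism, and $q$ never serves as
its own neighbor). Then

$$A_m(q,:) = \frac{1}{Q_m} \sum_{i=1}^{K} d^{\,i-1} \, S_M(m_i, q)\, A(m_i,:),
\qquad Q_m = \sum_{i=1}^{K} S_M(m_i, q),$$

with decay $d \in [0,1]$. The disease-side profile $A_d$ is built the same
way on columns. The two are fused with equal weights by default,
$A_{md} = (\varsigma_1 A_m + \varsigma_2 A_d)/(\varsigma_1+\varsigma_2)$,
and combined with the original matrix by an elementwise maximum, so every
curated 1 survives and all entries stay in $[0,1]$. A single pass is
performed.

Defaults: $K = 5$, $\varsigma_1 = \varsigma_2 = 1$. The decay is not
pinned down by the sources that popularized WKNKN-style completion for
bipartite interaction data; we default to $d = 0.9$, the conventional
choice in that literature, and expose it in `mdaParams()`. If all neighbor
similarities are zero ($Q = 0$) the profile is left at zero — the
documented fallback for entities the kernel cannot place.

## Features: adjacency plus dominant-energy PCA embedding

Each view carries $M = 2$ feature modalities. Modality 1 is the
association matrix seen from that view — the WKNKN-completed matrix, since
completion precedes fitting in the pipeline (a configuration switch allows
the raw binary matrix for ablation). Modality 2 is a PCA embedding of the
view's GIP kernel: with eigendecomposition $S = U \Lambda U^\top$
(negative eigenvalues clipped to zero; the kernel is PSD in exact
arithmetic), the embedding dimension $g$ is the smallest $x$ such that

$$\sum_{i \le x} \lambda_i \Big/ \sum_j \lambda_j \;\ge\; \sigma,$$

the *dominant energy* criterion with $\sigma = 0.7$ by default. The
features are $F = U_g \Lambda_g^{1/2}$: the eigenvalue scaling makes
$F F^\top$ the best rank-$g$ PSD approximation of $S$, so the embedding
reproduces the similarity in the Gram sense (set `scaled = FALSE` in
`pcaFeatures()` for plain eigenvectors). Eigenvector signs are fixed so
each column's largest-magnitude entry is positive; without this, runs
would differ across LAPACK builds.

## Model

For the microbe view (the disease view is symmetric with $A^\top$ and
$S_D$), the latent interaction matrix $G \in \mathbb{R}^{m \times n}$ and
nonnegative projections $P^{(i)} \in \mathbb{R}^{n \times g_i}$ minimize

$$\sum_{i=1}^{M} \lVert F^{(i)} P^{(i)\top} - G\rVert_F^2
  + \alpha \lVert G - A\rVert_F^2
  + \mathrm{tr}(G^\top L\, G)
  + \lambda \sum_{i=1}^{M} \lVert P^{(i)}\rVert_{1,2}^2,
\qquad P^{(i)} \ge 0,$$

where $L = D - S_M$ is the graph Laplacian of the view's kernel and
$\lVert P\rVert_{1,2}^2 = \sum_x \left(\sum_y |P_{xy}|\right)^2$ penalizes
squared row-wise L1 norms, promoting row-sparse projections (interpretable
feature weightings). The Laplacian term carries no extra coefficient — the
formulation has exactly two regularization weights, $\alpha = 10^2$ and
$\lambda = 10^{-3}$ by default. The first term projects both modalities
into a common subspace; the second anchors $G$ to the (completed)
catalogue; the third makes similar entities receive similar score rows.

### Optimization

The objective is alternately minimized:

* **G step (closed form).** With $P$ fixed, the subproblem is quadratic
  and its exact minimizer solves
  $(L + (M+\alpha) I)\, G = \alpha A + \sum_i F^{(i)} P^{(i)\top}$.
  The left-hand side is symmetric positive definite for $\alpha > 0$
  (L is PSD), is constant across iterations, and is Cholesky-factorized
  once; no explicit inverse is ever formed.
* **P step (sign-split multiplicative).** With $G$ fixed, each modality's
  projection is updated by
  $$P \leftarrow P \odot
    \frac{P B^- + C^+}{P B^+ + C^- + \epsilon},
    \qquad B = F^\top F + \lambda e e^\top,\; C = G^\top F,$$
  with $X^\pm = (|X| \pm X)/2$ and $e$ the all-ones vector. The split into
  positive and negative parts is what keeps the rule well-defined when $F$
  contains negative entries (the PCA modality does): all four matrices in
  the ratio are nonnegative, so nonnegativity of $P$ is preserved
  exactly, and because $B$ is PSD each step does not increase the
  subproblem objective. The numerator must collect the *negative* part of
  $B$ and the *positive* part of $C$ — this is the arrangement under
  which the descent guarantee holds, and the test suite verifies the
  monotone decrease empirically over long update chains rather than
  trusting typography. $\epsilon = 10^{-12}$ guards zero denominators,
  which the bare rule leaves undefined.

Projections are initialized uniform on $[0,1]$ from a caller-supplied
seed (an all-zero projection is an absorbing state of any multiplicative
rule, so zero initialization is never used). Iteration stops when the
relative objective change drops below `tol` $= 10^{-6}$ or after
`maxIter` $= 500$ iterations — the alternation is monotone, so the trace
is also a built-in diagnostic, recorded in every `ViewFit`. Given the
seed, fits are bitwise reproducible.

The final scores fuse the two views, $G = (G_m + G_d^\top)/2$; the
transpose is dimensionally forced since the disease view lives in
$\mathbb{R}^{n \times m}$.

### Ablation switches

`useGraphReg = FALSE` removes the Laplacian term from both the objective
and the G step (which then reduces to a scalar rescale of the right-hand
side); `useLpq = FALSE` removes the $\lambda e e^\top$ term from the P
step and the penalty from the objective. The switches remove exactly
their term — verified by term-wise accounting in the tests — so ablation
comparisons are clean.

## Evaluation without leakage

`globalLoocv()` masks each curated association in turn; `kfoldCv()` masks
random near-equal folds of them, repeatedly. In both schemes **every
derived quantity — GIP bandwidth and kernels, WKNKN completion, PCA
features, both view fits — is recomputed from the masked matrix**.
Scoring a pair whose own value leaked into its similarity profile would
be circular; this recomputation is the package's default and the reason
cross-validation costs one full pipeline run per round.
(`leakageSafe = FALSE` in `globalLoocv()` scores all rounds from a single
full-data fit, for comparison only.)

Held-out positives are ranked against the *candidate set*: all pairs
unvalidated in the original matrix. The AUC is the exact pairwise
Mann-Whitney statistic (ties count one half), pooled over rounds; since
candidate scores come from different per-round fits, pooling is done on
ranks, not raw scores. The standalone `rocAuc()` performs the classical
threshold sweep with FPR on the horizontal axis; its trapezoidal area
equals the Mann-Whitney statistic exactly, ties included, and the suite
checks the two routes against each other to $10^{-12}$. Fold assignment
and model initialization draw from two independent seed streams so either
can be varied alone.

## Synthetic data: what it emulates and what it does not

`simulateAssociations()` generates catalogues with the structure the model
assumes: nonnegative latent factors $U \in \mathbb{R}^{m \times r}$,
$V \in \mathbb{R}^{n \times r}$ (absolute Gaussians, matching the model's
nonnegative-projection bias), true scores $\Theta = U V^\top$, ones at
the top `density` fraction of $\Theta$, and optional Bernoulli entry
flips. Defaults emulate the scale of real curated catalogues — 292
microbes, 39 diseases, 4% density, rank 3, no flip noise (curated
literature links have few false entries). $\Theta$ is returned so tests
can compute oracle ranking ceilings.

Two honest caveats. First, absolute-Gaussian factors make $\Theta$
strongly margin-driven: a plain degree-product baseline is already a good
ranker on such data, and on a minority of generator seeds it is
near-ceiling, so "beats the baseline" holds on average but not on every
draw. Second, the generator reproduces neither the heavy-tailed degree
distribution of literature curation (a few celebrity taxa absorb many
links) nor name-level noise (spelling variants, taxonomic merges). Tests
passing on this generator therefore demonstrate correct mechanics and
genuine signal recovery on low-rank bipartite data, not performance on
any real catalogue.

Validation problem sizes used by the test suite and the acceptance
script — chosen as the smallest instances at which the properties of
interest are nondegenerate: $20 \times 8$ for solver monotonicity chains,
$6 \times 4$ for oracle equivalence, $100 \times 30$ (the generator's
recovery regime) for masked-link recovery, and $40 \times 12$ for full
leave-one-out and repeated 5-fold runs.

## Numerical choices, in one place

* Kernel distance matrix computed via the Gram identity
  $\lVert p_i - p_j \rVert^2 = \lVert p_i\rVert^2 + \lVert p_j\rVert^2 -
  2\langle p_i, p_j\rangle$, clipped at zero, then symmetrized.
* Negative eigenvalues of kernels clipped to zero before energy ratios
  and embeddings.
* Eigenvector sign convention: largest-magnitude component positive.
* WKNKN neighbor ties broken by ascending entity index.
* G step: one Cholesky factorization per fit, two triangular solves per
  iteration.
* P step denominator guard $\epsilon = 10^{-12}$.
* Convergence: relative objective change $< 10^{-6}$, cap 500 iterations.
* All randomness (projection init, fold assignment, generator) flows
  through private seeded RNG streams that restore the caller's RNG state.

## Limitations

* GIP similarity is the only side information; taxa or diseases absent
  from the catalogue are handled only through WKNKN, and a disease with
  no curated links at all cannot be ranked meaningfully.
* Hyperparameters are adopted, not searched; `mdaParams()` exposes them
  but the package offers no tuning harness.
* Leakage-safe leave-one-out refits the pipeline once per curated link —
  quadratic-feeling cost that is fine at catalogue scale (hundreds of
  links, seconds per fit) but not beyond.
* Scores are relative rankings, not calibrated probabilities.
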