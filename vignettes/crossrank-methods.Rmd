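---
title: "Ranking disease genes on networks of tissue-specific networks"
author: "CrossRankNoN authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking disease genes on networks of tissue-specific networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CrossRankNoN)
```

## The models

A *network of networks* (NoN) is a weighted disease similarity network in
which each disease node carries its own tissue-specific molecular network
over a global gene namespace, plus a seed vector of known disease genes
(uniform mass $1/s_i$ over the $s_i$ seeds present in the network, the zero
vector when none are known). A *network of star networks* (NoSN) extends
this: each disease carries a *center* network — in practice the most
reliable tissue-specific network available, e.g. a tissue-specific protein
interaction network — and $k_i \ge 0$ *auxiliary* networks such as
tissue-specific co-expression networks. An NoSN with all $k_i = 0$ is
structurally an NoN, and the solvers honour that degeneracy exactly.

CrossRank scores genes in all diseases jointly by minimizing

$$\mathrm{J} = \sum_i \Big[c\,\mathbf r_i^\top(I-\tilde G_i)\mathbf r_i +
(1-c)\lVert \mathbf r_i-\mathbf e_i\rVert^2\Big] + \beta \sum_{i,j}
\Theta_{\mathrm{cross}}(\mathbf r_i, \mathbf r_j),$$

where $\tilde G_i = D^{-1/2} G_i D^{-1/2}$ is the symmetrically normalized
adjacency (rows of isolated genes set to zero by the $0/0$ convention) and
the cross term, for each *ordered* disease pair with similarity
$A(i,j) > 0$, penalizes (a) differences between the degree-normalized
scores $\mathbf r_i(\mathcal I_{ij})/\sqrt{d_A(i)}$ and
$\mathbf r_j(\mathcal I_{ij})/\sqrt{d_A(j)}$ of shared genes and (b) the
scores of genes exclusive to either network — a gene absent from a similar
disease's tissue network is treated as having score zero there, which pulls
its score down everywhere. The double sum over ordered pairs counts every
unordered pair twice; we keep that convention so that the meaning of
$\beta$ matches the way it is usually reported for this model family.

The star objective adds, per disease, a coupling
$\Phi'(\mathbf r_{i*}, \mathbf r_{ip})$ between the center (scaled by
$1/\sqrt{k_i}$, making it comparable with its $k_i$ auxiliaries) and each
auxiliary, weighted by a scalar $\alpha$ (CRstar) or by learned weights
$\alpha_{ip}$ on the probability simplex with an
$\gamma\lVert\boldsymbol\alpha_i\rVert^2$ penalty (WCRstar). In the
weighted variant the coupling weight is $\alpha_{ip}$ alone — the scalar
$\alpha$ of the unweighted model is a separate hyperparameter and does not
multiply the learned weights — so settings for the two variants are
reconciled explicitly by the user, not implicitly by the code.

## Optimization

Collecting the concatenated score vector $\mathbf r$ (diseases in
ascending identifier order; within a disease the center first, then the
auxiliaries in stored order) the objective is the quadratic
$\mathbf r^\top M \mathbf r - 2(1-c)\,\mathbf e^\top \mathbf r + \text{const}$
with $M = D - C$: $D$ is a constant block diagonal ($1 + 2\beta$ for a
disease with neighbors, plus the auxiliary couplings in the star model) and
$C \ge 0$ collects $c\,\tilde G_i$ within each network plus the
cross-network couplings on matched shared genes. Two facts make the plain
Jacobi update

$$\mathbf r \leftarrow D^{-1}\big(C\mathbf r + (1-c)\mathbf e\big)$$

a globally convergent, entrywise non-negative fixed-point iteration: $M
\succeq (1-c)I$ (each quadratic term is a sum of squares, and the seed
preference contributes $(1-c)I$ outright), and $C$ is symmetric
non-negative, so the iteration matrix $D^{-1}C$ has spectral radius at most
$1 - (1-c)/\max(D) < 1$. The iteration starts from $\mathbf r = \mathbf e$;
by convexity the limit does not depend on the start, seeds merely shorten
the path. Scores are deterministic — no randomness enters the solvers.

The same stationarity system solved directly (sparse Cholesky) provides an
independent oracle; the test suite requires fixed point and direct solve to
agree to $10^{-6}$ relative $\ell_2$ error, and checks the analytic
gradient against central finite differences to $10^{-5}$ relative error.
The solver correctness is therefore enforced by oracles on the *stated
objectives*, not by transcribing any particular printed update formula.

For the weighted model the joint problem is biconvex, not convex. We
alternate (i) an exact score solve with the weights fixed (direct solve up
to a size guard, the fixed-point iteration beyond it) and (ii) the
closed-form weight update per disease: minimizing
$\sum_p \alpha_p d_p + \gamma \sum_p \alpha_p^2$ on the simplex, where
$d_p$ is the current center–auxiliary inconsistency, has the water-filling
solution $\alpha_p = \max\{0, (\lambda - d_p)/(2\gamma)\}$ with $\lambda$
fixing the sum to one. Each half-step decreases the objective, which is
bounded below by zero, so the recorded objective trace is non-increasing
and the loop terminates; we stop at a relative objective change of
$10^{-7}$ (at most 200 outer iterations), run the score update first, and
initialize the weights uniformly — an unbiased start for a biconvex
problem whose result we always report under that fixed initialization.
Small $\gamma$ concentrates all weight on the least inconsistent auxiliary;
large $\gamma$ spreads it toward uniform; the support size is
non-decreasing in $\gamma$.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `c` | 0.85 | within-network smoothness vs seed preference; the standard restart setting of label propagation / personalized PageRank |
| `beta` | 0.5 | cross-disease consistency weight |
| `alpha` | 0.3 | scalar center–auxiliary coupling (CRstar only) |
| `gamma` | 1.0 | $\ell_2$ penalty on learned auxiliary weights; exposed prominently because reasonable values depend on the scale of the inconsistencies |
| `tol`, `maxIter` | $10^{-9}$, 1000 | fixed-point stopping rule (relative $L_\infty$ change); tight enough for oracle-level agreement |
| `outerTol`, `outerMaxIter` | $10^{-7}$, 200 | alternating-solver stopping rule |

`c`, `beta` and `alpha` defaults are the standard settings for this model
family; `gamma`, the solver tolerances and iteration caps are this
package's documented choices.

## Network construction choices

* **Normalization**: co-expression similarity is
  $(0.5 + 0.5\,\mathrm{cor})^\kappa$ with $\kappa = 12$, mapping Pearson
  correlations monotonically onto $[0,1]$ and suppressing weak
  correlations.
* **Sparsification**: $k$-nearest-neighbor graphs ($k = 5$ by default) with
  *union* symmetrization — an edge survives if either endpoint selects it —
  and ties in neighbor selection broken by ascending node identifier, so
  construction is deterministic. kNN graphs are nested in $k$.
* **Expression filtering**: a gene participates in a tissue's network when
  its *mean* expression across the tissue's samples reaches the threshold;
  the mean is the simplest per-tissue statistic consistent with filtering
  "lowly expressed" genes, and zero-variance genes are removed because
  their correlation is undefined.
* **Tissue assignment**: a disease receives the network of its single most
  relevant tissue only when the association probability strictly exceeds
  0.4; there is deliberately no fallback to the second-best tissue, so
  assignment selects diseases with strong tissue specificity rather than
  covering all diseases.
* **Ingestion**: edge lists are stored once per unordered pair; duplicate
  records are symmetrized by the maximum weight (with a warning), and
  association genes absent from a disease's network are dropped from its
  seed vector (the seed vector is defined only over the network's genes).
* **Node order**: every vector and matrix uses the lexicographically sorted
  node order, and the concatenation order of the solvers is fixed, which
  makes runs bit-reproducible and the block algebra unambiguous.

## Evaluation protocol

Leave-one-out cross validation removes each association $(d, g)$ *together
with every other association of gene $g$*, rebuilds all seed vectors, and
ranks the genes of $d$'s network with $d$'s remaining seed genes excluded
from the candidate list (they are known positives). With one held-out
positive per run, the ROC area truncated at $k$ false positives is
$\max\{0, (k - f)/k\}$ where $f$ counts candidates ranked above $g$;
candidates tied with $g$ count one half each, the unbiased tie convention.
Associations whose gene is outside the query network are reported as
uncoverable rather than scored zero. Per-test AUC vectors of two methods
are compared by a standard paired t-test, with deterministic conventions
for degenerate differences (identical vectors give $p = 1$; constant
non-zero differences give $p = 0$). The temporal-split protocol scores a
later batch of associations with seeds built only from the earlier batch,
optionally masking the test gene's other earlier associations; masking can
only remove seed mass, so it never improves a test gene's rank. The pooled
ROC treats, per query, all non-seed non-test genes of that query's network
as negatives and pools runs on the rank scale.

Because the system matrix does not depend on the seed vectors, the
evaluation of the convex methods factorizes it once per bundle and solves
each validation run by back-substitution; results are identical to running
the solver from scratch.

## The synthetic benchmark

The generator emulates the *structure* such studies run on, with known
ground truth: a disease similarity network built as the kNN graph of a
Gaussian-kernel similarity over a 2-D latent embedding (kernel bandwidth
set to the median squared distance); per-disease gene sets drawn from a
global universe of about $n/\text{overlapFrac}$ genes, so any two diseases
share about the target fraction of genes; a planted module per disease
drawn from a common pool of twice the module size, so related diseases
have partially overlapping modules (full sharing would overstate the
cross-disease signal, disjoint modules would remove it); stochastic-block
edges with within-module probability `pIn` and background `pOut`; and
seed associations sampled from each module. Auxiliary networks for the
star model are corrupted copies of the centers: a fraction `noise` of
edges rewired by degree-preserving double-edge swaps (so topology changes
but the degree sequence — and hence a degree baseline — does not) and a
fraction `0.1 * noise` of genes dropped to emulate incomplete coverage.
Everything regenerates bit-identically from one integer seed.

The canonical benchmark conditions are the generator defaults: 20
diseases, 200 genes per network, gene overlap 0.5, module size 10, 3 seeds
per disease, `pIn = 0.3`, `pOut = 0.02`, kNN $k = 5$, generator seed 17 —
60 leave-one-out runs in total, sized so the full suite and the
reproduction script run in minutes on one CPU.

What passing on this benchmark does and does not show: the generator
produces unweighted stochastic-block networks with planted modules; it does
not reproduce the degree heterogeneity, clustering or noise structure of
real protein interaction or co-expression networks, nor realistic disease
similarity. Results on it validate the *mechanics* (objectives, solvers,
weight learning, protocol) and the qualitative behaviours — propagation
beating degree ranking, clean auxiliaries out-weighing rewired ones — not
clinical performance.

## Numerical and degenerate-input conventions

Isolated genes keep zero normalized weight ($0/0 \to 0$); diseases with no
similarity neighbors contribute no cross terms; all-zero seeds yield
exactly zero scores (the minimizer of a non-negative quadratic with zero
linear term); empty auxiliary lists make every star quantity collapse to
the plain model; ranking ties are broken by ascending gene identifier; the
direct oracle refuses systems above 5000 variables rather than silently
densifying.

## Known limitations

* The cross-network consistency couples only *identically named* genes;
  there is no orthology or identifier mapping layer.
* The weighted model's alternating solver finds a stationary point of a
  biconvex problem; multi-start exploration is left to the user.
* Truncated ROC areas saturate when the truncation point approaches the
  candidate-list size (with 200-gene networks every ranking attains
  AUC300 $\ge 1/3$), so deep-truncation comparisons between methods are
  compressed on small benchmarks; shallow truncations (AUC50) discriminate
  much more sharply there. The reproduction script reports both.
* Directed or signed molecular networks are out of scope; weights must be
  non-negative and symmetric.
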