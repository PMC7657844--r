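---
title: "Elastic embedding: model, optimization, and the row-partitioned backend"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic embedding: model, optimization, and the row-partitioned backend}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Elastic embedding (EE) maps $N$ samples $y_1,\dots,y_N \in \mathbb{R}^D$ to
low-dimensional coordinates $x_1,\dots,x_N \in \mathbb{R}^d$ by minimizing

$$E(X) \;=\; \sum_{m,n} w^+_{nm}\,\|x_n - x_m\|^2
\;+\; \lambda \sum_{m,n} w^-_{nm}\, e^{-\|x_n - x_m\|^2}.$$

The quadratic term pulls together samples with large attractive weight
$w^+$ (local structure); the exponential term pushes apart samples with
large repulsive weight $w^-$ (global structure). $\lambda > 0$ trades the
two off; the package default is $\lambda = 10$, a value that works robustly
for single-cell expression matrices.

The weights come from a single squared-distance computation
$D_{nm} = \|y_n - y_m\|^2$:

* **Repulsive**: $w^-_{nm} = D_{nm}$, diagonal zeroed, normalized so the
  matrix sums to 1.
* **Attractive**: $w^+_{nm} = \exp[-D_{nm} / (2\sigma_n^2)]$ with a
  per-sample bandwidth $\sigma_n$ (entropic affinities), then symmetrized
  as $W_P := W_P + W_P^\top$, diagonal zeroed, and normalized to sum 1.

Each $\sigma_n$ is calibrated so the conditional neighbor distribution
$p_m \propto \exp[-D_{nm}/(2\sigma_n^2)]$ attains a target *perplexity*
$2^{H(p)}$ (entropy in bits) — the effective neighbor count. The default
target is 20.

The time-series variant (TSEE) adds experimental time stamps: with
normalized pairwise time dissimilarities $t_{nm}$, the repulsive weight
becomes $w^-_{nm} + \beta\, t_{nm}$, so samples far apart in time repel
more. $\beta \ge 0$ (default 1) trades expression-space against temporal
dissimilarity on the same normalized scale.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `lambda` | 10 | attractive/repulsive trade-off; larger preserves more global structure |
| `perplexity` | 20 | target effective neighbor count for $\sigma_n$ calibration |
| `dim` | 2 | embedding dimension |
| `beta` | 1 | weight of the temporal term (TSEE only) |
| `mu` | `"auto"` | diagonal regularizer of the preconditioner; auto = $10^{-9}\,\mathrm{tr}(4 L_P)/N$ |
| `max_iter` | 200 | quasi-Newton iteration cap |
| `tol` | $10^{-6}$ | relative energy-change stopping rule |
| `init_scale` | $10^{-4}$ | s.d. of the seeded Gaussian initialization |

## Numerical optimization

The energy is minimized by a quasi-Newton iteration
$X_{k+1} = X_k + \alpha_k P_k$ with a *spectral direction*: the
positive-definite part of the Hessian is the attractive graph Laplacian
$L_P = \mathrm{diag}(W_P \mathbf 1) - W_P$, which does not change across
iterations. We therefore factorize $B = 4 L_P + \mu I$ once (Cholesky; any
triangular factorization of the symmetric positive-definite $B$ is
equivalent at the level of the solve contract) and obtain each direction by
two triangular solves of $B P_k = -G_k$.

Numerical choices made where the method description leaves freedom:

* **Gradient constant.** The analytic differential of $E$ is
  $G = 4 L_k X$ with $L_k$ the Laplacian of
  $W_k = W_P - \lambda (W_N + \beta T) \circ \mathrm{Ker}$,
  $\mathrm{Ker}_{mn} = e^{-\|x_m - x_n\|^2}$. Conventions that drop the
  constant 4 produce the same direction up to scale; we keep the factor 4
  (and correspondingly $B = 4L_P + \mu I$) so finite-difference checks of
  the gradient pass at $10^{-5}$ relative.
* **Laplacian form.** The standard $L = \mathrm{diag}(\text{row sums}) - W$.
  An element-wise shorthand sometimes written as
  $l^+_{mn} = \sum_k w^+_{mk} - w^+_{mn}$ agrees with this on the diagonal
  only; we treat it as shorthand for the standard operator.
* **Regularizer.** $L_P$ has the constant vector in its null space, so
  $\mu > 0$ is required. `"auto"` scales $\mu$ with the mean degree,
  $10^{-9}\,\mathrm{tr}(4 L_P)/N$, making conditioning invariant to weight
  normalization conventions.
* **Line search.** Armijo backtracking with $c = 10^{-4}$, $\rho = 0.8$,
  warm-started at $\min(1, 2\alpha_{k-1})$ (first iteration: 1); 60 failed
  reductions signal step failure, treated as convergence. Every accepted
  step strictly decreases the energy, so the energy trace is
  non-increasing by construction.
* **Convergence.** $|E_k - E_{k-1}| \le \mathrm{tol}\,|E_k|$ or `max_iter`.
* **Initialization.** i.i.d. $N(0, 10^{-4\,2})$ per coordinate under the
  user seed; fits are deterministic given parameters and seed.
* **Sigma root-finding.** Bisection on $\log\sigma$ after geometric bracket
  expansion from the warm start. Perplexity is monotone in $\sigma$, so the
  root is unique; the bracket is contracted to width $10^{-12}$ (about 40
  bisections), which both satisfies the $10^{-6}$ relative perplexity
  tolerance and makes the solution independent of the processing order —
  the warm-start order affects speed only. Serial calibration orders rows
  along a greedy nearest-neighbor chain (start at row 1, always move to
  the closest unvisited row), which keeps consecutive problems similar.
  The exact reordering rule used by earlier implementations is not
  specified; the chain is this package's choice.
* **Degenerate rows.** A row whose off-self distances are all zero cannot
  reach any perplexity target; it receives $\sigma$ equal to the smallest
  positive normal double (with a warning), which reproduces the uniform
  conditional over the exact duplicates in the attractive kernel.
* **Temporal dialect.** $t_{nm} = (t_n - t_m)^2$ by default, mirroring the
  squared repulsive distances; absolute differences are selectable. $T$ is
  normalized to sum 1 so $\beta$ acts on the same scale as $W_N$. Constant
  time stamps produce a zero $T$ (warning) and TSEE degrades exactly to EE;
  $\beta = 0$ reproduces the EE code path bitwise.

## The row-partitioned backend

`parallel_fit()` executes the identical algorithm under a $P$-worker
partition of all $N \times N$ matrices into contiguous row blocks whose
sizes differ by at most one. Per-row quantities (distances, kernel rows,
gradient rows, $\sigma$ calibration — ordered by the same nearest-neighbor
chain restricted to each block) are computed block-locally; symmetrization
exchanges transpose slices between workers; the weight normalizers and
every energy evaluation (including each line-search trial) are reduced
from per-block partial sums in a fixed worker-rank order, so runs are
reproducible for a given $P$. Coordinates and search directions are
re-assembled by all-gather each iteration.

The backend is an in-process worker loop honoring that dataflow. Workers
with message-passing semantics, a thread pool, or this sequential loop are
equivalent at the contract level: what is fixed is which blocks each worker
touches and the reduction order, not the transport. Two deviations from a
fully distributed realization are deliberate:

* the Cholesky factorization of $B$ is performed as a collective on the
  assembled matrix (the in-process analogue of a distributed factorization)
  and the factor is shared — worker-owned storage of the *iteration*
  matrices remains $O(N^2/P)$ rows each;
* with one worker the code path collapses to exactly the serial arithmetic,
  so `workers = 1` is bitwise identical to `ee_fit()`.

With $P > 1$ the only differences from the serial path are the grouping of
floating-point reductions and the per-block warm-start chains; measured
serial-vs-parallel relative Frobenius errors on the benchmark-scale
datasets are below $10^{-6}$ (the acceptance suite asserts the
$1.60 \times 10^{-6}$ and $2.42 \times 10^{-6}$ consistency bounds).

## Synthetic data: what it emulates, what it does not

The generators reproduce the *geometry* the embedding experiments need,
not single-cell noise:

* `make_tree()` — a branching developmental topology: unit-direction
  segments (length 5) attached at uniform positions on earlier branches,
  points at uniform arc positions, isotropic Gaussian noise (default s.d.
  0.1). The benchmark call is 10 branches × 144 points × 60 features,
  reduced to 7 principal components before embedding.
* `make_clusters()` — isotropic unit-variance blobs with centers at
  pairwise distance ≥ `separation`; the benchmark scale is 4,423 × 50 with
  4 blobs, a stand-in for a bifurcating hematopoietic population.
* `make_timeseries()` — stage centers on a unit-step random walk whose
  direction turns slowly (a curved but locally straight path), stage time
  stamps spaced `dt` (default 0.5, emulating half-day sampling; 39 stages
  matches the reprogramming design), within-stage spread 0.3.

None of these model dropout, library-size variation, or count noise —
inputs to the embedding are post-PCA continuous features, and the
preprocessing module (filter → log-normalize → variance-ranked gene
selection → PCA) is a minimal stand-in whose variable-gene step is
deliberately plain variance ranking, not a variance-stabilizing
transformation. A green test therefore establishes algorithmic
correctness and serial/parallel consistency on data with the right
geometry, not end-to-end fidelity to any particular sequencing protocol.

## Known limitations

* Dense $O(N^2)$ matrices bound practical problem sizes (tens of
  thousands of samples on a workstation); no sparse/approximate-neighbor
  affinities or fast-multipole acceleration.
* The in-process backend demonstrates the partitioned dataflow and its
  numerical consistency but does not deliver multi-machine speedups.
* Preprocessing diverges from variance-stabilizing gene selection, so
  selected gene sets will differ from pipelines using it.
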