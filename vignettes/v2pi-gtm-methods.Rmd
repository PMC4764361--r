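---
title: "Methods: interactive topographic mapping with v2pigtm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interactive topographic mapping with v2pigtm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(v2pigtm)
```

## The model

Generative topographic mapping (GTM) is a constrained Gaussian mixture for
visualizing N observations $x_i \in \mathbb{R}^p$ on a two-dimensional
display. A regular lattice of J latent points $r_j \in [-1,1]^2$ is mapped
through K radial Gaussian kernels ("attractors")
$\Phi_k(r) = \exp(-\lVert r-\mu_k\rVert^2 / 2\sigma^2)$ and a $K \times p$
loading matrix $W$ to reference points $y_j = W'\Phi(r_j)$ that sit on a
smooth manifold in data space. Each observation is modelled as drawn from
one of J isotropic Gaussians
$p(x \mid y_j, \beta) = (\beta/2\pi)^{p/2}\exp(-\tfrac{\beta}{2}\lVert x - y_j\rVert^2)$
with equal mixture weights $1/J$. Because the component means are tied to
the smooth image of a lattice, the posterior over lattice points is a
spatially coherent summary: the plotted coordinate of $x_i$ is the
posterior mean $\sum_j R_{ij} r_j$, where
$R_{ij} \propto p(x_i \mid y_j, \beta)$ are the responsibilities (the
shared prefactor cancels in the normalization; `project()` also offers the
posterior mode, ties broken by lowest lattice index for reproducibility).

`gtm_fit()` maximizes the mixture log-likelihood by EM. The E-step is the
responsibility computation above, done on log-scale exponents with a
per-row maximum shift so extreme $\beta$ cannot overflow. The M-step
solves the responsibility-weighted least-squares system
$(\Phi' G \Phi + \lambda I)\,W = \Phi' R' X$ with $G$ the diagonal of the
responsibility column sums, then sets $\beta^{-1}$ to the weighted mean
squared residual per dimension. The per-iteration log-likelihood trace is
monotone non-decreasing, which the test suite asserts with a slack of
1e-8 over many random fits.

Because local distance on the display is not uniform — the manifold may be
stretched or folded — `magnification()` reports the areal stretch
$\sqrt{\det(J'J)}$ of the latent-to-data Jacobian
$J = \partial y/\partial r$ at each lattice point, using the analytic
kernel derivative $\partial\Phi_k/\partial r = -((r-\mu_k)/\sigma^2)\Phi_k$.
Flat regions give small, nearly constant factors; hills and folds give
large ones. A rank-deficient Jacobian is reported as factor 0 and flagged.
The analytic factors are tested against central finite differences of the
manifold map at tolerance 1e-4.

## Tunable parameters and defaults

* `grid_shape = c(20, 20)` (J = 400) and `basis_shape = c(4, 4)` (K = 16):
  the standard configuration for desk-scale data; J controls display
  resolution, K controls manifold flexibility.
* `width_factor = 1`: the kernel width is
  $\sigma = \texttt{width\_factor} \times$ the spacing between adjacent
  basis centers, so kernels overlap their neighbours and cover the latent
  square. A single-center basis has no spacing, so `sigma2` must then be
  given explicitly.
* `ridge = 1e-6` on the M-step normal equations: with J far larger than K
  the system is usually well conditioned, but near-collinear bases can
  arise; the ridge bounds the condition number at negligible bias. A
  genuinely singular system raises an error advising a larger ridge.
* `rel_tol = 1e-5`, `max_iter = 200`: EM stops when the relative
  log-likelihood change falls below `rel_tol`; non-convergence is reported
  in the `converged` flag, not as an error.
* Initialization is deterministic: $W$ is the least-squares fit of the
  basis expansion to the plane of the top two principal components (lattice
  coordinates scaled by the square roots of the leading eigenvalues), and
  $\beta^{-1}$ starts at the larger of the third eigenvalue and half the
  mean squared spacing between adjacent manifold points. Identical data
  and controls therefore give bit-identical fits. The basis is kernels
  only; a constant (bias) column is available but off by default.

## Interaction: moving one plotted observation

`move_point()` turns a user's repositioning of one observation $x^*$ to
latent coordinates $r^*$ into a model update, in three stages that can be
invoked separately.

**Stage 1 — anchor.** The lattice gains the point $r^*$ and the basis
gains an attractor $\Phi^*$ centered at $\mu^* = r^*$ with the model's
$\sigma^2$, so J and K each grow by one per interaction. The new loading
row of $W$ starts at zero, leaving the manifold untouched until the refit.
The moved observation's responsibility row is pinned to the indicator of
the new lattice point in every subsequent E-step, which makes its
posterior-mean projection equal $r^*$ exactly, at every later stage. The
model is then refit by EM conditional on $r^*$ and $\mu^*$ (both held
fixed). Refits warm-start from the current $W$: re-initializing would
discard the layout the user is reacting to, and warm starts keep replayed
sessions deterministic.

**Stage 2 — local scaling.** Stage 1 alone often moves only the nearest
neighbour of $x^*$, because with K attractors already in place the single
new one cannot compete. Stage 2 rescales the anchor component's density as
$\exp(-\tfrac{\beta}{2} V(\Delta_i)\lVert x_i - y^*\rVert^2)$ with
$\Delta_i = \lVert x^* - x_i\rVert / h$. Observations near $x^*$ in data
space get small $V$, flattening the residual penalty and raising the
anchor's responsibility for them — they follow the moved point; distant
observations get large $V$ and are pushed off. Shipped families are
$\Delta, \Delta^2, \Delta^3, e^{-1/\Delta}, e^{-1/\Delta^2}$ and `none`;
the exponential families are set to 0 at $\Delta = 0$ by continuity, so
the moved observation itself is always maximally attracted. The bandwidth
$h$ is either given directly or derived as the distance to the m-th
nearest neighbour of $x^*$ (default m = 20), which reads as "I expect
about m observations to follow". The scaled density is used everywhere the
anchor component's density appears — responsibilities, the $W$ update
(each residual weighted by $R_{ij}V_i$ in the anchor column) and the
$\beta$ update — so the conditional EM ascends a single constrained
objective; its trace is exposed as `refit_trace` and tested for
monotonicity. The unnormalized Gaussian prefactor is kept unchanged under
scaling; it cancels in the responsibilities.

**Stage 3 — mixture of manifolds.** Scaling alone changes the manifold
globally: clusters far from the interaction drift. The final stage blends
the pre-move manifold $y^{(c)}$ and the refit manifold $y^{(u)}$ per
lattice point, $y_j^{(c+1)} = \delta_j y_j^{(c)} + (1-\delta_j) y_j^{(u)}$
with $\delta_j = \lVert r_j - r^*\rVert / b$ and
$b = \max_j \lVert r_j - r^*\rVert$ taken over the full expanded lattice —
the only reading under which $\delta \in [0,1]$ is guaranteed. At the
anchor $\delta = 0$ (pure refit); at the farthest lattice point
$\delta = 1$ exactly, and because $1\cdot y + 0\cdot y'$ is exact in
floating point, that column is bit-identical to the pre-move manifold.
Projections and responsibilities are then recomputed from the blended
manifold. Note the projection of an observation is unchanged by blending
only insofar as its responsibility mass sits on $\delta = 1$ columns; an
observation with mass at $\delta \approx 0.99$ still legitimately moves by
roughly 1% of the local manifold change. Blending is applied once per
completed move; a smooth animation can be emulated by scripting waypoint
moves.

The blended manifold is defined only at lattice points (it is no longer
$W'\Phi$). A subsequent move therefore uses the cached blended columns as
its "current" manifold, extended at the new anchor by parametric
evaluation with the current $W$; tagging (below) always uses the
parametric map. Moves accumulate on the model's `log` and
`replay_moves()` reproduces a session bit-exactly, which doubles as the
undo mechanism (replay a truncated log).

## Text features: the importance index

For document collections the package featurizes a term-document count
matrix $f_{ij}$ (term $i$, document $j$) with a Gini-style dispersion
score, $\mathrm{ImpI}_i = \sum_j\sum_k |f_{ij}-f_{ik}| \,/\, (2N^2\mu_i)$,
where $\mu_i$ is the term's mean frequency. Terms spread evenly across
documents score 0; terms concentrated in one document score maximally;
the score is invariant to rescaling a term's counts. Two denominator
dialects are shipped because the $2N^2\mu$ form caps at $(N-1)/N$ rather
than 1 for a single-document term: `"printed"` (default) uses $2N^2\mu_i$
and `"corrected"` uses the sample form $2N(N-1)\mu_i$, whose maximum is
exactly 1. Both are validated against an independent sort-based oracle
($\sum_{jk}|f_j - f_k| = 2\sum_i (2i-N-1) f_{(i)}$) at tolerance 1e-12.

After ranking and keeping the top n terms (default 1000, ties broken
lexicographically), counts are replaced by importance-weighted relative
frequencies. The default `"lift"` reading is
$f^*_{ij} = \mathrm{ImpI}_i \cdot f_{ij} F / (\lVert d_j\rVert\,\lVert e_i\rVert)$ —
the observed-over-expected lift of the cell under independent margins,
scaled by the term's importance, which is dimensionless and sparsity
preserving. The grouping of the defining fraction admits a second reading
that divides by $F$ instead; it is available as `reading = "inverse"`.
Preprocessing lowercases, tokenizes on non-letter boundaries, removes a
bundled English stopword list, and applies a Porter-style suffix stemmer
implemented in the package; stopword-only documents keep an all-zero
column and are flagged rather than dropped silently.

## Interpreting the latent space

`tag_latent_point()` maps any display location $r^+$ through the current
basis (including user-added attractors) to its manifold point
$y^+ = W'\Phi(r^+)$ and reports the top m variables (default 10, ties
lexicographic). When the model is fitted to $f^*$ features, $y^+$ is a
vector of importance-weighted term scores and the tag reads as the
keywords of that display region. `cluster_keywords()` clusters the 2-D
projections with k-means (default k = 4) and ranks terms within each
cluster by the sum of $f^*$ over member documents; terms appearing in
every cluster's top list are deleted from all of them and reported
separately as the shared vocabulary. k-means uses Lloyd's algorithm with
10 seeded restarts; rows are put in a canonical coordinate order before
clustering so the result is invariant to document order, and empty-cluster
runs are retried with a bumped seed up to a small cap. Whether cluster
ranking should use $f^*$ or raw ImpI-scaled counts is ambiguous; $f^*$ is
used, and a raw matrix can be passed directly where the other convention
is wanted.

## Synthetic test surfaces

Two generators give every module a download-free, seeded test bed.

`simulate_clusters()` draws the three-dimensional five-cluster testbed:
clusters 1–3 near one corner of the data cube and 4–5 near the opposite
corner, isotropic unit noise, 30 observations per cluster, nearest
centers 7 noise standard deviations apart. This reproduces the
qualitative geometry that a topographic projection should preserve — five
separable clusters in two corner groups — and the default fit recovers it:
k-means on the posterior-mean projections agrees with the true labels at
adjusted Rand well above 0.8.

`synthetic_corpus()` emulates a small collection of abstracts: 4 topics
times 15 documents, 10 planted terms per topic drawn Poisson(8) in their
own documents, a 60-term background drawn Poisson(1) everywhere. Planted
terms attain higher ImpI than background terms, topic documents separate
in the fitted view, and tags inside a topic recover most of its planted
vocabulary. Only count structure is emulated — no word order, syntax,
semantics, polysemy or realistic vocabulary growth — so passing tests
demonstrate the mechanics of the pipeline, not performance on real
abstracts.

## Numerical choices and degeneracies

* Responsibility rows are normalized after a per-row max shift; a row of
  equal exponents yields the uniform distribution rather than NaN.
* Zero-variance data cannot be initialized and raise an error; planar data
  are reproduced exactly by the PCA initialization.
* Anchor targets outside the lattice extent warn but proceed (the blend
  normalizer still caps $\delta$ at 1).
* Anchoring the same observation twice re-pins it to the newest anchor;
  earlier anchor components remain in the model.
* $V(0) = 0$ for all distance-based families; `family = "none"` is the
  all-ones weight used by stage 1.
* A degenerate blend (every lattice point at $r^*$) returns the
  user-adjusted manifold with a warning.
* All generator and k-means randomness flows through an internal
  `with_seed()` that restores the caller's RNG state.

## Problem sizes

The shipped tests fit the full J = 400, K = 16 configuration on the
150-observation testbed (a few seconds per fit), run 100 random small-grid
EM fits for the monotonicity property, 1000 random vectors against the
ImpI oracle, and 50 random models against the finite-difference
magnification oracle; the complete suite runs in well under a minute on
one CPU.

## Known limitations

* The latent space is fixed at two dimensions.
* Missing data are not handled; inputs must be finite.
* One observation moves per interaction; simultaneous multi-point drags
  are out of scope (a sequence of single moves is the supported idiom).
* The package provides coordinates, magnification factors and a
  convenience scatter, not an interactive front-end.
* Exploration is the goal; no inferential or uncertainty statements are
  attached to a fitted or interacted model.
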