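---
title: "Cell-specific networks: model, numerical choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-specific networks: model, numerical choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`csnet` treats a gene–gene association in a *single cell* as a local failure
of statistical independence. Independence of genes $x$ and $y$ means
$f(x, y) = f_X(x)\,f_Y(y)$ everywhere; around the observed point
$(x_k, y_k)$ of cell $k$ the discrepancy
$f(x_k, y_k) - f_X(x_k) f_Y(y_k)$ can be estimated by counting cells in
three neighborhood boxes: a window on gene $x$ around $x_k$ holding
$n_x^{(k)}$ cells, a window on gene $y$ holding $n_y^{(k)}$ cells, and their
intersection holding $n_{xy}^{(k)}$ cells. Substituting frequencies for
probabilities gives the statistic

$$\rho_{xy}^{(k)} \;=\; \frac{n_{xy}^{(k)}}{n} -
  \frac{n_x^{(k)}}{n}\cdot\frac{n_y^{(k)}}{n},
  \qquad \rho \in [-1, 1].$$

With the marginal occupancies fixed in advance, $n_{xy}$ under independence
is a hypergeometric draw, with mean $n_x n_y / n$ and standard deviation

$$\sigma_{xy}^{(k)} = \sqrt{\frac{n_x n_y (n-n_x)(n-n_y)}{n^4 (n-1)}},$$

so the standardized statistic

$$\hat\rho_{xy}^{(k)} = \frac{\rho_{xy}^{(k)}}{\sigma_{xy}^{(k)}}
  = \frac{\sqrt{n-1}\,\bigl(n\,n_{xy} - n_x n_y\bigr)}
         {\sqrt{n_x n_y (n-n_x)(n-n_y)}}$$

is approximately standard normal. The per-cell, per-pair hypothesis test is
one-sided: an edge is declared when $\hat\rho$ exceeds the upper-$\alpha$
normal quantile (positive local dependence only; local *avoidance* of a
region is not scored as association). Repeating the test over all
$m(m-1)/2$ pairs and all $n$ cells yields $n$ boolean networks, and the
network degree matrix $\mathrm{NDM}_{xk} = \sum_{y \ne x} e_{xy}^{(k)}$
summarizes them in the exact shape of the input, so any downstream
expression method runs unchanged on network degrees.

Assumptions worth keeping in mind: cells are treated as exchangeable draws
from a mixture of states, expression values are only used through their
ranks (any monotone normalization gives identical networks), and the sample
must be large enough that a box holding `box_size` of the cells is a
meaningful density estimate — below roughly 100 cells the default box holds
fewer than 10 cells and the statistic becomes coarse.

## Tunable parameters

* `box_size` (fraction of cells per marginal box, default **0.1**): the
  bandwidth of the local density estimate. Smaller boxes resolve sharper
  dependencies but raise variance.
* `alpha` (one-sided significance level, default **0.01**): the per-edge
  rejection level; with the default, $z^* \approx 2.3263$. Following the
  method's design, no multiple-testing correction is applied across pairs —
  the level is a per-edge operating point, not a family-wise guarantee.
* `zero_mode`: `"drop_zero_edges"` (default) forces $e_{xy}^{(k)} = 0$
  whenever $x_k = 0$ or $y_k = 0$, the safe policy when zeros may be
  technical dropouts; `"trust_zeros"` lets the statistic decide, the right
  policy when zeros are biological (and the policy used by this package's
  own simulations, whose zeros are generated by the latent program).
* `min_cells` (gene filter, default **10**): genes with nonzero expression
  in fewer than 10 cells are discarded before construction; a gene expressed
  in exactly 10 cells is kept. Filtering precedes the log transform, which
  only inspects the zero pattern either way.
* The `log(1+x)` transform uses the natural log; since the statistic is
  rank-based the base is immaterial for networks and matters only for
  methods run on the expression matrix itself.

## The window and tie rule

The box is defined on ranks, not distances. For one gene, cells are sorted
by value; the window is the contiguous block of target size
$h = \mathrm{round}(\texttt{box\_size} \cdot n)$ placed around the focal
cell's rank ($\lceil (h-1)/2 \rceil$ ranks below, $\lfloor (h-1)/2 \rfloor$
above) and shifted inward at the distribution's ends so the target size is
preserved. Two refinements handle the heavy ties of single-cell data:

1. **Boundary-tie expansion.** Every cell whose value equals a window
   boundary value is included. The occupancy that enters the statistic is
   the *post-expansion* count, so the null standardization stays consistent
   with the box actually counted.
2. **Run-median centering.** The focal cell's rank is taken as the middle of
   its tie run. Placement therefore depends on the data only through the
   values, making the box invariant to the ordering of cells in the input —
   an index-based tie-break would silently move boxes under column
   permutation. For untied focal values the two rules coincide.

A box that expands to all $n$ cells (a constant gene, or a tie run wider
than the window) has $\sigma = 0$; such pairs are assigned $\hat\rho = 0$
and no edge, with one warning per gene — a constant gene carries no
association evidence. The intersection box is the intersection of the two
expanded marginal boxes. Self-pairs are never tested.

## Empirical null behaviour

The package's calibration suite and `scripts/acceptance.R` simulate
independent uniform pairs at the reference settings ($n = 500$, boxes
$0.1n$, 200–250 replicate pairs) and standardize every (pair, cell)
statistic through the construction path. Two findings are worth stating
plainly:

* the pooled **variance** of $\hat\rho$ is close to 1 (about 0.98), and
* the pooled **mean** is *not* 0 but about **+0.40**, and the one-sided
  edge rate at $\alpha = 0.01$ is correspondingly about **0.04**.

The shift is structural, not a bug: the focal cell always lies inside all
three of its own boxes, so under independence
$E[n_{xy}] = 1 + (n_x-1)(n_y-1)/(n-1)$, which exceeds the null model's
$n_x n_y / n$ by $\approx 0.8$ counts at the reference settings — about
$0.4\,\sigma$. The closed-form null ignores this self-inclusion, making the
per-edge test mildly anticonservative at any fixed $\alpha$. For network
*contrasts* (differential edges, dark genes, clustering on degrees) the
bias is common to all cells and groups and cancels; for calibrated per-edge
error control, treat `alpha` as an operating point to be tuned on negative
controls rather than a literal false-positive rate.

## Degree normalization

Cells differ in how many edges their networks carry. `normalize_ndm()`
rescales each cell's degree column so all columns sum to the *mean raw
column sum*: parameter-free, scale-preserving, and within-cell degree
ratios are untouched. Cells with empty networks are left at zero with a
warning rather than silently inflated.

## Group-level tests

Differential edges, differential degrees, and the two halves of the dark
-gene definition all use the two-sided Wilcoxon rank-sum test, one group
versus the rest, with Benjamini–Hochberg adjustment across the tested
family — a distribution-free choice that tolerates the zero-inflated,
heavy-tailed distributions of degrees and local statistics. A pooled
constant sample is defined to give $p = 1$. A gene is *dark* for a contrast
when its degree q-value falls below `alpha_deg` (default 0.05) while its
expression q-value stays at or above `alpha_expr` (default 0.05); both
underlying results are returned for audit.

For clustering evaluation, ARI uses the standard pair-counting
chance-corrected form; F1 is the pairwise co-clustering variant; purity is
the weighted majority fraction; entropy is the base-2 conditional entropy
of reference labels within predicted clusters. Trajectory accuracy
$T/(T+F)$ counts ordered cross-stage cell pairs whose score ordering agrees
with the stage ordering; a tied score is *not larger* and counts as an
error, so constant scores earn 0, not 0.5.

## The synthetic-data generator

`generate_pair()` reproduces the canonical dependency scenarios used to
probe the statistic: independent pairs, pairs dependent in a chosen
fraction of cells, fully dependent pairs, with linear or unimodal nonlinear
(quadratic, circular-arc) dependence — the nonlinear shapes defeat global
correlation on purpose. Marginals are uniform by default (normal and
log-normal available); flags record the ground-truth dependent cells.

`generate_population()` builds the multi-type benchmark behind the dark
-gene and separability analyses. Each of 3 types (100 cells each, 30 genes
by default) owns a disjoint 10-gene module driven by a shared latent
program with within-module correlation **0.99** — the regime of tightly
co-regulated programs, chosen once as the generator's documented effect
size. Every gene's values are rank-remapped, within each type, onto one
common reference marginal: the deterministic quantile grid of a
zero-inflated log-normal (30% zeros, meanlog 0, sdlog 1). With equal type
sizes each gene's marginal is therefore *exactly* the same multiset in
every type: expression-level tests are null by construction and only the
association structure separates the types. Independent dropout masking is
available (`dropout_rate`, default 0, since the reference marginal already
carries a zero spike).

What the generator does **not** emulate: library-size and batch variation,
count noise (values are quantile-grid atoms, not counts), correlated or
expression-dependent dropout, overlapping modules, and negative or
nonlinear module dependence within types. Passing the suite therefore shows
that the statistic, degrees and tests behave as designed under clean
association signals of realistic sparsity — not that any particular real
dataset will cluster perfectly.

## Problem sizes and runtime

Construction is $O(m^2)$ in genes and near-linear in cells (per gene, an
$n \times n$ sparse box-membership matrix with about
$\texttt{box\_size}\cdot n^2$ nonzeros). The shipped analyses use desk-scale
sizes — 30 genes × 300 cells populations (a few seconds per network build)
and 200–250 replicate pairs at 500 cells for calibration — chosen so the
full suite runs in a couple of minutes; the implementation streams pairs,
so genome-scale inputs are bounded by the $m(m-1)/2$ pair loop, and the
`stat_tensor` sink deliberately refuses to materialize beyond a configured
cap.

## Known limitations

* Edges are correlational; no causal direction is implied or computable
  from this construction.
* The per-edge null is anticonservative (self-inclusion shift above);
  absolute edge counts and rates should be compared across conditions, not
  read as calibrated discoveries.
* Very small samples (n below ~100 at the default box) give coarse,
  discrete statistics.
* One module per type in the population generator; richer designs need the
  `modules` argument.
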