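---
title: "Estimating sparse and scale-free functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating sparse and scale-free functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbnlearn)
```

## The model

A functional brain network (FBN) is a graph on $n$ regions of interest
(ROIs) whose edge weights quantify statistical dependence between regional
fMRI time courses. Given a data matrix $X \in \mathbb{R}^{t \times n}$
(rows = time points), each column is centered and scaled to unit Euclidean
norm,
$$x_i \leftarrow \frac{x_i - \bar{x}_i}{\sqrt{(x_i-\bar{x}_i)^\top
(x_i-\bar{x}_i)}},$$
after which the Gram matrix $X^\top X$ is exactly the Pearson correlation
matrix. Crucially, that matrix is also the unique minimizer of
$$\min_W \; \lVert W - X^\top X \rVert_F^2 ,$$
which recasts plain correlation as an optimization problem. Priors on the
network then enter as penalties:

* **`estimate_pc_sparsity()`** solves
  $\min_W \lVert W - X^\top X\rVert_F^2 + \lambda \lVert W \rVert_1$.
  The problem is separable, so the exact solution is elementwise soft
  thresholding of the correlation matrix at $\lambda/2$ — a "soft" analogue
  of the usual practice of hard-thresholding correlation networks
  (`hard_threshold_network()`), with the advantage that the sparsification
  rule is part of the model rather than a post-hoc filter.
* **`estimate_pc_scale_free()`** solves the degree-reweighted problem
  $\min_W \lVert W - X^\top X\rVert_F^2 + \lambda \sum_{ij} \gamma_{ij}
  \lvert W_{ij}\rvert$ with
  $\gamma_{ij} = \exp\!\big(-\tfrac{1}{d_i+\varepsilon} -
  \tfrac{1}{d_j+\varepsilon}\big)$, where
  $d_i = \sum_{z \neq i} \lvert W_{iz}\rvert$ is the weighted degree of
  node $i$ in the current solution and $\varepsilon$ (default $10^{-4}$)
  guards the reciprocals. The weights couple the per-edge shrinkage to the
  degree sequence, the intent being to let hub structure — a hallmark of
  scale-free networks — shape which edges survive.
* **`estimate_sr()`** is the sparse-representation baseline
  $\min_W \lVert X - XW\rVert_F^2 + \lambda\lVert W\rVert_1$ s.t.
  $W_{ii}=0$: each ROI regressed on all others, a partial-correlation-
  flavoured alternative.

All estimators return symmetric matrices with a zero diagonal; a
self-connection is not a connection and must not leak into degrees,
s-metrics, or classification features.

## Numerical choices

**Proximal machinery.** The fidelity gradient is $2(W - X^\top X)$, so a
gradient step of size $\alpha$ followed by soft thresholding at
$\alpha\lambda$ has the exact minimizer as its fixed point for any
$\alpha \in (0, 1)$. The sparsity estimator defaults to $\alpha = 1/2$,
which lands on the closed form in a single step. Convergence is declared
when the relative Frobenius change between iterates falls below `tol`
($10^{-6}$ by default); tests that assert agreement with closed forms at
$10^{-8}$ tighten `tol` accordingly. A subtlety worth stating: pseudocode
for this family of algorithms is often written with the shrinkage applied
at $\lambda$ per iteration rather than $\alpha\lambda$; that convention
solves the same objective with $\lambda$ rescaled by two and is available
as `legacy_prox = TRUE`, but the default solves the stated objective
exactly. Since $\lambda$ is grid-searched downstream, the distinction does
not affect pipeline results.

**The scale-free alternation is damped.** The natural algorithm alternates
a full weighted-soft-threshold solve with a refresh of $\gamma$ from the
new degrees. That scheme is an undamped fixed-point iteration, and on
realistic inputs it falls into a period-2 oscillation: thresholding
collapses the weighted degrees, tiny degrees drive $\gamma \to 0$ (the
weight underflows to zero at $d = 0$), a zero penalty resurrects every
edge, and large degrees push $\gamma$ back up — forever. We therefore
interleave the two updates at a finer grain: each iteration takes a single
proximal-gradient step at $\alpha = 1/4$ (any $\alpha < 1/2$ retains
memory of the previous iterate; at exactly $1/2$ the gradient step erases
it and the oscillation returns) and then refreshes $\gamma$. Fixed points
of the damped scheme satisfy $W^\* = \arg\min_W \lVert W - X^\top
X\rVert_F^2 + \lambda\sum \gamma(W^\*)_{ij}\lvert W_{ij}\rvert$ — exactly
the self-consistent solutions of the full alternation — and the scheme
reaches them in a few dozen $O(n^2)$ iterations where the undamped version
orbits. With $\gamma$ frozen each step is a standard descent step
(step size $\le 1/L$), so the penalized objective never increases between
refreshes; the returned network records this in `monotone_descent`.

**Hard thresholding** ranks unordered pairs by $\lvert W_{ij}\rvert$ and
keeps the top $k = \mathrm{round}(p/100 \cdot n(n-1)/2)$, breaking rank
ties by $(i,j)$ lexicographic order for reproducibility. Ranking by
absolute value is deliberate: ranking by signed value (available as
`signed = TRUE`) silently deletes every strong negative correlation, which
is almost never what "keep the strongest $p\%$ of edges" means.

**Degenerate inputs.** A constant ROI column cannot be standardized; the
default policy is an error naming the ROI, because silently zeroing it
changes downstream feature ranks invisibly (`degenerate_policy = "zero"`
opts into that behaviour with a warning). Entries with magnitude below
$10^{-12}$ are treated as structural zeros when counting edges: proximal
solutions contain exact zeros, but file round-trips may leave float dust.

## A known limitation of the degree weights

As defined, $\gamma_{ij}$ is monotonically *increasing* in degree:
$\gamma \to 1$ as $d \to \infty$ and $\gamma \to 0$ as $d \to 0$. Edges
incident to high-degree nodes are therefore shrunk slightly *more*, and
low-degree nodes escape shrinkage entirely — the opposite of the
rich-get-richer reweighting that classical adaptive-L1 schemes use to
promote power-law degree sequences. On synthetic hub-structured cohorts
this is visible in the package's own diagnostics: at a matched edge count
the degree-weighted estimator produces a *flatter* degree distribution
than plain L1 shrinkage, scores a lower s-metric, and its degree-cCDF
upper tail does not grow with $\lambda$ (see the end-to-end checks and
`scripts/acceptance.R`, which compute exactly these quantities). We
implement the weight formula as defined rather than "fixing" it, and
surface the behaviour honestly: users wanting hub-preserving shrinkage on
their data should verify the s-metric comparison on their own cohorts
before relying on the scale-free variant.

## Graph diagnostics

`s_metric()` computes $S(W) = \sum_{(i,j) \in E,\, i<j} d_i d_j$ with
binary degrees on the thresholded support, each unordered edge counted
once. Among graphs with equal edge count, $S$ is maximal when high-degree
nodes attach to each other, so it quantifies hub concentration — but only
comparisons **at matched edge count** are meaningful, which is what
`match_edge_count()` provides (bisection on $\lambda$ over the
piecewise-constant edge-count function; exact matches can be unattainable
under ties, in which case the closest attainable count from above is
returned). `degree_ccdf()` pools node degrees over subjects and returns
$P(D \ge d)$ (weak inequality, so the curve starts at 1); zero-degree
nodes stay in the denominator but are dropped from log-log exports, where
their coordinate is undefined.

## The classification pipeline

`loo_evaluate()` implements the standard small-cohort protocol: the
strictly-upper-triangle edge weights are the feature vector (row-major,
$n(n-1)/2$ features — 6670 for a 116-ROI atlas); a two-sample pooled
t-test keeps features with $p < 0.05$ (Welch via `var_equal = FALSE`);
a linear SVM with $C = 1$ and no additional feature scaling (correlations
already live in $[-1,1]$) classifies. Hyperparameters are chosen by nested
leave-one-out: for each held-out subject, an inner LOO over the remaining
subjects scores every candidate parameter, ties resolve to the smallest
value for determinism, and the screen and SVM are refit on the full outer
training set before predicting the held-out subject. The screen is always
fit strictly inside the training partition — the per-fold selected
features are recorded so leakage can be audited by recomputation. Two
degenerate cases degrade gracefully rather than abort, because aborting
inside the grid search would bias it: an empty screen falls back to the
single smallest-$p$ feature, and an all-degenerate feature matrix (an
extreme $\lambda$ that empties every network) falls back to the
training-majority prediction. Typical grids are
$\lambda \in \{0.05, 0.10, \dots, 1\}$ and sparsity levels
$\{5, 10, \dots, 100\}\%$. `parameter_sweep()` produces the
accuracy-versus-parameter sensitivity curve with the parameter held fixed.

## What the synthetic cohorts do and do not emulate

`make_ground_truth()` draws either uniform (Erdős–Rényi) sparse supports
or hub topologies in which designated hubs carry a stated multiple of the
mean degree; weights are uniform on $\pm[0.2, 0.8]$. `simulate_timeseries()`
forms $\Sigma = W_{\mathrm{true}} + \delta I$ with $\delta$ lifting the
smallest eigenvalue to $0.1$ (a well-conditioned $\Sigma$ keeps the
implied population correlations stable oracles), draws $t$ i.i.d.
multivariate-normal samples, and adds independent observation noise
(default SD 0.5, a moderate noise floor relative to the unit-scale
signal). Sampling is i.i.d. in time by default because every estimator in
the package is a function of the sample covariance alone; an AR(1) option
exists for users who want BOLD-like smoothness but it adds no test power.
`make_cohort()` simulates a control group from the base network and a
positive group with a fixed effect added to randomly chosen differential
edges, under a **shared** diagonal loading so that group membership is
expressed only through those edges. Default shape and group sizes
(170 × 116, 45/47) mirror a typical single-site resting-state study.

Two caveats bound what passing tests show about real data. First, the
construction caps attainable correlation strength: a hub with $k$ strong
edges forces $\delta \approx w\sqrt{k}$, so hub-edge correlations scale
like $1/\sqrt{k}$, weaker than typical fMRI correlations where community
structure supports strong dependence; estimator operating points
($\lambda$ values) therefore do not transfer numerically to real data.
Second, the simulator has no temporal autocorrelation, head motion, site
effects, or hemodynamics — it validates the estimation and evaluation
machinery, not robustness to fMRI artifacts.

## Problem sizes used by the end-to-end checks

The packaged checks run at sizes chosen to exercise the full pipeline
while keeping a complete run in minutes: closed-form agreement on fifty
40 × 8 inputs across the twenty-point $\lambda$ grid; s-metric ordering on
twenty hub cohorts at the full 170 × 116 shape; nested-LOO calibration on
92-subject cohorts (45/47) with 30 ROIs and a three-point $\lambda$ grid,
under a null (effect 0) and a strong-effect (0.5 on 30 edges) condition;
t-test calibration on 1000 null features. `scripts/acceptance.R` recomputes
all of these from scratch at a caller-supplied seed.

## Worked example

```{r example, eval = FALSE}
gt <- make_ground_truth(30, "hub", density = 0.1, hub_count = 3, seed = 1)
xs <- standardize_columns(simulate_timeseries(gt, t = 170, seed = 2))

net_l1 <- estimate_pc_sparsity(xs, lambda = 0.4)
net_sf <- estimate_pc_scale_free(xs, lambda = 0.4)
c(edges_l1 = edge_count(net_l1), s_l1 = s_metric(net_l1),
  edges_sf = edge_count(net_sf), s_sf = s_metric(net_sf))

coh <- make_cohort(gt, n_pos = 10, n_neg = 10, differential_edges = 10,
                   effect = 0.6, t = 170, seed = 3)
loo_evaluate(coh, "pc_sparsity", grid = c(0.2, 0.5, 0.8))
```

## Limitations

* The scale-free weights behave as described above; the estimator is
  faithful to its defining formula, not to the hub-promoting behaviour
  that formula was intended to deliver.
* The constraint set of the general framework (positive definiteness,
  non-negativity) is not instantiated; estimated networks are not
  guaranteed positive definite.
* Group-level priors (shared structure across subjects) are out of scope;
  estimation is strictly per subject.
* No fMRI preprocessing is included: inputs are assumed to be cleaned,
  parcellated ROI time series.
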