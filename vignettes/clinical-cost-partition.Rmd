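---
title: "Partitioning the clinical cost space among rejection classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning the clinical cost space among rejection classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costspace)
```

## The models and their assumptions

A classifier with a reject option is summarised by three numbers: its
sensitivity $s_e$, specificity $s_p$ and coverage $\alpha$ (fraction of
inputs it calls; $1-\alpha$ is the rejection rate). Deployment contexts are
summarised by misclassification costs $c_0$ (pathogenic called benign) and
$c_1$ (benign called pathogenic), a rejection cost $c_2$, and the prevalence
$\rho$ of pathogenic variants among those tested.

The misclassification-only expected cost is
$c=\rho(1-s_e)c_0+(1-\rho)(1-s_p)c_1$. After normalizing by
$c_T=c_0+c_1$ and substituting $rc_0=1-rc_1$ this is linear in the single
scenario coordinate $rc_1$:
$$rc=\bigl[(1-\rho)(1-s_p)-\rho(1-s_e)\bigr]\,rc_1+\rho(1-s_e),$$
so the clinical space is the open interval $I=(0,1)$.

Adding rejection, $c=\alpha\rho(1-s_e)c_0+\alpha(1-\rho)(1-s_p)c_1
+(1-\alpha)c_2$ with $c_T=c_0+c_1+c_2$ and $rc_2=1-rc_0-rc_1$ gives an
affine function of $(rc_0,rc_1)$ over the triangle
$T=\{rc_0,rc_1\ge 0,\ rc_0+rc_1\le 1\}$. Both models assume the
performance parameters are context-independent constants, that costs are
additive averages over a variant stream, and that error rates are
*conditional on acceptance* (see below). Cost values always land in
$[0,1]$, decrease when $s_e$ or $s_p$ improve, and at the corner
$rc_2=1$ equal $1-\alpha$: rejection is the only cost left there.

## Solving the comparison problem

**Interval model.** Each classifier is a line in $rc_1$. All pairwise
crossings are solved analytically; crossings outside the open interval are
discarded (they mean one classifier dominates throughout), the rest are
sorted and de-duplicated. Between consecutive crossings no two lines cross,
so the minimal-cost classifier at the midpoint owns the whole sub-interval;
adjacent sub-intervals with the same owner are unified. The length of each
final interval is the fraction of clinical scenarios where its classifier
is the cheapest.

**Triangle model.** The equal-cost locus of classifiers $i,j$ is the line
$$\{\rho[\alpha_i(1-s_{e,i})-\alpha_j(1-s_{e,j})]+\alpha_i-\alpha_j\}rc_0
+\{(1-\rho)[\alpha_i(1-s_{p,i})-\alpha_j(1-s_{p,j})]+\alpha_i-\alpha_j\}rc_1
+\alpha_j-\alpha_i=0.$$
All pairwise lines are collected, coincident duplicates removed, and each
line clipped to $T$. The arrangement graph has as vertices the triangle
corners, line–side and in-triangle line–line intersections, and as edges
the maximal segments between consecutive vertices along each line and side.
Faces are enumerated by traversing the graph's rotation system (at every
vertex, incident edges sorted by angle; after arriving along a directed
edge the walk continues with the next edge clockwise from its reverse).
Every bounded face is convex, is crossed by no boundary line, and the faces
tile $T$. We chose this face-enumeration route over shortest-cycle search
because the rotation-system walk visits each directed edge exactly once,
needs no geometric side-conditions, and its correctness is easy to audit
through two global invariants that the test-suite enforces: face areas must
sum to the triangle area $0.5$, and an independent Monte-Carlo winner count
must reproduce the region fractions.

Each face is assigned the classifier with minimal cost at the arithmetic
mean of its vertices — an interior point of a convex face, so any interior
representative yields the same winner. Faces are then merged by winner into
regions; a region's area divided by $0.5$ is its classifier's fraction of
clinical scenarios. For large classifier sets, `partition_grouped()`
partitions smaller groups first and discards classifiers that win nowhere
in their group (a classifier dominated in a subset can never win in the
full problem), iterating until one direct run covers the survivors.

## Numerical choices

* **Exact scaled-integer coefficients.** When the inputs are exact decimal
  fractions (the usual case for published performance tables), line and
  crossing coefficients are lifted to integers over powers of ten and
  computed exactly in double precision (all magnitudes are kept below
  $2^{53}$; a digit-budget check falls back to floating point otherwise).
  Coincident cost surfaces and parallel lines are therefore detected by
  exact comparison, not tolerance. Geometric intersection *coordinates* in
  the triangle are computed in floating point.
* **Vertex merging.** Arrangement vertices are merged within a $10^{-12}$
  radius, which collapses concurrent-line intersection points computed
  through different line pairs into a single vertex. This matters most at
  small $\rho$, where boundary-line coefficients become nearly parallel and
  naive geometry accumulates error.
* **Slivers.** Faces with area below $10^{-14}$ are dropped before
  assignment; the tiling check then still requires total face area within
  $10^{-10}$ of $0.5$ and region fractions within $10^{-9}$ of 1.
* **Open interval / boundary scenarios.** Cost evaluation accepts boundary
  scenarios ($rc_1\in\{0,1\}$, triangle edges), but partitions are defined
  on the open interior; 1-D crossings exactly at 0 or 1 are discarded.
* **Ties.** Equal minimal costs (exact, or within $10^{-12}$) are broken by
  input order, and the full tie set is recorded on the partition object.
  The Monte-Carlo oracle breaks ties the same way so fractions are
  comparable.

## Tunable parameters

| parameter | meaning | default | rationale |
|---|---|---|---|
| `rho` | pathogenic fraction of tested variants (unitless) | 0.5 | clinically enriched panels approach balanced classes; sweeps explore other values |
| `alpha` | coverage, 1 − rejection rate | 1 | published tables often omit coverage; 1 reproduces the no-rejection model |
| `tol` | cost tie tolerance | 1e-12 | well above double rounding, far below any meaningful cost difference |
| `merge_tol` | vertex-merge radius | 1e-12 | collapses concurrent intersections without joining distinct vertices |
| `group_size` | classifiers per grouped run | 8 | inside the 5–10 range where direct runs are comfortably conditioned |
| `inclusive` (plug-in rules) | call scores equal to a threshold | TRUE | rejection bands are open: only scores strictly between thresholds are rejected |

## Estimation from labeled tables

`estimate_profile()` computes $s_e=TP/N_p$, $s_p=TN/N_b$ over covered
(non-rejected) variants only, and $\alpha=N/N_{tot}$. The conditional
denominators are deliberate: the rejection-model cost multiplies error
rates by $\alpha$ separately, so including rejected variants in $N_p,N_b$
would double-count rejection. Missing predictions count as rejections for
coverage and are excluded from the error rates. Classes with no covered
variants give `NA` rates plus an explicit flag rather than a silent 0/0.
Variants of uncertain significance are not representable in the label
column — benchmarks for this framework exclude them by construction.

## What the synthetic generators emulate — and what they do not

`generate_profiles()` draws $s_e,s_p\sim U(0.5,1)$ and
$\alpha\sim U(0.4,1)$: accuracies above chance and the coverage span
reported for published missense predictors. `generate_labeled_table()`
draws true labels with pathogenic frequency $\rho$ and, per classifier,
acceptance as Bernoulli($\alpha$) and correctness among accepted as
Bernoulli($s_e$ or $s_p$) — the exact sampling model under which
$(s_e,s_p,\alpha)$ are defined. What this deliberately does *not* emulate:
correlated predictors (real meta-predictors share features and training
data), variant-level difficulty (real errors cluster on borderline
variants), class-dependent rejection rates, or realistic score
distributions. Consequently, passing tests demonstrate the correctness of
the cost algebra, the geometry and the estimators — not that any particular
published tool is preferable; conclusions about real predictors are only as
good as the performance table supplied.

The bundled `inst/extdata/synthetic_17_predictor_profiles.tsv` is a
synthetic stand-in for a published multi-predictor performance table (17
classifiers, rounded to three decimals); it exercises the full pipeline at
a realistic scale but corresponds to no real tools.

## Verification strategy and problem sizes

The test-suite validates every partition against brute force that never
touches the geometry code: a dense-grid winner count on the interval and
Monte-Carlo winner counts on the triangle (the package's
`oracle_fractions()` plus an independent re-implementation in the test
helpers using the un-simplified three-term cost). The headline check runs
52 random classifier sets ($N$ cycling 2–17) crossed with
$\rho\in\{0.001,0.01,0.1,0.5\}$ at $10^6$ Monte-Carlo samples per run,
requiring per-classifier agreement within $\pm 0.005$ — ten binomial
standard errors at $n=10^6$, so the bound fails on any systematic
geometry error while remaining insensitive to sampling noise. These sizes
keep the whole suite at a few minutes on a single core while covering the
regime (near-parallel lines at $\rho=0.001$, dense arrangements at
$N=17$) where geometric errors would surface. Additional invariants:
convexity and pairwise disjointness of faces, the hypotenuse reduction
($\alpha=1$ restricted to $rc_0+rc_1=1$ must reproduce the interval model
to $10^{-12}$), permutation invariance, dominance (a classifier worse in
both $s_e$ and $s_p$ owns nothing), and continuity of fractions along
$\rho$ sweeps.

## Known limitations

* Region polygons are reported as the constituent arrangement faces; no
  geometric union into maximal polygons is performed (areas and fractions
  are unaffected).
* The exact-coefficient path requires decimal inputs within a 15-digit
  budget; irrational or very long inputs silently use the documented
  floating-point tolerances instead.
* Costs and prevalences are treated as known constants; eliciting them, or
  propagating their uncertainty into region boundaries, is out of scope.
* With hundreds of classifiers the arrangement grows quadratically in
  lines (quartically in faces); `partition_grouped()` mitigates but does
  not remove this.
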