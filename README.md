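# costspace

Cost-optimal comparison of rejection classifiers across clinical scenarios.

## The problem

Variant pathogenicity predictors — and binary classifiers with a reject
option generally — are usually compared by context-free performance metrics
(AUC, MCC, sensitivity/specificity). But which tool is *cheapest to deploy*
depends on the clinical context: how bad is a missed pathogenic variant
(cost c₀), how bad is a benign variant called pathogenic (c₁), how costly is
an abstained prediction (c₂), and how frequent are pathogenic variants among
those tested (prevalence ρ)? The best tool for a newborn-screening programme
is not necessarily the best tool for a cancer-panel lab.

`costspace` answers the question *"which classifier is cost-optimal, in
which clinical scenarios, and in what fraction of them?"* for any number of
classifiers, each characterised by sensitivity s_e, specificity s_p and
coverage α (rejection rate 1 − α).

## The models

**Misclassification-only (MISC).** Expected cost of deployment:

    c = ρ(1 − s_e)c₀ + (1 − ρ)(1 − s_p)c₁

Normalizing by c_T = c₀ + c₁ and writing rc₁ = c₁/c_T:

    rc = [(1 − ρ)(1 − s_p) − ρ(1 − s_e)]·rc₁ + ρ(1 − s_e)

Every classifier is a line in rc₁; the clinical space is the open interval
I = (0, 1). Comparing N classifiers means partitioning I at the crossing
points of N lines — `partition_interval()`.

**Misclassification + rejection (MISC+REJ).** With a rejection cost c₂ and
coverage α:

    c = αρ(1 − s_e)c₀ + α(1 − ρ)(1 − s_p)c₁ + (1 − α)c₂

Normalizing by c_T = c₀ + c₁ + c₂ and eliminating rc₂ = 1 − rc₀ − rc₁:

    rc = [αρ(1 − s_e) + α − 1]·rc₀ + [α(1 − ρ)(1 − s_p) + α − 1]·rc₁ + 1 − α

The clinical space is the triangle T with vertices (0,0), (1,0), (0,1) in
the (rc₀, rc₁) plane. The equal-cost locus of any two classifiers is a
straight line; `partition_triangle()` builds the arrangement of all pairwise
boundary lines inside T, enumerates its convex faces, assigns each face the
classifier with minimal rc at the face's vertex average (no line crosses a
face, so that winner holds throughout), and merges faces into regions. Each
region's area over 0.5 is the fraction of clinical scenarios where its
classifier is the cheapest choice.

Supporting machinery: `estimate_profile()` computes (s_e, s_p, α) from
labeled prediction tables, with `plugin_rule()` score-rejection bands
(e.g. reject calls with scores in (0.249, 0.733)); `generate_profiles()` /
`generate_labeled_table()` create synthetic inputs; `oracle_fractions()` is
an independent Monte-Carlo winner-counting check; `sweep_rho()` tracks the
partition across prevalence values; `run_analysis()` and the
`exec/costspace` CLI drive everything from files to JSON reports.

## Worked example

Two classifiers with mirrored trade-offs — A (s_e 0.9, s_p 0.7) vs
B (s_e 0.7, s_p 0.9) — at ρ = 0.5:

```r
library(costspace)
ps <- profile_set(c("A", "B"), se = c(0.9, 0.7), sp = c(0.7, 0.9))
partition_interval(ps, rho = 0.5)
#> Clinical-space partition, misclassification-only model (rho = 0.5)
#>   lo  hi predictor length ties
#>  0.0 0.5         A    0.5
#>  0.5 1.0         B    0.5
#> Fraction of clinical scenarios owned:
#>   A                      50.0%
#>   B                      50.0%
```

The sensitive classifier A wins where false positives are cheap
(rc₁ < 0.5); the specific classifier B wins where they are expensive. With
symmetric profiles and ρ = 0.5 the split is exactly even.

A larger, rejection-aware comparison using the bundled synthetic
17-classifier table (a stand-in performance table with realistic
sensitivity/specificity/coverage spreads):

```r
path <- system.file("extdata", "synthetic_17_predictor_profiles.tsv",
                    package = "costspace")
partition_triangle(read_profiles(path), rho = 0.5)
#> Clinical-space partition, misclassification+rejection model (rho = 0.5)
#> 2803 faces merged into 5 regions:
#>  predictor         area fraction n_polygons
#>    synth02 0.3755759061    75.1%       2559
#>    synth05 0.1158738151    23.2%        178
#>    synth12 0.0046962622     0.9%         43
#>    synth15 0.0037520295     0.8%         19
#>    synth06 0.0001019871     0.0%          4
```

Only 5 of the 17 classifiers are cost-optimal anywhere; the
high-coverage, high-accuracy `synth02` wins 75% of all clinical scenarios,
and the rest of the space belongs mostly to the more sensitive `synth05`.
`plot(partition_triangle(...))` draws the colored triangle.

From the shell:

```sh
costspace partition --model miscrej --profiles profiles.tsv --rho 0.5 \
          --group-size 8 --out report.json
costspace estimate --table variants.tsv --rules rules.json --out profiles.tsv
costspace oracle --profiles profiles.tsv --model miscrej --rho 0.5 --n 1000000 --seed 1
```

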