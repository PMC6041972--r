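---
title: "Methods: tissue-specific QTL meta-analysis on a reference map"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-specific QTL meta-analysis on a reference map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlmeta)
```

## The problem

Insect resistance in maize (and quantitative traits generally) is governed
by many small-effect quantitative trait loci (QTL). Individual mapping
studies report such QTL with imprecise positions, on maps with different
marker sets and inflated or compressed local distances, from populations of
different type (F2, F3, RIL, IRIL) and size. A meta-analysis pools these
reports: it standardizes their statistics, projects them onto one dense
reference map, and asks, per chromosome, how many *true* loci best explain
the observed scatter of reported positions. The consensus loci ("meta-QTL"
or MQTL) have far narrower confidence intervals than any single report and
are the natural targets for marker-assisted selection.

`qtlmeta` implements this pipeline end to end for summary statistics —
no genotype or phenotype data are touched.

## Standardization

Studies report different subsets of {LOD, LRS, R², CI}. The package fills
the gaps in a fixed precedence order (reported values are never overwritten):

* LOD from a likelihood-ratio statistic: `LOD = LRS / 4.6`.
* R² from LOD and the population size N: `R² = 1 − 10^(−2·LOD/N)`.
* The 95% confidence-interval width from the empirical population-size
  approximation `CI = k / (N · R²)`, with `k = 530` for F2/F3 populations
  and `k = 163` for RIL/IRIL populations (`ci_k_constants`; other population
  types must be mapped explicitly). The standardized CI is centered on the
  reported position and replaces the reported interval for all analysis;
  the reported bounds are retained as provenance only.

Within each (study, trait, chromosome) group, QTL whose standardized CIs
overlap are reduced to the single record with the highest R², so one
underlying locus detected twice in a study is not double-counted. Because
sources rarely state whether de-duplication should use reported or
standardized intervals, this is a switch (`use_reported_ci`), defaulting to
standardized — the intervals the analysis actually uses. Ties on R² keep
the narrower reported CI, then the smallest id, making output deterministic.

## Projection onto the reference map

Between a component map and the reference, markers present on both define
anchor pairs per chromosome. Markers whose order disagrees between the two
maps ("inverted markers") must be discarded; the package does this by
keeping the maximum-cardinality subset of anchors that is strictly
increasing in both coordinate systems (a longest-increasing-subsequence
computation; ties prefer anchors spanning the larger interval, which keeps
extrapolation stable). At least two consistent anchors are required, else
the chromosome is flagged `no_anchors` and its QTL are excluded and logged.

Positions between consecutive anchors are rescaled linearly with that
interval's specific ratio; positions outside the anchored span are
extrapolated from the nearest terminal anchor with the chromosome-wide
global ratio (reference span over component span of the retained anchors).
This piecewise map is monotone and, restricted to the anchored span,
invertible — the test suite exercises identity, monotonicity, and
round-trip properties on randomized maps.

A QTL is projected by passing its position and each CI bound independently
through this map. When a CI spans several anchor intervals its two bounds
therefore pick up different local ratios; this is a deliberate choice
(the alternative — rescaling the width by a single ratio — ignores what is
known about the interior). Bounds are re-ordered if needed and clamped to
bracket the projected position. Any projected coordinate below zero marks
the record `discarded_negative` and removes it from analysis, mirroring
standard practice when component maps extend beyond the reference origin.

A consensus map is built by projecting component maps one at a time onto
the growing consensus — components most similar to the reference first,
with shared-marker count as the similarity proxy (ties broken by map id) —
inserting unseen markers at their projected positions and never moving
existing ones, so reference coordinates are stable.

## The mixture model

On one chromosome, the projected positions \(x_1, \dots, x_n\) of \(n\) QTL
are modelled as draws from \(K\) true loci:

\[
L \;=\; \prod_{i=1}^{n} \sum_{k=1}^{K} p_k \,
\varphi\!\left(x_i;\ \mu_k,\ s_i^2\right),
\]

where \(\varphi\) is the normal density, and crucially the variance of each
observation is **fixed**, derived from its own projected 95% CI:
\(s_i = \mathrm{width}_i / (2 \times 1.96) = \mathrm{width}_i / 3.92\).
Only the \(K\) means and the \(K-1\) free weights are estimated, so the
model has \(\nu = 2K - 1\) parameters. This is the classical meta-analysis
formulation in which precise studies pull the consensus harder than vague
ones.

`fit_qtl_mixture()` maximizes \(L\) by EM. For \(K = 1\) the optimum is the
closed-form inverse-variance weighted mean and is returned analytically.
For \(K > 1\), means are seeded k-means++-style on the observed positions
and the EM is restarted 10 times (default), keeping the best
log-likelihood; the per-iteration log-likelihood trace is stored and is
non-decreasing by construction (asserted in tests). Numerical choices:
responsibilities are computed in log space with log-sum-exp; weights are
floored at 1e-12 and renormalized so a component cannot collapse to exact
zero mid-iteration; convergence is an absolute log-likelihood change below
1e-8, capped at 500 iterations (non-convergence is flagged, the best
iterate returned). All randomness is governed by an explicit seed.

## Choosing K

For each chromosome the model is fitted for \(K = 1, \dots, K_{\max}\)
(default \(\min(n, 10)\)) and five information criteria are evaluated:

* `AIC  = −2ℓ + 2ν`
* `AICc = AIC + 2ν(ν+1)/(n−ν−1)` (undefined, reported `Inf`, when `n ≤ ν+1`)
* `AIC3 = −2ℓ + 3ν`
* `BIC  = −2ℓ + ν·log n`
* `AWE  = −2ℓ_c + 2ν(3/2 + log n)`

where \(\ell\) is the mixture log-likelihood and \(\ell_c\) the
classification log-likelihood with each observation hardened to its most
probable component (the Banfield–Raftery form — the least standardized of
the five; the hardening rule is documented so values are reproducible).

"Take the lowest value across the five criteria" is ambiguous when the
criteria disagree, and the legacy software's exact rule is not published.
The default here is a majority vote among the per-criterion minima, ties
toward smaller K (parsimony); `aicc_only` and `consensus_min` (smallest
summed rank) are available as strategies.

## Declaring meta-QTL

At the chosen K, each QTL is assigned to its argmax-responsibility
component. The meta-QTL position is the inverse-variance weighted mean of
its members, its standard deviation \(\sqrt{1 / \sum_i 1/s_i^2}\), and its
95% CI the position ± 1.96 sd. Memberships are the soft responsibilities.
Components emptied by the hardening are dropped with a warning. Loci are
named `LIR`/`SIR`/`KIR` + ordinal (leaf/stem/kernel insect resistance) in
chromosome-then-position order, and flanking markers are the nearest
reference markers at or outside each CI bound.

Tissue classes are analyzed independently — a leaf analysis uses all QTL
measured in leaves (damage resistance and cell-wall constituents alike),
and numbering restarts per tissue.

## Coverage accounting

Two conventions coexist deliberately in `coverage_report()`:

* **QTL coverage** merges overlapping intervals per chromosome before
  summing (`merged_length()`), since overlapping original QTL cover the
  same ground.
* **Meta-QTL coverage** is the raw CI sum (`mqtl_coverage()`), matching the
  convention under which published meta-QTL coverage totals are reported.
  When a table carries a printed `ci95_width` column, that column is summed
  verbatim — printed widths can differ from `end − start` by rounding in
  the source, and the published totals are sums of the printed column.

Percentages are computed against the reference map length (default
7980.637 cM, the dense maize consensus map) and the coverage reduction is
`(QTL − MQTL)/QTL × 100`. Physical coverage sums `end − start` of the
meta-QTL physical intervals against the genome length (default
2,066,432,718 bp, maize B73 RefGen_v2), again without merging. Physical
intervals come from the CI flanking markers; a flanking marker without a
base-pair anchor is replaced by the next anchored marker outward, and a
side that exhausts the chromosome is flagged open-ended (such intervals
must be closed with a user-supplied chromosome length before coverage is
computed — none is bundled).

Cross-tissue overlap regions are connected components of the CI-overlap
graph per chromosome containing at least two distinct tissue classes,
computed on genetic CIs by default or physical intervals on request. No
published count is targeted: region counts are sensitive to the (usually
unstated) region definition, so the package simply reports regions under
this documented one. Rounding of reported percentages is half-up to
2 decimals and happens at report time only; all computation is at full
floating precision.

## The synthetic-data generator

`simulate_dataset()` produces the one thing the literature cannot: a
multi-study dataset with known truth. It emulates

* a dense reference map (sorted uniform marker positions, zero origin),
* component maps that keep each reference marker with probability
  `shared_marker_fraction` and rescale each retained interval by
  `exp(N(0, distortion_sd))` — monotone local distortion, the dominant mode
  of disagreement between real maps (marker inversions are tested by a
  separate adversarial fixture rather than generated, so the generator's
  maps stay order-consistent by construction),
* studies of mixed population type (F2/F3/RIL/IRIL) and size (100–472,
  the span typical of published bi-parental experiments),
* per-QTL R² drawn from Beta(1.2, 8) truncated to [0.005, 0.47], matching
  the 0.3–47% span seen in published per-QTL R² values,
* QTL scattered around each planted locus with exactly the dispersion the
  CI formula implies: width `k/(N·R²)`, sd `width/3.92`, position normal
  around the truth expressed on the component scale.

All randomness flows from the single config seed (study streams are
derived sub-seeds), so equal configs give byte-identical datasets.

What the generator does **not** emulate: selective reporting and
publication bias, correlated QTL across traits within a study, map errors
beyond monotone distortion, segregation distortion, and non-normal
position scatter. Passing recovery tests therefore demonstrate that the
machinery is correct under the stated model, not that real literature data
satisfy that model.

## Problem sizes and checks

The packaged experiments use desk-scale sizes chosen to make the checks
sharp but quick: projection properties on 100 randomized maps; EM-vs-
enumeration classification equivalence on 50 instances with n ≤ 6, K ≤ 2
(exhaustive over all label assignments); and parameter recovery on 100
seeded replicates of 3 loci planted on a 200 cM chromosome at 40/100/160 cM
re-detected by 4–8 of 10 RIL/IRIL studies (N 150–300, R² in [0.08, 0.4],
so the largest per-QTL sd is ≈3.5 cM and the 60 cM separation exceeds five
times that), analyzed with `Kmax = 6`. Under these conditions the planted
K = 3 is recovered in about 97% of replicates with recovered positions
within 2 cM of truth; the occasional miss is an overshoot to K = 4 when
one locus's draws happen to straddle it bimodally.

## Known limitations

* The EM works per chromosome and tissue; no joint model across
  chromosomes, traits, or tissues.
* Observation variances are taken at face value from reported CIs; no
  shrinkage or robustness weighting.
* The AWE hardening rule and the vote-combination strategy are documented
  conventions, not canon; both are exposed as options.
* Physical anchoring reproduces the flanking-marker lookup convention,
  which systematically widens physical relative to genetic intervals.
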