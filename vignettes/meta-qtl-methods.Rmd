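---
title: "Meta-QTL analysis with qtlmeta: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-QTL analysis with qtlmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlmeta)
```

## The problem

Individual QTL mapping experiments in crops report loci whose positions and
confidence intervals depend heavily on the mapping population's genetic
background, size, design and marker density. Meta-QTL analysis pools QTL
detections for the same trait from many independent studies onto one
consensus genetic map and asks: how many distinct underlying loci explain
these detections, and where are they? The pooled consensus loci (MQTLs) have
much narrower confidence intervals than any single study, which makes
candidate-gene inspection and marker development practical.

`qtlmeta` implements that pipeline end to end for a five-trait cereal
compendium (grain yield YLD, grain weight GW, heading date HD, plant height
PH, tiller number TN): compendium I/O and validation, CI estimation,
projection onto a reference map, mixture-model clustering with information-
criterion model selection, genome anchoring, feature co-location, cross-
species ortho-MQTL mining, and a synthetic-compendium generator for
benchmarking.

## Per-QTL confidence intervals

Most published QTLs do not report a positional confidence interval, so one is
reconstructed from quantities that nearly all studies do report: the
population design, the population size $N$ and the fraction of phenotypic
variance explained $R^2$. The closed forms are design-specific:

$$\mathrm{CI}_{95} = \frac{530}{N R^2} \;(\text{BC, F}_2), \qquad
  \frac{287}{N R^2} \;(\text{DH}), \qquad
  \frac{163}{N R^2} \;(\text{RIL}) \quad [\text{cM}].$$

QTLs lacking a LOD score are assigned LOD 3 and those lacking $R^2$ are
assigned 10%; both imputations are flagged (`lod_imputed`, `r2_imputed`) so
they stay auditable. An $R^2$ supplied as a percentage (value in (1, 100]) is
divided by 100 with a warning, since source tables mix conventions.

Clustering treats each projected peak as normally distributed around its true
locus, so the CI is converted to a standard deviation with the two-sided 95%
normal quantile: $\sigma = \mathrm{CI} / (2 \times 1.959964)$. We use the
full-precision quantile `2 * qnorm(0.975)` rather than the rounded 3.92;
the difference is 1 part in $10^5$ and matters only for exact-identity tests.

## Projection onto the reference map

Each QTL is relocated from its source linkage map to the consensus reference
map by linear interpolation between flanking markers shared by the two maps.
Three positions are projected per QTL — the peak and both CI endpoints — and
*each uses its own flank pair* (piecewise-linear projection). A single global
scale would distort wide intervals that span several map segments with
different local expansion factors.

Design choices and degenerate cases:

* **Extrapolation.** A position outside the outermost shared markers is
  projected with the outermost segment's scale and flagged. A peak needing
  more than 10 cM of extrapolation fails (`status = "failed"`), since the
  local scale is unsupported that far out. The threshold is a package choice;
  published analyses report unprojectable QTLs without stating criteria, so
  we prefer a bounded, flagged policy whose failures carry reasons.
* **Order conflicts.** If the shared markers appear in a different relative
  order on the two maps, the QTL fails with `"order conflict"` rather than
  being projected through a non-monotone transformation.
* **Degenerate source segments.** If a flank pair collapses to one source cM
  (co-locating markers), the reference midpoint of the pair is used.
* **Interval floor.** Projected CI widths are floored at 0.1 cM so no
  observation enters clustering with zero variance.
* **SNP-based studies.** QTLs from sequence-based maps carry physical flank
  positions instead of shared markers; `substitute_snp_flanks()` replaces
  each bp position by the reference marker with the nearest annotated bp
  (ties to the lower bp).

Projection between identical maps is the identity, projection is monotone in
the source position, and when a source map is a marker subset of the
reference with unchanged cM the projection error is exactly zero — all three
properties are asserted in the test suite.

## The clustering model

Within one trait × chromosome stratum, projected peaks $x_i$ with standard
deviations $\sigma_i$ are modelled as a $K$-component Gaussian mixture with
*observation-specific, fixed* variances:

$$p(x_i) = \sum_{k=1}^{K} w_k\, \phi(x_i;\, \mu_k,\, \sigma_i).$$

Only the $K$ means and $K-1$ free weights are estimated, so the free
parameter count is $p = 2K - 1$. The EM updates are

$$r_{ik} \propto w_k \phi(x_i; \mu_k, \sigma_i), \qquad
  \mu_k = \frac{\sum_i r_{ik} x_i / \sigma_i^2}{\sum_i r_{ik} / \sigma_i^2},
  \qquad w_k = \tfrac{1}{n}\sum_i r_{ik}.$$

Numerical choices: log-space responsibilities with log-sum-exp; convergence
when the log-likelihood improves by less than $10^{-8}$ (cap 1000
iterations); initial means at the $K$-quantiles of the data with 10 seeded
jittered restarts, keeping the best valid restart; a restart is invalid when
a component degenerates (weight below $1/(10n)$, empty hard assignment, or a
collapsed M step). The per-iteration log-likelihood trace is retained and its
monotonicity is asserted per fit.

### Model selection

$K$ runs from 1 to $\min(n, 10)$, and each candidate is scored by five
criteria:

* $\mathrm{AIC} = -2\ln L + 2p$
* $\mathrm{AICc} = \mathrm{AIC} + 2p(p+1)/(n-p-1)$, unavailable when
  $n - p - 1 \le 0$
* $\mathrm{AIC3} = -2\ln L + 3p$
* $\mathrm{BIC} = -2\ln L + p\ln n$
* $\mathrm{AWE} = -2\ln L_c + 2p(3/2 + \ln n)$, with $L_c$ the
  classification likelihood (mixture density evaluated under hard argmax
  assignments), the Banfield–Raftery form.

Each available criterion votes for the $K$ minimising it; the chosen $K$ is
the modal vote, ties resolving to the smallest $K$. The vote's tie-break and
the $K_{\max} = 10$ cap are package choices — "the prevalent value" among
criteria does not define either — and both are recorded in the per-stratum
audit table that `detect_mqtls()` returns, so a user can always see how close
the vote was.

### Consensus MQTLs

Members of each component are pooled by inverse-variance weighting:

$$\hat\mu = \frac{\sum_i x_i/\sigma_i^2}{\sum_i 1/\sigma_i^2}, \qquad
  \mathrm{Var}(\hat\mu) = \Big(\sum_i 1/\sigma_i^2\Big)^{-1}, \qquad
  \mathrm{CI}_{95} = 2 \times 1.959964 \sqrt{\mathrm{Var}(\hat\mu)}.$$

Two invariants follow and are asserted on every emitted MQTL: the consensus
position lies within the span of its members, and the pooled CI never
exceeds the narrowest member CI. Candidates whose members come from fewer
than two distinct studies are discarded — a cluster seen by a single study is
not evidence of a stable locus. Survivors are numbered within trait by
chromosome and position (`MQTL-GW1`, `MQTL-GW2`, ...). No weighting beyond
the CI-derived variance is applied (e.g. no extra sample-size weights).

## Genome anchoring, features, ortho-MQTLs

An MQTL's genomic interval spans the bp positions of the reference markers
flanking its CI; a flank without bp annotation borrows the nearest
bp-annotated marker in cM. All coordinates are 1-based closed (GFF3
convention); BED tracks are converted from 0-based half-open on import via
`rtracklayer`. Overlap means sharing at least one base pair, so a point SNP
inside an interval counts and abutting closed intervals count. Strand is
ignored throughout.

Ortho-MQTL detection links same-trait MQTL pairs across two species through
ortholog pairs whose two genes fall inside the respective intervals. Only
species-A MQTLs supported by at least three independent studies are
considered (`min_studies = 3`), the minimum number of linking ortholog pairs
is exposed as `min_links` (default 1, since no published threshold exists),
multiple partners per MQTL are allowed, and trait equivalence across species
is an explicit user-provided mapping defaulting to identity on the five
codes. Orthology itself is an input (a two-column table), not computed.

## The synthetic-data generator

`simulate_compendium()` generates exactly the structure the model assumes,
which makes it the right instrument for verifying the estimator and the
wrong instrument for claiming real-data performance:

* a uniformly spaced reference map (defaults: 12 chromosomes × 147.65 cM,
  581 markers per chromosome ≈ 0.25 cM spacing, bp at 250 kb/cM);
* true loci per trait × chromosome (fixed positions or random with a minimum
  separation, default 2 per cell at ≥ 20 cM);
* ~100 studies whose designs are drawn with probabilities 33:13:27:40
  (BC:DH:F2:RIL), population sizes uniform on 77..1024, $R^2$ uniform on
  (0.05, 0.30), each study detecting each true locus with probability 0.085
  (so a default run yields on the order of a thousand detections);
* observed peaks drawn from
  $\mathcal{N}(\text{true position},\, \mathrm{CI}/3.92)$ — the CI coming
  from the study's own design, $N$ and $R^2$ — clamped to the chromosome;
* per-study source maps that are random marker subsets (default 15%) of the
  reference with unchanged cM, so clustering error can be studied in
  isolation; an optional `cm_jitter` perturbs source cM to re-introduce
  projection error, and `noise_scale = 0` gives the zero-noise limit.

What the generator does *not* emulate: genotype/phenotype data (detections
are drawn directly), linkage-map estimation error (unless `cm_jitter` is
set), correlated detections between studies sharing parents, trait
correlations and pleiotropy, non-Gaussian peak errors, and selective
reporting. Passing recovery benchmarks therefore demonstrates correctness of
the estimator under its own assumptions, not robustness to their violation.

`evaluate_recovery()` matches MQTLs to true loci greedily by distance
(nearest pair first, 5 cM default tolerance; greedy rather than optimal
assignment is adequate at the separations tested and is deterministic). A
true locus detected by fewer than two distinct studies is excluded from the
recall denominator because the study-support filter removes it by
construction. With no MQTLs emitted, precision is reported as 1 with an
explicit `precision_undefined` flag.

## Benchmark problem sizes

`recovery_benchmark()` (used by `scripts/acceptance.R` and the acceptance
tests) runs 100 single-chromosome replicates with 1–3 true loci separated by
≥ 15 cM, 8 studies detecting every locus, and $N \sim U\{250..450\}$,
$R^2 \sim U(0.20, 0.35)$, chosen so the per-QTL noise sd stays below about
2.8 cM for every design. At those settings model selection recovers the true
locus count in well over 90% of replicates and matched positions land within
a fraction of a cM (RMSE ≈ 0.25 cM). The oracle-equivalence test uses
exhaustive enumeration of all hard assignments at $n \le 10$, which is the
largest size where $2^n$ enumeration stays trivially fast.

## Bundled reference tables

`rice_mqtl_summary()`, `rice_qtl_counts()` and `rice_qtl_studies()` expose a
transcribed summary of a published 114-MQTL rice compendium (per-MQTL
positions, CIs, genomic intervals and support counts; per-chromosome
projected-QTL counts; and 122 mapping-population descriptions). They drive
the reporting examples and the summary-statistics checks:

```{r fixture-summary}
s <- summarize_mqtls(rice_mqtl_summary(),
                     compiled_total = 1052,
                     qtl_counts = rowSums(rice_qtl_counts()[, -1]))
print(s)
```

Gene counts per MQTL interval in that table depend on the annotation
snapshot used at curation time, so they are reproduced only against bundled
fixtures, never asserted against live annotation releases.

## Known limitations

* The clustering is stratified per trait × chromosome; overlapping MQTLs of
  different traits are a post-hoc report, not a joint fit.
* Consensus-map construction is out of scope: the reference map is an input.
* The CI closed forms are the only interval estimators offered (no
  LOD-drop or bootstrap intervals).
* QTLs reported as marker intervals without a peak need a user-supplied
  point position (e.g. the flank midpoint) before import.
* The criteria vote can be close for weakly separated loci; inspect the
  audit table before trusting a marginal K.
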