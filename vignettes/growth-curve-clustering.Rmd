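---
title: "Clustering growth curves by warped distances: models, parameters and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering growth curves by warped distances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(growthwarp)
```

## What the pipeline assumes

`growthwarp` compares whole growth curves rather than fitted parameters. The
working assumptions are:

* Growth is multiplicative (binary fission), so curves are compared on a
  logarithmic OD scale. `logTransform()` performs the conversion; the
  simulator emits log-scale curves directly.
* Curves may differ in duration and in the number of points, but within one
  analysis they must share a sampling interval, because the warping distances
  are index-based: `dtwDistance()` never looks at time stamps. Aligning
  cadences is the job of `thinToInterval()`, applied upstream.
* Differences in record length are treated as signal, not nuisance. DTW
  accumulates cost over the full alignment, so a 48-h minimal-medium record
  is genuinely farther from a 24-h rich-medium record than from another long
  record. This is intentional: normalising curves to a common span would
  erase part of what distinguishes growth conditions.

## The distance

DTW uses the three-predecessor recurrence with local cost `|a − b|` and no
windowing constraint. Two choices here were genuinely open and are worth
recording:

* **Local cost.** Absolute difference rather than squared difference. It is
  robust to single-point spikes (a reader glitch contributes linearly, not
  quadratically) and makes the global-scaling identity exact:
  `dtw(kx, ky) = |k| dtw(x, y)`. That identity is what makes downstream
  cluster partitions provably invariant to the logarithm base — changing
  base rescales every log curve, hence every distance, by one constant,
  which Ward's linkage and every cut ignore. The base is therefore exposed
  (`logTransform(base =)`) but cosmetic; the default is 10, the OD
  convention.
* **No normalisation before combining.** `combinedDistance()` mixes the raw
  DTW and DDTW values even though they typically differ by an order of
  magnitude. Rescaling them (say, to unit variance) would silently re-weight
  the blend per dataset and make α values incomparable across runs. The fine
  α grid (step 0.01) exists precisely to absorb the scale difference.

DDTW is DTW on plain forward differences (`firstDerivative()`), not on the
smoothed three-point derivative some DDTW variants use: the forward
difference is the definition this pipeline standardises on, and its exact
vertical-shift invariance (`ddtw(x + c, y) = ddtw(x, y)`) is a tested
property, not an approximation.

## Preprocessing parameters

| parameter | default | units | role |
|---|---|---|---|
| `base` | 10 | — | log base; partitions are base-invariant |
| `floorEpsilon` | 1e-3 | OD | floor before the log; keeps blank/zero readings as finite points instead of dropping them |
| `interval` | 1 | h | thinning target; a reading matches grid point `k·Δ` within `Δ/10` |

The thinning tolerance `Δ/10` accommodates plate-reader time-stamp drift;
among several candidate readings the nearest wins, with the earlier time on
ties. Thinning is idempotent and commutes with the (point-wise) log
transform — both are tested invariants. Missing readings are dropped
point-wise at read time because the warping recurrence needs gap-free
sequences; a curve left with fewer than two points is rejected with a
warning rather than silently padded.

## Clustering

Ward's linkage is applied to the combined distance matrix via the
Lance–Williams update on the stored dissimilarities (`stats::hclust`,
`method = "ward.D"`; heights are reported as the recurrence returns them,
without square-root post-processing). Warping distances are not
squared Euclidean distances, so Ward's variance interpretation is a
surrogate here. This is the convention of the standard hierarchical
clustering stacks when handed a precomputed dissimilarity, and it is the
convention this package follows deliberately; merge-height monotonicity is
checked at run time and a violation is logged as a warning. One linkage pass
per α serves all cuts: `gridSearch()` never recomputes DTW/DDTW across the
grid (the matrices are built once) and runs one `wardLinkage()` per α and
one `cutToClusters()` per N.

## Benchmarks and their degenerate-case conventions

Four statistics score each cell; all increase towards 1 for better
agreement.

* **Silhouette** from the α-combined distance matrix, piecewise
  (`1 − a/b`, `0`, `b/a − 1`). Singleton clusters get silhouette 0 — `a(i)`
  is undefined for them, and the zero convention keeps the coefficient
  defined at every cut, including `N = n`.
* **ARI** from the cluster × medium contingency table. Numerator equal to
  denominator returns 1; a zero denominator returns 0.
* **AMI** as `(MI − E[MI]) / (max(H(C), H(G)) − E[MI])` — the standard
  parenthesisation of the max-normalised form — with `E[MI]` from the
  fixed-marginals permutation-model closed form and natural logarithms
  throughout (AMI, h, c and V are base-invariant; only a raw MI report would
  depend on the base). Identical partitions short-circuit to exactly 1; a
  degenerate denominator yields 0.
* **V-measure** `V = 2hc/(h + c)` with `h`/`c` set to 1 when the reference
  entropy is 0, and `V = 0` when `h + c = 0`.

These conventions exist so that degenerate inputs — identical curves,
single-category labels, all-singleton cuts — return defined values instead
of NaN, and they are exercised directly by the test suite.

## The error benchmark and model selection

`errorCount()` implements the majority-vote benchmark: each cluster's
majority medium is the truth and every other member is an error, attributed
to its own medium. The rule is per *cluster*, not per medium: a medium may
legitimately occupy several clusters (slow-growing replicates of a rich
medium can resemble a poor medium's typical curve), and only local
minorities are penalised. Ties go to the medium with the larger
dataset-wide count, then lexicographically — determinism, nothing more.

Model selection reads the per-N minimum-error profile
(`minErrorProfile()`, which also records the *largest* α attaining each
minimum):

* `selectByErrorKnee()` formalises "the errors decreased most
  significantly" as the largest single-step drop `e(N−1) − e(N)`; the
  selected N is the value right after that drop (ties to the smaller N). A
  flat profile triggers a warning and the smallest admissible N; a monotone
  increasing profile has no knee and is an error.
* The α-plateau inspection — is there a range of N over which the best α is
  constant and maximal? — is deliberately *not* folded into the automatic
  rule. It is exposed as a separate diagnostic,
  `alphaProfileAtErrorLevel()`, because it is an inspection step: the
  automatic rule must stay a function of the error profile alone, and a
  plateau heuristic would need its own arbitrary thresholds.

The largest-α tie-break (rather than smallest) reflects what the plateau
inspection looks for: the highest derivative weight that still achieves the
error minimum.

## What the simulator emulates — and what it does not

`simulateCurve()` draws from a modified Gompertz sigmoid in log-OD,

```
L(t) = L0 + A · exp(−exp((μ·e/A)(λ − t) + 1))
```

with lag λ (h), rate proxy μ (log-OD/h) and amplitude A (log-OD), plus
additive Gaussian noise (equivalently multiplicative on linear OD) and an
optional linear death-phase decline. The Gompertz parameterisation was
chosen over the logistic because its λ maps directly onto the lag contrast
that separates rich from minimal media. The presets encode the qualitative
ordering the pipeline must detect:

| archetype | λ (h) | μ (log10-OD/h) | A | record | interval |
|---|---|---|---|---|---|
| LB-like | 1.5 | 0.90 | 2.2 | 24 h | 0.5 h |
| MAA-like | 3.5 | 0.45 | 1.9 | 36 h | 1 h |
| M63-like | 7.0 | 0.25 | 1.6 | 48 h | 1 h |

Baseline is −2 log10-OD (OD 0.01 at inoculation); default noise is 0.05
log10-OD; per-curve jitter is 10 % relative on λ and μ, 5 % on A and on the
record duration, so replicate curves differ in shape *and* length. A
"high" inoculum raises the baseline by 0.4 log10-OD and shortens the
apparent lag by `0.4/μ` hours — a coupled vertical/horizontal shift,
which is exactly the perturbation DTW penalises and DDTW forgives. The
magnitudes are this package's choices (documented, fixed): realistic for
*E. coli* microplate growth, not fitted to any particular dataset. A single
`contrast` scalar interpolates λ, μ, A and duration towards their common
mean; at `contrast = 0` the media are statistically identical and recovery
collapses to chance, which the tests verify.

The simulator does **not** emulate: reader saturation and blank drift,
diauxic shifts, batch effects between plates, or genotype-dependent growth.
Passing tests on simulated data therefore show that the pipeline recovers
condition structure *when it exists in curve shape and length*; they cannot
show how often real data satisfy that premise.

## Problem sizes

The test suite and the acceptance script run at sizes chosen to exercise
every code path at full grid resolution while staying quick on one CPU:
50 curves per medium (150 total, ~11 000 curve pairs of length ≤ 52) for
the end-to-end grid (101 α × 27 N), 6–15 curves per medium for unit-level
end-to-end checks, and lengths ≤ 6 for the exhaustive warping-path oracle
(≤ 1 683 paths per pair). The DTW kernel is compiled (Rcpp); everything
else is plain R on top of `stats`.

## Known limitations

* Ward on a warping dissimilarity is a surrogate (above); complete or
  average linkage would avoid the caveat but change the method.
* The knee rule needs a profile over at least three N and a genuine drop;
  datasets whose error profile is flat (tiny n, or perfectly separable at
  N = 2) fall back with a warning.
* Index-based warping means unequal sampling *within* a curve is not
  handled — `thinToInterval()` must be applied first, and curves sparser
  than the target interval are rejected rather than interpolated.
* `E[MI]` is exact but O(cells × n) per table; for very large N grids on
  very large datasets AMI dominates the per-cell cost.
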