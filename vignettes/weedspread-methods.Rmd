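---
title: "Methods: residence-time-corrected spread analysis and attribute syndromes"
author: "weedspread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residence-time-corrected spread analysis and attribute syndromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the synthetic
tests do and do not establish about real data.

## 1. The scientific question

Darwin's naturalization hypothesis (DNH) predicts that a nonnative plant
arriving in a territory where native congeners occur will spread less than
one without close relatives, through competition and shared natural
enemies. Testing this on herbarium data requires disentangling *time* from
*kinship*: a species occupies more localities partly just because it has
been present longer. The pipeline therefore (i) estimates how long each
species has really been present, correcting the first herbarium record for
collection effort, (ii) regresses occupied localities on corrected
residence time and classifies species by their position relative to the
regression's confidence band, and only then (iii) asks whether kinship or
attribute syndromes explain who spread more than expected.

## 2. Detection-corrected residence time

**Model.** Yearly detections of new nonnative species saturate with the
collection effort `ef` (herbarium specimens collected that year):
`n(ef) = a·ef / (1 + b·ef)`. `fit_saturation()` estimates `(a, b)` by
nonlinear least squares (`stats::nls`, port of the rational model), with a
deterministic initialization — `a0` from the initial slope of `n` against
`ef` over the lowest-effort positive points, `b0 = a0 / max(n)` — and
`scaleOffset = 1` so the convergence criterion stays defined on
(near-)noise-free data. No random restarts: the 2-parameter problem is
well-behaved and determinism matters more.

**Rescaling.** `n_max = round(n(ref_effort))` with `ref_effort = 1800`
specimens is treated as the maximum number of species detectable in one
year. The curve's asymptote `a/b` is higher, but the rescaling point is a
modelling convention: detection probability `dp(ef) = n(ef)/n_max` then
slightly exceeds 1 above the reference effort and is clamped to `[0, 1]`.
`ref_effort` is configurable for sensitivity analyses.

**Correction.** A species first recorded in a year with effort `ef`
carries `pu = 1 − dp(ef)`, and its residence time `rt` (reference year
minus first-record year) is adjusted to `art = rt + 100·pu`. The 100-year
multiplier is a convention of the correction method, kept as a named,
configurable constant (`correction_scale`); the package derives no theory
for it. Consequences asserted as invariants: `art − rt ∈ [0, 100]` and
species first recorded in high-effort years receive smaller corrections.

**Choice: yearly totals.** The saturation curve is fitted to per-year
totals of species detected versus per-year effort (not cumulative counts),
matching the per-year reading of both quantities; the effort series
carries `n_species` and `n_new` so a cumulative variant can be fitted by
hand if wanted.

## 3. Spread regression and classification

`fit_spread()` runs OLS of `log10(localities)` on `log10(art)` within one
life-form group, exposing slope, intercept, `R²`, the two-sided slope
p-value and the sufficient statistics (`n`, `x̄`, `S_xx`, residual SD) for
band computation. Design choices:

* **Band type.** The classification band is the pointwise *confidence band
  for the mean response*, `ŷ(x) ± t_{n−2} · s · sqrt(1/n + (x−x̄)²/S_xx)` —
  narrow and curving, which is what makes most species classifiable. A
  prediction-interval option (`type = "prediction"`) is exposed for
  sensitivity; it is much wider and labels almost everything "expected".
* **Fit on all species, classify post-lag.** The regression is fitted on
  all species of the life-form group; the lag gate (`art ≤ 54` yr for
  herbs/subshrubs, `≤ 300` yr for trees/shrubs, both configurable) only
  decides who gets a spread label (`PRE_LAG` otherwise). `post_lag_only =
  TRUE` refits on naturalized species alone.
* Labels partition the input; residuals (observed − fitted log10
  localities) are stored for every species, since the kinship tests use
  them.

## 4. Kinship association tests

Standard tests, via base R where base R is the field's tool: equal-split
goodness-of-fit and 2×2 Pearson χ² (`chisq.test`), Spearman with midranks
and the t approximation (`cor.test`). Mann–Whitney U is the one hand-built
piece: the reported statistic is `min(U_a, U_b)` and, when the group sizes
make it feasible (`n_a·n_b ≤ 400` and `C(n_a+n_b, n_a) ≤ 2·10⁵`), the
two-sided p comes from exact enumeration of all group assignments — valid
under ties, which the base exact branch refuses; otherwise the tie-corrected
normal approximation (no continuity correction) is used. All p-values are
two-sided; no multiple-testing correction is applied anywhere in the
battery, a deliberate mirror of common practice in this literature and a
documented limitation.

A note on arithmetic: published analyses of this design sometimes print χ²
values that cannot be reproduced from their own printed counts under any
standard variant (equal-split, 2×2, or Yates-corrected), with p-values
inconsistent with df = 1. The package implements only the standard
definitions; its worked examples print values that satisfy them exactly.

## 5. Attribute screening

Jaccard distances (`stats::dist(method = "binary")`) with one convention:
two all-zero vectors get distance 0 rather than the undefined 0/0 — this
keeps such species in the analysis without NaN propagation, and the number
of affected pairs is reported. UPGMA is `stats::hclust(method =
"average")` over lexicographically pre-sorted labels, so distance ties
break by label order and runs are bit-reproducible under input
permutation.

"Attributes that do not contribute to the classification" has no unique
formalization; the package's reconstruction is a greedy leave-one-out
screen: constant attributes drop first, then repeatedly the attribute
whose removal most increases (or least decreases) the cophenetic
correlation of the species dendrogram, while the correlation stays within
`epsilon = 0.005` of its running maximum. Two facts about this criterion,
found during its construction and visible in the tests: it ranks noise
attributes below structural ones reliably, but it cannot see redundancy —
any one member of a mutually redundant structural set is individually
dispensable, so unconstrained greedy pruning runs essentially to
exhaustion. `min_retain` therefore bounds the depth (`prune_attributes()`
defaults to 1, preserving the degenerate `epsilon = Inf` limit; the
pipeline uses 30 of 50 attributes, the scale of screen a practitioner
would accept, and also because ordinations over very few binary attributes
degenerate through tied distances).

## 6. Ordination

`nmds()` is a from-scratch Kruskal stress-1 implementation:
`stress = sqrt(Σ(d − d̂)² / Σ d²)` where `d` are configuration distances
and `d̂` monotone disparities from pool-adjacent-violators regression
(`stats::isoreg`) on the dissimilarity order, with *primary* tie
treatment (tied dissimilarities ordered by current distance, so they may
receive distinct disparities). Minimization is steepest descent with
backtracking line search — only decreases are accepted, so the reported
stress trace is nonincreasing by construction — run from one metric-scaling
(`cmdscale`) start plus `restarts` random starts, keeping the best. The
analytic gradient treats the PAV fit as locally constant, which the
projection theorem justifies almost everywhere. Convergence: stop when the
per-iteration improvement falls below `tol = 1e-8` or at `max_iter = 200`.
Tests check the final stress against an independent numerical-gradient
(finite-difference BFGS) oracle from the same start, and against
`vegan::monoMDS` as an established reference — never using either as the
implementation. Reported alongside stress is `R²`, the squared correlation
between disparities and configuration distances. Two dimensions by
default, matching how such ordinations are plotted.

Grouping is `stats::kmeans` (Hartigan–Wong, best of `n_init = 25` starts)
rather than a hand-rolled Lloyd/k-means++: the contract that matters — the
best-of-starts partition by within-group sum of squares — is what base
`kmeans` delivers. `k` is either pinned (e.g. 6) or chosen by mean
silhouette width (`cluster::silhouette`); when even the best silhouette is
below 0.5 there is no real group structure, the choice is flagged
`low_confidence`, and the smallest candidate `k` is returned (a lone
Gaussian cloud scores ≈ 0.3–0.4 however it is split, so the argmax would
be noise).

`fit_vector()` projects a centered covariate onto the ordination axes
(least squares through the QR decomposition); `r²` is the explained
fraction of covariate variance and the p-value is `(1 + #{permuted r² ≥
observed}) / (n_perm + 1)` under random relabelling, with 999 permutations
by default — so p can never fall below `1/(n_perm+1)`.

## 7. COSA

The attribute-importance machinery is written from scratch (the reference
implementation is not on CRAN, and the method is the analytical core
here).

* **Dissimilarities.** Binary: `d_ijk = |x_ik − x_jk|`; numeric columns:
  `|x_ik − x_jk| / s_k` with `s_k` the mean absolute deviation
  (dispersion-free columns get 0 everywhere and are flagged).
* **Inverse-exponential distance.** `D_ij = −λ·ln Σ_k w_k e^{−d_ijk/λ}`,
  computed through log-sum-exp so both analytic limits are stable: the
  minimum over attributes as λ→0 and the weighted mean as λ→∞ (checked at
  λ = 10⁻⁶ and 10⁶ to 10⁻⁴).
* **Iteration.** From uniform weights: compute all pairwise distances
  under each object's weights, take each object's `k_nn = ⌈√n⌉` nearest
  neighbours, set `S_ik` to the mean attribute-k dissimilarity to those
  neighbours, and reset `w_ik ∝ exp(−S_ik/λ)`; stop when the largest
  weight change is below `tol = 1e-4`. λ defaults to 0.2. The returned
  matrix is the one from the last executed sweep, symmetrized, so a
  single-sweep call is exactly the uniform-weight distance. A limitation
  established during development and reflected in the tests: the update
  reliably upweights *blocks* of correlated discriminating attributes
  (the subset structure the method is designed for), but a single
  informative attribute among many independent noise attributes is not
  recoverable — neighbour selection under the soft-minimum is then driven
  by chance agreement on the noise attributes, a rich-get-richer effect no
  (λ, k_nn) setting overcame in simulation.
* **Group importance.** For a-priori groups (here ML/FL × with/without
  relatives), `S_kl = (1/N_l²) Σ_{i,j∈C_l} d_ijk` over *ordered* member
  pairs including `i = j` (which contribute zero), taking the printed
  `1/N²` normalization literally; an unordered-pairs option exists because
  the convention is ambiguous, and `N` is the group size, not the total
  object count (the latter would make importances incomparable across
  groups). Importance is `I_kl = 1/(S_kl + ε)`; relative importance
  normalizes `I` to sum to 1 within a group. `ε` defaults to 0.01, capping
  a dispersion-free attribute's importance at 100 — large enough to keep
  it top-ranked, small enough not to obliterate the scale. For all-binary
  matrices `S_kl` collapses to `2·m₁·(N−m₁)/N²` via column sums, and the
  randomization null uses this closed form; tests verify it equals the
  definitional pair sum.
* **Randomization null.** Group labels are permuted across species 1000
  times and importances recomputed; the null mean and 95th percentile per
  group × attribute are the reference lines. The exceedance flags compare
  *unnormalized* importances: relative importances are a zero-sum share,
  so a single near-constant attribute would depress every other
  attribute's share below its null and mask true syndrome members, whereas
  per-attribute importances are compared on a common footing. One
  consequence, deliberate and tested: under a true null the observed
  importance beats the (right-skewed) null mean somewhat less than half
  the time, and the 95th percentile about 5% of the time.

## 8. The synthetic world

`generate_dataset()` emulates the statistical structure the pipeline
assumes, with defaults chosen once as the study conditions: 305 species
(herb/subshrub-dominated, 278:27), true arrivals uniform over 1700–1995
with reference year 2003, collection effort ramping exponentially from ~5
to 2000 specimens/yr (lognormal noise, SD 0.1 on the log scale; a constant
shape exists for isolating the detection process), per-year detection
probability `ef/(ef + 500)`, locality counts
`round(10^(−2.549 + 1.8213·log10(rt_true) + N(0, 0.3) + shift))` floored
at 1, 20% planted outliers displaced ±1 log10 unit (the ML/FL ground
truth), zero-inflated-Poisson congener counts (45% structural zeros, mean
2), and a 50-attribute binary matrix with four planted 5-attribute
syndromes at incidence 0.9 against a 0.2 baseline. With `sigma = 0` and no
outliers the locality counts are left unrounded so the configuration is an
exact diagnostic line (integer rounding would otherwise break exact
recovery); with noise they are integers, as in real data, which censors
species whose expected count falls below ~1.

What it does *not* emulate: geography (locality identifiers are opaque),
taxonomy beyond a family label, phylogenetic correlation of attributes,
temporal trends in locality colonization, or any dependence of spread on
congeners — the null world is DNH-false by construction unless an effect
is planted. Green tests therefore establish that the machinery recovers
what was planted under these idealized conditions, not that the method is
unbiased on real herbarium data, where detection history and locality
definitions are far messier.

**Calibration designs.** Parameter-recovery tests use a dedicated
configuration fixed before the tests were frozen: arrivals over 1500–1940
(every species past the 54-year lag and expected counts clear of the
round/floor censoring), near-immediate detection (`detection_scale = 5`),
no planted outliers, n = 250, slope 1.8, noise SD 0.3. Under these
conditions 200 replicates recover the slope with bias well inside ±0.02;
per-replicate spread is SE ≈ 0.08 (the information ceiling set by n, the
noise SD and the attainable log10-residence-time spread), so the
per-replicate band asserted is ±0.16. Under the *default* world the
fitted slope exceeds the generating value — old species are detected late
and the 100-year correction cap cannot fully restore their residence
times — which is the detection-censoring behaviour the correction exists
to mitigate, not an estimator defect; the worked example in the README
shows it. The syndrome-power design uses four groups of 40 species, 20
attributes and a 5-attribute syndrome at 0.9 vs 0.2. Test problem sizes
throughout (tens to a few hundred species, hundreds to 2000 replicates)
are chosen to make the asserted properties statistically decidable with
comfortable margins.

## 9. Pipeline and reproducibility

`run_pipeline()` sequences ingest → deduplication (earliest record per
species × locality, exact string match on the locality identifier) →
effort series → saturation fit → profiles → per-life-form regression and
classification → kinship battery → attribute screen → NMDS/K-means/vector
fits → COSA report. Every stochastic stage consumes `sub_seed(master,
stage_name)`, a stable polynomial hash, so adding a stage never shifts
another stage's stream; outputs are TSV plus an MD5 manifest, and two runs
with the same master seed produce hash-identical trees. Records with a
missing collection year are dropped and counted (they cannot enter a
residence-time analysis); years outside `[1500, ref_year]` are rejected as
data errors, not clamped. A failing stage returns the bundle accumulated
so far with an error marker rather than throwing.

## 10. Known limitations

* The 100-year correction multiplier and the `n_max` rescaling point are
  conventions of the correction method, not estimated quantities.
* The attribute screen's stopping rule is weakly identified; only the
  contribution *ranking* is robust, and the retained-set size is
  effectively a user choice (`min_retain`).
* The kinship battery applies no multiple-testing correction.
* COSA cannot recover a lone informative attribute among many noise
  attributes (see §7), and its λ, `k_nn` and ε have no data-driven
  defaults here — ranks and null-exceedance flags, not absolute weights,
  are the outputs meant for interpretation.
* NMDS on heavily tied binary Jaccard distances can reach degenerate
  near-zero-stress configurations when very few attributes remain; the
  pipeline's retention floor exists partly for this reason.
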