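---
title: "Fragment saliency: model, stimuli, and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment saliency: model, stimuli, and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragsal)
```

This vignette is the package's own account of the science it implements:
the constrained maximum-entropy feature model, the geometry of
fragment-occluded 2IFC stimuli, the saliency metrics, the generative
observer used for synthetic studies, and the statistical analyses — with
the numerical conventions and design decisions a maintainer would need.

## The constrained maximum-entropy feature model

An early visual filter cannot transmit everything it sees. The model
treats the first stage of fast vision as a pattern filter over binarized
images: the image is partitioned into 3×3-pixel tiles, each tile is one of
the $2^9 = 512$ binary patterns, and only a limited repertoire of patterns
("features") is transmitted downstream. Two resources are limited:

* **storage** — at most $N$ distinct features can be represented
  (`n_max`, default 50, the size of the published feature set);
* **output bandwidth** — transmitted tiles occupy channel capacity, so
  the total probability of transmitted patterns is capped at $B$
  (`bandwidth_max`, default 0.2; see below).

Given the pattern distribution $p_i$ estimated from images, the selected
bank $D$ maximizes the transmitted (Shannon) entropy

$$H(D) = \sum_{i \in D} p_i \log_2 (1/p_i)
\quad\text{s.t.}\quad |D| \le N,\;\; \sum_{i \in D} p_i \le B .$$

This is a budgeted knapsack with per-item value $p\log_2(1/p)$ and weight
$p$. The formulation makes both qualitative exclusions of the model
automatic: uniform (all-black/all-white) patterns, which dominate
binarized natural scenes, are priced out by the bandwidth budget, while
vanishingly rare "noisy" patterns carry essentially no entropy and are
never worth a storage slot. What survives are the mid-probability,
bar- and edge-like textured patterns.

**Solver.** For alphabets of at most $2^4$ patterns the package
enumerates all subsets (vectorized over a cached membership matrix), so
selection is exact wherever exhaustive search is feasible; the test suite
pins this equivalence against an independently implemented enumeration
oracle. For the 512-pattern alphabet enumeration is impossible and a
local-search heuristic is used: greedy fills from three orderings (value,
value-to-weight ratio, weight) and from every single-item seed, refined by
add, best-single-swap, drop-and-refill and pair-drop-and-refill moves.
The heuristic always returns a feasible bank, and is provably exact when
the bandwidth budget is slack (the bank is then the $N$ highest-value
patterns) or when $N \le 2$; for budget-tight multi-feature optima it is
an approximation — cardinality-constrained knapsacks are NP-hard, and
stress tests with adversarial random 16-item instances defeat every
polynomial local search we tried, which is why exactness is promised only
where enumeration is feasible. Ties are always broken toward smaller
pattern ids, so selection is deterministic.

**Conventions.** Tiles are non-overlapping, anchored at the image's
top-left corner; incomplete edge tiles are dropped (the model speaks of an
image *partition*; a sliding-window variant was considered and rejected to
keep the feature count interpretation exact). Pattern statistics are
pooled over the whole image set before selection. A pattern id reads the
tile row-major as a binary number, top-left pixel most significant,
bit = 1 for white.

**Why `bandwidth_max = 0.2`.** The exact bandwidth that produced the
published 50-feature set is not restated in the study this package
follows, so the default is a package parameter, not a claim. It was fixed
once from the structure of the generative model: on the synthetic
naturalistic statistics (below), $B = 0.2$ is in the regime where both
constraints are meaningful exactly as in the published set — the bank
attains all $N = 50$ slots, the two uniform patterns (each with
probability ≈ 0.2 on its own) remain excluded, and per-fragment SNR spans
roughly 0–0.3, the range over which performance was analyzed. Much
smaller budgets leave most storage slots unused; budgets approaching the
uniform patterns' probability admit them and destroy the bank's textured
character.

## Stimulus geometry

The study display is 918×672 px subtending 32.4×23.7° (28.33 px/deg,
consistent between axes within 0.07%); background gray is level 127, and
the white/black/gray luminances (35/1/12 cd/m²) are carried as metadata
only — no photometric modeling is done. Degrees convert to pixels by
nearest integer with ties toward the smaller value, so 2.4° → 68 px and
0.3° → 8 px.

Fragments are squares placed in the **square-annulus frame** between
eccentricities 4.8° and 8.8°, where eccentricity is the Chebyshev distance
(max of |x|, |y| in degrees) from the image center — the strictest reading
of a "squared frame": every pixel of every fragment lies inside the band.
Even distribution over the frame is operationalized by partitioning the
band into four trapezoidal sectors along its diagonals and assigning each
fragment to a side by its center; side quotas (3/3/2/2 for ten fragments,
12/12/8/8 for forty, 40 each for one hundred sixty) are honored exactly.
Placement is seeded rejection sampling with a per-box retry budget and
whole-configuration restarts; genuinely infeasible requests (area demand
exceeding the band) fail with an explicit placement error. A separate
checker — written against a different formulation of the same constraints
(extrema of the Chebyshev distance over a box, pairwise rectangle
intersection, re-derived sector labels) — validates every configuration in
the test suite, one thousand seeded configurations per study condition.

Rendering copies source pixels inside the boxes and masks everything else
to gray; contrast inversion swaps black and white and leaves gray
untouched (an involution). Trial schedules implement the 2IFC design:
exact per-condition trial counts, uniform random target interval, a
distractor drawn uniformly from the other images, a uniform diagonal
±10 px displacement, per-image independent fair-coin contrast inversion in
the inverted task, and inclusive running repetition counters (occurrences
of each image as target or distractor). Presentation timings (fixation
300 ms, stimulus 25 ms, mask 500 ms, comparisons 350 ms each) are design
metadata; nothing is rendered in time, and the mask content is not
modeled. One open geometric point is documented rather than resolved: the
frame-condition visible area computed from the stated geometry is ≈ 28%
of the image, not the 35.8% printed with the original design, so the
frame stimulus is treated parametrically and its area is never used as a
target quantity.

## Saliency metrics

Per fragment, two quantities:

* **SNR** — the number of optimal features over the total number of
  features, where features are the complete 3×3 tiles of the fragment
  under the same partition convention as the model (top-left anchored,
  incomplete remainders dropped; a 68-px fragment yields 22×22 tiles).
  "Total number of features" means tiles in the fragment, the only
  reading that makes SNR a fraction in [0, 1].
* **Weber contrast** — |mean pixel level − 127| / 127 on the 0/255
  levels, so an all-black fragment scores 1 and an all-white one 128/127.

Ten-fragment stimuli are summarized by the unweighted means across
fragments. Performance curves use left-closed, right-open bins anchored
at 0 (width 0.05 for SNR, 0.2 for contrast, as in the study's analysis)
or at the pooled minimum for the signed standardized difference, with
per-bin binomial SDs $\sqrt{p(1-p)/n}$.

The two metrics are structurally anticorrelated on naturalistic binarized
images: feature-rich fragments are textured and average toward gray (low
contrast), while high-contrast fragments are dominated by uniform areas
containing few optimal features. The acceptance suite verifies this on a
synthetic study of 2,000 ten-fragment stimuli over 100 images, requiring
Pearson r ≤ −0.3; the observed correlations are substantially stronger.

## Synthetic data

**Images.** Each synthetic image is an isotropic Gaussian random field
with power spectrum ∝ $1/f^\beta$ (amplitude $f^{-\beta/2}$, DC removed),
thresholded at the `black_fraction` quantile (default 0.5). At the
default $\beta = 2$ — the spectral slope characteristic of natural
scenes — the binarized fields reproduce the statistical premises of the
model: the two uniform 3×3 patterns are the two most probable and the
pattern entropy is far below the 9-bit maximum, which is exactly the
compressibility the feature model exploits. $\beta = 0$ gives i.i.d. fair
bits (all 512 patterns equiprobable), a useful null. Defaults mirror the
study's materials: 327 images of 918×672 px. A thresholded-field
generator was preferred over dead-leaves models because a single
parameter ($\beta$) controls the uniformity/texture balance that drives
the SNR–contrast anticorrelation. What the generator does **not**
emulate: object structure, scene semantics, occlusion relationships, or
any dependence between images — so passing tests demonstrate the
pipeline's statistical behavior on naturalistic *statistics*, not
recognition of natural *content*.

**Observer.** Responses are simulated from the exact generative mirror of
the fitted GLMM: logit of a correct response equals
$\beta_0 + \beta_d d + \beta_{order}\,[\text{interval}=1] +
\beta_{rep}\log(1+\text{rep}) + \beta_{inv}\,[\text{target inverted}] +
u_{participant} + v_{stimulus}$, with normal random intercepts. The
mirror construction makes parameter recovery a well-posed test of the
analysis. Defaults ($\beta_0 = 0.5$, $\beta_d = 0.4$,
$\beta_{order} = 0.1$, $\beta_{rep} = 0.05$, $\beta_{inv} = -0.2$,
$\sigma = 0.3$ for both random effects) put overall accuracy near the
60–65% the task produces in practice, with qualitatively matching order,
repetition-learning and inversion effects; they were fixed once at design
time. The standardized difference $d$ is computed over the schedule being
simulated; trials without a defined measurement (the frame condition)
contribute $d = 0$ to simulation and are excluded from analysis.

## Statistical analysis

* **GLMM.** Bernoulli, logit link, fixed factors as above, random
  intercepts for participant and stimulus, fitted with `lme4::glmer`.
  Per-factor χ² statistics are likelihood-ratio tests against the model
  refitted without that factor (Wald z values are also reported in the
  coefficient table). `nAGQ = 1` (Laplace) is the accuracy default;
  `nAGQ = 0` is available where many refits are needed, as in the
  type-I-error simulation. All responses identical raises an explicit
  separation error; a random grouping with fewer than two levels falls
  back to a fixed-effects GLM with a warning flag.
* **Standardization** pools all visible-area conditions within a task
  (z-scores with sample SDs), then $d = z(\text{SNR}) -
  z(\text{contrast})$.
* **Two-proportion z-test** uses unpooled binomial standard errors —
  matching a comparison of proportions "with binomial standard
  deviations" — and a two-sided normal p.
* **Friedman test** uses within-subject average ranks with the standard
  tie adjustment, $\chi^2 = (k-1)\sum_j (R_j - n(k+1)/2)^2 / (A - C)$,
  Kendall's $W = \chi^2 / (n(k-1))$, and an exact p-value by full
  enumeration of within-subject permutations when $(k!)^n \le 10^5$
  (chi-square approximation otherwise). It agrees with
  `stats::friedman.test` on tie-free data and with a brute-force
  permutation oracle on 3×3 designs.
* **Wilcoxon against chance** wraps `stats::wilcox.test` (exact for
  n ≤ 15 without ties or zeros): ten subjects all above chance give the
  maximal statistic 55 with exact two-sided p = 2/1024 ≈ 0.002.

**Parameter recovery and calibration.** The acceptance suite fits the
GLMM to 20 replicate synthetic studies at 12,000 trials
($\beta_d = 0.4$, $\sigma = 0.3$); replicates share the expensive
stimulus pool (images, bank, configurations, measurements) but draw fresh
trial schedules, random effects and responses. The criterion is the
estimate falling within ±2 SE of truth in at least 90% of replicates —
note that with nominal ~95% coverage this binomial gate has an intrinsic
failure probability of roughly 10% even for a perfectly calibrated
estimator. The null calibration fits 200 replicates at 2,000 trials
(stratified as the first 200 trials of each participant, preserving both
grouping structures) with $\beta_d = 0$ and requires the LRT rejection
rate at α = 0.05 to lie in 0.05 ± 0.03.

## Problem sizes and determinism

The shipped tests and the acceptance script use the study's own design
scales where they are stated — 918×672 px geometry, 327 images × 5
configurations = 1,635 stimuli per condition, 3,000 preliminary trials,
12,000 inverted-task trials across 10 observers — and a 100-image /
2,000-stimulus synthetic study for the anticorrelation property, matching
the scale at which that property is specified. Every random draw flows
from an explicit seed: package functions take seeds as arguments and
restore the caller's RNG state, stage seeds are derived from one master
seed by a Lehmer step (always below $2^{31}$), and the pipeline's
manifest records them all, so reruns are byte-identical.

## Known limitations

* The published 50-feature set itself is not shipped (its pixel patterns
  are not machine-readable from the source figure); banks are derived
  from image statistics or loaded from a bank file.
* The large-alphabet selector is heuristic in the budget-tight
  multi-feature regime (see above); exactness is guaranteed only where
  enumeration is feasible.
* The synthetic images capture second-order (spectral) structure only;
  conclusions about real photographs require real image sets, which the
  IO layer (PNG/PGM) accepts directly.
* Eye movements, masking content, display calibration and reaction times
  are out of scope; the repetition covariate models visual learning only
  as a log-count trend.
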