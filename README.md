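# fragsal

Fragment saliency and fast-vision psychophysics pipelines in R.

## The problem

In natural viewing, objects are usually partly occluded: the visual system
must recognize a scene from a handful of visible fragments, and it must do
so fast. One influential account holds that an early, capacity-limited
stage of vision transmits only a small set of *optimal features* — local
binary patterns selected by **constrained maximum-entropy optimization** —
and that these features determine what is salient in fast vision.

`fragsal` implements the full computational pipeline needed to study that
hypothesis with fragment-occluded, two-interval forced-choice (2IFC)
discrimination experiments:

* **Feature model.** Binarized images are partitioned into 3×3-pixel
  tiles; the pattern distribution `p_i` over the `2^9 = 512` binary
  patterns is estimated, and the feature bank `D` maximizes the
  transmitted entropy

  `H(D) = Σ_{i∈D} p_i log2(1/p_i)`   subject to   `|D| ≤ N`, `Σ_{i∈D} p_i ≤ B`,

  where `N` is the feature-count limit (50 by default, matching the
  published set) and `B` the output-bandwidth limit. The bandwidth cap is
  what excludes the extremely frequent uniform (all-black/all-white)
  patterns of binarized natural scenes; vanishing-probability "noisy"
  patterns carry no entropy and are never selected. Images can be reduced
  to *sketches* retaining only optimal-feature tiles.
* **Stimulus generation.** Square fragments of a source image are placed
  in a square-annulus eccentricity frame (4.8°–8.8° by default) under the
  study's explicit rules — containment, even side quotas (e.g. 3 top,
  3 bottom, 2 left, 2 right for ten fragments), pairwise disjointness —
  with everything else masked to gray. 2IFC trial schedules add target
  interval, distractor, diagonal 10-px displacement, optional random
  contrast inversion, and running image-repetition counters.
* **Saliency metrics.** Per fragment: the optimal-feature SNR (number of
  optimal 3×3 features over the total number of features in the fragment)
  and the Weber contrast `|mean level − 127| / 127`; per stimulus, their
  unweighted means across fragments; binned performance curves and the
  SNR–contrast Pearson correlation.
* **Analysis.** Binomial (logit) GLMMs of response correctness with the
  standardized SNR−contrast difference, target order, log repetition
  count, and target contrast inversion as fixed factors and participant
  and stimulus random intercepts (via `lme4`), with per-factor
  likelihood-ratio χ² tests; two-proportion z-tests with unpooled binomial
  SEs; Friedman tests with Kendall's W (exact enumeration for small
  designs); one-sample Wilcoxon tests against chance.
* **Synthetic data.** Thresholded `1/f^β` Gaussian noise images whose
  binarized 3×3 pattern statistics reproduce the naturalistic regime
  (uniform patterns dominate; entropy well below 9 bits), and a generative
  logistic observer that mirrors the GLMM, so the whole pipeline is
  testable end to end without human data.

## Worked example

A small synthetic study — images, feature bank, stimuli, measurements and
simulated responses — followed by the mixed-model analysis:

```r
library(fragsal)

study <- generate_study(
  design       = main_design("inverted"),   # 4 conditions x 300 trials
  image_spec   = synthetic_image_spec(n_images = 6),
  n_participants = 3,
  seed         = 11
)
study$bank
#> Feature bank: 50 of at most 50 3x3 patterns
#>   bandwidth limit 0.2 (used 0.2), entropy 1.374 bits

analysis <- analyze_schedule(study$schedule, nAGQ = 0)
analysis$glmm
#> Binomial GLMM (logit link), 3600 trials
#> Fixed effects:
#>             estimate     se       z
#> (Intercept)  -0.2155 0.3400 -0.6338
#> d             0.4200 0.0264 15.9152
#> order1        0.0885 0.0744  1.1892
#> log_rep       0.1753 0.0390  4.4912
#> inverted     -0.1407 0.0745 -1.8873
#> Random-intercept SDs:
#>    stimulus participant
#>      0.3325      0.4075
#> Likelihood-ratio tests:
#>      factor  chisq df  p_value
#>           d 301.31  1 1.71e-67
#>       order   1.42  1 2.34e-01
#>  repetition  20.15  1 7.15e-06
#>   inversion   3.57  1 5.87e-02
#> logLik -2118.9, converged: TRUE

round(analysis$snr_contrast$r, 3)
#> [1] -0.657
```

Reading the output: the simulated observer was built with a true
coefficient of 0.4 on the standardized SNR−contrast difference `d`, and
the fitted GLMM recovers 0.42 ± 0.03 with an overwhelming likelihood-ratio
χ²(1); the negative correlation between per-stimulus mean SNR and mean
Weber contrast (−0.66) reproduces the structural anticorrelation of the
two metrics on naturalistic binarized images — textured, feature-rich
fragments average toward gray.

Individual stages are available directly, e.g.:

```r
geo  <- display_geometry()                       # 918x672 px, 32.4x23.7 deg
100 * visible_area_fraction(2.4, 10, geo)        # ten 2.4-deg fragments -> 7.5 (%)
cfg  <- place_fragments(geo, frame_region(), 2.4, 10,
                        c(top = 3, bottom = 3, left = 2, right = 2), seed = 1)
check_fragment_configuration(cfg, geo, frame_region())$ok   # TRUE
```

## Package layout

| Area | Functions |
|---|---|
| Feature model | `binarize_image`, `pattern_distribution`, `select_optimal_features`, `sketch_image`, `read/write_feature_bank` |
| Stimuli | `display_geometry`, `frame_region`, `place_fragments`, `check_fragment_configuration`, `render_stimulus`, `invert_contrast` |
| Schedules | `preliminary1_design`, `preliminary2_design`, `main_design`, `build_trial_schedule`, `build_configuration_pool`, `read/write_schedule` |
| Saliency | `fragment_snr`, `fragment_weber_contrast`, `stimulus_saliency`, `measure_schedule`, `bin_performance`, `pearson_correlation` |
| Synthetic data | `synthetic_image_spec`, `generate_image_set`, `observer_params`, `simulate_observer`, `generate_study` |
| Analysis | `standardized_difference`, `fit_binomial_glmm`, `two_proportion_ztest`, `friedman_test`, `wilcoxon_vs_chance`, `analyze_schedule`, `run_pipeline` |

The methods vignette (`vignettes/fragment-saliency.Rmd`) documents the
model, the geometric conventions, the synthetic-data generator and the
design decisions in detail.
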