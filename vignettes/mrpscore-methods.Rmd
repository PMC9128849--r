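---
title: "Methods: scoring and simulating massive-report patch discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring and simulating massive-report patch discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpscore)
```

## The paradigm and the scoring model

In a massive-report patch-discrimination experiment, an observer views a
briefly flashed natural scene (about 133 ms, masked) and is then probed with
a long sequence of square image patches, answering for each "was this part
of the image you just saw?" with a yes/no decision and a 1–4 confidence
rating. The image is cut into a 3×3 grid; probes are of four kinds: the
*original* patch containing the scene's critical object, a *modified* patch
in which that object has been swapped for another, *present* patches (other
parts of the viewed image), and *null* patches from unrelated scenes.

Decision and confidence are folded into one signed 8-level code,
D×C ∈ {−4 … −1, +1 … +4} (`encode_dxc()`): the sign is the decision, the
magnitude the confidence. Sweeping a criterion over this scale from
strictest (only +4 counts as yes) to most lenient (everything above −4)
yields 7 (hit rate, false-alarm rate) pairs; with the (0,0) and (1,1)
endpoints these define the Type 1 ROC, and its trapezoidal area is the
non-parametric measure of discriminability (`type1_roc()`,
`auc_trapezoid()`). Because the 7 criteria exhaust every cut point of the
8-level scale, this area equals the Mann–Whitney statistic

AUC = P(rating_signal > rating_noise) + ½ P(tie),

which `auc_rank_oracle()` computes directly from the two rating sets; the
test suite asserts exact equality on thousands of random instances, so the
two independent routes guard each other.

Type 2 (metacognitive) ROC applies the same sweep to confidence conditioned
on correctness: a correct trial rated ≥ c is a metacognitive hit, an
incorrect trial rated ≥ c a metacognitive false alarm, over the three cut
points of the 4-level confidence scale (`type2_roc()`). Correctness for the
present-vs-null task groups hits (yes to present/original) and correct
rejections (no to null); for original-vs-modified the same rule is applied
with the original patch in the signal role. The source text defines Type 2
scoring only for present-vs-null; extending the identical hit/CR rule to
the other task is this package's choice, made because the two tasks are
formally the same discrimination with relabelled classes. A participant
with no errors (or no correct trials) has an undefined Type 2 AUC and is
reported as missing, never as 1.0 — a ceiling artefact otherwise.

For image-level analyses the D×C code is shifted half a unit toward zero
(`transform_tdxc()`), making the 8 levels equally spaced from −3.5 to
+3.5; ΔtD×C (`delta_tdxc()`) is the difference of mean tD×C between
original and modified probes for one image pair, bounded by ±7.

## Design planning

`plan_experiment()` reproduces the two published trial structures. In
Experiment 1 each of 15 participants completes 80 trials (40 congruent +
40 incongruent initial images, no image repeated within a participant);
each trial probes 1 original + 1 modified patch at the critical location,
present patches at the remaining locations of the critical location's
parity set (odd {1,3,5,7,9} or even {2,4,6,8}, so successive probes are
never spatially contiguous), and 15 null patches — 21 probes for the odd
set, 20 for the even. Null patches are drawn disjointly across participants
(`allocate_nulls()`): 15 participants × 15 nulls = 225 distinct patches per
initial image. In Experiment 2 each of 240 participants completes 34 trials
(17 + 17) of 6 probes each (2 present + 3 null + exactly one of
original/modified), in 4 batches of 34 image pairs, plus 12 experimental
and 1 practice catch trial.

Grid locations are numbered row-major with 5 the centre; the scan order is
not stated in the source figure, and row-major is this package's choice.
Eccentricities are computed with planar projection geometry: patch-centre
offsets live on the display plane (`tan`/`atan`), not on the angular scale.
For a 19.4-dva image this gives 0, 6.50 and 9.155 → 9.2 dva for centre,
edge and corner patches, matching the printed values; the small-angle
linear formula would give 9.14 → 9.1 and was therefore rejected.

The catch-trial exclusion threshold (`catch_cutoff()`) is the exact
binomial inverse CDF: the smallest k with
`pbinom(k, n_catch, 1/n_options) ≥ q`, divided by `n_catch`. With 13 catch
trials (12 experimental + 1 practice), 8 response options and q = 0.99
this yields 5/13 = 0.3846 → 0.38. The published description is ambiguous
about whether 12 or 13 trials entered the original simulation; both give
k* = 5, but only 13 reproduces 0.38 at two decimals, so 13 is the default.
A seeded Monte-Carlo estimator ships as a cross-check. Exclusion is strict:
accuracy must exceed the cutoff, so exactly 0.38 is excluded.

## The synthetic-data generator: what it emulates, and what not

`simulate_responses()` draws, for every scheduled probe, a scalar evidence
value X ~ Normal(μ[role, eccentricity], σ[role, eccentricity]); seven fixed
criteria partition the evidence axis into the 8 D×C bins, the middle one
being the yes/no decision criterion. With probability `lapse_rate` the
response is uniform over the 8 options. This is standard unequal-variance
rating SDT with criteria shared across roles — the smallest model for
which the exact population AUC of the discretized ratings is available in
closed form (`true_rating_auc()`, from the Gaussian bin probabilities via
the rank formula), which is what makes parameter-recovery testing possible.

The shipped `default` preset states one world and is not tuned: null
evidence mean 0 (σ = 1); present/original means 2.0, 1.3, 0.9 evidence
units at fovea, parafovea, periphery (σ = 1.1), so discriminability
attenuates with eccentricity; modified patches sit 0.4 units below the
original, and a congruent scene gist widens that separation by a further
0.5 (±0.25 to each role); lapse rate 2%. Criteria are spaced 0.75 apart
and centred at +0.9 — the midpoint between the null and pooled present
means — rather than on the null mean: criteria centred on the null mean
would force a symmetric response distribution on null probes, whereas
attentive observers overwhelmingly reject null patches with high
confidence, and a preset unable to show that pattern could not serve its
directional purpose. These choices emulate the qualitative structure of
the empirical results (present ≫ null separation; smaller original/modified
separation, larger under congruence; eccentricity attenuation of
present-vs-null but near-ceiling rejection of nulls everywhere), not any
quantitative AUC. A green directional test therefore establishes that the
pipeline orders conditions correctly, nothing about effect sizes in real
data. Real response phenomena deliberately absent: criterion drift and
sequential dependencies, memory decay across the probe sequence,
participant heterogeneity beyond the lapse mixture, and any image-specific
effect (all pairs share the same parameters).

Catch-trial agents: an attentive agent fails a catch only through lapses; a
`random` agent answers uniformly (expected accuracy 1/8). At the 0.38
cutoff, random agents pass with probability < 1% by construction of the
99% quantile.

## Image statistics

The changed region between the two images of a pair is detected by
thresholding the per-pixel absolute RGB difference at 10 on the 0–255
scale (`object_size()`). The source does not state how the three channel
differences are aggregated; the default here is `max` (a pixel has changed
if any channel has), with `mean` behind a flag, and no morphological
cleanup by default. Strict inequality is used at the threshold. The
critical-object patch is the grid cell containing the most flagged pixels,
ties broken toward the lowest location number. Object sizes are strongly
right-skewed in natural image sets, hence the `log_object_size` column for
downstream modelling.

Scene clutter is indexed by the scale β of a two-parameter Weibull fitted
to the image's gradient-magnitude distribution. Grayscale conversion uses
ITU-R 601 luma weights; gradients come from separable Gaussian-derivative
filters at σ = 1 px by default (Sobel available as a dialect), with
replicate padding. The Weibull is fitted by maximum likelihood to the raw
strictly-positive magnitudes (zero-gradient pixels are outside the support
and excluded; binned-histogram fitting would lose information). The MLE is
a profile likelihood: the shape solves a one-dimensional score equation by
`uniroot`, the scale is then closed-form. `make_fixture_pair()` generates
image pairs with a planted rectangular change and seeded smooth or
cluttered backgrounds; the cluttered preset has a larger fitted β, which
is asserted empirically, not assumed.

## Statistical conventions

Two-sample comparisons default to the classical equal-variance Student
t-test, matching the published analysis wording, with Welch behind a flag;
zero-variance cells are reported untestable (NA) rather than guessed. The
image-pair classifier colours each pair by which congruence shows a
significant original-vs-modified difference at α = 0.05 uncorrected (grey /
blue / red / black), and flags the patch-type × congruence interaction by
an F-test of the ordinary least-squares interaction term against the
additive model — for this term that is the Type II = Type III comparison;
the sum-of-squares convention behind the published two-way ANOVA is not
stated, and model comparison is the convention adopted here. The 0.003 and
0.0001 proportion-curve annotation thresholds are display constants, not
recomputed corrections. Mixed-effects models are out of scope by design:
`modelling_export()` emits a tidy table (ΔtD×C with congruence and image
covariates) for external LME software, and `lrt_chi2()` consumes the
returned log-likelihoods.

## Numerical and degenerate-input choices

ROC points are sorted lexicographically by (FA, hit) and deduplicated
before trapezoidal integration. Non-divisible image dimensions are
truncated (trailing rows/columns) before grid splitting so patches stay
exactly equal. All randomization flows through per-participant and
per-trial substreams derived from one master seed, and the simulator never
touches (or depends on) the caller's global RNG state; identical configs
produce byte-identical pipeline artefacts. Empty signal/noise or
correct/incorrect sets raise insufficient-data errors at the ROC level and
surface as missing values in summaries. Participants with no catch trials
are retained with a warning rather than silently passed or excluded.

## Known limitations

Real-data quantities (the published AUC values, Table 1 χ² statistics)
require the archived behavioural deposit and an external mixed-model fit;
this package reproduces the design arithmetic, the scoring definitions and
the printed analysis constants, and validates the scoring machinery
against its own generative model. The simulator's parameter presets are
stated worlds for testing, not fits to data. The gradient filter and scale
behind the published contrast distributions are described only in
supplementary material and are not replicated exactly; β values are
comparable within this package's filter settings, not across publications.
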