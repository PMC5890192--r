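---
title: "Quantifying preplay-like pattern reactivation in resting-state fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying preplay-like pattern reactivation in resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(preplayr)
library(dplyr)
```

## The question and the measurement

In rodents, hippocampal place-cell sequences can appear spontaneously
*before* the corresponding experience ("preplay") and again after it
("replay"). preplayr implements a human analogue of that measurement for
resting-state fMRI: does a stimulus-specific multivoxel pattern appear
spontaneously in rest, and does the strength of that spontaneous
reactivation predict how well the stimulus is later understood — but only
when prior knowledge gives the new material something to attach to?

The experimental structure the package assumes is a two-day
sentence-comprehension design: subjects study a set of *prior* sentences on
day 1; on day 2 a resting scan is acquired *before* a set of *posterior*
sentences is presented, some of which each subject links to a prior
sentence ("w/prior") while the rest stay unlinked ("w/o prior"). Induced
(task) fMRI while subjects process each sentence supplies a per-sentence
neural representation; the resting scans supply the frames in which that
representation may spontaneously reappear.

## The statistic

For one subject and one region of interest (ROI):

1. **Representations.** A first-level GLM on the block-design induced
   sessions — one HRF-convolved boxcar regressor per sentence plus session
   intercepts, ordinary least squares per voxel — yields a t-statistic map
   per sentence. Voxels whose t-values barely vary across sentences carry no
   sentence information, so the lowest 3% of cross-sentence t-variances are
   discarded (ties at the cutoff are kept; prior and posterior map sets are
   filtered separately).
2. **Per-frame similarity.** Each voxel's resting time course is z-scored
   (population SD), then every resting frame is correlated with each
   sentence's t-map over the retained voxels, giving one correlation time
   course per sentence.
3. **Intensity.** Correlations are Fisher-transformed,
   \(Z = \tfrac{1}{2}\ln\frac{1+r}{1-r}\), and the mean of the top
   \(N_{top}\) values is the sentence's reactivation intensity. Because the
   transform is strictly increasing, selecting the top \(N_{top}\) before or
   after transforming picks the same frames (asserted as a property test);
   the transform is applied first, matching the definition.

The top-\(N\) mean is a compromise: reactivation is sparse, so the overall
mean would drown it in baseline frames, while the single maximum would be
pure noise. \(N_{top}\) itself is estimated from the data: the variance of
the intensities across sentences decomposes into a noise component
proportional to \(1/N\) and a signal component. For a grid of candidates
(default \(10, 15, \ldots, 80\)), the variance across sentences is
regressed on \(1/N\) with intercept; the fitted line absorbs the noise
component and the per-point residual is read as signal. The chosen \(N\) is
the residual's argmax, with exact ties (e.g. the all-zero residuals of pure
noise) resolved to the smallest candidate — deterministic, and favouring
less smoothing. Per-subject choices are averaged and snapped half-up to the
grid for a group value. Understanding ratings play no role in this
selection. Defaults are \(N_{top} = 15\) for the ROI analysis and 13 for
the searchlight, the values this estimator produces under the default
simulation conditions (15 embedded frames per sentence).

## Group-level inference

Each subject contributes a Pearson correlation \(r_i\) between sentence
intensities and 0–100 understanding ratings over their \(n_i\) sentences in
a condition. Because \(n_i\) varies across subjects (each subject links
their own subset of posterior sentences), correlations are merged with the
fixed-effect meta-analytic weighting:

\[
  Z_i = \operatorname{atanh}(r_i), \quad
  w_i = \frac{n_i - 3}{\sum_j (n_j - 3)}, \quad
  \zeta = \sum_i w_i Z_i, \quad
  SE_\zeta = \frac{1}{\sqrt{\sum_i (n_i - 3)}},
\]

with \(r_{merged} = \tanh(\zeta)\). The null \(\zeta = 0\) is tested by
referring \(\zeta / SE_\zeta\) to the standard normal; two conditions are
compared via \((\zeta_1 - \zeta_2)/\sqrt{SE_1^2 + SE_2^2}\). The weighting
needs \(n_i > 3\); subjects below that floor, or with degenerate (constant)
data, are dropped with a warning rather than imputed. A complementary,
correlation-free view splits each subject's sentences at their own mean
intensity ("above-average" vs "below-average" reactivation) and compares
the two sides' mean ratings with a paired t-test across subjects.

Sidedness follows the directional structure of the hypotheses: one-sided
tests where the hypothesis is directional (reactivation *facilitates*
understanding; post-task reactivation exceeds pre-task), two-sided
otherwise. Every test takes an explicit flag; the condition comparison
defaults to two-sided. Where a pair of conditions is tested, the two raw
p-values are Bonferroni-corrected with \(m = 2\).

```{r merge-example}
# two subjects, unequal sample sizes
m <- merge_correlations(data.frame(r = c(0.5, 0.0), n = c(13, 23)))
glance(test_merged_zero(m, "greater"))
```

## The synthetic cohort

No public dataset carries this design, so the generator is a first-class
module: it produces cohorts with exactly the statistical structure the
analysis assumes, with all ground truth retained, making every downstream
stage testable. Defaults mirror the study conditions: 16 subjects, 10 prior
and 20 posterior sentences, ~11 posterior sentences associated per subject,
resting sessions of 200 frames at TR 3 s (the leading 3 reserved as
discardable dummy frames), and five induced sessions built from 6-scan
sentence blocks with 2-scan rests and 3-scan session lead-in/out.

The reactivation model is deliberately the simplest one under which the
top-\(N\) statistic is consistent: each sentence's representation is a
unit-norm Gaussian voxel pattern; a resting session is i.i.d. Gaussian
noise into which, for each sentence, a fixed number of distinct frames
additionally receive `amplitude * pattern`. Events occupy single frames
(no temporal autocorrelation or extended epochs — a modelling choice, not a
claim about the underlying biology) and are never shared between sentences
or placed in the reserved dummy frames. With unit-norm patterns the
amplitude is the total embedded signal energy over the ROI; the default
(mean 12, SD 4, noise SD 1 over a \(8^3\) grid) puts single-frame
pattern-frame correlations near 0.45 — detectable but far from ceiling, and
dispersed enough across sentences for the \(N\) estimator to see signal
variance. The default of 8 events per sentence is the largest round number
whose embed budget (8 × 20 = 160 frames) fits the 197 usable frames of a
session, since embedded frames are mutually exclusive across the 20
posterior sentences; simulations that probe the \(N\) estimator use 15
events with 10 sentences (150 frames), which also fits.

Ratings are produced from a latent Gaussian coupled to the standardized
amplitudes with correlation \(\rho\) (default 0.4) **only for associated
sentences** — unassociated sentences get independent ratings — then mapped
to the 0–100 slider scale (mean 50, SD 15) and clamped. The day-2-post
resting session multiplies all amplitudes by 1.5 to emulate post-experience
stabilization of representations. Induced sessions convolve the block
boxcars with the canonical double-gamma HRF.

What the generator does **not** emulate: scanner drift, motion,
physiological noise, spatial autocorrelation of noise, temporal
autocorrelation, or anatomically realistic ROI geometry (the ROI is a full
cuboid grid standing in for a hippocampal–entorhinal mask). Passing tests
therefore demonstrate correctness of the statistical machinery under the
model's assumptions, not robustness to real-data artefacts.

```{r cohort, eval = FALSE}
res <- run_pipeline(pipeline_config()) # default 16-subject cohort
res
```

## Numerical choices and degenerate inputs

* Correlations with \(|r| \ge 1 - 10^{-12}\) are clamped before the Fisher
  transform so noiseless fixtures produce large finite Z instead of Inf.
* z-scoring uses the population SD; voxels with constant time courses are
  flagged degenerate and excluded from correlations (an all-constant series
  is an error). Zero-variance frames yield missing correlations, which the
  top-\(N\) mean skips; asking for more values than exist is an error, not
  a silent truncation.
* The 3% filter uses the population variance across sentences and drops
  voxels strictly below the quantile; ties at the cutoff are kept, so an
  all-tied profile drops nothing.
* The GLM concatenates sessions with per-session intercepts (a fixed-effect
  combination across sessions); rank deficiency is reported with the
  offending columns. No autocorrelation correction is applied — the
  synthetic noise is white.
* Searchlight cubes are truncated at volume edges rather than dropped;
  cubes retaining fewer than 3 usable voxels give missing values.
* The permutation contrast replaces the original pipeline's
  TFCE-with-`randomise` stage with a max-statistic FWE correction of a
  within-subject label-permutation null — a paired design with the same
  null hypothesis but not an equivalent correction; condition labels are
  permuted within subject. p-values use the add-one convention
  \((1 + \#\{max_b \ge s\})/(1 + B)\), so they are never zero.
* All randomness is seeded; a fixed spec seed regenerates a cohort — in
  memory or on disk — bit for bit.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path while completing quickly on one
core: ROI grids of \(5^3\)–\(8^3\), 60–200 resting frames, cohorts of 3–16
subjects; calibration uses 2000 statistic-level cohorts, sign recovery 500,
the \(N\) estimator 100 voxel-level runs, and the searchlight examples use
\(8^3\) volumes with 500 permutations. Because the searchlight statistic at
a voxel depends only on its cube, and the permutation null only on the
per-sentence intensity maps, these sizes probe the same mathematics as a
full-resolution brain at a tiny fraction of the cost. Where a planted
searchlight effect is localized, the relevant support is every voxel whose
cube overlaps the planted region (the statistic genuinely carries signal
there), and detections are assessed against that support.

## Known limitations

* The fixed-effect merge assumes a common underlying correlation;
  between-subject heterogeneity would call for a random-effects model,
  which is intentionally out of scope.
* The \(1/N\) noise law behind the \(N\) estimator premises i.i.d. frame
  values; autocorrelated resting noise would bias it, and no correction is
  attempted.
* Intensity is an attenuated estimate of the latent coupling (measurement
  noise in both the t-maps and the resting correlations); the merge is
  consistent in sign and approaches the latent value only as SNR grows.
* The searchlight's max-statistic correction is more conservative than
  cluster-sensitive methods for spatially extended effects.
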