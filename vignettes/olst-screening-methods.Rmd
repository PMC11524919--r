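---
title: "Screening high autistic trait from one-legged standing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening high autistic trait from one-legged standing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olstscreen)
```

## The screening problem

Children with elevated autistic traits tend to show atypical static balance:
smaller centre-of-pressure (COP) excursions, more repetitive (lower-entropy)
sway, and altered coordination between trunk/limb motion and the COP.
`olstscreen` implements a screening pipeline around the one-legged standing
test (OLST): a child stands on one leg on a pressure mat while a frontal
camera records full-body motion, both streams sampled synchronously at
20 Hz. Four trials are performed, alternating legs starting with the right,
each capped at 20 s.

From the first two seconds of the first trial — the feed-forward
two-to-one-leg weight-shift phase — sixteen explanatory variables are
computed per child:

* **COP sway** (4): total sway-path length, mean COP speed, approximate
  entropy of sway, and convex-hull sway area;
* **Overall balance** (2): the longest stand time across the four trials and
  the mean mediolateral COM–COP distance;
* **COP–joint coupling** (10): Pearson correlations between frame-to-frame
  changes in the mediolateral COP coordinate and changes in ten joint angles
  (neck, shoulder line, both elbows, both trunk angles, both hips, both
  knees).

Children are labelled **High** or **Low** autistic trait by their SRS-2
total score against sex-specific screening cutoffs (boys 53.5, girls 52.5;
strictly greater means High — the half-point cutoffs make ties impossible
for integer scores). A linear soft-margin SVM is trained to recover that
label from the movement variables, with the feature subset and the cost
parameter C selected simultaneously, and evaluated by leave-one-out
cross-validation (LOOCV). Platt scaling of the out-of-fold decision values
yields a calibrated probability of High trait, which is then correlated
(Spearman) with the SRS-2 total.

## COP estimation and the foot-aligned frame

Per frame, cells with pressure above 5% of the frame maximum are active; a
frame is valid when its total pressure exceeds 10% of the trial median and
at least three cells are active. The COP is the pressure-weighted centroid
of the active cell centres. The foot region is summarized by the
pressure-weighted second-moment ellipse pooled over valid frames; the
trajectory is rotated so the ellipse's major axis becomes the Y
(anteroposterior) axis and the minor axis the X (mediolateral) axis. All
sway statistics and the coupling correlations are computed in this
foot-aligned frame; "change in COP" for the coupling variables is the first
difference of the mediolateral coordinate (`cop_change = "x"`; `"y"` and
`"magnitude"` are available).

Approximate entropy uses the classical Pincus definition — `Phi^m -
Phi^(m+1)` with self-matches and Chebyshev distance — with the
posturography conventions `m = 2`, `r = 0.2 * SD` per axis, averaged over
the X and Y series. All three knobs are arguments of
`approximate_entropy()` / `extract_features()`. A constant series (zero
tolerance) returns 0 by convention. The COM is estimated from the 2-D
keypoints with Dempster segment mass fractions (head+neck 0.081, trunk
0.497, upper arms 0.028 each, forearms+hands 0.022 each, thighs 0.100
each, shanks+feet 0.061 each); because a frontal camera observes no depth
and the image-to-mat offset is unknown, the COM–COP distance uses the
mediolateral axis only after matching the two series' means over the
window.

Landmarks with confidence below 0.1 invalidate the angles that use them; a
feature is missing when fewer than half of the window frames are usable.
Missing features are never imputed — rows incomplete for a category are
excluded from that category's model with a logged count.

## Model selection and its optimism

`search_best_model()` scores candidate (subset, cost) pairs over the grid
`{0.001, 0.01, 0.1, 1, 10}` by LOOCV accuracy, breaking ties towards
higher sensitivity, then fewer variables, then smaller cost. Subsets are
enumerated exhaustively for the 6-variable conventional and 10-variable
proposed categories; the 16-variable combined category uses sequential
forward floating selection (SFFS) by default, stopping after two
consecutive non-improving forward steps (exhaustive search over
2^16 − 1 subsets remains available behind `strategy = "exhaustive"`).

Two evaluation modes are provided:

* **paper_faithful** (default): the same LOOCV is used to select and to
  report. This mirrors a common small-sample screening design, but the
  reported accuracy then contains selection optimism.
* **nested**: the entire selection is repeated inside each outer LOOCV
  fold and only outer out-of-fold predictions are reported. Inner
  selection is scored by stratified 5-fold cross-validation rather than a
  second LOOCV, and the inner greedy search stops at the first
  non-improving step: with 126 outer folds, a nested inner LOOCV over
  every (subset, cost) pair would cost millions of SVM fits for no
  practical gain in selection quality at this sample size.

The acceptance suite quantifies the optimism directly: on cohorts
generated with all severity effects zeroed, nested accuracy stays within
the 95% binomial band around the majority-class rate while paper-faithful
accuracy is systematically at least as high.

Features are z-scored with training-fold statistics before fitting (the
cost range 0.001–10 presumes comparable scales); `standardize = FALSE`
switches this off. The SVM itself is a standard soft-margin linear C-SVC
solved by a compact SMO routine with second-order working-set selection
(compiled code in `src/`), kept inside the package because the selection
search performs on the order of 10^5 cross-validated fits; the solver is
verified in the test suite against brute-force primal minimization and
against libsvm via e1071. Class weights are not used by default. Platt
scaling fits `p = 1/(1 + exp(A d + B))` to the out-of-fold decision values
with smoothed targets by the standard Newton iteration; using out-of-fold
values keeps the probability–SRS correlation from being inflated by
training fit.

SHAP attributions for a linear model on (approximately independent)
features have the exact closed form `w_j (x_ij - mean_j)`; `linear_shap()`
implements it directly on the standardized scale of the final refit on all
rows, so the additivity identity `base + sum(attributions) = decision`
holds to numerical precision. A sampling estimator would only add noise
here.

## What the synthetic cohort emulates

No recordings are distributed with the package, so `generate_cohort()`
produces cohorts with the statistical structure the analysis assumes. The
defaults are the study conditions: 64 boys and 62 girls; high-trait
fractions 9/64 and 10/62; SRS-2 totals drawn from group normals (high:
69.79, SD 23.66; low: 31.24, SD 11.48) truncated at the sex cutoff and
rounded to integers; group-dependent ages (5.13 SD 0.16 vs 5.06 SD 0.13
years); a 48-cm square mat at 48 × 48 cells; 20 Hz; four trials capped at
20 s.

A latent severity — the within-cohort SRS percentile mapped to [0, 1] —
drives every group contrast through `severity_effect()`:

* sway is a per-axis Ornstein–Uhlenbeck process (mean reversion
  `ou_theta = 1` /s; mediolateral stationary SD `1.1 - 0.7 * severity` cm,
  anteroposterior 1.3 times larger) mixed with a 0.9-Hz periodic component
  whose weight `min(0.9 * severity, 0.95)` makes high-severity sway more
  repetitive and lower-entropy;
* trial durations are exponential fall times with hazard
  `0.12 * severity` /s, right-censored at the 20-s cap; falls cannot occur
  before a 2-s minimum stand (the duration of the stance transition), which
  guarantees the 2-s feature window exists for every child;
* each trial begins with a 0.5-s ramp from a two-foot to a one-foot
  footprint (feet 8 cm apart), so the analysis window deliberately contains
  the weight-shift transient;
* pressure frames render Epanechnikov-tapered elliptical footprints
  (semi-axes 3 × 8.5 cm) whose continuous centroid equals the simulated COP;
  discretization keeps the frame centroid within half a cell of it (a
  tested invariant);
* keypoints come from a 15-landmark template skeleton (110-cm stature,
  3 px/cm) whose ten driven angles respond linearly to the mediolateral COP
  with gain `8 * severity` deg/cm scaled by per-joint factors that
  emphasize proximal joints (shoulder 1.2, trunk/hip 1.0, knee 0.8, neck
  0.6, elbow 0.4), plus AR(1) angle noise (innovation SD 0.4 deg) and
  0.3-px landmark jitter. An 8-degree habitual head tilt keeps the neck
  line away from the vertical inclination fold where a [-90, 90]-degree
  convention loses the coupling sign.

These defaults were chosen once as the plausible "strong effect" regime a
cohort separable by a linear SVM implies; `severity_effect_null()` zeroes
all four severity couplings for calibration work. The generator is
deterministic given (config, seed).

**What passing tests do not show.** The generator emulates the statistical
structure of the analysis — monotone severity effects, censored durations,
linear joint–COP coupling — not biomechanics. There is no ground-reaction
physics, no 3-D pose, no pose-estimator failure modes beyond confidence
jitter, and severity acts through a single latent dial. Recovery results on
synthetic cohorts therefore validate the pipeline's correctness and
calibration, not the clinical effect sizes; the study cohort's exact
accuracies and correlations are not reproducible without its data.

## Numerical conventions and degenerate inputs

* Inclination angles live in (−90, 90]; interior angles in [0, 180].
* An undefined correlation (zero variance) is missing, with a warning,
  never 0.
* The convex hull of fewer than three distinct or collinear points has
  area 0; `chull()` plus the shoelace formula otherwise.
* Spearman p-values use `t = r_s sqrt((n-2)/(1-r_s^2))` on n − 2 df,
  matching the r_s(124) convention for n = 126; Welch's t with
  Welch–Satterthwaite df for group comparisons; Pearson chi-squared without
  continuity correction for the 2 × 2 sex table.
* SVM ties at a decision value of exactly 0 predict Low.
* Cohort generation stores timestamps as frame-index/rate; round trips
  through the text formats preserve them to 1e-9 s.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run the full 126-child default
cohort for the end-to-end, parameter-recovery (10 seeds), and
null-calibration (10 seeds) checks; generator property checks that need
many cohorts use a 200-child, 3-s-cap, 24 × 24-grid variant of the
protocol, which leaves the severity effects untouched while keeping the
rendering cheap. Exhaustive selection is exercised on the 6- and
10-variable categories; the combined category uses SFFS, as in the
package defaults.

## Known limitations

* The coupling variables are identified on the mediolateral axis; a
  sagittal camera would need `cop_change = "y"` and a recalibrated
  skeleton.
* ApEn on 40-sample windows is short; the m = 2, r = 0.2 SD convention is
  standard but the estimate is high-variance, which is why it rarely
  survives subset selection on its own.
* `paper_faithful` accuracies are optimistic by construction; use
  `mode = "nested"` for generalization estimates.
* The OpenPose reader maps only the 15 landmarks this package uses and
  reads the first detected person per frame.

## Interfaces

All functionality is exposed as R functions returning tibbles (with
`tidy()`/`glance()`/`augment()` methods and `autoplot()`s); a shell
entry point is deliberately not shipped. `write_cohort()`,
`load_cohort()`, `write_feature_table()` and `write_model_report()` cover
batch workflows on the documented text formats.
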