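---
title: "PID treatment-effect estimation for tumor-volume trials: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PID treatment-effect estimation for tumor-volume trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pidtrial)
```

## Scope and rationale

Standard radiographic response criteria for gliomas classify scans into
response categories by thresholding size changes. That framing struggles
with cytostatic agents (which stop growth without shrinking anything),
with mixed enhancing/non-enhancing tumors, and with combination-therapy
questions where the interesting signal is a *change in growth dynamics*
rather than a crossed threshold. `pidtrial` implements a
control-systems view of the problem: a subject's volume trajectory
$V(t)$ is summarized by its proportional (burden), integral (tumor
control) and derivative (growth rate) components, which feed either a
Cox hazard model with time-varying covariates or, for early trials, a
pre-vs-post treatment comparison of per-subject parameters.

This vignette records the package's own account of the models, every
convention chosen where the underlying method left a gap, and the
operating points of the simulations used in the test suite.

## The generative model

`simulate_cohort()` draws, per subject:

- a true baseline volume $B \sim N(\mu_B, \sigma_B^2)$ anchored at the
  *earliest nominal scan* ($-6$ months by default), defaults
  $\mu_B = 10$ mL, $\sigma_B = 0.5$ mL;
- a piecewise-linear true curve: slope $g$ (default exactly $1/3$
  mL/month, i.e. 1 mL per 3 months) before treatment start, an
  arm-specific slope after it, continuous at $t = 0$. The default arms
  are `control` (slope unchanged) and `treated` (slope 0, a cytostatic
  effect);
- scan dates on a nominal grid $\{-6, -3, 0, +3, +6\}$ months (from the
  window lengths and the 3-month scan interval), each non-anchor date
  perturbed by $N(0, \sigma_j^2)$ jitter with $\sigma_j = 0.5$ months
  (about two weeks). The treatment-start scan is never jittered: it
  defines both evaluation windows. Jitter moves the *true* acquisition
  time — the recorded timestamp and the volume both reflect it — which
  mimics real scheduling variability;
- observed volume = true volume at the jittered date plus
  $N(0, \sigma_\epsilon^2)$ measurement noise, $\sigma_\epsilon = 0.25$
  mL (roughly 250 voxels of segmentation variability), floored at 0 mL.
  Floored observations are counted and reported on the cohort, since
  flooring perturbs noise symmetry (negligible at these tumor sizes).

Two numerical guards are part of the generator's definition. First,
jitter is truncated at just under half the scan interval (3 SD at the
defaults): a scan therefore never leaves its scheduling slot, scan order
cannot invert, and every boundary scan stays within the estimators'
matching tolerance. Untruncated jitter would abort roughly 1 cohort in
300 on a reference-matching error for a tail scan, which no real
scheduling process produces. Second, per-subject random substreams are
derived from `(seed, subject index)` through a Murmur3-style avalanche
hash before seeding R's generator. The hash matters: seeding
Mersenne–Twister with *affinely related* integers leaves measurable
correlation (~0.04) between the streams' first outputs, and during
development a linear substream derivation correlated each subject's
survival draw with their own volume noise strongly enough to bias
hazard-coefficient recovery by tens of percent. With hashed substreams
any subject is bitwise reproducible in isolation.

The baseline SD is placed on the $-6$-month volume; the time-0 volume's
distribution ($12$ mL mean, SD
$\sqrt{\sigma_B^2 + \sigma_\epsilon^2} \approx 0.56$) is emergent, and
the test suite checks it at $N = 10{,}000$.

What the generator does **not** emulate: nonlinear (exponential or
Gompertz) growth, per-lesion dynamics in multifocal disease, missed
visits and dropout, scanner or field-strength effects, and
pseudoprogression. Tests passing on this generator therefore demonstrate
correctness of the estimators under linear growth with additive
Gaussian noise — not robustness to those real-data phenomena.

## PID parameters and their conventions

For an evaluation window $[s, e]$ (`eval_window()`):

- **Window membership.** A scan belongs to the window when its recorded
  time lies within `tolerance` (default 1.5 months, half the nominal
  scan interval) of $[s, e]$. This keeps nominal boundary scans whose
  jittered dates fall just outside.
- **$\lambda_3$ (growth rate)** is the OLS slope of volume on time over
  the in-window scans. A linear slope over the whole window, rather than
  endpoint differencing, reduces variance.
- **$\lambda_2$ (burden)** is the observed volume of the scan nearest
  the requested time within tolerance; on an exact tie the earlier scan
  wins (deterministic and conservative: pre-treatment information).
- **$\lambda_1$ (tumor control)** is the quadrature approximation of
  $\int_s^e (V(t') - V_{\text{ref}})\,dt'$. The pre-treatment window is
  referenced to its earliest ("historic") scan — always available,
  whatever the jitter — and the post-treatment window to the
  treatment-start anchor. Integration runs over *exactly* $[s, e]$: the
  sampled polyline is clipped, or linearly extended by at most the
  matching tolerance, at the window bounds. The equal-duration
  convention is forced by the method's own premise — areas are only
  comparable "given the same time duration" — and a jitter-dependent
  integration span would inflate the expected area from $ge^2/2$ to
  $g(e^2 + \sigma_j^2)/2$. Extensions use the window's OLS slope: it is
  exact on linear data, and unlike the boundary segment's slope its
  variance does not explode when two jittered scan dates nearly
  coincide.

Three quadrature rules are provided for unevenly spaced samples:
trapezoid (consecutive samples joined linearly), midpoint (the linear
interpolant evaluated at the time midpoint of each two-interval panel),
and Simpson (a quadratic through each consecutive sample triplet with
uneven-spacing Newton–Cotes weights); midpoint and Simpson fall back to
one trapezoid panel when a lone interval remains. All three coincide on
window-linear data; trapezoid converges at order 2 and Simpson at order
4 on even grids (and is exact through cubics), which the suite verifies.
Trapezoid is the default and the rule used by all arm-level results:
with 3 scans per window the higher-order rules buy little and the
trapezoid's behavior under noise is the easiest to reason about.

$\Delta\lambda_n = \lambda_n(\text{post}) - \lambda_n(\text{pre})$ per
subject; arm-level inference uses a two-sided one-sample t test against
zero (the deltas are approximately normal by construction), with a
sign-flip permutation alternative for robustness, and Welch's t test for
arm-vs-arm contrasts. The working hypothesis for an effective therapy is
one-sided (lower is better), so the one-sided orientation is an explicit
flag rather than a default. No multiplicity adjustment is applied across
the three parameters; single-comparison reporting is deliberate and
documented here.

### Variance of difference parameters

Differencing doubles variance only for *independent* measurements. The
default design shares the unjittered anchor scan between the two
windows, and the anchor's measurement noise enters the pre-window slope
with weight $+1/6$ and the post-window slope with weight $-1/6$ (evenly
spaced 3-point OLS). Hence
$\mathrm{Var}(\Delta\lambda_3) = \sigma_\epsilon^2/6$ against a
single-window variance of $\sigma_\epsilon^2/18$: a ratio of **3**, not
2. The suite asserts the ratio near 3 for the shared-anchor design and
near 2 for windows with disjoint scan sets, where the classic doubling
reappears. For $\lambda_1$ the anchor enters with the same sign pattern
but smaller relative weight, and date jitter contributes variance that
is independent between windows, so its ratio lands between 2 and 3.

## The PID Cox model

The hazard is
$h(t) = h_0 \exp[\beta_1 \int_0^t V + \beta_2 V(t) + \beta_3 V'(t)]$,
with the three covariates operationalized as step functions updated at
scan times (the natural discrete form of a quantity only observed at
MRI visits): the running trapezoid integral of volume from treatment
start, the most recent observed volume, and the OLS slope of all
observations up to the interval start (an expanding window is less
noisy than the last two scans; `slope_window = "last2"` switches).
`simulate_survival()` draws event times from this hazard by
inverse-transform sampling of the piecewise-linear cumulative hazard,
with administrative censoring at `max_followup`; `fit_cox_pid()`
maximizes the counting-process partial likelihood (Breslow ties — exact
under continuous simulated times) by Newton–Raphson with step halving
on internally standardized covariates, converging at gradient norm
$10^{-8}$, and reports coefficients, observed-information standard
errors and the covariance on natural units. Constant covariates are
dropped from the optimization and reported as 0; divergent standardized
coefficients raise a monotone-likelihood error rather than returning a
pseudo-estimate.

### Design of the recovery study

The model is proposed rather than fitted to any patient series, so its
validation is parameter recovery. The default trial cohort is nearly
useless for this: with baseline SD 0.5 mL, the running integral and the
current volume are almost collinear (correlation above 0.95) and only
6 months of on-study dynamics exist. The recovery study in the
acceptance suite therefore uses a cohort designed for identifiability,
as one would design any such study *a priori*: 400 subjects with
heterogeneous baselines (SD 3 mL — a realistic spread for recurrent
disease), measurement noise 1.5 mL (about 10% of a typical FLAIR
volume), quarterly scans over 24 months of follow-up (long follow-up
rotates the integral/volume relationship over time and is what
separates $\beta_1$ from $\beta_2$), baseline hazard
$h_0 = 0.04$/month and a true burden effect $\beta_2 = 0.05$ per mL
(hazard ratio ~1.65 per 10 mL), censoring at 24 months. Fifty
replicates give the mean estimate and the 2-SE coverage of the two null
coefficients checked by the suite.

## The modified Levin engine

Scores are integers in $-3..+3$ per scan pair: 0 stable; $\pm 1$
possibly worse/better (no event); $-2$ definitely worse (PD); $+2$
definitely better (PR); $-3$ new lesion or emerging enhancement (PD);
$+3$ complete disappearance (CR). Conventions chosen where the scale's
description left room:

- **Compartments.** PD if *either* assessed compartment scores
  $\le -2$; PR/CR only if *every* assessed compartment reaches
  $+2$/$+3$; a missing compartment defers to the present one. Multifocal
  disease is scored as a single gestalt per compartment; per-lesion
  tracking is out of scope.
- **Confirmation.** A PD call is confirmed by any assessment at least 4
  weeks later whose worst compartment score is still $\le -1$ — a
  still-worse-or-worse-leaning scan sustains the call; an intervening
  recovery above that range cancels it. PR/CR require a qualifying
  assessment at least 4 weeks after onset. A $-3$ (new lesion) also
  requires confirmation by default, by symmetry with $-2$; a flag
  disables this for trials that treat new lesions as self-evident.
- **PFS dating.** Progression is dated at the *first* assessment of the
  confirmed pair (the standard trial convention); subjects without a
  confirmed progression are censored at their last assessment.
- **Pseudo-volume.** Scores digitize into a tumor-behavior signal via
  $\tilde V(t_k) = \tilde V(t_{k-1}) - s_k$, $\tilde V(t_0) = -s_0$, so
  worsening increases $\tilde V$; when both compartments are scored
  their scores are summed (which keeps the transform antisymmetric
  under score negation). The output feeds the same PID estimators in
  score units.
- **Synthetic rater.** Percent change between sequential scans maps to
  a score by thresholds (defaults $\ge +50\% \to -2$,
  $\ge +15\% \to -1$, $> -20\% \to 0$, $> -40\% \to +1$, else $+2$),
  blending ROC-derived cutoffs for progression/response with observed
  score medians from retrospective reader data; both sources are real
  data, so the thresholds are configurable rather than canonical.
  Rater noise perturbs the score by $\pm 1$ with total probability
  equal to the squared noise SD (the variance of a unit perturbation),
  clipped to $[-2, +2]$; $\pm 3$ arise only from explicit
  new-lesion/disappearance flags, never from thresholds.

With a zero-noise rater, the PFS derived from Levin scores equals the
PFS from thresholding the volume changes directly, subject by subject —
the testable core of the claim that a qualitative expert rating carries
the same progression information as quantitative volumetrics. The suite
checks this agreement exactly on a simulated fast-growing cohort; it
says nothing about inter-rater variability in real readings.

## ROC analysis

`roc_analysis()` sweeps every *observed* percent-change value as a
cutoff for "positive when value $\ge$ cutoff", reports sensitivity and
specificity per cutoff, the trapezoidal AUC (which equals the
Mann–Whitney probability with ties counted one half — asserted to
$10^{-12}$ against `prob_lower()`), and the Youden-optimal cutoff
(largest cutoff on ties). Cutoffs at observed values rather than
midpoints are deliberate: a deterministic rater's threshold is then
recovered *exactly*.

## Flipbook mosaics

`make_mosaic()` tiles `rows x columns` axial slices (default 6 x 4,
every 3 mm, inferior to superior) into one frame per time point,
normalized by a 2–98 percentile window (a degenerate window widens to
the data range; a constant volume renders flat); missing slices render
black and tile extraction is lossless up to windowing. Registration,
skull stripping and bias-field correction belong to upstream tools
(e.g. FSL `flirt`/`bet2`/`fast`); the package only verifies that affine
headers agree and warns otherwise. Export formats are multipage PDF and
a numbered-PNG directory, with frame index and label burned into a
corner; animated GIF is not offered because no GIF encoder is among the
package's dependencies.

## Problem sizes used by the test suite

All simulations in the suite are sized to make their Monte-Carlo error
small against the asserted bands while keeping a full run in minutes:
the emergent-baseline and variance-ratio checks use $10^4$ subjects
(SD estimates then carry ~0.7% relative error); the
exponential-survival KS test uses $10^4$ draws; arm-mean convergence
uses 5,000 subjects per arm; the Cox recovery study uses 50 replicates
of 400 subjects; p-value uniformity uses 400 replicates of 20-subject
arms. Fixed seeds make every run reproducible.

## Known limitations

- Linear growth only; the estimators remain defined for nonlinear
  trajectories but the generator cannot produce them.
- The Cox module estimates no baseline hazard beyond simulation use,
  and offers no frailty or regularization; with fewer than ~10 events
  it warns and with one event the MLE may not exist.
- The Levin engine scores scan *pairs*; it does not model reader drift
  across a series or inter-reader disagreement.
- CSV/YAML/JSON are the only interchange formats; no DICOM ingestion.
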