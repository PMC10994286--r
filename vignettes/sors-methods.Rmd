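---
title: "Reconstruction-based visual field testing: models, simulation and design choices"
author: "sorsvf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction-based visual field testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sorsvf)
```

## The problem

Standard automated perimetry measures differential light sensitivity at the
54 locations of the 24-2 grid, in decibels of stimulus attenuation (0 dB is
the brightest stimulus the instrument can show, 40 dB the dimmest; higher
thresholds mean better sensitivity). Determining each threshold with an
adaptive psychophysical procedure costs several yes/no trials, so a full
test runs to a few hundred stimulus presentations and several minutes —
long enough that patient fatigue degrades the data. All strategies that
shorten the test exploit the same fact: thresholds at nearby locations are
strongly correlated, because glaucomatous damage follows the retinal nerve
fiber bundle anatomy and produces a modest repertoire of spatial patterns
(arcuate defects, nasal steps, diffuse depression, hemifield loss).

This package implements, end to end and in simulation, a family of
*reconstruction-based* strategies: measure a subset of locations, predict
the whole field from that subset with a model fitted to a training set of
complete fields, use the running prediction to seed the remaining
procedures, and optionally stop early, letting the model fill in the
untested locations.

## Reconstruction models

Let $x \in \mathbb{R}^{54}$ be a field and $s$ the vector of thresholds
measured so far.

**Ordinary linear regression (LR)** predicts $\hat x = D s + \beta$ with
$D \in \mathbb{R}^{54 \times |s|}$ fitted by least squares on the training
matrix $X \in \mathbb{R}^{54\times N}$. We solve via the SVD pseudoinverse,
which returns the minimum-norm solution when the design is rank deficient
(fewer training fields than measured locations) rather than failing; no
regularization is added. LR has $54(|s|+1)$ free parameters, which is the
root of its fragility on small training sets.

**Transformed-target principal component regression (TTPCR)** interposes a
dimensionality reduction on the *target*. With the centered training matrix
$B = X - \mu$, the covariance $S = BB^\top/(N-1)$ is eigendecomposed and
the top $n$ eigenvectors $W$ retained; the training embeddings are
$T = W^\top B$. The regression $\hat t = Ds + \beta$ is fitted against $T$
and the prediction is expanded through the frozen basis,
$\hat x = W\hat t + \mu$. Only the $n(|s|+1)$ regression weights depend on
the measured subset; the basis is fitted once per training set and shared
by every subset, so sequence training costs the same as LR. The name
distinguishes it from classical principal component regression, which
transforms the *inputs*; here the inputs are raw thresholds and the targets
are embeddings. The default embedding dimension is $n = 8$, configurable in
1–54: the training data's compressibility curve
(`compressibilityCurve()`) flattens past roughly 8–12 components, and the
held-out error of the full pipeline is flat-to-worse beyond that (see the
embedding sweep below). At $n = 54$ TTPCR is algebraically identical to LR
— a limit the test suite asserts.

**Partial least squares (PLS)** fits the rank-constrained predictor
$\hat x = WDs + \beta$ directly, trading TTPCR's fixed unsupervised basis
for factors chosen to predict the target. There is no closed form; we use
NIPALS (PLS2) with both-block deflation, a convergence tolerance of
$10^{-6}$ on the weight vectors and at most 500 iterations per component
(on non-convergence the best iterate is kept and a warning raised). Whether
to deflate only the predictor block or both is a genuine algorithmic
choice; both-block deflation is the canonical PLS2 form and is what we use.
At full rank PLS also coincides with LR. In the tests, PLS is checked
against a reduced-rank-regression oracle: RRR is the rank-$n$ optimum, so
PLS can only match or exceed its training error; it attains it at full
rank. (PLS is *not* RRR, and at small $n$ its training error sits several
percent above the bound.)

**Baselines.** The *mean* model returns the training hill of vision
(per-location mean) regardless of measurements. The *quadrant* baseline
reproduces classical growth seeding: the four quadrant centers
$(\pm9^\circ, \pm9^\circ)$ are tested first, then testing grows outward
breadth-first within each quadrant, each new location starting at its own
normative value plus the mean deviation of its already-determined
within-quadrant neighbors.

Model predictions are clipped to the instrument range [0, 40] dB only at
prediction time; fitting always uses unclipped values so the estimators
stay linear.

## Sequence optimization (SORS)

`trainSORS()` orders the locations greedily: at step $k$, every remaining
candidate is appended to the current subset, a reconstructor is fitted, and
the candidate with the lowest whole-field training MSE (in dB², over all 54
targets and all training fields) wins; ties break to the lowest location
index so training is deterministic. The result is a permutation plus one
fitted model per prefix length. Greedy selection does not guarantee the
global optimum — an exhaustive search over orderings is infeasible — but on
toy instances small enough to enumerate, the test suite checks each greedy
step against brute force. For TTPCR the basis is fitted once before the
loop and frozen, which is what makes its training cost comparable to LR's.
The mean baseline's "sequence" is simply descending training variance.

Two numerical conventions worth flagging:

* **Measured-value substitution.** When an estimate is assembled, measured
  values are kept at tested locations and the model fills in the rest (the
  reconstruction also predicts tested locations, but substitution can only
  reduce error there and matches how perimeters report measured points).
  Both variants are computed throughout (`rmse` and `rmse_model_only` in
  trajectories) and substitution is a flag on `planEstimate()`.
* **Eigenvector signs** are fixed by making each component's
  largest-magnitude entry positive, so repeated fits are bit-identical
  across runs and platforms.

## Threshold procedures and the simulated responder

The simulated patient answers seen/not-seen according to a piecewise-linear
frequency-of-seeing curve: with true threshold $t$, ramp half-width $w$ and
stimulus $s$,
$$p(\text{seen}) = fp + (1 - fp - fn)\,
  \mathrm{clip}\!\left(\tfrac12 + \tfrac{t - s}{2w},\, 0,\, 1\right),$$
a symmetric linear ramp approximating a cumulative Gaussian of SD
$\approx 0.8w$. The default $w = 2$ dB corresponds to a frequency-of-seeing
slope typical of perimetry; $w$ is configurable, and $w = 0$ is the
deterministic limit (seen exactly when $s \le t$) used for parameter
recovery tests. The default responder is "reliable": 3% false positives,
3% false negatives; less reliable responders (e.g. 15%/3%, 15%/15%) are a
parameter away.

**ZEST** maintains a PMF over candidate thresholds (0–40 dB in 1-dB
steps). Each trial multiplies the PMF by the likelihood of the observed
response — computed from the *estimator's assumed* psychometric curve,
fixed at 3%/3% and $w = 2$ regardless of the simulated responder, a
deliberate and configurable estimator/responder mismatch — and
renormalizes. The stimulus is placed at the posterior mean rounded to the
1-dB grid (the classic ZEST placement rule), the procedure stops when the
posterior SD drops below 2.0 dB (strictly; SD = 2.0 continues), and the
unrounded posterior mean is the estimate. A safety cap of 30 presentations
per location guards degenerate configurations. The prior is the pooled
histogram of all training thresholds with additive smoothing of $10^{-3}$
per bin; per-location priors would be a straightforward variant, but the
pooled prior is the default since the seeding step already injects spatial
information. Seeding translates the empirical prior along the domain by an
integer shift to match a target mean, accumulating shifted-out mass in the
edge bins — so a seeded prior keeps the empirical shape rather than
switching to a parametric family.

**4–2 staircase.** Stimuli step 4 dB (dimmer after seen, brighter after
not seen) until the first response reversal, then 2 dB until the second;
the estimate is the last seen level, the floor if nothing was seen. Levels
clamp to [0, 40] and two consecutive identical responses at a range
extreme count as a reversal. These fine rules (start direction, estimate at
last-seen, extreme handling) follow the classic full-threshold convention
and are isolated behind the function's arguments.

## The simulation harness

`runFieldTest()` opens locations in plan order in batches (default four):
each opened location runs its threshold procedure with a prior seeded from
the current whole-field estimate (SORS), the quadrant growth value
(quadrant baseline) or the unshifted empirical prior (independent
testing); after each batch the estimate is refreshed. Within a batch,
locations are tested sequentially to completion — in simulation this is
distributionally identical to interleaving trials, since locations are
conditionally independent given their priors; batching exists so a deployed
test never queries the same location twice in a row. Stopping after $k$
locations leaves the remaining locations at their reconstructed values.
Trajectories record RMSE and cumulative trials at every batch checkpoint.

`crossValidate()` splits *eyes*, never fields, so repeated visits of one
eye cannot leak between training and testing. The small scheme is 5-fold
with 20% of eyes training / 80% testing per fold; the large scheme 10-fold
with 90/10. Severity stratification uses mean deviation against the
training fold's normative hill (unweighted mean over the 52 non-blind-spot
locations, no age correction — MD is only used for staging here), with the
standard cutoffs: mild MD > −6, moderate −12 < MD ≤ −6, severe
MD ≤ −12 dB.

Randomness flows through a master seed: per-fold, per-field and
per-location streams are derived with `childSeed()` (a small multiplicative
hash, always below $2^{31}$), so results are bit-reproducible and adding a
strategy does not perturb the draws of existing ones.

## The synthetic generator

`generateFields()` emulates the statistical structure the method relies
on, so the whole pipeline runs with no external data:

* a normal hill of vision $33 - 0.07\,(x^2+y^2)^{0.8}$ dB with a fixed 1 dB
  superior-hemifield drop and the blind-spot locations at 3 dB;
* six archetypical loss patterns (diffuse depression, superior/inferior
  arcuate, superior/inferior nasal step, temporal wedge), non-negative,
  unit-maximum, hemifield-confined where anatomy dictates;
* per eye: a severity class from the mixture 0.35 normal / 0.30 mild /
  0.20 moderate / 0.15 severe, a $N(0, 1.5^2)$ dB hill-height offset, one
  to three focal archetypes with severity-scaled uniform amplitudes
  (0–1 / 2–8 / 8–16 / 16–30 dB) plus a diffuse component, shared across
  that eye's visits (five by default);
* per visit: independent $N(0, 1)$ dB residual noise, then clipping to
  [0, 40] dB.

The mixture weights are a design choice, not an estimate — no per-severity
prevalence was available to fit them — and severity labels are always
re-derived from the realized MD, so the stratifier and the generator cannot
disagree. Under the default configuration the generated data reproduce the
properties the method needs: the first 8 principal components carry over
85% of the variance, adjacent same-hemifield locations correlate above 0.8
(median) in the damaged mixture, and a small-training-set embedding sweep
shows held-out error rising again past $n \approx 12$ while training error
keeps falling — the overfitting signature that motivates TTPCR.

What the generator does *not* emulate: longitudinal progression (visits
share one severity draw), fixation losses and response-time effects,
eccentricity-dependent variability growth, and the detailed covariance of
any real cohort. Passing simulations therefore demonstrate algorithmic
correctness and qualitative robustness, not clinical performance on real
patients; for that, a real dataset should be imported with `readFields()`
and substituted for the generator everywhere.

## Problem sizes used in the shipped checks

The test suite and the acceptance script are sized for a desk-scale rerun:
sequence training uses 56–250 training fields (the two cross-validation
regimes' fold sizes), the embedding sweep uses a 56/14 train/test split at
a 36-location checkpoint, and the independent-ZEST duration study uses a
200-field training sample and 30–100 test fields. These sizes are the
package's choices for a fast, reproducible demonstration; all of them are
ordinary function arguments and scale up directly.

## Known limitations

* The greedy sequence is locally optimal per step only; no look-ahead.
* NIPALS convergence is not guaranteed for pathological covariance
  structures (the fit warns and returns the best iterate).
* The OS-mirroring convention assumes the long-dialect input stores left
  eyes in their native coordinates; wide-dialect input is assumed already
  in anatomical (OD-equivalent) column order.
* MD here is an unweighted, non-age-corrected mean deviation against a
  training-derived normative surface; it is a staging device, not a
  clinical index.
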