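# sorsvf

Simulation and optimization of perimetric (visual field) testing strategies
on the 24-2 grid.

Standard automated perimetry estimates differential light sensitivity
thresholds (in dB of stimulus attenuation) at 54 retinal locations. Testing
every location independently takes roughly 3–7 stimulus presentations per
location, i.e. about 200–350 trials per eye. Because thresholds at nearby
locations are strongly correlated — glaucomatous loss follows a small set of
archetypical patterns — most of the field can be *reconstructed* from a
well-chosen subset of measured locations, and the remaining locations can be
seeded or skipped. This package implements that whole loop for
simulation studies, aimed at researchers developing perimetry algorithms.

## What it implements

**Reconstruction models.** Given thresholds `s` measured at a subset of
locations, predict the full field `x ∈ ℝ⁵⁴`:

* **LR** — ordinary linear regression, `x̂ = D s + β`, minimum-norm least
  squares.
* **TTPCR** — transformed-target principal component regression. PCA is
  fitted once to the training fields (`B = X − μ`, `S = B Bᵀ/(N−1)`,
  `S = V Λ Vᵀ`, keep the top-`n` eigenvector matrix `W`); a linear model
  maps `s` to the embeddings `t̂ = D s + β`, and the field is reconstructed
  as `x̂ = W t̂ + μ`. Cuts the parameter count from `54(|s|+1)` to
  `n(|s|+1)` plus a frozen basis, which resists overfitting on small
  training sets.
* **PLS** — rank-constrained predictor `x̂ = W D s + β`, fitted iteratively
  (NIPALS partial least squares).
* **Mean / quadrant baselines** — the training hill of vision, and classic
  quadrant-center growth seeding.

**SORS (sequentially optimized reconstruction strategy).** Greedy forward
selection of the test order: at each step the location whose addition
minimizes whole-field training reconstruction error is appended, yielding
one fitted reconstructor per prefix length (`trainSORS()`).

**Threshold procedures.** ZEST (Bayesian: posterior PMF over 0–40 dB,
stimulus at the posterior mean, stop when posterior SD < 2.0 dB, estimate =
posterior mean) and a 4–2 staircase, against simulated responders with a
piecewise-linear frequency-of-seeing curve and configurable false-positive /
false-negative rates.

**Monte Carlo harness.** Whole-field tests in batches with
reconstruction-seeded priors (`runFieldTest()`), group-wise (per-eye)
cross-validation with 5-fold 20/80 and 10-fold 90/10 schemes
(`crossValidate()`), severity stratification by mean deviation (mild
MD > −6, moderate −12 < MD ≤ −6, severe MD ≤ −12 dB), and
embedding-dimension sweeps (`embeddingSweep()`).

**Synthetic data.** `generateFields()` draws mixed-severity glaucomatous
fields from archetypical loss patterns (arcuate defects, nasal steps,
temporal wedge, diffuse depression) on a normal hill of vision, with
eye-level parameters shared across repeated visits — so everything above
runs without any external dataset. Rotterdam-style CSV import
(`readFields()`, long or wide dialect) is supported for real data.

## Worked example

```r
library(sorsvf)

# a small training cohort (56 eyes) and a ZEST configuration
train <- generateFields(generatorConfig(nEyes = 56, visitsPerEye = 1), seed = 1)
plan  <- trainSORS(train, kind = "ttpcr", n = 8)
plan
#> SORSPlan (ttpcr) over 54 locations; first four: 17, 50, 13, 38

# simulate a full test of an unseen patient, stopping after 36 locations
test  <- generateFields(generatorConfig(nEyes = 3, visitsPerEye = 1), seed = 2)
truth <- dbValues(test)[, 1]
zcfg  <- zestConfig(buildPrior(train))
res   <- runFieldTest(strategyConfig("sors", stopAfter = 36),
                      plan, truth, zcfg, seed = 3)
res$totalTrials
#> [1] 145
pointwiseRMSE(truth, res$finalEstimate)
#> [1] 1.13
head(round(res$trajectory, 2), 3)
#>   locations trials rmse rmse_model_only
#> 1         4     12 1.63            1.63
#> 2         8     29 1.36            1.35
#> 3        12     46 1.78            1.76
```

After 36 of 54 locations (145 trials instead of the ~220 a full independent
test takes), the whole-field estimate is within 1.1 dB RMSE of the true
field: the first four optimized locations land in four distinct quadrants,
and every untested location is filled in by the TTPCR reconstruction.

A command-line wrapper for the common workflows (generate / train /
simulate / sweep / sequence-map) is installed at
`inst/cli/sorsvf-cli.R`.

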