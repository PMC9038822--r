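---
title: "Trial-resolved analysis of temporal preparation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trial-resolved analysis of temporal preparation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prepdyn)
```

## The scientific problem

In a variable-foreperiod task, a warning stimulus (S1) precedes a target
(S2) by a foreperiod (FP) of variable duration, and participants implicitly
learn the FP distribution: mean RT as a function of FP — the RT–FP curve —
flattens where short FPs are frequent. `prepdyn` analyses the two-phase
variant of this paradigm in which the *category* of S1 (e.g. faces versus
scenes) predicts the FP distribution: one category is paired during an
Acquisition phase with an exponential distribution (mostly short FPs), the
other with its anti-exponential mirror, and in a later Transfer phase both
categories switch to a uniform distribution. Each S1 image is seen only
once, so any category-contingent ("differential") preparation must arise
from generalisation across unique exemplars. The analytical questions are
(1) whether the S1 category modulates the slope of the RT–FP curve, (2) how
that modulation develops trial by trial, and (3) whether it survives the
transition to Transfer, where participants are told the contingency no
longer holds.

## The analysis model

All models are fit on inverse RT, $y = 1000/\mathrm{rt\_ms}$ in units of
1/s, which substantially reduces the right skew of RT distributions. The
core mixed model is

$$ y_{it} = \beta_0 + \beta_{FP}\,fp_{it} + \beta_{S1}\,s1_{it}
   + \beta_{int}\,fp_{it}\,s1_{it} + b_{0i} + b_{1i}\,fp_{it}
   + \varepsilon_{it}, $$

with FP a *continuous linear* predictor in seconds, $s1$ coded $-0.5$
(exponential type E) / $+0.5$ (anti-exponential type A), and correlated
participant random effects $(b_{0i}, b_{1i})$. Phase enters the larger
models as a $\pm 0.5$ contrast with its interactions. Estimation is by
maximum likelihood, not REML, because model comparison crosses fixed-effect
structures; `fit_lmm()` delegates the optimisation to `lme4`. Evidence is
summarised by the BIC approximation to the Bayes factor,
$BF = \exp(\Delta BIC / 2)$, with $\Delta BIC > 0$ (and $BF > 1$) reported
as evidence for including a term and $\Delta BIC < 0$ reported as the
inverse Bayes factor.

Contrast codings are a genuinely open design point: centred $\pm 0.5$
contrasts and grand-mean-centred FP keep every main effect interpretable at
the average of the other factors, but BIC differences for non-factorial
comparisons can shift slightly under other codings. The codings above are
fixed throughout the package.

## The rolling-regression time course

To resolve *when* differential preparation emerges, a four-coefficient OLS
model (Intercept, FP, S1 type, FP × S1 type) is fit within a sliding
60-trial window over each participant's retained trials in experiment
order, and each window's estimates are assigned to the trial at the
window's centre. Windows deliberately cross block and phase boundaries.
Each coefficient series is then baselined to its first value,
$\Delta\beta(c) = \beta(c) - \beta(c_1)$, so the series reads as change
since the start of the experiment. Numerical choices worth knowing:

* FP is centred at the fixed design midpoint (750 ms), *not* re-centred
  per window, so coefficients are comparable across windows; S1 type is
  $\pm 0.5$.
* For the even default window of 60 trials the centre is position 30
  (left of middle); `center_pos` exposes the alternative.
* Windows are defined over *retained* (post-filter) trials; excluded
  trials do not occupy window slots. The window size (60 by default; 40
  and 120 as sensitivity analyses) trades temporal resolution against
  estimate stability.
* Rank-deficient windows (e.g. only one S1 type present) are flagged and
  dropped rather than regularised, to avoid silently biased estimates.

## Cluster-based permutation inference

Group inference on $\Delta\beta$ uses one-sample cluster-mass permutation
tests. Pointwise $t = \bar{x}/(s/\sqrt{n})$ statistics are thresholded at
the two-tailed critical value $t_{1-\alpha/2}(n-1)$ (2.01 for 49
participants), maximal same-sign suprathreshold runs form clusters whose
mass is the summed $t$, and the null distribution is the maximum absolute
cluster mass across permutations in which each participant's entire series
is sign-flipped independently — the standard null for a one-sample test of
a symmetric zero-mean hypothesis. Design choices:

* The max statistic pools positive and negative masses (two-sided control).
* Monte-Carlo p-values use the $(B+1)/(N+1)$ convention so $p > 0$; with
  $n \le 12$ participants all $2^n$ patterns are enumerated exactly.
* Zero-variance centres have undefined $t$ and are treated as
  subthreshold, with a warning when their mean is nonzero.
* If trial filtering leaves participants with unequal centre grids, series
  are aligned on ordinal centre position and truncated to the shortest
  series (no imputation), with a message.

The companion `permutation_trend_test()` asks a coarser question — does a
$\Delta\beta$ series *increase* over a span? Its statistic is the mean
across participants of the per-participant Pearson correlation between
series and centre order, which negates exactly under a participant sign
flip; this weights each participant's trend consistency rather than the
group-mean shape and is considerably more powerful than correlating the
group mean with time.

## The synthetic-data generator

Because the pipeline's inputs are behavioral data that cannot ship with
the package, `generate_design()` + `simulate_rts()` produce a fully
synthetic stand-in. The design side is exact, not stochastic: per block and
S1 type, FP counts 32/16/8/4 (type E) and 4/8/16/32 (type A) in
Acquisition, 15 per FP per type in Transfer, S2 side balanced within type
within block, trial order jointly shuffled within block, category-to-type
mapping alternating across participants, each S1 image unique.

The generative RT model lives on the inverse-RT scale and mirrors the
analysis model, with three time-varying twists chosen as the simplest
shapes matching the learning dynamics the analysis is meant to detect:

* the interaction coefficient follows a saturating ramp
  $\beta_{int}(k) = \beta_{int}^{max}(1 - 2^{-k/\lambda})$ over
  Acquisition trials ($\lambda$ = trials to half-asymptote, default 240,
  so the effect nears its maximum during Block 6);
* at the first Transfer trial the interaction is suppressed by
  `dip_depth` (default 1, a full transient return to baseline, reflecting
  the effect of countermanding instructions) and recovers linearly over
  `dip_span_trials` (default 60, within one block);
* the intercept drifts down linearly within each block by `fatigue_amp`
  (default 0.1/s) and resets at block breaks, producing the sawtooth
  fatigue pattern.

Default magnitudes: baseline 2.2/s (≈455 ms), FP slope 0.2/s per second,
S1-type main effect −0.02/s, residual SD 0.25/s (≈52 ms at the mean),
random-effect SDs 0.2 and 0.1 with correlation −0.3, 3% errors, 0.5%
outliers inflated ×3. The interaction asymptote is 0.2/s per second —
about a 37 ms RT difference between the two types' RT–FP slopes across the
900 ms FP range. This value was calibrated so that a 49-participant
synthetic dataset reliably shows the qualitative time-course the analysis
targets (a visible ramp peaking late in Acquisition with significant
clusters); substantially smaller asymptotes produce datasets in which the
60-trial-window estimator cannot distinguish the ramp from its own
sampling noise in an appreciable fraction of runs.

Degenerate-input conventions: `noise_sd = 0` is allowed and gives the
exact deterministic mean (useful as an oracle); draws implying RT ≤ 100 ms
are resampled; parameter sets whose deterministic mean inverse RT is
non-positive are rejected before simulation.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: sequential (previous-trial) FP effects,
asymptotic (rather than linear) RT–FP curvature, non-Gaussian residual
structure beyond the outlier contamination, ITI-dependent effects, and any
item-level (image) variance. Conclusions from this package about real
experiments rest on the correctness of the *procedures*, which the tests
establish against independent oracles, not on the generator being a
faithful model of human RT.

## Preprocessing rules

Participants are screened first (mean correct-trial RT beyond 2.5 sample
SDs of the sample of participant means; accuracy below 95%), then trials:
incorrect responses are discarded, then trials whose log RT deviates more
than 3 SDs from the participant's mean log RT. The outlier statistics are
computed once, on the post-accuracy data — a single pass, the conservative
reading of the usual wording; natural logs are used (the rule itself is
scale-free). A participant with fewer than two correct trials has an
undefined SD; their correct trials are all retained and the report flags
them. One consequence of single-pass statistics worth noting: with very
few trials an extreme outlier so inflates the SD that its own z cannot
exceed 3 (the maximum attainable |z| is $(n-1)/\sqrt{n}$), so the rule
only bites when a participant contributes a reasonable number of trials.

## Power simulation

`estimate_power()` re-implements the scaled-effect heuristic: scale the
S1-type main effect and interaction of a reference model (here, the
package's own generator, since the original reference was fitted to an
earlier experiment's unavailable data), simulate Transfer-phase datasets
over a sample-size × scale grid, and count 2-df likelihood-ratio tests
(FP + S1type + FP×S1type versus FP) significant at $\alpha$. Non-converged
fits are excluded from the denominator and reported. Because the ambiguity
of "significant in separate blocks" cannot be resolved from the usual
description, both per-block rules (`per_block_any`, `per_block_all`) are
exposed alongside the whole-phase rule. Per-cell and per-simulation seeds
derive deterministically from the master seed.

## Problem sizes used by the test suite

The suite exercises the full 49-participant, 8-block design for parameter
recovery (three replicate datasets, since recovery is a property of a
stochastic generator), a 10-participant 2-block null generator for the
200-replicate false-positive calibration of the complete pipeline
(exhaustive $2^{10}$ sign-flip null), and 200 null simulations plus a
2×2 grid at 40 simulations per cell for the power module. These sizes give
binomial standard errors small enough for the stated tolerances while
keeping the default `R CMD check`-style run in the minutes range.

## Known limitations

* BIC-based Bayes factors inherit the unit-information-prior
  approximation; they are reported to two decimals as estimates, not exact
  quantities.
* The trend and cluster tests assume exchangeability of participant signs
  under the null; asymmetric null distributions (e.g. skewed baselines)
  would make them conservative or liberal in ways the package does not
  model.
* The alignment-by-truncation rule for unequal centre grids discards
  late-experiment centres from longer series rather than aligning by trial
  index with gaps; with the default filter rates this affects only the
  last ~1% of centres.
* `estimate_power()` at the full published grid (11 sample sizes × scale
  grid × 250 simulations) is hours of lme4 fits on one CPU; the shipped
  analysis driver runs a corner grid and states so.
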